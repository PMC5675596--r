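#' Axon centerline trace
#'
#' Ordered 3D centerline nodes with cumulative arc length, plus optional
#' exclusion intervals (arc-length ranges annotated by the user, e.g. close
#' appositions of two axons or terminal-bouton side branches, that must not
#' enter any analysis).
#'
#' @param nodes numeric matrix `n x 3` of node positions (um), `n >= 2`,
#'   with strictly positive spacing between consecutive nodes.
#' @param axon_id,session_id identifier strings.
#' @param exclusions numeric matrix `m x 2` of closed arc-length intervals
#'   `[start, end]` in um, each within `[0, L]`; or `NULL`.
#' @return An object of class `axon_trace` with elements `nodes`,
#'   `arc_length` (cumulative Euclidean distance, starting at 0), `axon_id`,
#'   `session_id`, `exclusions`.
#' @export
axon_trace <- function(nodes, axon_id = "axon", session_id = "s1",
                       exclusions = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  if (ncol(nodes) != 3L) stop("`nodes` must be an n x 3 matrix")
  if (nrow(nodes) < 2L) stop("a trace needs at least 2 nodes")
  if (!all(is.finite(nodes))) stop("node coordinates must be finite")
  seg <- unname(sqrt(rowSums((nodes[-1L, , drop = FALSE] -
                              nodes[-nrow(nodes), , drop = FALSE])^2)))
  if (any(seg <= 0)) stop("consecutive node spacing must be > 0")
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (!is.null(exclusions)) {
    exclusions <- matrix(as.numeric(exclusions), ncol = 2L)
    if (any(!is.finite(exclusions)) || any(exclusions[, 1] > exclusions[, 2]))
      stop("exclusion intervals must be finite with start <= end")
    if (any(exclusions[, 1] < -1e-9) || any(exclusions[, 2] > L + 1e-9))
      stop("exclusion intervals must lie within [0, L]")
  }
  structure(
    list(nodes = nodes, arc_length = s, axon_id = as.character(axon_id),
         session_id = as.character(session_id), exclusions = exclusions),
    class = "axon_trace")
}

#' @export
print.axon_trace <- function(x, ...) {
  cat(sprintf("axon_trace '%s' (session '%s'): %d nodes, length %.2f um",
              x$axon_id, x$session_id, nrow(x$nodes), trace_length(x)))
  if (!is.null(x$exclusions))
    cat(sprintf(", %d exclusion interval(s)", nrow(x$exclusions)))
  cat("\n")
  invisible(x)
}

#' Total trace length in um
#' @param trace an [axon_trace].
#' @export
trace_length <- function(trace) {
  trace$arc_length[length(trace$arc_length)]
}

# logical vector: is each arc-length position inside an exclusion interval?
in_exclusion <- function(s, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0L)
    return(rep(FALSE, length(s)))
  out <- rep(FALSE, length(s))
  for (i in seq_len(nrow(exclusions)))
    out <- out | (s >= exclusions[i, 1] & s <= exclusions[i, 2])
  out
}

#' Read an unbranched SWC trace
#'
#' Reads a standard SWC file (columns: id, type, x, y, z, radius, parent;
#' `#` comments allowed). Only a single unbranched path is accepted: one
#' root and at most one child per node. Branch points bias bouton weights
#' and must be split upstream.
#'
#' @param path SWC file path.
#' @param voxel_size voxel edge lengths in um; used only when
#'   `units = "voxel"`.
#' @param units `"um"` (default) if SWC coordinates are already physical,
#'   `"voxel"` if they are 0-based voxel indices (converted to um at voxel
#'   centers, `(i + 0.5) * v`).
#' @param axon_id,session_id identifiers attached to the trace.
#' @param exclusions optional exclusion intervals, see [axon_trace]; or a
#'   path to a sidecar JSON file (see [read_exclusions]).
#' @return An [axon_trace].
#' @export
read_trace <- function(path, voxel_size = c(0.26, 0.26, 0.8), units = "um",
                       axon_id = sub("\\.swc$", "", basename(path)),
                       session_id = "s1", exclusions = NULL) {
  units <- match.arg(units, c("um", "voxel"))
  if (!file.exists(path)) stop("cannot read trace: no such file: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  if (nrow(tab) < 2L) stop("trace has fewer than 2 nodes: ", path)
  roots <- tab$id[tab$parent == -1]
  if (length(roots) != 1L) stop("branched trace: expected exactly one root")
  if (anyDuplicated(tab$parent[tab$parent != -1]))
    stop("branched trace: a node has more than one child")
  # follow the single child chain from the root
  child_of <- stats::setNames(tab$id, tab$parent)
  ord <- integer(nrow(tab))
  cur <- roots
  for (i in seq_len(nrow(tab))) {
    ord[i] <- cur
    cur <- if (as.character(cur) %in% names(child_of))
      child_of[[as.character(cur)]] else NA_integer_
  }
  if (!is.na(cur)) stop("malformed SWC: node chain does not cover all nodes")
  tab <- tab[match(ord, tab$id), ]
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  if (units == "voxel")
    xyz <- sweep(xyz + 0.5, 2L, as.numeric(voxel_size), `*`)
  if (is.character(exclusions)) exclusions <- read_exclusions(exclusions)
  axon_trace(xyz, axon_id = axon_id, session_id = session_id,
             exclusions = exclusions)
}

#' Write a trace to SWC (um coordinates)
#' @param trace an [axon_trace].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "axon_trace"))
  n <- nrow(trace$nodes)
  tab <- data.frame(id = seq_len(n), type = 2L,
                    x = trace$nodes[, 1], y = trace$nodes[, 2],
                    z = trace$nodes[, 3], radius = 0.3,
                    parent = c(-1L, seq_len(n - 1L)))
  lines <- sprintf("%d %d %.9g %.9g %.9g %.3g %d", tab$id, tab$type,
                   tab$x, tab$y, tab$z, tab$radius, tab$parent)
  writeLines(c("# SWC written by boutonkit (um units)", lines), path)
  invisible(path)
}

#' Read exclusion intervals from a sidecar JSON file
#'
#' The file holds an array of `[start, end]` arc-length pairs in um, e.g.
#' `[[12.0, 14.5], [30.1, 31.0]]`.
#'
#' @param path JSON file path.
#' @return numeric matrix `m x 2`, or `NULL` for an empty array.
#' @export
read_exclusions <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (length(x) == 0L) return(NULL)
  matrix(as.numeric(as.matrix(x)), ncol = 2L)
}

#' Write exclusion intervals to JSON
#' @param exclusions numeric matrix `m x 2` of `[start, end]` um intervals.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_exclusions <- function(exclusions, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(exclusions)), function(i) exclusions[i, ]),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Resample a trace to a target node density
#'
#' Nodes are placed by linear interpolation along the existing polyline at
#' uniform arc-length spacing `v / lambda_target`, where `v` is the mean
#' lateral voxel size; both endpoints are kept and the piecewise-linear
#' path (hence total length) is preserved.
#'
#' @param trace an [axon_trace].
#' @param lambda_target target node density in nodes per voxel (the
#'   profile-generation default is 4).
#' @param voxel_size voxel edge lengths in um (lateral sizes set the
#'   spacing unit).
#' @return A resampled [axon_trace].
#' @export
resample_trace <- function(trace, lambda_target = 4,
                           voxel_size = c(0.26, 0.26, 0.8)) {
  stopifnot(inherits(trace, "axon_trace"), lambda_target > 0)
  vbar <- mean(voxel_size[1:2])
  L <- trace_length(trace)
  spacing <- vbar / lambda_target
  n <- max(2L, round(L / spacing) + 1L)
  s_new <- seq(0, L, length.out = n)
  nodes <- apply(trace$nodes, 2L, function(col)
    stats::approx(trace$arc_length, col, xout = s_new)$y)
  axon_trace(nodes, axon_id = trace$axon_id, session_id = trace$session_id,
             exclusions = trace$exclusions)
}
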