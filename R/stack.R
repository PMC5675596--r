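#' 3D image stack with physical voxel sizes
#'
#' Container for a 3D fluorescence image. Values are stored as a numeric
#' array with dimensions `(nx, ny, nz)`; voxel `(i, j, k)` (1-based) has its
#' center at physical position `((i - 0.5) vx, (j - 0.5) vy, (k - 0.5) vz)`
#' in micrometers. All geometry downstream of construction is in um.
#'
#' @param values numeric 3D array of non-negative, finite intensities.
#'   A matrix is promoted to a single-plane stack.
#' @param voxel_size numeric length-3, voxel edge lengths `(vx, vy, vz)` in
#'   um; all positive. Two-photon stacks are typically anisotropic, e.g.
#'   `c(0.26, 0.26, 0.8)` after x-binning.
#' @param name identifier string.
#' @return An object of class `image_stack` with elements `values`,
#'   `voxel_size` and `name`.
#' @export
image_stack <- function(values, voxel_size = c(0.26, 0.26, 0.8),
                        name = "stack") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "double"
  if (any(dim(values) < 1L)) stop("stack must have >= 1 voxel per axis")
  if (!all(is.finite(values))) stop("stack intensities must be finite")
  if (any(values < 0)) stop("stack intensities must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || !all(is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values (um)")
  structure(
    list(values = values, voxel_size = voxel_size, name = as.character(name)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("image_stack '%s': %d x %d x %d voxels @ %.3g x %.3g x %.3g um\n",
              x$name, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  extent %.2f x %.2f x %.2f um, intensity range [%g, %g]\n",
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[3] * x$voxel_size[3], min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$values)

# physical extent (um) along each axis
stack_extent <- function(stack) dim(stack$values) * stack$voxel_size

#' Read a TIFF z-stack
#'
#' Reads a single- or multi-page integer TIFF into an [image_stack]. Page
#' rows/columns are mapped to the y/x axes, pages to z. Intensities are
#' raw integer counts cast to double.
#'
#' @param path TIFF file path.
#' @param voxel_size voxel edge lengths `(vx, vy, vz)` in um.
#' @param name identifier; defaults to the file name.
#' @return An [image_stack].
#' @export
read_stack <- function(path, voxel_size = c(0.26, 0.26, 0.8),
                       name = basename(path)) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (length(shp) != 2L)
    stop("multi-channel TIFF pages are not supported; single channel only")
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent page shapes in TIFF: ", path)
  # page matrix is [row = y, col = x]; store as [x, y, z]
  vals <- array(0, c(shp[2], shp[1], length(pages)))
  for (k in seq_along(pages)) vals[, , k] <- t(pages[[k]])
  image_stack(vals, voxel_size = voxel_size, name = name)
}

#' Write an image stack to a multi-page TIFF
#'
#' Values are rounded and stored as unsigned integers; they must lie in
#' `[0, 2^bits - 1]`. The round trip through [read_stack] is exact for
#' integer-valued stacks.
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"), bits %in% c(8L, 16L))
  mx <- 2^bits - 1
  v <- round(stack$values)
  if (any(v > mx))
    stop(sprintf("intensities exceed %d; rescale before writing", mx))
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / mx)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                                   reduce = FALSE, compression = "none"))
  invisible(path)
}
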