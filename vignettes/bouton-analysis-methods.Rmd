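---
title: "Measuring axonal bouton weights and their plasticity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring axonal bouton weights and their plasticity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonkit)
```

## The problem

Axonal boutons — presynaptic swellings along cortical axons — are the
anatomical proxy for synapses that in vivo two-photon laser scanning
microscopy (2PLSM) can actually see. Tracking their appearance,
disappearance and size changes over weeks is how structural plasticity is
quantified. Three obstacles make naive intensity measurements unreliable:
fluorescence depends multiplicatively on imaging conditions (laser power,
PMT voltage, cranial window quality) and on each axon's expression level;
the point-spread function is several-fold worse along the optical axis
than laterally; and boutons sit at high density, so neighbors blur into
one another. `boutonkit` implements a semi-automated pipeline that deals
with each of these, plus an explicit measurement-noise model so that
plasticity is scored probabilistically rather than by thresholding noisy
numbers.

## Pipeline overview

For one axon in one imaging session the pipeline runs:

1. **Trace optimization.** A manual centerline trace is refined against
   the image by maximizing a fitness = (image intensity integrated along
   the trace through a negative 3D Laplacian-of-Gaussian kernel of size
   `R_opt` = 3 voxels) − (a stiffness penalty `stiffness_alpha` = 0.001 on
   the discrete curvature of the node chain). The maximization uses a
   damped Newton method with a gradient-ascent fallback and stops at a
   relative fitness change below 1e-6. Working node density is
   `lambda_opt` = 0.5 nodes/voxel; afterwards the trace is resampled to
   `lambda_profile` = 4 nodes/voxel.
2. **Intensity profiles.** Two filters are convolved with the image at
   every node: a multi-scale in-plane Laplacian of Gaussian
   (`R_xy` ∈ [1.5, 3] lateral voxels, four scales, maximum response taken;
   axial size `R_z` = 2 axial voxels) that sharpens bouton boundaries, and
   an isotropic Gaussian (`R_G` = 2 voxels) suited to estimating shaft
   intensity. Kernel distances are physical (µm), so the z anisotropy of
   2PLSM stacks is honored. Each profile is rescaled to unit mean over
   non-excluded nodes, which cancels the session gain and the axon's
   expression level and isolates structure.
3. **Peak decomposition.** The LoG profile is decomposed into narrow
   foreground Gaussians (putative boutons; widths 0.5–2 µm) plus
   `ceiling(L/25µm)` wide background Gaussians (widths ≥ 20 µm, a slowly
   varying baseline) by constrained least squares with backward
   elimination: starting from `ceiling(L/0.5µm)` uniformly spaced
   candidates, one foreground peak with re-fitted amplitude < 0.3 is
   eliminated — or a pair closer than 1 µm (or overlapping by more than
   50% of either area) merged — and the model re-optimized, until no
   candidate remains.
4. **Weights.** Bouton intensity is the foreground amplitude plus the
   fitted LoG background at the peak; shaft intensity is the fitted
   background of the Gaussian profile (seeded from the LoG fit), averaged
   over nodes. The bouton weight `w = I_bouton / I_shaft` is a unitless
   size proxy; in the bundled CLEM reference data it correlates with
   EM-measured bouton volume at r = 0.93.
5. **Noise model and plasticity.** Repeated imaging of the same axons
   shows `var(Δw) = α⟨w⟩` with α = 0.24. Modeling a measured weight as
   true weight plus Gaussian noise of variance `αw/2` gives the
   probability that a putative bouton is a real (LM) bouton,
   `P(bouton|w) = (1 + erf((w − w_thr)/sqrt(αw)))/2` with `w_thr` = 2, and
   closed-form probabilities for addition, elimination, potentiation and
   depression between two sessions. A site's change is called significant
   when its event probability exceeds 0.95; chance levels come from
   shuffling each site's weights across sessions.

## Numerical choices in the peak decomposition

The constrained least-squares problem of step 3 is deceptively hard: the
model class itself contains a degenerate solution in which the dense set
of narrow foreground candidates tiles the profile baseline (a "picket
fence") while the background collapses to zero — and once candidate
amplitudes sit at baseline level (≈ 0.5–1 in unit-mean profiles), the
0.3-amplitude elimination rule can never remove them. Plain simultaneous
gradient descent wanders into this basin on a subset of realistic
profiles. Four structural choices keep the decomposition identifiable;
they change the optimization path, not the objective or its constraints:

* **Pinned background layout, exact amplitudes.** Background centers stay
  at their uniform layout and widths at `max(20 µm, L/3)`; only
  amplitudes are fitted, exactly, by active-set non-negative least
  squares. The width constraint exists to keep the baseline slowly
  varying, which the pinned layout guarantees by construction. Because
  the broad components overlap strongly on short axons (they are nearly
  collinear as basis vectors), the NNLS normal matrix carries a ridge on
  the amplitude-difference direction only — zero for equal amplitudes —
  so the baseline stays balanced instead of flipping to arbitrary
  corners.
* **Median-baseline seeding.** Foreground amplitudes are seeded from the
  profile minus a 5-µm running median (clipped at zero, corrected for
  neighbor-seed overlap). The median ignores bouton bumps, so seeds
  appear only at genuine local excess.
* **Anchored candidates.** Each foreground center is constrained to
  ±1 µm (the merge distance) around the position that seeded it. A
  candidate exists to model local structure; letting candidates migrate
  is what allows the fence to colonize baseline stretches the rigid
  background cannot follow.
* **Freeze–prune–polish schedule.** The background is fitted once against
  the seeded foreground and then frozen while the candidate set is pruned
  (foreground-only refits between eliminations/merges). Only when no
  candidate remains is the background released for a joint polish; if the
  polish creates new elimination candidates, pruning resumes, up to ten
  polish cycles. Freezing the baseline during pruning prevents the
  gradual hand-over of baseline mass from background to foreground that
  otherwise completes within a single long optimization.

Within the foreground block, steps are projected (bound-violating
parameters are set to the bounds) and diagonally scaled by the
Gauss–Newton curvature with a backtracking line search; a block converges
at a relative objective change below `fit_tol` = 1e-6.

Other numerical details: the elimination order is smallest amplitude
first (applied to re-fitted amplitudes, after the optimization pass);
merges take the closest qualifying pair, with the merged peak at the
amplitude-weighted center, the maximum amplitude and the
amplitude-weighted width clipped to bounds; peak-overlap areas are
computed by numerical integration of the pointwise minimum of the two
curves (step 0.02 µm) relative to each peak's own analytic area; an
all-zero profile short-circuits to a zero-amplitude model; profiles
shorter than 1 µm are rejected.

## Trace optimization details

The stiffness term penalizes the deviation of each interior node from the
midpoint of its neighbors. A neighbor-*distance* penalty would make every
finite-spacing trace pay a cost and, at large `stiffness_alpha`, collapse
the trace toward a point; the curvature form leaves straight, equally
spaced traces penalty-free and drives the trace toward a straight line in
the stiff limit, which is what a stiffness should do. The kernel is
evaluated by direct summation over voxel centers within `4 R_opt` of each
node (no image interpolation), with `R_opt` converted to µm via the
lateral voxel size. Endpoints are free: pinning them would bias weights
of boutons near trace ends, which are instead flagged (`near_end`,
default 2 µm) in the output. Newton steps are taken when the Hessian is
negative definite (checked by Cholesky of its negation), otherwise
normalized gradient ascent; both backtrack so accepted iterations never
decrease the fitness.

## The synthetic-data generator

`synthetic_axon()` and `render_stack()` exist so that every stage can be
validated against known ground truth without microscope data. The
generator emulates cytosolic labeling: total fluorescence is proportional
to cytosol volume. The shaft deposits line mass `π r²` per µm (default
radius 0.3 µm) and each bouton a blob of integrated mass equal to its
volume, drawn log-uniformly from 0.05–1 µm³, the range observed for
cortical boutons in EM. Gaussian-equivalent widths follow from solid-body
second moments (tube: σ = r/2; sphere of radius a: σ = a/√5, times a ±15%
shape jitter), and the anisotropic PSF (σ_xy = 0.15 µm, σ_z = 0.6 µm) is
applied analytically by adding variances. The rendered axon overhangs the
traced span by 5 µm per end — a traced segment is an excerpt of a longer
axon, so profiles must not roll off at trace ends. Default session
settings (gain 1000, additive noise s.d. 10 counts → shaft peak ≈ 200
counts) correspond to a well-labeled axon under in vivo 2PLSM; Poisson
noise is available but off by default.

What the generator does **not** emulate: crossing or touching axons,
depth-dependent scattering and vignetting, motion and bleaching within a
stack, boutons terminaux on side branches, and mitochondria-driven
intensity structure. Passing the recovery tests therefore demonstrates
the internal consistency of the pipeline under its own generative
assumptions, not performance on every real-data pathology. One known
scale difference: with the default shaft radius the rendered weights span
roughly 1–9 rather than the 1–13.5 seen in the reference CLEM data;
thinner shafts widen the range but degrade background identifiability, so
the stable regime was kept.

## Study sizes used by the validation suite

The bundled validation (`synthetic_recovery_study()`, also run by the
test suite) uses 20 axons of ~26 µm with 5 boutons each in 128×128×40
voxel stacks (0.26 × 0.26 × 0.8 µm voxels), a reference and a perturbed
condition per axon (halved gain, 1.5× expression, fresh noise), and a
doubled-gain exact-scaling check on six axons. Precision and recall are
reported for boutons with measured weight above 2.5, where detection is
expected to be essentially perfect; smaller boutons are genuinely
ambiguous at this resolution — which is precisely why the probabilistic
LM-bouton definition exists. The α-recovery check uses 10,000 simulated
weight pairs; the plasticity control uses 400 sites over 7 sessions with
100 shuffle replicates.

## Worked example

```{r example, eval = FALSE}
dims <- c(128L, 128L, 40L)
vs <- c(0.26, 0.26, 0.8)
ax <- synthetic_axon(extent = dims * vs, n_boutons = 5, seed = 42)
scene <- render_stack(ax, imaging_conditions(seed = 7),
                      dim = dims, voxel_size = vs)
trace <- resample_trace(scene$traces[[1]], 4, vs)
rec <- detect_boutons(scene$stack, trace)
rec[, c("position_um", "weight", "p_bouton")]

# plasticity scoring between two sessions
event_probabilities(wi = rec$weight, wf = rec$weight * 1.5)
```

## Known limitations

* Branched traces are rejected, not split; branch-adjacent boutons bias
  weights and must be handled upstream.
* The background model (few, ≥20 µm-wide components) cannot follow
  baseline tilts on short axons; the resulting residual (±0.1 in
  unit-mean units) folds into the measurement noise that α absorbs.
* Exclusion intervals are honored in normalization, shaft averaging and
  flagging, but the peak fit does not re-weight nodes adjacent to an
  exclusion boundary.
* `p_bouton` treats α as known; its ±0.01 calibration uncertainty is not
  propagated into event probabilities.
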