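# boutonkit

Semi-automated detection and probabilistic tracking of axonal boutons in
3D two-photon (2PLSM) image stacks.

Axonal boutons — presynaptic swellings along axons — are the structures
in vivo microscopy can follow to quantify synaptic plasticity. Their
fluorescence, however, confounds structure with imaging gain, expression
level and measurement noise. `boutonkit` implements a complete analysis
chain that separates these factors:

* **Trace optimization** — refines a manual SWC centerline against the
  image by maximizing
  `F = (1/λ) Σ_k Σ_m I(l_m) K(r_k − l_m) − (αλ/2) Σ_k ‖r_k − (r_{k−1}+r_{k+1})/2‖²`,
  a negative-Laplacian-of-Gaussian intensity term plus a curvature
  stiffness, with a damped Newton method.
* **Intensity profiles** — a multi-scale in-plane Laplacian-of-Gaussian
  filter (bouton detection) and an isotropic Gaussian filter (shaft
  estimation) convolved with the stack at every trace node, rescaled to
  unit mean so that gain and expression cancel.
* **Peak decomposition** — constrained least squares of narrow foreground
  Gaussians (0.5 ≤ σ ≤ 2 µm, putative boutons) plus wide background
  Gaussians (σ ≥ 20 µm, baseline), with backward elimination
  (amplitude < 0.3) and merging (closer than 1 µm or > 50% overlap).
* **Bouton weights** — `w = I_bouton / I_shaft`, a unitless volume proxy
  (r = 0.93 against EM volumes in the bundled CLEM reference table,
  `clem_boutons()`).
* **Noise model** — `var(Δw) = α⟨w⟩` with α = 0.24 from repeated
  imaging; LM-bouton probability
  `P(bouton|w) = ½(1 + erf((w − 2)/√(αw)))` and closed-form probabilities
  of addition, elimination, potentiation and depression between sessions;
  significant-event fractions with Poisson errors and shuffle-based
  chance levels.
* **Synthetic data** — a generator of ground-truth axons rendered with
  anisotropic PSF and noise, used to validate the whole pipeline
  (precision and recall 1.00 for boutons with weight > 2.5 at desk
  scale; Spearman 0.96 between weight and true volume).

## Worked example

```r
library(boutonkit)

dims <- c(128L, 128L, 40L)
vs <- c(0.26, 0.26, 0.8)            # um per voxel, anisotropic in z
ax <- synthetic_axon(extent = dims * vs, n_boutons = 5, seed = 42)
scene <- render_stack(ax, imaging_conditions(seed = 7),
                      dim = dims, voxel_size = vs)
trace <- resample_trace(scene$traces[[1]], 4, vs)
rec <- detect_boutons(scene$stack, trace)
round(rec[, c("position_um", "weight", "p_bouton")], 3)
#>   position_um weight p_bouton
#> 1       5.736  2.457    0.800
#> 2      12.273  1.525    0.134
#> 3      16.028  3.089    0.963
#> 4      21.971  3.134    0.968

round(ax$boutons$s_um, 3)            # ground truth positions
#> [1]  5.732  9.193 12.287 16.021 21.964
```

Four of the five programmed boutons are recovered at their true
arc-length positions (within 0.01 µm); the missed one is the smallest
(0.05 µm³, at 9.19 µm), genuinely below the reliable-detection size at
this resolution. The weight is the bouton's intensity relative to the
axon shaft, and `p_bouton` is the probability that the site is a real
(LM) bouton given measurement noise — the 0.09 µm³ bouton at 12.27 µm is
detected but uncertain (`p_bouton` = 0.13), which is exactly what the
probabilistic score is for.

Event scoring between two sessions:

```r
signif(event_probabilities(wi = 0.5, wf = 10), 3)   # appeared
#>   added eliminated potentiated depressed
#> 1     1   6.43e-23    4.57e-10         0
```

From the shell, the same steps are available as
`boutonkit optimize | profile | detect | match | plasticity | stats |
simulate` via the installed `exec/boutonkit` script.

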