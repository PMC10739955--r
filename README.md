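# crhmem

Hypothalamic CRH neurons — the corticotropin-releasing-hormone cells of
the paraventricular nucleus that drive the endocrine stress response —
form contextual memories: after foot shocks in a novel context,
re-exposure recruits previously *weakly* responding cells into the
active pool (a two-factor learning rule), while a rewarding experience
(hazelnut spread) scales the whole population's contextual response
down (a one-factor rule).  `crhmem` implements both the model and the
measurement chain behind this picture, for computational
neuroscientists who want to simulate the circuit and for imaging labs
who want the analysis pipeline:

* **Spiking network model** — 100 adaptive leaky integrate-and-fire
  neurons driven by filtered Poisson context input, shock and reward
  drives, with the delayed two-factor rule

  dω/dt ∝ (Ω − Σω) · r_slow(t) · H(r_slow(t) − r_thresh)

  (recruitment toward a weight ceiling Ω, gated by supra-threshold
  activity) and the one-factor rule da/dt = ε(Ω − Σω)·H(Nut(t) −
  nut_thresh) for appetitive memory.  Compiled core; full 2190 s
  protocol or a time-compressed variant that learns the same weights.
* **Fiber photometry preprocessing** — second-order polynomial
  bleaching correction fit on head/tail windows, isosbestic (405 nm)
  least-squares alignment and subtraction, dF/F via polynomial channel
  mapping, cross-day z-scoring z = (F − F0)/σF with a day-1 σF option.
* **Miniscope cross-day registration** — stochastic descent on the
  weighted Frobenius image metric 0.3·GA(masks) + 0.7·GA(raw) over
  rotation/translation/scale, with schedule (perturbation halved every
  500 iterations, day pair cycled every 400), restarts, and greedy
  one-to-one cell matching.
* **Subpopulation clustering** — affinity propagation (q = 0
  preference, damping 0.9) plus exemplar-based agglomerative merging to
  Weak/Intermediate/Strong pools; ±1 SD classifier as the simple
  alternative.
* **State-space statistics** — cross-day population matrices, PCA via
  SVD, paired Pre/Post tests, recruitment regressions, freezing-time
  summaries.
* **Synthetic data generators** with exact ground truth for all of the
  above (photometry sessions, cell tables, FOV image pairs, behavior
  barcodes) — the recordings themselves are not publicly deposited, so
  every quantitative check in the package is scored against generator
  truth.

## Worked example

Simulate the aversive protocol (4× compressed timeline), cluster cells
by their anticipatory (Pre) activity and test recruitment:

```r
library(crhmem)

params <- network_params("aversive")
proto  <- build_protocol("aversive", time_scale = 4)
sim    <- simulate_network(params, proto, seed = 1)
sim
#> CRH network simulation (aversive mode)
#>   100 neurons, 548 s simulated, 43243 spikes (0.79 Hz mean rate)
#>   population epoch means of the calcium proxy:
#>     home  0.225
#>     pre   0.822
#>     post  1.120
#>     fs    1.509

em <- sim$epoch_means
paired_comparison(em[, "pre"], em[, "post"])$t
#> [1] 12.41
```

The population's contextual response grows from Pre to Post (here
t ≈ 12 over 100 cells).  The increase is carried by the initially weak
cells: splitting cells into terciles of Pre activity, the bottom
tercile gains a median of 0.45 while the top tercile gains 0.10, and
the gain of a cell is predicted by its shock-epoch response
(`recruitment_regression`).  Running the same network with
`build_protocol("control")` (no shocks) leaves Post ≈ Pre with a
Pre/Post correlation of ~0.99 versus ~0.7 after shocks; the appetitive
preset (`"appetitive"`) instead lowers Post below Pre with the
correlation preserved.

The imaging side composes the same way on synthetic data:

```r
s <- synth_photometry(900, 100, bleach_coeffs_sig = c(1e-7, -4e-4, 1),
                      baseline_level = 10, event_times_s = 450,
                      event_amplitudes = 1, noise_sd = 0.02, seed = 1)
trace <- photometry_process(s$session, method = "zscore")

fov <- synth_fov_pair(rotation_deg = 7, translation_px = c(5, -3),
                      scale = 1.05, seed = 1)
al <- stochastic_align(list(fov$day1, fov$day2), iterations = 10000,
                       restarts = 5, seed = 2)
al$transforms[[2]]
#> Transform: rotation -7.005 deg, translation (-4.374, 3.419) px, scale 0.9522
```

which matches the inverse of the generating transform (rotation −7°,
translation (−4.378, 3.416) px, scale 0.9524) to within 0.005°,
0.005 px and 2×10⁻⁴ in scale.

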