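---
title: "Models and methods behind crhmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crhmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crhmem` packages two things that usually live in separate code bases: a
spiking-network model of how hypothalamic CRH neurons (the
corticotropin-releasing-hormone cells of the paraventricular nucleus,
the apex of the HPA stress axis) store contextual memories of aversive
and appetitive experience, and the calcium-imaging analysis chain used
to measure that memory in vivo — fiber-photometry preprocessing,
cross-day miniscope field-of-view registration, data-driven
subpopulation clustering, and population state-space statistics.
Because the recordings themselves are not publicly deposited, the
package ships synthetic-data generators with known ground truth; every
claim the test suite makes is scored against that ground truth.

This vignette documents the models, the tunable parameters, and the
design decisions that were genuinely open.

## The network model

A population of `N = 100` leaky integrate-and-fire neurons with spike
frequency adaptation represents the CRH population:

$$\tau_m \dot V_i = -V_i + I_{\mathrm{bias}} + I^{\mathrm{syn}}_i(t) - w_i(t) + \gamma_i(t),
\qquad \dot w_i = -w_i/\tau_w + d\sum_k \delta(t - t_{ik}),$$

with $\tau_m = 10$ ms, threshold $-40$ mV, reset $-65$ mV,
$I_{\mathrm{bias}} = -41$ pA (so the quiescent membrane sits 1 mV below
threshold and firing is fluctuation-driven), adaptation increment
$d = 20$ pA with $\tau_w = 100$ ms.  Input currents carry pA and add to
the voltage equation with an implicit unit resistance.  Everything is
integrated with forward Euler at `dt` = 1 ms; the synaptic filters use
exact exponential decay factors.

The synaptic drive has three parts: a context input (1000 Poisson
channels at 8 Hz in a novel environment, 1 Hz in the home cage,
filtered with a 20 ms decay / 2 ms rise double exponential) weighted by
the plastic weights $\omega_i$; a foot-shock input
$\mathrm{FS}(t)=\sum_{k}\exp(-(t-t_k)^2)$ (unit-width Gaussians at the
ten shock times) weighted by fixed $\omega^{FS}_i \sim \mathcal N(2,1)$;
and a hazelnut-spread input
$\mathrm{Nut}(t)=\exp(-(t-t^{Nut})^2/10^4)$ weighted by
$\omega^{Nut}_i \sim \mathcal U[-0.09, 0.01]$.  Each neuron also drives
a slow double-exponential spike filter $r^{\mathrm{slow}}_i$ (decay 1 s,
rise 100 ms) that serves both as the simulated calcium indicator and as
the activity signal gating plasticity.

### The learning rules

Aversive (two-factor, delayed):

$$\dot a_i = \epsilon\,(\Omega - \textstyle\sum\omega_i)\;
r^{\mathrm{slow}}_i(t)\;H\!\left(r^{\mathrm{slow}}_i(t) - r_{\mathrm{thresh}}\right),
\qquad \tau_\omega \dot\omega_i = -\omega_i + a_i,$$

with $\epsilon = 0.014\,\mathrm{s}^{-1}$, weight ceiling
$\Omega = 0.0031$, $\tau_\omega = 400$ s.  The first factor recruits
weakly-wired neurons toward the ceiling; the second factor is a
plasticity gate that only opens during strong activity — in practice,
during the shock response.  `H` is the Heaviside step with `H(0) = 0`:
ties never open the gate.  Appetitive (one-factor): the same relaxation
with $\dot a_i = \epsilon(\Omega-\sum\omega_i)H(\mathrm{Nut}(t) -
\mathrm{nut}_{\mathrm{thresh}})$, $\epsilon = 2\times10^{-6}\,
\mathrm{s}^{-1}$ and $\Omega = -1$: all weights are driven down while
the reward is present, more strongly the larger the current weight sum.
The auxiliary variable $a_i$ is a pure integrator while the gate is
open, so it can transiently overshoot $\Omega$ before $\omega$ catches
up; at equilibrium the weight sums sit within a few percent above the
ceiling, which is why the tests allow a 15% margin on the ceiling
invariant.

### The weight-sum reduction

The context channels are statistically exchangeable (same rate, same
kernel), the initial weights split each neuron's weight sum uniformly
across channels, and the learning increment is identical for every
channel of a neuron.  Under these conditions the full
$N \times N^{\mathrm{context}}$ weight matrix stays rank-one for all
time, and the dynamics depend only on each neuron's weight *sum* and on
the pooled filtered context train $R(t)$ (one filter driven by a
Poisson process of rate $N^{\mathrm{context}}\nu$).  The simulator
evolves exactly this reduction; it is not an approximation.

### Units of the context pathway, and why `context_gain` exists

The published parameter set leaves the context pathway without a
current scale: a filtered 8 Hz channel averages
$\nu(\tau_d-\tau_r) \approx 0.14$, so a weight sum at the ceiling
$\Omega = 0.0031$ would inject $\sim 5\times10^{-4}$ pA against a 1 pA
subthreshold gap — no weight change could ever alter firing, and the
model could not produce the recruitment it is built to explain.  We
therefore write the context current as

$$I^{\mathrm{context}}_i =
\frac{g}{N^{\mathrm{context}}}\,\Sigma\omega_i \, R(t),$$

with `context_gain` $g = N^{\mathrm{context}} = 1000$ by default.  This
is equivalent to reading the ceiling as a bound on the *mean*
per-channel weight and puts a ceiling-level weight sum at
$\approx 0.45$ pA of novel-context drive — enough to move a
near-threshold neuron, small enough that firing stays sparse.  The
learning rule itself uses $\Sigma\omega$ and $\Omega$ exactly as
written; only the unit convention of the filtered train is fixed here.

### Free parameters and their defaults

Three quantities are not specified by the published model and are
exposed as configuration with the following defaults:

* `noise_sd = 0.3` (mV).  The white-noise current is implemented as an
  Euler–Maruyama term scaled so that the *stationary voltage sd* it
  induces equals `noise_sd` regardless of `dt` (this is what makes the
  dt-halving convergence check meaningful).  0.3 mV against the 1 mV
  subthreshold gap gives sparse, fluctuation-driven background firing
  with strong (exponential) sensitivity to sub-pA changes in drive —
  the regime in which weight differences of order $\Omega$ translate
  into measurable rate differences.
* `r_thresh = 2` (units of the slow filter).  Pilot simulations put
  context-driven $r^{\mathrm{slow}}$ below $\approx 2.5$ even for the
  strongest cells, while shock bursts exceed 2 reliably; at this
  setting the gate essentially never opens in no-shock controls
  (weight drift $< 10^{-4}\,\Omega$), which is exactly the control
  behavior the model needs.
* `nut_thresh = 0.5`: the hazelnut gate is open for
  $|t - t^{Nut}| < 83$ s, about 167 s of reward exposure.

Initial weight sums are drawn $\mathcal U[0, 0.0031]$ in every mode
(`omega_init_max`), which creates the Weak/Intermediate/Strong
anticipatory heterogeneity and, in the aversive mode, spans the full
range below the ceiling.  A per-channel uniform draw would concentrate
every neuron's sum at the same value and produce no heterogeneity at
all, so the per-neuron draw implements the intent rather than the
letter of that choice.

### Timeline, epochs and the compressed protocol

The full protocol runs 2190 s: home cage, novel context at 500–1290 s
with ten foot shocks at 900, 930, …, 1170 s (the shock window
[900, 1200] s with 30 s spacing, endpoint excluded), return to home
cage, and a second context exposure at 1790 s.  Epoch means of
$r^{\mathrm{slow}}$ over `pre` = [500, 900] and `post` = [1790, 2190]
are the simulation analogue of the per-cell integrated dF/F.

`build_protocol(time_scale = s)` divides all protocol times and (inside
`simulate_network`) $\tau_\omega$ by `s`, while leaving $\epsilon$ and
the printed shock/reward Gaussian widths untouched.  Because the gated
plasticity exposure is the absolute time spent above threshold under
those fixed-width gates, the learned weight change matches the
full-length protocol (verified in the tests).  The packaged test suite
and the acceptance script run the 10-seed simulation batteries at
`time_scale = 4` (547.5 s per run); all other problem sizes (100
randomized photometry sessions of 900 s, 10 registration seeds at
10,000 iterations × 5 restarts, 120-cell clustering fixtures,
50 × 50 PCA oracles) are the sizes stated in the corresponding
checks.

## Photometry preprocessing

The chain mirrors standard dual-wavelength practice: trim the first and
last 5 min (handling transients), fit a second-order polynomial to each
channel using only the head/tail fit windows (so context-evoked
activity cannot bend the fit) and subtract it; least-squares align the
405 nm isosbestic channel to the signal channel; subtract pointwise
(ΔF).  Alternatively `dff()` maps the 405 channel onto the 465 channel
with a degree-2 polynomial and computes
$(F_{465}-F_{\mathrm{fit405}})/F_{\mathrm{fit405}}$.  Note that any
*static* channel scaling is absorbed by that fit — dF/F measures
transient departures, not constant gains.  Z-scoring uses
$z = (F - F_0)/\sigma_F$ with the sample (n−1) standard deviation; for
cross-day comparisons $\sigma_F$ can be supplied from the first day's
baseline while $F_0$ stays session-own (both sources are exposed; the
day-own $F_0$ is the default).

The synthetic session generator produces
`bleach(t)·(baseline + events + context) + motion + noise` against a
`bleach_ref(t)·baseline + motion` reference: multiplicative bleaching,
additive common-mode motion, instantaneous-rise/exponential-decay
calcium transients (kernel choice is irrelevant downstream, which is
why a single exponential suffices), and Gaussian noise.  What it does
*not* model: hemodynamic or autofluorescence contamination, slow drift
of the artifact gain between channels, or non-polynomial bleaching.
Recovery tests passing on these sessions therefore validate the
arithmetic of the chain, not its robustness to every failure mode of
real recordings.  Generator noise defaults (0.1–0.2% of baseline per
sample at 100 Hz) describe a good recording; they are free parameters
of the study design, not measured values.

## Cross-day registration

Each day contributes a two-channel image: the maximal-projection raw
image and the curated cell-mask channel.  The global alignment metric
GA is the sum of Frobenius distances over all unordered day pairs (a
configuration switch restricts it to distances against a fixed
reference day, the form in which the objective is sometimes written),
computed per channel after per-day min-max intensity normalization so
the two channels are commensurate; the optimization criterion is
`0.3·GA_mask + 0.7·GA_raw`.  Stochastic descent perturbs one day's
rotation/translation/scale per iteration (initial scales 5°, 10 px,
0.1), accepts only strict decreases (ties do not move), halves the
perturbation every 500 iterations, cycles the perturbed day every 400
iterations, and runs 10,000 iterations per restart with 5 restarts from
random initial conditions (the first restart starts at the identity).
The 10,000 iterations are counted per restart in this implementation;
both counts are configurable.  Cell correspondence then comes from
greedy nearest-centroid matching in the reference frame with a 6 px
cap, one-to-one, unmatched cells flagged — the mapping rule itself is
an implementation choice, as no published criterion exists.

The bilinear warp rotates about the image centre, then scales, then
translates; `warp_image` moves image features exactly the way
`apply_transform` moves points, which is what makes the recovered
transform directly comparable to the generator's ground truth.

## Subpopulation clustering

`affinity_propagation()` implements Frey–Dueck message passing with
similarity $-\lVert x_i - x_j\rVert^2$, damping 0.9, shared preference
equal to the minimum off-diagonal similarity (the `q = 0` convention
that yields few clusters), and convergence once the exemplar set is
stable for 50 iterations.  A degenerate input on which no exemplar
emerges (e.g. all points identical) falls back to the single
net-similarity exemplar.  The exemplar-based agglomerative step then
merges, at each move, the cluster pair whose best joint exemplar
maximizes the mean within-cluster similarity, down to `k = 3` pools
labeled Weak / Intermediate / Strong by ascending mean feature value
(the clustering feature is the Pre-epoch idF/F by convention).  The
merge objective is our reading of "exemplar-based agglomerative
clustering" — the cited method names no formula — and is validated
only on separable fixtures.  The ±1 SD classifier (Weak below
mean − sd, Strong above mean + sd, n−1 convention) is provided as the
simple alternative and agrees with ap+agg on well-separated tails.

## State-space statistics

`build_matrix` stacks per-cell traces across days on the cross-day
correspondence (cells unmatched on any day are dropped with a count);
`pca_svd` mean-centers each column (time sample) across cells — the
centering is switchable since the original description applies the SVD
"directly" — and returns components, per-sample projections and
variance fractions, which the tests pin to covariance eigenvalue ratios
within 1e-8.  Paired comparisons, Pre/Post Pearson correlations with
regression slopes, per-pool recruitment regressions and 3-min
freezing-time summaries (bouts under the 3 s immobility criterion are
excluded) are thin wrappers over `t.test`, `cor.test` and `lm`; the
package's contribution there is the epoching, grouping and recruitment
logic, not the statistical machinery.

## Synthetic cell tables

`synth_cell_table` draws three pools (40/40/20% by default) with
Pre-epoch idF/F means 2/8/18 and shock responses 40/28/18 (Weak cells
respond most strongly to the shock, as recorded).  The aversive rule
sets Post = Pre + 0.4·FS·(1, 0.5, 0 by pool): recruited Weak cells land
at the Strong ceiling (0.4 ≈ (18−2)/40), which is what makes the pools
statistically indistinguishable at recall.  The appetitive rule scales
Pre down by 5/30/60% per pool, so Strong cells drop most while the
cell ranking — and hence the Pre/Post correlation — is preserved.
These numbers emulate the qualitative structure of the recorded
contrasts, not any measured values.

## Numerical notes and limitations

* Spike times are recorded on the Euler grid; the closed-form LIF ISI
  is matched within one time step for drives up to ~1 pA above
  threshold (forward Euler shortens ISIs by ~5%, so at very long ISIs
  the discrepancy exceeds one step — a property of the integrator, not
  a bug).
* All generators take a `seed` and restore the caller's RNG state;
  `NULL` composes with the ambient stream.
* The simulator's appetitive epochs and the behavioral timeline carry
  the reward at 930 s inside the first context exposure, as specified.
* Known limitations: no synaptic connectivity among the CRH neurons
  (the model has none by design), no parameter fitting to real
  recordings, no non-rigid registration, no modeling of miniscope
  source extraction — the pipeline consumes its outputs.
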