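---
title: "Models and methods behind fretscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscape)
```

`fretscape` turns two-channel single-molecule FRET photon traces of
immobilized receptors into conformational state models, inter-fluorophore
distances, and occupancy-based energy landscapes. This vignette documents
the generative model the package assumes, every tunable that matters, the
numerical choices, and what the synthetic-data validation does and does
not establish about real data.

## The measurement model

A molecule carries a donor and an acceptor dye. Under donor excitation the
donor's photon stream is partitioned between the donor channel (fraction
$1-E$) and the acceptor channel (fraction $E$), where the transfer
efficiency depends on the inter-dye distance $r$ through the Förster
relation

$$E = \frac{1}{1 + (r/R_0)^6},$$

with $R_0$ the distance of half transfer for the dye pair. The package
estimates $E$ per analysis bin as the background-subtracted proximity
ratio $E = I_A / (I_D + I_A)$, i.e. with $\gamma = 1$ and no spectral
crosstalk or direct-excitation corrections. All distances the package
reports are therefore *ratiometric* distances between the fluorophores;
dye size and linker dynamics add systematic uncertainty, so differences
between conditions are more meaningful than absolute values.

**`R0` default (51 Å).** The default was frozen by requiring the inversion
$r = R_0(1/E-1)^{1/6}$, rounded to whole ångströms, to reproduce the
complete set of published efficiency–distance pairs for the
Alexa 555/Alexa 647 pair used on kainate receptors
(0.89→36, 0.95→31, 0.93→33, 0.69→45, 0.83→39, 0.92→34, 0.79→41,
0.70→44 Å); it is configurable everywhere it is used.

## What the simulator emulates

`sim_config()` / `simulate_trace()` generate photon traces with the
statistical structure the analysis assumes:

* **Conformational dynamics.** A continuous-time Markov chain over 1–5
  discrete states, sampled by the Gillespie algorithm and *then* binned to
  the acquisition resolution (1 ms), so dwells shorter than a bin survive
  as fractional bin occupancies exactly as in a real detector. The default
  rate matrix is a nearest-neighbour chain in efficiency order with a
  150 ms mean dwell.
* **Photons.** Per 1 ms bin, donor and acceptor counts are Poisson with
  means $I\,(1-E)$ and $I\,E$ plus background. Defaults $I = 50$ counts/ms
  and background 2 counts/bin give, after 5 ms binning, per-bin efficiency
  noise of $\sigma_E \approx 0.03$; $I = 20$ counts/ms gives
  $\sigma_E \approx 0.05$, the regime used for the state-recovery
  validation. Neither photon budget is a measured value — the published
  work reports none — so they are calibrated to give histogram widths
  comparable to the experimental figures.
* **Photobleaching.** Each fluorophore bleaches after an exponential time
  (default hazard $3\times10^{-4}$ ms⁻¹), putting the mean FRETing region
  of a donor–acceptor pair near 1.7 s, inside the reported 1–3 s range.
  The default 20 s trace length lets essentially every fluorophore bleach
  within the record, as in acquisitions run to the end of the bleach
  cascade — step counting needs the bleaches to be observed.
* **Labelling stoichiometry.** Molecules carry 1–4 fluorophores with
  probabilities (0.05, 0.35, 0.50, 0.10), matching the reported
  photobleach-step distribution for stochastically labelled homomeric
  receptors. The composition per step count is a package choice: 2-step
  molecules are one donor plus one acceptor (the analyzable class; this
  makes the accepted fraction track the 2-step weight), 1-step molecules
  are a lone donor or acceptor with equal probability, 3-step are 2D+1A or
  1D+2A, 4-step are 2D+2A. A donor transfers to *all* live acceptors with
  per-pair rate ratio $E/(1-E)$, so the bleach of one of two acceptors
  produces a visible acceptor-channel step — without this, 1D+2A molecules
  would masquerade as single pairs.
* **Direct acceptor excitation.** Simulated as a constant-mean Poisson
  stream per live acceptor. It carries no conformational signal and is
  used only to count acceptor bleach steps.

Not emulated: blinking, triplet states, spectral crosstalk, γ-factor
heterogeneity, drift, or diffusing background. Passing the validation
suite therefore shows the *algorithms* are correct under the stated noise
model, not that real instrument artifacts are handled.

## Quality control

Bleach steps are found by recursive binary segmentation with a Welch
t-statistic (threshold $|t| \ge 5$, minimum segment 10 bins) followed by
backward elimination of boundaries that are no longer significant against
their final neighbours; only downward steps are counted. Two choices
matter:

* **Donor steps are counted on the summed donor-excitation intensity**
  $I_D + I_A$. Conformational transitions shuttle intensity between the
  two channels but conserve their sum, so donor bleaches are the only
  downward steps of the total — counting on $I_D$ alone would mistake
  every state change for a bleach.
* **Acceptor steps are counted on the direct-excitation channel** when
  present (it is blind to FRET dynamics), else on the acceptor channel.

A molecule is accepted when both counts are exactly one and the channels
are anticorrelated (Pearson $r \le -0.3$ by default) over the window up to
the donor bleach, with counts summed to 5 ms before correlating to lift
the conformational signal above shot noise. Including an earlier acceptor
bleach in that window is deliberate: the acceptor falling as the donor
rises is the cleanest evidence of a genuine FRET pair, and for a molecule
that never changes state it is the *only* such evidence — single-state
molecules whose donor bleaches first are unverifiable and are rejected.
The "cross-correlation" label check of the original workflow is not
separately implemented; step counting on the direct-excitation channel
plays that role.

## Efficiency traces and denoising

Counts are binned 1 → 5 ms (trailing remainder dropped), the proximity
ratio computed with per-bin backgrounds scaled by the binning factor, and
bins with non-positive corrected totals flagged invalid and bridged by
linear interpolation. Denoising is Haar-wavelet shrinkage at the universal
threshold $\hat\sigma\sqrt{2\ln N}$ ($\hat\sigma$ = MAD of the finest
details), depth $\min(4, \lfloor\log_2 n\rfloor - 1)$, averaged over 16
circular shifts (cycle spinning). **Hard thresholding is the default**:
soft thresholding shrinks the detail coefficients that encode the steps
themselves, biasing extreme state levels toward the centre and leaving
block-boundary noise; measured on two-state traces with $\sigma = 0.08$,
translation-invariant hard thresholding reduces the RMSE to the true state
path by ~55–60 % where soft thresholding manages ~20 %. The soft mode
remains available (`denoise(mode = "soft")`).

## State identification

`stasi_fit()` follows the step-transition-and-state-identification scheme:

1. each denoised trace is segmented by the same t-test splitter (minimum
   segment 3 bins);
2. segment levels are merged hierarchically (nearest means,
   occupancy-weighted);
3. the state count minimizes a minimum-description-length cost
   $\mathrm{MDL}(K) = \frac{\mathrm{SS}(K)}{2\hat\sigma^2\ln 2} +
   \frac{K}{2}\log_2 N + T_K\,(\log_2 N + \log_2 K)$, where
   $\mathrm{SS}(K)$ is the residual sum of squares of the denoised data
   against the $K$ merged levels, $\hat\sigma$ is the raw per-bin noise
   from the finest wavelet details, and $T_K$ is the number of surviving
   transitions — each costing its position ($\log_2 N$) *and* the identity
   of the state it enters ($\log_2 K$). The last term matters: without it,
   sub-percent-occupancy artifact populations win ties worth a few tens of
   bits in costs of thousands.

Three refinements address the artifacts of analyzing 5 ms bins of
millisecond dynamics; all were adopted after the plain scheme produced
spurious states on synthetic data with known truth:

* **Blur masking.** A bin that straddles a transition records the
  time-average of two states. Bins flanking every detected change point
  keep their assignment but are excluded from all level statistics;
  otherwise the mid-gap "states" they form pass the MDL test.
* **Within-segment outlier masking.** Excursions shorter than the minimum
  segment length cannot be segmented out; their bins appear as >3σ
  outliers inside a segment and are likewise masked.
* **Raw-level refinement.** Because wavelet shrinkage pulls extreme levels
  toward the centre, cluster positions are refined by weighted 1-D k-means
  on the *raw* segment means, and reported state efficiencies and
  half-widths (Gaussian FWHM) come from the raw core bins of each state.

States closer than $\max(0.03, \hat\sigma)$ efficiency units are merged:
levels separated by less than the per-bin noise cannot be distinguished at
the analysis bin width, and in validation such pairs were always sub-noise
splits of one true state rather than genuine conformations. The 0.03
floor is configurable (`min_separation`).

`hmm_fit()` is the independent cross-check, fitted to the **raw**
efficiencies (multiple sequences jointly): Gaussian-emission hidden Markov
models for $K = 1..6$ by scaled Baum–Welch (Rcpp), 10 deterministic
restarts per $K$ (quantile initialization plus jitter), BIC selection with
$p = (K-1) + K(K-1) + 2K$ parameters, Viterbi assignments. Because it
models per-bin emission with transition probabilities, blurred bins sit in
the tails rather than forming states — which is exactly why agreement
between the two very different estimators is informative. On 66-molecule
synthetic datasets under the validation conditions the two agree to better
than 0.01 per state.

`fit_gaussians()` reproduces the conventional histogram readout:
least-squares Gaussian mixture with fixed component count on the pooled
histogram (0.01-wide bins on [0, 1.05], one count per 5 ms bin, normalized
over all molecules), initialized at the state-model efficiencies.

## Landscape

Occupancies are bin fractions per state. Free energies are
$\Delta G^0_i = -\ln(p_i/p_{\max})$ in $k_BT$ (most populated state
exactly 0; zero-occupancy states flagged infinite). Transitions are
bin-to-bin assignment changes counted strictly within molecules;
per-bin transition probabilities divide by the time spent in the starting
state, honouring the convention that the starting-state concentration is
its fractional occupancy. Rates use the first-order small-$p$ limit
$k = p/\Delta t$ by default ($-\ln(1-p)/\Delta t$ behind
`rate_method = "log"`; at the $p \lesssim 0.05$ values typical here the
two differ by <3 %). Barriers are $E_a = -\ln(k/A)$ with $A = 10$ ms⁻¹,
and forward/reverse pairs are averaged for the symmetrized map, omitting
pairs with an unobserved direction. Energies are reported in $k_BT$;
`kbt_to_kcal()` converts at a stated temperature (default 298 K — the
temperature, like $R_0$, is configuration, not a claimed measurement).

## Validation problem sizes and determinism

The test suite validates parameter recovery at the scale the method is
used: 66 molecules, five states at (0.93, 0.82, 0.70, 0.58, 0.39),
150 ms dwells, $\sigma_E \approx 0.05$, 1–3 s FRETing regions — the
segmentation fit must select $K = 5$ with every efficiency within ±0.02
and the HMM within ±0.03 of it; QC acceptance over 500 mixed-stoichiometry
molecules must match the 35 % single-pair weight within binomial error;
transition maps of nearest-neighbour chains must be ≥90 % adjacent.
Smaller oracle tests check exact results: change points on noiseless
traces against an exhaustive zero-variance segmentation, MDL state counts
against full set-partition enumeration (≤6 levels, one segment per trace
so the transition term vanishes), and the closed-form free-energy and
Arrhenius values to $10^{-12}$.

Every stochastic component is seeded: simulation through explicit seeds
(per-molecule seeds drawn from the master seed), HMM restarts from a
configuration seed. Identical inputs and configuration produce
byte-identical output bundles; provenance (versions, molecule counts,
full configuration) is written as JSON alongside the result tables.

## Known limitations

* The proximity ratio omits γ and crosstalk corrections; absolute
  efficiencies (hence distances) inherit that bias. Comparisons across
  conditions with the same dye pair are unaffected to first order.
* 5 ms binning hides dynamics faster than a few milliseconds; rapidly
  exchanging states appear as one averaged state, and blur handling
  discards the evidence of the fastest events by design.
* The QC fallback for files without a direct-excitation channel counts
  acceptor steps on the FRET acceptor channel, which can over-count for
  strongly dynamic molecules.
* Occupancy-based ΔG assumes equilibrium sampling within the FRETing
  region; barriers depend on the assumed pre-exponential $A$ through an
  additive $\ln A$ and are meaningful relative to each other.
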