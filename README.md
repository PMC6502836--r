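# fretscape

Conformational state and energy landscapes from single-molecule FRET
(smFRET) trajectories.

Immobilized membrane receptors carrying one donor and one acceptor
fluorophore report a single inter-label distance through the FRET
efficiency of two-channel photon traces. Because labelling of homomeric
receptors is stochastic, most molecules carry the wrong number of
fluorophores and must be discarded; the survivors are short (seconds),
shot-noise limited, and hop between a handful of discrete conformations.
`fretscape` implements the full analysis chain for such data:

1. **Trace QC** — photobleaching-step counting by change-point detection
   (molecules are kept only when both channels bleach in exactly one step)
   and donor/acceptor anticorrelation checks; the FRETing region ends at
   the first bleach event.
2. **Efficiency** — 1 ms photon counts binned to 5 ms; per-bin proximity
   ratio `E = IA / (ID + IA)` after background subtraction;
   translation-invariant Haar wavelet denoising.
3. **States** — STaSI-style identification (recursive t-test change-point
   segmentation, hierarchical merging of segment levels, state count by
   minimum description length), cross-checked by a Gaussian-emission
   hidden Markov model fitted to the raw data with BIC state-count
   selection; Gaussian fits to the pooled efficiency histogram.
4. **Distances** — Förster inversion `R = R0 (1/E − 1)^{1/6}` (default
   `R0 = 51 Å`, the Alexa 555/647 pair).
5. **Thermodynamics** — state free energies `ΔG⁰ = −k_B T ln K_eq` from
   occupancies (most-populated state ≡ 0), transition maps counted within
   molecules, first-order rates `k = p/Δt`, and Arrhenius barriers
   `E_a = −k_B T ln(k/A)` with `A = 10 ms⁻¹`, forward/reverse averaged.

A photon-level trace simulator (continuous-time Markov conformational
dynamics via Gillespie sampling, Poisson shot noise, exponential
photobleaching, mixed 1–4-fluorophore labelling stoichiometry) provides
ground truth for validating every stage.

## Worked example

Simulate an apo-like condition (one conformation at E = 0.89), run the
pipeline, and read off the state table:

```r
library(fretscape)

cfg <- sim_config(state_efficiencies = 0.89,
                  stoichiometry_weights = c(0, 1, 0, 0),  # all 1D+1A
                  duration = 8000)
simulate_dataset(cfg, 15, seed = 3, dir = "traces", condition = "apo_Na")

bundle <- run_pipeline(run_config("traces", output_dir = "results_apo",
                                  condition = "apo_Na", seed = 5))
print(bundle)
#> <fret_bundle> condition apo_Na: 6/15 molecules accepted
#> <state_model:stasi> 1 state(s) over 6 molecules, 1236 bins
#>  state efficiency   fwhm occupancy
#>      1     0.8903 0.0554         1
#> HMM cross-check: 1 state(s) at 0.891

bundle$distances
#>   state efficiency R0 distance_A distance_exact
#> 1     1  0.8903411 51         36       35.97367
```

Nine of the fifteen molecules are rejected (multiple bleach steps, short
FRETing regions, or weak anticorrelation — the `qc` element lists the
reason per molecule); the six survivors pool into a single state whose
mean efficiency, 0.890, converts to an inter-fluorophore distance of
36 Å. Multi-state conditions work identically: `bundle$landscape` then
carries the transition count matrix, per-state ΔG⁰ in k_BT, and the
symmetrized activation barriers.

A thin CLI wrapper is installed under `exec/` with subcommands
`simulate`, `run` and `compare` for shell use.

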