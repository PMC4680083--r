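# dcnvoc

Cochlear distortion products and selective spike responses to ultrasonic
vocalizations.

## The problem this package addresses

Mouse social vocalizations carry their spectral energy at 50–100 kHz,
far above the characteristic frequencies (CFs, typically 10–35 kHz) of
many auditory brainstem neurons that nevertheless respond to them. A
candidate explanation is that the cochlea's compressive nonlinearity
generates **distortion products** — components at combination
frequencies such as *f₂ − f₁* and *2f₁ − f₂* — that fall inside the
neurons' tuning, so that low-tuned cells effectively "hear" the
ultrasound through its in-cochlea distortions. Testing that idea
computationally needs four pieces, which this package provides for
anyone analysing spike responses to complex sounds:

1. **A nonlinear cochlea model.** A reverberation comb filter
   (`s'(t) = Σₙ s(t − nΔt)·e^(−nΔt/a)`, with Δt = 1 ms, a = 2 ms,
   N = 5 echoes) followed by a Boltzmann double-sigmoid
   `D(x) = 1 / [(1 + e^(a₂(x₂−x)))(1 + e^(a₁(x₁−x)))]`
   (x₁ = x₂ = −0.2, a₁ = 12.8, a₂ = a₁/3):
   `reverberate()`, `boltzmann()`, `apply_cochlea_filter()`, plus
   zero-phase 40 kHz band-splitting (`highpass_40k()`, `lowpass_40k()`)
   and spectral analysis (`psd()`, `spectrogram()`).
2. **A Bayesian deflection detector.** A four-parameter response model
   (rates λ₁/λ₂ outside/inside an interval [τ₁, τ₁+τ₂)), posterior
   sampled by Metropolis–Hastings; the Hellinger distance
   `HD = sqrt(½ Σᵢ (√Pᵢ(λ₁) − √Qᵢ(λ₂))²)` between the two rate
   marginals is the response probability, significant at `HD ≥ 0.95`.
   Suppression counts: the test is two-sided.
3. **A rate-independent spike-train similarity** (`spike_similarity()`):
   Gaussian-smoothed, unit-normalized single-trial trains, averaged
   inner products across trial pairs.
4. **Selectivity summaries.** `SI = (Cₜ − Cₑ)/Cₜ` per cell and
   population statistics (`selectivity_index()`, `population_summary()`).

Because the original recordings are not available, the package ships
first-class synthetic generators — USV-like syllables confined to
50–100 kHz (`generate_usv()`, `usv_suite_default35()`), Poisson and
gamma-renewal rasters with injected deflections (`generate_raster()`),
and model neurons with inhibitory sidebands whose inhibition outlasts
the stimulus (`model_cell_response()`) — and an orchestrated, seeded
end-to-end experiment (`run_experiment()`).

## Worked example

A two-component "harmonic" syllable sweeping 70 → 55 kHz is passed
through the cochlea filter; the *f₂ − f₁* product sweeps 35 → 27.5 kHz,
inside the tuning of a model cell with CF 30 kHz. Only the sub-40 kHz
distortion band is presented to the cell:

```r
library(dcnvoc)

syll <- syllable_spec("harmonic", 70000, 55000, duration = 0.05)
w    <- generate_usv(syll)
dist <- apply_cochlea_filter(w)
distortion_gain(w, dist)
#> # A tibble: 1 × 3
#>   band_db_in band_db_out introduced_db
#>        <dbl>       <dbl>         <dbl>
#> 1      -87.1       -13.7          73.4

cell <- model_cell_params(cf = 30000)
r    <- model_cell_response(cell, lowpass_40k(dist), seed = 21)
detect_response(r, seed = 22)
#> Response probability = 1.00 (significant at 0.95)
#> Magnitude = 2.33 +/- 0.24 spikes/bin, Latency = 2.10 +/- 1.93 ms
```

Reading: the original syllable has essentially no energy in the
10–35 kHz band (−87 dB re its peak); the cochlea filter introduces a
distortion product at −14 dB, a 73 dB gain in that band. The detector
gives the evoked deflection probability 1.00 — a response of 2.33
spikes/bin summed over the 20 trials (`magnitude_to_rate(2.33)` ≈ 117
spikes/s per trial) at ~2 ms latency. Presenting the *time-reversed*
syllable to a cell with a low-frequency inhibitory sideband
(`direction_selectivity_fixture()`) yields no significant response: the
upsweeping product enters the sideband first and the persistent
inhibition vetoes the later excitatory passage.

The full simulated experiment:

```r
res <- run_experiment(run_config(seed = 1), outdir = "results")
res$selectivity          # per-cell SI, median SI, threshold comparisons
res$pairs                # original vs distortion-band decision agreement
export_figures(res, "results/figures")
```

A thin command-line wrapper is installed at
`inst/scripts/dcnvoc.R` (`synth-stimuli`, `distort`, `detect`,
`run-all`).

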