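# stridesync

Analysis pipeline for mobile eye-tracking and EEG recorded while people
walk. The scientific question it serves: does the rhythm of locomotion
structure visual sampling and cortical excitability? Concretely, do saccade
onsets and band-limited EEG power oscillate with the stride cycle, and at
what phase?

The package is aimed at researchers running walking/VR paradigms with a
head-mounted tracker (head position, gaze origin, gaze direction at ~90 Hz)
and a mobile EEG system (10–20 montage at ~300 Hz). It provides the full
chain from raw streams to population-level statistics, plus a synthetic
session generator with complete ground truth so every stage can be validated
without any data downloads.

## What it computes

1. **Saccade detection** — blink handling (±0.8 m displacement criterion,
   linear interpolation over ±100 ms), conversion of gaze direction to
   head-fixed angles, first-difference velocity with 5-sample smoothing,
   per-trial median-based thresholds η = λ·σ̂ with
   σ̂ = √(median(v²) − median(v)²) and λ = 6, and elliptic 2D crossing
   `(vx/ηx)² + (vy/ηy)² > 1` with a 2-sample (22 ms) minimum duration.
2. **Gait extraction** — vertical head position is low-passed (6 Hz),
   detrended, and footfall troughs detected with prominence and separation
   rules; steps are bounded to [0.4, 1.2] s; strides (two steps) map any
   event time to a stride percentile in [0, 100).
3. **Cyclic statistics** — saccade stride percentiles binned into 40 bins,
   expressed as relative change from the participant mean, and fitted with a
   first-order Fourier model `f(θ) = a0 + a1 cos(wθ) + b1 sin(wθ) =
   a0 + A cos(wθ + φ)` at forced frequencies w = 0.2 … 10 cycles per stride
   (cps) in 0.2 steps. Significance comes from a within-participant
   bin-shuffling null (95th percentile of R² over permutations, per
   frequency); the population prevalence of the within-participant effect is
   the MAP of the posterior p(γ) ∝ θᵏ(1−θ)ⁿ⁻ᵏ with θ = γβ + (1−γ)α; phase
   consistency is tested with Rayleigh's Z = nR̄².
4. **EEG time–frequency** — A1/A2 re-referencing, 0.1–40 Hz zero-phase
   band-pass, deviation/correlation bad-channel rules, step epochs (−600 ms
   to +600 ms around each step), IQR outlier rejection, complex Morlet
   wavelets (50 linear frequencies 3–40 Hz, FWHM 600→100 ms, unit peak
   gain), resampling to a −30…+130% step-cycle grid (0.5% steps), and
   percent-change normalization against the full-epoch baseline. A
   saccade-locked variant (−600…+1100 ms) pools epochs into stance
   (quartiles 1 and 4) and swing (2 and 3) phases.
5. **Cluster statistics** — one-sample/paired t maps, two-tailed p < 0.01
   cluster forming with 4-connectivity (or a channel-adjacency graph for
   topographies), and sign-flip Monte Carlo permutation of the maximum
   cluster mass (2000 repetitions) for familywise-corrected `p_cluster`.

## Worked example

Simulate six participants whose saccade rate is modulated at 2 cps
(modulation depth 0.5, phase 0.8 rad), run detection, gait extraction and
the group statistics:

```r
library(stridesync)
dir <- tempfile("sessions")
percs <- lapply(1:6, function(p) {
  b <- simulate_session(dir, sprintf("p%02d", p),
                        walk = walk_params("slow", n_trials = 25),
                        sacc = saccade_params(modulation_depth = 0.5,
                                              modulation_phase = 0.8),
                        eeg  = eeg_params(),
                        seed = 100 + p)
  analyse_session(b)$percentiles
})
ent <- group_entrainment(percs,
                         analysis_config(cyclic = list(n_perm = 200))$cyclic,
                         seed = 5)
i2 <- which(ent$scan$grid == 2)
cat(sprintf("best frequency: %.1f cps (R^2 = %.2f; 95%% null bound at 2 cps = %.2f)\n",
            ent$scan$best_freq, ent$scan$r2[i2], ent$null$bound[i2]))
cat(sprintf("participants significant in the 1.5-2.5 cps band: %d of %d\n",
            ent$k, ent$n))
print(ent$prevalence)
```

Output:

```
best frequency: 2.0 cps (R^2 = 0.71; 95% null bound at 2 cps = 0.14)
participants significant in the 1.5-2.5 cps band: 6 of 6
prevalence: k=6/6, alpha=0.050, beta=1.00 -> MAP = 1.00, 95% HPDI [0.63, 1.00]
```

Reading this: the group-mean binned saccade density is best fitted at
exactly 2 cycles per stride — the step rate — with R² far above the
permutation null, every simulated participant shows the effect in the
1.5–2.5 cps band, and the estimated population prevalence is accordingly
high. With `modulation_depth = 0` the fits stay below the null bound at the
nominal rate.

A command-line interface wraps the same stages
(`inst/cli/stridesync simulate|detect-saccades|extract-gait|run-all ...`).

## Layout

- `R/` — modules: `io.R`, `simulate.R`, `saccades.R`, `gait.R`, `cyclic.R`,
  `eeg_tf.R`, `cluster.R`, `pipeline.R`
- `src/` — connected-component labelling for cluster statistics (Rcpp)
- `vignettes/stride-entrainment.Rmd` — the methods vignette: model
  assumptions, tunables, what the generator does and does not emulate,
  numerical choices, limitations
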