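# hebbrsa

Representational similarity analysis (RSA) for Hebb-repetition
working-memory experiments with supra-span tone sequences.

In a Hebb-repetition task, a few study sequences covertly repeat across
a session of novel filler sequences. `hebbrsa` asks the neural version
of Hebb's question: do regions engaged in working memory for auditory
sequences — area Spt and the wider auditory-motor network — build up
sequence-specific multivoxel patterns that persist and sharpen across
repetitions, even when recognition behaviour does not improve? The
package implements the full analysis path for a delayed
match-to-sample tone experiment (8 runs x 18 trials; nine-tone study
sequence, 3/6/9 s retention delay, match or adjacent-transposition
probe) and a synthetic BOLD generator so that every step runs and is
tested without scanner data.

## What it computes

* **Design generation** — constrained sessions with three repeating
  sequences (S1–S3) cycling among unique novels: 144 trials, 36 per
  sequence-type x probe-type cell, 24 study trials per repeating
  sequence, no repeating sequence on two successive trials, BIDS-style
  event tables.
* **Model RDMs** — Earth Mover's Distance between sequences as unit
  masses at (serial position, pitch) under the ground cost
  `c(i, j) = w_pos |i - j| + w_pitch |p_a(i) - p_b(j)|`, solved exactly
  as an assignment problem. Identical sequences have EMD 0.
* **Single-trial betas** — per-run nuisance denoising, one
  HRF-convolved regressor per trial plus a row-sum "fixed effect"
  column, and per-voxel partial least squares (SIMPLS) extraction of
  trialwise estimates; at full component count the estimates equal the
  least-squares solution.
* **RSA effects** — Spearman association between the lower triangles
  of the EMD model RDM and the correlation-distance neural RDM, per
  subject, ROI, phase and sequence type; pooled and per-run, with the
  repeat-minus-novel contrast and learning-slope trajectories.
* **ROI selection** — univariate phase GLM, one-sample t tests,
  Benjamini–Hochberg FDR, and the encoding/delay conjunction grouping
  ROIs into auditory / auditory+memory / memory sets.
* **Group inference** — `phase x seq_type` linear mixed models
  (lmerTest, Satterthwaite df, emmeans marginal means), the
  sequence-type-by-run slope test, per-ROI contrasts against zero with
  FDR, and signal-detection d-prime with log-linear boundary
  correction.
* **Synthetic BOLD** — phase-specific multivoxel patterns
  `amp * (w(run) * template + sqrt(1 - w^2) * noise)` whose
  sequence-specific component strengthens across runs for repeats,
  plus polynomial drift, shared nuisance components, AR(1) voxel noise
  (TR 1.37 s), and delay-dependent behavioural responses.

See `vignettes/hebb-rsa-methods.Rmd` for the model, assumptions,
parameter choices and limitations.

## Worked example

```r
library(hebbrsa)

design <- build_design(seed = 1)
design
#> <experiment_design> 8 runs x 18 trials (seed 1)
#>          match mismatch
#>   novel     36       36
#>   repeat    36       36

round(build_tone_pool()$frequencies, 1)
#> [1]  300.0  390.0  507.0  659.1  856.8 1113.9 1448.0 1882.5 2447.2

sequence_emd(design$sequences$S1, design$sequences$S1)
#> [1] 0
sequence_emd(design$sequences$S1, design$sequences$S2)
#> [1] 2

sim <- simulate_subject(design, sim_params(seed = 101))
eff <- subject_rsa_effects(sim, design, subject = "s01")
ctr <- repeat_novel_contrast(eff)
ctr[ctr$run == "pooled", ]
#>  subject roi    phase    run contrast
#>      s01 aud    delay pooled    0.205
#>      s01 aud encoding pooled    0.249
#>      s01 aud    probe pooled    0.082

bs <- behavioral_summary(sim$behavior)
round(tapply(bs$proportion_correct, bs$delay_s, mean), 3)
#>     3     6     9
#> 0.646 0.458 0.375
```

The nine pool frequencies are the 30%-step ladder from 300 Hz capped
at 2600 Hz. The EMD of a sequence with itself is exactly 0; between
two different repeating sequences it is the minimal transport cost in
position/pitch units. The pooled repeat-minus-novel contrasts are
positive and largest at encoding for this simulated subject — repeated
sequences evoke patterns that align with sequence similarity beyond
what novel sequences show — and simulated accuracy declines with
delay, mirroring the task's behavioural profile.

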