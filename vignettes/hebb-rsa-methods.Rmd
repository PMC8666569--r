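---
title: "Methods: representational similarity analysis of Hebb-repetition tone sequences"
author: "hebbrsa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity analysis of Hebb-repetition tone sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hebbrsa)
```

## The scientific problem

In a Hebb-repetition experiment, a small set of study sequences covertly
repeats across a session of otherwise novel sequences. The question
`hebbrsa` addresses is whether brain regions engaged in working memory
for auditory sequences also accumulate longer-lasting,
sequence-specific traces: if they do, the multivoxel activity pattern
evoked by a repeating nine-tone sequence should become progressively
more reliable (more self-similar, more distinct from other sequences)
as the session unfolds, even when recognition behaviour shows no
improvement.

The package implements the full analysis path for such an experiment on
a delayed match-to-sample tone task: design generation, model
dissimilarity matrices over the tone sequences themselves, single-trial
multivoxel pattern estimation, the representational similarity (RSA)
statistics, ROI selection by a univariate conjunction, and group-level
mixed-effects inference — together with a synthetic BOLD generator so
that every step is exercisable and testable without access to scanner
data.

## Task and design generation

A trial presents a nine-tone study sequence (200 ms pure tones, 150 ms
gaps, 3.0 s total), a silent retention delay of 3, 6 or 9 s, and a 3 s
probe sequence followed by a match/mismatch response. Tones come from a
geometric frequency ladder from 300 Hz upward in 30% steps capped at
2600 Hz — nine frequencies, so a study sequence is a pseudorandom
permutation of the pool. Mismatch probes swap one pair of adjacent
tones, preserving the frequency multiset; adjacent (rather than
arbitrary) transpositions are the stricter reading of the task and keep
discrimination difficult.

`build_design()` produces the default session of 8 runs of 18 trials:
per run, nine trials present the repeating sequences S1, S2, S3 (cycling
strictly in that order) and nine present unique novel sequences. The
cycling schedule is what enforces the constraint that the same
repeating sequence never occurs on two successive trials — including
across run boundaries, since each run ends its cycle on S3 and the next
begins at S1. Probe type and delay are balanced within every
sequence-type cell (36 trials per sequence-type x probe-type cell, 12
per condition label, 24 study trials per repeating sequence), and the
inter-trial interval is uniform on 4–10 s (mean 7 s), stored at
millisecond precision so event tables round-trip losslessly through
their TSV writer. Novel sequences are drawn with rejection so they
never coincide with a repeating sequence or with one another; task
"versions" differ only by the design seed.

## Model RDMs: Earth Mover's Distance over sequences

Sequence dissimilarity is the Earth Mover's Distance between two
sequences viewed as nine unit masses (1/9 each) at coordinates (serial
position, pitch). The ground cost between a tone at position $i$ with
pitch $p_a(i)$ and one at position $j$ with pitch $p_b(j)$ is

$$c(i, j) = w_{pos}\,|i - j| + w_{pitch}\,|p_a(i) - p_b(j)|,$$

an L1 combination of the two ingredients that matter — order and
frequency — so that moving a tone of a different frequency across a
larger serial distance is costlier. Neither the pitch unit nor the
weighting is canonical; the defaults are $w_{pos} = w_{pitch} = 1$ with
pitch in *pool steps* ($\log_{1.3}(f/300)$), which puts one pool step
and one serial position on the same scale. Semitones and log-Hz are
available for sensitivity analyses. Because the downstream statistic is
rank-based, the overall scale of the RDM is irrelevant; RDMs store raw
EMD with no normalization.

With equal unit masses the balanced transportation problem attains its
optimum at an assignment, so `sequence_emd()` solves it exactly with a
shortest-augmenting-path assignment solver ($O(n^3)$); ties among
optimal assignments cannot affect the optimal cost. The test suite pins
the solver to an exhaustive brute-force minimum over all $n!$
assignments for $n \le 6$, and checks the metric axioms empirically.
Two identical sequences have EMD exactly 0, which is why pairs of
trials presenting the identical repeating sequence form the
zero-dissimilarity blocks of the repeat model RDM, while the novel
model RDM is zero only on its diagonal.

## Single-trial pattern estimation

For each run and phase (encoding, delay, probe) the time series is
first residualized against the run's nuisance matrix — an intercept,
fifth-degree polynomial drift basis and five noise components — and a
per-trial design matrix is built: one HRF-convolved boxcar regressor
per trial (the delay regressors have each trial's own 3/6/9 s width),
plus a "fixed effect" column equal to the row-wise sum of the trial
columns. That column makes the design deliberately collinear; under
partial least squares it acts as a regularizer that absorbs the common
trial response, shrinking individual trial estimates toward their
shared component.

`pls_betas()` fits a univariate SIMPLS regression per voxel on the
centered design (columns centered, not variance-scaled, so beta units
follow the data) and returns the trial-column coefficients. Two
numerical contracts anchor the estimator: at full component count the
coefficients equal the (minimum-norm) least-squares solution, checked
against a QR/pseudoinverse oracle at 1e-6 relative tolerance; and on
noiseless simulated data the estimated betas reproduce the injected
patterns (correlation > 0.999) up to the per-voxel offset the fixed
column leaves unidentified. The default component count is 5 — the
component count is not canonical, and 5 trades shrinkage against bias
reasonably at 18-19 columns; the OLS-limit oracle pins correctness
independently of this choice. Estimation is per run, which matches
per-run RDM visualization and avoids run-boundary leakage.

One caveat is documented as a switch rather than hidden: denoising the
*time series only* (the default, matching the beta-series procedure's
contract) leaves a small low-frequency bias in trial estimates, because
the trial regressors retain their drift-like content. Passing
`denoise_design = TRUE` residualizes the design as well
(Frisch–Waugh), making noiseless recovery exact; the pipeline default
remains `FALSE`.

## RSA statistics

The neural RDM is correlation distance (1 − Pearson across voxels)
between trial beta patterns, in [0, 2]; Euclidean distance is available
as configuration. The RSA effect is the Spearman rank correlation
between the lower triangles of model and neural RDMs — the RSA field's
scale-free default, invariant to monotone transforms of either matrix
and insensitive to the EMD's arbitrary units. Identical-sequence pairs
(model dissimilarity 0) are included in the repeat analysis: they carry
the within-sequence similarity signal that defines the effect. The
model RDM depends only on the sequences, so the same matrix is matched
against each phase's neural RDM rather than being replicated per
phase.

Pooled effects use all trial pairs of a sequence type across the
session, including pairs spanning runs (betas are estimated per run,
mitigating boundary leakage); per-run effects restrict to each run's
nine trials. The pooled effect is computed on the concatenated pair set
and is *not* the mean of per-run effects — a constructed counterexample
in the test suite demonstrates the difference. The repeat-minus-novel
contrast is taken at the statistic level (matrix-level subtraction is
ill-defined across different trial sets), and per-run trajectories feed
the learning-slope test.

## Univariate ROI selection

The univariate path models encoding, delay and probe phases with
duration-matched boxcars convolved with the canonical HRF (split by
sequence type, probe regressors further by probe type), averages betas
within each ROI, computes one-sample t tests across subjects per ROI
and phase, adjusts by Benjamini–Hochberg FDR within phase, and labels
ROIs by the conjunction: *auditory* (encoding significant, delay not),
*auditory+memory* (both), *memory* (delay only), *none* otherwise.
Boundary values exactly at the 0.05 threshold count as not significant
(strict inequality). BH is used because it is the standard `p.adjust`
FDR routine; the groups partition the ROI set by construction.

## Group inference

`fit_effects_model()` fits `value ~ phase * seq_type` by REML with a
subject random intercept and random slopes for phase and sequence type;
singular or failing fits fall back to the intercept-only structure with
a warning, and F tests use Satterthwaite degrees of freedom (any
accepted approximation would do; the one used is reported in the
output). Marginal means come from `emmeans`. `run_slope_test()` adds
run as a linear covariate and reports the sequence-type-by-run
interaction coefficient, with novel as the reference level so a
positive estimate means the repeat trajectory grows faster — the
signature of gradually stabilizing repeat-sequence patterns.
`per_roi_contrasts()` tests repeat effects against zero per ROI and
phase with two-sided p values (direction read from the sign) and BH
FDR across ROIs within each phase.

d-prime is $\Phi^{-1}(\text{hit rate}) - \Phi^{-1}(\text{false-alarm
rate})$ with mismatch trials as signal; rates of exactly 0 or 1 are
corrected by the log-linear rule (add 0.5 to the count, 1 to the
denominator), so d-prime is otherwise invariant to trial counts at
fixed rates.

## The synthetic BOLD generator

The generator is the package's explicit stand-in for preprocessed fMRI
data; no real-data preprocessing (registration, tissue segmentation,
CompCor estimation, spatial geometry) is modeled. For each trial and
phase, the multivoxel response is

$$\mathbf{y} = a_{ph}\,\big(s\,\mathbf{t}_{seq} + \sqrt{1 - s^2}\,\boldsymbol{\varepsilon}\big) + m_{ph}\,g_{roi}\,\mathbf{1},$$

with $\mathbf{t}_{seq}$ a fixed unit-norm template per sequence,
$\boldsymbol{\varepsilon}$ a fresh unit-norm draw per event, and $s$
the template correlation: $s = w(r)$ for repeat trials — the
*stabilization schedule*, non-decreasing in run $r$, default rising
0.2 to 0.8 across eight runs — and $s$ equal to `novel_structure_gain`
(default 0) for novel trials. This correlation schedule on a fixed
template is the minimal mechanism that produces diverging repeat/novel
per-run trajectories; the underlying study offers no generative model,
so it is stated here as the simulator's assumption. Patterns are
convolved with the canonical double-gamma HRF (response peak 6 s,
undershoot 16 s, peak ratio 6, unit peak) at the event onsets and
durations, and summed with per-run polynomial drift (degree 5), five
shared smooth nuisance components with random voxel loadings (handed to
the estimator as known regressors, standing in for components that a
real pipeline estimates from tissue masks), and AR(1) voxel noise
(marginal SD 1, $\rho = 0.3$ — BOLD-like and cheap). ROIs are abstract
labelled voxel blocks with no spatial structure.

Two generator choices deserve emphasis:

* **Peak-normalized event regressors.** Inside the generator each
  event's regressor is normalized to unit peak, so `amp` is the *peak*
  amplitude of the response irrespective of event duration. Without
  this, 6–9 s delay boxcars integrate more BOLD than 3 s encoding
  boxcars and would invert the intended encoding > delay > probe
  amplitude ordering at the data level. The estimators still use
  conventional duration-matched (unnormalized) regressors; the
  per-trial scale factor this induces cancels in correlation-distance
  RDMs, which are scale-free per trial.
* **Effect sizes.** No quantitative effect sizes are published for
  these RSA effects (plots only), so the defaults — pattern amplitudes
  3 / 1.2 / 0.9 and uniform activations 1.5 / 0.8 / 0.8 in noise-SD
  units — were chosen once from a signal-to-noise argument (about 0.55
  noise-SD of per-voxel pattern deviation at encoding over 30 voxels)
  to reproduce the *sign and ordering* of the reported effects, not
  their magnitudes. The delay amplitude is set well below encoding
  because longer delay events have higher regressor energy, hence
  higher estimation SNR per unit amplitude; the amplitude ratio must
  therefore be steeper than the intended ratio of observed effects.
  Behavioural accuracies default to the published proportions
  (0.631 / 0.568 / 0.504 at 3 / 6 / 9 s).

What passing tests on this generator do show: the pipeline recovers
injected pattern structure, orderings and learning slopes, and its
null behaviour is calibrated. What they cannot show: robustness to
spatially structured noise, motion, physiological confounds,
heterogeneous HRFs, or any property of real tissue — conclusions about
real data require real data.

## Problem sizes and numerical choices

* Convolution uses a 0.1 s fine grid with batched power-of-two FFTs;
  HRF support is truncated at 32 s.
* The assignment solver requires finite costs; EMD of identical
  sequences is exactly 0 by construction (zero-cost identity
  assignment).
* Zero-variance beta patterns (possible in degenerate simulations)
  become missing RDM entries, excluded pairwise; an RSA effect needs at
  least 3 valid pairs.
* Degenerate d-prime inputs (no signal or no noise trials) error rather
  than return a value; zero-variance t tests flag an infinite t.
* Simulation studies in the test suite use reduced sizes chosen as the
  package's own trade-off between statistical resolution and runtime:
  recovery uses 20 seeded studies of 8 subjects at the full 8 x 18
  design with one 30-voxel ROI; null calibration uses 200 simulations
  of 5 subjects on a 2-run x 12-trial single-delay design with three
  10-voxel ROIs. Thresholds follow binomial bands at the nominal
  levels.

## Known limitations

* The generator's stabilization mechanism is one of several that could
  produce run-increasing RSA divergence; it does not model repetition
  suppression or template drift.
* Per-run PLS with 18–19 columns leaves trial estimates correlated
  within run; the rank statistic tolerates this but does not remove it.
* The mixed models report Satterthwaite tests; with few subjects the
  random-slope structure is frequently singular and the intercept-only
  fallback (with its warning) is the effective model.
* Hemisphere is supported only as an ROI label; there is no spatial
  model of homologous regions.
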