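# d-prime, behavioural summaries, and group-level mixed models.

test_that("d-prime matches the probit closed form", {
  expect_equal(d_prime(10, 10, 10, 10), 0)
  expect_equal(d_prime(20, 5, 5, 20), 2 * qnorm(0.8), tolerance = 1e-12)
  expect_equal(d_prime(20, 5, 5, 20), 1.6832, tolerance = 1e-3)
  # antisymmetry under swapping hits and false alarms
  expect_equal(d_prime(5, 20, 20, 5), -d_prime(20, 5, 5, 20))
  # invariant to total trial count at fixed rates
  expect_equal(d_prime(8, 2, 2, 8), d_prime(80, 20, 20, 80))
  # log-linear correction engages only at boundary rates
  expect_true(is.finite(d_prime(20, 0, 0, 20)))
  expect_equal(d_prime(20, 0, 0, 20),
               qnorm(20.5 / 21) - qnorm(0.5 / 21), tolerance = 1e-12)
  expect_identical(d_prime(20, 0, 5, 15, correction = "none"), Inf)
  expect_error(d_prime(0, 0, 5, 5), "at least one")
  expect_error(d_prime(-1, 5, 5, 5), "non-negative")
})

test_that("behavioural summaries aggregate hits and false alarms per cell", {
  beh <- expand.grid(trial = 1:20, delay_s = c(3, 9),
                     seq_type = c("repeat", "novel"),
                     stringsAsFactors = FALSE)
  beh$probe_type <- rep(c("match", "mismatch"), length.out = nrow(beh))
  # perfect at delay 3, at-chance-ish fixed pattern at delay 9
  beh$response <- ifelse(beh$delay_s == 3, beh$probe_type, "mismatch")
  bs <- behavioral_summary(beh)
  expect_equal(nrow(bs), 4L)
  d3 <- bs[bs$delay_s == 3, ]
  expect_true(all(d3$hit_rate == 1 & d3$fa_rate == 0))
  expect_true(all(d3$proportion_correct == 1))
  d9 <- bs[bs$delay_s == 9, ]
  expect_true(all(d9$hit_rate == 1 & d9$fa_rate == 1))
  expect_true(all(abs(d9$d_prime) < 1e-12))
})

test_that("the phase-by-type model detects a constructed interaction", {
  set.seed(41)
  subj <- sprintf("s%02d", 1:10)
  eff <- expand.grid(subject = subj,
                     phase = c("encoding", "delay", "probe"),
                     seq_type = c("repeat", "novel"),
                     stringsAsFactors = FALSE)
  mu <- ifelse(eff$seq_type == "repeat",
               c(encoding = 0.4, delay = 0.2, probe = 0.05)[eff$phase], 0)
  eff$value <- mu + rnorm(nrow(eff), sd = 0.05) +
    rep(rnorm(10, sd = 0.05), times = 6)
  fit <- suppressWarnings(fit_effects_model(eff))
  expect_s4_class(fit$model, "lmerModLmerTest")
  p_int <- fit$anova["phase:seq_type", "Pr(>F)"]
  expect_lt(p_int, 0.05)
  emm <- as.data.frame(fit$emmeans)
  expect_equal(nrow(emm), 6L)
  expect_error(fit_effects_model(eff[eff$subject == "s01", ]),
               "single subject")
})

test_that("marginal means under an intercept-only truth equal the grand mean", {
  set.seed(42)
  eff <- expand.grid(subject = sprintf("s%02d", 1:12),
                     phase = c("encoding", "delay", "probe"),
                     seq_type = c("repeat", "novel"),
                     stringsAsFactors = FALSE)
  eff$value <- 0.3 + rnorm(nrow(eff), sd = 0.1)
  fit <- suppressWarnings(fit_effects_model(eff, random = "intercept"))
  emm <- as.data.frame(fit$emmeans)
  expect_true(all(abs(emm$emmean - mean(eff$value)) < 0.1))
})

test_that("the run-slope test recovers sign, zero, and reflection", {
  set.seed(43)
  grid <- expand.grid(subject = sprintf("s%02d", 1:8),
                      phase = c("encoding", "delay", "probe"),
                      seq_type = c("repeat", "novel"),
                      run = as.character(1:8),
                      stringsAsFactors = FALSE)
  noise <- rnorm(nrow(grid), sd = 0.02)
  # equal trajectories: slope difference ~ 0
  eff0 <- grid
  eff0$value <- 0.05 * as.numeric(grid$run) + noise
  rs0 <- suppressWarnings(run_slope_test(eff0, random = "intercept"))
  expect_lt(abs(rs0$estimate), 0.01)
  # repeat-specific growth: positive and significant
  eff1 <- grid
  eff1$value <- ifelse(grid$seq_type == "repeat",
                       0.06 * as.numeric(grid$run), 0) + noise
  rs1 <- suppressWarnings(run_slope_test(eff1, random = "intercept"))
  expect_gt(rs1$estimate, 0)
  expect_lt(rs1$p, 0.05)
  expect_equal(rs1$estimate, 0.06, tolerance = 0.02)
  # reversing run order negates the slope estimate
  eff_rev <- eff1
  eff_rev$run <- as.character(9 - as.numeric(eff1$run))
  rs_rev <- suppressWarnings(run_slope_test(eff_rev, random = "intercept"))
  expect_equal(rs_rev$estimate, -rs1$estimate, tolerance = 1e-6)
  expect_error(run_slope_test(eff1[eff1$run %in% c("1", "2"), ]),
               "at least 3 runs")
})

test_that("per-ROI contrasts test repeat effects with FDR across ROIs", {
  set.seed(44)
  eff <- expand.grid(subject = sprintf("s%02d", 1:10),
                     roi = c("sig1", "sig2", paste0("null", 1:6)),
                     phase = c("encoding", "delay"),
                     seq_type = c("repeat", "novel"),
                     run = "pooled", stringsAsFactors = FALSE)
  eff$value <- rnorm(nrow(eff), sd = 0.05) +
    ifelse(eff$seq_type == "repeat" & eff$roi %in% c("sig1", "sig2") &
             eff$phase == "encoding", 0.4, 0)
  ct <- per_roi_contrasts(eff)
  expect_equal(nrow(ct), 8L * 2L)          # n_rois x n_phases
  sig <- ct[ct$phase == "encoding" & ct$roi %in% c("sig1", "sig2"), ]
  expect_true(all(sig$p_fdr < 0.05))
  nulls <- ct[ct$phase == "delay", ]
  expect_true(mean(nulls$p_fdr < 0.05) <= 0.25)
  expect_error(per_roi_contrasts(eff[0, ]), "no matching")
})
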