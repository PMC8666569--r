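# Group-level inference: signal-detection d-prime, mixed-effects models
# on RSA effects (phase x sequence-type), the sequence-type by run
# learning-slope test, and per-ROI contrasts against zero with FDR.

#' Signal-detection sensitivity (d-prime)
#'
#' `qnorm(hit_rate) - qnorm(false_alarm_rate)`. Rates of exactly 0 or 1
#' are corrected by the log-linear rule (add 0.5 to the count and 1 to
#' the denominator) before the probit transform; the correction only
#' engages at the boundary, so d-prime is otherwise invariant to the
#' total trial count at fixed rates.
#'
#' @param hits,misses counts on signal (mismatch) trials.
#' @param false_alarms,correct_rejections counts on noise (match) trials.
#' @param correction `"loglinear"` (default) or `"none"` (boundary rates
#'   then give infinite d-prime).
#' @return scalar d-prime.
#' @export
d_prime <- function(hits, misses, false_alarms, correct_rejections,
                    correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  n_signal <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_signal == 0 || n_noise == 0) {
    stop_invalid("need at least one signal and one noise trial")
  }
  rate <- function(x, n) {
    r <- x / n
    if (correction == "loglinear" && (r == 0 || r == 1)) {
      r <- (x + 0.5) / (n + 1)
    }
    r
  }
  stats::qnorm(rate(hits, n_signal)) - stats::qnorm(rate(false_alarms, n_noise))
}

#' Behavioural summary with d-prime per subject cell
#'
#' Aggregates a trialwise behaviour table (columns subject, delay_s,
#' seq_type, probe_type, response) into hit/false-alarm rates, d-prime
#' and proportion correct per subject x delay x sequence type. Mismatch
#' trials are treated as signal (a "mismatch" response to a mismatch
#' probe is a hit; to a match probe, a false alarm).
#'
#' @param behavior trialwise data.frame; a `subject` column is added as
#'   `"s01"` if absent (single-subject tables).
#' @return data.frame with subject, delay_s, seq_type, hit_rate, fa_rate,
#'   d_prime, proportion_correct.
#' @export
behavioral_summary <- function(behavior) {
  if (is.null(behavior$subject)) behavior$subject <- "s01"
  cells <- split(behavior, interaction(behavior$subject, behavior$delay_s,
                                       behavior$seq_type, drop = TRUE))
  rows <- lapply(cells, function(d) {
    sig <- d[d$probe_type == "mismatch", ]
    noi <- d[d$probe_type == "match", ]
    hits <- sum(sig$response == "mismatch")
    fas <- sum(noi$response == "mismatch")
    data.frame(
      subject = d$subject[1], delay_s = d$delay_s[1],
      seq_type = d$seq_type[1],
      hit_rate = hits / nrow(sig), fa_rate = fas / nrow(noi),
      d_prime = d_prime(hits, nrow(sig) - hits, fas, nrow(noi) - fas),
      proportion_correct = mean(d$response == d$probe_type),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Fit lmer, falling back to a subject random intercept when the requested
# random structure fails or is singular.
fit_lmer_with_fallback <- function(formula_full, formula_simple, data) {
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(formula_full, data = data)),
    error = function(e) NULL
  )
  simplified <- FALSE
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
    if (!is.null(fit)) {
      warning("singular random-effects fit; refitting with a subject ",
              "random intercept only")
    }
    fit <- suppressMessages(lmerTest::lmer(formula_simple, data = data))
    simplified <- TRUE
  }
  list(fit = fit, simplified = simplified)
}

#' Mixed-effects model on RSA effects
#'
#' Fits, by REML, `value ~ phase * seq_type` with a subject random
#' intercept and (by default) random slopes for phase and sequence type,
#' mirroring the group model used to test whether the repeat-novel
#' difference is phase dependent. F tests use the Satterthwaite degrees
#' of freedom of `lmerTest`; estimated marginal means come from
#' `emmeans`. A singular or failing random-slope fit falls back to the
#' intercept-only random structure with a warning.
#'
#' @param effects long data.frame with columns subject, phase, seq_type,
#'   value (typically the pooled rows of [subject_rsa_effects()],
#'   averaged over ROIs beforehand if several are present).
#' @param fixed fixed-effects formula (default `value ~ phase * seq_type`).
#' @param random `"slopes"` (default) or `"intercept"`.
#' @return list of class `rsa_lmm`: `model` (the lmerTest fit), `anova`
#'   (Satterthwaite F table), `emmeans` (marginal means by the fixed
#'   factors), `df_method`, `simplified`.
#' @export
fit_effects_model <- function(effects, fixed = value ~ phase * seq_type,
                              random = c("slopes", "intercept")) {
  random <- match.arg(random)
  if (length(unique(effects$subject)) < 2L) {
    stop_invalid("random intercept unidentifiable with a single subject")
  }
  rhs_vars <- all.vars(fixed[[3]])
  slope_terms <- paste(rhs_vars, collapse = " + ")
  f_simple <- stats::as.formula(
    paste(deparse(fixed), "+ (1 | subject)")
  )
  if (random == "slopes") {
    f_full <- stats::as.formula(
      paste(deparse(fixed), "+ (1 +", slope_terms, "| subject)")
    )
    fitted <- fit_lmer_with_fallback(f_full, f_simple, effects)
  } else {
    fitted <- list(fit = suppressMessages(lmerTest::lmer(f_simple,
                                                         data = effects)),
                   simplified = FALSE)
  }
  fit <- fitted$fit
  an <- stats::anova(fit)  # lmerTest: Satterthwaite F tests
  emm <- emmeans::emmeans(fit, stats::as.formula(
    paste("~", paste(rhs_vars, collapse = " * "))
  ), lmer.df = "satterthwaite")
  structure(
    list(model = fit, anova = an, emmeans = emm,
         df_method = "Satterthwaite", simplified = fitted$simplified),
    class = "rsa_lmm"
  )
}

#' @export
print.rsa_lmm <- function(x, ...) {
  cat("Mixed-effects model on RSA effects (REML,", x$df_method, "df)\n\n")
  print(x$anova)
  invisible(x)
}

#' Sequence-type by run learning-slope test
#'
#' Fits `value ~ phase + seq_type * run` (run as a linear covariate) on
#' per-run RSA effects with a subject random intercept and sequence-type
#' random slope, and returns the `seq_type:run` interaction coefficient.
#' With novel as the reference level, a positive estimate means the RSA
#' effect grows faster across runs for repeated than for novel sequences
#' (pattern stabilization).
#'
#' @param effects long data.frame of per-run effects (columns subject,
#'   phase, seq_type, run, value); rows with `run == "pooled"` or missing
#'   values are dropped.
#' @param random `"slopes"` (default; sequence-type slope by subject) or
#'   `"intercept"`.
#' @return list with `estimate`, `t`, `df`, `p`, `model`.
#' @export
run_slope_test <- function(effects, random = c("slopes", "intercept")) {
  random <- match.arg(random)
  d <- effects[effects$run != "pooled" & is.finite(effects$value), ]
  d$run_num <- as.numeric(d$run)
  if (length(unique(d$run_num)) < 3L) stop_invalid("need at least 3 runs")
  d$seq_type <- stats::relevel(factor(d$seq_type), ref = "novel")
  has_phase <- length(unique(d$phase)) > 1L
  fixed <- if (has_phase) "value ~ phase + seq_type * run_num"
  else "value ~ seq_type * run_num"
  f_simple <- stats::as.formula(paste(fixed, "+ (1 | subject)"))
  if (random == "slopes") {
    f_full <- stats::as.formula(paste(fixed, "+ (1 + seq_type | subject)"))
    fit <- fit_lmer_with_fallback(f_full, f_simple, d)$fit
  } else {
    fit <- suppressMessages(lmerTest::lmer(f_simple, data = d))
  }
  co <- stats::coef(summary(fit))
  row <- grep("^seq_typerepeat:run_num$", rownames(co))
  list(estimate = co[row, "Estimate"], t = co[row, "t value"],
       df = co[row, "df"], p = co[row, "Pr(>|t|)"], model = fit)
}

#' Per-ROI contrasts of repeat-sequence RSA effects against zero
#'
#' One-sample t test across subjects of the repeat-sequence effect in
#' every ROI x phase, with Benjamini-Hochberg FDR across ROIs within each
#' phase. P values are two-sided; the sign of t indicates the direction.
#'
#' @param effects long data.frame with columns subject, roi, phase,
#'   seq_type, run, value.
#' @param seq_type which sequence type to test (default `"repeat"`).
#' @param run which run stratum to use (default `"pooled"`).
#' @return data.frame with roi, phase, mean, t_stat, p_value, p_fdr; one
#'   row per ROI x phase.
#' @export
per_roi_contrasts <- function(effects, seq_type = "repeat", run = "pooled") {
  d <- effects[effects$seq_type == seq_type & effects$run == run &
                 is.finite(effects$value), ]
  if (nrow(d) == 0L) stop_invalid("no matching effects")
  rows <- lapply(split(d, interaction(d$roi, d$phase, drop = TRUE)),
                 function(cell) {
    tt <- one_sample_t(cell$value)
    data.frame(roi = cell$roi[1], phase = cell$phase[1], mean = tt$mean,
               t_stat = tt$t, p_value = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (ph in unique(out$phase)) {
    sel <- out$phase == ph
    out$p_fdr[sel] <- bh_fdr(out$p_value[sel])
  }
  rownames(out) <- NULL
  out
}
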