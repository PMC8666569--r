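# Univariate phase-regressor GLM per ROI, one-sample group tests,
# Benjamini-Hochberg FDR, and the encoding/delay conjunction that groups
# ROIs into auditory, auditory+memory, and memory sets.

# Phase regressors split by condition as in the univariate analysis:
# encoding and delay split by sequence type, probe additionally split by
# probe type.
univariate_task_design <- function(events, tr, n_timepoints) {
  cols <- list()
  for (st in c("repeat", "novel")) {
    for (ph in c("encoding", "delay")) {
      ev <- events[events$trial_type == ph & events$seq_type == st, ,
                   drop = FALSE]
      cols[[paste(ph, st, sep = "_")]] <-
        convolve_events(ev, tr, n_timepoints)
    }
    for (pt in c("match", "mismatch")) {
      ev <- events[events$trial_type == "probe" & events$seq_type == st &
                     events$probe_type == pt, , drop = FALSE]
      cols[[paste("probe", st, pt, sep = "_")]] <-
        convolve_events(ev, tr, n_timepoints)
    }
  }
  do.call(cbind, cols)
}

#' Univariate phase GLM with ROI averaging
#'
#' Fits, per run, a least-squares GLM with HRF-convolved phase regressors
#' (encoding and delay split by sequence type; probe split by sequence
#' and probe type) alongside the run's nuisance matrix, then averages the
#' phase betas across that phase's condition regressors, across runs, and
#' across the voxels of each ROI.
#'
#' @param sim a `sim_subject` from [simulate_subject()].
#' @return data.frame with columns roi, phase (encoding/delay/probe),
#'   mean_beta: one row per ROI x phase for this subject.
#' @export
phase_glm <- function(sim) {
  roi <- sim$runs[[1]]$roi
  acc <- NULL
  for (run in sim$runs) {
    n_tp <- ncol(run$data)
    Xtask <- univariate_task_design(run$events, run$tr_s, n_tp)
    X <- cbind(Xtask, run$nuisance)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep <- qrX$pivot[seq_len(qrX$rank)]
      bad <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
      stop_invalid("singular univariate design; collinear columns: ",
                   paste(bad, collapse = ", "))
    }
    B <- qr.coef(qrX, t(run$data))          # coefficients x voxels
    B <- B[seq_len(ncol(Xtask)), , drop = FALSE]
    rownames(B) <- colnames(Xtask)
    acc <- if (is.null(acc)) B else acc + B
  }
  acc <- acc / length(sim$runs)
  phase_of <- sub("_.*", "", rownames(acc))
  out <- list()
  for (ph in c("encoding", "delay", "probe")) {
    vox_beta <- colMeans(acc[phase_of == ph, , drop = FALSE])
    for (rl in unique(roi)) {
      out[[paste(ph, rl)]] <- data.frame(
        roi = rl, phase = ph, mean_beta = mean(vox_beta[roi == rl]),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-sample t test against zero
#'
#' Standard one-sample t statistic `mean / (sd / sqrt(n))` with a
#' two-sided p value. Zero-variance input yields an infinite t (signed by
#' the mean) with p = 0 and a warning.
#'
#' @param values numeric vector (n >= 2), e.g. one value per subject.
#' @return list with `t`, `p`, `df`, `mean`.
#' @export
one_sample_t <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop_invalid("need at least 2 finite values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero variance; t is infinite")
    t_stat <- sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  list(t = t_stat, p = p, df = n - 1, mean = m)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment (`min over k >= i of m p_(k) / k`, with
#' enforced monotonicity), as implemented by `p.adjust(method = "BH")`.
#'
#' @param p numeric p values in (0, 1].
#' @return adjusted p values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop_invalid("p values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Group-level ROI phase statistics
#'
#' Stacks per-subject ROI mean betas (from [phase_glm()]), computes a
#' one-sample t test across subjects for every ROI x phase, and adjusts
#' the p values by Benjamini-Hochberg FDR within each phase (across
#' ROIs).
#'
#' @param subject_betas list of per-subject data.frames from
#'   [phase_glm()], or one long data.frame with a `subject` column.
#' @return data.frame with columns roi, phase, mean_beta, t_stat,
#'   p_value, p_fdr.
#' @export
roi_phase_stats <- function(subject_betas) {
  if (is.data.frame(subject_betas)) {
    long <- subject_betas
  } else {
    long <- do.call(rbind, lapply(seq_along(subject_betas), function(i) {
      d <- subject_betas[[i]]
      d$subject <- sprintf("s%02d", i)
      d
    }))
  }
  rows <- lapply(split(long, interaction(long$roi, long$phase, drop = TRUE)),
                 function(d) {
    tt <- one_sample_t(d$mean_beta)
    data.frame(roi = d$roi[1], phase = d$phase[1], mean_beta = tt$mean,
               t_stat = tt$t, p_value = tt$p, stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, rows)
  stats_df$p_fdr <- NA_real_
  for (ph in unique(stats_df$phase)) {
    sel <- stats_df$phase == ph
    stats_df$p_fdr[sel] <- bh_fdr(stats_df$p_value[sel])
  }
  rownames(stats_df) <- NULL
  stats_df
}

#' Conjunction grouping of ROIs by encoding/delay significance
#'
#' Applies the conjunction rule at FDR-adjusted alpha: "auditory"
#' (encoding significant, delay not), "auditory+memory" (both
#' significant), "memory" (delay only), "none" otherwise. Boundary values
#' exactly at `alpha` count as not significant (strict `<`). Groups are
#' mutually exclusive and exhaustive.
#'
#' @param stats data.frame from [roi_phase_stats()] containing encoding
#'   and delay rows for every ROI.
#' @param alpha significance level on the FDR-adjusted p values.
#' @return data.frame with columns roi, group.
#' @export
conjunction_groups <- function(stats, alpha = 0.05) {
  need <- c("encoding", "delay")
  rois <- unique(stats$roi)
  rows <- lapply(rois, function(rl) {
    sub <- stats[stats$roi == rl, ]
    if (!all(need %in% sub$phase)) {
      stop_invalid("ROI '", rl, "' is missing encoding or delay statistics")
    }
    enc <- sub$p_fdr[sub$phase == "encoding"] < alpha
    del <- sub$p_fdr[sub$phase == "delay"] < alpha
    group <- if (enc && !del) "auditory"
    else if (enc && del) "auditory+memory"
    else if (!enc && del) "memory"
    else "none"
    data.frame(roi = rl, group = group, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
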