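# Representational similarity analysis: neural RDMs from trial betas,
# the model-neural association statistic, repeat-minus-novel contrasts,
# and per-run learning trajectories.

#' Neural representational dissimilarity matrix
#'
#' Entry (i, j) is one minus the Pearson correlation between the
#' multivoxel beta patterns of trials i and j, giving values in [0, 2]
#' (0 for identical patterns, 1 for uncorrelated, 2 for sign-flipped).
#' Trials with zero pattern variance get missing entries and are excluded
#' downstream.
#'
#' @param betas a `trial_betas` object or a trials x voxels matrix with
#'   trial ids as rownames.
#' @param roi optional ROI label stored as metadata.
#' @param method `"correlation"` (default) or `"euclidean"`.
#' @return Object of class `neural_rdm`: list with `matrix` (symmetric,
#'   zero diagonal), `trial_ids`, `roi`, `phase`, `method`.
#' @export
neural_rdm <- function(betas, roi = NA_character_,
                       method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  phase <- NA_character_
  if (inherits(betas, "trial_betas")) {
    phase <- betas$phase
    betas <- betas$betas
  }
  betas <- as.matrix(betas)
  if (nrow(betas) < 2L || ncol(betas) < 2L) {
    stop_invalid("need at least 2 trials and 2 voxels")
  }
  ids <- rownames(betas) %||% sprintf("trial%03d", seq_len(nrow(betas)))
  if (method == "correlation") {
    sds <- apply(betas, 1, stats::sd)
    degenerate <- sds == 0 | !is.finite(sds)
    if (any(degenerate)) {
      warning(sum(degenerate), " zero-variance trial pattern(s); ",
              "entries set to NA")
    }
    m <- 1 - suppressWarnings(stats::cor(t(betas)))
    m[degenerate, ] <- NA_real_
    m[, degenerate] <- NA_real_
  } else {
    m <- as.matrix(stats::dist(betas))
  }
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  structure(list(matrix = m, trial_ids = ids, roi = roi, phase = phase,
                 method = method),
            class = "neural_rdm")
}

#' RSA effect: association between a model and a neural RDM
#'
#' Spearman rank correlation between the lower-triangle entries of the
#' two matrices, aligned on trial ids; pairs with missing neural entries
#' are excluded. The statistic is invariant to any strictly monotone
#' transform of either RDM and lies in [-1, 1]. A positive value means
#' trials with more similar sequences have more similar activity
#' patterns.
#'
#' @param model a `model_rdm` (or square matrix with id dimnames).
#' @param neural a `neural_rdm` (or square matrix with id dimnames) over
#'   the same trials.
#' @param trial_ids optional subset of ids (e.g. one run's trials) on
#'   which to compute the association.
#' @return scalar Spearman correlation.
#' @export
rsa_effect <- function(model, neural, trial_ids = NULL) {
  M <- if (inherits(model, "model_rdm")) model$matrix else as.matrix(model)
  N <- if (inherits(neural, "neural_rdm")) neural$matrix else as.matrix(neural)
  ids <- trial_ids %||% rownames(M)
  if (!all(ids %in% rownames(M)) || !all(ids %in% rownames(N))) {
    stop_invalid("trial ids of model and neural RDMs do not match")
  }
  M <- M[ids, ids, drop = FALSE]
  N <- N[ids, ids, drop = FALSE]
  lt <- lower.tri(M)
  x <- M[lt]
  y <- N[lt]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop_invalid("fewer than 3 valid trial pairs")
  suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
}

#' RSA effects for one simulated subject
#'
#' The full subject-level path: per-run denoising and PLS beta estimation
#' ([subject_betas()]), then for every ROI, phase and sequence type the
#' Spearman association between the EMD model RDM and the neural RDM.
#' Pooled effects use all trial pairs of a type across the session
#' (including pairs spanning runs); per-run effects are restricted to
#' each run's trials.
#'
#' @param sim a `sim_subject`.
#' @param design the `experiment_design` the subject was simulated from.
#' @param metric ground metric for the model RDMs.
#' @param phases phases to analyse.
#' @param n_components PLS components.
#' @param rois ROI labels to analyse (default all).
#' @param per_run also compute per-run effects (default TRUE).
#' @param model_rdms optional precomputed list
#'   `list(repeat = model_rdm, novel = model_rdm)` to avoid recomputation
#'   across subjects.
#' @param subject subject label stored in the output.
#' @return long data.frame with columns subject, roi, phase, seq_type,
#'   run (`"pooled"` or the run number as character), value.
#' @export
subject_rsa_effects <- function(sim, design, metric = ground_metric(),
                                phases = c("encoding", "delay", "probe"),
                                n_components = 5L, rois = NULL,
                                per_run = TRUE, model_rdms = NULL,
                                subject = "s01") {
  betas <- subject_betas(sim, phases = phases, n_components = n_components)
  rois <- rois %||% unique(sim$runs[[1]]$roi)
  if (is.null(model_rdms)) {
    model_rdms <- list(
      "repeat" = build_model_rdm(design, "repeat", metric),
      "novel" = build_model_rdm(design, "novel", metric)
    )
  }
  runs_of <- split(design$trials$trial_id, design$trials$run)
  out <- list()
  for (roi_lab in rois) {
    vox <- sim$runs[[1]]$roi == roi_lab
    for (ph in phases) {
      tb <- betas[[ph]]
      for (stype in c("repeat", "novel")) {
        mr <- model_rdms[[stype]]
        nr <- neural_rdm(tb$betas[mr$trial_ids, vox, drop = FALSE],
                         roi = roi_lab)
        rows <- list(data.frame(
          subject = subject, roi = roi_lab, phase = ph, seq_type = stype,
          run = "pooled", value = rsa_effect(mr, nr),
          stringsAsFactors = FALSE
        ))
        if (per_run) {
          for (r in seq_len(design$n_runs)) {
            ids_r <- intersect(mr$trial_ids, runs_of[[as.character(r)]])
            val <- if (length(ids_r) >= 3L) {
              tryCatch(rsa_effect(mr, nr, trial_ids = ids_r),
                       error = function(e) NA_real_)
            } else NA_real_
            rows <- c(rows, list(data.frame(
              subject = subject, roi = roi_lab, phase = ph,
              seq_type = stype, run = as.character(r), value = val,
              stringsAsFactors = FALSE
            )))
          }
        }
        out <- c(out, rows)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repeat-minus-novel RSA contrast
#'
#' Subtracts the novel-sequence effect from the repeat-sequence effect
#' within each (subject, roi, phase, run) cell, testing whether repeated
#' sequences have more similar activity patterns than expected from
#' tone-sequence similarity alone. Cells missing either sequence type are
#' dropped with a warning.
#'
#' @param effects long data.frame as returned by [subject_rsa_effects()].
#' @return data.frame with columns subject, roi, phase, run, contrast.
#' @export
repeat_novel_contrast <- function(effects) {
  keys <- c("subject", "roi", "phase", "run")
  rep_df <- effects[effects$seq_type == "repeat", c(keys, "value")]
  nov_df <- effects[effects$seq_type == "novel", c(keys, "value")]
  names(rep_df)[5] <- "rep_value"
  names(nov_df)[5] <- "nov_value"
  m <- merge(rep_df, nov_df, by = keys, all = FALSE)
  n_unmatched <- (nrow(rep_df) - nrow(m)) + (nrow(nov_df) - nrow(m))
  if (n_unmatched > 0) {
    warning(n_unmatched, " unmatched effect cell(s) dropped from the contrast")
  }
  m$contrast <- m$rep_value - m$nov_value
  m[, c(keys, "contrast")]
}

#' Per-run RSA trajectory slopes
#'
#' Least-squares slope of the RSA effect over run number within each
#' (subject, roi, phase, seq_type) cell; the raw material for the
#' sequence-type by run (learning) interaction test.
#'
#' @param effects long data.frame with per-run rows (`run` != "pooled").
#' @return data.frame with columns subject, roi, phase, seq_type, slope.
#' @export
per_run_slopes <- function(effects) {
  pr <- effects[effects$run != "pooled" & is.finite(effects$value), ]
  if (nrow(pr) == 0L) stop_invalid("no per-run effects present")
  pr$run_num <- as.numeric(pr$run)
  keys <- interaction(pr$subject, pr$roi, pr$phase, pr$seq_type, drop = TRUE)
  rows <- lapply(split(pr, keys), function(d) {
    if (nrow(d) < 2L) return(NULL)
    data.frame(subject = d$subject[1], roi = d$roi[1], phase = d$phase[1],
               seq_type = d$seq_type[1],
               slope = unname(stats::coef(stats::lm(value ~ run_num, d))[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a long-format effects table as TSV
#'
#' @param effects data.frame of RSA effects.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_effects <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(run = "character"))
}
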