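# Single-trial beta-series estimation: nuisance denoising, per-trial
# HRF design matrices with a row-sum "fixed effect" column, and partial
# least squares extraction of trialwise activity estimates.

#' Project nuisance signals out of a time series
#'
#' Per-voxel least-squares residualization against the column space of
#' `nuisance` (intercept-spanning polynomial basis plus noise components).
#' A rank-deficient nuisance matrix triggers a warning and a pseudoinverse
#' projection (via the pivoted QR), which projects onto the achieved
#' column space.
#'
#' @param Y timepoints x voxels matrix (a vector is treated as one voxel).
#' @param nuisance timepoints x regressors matrix.
#' @return residual matrix with the dimensions of `Y`; residuals are
#'   orthogonal to every nuisance column.
#' @export
denoise <- function(Y, nuisance) {
  Y <- as.matrix(Y)
  nuisance <- as.matrix(nuisance)
  if (nrow(Y) != nrow(nuisance)) {
    stop_invalid("`Y` and `nuisance` must have the same number of rows")
  }
  qrN <- qr(nuisance)
  if (qrN$rank < ncol(nuisance)) {
    warning("nuisance matrix is rank-deficient (rank ", qrN$rank, " < ",
            ncol(nuisance), "); projecting onto its achieved column space")
  }
  qr.resid(qrN, Y)
}

#' Per-trial design matrix for one task phase
#'
#' One HRF-convolved regressor per trial of the target phase, each a
#' boxcar of the event's duration (the delay regressors therefore have
#' widths 3, 6 or 9 s matching each trial's delay), plus a "fixed effect"
#' column equal to the row-wise sum of the trial columns, which
#' regularizes the trialwise estimates under PLS.
#'
#' @param events event table (rows of [design_to_events()] for one run).
#' @param phase `"encoding"`, `"delay"` or `"probe"`.
#' @param tr repetition time in seconds.
#' @param n_timepoints number of volumes in the run.
#' @return Object of class `trial_design`: list with `X` (timepoints x
#'   (n_trials + 1), last column `fixed`), `trial_ids`, `phase`.
#' @export
build_trial_design <- function(events, phase, tr, n_timepoints) {
  ev <- events[events$trial_type == phase, , drop = FALSE]
  if (nrow(ev) == 0L) stop_invalid("no events of phase '", phase, "'")
  if (anyDuplicated(ev$trial_id)) {
    stop_invalid("duplicate trial events for phase '", phase, "'")
  }
  ev <- ev[order(ev$onset), , drop = FALSE]
  X <- event_regressors(ev, tr, n_timepoints)
  colnames(X) <- ev$trial_id
  X <- cbind(X, fixed = rowSums(X))
  structure(list(X = X, trial_ids = ev$trial_id, phase = phase),
            class = "trial_design")
}

# Univariate SIMPLS: regression coefficients of centered y on centered X
# with A latent components. At A = rank(X) the coefficients equal the
# (minimum-norm) least-squares solution.
simpls1 <- function(X, y, A) {
  p <- ncol(X)
  S <- crossprod(X, y)
  V <- matrix(0, p, A)
  R <- matrix(0, p, A)
  Q <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    r <- S
    t_sc <- X %*% r
    tn <- sqrt(sum(t_sc^2))
    if (!is.finite(tn) || tn < 1e-12) break
    t_sc <- t_sc / tn
    r <- r / tn
    pvec <- crossprod(X, t_sc)
    Q[a] <- sum(y * t_sc)
    R[, a] <- r
    v <- pvec
    if (a > 1L) {
      Vb <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vb %*% crossprod(Vb, pvec)
    }
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    S <- S - v %*% crossprod(v, S)
    a_used <- a
  }
  if (a_used == 0L) return(numeric(p))
  R[, seq_len(a_used), drop = FALSE] %*% Q[seq_len(a_used)]
}

#' Trialwise activity estimates by partial least squares
#'
#' For each voxel, fits a univariate PLS (SIMPLS) regression of the
#' denoised time series on the per-trial design matrix and extracts the
#' trial-column coefficients as the single-trial activity estimates.
#' Columns of `X` are centered (not variance-scaled) and the response is
#' centered per voxel, so beta units follow the data. At
#' `n_components = rank(X)` the coefficients coincide with the
#' (minimum-norm) ordinary least squares solution; smaller component
#' counts shrink the estimates. The fixed-effect coefficient is retained
#' in the `fixed_beta` attribute but excluded from the returned patterns.
#'
#' @param design a `trial_design` from [build_trial_design()], or a plain
#'   numeric design matrix (all columns then treated as trial columns).
#' @param Y timepoints x voxels matrix of denoised data.
#' @param n_components number of latent components (default 5); values
#'   above `rank(X)` are clipped with a warning.
#' @return Object of class `trial_betas`: list with `betas` (trials x
#'   voxels, rownames the trial ids), `trial_ids`, `phase`,
#'   `n_components`; attribute `fixed_beta` holds the fixed-effect
#'   coefficients per voxel when a `trial_design` is supplied.
#' @export
pls_betas <- function(design, Y, n_components = 5L) {
  has_fixed <- inherits(design, "trial_design")
  X <- if (has_fixed) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop_invalid("`design` and `Y` must have the same number of timepoints")
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  rk <- qr(Xc)$rank
  A <- as.integer(n_components)
  if (A < 1L) stop_invalid("`n_components` must be >= 1")
  if (A > rk) {
    warning("n_components = ", A, " exceeds rank(X) = ", rk, "; clipped")
    A <- rk
  }
  B <- matrix(0, ncol(X), ncol(Y))
  for (v in seq_len(ncol(Y))) {
    B[, v] <- simpls1(Xc, Yc[, v], A)
  }
  if (has_fixed) {
    betas <- B[-ncol(X), , drop = FALSE]
    fixed_beta <- B[ncol(X), ]
    ids <- design$trial_ids
    phase <- design$phase
  } else {
    betas <- B
    fixed_beta <- NULL
    ids <- colnames(X) %||% sprintf("col%d", seq_len(ncol(X)))
    phase <- NA_character_
  }
  rownames(betas) <- ids
  structure(
    list(betas = betas, trial_ids = ids, phase = phase, n_components = A),
    class = "trial_betas", fixed_beta = fixed_beta
  )
}

#' Single-trial betas for every phase of a simulated subject
#'
#' Runs the full estimation path per run: denoise against the run's
#' nuisance matrix, build the per-trial design for each phase, extract
#' PLS betas, and stack trials across runs in session order.
#'
#' @param sim a `sim_subject` from [simulate_subject()].
#' @param phases phases to estimate.
#' @param n_components PLS components (see [pls_betas()]); `NULL` uses the
#'   design rank (ordinary least squares limit).
#' @param denoise_design also residualize the trial design matrix against
#'   the nuisance matrix (Frisch-Waugh). The default `FALSE` denoises the
#'   time series only, which leaves a small low-frequency bias in the
#'   trial estimates but matches the beta-series procedure's contract;
#'   `TRUE` makes noiseless recovery exact.
#' @return named list (by phase) of `trial_betas` whose `betas` rows span
#'   all runs; a `run` vector maps rows to runs.
#' @export
subject_betas <- function(sim, phases = c("encoding", "delay", "probe"),
                          n_components = 5L, denoise_design = FALSE) {
  out <- lapply(phases, function(ph) NULL)
  names(out) <- phases
  acc <- lapply(phases, function(ph) list())
  names(acc) <- phases
  run_of <- lapply(phases, function(ph) integer(0))
  names(run_of) <- phases
  for (run in sim$runs) {
    Y <- t(run$data)
    Yres <- denoise(Y, run$nuisance)
    n_tp <- nrow(Y)
    for (ph in phases) {
      td <- build_trial_design(run$events, ph, run$tr_s, n_tp)
      if (denoise_design) {
        td$X <- qr.resid(qr(run$nuisance), td$X)
      }
      A <- n_components %||% qr(scale(td$X, TRUE, FALSE))$rank
      tb <- pls_betas(td, Yres, n_components = A)
      acc[[ph]] <- c(acc[[ph]], list(tb$betas))
      run_of[[ph]] <- c(run_of[[ph]], rep(run$run, nrow(tb$betas)))
    }
  }
  for (ph in phases) {
    betas <- do.call(rbind, acc[[ph]])
    out[[ph]] <- structure(
      list(betas = betas, trial_ids = rownames(betas), phase = ph,
           n_components = n_components, run = run_of[[ph]],
           roi = sim$runs[[1]]$roi),
      class = "trial_betas"
    )
  }
  out
}
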