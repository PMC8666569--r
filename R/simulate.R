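# Synthetic BOLD generator emulating the statistical structure the
# analysis assumes: phase-specific multivoxel response patterns whose
# sequence-specific component strengthens across runs for repeating
# sequences, superimposed on polynomial drift, shared nuisance components
# and AR(1) voxel noise, plus delay-dependent behavioural responses.

#' Simulation parameters
#'
#' Defaults describe the study conditions the generator emulates: TR of
#' 1.37 s, fifth-degree polynomial drift, five shared nuisance components,
#' AR(1) voxel noise, a pattern-stabilization schedule `w(r)` rising from
#' 0.2 to 0.8 across runs for repeating sequences (novel sequences get
#' `novel_structure_gain`, default 0), phase amplitudes ordered
#' encoding > delay > probe, and behavioural accuracy declining with
#' delay (0.631 / 0.568 / 0.504 at 3 / 6 / 9 s).
#'
#' Amplitudes are expressed in units of the voxel noise standard
#' deviation. `amp` scales the zero-mean multivoxel *pattern* carrying
#' sequence identity; `mean_amp` scales a uniform (univariate) activation
#' shared by all voxels of an ROI, optionally modulated per ROI by
#' `roi_gain` (named vector, default 1) so that ROIs with distinct
#' univariate phase profiles can be simulated.
#'
#' @param n_voxels named integer vector: voxels per ROI (names are ROI
#'   labels).
#' @param tr_s repetition time, seconds.
#' @param noise_sd marginal standard deviation of the AR(1) voxel noise.
#' @param ar1_rho lag-1 autocorrelation in `[0, 1)`.
#' @param drift_poly_degree degree of the per-run polynomial drift.
#' @param drift_sd per-timepoint standard deviation of the drift signal.
#' @param n_noise_components number of shared (smooth) nuisance components.
#' @param component_sd standard deviation of voxel loadings on components.
#' @param amp named peak amplitudes of the sequence pattern per phase
#'   (event regressors are unit-peak-normalized in the generator, so the
#'   amplitude ordering is independent of event duration).
#' @param mean_amp named peak amplitudes of the uniform ROI activation
#'   per phase.
#' @param roi_gain optional named per-ROI multiplier on `mean_amp`.
#' @param stabilization numeric vector over runs, or function
#'   `(run, n_runs) -> w`, giving the repeat-sequence pattern correlation
#'   schedule `w(r)` in `[0, 1]`, non-decreasing.
#' @param novel_structure_gain pattern correlation for novel sequences.
#' @param p_correct named vector of response accuracy by delay (seconds).
#' @param seed optional integer seed for [simulate_subject()].
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_voxels = c(aud = 30L),
                       tr_s = 1.37,
                       noise_sd = 1,
                       ar1_rho = 0.3,
                       drift_poly_degree = 5L,
                       drift_sd = 1,
                       n_noise_components = 5L,
                       component_sd = 1,
                       amp = c(encoding = 3, delay = 1.2, probe = 0.9),
                       mean_amp = c(encoding = 1.5, delay = 0.8, probe = 0.8),
                       roi_gain = NULL,
                       stabilization = function(run, n_runs) {
                         seq(0.2, 0.8, length.out = n_runs)[run]
                       },
                       novel_structure_gain = 0,
                       p_correct = c("3" = 0.631, "6" = 0.568, "9" = 0.504),
                       seed = NULL) {
  if (ar1_rho < 0 || ar1_rho >= 1) stop_invalid("`ar1_rho` must be in [0, 1)")
  if (any(amp < 0) || any(mean_amp < 0)) {
    stop_invalid("phase amplitudes must be non-negative")
  }
  if (is.null(names(n_voxels))) {
    names(n_voxels) <- sprintf("roi%02d", seq_along(n_voxels))
  }
  structure(
    list(n_voxels = n_voxels, tr_s = tr_s, noise_sd = noise_sd,
         ar1_rho = ar1_rho, drift_poly_degree = as.integer(drift_poly_degree),
         drift_sd = drift_sd,
         n_noise_components = as.integer(n_noise_components),
         component_sd = component_sd, amp = amp, mean_amp = mean_amp,
         roi_gain = roi_gain, stabilization = stabilization,
         novel_structure_gain = novel_structure_gain,
         p_correct = p_correct, seed = seed),
    class = "sim_params"
  )
}

# Resolve w(r) to a numeric vector over runs and validate it.
stabilization_schedule <- function(params, n_runs) {
  s <- params$stabilization
  w <- if (is.function(s)) {
    vapply(seq_len(n_runs), function(r) s(r, n_runs), numeric(1))
  } else {
    rep_len(s, n_runs)
  }
  if (any(w < 0 | w > 1)) stop_invalid("stabilization w(r) must be in [0, 1]")
  if (any(diff(w) < -1e-12)) {
    stop_invalid("stabilization w(r) must be non-decreasing")
  }
  w
}

# Unit-norm random vector per ROI block.
roi_unit_vector <- function(n_voxels) {
  unlist(lapply(n_voxels, function(nv) {
    v <- stats::rnorm(nv)
    v / sqrt(sum(v^2))
  }), use.names = FALSE)
}

#' Simulate one subject's BOLD runs and behaviour
#'
#' For each trial and phase the multivoxel response pattern is
#' `amp[phase] * (s * template(seq) + sqrt(1 - s^2) * fresh)` with
#' `s = w(run)` for repeat trials and `s = novel_structure_gain` for novel
#' trials, plus `mean_amp[phase] * roi_gain` uniformly over each ROI's
#' voxels. `template(seq)` is a fixed unit-norm pattern per sequence and
#' `fresh` an independent unit-norm draw per event, so `s` is the
#' correlation between a trial's pattern and the sequence template.
#' Patterns are convolved with the canonical HRF at the event onsets and
#' durations and summed with per-run polynomial drift, shared smooth
#' nuisance components with random voxel loadings, and AR(1) voxel noise.
#' Behavioural responses are drawn per trial with accuracy
#' `p_correct[delay]`.
#'
#' @param design an `experiment_design` from [build_design()].
#' @param params a [sim_params()] object.
#' @return list of class `sim_subject` with elements `runs` (list of
#'   `bold_run`: `data` voxels x timepoints, `tr_s`, `run`, `roi` labels
#'   per voxel, `nuisance` timepoints x regressors known to the estimator,
#'   `events`, `truth`), `behavior` (per-trial responses) and `params`.
#' @export
simulate_subject <- function(design, params = sim_params()) {
  phases <- c("encoding", "delay", "probe")
  if (!all(phases %in% names(params$amp)) ||
      !all(phases %in% names(params$mean_amp))) {
    stop_invalid("`amp` and `mean_amp` must be named encoding/delay/probe")
  }
  if (!all(as.character(design$delays_s) %in% names(params$p_correct))) {
    stop_invalid("`p_correct` must name every delay level in the design")
  }
  with_seed(params$seed, {
    nv <- params$n_voxels
    n_vox <- sum(nv)
    roi <- rep(names(nv), nv)
    gain <- rep(1, length(nv))
    names(gain) <- names(nv)
    if (!is.null(params$roi_gain)) gain[names(params$roi_gain)] <- params$roi_gain
    gain_vox <- gain[roi]
    w <- stabilization_schedule(params, design$n_runs)
    ev_all <- design_to_events(design)

    templates <- lapply(design$sequences, function(s) roi_unit_vector(nv))

    runs <- vector("list", design$n_runs)
    for (r in seq_len(design$n_runs)) {
      ev <- ev_all[ev_all$run == r, ]
      tr_rows <- design$trials[design$trials$run == r, ]
      run_dur <- max(tr_rows$onset_s + 3 + tr_rows$delay_s + 3 + tr_rows$iti_s)
      n_tp <- ceiling(run_dur / params$tr_s)

      # Per-event response patterns (events x voxels).
      P <- matrix(0, nrow(ev), n_vox)
      for (k in seq_len(nrow(ev))) {
        stype <- ev$seq_type[k]
        s_coef <- if (stype == "repeat") w[r] else params$novel_structure_gain
        tmpl <- templates[[ev$seq_id[k]]]
        fresh <- roi_unit_vector(nv)
        ph <- ev$trial_type[k]
        P[k, ] <- params$amp[[ph]] *
          (s_coef * tmpl + sqrt(1 - s_coef^2) * fresh) +
          params$mean_amp[[ph]] * gain_vox
      }
      # Regressors are normalized to unit peak so that `amp` is the peak
      # BOLD amplitude of an event regardless of its duration (otherwise
      # longer delay boxcars would integrate to larger responses and
      # invert the intended encoding > delay > probe ordering).
      R <- event_regressors(ev, params$tr_s, n_tp)
      R <- sweep(R, 2, pmax(apply(R, 2, max), 1e-12), "/")
      signal <- R %*% P

      # Per-run polynomial drift: orthonormal basis, per-voxel weights.
      B <- stats::poly(seq_len(n_tp), params$drift_poly_degree)
      Wd <- matrix(stats::rnorm(ncol(B) * n_vox,
                                sd = params$drift_sd * sqrt(n_tp)),
                   ncol(B), n_vox)
      drift <- B %*% Wd

      # Shared smooth nuisance components with random voxel loadings.
      k_comp <- params$n_noise_components
      C <- matrix(0, n_tp, k_comp)
      if (k_comp > 0) {
        for (k in seq_len(k_comp)) {
          z <- stats::filter(stats::rnorm(n_tp + 20), rep(1, 10) / 10,
                             sides = 1)
          z <- z[!is.na(z)][seq_len(n_tp)]
          C[, k] <- as.numeric(scale(z))
        }
      }
      L <- matrix(stats::rnorm(k_comp * n_vox, sd = params$component_sd),
                  k_comp, n_vox)
      comp <- if (k_comp > 0) C %*% L else matrix(0, n_tp, n_vox)

      # AR(1) voxel noise with marginal sd noise_sd.
      noise <- matrix(0, n_tp, n_vox)
      if (params$noise_sd > 0) {
        innov_sd <- params$noise_sd * sqrt(1 - params$ar1_rho^2)
        E <- matrix(stats::rnorm(n_tp * n_vox, sd = innov_sd), n_tp, n_vox)
        noise <- apply(E, 2, function(e) {
          as.numeric(stats::filter(e, params$ar1_rho, method = "recursive"))
        })
      }

      nuisance <- cbind(intercept = 1, B, C)
      colnames(nuisance) <- c("intercept",
                              paste0("poly", seq_len(ncol(B))),
                              if (k_comp > 0) paste0("comp", seq_len(k_comp)))

      runs[[r]] <- structure(
        list(data = t(signal + drift + comp + noise),
             tr_s = params$tr_s, run = r, roi = roi,
             nuisance = nuisance, events = ev,
             truth = list(patterns = P,
                          event_index = ev[, c("trial_id", "trial_type",
                                               "seq_id", "seq_type")],
                          stabilization = w[r])),
        class = "bold_run"
      )
    }

    tr <- design$trials
    p_corr <- params$p_correct[as.character(tr$delay_s)]
    correct <- stats::rbinom(nrow(tr), 1, p_corr) == 1
    response <- ifelse(correct, tr$probe_type,
                       ifelse(tr$probe_type == "match", "mismatch", "match"))
    behavior <- data.frame(
      run = tr$run, trial = tr$trial, trial_id = tr$trial_id,
      seq_type = tr$seq_type, probe_type = tr$probe_type,
      delay_s = tr$delay_s, response = response, correct = correct,
      stringsAsFactors = FALSE
    )

    structure(list(runs = runs, behavior = behavior, params = params,
                   templates = templates),
              class = "sim_subject")
  })
}

#' @export
print.sim_subject <- function(x, ...) {
  cat(sprintf("<sim_subject> %d runs, %d voxels (%s)\n", length(x$runs),
              sum(x$params$n_voxels),
              paste(names(x$params$n_voxels), collapse = ", ")))
  invisible(x)
}
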