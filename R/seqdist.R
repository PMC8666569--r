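# Earth Mover's Distance between tone sequences and model RDM assembly.
#
# A sequence is represented as nine unit masses (1/9 each) at coordinates
# (serial position, pitch). The ground cost between a tone at position i in
# one sequence and a tone at position j in the other is a weighted L1
# combination of serial-position distance and pitch distance. With equal
# unit masses the balanced transportation problem is an assignment
# problem, which is solved exactly.

#' Ground metric for the tone-sequence Earth Mover's Distance
#'
#' @param position_weight cost per unit of serial-position displacement.
#' @param pitch_weight cost per unit of pitch displacement.
#' @param pitch_scale pitch coordinate: `"pool_steps"` (default; number of
#'   proportional steps above `ref_hz`, i.e. `log(f/ref_hz)/log(step_ratio)`),
#'   `"semitones"` (`12 log2(f/ref_hz)`), or `"log_hz"` (`log f`).
#' @param ref_hz,step_ratio reference frequency and step ratio defining the
#'   pool-step / semitone coordinates.
#' @return An object of class `ground_metric`.
#' @export
ground_metric <- function(position_weight = 1, pitch_weight = 1,
                          pitch_scale = c("pool_steps", "semitones", "log_hz"),
                          ref_hz = 300, step_ratio = 1.3) {
  pitch_scale <- match.arg(pitch_scale)
  if (position_weight < 0 || pitch_weight < 0) {
    stop_invalid("metric weights must be non-negative")
  }
  if (position_weight == 0 && pitch_weight == 0) {
    stop_invalid("at least one metric weight must be positive")
  }
  structure(
    list(position_weight = position_weight, pitch_weight = pitch_weight,
         pitch_scale = pitch_scale, ref_hz = ref_hz, step_ratio = step_ratio),
    class = "ground_metric"
  )
}

# Map frequencies (Hz) to the metric's pitch coordinate.
pitch_coord <- function(freqs_hz, metric) {
  switch(metric$pitch_scale,
    pool_steps = log(freqs_hz / metric$ref_hz) / log(metric$step_ratio),
    semitones = 12 * log2(freqs_hz / metric$ref_hz),
    log_hz = log(freqs_hz)
  )
}

#' Exact solution of the linear assignment problem
#'
#' Shortest-augmenting-path (Jonker-Volgenant style) algorithm; returns
#' for each row the column index of the cost-minimal perfect matching.
#' O(n^3); exact for any finite square cost matrix.
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `a` with `a[i]` the column matched to row `i`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop_invalid("`cost` must be square")
  if (any(!is.finite(cost))) stop_invalid("`cost` must be finite")
  if (n == 1L) return(1L)
  # Columns are indexed 1..n+1 with column 1 a virtual start column.
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials (incl. virtual)
  p <- integer(n + 1L)     # p[j]: row currently matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(n + 1L)) assign[p[j]] <- j - 1L
  assign
}

#' Earth Mover's Distance between two tone sequences
#'
#' Places unit mass 1/n on each tone at coordinates (serial position,
#' pitch) and solves the balanced transportation problem under the ground
#' cost `position_weight * |i - j| + pitch_weight * |p_a(i) - p_b(j)|`.
#' With equal masses the optimum is attained at an assignment, found
#' exactly. The distance is symmetric, zero iff the sequences are
#' identical (for all-distinct tones), and satisfies the triangle
#' inequality. Moving tones of different frequency across larger
#' serial-position distances is costlier.
#'
#' @param a,b `tone_sequence` objects or numeric frequency vectors of
#'   equal length (Hz).
#' @param metric a [ground_metric()].
#' @return non-negative scalar dissimilarity.
#' @examples
#' pool <- build_tone_pool()
#' s <- make_sequence(pool, seed = 1)
#' sequence_emd(s, s)  # 0
#' @export
sequence_emd <- function(a, b, metric = ground_metric()) {
  fa <- if (inherits(a, "tone_sequence")) a$freqs_hz else a
  fb <- if (inherits(b, "tone_sequence")) b$freqs_hz else b
  n <- length(fa)
  if (length(fb) != n) stop_invalid("sequences must have equal length")
  pa <- pitch_coord(fa, metric)
  pb <- pitch_coord(fb, metric)
  pos <- seq_len(n)
  cost <- metric$position_weight * abs(outer(pos, pos, "-")) +
    metric$pitch_weight * abs(outer(pa, pb, "-"))
  a_idx <- solve_assignment(cost)
  sum(cost[cbind(pos, a_idx)]) / n
}

#' Model RDM over the study sequences of one trial subset
#'
#' Pairwise [sequence_emd()] over all trials of the requested sequence
#' type, ordered to match session trial order. For the repeat subset,
#' pairs of trials presenting the identical repeating sequence have
#' dissimilarity exactly 0, and the off-diagonal takes at most three
#' distinct positive values (the S1-S2, S1-S3, S2-S3 distances).
#'
#' @param design an `experiment_design`.
#' @param subset `"repeat"` or `"novel"`.
#' @param metric a [ground_metric()].
#' @param trial_ids optional subset of trial identifiers (e.g. one run's);
#'   default all trials of the requested type.
#' @return Object of class `model_rdm`: list with `matrix` (symmetric,
#'   zero diagonal, trial ids as dimnames), `trial_ids`, `kind`, `metric`.
#' @export
build_model_rdm <- function(design, subset = c("repeat", "novel"),
                            metric = ground_metric(), trial_ids = NULL) {
  subset <- match.arg(subset)
  tr <- design$trials[design$trials$seq_type == subset, ]
  if (!is.null(trial_ids)) tr <- tr[tr$trial_id %in% trial_ids, ]
  if (nrow(tr) == 0L) stop_invalid("no trials in subset '", subset, "'")
  ids <- tr$trial_id
  seq_ids <- tr$seq_id
  uniq <- unique(seq_ids)
  # Distances depend only on the underlying sequences: compute once per
  # unique sequence pair, then expand to trials.
  d_uniq <- matrix(0, length(uniq), length(uniq),
                   dimnames = list(uniq, uniq))
  if (length(uniq) > 1L) {
    for (i in seq_len(length(uniq) - 1L)) {
      for (j in (i + 1L):length(uniq)) {
        d <- sequence_emd(design$sequences[[uniq[i]]],
                          design$sequences[[uniq[j]]], metric)
        d_uniq[i, j] <- d_uniq[j, i] <- d
      }
    }
  }
  m <- d_uniq[seq_ids, seq_ids, drop = FALSE]
  dimnames(m) <- list(ids, ids)
  structure(
    list(matrix = m, trial_ids = ids, kind = subset, metric = metric),
    class = "model_rdm"
  )
}

#' @export
print.model_rdm <- function(x, ...) {
  cat(sprintf("<model_rdm> kind=%s, %d trials\n", x$kind, length(x$trial_ids)))
  invisible(x)
}

#' Write an RDM as CSV (square) or long TSV
#'
#' The square form is a CSV with trial ids as header and first column;
#' the long form is a TSV with columns trial_i, trial_j, dissimilarity
#' over the lower triangle.
#'
#' @param rdm a `model_rdm` or `neural_rdm`.
#' @param path output path.
#' @param format `"square"` (CSV) or `"long"` (TSV).
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path, format = c("square", "long")) {
  format <- match.arg(format)
  m <- rdm$matrix
  if (format == "square") {
    df <- data.frame(trial_id = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    lt <- which(lower.tri(m), arr.ind = TRUE)
    df <- data.frame(trial_i = rownames(m)[lt[, 1]],
                     trial_j = colnames(m)[lt[, 2]],
                     dissimilarity = m[lt])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
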