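# Stimulus and design generation for the Hebb-repetition tone-sequence task.
#
# The task presents a nine-tone study sequence, a silent retention delay of
# 3, 6 or 9 s, and a probe sequence that is either identical (match) or has
# one pair of adjacent tones swapped (mismatch). Three study sequences
# (S1, S2, S3) covertly repeat throughout the session, interleaved with
# novel filler sequences.

#' Build a geometric tone-frequency pool
#'
#' Constructs the maximal ladder of pure-tone frequencies
#' `base_hz * step_ratio^k` that fits inside `[base_hz, max_hz]`. With the
#' defaults (300 Hz, 30% proportional increments, 2600 Hz ceiling) the pool
#' contains nine frequencies, one per serial position of a sequence.
#'
#' @param base_hz lowest frequency in Hz (> 0).
#' @param step_ratio multiplicative increment between neighbouring
#'   frequencies (> 1).
#' @param max_hz upper frequency bound in Hz (>= `base_hz`).
#' @return An object of class `tone_pool` with fields `frequencies`,
#'   `base_hz`, `step_ratio`, `max_hz`.
#' @examples
#' pool <- build_tone_pool()
#' length(pool$frequencies)  # 9
#' @export
build_tone_pool <- function(base_hz = 300, step_ratio = 1.3, max_hz = 2600) {
  if (!is.numeric(base_hz) || base_hz <= 0) {
    stop_invalid("`base_hz` must be a positive number")
  }
  if (!is.numeric(step_ratio) || step_ratio <= 1) {
    stop_invalid("`step_ratio` must be > 1")
  }
  if (!is.numeric(max_hz) || max_hz < base_hz) {
    stop_invalid("`max_hz` must be >= `base_hz`")
  }
  n <- floor(log(max_hz / base_hz) / log(step_ratio) + 1e-9) + 1L
  freqs <- base_hz * step_ratio^(seq_len(n) - 1L)
  structure(
    list(frequencies = freqs, base_hz = base_hz, step_ratio = step_ratio,
         max_hz = max_hz),
    class = "tone_pool"
  )
}

#' @export
print.tone_pool <- function(x, ...) {
  cat(sprintf("<tone_pool> %d frequencies, %.6g..%.6g Hz (ratio %.6g)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$step_ratio))
  invisible(x)
}

new_tone_sequence <- function(freqs_hz, seq_id, tone_dur_s, gap_s) {
  structure(
    list(freqs_hz = freqs_hz, seq_id = seq_id,
         tone_dur_s = tone_dur_s, gap_s = gap_s),
    class = "tone_sequence"
  )
}

#' Total acoustic duration of a tone sequence
#'
#' Nine tones of `tone_dur_s` separated by eight silent gaps of `gap_s`;
#' 3.0 s at the defaults (200 ms tones, 150 ms gaps).
#'
#' @param seq a `tone_sequence`.
#' @return duration in seconds.
#' @export
sequence_duration <- function(seq) {
  n <- length(seq$freqs_hz)
  n * seq$tone_dur_s + (n - 1) * seq$gap_s
}

#' Draw a nine-tone sequence from a pool
#'
#' Under the default `"permutation"` policy the sequence is a pseudorandom
#' shuffle of the nine pool frequencies (all tones distinct);
#' `"with_replacement"` samples each position independently.
#'
#' @param pool a `tone_pool`.
#' @param seed optional integer seed; the draw is deterministic given the
#'   seed and the caller's RNG state is restored.
#' @param policy `"permutation"` (default) or `"with_replacement"`.
#' @param seq_id label for the sequence.
#' @param n_tones sequence length (default 9).
#' @param tone_dur_s,gap_s tone and gap durations in seconds.
#' @return A `tone_sequence`.
#' @export
make_sequence <- function(pool, seed = NULL,
                          policy = c("permutation", "with_replacement"),
                          seq_id = "novel", n_tones = 9L,
                          tone_dur_s = 0.2, gap_s = 0.15) {
  policy <- match.arg(policy)
  freqs <- pool$frequencies
  if (policy == "permutation" && length(freqs) < n_tones) {
    stop_invalid("pool has fewer than ", n_tones,
                 " frequencies; cannot draw a permutation sequence")
  }
  draw <- with_seed(seed, {
    if (policy == "permutation") {
      freqs[sample.int(length(freqs), n_tones, replace = FALSE)]
    } else {
      freqs[sample.int(length(freqs), n_tones, replace = TRUE)]
    }
  })
  new_tone_sequence(draw, seq_id, tone_dur_s, gap_s)
}

#' Create a mismatch probe by swapping two adjacent tones
#'
#' Swaps the tones at serial positions `position` and `position + 1`,
#' altering the ordering of the sequence while retaining the multiset of
#' frequencies. Applying the same transposition twice restores the
#' original sequence.
#'
#' @param seq a `tone_sequence`.
#' @param position 1-based position of the first element of the swapped
#'   pair (1..length-1), or `NULL` to draw uniformly among positions whose
#'   two adjacent tones differ.
#' @param seed optional seed used only when `position` is `NULL`.
#' @return A `tone_sequence` with `seq_id` suffixed `"_probe"`.
#' @export
transpose_probe <- function(seq, position = NULL, seed = NULL) {
  f <- seq$freqs_hz
  n <- length(f)
  if (is.null(position)) {
    valid <- which(f[-n] != f[-1])
    if (length(valid) == 0L) {
      stop_invalid("no valid probe: all adjacent tone pairs are equal")
    }
    position <- with_seed(seed, valid[sample.int(length(valid), 1L)])
  }
  if (!is.numeric(position) || position < 1L || position > n - 1L) {
    stop_invalid("`position` must be in 1..", n - 1L)
  }
  position <- as.integer(position)
  f[c(position, position + 1L)] <- f[c(position + 1L, position)]
  out <- seq
  out$freqs_hz <- f
  out$seq_id <- paste0(seq$seq_id, "_probe")
  out
}

#' Condition label for a trial
#'
#' The crossing of sequence type, probe type, and delay yields 12 distinct
#' condition labels (e.g. `"repeat_match_3"`).
#'
#' @param seq_type `"repeat"` or `"novel"`.
#' @param probe_type `"match"` or `"mismatch"`.
#' @param delay_s delay in seconds.
#' @return character label.
#' @export
condition_label <- function(seq_type, probe_type, delay_s) {
  paste(seq_type, probe_type, delay_s, sep = "_")
}

# Draw distinct permutation sequences, rejecting collisions with `avoid`
# (a list of frequency vectors).
draw_distinct_sequences <- function(pool, n, ids, avoid = list(),
                                    tone_dur_s, gap_s, max_tries = 1000L) {
  out <- vector("list", n)
  seen <- lapply(avoid, function(x) paste(x, collapse = ","))
  for (k in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      s <- make_sequence(pool, seq_id = ids[k],
                         tone_dur_s = tone_dur_s, gap_s = gap_s)
      key <- paste(s$freqs_hz, collapse = ",")
      if (!key %in% seen) break
      if (try == max_tries) {
        stop_invalid("could not draw ", n, " distinct sequences")
      }
    }
    seen <- c(seen, key)
    out[[k]] <- s
  }
  names(out) <- ids
  out
}

#' Generate a constrained Hebb-repetition experiment design
#'
#' Builds the full session: half of each run's trials present one of the
#' three repeating study sequences (S1, S2, S3, cycling in that order so
#' the same repeating sequence never occurs on two successive trials, run
#' boundaries included), and half present unique novel sequences. Probe
#' type (match/mismatch) and delay (3/6/9 s) are balanced within every
#' sequence-type cell. At the defaults (8 runs of 18 trials) this yields
#' 144 trials: 36 per sequence-type x probe-type cell, 24 study trials per
#' repeating sequence, and 12 trials per condition label.
#'
#' Trial timing accumulates a 3 s encoding phase, the trial's delay, a 3 s
#' probe phase, and a uniform inter-trial interval jittered on
#' `iti_range_s` (mean 7 s at the defaults). Onsets restart at 0 within
#' each run and are stored at millisecond precision.
#'
#' @param n_runs number of scanning runs (default 8).
#' @param trials_per_run trials per run (default 18); must be even with
#'   `trials_per_run / 2` divisible by 3, and the per-cell counts must be
#'   divisible by the number of probe-type x delay combinations.
#' @param seed integer RNG seed; the full design is deterministic given it.
#' @param iti_range_s inter-trial interval range in seconds.
#' @param delays_s the delay levels in seconds.
#' @param pool tone pool; defaults to `build_tone_pool()`.
#' @param tone_dur_s,gap_s tone and gap durations in seconds.
#' @return An object of class `experiment_design`: a list with `trials`
#'   (one row per trial: run, trial, trial_id, onset_s, seq_type, seq_id,
#'   probe_type, probe_swap_pos, delay_s, iti_s, condition), `sequences`
#'   (named list of `tone_sequence`s), and the generating parameters.
#' @export
build_design <- function(n_runs = 8L, trials_per_run = 18L, seed = 1L,
                         iti_range_s = c(4, 10), delays_s = c(3, 6, 9),
                         pool = build_tone_pool(),
                         tone_dur_s = 0.2, gap_s = 0.15) {
  n_runs <- as.integer(n_runs)
  trials_per_run <- as.integer(trials_per_run)
  if (n_runs < 1L || trials_per_run < 2L) {
    stop_invalid("`n_runs` and `trials_per_run` must be positive")
  }
  if (trials_per_run %% 2L != 0L) {
    stop_invalid("`trials_per_run` must be even (half repeat, half novel)")
  }
  n_rep_run <- trials_per_run %/% 2L
  if (n_rep_run %% 3L != 0L) {
    stop_invalid("repeat trials per run (", n_rep_run,
                 ") must be divisible by 3 so S1,S2,S3 can cycle")
  }
  n_cells <- 2L * length(delays_s)              # probe_type x delay
  per_seq <- n_runs * n_rep_run %/% 3L          # study trials per repeating seq
  n_novel <- n_runs * n_rep_run
  if (per_seq %% n_cells != 0L || n_novel %% n_cells != 0L) {
    stop_invalid("trial counts cannot be balanced over probe-type x delay ",
                 "cells; choose counts divisible by ", n_cells)
  }

  with_seed(seed, {
    rep_ids <- c("S1", "S2", "S3")
    rep_seqs <- draw_distinct_sequences(pool, 3L, rep_ids,
                                        tone_dur_s = tone_dur_s, gap_s = gap_s)
    novel_ids <- sprintf("N%03d", seq_len(n_novel))
    novel_seqs <- draw_distinct_sequences(
      pool, n_novel, novel_ids,
      avoid = lapply(rep_seqs, `[[`, "freqs_hz"),
      tone_dur_s = tone_dur_s, gap_s = gap_s
    )

    cells <- expand.grid(probe_type = c("match", "mismatch"),
                         delay_s = delays_s,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # Balanced, shuffled attribute stacks per repeating sequence and for
    # the novel trials.
    attr_stack <- function(n_total) {
      k <- n_total %/% nrow(cells)
      idx <- rep(seq_len(nrow(cells)), each = k)
      cells[sample(idx), , drop = FALSE]
    }
    rep_attrs <- lapply(rep_ids, function(id) attr_stack(per_seq))
    names(rep_attrs) <- rep_ids
    novel_attrs <- attr_stack(n_novel)

    rep_taken <- c(S1 = 0L, S2 = 0L, S3 = 0L)
    novel_taken <- 0L
    trials <- vector("list", n_runs * trials_per_run)
    row <- 0L
    for (r in seq_len(n_runs)) {
      # Which of the run's slots hold repeat trials; the repeats fill those
      # slots in strict S1,S2,S3 cycling order, which guarantees that no
      # two successive trials share a repeating study sequence.
      rep_slots <- sort(sample.int(trials_per_run, n_rep_run))
      cycle <- rep(rep_ids, n_rep_run %/% 3L)
      novel_order <- sample.int(n_rep_run)  # shuffle novel assignment
      t_now <- 0
      ci <- 0L; ni <- 0L
      for (tr in seq_len(trials_per_run)) {
        if (tr %in% rep_slots) {
          ci <- ci + 1L
          sid <- cycle[ci]
          rep_taken[sid] <- rep_taken[sid] + 1L
          att <- rep_attrs[[sid]][rep_taken[sid], ]
          stype <- "repeat"
        } else {
          ni <- ni + 1L
          sid <- novel_ids[novel_taken + novel_order[ni]]
          att <- novel_attrs[novel_taken + novel_order[ni], ]
          stype <- "novel"
        }
        study <- if (stype == "repeat") rep_seqs[[sid]] else novel_seqs[[sid]]
        swap_pos <- NA_integer_
        if (att$probe_type == "mismatch") {
          valid <- which(study$freqs_hz[-length(study$freqs_hz)] !=
                           study$freqs_hz[-1])
          swap_pos <- valid[sample.int(length(valid), 1L)]
        }
        iti <- round(stats::runif(1, iti_range_s[1], iti_range_s[2]), 3)
        row <- row + 1L
        trials[[row]] <- data.frame(
          run = r, trial = tr, trial_id = trial_id(r, tr),
          onset_s = round(t_now, 3),
          seq_type = stype, seq_id = sid,
          probe_type = att$probe_type, probe_swap_pos = swap_pos,
          delay_s = att$delay_s, iti_s = iti,
          condition = condition_label(stype, att$probe_type, att$delay_s),
          stringsAsFactors = FALSE
        )
        t_now <- t_now + 3 + att$delay_s + 3 + iti
      }
      novel_taken <- novel_taken + n_rep_run
    }
    trials <- do.call(rbind, trials)

    design <- structure(
      list(trials = trials,
           sequences = c(rep_seqs, novel_seqs),
           repeating_ids = rep_ids,
           pool = pool, n_runs = n_runs, trials_per_run = trials_per_run,
           tone_dur_s = tone_dur_s, gap_s = gap_s,
           iti_range_s = iti_range_s, delays_s = delays_s, seed = seed),
      class = "experiment_design"
    )
    validate_design(design)
    design
  })
}

# Internal consistency checks; errors if the generator produced an invalid
# design (should not happen by construction).
validate_design <- function(design) {
  tr <- design$trials
  rep_rows <- tr[tr$seq_type == "repeat", ]
  sid <- rep(NA_character_, nrow(tr))
  sid[tr$seq_type == "repeat"] <- tr$seq_id[tr$seq_type == "repeat"]
  adjacent_same <- !is.na(sid[-1]) & !is.na(sid[-length(sid)]) &
    sid[-1] == sid[-length(sid)]
  if (any(adjacent_same)) {
    stop_invalid("design infeasible: repeated study sequence on successive trials")
  }
  invisible(design)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %d runs x %d trials (seed %s)\n",
              x$n_runs, x$trials_per_run, format(x$seed)))
  print(table(x$trials$seq_type, x$trials$probe_type))
  invisible(x)
}

#' Probe sequence presented on a trial
#'
#' Reconstructs the probe: identical to the study sequence for match
#' trials, the stored adjacent transposition for mismatch trials.
#'
#' @param design an `experiment_design`.
#' @param trial_id trial identifier (e.g. `"r1_t03"`).
#' @return A `tone_sequence`.
#' @export
probe_sequence <- function(design, trial_id) {
  row <- design$trials[design$trials$trial_id == trial_id, ]
  if (nrow(row) != 1L) stop_invalid("unknown trial_id: ", trial_id)
  study <- design$sequences[[row$seq_id]]
  if (row$probe_type == "match") study
  else transpose_probe(study, position = row$probe_swap_pos)
}

#' Expand a design into a long event table
#'
#' One row per trial phase (encoding, delay, probe) with onset and
#' duration in seconds, in the style of a BIDS events table with extra
#' columns identifying the trial. Onsets are relative to run start.
#'
#' @param design an `experiment_design`.
#' @return data.frame with columns onset, duration, trial_type, run,
#'   trial, trial_id, seq_id, seq_type, probe_type, delay_s.
#' @export
design_to_events <- function(design) {
  tr <- design$trials
  phase <- function(type, onset, duration) {
    data.frame(onset = round(onset, 3), duration = round(duration, 3),
               trial_type = type, run = tr$run, trial = tr$trial,
               trial_id = tr$trial_id, seq_id = tr$seq_id,
               seq_type = tr$seq_type, probe_type = tr$probe_type,
               delay_s = tr$delay_s, stringsAsFactors = FALSE)
  }
  ev <- rbind(
    phase("encoding", tr$onset_s, 3),
    phase("delay", tr$onset_s + 3, tr$delay_s),
    phase("probe", tr$onset_s + 3 + tr$delay_s, 3)
  )
  ev <- ev[order(ev$run, ev$onset), ]
  rownames(ev) <- NULL
  ev
}

#' Write / read an events table as tab-separated text
#'
#' UTF-8, POSIX newlines, onsets and durations printed with 3 decimals.
#' `read_events(write_events(ev, f))` reproduces `ev` exactly because the
#' design stores timing at millisecond precision.
#'
#' @param events data.frame from [design_to_events()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- events
  ev$onset <- sprintf("%.3f", ev$onset)
  ev$duration <- sprintf("%.3f", ev$duration)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(ev, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  ev$onset <- as.numeric(ev$onset)
  ev$duration <- as.numeric(ev$duration)
  ev
}
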