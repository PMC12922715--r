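# Trial-table schema, delimited readers/writers, and the filtering and
# grouping rules (practice removal, RT median split, correctness series)
# that feed the consistency and psychometric stages.

#' Marker for a missed response deadline
#' @export
NO_RESPONSE <- "NO_RESPONSE"

#' Allowed corruption condition labels
#' @export
CORRUPTION_LEVELS <- c("none", "noise", "lowpass", "grayscale")

#' Default presentation-frame design set (120 Hz display)
#' @export
DESIGN_FRAMES <- c(1L, 2L, 4L, 8L, 16L, 32L)

TRIAL_COLUMNS <- c("observer_id", "session", "round", "block", "set_index",
                   "trial_index", "image_id", "true_class", "response_class",
                   "presentation_frames", "presentation_ms", "corruption",
                   "rt_ms", "is_practice", "is_repeat")

#' Convert display frames to milliseconds
#'
#' @param frames frame counts (>= 1).
#' @param refresh_hz display refresh rate; default 120 Hz, so one frame is
#'   8.33 ms and 32 frames are 266.67 ms.
#' @return Durations in ms.
#' @export
frames_to_ms <- function(frames, refresh_hz = 120) {
  stopifnot(all(frames >= 1), refresh_hz > 0)
  frames * 1000 / refresh_hz
}

#' Validate a trial table
#'
#' Checks the schema: required columns, class labels among the 8
#' superclasses (plus `NO_RESPONSE` for responses), frames in the design
#' set, `presentation_ms` consistent with the frame count at the given
#' refresh rate (within 0.01 ms), and positive reaction times where present.
#' Errors list the offending rows.
#'
#' @param trials data frame.
#' @param design_frames allowed presentation-frame values.
#' @param refresh_hz display refresh rate in Hz.
#' @return The validated table, invisibly unchanged.
#' @export
validate_trials <- function(trials, design_frames = DESIGN_FRAMES,
                            refresh_hz = 120) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  offending <- function(bad, what) {
    if (any(bad)) {
      stop(what, " in row(s): ",
           paste(utils::head(which(bad), 10L), collapse = ", "),
           if (sum(bad) > 10L) sprintf(" (and %d more)", sum(bad) - 10L),
           call. = FALSE)
    }
  }
  offending(!trials$true_class %in% SUPERCLASSES, "unknown true_class label")
  offending(!trials$response_class %in% c(SUPERCLASSES, NO_RESPONSE),
            "unknown response_class label")
  offending(!trials$corruption %in% CORRUPTION_LEVELS, "unknown corruption")
  offending(!trials$presentation_frames %in% design_frames,
            "presentation_frames outside the design set")
  expect_ms <- frames_to_ms(trials$presentation_frames, refresh_hz)
  offending(abs(trials$presentation_ms - expect_ms) > 0.01,
            "presentation_ms inconsistent with presentation_frames")
  offending(!is.na(trials$rt_ms) & trials$rt_ms <= 0, "nonpositive rt_ms")
  invisible(trials)
}

#' Read and write trial tables
#'
#' Tab-separated text with a header row.  Unknown columns are preserved;
#' `read_trials(write_trials(t))` is the identity.  The number of rows read
#' is reported as a message.
#'
#' @param path file path.
#' @param design_frames,refresh_hz passed to [validate_trials()].
#' @return A validated trial table.
#' @export
read_trials <- function(path, design_frames = DESIGN_FRAMES,
                        refresh_hz = 120) {
  trials <- utils::read.delim(path, stringsAsFactors = FALSE,
                              na.strings = "NA")
  for (col in c("is_practice", "is_repeat")) {
    if (col %in% names(trials)) trials[[col]] <- as.logical(trials[[col]])
  }
  validate_trials(trials, design_frames, refresh_hz)
  message("read ", nrow(trials), " trials from ", path)
  trials
}

#' @rdname read_trials
#' @param trials trial table to write.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Remove practice trials
#'
#' Drops the rows flagged `is_practice` (the first uncorrupted images of
#' each block, whose responses are discarded); the removal count is
#' reported.
#'
#' @param trials trial table.
#' @return Table without practice rows.
#' @export
filter_practice <- function(trials) {
  n_removed <- sum(trials$is_practice)
  message("removed ", n_removed, " practice trial(s)")
  trials[!trials$is_practice, , drop = FALSE]
}

#' Median split by reaction time
#'
#' Splits trials at the median RT computed *within* each
#' `(observer_id, presentation_frames, corruption)` cell, so the split is
#' not confounded with condition-level RT differences, and keeps the
#' requested half.  Trials tied with the cell median go to the faster half.
#' Rows without an RT are dropped; cells whose RTs are all missing are
#' skipped with a warning.
#'
#' @param trials trial table with `rt_ms`.
#' @param keep `"faster"` or `"slower"`.
#' @return The kept half of the table.
#' @export
median_split_by_rt <- function(trials, keep = c("faster", "slower")) {
  keep <- match.arg(keep)
  cell <- interaction(trials$observer_id, trials$presentation_frames,
                      trials$corruption, drop = TRUE)
  keep_row <- logical(nrow(trials))
  for (lv in levels(cell)) {
    idx <- which(cell == lv)
    rts <- trials$rt_ms[idx]
    if (all(is.na(rts))) {
      warning("all reaction times missing in cell ", lv, "; cell skipped",
              call. = FALSE)
      next
    }
    med <- stats::median(rts, na.rm = TRUE)
    faster <- !is.na(rts) & rts <= med
    keep_row[idx] <- if (keep == "faster") faster else (!is.na(rts) & !faster)
  }
  trials[keep_row, , drop = FALSE]
}

#' Per-image correctness sequence for one observer and condition
#'
#' Restricts the table to one observer and one
#' `(presentation_frames, corruption)` condition, excludes practice and
#' repeat presentations, orders by `image_id`, and returns a named 0/1
#' vector of correctness.  `NO_RESPONSE` counts as incorrect by default
#' (set `no_response = "exclude"` to drop those trials instead).  Duplicate
#' `(observer, image)` rows outside repeat presentations are an error.
#'
#' @param trials trial table.
#' @param observer observer id.
#' @param frames presentation frames of the condition.
#' @param corruption corruption label of the condition.
#' @param no_response `"incorrect"` or `"exclude"`.
#' @return Named integer vector (names are image ids) of correctness flags.
#' @export
correctness_series <- function(trials, observer, frames, corruption,
                               no_response = c("incorrect", "exclude")) {
  no_response <- match.arg(no_response)
  sub <- trials[trials$observer_id == observer &
                  trials$presentation_frames == frames &
                  trials$corruption == corruption &
                  !trials$is_practice, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no trials for observer '", observer, "' at ", frames, " frames, ",
         corruption, call. = FALSE)
  }
  # score the first scoreable presentation of each image; later rows must be
  # flagged repeat presentations, otherwise the table is malformed
  sub <- sub[order(sub$trial_index), , drop = FALSE]
  dup <- duplicated(sub$image_id)
  if (any(dup & !sub$is_repeat)) {
    bad <- unique(sub$image_id[dup & !sub$is_repeat])
    stop("duplicate (observer, image) rows outside repeat presentations: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  sub <- sub[!dup, , drop = FALSE]
  if (no_response == "exclude") {
    sub <- sub[sub$response_class != NO_RESPONSE, , drop = FALSE]
  }
  sub <- sub[order(sub$image_id), , drop = FALSE]
  stats::setNames(as.integer(sub$response_class == sub$true_class &
                               sub$response_class != NO_RESPONSE),
                  sub$image_id)
}

#' Self-consistency pair from repeated presentations
#'
#' Builds an aligned first/second-presentation correctness pair from the
#' images an observer saw more than once within a condition, for the
#' intra-observer consistency analysis (same kappa machinery as between
#' observers).
#'
#' @inheritParams correctness_series
#' @return A [binary_pair()] of first versus second presentations.
#' @export
repeat_pair <- function(trials, observer, frames, corruption) {
  sub <- trials[trials$observer_id == observer &
                  trials$presentation_frames == frames &
                  trials$corruption == corruption &
                  !trials$is_practice, , drop = FALSE]
  reps <- unique(sub$image_id[sub$is_repeat])
  if (length(reps) < 1L) {
    stop("no repeated presentations for this observer and condition",
         call. = FALSE)
  }
  first <- second <- integer(length(reps))
  for (i in seq_along(reps)) {
    rows <- sub[sub$image_id == reps[i], , drop = FALSE]
    correct <- as.integer(rows$response_class == rows$true_class &
                            rows$response_class != NO_RESPONSE)
    first[i] <- correct[1L]
    second[i] <- correct[2L]
  }
  binary_pair(first, second, item_ids = reps)
}

#' Pairwise error consistency per condition
#'
#' The pipeline glue: for every `(presentation_frames, corruption)` cell,
#' builds each observer's correctness series, computes all pairwise
#' agreement diagnostics, and (optionally) bootstrap intervals.  Practice
#' and repeat rows are excluded; run [filter_practice()] /
#' [median_split_by_rt()] beforehand as needed (the enforced order is
#' practice removal, then the median split).
#'
#' @param trials trial table.
#' @param align `"strict"` (default) demands identical image sets across
#'   observers within a condition; `"intersect"` restricts to common images.
#' @param threshold flip-distance stability threshold.
#' @param n_resamples bootstrap resamples per pair (0 disables intervals).
#' @param coverage bootstrap interval coverage.
#' @param seed seed for the bootstrap.
#' @param no_response passed to [correctness_series()].
#' @return Data frame with one row per condition and observer pair:
#'   `presentation_frames`, `presentation_ms`, `corruption`, `observer_a`,
#'   `observer_b`, `n`, `acc_a`, `acc_b`, `p_o`, `p_e`, `kappa`,
#'   `kappa_max`, `flip_distance`, `stable`, and `ci_low`/`ci_high` when
#'   bootstrapping.  Undefined pairs (p_e = 1) carry `NA` kappa.
#' @export
ec_by_condition <- function(trials, align = c("strict", "intersect"),
                            threshold = 10L, n_resamples = 0L,
                            coverage = 0.68, seed = NULL,
                            no_response = c("incorrect", "exclude")) {
  align <- match.arg(align)
  no_response <- match.arg(no_response)
  observers <- sort(unique(trials$observer_id))
  if (length(observers) < 2L) stop("need at least two observers", call. = FALSE)
  conds <- unique(trials[!trials$is_practice,
                         c("presentation_frames", "corruption")])
  conds <- conds[order(conds$presentation_frames, conds$corruption), ]
  out <- list()
  boot_i <- 0L
  for (r in seq_len(nrow(conds))) {
    fr <- conds$presentation_frames[r]
    co <- conds$corruption[r]
    series <- lapply(observers, function(o) {
      correctness_series(trials, o, fr, co, no_response = no_response)
    })
    names(series) <- observers
    if (align == "strict") {
      ref <- sort(names(series[[1L]]))
      for (o in observers) {
        if (!identical(sort(names(series[[o]])), ref)) {
          stop("observers saw different image sets at ", fr, " frames, ", co,
               "; use align = \"intersect\"", call. = FALSE)
        }
      }
      common <- ref
    } else {
      common <- sort(Reduce(intersect, lapply(series, names)))
      if (length(common) < 2L) next
    }
    series <- lapply(series, function(x) x[common])
    for (i in seq_len(length(observers) - 1L)) {
      for (j in seq((i + 1L), length(observers))) {
        pair <- binary_pair(series[[i]], series[[j]], item_ids = common)
        ag <- agreement(pair, threshold = threshold)
        row <- data.frame(
          presentation_frames = fr,
          presentation_ms = frames_to_ms(fr),
          corruption = co,
          observer_a = observers[i], observer_b = observers[j],
          n = ag$n, acc_a = ag$acc_a, acc_b = ag$acc_b,
          p_o = ag$p_o, p_e = ag$p_e, kappa = ag$kappa,
          kappa_max = ag$kappa_max, flip_distance = ag$flip_distance,
          stable = ag$stable, stringsAsFactors = FALSE)
        if (n_resamples > 0L) {
          boot_i <- boot_i + 1L
          bt <- tryCatch(
            bootstrap_kappa(pair, n_resamples = n_resamples,
                            coverage = coverage,
                            seed = if (is.null(seed)) NULL else seed + boot_i),
            error = function(e) NULL)
          row$ci_low <- if (is.null(bt)) NA_real_ else bt$lower
          row$ci_high <- if (is.null(bt)) NA_real_ else bt$upper
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}
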