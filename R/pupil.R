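#' Average the two eyes' pupil series
#'
#' Elementwise mean of the left and right pupil series at aligned timestamps.
#' When one eye is missing at a sample the other eye's value is used
#' (single-eye fallback); when both are missing the sample stays missing.
#'
#' @param left,right Numeric vectors of equal length (NA = missing).
#' @return Numeric vector of the same length.
#' @export
average_eyes <- function(left, right) {
  if (length(left) != length(right)) {
    stop("left and right eye series differ in length", call. = FALSE)
  }
  out <- rowMeans(cbind(left, right), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Interpolate blink gaps in batches
#'
#' Replaces missing runs (blinks) by linear interpolation between the nearest
#' valid neighbours, working within consecutive non-overlapping batches of
#' `batch` observations. Missing runs at a batch edge are filled from the
#' batch's nearest valid value. Valid samples are never altered. A batch with
#' no valid sample at all cannot be interpolated; it is left missing with a
#' warning.
#'
#' @param x Numeric series with NA for missing samples.
#' @param batch Batch length in observations, default 600. Set
#'   `whole_series = TRUE` to interpolate over the full series instead.
#' @param whole_series Ignore batching and interpolate across the whole
#'   series.
#' @return Gap-free numeric series (apart from fully-missing batches).
#' @export
interpolate_blinks <- function(x, batch = 600, whole_series = FALSE) {
  n <- length(x)
  if (n == 0) return(x)
  if (whole_series) batch <- n
  starts <- seq(1, n, by = batch)
  out <- x
  dead <- 0L
  for (s in starts) {
    e <- min(s + batch - 1, n)
    seg <- x[s:e]
    if (all(is.na(seg))) {
      dead <- dead + 1L
      next
    }
    if (anyNA(seg)) {
      out[s:e] <- zoo::na.approx(seg, na.rm = FALSE, rule = 2)
    }
  }
  if (dead > 0) {
    warning(dead, " fully-missing batch(es) could not be interpolated",
            call. = FALSE)
  }
  out
}

#' Baseline a turn window to its first sample
#'
#' Subtracts the first pupil datum of the turn window from every sample in
#' the window, so each trajectory starts at exactly 0 and trajectories are
#' comparable across turns and participants.
#'
#' @param x Numeric series of the turn window (interpolated, gap-free at the
#'   first sample).
#' @return `x - x[1]`.
#' @export
baseline_to_turn_start <- function(x) {
  if (length(x) == 0) {
    stop("cannot baseline an empty turn window", call. = FALSE)
  }
  x - x[1]
}

#' Split a turn's pupil samples into word-aligned bins
#'
#' Divides the window's samples into as many contiguous bins as the turn has
#' words. Bin sizes differ by at most one sample and sum to the window's
#' sample count; when the count does not divide evenly, the extra samples go
#' to the earliest bins (a fixed, order-preserving rule). E.g. 100 samples in
#' a 4-word turn give four bins of 25.
#'
#' @param x Baselined numeric series for one turn window.
#' @param n_words Turn size in grammatical words (>= 1; the analysis subset
#'   guarantees >= 3).
#' @return Tibble with `bin`, `norm_position` ((bin-1)/(n_words-1)),
#'   `bin_mean`, `bin_count`.
#' @export
bin_by_words <- function(x, n_words) {
  n <- length(x)
  if (n_words < 1) stop("n_words must be positive", call. = FALSE)
  if (n < n_words) {
    stop("turn window holds fewer samples (", n, ") than words (", n_words,
         "); pair must be excluded", call. = FALSE)
  }
  base <- as.integer(n %/% n_words)
  rem <- n %% n_words
  counts <- base + as.integer(seq_len(n_words) <= rem)
  grp <- rep(seq_len(n_words), times = counts)
  tibble::tibble(
    bin = seq_len(n_words),
    norm_position = if (n_words == 1) 0 else (seq_len(n_words) - 1) / (n_words - 1),
    bin_mean = as.numeric(tapply(x, grp, mean)),
    bin_count = counts
  )
}

#' Preprocess raw pupil streams into word-aligned baselined bin means
#'
#' Runs the full preprocessing chain per participant stream: average the two
#' eyes (single-eye fallback), linearly interpolate blink gaps in consecutive
#' batches, then for every turn window of that participant select the
#' window's samples, baseline them to the window's first datum, and bin them
#' into as many equal-sized bins as the turn has words.
#'
#' Turn-participant pairs whose window holds fewer samples than words, or no
#' samples at all, are excluded; exclusions are tallied in the `exclusions`
#' attribute.
#'
#' @param streams Tibble with columns `participant_id`, `timestamp_ms`,
#'   `pupil_left_px`, `pupil_right_px` (NA = missing sample).
#' @param windows Tibble with columns `conversation_id`, `turn_id`,
#'   `onset_ms`, `offset_ms`, `participant_id`, `role`
#'   ("speaker"/"recipient").
#' @param sizes Tibble mapping (`conversation_id`, `turn_id`) to `size`; e.g.
#'   distinct rows of a [select_turns()] subset. Turns absent from `sizes`
#'   (outside the analysis subset) are skipped.
#' @param batch Interpolation batch length, default 600 observations.
#' @param whole_series Passed to [interpolate_blinks()].
#' @return Tibble with one row per turn x participant x bin:
#'   `conversation_id`, `turn_id`, `participant_id`, `role`, `size`, `bin`,
#'   `norm_position`, `bin_mean`, `bin_count`, `window_samples`.
#' @export
preprocess_pupil <- function(streams, windows, sizes, batch = 600,
                             whole_series = FALSE) {
  need_s <- c("participant_id", "timestamp_ms", "pupil_left_px", "pupil_right_px")
  need_w <- c("conversation_id", "turn_id", "onset_ms", "offset_ms",
              "participant_id", "role")
  if (!all(need_s %in% names(streams))) {
    stop("pupil stream table is missing required columns", call. = FALSE)
  }
  if (!all(need_w %in% names(windows))) {
    stop("turn-window table is missing required columns", call. = FALSE)
  }
  win <- dplyr::inner_join(windows, sizes,
                           by = c("conversation_id", "turn_id"))
  excl <- c(not_in_subset = nrow(windows) - nrow(win),
            empty_window = 0L, too_few_samples = 0L)
  out <- vector("list", 0)
  for (pid in unique(win$participant_id)) {
    ss <- streams[streams$participant_id == pid, ]
    ss <- ss[order(ss$timestamp_ms), ]
    if (nrow(ss) == 0) next
    if (any(diff(ss$timestamp_ms) <= 0)) {
      stop("timestamps not strictly increasing for participant ", pid,
           call. = FALSE)
    }
    avg <- average_eyes(ss$pupil_left_px, ss$pupil_right_px)
    avg <- interpolate_blinks(avg, batch = batch, whole_series = whole_series)
    pw <- win[win$participant_id == pid, ]
    for (i in seq_len(nrow(pw))) {
      sel <- ss$timestamp_ms >= pw$onset_ms[i] & ss$timestamp_ms < pw$offset_ms[i]
      v <- avg[sel]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        excl["empty_window"] <- excl["empty_window"] + 1L
        next
      }
      if (length(v) < pw$size[i]) {
        excl["too_few_samples"] <- excl["too_few_samples"] + 1L
        next
      }
      b <- bin_by_words(baseline_to_turn_start(v), pw$size[i])
      b$conversation_id <- pw$conversation_id[i]
      b$turn_id <- pw$turn_id[i]
      b$participant_id <- pid
      b$role <- pw$role[i]
      b$size <- pw$size[i]
      b$window_samples <- length(v)
      out[[length(out) + 1]] <- b
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(bin = integer(), norm_position = numeric(),
                   bin_mean = numeric(), bin_count = integer(),
                   conversation_id = character(), turn_id = character(),
                   participant_id = character(), role = character(),
                   size = integer(), window_samples = integer())
  res <- dplyr::select(res, "conversation_id", "turn_id", "participant_id",
                       "role", "size", "bin", "norm_position", "bin_mean",
                       "bin_count", "window_samples")
  attr(res, "exclusions") <- excl
  res
}
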