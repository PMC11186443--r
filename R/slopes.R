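#' Ordinary least-squares slope
#'
#' The simple-regression slope of `y` on `x`,
#' sum((x - mean(x)) (y - mean(y))) / sum((x - mean(x))^2). Location shifts
#' in `y` leave the slope unchanged; scaling `y` scales it linearly.
#'
#' @param x,y Numeric vectors of equal length >= 2; `x` must not be constant.
#' @return The slope, a single number.
#' @export
ols_slope <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y differ in length", call. = FALSE)
  }
  if (length(x) < 2) {
    stop("at least two points are needed for a slope", call. = FALSE)
  }
  dx <- x - mean(x)
  sxx <- sum(dx^2)
  if (sxx == 0) {
    stop("slope undefined: x is constant", call. = FALSE)
  }
  sum(dx * (y - mean(y))) / sxx
}

#' Per-turn slopes of word frequency over position
#'
#' For every turn, the OLS slope of the words' per-thousand frequencies on
#' their normalised positions (0 to 1), i.e. the frequency change across the
#' whole turn. A declining, anticlimactic turn yields a negative slope.
#'
#' @param subset Token tibble with `frequency` and `norm_position` columns
#'   (see [assign_frequencies()]).
#' @return Tibble with `conversation_id`, `turn_id`, `speaker_id`, `size`,
#'   `slope_frequency`.
#' @export
turn_frequency_slopes <- function(subset) {
  stopifnot(all(c("frequency", "norm_position") %in% names(subset)))
  dplyr::summarise(
    dplyr::group_by(subset, .data$conversation_id, .data$turn_id),
    speaker_id = .data$speaker_id[1],
    size = dplyr::n(),
    slope_frequency = ols_slope(.data$norm_position, .data$frequency),
    .groups = "drop"
  )
}

#' Per-turn, per-participant slopes of binned pupil size
#'
#' For every turn x participant pair, the OLS slope of the baselined bin
#' means on the bins' normalised positions — the pupil-size change across the
#' whole turn, in the stream's pixel units.
#'
#' @param binned Binned-pupil tibble from [preprocess_pupil()].
#' @return Tibble with `conversation_id`, `turn_id`, `participant_id`,
#'   `role`, `size`, `slope_pupil`.
#' @export
turn_pupil_slopes <- function(binned) {
  dplyr::summarise(
    dplyr::group_by(binned, .data$conversation_id, .data$turn_id,
                    .data$participant_id),
    role = .data$role[1],
    size = .data$size[1],
    slope_pupil = ols_slope(.data$norm_position, .data$bin_mean),
    .groups = "drop"
  )
}

#' Assemble the slope-pair table
#'
#' Inner join of per-turn frequency slopes with per-turn, per-participant
#' pupil slopes on (conversation, turn). Turn size is standardised (mean 0,
#' SD 1) on the assembled table as `turn_size_scaled`. Unmatched rows on
#' either side are counted in the `unmatched` attribute.
#'
#' @param freq_slopes Output of [turn_frequency_slopes()].
#' @param pupil_slopes Output of [turn_pupil_slopes()].
#' @return Tibble with one row per turn x participant: identifiers, `role`,
#'   `slope_frequency`, `slope_pupil`, `size`, `turn_size_scaled`.
#' @export
assemble_slope_pairs <- function(freq_slopes, pupil_slopes) {
  pairs <- dplyr::inner_join(
    dplyr::select(freq_slopes, "conversation_id", "turn_id", "speaker_id",
                  "size", "slope_frequency"),
    dplyr::select(pupil_slopes, "conversation_id", "turn_id",
                  "participant_id", "role", "slope_pupil"),
    by = c("conversation_id", "turn_id")
  )
  if (nrow(pairs) == 0) {
    stop("no turn-participant pairs share keys between the frequency and ",
         "pupil slope tables", call. = FALSE)
  }
  pairs$turn_size_scaled <- as.numeric(scale(pairs$size))
  unmatched <- c(
    frequency_only = nrow(dplyr::anti_join(
      freq_slopes, pupil_slopes, by = c("conversation_id", "turn_id"))),
    pupil_only = nrow(dplyr::anti_join(
      pupil_slopes, freq_slopes, by = c("conversation_id", "turn_id")))
  )
  attr(pairs, "unmatched") <- unmatched
  pairs
}
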