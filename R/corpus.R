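#' Read a PoS-tagged transcript in vertical format
#'
#' Reads a tab-separated "vertical" transcript file with one token per row and
#' reconstructs the turns it contains. The expected columns are
#' `conversation_id`, `turn_id`, `speaker_id`, `index`, `form`, `tag`
#' (a `role` column is carried along when present). Token order within a turn
#' is given by `index`, which must run 1, 2, ... without gaps; rows may appear
#' in any order in the file.
#'
#' @param path Path to a UTF-8 tab-separated file with a header row.
#' @param tagset Tag set the `tag` column is drawn from, `"c5"` (CLAWS5,
#'   ~70 categories) or `"c7"` (CLAWS7, finer grained). Tags not
#'   recognised for the declared tag set are admitted with a warning; they are
#'   treated as function words downstream.
#' @return A tibble of tokens ordered by conversation, turn and index, with
#'   attribute `tagset`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "conversation_id\tturn_id\tspeaker_id\tindex\tform\ttag",
#'   "c1\tt1\ts1\t1\toh\tITJ",
#'   "c1\tt1\ts1\t2\tright\tAV0"
#' ), tf)
#' toks <- read_vertical_corpus(tf, tagset = "c5")
#' count_grammatical_words(toks)
#' @export
read_vertical_corpus <- function(path, tagset = c("c5", "c7")) {
  tagset <- match.arg(tagset)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("conversation_id", "turn_id", "speaker_id", "index", "form", "tag")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("vertical file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$.line <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad <- is.na(raw$form) | raw$form == "" | is.na(raw$tag) | raw$tag == "" |
    is.na(suppressWarnings(as.integer(raw$index)))
  if (any(bad)) {
    stop("malformed row(s) at line(s): ",
         paste(utils::head(raw$.line[bad], 20), collapse = ", "), call. = FALSE)
  }
  raw$index <- as.integer(raw$index)
  tokens <- dplyr::arrange(raw, .data$conversation_id, .data$turn_id, .data$index)
  # indices within each turn must be 1..n
  chk <- dplyr::summarise(
    dplyr::group_by(tokens, .data$conversation_id, .data$turn_id),
    ok = all(.data$index == seq_along(.data$index)),
    .groups = "drop"
  )
  if (any(!chk$ok)) {
    off <- chk[!chk$ok, ]
    stop("non-contiguous token indices in turn(s): ",
         paste(paste0(off$conversation_id, "/", off$turn_id)[seq_len(min(5, nrow(off)))],
               collapse = ", "), call. = FALSE)
  }
  unknown <- !is_known_tag(tokens$tag, tagset)
  if (any(unknown)) {
    warning(sum(unknown), " token(s) carry tags unknown to the ", tagset,
            " tag set; they will be classed as function words", call. = FALSE)
  }
  tokens$.line <- NULL
  tokens <- tibble::as_tibble(tokens)
  attr(tokens, "tagset") <- tagset
  tokens
}

#' Count grammatical words in a token sequence
#'
#' Turn size is the number of grammatical words, i.e. of tagged tokens.
#' Contracted forms are assumed to have been split by the tagger into their
#' underlying grammatical words, one tag each, so "I'm gonna" arrives as four
#' tokens (I, 'm, gon, na) and counts as four words.
#'
#' @param tokens A character vector of forms, or a token tibble (one row per
#'   token).
#' @return Integer count; 0 for an empty sequence.
#' @export
count_grammatical_words <- function(tokens) {
  if (is.data.frame(tokens)) nrow(tokens) else length(tokens)
}

#' Select turns by size and attach positional metadata
#'
#' Keeps the turns whose size (number of grammatical words) lies between
#' `min_size` and `max_size` inclusive, and adds per-token `size` and
#' `norm_position` columns. The normalised position of the i-th word in an
#' n-word turn is (i - 1) / (n - 1), so the first word sits at 0 and the last
#' at 1 regardless of turn length.
#'
#' @param tokens Token tibble as returned by [read_vertical_corpus()] or
#'   [generate_corpus()].
#' @param min_size,max_size Inclusive size bounds; defaults 3 and 25.
#' @return The retained tokens with `size` and `norm_position` columns.
#'   Attributes: `retention` (fraction of turns kept), `n_turns`,
#'   `total_tokens`, and the size bounds.
#' @export
select_turns <- function(tokens, min_size = 3, max_size = 25) {
  if (min_size > max_size) {
    stop("min_size must not exceed max_size", call. = FALSE)
  }
  sizes <- dplyr::summarise(
    dplyr::group_by(tokens, .data$conversation_id, .data$turn_id),
    size = dplyr::n(), .groups = "drop"
  )
  keep <- sizes$size >= min_size & sizes$size <= max_size
  retention <- if (nrow(sizes) == 0) NA_real_ else mean(keep)
  subset <- dplyr::inner_join(tokens, sizes[keep, ],
                              by = c("conversation_id", "turn_id"))
  if (nrow(subset) == 0) {
    warning("no turns fall within the requested size range", call. = FALSE)
    subset$norm_position <- numeric(0)
  } else {
    subset$norm_position <- normalize_position(subset$index, subset$size)
  }
  subset <- tibble::as_tibble(subset)
  attr(subset, "tagset") <- attr(tokens, "tagset")
  attr(subset, "retention") <- retention
  attr(subset, "n_turns") <- sum(keep)
  attr(subset, "total_tokens") <- nrow(subset)
  attr(subset, "size_bounds") <- c(min_size, max_size)
  subset
}

#' Normalised word position within a turn
#'
#' Maps the 1-based word index onto \[0, 1\] as (index - 1) / (size - 1):
#' 0 for the first word, 1 for the last, irrespective of turn size.
#'
#' @param index 1-based word position(s).
#' @param size Turn size(s) in grammatical words; must be >= 2.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_position <- function(index, size) {
  if (any(size < 2)) {
    stop("normalised position is undefined for turns of fewer than 2 words",
         call. = FALSE)
  }
  if (any(index < 1 | index > size)) {
    stop("index must lie between 1 and size", call. = FALSE)
  }
  (index - 1) / (size - 1)
}

#' Build a word-tag frequency table over a turn subset
#'
#' Counts tokens by word-tag combination (the counting type), so the same form
#' under two different tags yields two types. Frequencies are subset-internal:
#' they are computed on the selected turns only, and normalised per thousand
#' subset tokens.
#'
#' @param subset Token tibble from [select_turns()].
#' @param case_fold Lower-case forms before keying (default `TRUE`), so that
#'   orthographic variants of the same word-tag type pool.
#' @return A tibble with columns `form`, `tag`, `count`, `per_thousand`,
#'   ordered by decreasing count; attribute `total` holds the subset token
#'   count.
#' @export
build_frequency_table <- function(subset, case_fold = TRUE) {
  if (nrow(subset) == 0) {
    stop("cannot build a frequency table over an empty turn subset", call. = FALSE)
  }
  form_key <- if (case_fold) tolower(subset$form) else subset$form
  tab <- dplyr::count(
    tibble::tibble(form = form_key, tag = subset$tag),
    .data$form, .data$tag, name = "count"
  )
  total <- sum(tab$count)
  tab$per_thousand <- tab$count / total * 1000
  tab <- dplyr::arrange(tab, dplyr::desc(.data$count), .data$form, .data$tag)
  attr(tab, "total") <- total
  attr(tab, "case_fold") <- case_fold
  tab
}

#' Attach per-thousand frequencies to tokens
#'
#' Joins each token to its word-tag type's subset-internal normalised
#' frequency.
#'
#' @param subset Token tibble from [select_turns()].
#' @param table Frequency table from [build_frequency_table()].
#' @return `subset` with a `frequency` column (tokens per thousand).
#' @export
assign_frequencies <- function(subset, table) {
  case_fold <- isTRUE(attr(table, "case_fold"))
  key <- if (case_fold) tolower(subset$form) else subset$form
  idx <- match(paste(key, subset$tag, sep = "\r"),
               paste(table$form, table$tag, sep = "\r"))
  if (anyNA(idx)) {
    stop("some tokens have no entry in the frequency table; ",
         "was the table built on the same subset?", call. = FALSE)
  }
  out <- subset
  out$frequency <- table$per_thousand[idx]
  out
}

#' Mean frequency profile by turn position
#'
#' Averages per-thousand token frequencies over position cells, either one
#' cell per (turn size, word index) pair or over a grid of relative-position
#' bins pooled across sizes.
#'
#' @param subset Token tibble with a `frequency` column
#'   (see [assign_frequencies()]).
#' @param by `"turn_size"` for per-size, per-index cells, or
#'   `"relative_position"` for a pooled grid over normalised position.
#' @param n_bins Number of grid cells when `by = "relative_position"`.
#' @return A tibble of cell means with the number of tokens per cell.
#' @export
mean_frequency_profile <- function(subset, by = c("turn_size", "relative_position"),
                                   n_bins = 10) {
  by <- match.arg(by)
  stopifnot("frequency" %in% names(subset))
  if (by == "turn_size") {
    dplyr::summarise(
      dplyr::group_by(subset, size = .data$size, index = .data$index),
      norm_position = (.data$index[1] - 1) / (.data$size[1] - 1),
      mean_frequency = mean(.data$frequency),
      n = dplyr::n(), .groups = "drop"
    )
  } else {
    brks <- seq(0, 1, length.out = n_bins + 1)
    bin <- cut(subset$norm_position, breaks = brks, include.lowest = TRUE,
               labels = FALSE)
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(bin = bin,
                                     frequency = subset$frequency), .data$bin),
      position = (brks[.data$bin[1]] + brks[.data$bin[1] + 1]) / 2,
      mean_frequency = mean(.data$frequency),
      n = dplyr::n(), .groups = "drop"
    )
  }
}
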