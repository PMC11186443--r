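#' @keywords internal
c5_tags <- c(
  "AJ0", "AJC", "AJS", "AT0", "AV0", "AVP", "AVQ", "CJC", "CJS", "CJT",
  "CRD", "DPS", "DT0", "DTQ", "EX0", "ITJ", "NN0", "NN1", "NN2", "NP0",
  "ORD", "PNI", "PNP", "PNQ", "PNX", "POS", "PRF", "PRP", "PUL", "PUN",
  "PUQ", "PUR", "TO0", "UNC", "VBB", "VBD", "VBG", "VBI", "VBN", "VBZ",
  "VDB", "VDD", "VDG", "VDI", "VDN", "VDZ", "VHB", "VHD", "VHG", "VHI",
  "VHN", "VHZ", "VM0", "VVB", "VVD", "VVG", "VVI", "VVN", "VVZ", "XX0",
  "ZZ0"
)

# CLAWS7 is larger and has more ad-hoc subtags; a prefix check is used.
c7_prefixes <- c(
  "APPGE", "AT", "BCL", "CC", "CS", "CSA", "CSN", "CST", "CSW", "DA",
  "DB", "DD", "EX", "FO", "FU", "FW", "GE", "IF", "II", "IO", "IW",
  "JJ", "JK", "MC", "MD", "MF", "ND", "NN", "NP", "PN", "PPGE", "PPH",
  "PPI", "PPX", "PPY", "RA", "REX", "RG", "RL", "RP", "RR", "RT", "TO",
  "UH", "VA", "VB", "VD", "VH", "VM", "VV", "XX", "ZZ"
)

#' @keywords internal
is_known_tag <- function(tag, tagset) {
  if (tagset == "c5") {
    toupper(tag) %in% c5_tags
  } else {
    up <- toupper(tag)
    Reduce(`|`, lapply(c7_prefixes, function(p) startsWith(up, p)),
           rep(FALSE, length(up)))
  }
}

#' Default word-class map for a tag set
#'
#' Returns the ordered rule table mapping tag patterns (and form-specific
#' overrides) to one of three word classes — content, function, insert — and,
#' for content words, a subtype (noun, adjective, adverb, lexical_verb).
#' Content tags are adjectives, adverbs, nouns and lexical verbs; auxiliary
#' and modal verbs stay function words. The forms "well" and "so" are
#' re-classed as inserts when they carry an adverb tag (corpora regularly
#' mis-tag these discourse items as adverbs); under any other tag they keep
#' their tag-derived class. Everything not matched by a content or insert
#' rule is a function word.
#'
#' Rules apply in order; the first match wins, so the form overrides sit at
#' the top of the table. The map is plain data and can be written out, edited
#' and read back with [write_classmap()] / [read_classmap()]; editable copies
#' of both default maps ship under
#' `system.file("extdata", package = "turnload")`.
#'
#' @param tagset `"c5"` or `"c7"`.
#' @return A tibble with columns `form` (NA for pure tag rules),
#'   `tag_pattern` (regular expression), `word_class`, `content_subtype`.
#' @export
default_classmap <- function(tagset = c("c5", "c7")) {
  tagset <- match.arg(tagset)
  rules <- if (tagset == "c5") {
    tibble::tribble(
      ~form,  ~tag_pattern, ~word_class, ~content_subtype,
      "well", "^AV",        "insert",    "none",
      "so",   "^AV",        "insert",    "none",
      NA,     "^ITJ",       "insert",    "none",
      NA,     "^AJ",        "content",   "adjective",
      NA,     "^AV",        "content",   "adverb",
      NA,     "^NN",        "content",   "noun",
      NA,     "^NP0",       "content",   "noun",
      NA,     "^VV",        "content",   "lexical_verb",
      NA,     ".",          "function",  "none"
    )
  } else {
    tibble::tribble(
      ~form,  ~tag_pattern, ~word_class, ~content_subtype,
      "well", "^R",         "insert",    "none",
      "so",   "^R",         "insert",    "none",
      NA,     "^UH",        "insert",    "none",
      NA,     "^JJ|^JK",    "content",   "adjective",
      NA,     "^R[AEGLPRT]","content",   "adverb",
      NA,     "^N[DNP]",    "content",   "noun",
      NA,     "^VV",        "content",   "lexical_verb",
      NA,     ".",          "function",  "none"
    )
  }
  attr(rules, "tagset") <- tagset
  rules
}

#' Write / read a word-class map
#'
#' The map is stored as a plain tab-separated file so it can be edited by
#' hand; a written map reads back rule-for-rule identical.
#'
#' @param map Class-map tibble as from [default_classmap()].
#' @param path File path.
#' @return `read_classmap()` returns the class-map tibble.
#' @export
write_classmap <- function(map, path) {
  readr::write_tsv(map, path, na = "")
  invisible(path)
}

#' @rdname write_classmap
#' @export
read_classmap <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character())
  map$form[map$form == ""] <- NA_character_
  tibble::as_tibble(map)
}

#' Classify tokens into content / function / insert
#'
#' Applies the class-map rules in order (first match wins). Form overrides
#' match on the lower-cased form together with their tag pattern. Tokens whose
#' tag matches no rule fall back to function words.
#'
#' @param tokens Token tibble with `form` and `tag` columns.
#' @param map Class map, default [default_classmap()] for the tokens' tag set.
#' @return `tokens` with `word_class` and `content_subtype` columns added.
#' @export
classify_tokens <- function(tokens, map = NULL) {
  if (is.null(map)) {
    tagset <- attr(tokens, "tagset")
    if (is.null(tagset)) tagset <- "c5"
    map <- default_classmap(tagset)
  }
  n <- nrow(tokens)
  word_class <- rep("function", n)
  content_subtype <- rep("none", n)
  unmatched <- rep(TRUE, n)
  lform <- tolower(tokens$form)
  for (r in seq_len(nrow(map))) {
    hit <- unmatched & grepl(map$tag_pattern[r], tokens$tag)
    if (!is.na(map$form[r])) hit <- hit & lform == map$form[r]
    if (any(hit)) {
      word_class[hit] <- map$word_class[r]
      content_subtype[hit] <- map$content_subtype[r]
      unmatched[hit] <- FALSE
    }
  }
  out <- tokens
  out$word_class <- word_class
  out$content_subtype <- content_subtype
  out
}

#' Hapax legomena of a frequency table
#'
#' Word-tag types with a total count of exactly one token in the counting
#' universe (by default the selected turn subset, the same universe the
#' normalised frequencies are computed on).
#'
#' @param table Frequency table from [build_frequency_table()].
#' @return Tibble of `form`, `tag` pairs with count 1.
#' @export
find_hapaxes <- function(table) {
  dplyr::select(table[table$count == 1L, ], "form", "tag")
}

#' Word-class percentages by turn position
#'
#' For each (turn size, word index) cell, the percentage of tokens falling in
#' each of the three word classes. Percentages within a cell sum to 100. The
#' `norm_position` column makes the table directly usable as input to the
#' positional regression stage, pooled across sizes.
#'
#' @param subset Token tibble from [select_turns()].
#' @param map Class map; default derived from the subset's tag set.
#' @param sizes Optional turn sizes to restrict to (e.g. `seq(3, 25, 2)`);
#'   sizes absent from the subset yield no rows and are reported in the
#'   `missing_sizes` attribute.
#' @param noun_separate Split the content class into `noun` and
#'   `content_other`, the granularity the positional word-class regression
#'   is coded at (noun vs function vs insert).
#' @return Tibble with `size`, `index`, `norm_position`, `word_class`, `pct`,
#'   `n` (tokens in the cell).
#' @export
class_position_profile <- function(subset, map = NULL, sizes = NULL,
                                   noun_separate = FALSE) {
  toks <- classify_tokens(subset, map)
  class_levels <- c("content", "function", "insert")
  if (noun_separate) {
    toks$word_class <- ifelse(
      toks$word_class == "content",
      ifelse(toks$content_subtype == "noun", "noun", "content_other"),
      toks$word_class
    )
    class_levels <- c("noun", "content_other", "function", "insert")
  }
  if (!is.null(sizes)) {
    missing_sizes <- setdiff(sizes, unique(toks$size))
    toks <- toks[toks$size %in% sizes, ]
  } else {
    missing_sizes <- integer(0)
  }
  cells <- dplyr::summarise(
    dplyr::group_by(toks, .data$size, .data$index, .data$word_class),
    k = dplyr::n(), .groups = "drop"
  )
  cells <- tidyr::complete(cells, tidyr::nesting(size, index),
                           word_class = class_levels,
                           fill = list(k = 0L))
  cells <- dplyr::mutate(
    dplyr::group_by(cells, .data$size, .data$index),
    n = sum(.data$k), pct = 100 * .data$k / sum(.data$k)
  )
  cells <- dplyr::ungroup(cells)
  cells$norm_position <- (cells$index - 1) / (cells$size - 1)
  out <- dplyr::select(cells, "size", "index", "norm_position", "word_class",
                       "pct", "n")
  out <- dplyr::arrange(out, .data$size, .data$index, .data$word_class)
  if (length(missing_sizes) > 0) {
    warning("requested size(s) absent from subset: ",
            paste(missing_sizes, collapse = ", "), call. = FALSE)
  }
  attr(out, "missing_sizes") <- missing_sizes
  out
}

#' Hapax-noun percentage by turn position
#'
#' For each (turn size, word index) cell, 100 x (tokens that are hapax
#' legomena and nouns) / (all tokens at that cell). Hapax status is computed
#' on the supplied frequency table, i.e. on the selected subset by default.
#'
#' @param subset Token tibble from [select_turns()].
#' @param table Frequency table the hapaxes are read off;
#'   default `build_frequency_table(subset)`.
#' @param map Class map; default from the subset's tag set.
#' @return Tibble with `size`, `index`, `norm_position`, `pct_hapax_noun`, `n`.
#' @export
hapax_noun_profile <- function(subset, table = NULL, map = NULL) {
  if (is.null(table)) table <- build_frequency_table(subset)
  toks <- classify_tokens(subset, map)
  hap <- find_hapaxes(table)
  case_fold <- isTRUE(attr(table, "case_fold"))
  key <- if (case_fold) tolower(toks$form) else toks$form
  is_hapax <- paste(key, toks$tag, sep = "\r") %in%
    paste(hap$form, hap$tag, sep = "\r")
  toks$is_hapax_noun <- is_hapax & toks$word_class == "content" &
    toks$content_subtype == "noun"
  out <- dplyr::summarise(
    dplyr::group_by(toks, .data$size, .data$index),
    norm_position = (.data$index[1] - 1) / (.data$size[1] - 1),
    pct_hapax_noun = 100 * mean(.data$is_hapax_noun),
    n = dplyr::n(), .groups = "drop"
  )
  out
}

#' Default pro-form inventory
#'
#' The personal and demonstrative pro-forms plus existential "there" that
#' typically realise the grammatical subject in conversation.
#' @return Character vector of lower-cased forms.
#' @export
default_proforms <- function() {
  c("i", "you", "he", "she", "it", "we", "they",
    "this", "that", "these", "those", "there")
}

#' Share of turns with an early pro-form
#'
#' Fraction of turns containing at least one of the listed pro-forms at a
#' normalised position at or below `threshold` — a positional heuristic for
#' pro-form subjects near the turn beginning.
#'
#' @param subset Token tibble from [select_turns()].
#' @param proforms Character vector of (lower-cased) forms;
#'   default [default_proforms()].
#' @param threshold Normalised-position cutoff, default 0.2.
#' @return A single proportion in \[0, 1\].
#' @export
proform_early_share <- function(subset, proforms = default_proforms(),
                                threshold = 0.2) {
  if (length(proforms) == 0) {
    stop("the pro-form list must not be empty", call. = FALSE)
  }
  tmp <- subset
  tmp$.hit <- tolower(subset$form) %in% tolower(proforms) &
    subset$norm_position <= threshold
  per_turn <- dplyr::summarise(
    dplyr::group_by(tmp, .data$conversation_id, .data$turn_id),
    any_hit = any(.data$.hit), .groups = "drop"
  )
  mean(per_turn$any_hit)
}
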