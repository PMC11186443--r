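# Shared fixture builders; all fixtures are generated in code.

# Token tibble from a list of turns; each turn is a character vector of
# "form_TAG" strings.
toy_tokens <- function(turns, conversation_id = "c1", speakers = NULL) {
  if (is.null(speakers)) speakers <- rep("s1", length(turns))
  rows <- lapply(seq_along(turns), function(i) {
    parts <- strsplit(turns[[i]], "_", fixed = TRUE)
    tibble::tibble(
      conversation_id = conversation_id,
      turn_id = sprintf("t%03d", i),
      speaker_id = speakers[i],
      index = seq_along(turns[[i]]),
      form = vapply(parts, `[`, "", 1),
      tag = vapply(parts, `[`, "", 2)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "tagset") <- "c5"
  out
}

# Write a token tibble as a vertical TSV and return the path.
write_vertical <- function(tokens, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(tokens, path)
  path
}

# Random token tibble: n_turns turns with sizes drawn from `sizes`, forms
# sampled from a small vocabulary.
random_tokens <- function(n_turns, sizes = 1:30, vocab = 12, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    turn_sizes <- sample(sizes, n_turns, replace = TRUE)
    turns <- lapply(turn_sizes, function(k) {
      paste0("w", sample.int(vocab, k, replace = TRUE), "_NN1")
    })
    toy_tokens(turns)
  })
}

# Default synthetic bundle shared across acceptance tests, built once per
# (n_turns, seed) and cached for the session.
.bundle_cache <- new.env(parent = emptyenv())
acceptance_bundle <- function(n_turns = 2000, seed = 20260920) {
  key <- paste0("b", n_turns, "_", seed)
  if (!is.null(.bundle_cache[[key]])) return(.bundle_cache[[key]])
  config <- sim_config(n_turns = n_turns)
  corpus <- generate_corpus(config, seed = seed)
  pup <- generate_pupil(corpus, config, seed = seed)
  subset <- select_turns(corpus)
  tab <- build_frequency_table(subset)
  fr <- assign_frequencies(subset, tab)
  sizes <- dplyr::distinct(subset, conversation_id, turn_id, size)
  binned <- preprocess_pupil(pup$streams, pup$windows, sizes)
  pairs <- assemble_slope_pairs(turn_frequency_slopes(fr),
                                turn_pupil_slopes(binned))
  out <- list(config = config, corpus = corpus, subset = subset, table = tab,
              tokens_freq = fr, pupil = pup, binned = binned, pairs = pairs)
  .bundle_cache[[key]] <- out
  out
}
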