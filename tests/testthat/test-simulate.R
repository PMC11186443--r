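test_that("lexicon weights are Zipfian within classes", {
  cfg <- sim_config(zipf_s = 1, insert_zipf_s = 1)
  lex <- make_lexicon(cfg)
  nouns <- lex[lex$class == "noun", ]
  # rank 1 sampled twice as often as rank 2 at s = 1
  expect_equal(nouns$weight[1] / nouns$weight[2], 2)
  expect_equal(nouns$weight[1] / nouns$weight[3], 3)
  ins <- lex[lex$class == "insert", ]
  expect_equal(sum(ins$weight), 1)
  # nouns carry the largest type inventory
  expect_gt(nrow(nouns), sum(lex$class == "function"))
  # the mis-tagged insert is present to exercise the class-map override
  expect_equal(lex$tag[lex$form == "well"], "AV0")

  one <- sim_config(n_insert = 1)
  corp <- generate_corpus(sim_config(n_insert = 1, n_turns = 50), seed = 2)
  ins_forms <- unique(corp$form[corp$tag == "ITJ"])
  expect_lte(length(ins_forms), 1)   # single-type class: only that type
})

test_that("generated corpora are deterministic and vertically well-formed", {
  cfg <- sim_config(n_turns = 40)
  a <- generate_corpus(cfg, seed = 123)
  b <- generate_corpus(cfg, seed = 123)
  expect_identical(a, b)
  c <- generate_corpus(cfg, seed = 124)
  expect_false(identical(a, c))

  # round-trips through the vertical reader without warnings
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(a, path)
  expect_no_warning(back <- read_vertical_corpus(path, tagset = "c5"))
  expect_equal(nrow(back), nrow(a))

  empty <- generate_corpus(sim_config(n_turns = 0), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("conversation_id", "turn_id", "speaker_id",
                        "index", "form", "tag"))
})

test_that("class composition follows the configured position curves", {
  cfg <- sim_config(n_turns = 3000)
  corp <- generate_corpus(cfg, seed = 31)
  sub <- select_turns(corp)
  cls <- classify_tokens(sub)
  cls$word_class <- ifelse(cls$word_class == "content",
                           ifelse(cls$content_subtype == "noun", "noun",
                                  "content_other"),
                           cls$word_class)
  for (p0 in c(0, 1)) {
    at <- cls[cls$norm_position == p0, ]
    obs <- table(factor(at$word_class,
                        levels = c("insert", "function", "noun", "content_other")))
    curve <- cfg$class_curves[cfg$class_curves$position == p0, ]
    expected_p <- c(curve$p_insert, curve$p_function, curve$p_noun,
                    curve$p_content_other)
    gof <- suppressWarnings(stats::chisq.test(obs, p = expected_p))
    expect_gt(gof$p.value, 0.01)
  }
  # every turn starts with an insert when the curve says so
  curves <- default_class_curves()
  curves$p_insert[curves$position == 0] <- 1
  curves$p_function[curves$position == 0] <- 0
  curves$p_noun[curves$position == 0] <- 0
  curves$p_content_other[curves$position == 0] <- 0
  cfg1 <- sim_config(n_turns = 80, class_curves = curves)
  corp1 <- generate_corpus(cfg1, seed = 5)
  first <- classify_tokens(select_turns(corp1))
  first <- first[first$norm_position == 0, ]
  expect_true(all(first$word_class == "insert"))
})

test_that("pupil generation encodes the programmed trajectories and coupling", {
  # coupling is exactly linear in the turn's frequency slope
  cfg <- sim_config(n_turns = 30, coupling_speaker = -1, trend_sd = 0,
                    participant_trend_sd = 0, conversation_trend_sd = 0)
  corp <- generate_corpus(cfg, seed = 17)
  pup <- generate_pupil(corp, cfg, seed = 17)
  tr <- pup$truth$turn_truth
  sp <- tr[tr$role == "speaker", ]
  expect_equal(sp$lin_truth - cfg$speaker_slope_mean,
               -1 * sp$slope_frequency, tolerance = 1e-10)
  # two turns whose frequency slopes differ by d have truth slopes apart by d
  d_f <- sp$slope_frequency[1] - sp$slope_frequency[2]
  expect_equal(sp$lin_truth[2] - sp$lin_truth[1], d_f, tolerance = 1e-10)

  # recipients: plateau-shaped quadratic, no coupling by default
  expect_true(all(tr$quad_truth[tr$role == "recipient"] == cfg$recipient_quad))
  expect_true(all(tr$quad_truth[tr$role == "speaker"] == 0))

  # noise-free speaker traces yield the programmed slope through the
  # complete preprocessing + slope pipeline
  cfg0 <- sim_config(n_turns = 20, coupling_speaker = 0, trend_sd = 0,
                     participant_trend_sd = 0, conversation_trend_sd = 0,
                     noise_sd = 0, eye_noise_sd = 0, blink_rate_hz = 0,
                     single_eye_dropout = 0, speaker_slope_mean = 12)
  corp0 <- generate_corpus(cfg0, seed = 3)
  pup0 <- generate_pupil(corp0, cfg0, seed = 3)
  sub0 <- select_turns(corp0)
  sizes0 <- dplyr::distinct(sub0, conversation_id, turn_id, size)
  b0 <- preprocess_pupil(pup0$streams, pup0$windows, sizes0)
  psl <- turn_pupil_slopes(b0)
  spk <- psl$slope_pupil[psl$role == "speaker"]
  expect_equal(mean(spk), 12, tolerance = 0.05)
  expect_lt(stats::sd(spk), 0.5)
})

test_that("blink gaps appear as missing runs at the configured rate", {
  cfg <- sim_config(n_turns = 40, blink_rate_hz = 0.5, single_eye_dropout = 0)
  pup <- generate_pupil(generate_corpus(cfg, seed = 21), cfg, seed = 21)
  s <- pup$streams
  expect_gt(sum(is.na(s$pupil_left_px)), 0)
  # blinks hit both eyes at the same samples
  expect_equal(which(is.na(s$pupil_left_px)), which(is.na(s$pupil_right_px)))

  none <- sim_config(n_turns = 10, blink_rate_hz = 0, single_eye_dropout = 0)
  pup0 <- generate_pupil(generate_corpus(none, seed = 21), none, seed = 21)
  expect_equal(sum(is.na(pup0$streams$pupil_left_px)), 0)
})

test_that("dataset bundles are byte-identical under the same seed", {
  cfg <- sim_config(n_turns = 25)
  d1 <- tempfile("bundle1_"); d2 <- tempfile("bundle2_")
  p1 <- generate_dataset(cfg, d1, seed = 99)
  p2 <- generate_dataset(cfg, d2, seed = 99)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  # the bundle is readable by the upstream readers
  toks <- read_vertical_corpus(p1$transcript, tagset = "c5")
  expect_gt(nrow(toks), 0)
  truth <- jsonlite::read_json(p1$truth, simplifyVector = TRUE)
  expect_true(all(c("turn_truth", "participant_effects",
                    "conversation_effects", "config") %in% names(truth)))

  # empty bundles still carry headers
  d0 <- tempfile("bundle0_")
  p0 <- generate_dataset(sim_config(n_turns = 0), d0, seed = 1)
  expect_equal(length(readLines(p0$transcript)), 1)
  expect_match(readLines(p0$pupil)[1], "participant_id")
})

test_that("the analytic frequency curve matches the sampled corpus", {
  cfg <- sim_config(n_turns = 1500)
  corp <- generate_corpus(cfg, seed = 8)
  sub <- select_turns(corp)
  fr <- assign_frequencies(sub, build_frequency_table(sub))
  ef <- expected_token_frequency(sub, cfg)
  # observed and analytic means agree at the anchor positions
  for (p0 in c(0, 1)) {
    sel <- sub$norm_position == p0
    obs <- mean(fr$frequency[sel])
    expect_equal(obs, mean(ef[sel]), tolerance = 0.12)
  }
  # the programmed profile declines across the turn
  expect_gt(mean(ef[sub$norm_position == 0]), mean(ef[sub$norm_position == 1]))
})
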