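test_that("vertical files are reconstructed into ordered turns", {
  toks <- toy_tokens(list(c("oh_ITJ", "right_AV0")))
  path <- write_vertical(toks)
  got <- read_vertical_corpus(path, tagset = "c5")
  expect_equal(nrow(got), 2)
  expect_equal(got$form, c("oh", "right"))
  expect_equal(count_grammatical_words(got), 2)

  # two conversations: turns grouped by (conversation, turn)
  two <- dplyr::bind_rows(
    toy_tokens(list(c("i_PNP", "know_VVB")), conversation_id = "cA"),
    toy_tokens(list(c("yeah_ITJ", "right_AV0", "ok_ITJ")), conversation_id = "cB")
  )
  got2 <- read_vertical_corpus(write_vertical(two), tagset = "c5")
  grp <- dplyr::count(got2, conversation_id, turn_id)
  expect_equal(nrow(grp), 2)
  expect_setequal(grp$n, c(2, 3))
})

test_that("row order in the file does not matter", {
  toks <- random_tokens(25, sizes = 2:8, seed = 42)
  sorted_path <- write_vertical(toks)
  set.seed(1)
  shuffled_path <- write_vertical(toks[sample.int(nrow(toks)), ])
  expect_equal(read_vertical_corpus(shuffled_path),
               read_vertical_corpus(sorted_path))
})

test_that("malformed vertical input is rejected with a useful message", {
  toks <- toy_tokens(list(c("a_NN1", "b_NN1")))
  missing_col <- dplyr::select(toks, -tag)
  expect_error(read_vertical_corpus(write_vertical(missing_col)),
               "missing required column")

  gap <- toks
  gap$index <- c(1L, 3L)
  expect_error(read_vertical_corpus(write_vertical(gap)), "non-contiguous")

  blank <- toks
  blank$form[2] <- ""
  expect_error(read_vertical_corpus(write_vertical(blank)), "malformed")

  odd_tag <- toy_tokens(list(c("a_QQQ9", "b_NN1")))
  expect_warning(read_vertical_corpus(write_vertical(odd_tag)), "unknown")
})

test_that("turn size counts grammatical words, contractions already split", {
  # "I'm gonna" arrives from the tagger as four grammatical words
  im_gonna <- c("I_PPIS1", "'m_VBM", "gon_VVGK", "na_TO")
  expect_equal(count_grammatical_words(im_gonna), 4)
  expect_equal(count_grammatical_words(character(0)), 0)
  for (n in c(1, 5, 17)) {
    expect_equal(count_grammatical_words(rep("x_NN1", n)), n)
  }
})

test_that("turn selection keeps exactly the 3-25 word range, inclusive", {
  toks <- toy_tokens(lapply(c(2, 3, 25, 26), function(k) rep("w_NN1", k)))
  sub <- select_turns(toks, 3, 25)
  kept <- unique(sub$size)
  expect_setequal(kept, c(3, 25))
  expect_equal(attr(sub, "retention"), 0.5)

  ones <- toy_tokens(lapply(1:4, function(i) "w_NN1"))
  expect_warning(sub1 <- select_turns(ones), "no turns")
  expect_equal(nrow(sub1), 0)

  expect_error(select_turns(toks, 10, 3), "min_size")
})

test_that("turn selection matches a brute-force scan and is idempotent", {
  toks <- random_tokens(100, sizes = 1:25, seed = 7)
  sub <- select_turns(toks, 3, 25)
  sizes <- table(dplyr::count(toks, conversation_id, turn_id)$n)
  brute <- sum(sizes[as.integer(names(sizes)) >= 3 & as.integer(names(sizes)) <= 25])
  expect_equal(attr(sub, "n_turns"), brute)
  again <- select_turns(dplyr::select(sub, -size, -norm_position), 3, 25)
  expect_equal(attr(again, "n_turns"), attr(sub, "n_turns"))
  expect_equal(again$form, sub$form)
})

test_that("normalised positions span [0, 1] with exact endpoints", {
  expect_equal(normalize_position(1, 4), 0)
  expect_equal(normalize_position(4, 4), 1)
  expect_equal(normalize_position(2, 4), 1 / 3)
  expect_error(normalize_position(1, 1), "undefined")
  expect_error(normalize_position(5, 4), "between")

  toks <- random_tokens(50, sizes = 3:25, seed = 3)
  sub <- select_turns(toks)
  expect_true(all(sub$norm_position >= 0 & sub$norm_position <= 1))
  expect_true(all(sub$norm_position[sub$index == 1] == 0))
  expect_true(all(sub$norm_position[sub$index == sub$size] == 1))
})

test_that("frequency tables count word-tag types and normalise per thousand", {
  toks <- toy_tokens(list(c("a_AT0", "a_AT0", "b_NN1")))
  sub <- select_turns(toks, 3, 25)
  tab <- build_frequency_table(sub)
  expect_equal(attr(tab, "total"), 3)
  expect_equal(tab$count[tab$form == "a"], 2)
  expect_equal(tab$count[tab$form == "b"], 1)
  expect_equal(tab$per_thousand, tab$count / 3 * 1000)

  # same form under two tags => two types
  toks2 <- toy_tokens(list(c("run_NN1", "run_VVB", "x_NN1")))
  tab2 <- build_frequency_table(select_turns(toks2))
  expect_equal(sum(tab2$form == "run"), 2)
  expect_true(all(tab2$count[tab2$form == "run"] == 1))

  # case folding pools variants; switching it off separates them
  toks3 <- toy_tokens(list(c("The_AT0", "the_AT0", "x_NN1")))
  sub3 <- select_turns(toks3)
  expect_equal(build_frequency_table(sub3)$count[1], 2)
  expect_true(all(build_frequency_table(sub3, case_fold = FALSE)$count == 1))

  expect_error(build_frequency_table(sub[0, ]), "empty")
})

test_that("frequency mass is conserved", {
  toks <- random_tokens(80, sizes = 3:25, vocab = 30, seed = 11)
  sub <- select_turns(toks)
  tab <- build_frequency_table(sub)
  expect_equal(sum(tab$count), attr(tab, "total"))
  expect_equal(sum(tab$per_thousand * attr(tab, "total") / 1000),
               attr(tab, "total"), tolerance = 1e-9)
})

test_that("mean frequency profile matches hand computation", {
  # one turn type repeated: profile equals the single turn's frequencies
  toks <- toy_tokens(list(c("a_AT0", "b_NN1", "a_AT0"),
                          c("a_AT0", "b_NN1", "a_AT0")))
  sub <- select_turns(toks)
  fr <- assign_frequencies(sub, build_frequency_table(sub))
  prof <- mean_frequency_profile(fr, by = "turn_size")
  # counts: a = 4 of 6, b = 2 of 6
  expect_equal(prof$mean_frequency,
               c(4 / 6, 2 / 6, 4 / 6) * 1000)

  # two turns of different shape: means computed by hand per cell
  toks2 <- toy_tokens(list(c("a_AT0", "a_AT0", "b_NN1"),
                           c("b_NN1", "a_AT0", "c_NN1")))
  sub2 <- select_turns(toks2)
  fr2 <- assign_frequencies(sub2, build_frequency_table(sub2))
  prof2 <- mean_frequency_profile(fr2, by = "turn_size")
  # a: 3/6, b: 2/6, c: 1/6 per thousand
  a <- 500; b <- 1000 / 3; c <- 1000 / 6
  expect_equal(prof2$mean_frequency,
               c(mean(c(a, b)), mean(c(a, a)), mean(c(b, c))))
  expect_equal(prof2$n, c(2L, 2L, 2L))
})
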