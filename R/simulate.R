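#' Run code with a fixed RNG seed, restoring the RNG state afterwards
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Default class-position probability curves
#'
#' A grid over relative position \[0, 1\] giving the probability that the
#' word at that position is an insert, a noun, another content word, or a
#' function word. The default shapes mirror the positional structure of
#' conversational English: insert probability is concentrated at the turn
#' start and decays fast; noun probability starts low (about 4%) and rises
#' steeply toward the turn end (about 30% at the final word); other content
#' words are roughly flat; function words take the remaining mass and so
#' dominate turn-medial positions.
#'
#' @param positions Grid of relative positions.
#' @return Tibble with `position`, `p_insert`, `p_noun`, `p_content_other`,
#'   `p_function` (rows sum to 1).
#' @export
default_class_curves <- function(positions = seq(0, 1, by = 0.01)) {
  p_insert <- 0.55 * exp(-positions / 0.07)
  p_noun <- 0.04 + 0.28 * positions^3
  p_content_other <- rep(0.17, length(positions))
  p_function <- 1 - p_insert - p_noun - p_content_other
  stopifnot(all(p_function >= 0))
  tibble::tibble(position = positions, p_insert = p_insert, p_noun = p_noun,
                 p_content_other = p_content_other, p_function = p_function)
}

#' Simulation configuration
#'
#' All parameters of the synthetic transcript + pupillometry generator, with
#' defaults chosen to emulate the statistical structure the analysis assumes:
#' a Zipf-distributed lexicon partitioned into word classes with a hapax-rich
#' noun inventory, turns whose class composition varies by relative position
#' (inserts early, nouns late, giving an S-shaped mean-frequency decline),
#' and 60 Hz pupil traces in which speakers show a linear rise whose per-turn
#' slope is negatively coupled to the turn's frequency slope, recipients show
#' a quadratic rise-plateau with no coupling, with random trend offsets by
#' participant and conversation, sample noise, and blink gaps.
#'
#' @param n_conversations Number of conversations.
#' @param participants_per_conversation 2 (dyads) or 3 (triads).
#' @param n_turns Total number of turns across conversations.
#' @param sizes,size_probs Turn-size support (grammatical words) and
#'   sampling weights; the default decays geometrically over 3..25.
#' @param tagset Tag set for the synthetic tags, `"c5"` or `"c7"`.
#' @param n_insert,n_function,n_noun,n_adjective,n_adverb,n_verb Vocabulary
#'   sizes per class; nouns get by far the largest type inventory, producing
#'   the hapax-rich tail.
#' @param zipf_s Zipf exponent: within each class, type k is sampled with
#'   weight k^(-s).
#' @param insert_zipf_s Zipf exponent of the insert class only. Inserts are a
#'   tiny closed class dominated by a handful of forms, far more skewed than
#'   the open classes; the steep default makes insert tokens the
#'   highest-frequency tokens in the corpus, which is what produces the high
#'   turn-initial mean frequency.
#' @param class_curves Position-dependent class probabilities, see
#'   [default_class_curves()].
#' @param hz Pupil sample rate.
#' @param ms_per_word Mean turn duration per word, ms.
#' @param duration_sd_ms SD of the per-turn duration noise, ms.
#' @param gap_ms Silence between consecutive turns, ms.
#' @param baseline_px Grand-mean pupil area, px.
#' @param participant_level_sd SD of per-participant baseline offsets, px.
#' @param noise_sd Per-sample Gaussian noise SD, px.
#' @param eye_noise_sd Extra per-eye noise SD, px.
#' @param speaker_slope_mean Mean of the speaker trend's baseline linear
#'   coefficient (px change across the whole turn), before coupling.
#' @param recipient_linear,recipient_quad Recipient trajectory coefficients:
#'   value at normalised time t is linear * t + quad * t^2; the default
#'   quad = -linear/2 flattens the curve into a plateau at the turn end.
#' @param coupling_speaker Pupil-slope change per unit frequency slope in
#'   speakers (negative by default: steeper frequency declines give steeper
#'   pupil rises).
#' @param coupling_recipient Same for recipients; 0 by default.
#' @param trend_sd SD of the per-turn, per-participant trend residual.
#' @param participant_trend_sd,conversation_trend_sd SDs of the random trend
#'   intercepts by participant and by conversation.
#' @param blink_rate_hz Blink events per second per participant.
#' @param blink_len_mean_ms Mean blink (missing-run) length, ms.
#' @param single_eye_dropout Per-sample probability that exactly one eye is
#'   missing.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_conversations = 3,
                       participants_per_conversation = 2,
                       n_turns = 2000,
                       sizes = 3:25,
                       size_probs = exp(-(sizes - min(sizes)) / 5),
                       tagset = "c5",
                       n_insert = 12, n_function = 80, n_noun = 4000,
                       n_adjective = 300, n_adverb = 150, n_verb = 600,
                       zipf_s = 1, insert_zipf_s = 3,
                       class_curves = default_class_curves(),
                       hz = 60, ms_per_word = 400, duration_sd_ms = 300,
                       gap_ms = 500,
                       baseline_px = 1000, participant_level_sd = 50,
                       noise_sd = 5, eye_noise_sd = 0.5,
                       speaker_slope_mean = 15,
                       recipient_linear = 20, recipient_quad = -10,
                       coupling_speaker = -0.5, coupling_recipient = 0,
                       trend_sd = 8,
                       participant_trend_sd = 5, conversation_trend_sd = 3,
                       blink_rate_hz = 0.15, blink_len_mean_ms = 150,
                       single_eye_dropout = 0.01) {
  stopifnot(participants_per_conversation %in% 2:3, zipf_s > 0,
            all(size_probs >= 0), noise_sd >= 0, trend_sd >= 0,
            participant_trend_sd >= 0, conversation_trend_sd >= 0)
  cfg <- as.list(environment())
  cfg$size_probs <- size_probs / sum(size_probs)
  class(cfg) <- "sim_config"
  cfg
}

zipf_weights <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

c5_to_c7 <- c(ITJ = "UH", AV0 = "RR", AJ0 = "JJ", NN1 = "NN1", VVB = "VV0",
              PNP = "PPHS1", DT0 = "DD1", EX0 = "EX", AT0 = "AT", CJC = "CC",
              PRF = "IO", TO0 = "TO", VBD = "VBDZ", VBZ = "VBZ", PRP = "II",
              VHB = "VH0", VDB = "VD0", XX0 = "XX", VBI = "VBI", CJS = "CS")

#' Build the synthetic tagged lexicon
#'
#' One Zipfian sub-lexicon per sampling class. Within a class, type k carries
#' weight k^(-s), so at s = 1 the top type is sampled twice as often as the
#' second, three times as often as the third, and so on. Inserts and function
#' words are small, high-mass inventories (the function inventory leads with
#' the pro-form set); nouns are a large, hapax-rich inventory. The insert
#' "well" deliberately carries an adverb tag, mimicking the mis-tagging the
#' class map's form override corrects.
#'
#' @param config A [sim_config()].
#' @return Tibble with `class` (insert/function/noun/content_other),
#'   `content_subtype`, `form`, `tag`, `rank`, `weight` (normalised within
#'   class for insert/function/noun, within subtype for content_other).
#' @export
make_lexicon <- function(config) {
  ins_pool <- c("oh", "well", "yeah", "mm", "uh", "right", "okay", "hm",
                "ah", "huh", "eh", "ooh")
  n_ins <- config$n_insert
  ins_forms <- c(ins_pool, sprintf("int%03d", seq_len(max(0, n_ins - length(ins_pool)))))[seq_len(n_ins)]
  ins_tags <- ifelse(ins_forms == "well", "AV0", "ITJ")
  ins <- tibble::tibble(class = "insert", content_subtype = "none",
                        form = ins_forms, tag = ins_tags,
                        rank = seq_len(n_ins),
                        weight = zipf_weights(n_ins, config$insert_zipf_s))

  fun_pool <- tibble::tribble(
    ~form, ~tag,
    "i", "PNP", "you", "PNP", "it", "PNP", "that", "DT0", "the", "AT0",
    "and", "CJC", "a", "AT0", "to", "TO0", "of", "PRF", "he", "PNP",
    "they", "PNP", "she", "PNP", "we", "PNP", "this", "DT0", "there", "EX0",
    "was", "VBD", "is", "VBZ", "in", "PRP", "on", "PRP", "so", "CJC",
    "do", "VDB", "have", "VHB", "not", "XX0", "but", "CJC", "at", "PRP",
    "for", "PRP", "with", "PRP", "be", "VBI", "as", "CJS",
    "these", "DT0", "those", "DT0"
  )
  n_fun <- config$n_function
  extra <- max(0, n_fun - nrow(fun_pool))
  fun <- tibble::tibble(
    class = "function", content_subtype = "none",
    form = c(fun_pool$form, sprintf("fw%03d", seq_len(extra)))[seq_len(n_fun)],
    tag = c(fun_pool$tag, rep("PRP", extra))[seq_len(n_fun)],
    rank = seq_len(n_fun),
    weight = zipf_weights(n_fun, config$zipf_s)
  )

  noun <- tibble::tibble(class = "noun", content_subtype = "noun",
                         form = sprintf("n%05d", seq_len(config$n_noun)),
                         tag = "NN1", rank = seq_len(config$n_noun),
                         weight = zipf_weights(config$n_noun, config$zipf_s))

  sub <- function(n, stem, tag, subtype) {
    tibble::tibble(class = "content_other", content_subtype = subtype,
                   form = sprintf("%s%04d", stem, seq_len(n)), tag = tag,
                   rank = seq_len(n), weight = zipf_weights(n, config$zipf_s))
  }
  other <- dplyr::bind_rows(
    sub(config$n_adjective, "adj", "AJ0", "adjective"),
    sub(config$n_adverb, "adv", "AV0", "adverb"),
    sub(config$n_verb, "verb", "VVB", "lexical_verb")
  )

  lex <- dplyr::bind_rows(ins, fun, noun, other)
  if (config$tagset == "c7") {
    mapped <- unname(c5_to_c7[lex$tag])
    lex$tag <- ifelse(is.na(mapped), lex$tag, mapped)
  }
  lex
}

# subtype mixing proportions within the content_other class
content_other_mix <- c(adjective = 0.30, adverb = 0.35, lexical_verb = 0.35)

class_probs_at <- function(curves, p) {
  P <- cbind(
    insert = stats::approx(curves$position, curves$p_insert, xout = p)$y,
    "function" = stats::approx(curves$position, curves$p_function, xout = p)$y,
    noun = stats::approx(curves$position, curves$p_noun, xout = p)$y,
    content_other = stats::approx(curves$position, curves$p_content_other, xout = p)$y
  )
  P / rowSums(P)
}

#' Generate a synthetic tagged conversational corpus
#'
#' Draws turns with sizes from the configured size distribution, assigns each
#' turn to a conversation and a speaker, and samples every word's class from
#' the position-dependent class curves and its form from the class's Zipfian
#' lexicon. Output is vertical-format writable and deterministic under the
#' seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Token tibble (`conversation_id`, `turn_id`, `speaker_id`, `index`,
#'   `form`, `tag`) with attribute `tagset`.
#' @export
generate_corpus <- function(config, seed = 1) {
  with_seed(seed, {
    n <- config$n_turns
    empty <- tibble::tibble(conversation_id = character(),
                            turn_id = character(), speaker_id = character(),
                            index = integer(), form = character(),
                            tag = character())
    if (n == 0) {
      attr(empty, "tagset") <- config$tagset
      return(empty)
    }
    sizes <- sample(config$sizes, n, replace = TRUE, prob = config$size_probs)
    conv <- sprintf("c%02d", 1 + (seq_len(n) - 1) %% config$n_conversations)
    ppc <- config$participants_per_conversation
    conv_idx <- 1 + (seq_len(n) - 1) %% config$n_conversations
    turn_in_conv <- stats::ave(seq_len(n), conv_idx, FUN = seq_along)
    speaker <- sprintf("p%02d", (conv_idx - 1) * ppc +
                         1 + (turn_in_conv - 1) %% ppc)
    turn_id <- sprintf("t%06d", seq_len(n))

    toks <- tibble::tibble(
      conversation_id = rep(conv, sizes),
      turn_id = rep(turn_id, sizes),
      speaker_id = rep(speaker, sizes),
      index = unlist(lapply(sizes, seq_len), use.names = FALSE),
      size = rep(sizes, sizes)
    )
    p <- (toks$index - 1) / (toks$size - 1)
    P <- class_probs_at(config$class_curves, p)
    u <- stats::runif(nrow(toks))
    c1 <- P[, "insert"]
    c2 <- c1 + P[, "function"]
    c3 <- c2 + P[, "noun"]
    cls_idx <- 1L + (u > c1) + (u > c2) + (u > c3)
    cls <- c("insert", "function", "noun", "content_other")[cls_idx]

    lex <- make_lexicon(config)
    form <- character(nrow(toks))
    tag <- character(nrow(toks))
    for (cl in c("insert", "function", "noun")) {
      rows <- which(cls == cl)
      sublex <- lex[lex$class == cl, ]
      pick <- sample.int(nrow(sublex), length(rows), replace = TRUE,
                         prob = sublex$weight)
      form[rows] <- sublex$form[pick]
      tag[rows] <- sublex$tag[pick]
    }
    rows <- which(cls == "content_other")
    if (length(rows) > 0) {
      subty <- sample(names(content_other_mix), length(rows), replace = TRUE,
                      prob = content_other_mix)
      for (st in names(content_other_mix)) {
        r2 <- rows[subty == st]
        if (length(r2) == 0) next
        sublex <- lex[lex$class == "content_other" & lex$content_subtype == st, ]
        pick <- sample.int(nrow(sublex), length(r2), replace = TRUE,
                           prob = sublex$weight)
        form[r2] <- sublex$form[pick]
        tag[r2] <- sublex$tag[pick]
      }
    }
    toks$form <- form
    toks$tag <- tag
    toks$size <- NULL
    attr(toks, "tagset") <- config$tagset
    toks
  })
}

#' Generate synthetic pupil streams and turn windows for a corpus
#'
#' Lays the corpus's turns out on a 60 Hz timeline (duration roughly 400 ms
#' per word plus noise, separated by silent gaps) and simulates each
#' participant's continuous pupil stream. Latent processing load is tied to
#' words: within a turn the trajectory steps once per word, rising along the
#' word's normalised position with a per-turn slope
#' `speaker_slope_mean + a_participant + c_conversation +
#' coupling_speaker * slope_frequency(turn) + residual` for speakers, and
#' following a quadratic rise-plateau (no frequency coupling by default) for
#' recipients, so the word-aligned binned estimator measures exactly the
#' programmed coefficients for every turn size. Per-sample
#' noise, per-eye noise, blink gaps (missing runs in both eyes) and
#' occasional single-eye dropouts are added. All latent parameters are
#' returned in the truth log for parameter-recovery testing.
#'
#' @param corpus Token tibble from [generate_corpus()].
#' @param config The same [sim_config()].
#' @param seed Integer seed.
#' @return List with `streams` (participant_id, timestamp_ms, pupil_left_px,
#'   pupil_right_px), `windows` (conversation_id, turn_id, onset_ms,
#'   offset_ms, participant_id, role), and `truth` (turn-level latent
#'   trajectory coefficients and frequency slopes, participant and
#'   conversation effects).
#' @export
generate_pupil <- function(corpus, config, seed = 1) {
  with_seed(seed + 1L, {
    empty <- list(
      streams = tibble::tibble(participant_id = character(),
                               timestamp_ms = numeric(),
                               pupil_left_px = numeric(),
                               pupil_right_px = numeric()),
      windows = tibble::tibble(conversation_id = character(),
                               turn_id = character(), onset_ms = numeric(),
                               offset_ms = numeric(),
                               participant_id = character(),
                               role = character()),
      truth = NULL
    )
    if (nrow(corpus) == 0) return(empty)

    subset <- select_turns(corpus, min(config$sizes), max(config$sizes))
    tab <- build_frequency_table(subset)
    fr <- assign_frequencies(subset, tab)
    fsl <- turn_frequency_slopes(fr)
    fsl <- fsl[order(fsl$conversation_id, fsl$turn_id), ]

    ppc <- config$participants_per_conversation
    convs <- sort(unique(fsl$conversation_id))
    participants <- lapply(seq_along(convs), function(j) {
      sprintf("p%02d", (j - 1) * ppc + seq_len(ppc))
    })
    names(participants) <- convs
    all_p <- unlist(participants)

    a_part <- stats::rnorm(length(all_p), 0, config$participant_trend_sd)
    names(a_part) <- all_p
    c_conv <- stats::rnorm(length(convs), 0, config$conversation_trend_sd)
    names(c_conv) <- convs
    level_part <- stats::rnorm(length(all_p), 0, config$participant_level_sd)
    names(level_part) <- all_p

    # timeline per conversation
    fsl$duration_ms <- pmax(
      fsl$size * config$ms_per_word +
        stats::rnorm(nrow(fsl), 0, config$duration_sd_ms),
      fsl$size * 150
    )
    fsl <- dplyr::mutate(
      dplyr::group_by(fsl, .data$conversation_id),
      offset_ms = 1000 + cumsum(.data$duration_ms + config$gap_ms),
      onset_ms = .data$offset_ms - .data$duration_ms
    )
    fsl <- dplyr::ungroup(fsl)

    # truth per turn x participant
    tt <- list()
    for (cv in convs) {
      turns <- fsl[fsl$conversation_id == cv, ]
      for (pid in participants[[cv]]) {
        role <- ifelse(turns$speaker_id == pid, "speaker", "recipient")
        eps <- stats::rnorm(nrow(turns), 0, config$trend_sd)
        lin <- ifelse(
          role == "speaker",
          config$speaker_slope_mean + a_part[pid] + c_conv[cv] +
            config$coupling_speaker * turns$slope_frequency + eps,
          config$recipient_linear + a_part[pid] + c_conv[cv] +
            config$coupling_recipient * turns$slope_frequency + eps
        )
        quad <- ifelse(role == "speaker", 0, config$recipient_quad)
        tt[[length(tt) + 1]] <- tibble::tibble(
          conversation_id = cv, turn_id = turns$turn_id,
          participant_id = pid, role = role,
          onset_ms = turns$onset_ms, offset_ms = turns$offset_ms,
          slope_frequency = turns$slope_frequency, size = turns$size,
          lin_truth = lin, quad_truth = quad
        )
      }
    }
    turn_truth <- dplyr::bind_rows(tt)

    # streams
    streams <- list()
    step <- 1000 / config$hz
    for (cv in convs) {
      conv_end <- max(fsl$offset_ms[fsl$conversation_id == cv]) + 1000
      ts <- seq(0, conv_end, by = step)
      for (pid in participants[[cv]]) {
        v <- rep(config$baseline_px + level_part[pid], length(ts))
        rows <- turn_truth[turn_truth$conversation_id == cv &
                             turn_truth$participant_id == pid, ]
        for (i in seq_len(nrow(rows))) {
          sel <- ts >= rows$onset_ms[i] & ts < rows$offset_ms[i]
          tn <- (ts[sel] - rows$onset_ms[i]) /
            (rows$offset_ms[i] - rows$onset_ms[i])
          # latent load is per word: the trajectory is a staircase, constant
          # within word w at lin * x_w + quad * x_w^2 with x_w the word's
          # normalised position. Word-aligned bin means then equal the
          # programmed polynomial exactly for every turn size (a trajectory
          # continuous in time would leave bin 1 about slope/(2(size-1))
          # above the baseline datum, a size-dependent offset that aggregates
          # into spurious curvature across turn sizes).
          K <- rows$size[i]
          xw <- (pmin(floor(tn * K), K - 1)) / (K - 1)
          v[sel] <- v[sel] + rows$lin_truth[i] * xw + rows$quad_truth[i] * xw^2
        }
        v <- v + stats::rnorm(length(v), 0, config$noise_sd)
        left <- v + stats::rnorm(length(v), 0, config$eye_noise_sd)
        right <- v + stats::rnorm(length(v), 0, config$eye_noise_sd)
        # blink gaps: missing runs in both eyes
        total_s <- conv_end / 1000
        n_blinks <- stats::rpois(1, config$blink_rate_hz * total_s)
        if (n_blinks > 0) {
          starts <- stats::runif(n_blinks, 0, conv_end)
          lens <- stats::rexp(n_blinks, 1 / config$blink_len_mean_ms)
          for (b in seq_len(n_blinks)) {
            gap <- ts >= starts[b] & ts <= starts[b] + lens[b]
            left[gap] <- NA_real_
            right[gap] <- NA_real_
          }
        }
        if (config$single_eye_dropout > 0) {
          drop <- stats::runif(length(ts)) < config$single_eye_dropout
          which_eye <- stats::runif(length(ts)) < 0.5
          left[drop & which_eye] <- NA_real_
          right[drop & !which_eye] <- NA_real_
        }
        streams[[length(streams) + 1]] <- tibble::tibble(
          participant_id = pid, timestamp_ms = ts,
          pupil_left_px = left, pupil_right_px = right
        )
      }
    }

    windows <- dplyr::select(turn_truth, "conversation_id", "turn_id",
                             "onset_ms", "offset_ms", "participant_id", "role")
    list(
      streams = dplyr::bind_rows(streams),
      windows = windows,
      truth = list(
        turn_truth = turn_truth,
        participant_effects = tibble::tibble(participant_id = all_p,
                                             trend_offset = unname(a_part),
                                             level_offset = unname(level_part)),
        conversation_effects = tibble::tibble(conversation_id = convs,
                                              trend_offset = unname(c_conv)),
        config = config
      )
    )
  })
}

#' Generate and write a complete synthetic dataset bundle
#'
#' Writes `transcript.tsv` (vertical corpus), `pupil.csv` (streams),
#' `windows.csv` (turn windows with roles) and `truth.json` (latent
#' parameters) to a directory. Identical seeds give byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the list of written file paths.
#' @export
generate_dataset <- function(config, dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(config, seed)
  pup <- generate_pupil(corpus, config, seed)
  paths <- list(
    transcript = file.path(dir, "transcript.tsv"),
    pupil = file.path(dir, "pupil.csv"),
    windows = file.path(dir, "windows.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(corpus, paths$transcript)
  readr::write_csv(pup$streams, paths$pupil)
  readr::write_csv(pup$windows, paths$windows)
  truth <- pup$truth
  if (!is.null(truth)) {
    truth$config <- unclass(truth$config)
    truth$config$class_curves <- as.list(truth$config$class_curves)
  }
  jsonlite::write_json(truth, paths$truth, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(paths)
}

#' Analytic expected token frequency by position
#'
#' Under the generator, the normalised per-thousand frequency assigned to a
#' token is its word-tag type's subset-internal count over the subset total.
#' For a token at relative position p this has a closed-form expectation:
#' conditioning on the token's type w, the other N - 1 tokens each realise w
#' independently with the type's marginal probability, so
#' E\[freq | p\] = 1000 * sum_c P(c | p) * (1/N + (N-1)/N * m_c * S2_c),
#' where m_c is the marginal class share over the subset's realised positions
#' and S2_c the sum of squared within-class type probabilities. This is the
#' generator's programmed mean-frequency curve, used as ground truth for
#' trend-recovery tests.
#'
#' @param subset Token tibble from [select_turns()] on a generated corpus.
#' @param config The generating [sim_config()].
#' @return Numeric vector: expected per-thousand frequency for each token.
#' @export
expected_token_frequency <- function(subset, config) {
  N <- nrow(subset)
  P <- class_probs_at(config$class_curves, subset$norm_position)
  m <- colMeans(P)
  s2_class <- function(w) sum(w^2)
  S2 <- c(
    insert = s2_class(zipf_weights(config$n_insert, config$insert_zipf_s)),
    "function" = s2_class(zipf_weights(config$n_function, config$zipf_s)),
    noun = s2_class(zipf_weights(config$n_noun, config$zipf_s)),
    content_other = sum(content_other_mix^2 * c(
      s2_class(zipf_weights(config$n_adjective, config$zipf_s)),
      s2_class(zipf_weights(config$n_adverb, config$zipf_s)),
      s2_class(zipf_weights(config$n_verb, config$zipf_s))
    ))
  )
  per_class <- 1 / N + (N - 1) / N * m[colnames(P)] * S2[colnames(P)]
  as.numeric(1000 * P %*% per_class)
}

#' Programmed positional frequency trend
#'
#' Projects the generator's analytic mean-frequency curve (see
#' [expected_token_frequency()]) onto the orthonormal polynomial basis of the
#' subset's realised positions. The result is the ground-truth coefficient
#' vector that a correctly specified positional trend model estimates.
#'
#' @param subset Token tibble from [select_turns()] on a generated corpus.
#' @param config The generating [sim_config()].
#' @param degree Polynomial degree, default 3.
#' @return Named numeric vector `poly1` ... `poly<degree>`.
#' @export
true_frequency_trend <- function(subset, config, degree = 3) {
  basis <- orthogonal_poly(subset$norm_position, degree)
  ef <- expected_token_frequency(subset, config)
  coefs <- as.numeric(crossprod(basis, ef))
  names(coefs) <- colnames(basis)
  coefs
}

#' Log-log rank-frequency slope
#'
#' Sorts type counts in decreasing order and regresses log10(count) on
#' log10(rank). For a Zipfian sample the slope approximates -s.
#'
#' @param counts Integer vector of type counts (zeros dropped).
#' @return The OLS slope.
#' @export
zipf_slope <- function(counts) {
  counts <- sort(counts[counts > 0], decreasing = TRUE)
  ols_slope(log10(seq_along(counts)), log10(counts))
}
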