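#' Pipeline run configuration
#'
#' Exactly one input source: either the three input files (`transcript`,
#' `pupil`, `windows`) or a simulation config, in which case the bundle is
#' generated under the seed first.
#'
#' @param transcript,pupil,windows Input file paths (vertical TSV, pupil CSV,
#'   turn-window CSV), or NULL when simulating.
#' @param simulate A [sim_config()], or NULL when reading files.
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Integer seed for simulation mode.
#' @param tagset Tag set of the transcript.
#' @param min_size,max_size Turn-size bounds for the analysis subset.
#' @param class_sizes Turn sizes shown in the class-percentage profile.
#' @param max_degree Highest polynomial degree offered to model selection.
#' @param stages Character vector of stages to run, a subset of the default
#'   order.
#' @return A list of class `run_config`.
#' @export
run_config <- function(transcript = NULL, pupil = NULL, windows = NULL,
                       simulate = NULL, out_dir = tempfile("turnload_run_"),
                       seed = 1, tagset = "c5", min_size = 3, max_size = 25,
                       class_sizes = seq(3, 25, by = 2), max_degree = 5,
                       stages = c("load", "frequencies", "classes", "pupil",
                                  "slopes", "fits", "report")) {
  have_files <- !is.null(transcript)
  have_sim <- !is.null(simulate)
  if (have_files == have_sim) {
    stop("configure exactly one input source: input files or a simulation",
         call. = FALSE)
  }
  if (have_files && ("pupil" %in% stages) &&
      (is.null(pupil) || is.null(windows))) {
    stop("pupil stage enabled but no pupil/window files configured",
         call. = FALSE)
  }
  structure(as.list(environment())[names(formals(run_config))],
            class = "run_config")
}

write_stage <- function(df, dir, name) {
  readr::write_csv(df, file.path(dir, paste0(name, ".csv")))
  nrow(df)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load (or simulate), turn selection +
#' frequency profiling, word-class/hapax profiling, pupil preprocessing,
#' slope assembly, model fits, report — writing every intermediate table as
#' plain CSV so each stage is independently re-runnable and diffable, plus a
#' `manifest.json` with seed, per-stage row counts and exclusion tallies.
#' A failing stage aborts with the stage named; artifacts of completed stages
#' are preserved.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   package_version = as.character(utils::packageVersion("turnload")))
  counts <- list()
  env <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    ok <- tryCatch({fun(); TRUE},
                   error = function(e) {
                     stop("stage '", name, "' failed: ", conditionMessage(e),
                          call. = FALSE)
                   })
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(stage = name, rows = counts[[name]])
    invisible(NULL)
  }

  run_stage("load", function() {
    if (!is.null(config$simulate)) {
      paths <- generate_dataset(config$simulate, file.path(config$out_dir, "input"),
                                seed = config$seed)
      env$tokens <- read_vertical_corpus(paths$transcript,
                                         tagset = config$simulate$tagset)
      env$pupil_path <- paths$pupil
      env$windows_path <- paths$windows
    } else {
      env$tokens <- read_vertical_corpus(config$transcript, tagset = config$tagset)
      env$pupil_path <- config$pupil
      env$windows_path <- config$windows
    }
    counts[["load"]] <<- nrow(env$tokens)
  })

  run_stage("frequencies", function() {
    env$subset <- select_turns(env$tokens, config$min_size, config$max_size)
    env$freq_table <- build_frequency_table(env$subset)
    env$subset_freq <- assign_frequencies(env$subset, env$freq_table)
    write_stage(env$freq_table, config$out_dir, "frequency_table")
    prof <- mean_frequency_profile(env$subset_freq, by = "turn_size")
    write_stage(prof, config$out_dir, "frequency_profile")
    manifest$retention <<- attr(env$subset, "retention")
    counts[["frequencies"]] <<- nrow(env$subset)
  })

  run_stage("classes", function() {
    tagset <- attr(env$tokens, "tagset")
    map <- default_classmap(if (is.null(tagset)) config$tagset else tagset)
    cp <- class_position_profile(env$subset, map, sizes = config$class_sizes)
    write_stage(cp, config$out_dir, "class_profile")
    env$class_profile_noun <- class_position_profile(env$subset, map,
                                                     noun_separate = TRUE)
    hp <- hapax_noun_profile(env$subset, env$freq_table, map)
    write_stage(hp, config$out_dir, "hapax_noun_profile")
    env$class_profile <- cp
    env$hapax_profile <- hp
    env$proform_share <- proform_early_share(env$subset)
    manifest$proform_early_share <<- env$proform_share
    counts[["classes"]] <<- nrow(cp)
  })

  run_stage("pupil", function() {
    streams <- readr::read_csv(env$pupil_path, col_types = readr::cols(
      participant_id = readr::col_character(), timestamp_ms = readr::col_double(),
      pupil_left_px = readr::col_double(), pupil_right_px = readr::col_double()))
    windows <- readr::read_csv(env$windows_path, col_types = readr::cols(
      conversation_id = readr::col_character(), turn_id = readr::col_character(),
      onset_ms = readr::col_double(), offset_ms = readr::col_double(),
      participant_id = readr::col_character(), role = readr::col_character()))
    sizes <- dplyr::distinct(env$subset, .data$conversation_id, .data$turn_id,
                             .data$size)
    env$binned <- preprocess_pupil(streams, windows, sizes)
    write_stage(env$binned, config$out_dir, "binned_pupil")
    manifest$pupil_exclusions <<- as.list(attr(env$binned, "exclusions"))
    manifest$mean_samples_per_bin <<- mean(env$binned$bin_count)
    counts[["pupil"]] <<- nrow(env$binned)
  })

  run_stage("slopes", function() {
    fsl <- turn_frequency_slopes(env$subset_freq)
    psl <- turn_pupil_slopes(env$binned)
    env$slope_pairs <- assemble_slope_pairs(fsl, psl)
    write_stage(env$slope_pairs, config$out_dir, "slope_pairs")
    manifest$slope_unmatched <<- as.list(attr(env$slope_pairs, "unmatched"))
    counts[["slopes"]] <<- nrow(env$slope_pairs)
  })

  run_stage("fits", function() {
    fits <- fit_stage(env, config)
    for (nm in names(fits$tables)) {
      write_stage(fits$tables[[nm]], config$out_dir, nm)
    }
    env$fits <- fits
    counts[["fits"]] <<- length(fits$tables)
  })

  run_stage("report", function() {
    figs <- render_report(config$out_dir)
    counts[["report"]] <<- length(figs)
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

selection_tables <- function(sel, stem) {
  out <- list()
  out[[paste0(stem, "_coefficients")]] <- sel$fit$coefficients
  out[[paste0(stem, "_selection_trace")]] <- sel$trace
  out
}

# The inference stage: positional trend models mirroring the four analysis
# questions (token frequency by position; word-class percentages by position;
# hapax-noun percentages by position; binned pupil size by position and role)
# plus the slope-coupling model, with EMM post-hoc trends per role.
fit_stage <- function(env, config) {
  tables <- list()

  # token frequency ~ polynomial(position) x scaled size, random intercepts
  d1 <- env$subset_freq
  d1$size_z <- as.numeric(scale(d1$size))
  sel_freq <- select_polynomial_model(
    d1, response = "frequency", position = "norm_position",
    controls = "size_z", random = c("speaker_id", "conversation_id"),
    max_degree = config$max_degree
  )
  tables <- c(tables, selection_tables(sel_freq, "fit_frequency"))

  # word-class percentages ~ polynomial(position) x class (aggregated: lm);
  # coded at noun vs function vs insert granularity
  d2 <- env$class_profile_noun
  d2 <- d2[d2$word_class %in% c("noun", "insert", "function"), ]
  d2$word_class <- code_wordclass(d2$word_class)
  sel_class <- select_polynomial_model(
    d2, response = "pct", position = "norm_position",
    interest = "word_class", max_degree = config$max_degree
  )
  tables <- c(tables, selection_tables(sel_class, "fit_wordclass"))

  # hapax-noun percentages ~ polynomial(position) (aggregated: lm)
  sel_hapax <- select_polynomial_model(
    env$hapax_profile, response = "pct_hapax_noun",
    position = "norm_position", max_degree = config$max_degree
  )
  tables <- c(tables, selection_tables(sel_hapax, "fit_hapax"))

  fits <- list(frequency = sel_freq, wordclass = sel_class, hapax = sel_hapax)

  if (!is.null(env$binned)) {
    d4 <- env$binned
    d4$role <- code_role(d4$role)
    d4$size_z <- as.numeric(scale(d4$size))
    sel_pupil <- select_polynomial_model(
      d4, response = "bin_mean", position = "norm_position",
      interest = "role", controls = "size_z",
      random = c("participant_id", "conversation_id"),
      max_degree = min(config$max_degree, 3)
    )
    tables <- c(tables, selection_tables(sel_pupil, "fit_pupil"))
    emm_lin <- emm_simple_effects(sel_pupil$fit, "poly1", "role")
    emm_lin$trend <- "position"
    pupil_emm <- emm_lin
    if (sel_pupil$degree >= 2) {
      emm_quad <- emm_simple_effects(sel_pupil$fit, "poly2", "role")
      emm_quad$trend <- "position2"
      pupil_emm <- dplyr::bind_rows(emm_lin, emm_quad)
    }
    tables$fit_pupil_posthoc <- pupil_emm
    fits$pupil <- sel_pupil

    # predictions for the report: modeled pupil trajectory by role
    grid <- expand.grid(norm_position = seq(0, 1, by = 0.05),
                        role = levels(d4$role))
    basis_data <- orthogonal_poly(d4$norm_position, max(sel_pupil$degree, 1))
    # map grid positions onto the fitted orthonormal basis by interpolation
    for (k in seq_len(sel_pupil$degree)) {
      ip <- stats::approx(d4$norm_position, basis_data[, k],
                          xout = grid$norm_position, ties = mean)
      grid[[paste0("poly", k)]] <- ip$y
    }
    grid$size_z <- 0
    grid$role <- code_role(grid$role)
    grid$predicted <- stats::predict(sel_pupil$fit$model, newdata = grid,
                                     re.form = NA)
    grid$role <- as.character(grid$role)
    tables$pupil_predictions <- tibble::as_tibble(grid)
  }

  if (!is.null(env$slope_pairs)) {
    d5 <- env$slope_pairs
    d5$role <- code_role(d5$role)
    coupling <- fit_mixed(
      slope_pupil ~ slope_frequency * role + turn_size_scaled +
        (1 | participant_id) + (1 | conversation_id),
      d5
    )
    tables$fit_coupling_coefficients <- coupling$coefficients
    emm <- emm_simple_effects(coupling, "slope_frequency", "role")
    tables$fit_coupling_posthoc <- emm
    fits$coupling <- coupling
  }

  list(tables = tables, fits = fits)
}

#' Render figures and summary tables from a completed run directory
#'
#' Draws the per-position frequency profile, the word-class percentage
#' curves, the modeled pupil trajectories by role and the slope-coupling
#' scatter from the stage CSVs in a run directory. Every plotted series comes
#' straight from a CSV written by the pipeline, so the plot data are
#' diffable. Stages whose outputs are missing are skipped with a message.
#'
#' @param dir Run directory written by [run_pipeline()].
#' @return Invisibly, the paths of the figures written.
#' @export
render_report <- function(dir) {
  figs <- character()
  save_fig <- function(p, name) {
    path <- file.path(dir, paste0(name, ".png"))
    suppressMessages(ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 120))
    figs <<- c(figs, path)
  }
  has <- function(name) file.exists(file.path(dir, paste0(name, ".csv")))
  rd <- function(name) readr::read_csv(file.path(dir, paste0(name, ".csv")),
                                       show_col_types = FALSE)

  if (has("frequency_profile")) {
    prof <- rd("frequency_profile")
    p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$index,
                                            y = .data$mean_frequency,
                                            group = .data$size,
                                            colour = factor(.data$size))) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::labs(x = "word position in turn",
                    y = "mean frequency (per thousand)",
                    colour = "turn size",
                    title = "Mean word frequency per turn position") +
      ggplot2::theme_minimal()
    save_fig(p, "fig_frequency_profile")
  } else message("frequency profile missing; panel skipped")

  if (has("class_profile")) {
    cp <- rd("class_profile")
    p <- ggplot2::ggplot(cp, ggplot2::aes(x = .data$norm_position,
                                          y = .data$pct,
                                          colour = .data$word_class)) +
      ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
      ggplot2::labs(x = "relative position", y = "% of tokens",
                    title = "Word-class percentages by position") +
      ggplot2::theme_minimal()
    save_fig(p, "fig_class_profile")
  } else message("class profile missing; panel skipped")

  if (has("pupil_predictions")) {
    pp <- rd("pupil_predictions")
    p <- ggplot2::ggplot(pp, ggplot2::aes(x = .data$norm_position,
                                          y = .data$predicted,
                                          colour = .data$role)) +
      ggplot2::geom_line(linewidth = 1) +
      ggplot2::labs(x = "relative position", y = "baselined pupil size (px)",
                    title = "Modeled pupil size within turns by role") +
      ggplot2::theme_minimal()
    save_fig(p, "fig_pupil_by_role")
  } else message("pupil predictions missing; panel skipped")

  if (has("slope_pairs")) {
    sp <- rd("slope_pairs")
    p <- ggplot2::ggplot(sp, ggplot2::aes(x = .data$slope_frequency,
                                          y = .data$slope_pupil,
                                          colour = .data$role)) +
      ggplot2::geom_point(alpha = 0.2, size = 0.6) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
      ggplot2::labs(x = "frequency slope (per-thousand / turn)",
                    y = "pupil slope (px / turn)",
                    title = "Pupil-slope vs frequency-slope coupling by role") +
      ggplot2::theme_minimal()
    save_fig(p, "fig_slope_coupling")
  } else message("slope pairs missing; panel skipped")

  invisible(figs)
}
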