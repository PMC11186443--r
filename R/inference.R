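#' Orthonormal polynomial basis
#'
#' Builds polynomial transforms of `x` up to the requested degree whose
#' columns are mutually orthogonal with unit norm, the constant term
#' excluded (so every column is also orthogonal to the intercept). The basis
#' is constructed by modified Gram-Schmidt with reorthogonalisation on the
#' centred power sequence, and is nested: the degree-k column of a degree-d
#' basis equals the degree-k column of any higher-degree basis on the same
#' `x`.
#'
#' @param x Numeric vector with more than `degree` distinct values.
#' @param degree Highest polynomial degree.
#' @return An n x degree matrix with columns `poly1`, ..., `poly<degree>`;
#'   attribute `degree`.
#' @export
orthogonal_poly <- function(x, degree) {
  if (degree < 1) stop("degree must be at least 1", call. = FALSE)
  if (length(unique(x)) <= degree) {
    stop("need more than ", degree, " distinct x values for a degree-",
         degree, " basis", call. = FALSE)
  }
  n <- length(x)
  xc <- x - mean(x)
  V <- outer(xc, 0:degree, `^`)
  Q <- matrix(0, n, degree + 1)
  for (j in seq_len(degree + 1)) {
    v <- V[, j]
    for (pass in 1:2) {
      for (k in seq_len(j - 1)) {
        v <- v - sum(Q[, k] * v) * Q[, k]
      }
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10 * max(1, sqrt(sum(V[, j]^2)))) {
      stop("x is numerically rank deficient at degree ", j - 1, call. = FALSE)
    }
    Q[, j] <- v / nv
  }
  out <- Q[, -1, drop = FALSE]
  colnames(out) <- paste0("poly", seq_len(degree))
  attr(out, "degree") <- degree
  out
}

#' Add orthogonal polynomial columns to a data frame
#'
#' @param data A data frame.
#' @param var Name of the numeric column to expand.
#' @param degree Highest degree.
#' @param prefix Column-name prefix, default `"poly"`.
#' @return `data` with `prefix1` ... `prefix<degree>` columns appended.
#' @export
add_poly <- function(data, var, degree, prefix = "poly") {
  basis <- orthogonal_poly(data[[var]], degree)
  for (k in seq_len(degree)) {
    data[[paste0(prefix, k)]] <- basis[, k]
  }
  data
}

#' Contrast-code participant role
#'
#' Two-level factor (recipient, speaker) with a centred +/-0.5 contrast:
#' recipient -0.5, speaker +0.5. The role main effect is then the
#' speaker-minus-recipient difference and interactions with role read as
#' difference-in-trend terms.
#'
#' @param x Character or factor vector of roles.
#' @return Factor with the contrast attached.
#' @export
code_role <- function(x) {
  f <- factor(x, levels = c("recipient", "speaker"))
  if (anyNA(f)) stop("role must be 'speaker' or 'recipient'", call. = FALSE)
  stats::contrasts(f) <- matrix(c(-0.5, 0.5), ncol = 1,
                                dimnames = list(levels(f), "spk"))
  f
}

#' Deviation-code word class
#'
#' Three-level factor coded so each named level is compared with the grand
#' mean (sum coding); the omitted level (default the function-word class) has
#' no own coefficient. Codes sum to zero across levels.
#'
#' @param x Character or factor vector of word classes.
#' @param levels Level order; the last level is the omitted one.
#' @return Factor with sum contrasts whose columns are named after the
#'   non-omitted levels.
#' @export
code_wordclass <- function(x, levels = c("noun", "insert", "function")) {
  f <- factor(x, levels = levels)
  if (anyNA(f)) {
    stop("word class must be one of: ", paste(levels, collapse = ", "),
         call. = FALSE)
  }
  k <- length(levels)
  cm <- stats::contr.sum(k)
  dimnames(cm) <- list(levels, levels[-k])
  stats::contrasts(f) <- cm
  f
}

new_turnload_fit <- function(model, coefficients, method, converged, singular,
                             ranef_var, data) {
  structure(
    list(model = model, coefficients = coefficients, method = method,
         converged = converged, singular = singular, ranef_var = ranef_var,
         data = data),
    class = "turnload_fit"
  )
}

#' @exportS3Method base::print
print.turnload_fit <- function(x, ...) {
  cat("<turnload_fit> method:", x$method,
      if (x$singular) "(singular fit)" else "",
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' Fixed-effects regression fit
#'
#' Least-squares fit with classical standard errors and two-sided t tests,
#' returned as a tidy coefficient table. Used for the aggregated
#' word-class-percentage and hapax-noun models, where grouping information is
#' lost by aggregation and no random effects apply.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @return A `turnload_fit` with a `coefficients` tibble
#'   (`term`, `estimate`, `se`, `statistic`, `df`, `p_value`).
#' @export
fit_lm <- function(formula, data) {
  model <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(model))) {
    aliased <- names(stats::coef(model))[is.na(stats::coef(model))]
    stop("design matrix is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  s <- summary(model)$coefficients
  coefs <- tibble::tibble(
    term = rownames(s), estimate = unname(s[, 1]), se = unname(s[, 2]),
    statistic = unname(s[, 3]), df = stats::df.residual(model),
    p_value = unname(s[, 4])
  )
  new_turnload_fit(model, coefs, "lm", TRUE, FALSE, NULL, data)
}

#' Mixed-effects regression fit with random intercepts
#'
#' REML fit of the fixed effects with the requested random-intercept terms,
#' via lme4; p-values use the Satterthwaite degrees-of-freedom approximation
#' (lmerTest). A singular fit (a variance estimated at the boundary, common
#' with few grouping levels) is reported through the `singular` flag, not
#' hidden; non-convergence is reported through `converged`.
#'
#' @param formula An lme4-style formula, e.g.
#'   `y ~ poly1 * role + (1 | participant_id) + (1 | conversation_id)`.
#' @param data Data frame.
#' @param reml Use REML (default) or ML.
#' @return A `turnload_fit`; `ranef_var` holds the random-intercept
#'   variances.
#' @export
fit_mixed <- function(formula, data, reml = TRUE) {
  model <- suppressMessages(lmerTest::lmer(formula, data = data, REML = reml))
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  # a boundary (singular) fit is not a convergence failure; it is reported
  # through the singular flag instead
  conv <- length(grep("boundary", msgs, invert = TRUE, value = TRUE)) == 0
  singular <- lme4::isSingular(model)
  s <- stats::coef(summary(model))
  coefs <- tibble::tibble(
    term = rownames(s), estimate = unname(s[, "Estimate"]),
    se = unname(s[, "Std. Error"]), statistic = unname(s[, "t value"]),
    df = unname(s[, "df"]), p_value = unname(s[, "Pr(>|t|)"])
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  ranef_var <- tibble::tibble(group = vc$grp, variance = vc$vcov)
  new_turnload_fit(model, coefs, if (reml) "lmer-REML" else "lmer-ML",
                   conv, singular, ranef_var, data)
}

fit_any <- function(formula, data, random = NULL, reml = TRUE) {
  if (is.null(random) || length(random) == 0) {
    fit_lm(formula, data)
  } else {
    rterms <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    f <- stats::as.formula(paste(deparse(formula, width.cutoff = 500),
                                 "+", rterms))
    fit_mixed(f, data, reml = reml)
  }
}

term_p <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) NA_real_ else fit$coefficients$p_value[i]
}

#' Incremental polynomial model selection
#'
#' Implements the two-phase selection procedure for positional trend models.
#' Phase 1 starts from the linear-position model with all interactions of the
#' position term with the control variables and removes the control
#' interactions that are not significant (p > `alpha`). Phase 2 then grows
#' the polynomial: the next-higher orthogonal position term (plus its
#' interactions with the factors of interest and with the retained controls)
#' is added and kept while the newly added main term is significant below
#' `alpha`, stopping at the first non-significant addition or at
#' `max_degree`.
#'
#' Polynomial columns are orthonormal transforms of `position`
#' (see [orthogonal_poly()]), so lower-order coefficients are stable as terms
#' are added.
#'
#' @param data Data frame holding the response, position, factors and
#'   controls.
#' @param response Name of the response column.
#' @param position Name of the (normalised) position column.
#' @param interest Character vector of factor-of-interest columns (e.g.
#'   `"role"`, `"word_class"`) whose interactions with every polynomial term
#'   are always carried.
#' @param controls Character vector of control-variable columns (e.g. scaled
#'   turn size).
#' @param random Character vector of random-intercept grouping columns, or
#'   NULL for a fixed-effects fit.
#' @param max_degree Highest degree considered, default 5.
#' @param alpha Significance threshold, default 0.05.
#' @return List of class `turnload_selection`: `fit` (the final
#'   `turnload_fit`), `degree`, `kept_control_interactions`, and a `trace`
#'   tibble of every decision.
#' @export
select_polynomial_model <- function(data, response, position,
                                    interest = character(),
                                    controls = character(),
                                    random = NULL,
                                    max_degree = 5, alpha = 0.05) {
  data <- add_poly(data, position, max_degree)
  trace <- list()
  note <- function(step, action, term, p, kept) {
    trace[[length(trace) + 1]] <<- tibble::tibble(
      step = step, action = action, term = term, p_value = p, kept = kept)
  }

  build_formula <- function(degree, ctrl_inter) {
    polys <- paste0("poly", seq_len(degree))
    terms <- polys
    for (f in interest) {
      terms <- c(terms, f, paste0(polys, ":", f))
    }
    terms <- c(terms, controls)
    for (ci in ctrl_inter) {
      terms <- c(terms, paste0(polys, ":", ci))
    }
    stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  }

  # Phase 1: prune non-significant control interactions at degree 1.
  fit1 <- fit_any(build_formula(1, controls), data, random)
  kept_ctrl <- character()
  for (ci in controls) {
    tname <- grep(paste0("^poly1:", ci, "$|^", ci, ":poly1$"),
                  fit1$coefficients$term, value = TRUE)
    p <- if (length(tname)) term_p(fit1, tname[1]) else NA_real_
    keep <- !is.na(p) && p <= alpha
    note(1L, "prune_control_interaction", paste0("poly1:", ci), p, keep)
    if (keep) kept_ctrl <- c(kept_ctrl, ci)
  }
  fit <- fit_any(build_formula(1, kept_ctrl), data, random)
  degree <- 1L
  note(1L, "base_model", "poly1", term_p(fit, "poly1"), TRUE)

  # Phase 2: grow the polynomial while the newly added term is significant.
  while (degree < max_degree) {
    cand <- degree + 1L
    cand_fit <- fit_any(build_formula(cand, kept_ctrl), data, random)
    p_new <- term_p(cand_fit, paste0("poly", cand))
    keep <- !is.na(p_new) && p_new < alpha
    note(2L, "add_polynomial", paste0("poly", cand), p_new, keep)
    if (!keep) break
    fit <- cand_fit
    degree <- cand
  }

  structure(
    list(fit = fit, degree = degree,
         kept_control_interactions = kept_ctrl,
         trace = dplyr::bind_rows(trace)),
    class = "turnload_selection"
  )
}

#' @exportS3Method base::print
print.turnload_selection <- function(x, ...) {
  cat("<turnload_selection> selected degree:", x$degree, "\n")
  cat("kept control interactions:",
      if (length(x$kept_control_interactions))
        paste(x$kept_control_interactions, collapse = ", ") else "none", "\n")
  print(x$fit)
  invisible(x)
}

#' Estimated-marginal-means simple-effect trends
#'
#' For a model in which a numeric trend term (e.g. the linear or quadratic
#' orthogonal position term, or the per-turn frequency slope) interacts with
#' a factor, computes the estimated trend within each factor level, with
#' standard errors and multiplicity-adjusted p-values across the level family
#' (Bonferroni by default).
#'
#' @param fit A `turnload_fit` whose model contains `trend` interacting with
#'   `by`.
#' @param trend Name of the numeric trend column.
#' @param by Name of the factor.
#' @param adjust Multiplicity adjustment passed to emmeans, default
#'   `"bonferroni"`.
#' @return Tibble with `level`, `estimate`, `se`, `statistic`, `p_value`
#'   (adjusted) and `p_unadjusted`.
#' @export
emm_simple_effects <- function(fit, trend, by, adjust = "bonferroni") {
  if (!by %in% names(fit$data)) {
    stop("factor '", by, "' is not present in the model data", call. = FALSE)
  }
  emt <- suppressMessages(
    emmeans::emtrends(fit$model, stats::as.formula(paste("~", by)),
                      var = trend, data = fit$data,
                      lmer.df = "satterthwaite")
  )
  adj <- suppressMessages(as.data.frame(emmeans::test(emt, adjust = adjust)))
  raw <- suppressMessages(as.data.frame(emmeans::test(emt, adjust = "none")))
  est_col <- grep("\\.trend$", names(adj), value = TRUE)[1]
  stat_col <- intersect(c("t.ratio", "z.ratio"), names(adj))[1]
  tibble::tibble(
    level = as.character(adj[[by]]),
    estimate = adj[[est_col]],
    se = adj[["SE"]],
    statistic = adj[[stat_col]],
    p_value = adj[["p.value"]],
    p_unadjusted = raw[["p.value"]]
  )
}
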