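test_that("orthogonal polynomial bases are orthonormal and match stats::poly", {
  set.seed(6)
  for (i in 1:100) {
    n <- sample(8:60, 1)
    d <- sample(1:5, 1)
    x <- rnorm(n)
    Q <- orthogonal_poly(x, d)
    G <- crossprod(cbind(1 / sqrt(n), Q))
    expect_lt(max(abs(G - diag(d + 1))), 1e-8)
    # columns agree with stats::poly up to sign
    P <- unclass(stats::poly(x, d))
    agree <- abs(colSums(Q * P))
    expect_true(all(abs(agree - 1) < 1e-8))
  }
})

test_that("equispaced bases reproduce classical polynomial contrasts", {
  Q <- orthogonal_poly(1:5, 3)
  C <- stats::contr.poly(5)[, 1:3]
  for (k in 1:3) {
    expect_equal(abs(Q[, k]), abs(C[, k]), tolerance = 1e-10)
  }
  # symmetric x: odd-degree columns odd, even-degree columns even
  x <- seq(-1, 1, length.out = 9)
  Q2 <- orthogonal_poly(x, 2)
  expect_equal(Q2[, 1], -rev(Q2[, 1]))
  expect_equal(Q2[, 2], rev(Q2[, 2]))
  # nested: lower columns unchanged when the degree grows
  x3 <- runif(30)
  expect_equal(orthogonal_poly(x3, 2)[, 1:2], orthogonal_poly(x3, 4)[, 1:2],
               ignore_attr = TRUE)
  expect_error(orthogonal_poly(c(1, 1, 2), 2), "distinct")
})

test_that("factor codings are centred and releveling leaves predictions alone", {
  role <- code_role(c("speaker", "recipient", "speaker"))
  expect_equal(sum(unique(stats::contrasts(role))), 0)
  expect_equal(unname(stats::contrasts(role)["speaker", ]), 0.5)

  wc <- code_wordclass(rep(c("noun", "insert", "function"), 4))
  expect_true(all(colSums(stats::contrasts(wc)) == 0))
  expect_equal(colnames(stats::contrasts(wc)), c("noun", "insert"))

  set.seed(7)
  d <- data.frame(y = rnorm(30),
                  g = rep(c("noun", "insert", "function"), 10))
  d$g1 <- code_wordclass(d$g)
  d$g2 <- code_wordclass(d$g, levels = c("insert", "function", "noun"))
  f1 <- fit_lm(y ~ g1, d)
  f2 <- fit_lm(y ~ g2, d)
  expect_equal(unname(stats::fitted(f1$model)), unname(stats::fitted(f2$model)),
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f1$coefficients$estimate,
                                f2$coefficients$estimate)))
})

test_that("fixed-effects fits match the normal equations", {
  set.seed(8)
  x <- runif(40)
  d <- data.frame(x = x, y = 2 - 3 * x)
  f <- suppressWarnings(fit_lm(y ~ x, d))   # exact fit: summary warns
  expect_equal(f$coefficients$estimate, c(2, -3), tolerance = 1e-10)
  expect_equal(sum(stats::resid(f$model)^2), 0, tolerance = 1e-12)

  d2 <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  d2$y <- 1 + d2$x1 - 0.5 * d2$x2 + rnorm(50)
  f2 <- fit_lm(y ~ x1 + x2, d2)
  X <- cbind(1, d2$x1, d2$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d2$y)
  expect_equal(f2$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)

  d3 <- d2; d3$x3 <- d3$x1 * 2
  expect_error(fit_lm(y ~ x1 + x3, d3), "rank deficient")
})

test_that("mixed fits collapse to fixed-effects fits when variances are zero", {
  set.seed(9)
  d <- data.frame(x = rnorm(120),
                  participant = rep(sprintf("p%d", 1:6), each = 20),
                  conversation = rep(sprintf("c%d", 1:3), each = 40))
  d$y <- 1 + 2 * d$x + rnorm(120)    # no group structure at all
  fm <- fit_mixed(y ~ x + (1 | participant) + (1 | conversation), d)
  fl <- fit_lm(y ~ x, d)
  expect_equal(fm$coefficients$estimate, fl$coefficients$estimate,
               tolerance = 1e-4)
  expect_true(fm$singular)           # boundary fit is reported, not hidden
  expect_equal(fm$ranef_var$variance[fm$ranef_var$group == "Residual"],
               stats::sigma(fm$model)^2)
})

test_that("mixed fits recover a programmed group effect", {
  set.seed(10)
  n_g <- 12; per <- 30
  u <- rnorm(n_g, 0, 2)
  d <- data.frame(
    g = rep(sprintf("g%02d", 1:n_g), each = per),
    x = rep(c(-0.5, 0.5), n_g * per / 2)
  )
  delta <- 1.5
  d$y <- 3 + delta * d$x + u[as.integer(factor(d$g))] + rnorm(nrow(d))
  fm <- fit_mixed(y ~ x + (1 | g), d)
  i <- match("x", fm$coefficients$term)
  expect_lt(abs(fm$coefficients$estimate[i] - delta), 3 * fm$coefficients$se[i])
  expect_gt(fm$ranef_var$variance[fm$ranef_var$group == "g"], 0.5)
})

test_that("polynomial selection stops where the signal stops", {
  set.seed(11)
  n <- 1500
  d <- data.frame(pos = runif(n), noise = rnorm(n))
  # pure linear trend, strong; next term should fail to enter
  d$y <- 5 - 4 * d$pos + rnorm(n, 0, 0.5)
  sel_lin <- select_polynomial_model(d, "y", "pos", max_degree = 5)
  expect_equal(sel_lin$degree, 1)

  # strong cubic trend (with non-vanishing quadratic component, so the
  # stepwise path linear -> quadratic -> cubic can reach it)
  d$y3 <- 2 * d$pos + 3 * d$pos^2 - 8 * d$pos^3 + rnorm(n, 0, 0.05)
  sel_cub <- select_polynomial_model(d, "y3", "pos", max_degree = 5)
  expect_equal(sel_cub$degree, 3)

  # max_degree = 1 returns the linear fit untouched
  sel1 <- select_polynomial_model(d, "y3", "pos", max_degree = 1)
  expect_equal(sel1$degree, 1)
  expect_equal(sum(sel1$trace$action == "add_polynomial"), 0)

  # an uninformative control's interaction is pruned in phase 1
  sel_ctrl <- select_polynomial_model(d, "y", "pos", controls = "noise",
                                      max_degree = 2)
  expect_false("noise" %in% sel_ctrl$kept_control_interactions)
  expect_true("noise:poly1" %in% sel_ctrl$trace$term |
                "poly1:noise" %in% sel_ctrl$trace$term)
  # the pruned interaction is absent from the final model
  expect_false(any(grepl("noise:poly|poly1:noise",
                         sel_ctrl$fit$coefficients$term)))
})

test_that("selection is deterministic given the data", {
  set.seed(12)
  d <- data.frame(pos = runif(400))
  d$y <- d$pos + rnorm(400, 0, 0.3)
  s1 <- select_polynomial_model(d, "y", "pos", max_degree = 4)
  s2 <- select_polynomial_model(d, "y", "pos", max_degree = 4)
  expect_equal(s1$degree, s2$degree)
  expect_equal(s1$fit$coefficients, s2$fit$coefficients)
})

test_that("EMM simple effects follow the coding algebra on balanced designs", {
  set.seed(13)
  n <- 400
  d <- data.frame(x = runif(n), role = rep(c("speaker", "recipient"), n / 2))
  d$y <- 1 + 2 * d$x + 3 * d$x * (d$role == "speaker") + rnorm(n, 0, 0.3)
  d$role <- code_role(d$role)
  f <- fit_lm(y ~ x * role, d)
  emm <- emm_simple_effects(f, "x", "role")
  b <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
  # with the +/-0.5 coding: level trends are main +/- half the interaction
  expect_equal(emm$estimate[emm$level == "speaker"],
               unname(b["x"] + 0.5 * b["x:rolespk"]), tolerance = 1e-8)
  expect_equal(emm$estimate[emm$level == "recipient"],
               unname(b["x"] - 0.5 * b["x:rolespk"]), tolerance = 1e-8)
  expect_true(all(emm$p_value >= emm$p_unadjusted - 1e-15))

  # no interaction: per-level trends equal the main-effect trend
  d$y0 <- 1 + 2 * d$x + rnorm(n, 0, 0.3)
  f0 <- fit_lm(y0 ~ x + role, d)
  emm0 <- emm_simple_effects(f0, "x", "role")
  expect_equal(emm0$estimate[1], emm0$estimate[2], tolerance = 1e-8)

  expect_error(emm_simple_effects(f, "x", "word_class"), "not present")
})
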