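test_that("model_spec validates disjointness and the order condition", {
  expect_error(model_spec("y", "x", c("x", "w"), "z"), "both")
  expect_error(model_spec("y", c("x1", "x2"), "w", "z"), "order condition")
  expect_error(model_spec("y", "x", "w", c("z", "y")), "outcome")
  sp <- model_spec("y", "x", "w", c("z1", "z2"))
  expect_s3_class(sp, "model_spec")
})

test_that("OLS recovers exact fits on hand-computable data", {
  d <- data.frame(y = c(0, 1, 2), x = c(0, 1, 2), w = c(1, -1, 0))
  sp <- model_spec("y", "x", "w", c("z"))
  d$z <- rnorm(3)
  fit <- fit_ols(sp, d)
  expect_equal(unname(fit$coefficients["x"]), 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["w"]), 0, tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-12)
})

test_that("OLS HC1 covariance matches the sandwich package", {
  skip_if_not_installed("sandwich")
  set.seed(11)
  n <- 120
  d <- data.frame(x = rnorm(n), w = rnorm(n))
  d$y <- 1 + 0.5 * d$x - 0.2 * d$w + rnorm(n) * (1 + abs(d$x))
  d$z <- rnorm(n)
  fit <- fit_ols(model_spec("y", "x", "w", "z"), d)
  lmfit <- lm(y ~ x + w, data = d)
  V <- sandwich::vcovHC(lmfit, type = "HC1")
  expect_equal(unname(fit$vcov[c("(Intercept)", "x", "w"), c("(Intercept)", "x", "w")]),
               unname(V), tolerance = 1e-10)
  expect_true(all(fit$se > 0 & is.finite(fit$se)))
})

test_that("rank-deficient designs raise an informative error", {
  d <- data.frame(y = rnorm(10), x = rnorm(10))
  d$w <- 2 * d$x
  d$z <- rnorm(10)
  expect_error(fit_ols(model_spec("y", "x", "w", "z"), d), "singular design")
})

test_that("2SLS matches the closed-form IV solution from projection algebra", {
  for (seed in 1:10) {
    inst <- random_iv_instance(seed, n = 40,
                               k_endog = 1 + seed %% 2,
                               k_instr = 2 + seed %% 3, k_exog = 2)
    if (length(inst$spec$instruments) < length(inst$spec$endogenous)) next
    fit <- fit_2sls(inst$spec, inst$data)
    X <- cbind(1, as.matrix(inst$data[, c(inst$spec$endogenous, inst$spec$exogenous)]))
    Z <- cbind(1, as.matrix(inst$data[, c(inst$spec$exogenous, inst$spec$instruments)]))
    want <- oracle_iv(inst$data$y, X, Z)
    got <- fit$coefficients[c("(Intercept)", inst$spec$endogenous, inst$spec$exogenous)]
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("just-identified single-endogenous 2SLS equals (Z'X)^-1 Z'y", {
  # printed six-observation fixture
  d <- data.frame(y = c(1.2, 0.7, 2.4, 1.9, 3.1, 0.2),
                  en = c(0.5, 0.1, 1.0, 0.8, 1.4, -0.2),
                  ex = c(1, 0, 1, 0, 1, 0),
                  z = c(0.3, -0.1, 0.9, 0.7, 1.2, -0.5))
  sp <- model_spec("y", "en", "ex", "z")
  fit <- fit_2sls(sp, d)
  X <- cbind(1, d$en, d$ex)
  Z <- cbind(1, d$ex, d$z)
  want <- solve(t(Z) %*% X, t(Z) %*% d$y)[, 1]
  expect_equal(unname(fit$coefficients[c("(Intercept)", "en", "ex")]),
               unname(want), tolerance = 1e-10)
})

test_that("2SLS with instruments equal to the endogenous column reduces to OLS", {
  set.seed(4)
  n <- 60
  d <- data.frame(en = rnorm(n), ex = rnorm(n))
  d$y <- 0.3 + 0.8 * d$en - 0.1 * d$ex + rnorm(n)
  d$z <- d$en   # projection of en on z is the identity
  sp <- model_spec("y", "en", "ex", "z")
  ols <- fit_ols(sp, d)
  tsls <- fit_2sls(sp, d)
  expect_equal(unname(tsls$coefficients), unname(ols$coefficients),
               tolerance = 1e-10)
})

test_that("first-stage F equals the squared t statistic in the 1x1 case", {
  set.seed(12)
  n <- 80
  d <- data.frame(ex = rnorm(n), z = rnorm(n), v = rnorm(n))
  d$en <- 0.6 * d$z + 0.2 * d$ex + d$v
  d$y <- 1 + 0.5 * d$en + 0.3 * d$ex + rnorm(n)
  fit <- fit_2sls(model_spec("y", "en", "ex", "z"), d)
  diag <- weak_instrument_diagnostics(fit)
  # robust F vs robust squared t from an HC1 first-stage regression
  fs <- lm(en ~ ex + z, data = d)
  Vr <- rxpeer:::hc1_vcov(solve(crossprod(model.matrix(fs))),
                          model.matrix(fs), residuals(fs), n, 3)
  t_rob <- coef(fs)["z"] / sqrt(Vr[3, 3])
  expect_equal(diag$first_stage$F_robust, unname(t_rob^2), tolerance = 1e-8)
  # classical F vs the anova-style squared t
  t_cls <- summary(fs)$coefficients["z", "t value"]
  expect_equal(diag$first_stage$F_classical, unname(t_cls^2), tolerance = 1e-8)
})

test_that("Cragg-Donald equals the classical first-stage F with one endogenous", {
  set.seed(13)
  n <- 100
  d <- data.frame(ex = rnorm(n), z1 = rnorm(n), z2 = rnorm(n))
  d$en <- 0.4 * d$z1 - 0.3 * d$z2 + 0.2 * d$ex + rnorm(n)
  d$y <- 1 + 0.5 * d$en + rnorm(n)
  fit <- fit_2sls(model_spec("y", "en", "ex", c("z1", "z2")), d)
  diag <- weak_instrument_diagnostics(fit)
  expect_equal(diag$cragg_donald$statistic, diag$first_stage$F_classical,
               tolerance = 1e-8)
})

test_that("pure-noise instruments are flagged weak", {
  set.seed(14)
  n <- 500
  d <- data.frame(ex = rnorm(n), z1 = rnorm(n), z2 = rnorm(n), z3 = rnorm(n))
  d$en <- 0.2 * d$ex + rnorm(n)
  d$y <- 1 + 0.5 * d$en + rnorm(n)
  fit <- fit_2sls(model_spec("y", "en", "ex", c("z1", "z2", "z3")), d)
  diag <- weak_instrument_diagnostics(fit)
  expect_false(diag$first_stage$reliable)
  expect_true("en" %in% diag$unreliable)
})

test_that("overidentification test degrades gracefully when just identified", {
  set.seed(15)
  n <- 50
  d <- data.frame(ex = rnorm(n), z = rnorm(n), v = rnorm(n))
  d$en <- 0.7 * d$z + d$v
  d$y <- 1 + 0.5 * d$en + rnorm(n) + 0.5 * d$v
  fit <- fit_2sls(model_spec("y", "en", "ex", "z"), d)
  o <- overidentification_test(fit)
  expect_equal(o$df, 0L)
  expect_true(is.na(o$p_value))
})

test_that("overidentification test rejects an instrument entering the outcome", {
  set.seed(16)
  n <- 2000
  d <- data.frame(z1 = rnorm(n), z2 = rnorm(n), ex = rnorm(n), v = rnorm(n))
  d$en <- 0.8 * d$z1 + 0.8 * d$z2 + 0.3 * d$ex + d$v
  d$y <- 1 + 0.5 * d$en + 0.6 * d$z2 + rnorm(n) + 0.5 * d$v  # z2 invalid
  fit <- fit_2sls(model_spec("y", "en", "ex", c("z1", "z2")), d)
  for (m in c("robust", "sargan")) {
    o <- overidentification_test(fit, method = m)
    expect_equal(o$df, 1L)
    expect_lt(o$p_value, 0.01)
  }
})

test_that("overidentification tests hold their nominal size on iid data", {
  set.seed(19)
  pvals <- vapply(seq_len(300), function(i) {
    n <- 400
    Z <- matrix(rnorm(n * 4), n, 4)
    ex <- rnorm(n)
    v <- rnorm(n)
    en <- Z %*% rep(0.6, 4) + 0.2 * ex + v
    y <- 1 + 0.5 * en + 0.4 * ex + rnorm(n) + 0.5 * v
    d <- data.frame(y = y[, 1], en = en[, 1], ex = ex, Z)
    names(d)[4:7] <- paste0("z", 1:4)
    f <- fit_2sls(model_spec("y", "en", "ex", paste0("z", 1:4)), d)
    c(sar = overidentification_test(f, "sargan")$p_value,
      rob = overidentification_test(f, "robust")$p_value)
  }, numeric(2))
  # binomial(300, 0.05) band
  expect_gt(mean(pvals["sar", ] < 0.05), 0.02)
  expect_lt(mean(pvals["sar", ] < 0.05), 0.09)
  expect_gt(mean(pvals["rob", ] < 0.05), 0.02)
  expect_lt(mean(pvals["rob", ] < 0.05), 0.09)
})

test_that("network-aware overid weight reduces to the robust J without edges", {
  set.seed(23)
  n <- 300
  Z <- matrix(rnorm(n * 4), n, 4)
  ex <- rnorm(n); v <- rnorm(n)
  en <- Z %*% rep(0.6, 4) + 0.2 * ex + v
  d <- data.frame(y = 1 + 0.5 * en[, 1] + 0.4 * ex + rnorm(n) + 0.5 * v,
                  en = en[, 1], ex = ex, Z)
  names(d)[4:7] <- paste0("z", 1:4)
  f <- fit_2sls(model_spec("y", "en", "ex", paste0("z", 1:4)), d)
  empty <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n))
  o_net <- overidentification_test(f, "network", adjacency = empty)
  o_rob <- overidentification_test(f, "robust")
  expect_equal(o_net$statistic, o_rob$statistic, tolerance = 1e-6)
  expect_equal(o_net$df, o_rob$df)

  # on peer data the adjacency is required
  coh <- simulate_cohort(tiny_config(n = 400, seed = 23))
  tbl <- build_analysis_table(coh)
  f2 <- fit_2sls(default_model_spec(tbl), tbl)
  expect_error(overidentification_test(f2, "network"), "adjacency")
  A <- union_adjacency(coh$networks, coh$physicians$id)
  o2 <- overidentification_test(f2, "network", adjacency = A)
  expect_true(is.finite(o2$statistic) && o2$statistic >= 0)
  expect_equal(o2$df, length(f2$spec$instruments) - length(f2$spec$endogenous))
})

test_that("2SLS standard errors use the observed-endogenous residual", {
  # if residuals were (wrongly) based on fitted endogenous columns the
  # residual variance would shrink; check ours against the textbook formula
  set.seed(17)
  n <- 300
  d <- data.frame(z = rnorm(n), ex = rnorm(n), v = rnorm(n))
  d$en <- 0.9 * d$z + d$v
  d$y <- 1 + 0.5 * d$en + 0.2 * d$ex + rnorm(n) + 0.7 * d$v
  fit <- fit_2sls(model_spec("y", "en", "ex", "z"), d)
  X <- cbind(1, d$en, d$ex)
  b <- fit$coefficients[c("(Intercept)", "en", "ex")]
  e_obs <- d$y - X %*% b
  expect_equal(unname(fit$residuals), e_obs[, 1], tolerance = 1e-12)
  expect_true(all(fit$se > 0))
  ev <- eigen(fit$vcov, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
})

test_that("LPM and logistic fitted probabilities are close on interior data", {
  set.seed(18)
  n <- 4000
  d <- data.frame(x = runif(n, -1, 1), z = rnorm(n))
  p <- 0.5 + 0.25 * d$x            # linear truth, p in [0.25, 0.75]
  d$y <- rbinom(n, 1, p)
  sp <- model_spec("y", "x", character(0), "z")
  cmp <- compare_lpm_logit(sp, d)
  expect_lt(abs(cmp$median), 0.02)
  expect_lte(cmp$q1, cmp$median)
  expect_lte(cmp$median, cmp$q3)
  expect_false(cmp$separation)
})
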