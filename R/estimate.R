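# Linear probability model of adoption: OLS and two-stage least squares
# with peer-mean instruments, HC1-robust covariance, and the weak-instrument
# and overidentification diagnostics used to judge which peer-effect
# estimates are reliable.

#' Model specification for the adoption regression
#'
#' Declares the outcome, the endogenous peer adoption rates, the included
#' exogenous controls and the excluded instruments, and validates the order
#' condition. The three column sets must be disjoint.
#'
#' @param outcome outcome column name (binary adoption flag).
#' @param endogenous endogenous regressor columns (the peer adoption rates).
#' @param exogenous included exogenous columns (own covariates, peer
#'   composition shares, no-peer indicators, region indicators).
#' @param instruments excluded instrument columns (peer-mean
#'   characteristics); at least as many as endogenous columns.
#' @param robust robust-covariance flavor; only `"HC1"` is implemented.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome, endogenous, exogenous, instruments,
                       robust = "HC1") {
  robust <- match.arg(robust, "HC1")
  all_cols <- list(endogenous = endogenous, exogenous = exogenous,
                   instruments = instruments)
  for (i in seq_along(all_cols)) for (j in seq_along(all_cols)) {
    if (i < j) {
      shared <- intersect(all_cols[[i]], all_cols[[j]])
      if (length(shared))
        stop("specification error: columns in both ", names(all_cols)[i], " and ",
             names(all_cols)[j], ": ", paste(shared, collapse = ", "))
    }
  }
  if (outcome %in% unlist(all_cols))
    stop("specification error: outcome also appears among the regressors")
  if (length(instruments) < length(endogenous))
    stop("specification error: order condition fails (",
         length(instruments), " instruments < ",
         length(endogenous), " endogenous regressors)")
  structure(list(outcome = outcome, endogenous = endogenous,
                 exogenous = exogenous, instruments = instruments,
                 robust = robust),
            class = "model_spec")
}

#' Default model specification from an analysis table
#'
#' Uses every `ybar_*` column as endogenous, every `z_*` column as an
#' instrument, and the covariates, peer composition shares, no-peer and
#' region indicators as included exogenous controls.
#'
#' @param data analysis table from [build_analysis_table()].
#' @return a [model_spec()].
#' @export
default_model_spec <- function(data) {
  nm <- names(data)
  endog <- grep("^ybar_", nm, value = TRUE)
  instr <- grep("^z_", nm, value = TRUE)
  exog <- setdiff(nm, c("id", "adopter", "promo_exposure", endog, instr))
  # constant columns (e.g. a no-peer indicator when nobody is isolated)
  # carry no information and would make the design singular
  keep <- vapply(exog, function(v) stats::var(as.numeric(data[[v]])) > 0,
                 logical(1))
  model_spec("adopter", endog, exog[keep], instr)
}

design_matrix <- function(data, cols, label) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns absent from data (", label, "): ",
         paste(missing_cols, collapse = ", "))
  m <- as.matrix(as.data.frame(data)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

check_full_rank <- function(X, label) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("singular design (", label, "): collinear columns ",
         paste(dropped, collapse = ", "))
  }
  q
}

# least-squares solve via SVD pseudo-inverse; tolerant of the near-singular
# moment matrices that arise on very small cohorts
pinv_solve <- function(A, b, tol = 1e-12) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  d_inv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (d_inv * crossprod(sv$u, b))
}

hc1_vcov <- function(A_inv, Xw, e, n, k) {
  meat <- crossprod(Xw * e)
  V <- A_inv %*% meat %*% A_inv * n / (n - k)
  (V + t(V)) / 2
}

new_iv_estimate <- function(coef, vcov, n, estimator, residuals, fitted, spec,
                            extra = list()) {
  se <- sqrt(diag(vcov))
  t_stat <- coef / se
  df_resid <- n - length(coef)
  p <- if (df_resid > 0) 2 * stats::pt(-abs(t_stat), df = df_resid)
       else rep(NA_real_, length(coef))   # saturated fit: no residual df
  out <- c(list(coefficients = coef, se = se, vcov = vcov,
                t = t_stat, p = p, n = n, k = length(coef),
                estimator = estimator, residuals = residuals,
                fitted = fitted, spec = spec), extra)
  class(out) <- "iv_estimate"
  out
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat("<iv_estimate> ", x$estimator, ", n = ", x$n, "\n", sep = "")
  print(coef_table(x), digits = 4)
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param fit an `iv_estimate`.
#' @return data.frame with estimate, robust SE, t and p per coefficient.
#' @export
coef_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             robust_se = unname(fit$se),
             t = unname(fit$t),
             p = unname(fit$p),
             row.names = NULL)
}

#' Ordinary least squares fit of the linear probability model
#'
#' Fits the adoption equation by OLS with the endogenous peer adoption rates
#' entered as-is — the naive benchmark that is inconsistent under
#' simultaneity or peer-correlated confounding. Standard errors are
#' heteroskedasticity-robust (HC1).
#'
#' @param spec a [model_spec()].
#' @param data analysis table.
#' @return an `iv_estimate` with `estimator = "OLS"`.
#' @export
fit_ols <- function(spec, data) {
  y <- design_matrix(data, spec$outcome, "outcome")[, 1]
  X <- cbind(`(Intercept)` = 1,
             design_matrix(data, c(spec$endogenous, spec$exogenous), "regressors"))
  n <- nrow(X); k <- ncol(X)
  qx <- check_full_rank(X, "OLS")
  b <- qr.coef(qx, y)
  e <- y - as.vector(X %*% b)
  A_inv <- solve(crossprod(X))
  V <- hc1_vcov(A_inv, X, e, n, k)
  dimnames(V) <- list(colnames(X), colnames(X))
  new_iv_estimate(b, V, n, "OLS", e, y - e, spec)
}

#' Two-stage least squares fit with peer-mean instruments
#'
#' First stage: each endogenous peer adoption rate is regressed on all
#' excluded instruments plus every included exogenous column. Second stage:
#' the fitted rates replace the observed ones. Coefficients equal the
#' classical IV closed form; standard errors use the proper 2SLS residual
#' (observed endogenous columns, not fitted) with an HC1 sandwich. First
#' stage artifacts are retained for [weak_instrument_diagnostics()].
#'
#' @param spec a [model_spec()].
#' @param data analysis table.
#' @return an `iv_estimate` with `estimator = "2SLS"` and a `first_stage`
#'   element.
#' @export
fit_2sls <- function(spec, data) {
  if (length(spec$instruments) < length(spec$endogenous))
    stop("specification error: under-identified model")
  y <- design_matrix(data, spec$outcome, "outcome")[, 1]
  Xen <- design_matrix(data, spec$endogenous, "endogenous")
  Xex <- cbind(`(Intercept)` = 1,
               if (length(spec$exogenous))
                 design_matrix(data, spec$exogenous, "exogenous"))
  Zex <- design_matrix(data, spec$instruments, "instruments")
  Z <- cbind(Xex, Zex)
  n <- nrow(Z)
  qz <- check_full_rank(Z, "first stage")

  proj_rank <- qr(cbind(Xex, qr.fitted(qz, Xen)))$rank
  if (proj_rank < ncol(Xex) + ncol(Xen))
    warning("weak-rank warning: instrument projection of the endogenous ",
            "columns is near-singular")

  Xhat_en <- qr.fitted(qz, Xen)
  colnames(Xhat_en) <- colnames(Xen)
  first_stage <- list(
    coef = qr.coef(qz, Xen),
    residuals = Xen - Xhat_en,
    Z_names = colnames(Z),
    instrument_names = spec$instruments,
    exog = Xex, instruments = Zex, endogenous = Xen)

  X <- cbind(Xex[, 1, drop = FALSE], Xen, Xex[, -1, drop = FALSE])
  Xhat <- cbind(Xex[, 1, drop = FALSE], Xhat_en, Xex[, -1, drop = FALSE])
  k <- ncol(Xhat)
  qxh <- check_full_rank(Xhat, "second stage")
  b <- qr.coef(qxh, y)
  e <- y - as.vector(X %*% b)     # residual with observed endogenous values
  A_inv <- solve(crossprod(Xhat))
  V <- hc1_vcov(A_inv, Xhat, e, n, k)
  dimnames(V) <- list(colnames(Xhat), colnames(Xhat))
  new_iv_estimate(b, V, n, "2SLS", e, as.vector(X %*% b), spec,
                  extra = list(first_stage = first_stage))
}

first_stage_f <- function(fs, endog_name, robust = TRUE) {
  Z <- cbind(fs$exog, fs$instruments)
  yk <- fs$endogenous[, endog_name]
  n <- nrow(Z); k <- ncol(Z)
  qz <- qr(Z)
  b <- qr.coef(qz, yk)
  e <- yk - qr.fitted(qz, yk)
  q <- ncol(fs$instruments)
  idx <- (ncol(fs$exog) + 1L):k
  if (robust) {
    A_inv <- solve(crossprod(Z))
    V <- hc1_vcov(A_inv, Z, e, n, k)
    Vpp <- V[idx, idx, drop = FALSE]
    bp <- b[idx]
    stat <- as.numeric(t(bp) %*% solve(Vpp, bp)) / q
  } else {
    rss1 <- sum(e^2)
    q0 <- qr(fs$exog)
    e0 <- yk - qr.fitted(q0, yk)
    rss0 <- sum(e0^2)
    stat <- ((rss0 - rss1) / q) / (rss1 / (n - k))
  }
  c(stat = stat, df1 = q, df2 = n - k)
}

#' Weak-instrument diagnostics for a 2SLS fit
#'
#' Reports, per endogenous peer adoption rate, the first-stage F statistic
#' for the joint significance of the excluded instruments
#' (heteroskedasticity-robust Wald form by default; the classical
#' homoskedastic form is also returned), flagging each network as reliable
#' when F exceeds 10. For a designated subset of endogenous columns the
#' Cragg-Donald minimum-eigenvalue statistic is computed; with a single
#' endogenous regressor it coincides with the classical first-stage F.
#'
#' @param fit an `iv_estimate` from [fit_2sls()].
#' @param joint endogenous column names for the Cragg-Donald statistic
#'   (default: all).
#' @param f_threshold relevance bar for flagging (conventional 10).
#' @return list of class `weak_instrument_report` with a `first_stage`
#'   data.frame (`endogenous`, `F_robust`, `F_classical`, `df1`, `df2`,
#'   `reliable`), `cragg_donald` (statistic and the subset used) and
#'   `unreliable` (endogenous columns whose estimates should not be
#'   trusted).
#' @export
weak_instrument_diagnostics <- function(fit, joint = NULL, f_threshold = 10) {
  fs <- fit$first_stage
  if (is.null(fs)) stop("fit has no first-stage artifacts; use fit_2sls()")
  endog <- colnames(fs$endogenous)
  rows <- lapply(endog, function(en) {
    fr <- first_stage_f(fs, en, robust = TRUE)
    fc <- first_stage_f(fs, en, robust = FALSE)
    data.frame(endogenous = en, F_robust = fr[["stat"]],
               F_classical = fc[["stat"]], df1 = fr[["df1"]], df2 = fr[["df2"]],
               reliable = fr[["stat"]] > f_threshold)
  })
  tab <- do.call(rbind, rows)
  if (is.null(joint)) joint <- endog
  cd <- cragg_donald(fs, joint)
  structure(list(first_stage = tab,
                 cragg_donald = cd,
                 f_threshold = f_threshold,
                 unreliable = tab$endogenous[!tab$reliable]),
            class = "weak_instrument_report")
}

#' @export
print.weak_instrument_report <- function(x, ...) {
  print(x$first_stage, digits = 4)
  cat("Cragg-Donald minimum eigenvalue (", paste(x$cragg_donald$endogenous,
      collapse = ", "), "): ", signif(x$cragg_donald$statistic, 5), "\n", sep = "")
  if (length(x$unreliable))
    cat("estimates not reliable (F <= ", x$f_threshold, "): ",
        paste(x$unreliable, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Cragg-Donald minimum-eigenvalue statistic: residualize the endogenous
# block and the excluded instruments on the included exogenous columns, then
# take the smallest eigenvalue of Svv^-1 (Y~' P_Z~ Y~) / k2.
cragg_donald <- function(fs, endog_names) {
  Y <- fs$endogenous[, endog_names, drop = FALSE]
  X1 <- fs$exog
  Z2 <- fs$instruments
  n <- nrow(Y)
  q1 <- qr(X1)
  Yt <- Y - qr.fitted(q1, Y)
  Zt <- Z2 - qr.fitted(q1, Z2)
  qz <- qr(Zt)
  PY <- qr.fitted(qz, Yt)
  B <- crossprod(Yt, PY)
  Svv <- (crossprod(Yt) - B) / (n - ncol(X1) - ncol(Z2))
  ev <- eigen(solve(Svv, B), only.values = TRUE)$values
  stat <- min(Re(ev)) / ncol(Z2)
  list(statistic = stat, endogenous = endog_names,
       n_instruments = ncol(Z2))
}

#' Overidentification ("no confounding") test
#'
#' Tests whether the surplus instruments are uncorrelated with the
#' structural residual. Two forms are available. `"robust"` (default) is the
#' heteroskedasticity-robust two-step GMM J statistic — appropriate here
#' because the linear probability model's errors are heteroskedastic by
#' construction, which makes the classical Sargan statistic mis-sized.
#' `"sargan"` is the classical homoskedastic form, `n * R^2` from regressing
#' the 2SLS residuals on the full instrument set. Both are chi-square with
#' degrees of freedom equal to the overidentification degree under the null.
#' For a just-identified model the test is undefined and a `df = 0` result
#' is returned rather than an error.
#'
#' @param fit an `iv_estimate` from [fit_2sls()].
#' @param method `"robust"` (GMM J), `"sargan"`, or `"network"` (GMM J with
#'   an edge-aware weight; requires `adjacency`).
#' @param adjacency for `method = "network"`: a symmetric sparse 0/1 peer
#'   adjacency matrix (e.g. the union of the peer networks) aligned with the
#'   rows of the analysis table. The weight matrix then includes the
#'   first-order cross terms `e_i e_j z_i z_j'` over peer pairs, accounting
#'   for the residual dependence a linear-in-means outcome induces between
#'   connected physicians.
#' @return list with `statistic`, `df`, `p_value` (statistic and p `NA` when
#'   just-identified) and the `method` used.
#' @export
overidentification_test <- function(fit, method = c("robust", "sargan", "network"),
                                    adjacency = NULL) {
  method <- match.arg(method)
  fs <- fit$first_stage
  if (is.null(fs)) stop("fit has no first-stage artifacts; use fit_2sls()")
  df <- ncol(fs$instruments) - ncol(fs$endogenous)
  if (df <= 0L)
    return(list(statistic = NA_real_, df = 0L, p_value = NA_real_,
                method = method,
                note = "test undefined for a just-identified model"))
  Z <- cbind(fs$exog, fs$instruments)
  n <- fit$n
  e <- fit$residuals
  if (method == "sargan") {
    qz <- qr(Z)
    ehat <- qr.fitted(qz, e)
    r2 <- sum(ehat^2) / sum(e^2)  # uncentered; e has mean 0 by construction
    stat <- n * r2
  } else {
    # two-step GMM J; the weight is HC by default, optionally augmented
    # with peer cross terms under method = "network"
    X <- cbind(fs$endogenous, fs$exog)
    y <- fit$fitted + e
    S <- crossprod(Z * e) / n
    if (method == "network") {
      if (is.null(adjacency))
        stop("method = 'network' requires the peer adjacency matrix")
      Ze <- Z * e
      S2 <- crossprod(Ze, as.matrix(adjacency %*% Ze)) / n
      S <- S + as.matrix(S2 + t(S2)) / 2
      # the untapered edge correction can leave S indefinite; floor the
      # spectrum at a small positive value
      es <- eigen(S, symmetric = TRUE)
      floor_ev <- 1e-8 * max(es$values)
      S <- es$vectors %*% (pmax(es$values, floor_ev) * t(es$vectors))
    }
    # tiny ridge keeps the weight invertible when instrument columns are
    # nearly collinear (e.g. peer means over very large organizations)
    diag(S) <- diag(S) + 1e-10 * mean(diag(S))
    ZX <- crossprod(Z, X); Zy <- crossprod(Z, y)
    SinvZX <- solve(S, ZX)
    b <- pinv_solve(crossprod(ZX, SinvZX), crossprod(SinvZX, Zy))
    g <- crossprod(Z, y - X %*% b) / n
    stat <- n * as.numeric(crossprod(g, solve(S, g)))
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       method = method)
}

#' Compare linear-probability and logistic fitted probabilities
#'
#' Fits the same specification (endogenous columns entered as-is) by OLS and
#' by maximum-likelihood logistic regression and summarizes the
#' per-physician differences in fitted probabilities. Small differences
#' justify the linear probability model, which is what makes 2SLS
#' straightforward.
#'
#' @param spec a [model_spec()].
#' @param data analysis table; the outcome must be binary and non-degenerate.
#' @return list with `mean`, `median`, `q1`, `q3` of the differences
#'   (LPM minus logistic), the full `differences` vector, and a `separation`
#'   flag when the logistic fit did not converge cleanly.
#' @export
compare_lpm_logit <- function(spec, data) {
  y <- design_matrix(data, spec$outcome, "outcome")[, 1]
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("outcome must be binary and non-degenerate")
  X <- cbind(`(Intercept)` = 1,
             design_matrix(data, c(spec$endogenous, spec$exogenous), "regressors"))
  check_full_rank(X, "LPM-logit comparison")
  lpm <- as.vector(X %*% qr.coef(qr(X), y))
  glm_fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  separation <- !glm_fit$converged ||
    any(glm_fit$fitted.values > 1 - 1e-10) || any(glm_fit$fitted.values < 1e-10)
  d <- lpm - glm_fit$fitted.values
  qs <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  list(mean = mean(d), median = qs[2], q1 = qs[1], q3 = qs[3],
       differences = d, separation = separation)
}
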