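# Social multiplier: expected number of additional adopters induced by one
# physician's adoption, summed over all direct and indirect influence paths.
#
# Walk-direction convention: adoption by physician i raises each peer j's
# peer adoption rate by W[j, i] (the weight j places on i in j's peer
# average), so the first-order effect of i is gamma times the i-th column
# sum of W, and the t-th order term is the i-th entry of 1' (gamma W)^t.

check_gamma <- function(W, gamma) {
  if (abs(gamma) >= 1)
    stop("divergence error: |gamma| >= 1 with a row-stochastic influence ",
         "matrix; the multiplier series does not converge")
}

new_multiplier_result <- function(m, gamma, method, terms_used = NA_integer_,
                                  residual_bound = 0) {
  structure(list(multiplier = m, gamma = gamma, method = method,
                 terms_used = terms_used, residual_bound = residual_bound),
            class = "multiplier_result")
}

#' @export
print.multiplier_result <- function(x, ...) {
  cat("<multiplier_result> ", length(x$multiplier), " physicians, gamma = ",
      x$gamma, " (", x$method, ")\n", sep = "")
  print(summary(unname(x$multiplier)))
  invisible(x)
}

#' Social multiplier by power-series summation
#'
#' Sums the series `m = sum_{t>=1} gamma^t 1' W^t` entry by entry: the
#' `i`-th entry accumulates, over walk lengths `t`, the products of
#' influence weights along all length-`t` walks terminating at `i`,
#' attenuated by `gamma^t`. Truncation occurs when the current term's
#' 1-norm falls below `tol` or `max_terms` is reached; the geometric-tail
#' residual bound `||term||_1 * gamma / (1 - gamma)` is reported.
#'
#' @param W row-normalized influence matrix (rows sum to 1 or 0).
#' @param gamma attenuation parameter, `|gamma| < 1` (typically the
#'   estimated patient-sharing peer effect).
#' @param tol truncation tolerance on the term 1-norm.
#' @param max_terms cap on the number of series terms.
#' @return a `multiplier_result`; `multiplier` is named by physician when
#'   `W` has dimnames.
#' @export
multiplier_series <- function(W, gamma, tol = 1e-12, max_terms = 10000L) {
  check_gamma(W, gamma)
  n <- nrow(W)
  m <- numeric(n)
  if (gamma == 0)
    return(new_multiplier_result(stats::setNames(m, rownames(W)), gamma, "series", 0L))
  u <- rep(1, n)
  terms <- 0L
  for (t in seq_len(max_terms)) {
    u <- gamma * as.vector(Matrix::crossprod(W, u))  # u' <- gamma * u' W
    m <- m + u
    terms <- t
    if (sum(abs(u)) < tol) break
  }
  bound <- sum(abs(u)) * abs(gamma) / (1 - abs(gamma))
  new_multiplier_result(stats::setNames(m, rownames(W)), gamma, "series",
                        terms, bound)
}

#' Social multiplier in closed form
#'
#' The exact series sum obtained from one linear solve:
#' `m' = 1' gamma W (I - gamma W)^{-1}`, the column totals of the Neumann
#' series of `gamma W` — a Bonacich power centrality of the weighted,
#' directed influence graph with attenuation `gamma`.
#'
#' @param W row-normalized influence matrix.
#' @param gamma attenuation parameter, `|gamma| < 1`.
#' @return a `multiplier_result`.
#' @export
multiplier_closed_form <- function(W, gamma) {
  check_gamma(W, gamma)
  n <- nrow(W)
  if (gamma == 0)
    return(new_multiplier_result(stats::setNames(numeric(n), rownames(W)),
                                 gamma, "closed_form"))
  A <- Matrix::Diagonal(n) - gamma * W
  rhs <- gamma * Matrix::colSums(W)
  m <- tryCatch(as.vector(Matrix::solve(Matrix::t(A), rhs)),
                error = function(err) {
                  kappa <- tryCatch(Matrix::condest(A)$est, error = function(e2) NA)
                  stop("divergence error: (I - gamma W) is singular ",
                       "(condition estimate ", signif(kappa, 3), ")")
                })
  new_multiplier_result(stats::setNames(m, rownames(W)), gamma, "closed_form")
}

#' Decile-based targeting comparison
#'
#' Ranks physicians into deciles by network degree and, separately, by
#' prescribing volume, and compares the mean social multiplier across
#' deciles — the expected yield of targeting an adoption intervention at
#' each group. Ties are broken by stable physician-id order so decile
#' membership is reproducible; decile sizes differ by at most one.
#'
#' @param multiplier a `multiplier_result` or a numeric vector.
#' @param degree per-physician peer count (patient-sharing degree).
#' @param volume per-physician prescribing volume.
#' @param ids physician ids (defaults to the multiplier's names).
#' @return list of class `targeting_summary`: `table` (data.frame with
#'   `ranking`, `decile` 1-10, `n`, `mean_multiplier`) and `ratios`
#'   (`top_bottom_degree`, `top_bottom_volume`, `top_degree_vs_top_volume`).
#' @export
decile_targeting <- function(multiplier, degree, volume, ids = NULL) {
  m <- if (inherits(multiplier, "multiplier_result")) multiplier$multiplier
       else multiplier
  n <- length(m)
  if (n < 10L)
    stop("degenerate deciles: need at least 10 physicians, got ", n)
  if (length(degree) != n || length(volume) != n)
    stop("alignment error: degree/volume must match the multiplier length")
  if (is.null(ids)) ids <- names(m)
  if (is.null(ids)) ids <- sprintf("i%06d", seq_len(n))

  decile_of <- function(v) {
    ord <- order(v, ids)           # ascending; ties broken by id
    dec <- integer(n)
    dec[ord] <- ceiling(seq_len(n) * 10 / n)
    dec
  }
  one <- function(v, label) {
    dec <- decile_of(v)
    agg <- stats::aggregate(m, by = list(decile = dec), FUN = mean)
    data.frame(ranking = label, decile = agg$decile,
               n = as.vector(table(dec)[as.character(agg$decile)]),
               mean_multiplier = agg$x)
  }
  tab <- rbind(one(degree, "degree"), one(volume, "volume"))
  pick <- function(label, dec) {
    tab$mean_multiplier[tab$ranking == label & tab$decile == dec]
  }
  ratios <- list(
    top_bottom_degree = pick("degree", 10) / pick("degree", 1),
    top_bottom_volume = pick("volume", 10) / pick("volume", 1),
    top_degree_vs_top_volume = pick("degree", 10) / pick("volume", 10))
  structure(list(table = tab, ratios = ratios), class = "targeting_summary")
}

#' @export
print.targeting_summary <- function(x, ...) {
  print(x$table, digits = 4)
  cat("top/bottom (degree): ", signif(x$ratios$top_bottom_degree, 4),
      "; top/bottom (volume): ", signif(x$ratios$top_bottom_volume, 4),
      "; top degree vs top volume: ",
      signif(x$ratios$top_degree_vs_top_volume, 4), "\n", sep = "")
  invisible(x)
}
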