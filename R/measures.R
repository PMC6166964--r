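# Median-rule adoption classification and per-physician peer measures.

new_drug_totals <- function(prescribing, physicians_ids, window_quarters = 5L,
                            drug = "new_drug") {
  p <- data.table::as.data.table(prescribing)
  drug_label <- drug
  p <- p[p$drug == drug_label & p$quarter >= 1L & p$quarter <= window_quarters, ]
  tot <- p[, list(total = sum(n_prescriptions)), by = "physician"]
  out <- stats::setNames(rep(0L, length(physicians_ids)), physicians_ids)
  out[tot$physician] <- as.integer(tot$total)
  out
}

#' Median adoption threshold
#'
#' The adoption threshold is the median number of new-drug prescriptions
#' among physicians who prescribed the drug at least once inside the window
#' (the first 15 months on the market at the default of 5 quarters). For an
#' even number of prescribers the lower median is used, so the threshold is
#' always an integer actually attained and "at least the median" keeps its
#' meaning.
#'
#' @param prescribing long prescribing table (`physician`, `drug`, `quarter`,
#'   `n_prescriptions`).
#' @param window_quarters quarters included in the adoption window.
#' @param drug drug label of the newly introduced product.
#' @return integer threshold.
#' @export
compute_adoption_threshold <- function(prescribing, window_quarters = 5L,
                                       drug = "new_drug") {
  stopifnot(window_quarters >= 1L)
  p <- data.table::as.data.table(prescribing)
  drug_label <- drug
  p <- p[p$drug == drug_label & p$quarter >= 1L & p$quarter <= window_quarters, ]
  tot <- p[, list(total = sum(n_prescriptions)), by = "physician"]
  tot <- tot$total[tot$total >= 1L]
  if (length(tot) == 0L)
    stop("no physician prescribed the drug in the window; median undefined")
  lower_median(tot)
}

# lower median: the floor((n+1)/2)-th order statistic
lower_median <- function(x) {
  x <- sort(x)
  as.integer(x[floor((length(x) + 1) / 2)])
}

#' Classify adopters
#'
#' A physician is an adopter when their total new-drug prescriptions inside
#' the window reach the threshold; physicians with zero new-drug
#' prescriptions are never adopters. The threshold may be an explicit
#' integer or one of the rules `"median"` (computed with
#' [compute_adoption_threshold()]), `">=1"`, `">=15"`.
#'
#' @param prescribing long prescribing table.
#' @param threshold integer threshold or rule string.
#' @param physicians_ids ids defining the output order (defaults to the
#'   physicians appearing in `prescribing`).
#' @param window_quarters quarters included in the window.
#' @return an object of class `adoption_outcome`: list with named binary
#'   vector `adopter`, the `threshold` used and the `window_quarters`.
#' @export
classify_adopters <- function(prescribing, threshold = "median",
                              physicians_ids = NULL, window_quarters = 5L) {
  if (is.character(threshold)) {
    threshold <- switch(threshold,
      "median" = compute_adoption_threshold(prescribing, window_quarters),
      ">=1" = 1L,
      ">=15" = 15L,
      stop("unknown adoption rule: ", threshold))
  }
  threshold <- as.integer(threshold)
  stopifnot(threshold >= 1L)
  if (is.null(physicians_ids))
    physicians_ids <- sort(unique(data.table::as.data.table(prescribing)$physician))
  tot <- new_drug_totals(prescribing, physicians_ids, window_quarters)
  structure(list(adopter = as.integer(tot >= threshold & tot >= 1L),
                 ids = physicians_ids,
                 threshold = threshold,
                 window_quarters = window_quarters),
            class = "adoption_outcome")
}

#' Peer adoption rate
#'
#' The (weighted) fraction of a physician's peers who adopted:
#' `ybar_i = sum_j W[i, j] * y_j`. With an equal-weight influence matrix this
#' is the plain fraction of adopting peers; in the patient-sharing network
#' the weights are shared-patient proportions. Physicians without peers get
#' rate 0 and the no-peer indicator set.
#'
#' @param W row-normalized influence matrix from [row_normalize()].
#' @param y binary adoption vector or an `adoption_outcome`; must align with
#'   the rows of `W` (names are checked when present).
#' @return list with numeric `rate` and integer `no_peer`, both named.
#' @export
peer_adoption_rate <- function(W, y) {
  y <- align_outcome(W, y)
  rate <- as.vector(W %*% y)
  no_peer <- as.integer(Matrix::rowSums(W) == 0)
  rate[no_peer == 1L] <- 0
  list(rate = stats::setNames(rate, rownames(W)),
       no_peer = stats::setNames(no_peer, rownames(W)))
}

align_outcome <- function(W, y) {
  if (inherits(y, "adoption_outcome")) {
    y <- stats::setNames(y$adopter, y$ids)
  }
  if (!is.null(names(y)) && !is.null(rownames(W))) {
    if (!all(rownames(W) %in% names(y)))
      stop("alignment error: outcome missing for some physicians in W")
    y <- y[rownames(W)]
  } else if (length(y) != nrow(W)) {
    stop("alignment error: outcome length ", length(y),
         " does not match W dimension ", nrow(W))
  }
  as.numeric(y)
}

#' Peer composition shares
#'
#' Shares of a physician's peers who are relevant specialists and who are
#' high-volume prescribers, computed with the same influence weights as the
#' peer adoption rate (so the patient-sharing shares are patient-weighted and
#' the other networks are simple fractions). Zero-imputed for isolates.
#'
#' @param W row-normalized influence matrix.
#' @param specialist_flag,high_volume_flag binary per-physician vectors
#'   aligned with `W`.
#' @return list with named vectors `specialist_share`, `high_volume_share`,
#'   `no_peer`.
#' @export
peer_composition <- function(W, specialist_flag, high_volume_flag) {
  cbar <- as.vector(W %*% as.numeric(specialist_flag))
  vbar <- as.vector(W %*% as.numeric(high_volume_flag))
  no_peer <- as.integer(Matrix::rowSums(W) == 0)
  list(specialist_share = stats::setNames(cbar, rownames(W)),
       high_volume_share = stats::setNames(vbar, rownames(W)),
       no_peer = stats::setNames(no_peer, rownames(W)))
}

# columns that proxy specialty mix or prescribing volume; never instruments
endogenous_adjacent_columns <- c("specialist", "other_specialty", "pcp",
                                 "high_volume", "volume", "log_volume_z")

#' Peer-mean instrument columns
#'
#' Means of designated exogenous peer characteristics (sex, age cohort,
#' location type, payer and patient-age mix, ...) over each physician's
#' peers, weighted by the influence matrix. These serve as instruments for
#' the peer adoption rate: they predict peer adoption through the peers' own
#' adoption propensities but are excluded from the outcome equation.
#' Specialty-mix and prescribing-volume characteristics are refused — they
#' plausibly affect adoption directly and enter the model as controls
#' instead.
#'
#' @param W row-normalized influence matrix.
#' @param X_exog data.frame/matrix of exogenous characteristic columns
#'   aligned with `W`.
#' @return matrix of peer means (zero-imputed for isolates), one column per
#'   characteristic.
#' @export
peer_mean_instruments <- function(W, X_exog) {
  X <- as.matrix(X_exog)
  bad <- intersect(colnames(X), endogenous_adjacent_columns)
  if (length(bad))
    stop("specification error: specialty/volume characteristics cannot be ",
         "instruments: ", paste(bad, collapse = ", "))
  Z <- as.matrix(W %*% X)
  rownames(Z) <- rownames(W)
  Z
}

#' Assemble the per-physician analysis table
#'
#' Builds the single table consumed by the estimation stage: the adoption
#' outcome, the four peer adoption rates with no-peer indicators, peer
#' specialist and high-volume shares per network, peer-mean instrument
#' columns per network, own covariates and region indicators.
#'
#' @param cohort a `synthetic_cohort`, or `NULL` when the record tables are
#'   passed explicitly.
#' @param physicians,prescribing,networks explicit inputs overriding the
#'   cohort's.
#' @param adoption_rule threshold rule passed to [classify_adopters()].
#' @param instrument_vars exogenous characteristic columns whose peer means
#'   become instruments.
#' @param window_quarters adoption window.
#' @return a `data.frame` keyed by `id` with columns `adopter`, covariates,
#'   `ybar_*`, `nopeer_*`, `cbar_*`, `vbar_*` and `z_<network>_<var>`
#'   instrument columns; the networks used are recorded in
#'   `attr(, "networks")`.
#' @export
build_analysis_table <- function(cohort = NULL,
                                 physicians = cohort$physicians,
                                 prescribing = cohort$prescribing,
                                 networks = cohort$networks,
                                 adoption_rule = "median",
                                 instrument_vars = c("female", "grad_z", "metro",
                                                     "share_medicare", "share_medicaid",
                                                     "share_age65"),
                                 window_quarters = 5L) {
  ph <- data.table::as.data.table(physicians)
  ids <- ph$id
  outcome <- classify_adopters(prescribing, adoption_rule,
                               physicians_ids = ids,
                               window_quarters = window_quarters)
  covs <- physician_covariates(ph)

  class_tot <- new_drug_totals(prescribing, ids, window_quarters, drug = "class_other")
  high_volume <- as.integer(class_tot >= stats::median(class_tot))

  tbl <- data.table::data.table(id = ids, adopter = outcome$adopter)
  keep_covs <- c("female", "grad_z", "metro", "share_medicare", "share_medicaid",
                 "share_age65", "specialist", "other_specialty", "promo_exposure")
  for (v in keep_covs) tbl[, (v) := covs[[v]]]
  tbl[, "high_volume" := high_volume]

  loc <- factor(ph$location)
  if (nlevels(loc) > 1L) {
    mm <- stats::model.matrix(~loc)[, -1, drop = FALSE]
    colnames(mm) <- paste0("loc_", levels(loc)[-1])
    for (v in colnames(mm)) tbl[, (v) := mm[, v]]
  }

  y <- stats::setNames(outcome$adopter, ids)
  for (k in names(networks)) {
    W <- row_normalize(networks[[k]], nodes = ids)
    pr <- peer_adoption_rate(W, y)
    comp <- peer_composition(W, covs$specialist, high_volume)
    Z <- peer_mean_instruments(W, covs[, instrument_vars, with = FALSE])
    tbl[, (paste0("ybar_", k)) := pr$rate]
    tbl[, (paste0("nopeer_", k)) := pr$no_peer]
    tbl[, (paste0("cbar_", k)) := comp$specialist_share]
    tbl[, (paste0("vbar_", k)) := comp$high_volume_share]
    for (v in instrument_vars)
      tbl[, (paste0("z_", k, "_", v)) := Z[, v]]
  }
  out <- as.data.frame(tbl)
  attr(out, "threshold") <- outcome$threshold
  attr(out, "network_kinds") <- names(networks)
  attr(out, "instrument_vars") <- instrument_vars
  out
}
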