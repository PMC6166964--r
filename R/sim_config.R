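#' Simulation configuration for a synthetic physician cohort
#'
#' Collects every parameter of the synthetic-cohort generator and validates
#' it. The generator simulates a cohort of physicians, a bipartite
#' patient-to-physician assignment (from which the patient-sharing network is
#' built), medical-group and hospital affiliations, training histories, and a
#' binary adoption outcome produced by a linear-in-means structural equation
#' with known peer-effect coefficients. Defaults emulate the observed regime
#' of physician prescribing studies: small medical groups (about 10 peers),
#' large hospital staffs (about 185 peers), a quarter of the cohort adopting
#' within the first five quarters, and a median adoption threshold of 7
#' prescriptions.
#'
#' Geography has two levels: `n_locations` coarse regions (the location
#' covariate entered in models) subdivided into practice communities of about
#' `community_size` physicians. Patient sharing is concentrated within
#' communities, and the optional peer-correlated confounder is a shock shared
#' within a community, so it is *not* absorbed by the region control.
#'
#' @param n_physicians number of physicians in the cohort.
#' @param n_patients number of synthetic patients; default
#'   `round(n_physicians * patients_per_physician_mean)`.
#' @param n_groups,n_hospitals,n_schools,n_residencies numbers of
#'   organizations; defaults derived from coverage and mean-size parameters.
#' @param grad_year_range inclusive integer interval of medical-school
#'   graduation years.
#' @param patients_per_physician_mean mean patients per physician, drives the
#'   default patient count.
#' @param sharing_concentration mean number of physicians a patient sees
#'   (typically 1--3); exactly 1 produces no shared patients.
#' @param sharing_skew lognormal sdlog of a physician's patient-draw
#'   propensity; larger values give a heavier-tailed patient-sharing degree
#'   distribution (0 makes all physicians equally likely to be seen).
#' @param true_gamma named numeric, peer-effect coefficients for networks
#'   `P`, `G`, `H`, `T`; each must have absolute value < 1 and their absolute
#'   sum must be < 1 so the structural fixed point is a contraction.
#' @param true_beta named numeric of structural covariate effects; see
#'   [simulate_adoption()] for the recognized names. `NULL` uses defaults.
#' @param beta0 structural intercept. `NULL` (default) calibrates it by a
#'   secant search so the mean equilibrium adoption propensity matches
#'   `target_adoption_rate` to within 0.001.
#' @param confounder_sd standard deviation of the community-level shared
#'   shock (the peer-correlated confounder); 0 disables it.
#' @param idiosyncratic_sd standard deviation of smooth per-physician
#'   residual heterogeneity.
#' @param bernoulli_noise if `TRUE` (default) realized adoption is an
#'   independent Bernoulli draw from the equilibrium propensity; if `FALSE`
#'   the top `target_adoption_rate` quantile of propensities adopts.
#' @param target_adoption_rate cohort adoption rate the intercept is
#'   calibrated to, in (0, 1).
#' @param n_locations number of coarse geographic regions.
#' @param community_size approximate physicians per practice community.
#' @param specialty_shares named numeric shares for `pcp`, `specialist`,
#'   `other`; must sum to 1.
#' @param group_coverage,hospital_coverage probability a physician has at
#'   least one group / hospital affiliation.
#' @param group_size_mean,hospital_size_mean mean organization sizes used to
#'   derive the default organization counts.
#' @param metro_share share of physicians in metropolitan areas.
#' @param contaminated_instrument if `TRUE`, the `promo_exposure` physician
#'   characteristic is overwritten with confounder + noise, so its peer mean
#'   is an invalid instrument (used to demonstrate overidentification-test
#'   power).
#' @param nonprescriber_frac fraction of non-adopters who never prescribe the
#'   new drug.
#' @param intended_median target median prescription count among new-drug
#'   prescribers; adopter counts are drawn at or above it, non-adopter counts
#'   below it, so the median adoption rule can recover the simulated truth.
#' @param n_quarters quarters of prescribing data (the 15-month window is 5).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_physicians = 200, seed = 1)
#' cfg$true_gamma
sim_config <- function(n_physicians = 2000L,
                       n_patients = NULL,
                       n_groups = NULL,
                       n_hospitals = NULL,
                       n_schools = NULL,
                       n_residencies = NULL,
                       grad_year_range = c(1975L, 2005L),
                       patients_per_physician_mean = 10,
                       sharing_concentration = 1.8,
                       sharing_skew = 0.5,
                       true_gamma = c(P = 0.6, G = 0, H = 0.3, T = 0),
                       true_beta = NULL,
                       beta0 = NULL,
                       confounder_sd = 0.05,
                       idiosyncratic_sd = 0.05,
                       bernoulli_noise = TRUE,
                       target_adoption_rate = 0.25,
                       n_locations = 8L,
                       community_size = 40L,
                       specialty_shares = c(pcp = 0.7, specialist = 0.1, other = 0.2),
                       group_coverage = 0.72,
                       hospital_coverage = 0.9,
                       group_size_mean = 10,
                       hospital_size_mean = 185,
                       metro_share = 0.6,
                       contaminated_instrument = FALSE,
                       nonprescriber_frac = 0.8,
                       intended_median = 7L,
                       n_quarters = 5L,
                       seed = 1L) {
  n_physicians <- as.integer(n_physicians)
  if (is.na(n_physicians) || n_physicians < 1)
    stop("invalid configuration: n_physicians must be a positive integer")
  if (is.null(n_patients))
    n_patients <- max(1L, as.integer(round(n_physicians * patients_per_physician_mean)))
  n_patients <- as.integer(n_patients)

  if (is.null(n_groups))
    n_groups <- max(1L, as.integer(round(n_physicians * group_coverage / group_size_mean)))
  if (is.null(n_hospitals))  # 1.15: some physicians hold a second affiliation
    n_hospitals <- max(1L, as.integer(round(n_physicians * hospital_coverage * 1.15 /
                                              hospital_size_mean)))
  if (is.null(n_schools))
    n_schools <- max(2L, as.integer(round(n_physicians / 50)))
  if (is.null(n_residencies))
    n_residencies <- max(2L, as.integer(round(n_physicians / 35)))

  counts <- c(n_patients = n_patients, n_groups = n_groups,
              n_hospitals = n_hospitals, n_schools = n_schools,
              n_residencies = n_residencies, n_locations = n_locations,
              community_size = community_size, n_quarters = n_quarters,
              intended_median = intended_median)
  for (nm in names(counts)) {
    if (is.na(counts[[nm]]) || counts[[nm]] < 1)
      stop("invalid configuration: ", nm, " must be >= 1")
  }

  if (length(grad_year_range) != 2L || grad_year_range[1] > grad_year_range[2])
    stop("invalid configuration: grad_year_range must be an inclusive interval")
  if (patients_per_physician_mean <= 0)
    stop("invalid configuration: patients_per_physician_mean must be positive")
  if (sharing_concentration <= 0)
    stop("invalid configuration: sharing_concentration must be positive")
  if (sharing_skew < 0)
    stop("invalid configuration: sharing_skew must be nonnegative")

  kinds <- c("P", "G", "H", "T")
  if (!all(kinds %in% names(true_gamma)))
    stop("invalid configuration: true_gamma must be named with P, G, H, T")
  true_gamma <- true_gamma[kinds]
  if (any(abs(true_gamma) >= 1))
    stop("invalid configuration: every true_gamma must have |gamma| < 1")
  if (sum(abs(true_gamma)) >= 1)
    stop("invalid configuration: sum of |true_gamma| must be < 1 (contraction)")

  if (is.null(true_beta)) true_beta <- default_true_beta()
  if (is.null(names(true_beta)) || any(!nzchar(names(true_beta))))
    stop("invalid configuration: true_beta must be a named vector")

  if (confounder_sd < 0)
    stop("invalid configuration: confounder_sd must be nonnegative")
  if (idiosyncratic_sd < 0)
    stop("invalid configuration: idiosyncratic_sd must be nonnegative")
  if (target_adoption_rate <= 0 || target_adoption_rate >= 1)
    stop("invalid configuration: target_adoption_rate must lie in (0, 1)")
  if (abs(sum(specialty_shares) - 1) > 1e-8 || any(specialty_shares < 0))
    stop("invalid configuration: specialty_shares must be nonnegative and sum to 1")
  if (!all(c("pcp", "specialist", "other") %in% names(specialty_shares)))
    stop("invalid configuration: specialty_shares must name pcp, specialist, other")
  for (p in c(group_coverage = group_coverage, hospital_coverage = hospital_coverage,
              metro_share = metro_share, nonprescriber_frac = nonprescriber_frac)) {
    if (p < 0 || p > 1)
      stop("invalid configuration: coverage/share parameters must lie in [0, 1]")
  }

  cfg <- list(
    n_physicians = n_physicians, n_patients = n_patients,
    n_groups = as.integer(n_groups), n_hospitals = as.integer(n_hospitals),
    n_schools = as.integer(n_schools), n_residencies = as.integer(n_residencies),
    grad_year_range = as.integer(grad_year_range),
    patients_per_physician_mean = patients_per_physician_mean,
    sharing_concentration = sharing_concentration,
    sharing_skew = sharing_skew,
    true_gamma = true_gamma, true_beta = true_beta, beta0 = beta0,
    confounder_sd = confounder_sd, idiosyncratic_sd = idiosyncratic_sd,
    bernoulli_noise = isTRUE(bernoulli_noise),
    target_adoption_rate = target_adoption_rate,
    n_locations = as.integer(n_locations),
    community_size = as.integer(community_size),
    specialty_shares = specialty_shares,
    group_coverage = group_coverage, hospital_coverage = hospital_coverage,
    group_size_mean = group_size_mean, hospital_size_mean = hospital_size_mean,
    metro_share = metro_share,
    contaminated_instrument = isTRUE(contaminated_instrument),
    nonprescriber_frac = nonprescriber_frac,
    intended_median = as.integer(intended_median),
    n_quarters = as.integer(n_quarters),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Structural covariate effects: chosen so the linear index has a standard
# deviation near 0.12; the payer- and age-mix effects act on covariates with
# a community-level component, giving peer-mean instruments genuine signal.
default_true_beta <- function() {
  c(female = -0.06,
    grad_z = 0.08,
    metro = 0.05,
    specialist = 0.15,
    log_volume_z = 0.06,
    share_medicare = 0.10,
    share_medicaid = -0.10,
    share_age65 = 0.12)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_physicians, "physicians,", x$n_patients, "patients\n")
  cat("  gamma:", paste(names(x$true_gamma), signif(x$true_gamma, 3),
                        sep = "=", collapse = " "), "\n")
  cat("  target adoption rate:", x$target_adoption_rate,
      " confounder sd:", x$confounder_sd, " seed:", x$seed, "\n")
  invisible(x)
}
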