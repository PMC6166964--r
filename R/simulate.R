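# Synthetic-cohort generator. Each generate_* step reseeds from
# config$seed plus a fixed offset so the steps are individually
# deterministic and the whole cohort is a pure function of the config.

seed_offset <- c(physicians = 101L, sharing = 202L, affiliations = 303L,
                 adoption = 404L, contamination = 606L)

#' Generate a synthetic physician roster
#'
#' Draws a cohort of physicians with demographics, specialty, training
#' history, two-level geography (region and practice community), a
#' right-skewed prescribing volume, and payer- and patient-age-mix
#' proportions. Covariates are drawn independently with configurable
#' marginals; any correlation structure between them is left to the user.
#'
#' @param config a [sim_config()].
#' @return a `data.table` with one row per physician. Columns include `id`,
#'   `female`, `grad_year`, `residency_year`, `specialty`, `school`,
#'   `residency`, `location`, `community`, `metro`, `volume` (expected
#'   class-level prescriptions over the window), `share_medicare`,
#'   `share_medicaid`, `share_cash` (sum to 1), `share_age_lt50`,
#'   `share_age50_64`, `share_age65` (sum to 1), `promo_exposure`, and the
#'   internal patient-draw propensity `attract`.
#' @export
generate_physicians <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + seed_offset[["physicians"]])
  n <- config$n_physicians

  location <- sprintf("loc%02d", sample.int(config$n_locations, n, replace = TRUE))
  # practice communities subdivide regions; sized near community_size
  comm_per_loc <- max(1L, as.integer(round(n / (config$n_locations * config$community_size))))
  community <- paste0(location, "_c",
                      sprintf("%02d", sample.int(comm_per_loc, n, replace = TRUE)))

  yr <- config$grad_year_range
  grad_year <- sample(seq(yr[1], yr[2]), n, replace = TRUE)
  shares <- config$specialty_shares[c("pcp", "specialist", "other")]
  specialty <- sample(names(shares), n, replace = TRUE, prob = shares)

  # payer and patient-age mixes vary at the community level (local payer
  # populations), giving peer means genuine signal beyond individual noise
  comm_f <- factor(community)
  delta_medicaid <- stats::rnorm(nlevels(comm_f), sd = 0.7)[as.integer(comm_f)]
  delta_age <- stats::rnorm(nlevels(comm_f), sd = 0.5)[as.integer(comm_f)]
  payer <- dirichlet_rows(n, cbind(4, 2 * exp(delta_medicaid), 1.2))
  agemix <- dirichlet_rows(n, cbind(2, 3, 3 * exp(delta_age)))

  dt <- data.table::data.table(
    id = sprintf("phy%05d", seq_len(n)),
    female = stats::rbinom(n, 1L, 0.35),
    grad_year = grad_year,
    residency_year = grad_year + 4L,
    specialty = specialty,
    school = sprintf("sch%03d", sample.int(config$n_schools, n, replace = TRUE)),
    residency = sprintf("res%03d", sample.int(config$n_residencies, n, replace = TRUE)),
    location = location,
    community = community,
    metro = stats::rbinom(n, 1L, config$metro_share),
    volume = stats::rlnorm(n, meanlog = log(50), sdlog = 0.8),
    share_medicare = payer[, 1], share_medicaid = payer[, 2], share_cash = payer[, 3],
    share_age_lt50 = agemix[, 1], share_age50_64 = agemix[, 2], share_age65 = agemix[, 3],
    promo_exposure = stats::rnorm(n),
    attract = stats::rlnorm(n, meanlog = 0, sdlog = config$sharing_skew)
  )
  dt[]
}

# alpha: vector (common to all rows) or n-row matrix of per-row parameters
dirichlet_rows <- function(n, alpha) {
  if (is.matrix(alpha)) {
    g <- matrix(stats::rgamma(n * ncol(alpha), shape = alpha), nrow = n)
  } else {
    g <- vapply(alpha, function(a) stats::rgamma(n, shape = a), numeric(n))
    if (n == 1L) g <- matrix(g, nrow = 1L)
  }
  g / rowSums(g)
}

#' Pairwise shared-patient records from a patient-physician assignment
#'
#' Collapses a long patient-to-physician assignment table into unordered
#' physician-pair records counting unique patients per payer: for every
#' patient, every pair of distinct physicians the patient sees contributes
#' one shared patient under the patient's payer.
#'
#' @param assignments a data.frame with columns `patient`, `payer`,
#'   `physician` (one row per patient-physician contact; duplicates are
#'   collapsed).
#' @return a `data.table` with columns `physician_a`, `physician_b`
#'   (`physician_a < physician_b`), `payer`, `n_unique_patients`.
#' @export
pairs_from_patient_assignments <- function(assignments) {
  a <- data.table::as.data.table(assignments)[, c("patient", "payer", "physician")]
  a <- unique(a)
  j <- merge(a, a, by = c("patient", "payer"), allow.cartesian = TRUE,
             suffixes = c("_a", "_b"))
  j <- j[j$physician_a < j$physician_b, ]
  if (nrow(j) == 0L) {
    return(data.table::data.table(physician_a = character(), physician_b = character(),
                                  payer = character(), n_unique_patients = integer()))
  }
  out <- j[, list(n_unique_patients = data.table::uniqueN(patient)),
           by = c("physician_a", "physician_b", "payer")]
  data.table::setorderv(out, c("physician_a", "physician_b", "payer"))
  out[]
}

#' Generate shared-patient records from a bipartite patient assignment
#'
#' Assigns each synthetic patient a payer (Medicare or Medicaid) and a set of
#' 1 or more physicians. The first physician is drawn cohort-wide with
#' probability proportional to the `attract` propensity; additional
#' physicians (their number driven by `sharing_concentration`) are drawn
#' mostly from the same practice community, occasionally from the wider
#' region, so physicians practicing near each other share more patients.
#' Emits unordered pair counts of unique patients per payer.
#'
#' @param config a [sim_config()].
#' @param physicians roster from [generate_physicians()].
#' @return shared-patient records as in [pairs_from_patient_assignments()].
#' @export
generate_patient_sharing <- function(config, physicians) {
  stopifnot(inherits(config, "sim_config"), nrow(physicians) > 0L)
  set.seed(config$seed + seed_offset[["sharing"]])
  np <- config$n_patients
  ph <- data.table::as.data.table(physicians)

  k <- 1L + stats::rpois(np, max(config$sharing_concentration - 1, 0))
  k <- pmin(k, 6L)
  payer <- sample(c("medicare", "medicaid"), np, replace = TRUE, prob = c(0.6, 0.4))
  anchor <- sample.int(nrow(ph), np, replace = TRUE, prob = ph$attract)

  extra_n <- k - 1L
  rows <- list(data.table::data.table(patient = seq_len(np), payer = payer,
                                      phys_idx = anchor))
  if (any(extra_n > 0L)) {
    pat <- rep.int(seq_len(np), extra_n)
    same_comm <- stats::runif(length(pat)) < 0.85
    key <- ifelse(same_comm, ph$community[anchor[pat]], ph$location[anchor[pat]])
    idx <- integer(length(pat))
    # one weighted sample() per community/region keeps this vectorized
    for (grp in split(seq_along(pat), key)) {
      k1 <- key[grp[1]]
      members <- if (grepl("_c", k1, fixed = TRUE)) which(ph$community == k1)
                 else which(ph$location == k1)
      idx[grp] <- if (length(members) == 1L) members
                  else members[sample.int(length(members), length(grp), replace = TRUE,
                                          prob = ph$attract[members])]
    }
    rows[[2]] <- data.table::data.table(patient = pat, payer = payer[pat], phys_idx = idx)
  }
  assign <- data.table::rbindlist(rows)
  assign[, "physician" := ph$id[assign$phys_idx]]
  assign[, "phys_idx" := NULL]
  pairs_from_patient_assignments(assign)
}

#' Generate medical-group and hospital affiliations
#'
#' Each physician joins at most one medical group (probability
#' `group_coverage`) and one or two hospitals (probability
#' `hospital_coverage`, with a 15% chance of a second hospital).
#' Organizations are stratified by region so the affiliation networks track
#' geography without collapsing onto the patient-sharing network; group sizes
#' are small and hospital staffs large, reflecting typical co-practice
#' settings.
#'
#' @param config a [sim_config()].
#' @param physicians roster from [generate_physicians()].
#' @return a `data.table` with columns `physician`, `organization_id`,
#'   `organization_kind` (`"group"` or `"hospital"`).
#' @export
generate_affiliations <- function(config, physicians) {
  stopifnot(inherits(config, "sim_config"), nrow(physicians) > 0L)
  set.seed(config$seed + seed_offset[["affiliations"]])
  ph <- data.table::as.data.table(physicians)
  n <- nrow(ph)
  locs <- sort(unique(ph$location))
  loc_size <- as.numeric(table(factor(ph$location, levels = locs)))

  org_assign <- function(n_orgs, prefix, coverage, second_prob = 0,
                         region_affinity = 1) {
    org_loc <- locs[sample.int(length(locs), n_orgs, replace = TRUE, prob = loc_size)]
    orgs_by_loc <- split(seq_len(n_orgs), org_loc)
    pick <- function(members) {
      # each member picks an organization from the home region with
      # probability region_affinity, otherwise from the whole roster
      m <- length(members)
      out <- integer(m)
      local_pick <- stats::runif(m) < region_affinity
      for (loc in locs) {
        sel <- which(ph$location[members] == loc & local_pick)
        cand <- orgs_by_loc[[loc]]
        if (is.null(cand)) cand <- seq_len(n_orgs)
        if (length(sel)) out[sel] <- cand[sample.int(length(cand), length(sel),
                                                     replace = TRUE)]
      }
      far <- which(!local_pick)
      if (length(far)) out[far] <- sample.int(n_orgs, length(far), replace = TRUE)
      out
    }
    member <- which(stats::runif(n) < coverage)
    res <- data.table::data.table(phys = member, org = pick(member))
    if (second_prob > 0) {
      twice <- member[stats::runif(length(member)) < second_prob]
      if (length(twice))
        res <- rbind(res, data.table::data.table(phys = twice, org = pick(twice)))
    }
    res[, "organization_id" := sprintf("%s%03d", prefix, res$org)]
    unique(data.table::data.table(physician = ph$id[res$phys],
                                  organization_id = res$organization_id))
  }

  grp <- org_assign(config$n_groups, "grp", config$group_coverage)
  hos <- org_assign(config$n_hospitals, "hos", config$hospital_coverage,
                    second_prob = 0.15, region_affinity = 0.35)
  grp[, "organization_kind" := "group"]
  hos[, "organization_kind" := "hospital"]
  out <- rbind(grp, hos)
  data.table::setorderv(out, c("organization_kind", "organization_id", "physician"))
  out[]
}

#' Derived physician covariates used in the structural and estimated models
#'
#' Standardizes graduation year and log prescribing volume, expands the
#' specialty factor into indicator columns and carries the remaining
#' characteristics through. Used both by the adoption simulator (structural
#' equation) and by the analysis-table builder, so the two stay consistent.
#'
#' @param physicians roster table.
#' @return a `data.table` of numeric covariate columns aligned with the
#'   roster rows.
#' @export
physician_covariates <- function(physicians) {
  ph <- data.table::as.data.table(physicians)
  data.table::data.table(
    female = as.numeric(ph$female),
    grad_z = (ph$grad_year - stats::median(range(ph$grad_year))) / 10,
    metro = as.numeric(ph$metro),
    specialist = as.numeric(ph$specialty == "specialist"),
    other_specialty = as.numeric(ph$specialty == "other"),
    log_volume_z = (log(ph$volume) - log(50)) / 0.8,
    share_medicare = ph$share_medicare,
    share_medicaid = ph$share_medicaid,
    share_age65 = ph$share_age65,
    share_age50_64 = ph$share_age50_64,
    promo_exposure = ph$promo_exposure
  )
}

#' Solve the structural adoption fixed point
#'
#' Iterates the clipped linear-in-means map
#' `p <- clip(base + sum_k gamma_k W_k p, lo, hi)` to its fixed point. With
#' row-stochastic weight matrices and `sum(|gamma|) < 1` the map is a
#' contraction (clipping is 1-Lipschitz), so the fixed point is unique and
#' reached from any start.
#'
#' @param base numeric vector `beta0 + X beta + u`.
#' @param W_list named list of row-stochastic influence matrices.
#' @param gamma named numeric attenuation per network, `names(W_list)`.
#' @param clip lower/upper propensity bounds.
#' @param tol sup-norm convergence tolerance.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @param start optional warm start.
#' @return the equilibrium propensity vector.
#' @export
solve_equilibrium <- function(base, W_list, gamma, clip = c(0.01, 0.99),
                              tol = 1e-10, max_iter = 5000L, start = NULL) {
  active <- names(gamma)[abs(gamma) > 0]
  if (length(active) == 0L)
    return(pmin(pmax(base, clip[1]), clip[2]))
  stopifnot(all(active %in% names(W_list)))
  A <- combine_influence(W_list, gamma)
  solve_equilibrium_A(base, A, clip, tol, max_iter, start)
}

# single coefficient matrix sum_k gamma_k W_k, reusable across solves
combine_influence <- function(W_list, gamma) {
  A <- NULL
  for (k in names(gamma)) {
    if (abs(gamma[[k]]) == 0) next
    A <- if (is.null(A)) gamma[[k]] * W_list[[k]] else A + gamma[[k]] * W_list[[k]]
  }
  A
}

# Fixed-point iteration with periodic Aitken (geometric) extrapolation:
# the plain map converges linearly at rate sum|gamma|, which can be slow
# near 1; extrapolating the dominant geometric mode cuts the iteration
# count several-fold. Convergence is always certified on the plain map.
solve_equilibrium_A <- function(base, A, clip = c(0.01, 0.99), tol = 1e-10,
                                max_iter = 5000L, start = NULL) {
  p <- if (is.null(start)) pmin(pmax(base, clip[1]), clip[2]) else start
  delta_prev <- NULL
  resid <- Inf
  for (it in seq_len(max_iter)) {
    p_new <- pmin(pmax(base + as.vector(A %*% p), clip[1]), clip[2])
    delta <- p_new - p
    resid <- max(abs(delta))
    if (resid < tol) return(p_new)
    if (it %% 8L == 0L && !is.null(delta_prev)) {
      rho <- sqrt(sum(delta^2)) / sqrt(sum(delta_prev^2))
      if (is.finite(rho) && rho > 0 && rho < 0.995) {
        p_new <- pmin(pmax(p_new + delta * rho / (1 - rho), clip[1]), clip[2])
        delta <- NULL  # extrapolated step: restart rho tracking
      }
    }
    delta_prev <- delta
    p <- p_new
  }
  stop("fixed point not converged within ", max_iter,
       " iterations; residual = ", signif(resid, 4))
}

#' Simulate adoption outcomes from the linear-in-means structural model
#'
#' Solves the equilibrium adoption propensity
#' `p = clip(beta0 + X beta + sum_k gamma_k W_k p + u, 0.01, 0.99)`, where
#' `u` combines an idiosyncratic draw with a practice-community shock (the
#' peer-correlated confounder) when `confounder_sd > 0`. Unless an explicit
#' `beta0` is supplied, the intercept is calibrated by a secant search so the
#' mean equilibrium propensity matches `target_adoption_rate` within 0.001.
#' Realized adoption is an independent Bernoulli draw from `p` (or a
#' quantile threshold when `bernoulli_noise = FALSE`). Prescribing counts are
#' then constructed so adopters write at least `intended_median` new-drug
#' prescriptions and non-adopters fewer, letting the downstream median rule
#' recover the simulated truth exactly at default settings.
#'
#' @param physicians roster table.
#' @param networks named list of `peer_network` objects (`P`, `G`, `H`, `T`);
#'   any subset whose `true_gamma` is nonzero must be present.
#' @param config a [sim_config()].
#' @return a list with elements `truth` (class `simulation_truth`: physician
#'   ids, `equilibrium_propensity`, `realized_adoption`, `confounder_values`,
#'   the calibrated `beta0` and the intended `threshold`) and `prescribing`
#'   (long table: `physician`, `drug` in `new_drug`/`class_other`, `quarter`,
#'   `n_prescriptions`; zero rows omitted).
#' @export
simulate_adoption <- function(physicians, networks, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + seed_offset[["adoption"]])
  ph <- data.table::as.data.table(physicians)
  n <- nrow(ph)
  gamma <- config$true_gamma

  W_list <- lapply(networks, row_normalize, nodes = ph$id)
  missing_nets <- setdiff(names(gamma)[abs(gamma) > 0], names(W_list))
  if (length(missing_nets))
    stop("networks with nonzero true_gamma missing: ",
         paste(missing_nets, collapse = ", "))

  covs <- physician_covariates(ph)
  beta <- config$true_beta
  unknown <- setdiff(names(beta), names(covs))
  if (length(unknown))
    stop("true_beta names not among generated covariates: ",
         paste(unknown, collapse = ", "))
  xb <- as.vector(as.matrix(covs[, names(beta), with = FALSE]) %*% beta)

  comm <- factor(ph$community)
  comm_shock <- stats::rnorm(nlevels(comm), sd = config$confounder_sd)
  confounder <- comm_shock[as.integer(comm)]
  u <- confounder + stats::rnorm(n, sd = config$idiosyncratic_sd)

  promo <- NULL
  if (config$contaminated_instrument) {
    # invalid-instrument dial: promotional exposure loads on the community
    # shock (targeted detailing) and peers' exposure shifts own adoption
    # directly, without routing through peer adoption - the classic
    # exclusion-restriction failure the test is meant to detect
    promo <- contaminated_promo(confounder, config)
  }

  A <- combine_influence(W_list, gamma)
  solve_at <- function(b0, start, tol) {
    if (is.null(A))
      return(pmin(pmax(b0 + xb + u, 0.01), 0.99))
    solve_equilibrium_A(b0 + xb + u, A, tol = tol, start = start)
  }

  if (is.null(config$beta0)) {
    # secant search on the intercept; in the unclipped regime the mean
    # propensity responds to beta0 with slope about 1/(1 - sum(gamma))
    target <- config$target_adoption_rate
    slope <- 1 / (1 - sum(gamma))
    beta0 <- (target - mean(xb + u)) / slope
    p <- solve_at(beta0, start = NULL, tol = 1e-8)
    gap <- mean(p) - target
    b_prev <- beta0; gap_prev <- gap
    for (i in seq_len(25L)) {
      if (abs(gap) < 1e-3) break
      step <- if (i == 1L || abs(gap - gap_prev) < 1e-12) gap / slope
              else gap * (beta0 - b_prev) / (gap - gap_prev)
      b_prev <- beta0; gap_prev <- gap
      beta0 <- beta0 - step
      p <- solve_at(beta0, start = p, tol = 1e-8)
      gap <- mean(p) - target
    }
    if (abs(gap) > 0.02)
      stop("intercept calibration failed: mean propensity ", signif(mean(p), 4),
           " vs target ", target)
    p <- solve_at(beta0, start = p, tol = 1e-10)
  } else {
    beta0 <- config$beta0
    p <- solve_at(beta0, start = NULL, tol = 1e-10)
  }

  p_draw <- p
  if (!is.null(promo))   # direct peer-exposure effect, outside the equilibrium
    p_draw <- pmin(pmax(p + 0.35 * as.vector(W_list[["P"]] %*% promo), 0.01), 0.99)
  if (config$bernoulli_noise) {
    y <- stats::rbinom(n, 1L, p_draw)
  } else {
    y <- as.integer(p_draw >= stats::quantile(p_draw, 1 - config$target_adoption_rate,
                                              type = 1))
  }

  prescribing <- draw_prescribing(ph, y, config)

  truth <- structure(
    list(id = ph$id,
         equilibrium_propensity = p,
         realized_adoption = y,
         confounder_values = confounder,
         promo_exposure = promo,
         beta0 = beta0,
         threshold = config$intended_median),
    class = "simulation_truth")
  list(truth = truth, prescribing = prescribing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# New-drug counts honor the median rule (adopters >= intended_median,
# non-adopters below); class counts scale with the volume covariate.
draw_prescribing <- function(ph, y, config) {
  n <- nrow(ph)
  nq <- config$n_quarters
  med <- config$intended_median

  total <- integer(n)
  adopt <- which(y == 1L)
  total[adopt] <- med + stats::rgeom(length(adopt), prob = 0.4)
  non <- which(y == 0L)
  if (length(non) && med > 1L) {
    writes <- non[stats::runif(length(non)) >= config$nonprescriber_frac]
    if (length(writes))
      total[writes] <- sample.int(med - 1L, length(writes), replace = TRUE)
  }

  ramp <- seq_len(nq) + 1  # mild diffusion ramp across quarters
  ramp <- ramp / sum(ramp)
  has <- which(total > 0L)
  new_rows <- NULL
  if (length(has)) {
    qmat <- vapply(has, function(i) stats::rmultinom(1L, total[i], ramp)[, 1],
                   integer(nq))
    new_rows <- data.table::data.table(
      physician = rep(ph$id[has], each = nq),
      drug = "new_drug",
      quarter = rep.int(seq_len(nq), length(has)),
      n_prescriptions = as.integer(qmat))
    new_rows <- new_rows[new_rows$n_prescriptions > 0L, ]
  }

  lam <- pmax(ph$volume / nq - 1, 0.3)
  class_counts <- 1L + stats::rpois(n * nq, rep(lam, each = nq))
  class_rows <- data.table::data.table(
    physician = rep(ph$id, each = nq),
    drug = "class_other",
    quarter = rep.int(seq_len(nq), n),
    n_prescriptions = class_counts)

  out <- data.table::rbindlist(list(new_rows, class_rows))
  data.table::setorderv(out, c("physician", "drug", "quarter"))
  out[]
}

#' Generate a complete synthetic cohort
#'
#' Runs every generator stage in order — roster, patient sharing,
#' affiliations, the four peer networks, structural adoption, prescribing —
#' and returns them with the simulation truth. Identical configurations give
#' identical cohorts.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_cohort`: list with `physicians`,
#'   `shared_patients`, `affiliations`, `prescribing`, `networks` (named list
#'   of `peer_network`: `P`, `G`, `H`, `T`), `truth` and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_physicians = 150, seed = 3))
#' mean(coh$truth$realized_adoption)
simulate_cohort <- function(config) {
  physicians <- generate_physicians(config)
  shared <- generate_patient_sharing(config, physicians)
  affiliations <- generate_affiliations(config, physicians)
  networks <- list(
    P = build_patient_sharing_network(shared, nodes = physicians$id),
    G = build_affiliation_network(affiliations, kind = "G", nodes = physicians$id),
    H = build_affiliation_network(affiliations, kind = "H", nodes = physicians$id),
    T = build_training_network(physicians)
  )
  sim <- simulate_adoption(physicians, networks, config)
  if (config$contaminated_instrument)
    physicians$promo_exposure <- sim$truth$promo_exposure
  structure(list(physicians = physicians,
                 shared_patients = shared,
                 affiliations = affiliations,
                 prescribing = sim$prescribing,
                 networks = networks,
                 truth = sim$truth,
                 config = config),
            class = "synthetic_cohort")
}


# Promotional exposure loading on the community shock with idiosyncratic
# variation; used only under the contaminated-instrument dial.
contaminated_promo <- function(confounder_values, config) {
  scale <- if (config$confounder_sd > 0) 0.3 / config$confounder_sd else 0
  confounder_values * scale + stats::rnorm(length(confounder_values), sd = 0.8)
}

#' Redraw the adoption process on a fixed cohort
#'
#' Keeps the roster, covariates and networks of an existing cohort and
#' redraws only the adoption process (community confounder, equilibrium,
#' Bernoulli realization, prescribing counts) under a new seed. This is the
#' natural replicate for studying the sampling behavior of the estimators
#' and tests: the cohort structure is a fixed design, the outcomes are
#' random.
#'
#' @param cohort a `synthetic_cohort`.
#' @param seed seed for the redraw.
#' @return the cohort with refreshed `truth`, `prescribing` (and
#'   `promo_exposure` under the contaminated-instrument dial) and the new
#'   seed in its config.
#' @export
redraw_adoption <- function(cohort, seed) {
  config <- cohort$config
  config$seed <- as.integer(seed)
  sim <- simulate_adoption(cohort$physicians, cohort$networks, config)
  cohort$truth <- sim$truth
  cohort$prescribing <- sim$prescribing
  if (config$contaminated_instrument)
    cohort$physicians$promo_exposure <- sim$truth$promo_exposure
  cohort$config <- config
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$physicians), "physicians;",
      nrow(x$shared_patients), "shared-patient records;",
      nrow(x$affiliations), "affiliations\n")
  cat("  adoption rate:", round(mean(x$truth$realized_adoption), 3),
      " beta0:", round(x$truth$beta0, 3), "\n")
  invisible(x)
}

#' Write / read a synthetic cohort as plain-text files
#'
#' `write_cohort()` writes the four record tables as CSV plus the simulation
#' truth as JSON; `read_cohort()` reads them back (networks are rebuilt from
#' the records, not stored).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `synthetic_cohort` without `config`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort$physicians, file.path(dir, "physicians.csv"))
  data.table::fwrite(cohort$shared_patients, file.path(dir, "shared_patients.csv"))
  data.table::fwrite(cohort$affiliations, file.path(dir, "affiliations.csv"))
  data.table::fwrite(cohort$prescribing, file.path(dir, "prescribing.csv"))
  jsonlite::write_json(unclass(cohort$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  physicians <- data.table::fread(file.path(dir, "physicians.csv"))
  shared <- data.table::fread(file.path(dir, "shared_patients.csv"))
  affiliations <- data.table::fread(file.path(dir, "affiliations.csv"))
  prescribing <- data.table::fread(file.path(dir, "prescribing.csv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    structure(tr, class = "simulation_truth")
  }
  networks <- list(
    P = build_patient_sharing_network(shared, nodes = physicians$id),
    G = build_affiliation_network(affiliations, kind = "G", nodes = physicians$id),
    H = build_affiliation_network(affiliations, kind = "H", nodes = physicians$id),
    T = build_training_network(physicians)
  )
  structure(list(physicians = physicians, shared_patients = shared,
                 affiliations = affiliations, prescribing = prescribing,
                 networks = networks, truth = truth, config = NULL),
            class = "synthetic_cohort")
}
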