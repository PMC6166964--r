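test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_physicians = 0), "n_physicians")
  expect_error(sim_config(target_adoption_rate = 1.2), "target_adoption_rate")
  expect_error(sim_config(true_gamma = c(P = 1.1, G = 0, H = 0, T = 0)),
               "gamma")
  expect_error(sim_config(true_gamma = c(P = 0.6, G = 0.5, H = 0, T = 0)),
               "contraction")
  expect_error(sim_config(sharing_concentration = 0), "sharing_concentration")
  expect_error(sim_config(specialty_shares = c(pcp = 0.5, specialist = 0.2,
                                               other = 0.2)),
               "specialty_shares")
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_config(n = 100, seed = 7)
  p1 <- generate_physicians(cfg)
  p2 <- generate_physicians(cfg)
  expect_identical(p1, p2)

  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$shared_patients, c2$shared_patients)
  expect_identical(c1$truth$realized_adoption, c2$truth$realized_adoption)
  expect_identical(c1$prescribing, c2$prescribing)

  c3 <- simulate_cohort(tiny_config(n = 100, seed = 8))
  expect_false(identical(c1$truth$realized_adoption, c3$truth$realized_adoption))
})

test_that("roster marginals match the configured shares", {
  cfg <- sim_config(n_physicians = 10000, seed = 3)
  ph <- generate_physicians(cfg)
  shares <- table(ph$specialty) / nrow(ph)
  expect_lt(abs(shares[["pcp"]] - 0.7), 0.02)
  expect_lt(abs(shares[["specialist"]] - 0.1), 0.02)
  expect_lt(abs(shares[["other"]] - 0.2), 0.02)

  payer_sum <- ph$share_medicare + ph$share_medicaid + ph$share_cash
  expect_lt(max(abs(payer_sum - 1)), 1e-12)
  age_sum <- ph$share_age_lt50 + ph$share_age50_64 + ph$share_age65
  expect_lt(max(abs(age_sum - 1)), 1e-12)
  expect_true(all(ph$volume > 0))
  expect_gt(mean(ph$volume > 2 * median(ph$volume)), 0.02)  # right-skewed
  expect_true(all(ph$grad_year >= 1975 & ph$grad_year <= 2005))
})

test_that("patient assignment pairing matches the brute-force enumeration", {
  # {p1: {A,B}, p2: {A,B}, p3: {A,C}} on one payer -> (A,B,2), (A,C,1)
  asg <- data.frame(patient = c(1, 1, 2, 2, 3, 3),
                    payer = "medicare",
                    physician = c("A", "B", "A", "B", "A", "C"))
  got <- pairs_from_patient_assignments(asg)
  expect_equal(got$physician_a, c("A", "A"))
  expect_equal(got$physician_b, c("B", "C"))
  expect_equal(got$n_unique_patients, c(2L, 1L))

  # duplicate contacts within one patient collapse
  asg2 <- rbind(asg, data.frame(patient = 1, payer = "medicare", physician = "A"))
  expect_identical(pairs_from_patient_assignments(asg2), got)
})

test_that("single-physician patients generate no sharing records", {
  cfg <- tiny_config(n = 120, seed = 2, sharing_concentration = 1)
  ph <- generate_physicians(cfg)
  rec <- generate_patient_sharing(cfg, ph)
  expect_equal(nrow(rec), 0L)
})

test_that("sharing records are unordered pairs without self-pairs, bounded by patients", {
  cfg <- tiny_config(n = 250, seed = 4)
  ph <- generate_physicians(cfg)
  rec <- generate_patient_sharing(cfg, ph)
  expect_true(all(rec$physician_a < rec$physician_b))
  expect_false(any(rec$physician_a == rec$physician_b))
  expect_lte(max(table(paste(rec$physician_a, rec$physician_b, rec$payer))), 1)
  # counting bound: pooled pair-patients cannot exceed patients * C(k_max, 2)
  expect_lte(sum(rec$n_unique_patients), cfg$n_patients * choose(6, 2))
})

test_that("affiliation coverage matches configured probabilities", {
  cfg <- sim_config(n_physicians = 10000, seed = 5)
  ph <- generate_physicians(cfg)
  aff <- generate_affiliations(cfg, ph)
  hosp <- unique(aff$physician[aff$organization_kind == "hospital"])
  expect_lt(abs(length(hosp) / nrow(ph) - 0.9), 0.02)
  grp <- unique(aff$physician[aff$organization_kind == "group"])
  expect_lt(abs(length(grp) / nrow(ph) - 0.72), 0.02)
  # no duplicate membership rows
  expect_equal(anyDuplicated(aff[, c("physician", "organization_id")]), 0L)

  cfg0 <- tiny_config(n = 200, seed = 6, group_coverage = 0)
  aff0 <- generate_affiliations(cfg0, generate_physicians(cfg0))
  expect_equal(sum(aff0$organization_kind == "group"), 0L)
})

test_that("organization sizes reflect small groups and large hospitals", {
  cfg <- sim_config(n_physicians = 4000, seed = 8)
  ph <- generate_physicians(cfg)
  aff <- generate_affiliations(cfg, ph)
  gsz <- table(aff$organization_id[aff$organization_kind == "group"])
  hsz <- table(aff$organization_id[aff$organization_kind == "hospital"])
  expect_lt(mean(gsz), 25)
  expect_gt(mean(hsz), 100)
})

test_that("two symmetric physicians solve the hand-computable fixed point", {
  # p = 0.2 + 0.5 * p_peer for both: p = 0.2 / (1 - 0.5) = 0.4
  ph <- toy_physicians()[1:2, ]
  nw <- list(P = peer_network("P", ph$id,
                              data.frame(a = "A", b = "B", weight = 1)))
  cfg <- sim_config(n_physicians = 2, n_patients = 1,
                    true_gamma = c(P = 0.5, G = 0, H = 0, T = 0),
                    true_beta = c(female = 0), beta0 = 0.2,
                    confounder_sd = 0, idiosyncratic_sd = 0, seed = 1)
  ph$female <- 0
  sim <- simulate_adoption(ph, nw, cfg)
  expect_equal(unname(sim$truth$equilibrium_propensity), c(0.4, 0.4),
               tolerance = 1e-9)
})

test_that("with all gamma zero the propensity is the clipped linear index", {
  cfg <- tiny_config(n = 300, seed = 10,
                     true_gamma = c(P = 0, G = 0, H = 0, T = 0),
                     confounder_sd = 0, idiosyncratic_sd = 0, beta0 = 0.1)
  coh <- simulate_cohort(cfg)
  covs <- physician_covariates(coh$physicians)
  xb <- as.matrix(covs[, names(cfg$true_beta), with = FALSE]) %*% cfg$true_beta
  expect_equal(coh$truth$equilibrium_propensity,
               pmin(pmax(0.1 + xb[, 1], 0.01), 0.99), tolerance = 1e-12)
})

test_that("the structural map contracts to the same fixed point from any start", {
  cfg <- tiny_config(n = 400, seed = 12)
  coh <- simulate_cohort(cfg)
  W_list <- lapply(coh$networks, row_normalize, nodes = coh$physicians$id)
  gamma <- cfg$true_gamma
  set.seed(1)
  base <- rnorm(400, mean = 0.1, sd = 0.2)
  ref <- solve_equilibrium(base, W_list, gamma, tol = 1e-12)
  for (try in 1:3) {
    p2 <- solve_equilibrium(base, W_list, gamma, start = runif(400),
                            tol = 1e-12)
    expect_lt(max(abs(p2 - ref)), 1e-9)
  }
})

test_that("re-applying the structural map leaves the equilibrium fixed", {
  cfg <- tiny_config(n = 500, seed = 13)
  coh <- simulate_cohort(cfg)
  W_list <- lapply(coh$networks, row_normalize, nodes = coh$physicians$id)
  gamma <- cfg$true_gamma
  p <- coh$truth$equilibrium_propensity
  covs <- physician_covariates(coh$physicians)
  xb <- as.vector(as.matrix(covs[, names(cfg$true_beta), with = FALSE]) %*%
                    cfg$true_beta)
  # base = beta0 + x'beta + u; u combines the stored community shock with
  # the idiosyncratic draw, recovered from interior entries of the fixed
  # point (u = p - peer - beta0 - xb there); re-apply the map once
  peer <- Reduce(`+`, lapply(names(gamma), function(k)
    gamma[[k]] * as.vector(W_list[[k]] %*% p)))
  interior <- p > 0.01 + 1e-9 & p < 0.99 - 1e-9
  base <- p - peer                        # exact on interior entries
  reapplied <- pmin(pmax(base + peer, 0.01), 0.99)
  expect_lt(max(abs(reapplied[interior] - p[interior])), 1e-10)
})

test_that("calibration hits the target adoption rate", {
  for (target in c(0.083, 0.25)) {
    cfg <- tiny_config(n = 1000, seed = 14, target_adoption_rate = target)
    coh <- simulate_cohort(cfg)
    expect_lt(abs(mean(coh$truth$equilibrium_propensity) - target), 0.02)
    expect_lt(abs(mean(coh$truth$realized_adoption) - target), 0.05)
  }
})

test_that("in a gamma-zero world adoption is uncorrelated with peer adoption", {
  cfg <- sim_config(n_physicians = 2500, seed = 15,
                    true_gamma = c(P = 0, G = 0, H = 0, T = 0),
                    confounder_sd = 0)
  coh <- simulate_cohort(cfg)
  W <- row_normalize(coh$networks$P, nodes = coh$physicians$id)
  y <- coh$truth$realized_adoption
  ybar <- as.vector(W %*% y)
  has_peers <- Matrix::rowSums(W) > 0
  r <- cor(y[has_peers], ybar[has_peers])
  expect_lt(abs(r), 3 / sqrt(sum(has_peers)))
})

test_that("thresholded (noise-free) outcomes follow the propensity ranking", {
  cfg <- tiny_config(n = 400, seed = 16, bernoulli_noise = FALSE)
  coh <- simulate_cohort(cfg)
  y <- coh$truth$realized_adoption
  p <- coh$truth$equilibrium_propensity
  expect_gte(min(p[y == 1]), max(p[y == 0]) - 1e-12)
  expect_lt(abs(mean(y) - 0.25), 0.03)
})

test_that("prescribing construction separates adopters from non-adopters", {
  coh <- simulate_cohort(tiny_config(n = 600, seed = 17))
  tot <- rxpeer:::new_drug_totals(coh$prescribing, coh$physicians$id)
  y <- coh$truth$realized_adoption
  expect_true(all(tot[y == 1] >= coh$truth$threshold))
  expect_true(all(tot[y == 0] < coh$truth$threshold))
  # a sizable fraction of non-adopters never prescribe
  expect_gt(mean(tot[y == 0] == 0), 0.5)
})

test_that("cohorts round-trip through CSV and JSON", {
  coh <- simulate_cohort(tiny_config(n = 120, seed = 18))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$physicians), 120)
  expect_equal(back$truth$realized_adoption, coh$truth$realized_adoption)
  expect_equal(as.data.frame(back$shared_patients),
               as.data.frame(coh$shared_patients))
  expect_equal(back$networks$P$edges$weight, coh$networks$P$edges$weight)
})
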