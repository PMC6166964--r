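# Shared fixtures and independent oracles used across test files.

# small default-condition cohort config; n kept modest for unit tests
tiny_config <- function(n = 400, seed = 42, ...) {
  sim_config(n_physicians = n, seed = seed, ...)
}

# hand-built roster for network construction tests
toy_physicians <- function() {
  data.frame(
    id = c("A", "B", "C", "D", "E"),
    female = c(1, 0, 0, 1, 0),
    grad_year = c(2000, 2001, 2002, 2000, 1990),
    residency_year = c(2004, 2005, 2006, 2004, 1994),
    specialty = c("pcp", "specialist", "pcp", "other", "pcp"),
    school = c("s1", "s1", "s1", "s2", "s2"),
    residency = c("r1", "r2", "r2", "r3", "r3"),
    location = "loc01",
    community = "loc01_c01",
    metro = c(1, 1, 0, 0, 1),
    volume = c(10, 50, 30, 80, 20),
    share_medicare = 0.5, share_medicaid = 0.3, share_cash = 0.2,
    share_age_lt50 = 0.2, share_age50_64 = 0.4, share_age65 = 0.4,
    promo_exposure = 0,
    attract = 1,
    stringsAsFactors = FALSE)
}

# brute-force co-affiliation projection: enumerate all pairs, check any
# shared organization of the kind
oracle_projection <- function(affiliations, org_kind, nodes) {
  aff <- affiliations[affiliations$organization_kind == org_kind, ]
  out <- list()
  nodes <- sort(nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    a <- unique(aff$organization_id[aff$physician == nodes[i]])
    b <- unique(aff$organization_id[aff$physician == nodes[j]])
    if (length(intersect(a, b)) > 0)
      out[[length(out) + 1L]] <- c(nodes[i], nodes[j])
  }
  if (!length(out)) return(data.frame(a = character(), b = character()))
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
}

# brute-force patient-sharing pooling and thresholding
oracle_patient_sharing <- function(records, min_shared) {
  key <- paste(pmin(records$physician_a, records$physician_b),
               pmax(records$physician_a, records$physician_b), sep = "|")
  pooled <- tapply(records$n_unique_patients, key, sum)
  pooled <- pooled[pooled >= min_shared]
  out <- do.call(rbind, strsplit(names(pooled), "|", fixed = TRUE))
  if (is.null(out)) return(data.frame(a = character(), b = character(),
                                      weight = numeric()))
  df <- data.frame(a = out[, 1], b = out[, 2], weight = as.numeric(pooled),
                   stringsAsFactors = FALSE)
  df[order(df$a, df$b), ]
}

# closed-form IV estimate via explicit projection algebra, independent of
# fit_2sls: b = (X'Pz X)^-1 X'Pz y
oracle_iv <- function(y, X, Z) {
  Pz <- Z %*% solve(crossprod(Z), t(Z))
  solve(t(X) %*% Pz %*% X, t(X) %*% Pz %*% y)[, 1]
}

# random small 2SLS instance; returns data + spec with n <= 50
random_iv_instance <- function(seed, n = 40, k_endog = 1, k_instr = 2,
                               k_exog = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * k_instr), n, k_instr)
  Xex <- matrix(rnorm(n * k_exog), n, k_exog)
  V <- matrix(rnorm(n * k_endog), n, k_endog)
  Xen <- Z %*% matrix(runif(k_instr * k_endog, 0.5, 1.5), k_instr) +
    Xex %*% matrix(0.3, k_exog, k_endog) + V
  eps <- rnorm(n) + rowSums(V)          # endogenous: eps correlated with V
  y <- 1 + Xen %*% rep(0.7, k_endog) + Xex %*% rep(0.5, k_exog) + eps
  d <- data.frame(y = y[, 1], Xen, Xex, Z)
  names(d) <- c("y", paste0("en", seq_len(k_endog)), paste0("ex", seq_len(k_exog)),
                paste0("z", seq_len(k_instr)))
  list(data = d,
       spec = model_spec("y", paste0("en", seq_len(k_endog)),
                         paste0("ex", seq_len(k_exog)),
                         paste0("z", seq_len(k_instr))))
}

# walk-enumeration oracle for the multiplier: sum over the first n_terms of
# gamma^t column sums of W^t using dense matrix powers
oracle_multiplier <- function(W, gamma, n_terms = 50) {
  Wd <- as.matrix(W)
  acc <- rep(0, nrow(Wd))
  P <- diag(nrow(Wd))
  for (t in seq_len(n_terms)) {
    P <- P %*% Wd
    acc <- acc + gamma^t * colSums(P)
  }
  acc
}

# random row-stochastic matrix with zero diagonal
random_row_stochastic <- function(n, seed) {
  set.seed(seed)
  M <- matrix(runif(n * n), n, n)
  diag(M) <- 0
  M / rowSums(M)
}
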