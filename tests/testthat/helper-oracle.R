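# Independent brute-force FIML deviance: loops over families one at a time and
# evaluates the multivariate-normal log-density of each family's observed
# values directly with determinant() and solve(). Shares no code with the
# grouped/Cholesky production path.
oracle_m2ll <- function(data, traits, covariates, vc, B) {
  p <- length(vc$A[, 1])
  d <- encode_covariates(tibble::as_tibble(data))
  covs <- ifelse(covariates == "sex", "sex01", covariates)
  total <- 0
  for (fid in unique(d$family_id)) {
    fam <- d[d$family_id == fid, , drop = FALSE]
    y <- rep(NA_real_, 2 * p)
    mu <- rep(NA_real_, 2 * p)
    zyg <- fam$zygosity[1]
    for (k in seq_len(nrow(fam))) {
      slot <- fam$twin_order[k]
      x <- c(1, as.numeric(fam[k, covs, drop = FALSE]))
      idx <- (slot - 1) * p + seq_len(p)
      y[idx] <- as.numeric(fam[k, traits, drop = FALSE])
      mu[idx] <- as.vector(t(B) %*% x)
    }
    obs <- !is.na(y)
    if (!any(obs)) next
    sig <- expected_pair_covariance(vc, zyg)[obs, obs, drop = FALSE]
    r <- y[obs] - mu[obs]
    k <- sum(obs)
    total <- total + k * log(2 * pi) + log(det(sig)) +
      as.numeric(t(r) %*% solve(sig) %*% r)
  }
  total
}

# tiny hand-made twin table
make_twin_tbl <- function() {
  d <- tibble::tibble(
    family_id = c("f1", "f1", "f2", "f2", "f3", "f3", "f4"),
    twin_order = c(1, 2, 1, 2, 1, 2, 1),
    zygosity = c("MZ", "MZ", "MZ", "MZ", "DZ", "DZ", "DZ"),
    sex = c("female", "female", "male", "male", "female", "male", "female"),
    age = c(40, 40, 55, 55, 30, 30, 62),
    y = c(1.2, 0.8, -0.5, -0.2, 0.1, 0.4, 1.5),
    z = c(2.0, NA, 1.1, 0.9, -0.3, 0.2, 0.5))
  validate_twin_data(d, phenotypes = c("y", "z"))
}

# quick univariate simulation shorthand
sim_uni <- function(a, c, e, n_mz, n_dz, seed, n_singletons = 0, mm = NULL) {
  vc <- vc_from_shares(a = a, c = c, e = e)
  cfg <- twin_sim_config(vc, mm = mm, n_mz = n_mz, n_dz = n_dz,
                         n_singletons = n_singletons, training_mean = NULL)
  simulate_twin_data(cfg, seed = seed)
}
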