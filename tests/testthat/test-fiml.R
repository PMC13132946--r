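test_that("deviance matches closed-form Gaussian densities in trivial cases", {
  # one complete pair, mu = 0, Sigma = I  ->  2 log(2 pi)
  d <- tibble::tibble(family_id = "f", twin_order = c(1, 2),
                      zygosity = "MZ", sex = "female", age = 40, y = c(0, 0))
  d <- validate_twin_data(d, phenotypes = "y")
  spec <- ace_model_spec("y", covariates = character())
  th <- c(A11 = 0, C11 = 0, E11 = 1, b0_1 = 0)
  expect_equal(minus_two_loglik(d, spec, th), 2 * log(2 * pi),
               tolerance = 1e-12)

  # a singleton contributes its marginal density: log(2 pi)
  s <- validate_twin_data(
    tibble::tibble(family_id = "g", twin_order = 1, zygosity = "DZ",
                   sex = "male", age = 50, y = 0), phenotypes = "y")
  expect_equal(minus_two_loglik(s, spec, th), log(2 * pi), tolerance = 1e-12)
})

test_that("grouped deviance equals per-pair brute-force density evaluation", {
  set.seed(77)
  for (rep in 1:5) {
    vc <- vc_from_shares(a = c(40, 50), c = c(35, 20), e = c(25, 30),
                         rg = 0.5, rc = 0.4, re = 0.2,
                         traits = c("y", "z"))
    mm <- mean_model(c(0.5, -0.2), beta_age = c(0.01, 0),
                     beta_sex = c(0.3, -0.1))
    cfg <- twin_sim_config(vc, mm = mm, n_mz = 15, n_dz = 10,
                           n_singletons = 5, training_mean = NULL,
                           missing_rate = 0.15)
    d <- simulate_twin_data(cfg, seed = 1000 + rep)
    spec <- ace_model_spec(c("y", "z"), covariates = c("age", "sex"))
    info_classes <- unique(spec$params$class[spec$params$free])
    th <- stats::setNames(runif(length(info_classes), -0.2, 0.6),
                          info_classes)
    # keep the total covariance PD for a fair comparison
    th[c("E11", "E22")] <- abs(th[c("E11", "E22")]) + 1
    th["E21"] <- 0.1
    vals <- twinace:::realize_params(spec, th)
    vc_th <- twinace:::vc_from_values(spec, vals)
    B_th <- twinace:::meanmat_from_values(spec, vals)
    expect_equal(minus_two_loglik(d, spec, th),
                 oracle_m2ll(d, c("y", "z"), c("age", "sex"), vc_th, B_th),
                 tolerance = 1e-10)
  }
})

test_that("saturated fit on complete balanced data attains the closed-form MLE", {
  d <- sim_uni(50, 30, 20, n_mz = 200, n_dz = 0, seed = 21)
  # single subgroup: force all female so one group of complete pairs
  d$sex <- "female"
  spec <- saturated_spec("trait1", "MZF")
  fit <- fit_twin_model(d, spec, n_restarts = 0)
  y1 <- d$trait1[d$twin_order == 1]
  y2 <- d$trait1[d$twin_order == 2]
  n <- length(y1)
  Y <- cbind(y1, y2)
  S_ml <- stats::cov(Y) * (n - 1) / n
  mu <- colMeans(Y)
  m2ll_closed <- n * (2 * log(2 * pi) + log(det(S_ml)) + 2)
  expect_equal(fit$minus2LL, m2ll_closed, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$AIC, fit$minus2LL + 2 * fit$EP)
  expect_equal(fit$df + fit$EP, 2 * n)
})

test_that("univariate ACE recovery from simulated twin data", {
  d <- sim_uni(50, 30, 20, n_mz = 3000, n_dz = 3000, seed = 300)
  spec <- ace_model_spec("trait1", covariates = character())
  fit <- fit_twin_model(d, spec, n_restarts = 1)
  sh <- standardize_components(fit$vc)
  expect_true(fit$converged)
  expect_lt(abs(sh$A - 50), 5)
  expect_lt(abs(sh$C - 30), 5)
  expect_lt(abs(sh$E - 20), 2.5)
})

test_that("null components are recovered near zero", {
  d <- sim_uni(0, 0, 100, n_mz = 3000, n_dz = 3000, seed = 301)
  spec <- ace_model_spec("trait1", covariates = character())
  fit <- fit_twin_model(d, spec, n_restarts = 1)
  sh <- standardize_components(fit$vc)
  expect_lt(abs(sh$A), 6)
  expect_lt(abs(sh$C), 6)
})

test_that("mean-model covariate effects are estimated", {
  mm <- mean_model(1, beta_age = 0.05, beta_sex = -0.4)
  d <- sim_uni(50, 30, 20, n_mz = 1500, n_dz = 1500, seed = 302, mm = mm)
  spec <- ace_model_spec("trait1", covariates = c("age", "sex"))
  fit <- fit_twin_model(d, spec, n_restarts = 0)
  expect_equal(unname(fit$mean_coef["age", 1]), 0.05, tolerance = 0.01)
  expect_equal(unname(fit$mean_coef["sex", 1]), -0.4, tolerance = 0.15)
})

test_that("likelihood-ratio machinery matches chi-square arithmetic", {
  expect_equal(lrt_pvalue(13.24, 6), 0.0394, tolerance = 1e-3)
  expect_equal(lrt_pvalue(0, 3), 1)
  expect_equal(lrt_pvalue(stats::qchisq(0.95, 1), 1), 0.05, tolerance = 1e-12)

  expect_equal(aic(6941.98, 24), 6989.98)
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(100, 5), 110)
  expect_error(aic(10, -1), "nonnegative")
})

test_that("nested submodels never beat their parent and LRT validates nesting", {
  d <- sim_uni(45, 25, 30, n_mz = 400, n_dz = 300, seed = 303,
               n_singletons = 30)
  full_spec <- ace_model_spec("trait1")
  full <- fit_twin_model(d, full_spec, n_restarts = 0)
  fits <- list(full)
  for (sub in list(drop_component(full_spec, "C"),
                   drop_component(full_spec, "A"),
                   drop_component(drop_component(full_spec, "A"), "C"))) {
    f <- fit_twin_model(d, sub, n_restarts = 0)
    expect_gte(f$minus2LL, full$minus2LL - 1e-6)
    lr <- likelihood_ratio_test(full, f)
    expect_gte(lr$p, 0)
    expect_lte(lr$p, 1)
    expect_equal(lr$delta_df, full$EP - f$EP)
    fits <- c(fits, list(f))
  }
  # E-only nests in CE: deviance ordering again
  expect_gte(fits[[4]]$minus2LL, fits[[3]]$minus2LL - 1e-6)
  # reversed arguments are rejected
  expect_error(likelihood_ratio_test(fits[[2]], full), "fewer")
})

test_that("identical seeds give bit-identical fits", {
  d <- sim_uni(40, 30, 30, n_mz = 150, n_dz = 100, seed = 304)
  spec <- ace_model_spec("trait1")
  f1 <- fit_twin_model(d, spec, n_restarts = 2, seed = 9)
  f2 <- fit_twin_model(d, spec, n_restarts = 2, seed = 9)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$minus2LL, f2$minus2LL)
})

test_that("profile intervals agree with the Wald interval at large n", {
  d <- sim_uni(50, 30, 20, n_mz = 1500, n_dz = 1500, seed = 305)
  spec <- ace_model_spec("trait1", covariates = character())
  fit <- fit_twin_model(d, spec, n_restarts = 0)
  ci <- profile_ci(d, fit, "A11")
  # independent Wald oracle: numerical Hessian of the deviance at the MLE
  th <- fit$estimates
  obj <- function(t) minus_two_loglik(d, spec, t)
  np <- length(th)
  h <- 1e-4 * (1 + abs(th))
  H <- matrix(0, np, np)
  for (a in seq_len(np)) {
    for (b in seq_len(np)) {
      tpp <- th; tpm <- th; tmp <- th; tmm <- th
      tpp[a] <- tpp[a] + h[a]; tpp[b] <- tpp[b] + h[b]
      tpm[a] <- tpm[a] + h[a]; tpm[b] <- tpm[b] - h[b]
      tmp[a] <- tmp[a] - h[a]; tmp[b] <- tmp[b] + h[b]
      tmm[a] <- tmm[a] - h[a]; tmm[b] <- tmm[b] - h[b]
      H[a, b] <- (obj(tpp) - obj(tpm) - obj(tmp) + obj(tmm)) /
        (4 * h[a] * h[b])
    }
  }
  se <- sqrt(2 * solve(H)[1, 1])  # cov(theta) = 2 H^{-1} for a deviance
  est <- unname(th["A11"])
  wald <- c(est - 1.96 * se, est + 1.96 * se)
  halfwidth <- 1.96 * se
  expect_lt(abs(ci$lower - wald[1]), 0.05 * halfwidth)
  expect_lt(abs(ci$upper - wald[2]), 0.05 * halfwidth)

  # intervals widen monotonically with the level
  ci99 <- profile_ci(d, fit, "A11", level = 0.99)
  expect_lt(ci99$lower, ci$lower)
  expect_gt(ci99$upper, ci$upper)
})

test_that("share profiles hit the natural zero boundary when C vanishes", {
  d <- sim_uni(60, 0, 40, n_mz = 400, n_dz = 400, seed = 306)
  spec <- ace_model_spec("trait1", covariates = character())
  fit <- fit_twin_model(d, spec, n_restarts = 0)
  sh <- standardize_components(fit$vc)
  expect_gt(sh$C, 0)  # the boundary convention applies to positive estimates
  ci <- profile_share_ci(d, fit, "C", 1)
  expect_identical(ci$lower, 0)
  expect_true(ci$boundary_lower)
})
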