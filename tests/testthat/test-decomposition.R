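test_that("standardized shares are percentages of total variance", {
  vc <- variance_components(A = 0.5, C = 0.3, E = 0.2)
  sh <- standardize_components(vc)
  expect_equal(c(sh$A, sh$C, sh$E), c(50, 30, 20))

  # an already standardized set reproduces its own shares
  vc2 <- vc_from_shares(a = 35.23, c = 41.88, e = 22.88)
  sh2 <- standardize_components(vc2)
  expect_equal(sh2$A, 35.23, tolerance = 1e-3)
  expect_equal(sh2$C, 41.88, tolerance = 1e-3)

  set.seed(12)
  for (rep in 1:10) {
    m <- matrix(rnorm(9), 3)
    vcr <- variance_components(A = m %*% t(m), C = diag(runif(3, 0.1, 1)),
                               E = diag(runif(3, 0.1, 1)))
    shr <- standardize_components(vcr)
    expect_equal(shr$A + shr$C + shr$E, rep(100, 3), tolerance = 1e-9)
  }
})

test_that("component correlations match covariance-to-correlation conversion", {
  A <- matrix(c(0.4, 0, 0, 0.4), 2, 2)
  expect_equal(genetic_correlation(A), 0)
  A1 <- matrix(0.4, 2, 2)
  expect_equal(genetic_correlation(A1), 1)

  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(rnorm(9), 3)
    A <- m %*% t(m) + diag(3) * 0.1
    cc <- stats::cov2cor(A)
    for (i in 1:2) for (j in (i + 1):3) {
      expect_equal(component_correlation(A, i, j), cc[i, j],
                   tolerance = 1e-12)
    }
  }
  expect_error(component_correlation(matrix(c(-1, 0, 0, 1), 2), 1, 2),
               "positive diagonal")

  # scale invariance: rescaling a trait's variance leaves r_g unchanged
  m <- matrix(rnorm(4), 2)
  A <- m %*% t(m) + diag(2) * 0.1
  k <- 3.7
  As <- diag(c(k, 1)) %*% A %*% diag(c(k, 1))
  expect_equal(component_correlation(As, 1, 2),
               component_correlation(A, 1, 2), tolerance = 1e-12)
})

test_that("bivariate contributions decompose the phenotypic correlation", {
  # single-path: only the genetic cross-path is open
  vc <- vc_from_shares(a = c(40, 40), c = c(30, 30), e = c(30, 30),
                       rg = 0.5, rc = 0, re = 0)
  ct <- bivariate_contributions(vc)
  expect_equal(ct$A, 100, tolerance = 1e-9)

  set.seed(14)
  for (rep in 1:10) {
    vcr <- vc_from_shares(a = c(40, 35), c = c(30, 40), e = c(30, 25),
                          rg = runif(1, -0.8, 0.8), rc = runif(1, -0.8, 0.8),
                          re = runif(1, 0.05, 0.8))
    ctr <- bivariate_contributions(vcr)
    expect_equal(ctr$A + ctr$C + ctr$E, 100, tolerance = 1e-9)
  }

  # invariance to simultaneous rescaling of both traits
  scale2 <- function(vc, k1, k2) {
    Dm <- diag(c(k1, k2))
    variance_components(A = Dm %*% vc$A %*% Dm, C = Dm %*% vc$C %*% Dm,
                        E = Dm %*% vc$E %*% Dm, traits = vc$traits)
  }
  vcs <- scale2(vc, 2.5, 0.4)
  expect_equal(bivariate_contributions(vcs)[, c("r_p", "A", "C", "E")],
               ct[, c("r_p", "A", "C", "E")], tolerance = 1e-10)
})

test_that("published-style cross-paths reproduce their printed decomposition", {
  # unit-variance traits with cross-terms equal to contribution * r_p:
  # feeding the decomposition back through the formula recovers the printed
  # percentages 36.64 / 52.35 / 11.00 at r_p = .68
  r_p <- 0.68
  a <- c(41.71, 35.23) / 100
  c_ <- c(28.92, 41.88) / 100
  e <- c(29.37, 22.88) / 100
  A <- diag(a); C <- diag(c_); E <- diag(e)
  A[1, 2] <- A[2, 1] <- 0.3664 * r_p
  C[1, 2] <- C[2, 1] <- 0.5235 * r_p
  E[1, 2] <- E[2, 1] <- 0.1100 * r_p
  vc <- variance_components(A = A, C = C, E = E,
                            traits = c("SSE_Factor", "SPI"))
  ct <- bivariate_contributions(vc)
  expect_equal(ct$r_p, 0.68, tolerance = 0.005)
  expect_equal(ct$A, 36.64, tolerance = 0.15)
  expect_equal(ct$C, 52.35, tolerance = 0.15)
  expect_equal(ct$E, 11.00, tolerance = 0.15)
})

test_that("model family selection follows the twice-DZ rule", {
  expect_equal(select_model_family(0.77, 0.60), "ACE")
  expect_equal(select_model_family(0.8, 0.2), "ADE")
  expect_equal(select_model_family(0.5, 0.25), "ACE")  # tie goes to ACE
})

test_that("intraclass correlation is ML-consistent", {
  # degenerate: twin 2 identical to twin 1
  d <- sim_uni(50, 30, 20, n_mz = 50, n_dz = 0, seed = 500)
  d$trait1 <- rep(d$trait1[d$twin_order == 1], each = 2)
  icc <- intraclass_correlation(d, "trait1", "MZ", conf = FALSE)
  expect_gt(icc$icc, 0.999)

  # independent twins: correlation near zero
  d0 <- sim_uni(0, 0, 100, n_mz = 4000, n_dz = 0, seed = 501)
  icc0 <- intraclass_correlation(d0, "trait1", "MZ", conf = FALSE)
  expect_lt(abs(icc0$icc), 0.04)

  # generating implied MZ correlation 0.77 is recovered
  d77 <- sim_uni(35.23, 41.88, 22.88, n_mz = 3000, n_dz = 0, seed = 502)
  icc77 <- intraclass_correlation(d77, "trait1", "MZ")
  expect_equal(icc77$icc, 0.7711, tolerance = 0.03)
  expect_lt(icc77$lower, icc77$icc)
  expect_gt(icc77$upper, icc77$icc)

  # double-entry Pearson diagnostic agrees with the ML estimate
  de <- intraclass_correlation(d77, "trait1", "MZ", method = "double_entry")
  expect_equal(de$icc, icc77$icc, tolerance = 0.02)

  expect_error(intraclass_correlation(d[1:4, ], "trait1", "DZ"),
               "at least 3")
})

test_that("cross-twin cross-trait correlation recovers its generating value", {
  traits <- c("SSE_Factor", "SPI")
  vc <- vc_from_shares(a = c(41.71, 35.23), c = c(28.92, 41.88),
                       e = c(29.37, 22.88), rg = 0.63, rc = 0.90, re = 0.29,
                       traits = traits)
  implied_mz_ctct <- vc$A[1, 2] + vc$C[1, 2]
  cfg <- twin_sim_config(vc, n_mz = 3000, n_dz = 0, training_mean = NULL)
  d <- simulate_twin_data(cfg, seed = 503)
  ct <- ctct_correlation(d, "SSE_Factor", "SPI", "MZ", conf = FALSE)
  expect_equal(ct$ctct, implied_mz_ctct, tolerance = 0.03)

  # same trait reduces to the intraclass correlation
  same <- ctct_correlation(d, "SPI", "SPI", "MZ", conf = FALSE)
  icc <- intraclass_correlation(d, "SPI", "MZ", conf = FALSE)
  expect_equal(same$ctct, icc$icc)

  # independent traits on independent twins decorrelate
  vc0 <- vc_from_shares(a = c(0, 0), c = c(0, 0), e = c(100, 100),
                        rg = 0, rc = 0, re = 0, traits = traits)
  d0 <- simulate_twin_data(twin_sim_config(vc0, n_mz = 3000, n_dz = 0,
                                           training_mean = NULL), seed = 504)
  ct0 <- ctct_correlation(d0, "SSE_Factor", "SPI", "MZ", conf = FALSE)
  expect_lt(abs(ct0$ctct), 0.04)
})

test_that("decompose_fit flags out-of-range component correlations", {
  A <- matrix(c(0.4, 0.25, 0.25, 0.4), 2)
  C <- matrix(c(0.3, 0.35, 0.35, 0.3), 2)  # r_c > 1 (boundary)
  E <- matrix(c(0.3, 0.05, 0.05, 0.3), 2)
  fit <- structure(list(vc = variance_components(A = A, C = C, E = E,
                                                 traits = c("x", "y"))),
                   class = "twin_fit")
  dec <- decompose_fit(fit)
  expect_gt(dec$pairs$r_c, 1)
  expect_true(dec$pairs$boundary)
  expect_equal(dec$pairs$r_c_display, 1)
  expect_equal(dec$pairs$pct_A + dec$pairs$pct_C + dec$pairs$pct_E, 100,
               tolerance = 1e-9)
})
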