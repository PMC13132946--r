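test_that("expected pair covariance follows the twin block structure", {
  vc <- variance_components(A = 0.5, C = 0.3, E = 0.2)
  expect_equal(expected_pair_covariance(vc, "MZ"),
               matrix(c(1, 0.8, 0.8, 1), 2, 2))
  expect_equal(expected_pair_covariance(vc, "DZ"),
               matrix(c(1, 0.55, 0.55, 1), 2, 2))

  # independence limit: no familial components, cross block vanishes
  vc0 <- variance_components(A = 0, C = 0, E = 0.7)
  expect_equal(expected_pair_covariance(vc0, "MZ")[1, 2], 0)
  expect_equal(expected_pair_covariance(vc0, "DZ")[2, 1], 0)

  expect_error(variance_components(A = matrix(c(1, 0.2, 0.3, 1), 2, 2),
                                   C = diag(2), E = diag(2)),
               "symmetric")
})

test_that("ADE cross-twin blocks weight dominance by quarter in DZ pairs", {
  vc <- variance_components(A = 0.4, D = 0.2, E = 0.4, C = NULL)
  expect_equal(expected_pair_covariance(vc, "DZ")[1, 2], 0.25)
  expect_equal(expected_pair_covariance(vc, "MZ")[1, 2], 0.6)

  # D = 0 nests the ACE result with C = 0
  vc_d0 <- variance_components(A = 0.4, D = 0, E = 0.6, C = NULL)
  vc_c0 <- variance_components(A = 0.4, C = 0, E = 0.6)
  for (z in c("MZ", "DZ")) {
    expect_equal(expected_pair_covariance(vc_d0, z),
                 expected_pair_covariance(vc_c0, z))
  }
})

test_that("pair covariance identities hold for random component sets", {
  set.seed(42)
  for (rep in 1:20) {
    p <- sample(1:3, 1)
    rnd_psd <- function() {
      m <- matrix(rnorm(p * p), p)
      m %*% t(m) / p
    }
    vc <- variance_components(A = rnd_psd(), C = rnd_psd(), E = rnd_psd())
    smz <- expected_pair_covariance(vc, "MZ")
    sdz <- expected_pair_covariance(vc, "DZ")
    for (s in list(smz, sdz)) {
      expect_equal(s, t(s))
      expect_equal(s[seq_len(p), seq_len(p)],
                   s[p + seq_len(p), p + seq_len(p)])
    }
    # MZ cross-block minus DZ cross-block is exactly half the A matrix
    expect_equal(smz[seq_len(p), p + seq_len(p), drop = FALSE] -
                   sdz[seq_len(p), p + seq_len(p), drop = FALSE], 0.5 * vc$A)
  }
})

test_that("expected pair means are linear in covariates and twin-symmetric", {
  mm <- mean_model(c(1, 2, 3))
  expect_equal(expected_pair_mean(mm, list(age = 50, sex01 = 0),
                                  list(age = 20, sex01 = 1)),
               c(1, 2, 3, 1, 2, 3))
  mm2 <- mean_model(0, beta_age = 1, beta_sex = 0)
  expect_equal(expected_pair_mean(mm2, list(age = 40, sex01 = 0),
                                  list(age = 50, sex01 = 0)),
               c(40, 50))
  # sex enters only through its slope
  mm3 <- mean_model(1, beta_age = 0, beta_sex = 2)
  mu <- expected_pair_mean(mm3, list(age = 10, sex01 = 1),
                           list(age = 10, sex01 = 0))
  expect_equal(mu, c(3, 1))
  expect_error(expected_pair_mean(mm3, list(age = 10), list(age = 10, sex01 = 0)),
               "covariates")
})

test_that("parameter counts follow the transparent convention", {
  s3 <- ace_model_spec(c("x", "y", "z"))
  expect_equal(count_parameters(s3), 27)  # 18 component + 9 mean
  s1 <- ace_model_spec("x")
  expect_equal(count_parameters(s1), 6)
  e3 <- drop_component(drop_component(s3, "A"), "C")
  expect_equal(count_parameters(e3), 15)  # 6 E + 9 mean
})

test_that("constraints remove the documented numbers of parameters", {
  s3 <- ace_model_spec(c("x", "y", "z"))
  expect_equal(count_parameters(s3) - count_parameters(drop_component(s3, "C")), 6)
  expect_equal(count_parameters(s3) -
                 count_parameters(fix_component_correlation(s3, "C", 0.90)), 3)
  expect_equal(count_parameters(s3) -
                 count_parameters(equate_params(s3, c("C22", "C33"))), 1)
  expect_equal(count_parameters(s3) -
                 count_parameters(drop_component_for(s3, "C", "y")), 3)

  expect_error(equate_params(s3, c("A11", "C11")), "different matrices")
})

test_that("constraint application commutes and preserves nesting", {
  s3 <- ace_model_spec(c("x", "y", "z"))
  ab <- drop_component_for(drop_component_for(s3, "C", 1), "C", 2)
  ba <- drop_component_for(drop_component_for(s3, "C", 2), "C", 1)
  expect_identical(ab$params, ba$params)

  free_of <- function(sp) unique(sp$params$class[sp$params$free])
  e_spec <- drop_component(drop_component(s3, "A"), "C")
  ce_spec <- drop_component(s3, "A")
  ae_spec <- drop_component(s3, "C")
  expect_true(all(free_of(e_spec) %in% free_of(ce_spec)))
  expect_true(all(free_of(ce_spec) %in% free_of(s3)))
  expect_true(all(free_of(ae_spec) %in% free_of(s3)))
})

test_that("model specs survive a JSON round trip", {
  s <- fix_component_correlation(ace_model_spec(c("x", "y")), "C", 0.9)
  s2 <- spec_from_json(spec_to_json(s))
  expect_equal(s2$family, s$family)
  expect_equal(s2$rc_rho, s$rc_rho)
  expect_equal(count_parameters(s2), count_parameters(s))
  expect_equal(as.data.frame(s2$params), as.data.frame(s$params))
})
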