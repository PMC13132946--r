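sim_ladder_data <- function(n_mz, n_dz, seed, beta_sex = 0, dz_os = 0.06) {
  vc <- vc_from_shares(a = 45, c = 25, e = 30)
  mm <- mean_model(0, beta_age = 0, beta_sex = beta_sex)
  cfg <- twin_sim_config(vc, mm = mm, n_mz = n_mz, n_dz = n_dz,
                         n_singletons = round(0.1 * n_mz), dz_os = dz_os,
                         training_mean = NULL)
  simulate_twin_data(cfg, seed = seed)
}

test_that("under equal subgroup moments every pass/fail rung passes", {
  d <- sim_ladder_data(300, 200, seed = 400)
  lad <- run_assumption_ladder(d, "trait1", alpha = 0.01)
  expect_true(ladder_passed(lad))
  expect_s3_class(lad, "twin_ladder")
  # rungs are cumulative: EP never increases, deviance never decreases
  expect_true(all(diff(lad$EP) <= 0))
  expect_true(all(diff(lad$minus2LL) >= -1e-6))
})

test_that("rung df equals the number of parameters merged", {
  d <- sim_ladder_data(200, 150, seed = 401, dz_os = 0.1)
  lad <- run_assumption_ladder(d, "trait1")
  groups <- attr(lad, "groups")
  expect_setequal(groups, c("MZF", "MZM", "DZF", "DZM", "DZOS"))
  dd <- lad[!is.na(lad$delta_df) & lad$delta_df > 0, ]
  # 5 groups: twin-order merges 5; zygosity merges F and M pairs (2);
  # sex merges the remaining 3 classes (2); covariances across sex merge
  # within MZ and within DZ excluding OS (2); across zygosity merges the
  # remaining 3 covariance classes (2)
  expect_equal(dd$delta_df[dd$step %in% 1:8],
               c(5L, 2L, 2L, 5L, 2L, 2L, 2L, 2L))
})

test_that("an injected sex difference in means is detected", {
  d <- sim_ladder_data(700, 500, seed = 402, beta_sex = 1)
  lad <- run_assumption_ladder(d, "trait1", alpha = 0.01)
  sex_rung <- lad[lad$constraint == "means equal across sex", ]
  expect_false(sex_rung$pass)
  expect_lt(sex_rung$p, 1e-6)
})

test_that("zygosity-covariance rung is reporting-only by default but fails under genetic effects", {
  d <- sim_ladder_data(450, 300, seed = 403)
  lad <- run_assumption_ladder(d, "trait1")
  zyg_rung <- lad[lad$constraint == "covariances equal across zygosity", ]
  expect_true(zyg_rung$reporting_only)
  expect_true(is.na(zyg_rung$pass))
  expect_lt(zyg_rung$p, 0.01)  # familial aggregation genuinely differs
  expect_true(ladder_passed(lad))

  lad2 <- run_assumption_ladder(d, "trait1", zygosity_cov_pass_fail = TRUE)
  expect_false(ladder_passed(lad2))
})

test_that("study-composition data reproduce a clean assumption profile", {
  d <- simulate_twin_data(twin_sim_preset(), seed = 404)
  rungs <- dplyr::bind_rows(lapply(attr(d, "phenotypes"), function(tr) {
    tidy(run_assumption_ladder(d, tr, alpha = 0.01))
  }))
  failed <- sum(!rungs$pass, na.rm = TRUE)
  # 21 null rungs at alpha = 0.01: more than one failure would indicate a
  # real subgroup difference rather than chance
  expect_lte(failed, 1)
})

test_that("rung p-values are uniform under the null", {
  # distribution of the means-across-twin-order LRT over replicates
  vc <- vc_from_shares(a = 45, c = 25, e = 30)
  # all-female pairs: two subgroups keep each replicate fit small
  cfg <- twin_sim_config(vc, n_mz = 100, n_dz = 80, mz_female = 1,
                         dz_female = 1, training_mean = NULL)
  pvals <- vapply(1:500, function(r) {
    d <- simulate_twin_data(cfg, seed = 5000 + r)
    prep <- twinace:::fiml_prepare(d, "trait1", character(),
                                   use_subgroups = TRUE)
    groups <- sort(unique(vapply(prep$groups, function(g) g$group,
                                 character(1))))
    spec0 <- saturated_spec("trait1", groups)
    spec1 <- spec0
    for (g in groups) {
      spec1 <- equate_params(spec1, sprintf(c("m1.%s", "m2.%s"), g))
    }
    f0 <- twinace:::fit_twin_model_prepared(prep, spec0, n_restarts = 0,
                                            grad_check = FALSE)
    f1 <- twinace:::fit_twin_model_prepared(prep, spec1, n_restarts = 0,
                                            grad_check = FALSE)
    likelihood_ratio_test(f0, f1)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
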