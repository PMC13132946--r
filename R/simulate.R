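#' Configuration for the twin-data simulator
#'
#' Describes the generating model and sample composition for
#' [simulate_twin_data()]: the generating A/C/E matrices (twin-pair
#' covariance structure follows [expected_pair_covariance()]), the linear
#' mean model, group sizes, pair sex composition, the age distribution
#' (normal, truncated), optional Likert discretization of selected traits,
#' and per-phenotype missingness.
#'
#' @param vc A [variance_components()] object (ACE) giving the generating
#'   components; the total `A + C + E` must be positive-definite.
#' @param mm A [mean_model()] (defaults to all-zero coefficients).
#' @param n_mz,n_dz Numbers of complete MZ and DZ pairs.
#' @param n_singletons Number of lone twins (drawn from the marginal
#'   single-twin distribution; they help estimate variances and covariances
#'   under FIML).
#' @param mz_female,dz_female,dz_os Proportions of MZ female-female pairs, DZ
#'   female-female pairs, and DZ opposite-sex pairs (remainders are
#'   male-male).
#' @param age_mean,age_sd,age_range Age distribution: normal truncated to the
#'   range; age is shared within a pair.
#' @param training_mean Mean of the exponential years-of-training draw
#'   (winsorized at `training_cap`); `NULL` omits the column.
#' @param training_cap Winsorization cap for training years.
#' @param likert Named list mapping trait names to strictly increasing
#'   6-threshold vectors; those traits are discretized to 1..7 after
#'   continuous generation (off by default).
#' @param missing_rate Per-phenotype probability that an observed value is
#'   set missing (scalar or named vector).
#' @return A list of class `twin_sim_config`.
#' @export
twin_sim_config <- function(vc, mm = NULL, n_mz = 100, n_dz = 100,
                            n_singletons = 0, mz_female = 0.5,
                            dz_female = 0.5, dz_os = 0,
                            age_mean = 45.70, age_sd = 16.27,
                            age_range = c(15, 90), training_mean = 4.55,
                            training_cap = 20, likert = NULL,
                            missing_rate = 0) {
  assert_that(inherits(vc, "variance_components"), "vc must be variance_components")
  assert_that(is.null(vc$D), "the simulator generates from ACE structures")
  assert_that(n_mz >= 0 && n_dz >= 0 && n_singletons >= 0,
              "group counts must be nonnegative")
  V <- vc$A + vc$C + vc$E
  assert_that(!is.null(chol_or_null(V)),
              "generating total covariance A + C + E must be positive-definite")
  mm <- mm %||% mean_model(rep(0, vc$p))
  assert_that(mm$p == vc$p, "mean model dimension must match vc")
  for (tr in names(likert)) {
    th <- likert[[tr]]
    assert_that(tr %in% vc$traits, paste0("likert trait not in vc: ", tr))
    assert_that(length(th) == 6 && all(diff(th) > 0),
                "likert thresholds must be 6 strictly increasing values")
  }
  if (is.null(names(missing_rate))) {
    missing_rate <- stats::setNames(rep_len(missing_rate, vc$p), vc$traits)
  }
  structure(list(vc = vc, mm = mm, n_mz = n_mz, n_dz = n_dz,
                 n_singletons = n_singletons, mz_female = mz_female,
                 dz_female = dz_female, dz_os = dz_os, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 training_mean = training_mean, training_cap = training_cap,
                 likert = likert, missing_rate = missing_rate),
            class = "twin_sim_config")
}

#' Study-composition simulation preset
#'
#' A ready-made [twin_sim_config()] emulating a realistic singing-ability
#' twin study: 335 MZ complete pairs (252 female-female, 83 male-male), 118
#' DZ pairs (85 female-female, 26 male-male, 7 opposite-sex), 90 singletons,
#' age normal(45.70, 16.27) truncated to 15-90, training winsorized at 20
#' years. The generating trivariate ACE structure has standardized shares
#' SPI 35.23/41.88/22.88, SSE-Factor 41.71/28.92/29.37 and SSE-Single
#' 53.42/17.38/29.20 (percent A/C/E, unit total variances), genetic
#' correlations 0.63/0.64/0.82 and unshared-environment correlations
#' 0.29/0.22/0.36 for the (SPI, SSE-Factor), (SPI, SSE-Single) and
#' (SSE-Factor, SSE-Single) pairs; shared-environment correlations are
#' capped at 0.95 so the generating model stays proper (the estimated values
#' sit at or above 1, which a generating covariance cannot use).
#'
#' @param likert Discretize SSE-Single to its 7-point scale (default `FALSE`:
#'   the modelling treats it as continuous; enable to study coarsening bias).
#' @return A `twin_sim_config`.
#' @export
twin_sim_preset <- function(likert = FALSE) {
  traits <- c("SPI", "SSE_Factor", "SSE_Single")
  rg <- matrix(c(1, 0.63, 0.64,
                 0.63, 1, 0.82,
                 0.64, 0.82, 1), 3, 3)
  rc <- matrix(c(1, 0.95, 0.95,
                 0.95, 1, 0.95,
                 0.95, 0.95, 1), 3, 3)
  re <- matrix(c(1, 0.29, 0.22,
                 0.29, 1, 0.36,
                 0.22, 0.36, 1), 3, 3)
  vc <- vc_from_shares(a = c(35.23, 41.71, 53.42),
                       c = c(41.88, 28.92, 17.38),
                       e = c(22.88, 29.37, 29.20),
                       rg = rg, rc = rc, re = re, traits = traits)
  lk <- NULL
  if (likert) {
    lk <- list(SSE_Single = stats::qnorm(seq_len(6) / 7))
  }
  twin_sim_config(vc, mm = mean_model(rep(0, 3)),
                  n_mz = 335, n_dz = 118, n_singletons = 90,
                  mz_female = 252 / 335, dz_female = 85 / 118,
                  dz_os = 7 / 118, likert = lk)
}

#' Simulate a twin dataset
#'
#' Draws twin pairs with the covariance structure implied by the generating
#' components: each pair's stacked 2p phenotype vector is multivariate normal
#' with cross-twin covariance A + C (MZ) or 0.5 A + C (DZ), plus the linear
#' mean model evaluated at each twin's covariates. Age is shared within a
#' pair; singletons are lone twins drawn from the single-twin marginal.
#' Likert traits are discretized by their thresholds after continuous
#' generation. Deterministic given `seed` (which is passed to
#' [set.seed()] when non-`NULL`).
#'
#' @param config A [twin_sim_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `twin_df` tibble, one row per individual.
#' @export
simulate_twin_data <- function(config, seed = NULL) {
  assert_that(inherits(config, "twin_sim_config"), "config must be a twin_sim_config")
  if (!is.null(seed)) set.seed(seed)
  vc <- config$vc
  p <- vc$p
  V <- vc$A + vc$C + vc$E

  pair_sexes <- function(n, f_prop, os_prop = 0) {
    u <- stats::runif(n)
    type <- ifelse(u < os_prop, "OS",
                   ifelse(u < os_prop + (1 - os_prop) * f_prop, "F", "M"))
    t(vapply(type, function(tp) {
      switch(tp,
             F = c("female", "female"),
             M = c("male", "male"),
             OS = sample(c("female", "male")))
    }, character(2)))
  }

  draw_group <- function(n, zyg) {
    if (n == 0) return(NULL)
    sig <- expected_pair_covariance(vc, zyg)
    Y <- MASS::mvrnorm(n, mu = rep(0, 2 * p), Sigma = sig)
    if (n == 1) Y <- matrix(Y, 1)
    sexes <- pair_sexes(n, if (zyg == "MZ") config$mz_female else config$dz_female,
                        if (zyg == "MZ") 0 else config$dz_os)
    age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                       config$age_range[1], config$age_range[2])
    list(Y = Y, sexes = sexes, age = age, zyg = zyg)
  }

  mz <- draw_group(config$n_mz, "MZ")
  dz <- draw_group(config$n_dz, "DZ")

  fam0 <- 0L
  assemble_pairs <- function(grp) {
    if (is.null(grp)) return(NULL)
    n <- nrow(grp$Y)
    fid <- fam0 + seq_len(n)
    fam0 <<- fam0 + n
    mk <- function(ord) {
      sex <- grp$sexes[, ord]
      tibble::tibble(family_id = sprintf("fam%05d", fid), twin_order = ord,
                     zygosity = grp$zyg, sex = sex, age = grp$age,
                     sex01 = as.numeric(sex == "male"))
    }
    d <- dplyr::bind_rows(mk(1L), mk(2L))
    Yb <- rbind(grp$Y[, seq_len(p), drop = FALSE],
                grp$Y[, p + seq_len(p), drop = FALSE])
    list(d = d, Y = Yb)
  }
  parts <- purrr::compact(list(assemble_pairs(mz), assemble_pairs(dz)))

  if (config$n_singletons > 0) {
    n <- config$n_singletons
    fid <- fam0 + seq_len(n)
    fam0 <- fam0 + n
    Ys <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = V)
    if (n == 1) Ys <- matrix(Ys, 1)
    zyg <- sample(c("MZ", "DZ"), n, replace = TRUE,
                  prob = c(config$n_mz + 1, config$n_dz + 1))
    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(max(config$mz_female, 1e-6),
                           max(1 - config$mz_female, 1e-6)))
    age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                       config$age_range[1], config$age_range[2])
    d <- tibble::tibble(family_id = sprintf("fam%05d", fid), twin_order = 1L,
                        zygosity = zyg, sex = sex, age = age,
                        sex01 = as.numeric(sex == "male"))
    parts <- c(parts, list(list(d = d, Y = Ys)))
  }

  d <- dplyr::bind_rows(purrr::map(parts, "d"))
  Y <- do.call(rbind, purrr::map(parts, "Y"))

  if (!is.null(config$training_mean)) {
    d$music_training <- winsorize_training(
      stats::rexp(nrow(d), rate = 1 / config$training_mean),
      cap = config$training_cap)
  }

  # mean model: mu_i + beta_age_i * age + beta_sex_i * sex01 (+ training)
  mm <- config$mm
  for (t in seq_len(p)) {
    mu <- mm$intercepts[t] + mm$beta_age[t] * d$age + mm$beta_sex[t] * d$sex01
    if (!is.null(mm$beta_training)) {
      mu <- mu + mm$beta_training[t] * d$music_training
    }
    Y[, t] <- Y[, t] + mu
  }

  for (tr in names(config$likert)) {
    t <- match(tr, vc$traits)
    Y[, t] <- discretize_likert(Y[, t], config$likert[[tr]])
  }
  for (t in seq_len(p)) {
    rate <- config$missing_rate[[vc$traits[t]]]
    if (!is.null(rate) && rate > 0) {
      Y[stats::runif(nrow(Y)) < rate, t] <- NA_real_
    }
    d[[vc$traits[t]]] <- Y[, t]
  }
  d$sex01 <- NULL
  d <- dplyr::arrange(d, .data$family_id, .data$twin_order)
  validate_twin_data(d, phenotypes = vc$traits,
                     age_range = config$age_range + c(-1, 1))
}

#' Discretize continuous values to a 1-7 Likert scale
#'
#' Values below the first threshold map to 1, values between thresholds k and
#' k + 1 map to k + 1, values above the sixth threshold map to 7; the mapping
#' is monotone in the input.
#'
#' @param values Numeric vector.
#' @param thresholds Six strictly increasing cut points.
#' @return Integer vector in 1..7 (`NA` preserved).
#' @export
discretize_likert <- function(values, thresholds) {
  assert_that(length(thresholds) == 6 && all(diff(thresholds) > 0),
              "thresholds must be 6 strictly increasing values")
  findInterval(values, thresholds) + 1L
}
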