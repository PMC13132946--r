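#' Maximum-likelihood intraclass twin correlation
#'
#' Fits, to the complete pairs of one zygosity group, a bivariate-normal
#' model with means and variances equated across twin order (means adjusted
#' for covariates, identical coefficients for both twins) and returns the ML
#' within-pair correlation, which is therefore pooled symmetrically over twin
#' order. A double-entry Pearson estimate is available as a diagnostic
#' cross-check via `method = "double_entry"`.
#'
#' @param data A `twin_df` tibble.
#' @param trait Phenotype name.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param covariates Covariates adjusting the means (default age and sex).
#' @param conf Compute a profile-likelihood CI (Fisher-z Wald CI for the
#'   double-entry method)?
#' @param level Confidence level.
#' @param method `"ml"` (default) or `"double_entry"`.
#' @return One-row tibble: `trait`, `zygosity`, `icc`, `lower`, `upper`,
#'   `n_pairs`, `method`.
#' @export
intraclass_correlation <- function(data, trait, zygosity,
                                   covariates = c("age", "sex"),
                                   conf = TRUE, level = 0.95,
                                   method = c("ml", "double_entry")) {
  method <- match.arg(method)
  dd <- prepare_pair_matrix(data, c(trait, trait), zygosity, covariates)
  Y <- dd$Y[, c(1, 3), drop = FALSE]  # twin1 trait, twin2 trait
  n <- nrow(Y)
  assert_that(n >= 3, "need at least 3 complete pairs")
  if (method == "double_entry") {
    res <- double_entry_residuals(Y, dd$X1, dd$X2)
    r <- stats::cor(res[, 1], res[, 2])
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    crit <- stats::qnorm(1 - (1 - level) / 2)
    return(tibble::tibble(trait = trait, zygosity = zygosity, icc = r,
                          lower = if (conf) tanh(z - crit * se) else NA_real_,
                          upper = if (conf) tanh(z + crit * se) else NA_real_,
                          n_pairs = n, method = method))
  }
  q <- ncol(dd$X1)
  obj <- function(par) {
    beta <- par[seq_len(q)]; v <- par[q + 1]; r <- par[q + 2]
    if (v <= 0 || abs(r) >= 1) return(PENALTY_BASE)
    mu1 <- as.vector(dd$X1 %*% beta)
    mu2 <- as.vector(dd$X2 %*% beta)
    r1 <- Y[, 1] - mu1; r2 <- Y[, 2] - mu2
    quad <- (r1^2 + r2^2 - 2 * r * r1 * r2) / (v * (1 - r^2))
    n * 2 * log(2 * pi) + n * log(v^2 * (1 - r^2)) + sum(quad)
  }
  b0 <- stats::coef(stats::lm.fit(rbind(dd$X1, dd$X2), c(Y[, 1], Y[, 2])))
  b0[is.na(b0)] <- 0
  v0 <- stats::var(c(Y[, 1], Y[, 2]))
  r0 <- stats::cor(Y[, 1], Y[, 2])
  start <- c(b0, v0, max(min(r0, 0.95), -0.95))
  lower <- c(rep(-Inf, q), 1e-10, -0.9999)
  upper <- c(rep(Inf, q), Inf, 0.9999)
  res <- stats::nlminb(start, obj, lower = lower, upper = upper,
                       control = list(iter.max = 500))
  r_hat <- unname(res$par[q + 2])
  lo <- hi <- NA_real_
  if (conf) {
    pro <- function(rv) {
      o2 <- function(par) obj(c(par, rv))
      stats::nlminb(res$par[seq_len(q + 1)], o2,
                    lower = lower[seq_len(q + 1)],
                    control = list(iter.max = 300))$objective
    }
    lo_r <- profile_root(pro, r_hat, res$objective, level, 0.1, "lower",
                         floor_at = -0.9999)
    hi_r <- profile_root(function(v) pro(min(v, 0.9999)), r_hat,
                         res$objective, level, 0.1, "upper")
    lo <- lo_r$bound
    hi <- min(hi_r$bound, 1)
  }
  tibble::tibble(trait = trait, zygosity = zygosity, icc = r_hat,
                 lower = lo, upper = hi, n_pairs = n, method = method)
}

#' Maximum-likelihood cross-twin cross-trait correlation
#'
#' Fits a 4-variate normal model to (twin 1 trait i, twin 1 trait j, twin 2
#' trait i, twin 2 trait j) with means, variances and covariances equated
#' across twin order, so both twin-order assignments contribute
#' symmetrically. The CTCT correlation is the equated cross-twin cross-trait
#' covariance standardized by the trait variances. When `trait_j` equals
#' `trait_i` this reduces to the intraclass correlation.
#'
#' @inheritParams intraclass_correlation
#' @param trait_i,trait_j Phenotype names.
#' @return One-row tibble: `trait_i`, `trait_j`, `zygosity`, `ctct`, `lower`,
#'   `upper`, `n_pairs`.
#' @export
ctct_correlation <- function(data, trait_i, trait_j, zygosity,
                             covariates = c("age", "sex"), conf = TRUE,
                             level = 0.95) {
  if (trait_i == trait_j) {
    icc <- intraclass_correlation(data, trait_i, zygosity, covariates, conf,
                                  level)
    return(tibble::tibble(trait_i = trait_i, trait_j = trait_j,
                          zygosity = zygosity, ctct = icc$icc,
                          lower = icc$lower, upper = icc$upper,
                          n_pairs = icc$n_pairs))
  }
  dd <- prepare_pair_matrix(data, c(trait_i, trait_j), zygosity, covariates)
  Y <- dd$Y  # columns: i1, j1, i2, j2
  n <- nrow(Y)
  assert_that(n >= 3, "need at least 3 complete pairs")
  q <- ncol(dd$X1)
  # parameters: beta_i (q), beta_j (q), v_i, v_j, w (within-person cross),
  # c_i, c_j (cross-twin same trait), x (cross-twin cross-trait)
  obj <- function(par) {
    bi <- par[seq_len(q)]; bj <- par[q + seq_len(q)]
    v_i <- par[2 * q + 1]; v_j <- par[2 * q + 2]; w <- par[2 * q + 3]
    c_i <- par[2 * q + 4]; c_j <- par[2 * q + 5]; x <- par[2 * q + 6]
    if (v_i <= 0 || v_j <= 0) return(PENALTY_BASE)
    S <- matrix(c(v_i, w, c_i, x,
                  w, v_j, x, c_j,
                  c_i, x, v_i, w,
                  x, c_j, w, v_j), 4, 4)
    ch <- chol_or_null(S)
    if (is.null(ch)) return(penalized_objective(S))
    MU <- cbind(dd$X1 %*% bi, dd$X1 %*% bj, dd$X2 %*% bi, dd$X2 %*% bj)
    R <- Y - MU
    z <- backsolve(ch, t(R), transpose = TRUE)
    n * (4 * log(2 * pi) + 2 * sum(log(diag(ch)))) + sum(z * z)
  }
  Xs <- rbind(dd$X1, dd$X2)
  bi0 <- stats::coef(stats::lm.fit(Xs, c(Y[, 1], Y[, 3])))
  bj0 <- stats::coef(stats::lm.fit(Xs, c(Y[, 2], Y[, 4])))
  bi0[is.na(bi0)] <- 0; bj0[is.na(bj0)] <- 0
  v_i0 <- stats::var(c(Y[, 1], Y[, 3])); v_j0 <- stats::var(c(Y[, 2], Y[, 4]))
  w0 <- (stats::cov(Y[, 1], Y[, 2]) + stats::cov(Y[, 3], Y[, 4])) / 2
  c_i0 <- stats::cov(Y[, 1], Y[, 3]); c_j0 <- stats::cov(Y[, 2], Y[, 4])
  x0 <- (stats::cov(Y[, 1], Y[, 4]) + stats::cov(Y[, 2], Y[, 3])) / 2
  start <- c(bi0, bj0, v_i0, v_j0, w0, c_i0, c_j0, x0)
  lower <- c(rep(-Inf, 2 * q), 1e-10, 1e-10, rep(-Inf, 4))
  res <- stats::nlminb(start, obj, lower = lower,
                       control = list(iter.max = 1000))
  xk <- 2 * q + 6
  x_hat <- unname(res$par[xk])
  ctct <- x_hat / unname(sqrt(res$par[2 * q + 1] * res$par[2 * q + 2]))
  lo <- hi <- NA_real_
  if (conf) {
    pro <- function(xv) {
      o2 <- function(par) obj(c(par[seq_len(xk - 1)], xv))
      stats::nlminb(res$par[seq_len(xk - 1)], o2,
                    lower = lower[seq_len(xk - 1)],
                    control = list(iter.max = 500))$objective
    }
    sd_scale <- sqrt(res$par[2 * q + 1] * res$par[2 * q + 2])
    lo_r <- profile_root(pro, x_hat, res$objective, level, 0.1 * sd_scale,
                         "lower")
    hi_r <- profile_root(pro, x_hat, res$objective, level, 0.1 * sd_scale,
                         "upper")
    lo <- lo_r$bound / sd_scale
    hi <- hi_r$bound / sd_scale
  }
  tibble::tibble(trait_i = trait_i, trait_j = trait_j, zygosity = zygosity,
                 ctct = ctct, lower = lo, upper = hi, n_pairs = n)
}

# complete pairs of one zygosity; Y columns: trait_a twin1, trait_b twin1,
# trait_a twin2, trait_b twin2 (duplicated trait allowed); X1/X2 designs
prepare_pair_matrix <- function(data, traits2, zygosity, covariates) {
  traits <- unique(traits2)
  d <- data[data$zygosity == zygosity, , drop = FALSE]
  attr(d, "phenotypes") <- attr(data, "phenotypes")
  class(d) <- class(data)
  d <- subset_complete_pairs(d, traits)
  d <- encode_covariates(d)
  covs <- ifelse(covariates == "sex", "sex01", covariates)
  d <- dplyr::arrange(d, .data$family_id, .data$twin_order)
  d1 <- d[d$twin_order == 1, , drop = FALSE]
  d2 <- d[d$twin_order == 2, , drop = FALSE]
  Y <- cbind(as.matrix(d1[, traits2, drop = FALSE]),
             as.matrix(d2[, traits2, drop = FALSE]))
  mkX <- function(dd) {
    cbind(rep(1, nrow(dd)),
          if (length(covs)) as.matrix(dd[, covs, drop = FALSE]))
  }
  list(Y = Y, X1 = mkX(d1), X2 = mkX(d2))
}

double_entry_residuals <- function(Y, X1, X2) {
  ys <- c(Y[, 1], Y[, 2], Y[, 2], Y[, 1])
  Xs <- rbind(X1, X2, X2, X1)
  res <- stats::lm.fit(Xs, ys)$residuals
  n <- nrow(Y)
  cbind(res[seq_len(2 * n)], res[2 * n + seq_len(2 * n)])
}

#' Intraclass correlations for every trait and zygosity
#'
#' @param data A `twin_df` tibble.
#' @param traits Phenotype names (default all).
#' @param covariates Covariates adjusting means.
#' @param conf Compute profile CIs?
#' @return Tibble with one row per trait x zygosity, plus the indicated model
#'   family per trait from [select_model_family()].
#' @export
twin_correlations <- function(data, traits = NULL,
                              covariates = c("age", "sex"), conf = TRUE) {
  traits <- traits %||% attr(data, "phenotypes")
  tab <- purrr::map_dfr(traits, function(tr) {
    dplyr::bind_rows(
      intraclass_correlation(data, tr, "MZ", covariates, conf),
      intraclass_correlation(data, tr, "DZ", covariates, conf))
  })
  fam <- purrr::map_chr(traits, function(tr) {
    select_model_family(tab$icc[tab$trait == tr & tab$zygosity == "MZ"],
                        tab$icc[tab$trait == tr & tab$zygosity == "DZ"])
  })
  dplyr::left_join(tab, tibble::tibble(trait = traits, family = fam),
                   by = "trait")
}
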