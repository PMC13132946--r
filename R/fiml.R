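# ---------------------------------------------------------------------------
# FIML data preparation: families -> pattern-grouped matrices
# ---------------------------------------------------------------------------

# Builds, for each (group x missingness pattern), the observation matrix and
# per-twin covariate design matrices. Group is zygosity for structured models
# and the zygosity-by-pair-sex subgroup for saturated models.
fiml_prepare <- function(data, traits, covariates = c("age", "sex"),
                         use_subgroups = FALSE) {
  assert_that(all(traits %in% names(data)),
              paste0("trait columns missing: ",
                     paste(setdiff(traits, names(data)), collapse = ", ")))
  assert_that(nrow(data) > 0, "empty dataset")
  data <- encode_covariates(tibble::as_tibble(data))
  covs <- ifelse(covariates == "sex", "sex01", covariates)
  assert_that(all(covs %in% names(data)),
              paste0("covariate columns missing: ",
                     paste(setdiff(covs, names(data)), collapse = ", ")))
  p <- length(traits)
  q <- 1L + length(covs)

  key <- paste(data$family_id, data$twin_order)
  assert_that(!anyDuplicated(key), "duplicate (family_id, twin_order)")
  fams <- unique(data$family_id)
  i1 <- match(paste(fams, 1), key)
  i2 <- match(paste(fams, 2), key)

  getY <- function(idx) {
    m <- matrix(NA_real_, length(fams), p)
    ok <- !is.na(idx)
    m[ok, ] <- as.matrix(data[idx[ok], traits, drop = FALSE])
    m
  }
  getX <- function(idx) {
    m <- matrix(NA_real_, length(fams), q)
    ok <- !is.na(idx)
    m[ok, 1] <- 1
    if (q > 1) m[ok, -1] <- as.matrix(data[idx[ok], covs, drop = FALSE])
    m
  }
  Y <- cbind(getY(i1), getY(i2))
  X1 <- getX(i1)
  X2 <- getX(i2)

  # covariates must be observed for every twin with any modelled phenotype
  obs1 <- rowSums(!is.na(Y[, seq_len(p), drop = FALSE])) > 0
  obs2 <- rowSums(!is.na(Y[, p + seq_len(p), drop = FALSE])) > 0
  assert_that(!any(obs1 & rowSums(is.na(X1)) > 0) &&
                !any(obs2 & rowSums(is.na(X2)) > 0),
              "missing covariate on a modelled individual")

  zrow <- ifelse(is.na(i1), i2, i1)
  zyg <- data$zygosity[zrow]
  gvar <- zyg
  if (use_subgroups) {
    gvar <- vapply(seq_along(fams), function(f) {
      rows <- c(i1[f], i2[f])
      pair_subgroup(zyg[f], data$sex[rows[!is.na(rows)]])
    }, character(1))
  }

  mask <- !is.na(Y)
  n_dropped <- sum(rowSums(mask) == 0)
  keep <- rowSums(mask) > 0
  Y <- Y[keep, , drop = FALSE]; X1 <- X1[keep, , drop = FALSE]
  X2 <- X2[keep, , drop = FALSE]; mask <- mask[keep, , drop = FALSE]
  gvar <- gvar[keep]; zyg <- zyg[keep]

  pat <- as.vector(mask %*% (2^(seq_len(2 * p) - 1)))
  gkey <- paste(gvar, pat)
  groups <- lapply(split(seq_along(gkey), gkey), function(idx) {
    list(zygosity = zyg[idx[1]], group = gvar[idx[1]],
         mask = mask[idx[1], ], n = length(idx),
         Y = Y[idx, mask[idx[1], ], drop = FALSE],
         X1 = X1[idx, , drop = FALSE], X2 = X2[idx, , drop = FALSE])
  })
  list(groups = groups, p = p, q = q, traits = traits, covariates = covs,
       n_pairs = sum(keep), n_values = sum(mask), n_dropped = n_dropped)
}

# core FIML deviance on prepared data
m2ll_prepared <- function(prep, spec, theta) {
  p <- prep$p
  vals <- realize_params(spec, theta)
  if (spec$kind == "structured") {
    vc <- vc_from_values(spec, vals)
    B <- meanmat_from_values(spec, vals)
    sig <- list(MZ = expected_pair_covariance(vc, "MZ"),
                DZ = expected_pair_covariance(vc, "DZ"))
    total <- 0
    for (g in prep$groups) {
      S <- sig[[g$zygosity]][g$mask, g$mask, drop = FALSE]
      ch <- chol_or_null(S)
      if (is.null(ch)) return(penalized_objective(S))
      k <- sum(g$mask)
      MU <- matrix(0, g$n, 2 * p)
      m1 <- g$mask[seq_len(p)]
      m2 <- g$mask[p + seq_len(p)]
      if (any(m1)) MU[, seq_len(p)] <- g$X1 %*% B
      if (any(m2)) MU[, p + seq_len(p)] <- g$X2 %*% B
      R <- g$Y - MU[, g$mask, drop = FALSE]
      z <- backsolve(ch, t(R), transpose = TRUE)
      total <- total + g$n * (k * log(2 * pi) + 2 * sum(log(diag(ch)))) +
        sum(z * z)
    }
    total
  } else {
    pp <- spec$params
    total <- 0
    for (g in prep$groups) {
      sel_g <- pp$group == g$group
      getv <- function(b) vals[sel_g & pp$block == b]
      mu <- c(getv("m1"), getv("m2"))
      v1 <- getv("v1"); v2 <- getv("v2"); cc <- getv("c")
      S <- matrix(c(v1, cc, cc, v2), 2, 2)[g$mask, g$mask, drop = FALSE]
      ch <- chol_or_null(S)
      if (is.null(ch)) return(penalized_objective(S))
      k <- sum(g$mask)
      R <- g$Y - matrix(mu[g$mask], g$n, k, byrow = TRUE)
      z <- backsolve(ch, t(R), transpose = TRUE)
      total <- total + g$n * (k * log(2 * pi) + 2 * sum(log(diag(ch)))) +
        sum(z * z)
    }
    total
  }
}

#' FIML deviance (-2 log-likelihood) of a model at given parameter values
#'
#' Each family contributes the multivariate-normal log-density of its
#' observed values only: rows/columns of the expected 2p mean and 2p x 2p
#' covariance corresponding to missing values are deleted, which is how
#' singletons and partially observed pairs enter the likelihood (full
#' information, no imputation). Parameter points where an implied observed
#' covariance is not positive-definite return a large penalized value.
#'
#' @param data A `twin_df` tibble.
#' @param spec A `twin_model_spec`.
#' @param params Named numeric vector over the spec's free parameter classes
#'   (names as in `spec$params$class`).
#' @return The deviance, `sum(k log 2 pi + log|S| + r' S^-1 r)` over families.
#' @export
minus_two_loglik <- function(data, spec, params) {
  info <- free_theta_info(spec)
  assert_that(length(params) == length(info$classes),
              sprintf("expected %d free parameters, got %d",
                      length(info$classes), length(params)))
  if (is.null(names(params))) names(params) <- info$classes
  prep <- fiml_prepare(data, spec$traits, spec_covnames(spec),
                       use_subgroups = spec$kind == "saturated")
  m2ll_prepared(prep, spec, params)
}

spec_covnames <- function(spec) {
  sub("^sex01$", "sex", spec$covariates)
}

# ---------------------------------------------------------------------------
# Starting values from sample moments
# ---------------------------------------------------------------------------

start_values <- function(prep, spec, data = NULL) {
  pp <- spec$params
  starts <- numeric(nrow(pp))
  if (spec$kind == "structured") {
    p <- prep$p
    # pooled individual-level matrix across twin slots
    Yall <- NULL; Xall <- NULL
    for (g in prep$groups) {
      m1 <- g$mask[seq_len(p)]; m2 <- g$mask[p + seq_len(p)]
      if (any(m1)) {
        Yp <- matrix(NA_real_, g$n, p); Yp[, m1] <- g$Y[, seq_len(sum(m1)), drop = FALSE]
        Yall <- rbind(Yall, Yp); Xall <- rbind(Xall, g$X1)
      }
      if (any(m2)) {
        Yp <- matrix(NA_real_, g$n, p)
        Yp[, m2] <- g$Y[, sum(m1) + seq_len(sum(m2)), drop = FALSE]
        Yall <- rbind(Yall, Yp); Xall <- rbind(Xall, g$X2)
      }
    }
    S <- stats::cov(Yall, use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
    diag(S)[diag(S) <= 0] <- 1
    # pairwise-complete covariances need not be PD; ridge until they are
    while (is.null(chol_or_null(S))) {
      S <- 0.9 * S + 0.1 * diag(diag(S), nrow(S))
    }
    B0 <- matrix(0, prep$q, p)
    for (t in seq_len(p)) {
      ok <- !is.na(Yall[, t])
      if (sum(ok) > prep$q) {
        cf <- tryCatch(stats::coef(stats::lm.fit(Xall[ok, , drop = FALSE],
                                                 Yall[ok, t])),
                       error = function(e) NULL)
        if (!is.null(cf)) {
          cf[is.na(cf)] <- 0
          B0[, t] <- cf
        }
      } else {
        B0[1, t] <- mean(Yall[, t], na.rm = TRUE)
      }
    }
    ncomp <- length(component_blocks(spec))
    for (k in seq_len(nrow(pp))) {
      if (pp$block[k] == "mean") {
        starts[k] <- B0[match(pp$term[k], c("(Intercept)", spec$covariates)),
                        pp$i[k]]
      } else {
        starts[k] <- S[pp$i[k], pp$j[k]] / ncomp
      }
    }
  } else {
    w <- numeric(nrow(pp))
    for (g in prep$groups) {
      sel <- pp$group == g$group
      if (!any(sel)) next
      m1 <- g$mask[1]; m2 <- g$mask[2]
      y1 <- if (m1) g$Y[, 1] else NA
      y2 <- if (m2) g$Y[, 1 + m1] else NA
      add <- function(block, v) {
        k <- which(sel & pp$block == block)
        if (!is.na(v)) {
          starts[k] <<- starts[k] + v * g$n
          w[k] <<- w[k] + g$n
        }
      }
      add("m1", if (m1) mean(y1) else NA)
      add("m2", if (m2) mean(y2) else NA)
      add("v1", if (m1 && g$n > 1) stats::var(y1) else NA)
      add("v2", if (m2 && g$n > 1) stats::var(y2) else NA)
      add("c", if (m1 && m2 && g$n > 1) stats::cov(y1, y2) else NA)
    }
    pos <- w > 0
    starts[pos] <- starts[pos] / w[pos]
    vsel <- pp$block %in% c("v1", "v2")
    vfloor <- 1e-3 * max(1, stats::median(starts[vsel & starts > 0], na.rm = TRUE))
    starts[vsel & starts < vfloor] <- vfloor
    # keep each group's starting covariance inside the feasible cone
    for (g in unique(pp$group)) {
      sel <- pp$group == g
      v1 <- starts[sel & pp$block == "v1"]
      v2 <- starts[sel & pp$block == "v2"]
      csel <- sel & pp$block == "c"
      cap <- 0.9 * sqrt(v1 * v2)
      starts[csel] <- sign(starts[csel]) * pmin(abs(starts[csel]), cap)
    }
  }
  info <- free_theta_info(spec)
  theta <- vapply(info$classes, function(cl) {
    mean(starts[pp$free & pp$class == cl])
  }, numeric(1))
  pmax(theta, info$lower + ifelse(is.finite(info$lower), 1e-8, 0))
}

# ---------------------------------------------------------------------------
# Fitting
# ---------------------------------------------------------------------------

#' Fit a twin model by full-information maximum likelihood
#'
#' Minimizes the FIML deviance of [minus_two_loglik()] over the spec's free
#' parameters with a quasi-Newton box-constrained optimizer
#' ([stats::nlminb()], objective tolerance 1e-8). Starting values come from
#' sample moments (saturated models) or an equal split of the sample
#' covariance across components (structured models); additional jittered
#' restarts (jitter scale 0.1 x parameter scale, seeded) guard against local
#' minima and the best converged solution is kept. Deterministic given
#' `seed`.
#'
#' @param data A `twin_df` tibble.
#' @param spec A `twin_model_spec`.
#' @param starts Optional explicit named start vector (default: automatic).
#' @param n_restarts Number of additional jittered starts (default 2, so up
#'   to 3 optimizations).
#' @param seed Integer seed for the restart jitter.
#' @param control Passed to [stats::nlminb()] (merged over defaults).
#' @param grad_check Verify the solution with a central-difference gradient
#'   norm (stored as `grad_norm`; costs 2 x EP extra evaluations).
#' @return An object of class `twin_fit` with elements `spec`, `estimates`
#'   (named free-parameter vector), `vc` and `mean_coef` (structured models),
#'   `minus2LL`, `EP`, `df` (observed non-missing values minus EP), `AIC`,
#'   `converged`, `grad_norm`, `n_pairs_used`, `n_values`.
#' @export
fit_twin_model <- function(data, spec, starts = NULL, n_restarts = 2,
                           seed = 1, control = list(), grad_check = TRUE) {
  prep <- fiml_prepare(data, spec$traits, spec_covnames(spec),
                       use_subgroups = spec$kind == "saturated")
  fit_twin_model_prepared(prep, spec, starts = starts,
                          n_restarts = n_restarts, seed = seed,
                          control = control, grad_check = grad_check)
}

fit_twin_model_prepared <- function(prep, spec, starts = NULL, n_restarts = 2,
                                    seed = 1, control = list(),
                                    grad_check = TRUE) {
  info <- free_theta_info(spec)
  npar <- length(info$classes)
  assert_that(npar > 0, "model has no free parameters")
  base_start <- if (is.null(starts)) start_values(prep, spec) else {
    assert_that(length(starts) == npar, "starts length must equal EP")
    s <- as.numeric(starts)
    names(s) <- info$classes
    s
  }
  names(base_start) <- info$classes
  obj <- function(th) m2ll_prepared(prep, spec, stats::setNames(th, info$classes))
  ctrl <- utils::modifyList(list(iter.max = 1000, eval.max = 4000,
                                 abs.tol = 1e-8, rel.tol = 1e-10), control)
  scale <- pmax(abs(base_start), 0.1)
  best <- NULL
  for (r in 0:n_restarts) {
    th0 <- base_start
    if (r > 0) {
      set.seed(seed + r)
      th0 <- base_start + stats::rnorm(npar) * 0.1 * scale
      th0 <- pmax(th0, info$lower + ifelse(is.finite(info$lower), 1e-8, 0))
    }
    if (!is.finite(obj(th0)) || obj(th0) >= PENALTY_BASE) next
    res <- tryCatch(stats::nlminb(th0, obj, lower = info$lower, control = ctrl),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective - 1e-9) best <- res
  }
  if (is.null(best) && is.null(starts)) {
    # explicit-start path failed or the moment start was infeasible: retry
    # from a deliberately conservative start (inflated variances, no
    # covariances) which is always inside the feasible region
    safe <- base_start
    pp <- spec$params
    for (cl in info$classes) {
      rows <- pp$free & pp$class == cl
      if (spec$kind == "structured") {
        if (any(pp$block[rows] != "mean" & pp$i[rows] != pp$j[rows])) safe[cl] <- 0
        if (any(pp$block[rows] == "E" & pp$i[rows] == pp$j[rows])) {
          safe[cl] <- abs(safe[cl]) + 1
        }
      } else {
        if (any(pp$block[rows] == "c")) safe[cl] <- 0
        if (any(pp$block[rows] %in% c("v1", "v2"))) safe[cl] <- abs(safe[cl]) + 1
      }
    }
    if (is.finite(obj(safe)) && obj(safe) < PENALTY_BASE) {
      res <- tryCatch(stats::nlminb(safe, obj, lower = info$lower,
                                    control = ctrl),
                      error = function(e) NULL)
      if (!is.null(res) && is.finite(res$objective)) best <- res
    }
  }
  if (is.null(best)) {
    best <- list(par = base_start, objective = obj(base_start),
                 convergence = 1L)
  }
  theta <- stats::setNames(best$par, info$classes)
  m2ll <- best$objective
  # central-difference gradient check at the solution
  gn <- NA_real_
  if (grad_check && m2ll < PENALTY_BASE) {
    h <- 1e-5 * (1 + abs(theta))
    gr <- vapply(seq_len(npar), function(k) {
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h[k]; tm[k] <- max(tm[k] - h[k], info$lower[k])
      (obj(tp) - obj(tm)) / (tp[k] - tm[k])
    }, numeric(1))
    gn <- sqrt(sum(gr^2))
  }
  converged <- best$convergence == 0 && m2ll < PENALTY_BASE
  ep <- npar
  vals <- realize_params(spec, theta)
  out <- list(spec = spec, estimates = theta,
              param_values = stats::setNames(vals, spec$params$label),
              minus2LL = m2ll, EP = ep, df = prep$n_values - ep,
              AIC = m2ll + 2 * ep, converged = converged, grad_norm = gn,
              n_pairs_used = prep$n_pairs, n_values = prep$n_values,
              n_dropped = prep$n_dropped, seed = seed)
  if (spec$kind == "structured") {
    out$vc <- vc_from_values(spec, vals)
    out$mean_coef <- meanmat_from_values(spec, vals)
  }
  structure(out, class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("<twin_fit> %s, EP = %d, -2LL = %.2f, df = %d, AIC = %.2f%s\n",
              x$spec$family, x$EP, x$minus2LL, x$df, x$AIC,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @method tidy twin_fit
#' @export
tidy.twin_fit <- function(x, ...) {
  pp <- x$spec$params
  tibble::tibble(term = pp$label, block = pp$block, i = pp$i, j = pp$j,
                 covariate = pp$term, group = pp$group,
                 estimate = unname(x$param_values), free = pp$free)
}

#' @method glance twin_fit
#' @export
glance.twin_fit <- function(x, ...) {
  tibble::tibble(family = x$spec$family, EP = x$EP, minus2LL = x$minus2LL,
                 df = x$df, AIC = x$AIC, converged = x$converged,
                 n_pairs = x$n_pairs_used, n_values = x$n_values)
}

#' Akaike information criterion from deviance
#'
#' @param minus2LL Model deviance (-2 log-likelihood).
#' @param EP Number of estimated parameters (>= 0).
#' @return `minus2LL + 2 * EP`.
#' @export
aic <- function(minus2LL, EP) {
  assert_that(all(EP >= 0), "EP must be nonnegative")
  minus2LL + 2 * EP
}

#' Likelihood-ratio test between nested fits
#'
#' @param full The less constrained `twin_fit`.
#' @param nested A `twin_fit` whose free-parameter set is a restriction of
#'   `full`'s, fitted to the same data.
#' @param tol Numerical tolerance on a slightly negative deviance difference.
#' @return One-row tibble with `delta_m2ll`, `delta_df`, `p`.
#' @export
likelihood_ratio_test <- function(full, nested, tol = 1e-4) {
  assert_that(nested$EP < full$EP,
              "nested model must have fewer estimated parameters")
  assert_that(nested$n_values == full$n_values,
              "models were fitted to different data")
  free_full <- unique(full$spec$params$class[full$spec$params$free])
  free_nested <- unique(nested$spec$params$class[nested$spec$params$free])
  delta <- nested$minus2LL - full$minus2LL
  if (delta < -tol * (1 + abs(full$minus2LL))) {
    stop_ta(sprintf(
      "models are not nested or did not converge: nested %s fits better (-2LL %.6f) than full %s (-2LL %.6f)",
      nested$spec$family, nested$minus2LL, full$spec$family, full$minus2LL))
  }
  delta <- max(delta, 0)
  ddf <- nested$df - full$df
  tibble::tibble(delta_m2ll = delta, delta_df = ddf,
                 p = lrt_pvalue(delta, ddf))
}

#' Chi-square upper-tail p-value for a likelihood-ratio statistic
#'
#' @param delta_m2ll Deviance difference (>= 0).
#' @param delta_df Degrees-of-freedom difference (> 0); `delta_m2ll = 0`
#'   returns p = 1.
#' @return Upper-tail probability of a chi-square with `delta_df` df.
#' @export
lrt_pvalue <- function(delta_m2ll, delta_df) {
  stats::pchisq(delta_m2ll, df = delta_df, lower.tail = FALSE)
}
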