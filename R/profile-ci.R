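# root-finding on the profiled deviance: pro(v) re-optimizes all other
# parameters with the target fixed at v; a bound is where pro crosses
# m2ll_min + qchisq(level, 1)
profile_root <- function(pro, est, m2ll_min, level, step,
                         direction = c("lower", "upper"),
                         floor_at = NULL, max_expand = 14) {
  direction <- match.arg(direction)
  crit <- stats::qchisq(level, df = 1)
  target <- m2ll_min + crit
  sgn <- if (direction == "lower") -1 else 1
  v_in <- est
  f_in <- -crit  # pro(est) equals the minimized deviance
  for (k in seq_len(max_expand)) {
    v_out <- est + sgn * step * 2^(k - 1)
    at_floor <- FALSE
    if (!is.null(floor_at) && direction == "lower" && v_out <= floor_at) {
      v_out <- floor_at
      at_floor <- TRUE
    }
    f_out <- pro(v_out) - target
    if (is.na(f_out)) f_out <- Inf
    if (f_out > 0) {
      r <- stats::uniroot(function(v) pro(v) - target, lower = min(v_in, v_out),
                          upper = max(v_in, v_out), f.lower = if (direction == "lower") f_out else f_in,
                          f.upper = if (direction == "lower") f_in else f_out,
                          tol = max(1e-4 * step, 1e-8))
      return(list(bound = r$root, boundary = FALSE, ok = TRUE))
    }
    if (at_floor) {
      return(list(bound = floor_at, boundary = TRUE, ok = TRUE))
    }
    v_in <- v_out
    f_in <- f_out
  }
  list(bound = sgn * Inf, boundary = FALSE, ok = FALSE)
}

#' Profile-likelihood confidence interval for a raw model parameter
#'
#' Bounds are the values at which the profiled deviance (re-optimizing all
#' other free parameters) exceeds the minimized deviance by the chi-square(1)
#' quantile (3.841 at 95%). Intervals widen monotonically with `level`. If a
#' bound cannot be bracketed the interval is flagged (`ok = FALSE`) rather
#' than silently guessed.
#'
#' @param data A `twin_df` tibble (the data the model was fitted to).
#' @param fit A converged `twin_fit`.
#' @param param Label of a free parameter (e.g. `"A11"`).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `param`, `estimate`, `lower`, `upper`, `level`,
#'   `boundary_lower`, `boundary_upper`, `ok`.
#' @export
profile_ci <- function(data, fit, param, level = 0.95) {
  assert_that(fit$converged, "profile_ci requires a converged fit")
  spec <- fit$spec
  idx <- match(param, spec$params$label)
  assert_that(!is.na(idx) && spec$params$free[idx],
              paste0("not a free parameter: ", param))
  cls <- spec$params$class[idx]
  est <- unname(fit$estimates[cls])
  prep <- fiml_prepare(data, spec$traits, spec_covnames(spec),
                       use_subgroups = spec$kind == "saturated")
  pro <- function(v) {
    spec2 <- fix_params(spec, param, v)
    st <- fit$estimates[setdiff(names(fit$estimates), cls)]
    f2 <- fit_twin_model_prepared(prep, spec2, starts = st, n_restarts = 0,
                                  seed = fit$seed, grad_check = FALSE)
    f2$minus2LL
  }
  step <- max(abs(est) * 0.25, 0.05)
  lo <- profile_root(pro, est, fit$minus2LL, level, step, "lower")
  hi <- profile_root(pro, est, fit$minus2LL, level, step, "upper")
  tibble::tibble(param = param, estimate = est, lower = lo$bound,
                 upper = hi$bound, level = level,
                 boundary_lower = lo$boundary, boundary_upper = hi$boundary,
                 ok = lo$ok && hi$ok)
}

#' Profile-likelihood confidence interval for a standardized share
#'
#' Profiles the standardized variance share of one component for one trait
#' (in percent of total variance) by constrained refitting: at each trial
#' share s the component's variance for that trait is derived from the other
#' components' variances so that it accounts for exactly s of the total, and
#' all remaining parameters are re-optimized. When the lower profile reaches
#' the natural boundary 0 the bound is reported as exactly 0 with
#' `boundary_lower = TRUE`.
#'
#' @param data A `twin_df` tibble.
#' @param fit A converged structured `twin_fit`.
#' @param component `"A"`, `"C"`, `"D"` or `"E"`.
#' @param trait Trait name or index.
#' @param level Confidence level.
#' @return One-row tibble as in [profile_ci()] with `param` like `"A%/SPI"`.
#' @export
profile_share_ci <- function(data, fit, component, trait, level = 0.95) {
  assert_that(fit$converged, "profile_share_ci requires a converged fit")
  spec <- fit$spec
  assert_that(spec$kind == "structured", "shares require a structured model")
  if (is.character(trait)) trait <- match(trait, spec$traits)
  sh <- standardize_components(fit$vc)
  est <- sh[[component]][trait]
  prep <- fiml_prepare(data, spec$traits, spec_covnames(spec),
                       use_subgroups = FALSE)
  diag_lab <- sprintf("%s%d%d", component, trait, trait)
  cls <- spec$params$class[match(diag_lab, spec$params$label)]
  pro <- function(s_pct) {
    spec2 <- constrain_share(spec, component, trait, s_pct / 100)
    st <- fit$estimates[setdiff(names(fit$estimates), cls)]
    f2 <- fit_twin_model_prepared(prep, spec2, starts = st, n_restarts = 0,
                                  seed = fit$seed, grad_check = FALSE)
    f2$minus2LL
  }
  step <- 8
  lo <- profile_root(pro, est, fit$minus2LL, level, step, "lower",
                     floor_at = if (est > 0) 0 else NULL)
  hi <- profile_root(pro, est, fit$minus2LL, level, step, "upper")
  tibble::tibble(param = sprintf("%s%%/%s", component, spec$traits[trait]),
                 estimate = est, lower = lo$bound, upper = hi$bound,
                 level = level, boundary_lower = lo$boundary,
                 boundary_upper = hi$boundary, ok = lo$ok && hi$ok)
}
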