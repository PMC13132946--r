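#' Assumption ladder for one phenotype
#'
#' Fits the fully saturated per-subgroup model (subgroups: zygosity by
#' pair-sex composition, e.g. MZF, MZM, DZF, DZM, DZOS) and then a fixed
#' cumulative sequence of equality constraints, each compared to the previous
#' model by likelihood-ratio test at `alpha`:
#' means equal across twin order, then across zygosity, then across sex;
#' variances in the same order; within-pair covariances across sexes and
#' finally across zygosities. Each rung nests the previous one, and each
#' rung's df difference equals the number of parameters merged by its
#' equality constraint.
#'
#' Opposite-sex DZ pairs form their own subgroup for the mean/variance rungs
#' and are excluded from the sex-equality covariance rung. The final
#' covariances-across-zygosities rung is computed but by default excluded
#' from pass/fail (`reporting_only`): equating MZ and DZ within-pair
#' covariances tests familial-aggregation equality, which genuinely differs
#' whenever genetic effects are present.
#'
#' Rungs that would reference an absent subgroup are adapted or skipped with
#' an explicit note. Singletons contribute through their marginal densities.
#'
#' @param data A `twin_df` tibble.
#' @param trait Phenotype name.
#' @param alpha Significance level per comparison (default 0.01).
#' @param zygosity_cov_pass_fail Include the covariances-across-zygosities
#'   rung in pass/fail (default `FALSE`, reporting-only)?
#' @param min_group_pairs Subgroups with fewer complete pairs than this are
#'   excluded with an explicit note (default 3; two pairs always give a
#'   degenerate sample correlation of +-1).
#' @param n_restarts,seed Passed to [fit_twin_model()].
#' @return An object of class `twin_ladder`: tibble of rungs with
#'   `step`, `constraint`, `EP`, `minus2LL`, `delta_m2ll`, `delta_df`, `p`,
#'   `pass`, `reporting_only`, `note`, with `alpha` and the baseline fit as
#'   attributes.
#' @export
run_assumption_ladder <- function(data, trait, alpha = 0.01,
                                  zygosity_cov_pass_fail = FALSE,
                                  min_group_pairs = 3, n_restarts = 0,
                                  seed = 1) {
  assert_that(trait %in% names(data), paste0("no such phenotype: ", trait))
  prep <- fiml_prepare(data, trait, covariates = character(),
                       use_subgroups = TRUE)
  # a subgroup's within-pair covariance is degenerate below ~3 complete
  # pairs (2 pairs always give a sample correlation of +-1); such subgroups
  # are dropped with an explicit note rather than silently fitted
  gq <- vapply(prep$groups, function(g) g$group, character(1))
  complete_n <- tapply(
    vapply(prep$groups, function(g) if (all(g$mask)) g$n else 0L, integer(1)),
    gq, sum)
  small <- names(complete_n)[complete_n < min_group_pairs]
  dropped_note <- character()
  if (length(small) > 0) {
    dropped_note <- sprintf(
      "subgroup %s excluded (fewer than %d complete pairs)", small,
      min_group_pairs)
    prep$groups <- prep$groups[!gq %in% small]
    assert_that(length(prep$groups) > 0, "no usable subgroups")
    prep$n_pairs <- sum(vapply(prep$groups, function(g) g$n, integer(1)))
    prep$n_values <- sum(vapply(prep$groups,
                                function(g) g$n * sum(g$mask), numeric(1)))
  }
  groups <- sort(unique(vapply(prep$groups, function(g) g$group, character(1))))
  meta <- tibble::tibble(
    group = groups,
    zyg = substr(groups, 1, 2),
    sextag = substring(groups, 3))
  spec <- saturated_spec(trait, groups)
  fits <- list(baseline = fit_twin_model_prepared(prep, spec,
                                                  n_restarts = n_restarts,
                                                  seed = seed,
                                                  grad_check = FALSE))
  lab <- function(par, g) sprintf("%s.%s", par, g)
  eq <- function(sp, labels) if (length(labels) >= 2) equate_params(sp, labels) else sp

  # cumulative constraint builders; each returns (spec, note)
  steps <- list(
    list(name = "means equal across twin order", fn = function(sp) {
      for (g in groups) sp <- eq(sp, c(lab("m1", g), lab("m2", g)))
      sp
    }),
    list(name = "means equal across zygosity", fn = function(sp) {
      for (tag in unique(meta$sextag)) {
        gs <- meta$group[meta$sextag == tag]
        sp <- eq(sp, lab("m1", gs))
      }
      sp
    }),
    list(name = "means equal across sex", fn = function(sp) {
      sp <- eq(sp, lab("m1", groups))
      sp
    }),
    list(name = "variances equal across twin order", fn = function(sp) {
      for (g in groups) sp <- eq(sp, c(lab("v1", g), lab("v2", g)))
      sp
    }),
    list(name = "variances equal across zygosity", fn = function(sp) {
      for (tag in unique(meta$sextag)) {
        gs <- meta$group[meta$sextag == tag]
        sp <- eq(sp, lab("v1", gs))
      }
      sp
    }),
    list(name = "variances equal across sex", fn = function(sp) {
      sp <- eq(sp, lab("v1", groups))
      sp
    }),
    list(name = "covariances equal across sex", fn = function(sp) {
      for (z in unique(meta$zyg)) {
        gs <- meta$group[meta$zyg == z & meta$sextag != "OS"]
        sp <- eq(sp, lab("c", gs))
      }
      sp
    }),
    list(name = "covariances equal across zygosity", fn = function(sp) {
      sp <- eq(sp, lab("c", groups))
      sp
    })
  )

  rows <- list()
  prev_fit <- fits$baseline
  cur_spec <- spec
  rows[[1]] <- tibble::tibble(step = 0L, constraint = "saturated baseline",
                              EP = prev_fit$EP, minus2LL = prev_fit$minus2LL,
                              delta_m2ll = NA_real_, delta_df = NA_integer_,
                              p = NA_real_, pass = NA,
                              reporting_only = FALSE, note = "")
  for (k in seq_along(steps)) {
    new_spec <- steps[[k]]$fn(cur_spec)
    d_ep <- count_parameters(cur_spec) - count_parameters(new_spec)
    if (d_ep == 0) {
      rows[[k + 1]] <- tibble::tibble(
        step = k, constraint = steps[[k]]$name, EP = count_parameters(cur_spec),
        minus2LL = prev_fit$minus2LL, delta_m2ll = NA_real_,
        delta_df = 0L, p = NA_real_, pass = NA, reporting_only = FALSE,
        note = "skipped: constraint references no additional parameters")
      next
    }
    new_fit <- fit_twin_model_prepared(prep, new_spec,
                                       n_restarts = n_restarts, seed = seed,
                                       grad_check = FALSE)
    lr <- likelihood_ratio_test(prev_fit, new_fit)
    rep_only <- k == length(steps) && !zygosity_cov_pass_fail
    rows[[k + 1]] <- tibble::tibble(
      step = k, constraint = steps[[k]]$name, EP = new_fit$EP,
      minus2LL = new_fit$minus2LL, delta_m2ll = lr$delta_m2ll,
      delta_df = lr$delta_df, p = lr$p,
      pass = if (rep_only) NA else lr$p >= alpha,
      reporting_only = rep_only,
      note = if (rep_only) "reporting-only: equating MZ and DZ covariances contradicts genetic effects" else "")
    prev_fit <- new_fit
    cur_spec <- new_spec
    fits[[steps[[k]]$name]] <- new_fit
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("twin_ladder", class(out)), alpha = alpha,
            trait = trait, groups = groups, fits = fits,
            notes = dropped_note)
}

#' @method tidy twin_ladder
#' @export
tidy.twin_ladder <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @export
print.twin_ladder <- function(x, ...) {
  cat(sprintf("<twin_ladder> trait %s, alpha = %g, subgroups: %s\n",
              attr(x, "trait"), attr(x, "alpha"),
              paste(attr(x, "groups"), collapse = ", ")))
  df <- as.data.frame(tidy(x))
  df$minus2LL <- round(df$minus2LL, 2)
  df$delta_m2ll <- round(df$delta_m2ll, 3)
  df$p <- round(df$p, 3)
  print(df)
  invisible(x)
}

#' Did all pass/fail rungs of a ladder pass?
#'
#' @param ladder A `twin_ladder`.
#' @return Logical.
#' @export
ladder_passed <- function(ladder) {
  all(ladder$pass[!is.na(ladder$pass)])
}
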