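#' Run the full twin-analysis sequence
#'
#' Orchestrates the complete analysis on a twin dataset, in order:
#' (1) per-variable assumption ladders (singletons included);
#' (2) ML intraclass twin correlations and ACE/ADE family selection per
#' trait; (3) univariate structured fits with covariate-adjusted means (and
#' optional profile CIs on the standardized shares); (4) the multivariate
#' correlated-factors ACE model on pairs complete for all traits;
#' (5) AE, CE and E submodels with likelihood-ratio tests against the full
#' model; (6) post-hoc shared-environment tests: per-variable drop-C,
#' all component correlations of C fixed to `rc_constraint`, and equating
#' the free C variances of `equate_c_traits`; (7) an optional refit with
#' training years as an extra covariate; (8) decomposition of the phenotypic
#' correlations with ICC/CTCT tables.
#'
#' Singletons and partial pairs contribute to ladders and univariate fits
#' through their FIML marginal densities; the multivariate stage uses only
#' pairs complete on all modelled traits and reports their count.
#'
#' @param data A `twin_df` tibble.
#' @param traits Modelled phenotypes, in a fixed order (default: all).
#' @param covariates Mean-model covariates (default `c("age", "sex")`).
#' @param alpha_ladder Significance level of the assumption ladders (0.01).
#' @param alpha_model Reporting level for model comparisons (0.05).
#' @param ci Compute profile CIs for the univariate standardized shares and
#'   ICC/CTCT intervals (slower; default `FALSE`).
#' @param rc_constraint Value of the fixed shared-environment correlation in
#'   the constrained submodel (default 0.90).
#' @param equate_c_traits Two traits whose free C variances are equated in
#'   the final post-hoc submodel (default: the last two traits, the two
#'   self-evaluation measures in the standard layout).
#' @param include_training Also refit the multivariate model with
#'   `music_training` as an extra covariate.
#' @param univariate_singletons Include singletons/partial pairs in the
#'   univariate fits (default `TRUE`).
#' @param n_restarts,seed Passed to the fits.
#' @return An object of class `twin_analysis_report`.
#' @export
run_twin_analysis <- function(data, traits = NULL,
                              covariates = c("age", "sex"),
                              alpha_ladder = 0.01, alpha_model = 0.05,
                              ci = FALSE, rc_constraint = 0.90,
                              equate_c_traits = NULL,
                              include_training = FALSE,
                              univariate_singletons = TRUE,
                              n_restarts = 1, seed = 1) {
  traits <- traits %||% attr(data, "phenotypes")
  assert_that(length(traits) >= 1, "no traits to analyse")
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  counts <- twin_counts(data)
  note("dataset: %d MZ pairs, %d DZ pairs, %d singletons",
       counts$n_mz_pairs, counts$n_dz_pairs, counts$n_singletons)

  # (1) assumption ladders
  ladders <- purrr::map(traits, function(tr) {
    l <- run_assumption_ladder(data, tr, alpha = alpha_ladder, seed = seed)
    note("ladder[%s]: %s", tr,
         if (ladder_passed(l)) "all rungs passed" else "FAILED rung(s)")
    l
  })
  names(ladders) <- traits

  # (2) twin correlations and family selection
  icc <- twin_correlations(data, traits, covariates, conf = ci)
  for (tr in traits) {
    note("icc[%s]: MZ %.3f DZ %.3f -> %s", tr,
         icc$icc[icc$trait == tr & icc$zygosity == "MZ"],
         icc$icc[icc$trait == tr & icc$zygosity == "DZ"],
         icc$family[icc$trait == tr][1])
  }

  # (3) univariate fits
  uni_data <- if (univariate_singletons) data else
    subset_complete_pairs(data, character(0))
  univariate <- purrr::map(traits, function(tr) {
    fam <- icc$family[icc$trait == tr][1]
    spec <- ace_model_spec(tr, family = fam, covariates = covariates)
    fit <- fit_twin_model(uni_data, spec, n_restarts = n_restarts, seed = seed)
    assert_that(fit$converged, paste0("univariate fit did not converge: ", tr))
    shares <- standardize_components(fit$vc)
    cis <- NULL
    if (ci) {
      comps <- component_blocks(spec)
      cis <- purrr::map_dfr(comps, function(cmp) {
        profile_share_ci(uni_data, fit, cmp, tr)
      })
    }
    list(trait = tr, family = fam, fit = fit, shares = shares, share_ci = cis)
  })
  names(univariate) <- traits
  table1 <- purrr::map_dfr(univariate, function(u) {
    sh <- u$shares
    row <- tibble::tibble(trait = u$trait, family = u$family)
    for (cn in setdiff(names(sh), "trait")) row[[cn]] <- sh[[cn]]
    row <- dplyr::mutate(row,
                          icc_mz = icc$icc[icc$trait == u$trait & icc$zygosity == "MZ"],
                          icc_dz = icc$icc[icc$trait == u$trait & icc$zygosity == "DZ"],
                          minus2LL = u$fit$minus2LL, EP = u$fit$EP,
                          n_pairs = u$fit$n_pairs_used)
    if (!is.null(u$share_ci)) {
      for (k in seq_len(nrow(u$share_ci))) {
        cmp <- sub("%.*", "", u$share_ci$param[k])
        row[[paste0(cmp, "_lower")]] <- u$share_ci$lower[k]
        row[[paste0(cmp, "_upper")]] <- u$share_ci$upper[k]
      }
    }
    row
  })

  # (4) multivariate correlated-factors model on complete pairs
  multi <- NULL
  table2 <- NULL
  posthoc <- NULL
  decomposition <- NULL
  table3 <- NULL
  training_fit <- NULL
  if (length(traits) >= 2) {
    mdata <- subset_complete_pairs(data, traits)
    note("multivariate stage: %d complete pairs",
         nrow(mdata) / 2)
    full_spec <- ace_model_spec(traits, family = "ACE", covariates = covariates)
    full <- fit_twin_model(mdata, full_spec, n_restarts = n_restarts,
                           seed = seed)
    assert_that(full$converged, "multivariate ACE fit did not converge")

    # (5) nested submodels
    sub_specs <- list(AE = drop_component(full_spec, "C"),
                      CE = drop_component(full_spec, "A"),
                      E = drop_component(drop_component(full_spec, "A"), "C"))
    sub_fits <- purrr::imap(sub_specs, function(sp, nm) {
      f <- fit_twin_model(mdata, sp, n_restarts = n_restarts, seed = seed)
      assert_that(f$converged, paste0("submodel did not converge: ", nm))
      f
    })
    comp_rows <- purrr::imap_dfr(sub_fits, function(f, nm) {
      lr <- likelihood_ratio_test(full, f)
      tibble::tibble(model = nm, EP = f$EP, minus2LL = f$minus2LL, df = f$df,
                     AIC = f$AIC, delta_m2ll = lr$delta_m2ll,
                     delta_df = lr$delta_df, p = lr$p)
    })
    table2 <- dplyr::bind_rows(
      tibble::tibble(model = "ACE", EP = full$EP, minus2LL = full$minus2LL,
                     df = full$df, AIC = full$AIC, delta_m2ll = NA_real_,
                     delta_df = NA_integer_, p = NA_real_),
      comp_rows)

    # (6) post-hoc shared-environment submodels
    ph <- list()
    for (tr in traits) {
      sp <- drop_component_for(full_spec, "C", tr)
      f <- fit_twin_model(mdata, sp, n_restarts = n_restarts, seed = seed)
      lr <- likelihood_ratio_test(full, f)
      ph[[paste0("drop_C_", tr)]] <- tibble::tibble(
        test = paste0("drop C: ", tr), EP = f$EP, minus2LL = f$minus2LL,
        delta_m2ll = lr$delta_m2ll, delta_df = lr$delta_df, p = lr$p,
        significant = lr$p < alpha_model)
    }
    sp_rc <- fix_component_correlation(full_spec, "C", rc_constraint)
    f_rc <- fit_twin_model(mdata, sp_rc, n_restarts = n_restarts, seed = seed)
    lr_rc <- likelihood_ratio_test(full, f_rc)
    ph$fix_rc <- tibble::tibble(
      test = sprintf("fix r_c = %.2f", rc_constraint), EP = f_rc$EP,
      minus2LL = f_rc$minus2LL, delta_m2ll = lr_rc$delta_m2ll,
      delta_df = lr_rc$delta_df, p = lr_rc$p,
      significant = lr_rc$p < alpha_model)
    equate_c_traits <- equate_c_traits %||% utils::tail(traits, 2)
    if (length(equate_c_traits) == 2 && length(traits) >= 2) {
      it <- match(equate_c_traits, traits)
      labs <- sprintf("C%d%d", it, it)
      sp_eq <- equate_params(full_spec, labs)
      f_eq <- fit_twin_model(mdata, sp_eq, n_restarts = n_restarts,
                             seed = seed)
      lr_eq <- likelihood_ratio_test(full, f_eq)
      ph$equate_c <- tibble::tibble(
        test = paste0("equate C: ", paste(equate_c_traits, collapse = " = ")),
        EP = f_eq$EP, minus2LL = f_eq$minus2LL,
        delta_m2ll = lr_eq$delta_m2ll, delta_df = lr_eq$delta_df, p = lr_eq$p,
        significant = lr_eq$p < alpha_model)
    }
    posthoc <- dplyr::bind_rows(ph)

    # (7) optional refit with training covariate
    if (include_training) {
      sp_tr <- ace_model_spec(traits, family = "ACE",
                              covariates = c(covariates, "music_training"))
      training_fit <- fit_twin_model(mdata, sp_tr, n_restarts = n_restarts,
                                     seed = seed)
      note("training-covariate refit: -2LL %.2f (EP %d)",
           training_fit$minus2LL, training_fit$EP)
    }

    # (8) decomposition + CTCT
    decomposition <- decompose_fit(full)
    ctct <- purrr::map_dfr(utils::combn(traits, 2, simplify = FALSE),
                           function(prs) {
      dplyr::bind_rows(
        ctct_correlation(mdata, prs[1], prs[2], "MZ", covariates, conf = ci),
        ctct_correlation(mdata, prs[1], prs[2], "DZ", covariates, conf = ci))
    })
    table3 <- dplyr::left_join(
      decomposition$pairs,
      tidyr::pivot_wider(ctct[, c("trait_i", "trait_j", "zygosity", "ctct")],
                         names_from = "zygosity", values_from = "ctct",
                         names_prefix = "ctct_"),
      by = c("trait_i", "trait_j"))
    multi <- list(full = full, submodels = sub_fits, ctct = ctct)
  }

  structure(list(
    ladders = ladders, icc = icc, univariate = univariate, table1 = table1,
    multivariate = multi, table2 = table2, posthoc = posthoc,
    decomposition = decomposition, table3 = table3,
    training_fit = training_fit, log = log_lines,
    provenance = list(seed = seed, traits = traits, covariates = covariates,
                      alpha_ladder = alpha_ladder, alpha_model = alpha_model,
                      rc_constraint = rc_constraint,
                      package_version = as.character(utils::packageVersion("twinace")))),
    class = "twin_analysis_report")
}

#' @export
print.twin_analysis_report <- function(x, ...) {
  cat("<twin_analysis_report>\n")
  cat("Univariate estimates (table 1):\n")
  print(as.data.frame(dplyr::mutate(x$table1,
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ round(.x, 2)))))
  if (!is.null(x$table2)) {
    cat("\nModel comparison (table 2):\n")
    print(as.data.frame(dplyr::mutate(x$table2,
                                      dplyr::across(dplyr::where(is.numeric),
                                                    ~ round(.x, 3)))))
  }
  if (!is.null(x$table3)) {
    cat("\nDecomposition (table 3):\n")
    print(as.data.frame(dplyr::mutate(
      x$table3[, c("trait_i", "trait_j", "r_p", "pct_A", "pct_C", "pct_E",
                   "r_g", "r_c", "r_e", "ctct_MZ", "ctct_DZ")],
      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2)))))
  }
  invisible(x)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

#' Write a report bundle to disk
#'
#' Writes exactly five files to `outdir`: `table1_univariate.csv`,
#' `table2_model_comparison.csv`, `table3_decomposition.csv` (formatted:
#' shares and correlations to 2 decimals, deviances to 2, p-values to 3),
#' `report.json` (full precision; re-reading it reproduces all table values)
#' and `analysis_log.txt`.
#'
#' @param report A `twin_analysis_report`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the five file paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(outdir), paste0("cannot create directory: ", outdir))
  p1 <- file.path(outdir, "table1_univariate.csv")
  p2 <- file.path(outdir, "table2_model_comparison.csv")
  p3 <- file.path(outdir, "table3_decomposition.csv")
  pj <- file.path(outdir, "report.json")
  pl <- file.path(outdir, "analysis_log.txt")

  t1 <- report$table1
  t1f <- dplyr::mutate(t1,
                       dplyr::across(dplyr::any_of(c("A", "C", "E")), ~ fmt_num(.x, 2)),
                       dplyr::across(dplyr::any_of(c("icc_mz", "icc_dz")), ~ fmt_num(.x, 2)),
                       dplyr::across(dplyr::any_of("minus2LL"), ~ fmt_num(.x, 2)))
  readr::write_csv(t1f, p1)

  if (!is.null(report$table2)) {
    t2f <- dplyr::mutate(report$table2,
                         dplyr::across(dplyr::any_of(c("minus2LL", "AIC", "delta_m2ll")),
                                       ~ fmt_num(.x, 2)),
                         dplyr::across(dplyr::any_of("p"), ~ fmt_num(.x, 3)))
    readr::write_csv(t2f, p2)
  } else {
    readr::write_csv(tibble::tibble(), p2)
  }
  if (!is.null(report$table3)) {
    t3f <- dplyr::mutate(report$table3,
                         dplyr::across(dplyr::where(is.numeric), ~ fmt_num(.x, 2)))
    readr::write_csv(t3f, p3)
  } else {
    readr::write_csv(tibble::tibble(), p3)
  }

  json <- list(
    provenance = report$provenance,
    table1 = report$table1,
    table2 = report$table2,
    table3 = report$table3,
    posthoc = report$posthoc,
    icc = report$icc,
    ladders = purrr::map(report$ladders, tidy),
    log = report$log)
  jsonlite::write_json(json, pj, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  writeLines(report$log, pl)
  invisible(c(p1, p2, p3, pj, pl))
}
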