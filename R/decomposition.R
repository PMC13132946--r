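#' Standardized variance shares per trait
#'
#' Converts raw component matrices to percent-of-total-variance shares:
#' `a_i = 100 * A_ii / (A_ii + C_ii + E_ii)` and likewise for the other
#' components. Shares sum to 100 per trait by construction.
#'
#' @param vc A [variance_components()] object.
#' @return Tibble with one row per trait and columns `trait`, `A`, `C`/`D`,
#'   `E` (percent).
#' @export
standardize_components <- function(vc) {
  comps <- Filter(Negate(is.null), list(A = vc$A, C = vc$C, D = vc$D, E = vc$E))
  tot <- Reduce(`+`, comps)
  assert_that(all(diag(tot) > 0), "total variance must be positive")
  out <- tibble::tibble(trait = vc$traits)
  for (nm in names(comps)) out[[nm]] <- 100 * diag(comps[[nm]]) / diag(tot)
  out
}

#' Component correlation between two traits
#'
#' The correlation implied by one component covariance matrix,
#' `M[i,j] / sqrt(M[i,i] * M[j,j])`. With the A matrix this is the genetic
#' correlation r_g; with C or E it gives r_c and r_e. Under direct symmetric
#' parameterisation the value may legitimately fall outside \[-1, 1\] when the
#' component matrix is not positive semidefinite; such values are returned
#' verbatim.
#'
#' @param x A p x p symmetric component matrix, or a `variance_components`
#'   object together with `component`.
#' @param i,j Trait indices (or names when `x` is `variance_components`).
#' @param component Component name when `x` is a `variance_components`.
#' @return The component correlation (scalar).
#' @export
component_correlation <- function(x, i = 1, j = 2, component = NULL) {
  if (inherits(x, "variance_components")) {
    assert_that(!is.null(component), "supply component = \"A\", \"C\", \"D\" or \"E\"")
    if (is.character(i)) i <- match(i, x$traits)
    if (is.character(j)) j <- match(j, x$traits)
    x <- x[[component]]
  }
  assert_that(x[i, i] > 0 && x[j, j] > 0,
              "component correlation requires positive diagonal entries")
  x[i, j] / sqrt(x[i, i] * x[j, j])
}

#' @rdname component_correlation
#' @param A Additive-genetic covariance matrix (or `variance_components`).
#' @export
genetic_correlation <- function(A, i = 1, j = 2) {
  component_correlation(A, i, j, component = "A")
}

#' Contribution of each component to a phenotypic correlation
#'
#' Decomposes the model-implied phenotypic correlation
#' `r_p = (A_ij + C_ij + E_ij) / sqrt(V_ii V_jj)` into the cross-paths through
#' each component: on standardized components the A contribution is
#' `sqrt(a_i) * r_g * sqrt(a_j) / r_p` (and likewise for C and E), expressed
#' in percent of r_p. The three contributions sum to 100 by construction.
#' Computed on the raw covariance matrices and standardized internally, which
#' is algebraically identical to the standardized-unit formulation.
#'
#' @param vc A [variance_components()] object (ACE).
#' @param i,j Trait indices or names.
#' @return One-row tibble: `trait_i`, `trait_j`, `r_p`, `A`, `C`, `E`
#'   (percent of r_p).
#' @export
bivariate_contributions <- function(vc, i = 1, j = 2) {
  if (is.character(i)) i <- match(i, vc$traits)
  if (is.character(j)) j <- match(j, vc$traits)
  assert_that(is.null(vc$D), "bivariate contributions are defined for ACE models")
  V <- vc$A + vc$C + vc$E
  denom <- sqrt(V[i, i] * V[j, j])
  r_p <- (vc$A[i, j] + vc$C[i, j] + vc$E[i, j]) / denom
  assert_that(abs(r_p) > 1e-12,
              "phenotypic correlation is numerically zero; contributions undefined")
  contrib <- function(M) 100 * (M[i, j] / denom) / r_p
  tibble::tibble(trait_i = vc$traits[i], trait_j = vc$traits[j], r_p = r_p,
                 A = contrib(vc$A), C = contrib(vc$C), E = contrib(vc$E))
}

#' Choose between ACE and ADE model families
#'
#' The classical decision rule from the MZ/DZ intraclass correlations: when
#' the MZ correlation is less than twice the DZ correlation shared
#' environment is indicated (ACE); when it exceeds twice the DZ correlation
#' dominance is indicated (ADE). Exact equality returns ACE.
#'
#' @param icc_mz,icc_dz Intraclass correlations for MZ and DZ pairs.
#' @return `"ACE"` or `"ADE"`.
#' @export
select_model_family <- function(icc_mz, icc_dz) {
  assert_that(is.finite(icc_mz) && is.finite(icc_dz),
              "correlations must be finite")
  if (icc_mz <= 2 * icc_dz) "ACE" else "ADE"
}

#' Full decomposition of a fitted multivariate model
#'
#' Collects, from a fitted correlated-factors ACE model, the per-trait
#' standardized shares, and for every trait pair the model-implied phenotypic
#' correlation, the component correlations r_g, r_c, r_e (flagged when
#' outside \[-1, 1\], where a capped display value is also provided), and the
#' percent contributions of A, C and E to r_p.
#'
#' @param fit A converged structured `twin_fit` (ACE family).
#' @return An object of class `twin_decomposition`: list with `shares` and
#'   `pairs` tibbles.
#' @export
decompose_fit <- function(fit) {
  vc <- fit$vc
  assert_that(!is.null(vc), "decompose_fit requires a structured fit")
  shares <- standardize_components(vc)
  pairs <- NULL
  if (vc$p >= 2) {
    idx <- utils::combn(vc$p, 2)
    # a fitted component diagonal may be negative under direct symmetric
    # parameterisation; the correlation is then undefined and reported NA
    safe_corr <- function(M, i, j) {
      if (M[i, i] <= 0 || M[j, j] <= 0) return(NA_real_)
      component_correlation(M, i, j)
    }
    pairs <- purrr::map_dfr(seq_len(ncol(idx)), function(k) {
      i <- idx[1, k]; j <- idx[2, k]
      ct <- bivariate_contributions(vc, i, j)
      rg <- safe_corr(vc$A, i, j)
      rc <- safe_corr(vc$C, i, j)
      re <- safe_corr(vc$E, i, j)
      tibble::tibble(
        trait_i = vc$traits[i], trait_j = vc$traits[j], r_p = ct$r_p,
        pct_A = ct$A, pct_C = ct$C, pct_E = ct$E,
        r_g = rg, r_c = rc, r_e = re,
        r_g_display = pmin(pmax(rg, -1), 1),
        r_c_display = pmin(pmax(rc, -1), 1),
        r_e_display = pmin(pmax(re, -1), 1),
        boundary = is.na(rg) | is.na(rc) | is.na(re) |
          abs(rg) > 1 | abs(rc) > 1 | abs(re) > 1)
    })
  }
  structure(list(shares = shares, pairs = pairs, traits = vc$traits),
            class = "twin_decomposition")
}

#' @export
print.twin_decomposition <- function(x, ...) {
  cat("<twin_decomposition>\nStandardized shares (%):\n")
  print(as.data.frame(dplyr::mutate(x$shares,
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ round(.x, 2)))))
  if (!is.null(x$pairs)) {
    cat("Pairwise decomposition:\n")
    print(as.data.frame(dplyr::mutate(
      x$pairs[, c("trait_i", "trait_j", "r_p", "pct_A", "pct_C", "pct_E",
                  "r_g", "r_c", "r_e", "boundary")],
      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2)))))
  }
  invisible(x)
}

#' @method tidy twin_decomposition
#' @export
tidy.twin_decomposition <- function(x, ...) {
  if (is.null(x$pairs)) return(x$shares)
  x$pairs
}
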