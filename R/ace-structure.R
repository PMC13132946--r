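#' Variance components of a twin model
#'
#' Container for the p x p symmetric additive-genetic (A), shared-environment
#' (C), unshared-environment (E) and optional dominance (D) covariance
#' matrices under direct symmetric parameterisation. Entries are free real
#' numbers: components are deliberately not constrained to be positive
#' semidefinite and implied component correlations may fall outside
#' \[-1, 1\] at boundaries; only the total within-person covariance
#' V = A + C + E (+ D) must be positive-definite wherever a likelihood is
#' evaluated.
#'
#' @param A,E p x p symmetric matrices (scalars allowed for p = 1).
#' @param C Shared-environment matrix, or `NULL` for ADE models.
#' @param D Dominance matrix, or `NULL` for ACE models.
#' @param traits Optional character vector of trait names.
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(A, C = NULL, E, D = NULL, traits = NULL) {
  as_m <- function(x) {
    if (is.null(x)) return(NULL)
    if (!is.matrix(x)) x <- matrix(x, 1, 1)
    assert_that(is_symmetric_tol(x), "component matrices must be symmetric")
    unname(x)
  }
  A <- as_m(A); C <- as_m(C); E <- as_m(E); D <- as_m(D)
  p <- nrow(A)
  for (m in list(C, E, D)) {
    if (!is.null(m)) assert_that(nrow(m) == p, "component matrices must share dimension")
  }
  assert_that(!is.null(C) || !is.null(D), "supply C (ACE) or D (ADE)")
  traits <- traits %||% paste0("trait", seq_len(p))
  assert_that(length(traits) == p, "traits length must equal p")
  structure(list(A = A, C = C, E = E, D = D, traits = traits, p = p),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> %s model, p = %d (%s)\n",
              if (is.null(x$D)) "ACE" else "ADE", x$p,
              paste(x$traits, collapse = ", ")))
  for (nm in c("A", "C", "E", "D")) {
    if (!is.null(x[[nm]])) {
      cat(nm, ":\n", sep = "")
      print(round(x[[nm]], 4))
    }
  }
  invisible(x)
}

#' Build variance components from standardized shares and correlations
#'
#' Convenience constructor: takes per-trait standardized shares (percent of
#' total variance, unit total variance per trait) and pairwise component
#' correlations, and assembles the raw A, C, E matrices with
#' `A[i,j] = r_g[i,j] * sqrt(A[i,i] * A[j,j])` and likewise for C and E.
#'
#' @param a,c,e Numeric vectors of standardized shares in percent (summing to
#'   about 100 per trait).
#' @param rg,rc,re Pairwise component correlations: a scalar for p = 2 or a
#'   p x p symmetric matrix; ignored for p = 1.
#' @param traits Optional trait names.
#' @return A `variance_components` object with unit total variances.
#' @export
vc_from_shares <- function(a, c, e, rg = NULL, rc = NULL, re = NULL,
                           traits = NULL) {
  p <- length(a)
  assert_that(length(c) == p && length(e) == p, "share vectors must share length")
  as_corr <- function(r) {
    if (p == 1) return(matrix(1, 1, 1))
    if (is.null(r)) r <- 0
    if (!is.matrix(r)) {
      assert_that(p == 2 && length(r) == 1,
                  "pass a p x p correlation matrix when p > 2")
      r <- matrix(c(1, r, r, 1), 2, 2)
    }
    r
  }
  build <- function(shares, r) {
    d <- shares / 100
    m <- as_corr(r) * (sqrt(d) %o% sqrt(d))
    diag(m) <- d
    m
  }
  variance_components(A = build(a, rg), C = build(c, rc), E = build(e, re),
                      traits = traits)
}

#' Expected twin-pair covariance matrix
#'
#' The model-implied 2p x 2p covariance of the stacked phenotype vector
#' (twin 1's p traits, then twin 2's). Within-twin blocks are A + C + E
#' (or A + D + E); the cross-twin block is A + C for MZ pairs and
#' 0.5 A + C for DZ pairs, reflecting that MZ twins share all and DZ twins on
#' average half of their segregating genes (ADE: A + D for MZ,
#' 0.5 A + 0.25 D for DZ).
#'
#' @param vc A [variance_components()] object. Supplying both C and D is an
#'   error: they are not jointly identifiable in the classical twin design.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A 2p x 2p symmetric matrix.
#' @export
expected_pair_covariance <- function(vc, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  assert_that(inherits(vc, "variance_components"), "vc must be variance_components")
  assert_that(is.null(vc$C) || is.null(vc$D),
              "C and D cannot both be present (confounded in a twin design)")
  if (is.null(vc$D)) {
    within <- vc$A + vc$C + vc$E
    cross <- if (zygosity == "MZ") vc$A + vc$C else 0.5 * vc$A + vc$C
  } else {
    within <- vc$A + vc$D + vc$E
    cross <- if (zygosity == "MZ") vc$A + vc$D else 0.5 * vc$A + 0.25 * vc$D
  }
  rbind(cbind(within, cross), cbind(t(cross), within))
}

#' Mean model for twin phenotypes
#'
#' Linear mean structure shared by both members of a pair: for twin t and
#' trait i, `mu_i + beta_age_i * age_t + beta_sex_i * sex_t` (plus an optional
#' training slope). Identical coefficients for twin 1 and twin 2 (twin order
#' is exchangeable).
#'
#' @param intercepts Length-p numeric vector.
#' @param beta_age,beta_sex Length-p slopes (recycled from scalars).
#' @param beta_training Optional length-p slope for years of music training.
#' @return An object of class `mean_model`.
#' @export
mean_model <- function(intercepts, beta_age = 0, beta_sex = 0,
                       beta_training = NULL) {
  p <- length(intercepts)
  rec <- function(x) if (is.null(x)) NULL else rep_len(x, p)
  structure(list(intercepts = intercepts, beta_age = rec(beta_age),
                 beta_sex = rec(beta_sex), beta_training = rec(beta_training),
                 p = p),
            class = "mean_model")
}

#' Expected twin-pair mean vector
#'
#' @param mm A [mean_model()].
#' @param x1,x2 Named lists/vectors of covariate values for twin 1 and twin 2
#'   (`age`, `sex01`, optionally `music_training`).
#' @return Length-2p vector (twin 1's trait means, then twin 2's).
#' @export
expected_pair_mean <- function(mm, x1, x2) {
  one <- function(x) {
    assert_that(!is.null(x[["age"]]) && !is.null(x[["sex01"]]),
                "covariates age and sex01 are required")
    mu <- mm$intercepts + mm$beta_age * x[["age"]] + mm$beta_sex * x[["sex01"]]
    if (!is.null(mm$beta_training)) {
      assert_that(!is.null(x[["music_training"]]),
                  "music_training covariate required by this mean model")
      mu <- mu + mm$beta_training * x[["music_training"]]
    }
    mu
  }
  c(one(x1), one(x2))
}

# ---------------------------------------------------------------------------
# Model specifications
# ---------------------------------------------------------------------------

#' Structured ACE/ADE model specification
#'
#' Defines the free parameters of a p-trait twin model under direct symmetric
#' parameterisation: every unique element of each component matrix is a free
#' parameter (p(p+1)/2 per component), plus an intercept and one slope per
#' covariate per trait. Constraints ([drop_component()],
#' [drop_component_for()], [fix_component_correlation()], [equate_params()])
#' produce all nested submodels.
#'
#' Component parameters are labelled `A11`, `A21`, `A22`, ... (row >= col);
#' mean parameters `b0_i` and `b_<covariate>_i` for trait i.
#'
#' @param traits Character vector of phenotype names (order fixed and shared
#'   by all downstream matrices).
#' @param family `"ACE"` or `"ADE"`.
#' @param covariates Covariate columns entering the mean model (default
#'   `c("age", "sex")`; `"sex"` is encoded 0/1 internally).
#' @return An object of class `twin_model_spec`.
#' @export
ace_model_spec <- function(traits, family = c("ACE", "ADE"),
                           covariates = c("age", "sex")) {
  family <- match.arg(family)
  p <- length(traits)
  blocks <- if (family == "ACE") c("A", "C", "E") else c("A", "D", "E")
  rows <- list()
  for (b in blocks) {
    for (j in seq_len(p)) {
      for (i in j:p) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          label = sprintf("%s%d%d", b, i, j), block = b, i = i, j = j,
          term = NA_character_, group = NA_character_)
      }
    }
  }
  for (t in seq_len(p)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = sprintf("b0_%d", t), block = "mean", i = t, j = NA_integer_,
      term = "(Intercept)", group = NA_character_)
    for (cv in covariates) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = sprintf("b_%s_%d", cv, t), block = "mean", i = t,
        j = NA_integer_, term = cv, group = NA_character_)
    }
  }
  params <- dplyr::bind_rows(rows)
  params$free <- TRUE
  params$value <- NA_real_
  params$class <- params$label
  params$derived <- NA_character_
  params$lower <- -Inf
  structure(list(kind = "structured", family = family, traits = traits, p = p,
                 covariates = covariates, params = params, rc_rho = NULL,
                 share_constraint = NULL),
            class = "twin_model_spec")
}

#' Saturated per-group specification for one phenotype
#'
#' A univariate saturated model over twin-pair subgroups: each group gets its
#' own twin-1 mean, twin-2 mean, twin-1 variance, twin-2 variance and
#' within-pair covariance (labels `m1.<g>`, `m2.<g>`, `v1.<g>`, `v2.<g>`,
#' `c.<g>`). This is the baseline of the assumption ladder; equality
#' constraints across twin order, zygosity and sex generate its rungs.
#'
#' @param trait Phenotype name.
#' @param groups Character vector of subgroup labels (e.g. `"MZF"`, `"DZOS"`).
#' @return A `twin_model_spec` of kind `"saturated"`.
#' @export
saturated_spec <- function(trait, groups) {
  rows <- list()
  for (g in groups) {
    for (par in c("m1", "m2", "v1", "v2", "c")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = sprintf("%s.%s", par, g), block = par, i = NA_integer_,
        j = NA_integer_, term = NA_character_, group = g)
    }
  }
  params <- dplyr::bind_rows(rows)
  params$free <- TRUE
  params$value <- NA_real_
  params$class <- params$label
  params$derived <- NA_character_
  params$lower <- ifelse(params$block %in% c("v1", "v2"), 1e-10, -Inf)
  structure(list(kind = "saturated", family = "saturated", traits = trait,
                 p = 1, covariates = character(), params = params,
                 rc_rho = NULL, share_constraint = NULL, groups = groups),
            class = "twin_model_spec")
}

#' @export
print.twin_model_spec <- function(x, ...) {
  cat(sprintf("<twin_model_spec> %s, traits: %s, EP = %d\n", x$family,
              paste(x$traits, collapse = ", "), count_parameters(x)))
  invisible(x)
}

#' Count freely estimated parameters
#'
#' The number of estimated parameters (EP) after equality classes (each class
#' counts once) and derived constraints (derived parameters do not count).
#'
#' @param spec A `twin_model_spec`.
#' @return Integer EP.
#' @export
count_parameters <- function(spec) {
  p <- spec$params
  length(unique(p$class[p$free]))
}

free_theta_info <- function(spec) {
  p <- spec$params
  cls <- unique(p$class[p$free])
  lower <- vapply(cls, function(cl) {
    max(p$lower[p$free & p$class == cl])
  }, numeric(1))
  list(classes = cls, lower = lower)
}

# realized value for every parameter row given free-parameter vector theta
realize_params <- function(spec, theta) {
  p <- spec$params
  vals <- numeric(nrow(p))
  free <- p$free
  vals[free] <- theta[match(p$class[free], names(theta))]
  fixed <- !free & is.na(p$derived)
  vals[fixed] <- p$value[fixed]
  der <- which(!free & !is.na(p$derived))
  if (length(der) > 0) {
    for (k in der) {
      if (p$derived[k] == "rc") {
        di <- vals[p$block == p$block[k] & p$i == p$i[k] & p$j == p$i[k]]
        dj <- vals[p$block == p$block[k] & p$i == p$j[k] & p$j == p$j[k]]
        vals[k] <- spec$rc_rho * sqrt(max(di, 0) * max(dj, 0))
      } else if (p$derived[k] == "share") {
        sc <- spec$share_constraint
        others <- setdiff(component_blocks(spec), sc$component)
        tot <- 0
        for (b in others) {
          tot <- tot + vals[p$block == b & p$i == sc$trait & p$j == sc$trait]
        }
        s <- sc$share
        vals[k] <- if (s >= 1) 1e8 else s / (1 - s) * tot
      }
    }
  }
  vals
}

component_blocks <- function(spec) {
  if (spec$family == "ADE") c("A", "D", "E") else c("A", "C", "E")
}

vc_from_values <- function(spec, vals) {
  p <- spec$p
  mats <- list()
  for (b in component_blocks(spec)) {
    m <- matrix(0, p, p)
    sel <- spec$params$block == b
    ii <- spec$params$i[sel]; jj <- spec$params$j[sel]; vv <- vals[sel]
    m[cbind(ii, jj)] <- vv
    m[cbind(jj, ii)] <- vv
    mats[[b]] <- m
  }
  variance_components(A = mats$A, C = mats$C, E = mats$E, D = mats$D,
                      traits = spec$traits)
}

# q x p coefficient matrix, rows = (Intercept, covariates...), cols = traits
meanmat_from_values <- function(spec, vals) {
  terms <- c("(Intercept)", spec$covariates)
  B <- matrix(0, length(terms), spec$p,
              dimnames = list(terms, spec$traits))
  sel <- spec$params$block == "mean"
  B[cbind(match(spec$params$term[sel], terms), spec$params$i[sel])] <- vals[sel]
  B
}

# ---------------------------------------------------------------------------
# Constraints
# ---------------------------------------------------------------------------

#' Drop an entire variance component
#'
#' Fixes every element of one component matrix to zero, producing the AE, CE
#' or E submodels (for p traits this removes p(p+1)/2 parameters).
#'
#' @param spec A structured `twin_model_spec`.
#' @param component `"A"`, `"C"`, `"D"` or `"E"`.
#' @return The constrained spec.
#' @export
drop_component <- function(spec, component) {
  assert_that(component %in% component_blocks(spec),
              paste0("no such component: ", component))
  sel <- spec$params$block == component
  spec$params$free[sel] <- FALSE
  spec$params$value[sel] <- 0
  spec$params$derived[sel] <- NA_character_
  spec
}

#' Drop one trait's share of a component
#'
#' Fixes the component's variance for one trait and all its covariances with
#' the other traits to zero (p parameters when there are p traits), as in
#' per-variable drop-C tests.
#'
#' @param spec A structured `twin_model_spec`.
#' @param component Component matrix name.
#' @param trait Trait name or index.
#' @return The constrained spec.
#' @export
drop_component_for <- function(spec, component, trait) {
  if (is.character(trait)) trait <- match(trait, spec$traits)
  assert_that(!is.na(trait) && trait >= 1 && trait <= spec$p, "unknown trait")
  sel <- spec$params$block == component &
    (spec$params$i == trait | spec$params$j == trait)
  spec$params$free[sel] <- FALSE
  spec$params$value[sel] <- 0
  spec$params$derived[sel] <- NA_character_
  spec
}

#' Constrain all component correlations to a fixed value
#'
#' Replaces every off-diagonal element of a component by the derived quantity
#' `rho * sqrt(X_ii * X_jj)` while bounding that component's diagonal at zero
#' (the derived covariance is only defined for nonnegative variances). For p
#' traits this removes p(p-1)/2 free parameters.
#'
#' @param spec A structured `twin_model_spec`.
#' @param component Component matrix name (typically `"C"`).
#' @param rho The fixed correlation (e.g. 0.90).
#' @return The constrained spec.
#' @export
fix_component_correlation <- function(spec, component, rho) {
  assert_that(component %in% component_blocks(spec),
              paste0("no such component: ", component))
  diag_sel <- spec$params$block == component & spec$params$i == spec$params$j
  bad <- diag_sel & !spec$params$free & !is.na(spec$params$value) &
    spec$params$value < 0
  assert_that(!any(bad), "fix_component_correlation requires nonnegative diagonals")
  off <- spec$params$block == component & spec$params$i != spec$params$j
  spec$params$free[off] <- FALSE
  spec$params$value[off] <- NA_real_
  spec$params$derived[off] <- "rc"
  spec$params$lower[diag_sel] <- 0
  spec$rc_rho <- rho
  spec
}

#' Equate a set of parameters
#'
#' Merges the listed parameters into one equality class (removing
#' `length(labels) - 1` estimated parameters). Parameters must belong to the
#' same kind of matrix/block; equating across component matrices is an error.
#'
#' @param spec A `twin_model_spec`.
#' @param labels Character vector of parameter labels.
#' @return The constrained spec.
#' @export
equate_params <- function(spec, labels) {
  idx <- match(labels, spec$params$label)
  assert_that(!anyNA(idx), paste0("unknown parameter label: ",
                                  paste(labels[is.na(idx)], collapse = ", ")))
  blocks <- spec$params$block[idx]
  if (spec$kind == "structured") {
    assert_that(length(unique(blocks)) == 1,
                "cannot equate parameters from different matrices")
  } else {
    base <- sub("[12]$", "", blocks)
    assert_that(length(unique(base)) == 1,
                "cannot equate parameters of different kinds")
  }
  assert_that(all(spec$params$free[idx]), "can only equate free parameters")
  classes <- unique(spec$params$class[idx])
  target <- classes[1]
  spec$params$class[spec$params$class %in% classes] <- target
  spec
}

#' Fix named parameters to values
#'
#' @param spec A `twin_model_spec`.
#' @param labels Parameter labels.
#' @param values Values (recycled).
#' @return The constrained spec.
#' @export
fix_params <- function(spec, labels, values) {
  idx <- match(labels, spec$params$label)
  assert_that(!anyNA(idx), "unknown parameter label")
  values <- rep_len(values, length(idx))
  # fixing one member of an equality class fixes the whole class
  classes <- spec$params$class[idx]
  for (k in seq_along(idx)) {
    sel <- spec$params$class == classes[k] & spec$params$free
    spec$params$free[sel] <- FALSE
    spec$params$value[sel] <- values[k]
    spec$params$derived[sel] <- NA_character_
  }
  spec
}

# constrain one trait's standardized share of a component to s (fraction of
# total variance); used by profile CIs over shares
constrain_share <- function(spec, component, trait, share) {
  if (is.character(trait)) trait <- match(trait, spec$traits)
  sel <- spec$params$block == component & spec$params$i == trait &
    spec$params$j == trait
  spec$params$free[sel] <- FALSE
  spec$params$value[sel] <- NA_real_
  spec$params$derived[sel] <- "share"
  others <- setdiff(component_blocks(spec), component)
  osel <- spec$params$block %in% others & spec$params$i == trait &
    spec$params$j == trait
  spec$params$lower[osel] <- 0
  spec$share_constraint <- list(component = component, trait = trait,
                                share = share)
  spec
}

#' Serialize / deserialize a model specification
#'
#' @param spec A `twin_model_spec`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly).
#' @export
spec_to_json <- function(spec, path = NULL) {
  obj <- list(kind = spec$kind, family = spec$family, traits = spec$traits,
              p = spec$p, covariates = spec$covariates,
              params = spec$params, rc_rho = spec$rc_rho,
              share_constraint = spec$share_constraint,
              groups = spec$groups)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname spec_to_json
#' @param json JSON string or file path produced by [spec_to_json()].
#' @export
spec_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  params <- tibble::as_tibble(obj$params)
  # all-NA columns are dropped in serialization; restore them
  for (col in c("value", "derived", "term", "group")) {
    if (is.null(params[[col]])) params[[col]] <- NA
  }
  for (col in c("i", "j")) {
    if (is.null(params[[col]])) params[[col]] <- NA_integer_
  }
  params$value <- as.numeric(params$value)
  params$derived <- as.character(params$derived)
  params$term <- as.character(params$term)
  params$group <- as.character(params$group)
  params$i <- as.integer(params$i)
  params$j <- as.integer(params$j)
  # JSON has no -Inf; unbounded parameters round-trip as null
  params$lower <- as.numeric(params$lower)
  params$lower[is.na(params$lower)] <- -Inf
  params <- params[, c("label", "block", "i", "j", "term", "group", "free",
                       "value", "class", "derived", "lower")]
  if (!is.null(obj$share_constraint) && length(obj$share_constraint) == 0) {
    obj$share_constraint <- NULL
  }
  structure(list(kind = obj$kind, family = obj$family, traits = obj$traits,
                 p = obj$p, covariates = obj$covariates %||% character(),
                 params = params, rc_rho = obj$rc_rho,
                 share_constraint = obj$share_constraint,
                 groups = obj$groups),
            class = "twin_model_spec")
}
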