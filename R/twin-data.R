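#' Read a twin phenotype table
#'
#' Reads a delimited file with one row per individual twin and validates it
#' into the standard twin-data layout used throughout the package: columns
#' `family_id`, `twin_order` (1 or 2), `zygosity` (`"MZ"`/`"DZ"`), `sex`
#' (`"female"`/`"male"`), `age`, optionally `music_training`, and one column
#' per phenotype. Rows sharing a `family_id` form a twin pair; a family with a
#' single row is a singleton and still contributes to FIML fits through its
#' marginal density.
#'
#' @param path Path to a delimited text file.
#' @param phenotypes Character vector of phenotype column names (after schema
#'   renaming). If `NULL`, every column not recognised as an identifier or
#'   covariate is treated as a phenotype.
#' @param schema Optional named character vector mapping standard column names
#'   (names) to the column names used in the file (values), e.g.
#'   `c(family_id = "fid", age = "age_yrs")`.
#' @param delimiter Field delimiter, default `","`.
#' @param training_cap If non-`NULL`, years of music training are winsorized at
#'   this cap at load time (default 20); the raw value is kept in
#'   `music_training_raw` for audit.
#' @param age_range Plausible age range; out-of-range ages are an error, never
#'   silently clipped.
#' @return A tibble of class `twin_df` with one row per individual and a
#'   `"phenotypes"` attribute giving the phenotype column ordering.
#' @export
read_twin_table <- function(path, phenotypes = NULL, schema = NULL,
                            delimiter = ",", training_cap = 20,
                            age_range = c(10, 100)) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      assert_that(schema[[std]] %in% names(raw),
                  paste0("schema column not in file: ", schema[[std]]))
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  reserved <- c("family_id", "twin_order", "zygosity", "sex", "age",
                "music_training", "music_training_raw")
  for (col in c("family_id", "twin_order", "zygosity", "sex", "age")) {
    assert_that(col %in% names(raw), paste0("required column missing: ", col))
  }
  if (is.null(phenotypes)) phenotypes <- setdiff(names(raw), reserved)
  assert_that(length(phenotypes) > 0, "no phenotype columns found")
  assert_that(all(phenotypes %in% names(raw)),
              paste0("phenotype columns not in file: ",
                     paste(setdiff(phenotypes, names(raw)), collapse = ", ")))

  parse_num <- function(x, col, allow_na = TRUE) {
    x <- trimws(x)
    miss <- x == "" | x == "NA"
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!miss & is.na(out))
    if (length(bad) > 0) {
      stop_ta(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                      x[bad[1]], col, bad[1]))
    }
    if (!allow_na && any(miss)) {
      stop_ta(sprintf("missing value in column '%s' at data row %d", col,
                      which(miss)[1]))
    }
    out[miss] <- NA_real_
    out
  }

  out <- tibble::tibble(
    family_id = as.character(raw$family_id),
    twin_order = parse_num(raw$twin_order, "twin_order", allow_na = FALSE),
    zygosity = toupper(trimws(raw$zygosity)),
    sex = tolower(trimws(raw$sex)),
    age = parse_num(raw$age, "age", allow_na = FALSE)
  )
  bad_zyg <- which(!out$zygosity %in% c("MZ", "DZ"))
  if (length(bad_zyg) > 0) {
    stop_ta(sprintf("unrecognized zygosity code '%s' at data row %d",
                    raw$zygosity[bad_zyg[1]], bad_zyg[1]))
  }
  out$sex <- dplyr::case_match(out$sex, "f" ~ "female", "m" ~ "male",
                               .default = out$sex)
  bad_sex <- which(!out$sex %in% c("female", "male"))
  if (length(bad_sex) > 0) {
    stop_ta(sprintf("unrecognized sex code '%s' at data row %d",
                    raw$sex[bad_sex[1]], bad_sex[1]))
  }
  if ("music_training" %in% names(raw)) {
    tr <- parse_num(raw$music_training, "music_training")
    out$music_training_raw <- tr
    out$music_training <- if (is.null(training_cap)) tr else
      winsorize_training(tr, cap = training_cap)
  }
  for (ph in phenotypes) out[[ph]] <- parse_num(raw[[ph]], ph)
  validate_twin_data(out, phenotypes = phenotypes, age_range = age_range)
}

#' Write a twin phenotype table
#'
#' Inverse of [read_twin_table()]: writes one row per individual as delimited
#' text, with missing phenotypes as empty cells. Numeric cells survive a
#' write/read round trip bit-exactly.
#'
#' @param data A `twin_df` tibble.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_twin_table <- function(data, path, delimiter = ",") {
  readr::write_delim(data, path, delim = delimiter, na = "")
  invisible(path)
}

#' Validate a twin data frame
#'
#' Checks the structural invariants of the one-row-per-individual layout:
#' `twin_order` is 1 or 2 and unique within family, at most two rows per
#' family, zygosity and family id agree within a pair, ages fall inside the
#' plausible range, and (when `ordinal` names a phenotype) observed values of
#' that phenotype are integers in 1..7.
#'
#' @param data Data frame, one row per individual.
#' @param phenotypes Phenotype column names (default: taken from the
#'   `"phenotypes"` attribute).
#' @param age_range Plausible age range; out-of-range is an error.
#' @param ordinal Optional character vector of phenotypes constrained to
#'   integer values in `[1, 7]`.
#' @return The validated data as a `twin_df` tibble (invisible errors
#'   otherwise).
#' @export
validate_twin_data <- function(data, phenotypes = NULL,
                               age_range = c(10, 100), ordinal = NULL) {
  phenotypes <- phenotypes %||% attr(data, "phenotypes")
  assert_that(!is.null(phenotypes), "phenotype names must be supplied")
  data <- tibble::as_tibble(data)
  assert_that(all(data$twin_order %in% c(1, 2)),
              "twin_order must be 1 or 2")
  key <- paste(data$family_id, data$twin_order)
  if (anyDuplicated(key)) {
    stop_ta(sprintf("duplicate (family_id, twin_order): %s",
                    key[duplicated(key)][1]))
  }
  per_fam <- table(data$family_id)
  assert_that(all(per_fam <= 2), "a family may have at most two rows")
  zyg_n <- tapply(data$zygosity, data$family_id,
                  function(z) length(unique(z)))
  assert_that(all(zyg_n == 1), "zygosity must agree within a family")
  bad_age <- which(is.na(data$age) | data$age < age_range[1] |
                     data$age > age_range[2])
  if (length(bad_age) > 0) {
    stop_ta(sprintf("age %s outside plausible range [%g, %g] at row %d",
                    format(data$age[bad_age[1]]), age_range[1], age_range[2],
                    bad_age[1]))
  }
  if (!is.null(data[["music_training"]])) {
    assert_that(all(is.na(data$music_training) | data$music_training >= 0),
                "music_training must be nonnegative")
  }
  for (ph in ordinal) {
    v <- data[[ph]]
    v <- v[!is.na(v)]
    assert_that(all(v == round(v) & v >= 1 & v <= 7),
                paste0(ph, " must contain integers in [1, 7]"))
  }
  attr(data, "phenotypes") <- phenotypes
  class(data) <- unique(c("twin_df", class(data)))
  data
}

#' Winsorize years of music training
#'
#' Caps self-reported training years at `cap` (default 20 years) to guard
#' against implausible values; order and below-cap values are preserved.
#'
#' @param values Nonnegative numeric vector of training years (`NA` allowed).
#' @param cap Upper cap in years.
#' @return Numeric vector with each value replaced by `min(value, cap)`.
#' @export
winsorize_training <- function(values, cap = 20) {
  assert_that(all(is.na(values) | values >= 0),
              "training years must be nonnegative")
  pmin(values, cap)
}

#' Count pairs and singletons by zygosity
#'
#' @param data A `twin_df` tibble.
#' @return One-row tibble with `n_mz_pairs`, `n_dz_pairs`, `n_singletons`.
#' @export
twin_counts <- function(data) {
  fam <- dplyr::summarise(dplyr::group_by(data, .data$family_id),
                          n = dplyr::n(),
                          zygosity = .data$zygosity[1], .groups = "drop")
  tibble::tibble(
    n_mz_pairs = sum(fam$n == 2 & fam$zygosity == "MZ"),
    n_dz_pairs = sum(fam$n == 2 & fam$zygosity == "DZ"),
    n_singletons = sum(fam$n == 1)
  )
}

#' Keep only pairs complete on a set of phenotypes
#'
#' Returns the families in which both twins are present and every listed
#' phenotype is observed for both; singletons are always dropped. With an
#' empty phenotype list only the singleton-dropping applies. Idempotent.
#'
#' @param data A `twin_df` tibble.
#' @param phenotypes Phenotypes that must be observed on both twins (default:
#'   all phenotypes of `data`).
#' @return Filtered `twin_df` tibble.
#' @export
subset_complete_pairs <- function(data, phenotypes = NULL) {
  all_ph <- attr(data, "phenotypes")
  phenotypes <- phenotypes %||% all_ph
  assert_that(all(phenotypes %in% all_ph),
              paste0("unknown phenotype: ",
                     paste(setdiff(phenotypes, all_ph), collapse = ", ")))
  ok_row <- rep(TRUE, nrow(data))
  for (ph in phenotypes) ok_row <- ok_row & !is.na(data[[ph]])
  fam_ok <- tapply(ok_row, data$family_id, function(x) length(x) == 2 && all(x))
  keep <- data$family_id %in% names(fam_ok)[unlist(fam_ok)]
  out <- data[keep, , drop = FALSE]
  attr(out, "phenotypes") <- all_ph
  class(out) <- unique(c("twin_df", class(out)))
  out
}

#' Encode model covariates per individual
#'
#' Produces the numeric design values used in the mean model: `sex01` coded
#' 0 = female, 1 = male, and `age` optionally grand-mean centered. A/C/E
#' estimates are invariant to the sex reference choice; only mean parameters
#' change.
#'
#' @param data A `twin_df` tibble.
#' @param centering `"none"` (default) or `"grand_mean"` for age.
#' @return The input tibble with columns `sex01` and (centered) `age`, and a
#'   `"age_grand_mean"` attribute when centering is applied.
#' @export
encode_covariates <- function(data, centering = c("none", "grand_mean")) {
  centering <- match.arg(centering)
  assert_that(!anyNA(data$sex) && !anyNA(data$age),
              "age and sex must be present for every individual")
  data$sex01 <- as.numeric(data$sex == "male")
  if (centering == "grand_mean") {
    gm <- mean(data$age)
    data$age <- data$age - gm
    attr(data, "age_grand_mean") <- gm
  }
  data
}

# pair-sex subgroup label: MZF, MZM, DZF, DZM, DZOS (and MZOS if it occurs)
pair_subgroup <- function(zygosity, sexes) {
  sexes <- sexes[!is.na(sexes)]
  tag <- if (length(unique(sexes)) > 1) "OS" else if (sexes[1] == "male") "M" else "F"
  paste0(zygosity, tag)
}
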