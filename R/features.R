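# Cohort ingestion, inclusion filtering and feature construction.
#
# A cohort is a plain data.frame with one row per eye, using the documented
# CSV schema: case_id, patient_id?, eye?, al_mm, k_flat_d, k_steep_d, acd_mm,
# lt_mm, cd_mm, lens_model, iol_power_d, postop_se_d, postop_bcva_logmar?.

.cohort_required_cols <- c("case_id", "al_mm", "k_flat_d", "k_steep_d",
                           "acd_mm", "lt_mm", "cd_mm", "lens_model",
                           "iol_power_d", "postop_se_d")

.biometry_cols <- c("al_mm", "k_flat_d", "k_steep_d", "acd_mm", "lt_mm", "cd_mm")

#' Read a cohort CSV
#'
#' Reads the documented per-eye cohort schema (comma-separated, UTF-8, dot
#' decimal) and checks that all required columns are present.
#'
#' @param path path to the CSV file.
#' @return A data.frame, one row per eye.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.cohort_required_cols, names(df))
  if (length(missing)) {
    stop("cohort CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a cohort CSV
#'
#' @param cohort a cohort data.frame.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Apply the inclusion criteria to one cohort record
#'
#' A record is accepted iff axial length is at least 26.00 mm (the high-myopia
#' threshold), all six biometric fields and the postoperative spherical
#' equivalent are present and finite, and — when a postoperative BCVA is
#' supplied — BCVA is at least 20/40 (logMAR <= 0.30). Rejections carry a
#' machine-readable reason code.
#'
#' @param record a one-row data.frame (or named list) in the cohort schema.
#' @return A list with `accepted` (logical), `reason` (`NA` or one of
#'   `"AL_BELOW_26"`, `"INCOMPLETE_BIOMETRY"`, `"MISSING_POSTOP_SE"`,
#'   `"BCVA_BELOW_20_40"`), and `case` (the record, when accepted).
#' @export
include_case <- function(record) {
  record <- as.list(record)
  bio <- suppressWarnings(as.numeric(record[.biometry_cols]))
  if (any(is.na(bio)) || any(!is.finite(bio)) || any(bio <= 0)) {
    return(list(accepted = FALSE, reason = "INCOMPLETE_BIOMETRY", case = NULL))
  }
  if (record$al_mm < 26.00) {
    return(list(accepted = FALSE, reason = "AL_BELOW_26", case = NULL))
  }
  se <- suppressWarnings(as.numeric(record$postop_se_d))
  if (is.null(record$postop_se_d) || is.na(se) || !is.finite(se)) {
    return(list(accepted = FALSE, reason = "MISSING_POSTOP_SE", case = NULL))
  }
  bcva <- record$postop_bcva_logmar
  if (!is.null(bcva) && !is.na(suppressWarnings(as.numeric(bcva)))) {
    if (as.numeric(bcva) > 0.30) {
      return(list(accepted = FALSE, reason = "BCVA_BELOW_20_40", case = NULL))
    }
  }
  list(accepted = TRUE, reason = NA_character_, case = record)
}

#' Filter a cohort by the inclusion criteria
#'
#' Row-wise application of [include_case()]; when a `patient_id` column is
#' present and a patient contributes several eligible eyes, one eye per
#' patient is retained by seeded random choice.
#'
#' @param cohort a cohort data.frame.
#' @param seed seed for the one-eye-per-patient draw.
#' @return A list with `included` (data.frame), `rejected` (data.frame with a
#'   `reason` column).
#' @export
filter_cohort <- function(cohort, seed = 1L) {
  reasons <- character(nrow(cohort))
  keep <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    res <- include_case(cohort[i, , drop = FALSE])
    keep[i] <- res$accepted
    reasons[i] <- if (res$accepted) NA_character_ else res$reason
  }
  inc <- cohort[keep, , drop = FALSE]
  rej <- cohort[!keep, , drop = FALSE]
  if (nrow(rej)) rej$reason <- reasons[!keep]
  if ("patient_id" %in% names(inc) && anyDuplicated(inc$patient_id)) {
    rng <- .seeded_rng(seed)
    pick <- unlist(lapply(split(seq_len(nrow(inc)), inc$patient_id),
                          function(idx) {
                            if (length(idx) == 1L) idx
                            else idx[floor(rng() * length(idx)) + 1L]
                          }))
    inc <- inc[sort(pick), , drop = FALSE]
  }
  list(included = inc, rejected = rej)
}

# Small deterministic uniform generator so per-patient draws do not disturb
# the global RNG stream.
.seeded_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

.case_biometry <- function(row) {
  biometry(row$al_mm, row$k_flat_d, row$k_steep_d, row$acd_mm, row$lt_mm,
           row$cd_mm)
}

#' Feature schema of the two learning feature sets
#'
#' Set 1 augments the nine base features (six biometrics, implanted IOL power,
#' A constant, Haigis-predicted refraction) with the SRK/T-predicted
#' refraction; set 2 uses the Haigis output only.
#'
#' @param set_id `"SET1"` or `"SET2"`.
#' @return Character vector of ordered feature names.
#' @export
feature_schema <- function(set_id = c("SET1", "SET2")) {
  set_id <- match.arg(set_id)
  base <- c("al_mm", "k_flat_d", "k_steep_d", "acd_mm", "lt_mm", "cd_mm",
            "iol_power_d", "a_constant", "haigis_pred_refraction")
  if (set_id == "SET1") c(base, "srkt_pred_refraction") else base
}

#' Build the learning feature matrix for a cohort
#'
#' For each case the theoretical predicted refractions are computed with the
#' optics engines at the queried IOL power (by default the implanted power);
#' the result is the ordered numeric feature matrix for the requested set.
#'
#' @param cohort a cohort data.frame.
#' @param set_id `"SET1"` (with SRK/T output) or `"SET2"` (Haigis only).
#' @param registry a constants registry (see [constants_registry()]) used to
#'   resolve each case's lens model; when `NULL`, the cohort must carry an
#'   `a_constant` column.
#' @param iol_power optional vector of powers overriding `iol_power_d`
#'   (recycled), used when predicting at candidate powers.
#' @return A numeric matrix, rows aligned with `cohort`, columns per
#'   [feature_schema()].
#' @export
build_features <- function(cohort, set_id = c("SET1", "SET2"),
                           registry = NULL, iol_power = NULL) {
  set_id <- match.arg(set_id)
  n <- nrow(cohort)
  power <- if (is.null(iol_power)) cohort$iol_power_d else rep_len(iol_power, n)
  consts <- .resolve_cohort_constants(cohort, registry)
  mk <- (cohort$k_flat_d + cohort$k_steep_d) / 2
  haig <- .haigis_refraction(cohort$al_mm, cohort$acd_mm, mk,
                             consts$a0, consts$a1, consts$a2, power)$ref
  x <- cbind(al_mm = cohort$al_mm, k_flat_d = cohort$k_flat_d,
             k_steep_d = cohort$k_steep_d, acd_mm = cohort$acd_mm,
             lt_mm = cohort$lt_mm, cd_mm = cohort$cd_mm,
             iol_power_d = power, a_constant = consts$a_constant,
             haigis_pred_refraction = haig)
  if (set_id == "SET1") {
    srkt <- .srkt_refraction(cohort$al_mm, mk, consts$a_constant, power)$ref
    x <- cbind(x, srkt_pred_refraction = srkt)
  }
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  x[, feature_schema(set_id), drop = FALSE]
}

# Per-case constants: explicit columns win, else registry lookup by lens model.
.resolve_cohort_constants <- function(cohort, registry) {
  n <- nrow(cohort)
  if (all(c("a_constant", "a0", "a1", "a2") %in% names(cohort))) {
    return(list(a_constant = cohort$a_constant, a0 = cohort$a0,
                a1 = cohort$a1, a2 = cohort$a2))
  }
  if ("a_constant" %in% names(cohort) && is.null(registry)) {
    h <- convert_a_to_haigis(cohort$a_constant)
    return(list(a_constant = cohort$a_constant, a0 = h$a0, a1 = h$a1, a2 = h$a2))
  }
  if (is.null(registry)) {
    stop("no constants available: supply a registry or constant columns",
         call. = FALSE)
  }
  out <- list(a_constant = numeric(n), a0 = numeric(n), a1 = numeric(n),
              a2 = numeric(n))
  for (model in unique(cohort$lens_model)) {
    idx <- cohort$lens_model == model
    k <- lookup_constants(registry, model)
    out$a_constant[idx] <- k$a_constant
    out$a0[idx] <- k$a0; out$a1[idx] <- k$a1; out$a2[idx] <- k$a2
  }
  out
}

#' Split a cohort into training and test partitions
#'
#' Deterministic seeded random split; the training partition receives
#' `floor(n * train_fraction)` rows, so 1828 eyes at 8:2 give 1462 training
#' and 366 test eyes.
#'
#' @param cohort a cohort data.frame.
#' @param train_fraction fraction of rows assigned to training, in (0, 1).
#' @param seed integer seed controlling the permutation.
#' @return A list with `train` and `test` data.frames (disjoint, exhaustive).
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1L) {
  n <- nrow(cohort)
  if (n < 2) stop("cohort must have at least 2 records", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  n_train <- floor(n * train_fraction)
  old <- .Random.seed_exists()
  set.seed(seed)
  idx <- sample.int(n)
  .restore_seed(old)
  train_idx <- sort(idx[seq_len(n_train)])
  test_idx <- sort(idx[-seq_len(n_train)])
  list(train = cohort[train_idx, , drop = FALSE],
       test = cohort[test_idx, , drop = FALSE])
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Exclude cases above an axial-length limit
#'
#' Some comparator formulas only accept axial lengths up to a maximum
#' (35.00 mm for the Kane and RBF 3.0 formulas); cases above the limit are
#' excluded from head-to-head comparisons. The boundary is closed: a case at
#' exactly the limit is retained.
#'
#' @param cohort a cohort data.frame.
#' @param max_al axial-length limit in mm (default 35.00).
#' @return A list with `retained`, `excluded` data.frames and their counts
#'   `n_retained`, `n_excluded`.
#' @export
al_limit_filter <- function(cohort, max_al = 35.00) {
  if (max_al <= 26) stop("max_al must exceed 26 mm", call. = FALSE)
  keep <- cohort$al_mm <= max_al
  list(retained = cohort[keep, , drop = FALSE],
       excluded = cohort[!keep, , drop = FALSE],
       n_retained = sum(keep), n_excluded = sum(!keep))
}

#' Assign axial-length subgroups
#'
#' Bins 26.00-28.00 mm, 28.00-30.00 mm and >= 30.00 mm, with interior
#' boundaries assigned to the upper bin (half-open intervals).
#'
#' @param al axial length(s) in mm, all >= 26.
#' @param boundaries the two interior cut points, default `c(28, 30)`.
#' @return Factor with levels `"26_28"`, `"28_30"`, `"GE_30"`.
#' @export
al_subgroup <- function(al, boundaries = c(28, 30)) {
  .check_finite(al, "al")
  if (any(al < 26)) stop("axial length below the 26 mm inclusion threshold",
                         call. = FALSE)
  cut(al, breaks = c(26, boundaries, Inf), right = FALSE,
      labels = c("26_28", "28_30", "GE_30"), include.lowest = TRUE)
}
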