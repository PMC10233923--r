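# Formula benchmarking: prediction-error summaries, accuracy bands,
# cumulative absolute-error curves, the formula performance index, axial
# length subgroup reports, and the paired statistical comparison suite
# (Friedman, Cochran's Q, log-rank, Pearson), all on the convention
# PE = actual - predicted postoperative refraction.

#' Prediction error
#'
#' Signed prediction error: actual minus predicted postoperative refraction,
#' so a negative PE means the eye ended up more myopic than predicted.
#'
#' @param actual,predicted spherical equivalents in diopters.
#' @return PE in diopters (vectorized).
#' @export
compute_pe <- function(actual, predicted) {
  .check_finite(actual, "actual"); .check_finite(predicted, "predicted")
  actual - predicted
}

.default_bands <- c(0.25, 0.50, 0.75, 1.00)

#' Summarize a prediction-error series
#'
#' The standard accuracy battery for one formula on one cohort: mean and SD
#' of the signed PE, mean and median absolute error (with the SD of the
#' absolute errors), percentages of eyes within closed absolute-error bands,
#' and — when axial lengths are supplied — the Pearson correlation and
#' least-squares slope of PE on AL plus the formula performance index
#' `FPI = 1 / (SD + MedAE + |slope| + 10 / pct_within_0.50)`.
#'
#' @param pe numeric vector of signed prediction errors (D).
#' @param al optional axial lengths (mm) aligned with `pe`.
#' @param bands absolute-error thresholds for the band percentages.
#' @return An object of class `"evaluation_report"` (a list).
#' @examples
#' summarize_pe(c(-0.6, -0.2, 0.2, 0.6))
#' @export
summarize_pe <- function(pe, al = NULL, bands = .default_bands) {
  .check_finite(pe, "pe")
  n <- length(pe)
  ae <- abs(pe)
  pct <- vapply(bands, function(t) 100 * mean(ae <= t), numeric(1))
  names(pct) <- sprintf("%.2f", bands)
  rep_ <- list(n = n,
               mean_pe = mean(pe),
               sd_pe = if (n >= 2) stats::sd(pe) else NA_real_,
               mae = mean(ae),
               mae_sd = if (n >= 2) stats::sd(ae) else NA_real_,
               medae = stats::median(ae),
               pct_within = pct,
               pearson_r_pe_al = NA_real_, slope_pe_al = NA_real_,
               p_pe_al = NA_real_, fpi = NA_real_)
  if (!is.null(al) && n >= 3) {
    tr <- pe_vs_al(pe, al)
    rep_$pearson_r_pe_al <- tr$r
    rep_$slope_pe_al <- tr$slope
    rep_$p_pe_al <- tr$p
    if (n >= 2 && is.finite(rep_$sd_pe) && pct[["0.50"]] > 0 &&
        is.finite(tr$slope)) {
      rep_$fpi <- 1 / (rep_$sd_pe + rep_$medae + abs(tr$slope) +
                         10 / pct[["0.50"]])
    }
  }
  structure(rep_, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("n = %d eyes\n", x$n))
  cat(sprintf("PE   mean %+.3f D, SD %.3f D\n", x$mean_pe, x$sd_pe))
  cat(sprintf("MAE  %.3f +/- %.3f D, MedAE %.3f D\n", x$mae, x$mae_sd, x$medae))
  cat("within +/-", paste(names(x$pct_within), collapse = " / "), "D: ",
      paste(sprintf("%.2f%%", x$pct_within), collapse = " / "), "\n")
  if (is.finite(x$fpi)) {
    cat(sprintf("PE~AL r %.3f (slope %.4f D/mm), FPI %.3f\n",
                x$pearson_r_pe_al, x$slope_pe_al, x$fpi))
  }
  invisible(x)
}

#' Cumulative absolute-error curve
#'
#' Empirical cumulative percentage of eyes whose absolute prediction error
#' does not exceed each threshold (right-continuous, closed thresholds), the
#' data behind cumulative-distribution comparison plots.
#'
#' @param pe signed prediction errors (D).
#' @param grid absolute-error thresholds; default a 0.05 D grid to 2 D.
#' @return A data.frame with columns `threshold` and `cum_pct`.
#' @export
cumulative_curve <- function(pe, grid = seq(0, 2, by = 0.05)) {
  .check_finite(pe, "pe")
  if (!length(pe)) stop("empty prediction-error series", call. = FALSE)
  data.frame(threshold = grid,
             cum_pct = vapply(grid, function(t) 100 * mean(abs(pe) <= t),
                              numeric(1)))
}

#' Pearson correlation of prediction error with axial length
#'
#' @param pe signed prediction errors (D).
#' @param al axial lengths (mm), aligned.
#' @return List with `r`, `slope` (D/mm, least squares) and two-sided `p`.
#'   Zero variance in either variable yields `r = 0`, `slope = 0`, `p = 1`
#'   with a flag `degenerate = TRUE`.
#' @export
pe_vs_al <- function(pe, al) {
  stopifnot(length(pe) == length(al))
  if (length(pe) < 3) stop("need at least 3 cases", call. = FALSE)
  if (stats::sd(al) == 0) {
    return(list(r = NA_real_, slope = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  if (stats::sd(pe) == 0) {
    return(list(r = 0, slope = 0, p = 1, degenerate = TRUE))
  }
  ct <- stats::cor.test(al, pe, method = "pearson")
  list(r = unname(ct$estimate),
       slope = unname(stats::coef(stats::lm(pe ~ al))[2]),
       p = ct$p.value, degenerate = FALSE)
}

#' Per-axial-length-subgroup evaluation reports
#'
#' Splits the series into the 26-28, 28-30 and >= 30 mm subgroups and
#' summarizes each; empty subgroups are omitted with a notice.
#'
#' @param pe signed prediction errors (D).
#' @param al axial lengths (mm), aligned.
#' @param bands band thresholds passed to [summarize_pe()].
#' @return Named list of [summarize_pe()] reports (by subgroup label), with
#'   attribute `counts` giving the bin sizes (summing to `length(pe)`).
#' @export
subgroup_report <- function(pe, al, bands = .default_bands) {
  stopifnot(length(pe) == length(al))
  grp <- al_subgroup(al)
  counts <- table(grp)
  out <- list()
  for (g in levels(grp)) {
    idx <- grp == g
    if (!any(idx)) {
      message("subgroup ", g, " empty; report omitted")
      next
    }
    out[[g]] <- summarize_pe(pe[idx], if (sum(idx) >= 3) al[idx], bands)
  }
  attr(out, "counts") <- counts
  out
}

# ---------------------------------------------------------------------------
# Paired comparison suite. All operations take a matrix/data.frame of signed
# PEs with one column per formula and one row per case (complete blocks).

.pe_matrix <- function(pe_by_formula) {
  m <- as.matrix(pe_by_formula)
  if (any(!is.finite(m))) stop("non-finite prediction errors", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("F", seq_len(ncol(m)))
  m
}

.new_comparison <- function(test_name, statistic, p_value, raw_pairwise,
                            adjusted_pairwise) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, raw_pairwise = raw_pairwise,
                 adjusted_pairwise = adjusted_pairwise),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test_name, ": statistic ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  if (length(x$adjusted_pairwise)) {
    cat("Bonferroni-adjusted pairwise p:\n")
    for (nm in names(x$adjusted_pairwise)) {
      cat(sprintf("  %-30s %s\n", nm,
                  format(x$adjusted_pairwise[[nm]], digits = 4)))
    }
  }
  invisible(x)
}

.pairwise_names <- function(cols) {
  cmb <- utils::combn(cols, 2)
  paste(cmb[1, ], cmb[2, ], sep = " vs ")
}

#' Friedman comparison of absolute prediction errors across formulas
#'
#' Omnibus Friedman rank test on the paired absolute errors (the
#' distribution-free comparison of MedAEs among formulas), followed by
#' pairwise Wilcoxon signed-rank post-hoc tests with Bonferroni adjustment
#' over all formula pairs.
#'
#' @param pe_by_formula matrix/data.frame of signed PEs, one column per
#'   formula, rows paired by case.
#' @return A `"comparison_result"`.
#' @export
friedman_medae_comparison <- function(pe_by_formula) {
  m <- abs(.pe_matrix(pe_by_formula))
  k <- ncol(m)
  if (k < 2) stop("need at least two formulas", call. = FALSE)
  if (all(apply(m, 1, function(r) max(r) == min(r)))) {
    # every block fully tied: no evidence of any difference
    nm <- .pairwise_names(colnames(m))
    unit <- stats::setNames(rep(1, length(nm)), nm)
    return(.new_comparison("FRIEDMAN_BONFERRONI", 0, 1, unit, unit))
  }
  ft <- stats::friedman.test(m)
  cmb <- utils::combn(colnames(m), 2)
  raw <- apply(cmb, 2, function(pair) {
    d <- m[, pair[1]] - m[, pair[2]]
    if (all(d == 0)) 1 else
      stats::wilcox.test(m[, pair[1]], m[, pair[2]], paired = TRUE,
                         exact = FALSE)$p.value
  })
  names(raw) <- .pairwise_names(colnames(m))
  adj <- pmin(raw * length(raw), 1)
  .new_comparison("FRIEDMAN_BONFERRONI", unname(ft$statistic), ft$p.value,
                  raw, adj)
}

#' Cochran's Q comparison of band hit rates across formulas
#'
#' Tests whether the proportions of eyes within a closed absolute-error band
#' differ among formulas, on the paired binary indicators
#' `|PE| <= threshold`; pairwise McNemar post-hoc tests with Bonferroni
#' adjustment. Identical indicator columns (or no between-case variation)
#' yield the no-difference result.
#'
#' @param pe_by_formula matrix/data.frame of signed PEs, columns = formulas.
#' @param threshold band threshold in diopters (e.g. 0.50).
#' @return A `"comparison_result"`.
#' @export
cochran_q_bands <- function(pe_by_formula, threshold) {
  m <- .pe_matrix(pe_by_formula)
  x <- (abs(m) <= threshold) * 1L
  k <- ncol(x); n <- nrow(x)
  if (k < 2) stop("need at least two formulas", call. = FALSE)
  row_tot <- rowSums(x)
  col_tot <- colSums(x)
  denom <- k * sum(row_tot) - sum(row_tot^2)
  nm <- .pairwise_names(colnames(x))
  if (denom == 0) {
    unit <- stats::setNames(rep(1, length(nm)), nm)
    return(.new_comparison("COCHRAN_Q_BONFERRONI", 0, 1, unit, unit))
  }
  q <- (k - 1) * (k * sum(col_tot^2) - sum(col_tot)^2) / denom
  p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  cmb <- utils::combn(colnames(x), 2)
  raw <- apply(cmb, 2, function(pair) {
    a <- x[, pair[1]]; b <- x[, pair[2]]
    if (all(a == b)) return(1)
    stats::mcnemar.test(table(factor(a, 0:1), factor(b, 0:1)))$p.value
  })
  names(raw) <- nm
  adj <- pmin(raw * length(raw), 1)
  .new_comparison("COCHRAN_Q_BONFERRONI", q, p, raw, adj)
}

#' Log-rank comparison of two cumulative absolute-error curves
#'
#' Treats the absolute prediction error as an "event time" with no censoring
#' and applies the log-rank test, comparing the whole cumulative
#' absolute-error distribution of two formulas rather than a single summary
#' point.
#'
#' @param pe_a,pe_b signed prediction-error series of the two formulas.
#' @return A `"comparison_result"` (no pairwise component).
#' @export
logrank_curves <- function(pe_a, pe_b) {
  .check_finite(pe_a, "pe_a"); .check_finite(pe_b, "pe_b")
  if (!length(pe_a) || !length(pe_b)) stop("empty series", call. = FALSE)
  time <- c(abs(pe_a), abs(pe_b))
  group <- rep(c("A", "B"), c(length(pe_a), length(pe_b)))
  if (identical(abs(pe_a), abs(pe_b))) {
    return(.new_comparison("LOGRANK", 0, 1, NULL, NULL))
  }
  sd_ <- survival::survdiff(survival::Surv(time, rep(1L, length(time))) ~ group)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  .new_comparison("LOGRANK", unname(sd_$chisq), p, NULL, NULL)
}

#' Full formula-comparison battery on a predictions table
#'
#' Mirrors the complete evaluation protocol for a table of per-case actual
#' refractions and per-formula predicted refractions: per-formula summary
#' reports (overall and per AL subgroup), cumulative curves, and the
#' Friedman / Cochran's Q / pairwise log-rank / Pearson comparison suite.
#'
#' @param predictions data.frame with columns `case_id`, `al_mm`,
#'   `actual_se_d`, plus one column of predicted refraction per formula.
#' @param formulas character vector of formula column names; default = all
#'   non-key columns.
#' @param bands band thresholds in diopters.
#' @return A list with elements `reports`, `subgroups`, `curves`,
#'   `pe` (the PE matrix), `friedman`, `cochran_q` (one per band),
#'   `logrank` (pairwise list) and `pe_al` (per formula).
#' @export
evaluate_formulas <- function(predictions, formulas = NULL,
                              bands = .default_bands) {
  key <- c("case_id", "al_mm", "actual_se_d")
  if (!all(key %in% names(predictions))) {
    stop("predictions table needs columns ", paste(key, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(formulas)) formulas <- setdiff(names(predictions), key)
  if (length(formulas) < 1) stop("no formula columns", call. = FALSE)
  pe <- sapply(formulas, function(f)
    compute_pe(predictions$actual_se_d, predictions[[f]]))
  pe <- matrix(pe, ncol = length(formulas),
               dimnames = list(NULL, formulas))
  al <- predictions$al_mm
  reports <- lapply(formulas, function(f) summarize_pe(pe[, f], al, bands))
  names(reports) <- formulas
  subgroups <- lapply(formulas, function(f) subgroup_report(pe[, f], al, bands))
  names(subgroups) <- formulas
  curves <- lapply(formulas, function(f) cumulative_curve(pe[, f]))
  names(curves) <- formulas
  out <- list(reports = reports, subgroups = subgroups, curves = curves,
              pe = pe)
  if (length(formulas) >= 2) {
    out$friedman <- friedman_medae_comparison(pe)
    out$cochran_q <- lapply(bands, function(t) cochran_q_bands(pe, t))
    names(out$cochran_q) <- sprintf("%.2f", bands)
    cmb <- utils::combn(formulas, 2)
    lr <- apply(cmb, 2, function(pair)
      logrank_curves(pe[, pair[1]], pe[, pair[2]]), simplify = FALSE)
    names(lr) <- .pairwise_names(formulas)
    out$logrank <- lr
  }
  out$pe_al <- lapply(formulas, function(f) pe_vs_al(pe[, f], al))
  names(out$pe_al) <- formulas
  out
}

#' Flatten evaluation reports to a Table-2-style data.frame
#'
#' @param reports named list of [summarize_pe()] reports (one per formula).
#' @return data.frame with one row per formula.
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(f) {
    r <- reports[[f]]
    data.frame(formula = f, n = r$n, mean_pe = r$mean_pe, sd_pe = r$sd_pe,
               mae = r$mae, mae_sd = r$mae_sd, medae = r$medae,
               pct_within_025 = r$pct_within[["0.25"]],
               pct_within_050 = r$pct_within[["0.50"]],
               pct_within_075 = r$pct_within[["0.75"]],
               pct_within_100 = r$pct_within[["1.00"]],
               pearson_r_pe_al = r$pearson_r_pe_al,
               slope_pe_al = r$slope_pe_al, fpi = r$fpi,
               stringsAsFactors = FALSE)
  }))
}
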