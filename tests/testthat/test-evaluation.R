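test_that("prediction error is actual minus predicted", {
  expect_equal(compute_pe(-0.50, -0.25), -0.25)
  expect_equal(compute_pe(1.25, 1.25), 0)
  # negative PE = outcome more myopic than predicted
  expect_lt(compute_pe(-1.0, -0.5), 0)
})

test_that("the summary battery matches hand arithmetic", {
  r0 <- summarize_pe(rep(0, 4))
  expect_equal(r0$mean_pe, 0); expect_equal(r0$sd_pe, 0)
  expect_equal(r0$mae, 0); expect_equal(r0$medae, 0)
  expect_true(all(r0$pct_within == 100))

  r <- summarize_pe(c(-0.6, -0.2, 0.2, 0.6))
  expect_equal(r$mae, 0.4)
  expect_equal(r$medae, 0.4)
  expect_equal(r$pct_within[["0.50"]], 50)
  expect_equal(r$pct_within[["0.25"]], 50)
  expect_equal(r$pct_within[["1.00"]], 100)
  expect_equal(r$mean_pe, 0)
  expect_equal(r$sd_pe, sd(c(-0.6, -0.2, 0.2, 0.6)))
})

test_that("summary identities hold on random series", {
  set.seed(31)
  for (i in 1:20) {
    pe <- rnorm(50, sd = 0.5)
    r <- summarize_pe(pe)
    expect_true(all(diff(r$pct_within) >= 0))          # bands monotone
    expect_gte(r$mae, abs(r$mean_pe))                  # mean|PE| >= |mean PE|
    expect_equal(summarize_pe(-pe)$sd_pe, r$sd_pe)     # SD sign invariance
    cc <- cumulative_curve(pe, grid = c(0.25, 0.50, 0.75, 1.00))
    expect_equal(cc$cum_pct, unname(r$pct_within))     # curve equals bands
  }
  cc <- cumulative_curve(rnorm(30), grid = c(0, 10))
  expect_equal(cc$cum_pct[2], 100)                     # CDF(large) = 100%
})

test_that("the formula performance index combines its four components", {
  set.seed(8)
  al <- runif(60, 26, 35)
  pe <- 0.05 * (al - 30) + rnorm(60, sd = 0.3)
  r <- summarize_pe(pe, al)
  expect_equal(r$fpi,
               1 / (r$sd_pe + r$medae + abs(r$slope_pe_al) +
                      10 / r$pct_within[["0.50"]]))
  expect_gt(r$fpi, 0)
})

test_that("PE-axial-length correlation matches closed-form arithmetic", {
  al <- c(26, 28, 30, 32, 34)
  expect_equal(pe_vs_al(0.1 * al, al)$r, 1)
  expect_equal(pe_vs_al(0.1 * al, al)$slope, 0.1)
  expect_equal(pe_vs_al(rep(0.3, 5), al)$r, 0)
  pe <- c(-0.2, 0.1, 0.0, 0.4, -0.1)
  got <- pe_vs_al(pe, al)
  # independent hand computation from the moment definitions
  r_hand <- sum((al - mean(al)) * (pe - mean(pe))) /
    sqrt(sum((al - mean(al))^2) * sum((pe - mean(pe))^2))
  slope_hand <- sum((al - mean(al)) * (pe - mean(pe))) / sum((al - mean(al))^2)
  expect_equal(got$r, r_hand)
  expect_equal(got$slope, slope_hand)
  expect_error(pe_vs_al(c(0, 1), c(26, 27)), "at least 3")
})

test_that("subgroup reports partition the cohort and degenerate to the global report", {
  set.seed(5)
  al <- runif(90, 26, 35)
  pe <- rnorm(90, sd = 0.4)
  rep_ <- subgroup_report(pe, al)
  expect_equal(sum(attr(rep_, "counts")), 90)
  expect_equal(sum(vapply(rep_, function(r) r$n, numeric(1))), 90)
  # all cases in one bin: that bin equals the global summary
  al1 <- runif(40, 26, 27.9)
  rep1 <- subgroup_report(pe[1:40], al1)
  expect_length(rep1, 1)
  glob <- summarize_pe(pe[1:40], al1)
  expect_equal(rep1$`26_28`$mae, glob$mae)
  expect_equal(rep1$`26_28`$pct_within, glob$pct_within)
})

test_that("Friedman comparison agrees with a within-block permutation oracle", {
  set.seed(77)
  pe <- cbind(A = rnorm(12, 0, 0.4), B = rnorm(12, 0.15, 0.4),
              C = rnorm(12, -0.1, 0.5))
  res <- friedman_medae_comparison(pe)
  orc <- oracle_friedman_perm_p(abs(pe), n_perm = 4000, seed = 42)
  expect_equal(res$statistic, orc$stat, tolerance = 1e-8)
  expect_lt(abs(res$p_value - orc$p), 0.05)
  expect_true(all(res$adjusted_pairwise >= res$raw_pairwise - 1e-12))
  expect_true(all(res$adjusted_pairwise <= 1))
})

test_that("Friedman handles identical columns and ranks a dominated formula worst", {
  pe <- matrix(rnorm(30), ncol = 3)
  colnames(pe) <- c("A", "B", "C")
  same <- cbind(A = pe[, 1], B = pe[, 1], C = pe[, 1])
  res <- friedman_medae_comparison(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # one formula uniformly worse by |PE| in every block
  set.seed(9)
  base <- abs(rnorm(15, 0, 0.3))
  dom <- cbind(A = base, B = base + 0.02 * runif(15),
               C = base + 1.0)
  resd <- friedman_medae_comparison(dom)
  pw <- resd$adjusted_pairwise
  worst <- pw[grepl("C", names(pw))]
  expect_true(max(worst) <= min(pw[!grepl("C", names(pw))]) + 1e-12)
})

test_that("Cochran's Q matches the exact enumeration oracle on an 8-case fixture", {
  pe <- cbind(A = c(0.1, 0.6, 0.2, 0.8, 0.3, 0.9, 0.1, 0.7),
              B = c(0.6, 0.7, 0.1, 0.9, 0.8, 0.2, 0.6, 0.8),
              C = c(0.7, 0.8, 0.6, 0.95, 0.85, 0.75, 0.65, 0.9))
  res <- cochran_q_bands(pe, threshold = 0.5)
  orc <- oracle_cochran_exact((abs(pe) <= 0.5) * 1L)
  expect_equal(res$statistic, orc$q, tolerance = 1e-10)
  # the chi-square p approximates the mid-p of the discrete exact null and
  # must not exceed the conservative exact tail
  expect_lt(abs(res$p_value - orc$midp), 0.1)
  expect_lte(res$p_value, orc$p + 0.01)
  expect_true(all(res$adjusted_pairwise >= res$raw_pairwise - 1e-12))
})

test_that("Cochran's Q reduces to McNemar for two formulas and degenerates gracefully", {
  set.seed(12)
  pe <- cbind(A = rnorm(40, 0, 0.5), B = rnorm(40, 0.2, 0.5))
  res <- cochran_q_bands(pe, 0.5)
  a <- abs(pe[, 1]) <= 0.5; b <- abs(pe[, 2]) <= 0.5
  n01 <- sum(!a & b); n10 <- sum(a & !b)
  expect_equal(res$statistic, (n10 - n01)^2 / (n10 + n01))  # McNemar, uncorrected
  same <- cbind(A = pe[, 1], B = pe[, 1])
  expect_equal(cochran_q_bands(same, 0.5)$p_value, 1)
})

test_that("log-rank on absolute-error curves matches the textbook sums", {
  set.seed(3)
  pe_a <- rnorm(20, 0, 0.4)
  pe_b <- rnorm(20, 0.3, 0.5)
  res <- logrank_curves(pe_a, pe_b)
  expect_equal(res$statistic, oracle_logrank_chisq(abs(pe_a), abs(pe_b)),
               tolerance = 1e-8)
  expect_equal(logrank_curves(pe_a, pe_a)$p_value, 1)
  # a 1 D uniform shift is detected decisively at n = 100
  set.seed(4)
  x <- abs(rnorm(100, 0, 0.3))
  shifted <- logrank_curves(x, x + 1.0)
  expect_lt(shifted$p_value, 1e-6)
})

test_that("the full battery mirrors the benchmarking table structure", {
  set.seed(19)
  n <- 80
  preds <- data.frame(case_id = sprintf("C%03d", 1:n),
                      al_mm = runif(n, 26, 35),
                      actual_se_d = rnorm(n, -3, 0.6))
  preds$FormulaX <- preds$actual_se_d + rnorm(n, 0, 0.3)
  preds$FormulaY <- preds$actual_se_d + rnorm(n, 0.2, 0.5)
  ev <- evaluate_formulas(preds)
  expect_named(ev$reports, c("FormulaX", "FormulaY"))
  tab <- report_table(ev$reports)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("mae", "medae", "pct_within_050", "fpi") %in% names(tab)))
  # the better-calibrated formula wins on MAE here
  expect_lt(tab$mae[tab$formula == "FormulaX"],
            tab$mae[tab$formula == "FormulaY"])
  expect_length(ev$cochran_q, 4)
  expect_named(ev$logrank, "FormulaX vs FormulaY")
  expect_equal(unname(sapply(ev$curves, nrow)), c(41, 41))
})
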