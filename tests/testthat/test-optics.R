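test_that("mean keratometry and corneal radius follow the keratometer convention", {
  expect_equal(mean_k(43.0, 43.0), 43.0)
  expect_equal(mean_k(43.24, 44.29), 43.765)
  expect_equal(mean_k(40.0, 44.0), 42.0)
  expect_equal(corneal_radius(43.765), 337.5 / 43.765)
  expect_error(mean_k(44, 43), "k_flat")
  expect_error(mean_k(NA_real_, 43), "finite")
})

test_that("refraction standardization shifts by -0.03 D and round-trips", {
  expect_equal(standardize_refraction(0.00), -0.03)
  expect_equal(standardize_refraction(-10.00), -10.03)
  x <- c(-8.25, 0.5, 1.75)
  expect_equal(unstandardize_refraction(standardize_refraction(x)), x)
})

test_that("A-constant to Haigis conversion is the pinned linear map", {
  h <- convert_a_to_haigis(118.0)
  expect_equal(h$a0, 1.27706)
  expect_equal(h$a1, 0.4)
  expect_equal(h$a2, 0.1)
  a_zero <- 72.434 / 0.62467
  expect_equal(convert_a_to_haigis(a_zero)$a0, 0, tolerance = 1e-12)
  expect_lt(convert_a_to_haigis(115)$a0, convert_a_to_haigis(120)$a0)
  expect_error(convert_a_to_haigis(100), "range")
})

test_that("biometry and constants constructors enforce their invariants", {
  expect_error(biometry(28, 44, 43, 3.4, 4.4, 11.8), "k_flat")
  expect_error(biometry(-28, 43, 44, 3.4, 4.4, 11.8), "positive")
  expect_error(iol_constants(), "supply")
  expect_error(iol_constants(a_constant = 150), "range")
  expect_silent(iol_constants(a0 = 1, a1 = 0.4, a2 = 0.1))
})

test_that("SRK/T intermediates match the published algorithm steps", {
  b <- biometry(30, 43, 44, 3.4, 4.4, 11.8)
  k <- iol_constants(a_constant = 118)
  p <- srkt_predict_refraction(b, 10, k)
  im <- p$intermediates
  expect_equal(im$lcor, 26.704)           # -3.446 + 1.716*30 - 0.0237*900
  expect_equal(im$mean_k, 43.5)
  expect_equal(im$retinal_thickness, 0.65696 - 0.02029 * 30)
  expect_equal(im$optical_axial_length, 30 + im$retinal_thickness)
  expect_equal(p$elp, im$corneal_height_h + 0.62467 * 118 - 68.747 - 3.336)
  # LCOR branch is near-continuous at 24.2 mm
  lcor_above <- -3.446 + 1.716 * 24.2 - 0.0237 * 24.2^2
  expect_lt(abs(lcor_above - 24.2), 0.01)
})

test_that("both engines agree with the stepwise vergence oracle on a case grid", {
  k <- iol_constants(a_constant = 118.0)
  grid <- expand.grid(al = c(26.5, 28, 30, 33, 36),
                      kf = c(41, 43, 45), acd = c(3.0, 3.8),
                      power = c(2, 18))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    b <- biometry(g$al, g$kf, g$kf + 1, g$acd, 4.4, 11.8)
    srkt <- suppressWarnings(
      srkt_predict_refraction(b, g$power, k))$predicted_refraction
    expect_equal(srkt,
                 oracle_srkt_refraction(g$al, g$kf, g$kf + 1, 118, g$power),
                 tolerance = 0.01)
    haig <- haigis_predict_refraction(b, g$power, k)$predicted_refraction
    expect_equal(haig,
                 oracle_haigis_refraction(g$al, g$acd, g$kf, g$kf + 1,
                                          1.27706, 0.4, 0.1, g$power),
                 tolerance = 0.01)
  }
})

test_that("Haigis ELP is the three-constant regression, exactly linear", {
  b <- biometry(30, 43, 44, 3.5, 4.4, 11.8)
  k <- iol_constants(a0 = 1.0, a1 = 0.4, a2 = 0.1)
  expect_equal(haigis_predict_refraction(b, 10, k)$elp, 5.4)
  # finite differences recover a1 and a2 to machine precision
  d <- 0.5
  b_acd <- biometry(30, 43, 44, 3.5 + d, 4.4, 11.8)
  b_al <- biometry(30 + d, 43, 44, 3.5, 4.4, 11.8)
  e0 <- haigis_predict_refraction(b, 10, k)$elp
  expect_equal((haigis_predict_refraction(b_acd, 10, k)$elp - e0) / d, 0.4,
               tolerance = 1e-10)
  expect_equal((haigis_predict_refraction(b_al, 10, k)$elp - e0) / d, 0.1,
               tolerance = 1e-10)
})

test_that("forward/inverse round trips vanish and power solutions match a root finder", {
  set.seed(42)
  k <- iol_constants(a_constant = 118.0)
  for (i in 1:100) {
    # envelope where the emmetropia power stays within the manufacturable range
    al <- runif(1, 26, 33)
    kf <- runif(1, 41, 44.5)
    b <- biometry(al, kf, kf + runif(1, 0, 1.5), runif(1, 2.8, 4.0), 4.4, 11.8)
    ps <- srkt_emmetropia_power(b, k)
    ph <- haigis_emmetropia_power(b, k)
    expect_lt(abs(srkt_predict_refraction(b, ps, k)$predicted_refraction), 1e-9)
    expect_lt(abs(haigis_predict_refraction(b, ph, k)$predicted_refraction), 1e-9)
    # closed-form inversion agrees with bracketed root finding
    expect_equal(ps, oracle_emmetropia_power(function(p)
      srkt_predict_refraction(b, p, k)$predicted_refraction), tolerance = 1e-4)
    expect_equal(ph, oracle_emmetropia_power(function(p)
      haigis_predict_refraction(b, p, k)$predicted_refraction), tolerance = 1e-4)
    # non-zero targets round-trip too
    tgt <- runif(1, -4, 0.5)
    expect_equal(srkt_predict_refraction(
      b, srkt_power_for_target(b, k, tgt), k)$predicted_refraction, tgt,
      tolerance = 1e-9)
    expect_equal(haigis_predict_refraction(
      b, haigis_power_for_target(b, k, tgt), k)$predicted_refraction, tgt,
      tolerance = 1e-9)
  }
})

test_that("predicted refraction is strictly decreasing in IOL power", {
  k <- iol_constants(a_constant = 118.0)
  powers <- seq(0, 35, by = 0.25)
  for (al in c(26.2, 29, 34)) {
    b <- biometry(al, 43, 44, 3.4, 4.4, 11.8)
    rs <- suppressWarnings(vapply(powers, function(p)
      srkt_predict_refraction(b, p, k)$predicted_refraction, numeric(1)))
    rh <- vapply(powers, function(p)
      haigis_predict_refraction(b, p, k)$predicted_refraction, numeric(1))
    expect_true(all(diff(rs) < 0))
    expect_true(all(diff(rh) < 0))
  }
})

test_that("longer eyes need less power for emmetropia", {
  k <- iol_constants(a_constant = 118.0)
  pw <- vapply(seq(26.5, 35, by = 0.5), function(al)
    srkt_emmetropia_power(biometry(al, 43, 44, 3.4, 4.4, 11.8), k), numeric(1))
  expect_true(all(diff(pw) < 0))
})

test_that("degenerate geometry and extreme corneas are handled as specified", {
  b <- biometry(26.5, 43, 44, 3.4, 4.4, 11.8)
  # absurd Haigis constants push ELP beyond the eye
  expect_error(haigis_predict_refraction(b, 10,
                                         iol_constants(a0 = 25, a1 = 0.4, a2 = 0.1)),
               "degenerate")
  # very long eye with a steep cornea: sqrt clamped with a warning, no error
  b2 <- biometry(37, 45.5, 46.5, 3.4, 4.4, 11.8)
  expect_warning(srkt_predict_refraction(b2, 2, iol_constants(a_constant = 118)),
                 "clamped")
})
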