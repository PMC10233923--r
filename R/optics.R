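# Optical constants shared by both vergence engines. The keratometer index
# 1.3375 converts keratometry to corneal radius (IOLMaster convention); the
# vertex distance of 12 mm refers the refraction to the spectacle plane.
.optical <- list(
  n_aqueous      = 1.336,   # aqueous/vitreous refractive index
  n_cornea_srkt  = 1.333,   # fictitious corneal index used by SRK/T
  n_cornea_haigis = 1.3315, # corneal index used by Haigis for power from radius
  keratometer_index = 1.3375,
  vertex_mm      = 12
)

.check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

#' Construct an ocular biometry record
#'
#' Bundles the six preoperative biometric measurements used throughout the
#' package: axial length (AL), flattest and steepest keratometry (K),
#' anterior chamber depth (ACD, corneal epithelium to lens front surface),
#' lens thickness (LT) and horizontal corneal diameter (CD).
#'
#' @param axial_length axial length in mm; must be positive.
#' @param k_flat,k_steep flattest and steepest keratometry in diopters;
#'   `k_flat <= k_steep` is enforced.
#' @param acd anterior chamber depth in mm (epithelium to lens).
#' @param lt crystalline lens thickness in mm.
#' @param cd horizontal corneal (white-to-white) diameter in mm.
#' @return An object of class `"biometry"` (a named list).
#' @examples
#' biometry(29.2, 43.3, 44.3, 3.4, 4.4, 11.8)
#' @export
biometry <- function(axial_length, k_flat, k_steep, acd, lt, cd) {
  vals <- c(axial_length = axial_length, k_flat = k_flat, k_steep = k_steep,
            acd = acd, lt = lt, cd = cd)
  .check_finite(vals, "biometry fields")
  if (any(vals <= 0)) stop("all biometry fields must be positive", call. = FALSE)
  if (k_flat > k_steep) stop("k_flat must not exceed k_steep", call. = FALSE)
  structure(as.list(vals), class = "biometry")
}

#' @export
print.biometry <- function(x, ...) {
  cat(sprintf(
    "biometry: AL %.2f mm, K %.2f/%.2f D, ACD %.2f mm, LT %.2f mm, CD %.2f mm\n",
    x$axial_length, x$k_flat, x$k_steep, x$acd, x$lt, x$cd))
  invisible(x)
}

#' Construct a set of IOL constants
#'
#' Lens-model calibration constants: the SRK/T A constant and/or the Haigis
#' triple (a0, a1, a2). At least one of the two parameterizations must be
#' supplied; a missing Haigis triple can be derived from A with
#' [convert_a_to_haigis()].
#'
#' @param a_constant SRK/T A constant (dimensionless, typically 110-125).
#' @param a0,a1,a2 Haigis constants (a0 in mm; a1, a2 dimensionless).
#' @return An object of class `"iol_constants"`.
#' @examples
#' iol_constants(a_constant = 118.0)
#' iol_constants(a0 = 1.28, a1 = 0.4, a2 = 0.1)
#' @export
iol_constants <- function(a_constant = NULL, a0 = NULL, a1 = NULL, a2 = NULL) {
  have_a <- !is.null(a_constant)
  have_haigis <- !is.null(a0) && !is.null(a1) && !is.null(a2)
  if (!have_a && !have_haigis) {
    stop("supply a_constant and/or the full Haigis triple (a0, a1, a2)",
         call. = FALSE)
  }
  if (have_a) {
    .check_finite(a_constant, "a_constant")
    if (a_constant < 110 || a_constant > 125) {
      stop("a_constant out of plausible range [110, 125]", call. = FALSE)
    }
  }
  if (have_haigis) .check_finite(c(a0, a1, a2), "Haigis constants")
  structure(list(a_constant = a_constant, a0 = a0, a1 = a1, a2 = a2),
            class = "iol_constants")
}

#' @export
print.iol_constants <- function(x, ...) {
  a <- if (is.null(x$a_constant)) "-" else sprintf("%.2f", x$a_constant)
  h <- if (is.null(x$a0)) "-" else sprintf("%.5f/%.3f/%.3f", x$a0, x$a1, x$a2)
  cat(sprintf("IOL constants: A = %s, Haigis a0/a1/a2 = %s\n", a, h))
  invisible(x)
}

#' Mean keratometry
#'
#' Arithmetic mean of the flat and steep keratometry readings, the corneal
#' power entering both vergence formulas.
#'
#' @param k_flat,k_steep keratometry in diopters, `k_flat <= k_steep`.
#' @return Mean K in diopters.
#' @examples
#' mean_k(43.24, 44.29)
#' @export
mean_k <- function(k_flat, k_steep) {
  .check_finite(c(k_flat, k_steep), "keratometry")
  if (any(k_flat > k_steep)) stop("k_flat must not exceed k_steep", call. = FALSE)
  (k_flat + k_steep) / 2
}

#' Corneal radius of curvature from keratometry
#'
#' Uses the keratometer index 1.3375, i.e. `r = 337.5 / K`.
#'
#' @param k corneal power in diopters.
#' @return Radius in mm.
#' @export
corneal_radius <- function(k) {
  .check_finite(k, "k")
  if (any(k <= 0)) stop("keratometry must be positive", call. = FALSE)
  337.5 / k
}

#' Standardize a spherical equivalent from 5 m to 6 m testing distance
#'
#' Refractions measured at a 5 m lane are referred to 6 m by adding
#' -0.03 D to the spherical equivalent.
#'
#' @param se_at_5m spherical equivalent measured at 5 m, in diopters.
#' @return Spherical equivalent at 6 m, in diopters.
#' @examples
#' standardize_refraction(0)     # -0.03
#' @export
standardize_refraction <- function(se_at_5m) {
  .check_finite(se_at_5m, "se_at_5m")
  se_at_5m - 0.03
}

#' @rdname standardize_refraction
#' @param se_at_6m spherical equivalent at 6 m, in diopters.
#' @export
unstandardize_refraction <- function(se_at_6m) {
  .check_finite(se_at_6m, "se_at_6m")
  se_at_6m + 0.03
}

#' Derive Haigis constants from an SRK/T A constant
#'
#' Standard fallback when a lens model publishes only an A constant:
#' `a0 = 0.62467 * A - 72.434`, `a1 = 0.4`, `a2 = 0.1` (the classical
#' single-optimized parameterization).
#'
#' @param a_constant SRK/T A constant in `[110, 125]`.
#' @return A list with elements `a0`, `a1`, `a2`.
#' @examples
#' convert_a_to_haigis(118.0)  # a0 = 1.27706
#' @export
convert_a_to_haigis <- function(a_constant) {
  .check_finite(a_constant, "a_constant")
  if (any(a_constant < 110 | a_constant > 125)) {
    stop("a_constant out of plausible range [110, 125]", call. = FALSE)
  }
  list(a0 = 0.62467 * a_constant - 72.434, a1 = 0.4, a2 = 0.1)
}

# Resolve a usable Haigis triple, deriving from A when absent.
.resolve_haigis <- function(c) {
  if (!is.null(c$a0) && !is.null(c$a1) && !is.null(c$a2)) {
    list(a0 = c$a0, a1 = c$a1, a2 = c$a2)
  } else if (!is.null(c$a_constant)) {
    convert_a_to_haigis(c$a_constant)
  } else {
    stop("Haigis constants unavailable and no A constant to derive them from",
         call. = FALSE)
  }
}

# ---------------------------------------------------------------------------
# SRK/T vergence engine (vectorized internal kernels)
#
# The published algorithm, step by step: corneal radius from mean K; axial
# length corrected for long eyes (LCOR); corneal width and height; ELP as
# corneal height plus an A-constant-derived offset; retinal thickness
# correction; then a two-surface thin-lens vergence expression giving the
# spectacle-plane refraction at 12 mm vertex.

.srkt_intermediates <- function(al, mk, a_constant) {
  r <- 337.5 / mk
  if (any(r <= 0)) stop("negative corneal radius", call. = FALSE)
  lcor <- ifelse(al <= 24.2, al, -3.446 + 1.716 * al - 0.0237 * al^2)
  cw <- -5.41 + 0.58412 * lcor + 0.098 * mk
  sq_arg <- r^2 - cw^2 / 4
  if (any(sq_arg < 0)) {
    warning("corneal height sqrt argument negative; clamped to 0")
    sq_arg <- pmax(sq_arg, 0)
  }
  h <- r - sqrt(sq_arg)
  acd_const <- 0.62467 * a_constant - 68.747
  offset <- acd_const - 3.336
  elp <- h + offset
  rt <- 0.65696 - 0.02029 * al
  lopt <- al + rt
  if (any(elp >= lopt)) {
    stop("degenerate geometry: ELP not anterior to optical axial length",
         call. = FALSE)
  }
  list(r = r, lcor = lcor, cw = cw, h = h, offset = offset, elp = elp,
       rt = rt, lopt = lopt, mk = mk)
}

# Spectacle refraction as a linear-fractional function of IOL power:
# REF(P) = (N1 - P * N2) / (D1 - 0.001 * P * D2)
.srkt_ref_coefs <- function(im) {
  na <- .optical$n_aqueous
  ncm1 <- .optical$n_cornea_srkt - 1
  v <- .optical$vertex_mm
  n1 <- 1000 * na * (na * im$r - ncm1 * im$lopt)
  n2 <- (im$lopt - im$elp) * (na * im$r - ncm1 * im$elp)
  d1 <- na * (v * (na * im$r - ncm1 * im$lopt) + im$lopt * im$r)
  d2 <- (im$lopt - im$elp) * (v * (na * im$r - ncm1 * im$elp) + im$elp * im$r)
  list(n1 = n1, n2 = n2, d1 = d1, d2 = d2)
}

.srkt_refraction <- function(al, mk, a_constant, power) {
  im <- .srkt_intermediates(al, mk, a_constant)
  cf <- .srkt_ref_coefs(im)
  ref <- (cf$n1 - power * cf$n2) / (cf$d1 - 0.001 * power * cf$d2)
  list(ref = ref, im = im)
}

.srkt_power_for_target <- function(al, mk, a_constant, target) {
  im <- .srkt_intermediates(al, mk, a_constant)
  cf <- .srkt_ref_coefs(im)
  (cf$n1 - target * cf$d1) / (cf$n2 - 0.001 * target * cf$d2)
}

# ---------------------------------------------------------------------------
# Haigis vergence engine
#
# ELP = a0 + a1 * ACD + a2 * AL; corneal power from radius with index
# 1.3315; thin-lens vergence chain in aqueous (n = 1.336), refraction
# referred to the spectacle plane at 12 mm.

.haigis_elp <- function(al, acd, a0, a1, a2) a0 + a1 * acd + a2 * al

.haigis_refraction <- function(al, acd, mk, a0, a1, a2, power) {
  n <- .optical$n_aqueous
  rc <- 337.5 / mk                                   # mm
  dc <- (.optical$n_cornea_haigis - 1) * 1000 / rc   # D
  d <- .haigis_elp(al, acd, a0, a1, a2)              # mm
  if (any(d >= al)) {
    stop("degenerate geometry: ELP not anterior to axial length", call. = FALSE)
  }
  l_m <- al / 1000
  d_m <- d / 1000
  q <- n / (l_m - d_m) - power        # vergence required behind the IOL
  z <- n / (d_m + n / q)              # vergence just behind the cornea
  ref_corneal <- z - dc               # at the corneal plane
  ref <- ref_corneal / (1 + 0.001 * .optical$vertex_mm * ref_corneal)
  list(ref = ref, elp = d, dc = dc)
}

.haigis_power_for_target <- function(al, acd, mk, a0, a1, a2, target) {
  n <- .optical$n_aqueous
  rc <- 337.5 / mk
  dc <- (.optical$n_cornea_haigis - 1) * 1000 / rc
  d <- .haigis_elp(al, acd, a0, a1, a2)
  if (any(d >= al)) {
    stop("degenerate geometry: ELP not anterior to axial length", call. = FALSE)
  }
  l_m <- al / 1000
  d_m <- d / 1000
  ref_corneal <- target / (1 - 0.001 * .optical$vertex_mm * target)
  z <- dc + ref_corneal
  n / (l_m - d_m) - n / (n / z - d_m)
}

# ---------------------------------------------------------------------------
# Public prediction interface

.new_prediction <- function(formula_name, ref, elp, intermediates) {
  structure(list(formula_name = formula_name,
                 predicted_refraction = ref,
                 elp = elp,
                 intermediates = intermediates),
            class = "theoretical_prediction")
}

#' @export
print.theoretical_prediction <- function(x, ...) {
  cat(sprintf("%s prediction: refraction %.3f D (ELP %.3f mm)\n",
              x$formula_name, x$predicted_refraction, x$elp))
  invisible(x)
}

#' Predict spectacle refraction with the SRK/T formula
#'
#' Forward vergence calculation: given biometry, an implanted (or candidate)
#' IOL power and the lens A constant, returns the predicted spectacle-plane
#' spherical equivalent at 12 mm vertex, together with all algorithm
#' intermediates (corneal radius, corrected axial length LCOR, corneal width
#' and height, ELP, retinal thickness, optical axial length).
#'
#' @param b a [biometry()] object.
#' @param iol_power IOL power in diopters.
#' @param c an [iol_constants()] object with `a_constant` present.
#' @return A `"theoretical_prediction"` object.
#' @examples
#' b <- biometry(30, 43, 44, 3.4, 4.4, 11.8)
#' k <- iol_constants(a_constant = 118)
#' srkt_predict_refraction(b, 12, k)
#' @export
srkt_predict_refraction <- function(b, iol_power, c) {
  stopifnot(inherits(b, "biometry"), inherits(c, "iol_constants"))
  .check_finite(iol_power, "iol_power")
  if (is.null(c$a_constant)) stop("SRK/T requires an A constant", call. = FALSE)
  mk <- mean_k(b$k_flat, b$k_steep)
  res <- .srkt_refraction(b$axial_length, mk, c$a_constant, iol_power)
  im <- res$im
  .new_prediction("SRKT", res$ref, im$elp,
                  list(mean_k = im$mk, corneal_radius_r = im$r, lcor = im$lcor,
                       corneal_width_cw = im$cw, corneal_height_h = im$h,
                       retinal_thickness = im$rt, optical_axial_length = im$lopt))
}

#' Predict spectacle refraction with the Haigis formula
#'
#' ELP is the three-constant regression `a0 + a1 * ACD + a2 * AL`; corneal
#' power is derived from the keratometric radius with index 1.3315; the
#' thin-lens vergence chain uses aqueous index 1.336 and a 12 mm vertex.
#'
#' @inheritParams srkt_predict_refraction
#' @param c an [iol_constants()] object; a missing Haigis triple is derived
#'   from the A constant via [convert_a_to_haigis()].
#' @return A `"theoretical_prediction"` object.
#' @examples
#' b <- biometry(30, 43, 44, 3.5, 4.4, 11.8)
#' k <- iol_constants(a0 = 1.0, a1 = 0.4, a2 = 0.1)
#' haigis_predict_refraction(b, 12, k)
#' @export
haigis_predict_refraction <- function(b, iol_power, c) {
  stopifnot(inherits(b, "biometry"), inherits(c, "iol_constants"))
  .check_finite(iol_power, "iol_power")
  h <- .resolve_haigis(c)
  mk <- mean_k(b$k_flat, b$k_steep)
  res <- .haigis_refraction(b$axial_length, b$acd, mk, h$a0, h$a1, h$a2,
                            iol_power)
  .new_prediction("HAIGIS", res$ref, res$elp, list(corneal_power = res$dc))
}

#' IOL power for a target refraction (closed-form vergence inversion)
#'
#' Both vergence formulas are linear-fractional in IOL power, so the power
#' achieving any finite target refraction has a closed form.
#' `srkt_emmetropia_power()` and `haigis_emmetropia_power()` are the
#' zero-target specializations.
#'
#' @inheritParams srkt_predict_refraction
#' @param target target spectacle refraction in diopters.
#' @return IOL power in diopters. An error is raised if the solution falls
#'   outside the manufacturable range `[-10, 40]` D.
#' @examples
#' b <- biometry(28, 43, 44, 3.4, 4.4, 11.8)
#' k <- iol_constants(a_constant = 118)
#' srkt_power_for_target(b, k, target = -3)
#' srkt_emmetropia_power(b, k)
#' @export
srkt_power_for_target <- function(b, c, target = 0) {
  stopifnot(inherits(b, "biometry"), inherits(c, "iol_constants"))
  .check_finite(target, "target")
  if (is.null(c$a_constant)) stop("SRK/T requires an A constant", call. = FALSE)
  mk <- mean_k(b$k_flat, b$k_steep)
  p <- .srkt_power_for_target(b$axial_length, mk, c$a_constant, target)
  .check_power_range(p)
}

#' @rdname srkt_power_for_target
#' @export
haigis_power_for_target <- function(b, c, target = 0) {
  stopifnot(inherits(b, "biometry"), inherits(c, "iol_constants"))
  .check_finite(target, "target")
  h <- .resolve_haigis(c)
  mk <- mean_k(b$k_flat, b$k_steep)
  p <- .haigis_power_for_target(b$axial_length, b$acd, mk, h$a0, h$a1, h$a2,
                                target)
  .check_power_range(p)
}

#' @rdname srkt_power_for_target
#' @export
srkt_emmetropia_power <- function(b, c) srkt_power_for_target(b, c, 0)

#' @rdname srkt_power_for_target
#' @export
haigis_emmetropia_power <- function(b, c) haigis_power_for_target(b, c, 0)

.check_power_range <- function(p) {
  if (any(!is.finite(p)) || any(p < -10) || any(p > 40)) {
    stop("required IOL power outside [-10, 40] D", call. = FALSE)
  }
  p
}
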