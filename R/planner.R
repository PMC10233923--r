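# Clinical forward use: choose the IOL power whose ensemble-predicted
# refraction is closest to the surgeon's target, by exhaustive evaluation
# over the manufacturable power grid.

#' Select the optimal IOL power for a target refraction
#'
#' Evaluates the ensemble's predicted postoperative spherical equivalent at
#' every candidate power on the grid and selects the power whose prediction
#' is closest to the target; ties go to the higher power (the more myopic
#' outcome, the safer surprise for a myopic patient). With
#' `avoid_hyperopic = TRUE` candidates are restricted to predictions at or
#' below the target (no hyperopic surprise); if no candidate qualifies, the
#' most myopic prediction is chosen. No restriction is imposed on the target
#' refraction or the axial length.
#'
#' @param ensemble a [train_ensemble()] fit.
#' @param b a [biometry()] object.
#' @param constants an [iol_constants()] object (or registry lookup result).
#' @param target target spectacle refraction in diopters (default 0).
#' @param grid_min,grid_max,step candidate power grid in diopters
#'   (default -5 to 35 by 0.5, manufacturable increments).
#' @param avoid_hyperopic restrict candidates to predictions <= target.
#' @param registry optional constants registry (unused when `constants`
#'   carries the full set).
#' @return An object of class `"power_plan"`: `selected_power`,
#'   `predicted_refraction`, `target_refraction`, and the full
#'   `candidate_table` (data.frame sorted by power).
#' @export
select_iol_power <- function(ensemble, b, constants, target = 0,
                             grid_min = -5, grid_max = 35, step = 0.5,
                             avoid_hyperopic = FALSE, registry = NULL) {
  stopifnot(inherits(b, "biometry"))
  .check_finite(target, "target")
  if (step <= 0) stop("grid step must be positive", call. = FALSE)
  if (grid_min > grid_max) stop("empty power grid", call. = FALSE)
  powers <- seq(grid_min, grid_max, by = step)

  k <- if (inherits(constants, "iol_constants") || is.list(constants)) {
    constants
  } else {
    stop("constants must be an iol_constants object or list", call. = FALSE)
  }
  h <- .resolve_haigis(k)
  if (is.null(k$a_constant)) {
    stop("planner requires an A constant for the SRK/T feature", call. = FALSE)
  }
  pseudo <- data.frame(case_id = "PLAN", al_mm = b$axial_length,
                       k_flat_d = b$k_flat, k_steep_d = b$k_steep,
                       acd_mm = b$acd, lt_mm = b$lt, cd_mm = b$cd,
                       lens_model = "PLAN", iol_power_d = NA_real_,
                       postop_se_d = NA_real_,
                       a_constant = k$a_constant,
                       a0 = h$a0, a1 = h$a1, a2 = h$a2,
                       stringsAsFactors = FALSE)
  cases <- pseudo[rep(1L, length(powers)), , drop = FALSE]
  pred <- predict_se(ensemble, cases, iol_power = powers, registry = registry)

  cand <- data.frame(power = powers, predicted_refraction = pred)
  pool <- if (avoid_hyperopic && any(pred <= target)) {
    which(pred <= target)
  } else {
    seq_along(powers)
  }
  dev <- abs(pred[pool] - target)
  best <- pool[dev == min(dev)]
  sel <- max(powers[best])   # tie -> higher power (more myopic)
  structure(list(selected_power = sel,
                 predicted_refraction = pred[match(sel, powers)],
                 target_refraction = target,
                 candidate_table = cand),
            class = "power_plan")
}

#' @export
print.power_plan <- function(x, ...) {
  cat(sprintf("target %+.2f D -> IOL power %.1f D (predicted %+.3f D)\n",
              x$target_refraction, x$selected_power, x$predicted_refraction))
  cat(nrow(x$candidate_table), "candidate powers evaluated on the grid\n")
  invisible(x)
}
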