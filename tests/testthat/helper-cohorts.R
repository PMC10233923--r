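# Shared fixtures built in code.

# A minimal hand-written cohort row in the documented CSV schema.
make_record <- function(al = 28, k_flat = 43, k_steep = 44, acd = 3.4,
                        lt = 4.4, cd = 11.8, power = 10, se = -3,
                        bcva = 0.05, id = "C1") {
  data.frame(case_id = id, al_mm = al, k_flat_d = k_flat, k_steep_d = k_steep,
             acd_mm = acd, lt_mm = lt, cd_mm = cd, lens_model = "GENERIC-118",
             iol_power_d = power, postop_se_d = se,
             postop_bcva_logmar = bcva, a_constant = 118,
             a0 = 1.27706, a1 = 0.4, a2 = 0.1, stringsAsFactors = FALSE)
}

# Small generated cohort, memoised per (n, seed, noise) to keep the suite fast.
local({
  cache <- new.env()
  small_cohort <<- function(n = 200, seed = 7, noise_sd = 0.3) {
    key <- paste(n, seed, noise_sd)
    if (is.null(cache[[key]])) {
      cache[[key]] <- suppressWarnings(
        generate_cohort(cohort_spec(n = n, seed = seed, noise_sd = noise_sd)))
    }
    cache[[key]]
  }
})

# A quick-to-train ensemble on a small cohort (reduced boosting rounds).
fast_hyper <- list(GRADIENT_BOOSTED_TREES = list(nrounds = 120))

# Generated cohorts legitimately contain a few extreme eyes where SRK/T
# clamps its corneal-height square root (with a warning, by design); these
# wrappers keep that expected condition out of unrelated assertions.
quiet_train <- function(...) suppressWarnings(train_ensemble(...))
quiet_predict <- function(...) suppressWarnings(predict_se(...))
quiet_features <- function(...) suppressWarnings(build_features(...))
quiet_submodel <- function(...) suppressWarnings(train_submodel(...))
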