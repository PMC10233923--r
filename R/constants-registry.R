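# Lens-constant registry: maps lens-model names to their SRK/T A constant
# and Haigis triple. Constants are user-supplied (typically manufacturer or
# optimized values); a missing Haigis triple is derived from A.

#' Load a lens-constants registry
#'
#' Reads a CSV with columns `lens_model`, `a_constant` and optionally `a0`,
#' `a1`, `a2`. Rows lacking the Haigis triple fall back to
#' [convert_a_to_haigis()] at lookup time, with a notice.
#'
#' @param path path to the registry CSV. The default points to the small
#'   example registry shipped with the package (synthetic, illustrative
#'   values — not optimized clinical constants).
#' @return An object of class `"constants_registry"`.
#' @export
constants_registry <- function(path = system.file("extdata",
                                                  "lens_constants_synthetic.csv",
                                                  package = "hmiol")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lens_model", "a_constant") %in% names(df))) {
    stop("registry must have lens_model and a_constant columns", call. = FALSE)
  }
  for (col in c("a0", "a1", "a2")) if (!col %in% names(df)) df[[col]] <- NA_real_
  structure(df, class = c("constants_registry", "data.frame"))
}

#' Look up constants for a lens model
#'
#' @param registry a [constants_registry()].
#' @param lens_model lens-model name as it appears in the cohort.
#' @return An [iol_constants()]-compatible list with `a_constant`, `a0`,
#'   `a1`, `a2` all populated.
#' @export
lookup_constants <- function(registry, lens_model) {
  i <- match(lens_model, registry$lens_model)
  if (is.na(i)) stop("lens model not in registry: ", lens_model, call. = FALSE)
  row <- registry[i, ]
  if (any(is.na(c(row$a0, row$a1, row$a2)))) {
    message("Haigis constants for '", lens_model,
            "' derived from A constant")
    h <- convert_a_to_haigis(row$a_constant)
    row$a0 <- h$a0; row$a1 <- h$a1; row$a2 <- h$a2
  }
  list(a_constant = row$a_constant, a0 = row$a0, a1 = row$a1, a2 = row$a2)
}
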