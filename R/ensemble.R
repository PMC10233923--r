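# The assembled prediction model: four sub-models — gradient-boosted trees
# (xgboost) and RBF-kernel support vector regression (e1071), each trained on
# two feature sets — combined by a weighted average. The training target is
# the actual postoperative spherical equivalent; the theoretical Haigis and
# SRK/T outputs enter as features, so the learners model the residual
# structure the vergence formulas miss in long eyes.

.learners <- c("GRADIENT_BOOSTED_TREES", "KERNEL_SVR")
.feature_sets <- c("SET1", "SET2")
.ensemble_version <- "hmiol-ensemble-1"

#' Default sub-model hyperparameters
#'
#' Conservative, reproducibility-oriented defaults: boosted trees with depth
#' 4, 300 rounds at learning rate 0.05; SVR with an RBF kernel, `C = 10`,
#' `epsilon = 0.1` and internally standardized features (tree learners are
#' scale-invariant and use raw features).
#'
#' @param learner `"GRADIENT_BOOSTED_TREES"` or `"KERNEL_SVR"`.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(learner = .learners) {
  learner <- match.arg(learner)
  if (learner == "GRADIENT_BOOSTED_TREES") {
    list(max_depth = 4, nrounds = 300, eta = 0.05, nthread = 1)
  } else {
    list(cost = 10, epsilon = 0.1, kernel = "radial")
  }
}

#' Specify one ensemble sub-model
#'
#' @param learner `"GRADIENT_BOOSTED_TREES"` or `"KERNEL_SVR"`.
#' @param feature_set `"SET1"` or `"SET2"`.
#' @param hyperparameters named list overriding [default_hyperparameters()].
#' @param seed integer seed for the fit.
#' @return An object of class `"submodel_spec"`.
#' @export
submodel_spec <- function(learner = .learners, feature_set = .feature_sets,
                          hyperparameters = list(), seed = 1L) {
  learner <- match.arg(learner)
  feature_set <- match.arg(feature_set)
  hp <- utils::modifyList(default_hyperparameters(learner), hyperparameters)
  structure(list(learner = learner, feature_set = feature_set,
                 hyperparameters = hp, seed = as.integer(seed)),
            class = "submodel_spec")
}

#' The four canonical sub-model specifications
#'
#' Both learner families crossed with both feature sets.
#'
#' @inheritParams submodel_spec
#' @param hyperparameters list with optional elements
#'   `GRADIENT_BOOSTED_TREES` and `KERNEL_SVR`, each a named override list.
#' @return List of four [submodel_spec()] objects.
#' @export
full_ensemble_specs <- function(hyperparameters = list(), seed = 1L) {
  out <- list()
  for (fs in .feature_sets) {
    for (le in .learners) {
      out[[paste(le, fs, sep = ".")]] <-
        submodel_spec(le, fs, hyperparameters[[le]] %||% list(), seed)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train one sub-model
#'
#' Fits the requested learner on the requested feature set, with the
#' postoperative spherical equivalent as target. Deterministic under the
#' spec's seed.
#'
#' @param train_cohort training cohort data.frame (>= 50 cases).
#' @param spec a [submodel_spec()].
#' @param registry optional [constants_registry()] for lens-constant lookup.
#' @return An object of class `"hmiol_submodel"`.
#' @export
train_submodel <- function(train_cohort, spec, registry = NULL) {
  stopifnot(inherits(spec, "submodel_spec"))
  if (nrow(train_cohort) < 50) {
    stop("at least 50 training cases required", call. = FALSE)
  }
  y <- train_cohort$postop_se_d
  if (stats::sd(y) < .Machine$double.eps) {
    # degenerate target: the only consistent predictor is the constant itself
    return(structure(list(spec = spec, constant = y[1],
                          schema = feature_schema(spec$feature_set)),
                     class = "hmiol_submodel"))
  }
  x <- build_features(train_cohort, spec$feature_set, registry)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  hp <- spec$hyperparameters
  fit <- if (spec$learner == "GRADIENT_BOOSTED_TREES") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    xgboost::xgb.train(
      params = list(max_depth = hp$max_depth, eta = hp$eta,
                    nthread = hp$nthread, objective = "reg:squarederror"),
      data = dtrain, nrounds = hp$nrounds, verbose = 0)
  } else {
    # standardize non-degenerate columns only (constant columns cannot scale)
    e1071::svm(x, y, type = "eps-regression", kernel = hp$kernel,
               cost = hp$cost, epsilon = hp$epsilon,
               scale = apply(x, 2, stats::sd) > 0)
  }
  structure(list(spec = spec, fit = fit,
                 schema = feature_schema(spec$feature_set)),
            class = "hmiol_submodel")
}

.predict_submodel <- function(sm, x) {
  if (!is.null(sm$constant)) return(rep(sm$constant, nrow(x)))
  if (!identical(colnames(x), sm$schema)) {
    stop("feature schema mismatch for sub-model prediction", call. = FALSE)
  }
  if (sm$spec$learner == "GRADIENT_BOOSTED_TREES") {
    stats::predict(sm$fit, xgboost::xgb.DMatrix(x))
  } else {
    unname(stats::predict(sm$fit, x))
  }
}

#' Combination weights from validation errors
#'
#' Weights proportional to the inverse validation mean absolute error of each
#' sub-model, normalized to sum to one; `"EQUAL"` mode returns uniform
#' weights. A sub-model with zero validation MAE receives the whole weight
#' (indicator fallback).
#'
#' @param validation_mae numeric vector of per-sub-model validation MAEs (D).
#' @param mode `"INVERSE_MAE"` or `"EQUAL"`.
#' @return Numeric weight vector (non-negative, sums to 1), named like
#'   `validation_mae`.
#' @examples
#' weights_from_mae(c(0.2, 0.2, 0.4, 0.4))  # 1/3, 1/3, 1/6, 1/6
#' @export
weights_from_mae <- function(validation_mae, mode = c("INVERSE_MAE", "EQUAL")) {
  mode <- match.arg(mode)
  k <- length(validation_mae)
  if (mode == "EQUAL") {
    w <- rep(1 / k, k)
  } else if (any(validation_mae == 0)) {
    w <- as.numeric(validation_mae == 0)
    w <- w / sum(w)
  } else {
    w <- (1 / validation_mae) / sum(1 / validation_mae)
  }
  names(w) <- names(validation_mae)
  w
}

#' Combination weights from a validation cohort
#'
#' Evaluates each fitted sub-model on a validation cohort disjoint from its
#' training data and converts the MAEs to weights via [weights_from_mae()].
#'
#' @param sub_models list of [train_submodel()] fits.
#' @param validation_cohort validation cohort data.frame.
#' @param registry optional constants registry.
#' @param mode weight mode, see [weights_from_mae()].
#' @return Named weight vector.
#' @export
fit_weights <- function(sub_models, validation_cohort, registry = NULL,
                        mode = c("INVERSE_MAE", "EQUAL")) {
  mae <- vapply(sub_models, function(sm) {
    x <- build_features(validation_cohort, sm$spec$feature_set, registry)
    mean(abs(validation_cohort$postop_se_d - .predict_submodel(sm, x)))
  }, numeric(1))
  weights_from_mae(mae, match.arg(mode))
}

#' Train the assembled four-sub-model ensemble
#'
#' Trains both learner families on both feature sets, derives combination
#' weights from out-of-fold validation MAEs (an internal k-fold scheme on the
#' training cohort, so every validation fold is disjoint from the folds used
#' to fit it), then refits each sub-model on the full training cohort.
#'
#' @param train_cohort training cohort data.frame.
#' @param weight_mode `"INVERSE_MAE"` (default) or `"EQUAL"`.
#' @param k_folds folds for the internal validation scheme (default 5).
#' @param seed integer seed governing fold assignment and sub-model fits.
#' @param hyperparameters per-learner override list, see
#'   [full_ensemble_specs()].
#' @param registry optional constants registry.
#' @return An object of class `"trained_ensemble"`.
#' @export
train_ensemble <- function(train_cohort,
                           weight_mode = c("INVERSE_MAE", "EQUAL"),
                           k_folds = 5L, seed = 1L,
                           hyperparameters = list(), registry = NULL) {
  weight_mode <- match.arg(weight_mode)
  specs <- full_ensemble_specs(hyperparameters, seed)
  n <- nrow(train_cohort)

  if (weight_mode == "INVERSE_MAE") {
    old <- .Random.seed_exists()
    set.seed(seed)
    fold <- sample(rep_len(seq_len(k_folds), n))
    .restore_seed(old)
    oof_mae <- vapply(specs, function(sp) {
      err <- numeric(0)
      for (f in seq_len(k_folds)) {
        sm <- train_submodel(train_cohort[fold != f, , drop = FALSE], sp,
                             registry)
        hold <- train_cohort[fold == f, , drop = FALSE]
        x <- build_features(hold, sp$feature_set, registry)
        err <- c(err, abs(hold$postop_se_d - .predict_submodel(sm, x)))
      }
      mean(err)
    }, numeric(1))
    weights <- weights_from_mae(oof_mae)
  } else {
    oof_mae <- NULL
    weights <- weights_from_mae(stats::setNames(rep(1, length(specs)),
                                                names(specs)), mode = "EQUAL")
  }

  sub_models <- lapply(specs, train_submodel, train_cohort = train_cohort,
                       registry = registry)
  structure(list(sub_models = sub_models, weights = weights,
                 feature_schema = list(SET1 = feature_schema("SET1"),
                                       SET2 = feature_schema("SET2")),
                 training_metadata = list(
                   n_train = n, seed = seed, weight_mode = weight_mode,
                   k_folds = k_folds, oof_mae = oof_mae,
                   cohort_hash = .cohort_checksum(train_cohort),
                   trained_at = format(Sys.time(), tz = "UTC"),
                   version = .ensemble_version)),
            class = "trained_ensemble")
}

.cohort_checksum <- function(cohort) {
  num <- vapply(cohort, is.numeric, logical(1))
  sums <- vapply(cohort[num], function(col) sum(as.numeric(col)), numeric(1))
  paste0(nrow(cohort), ":", ncol(cohort), ":",
         format(sum(sums), digits = 17))
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat("Assembled IOL refraction model (", length(x$sub_models),
      " sub-models)\n", sep = "")
  for (nm in names(x$sub_models)) {
    cat(sprintf("  %-35s weight %.4f\n", nm, x$weights[[nm]]))
  }
  cat("trained on", x$training_metadata$n_train, "eyes; weight mode",
      x$training_metadata$weight_mode, "\n")
  invisible(x)
}

#' Predict postoperative spherical equivalent
#'
#' The weighted average of the four sub-model predictions. Features are
#' recomputed at the queried IOL power — the theoretical Haigis/SRK/T feature
#' entries depend on it — so the same ensemble answers both "what refraction
#' did the implanted lens produce?" and "what would candidate power P give?".
#'
#' @param ensemble a [train_ensemble()] fit.
#' @param cases cohort data.frame (one or more rows).
#' @param iol_power optional power(s) in diopters overriding the implanted
#'   power column; must lie in `[-10, 40]`.
#' @param registry optional constants registry.
#' @return Numeric vector of predicted spherical equivalents (D).
#' @export
predict_se <- function(ensemble, cases, iol_power = NULL, registry = NULL) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  if (!is.null(iol_power)) {
    .check_finite(iol_power, "iol_power")
    if (any(iol_power < -10 | iol_power > 40)) {
      stop("iol_power outside [-10, 40] D", call. = FALSE)
    }
  }
  x_by_set <- list(
    SET1 = build_features(cases, "SET1", registry, iol_power),
    SET2 = build_features(cases, "SET2", registry, iol_power))
  pred <- rep(0, nrow(cases))
  for (nm in names(ensemble$sub_models)) {
    sm <- ensemble$sub_models[[nm]]
    pred <- pred +
      ensemble$weights[[nm]] * .predict_submodel(sm, x_by_set[[sm$spec$feature_set]])
  }
  pred
}

#' Persist / restore a trained ensemble
#'
#' The artifact is a single portable file embedding a version tag, the
#' feature schema, the combination weights and the serialized sub-models
#' (boosted trees as their raw byte representation). A save/load round trip
#' reproduces predictions bit-exactly; files with a foreign version tag or a
#' tampered schema are rejected.
#'
#' @param ensemble a [train_ensemble()] fit.
#' @param path file path for the artifact.
#' @return `save_ensemble` returns `path` invisibly; `load_ensemble` returns
#'   the restored `"trained_ensemble"`.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  portable <- ensemble
  portable$sub_models <- lapply(ensemble$sub_models, function(sm) {
    if (is.null(sm$constant) &&
        sm$spec$learner == "GRADIENT_BOOSTED_TREES") {
      sm$fit <- xgboost::xgb.save.raw(sm$fit)
      sm$fit_format <- "xgb_raw"
    }
    sm
  })
  saveRDS(portable, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("not a readable ensemble artifact: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) ||
      !identical(obj$training_metadata$version, .ensemble_version)) {
    stop("ensemble artifact version mismatch or corrupt file", call. = FALSE)
  }
  expected <- list(SET1 = feature_schema("SET1"), SET2 = feature_schema("SET2"))
  if (!identical(obj$feature_schema, expected)) {
    stop("ensemble artifact feature schema does not match this package",
         call. = FALSE)
  }
  obj$sub_models <- lapply(obj$sub_models, function(sm) {
    if (identical(sm$fit_format, "xgb_raw")) {
      sm$fit <- xgboost::xgb.load.raw(sm$fit)
      sm$fit_format <- NULL
    }
    sm
  })
  class(obj) <- "trained_ensemble"
  obj
}
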