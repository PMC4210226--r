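#' Pipeline configuration
#'
#' Collects the tunable parameters of the encoders and the class-weighted SVM.
#'
#' @param cost Soft-margin cost C (default 1).
#' @param gamma RBF kernel width; `NULL` means `1/d` with d the number of
#'   selected features.
#' @param kernel SVM kernel (default `"radial"`).
#' @param class_weight `"balanced"` (positive class weighted by
#'   `n_negative / n_positive`) or a single numeric weight for the positive
#'   class.
#' @param threshold Decision threshold on the calibrated probability.
#' @param sigma_mode,frequency_mode Propensity-matrix options, see
#'   [build_propensity_matrices()].
#' @param knn_clamp Clamp KNN neighbour counts when references are scarce.
#' @return A `carb_config` list.
#' @export
carb_config <- function(cost = 1, gamma = NULL, kernel = "radial",
                        class_weight = "balanced", threshold = 0.5,
                        sigma_mode = "difference", frequency_mode = "count",
                        knn_clamp = FALSE) {
  structure(list(
    cost = cost, gamma = gamma, kernel = kernel,
    class_weight = class_weight, threshold = threshold,
    sigma_mode = sigma_mode, frequency_mode = frequency_mode,
    knn_clamp = knn_clamp
  ), class = "carb_config")
}

# min-max scaling learned on training rows; constant features map to 0
fit_scaler <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$lo), 2, scaler$rng, "/")
}

label_factor <- function(labels) {
  factor(labels, levels = c("negative", "positive"))
}

#' Train a class-weighted RBF support vector machine
#'
#' Fits a soft-margin SVM with the positive class weighted by
#' `n_negative / n_positive` (imbalance compensation) and probability
#' calibration enabled. Features are min-max scaled to \[0, 1\] with
#' parameters learned from the training rows. Deterministic for a fixed seed.
#'
#' @param feature_matrix Numeric matrix of training features (already
#'   restricted to the selected set).
#' @param labels `positive`/`negative` labels.
#' @param config A [carb_config()].
#' @param seed Integer seed (probability-calibration shuffling).
#' @return A `carb_wsvm` fit (svm model + scaler + weights).
#' @export
train_wsvm <- function(feature_matrix, labels, config = carb_config(), seed = 1L) {
  y <- label_factor(labels)
  if (nlevels(droplevels(y)) < 2) abort("training data must contain both classes")
  x <- as.matrix(feature_matrix)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  w_pos <- if (identical(config$class_weight, "balanced")) {
    sum(y == "negative") / sum(y == "positive")
  } else {
    as.numeric(config$class_weight)
  }
  gamma <- config$gamma %||% (1 / ncol(xs))
  fit <- withr::with_seed(seed, e1071::svm(
    x = xs, y = y,
    kernel = config$kernel, cost = config$cost, gamma = gamma,
    class.weights = c(negative = 1, positive = w_pos),
    probability = TRUE, scale = FALSE
  ))
  structure(list(
    svm = fit, scaler = scaler, positive_weight = w_pos,
    gamma = gamma, config = config, seed = seed,
    feature_names = colnames(x)
  ), class = "carb_wsvm")
}

# positive-class probabilities for a feature matrix
predict_wsvm <- function(fit, feature_matrix) {
  xs <- apply_scaler(as.matrix(feature_matrix), fit$scaler)
  pred <- predict(fit$svm, xs, probability = TRUE)
  attr(pred, "probabilities")[, "positive"]
}

#' Train a carbonylation-site model end to end
#'
#' Builds the encoder context from all training windows, assembles the
#' candidate features, optionally ranks them (mRMR) and prunes them by
#' incremental feature selection, then fits the final class-weighted SVM.
#'
#' @param windows Training window tibble (`label` in `positive`/`negative`).
#' @param selection `"none"` (all candidate features), `"top_k"` (first
#'   `k` mRMR features) or `"ifs"` (dimension chosen by the CV-MCC curve).
#' @param k Prefix size for `selection = "top_k"`; for `"ifs"`, the largest
#'   prefix evaluated (default: all).
#' @param folds CV folds used by IFS.
#' @param seed Integer seed.
#' @param config A [carb_config()].
#' @return A `carb_model` containing the encoder context, selected features,
#'   the SVM fit, and (when computed) the ranking and IFS curve.
#' @export
carb_train <- function(windows, selection = c("none", "top_k", "ifs"), k = NULL,
                       folds = 10L, seed = 1L, config = carb_config()) {
  selection <- match.arg(selection)
  context <- build_encoder_context(windows,
    sigma_mode = config$sigma_mode, frequency_mode = config$frequency_mode
  )
  x <- assemble_features(windows, context,
    exclude_self = TRUE, knn_clamp = config$knn_clamp
  )
  ranking <- NULL
  ifs <- NULL
  if (selection == "none") {
    feats <- seq_len(ncol(x))
  } else {
    ranking <- mrmr_rank(x, windows$label)
    if (selection == "top_k") {
      if (is.null(k)) abort("k is required for selection = 'top_k'")
      feats <- ranking$feature[seq_len(k)]
    } else {
      k_values <- seq_len(min(k %||% nrow(ranking), nrow(ranking)))
      ifs <- ifs_select(windows, ranking,
        k_values = k_values, folds = folds,
        seed = seed, config = config
      )
      feats <- ifs$chosen_features
    }
  }
  fit <- train_wsvm(x[, feats, drop = FALSE], windows$label, config, seed)
  structure(list(
    format_version = "1",
    residue = context$residue,
    n = context$n,
    feature_indices = feats,
    feature_names = colnames(x)[feats],
    context = context,
    fit = fit,
    ranking = ranking,
    ifs = ifs,
    config = config,
    threshold = config$threshold,
    seed = seed
  ), class = "carb_model")
}

#' @export
print.carb_model <- function(x, ...) {
  cat(sprintf(
    "<carb_model> residue %s, n = %d, %d selected features, positive weight %.3f\n",
    x$residue, x$n, length(x$feature_indices), x$fit$positive_weight
  ))
  invisible(x)
}

#' Score candidate-site windows with a trained model
#'
#' Windows are encoded with the model's stored encoder context (so training
#' data, not the query, defines every feature) and scored by the calibrated
#' SVM. Windows whose centre residue does not match the model's residue type
#' are skipped with a warning.
#'
#' @param model A `carb_model`.
#' @param windows Window tibble (length `2n + 1` sequences).
#' @return Prediction tibble: `protein_id`, `position`, `residue`,
#'   `probability`, `call` (probability at or above the model threshold).
#' @export
predict_probability <- function(model, windows) {
  keep <- windows$residue == model$residue
  if (any(!keep)) {
    warn(sprintf("%d window(s) skipped: centre residue does not match model residue %s",
      sum(!keep), model$residue))
  }
  w <- windows[keep, , drop = FALSE]
  if (nrow(w) == 0) {
    return(tibble::tibble(
      protein_id = character(), position = integer(), residue = character(),
      probability = numeric(), call = logical()
    ))
  }
  x <- assemble_features(w, model$context,
    exclude_self = FALSE, knn_clamp = model$config$knn_clamp
  )
  p <- predict_wsvm(model$fit, x[, model$feature_indices, drop = FALSE])
  tibble::tibble(
    protein_id = w$protein_id,
    position = as.integer(w$position),
    residue = w$residue,
    probability = unname(p),
    call = unname(p) >= model$threshold
  )
}

#' @export
tidy.carb_model <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_indices,
    name = x$feature_names,
    group = as.character(feature_groups(x$feature_names)),
    relevance = if (!is.null(x$ranking)) {
      x$ranking$relevance[match(x$feature_indices, x$ranking$feature)]
    } else {
      NA_real_
    }
  )
}

#' @export
glance.carb_model <- function(x, ...) {
  tibble::tibble(
    residue = x$residue, n = x$n,
    n_features = length(x$feature_indices),
    positive_weight = x$fit$positive_weight,
    cost = x$fit$config$cost, gamma = x$fit$gamma,
    threshold = x$threshold, format_version = x$format_version
  )
}

MODEL_FORMAT_VERSION <- "1"
MODEL_REQUIRED_FIELDS <- c(
  "format_version", "residue", "n", "feature_indices", "feature_names",
  "context", "fit", "config", "threshold", "seed"
)

#' Save / load a trained model archive
#'
#' The archive is a single-file serialized container holding every
#' `carb_model` field (encoder context included) plus the format version;
#' loading verifies the version and the presence of all fields, so
#' `load_model(save_model(m))` reproduces predictions exactly.
#'
#' @param model A `carb_model`.
#' @param path Archive path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `carb_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "carb_model")) abort("model must be a carb_model")
  saveRDS(unclass(model), path, version = 2)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model archive not found: %s", path))
  obj <- readRDS(path)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    abort(sprintf(
      "model archive format version %s; this loader reads version %s",
      obj$format_version %||% "<missing>", MODEL_FORMAT_VERSION
    ))
  }
  missing <- setdiff(MODEL_REQUIRED_FIELDS, names(obj))
  if (length(missing) > 0) {
    abort(sprintf("model archive is missing field(s): %s", paste(missing, collapse = ", ")))
  }
  structure(obj, class = "carb_model")
}
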