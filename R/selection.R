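#' Discretize feature columns into three bins
#'
#' Per column, values below `mean - sd` map to bin 0, values above `mean + sd`
#' to bin 2, the rest to bin 1 (the convention of the mRMR literature).
#' Constant columns map to a single bin 0.
#'
#' @param feature_matrix Numeric matrix, one column per feature.
#' @return Integer matrix of the same shape with values in 0..2.
#' @export
discretize_features <- function(feature_matrix) {
  m <- as.matrix(feature_matrix)
  mu <- colMeans(m)
  s <- sqrt(colMeans(sweep(m, 2, mu)^2))
  out <- base::matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m))
  lo <- sweep(m, 2, mu - s, "<")
  hi <- sweep(m, 2, mu + s, ">")
  out[lo] <- 0L
  out[hi] <- 2L
  out[, s == 0] <- 0L
  out
}

# plug-in MI from integer codes (any small alphabets), natural log
mi_codes <- function(a, b, la, lb) {
  n <- length(a)
  joint <- tabulate((a - 1L) * lb + b, la * lb) / n
  pa <- tabulate(a, la) / n
  pb <- tabulate(b, lb) / n
  pp <- outer(pa, pb)
  j <- joint > 0
  sum(joint[j] * log(joint[j] / as.vector(t(pp))[j]))
}

#' Plug-in mutual information of two discrete vectors
#'
#' Estimated from the joint contingency table with natural logarithms.
#'
#' @param x_discrete,y_discrete Equal-length vectors of discrete codes.
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(x_discrete, y_discrete) {
  if (length(x_discrete) != length(y_discrete)) abort("vectors must have equal length")
  a <- as.integer(factor(x_discrete))
  b <- as.integer(factor(y_discrete))
  mi_codes(a, b, max(a), max(b))
}

#' Rank features by minimum redundancy, maximum relevance
#'
#' Greedy mutual-information difference (MID) scheme: the first feature
#' maximizes relevance MI(f, label); each subsequent feature maximizes
#' relevance minus the mean MI with the already selected features. The
#' quotient (MIQ) scheme is available via `method`. Ties break by feature
#' index.
#'
#' @param features Numeric feature matrix (discretized internally via
#'   [discretize_features()] unless already integer).
#' @param labels Binary label vector (`positive`/`negative`, logical, or 0/1).
#' @param method `"MID"` (default) or `"MIQ"`.
#' @param max_rank Number of features to place in the ranking (default: all).
#' @return A `carb_ranking` tibble with columns `rank`, `feature` (index),
#'   `name`, `relevance` (MI with label) and `score` (mRMR objective at
#'   selection time).
#' @export
mrmr_rank <- function(features, labels, method = c("MID", "MIQ"), max_rank = NULL) {
  method <- match.arg(method)
  m <- as.matrix(features)
  d <- ncol(m)
  if (d == 0) abort("no features to rank")
  disc <- if (is.integer(m)) m else discretize_features(m)
  disc <- disc + 1L
  levs <- apply(disc, 2, max)
  y <- as.integer(factor(labels))
  ly <- max(y)
  rel <- vapply(seq_len(d), function(j) mi_codes(disc[, j], y, levs[j], ly), numeric(1))
  k <- min(max_rank %||% d, d)

  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(d)
  remaining <- rep(TRUE, d)
  for (step in seq_len(k)) {
    obj <- if (step == 1) {
      rel
    } else if (method == "MID") {
      rel - red_sum / length(selected)
    } else {
      rel / pmax(red_sum / length(selected), 1e-12)
    }
    obj[!remaining] <- -Inf
    pick <- which.max(obj) # which.max takes the first (smallest index) on ties
    selected <- c(selected, pick)
    scores <- c(scores, obj[pick])
    remaining[pick] <- FALSE
    if (step < k) {
      idx <- which(remaining)
      red_sum[idx] <- red_sum[idx] + vapply(
        idx,
        function(j) mi_codes(disc[, j], disc[, pick], levs[j], levs[pick]),
        numeric(1)
      )
    }
  }
  out <- tibble::tibble(
    rank = seq_along(selected),
    feature = selected,
    name = colnames(m)[selected] %||% as.character(selected),
    relevance = rel[selected],
    score = scores
  )
  class(out) <- c("carb_ranking", class(out))
  out
}

#' Incremental feature selection on the cross-validated MCC curve
#'
#' For each prefix size k of the mRMR ranking, runs the fold-aware
#' cross-validation with the top-k features and records the average per-fold
#' Matthews correlation coefficient. The chosen dimension is the curve's
#' argmax, smallest k on ties.
#'
#' @param dataset Window tibble (`label` in `positive`/`negative`), in which
#'   case the encoder contexts are rebuilt per fold; or a plain numeric
#'   feature matrix (then `labels` is required and the features are used
#'   as-is).
#' @param ranking A `carb_ranking` from [mrmr_rank()] over the candidate
#'   features of this dataset.
#' @param k_values Prefix sizes to evaluate (default: 1..`nrow(ranking)`).
#' @param folds Number of CV folds.
#' @param seed Integer seed (fold assignment and classifier).
#' @param config Classifier/encoder configuration from [carb_config()].
#' @param labels Labels when `dataset` is a feature matrix.
#' @return A `carb_ifs` object: tibble `curve` (`k`, `mcc`), `chosen_dimension`,
#'   `chosen_features` (indices into the candidate feature order).
#' @export
ifs_select <- function(dataset, ranking, k_values = NULL, folds = 10L,
                       seed = 1L, config = carb_config(), labels = NULL) {
  k_values <- sort(unique(k_values %||% seq_len(nrow(ranking))))
  if (max(k_values) > nrow(ranking)) abort("k_values exceed the ranking length")
  fold_data <- if (is.matrix(dataset)) {
    if (is.null(labels)) abort("labels are required when dataset is a feature matrix")
    matrix_cv_folds(dataset, labels, folds = folds, seed = seed)
  } else {
    encode_cv_folds(dataset, folds = folds, seed = seed, config = config)
  }
  mcc <- vapply(k_values, function(k) {
    feats <- ranking$feature[seq_len(k)]
    res <- cv_fit_score(fold_data, feats, config = config, seed = seed)
    mean(res$per_fold$mcc)
  }, numeric(1))
  curve <- tibble::tibble(k = k_values, mcc = mcc)
  chosen <- k_values[which.max(mcc)]
  structure(list(
    curve = curve,
    chosen_dimension = chosen,
    chosen_features = ranking$feature[seq_len(chosen)],
    n = if (is.matrix(dataset)) NA_integer_ else attr(dataset, "n") %||% window_half_width(dataset)
  ), class = "carb_ifs")
}

# fold splits over a fixed feature matrix (no per-fold re-encoding)
matrix_cv_folds <- function(x, labels, folds = 10L, seed = 1L) {
  ds <- tibble::tibble(
    protein_id = sprintf("row%05d", seq_len(nrow(x))),
    position = 1L, residue = "K", label = labels
  )
  ds <- stratified_folds(ds, k = folds, seed = seed)
  purrr::map(seq_len(folds), function(f) {
    tr <- ds$.fold != f
    list(
      fold = f,
      train_x = x[tr, , drop = FALSE], train_y = labels[tr],
      test_x = x[!tr, , drop = FALSE], test = ds[!tr, , drop = FALSE]
    )
  })
}

#' @export
print.carb_ifs <- function(x, ...) {
  cat(sprintf(
    "<carb_ifs> chosen dimension %d (peak mean MCC %.4f) over %d evaluated sizes\n",
    x$chosen_dimension, max(x$curve$mcc), nrow(x$curve)
  ))
  invisible(x)
}

#' @export
tidy.carb_ifs <- function(x, ...) x$curve

#' @export
glance.carb_ifs <- function(x, ...) {
  tibble::tibble(
    chosen_dimension = x$chosen_dimension,
    peak_mcc = max(x$curve$mcc),
    n_evaluated = nrow(x$curve)
  )
}
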