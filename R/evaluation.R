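#' Confusion-matrix metrics
#'
#' Specificity `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, total accuracy and the
#' Matthews correlation coefficient. MCC is defined as 0 whenever any marginal
#' of the confusion matrix is zero.
#'
#' @param labels True labels (`positive`/`negative`, logical or 0/1).
#' @param calls Predicted labels, same encoding.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sp`, `sn`, `acc`, `mcc`.
#' @export
confusion_metrics <- function(labels, calls) {
  if (length(labels) == 0) abort("empty input")
  if (length(labels) != length(calls)) abort("labels and calls must have equal length")
  y <- as_binary(labels)
  p <- as_binary(calls)
  tp <- sum(y & p); fn <- sum(y & !p)
  tn <- sum(!y & !p); fp <- sum(!y & p)
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sp = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    sn = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    acc = (tp + tn) / length(y),
    mcc = mcc
  )
}

as_binary <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x > 0.5)
  x == "positive" | x == "1" | x == "TRUE"
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) statistic with the midrank tie convention;
#' ROC points by sweeping every distinct score as a threshold, equivalent to
#' trapezoidal integration.
#'
#' @param labels True labels (`positive`/`negative`, logical or 0/1).
#' @param scores Real-valued scores, larger meaning more positive.
#' @return List with `auc` (scalar) and `roc` (tibble `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("both classes are required for ROC analysis")
  r <- rank(scores) # midranks on ties
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- !duplicated(ss, fromLast = TRUE) # one point per distinct threshold
  roc <- tibble::tibble(
    threshold = c(Inf, ss[last]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1)
  )
  list(auc = auc, roc = roc)
}

# per-fold encoding cache ------------------------------------------------------

# Rebuild the encoder context on each training partition and encode both
# partitions once over the full candidate feature set, so IFS can subset
# features without re-encoding.
encode_cv_folds <- function(dataset, folds = 10L, seed = 1L, config = carb_config()) {
  ds <- if (".fold" %in% names(dataset)) dataset else stratified_folds(dataset, k = folds, seed = seed)
  k <- max(ds$.fold)
  purrr::map(seq_len(k), function(f) {
    train <- ds[ds$.fold != f, , drop = FALSE]
    test <- ds[ds$.fold == f, , drop = FALSE]
    context <- build_encoder_context(train,
      sigma_mode = config$sigma_mode, frequency_mode = config$frequency_mode
    )
    list(
      fold = f,
      train_x = assemble_features(train, context,
        exclude_self = TRUE, knn_clamp = config$knn_clamp
      ),
      train_y = train$label,
      test_x = assemble_features(test, context,
        exclude_self = FALSE, knn_clamp = config$knn_clamp
      ),
      test = test
    )
  })
}

# fit + score every fold on a feature subset; splice held-out probabilities
cv_fit_score <- function(fold_data, feature_idx = NULL, config = carb_config(), seed = 1L) {
  per_fold <- purrr::map(fold_data, function(fd) {
    idx <- feature_idx %||% seq_len(ncol(fd$train_x))
    fit <- train_wsvm(fd$train_x[, idx, drop = FALSE], fd$train_y, config, seed)
    p <- predict_wsvm(fit, fd$test_x[, idx, drop = FALSE])
    dplyr::mutate(
      dplyr::select(fd$test, dplyr::any_of(c("protein_id", "position", "residue", "label"))),
      probability = unname(p), fold = fd$fold
    )
  })
  predictions <- dplyr::bind_rows(per_fold)
  fold_metrics <- dplyr::bind_rows(purrr::map(per_fold, function(pf) {
    dplyr::bind_cols(
      tibble::tibble(fold = pf$fold[1]),
      confusion_metrics(pf$label, pf$probability >= config$threshold)
    )
  }))
  list(predictions = predictions, per_fold = fold_metrics)
}

#' Spliced-probability cross-validation
#'
#' Stratified k-fold CV of the full pipeline: for each fold the encoder
#' context (propensity matrices, diversity pools, KNN references) is rebuilt
#' from the training partition only, a class-weighted SVM is fitted, and the
#' held-out windows are scored. The held-out probabilities of all folds are
#' spliced into one vector; accuracy, MCC and the ROC/AUC are computed once on
#' the spliced vector (per-fold metrics are also reported).
#'
#' @param dataset Window tibble (`label` in `positive`/`negative`).
#' @param features Optional indices into the candidate feature order to
#'   restrict the model to (e.g. an mRMR/IFS selection); default all.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (fold assignment, classifier).
#' @param config A [carb_config()].
#' @return A `carb_eval` object: `metrics` (one-row tibble with sp, sn, acc,
#'   mcc, auc and confusion counts), `roc` points, `per_fold` metrics and the
#'   spliced `predictions`.
#' @export
cross_validate <- function(dataset, features = NULL, folds = 10L, seed = 1L,
                           config = carb_config()) {
  fold_data <- encode_cv_folds(dataset, folds = folds, seed = seed, config = config)
  res <- cv_fit_score(fold_data, features, config = config, seed = seed)
  new_carb_eval(res$predictions, config$threshold, per_fold = res$per_fold)
}

new_carb_eval <- function(predictions, threshold, per_fold = NULL) {
  cm <- confusion_metrics(predictions$label, predictions$probability >= threshold)
  ra <- roc_auc(predictions$label, predictions$probability)
  structure(list(
    metrics = dplyr::bind_cols(cm, tibble::tibble(auc = ra$auc)),
    roc = ra$roc,
    per_fold = per_fold,
    predictions = predictions,
    threshold = threshold
  ), class = "carb_eval")
}

#' Evaluate a frozen model on labelled windows
#'
#' Scores the windows with the stored model (resubstitution if they are the
#' training windows themselves) and reports the full metric set.
#'
#' @param model A `carb_model`.
#' @param windows Labelled window tibble matching the model residue and n.
#' @return A `carb_eval` object.
#' @export
carb_evaluate <- function(model, windows) {
  if (nrow(windows) == 0) abort("no windows to evaluate")
  if (window_half_width(windows) != model$n) {
    abort(sprintf("windows have n = %d but the model expects n = %d",
      window_half_width(windows), model$n))
  }
  pred <- predict_probability(model, windows)
  pred$label <- windows$label[windows$residue == model$residue]
  new_carb_eval(pred, model$threshold)
}

#' @export
print.carb_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<carb_eval> %d windows (%d pos / %d neg)\n  Sp %.4f  Sn %.4f  Acc %.4f  MCC %.4f  AUC %.4f\n",
    nrow(x$predictions), m$tp + m$fn, m$tn + m$fp, m$sp, m$sn, m$acc, m$mcc, m$auc
  ))
  invisible(x)
}

#' @export
tidy.carb_eval <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x$metrics, "sp", "sn", "acc", "mcc", "auc"),
    dplyr::everything(), names_to = "metric", values_to = "value"
  )
}

#' @export
glance.carb_eval <- function(x, ...) x$metrics

# Results-section analyses -----------------------------------------------------

#' Per-position residue enrichment/depletion between classes
#'
#' For each flanking position (centre excluded) and each of the 21 residues,
#' a Welch two-sample t-test on the residue indicator (1 if that residue
#' occupies the position) compares positive against negative windows. The
#' signed difference of position-specific composition and a significance flag
#' at `alpha` are reported.
#'
#' @param pos_windows,neg_windows Character vectors of windows with equal n.
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble: `offset`, `residue`, `diff` (positive-class minus
#'   negative-class composition), `statistic`, `p_value`, `significant`,
#'   `direction` (`enriched`/`depleted`).
#' @export
position_composition_test <- function(pos_windows, neg_windows, alpha = 0.05) {
  if (length(pos_windows) < 2 || length(neg_windows) < 2) {
    abort("each class needs at least 2 windows")
  }
  pc <- flank_codes(pos_windows)
  nc <- flank_codes(neg_windows)
  if (ncol(pc) != ncol(nc)) abort("classes disagree on n")
  n <- ncol(pc) %/% 2L
  off <- flank_offsets(n)
  n1 <- nrow(pc); n2 <- nrow(nc)
  out <- purrr::map_dfr(seq_len(ncol(pc)), function(j) {
    c1 <- tabulate(pc[, j], N_AA); c2 <- tabulate(nc[, j], N_AA)
    p1 <- c1 / n1; p2 <- c2 / n2
    v1 <- p1 * (1 - p1) * n1 / (n1 - 1) # unbiased indicator variance
    v2 <- p2 * (1 - p2) * n2 / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tstat <- ifelse(se2 > 0, (p1 - p2) / sqrt(se2), NA_real_)
    df <- ifelse(se2 > 0,
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
      NA_real_
    )
    pval <- 2 * stats::pt(-abs(tstat), df)
    tibble::tibble(
      offset = off[j], residue = AA21,
      diff = p1 - p2, statistic = tstat, p_value = pval
    )
  })
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$direction <- ifelse(out$diff >= 0, "enriched", "depleted")
  out
}

#' Class-wise mean hydrophobicity per flanking position
#'
#' Uses the normalized hydrophobicity index of the HQI8 set; `X` residues are
#' skipped from each positional mean (a position seeing only `X` in a class is
#' reported as `NA`). The centre position is excluded.
#'
#' @param pos_windows,neg_windows Character vectors of windows with equal n.
#' @return Tibble: `offset`, `class`, `mean_hydrophobicity`.
#' @export
hydrophobicity_profile <- function(pos_windows, neg_windows) {
  hyd <- hqi8_table()[, "hydrophobicity"]
  profile_one <- function(windows, cls) {
    codes <- flank_codes(windows)
    n <- ncol(codes) %/% 2L
    vals <- vapply(seq_len(ncol(codes)), function(j) {
      cj <- codes[, j]
      keep <- cj != N_AA
      if (!any(keep)) NA_real_ else mean(hyd[cj[keep]])
    }, numeric(1))
    tibble::tibble(offset = flank_offsets(n), class = cls, mean_hydrophobicity = vals)
  }
  dplyr::bind_rows(
    profile_one(pos_windows, "positive"),
    profile_one(neg_windows, "negative")
  )
}

#' Distribution of selected features across encoder families
#'
#' Counts the selected features per encoder family and reports the family's
#' mean relevance (mutual information with the label, the Maximum Relevance
#' score of the ranking).
#'
#' @param ifs_result A `carb_ifs` (or `NULL` to use the first
#'   `chosen_dimension` of the ranking as-is via `k`).
#' @param ranking A `carb_ranking` from [mrmr_rank()].
#' @param names Candidate feature name vector (`feature_names_for(n)` order).
#' @param k Number of top-ranked features when `ifs_result` is `NULL`.
#' @return Tibble: `group`, `count`, `mean_relevance` (all four families
#'   always reported; empty families have count 0 and `NA` relevance).
#' @export
feature_group_distribution <- function(ifs_result = NULL, ranking, names, k = NULL) {
  d <- if (!is.null(ifs_result)) ifs_result$chosen_dimension else k %||% nrow(ranking)
  sel <- ranking[seq_len(d), , drop = FALSE]
  grp <- feature_groups(names[sel$feature])
  tab <- tibble::tibble(group = grp, relevance = sel$relevance)
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$group, .drop = FALSE),
    count = dplyr::n(),
    mean_relevance = mean(.data$relevance),
    .groups = "drop"
  )
  out$group <- as.character(out$group)
  out
}
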