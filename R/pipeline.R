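#' Train a model from files (command-style entry point)
#'
#' Reads proteins and annotations, prepares the residue-specific dataset,
#' optionally sweeps the window half-width, trains the final model and writes
#' the model archive plus report files to `out_dir`. When `sweep` is given,
#' the (n, k) pair is chosen jointly by the peak IFS mean MCC across the
#' sweep.
#'
#' @param fasta_path Protein FASTA.
#' @param annotations_path Positive-site annotation TSV.
#' @param residue One of K, R, T, P.
#' @param n Window half-width (used when `sweep` is `NULL`).
#' @param sweep Optional vector of half-widths (5..13) to sweep.
#' @param selection Feature-selection mode, see [carb_train()].
#' @param k Selection prefix size / IFS cap.
#' @param ratio Negative:positive sampling ratio.
#' @param folds CV folds.
#' @param seed Integer seed.
#' @param config A [carb_config()].
#' @param out_dir Output directory (`NULL` to skip writing).
#' @return The trained `carb_model` (invisibly carries the dataset in
#'   attribute `dataset`).
#' @export
cmd_train <- function(fasta_path, annotations_path, residue, n = 13L,
                      sweep = NULL, selection = "none", k = NULL, ratio = 6,
                      folds = 10L, seed = 1L, config = carb_config(),
                      out_dir = NULL) {
  proteins <- read_fasta(fasta_path)
  annotations <- read_site_annotations(annotations_path, proteins)
  inform(sprintf(
    "train: residue %s, %d proteins, %d annotation rows, seed %d",
    residue, nrow(proteins), nrow(annotations), seed
  ))
  ns <- sweep %||% n
  best <- NULL
  for (ni in ns) {
    dataset <- prepare_dataset(proteins, annotations, residue,
      n = ni, ratio = ratio, seed = seed
    )
    model <- carb_train(dataset,
      selection = selection, k = k, folds = folds,
      seed = seed, config = config
    )
    score <- if (!is.null(model$ifs)) max(model$ifs$curve$mcc) else {
      mean(cv_quick_mcc(dataset, model, folds, seed, config))
    }
    if (is.null(best) || score > best$score) {
      best <- list(model = model, dataset = dataset, score = score, n = ni)
    }
  }
  model <- best$model
  attr(model, "dataset") <- best$dataset
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_model(model, file.path(out_dir, sprintf("model_%s.rds", residue)))
    readr::write_tsv(glance(model), file.path(out_dir, "model_summary.tsv"), progress = FALSE)
    if (!is.null(model$ifs)) {
      readr::write_tsv(model$ifs$curve, file.path(out_dir, "ifs_curve.tsv"), progress = FALSE)
    }
    if (!is.null(model$ranking)) {
      readr::write_tsv(model$ranking, file.path(out_dir, "feature_ranking.tsv"), progress = FALSE)
    }
  }
  invisible(model)
}

# mean per-fold MCC without feature selection (used only to compare sweep n's)
cv_quick_mcc <- function(dataset, model, folds, seed, config) {
  ev <- cross_validate(dataset,
    features = model$feature_indices,
    folds = folds, seed = seed, config = config
  )
  ev$per_fold$mcc
}

#' Scan query proteins and score every residue of the model's type
#'
#' @param model A `carb_model` (or archive path).
#' @param fasta_path Query FASTA.
#' @param out_path Optional prediction TSV to write.
#' @return Prediction tibble (also written to `out_path` when given).
#' @export
carb_predict_fasta <- function(model, fasta_path, out_path = NULL) {
  if (is.character(model)) model <- load_model(model)
  proteins <- read_fasta(fasta_path)
  sites <- purrr::map2_dfr(proteins$protein_id, proteins$sequence, function(id, s) {
    at <- stringr::str_locate_all(s, stringr::fixed(model$residue))[[1]][, 1]
    tibble::tibble(
      protein_id = id, position = as.integer(at),
      residue = model$residue, label = "unknown"
    )
  })
  pred <- if (nrow(sites) == 0) {
    tibble::tibble(
      protein_id = character(), position = integer(), residue = character(),
      probability = numeric(), call = logical()
    )
  } else {
    windows <- extract_windows(proteins, sites, model$n)
    predict_probability(model, windows)
  }
  if (!is.null(out_path)) write_predictions(pred, out_path)
  pred
}

#' Evaluate a frozen model on a labelled window file
#'
#' @param model A `carb_model` (or archive path).
#' @param windows_path Window TSV readable by [read_windows_tsv()].
#' @param out_path Optional metrics TSV to write.
#' @return A `carb_eval`.
#' @export
cmd_evaluate <- function(model, windows_path, out_path = NULL) {
  if (is.character(model)) model <- load_model(model)
  windows <- read_windows_tsv(windows_path, residue = model$residue)
  ev <- carb_evaluate(model, windows)
  if (!is.null(out_path)) readr::write_tsv(ev$metrics, out_path, progress = FALSE)
  ev
}
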