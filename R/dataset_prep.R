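#' Enumerate positive sites and candidate negative sites for one residue type
#'
#' Positives are the annotated sites of the requested residue type. A residue
#' qualifies as a candidate negative when (i) it has the same residue type,
#' (ii) it is not itself reported positive, (iii) it lies in a protein that
#' contains known carbonylation sites, and (iv) — when annotations carry a
#' `source` tag — the protein was seen in at least one study in which that
#' residue type was assayed.
#'
#' @param proteins Protein tibble (`protein_id`, `sequence`).
#' @param annotations Validated annotation tibble of positive sites.
#' @param residue One of `"K"`, `"R"`, `"T"`, `"P"`.
#' @return Site tibble (`protein_id`, `position`, `residue`, `label`) where
#'   `label` is `positive` or `candidate_negative`.
#' @export
enumerate_candidates <- function(proteins, annotations, residue) {
  if (!residue %in% c("K", "R", "T", "P")) abort("residue must be one of K, R, T, P")
  ann <- dplyr::filter(tibble::as_tibble(annotations), .data$label == "positive")
  pos <- dplyr::filter(ann, .data$residue == !!residue)
  annotated_proteins <- unique(ann$protein_id)
  eligible <- annotated_proteins
  if ("source" %in% names(ann) && nrow(pos) > 0) {
    assayed_sources <- unique(pos$source)
    eligible <- unique(ann$protein_id[ann$source %in% assayed_sources])
  }
  scan <- dplyr::filter(proteins, .data$protein_id %in% eligible)
  cand <- purrr::map2_dfr(scan$protein_id, scan$sequence, function(id, s) {
    at <- stringr::str_locate_all(s, stringr::fixed(residue))[[1]][, 1]
    tibble::tibble(protein_id = id, position = as.integer(at))
  })
  if (nrow(cand) > 0) {
    cand <- dplyr::anti_join(cand, pos, by = c("protein_id", "position"))
  }
  dplyr::bind_rows(
    tibble::tibble(
      protein_id = pos$protein_id, position = pos$position,
      residue = residue, label = "positive"
    ),
    tibble::tibble(
      protein_id = cand$protein_id, position = cand$position,
      residue = residue, label = "candidate_negative"
    )
  )
}

# ungapped fractional identity between one window and a set of windows,
# X-X counted as a match
window_identity <- function(codes_one, codes_set) {
  rowMeans(codes_set == matrix(codes_one, nrow(codes_set), length(codes_one), byrow = TRUE))
}

#' Remove redundant windows by greedy identity clustering
#'
#' Windows are ordered deterministically (by sequence, then protein id, then
#' position); each window is kept unless its ungapped identity (matching
#' positions / window length, X-X counting as a match) to an already retained
#' window exceeds the cut-off. The operation is idempotent.
#'
#' @param windows Window tibble.
#' @param identity_threshold Identity cut-off (default 0.30).
#' @return The retained windows, in the deterministic order.
#' @export
reduce_redundancy <- function(windows, identity_threshold = 0.30) {
  if (nrow(windows) <= 1) return(windows)
  ord <- order(windows$window, windows$protein_id, windows$position)
  w <- windows[ord, , drop = FALSE]
  codes <- seq_codes(w$window)
  keep <- logical(nrow(w))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(w))) {
    if (length(kept_idx) == 0) {
      keep[i] <- TRUE
      kept_idx <- i
      next
    }
    ident <- window_identity(codes[i, ], codes[kept_idx, , drop = FALSE])
    if (all(ident <= identity_threshold)) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  w[keep, , drop = FALSE]
}

#' Randomly sample negatives to a target class ratio
#'
#' Uniform sampling without replacement of `min(round(ratio * n_positives),
#' nrow(candidates))` windows, reproducible for a fixed seed.
#'
#' @param candidates Candidate-negative window tibble.
#' @param n_positives Number of positive windows to match against.
#' @param ratio Target negative:positive ratio (default 6).
#' @param seed Integer seed.
#' @return Sampled windows with `label` set to `"negative"`.
#' @export
sample_negatives <- function(candidates, n_positives, ratio = 6, seed = 1L) {
  if (nrow(candidates) == 0) abort("candidate negative pool is empty")
  if (ratio <= 0) abort("ratio must be positive")
  size <- min(round(ratio * n_positives), nrow(candidates))
  idx <- withr::with_seed(seed, sample.int(nrow(candidates), size))
  out <- candidates[sort(idx), , drop = FALSE]
  out$label <- "negative"
  out
}

#' Prepare a residue-type-specific training dataset
#'
#' Runs the full sample-preparation chain: enumerate positives and candidate
#' negatives, reduce redundancy over the pooled sample set at the identity
#' cut-off, cut +/-n windows for the surviving sites, then down-sample the
#' candidate negatives to about `ratio` times the positives.
#'
#' Redundancy is judged on the maximal +/-`dedup_n` windows (default 13), not
#' on the working-`n` windows, so the retained sample set — like the class
#' counts it produces — does not depend on the half-width later used for
#' encoding.
#'
#' @inheritParams enumerate_candidates
#' @param n Window half-width (5..13).
#' @param ratio Negative:positive sampling ratio.
#' @param identity_threshold Redundancy cut-off.
#' @param seed Integer seed for negative sampling.
#' @param dedup_n Half-width of the windows used for redundancy reduction.
#' @return Window tibble with `label` in `positive`/`negative`; attributes
#'   `residue` and `n`.
#' @export
prepare_dataset <- function(proteins, annotations, residue, n,
                            ratio = 6, identity_threshold = 0.30, seed = 1L,
                            dedup_n = 13L) {
  sites <- enumerate_candidates(proteins, annotations, residue)
  wide <- extract_windows(proteins, sites, max(n, dedup_n))
  wide <- reduce_redundancy(wide, identity_threshold)
  win <- extract_windows(proteins, dplyr::select(wide, -"window"), n)
  pos <- dplyr::filter(win, .data$label == "positive")
  cand <- dplyr::filter(win, .data$label == "candidate_negative")
  if (nrow(pos) == 0) abort("no positive windows after redundancy reduction")
  neg <- sample_negatives(cand, nrow(pos), ratio = ratio, seed = seed)
  out <- dplyr::bind_rows(pos, neg)
  attr(out, "residue") <- residue
  attr(out, "n") <- as.integer(n)
  out
}

#' Assign stratified cross-validation folds
#'
#' Positives and negatives are permuted independently and dealt round-robin
#' into `k` folds, so per-fold class counts differ by at most one from the
#' even split. Deterministic for a fixed seed.
#'
#' @param dataset Window tibble with a `label` column.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return The dataset with an integer `.fold` column in `1..k`.
#' @export
stratified_folds <- function(dataset, k = 10L, seed = 1L) {
  n_pos <- sum(dataset$label == "positive")
  n_neg <- sum(dataset$label == "negative")
  if (n_pos < k || n_neg < k) {
    abort(sprintf("need at least %d windows per class for %d folds", k, k))
  }
  fold <- integer(nrow(dataset))
  withr::with_seed(seed, {
    for (lab in c("positive", "negative")) {
      idx <- which(dataset$label == lab)
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  out <- dataset
  out$.fold <- fold
  out
}
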