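#' Number of candidate features for a half-width n
#'
#' Sums the four encoder dimensions: `2n` positional amino-acid propensities,
#' `n(2n-1)` position-pair propensities, 2 diversity increments, 5 KNN scores
#' and `16n` physicochemical values.
#'
#' @param n Window half-width, in the supported sweep 5..13.
#' @return Integer feature count (566 at `n = 13`).
#' @export
candidate_dimension <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 5 || n > 13 || n != round(n)) {
    abort("n must be an integer in 5..13")
  }
  n <- as.integer(n)
  2L * n + n * (2L * n - 1L) + 2L + 5L + 16L * n
}

# position offsets of the 2n flank columns (centre excluded)
flank_offsets <- function(n) c(-(n:1), 1:n)

# integer codes of the 2n flanking residues (centre column dropped)
flank_codes <- function(windows_chr) {
  codes <- seq_codes(windows_chr)
  n <- (ncol(codes) - 1L) %/% 2L
  codes[, -(n + 1L), drop = FALSE]
}

#' Candidate feature names for a half-width n
#'
#' Names follow the assembled column order of [assemble_features()]:
#' positional propensities (`psp_aa_`), position-pair propensities
#' (`psp_pair_`), diversity increments (`div_`), KNN scores (`knn_`) and
#' physicochemical values (`hqi_`).
#'
#' @param n Window half-width, 5..13.
#' @return Character vector of length `candidate_dimension(n)`.
#' @export
feature_names_for <- function(n) {
  off <- flank_offsets(n)
  pr <- utils::combn(2L * n, 2L)
  c(
    sprintf("psp_aa_p%+d", off),
    sprintf("psp_pair_p%+d_p%+d", off[pr[1, ]], off[pr[2, ]]),
    c("div_k1", "div_k2"),
    sprintf("knn_k%d", c(11L, 21L, 31L, 41L, 51L)),
    as.vector(t(outer(off, names(HQI8_ACCESSIONS), function(o, h) sprintf("hqi_p%+d_%s", o, h))))
  )
}

#' Encoder family of each feature name
#'
#' @param names Feature name vector as produced by [assemble_features()].
#' @return Factor with levels `pspaksap`, `diversity`, `knn`, `hqi8`.
#' @export
feature_groups <- function(names) {
  pre <- stringr::str_extract(names, "^[a-z0-9]+")
  map <- c(psp = "pspaksap", div = "diversity", knn = "knn", hqi = "hqi8")
  factor(unname(map[pre]), levels = c("pspaksap", "diversity", "knn", "hqi8"))
}

# column-wise class counts of residues at each flank position ----------------

aa_position_counts <- function(codes) {
  out <- matrix(0, N_AA, ncol(codes), dimnames = list(AA21, NULL))
  for (j in seq_len(ncol(codes))) out[, j] <- tabulate(codes[, j], N_AA)
  out
}

pair_position_counts <- function(codes, pair_idx) {
  out <- matrix(0, N_PAIR, ncol(pair_idx))
  for (c in seq_len(ncol(pair_idx))) {
    pc <- pair_code(codes[, pair_idx[1, c]], codes[, pair_idx[2, c]])
    out[, c] <- tabulate(pc, N_PAIR)
  }
  out
}

# population standard deviation of each column, floored at eps
column_sds <- function(m, eps = 1e-6) {
  mu <- colMeans(m)
  s <- sqrt(colMeans(sweep(m, 2, mu)^2))
  pmax(s, eps)
}

#' Build position-specific propensity matrices from training windows
#'
#' For the 2n flank positions (centre excluded), class-wise absolute frequency
#' matrices of residues (21 rows) and of ordered residue pairs over all
#' position pairs p < q (441 rows) are accumulated. The propensity score is
#' the positive-minus-negative count difference divided by a per-column
#' standard deviation.
#'
#' @param pos_windows,neg_windows Character vectors of training windows
#'   (length `2n + 1`, shared `n`).
#' @param sigma_mode Column statistic: `"difference"` (sd of the difference
#'   matrix column, the default) or `"positive"` (sd of the positive-count
#'   column).
#' @param frequency_mode `"count"` (absolute frequencies, default) or
#'   `"relative"` (counts divided by class size before differencing).
#' @param eps Floor applied to each column sd.
#' @return An object of class `carb_propensity` with elements `aa` (21 x 2n
#'   score matrix), `pair` (441 x n(2n-1) score matrix), the count matrices
#'   and the column sds.
#' @export
build_propensity_matrices <- function(pos_windows, neg_windows,
                                      sigma_mode = c("difference", "positive"),
                                      frequency_mode = c("count", "relative"),
                                      eps = 1e-6) {
  sigma_mode <- match.arg(sigma_mode)
  frequency_mode <- match.arg(frequency_mode)
  if (length(pos_windows) == 0 || length(neg_windows) == 0) {
    abort("both training classes must be non-empty")
  }
  pc <- flank_codes(pos_windows)
  nc <- flank_codes(neg_windows)
  if (ncol(pc) != ncol(nc)) abort("positive and negative windows disagree on n")
  n <- ncol(pc) %/% 2L
  pair_idx <- utils::combn(2L * n, 2L)

  f_pos <- aa_position_counts(pc)
  f_neg <- aa_position_counts(nc)
  fp_pos <- pair_position_counts(pc, pair_idx)
  fp_neg <- pair_position_counts(nc, pair_idx)
  if (frequency_mode == "relative") {
    f_pos <- f_pos / length(pos_windows); fp_pos <- fp_pos / length(pos_windows)
    f_neg <- f_neg / length(neg_windows); fp_neg <- fp_neg / length(neg_windows)
  }
  d_aa <- f_pos - f_neg
  d_pair <- fp_pos - fp_neg
  sd_aa <- column_sds(if (sigma_mode == "difference") d_aa else f_pos, eps)
  sd_pair <- column_sds(if (sigma_mode == "difference") d_pair else fp_pos, eps)
  structure(list(
    n = n,
    aa = sweep(d_aa, 2, sd_aa, "/"),
    pair = sweep(d_pair, 2, sd_pair, "/"),
    aa_pos_counts = f_pos, aa_neg_counts = f_neg,
    pair_pos_counts = fp_pos, pair_neg_counts = fp_neg,
    aa_sd = sd_aa, pair_sd = sd_pair,
    pair_idx = pair_idx,
    sigma_mode = sigma_mode, frequency_mode = frequency_mode
  ), class = "carb_propensity")
}

#' Encode windows with the position-specific propensity matrices
#'
#' @param windows Character vector of windows (length `2n + 1`).
#' @param matrix A `carb_propensity` object built with the same `n`.
#' @return Numeric matrix, one row per window, `2n + n(2n-1)` columns.
#' @export
encode_pspaksap <- function(windows, matrix) {
  codes <- flank_codes(windows)
  if (ncol(codes) != 2L * matrix$n) abort("window length does not match the propensity matrix n")
  L <- ncol(codes)
  pair_idx <- matrix$pair_idx
  out <- base::matrix(0, nrow(codes), L + ncol(pair_idx))
  for (j in seq_len(L)) out[, j] <- matrix$aa[cbind(codes[, j], j)]
  for (c in seq_len(ncol(pair_idx))) {
    pc <- pair_code(codes[, pair_idx[1, c]], codes[, pair_idx[2, c]])
    out[, L + c] <- matrix$pair[cbind(pc, c)]
  }
  out
}

# increment-of-diversity features ---------------------------------------------

#' Diversity measure of a count vector
#'
#' `D = N log N - sum(n_i log n_i)` with natural logarithms and
#' `0 log 0 = 0`; equals `N` times the empirical Shannon entropy.
#'
#' @param counts Non-negative count vector over the state space.
#' @return Non-negative scalar.
#' @export
diversity_measure <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  n_total <- sum(counts)
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  xlx(n_total) - sum(xlx(counts))
}

#' Increment of diversity between two count sources
#'
#' `ID(X, Y) = D(X + Y) - D(X) - D(Y)`; non-negative, symmetric, zero when
#' the sources have identical single-state support. Smaller values indicate
#' more similar sources.
#'
#' @param source_x,source_y Count vectors over the same state space.
#' @return Non-negative scalar.
#' @export
diversity_increment <- function(source_x, source_y) {
  if (length(source_x) != length(source_y)) abort("sources must share a state space")
  diversity_measure(source_x + source_y) -
    diversity_measure(source_x) - diversity_measure(source_y)
}

# k-mer counts over the concatenated flanks (centre residue excluded)
kmer_counts <- function(codes, k) {
  if (k == 1) {
    tabulate(codes, N_AA)
  } else if (k == 2) {
    L <- ncol(codes)
    pc <- pair_code(codes[, 1:(L - 1), drop = FALSE], codes[, 2:L, drop = FALSE])
    tabulate(pc, N_PAIR)
  } else {
    abort("only k = 1 and k = 2 are supported")
  }
}

build_diversity_pools <- function(pos_windows, neg_windows) {
  pc <- flank_codes(pos_windows)
  nc <- flank_codes(neg_windows)
  list(
    pos_k1 = kmer_counts(pc, 1), neg_k1 = kmer_counts(nc, 1),
    pos_k2 = kmer_counts(pc, 2), neg_k2 = kmer_counts(nc, 2)
  )
}

#' Encode the two increment-of-diversity features
#'
#' For k = 1 and k = 2, the feature is the increment of k-mer diversity of the
#' query against the negative pool minus the increment against the positive
#' pool, so larger values mean the query is more similar to the positive
#' class.
#'
#' @param windows Character vector of windows.
#' @param pools Class k-mer pools from the training windows (internal list
#'   with `pos_k1`, `neg_k1`, `pos_k2`, `neg_k2`).
#' @return Numeric matrix with columns `div_k1`, `div_k2`.
#' @export
encode_diversity_features <- function(windows, pools) {
  if (sum(pools$pos_k1) == 0 || sum(pools$neg_k1) == 0) abort("empty diversity pool")
  codes <- flank_codes(windows)
  out <- base::matrix(0, nrow(codes), 2L)
  for (i in seq_len(nrow(codes))) {
    row <- codes[i, , drop = FALSE]
    q1 <- kmer_counts(row, 1)
    q2 <- kmer_counts(row, 2)
    out[i, 1] <- diversity_increment(q1, pools$neg_k1) - diversity_increment(q1, pools$pos_k1)
    out[i, 2] <- diversity_increment(q2, pools$neg_k2) - diversity_increment(q2, pools$pos_k2)
  }
  out
}

# KNN scores -------------------------------------------------------------------

#' BLOSUM62 distance between two equal-length windows
#'
#' Per aligned position where neither residue is `X`, the BLOSUM62 score is
#' min-max normalized to \[0, 1\] with the matrix's global range (-4, 11);
#' the distance is one minus the mean normalized similarity over those
#' positions. If every position involves `X` the distance is 1 by convention.
#'
#' @param window_a,window_b Window strings of equal length.
#' @return Distance in \[0, 1\].
#' @export
window_distance <- function(window_a, window_b) {
  if (nchar(window_a) != nchar(window_b)) abort("windows must have equal length")
  drop(window_distance_matrix(
    seq_codes(window_a), seq_codes(window_b)
  ))
}

# queries x references distance matrix from window code matrices
window_distance_matrix <- function(q_codes, r_codes) {
  sim <- blosum62_similarity()
  L <- ncol(q_codes)
  ssum <- base::matrix(0, nrow(q_codes), nrow(r_codes))
  cnt <- base::matrix(0, nrow(q_codes), nrow(r_codes))
  for (j in seq_len(L)) {
    m <- sim[q_codes[, j], r_codes[, j], drop = FALSE]
    ok <- !is.na(m)
    m[!ok] <- 0
    ssum <- ssum + m
    cnt <- cnt + ok
  }
  d <- 1 - ssum / pmax(cnt, 1)
  d[cnt == 0] <- 1
  d
}

#' Encode KNN score features
#'
#' Each query is compared with every training reference window under the
#' BLOSUM62 distance; for k in 11, 21, 31, 41, 51 the feature is the fraction
#' of positive windows among the k nearest references. Ties at equal distance
#' resolve by the deterministic reference order (sorted by sequence, then id).
#'
#' @param windows Character vector of query windows.
#' @param refs Reference list (internal) with `codes`, `labels`, `ids`.
#' @param exclude_ids Optional per-query identifier matched against reference
#'   ids; a reference equal to the query's id is ignored (leave-one-out for
#'   training windows).
#' @param k_values Neighbour counts.
#' @param clamp If `TRUE`, k values larger than the available reference count
#'   are clamped instead of raising an error.
#' @return Numeric matrix, one column per k.
#' @export
encode_knn_scores <- function(windows, refs, exclude_ids = NULL,
                              k_values = c(11L, 21L, 31L, 41L, 51L),
                              clamp = FALSE) {
  q_codes <- seq_codes(windows)
  d <- window_distance_matrix(q_codes, refs$codes)
  n_ref <- ncol(d)
  if (!is.null(exclude_ids)) {
    for (i in seq_along(exclude_ids)) {
      d[i, refs$ids == exclude_ids[i]] <- Inf
    }
  }
  avail <- if (is.null(exclude_ids)) n_ref else n_ref - 1L
  if (max(k_values) > avail) {
    if (!clamp) {
      abort(sprintf(
        "need at least %d reference windows for the KNN scores, have %d",
        max(k_values), avail
      ))
    }
    k_values <- pmin(k_values, avail)
  }
  is_pos <- refs$labels == "positive"
  out <- base::matrix(0, nrow(d), length(k_values))
  for (i in seq_len(nrow(d))) {
    ord <- order(d[i, ])
    cum <- cumsum(is_pos[ord])
    out[i, ] <- cum[k_values] / k_values
  }
  out
}

build_knn_refs <- function(windows) {
  ord <- order(windows$window, windows$protein_id, windows$position)
  w <- windows[ord, , drop = FALSE]
  list(
    codes = seq_codes(w$window),
    labels = w$label,
    ids = paste(w$protein_id, w$position, sep = "@")
  )
}

#' Encode the normalized physicochemical (HQI8) features
#'
#' Per non-central position the eight min-max-normalized HQI8 index values of
#' the residue; the dummy residue `X` contributes a zero block.
#'
#' @param windows Character vector of windows.
#' @return Numeric matrix with `16n` columns (position-major blocks of 8).
#' @export
encode_hqi8 <- function(windows) {
  codes <- flank_codes(windows)
  hqi <- hqi8_table()
  L <- ncol(codes)
  out <- base::matrix(0, nrow(codes), 8L * L)
  for (j in seq_len(L)) {
    out[, (8L * (j - 1L) + 1L):(8L * j)] <- hqi[codes[, j], , drop = FALSE]
  }
  out
}

# encoder context --------------------------------------------------------------

#' Build the encoder context from training windows
#'
#' Bundles everything the four encoders need: the propensity matrices, the
#' class k-mer pools, the KNN reference windows and the half-width. Contexts
#' are rebuilt per cross-validation fold from that fold's training partition
#' so that held-out windows never inform their own features.
#'
#' @param train_windows Window tibble with `label` in `positive`/`negative`.
#' @param sigma_mode,frequency_mode Passed to [build_propensity_matrices()].
#' @return An object of class `carb_context`.
#' @export
build_encoder_context <- function(train_windows,
                                  sigma_mode = "difference",
                                  frequency_mode = "count") {
  n <- window_half_width(train_windows)
  pos <- train_windows$window[train_windows$label == "positive"]
  neg <- train_windows$window[train_windows$label == "negative"]
  if (length(pos) == 0 || length(neg) == 0) abort("both classes required to build a context")
  structure(list(
    n = n,
    residue = train_windows$residue[1],
    propensity = build_propensity_matrices(pos, neg, sigma_mode, frequency_mode),
    pools = build_diversity_pools(pos, neg),
    knn_refs = build_knn_refs(train_windows),
    n_pos = length(pos), n_neg = length(neg)
  ), class = "carb_context")
}

#' @export
print.carb_context <- function(x, ...) {
  cat(sprintf(
    "<carb_context> residue %s, n = %d, %d positive / %d negative training windows\n",
    x$residue, x$n, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Assemble the full candidate feature matrix
#'
#' Concatenates the four encoders in fixed order: position-specific
#' propensities (amino acid, then position pairs), diversity increments, KNN
#' scores, HQI8 values. Column names carry the encoder provenance
#' (`psp_`, `div_`, `knn_`, `hqi_` prefixes).
#'
#' @param windows Window tibble.
#' @param context `carb_context` built with the same `n`.
#' @param exclude_self If `TRUE`, each window is excluded from its own KNN
#'   reference set (use when encoding the training windows themselves).
#' @param knn_clamp Clamp KNN k values when references are scarce.
#' @return Numeric matrix with one row per window and
#'   `candidate_dimension(n)` named columns.
#' @export
assemble_features <- function(windows, context, exclude_self = FALSE,
                              knn_clamp = FALSE) {
  if (window_half_width(windows) != context$n) {
    abort("window length does not match the encoder context n")
  }
  ids <- if (exclude_self) paste(windows$protein_id, windows$position, sep = "@") else NULL
  out <- cbind(
    encode_pspaksap(windows$window, context$propensity),
    encode_diversity_features(windows$window, context$pools),
    encode_knn_scores(windows$window, context$knn_refs,
      exclude_ids = ids, clamp = knn_clamp
    ),
    encode_hqi8(windows$window)
  )
  colnames(out) <- feature_names_for(context$n)
  rownames(out) <- paste(windows$protein_id, windows$position, sep = "@")
  out
}
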