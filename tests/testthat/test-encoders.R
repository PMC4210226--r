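test_that("candidate dimension follows the four-group formula", {
  expect_equal(candidate_dimension(13), 566L)
  expect_equal(candidate_dimension(12), 499L)
  expect_equal(candidate_dimension(6), 181L)
  expect_equal(candidate_dimension(5), 142L)
  for (n in 5:13) {
    expect_equal(candidate_dimension(n), 2 * n + n * (2 * n - 1) + 2 + 5 + 16 * n)
    expect_equal(length(feature_names_for(n)), candidate_dimension(n))
  }
  expect_error(candidate_dimension(4), "5\\.\\.13")
  expect_error(candidate_dimension(14), "5\\.\\.13")
  expect_error(candidate_dimension(7.5), "5\\.\\.13")
  expect_error(candidate_dimension(NA), "5\\.\\.13")
})

test_that("feature names map onto the four encoder groups", {
  g <- table(feature_groups(feature_names_for(13)))
  expect_equal(as.integer(g), c(351L, 2L, 5L, 208L))
  expect_equal(names(g), c("pspaksap", "diversity", "knn", "hqi8"))
  expect_false(any(duplicated(feature_names_for(13))))
})

test_that("propensity matrices reproduce the hand-computed toy score", {
  pm <- build_propensity_matrices(c("AKA", "AKA"), c("CKC", "CKC"))
  # count difference +2 for A / -2 for C; column sd of the difference
  # column over 21 rows is sqrt(8/21), so the score is 2 / sqrt(8/21)
  want <- 2 / sqrt(8 / 21)
  expect_equal(unname(pm$aa["A", 1]), want, tolerance = 1e-12)
  expect_equal(unname(pm$aa["A", 1]), 3.2403703, tolerance = 1e-6)
  expect_equal(unname(pm$aa["C", 1]), -want)
  expect_equal(unname(pm$aa["G", 2]), 0)
  expect_equal(dim(pm$aa), c(21L, 2L))
  expect_equal(dim(pm$pair), c(441L, 1L))
  # the pair column spans 441 states, so its sd is sqrt(8/441)
  want_pair <- 2 / sqrt(8 / 441)
  expect_equal(pm$pair[pair_code(1L, 1L), 1], want_pair) # A,A pair

  enc <- encode_pspaksap(c("AKA", "CKC", "GKG"), pm)
  expect_equal(enc[1, ], c(want, want, want_pair))
  expect_equal(enc[2, ], c(-want, -want, -want_pair))
  expect_equal(enc[3, ], c(0, 0, 0))
})

test_that("identical classes give an all-zero propensity matrix", {
  pm <- build_propensity_matrices(c("AKC", "GKD"), c("AKC", "GKD"))
  expect_true(all(pm$aa == 0))
  expect_true(all(pm$pair == 0))
  pm2 <- build_propensity_matrices(c("AKA", "AKA"), c("CKC", "CKC"),
    sigma_mode = "positive"
  )
  expect_true(all(is.finite(pm2$aa)))
  expect_false(isTRUE(all.equal(pm2$aa["A", 1], 2 / sqrt(8 / 21))))
  expect_error(build_propensity_matrices(character(), "AKA"), "non-empty")
  expect_error(build_propensity_matrices("AAKAA", "AKA"), "disagree")
})

test_that("diversity measure and increment match closed forms", {
  expect_equal(diversity_measure(c(1, 1)), 2 * log(2))
  expect_equal(diversity_measure(c(2, 2)), 4 * log(2))
  expect_equal(diversity_measure(c(5, 0, 0)), 0)
  expect_equal(diversity_measure(numeric(21)), 0)
  # identical single-state sources have zero increment
  expect_equal(diversity_increment(c(3, 0), c(5, 0)), 0)
  expect_equal(diversity_increment(c(1, 0), c(0, 1)), 2 * log(2))
  expect_error(diversity_measure(c(-1, 2)), "non-negative")
  expect_error(diversity_increment(c(1, 2), c(1, 2, 3)), "state space")
})

test_that("the diversity increment is non-negative and symmetric (fuzz)", {
  withr::with_seed(17, {
    for (i in 1:500) {
      x <- rpois(21, sample(c(0.2, 2, 20), 1))
      y <- rpois(21, sample(c(0.2, 2, 20), 1))
      id_xy <- diversity_increment(x, y)
      expect_gte(id_xy, -1e-9)
      expect_equal(id_xy, diversity_increment(y, x))
    }
  })
})

test_that("diversity features match a direct recomputation", {
  pos <- c("ARKAR", "RAKRA", "ARKRA")
  neg <- c("DEKDE", "EDKED", "DDKEE", "EEKDD")
  pools <- build_diversity_pools(pos, neg)
  got <- encode_diversity_features(c("RRKAA", "DEKED"), pools)
  for (i in 1:2) {
    q <- c("RRKAA", "DEKED")[i]
    ch <- strsplit(q, "")[[1]][-3]
    q1 <- tabulate(match(ch, aa_alphabet()), 21)
    q2 <- tabulate((match(ch[-4], aa_alphabet()) - 1) * 21 +
      match(ch[-1], aa_alphabet()), 441)
    expect_equal(
      got[i, 1],
      diversity_increment(q1, pools$neg_k1) - diversity_increment(q1, pools$pos_k1)
    )
    expect_equal(
      got[i, 2],
      diversity_increment(q2, pools$neg_k2) - diversity_increment(q2, pools$pos_k2)
    )
  }
  # the positive-like query scores higher than the negative-like one
  expect_gt(got[1, 1], got[2, 1])
})

test_that("window distances follow the normalized BLOSUM62 convention", {
  # identical alanine windows: per-position similarity (4+4)/15
  expect_equal(window_distance("AAAA", "AAAA"), 1 - 8 / 15)
  expect_equal(window_distance("AAAA", "AAAA"), 0.4666667, tolerance = 1e-6)
  # X positions are skipped; all-X pairs default to distance 1
  expect_equal(window_distance("AX", "AX"), 1 - 8 / 15)
  expect_equal(window_distance("XX", "XX"), 1)
  expect_equal(window_distance("AX", "XA"), 1)
  # symmetry and range on random windows
  w <- random_windows(10, 3, seed = 8)$window
  for (i in 1:5) {
    d <- window_distance(w[i], w[i + 5])
    expect_equal(d, window_distance(w[i + 5], w[i]))
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
  expect_error(window_distance("AA", "AAA"), "equal length")
})

test_that("KNN scores match a brute-force neighbour count", {
  tw <- toy_training_windows(n = 3, m_pos = 10, m_neg = 14, seed = 12)
  refs <- build_knn_refs(tw)
  q <- random_windows(6, 3, seed = 30)$window
  got <- encode_knn_scores(q, refs, k_values = c(1L, 5L, 9L))
  ref_w <- apply(refs$codes, 1, function(r) paste(aa_alphabet()[r], collapse = ""))
  for (i in seq_along(q)) {
    d <- vapply(ref_w, function(r) window_distance(q[i], r), numeric(1))
    ord <- order(d)
    for (j in seq_along(c(1, 5, 9))) {
      k <- c(1, 5, 9)[j]
      expect_equal(got[i, j], mean(refs$labels[ord[1:k]] == "positive"))
    }
  }
})

test_that("leave-one-out excludes a training window from its own neighbours", {
  tw <- toy_training_windows(n = 3, m_pos = 10, m_neg = 14, seed = 5)
  refs <- build_knn_refs(tw)
  # the first positive window queried against the full set: without
  # exclusion its own copy sits at distance 0 and k = 1 must return 1
  first_pos <- tw[tw$label == "positive", ][1, ]
  q <- first_pos$window
  id <- paste(first_pos$protein_id, first_pos$position, sep = "@")
  with_self <- encode_knn_scores(q, refs, k_values = 1L)
  without <- encode_knn_scores(q, refs, exclude_ids = id, k_values = 1L)
  expect_equal(with_self[1, 1], 1)
  ref_w <- apply(refs$codes, 1, function(r) paste(aa_alphabet()[r], collapse = ""))
  d <- vapply(ref_w, function(r) window_distance(q, r), numeric(1))
  d[refs$ids == id] <- Inf
  expect_equal(without[1, 1], as.numeric(refs$labels[which.min(d)] == "positive"))
  expect_error(encode_knn_scores(q, refs, k_values = 51L), "at least 51")
  clamped <- encode_knn_scores(q, refs, k_values = c(11L, 51L), clamp = TRUE)
  expect_equal(ncol(clamped), 2L)
})

test_that("the HQI8 table is normalized with a zero dummy row", {
  h <- hqi8_table()
  expect_equal(dim(h), c(21L, 8L))
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(unname(apply(h[1:20, ], 2, min)), rep(0, 8))
  expect_equal(unname(apply(h[1:20, ], 2, max)), rep(1, 8))
  expect_equal(unname(h["X", ]), rep(0, 8))

  enc <- encode_hqi8(c("AKC", "XKX"))
  expect_equal(dim(enc), c(2L, 16L))
  expect_equal(enc[1, 1:8], unname(h["A", ]))
  expect_equal(enc[1, 9:16], unname(h["C", ]))
  expect_equal(enc[2, ], rep(0, 16))
})

test_that("assembled features have the candidate layout and no self-leakage", {
  tw <- toy_training_windows(n = 13, m_pos = 25, m_neg = 60, seed = 3)
  ctx <- build_encoder_context(tw)
  x <- assemble_features(tw, ctx, exclude_self = TRUE)
  expect_equal(ncol(x), 566L)
  expect_equal(colnames(x), feature_names_for(13))
  expect_equal(as.integer(table(feature_groups(colnames(x)))), c(351L, 2L, 5L, 208L))
  expect_equal(rownames(x)[1], paste(tw$protein_id[1], tw$position[1], sep = "@"))
  expect_true(all(is.finite(x)))

  # without leave-one-out every training window is its own nearest
  # neighbour, inflating the KNN scores of the positives
  x_leaky <- assemble_features(tw, ctx, exclude_self = FALSE)
  knn_cols <- feature_groups(colnames(x)) == "knn"
  pos_rows <- tw$label == "positive"
  expect_gt(
    mean(x_leaky[pos_rows, knn_cols]),
    mean(x[pos_rows, knn_cols])
  )
  expect_error(
    assemble_features(random_windows(3, 5, seed = 1), ctx),
    "does not match"
  )
})
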