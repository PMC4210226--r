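test_that("confusion metrics match the hand-computed table", {
  labels <- c(rep("positive", 4), rep("negative", 6))
  calls <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  m <- confusion_metrics(labels, calls)
  expect_equal(m$tp, 3L)
  expect_equal(m$fn, 1L)
  expect_equal(m$fp, 1L)
  expect_equal(m$tn, 5L)
  expect_equal(m$sn, 3 / 4)
  expect_equal(m$sp, 5 / 6)
  expect_equal(m$acc, 8 / 10)
  expect_equal(m$mcc, 14 / 24) # (3*5 - 1*1) / sqrt(4*4*6*6)
  expect_equal(m$mcc, 0.5833333, tolerance = 1e-6)
})

test_that("confusion metrics agree with the brute-force oracle", {
  withr::with_seed(6, {
    for (i in 1:20) {
      y <- sample(c("positive", "negative"), 50, TRUE)
      p <- sample(c(TRUE, FALSE), 50, TRUE)
      m <- confusion_metrics(y, p)
      o <- oracle_confusion(y, p)
      expect_equal(m$sp, o$sp)
      expect_equal(m$sn, o$sn)
      expect_equal(m$acc, o$acc)
      expect_equal(m$mcc, o$mcc)
    }
  })
})

test_that("MCC is zero on degenerate confusion marginals", {
  expect_equal(confusion_metrics(c("positive", "negative"), c(FALSE, FALSE))$mcc, 0)
  m <- confusion_metrics(c("positive", "positive"), c(TRUE, FALSE))
  expect_equal(m$mcc, 0)
  expect_true(is.na(m$sp)) # no negatives to compute specificity on
  expect_error(confusion_metrics(character(), logical()), "empty")
  expect_error(confusion_metrics("positive", c(TRUE, FALSE)), "equal length")
})

test_that("AUC matches the pair-counting value with midrank ties", {
  r <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.6, 0.7, 0.2))
  expect_equal(r$auc, 0.75) # 3 of 4 pairs correctly ordered
  expect_equal(roc_auc(c(1, 0), c(0.5, 0.5))$auc, 0.5) # tie counts half
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  expect_error(roc_auc(rep(1, 3), 1:3), "both classes")
})

test_that("AUC agrees with the oracle and with pROC on random data", {
  withr::with_seed(13, {
    for (i in 1:10) {
      y <- sample(c("positive", "negative"), 60, TRUE)
      s <- round(rnorm(60), 1) # rounding forces ties
      a <- roc_auc(y, s)$auc
      expect_equal(a, oracle_auc(y, s))
      expect_equal(
        a,
        as.numeric(pROC::auc(pROC::roc(
          response = y, predictor = s,
          levels = c("negative", "positive"), direction = "<", quiet = TRUE
        )))
      )
    }
  })
})

test_that("spliced cross-validation scores every window exactly once", {
  tw <- toy_training_windows(n = 5, m_pos = 30, m_neg = 70, seed = 3)
  ev <- cross_validate(tw, folds = 10, seed = 1)
  expect_s3_class(ev, "carb_eval")
  expect_equal(nrow(ev$predictions), nrow(tw))
  got_ids <- sort(paste(ev$predictions$protein_id, ev$predictions$position))
  expect_equal(got_ids, sort(paste(tw$protein_id, tw$position)))
  expect_equal(nrow(ev$per_fold), 10L)
  expect_true(all(ev$predictions$probability >= 0 & ev$predictions$probability <= 1))
  # the planted compositional signal is learnable
  expect_gt(ev$metrics$auc, 0.6)
  # determinism
  ev2 <- cross_validate(tw, folds = 10, seed = 1)
  expect_equal(ev$metrics, ev2$metrics)

  expect_output(print(ev), "AUC")
  td <- tidy(ev)
  expect_equal(td$metric, c("sp", "sn", "acc", "mcc", "auc"))
  expect_equal(td$value[td$metric == "auc"], ev$metrics$auc)
  expect_equal(glance(ev), ev$metrics)
})

test_that("evaluating a frozen model reports the full metric set", {
  tw <- toy_training_windows(n = 5, m_pos = 26, m_neg = 60, seed = 8)
  m <- carb_train(tw, selection = "none", seed = 2)
  ev <- carb_evaluate(m, tw) # resubstitution
  expect_equal(nrow(ev$predictions), nrow(tw))
  expect_true(all(c("sp", "sn", "acc", "mcc", "auc") %in% names(ev$metrics)))
  expect_error(carb_evaluate(m, random_windows(5, 7, seed = 1)), "expects n")
  expect_error(carb_evaluate(m, tw[0, ]), "no windows")
})

test_that("position composition tests match stats::t.test (Welch)", {
  tw <- toy_training_windows(n = 4, m_pos = 30, m_neg = 60, seed = 10)
  pos <- tw$window[tw$label == "positive"]
  neg <- tw$window[tw$label == "negative"]
  out <- position_composition_test(pos, neg)
  expect_equal(nrow(out), 8 * 21)
  expect_setequal(unique(out$offset), c(-(4:1), 1:4))

  ind <- function(wins, off, res) {
    n <- (nchar(wins[1]) - 1) / 2
    j <- n + 1 + off
    as.numeric(substr(wins, j, j) == res)
  }
  checked <- 0
  for (row in sample(seq_len(nrow(out)), 40)) {
    o <- out$offset[row]; res <- out$residue[row]
    a <- ind(pos, o, res); b <- ind(neg, o, res)
    if (stats::var(a) > 0 && stats::var(b) > 0) {
      tt <- stats::t.test(a, b)
      expect_equal(out$statistic[row], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(out$p_value[row], tt$p.value, tolerance = 1e-10)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)
  expect_error(position_composition_test(pos[1], neg), "at least 2")
})

test_that("the planted flank enrichment is detected as significant", {
  tw <- toy_training_windows(n = 5, m_pos = 120, m_neg = 240, seed = 2)
  out <- position_composition_test(
    tw$window[tw$label == "positive"], tw$window[tw$label == "negative"]
  )
  hits <- out[out$residue %in% c("R", "P", "T") & out$significant, ]
  expect_gt(nrow(hits), 3)
  expect_true(all(hits$direction == "enriched"))
})

test_that("hydrophobicity profiles average the normalized index per position", {
  hyd <- hqi8_table()[, "hydrophobicity"]
  prof <- hydrophobicity_profile(c("VKV", "VKD"), c("DKD", "DKD"))
  expect_equal(nrow(prof), 4L)
  v <- prof$mean_hydrophobicity
  expect_equal(v[prof$class == "positive" & prof$offset == -1], unname(hyd["V"]))
  expect_equal(
    v[prof$class == "positive" & prof$offset == 1],
    unname((hyd["V"] + hyd["D"]) / 2)
  )
  expect_equal(v[prof$class == "negative" & prof$offset == -1], unname(hyd["D"]))
  # positions seeing only X are NA
  px <- hydrophobicity_profile("XKV", c("DKD", "EKE"))
  expect_true(is.na(px$mean_hydrophobicity[px$class == "positive" & px$offset == -1]))
})

test_that("feature group distributions always report all four families", {
  nm <- feature_names_for(5)
  ranking <- tibble::tibble(
    rank = 1:4,
    feature = match(c("div_k1", "knn_k11", "psp_aa_p-5", "div_k2"), nm),
    name = nm[c(143, 145, 1, 144)],
    relevance = c(0.4, 0.3, 0.2, 0.1),
    score = c(0.4, 0.2, 0.1, 0.05)
  )
  out <- feature_group_distribution(ranking = ranking, names = nm, k = 3)
  expect_equal(out$group, c("pspaksap", "diversity", "knn", "hqi8"))
  expect_equal(out$count, c(1L, 1L, 1L, 0L))
  expect_equal(sum(out$count), 3L)
  expect_true(is.na(out$mean_relevance[out$group == "hqi8"]))
  expect_equal(out$mean_relevance[out$group == "diversity"], 0.4)
})
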