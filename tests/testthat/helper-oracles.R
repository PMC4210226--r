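# Shared toy builders and independent oracles used across the suite.

# random windows of half-width n centred on `residue`
random_windows <- function(m, n, residue = "K", seed = 1, labels = NULL) {
  withr::with_seed(seed, {
    aa <- setdiff(aa_alphabet(), "X")
    w <- vapply(seq_len(m), function(i) {
      ch <- sample(aa, 2 * n + 1, replace = TRUE)
      ch[n + 1] <- residue
      paste(ch, collapse = "")
    }, character(1))
    lab <- labels %||% sample(c("positive", "negative"), m,
      replace = TRUE, prob = c(0.3, 0.7)
    )
    tibble::tibble(
      protein_id = sprintf("p%04d", seq_len(m)),
      position = n + 1L, residue = residue, label = lab, window = w
    )
  })
}

# a small labelled window set with a planted compositional difference,
# enough for KNN references (>= 51 windows)
toy_training_windows <- function(n = 5, m_pos = 25, m_neg = 60, seed = 3) {
  withr::with_seed(seed, {
    aa <- setdiff(aa_alphabet(), "X")
    mk <- function(m, enriched) {
      vapply(seq_len(m), function(i) {
        p <- rep(1 / 19, 19)
        names(p) <- setdiff(aa, "K")
        if (enriched) p[c("R", "P", "T")] <- p[c("R", "P", "T")] + 0.12
        ch <- sample(names(p), 2 * n + 1, replace = TRUE, prob = p / sum(p))
        ch[n + 1] <- "K"
        paste(ch, collapse = "")
      }, character(1))
    }
    dplyr::bind_rows(
      tibble::tibble(
        protein_id = sprintf("pos%03d", seq_len(m_pos)), position = n + 1L,
        residue = "K", label = "positive", window = mk(m_pos, TRUE)
      ),
      tibble::tibble(
        protein_id = sprintf("neg%03d", seq_len(m_neg)), position = n + 1L,
        residue = "K", label = "negative", window = mk(m_neg, FALSE)
      )
    )
  })
}

# brute-force confusion metrics from first principles
oracle_confusion <- function(labels, calls) {
  y <- labels == "positive" | labels == TRUE
  p <- calls == "positive" | calls == TRUE
  tp <- sum(y & p); fp <- sum(!y & p); tn <- sum(!y & !p); fn <- sum(y & !p)
  num <- as.numeric(tp) * tn - as.numeric(fp) * fn
  den <- sqrt(as.numeric(tp + fp)) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    sp = tn / (tn + fp), sn = tp / (tp + fn),
    acc = (tp + tn) / length(y),
    mcc = if (den == 0) 0 else num / den
  )
}

# AUC by exhaustive pair counting (ties count 1/2)
oracle_auc <- function(labels, scores) {
  y <- labels == "positive" | labels == TRUE
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# independent mutual information via entropies of contingency tables
oracle_mi <- function(a, b) {
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pj <- as.vector(table(a, b)) / length(a)
  ent(table(a) / length(a)) + ent(table(b) / length(b)) - ent(pj)
}

# exhaustive greedy MID ordering using oracle_mi only
oracle_mid_order <- function(disc, labels) {
  d <- ncol(disc)
  rel <- vapply(seq_len(d), function(j) oracle_mi(disc[, j], labels), numeric(1))
  sel <- integer(0)
  remaining <- seq_len(d)
  while (length(remaining) > 0) {
    obj <- vapply(remaining, function(j) {
      if (length(sel) == 0) return(rel[j])
      rel[j] - mean(vapply(sel, function(g) oracle_mi(disc[, j], disc[, g]), numeric(1)))
    }, numeric(1))
    pick <- remaining[which.max(obj)]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  sel
}

# greedy window identity filter, all-pairs recomputation (redundancy oracle)
oracle_reduce <- function(windows, threshold) {
  ord <- order(windows$window, windows$protein_id, windows$position)
  w <- windows[ord, , drop = FALSE]
  kept <- integer(0)
  ident <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    mean(ca == cb)
  }
  for (i in seq_len(nrow(w))) {
    if (all(vapply(kept, function(j) ident(w$window[i], w$window[j]) <= threshold, logical(1)))) {
      kept <- c(kept, i)
    }
  }
  w[kept, , drop = FALSE]
}
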