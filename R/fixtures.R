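#' Configuration for the synthetic carbonylation fixture generator
#'
#' The generator emulates the statistical structure of real carbonylation
#' data: positive sites sit in RKPT-enriched flanking regions with stronger
#' enrichment upstream of the site than downstream, plus a hydrophobic band
#' at upstream offsets -6..-2; negative candidates of the same residue type
#' arise from the background composition of the same proteins. Default sizes
#' mirror the K-type training scale (266 positives, a candidate pool
#' supporting ~6x negatives).
#'
#' @param residue Centre residue type of the planted sites.
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (inclusive).
#' @param n_positive Number of planted positive sites.
#' @param enrich_upstream Extra probability mass moved onto R/K/P/T at each
#'   enriched upstream flank position of a positive site.
#' @param enrich_downstream Same, downstream.
#' @param enrich_span Half-width of the enriched flank band.
#' @param hydro_boost Extra probability mass moved onto strongly hydrophobic
#'   residues at offsets `hydro_band` of positive sites.
#' @param hydro_band Offsets (relative to the site) carrying the hydrophobic
#'   shift.
#' @param background `"uniform"` (default) or `"human"` for a human-proteome-
#'   like residue frequency table.
#' @param seed Mandatory integer seed.
#' @return A `carb_fixture_config` list.
#' @export
fixture_config <- function(residue = "K", n_proteins = 150L,
                           length_range = c(150L, 350L), n_positive = 266L,
                           enrich_upstream = 0.30, enrich_downstream = 0.15,
                           enrich_span = 10L,
                           hydro_boost = 0.25, hydro_band = -6:-2,
                           background = c("uniform", "human"), seed) {
  if (missing(seed)) abort("a seed is mandatory for fixture generation")
  background <- match.arg(background)
  if (enrich_upstream < 0 || enrich_upstream > 0.8 ||
    enrich_downstream < 0 || enrich_downstream > 0.8 ||
    hydro_boost < 0 || hydro_boost > 0.8) {
    abort("enrichment boosts must lie in [0, 0.8]")
  }
  structure(list(
    residue = residue, n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range), n_positive = as.integer(n_positive),
    enrich_upstream = enrich_upstream, enrich_downstream = enrich_downstream,
    enrich_span = as.integer(enrich_span),
    hydro_boost = hydro_boost, hydro_band = as.integer(hydro_band),
    background = background, seed = as.integer(seed)
  ), class = "carb_fixture_config")
}

# approximate human-proteome residue frequencies (UniProt-scale averages)
HUMAN_AA_FREQ <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, Q = 0.048, E = 0.071,
  G = 0.066, H = 0.026, I = 0.043, L = 0.100, K = 0.057, M = 0.021, F = 0.037,
  P = 0.063, S = 0.083, T = 0.054, Y = 0.027, V = 0.060, W = 0.012
)

HYDROPHOBIC_SET <- c("I", "L", "V", "F", "M", "W", "C")
RKPT_SET <- c("R", "K", "P", "T")

# shift `boost` probability mass onto `set`, proportionally within the set
boost_probs <- function(base, set, boost) {
  p <- base * (1 - boost)
  p[set] <- p[set] + boost * base[set] / sum(base[set])
  p / sum(p)
}

#' Generate a synthetic carbonylation dataset
#'
#' Proteins are drawn from the background composition; positive sites are
#' planted with RKPT-boosted, upstream-skewed flank composition and a
#' hydrophobic shift at the configured upstream band. Every residue of the
#' target type is listed in the truth table. Reproducible: the same config
#' (seed included) yields byte-identical output.
#'
#' @param config A [fixture_config()].
#' @return List with `proteins` (tibble `protein_id`, `sequence`),
#'   `annotations` (positive-site tibble accepted by [validate_annotations()])
#'   and `truth` (every target-type residue with `is_positive`).
#' @export
generate_fixture <- function(config) {
  stopifnot(inherits(config, "carb_fixture_config"))
  base <- if (config$background == "uniform") {
    setNames(rep(1 / 20, 20), AA20)
  } else {
    HUMAN_AA_FREQ[AA20] / sum(HUMAN_AA_FREQ)
  }
  span <- config$enrich_span
  min_sep <- 2L * 13L + 2L # keep planted flanks from overlapping
  per_protein <- ceiling(config$n_positive / config$n_proteins)
  max_per <- max(per_protein + 1L, 3L)

  withr::with_seed(config$seed, {
    lens <- sample(config$length_range[1]:config$length_range[2],
      config$n_proteins, replace = TRUE
    )
    if (sum(pmax(lens %/% min_sep - 1L, 0L)) < config$n_positive) {
      abort("infeasible fixture: too few/short proteins for the requested positives")
    }
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = base), collapse = "")
    }, character(1))
    ids <- sprintf("FIXP%03d", seq_len(config$n_proteins))

    # choose non-overlapping site positions, spread over the proteins
    slots <- purrr::map2_dfr(seq_len(config$n_proteins), lens, function(i, L) {
      k <- min(max_per, max(L %/% min_sep - 1L, 0L))
      if (k == 0) return(tibble::tibble(protein = integer(), position = integer()))
      at <- 14L + (seq_len(k) - 1L) * min_sep + sample.int(min_sep %/% 2L, k, replace = TRUE)
      at <- at[at <= L - 13L]
      tibble::tibble(protein = i, position = at)
    })
    if (nrow(slots) < config$n_positive) {
      abort("infeasible fixture: could not place the requested positive sites")
    }
    pick <- slots[sample.int(nrow(slots), config$n_positive), , drop = FALSE]
    pick <- pick[order(pick$protein, pick$position), , drop = FALSE]

    chars <- strsplit(seqs, "", fixed = TRUE)
    # Planted flanks never draw the site's own residue type: every residue of
    # that type in the fixture then sits in background-composition context, so
    # the candidate negatives keep the clean class contrast the generator is
    # meant to emulate.
    flank_base <- base
    flank_base[config$residue] <- 0
    flank_base <- flank_base / sum(flank_base)
    enrich_set <- setdiff(RKPT_SET, config$residue)
    up_p <- boost_probs(flank_base, enrich_set, config$enrich_upstream)
    down_p <- boost_probs(flank_base, enrich_set, config$enrich_downstream)
    for (r in seq_len(nrow(pick))) {
      i <- pick$protein[r]; pos <- pick$position[r]
      chars[[i]][pos] <- config$residue
      for (o in c(-(span:1), 1:span)) {
        at <- pos + o
        if (at < 1 || at > lens[i]) next
        p <- if (o < 0) up_p else down_p
        if (o %in% config$hydro_band) p <- boost_probs(p, HYDROPHOBIC_SET, config$hydro_boost)
        chars[[i]][at] <- sample(AA20, 1, prob = p)
      }
      chars[[i]][pos] <- config$residue # re-assert in case bands overlap
    }
    seqs <- vapply(chars, paste, character(1), collapse = "")
  })

  proteins <- tibble::tibble(protein_id = ids, sequence = seqs)
  annotations <- tibble::tibble(
    protein_id = ids[pick$protein],
    position = pick$position,
    residue = config$residue,
    label = "positive",
    source = "fixture"
  )
  truth <- purrr::map2_dfr(proteins$protein_id, proteins$sequence, function(id, s) {
    at <- stringr::str_locate_all(s, stringr::fixed(config$residue))[[1]][, 1]
    tibble::tibble(protein_id = id, position = as.integer(at))
  })
  truth <- dplyr::mutate(truth,
    residue = config$residue,
    is_positive = paste(.data$protein_id, .data$position) %in%
      paste(annotations$protein_id, annotations$position)
  )
  list(proteins = proteins, annotations = annotations, truth = truth)
}

#' Write a generated fixture to standard files
#'
#' Emits `proteins.fasta`, `annotations.tsv` and `truth.tsv` in `dir`.
#'
#' @param fixture Result of [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$proteins, file.path(dir, "proteins.fasta"))
  readr::write_tsv(fixture$annotations, file.path(dir, "annotations.tsv"), progress = FALSE)
  readr::write_tsv(fixture$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Prepare a ready-to-train dataset from a fixture config
#'
#' Convenience wrapper: generate the fixture, then run [prepare_dataset()] on
#' it at the given half-width.
#'
#' @param config A [fixture_config()].
#' @param n Window half-width.
#' @param ratio Negative:positive sampling ratio.
#' @return Window tibble as from [prepare_dataset()].
#' @export
fixture_dataset <- function(config, n, ratio = 6) {
  fx <- generate_fixture(config)
  prepare_dataset(fx$proteins, fx$annotations, config$residue,
    n = n, ratio = ratio, seed = config$seed
  )
}
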