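#' The 21-letter amino-acid alphabet
#'
#' Twenty standard residues plus the dummy residue `X`, which stands for
#' unknown letters and for window positions that fall outside a protein.
#' `X` always carries the last code (21).
#'
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() c(AA20, "X")

AA20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "Y", "V", "W"
)
AA21 <- c(AA20, "X")
N_AA <- 21L
N_PAIR <- 441L

# internal cache for lazily built constant tables
.carb_cache <- new.env(parent = emptyenv())

#' Replace non-standard residue letters by the dummy residue X
#'
#' Sequences are uppercased; any character outside the 20 standard one-letter
#' codes is mapped to `X`. The mapping is idempotent. A warning reports how
#' many letters were replaced.
#'
#' @param x Character vector of amino-acid sequences.
#' @param quiet Suppress the replacement warning.
#' @return Character vector of sanitized sequences.
#' @export
sanitize_sequence <- function(x, quiet = FALSE) {
  x <- toupper(x)
  bad <- stringr::str_count(x, paste0("[^", paste(AA20, collapse = ""), "]"))
  out <- stringr::str_replace_all(x, paste0("[^", paste(AA20, collapse = ""), "]"), "X")
  n_bad <- sum(stringr::str_count(x, "[^ARNDCQEGHILKMFPSTYVWX]"))
  if (!quiet && n_bad > 0) {
    warn(sprintf("%d non-standard residue letter(s) replaced by X", n_bad))
  }
  out
}

# Integer codes 1..21 for each character of equal-length sequences,
# as an n_seq x width matrix. Unknown letters map to X's code.
seq_codes <- function(x) {
  if (length(x) == 0) return(matrix(integer(), nrow = 0))
  w <- unique(nchar(x))
  if (length(w) != 1) abort("all sequences must have equal length")
  m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)), AA21),
    nrow = length(x), ncol = w, byrow = TRUE
  )
  m[is.na(m)] <- N_AA
  m
}

# code of an ordered residue pair (a, b), in 1..441
pair_code <- function(a, b) (a - 1L) * N_AA + b

# BLOSUM62 similarity on the 21-letter alphabet, min-max normalized to [0, 1]
# using the matrix's global range (-4, 11); entries involving X are NA so the
# distance computation can skip them.
blosum62_similarity <- function() {
  if (!is.null(.carb_cache$b62)) return(.carb_cache$b62)
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings", envir = environment()))
  b <- b62[AA20, AA20]
  s <- (b - (-4)) / (11 - (-4))
  out <- matrix(NA_real_, N_AA, N_AA, dimnames = list(AA21, AA21))
  out[1:20, 1:20] <- s
  .carb_cache$b62 <- out
  out
}

# AAindex accessions of the eight consensus high-quality indices (HQI8):
# electric property, hydrophobicity, alpha/turn propensity, volume,
# membrane-protein composition, intracellular composition, beta propensity,
# optimized contact energy.
HQI8_ACCESSIONS <- c(
  electric        = "BLAM930101",
  hydrophobicity  = "BIOV880101",
  alpha_turn      = "MAXF760101",
  volume          = "TSAJ990101",
  composition_mem = "NAKH920108",
  composition_ic  = "CEDJ970104",
  beta            = "LIFS790101",
  contact_energy  = "MIYS990104"
)

#' The normalized HQI8 physicochemical index table
#'
#' Eight consensus amino-acid indices (electric property, hydrophobicity,
#' alpha/turn propensity, volume, two composition indices, beta propensity and
#' an optimized contact energy), each min-max normalized to \[0, 1\] over the
#' 20 standard residues. The dummy residue `X` is all zero.
#'
#' @return A 21 x 8 numeric matrix (rows: residues incl. X, columns: indices).
#' @export
hqi8_table <- function() {
  if (!is.null(.carb_cache$hqi8)) return(.carb_cache$hqi8)
  aaindex <- get(utils::data("aaindex", package = "seqinr", envir = environment()))
  acc_all <- vapply(aaindex, function(e) e$H, character(1))
  out <- matrix(0, N_AA, length(HQI8_ACCESSIONS),
    dimnames = list(AA21, names(HQI8_ACCESSIONS))
  )
  for (j in seq_along(HQI8_ACCESSIONS)) {
    i <- match(HQI8_ACCESSIONS[j], acc_all)
    if (is.na(i)) abort(sprintf("AAindex accession %s not found", HQI8_ACCESSIONS[j]))
    v <- aaindex[[i]]$I
    one <- toupper(vapply(names(v), function(n3) seqinr::a(n3), character(1)))
    v <- v[match(AA20, one)]
    out[1:20, j] <- (v - min(v)) / (max(v) - min(v))
  }
  .carb_cache$hqi8 <- out
  out
}
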