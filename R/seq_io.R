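#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and letters outside the 20 standard one-letter
#' codes are replaced by the dummy residue `X` (with a warning giving the
#' replacement count).
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return A tibble with columns `protein_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(sprintf("FASTA parse error in %s: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0) abort(sprintf("no FASTA records in %s", path))
  ids <- stringr::str_split_fixed(names(set), "\\s+", 2)[, 1]
  if (any(!nzchar(ids))) abort("malformed FASTA header: empty record id")
  seqs <- sanitize_sequence(as.character(set))
  if (any(!nzchar(seqs))) abort("empty sequence in FASTA record")
  tibble::tibble(protein_id = ids, sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with columns `protein_id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  lines <- purrr::map2(proteins$protein_id, proteins$sequence, function(id, s) {
    body <- substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    c(paste0(">", id), body)
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a site annotation table
#'
#' The table is tab-delimited with columns `protein_id`, `position` (1-based),
#' `residue` (one of K, R, T, P) and `label` (`positive` or
#' `candidate_negative`); an optional `source` column tags the study each row
#' came from. When `proteins` is supplied the rows are validated against the
#' sequences: rows whose position is out of range or whose residue does not
#' match the sequence are removed, reported with a warning, and returned in
#' the `rejected` attribute of the result.
#'
#' @param path Path to the TSV file.
#' @param proteins Optional protein tibble from [read_fasta()] for validation.
#' @return Tibble of accepted annotations; attribute `rejected` holds a tibble
#'   of rejected rows with a `reason` column.
#' @export
read_site_annotations <- function(path, proteins = NULL) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("protein_id", "position", "residue", "label")
  if (!all(need %in% names(ann))) {
    abort(sprintf(
      "annotation table must have columns %s",
      paste(need, collapse = ", ")
    ))
  }
  ann$position <- as.integer(ann$position)
  if (is.null(proteins)) return(tibble::as_tibble(ann))
  validate_annotations(ann, proteins)
}

#' Validate site annotations against protein sequences
#'
#' @param annotations Annotation tibble (see [read_site_annotations()]).
#' @param proteins Protein tibble with `protein_id`, `sequence`.
#' @return Accepted rows as a tibble, with rejected rows (plus a `reason`
#'   column) in the `rejected` attribute. A warning summarizes rejections.
#' @export
validate_annotations <- function(annotations, proteins) {
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  ann <- tibble::as_tibble(annotations)
  reason <- rep(NA_character_, nrow(ann))
  known <- ann$protein_id %in% names(seqs)
  reason[!known] <- "unknown protein_id"
  len <- nchar(seqs[ann$protein_id])
  in_range <- known & !is.na(ann$position) & ann$position >= 1L & ann$position <= len
  reason[known & !in_range] <- "position out of range"
  at <- rep(NA_character_, nrow(ann))
  at[in_range] <- substring(seqs[ann$protein_id[in_range]], ann$position[in_range], ann$position[in_range])
  match_res <- in_range & at == ann$residue
  reason[in_range & !match_res] <- "residue mismatch"
  bad_res <- !ann$residue %in% c("K", "R", "T", "P")
  reason[bad_res & is.na(reason)] <- "residue not one of K/R/T/P"
  ok <- is.na(reason)
  rejected <- dplyr::mutate(ann[!ok, , drop = FALSE], reason = reason[!ok])
  if (nrow(rejected) > 0) {
    warn(sprintf("%d annotation row(s) rejected during validation", nrow(rejected)))
  }
  out <- ann[ok, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Extract a fixed +/-n window around one sequence position
#'
#' Returns the `2n + 1` residues centred on `position` (1-based); positions
#' that fall outside the protein are padded with the dummy residue `X`.
#'
#' @param sequence A single protein sequence.
#' @param position 1-based centre position.
#' @param n Half-width (number of flanking residues on each side).
#' @return A string of length `2n + 1`.
#' @export
extract_window <- function(sequence, position, n) {
  len <- nchar(sequence)
  if (position < 1L || position > len) {
    abort(sprintf("position %d out of range 1..%d", position, len))
  }
  idx <- (position - n):(position + n)
  chars <- rep("X", length(idx))
  inside <- idx >= 1L & idx <= len
  chars[inside] <- substring(sequence, idx[inside], idx[inside])
  paste(chars, collapse = "")
}

#' Cut sample windows for a set of annotated sites
#'
#' @param proteins Protein tibble (`protein_id`, `sequence`).
#' @param annotations Validated annotation tibble.
#' @param n Window half-width.
#' @return Tibble with `protein_id`, `position`, `residue`, `label`, `window`.
#' @export
extract_windows <- function(proteins, annotations, n) {
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  win <- purrr::map2_chr(
    annotations$protein_id, annotations$position,
    function(id, p) extract_window(seqs[[id]], p, n)
  )
  out <- dplyr::select(
    tibble::as_tibble(annotations),
    dplyr::any_of(c("protein_id", "position", "residue", "label", "source"))
  )
  out$window <- win
  out
}

#' Write a prediction table
#'
#' Tab-delimited with header; probabilities are printed with six decimals.
#'
#' @param results Prediction tibble (`protein_id`, `position`, `residue`,
#'   `probability`, `call`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(results, path) {
  out <- tibble::tibble(
    protein_id = as.character(results$protein_id %||% character()),
    position = as.integer(results$position %||% integer()),
    residue = as.character(results$residue %||% character()),
    probability = sprintf("%.6f", results$probability %||% numeric()),
    call = as.logical(results$call %||% logical())
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a prediction table written by [write_predictions()]
#'
#' @param path Path to the prediction TSV.
#' @return Prediction tibble.
#' @export
read_predictions <- function(path) {
  out <- readr::read_tsv(path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      position = readr::col_integer(),
      residue = readr::col_character(),
      probability = readr::col_double(),
      call = readr::col_logical()
    ), progress = FALSE
  )
  tibble::as_tibble(out)
}

#' Read a pre-cut window table
#'
#' Supports the two-column layout (window sequence, label) used for exchanging
#' training/testing windows, e.g. after converting a spreadsheet of sample
#' sequences to TSV. The centre residue and half-width are inferred from the
#' sequences.
#'
#' @param path Path to a TSV with columns `window` (or `sequence`) and `label`
#'   (`positive`/`negative`, or 1/0).
#' @param residue Optional expected centre residue; checked when given.
#' @return Window tibble with synthetic `protein_id`/`position` provenance.
#' @export
read_windows_tsv <- function(path, residue = NULL) {
  if (!file.exists(path)) abort(sprintf("window file not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  seq_col <- intersect(c("window", "sequence"), names(tab))[1]
  if (is.na(seq_col) || !"label" %in% names(tab)) {
    abort("window table must have columns window/sequence and label")
  }
  w <- sanitize_sequence(as.character(tab[[seq_col]]), quiet = TRUE)
  widths <- unique(nchar(w))
  if (length(widths) != 1 || widths %% 2 != 1) {
    abort("windows must share one odd length")
  }
  n <- (widths - 1L) %/% 2L
  centre <- substring(w, n + 1L, n + 1L)
  if (!is.null(residue) && any(centre != residue)) {
    abort(sprintf("%d window(s) are not centred on %s", sum(centre != residue), residue))
  }
  lab <- tolower(as.character(tab$label))
  lab[lab %in% c("1", "pos", "positive", "true")] <- "positive"
  lab[lab %in% c("0", "neg", "negative", "false")] <- "negative"
  if (!all(lab %in% c("positive", "negative"))) abort("labels must be positive/negative")
  tibble::tibble(
    protein_id = sprintf("win%05d", seq_along(w)),
    position = n + 1L,
    residue = centre,
    label = lab,
    window = w
  )
}

# half-width implied by a window tibble
window_half_width <- function(windows) {
  widths <- unique(nchar(windows$window))
  if (length(widths) != 1) abort("windows must share one length")
  (widths - 1L) %/% 2L
}
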