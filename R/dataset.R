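#' Scored-sequence records and datasets
#'
#' A `scored_seq` pairs an amino-acid sequence (20-letter alphabet plus X)
#' with a scalar score in (0, 1) and/or a per-residue score track of the
#' same length — the unit record of a distillation training set. A
#' `scored_dataset` is a list of such records with per-record provenance
#' tags (`original`, `augmented` or `synthetic`) and a bin histogram.
#'
#' @param id record identifier.
#' @param sequence one-letter amino-acid string.
#' @param scalar_score optional scalar in (0, 1).
#' @param residue_scores optional numeric vector in (0, 1), one per residue.
#' @param provenance one of `"original"`, `"augmented"`, `"synthetic"`.
#' @return `scored_seq()` returns a record of class `scored_seq`.
#' @examples
#' r <- scored_seq("r1", "ACDEFG", scalar_score = 0.7)
#' @export
scored_seq <- function(id, sequence, scalar_score = NULL,
                       residue_scores = NULL, provenance = "original") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 1L) stop("sequence must have length >= 1")
  seq_to_tokens(sequence)  # validates the alphabet
  if (is.null(scalar_score) && is.null(residue_scores))
    stop("at least one of scalar_score / residue_scores must be present")
  if (!is.null(scalar_score)) {
    stopifnot(length(scalar_score) == 1L, is.finite(scalar_score))
    if (scalar_score <= 0 || scalar_score >= 1)
      stop("scalar_score must lie strictly inside (0, 1)")
  }
  if (!is.null(residue_scores)) {
    if (length(residue_scores) != n)
      stop("residue_scores length must equal sequence length")
    if (any(!is.finite(residue_scores)) ||
        any(residue_scores <= 0) || any(residue_scores >= 1))
      stop("residue_scores must lie strictly inside (0, 1)")
  }
  provenance <- match.arg(provenance, c("original", "augmented", "synthetic"))
  structure(list(id = as.character(id), sequence = sequence,
                 scalar_score = scalar_score,
                 residue_scores = residue_scores,
                 provenance = provenance),
            class = "scored_seq")
}

# Mean score of a record: the scalar if present, else mean of the track.
record_mean_score <- function(record) {
  if (!is.null(record$scalar_score)) record$scalar_score
  else mean(record$residue_scores)
}

#' @rdname scored_seq
#' @param records list of `scored_seq` records.
#' @param binning a [score_binning()] used for the manifest histogram.
#' @return `scored_dataset()` returns an object of class `scored_dataset`.
#' @export
scored_dataset <- function(records, binning = score_binning()) {
  stopifnot(is.list(records))
  ok <- vapply(records, inherits, logical(1), what = "scored_seq")
  if (!all(ok)) stop("all records must be scored_seq objects")
  structure(list(records = records, binning = binning,
                 bin_histogram = dataset_bin_histogram(records, binning)),
            class = "scored_dataset")
}

#' @export
length.scored_dataset <- function(x) length(x$records)

#' @export
print.scored_dataset <- function(x, ...) {
  prov <- table(vapply(x$records, function(r) r$provenance, character(1)))
  cat(sprintf("<scored_dataset> %d records (%s)\n", length(x),
              paste(sprintf("%s: %d", names(prov), prov), collapse = ", ")))
  invisible(x)
}

# Histogram of (mean-)score bins over records.
dataset_bin_histogram <- function(records, binning = score_binning()) {
  h <- integer(binning$n_bins)
  if (length(records) == 0L) return(h)
  labs <- vapply(records, function(r)
    discretize_score(record_mean_score(r), binning), integer(1))
  tab <- tabulate(labs + 1L, nbins = binning$n_bins)
  as.integer(tab)
}

#' Read and write scored-sequence datasets as JSONL
#'
#' One JSON object per line with fields `id`, `sequence`, `scalar_score`,
#' `residue_scores` and `provenance`; absent scores are omitted.
#'
#' @param x a `scored_dataset` or list of [scored_seq()] records.
#' @param path file path.
#' @return `read_jsonl_dataset()` returns a `scored_dataset`.
#' @export
write_jsonl_dataset <- function(x, path) {
  records <- if (inherits(x, "scored_dataset")) x$records else x
  lines <- vapply(records, function(r) {
    obj <- Filter(Negate(is.null),
                  list(id = r$id, sequence = r$sequence,
                       scalar_score = r$scalar_score,
                       residue_scores = r$residue_scores,
                       provenance = r$provenance))
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_jsonl_dataset
#' @export
read_jsonl_dataset <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  records <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    scored_seq(o$id, o$sequence,
               scalar_score = o$scalar_score,
               residue_scores = o$residue_scores,
               provenance = o$provenance %||% "original")
  })
  scored_dataset(records)
}

#' Export a scored dataset as CSV
#'
#' Columns `id`, `sequence`, `scalar_score`, `residue_scores`
#' (semicolon-joined) and `provenance`.
#'
#' @inheritParams write_jsonl_dataset
#' @export
write_csv_dataset <- function(x, path) {
  records <- if (inherits(x, "scored_dataset")) x$records else x
  df <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    sequence = vapply(records, `[[`, character(1), "sequence"),
    scalar_score = vapply(records, function(r)
      r$scalar_score %||% NA_real_, numeric(1)),
    residue_scores = vapply(records, function(r)
      if (is.null(r$residue_scores)) "" else
        paste(format(r$residue_scores, digits = 8, trim = TRUE),
              collapse = ";"), character(1)),
    provenance = vapply(records, `[[`, character(1), "provenance")
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Dataset manifest with bin histogram
#'
#' Writes a JSON manifest recording record counts, provenance breakdown and
#' the score-bin histogram of a dataset.
#'
#' @param x a `scored_dataset`.
#' @param path output JSON path.
#' @export
write_manifest <- function(x, path) {
  stopifnot(inherits(x, "scored_dataset"))
  prov <- table(vapply(x$records, function(r) r$provenance, character(1)))
  obj <- list(n_records = length(x),
              provenance = as.list(prov),
              n_bins = x$binning$n_bins,
              bin_histogram = x$bin_histogram)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' FASTA input and output for plain sequences
#'
#' Thin wrappers over \pkg{Biostrings}.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  if (is.null(names(sequences)))
    names(x) <- paste0("seq", seq_along(sequences))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
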