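# Dataset curation: similarity filtering against holdout splits, length
# cropping, sequence perturbation for augmentation, score balancing and
# inverse-frequency sampling weights.

kmer_set <- function(sequence, k = 3L) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  unique(substring(sequence, 1:(n - k + 1L), k:n))
}

#' Sequence similarity (percent) between a query and a subject
#'
#' Two interchangeable definitions. `"kmer"` (default): the fraction of the
#' query's distinct k-mers (k = 3) contained in the subject's k-mer set,
#' times 100 — a cheap containment proxy that is 100 for identical
#' sequences. `"identity"`: exact global Needleman-Wunsch identity
#' (match = 1, mismatch = 0, gap = 0, via \pkg{Biostrings}) normalized by
#' the query length, times 100.
#'
#' @param query,subject amino-acid strings.
#' @param method `"kmer"` or `"identity"`.
#' @param k k-mer size for the containment proxy.
#' @return Similarity in `[0, 100]`.
#' @export
seq_similarity <- function(query, subject, method = c("kmer", "identity"),
                           k = 3L) {
  method <- match.arg(method)
  if (method == "kmer") {
    qk <- kmer_set(query, k)
    if (length(qk) == 0L)   # query shorter than k: fall back to identity
      return(seq_similarity(query, subject, method = "identity"))
    sk <- kmer_set(subject, k)
    100 * mean(qk %in% sk)
  } else {
    m <- diag(1, length(AAX))
    dimnames(m) <- list(AAX, AAX)
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(subject),
      substitutionMatrix = m, gapOpening = 0, gapExtension = 0,
      type = "global", scoreOnly = TRUE)
    100 * sc / nchar(query)
  }
}

#' Remove candidates similar to a holdout split
#'
#' Drops every candidate record whose similarity to any holdout sequence is
#' at or above `threshold` percent (default 40, the usual leakage guard
#' against validation/test splits of a downstream benchmark).
#'
#' @param candidates list of [scored_seq()] records (or a `scored_dataset`).
#' @param holdout character vector of holdout sequences.
#' @param threshold percent similarity in (0, 100].
#' @param method,k passed to [seq_similarity()].
#' @return The retained records, as a list.
#' @export
filter_by_similarity <- function(candidates, holdout, threshold = 40,
                                 method = c("kmer", "identity"), k = 3L) {
  method <- match.arg(method)
  if (inherits(candidates, "scored_dataset")) candidates <- candidates$records
  if (length(candidates) == 0L) return(list())
  stopifnot(length(holdout) > 0L, threshold > 0, threshold <= 100)
  keep <- vapply(candidates, function(r) {
    sims <- vapply(holdout, function(h)
      seq_similarity(r$sequence, h, method = method, k = k), numeric(1))
    all(sims < threshold)
  }, logical(1))
  candidates[keep]
}

#' Crop a record to a maximum length
#'
#' Sequences longer than `max_len` (default 500) are cut to a contiguous
#' window whose start is chosen uniformly at random; the per-residue score
#' track, when present, is cropped with the same window. Shorter records
#' are returned unchanged.
#'
#' @param record a [scored_seq()].
#' @param max_len maximum length (>= 1).
#' @param seed optional integer seed for the window choice.
#' @return A [scored_seq()] of length at most `max_len`.
#' @export
crop_sequence <- function(record, max_len = 500L, seed = NULL) {
  stopifnot(inherits(record, "scored_seq"), max_len >= 1L)
  n <- nchar(record$sequence)
  if (n <= max_len) return(record)
  start <- with_seed(seed, sample.int(n - max_len + 1L, 1L))
  scored_seq(record$id,
             substr(record$sequence, start, start + max_len - 1L),
             scalar_score = record$scalar_score,
             residue_scores = if (is.null(record$residue_scores)) NULL else
               record$residue_scores[start:(start + max_len - 1L)],
             provenance = record$provenance)
}

#' Perturb a sequence for dataset augmentation
#'
#' Length-preserving perturbations of a contiguous segment covering
#' approximately `intensity` of the sequence: `segment_permute` shuffles the
#' segment in place; `segment_replace` substitutes it with residues drawn
#' from a supplied amino-acid frequency (uniform by default — pass the
#' dataset's empirical frequency to mimic its composition). The output
#' carries no score: perturbed sequences are to be re-scored by a scorer
#' (a trained distill model or the synthetic oracle).
#'
#' @param record a [scored_seq()].
#' @param op `"segment_permute"` or `"segment_replace"`.
#' @param intensity fraction of the length to perturb, in (0, 1].
#' @param freq optional amino-acid sampling weights named by `AA20` letters
#'   (for `segment_replace`).
#' @param seed optional integer seed.
#' @return A list with class `scored_seq` shape but `scalar_score` and
#'   `residue_scores` both NULL and provenance `"augmented"` (scores must be
#'   assigned before it can enter a `scored_dataset`).
#' @export
augment_perturb <- function(record, op = c("segment_permute",
                                           "segment_replace"),
                            intensity = 0.3, freq = NULL, seed = NULL) {
  op <- match.arg(op)
  stopifnot(inherits(record, "scored_seq"))
  if (intensity <= 0 || intensity > 1)
    stop("intensity must lie in (0, 1]")
  n <- nchar(record$sequence)
  out <- record
  out$scalar_score <- NULL
  out$residue_scores <- NULL
  out$provenance <- "augmented"
  if (n < 2L) {
    warning("sequence too short for segment operations; returned unchanged")
    return(out)
  }
  with_seed(seed, {
    seg_len <- max(1L, min(n, as.integer(ceiling(intensity * n))))
    start <- sample.int(n - seg_len + 1L, 1L)
    ch <- strsplit(record$sequence, "")[[1]]
    idx <- start:(start + seg_len - 1L)
    if (op == "segment_permute") {
      ch[idx] <- ch[sample(idx)]
    } else {
      w <- if (is.null(freq)) rep(1, 20) else freq[AA20]
      ch[idx] <- sample(AA20, seg_len, replace = TRUE, prob = w)
    }
    out$sequence <- paste(ch, collapse = "")
  })
  out
}

#' Balance a dataset by thinning high-score records
#'
#' The distillation corpora are heavily skewed towards high scores; this
#' keeps every record whose mean score is below `keep_below` and retains
#' records at or above the cutoff independently with probability
#' `keep_fraction_above`. Before/after bin histograms are attached as
#' attributes `hist_before` / `hist_after`.
#'
#' @param records list of [scored_seq()] records (or a `scored_dataset`).
#' @param keep_below score cutoff in (0, 1).
#' @param keep_fraction_above retention probability for records above the
#'   cutoff, in `[0, 1]`.
#' @param binning a [score_binning()] for the reported histograms.
#' @param seed optional integer seed.
#' @return The retained records (list), with histogram attributes.
#' @export
balance_filter <- function(records, keep_below = 0.8,
                           keep_fraction_above = 0.25,
                           binning = score_binning(), seed = NULL) {
  if (inherits(records, "scored_dataset")) records <- records$records
  stopifnot(keep_below > 0, keep_below < 1,
            keep_fraction_above >= 0, keep_fraction_above <= 1)
  if (length(records) == 0L) return(records)
  ms <- vapply(records, record_mean_score, numeric(1))
  keep <- with_seed(seed,
    ms < keep_below | stats::runif(length(records)) < keep_fraction_above)
  out <- records[keep]
  attr(out, "hist_before") <- dataset_bin_histogram(records, binning)
  attr(out, "hist_after") <- dataset_bin_histogram(out, binning)
  out
}

#' Inverse-frequency sampling weights
#'
#' Weight of a record is proportional to the inverse frequency of its
#' (mean-)score bin; weights are normalized to sum to one. Drawing
#' minibatches with these weights exposes all score bins near-uniformly,
#' countering the skew of the training corpus.
#'
#' @param records list of [scored_seq()] records (or a `scored_dataset`).
#' @param binning a [score_binning()].
#' @return Positive numeric weights summing to 1, one per record.
#' @export
sampling_weights <- function(records, binning = score_binning()) {
  if (inherits(records, "scored_dataset")) records <- records$records
  if (length(records) == 0L) stop("no records")
  labs <- vapply(records, function(r)
    discretize_score(record_mean_score(r), binning), integer(1))
  counts <- tabulate(labs + 1L, nbins = binning$n_bins)
  w <- 1 / counts[labs + 1L]
  w / sum(w)
}

#' Generate random synthetic scored sequences
#'
#' Uniform-random sequences over the 20-letter alphabet, scored by the
#' supplied scorer (a trained distill model via [predict()][sc_distill], or
#' the [synthetic oracle][make_oracle]). Scores outside (0, 1) raise an
#' error.
#'
#' @param n number of records (>= 1).
#' @param scorer function taking a sequence and returning either a scalar
#'   in (0, 1) or a list with elements `scalar` and/or `residue`.
#' @param length_range integer bounds for sequence length.
#' @param seed optional integer seed.
#' @return A list of [scored_seq()] records with provenance `"synthetic"`.
#' @export
generate_synthetic_scored <- function(n, scorer, length_range = c(30L, 80L),
                                      seed = NULL) {
  stopifnot(n >= 1L, is.function(scorer), length(length_range) == 2L)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      s <- random_sequence(len)
      sc <- scorer(s)
      if (is.numeric(sc)) sc <- list(scalar = sc)
      if (!is.null(sc$scalar) &&
          (sc$scalar <= 0 || sc$scalar >= 1))
        stop("scorer returned scalar outside (0, 1)")
      if (!is.null(sc$residue) &&
          (any(sc$residue <= 0) || any(sc$residue >= 1)))
        stop("scorer returned residue scores outside (0, 1)")
      scored_seq(sprintf("synth%05d", i), s,
                 scalar_score = sc$scalar,
                 residue_scores = sc$residue,
                 provenance = "synthetic")
    })
  })
}
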