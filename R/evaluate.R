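#' Sequence recovery
#'
#' Percentage of positions at which two equal-length sequences carry the
#' same residue: `100 * matches / length`. Symmetric in its arguments.
#'
#' @param predicted,truth equal-length amino-acid strings.
#' @return Recovery in `[0, 100]`.
#' @examples
#' recovery("ACDE", "ACDF")  # 75
#' @export
recovery <- function(predicted, truth) {
  if (nchar(predicted) != nchar(truth))
    stop("sequences differ in length")
  a <- strsplit(predicted, "")[[1]]
  b <- strsplit(truth, "")[[1]]
  100 * mean(a == b)
}

#' Sequence diversity of a design set
#'
#' The complement of the mean pairwise recovery over all ordered pairs of
#' distinct samples: `100 - mean_{i != j} recovery(s_i, s_j)`. 0 when all
#' samples are identical, 100 when every pair disagrees at every position.
#'
#' @param samples character vector of >= 2 equal-length sequences.
#' @return Diversity in `[0, 100]`.
#' @export
diversity <- function(samples) {
  if (length(samples) < 2L) stop("diversity needs at least 2 samples")
  M <- do.call(rbind, strsplit(samples, ""))
  n <- nrow(M)
  tot <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      tot <- tot + mean(M[i, ] == M[j, ])
  100 - 100 * tot / (n * (n - 1L) / 2L)
}

#' Perplexity of the true residues under a model
#'
#' `exp` of the mean negative natural log of the per-position probabilities
#' assigned to the ground-truth residues. 1 for a perfect model; equals the
#' alphabet size for a uniform model. Zero probabilities are clamped at
#' 1e-12 with a warning.
#'
#' @param probs_of_truth numeric vector of per-position probabilities in
#'   `(0, 1]`.
#' @return Perplexity >= 1.
#' @examples
#' perplexity(rep(1 / 20, 50))  # 20
#' @export
perplexity <- function(probs_of_truth) {
  stopifnot(length(probs_of_truth) >= 1L)
  if (any(probs_of_truth <= 0)) {
    warning("zero probabilities clamped at 1e-12")
    probs_of_truth <- pmax(probs_of_truth, 1e-12)
  }
  if (any(probs_of_truth > 1)) stop("probabilities above 1")
  exp(mean(-log(probs_of_truth)))
}

#' Recovery and diversity broken down by residue burial class
#'
#' Classifies every residue of the target structure by Cα neighbor density
#' ([neighbor_density_class()]: core >= 24 neighbors within 10 Å, surface
#' <= 16, else intermediate) and computes recovery (mean over samples,
#' restricted to each class's positions) and diversity (pairwise, ditto)
#' per class and over all positions.
#'
#' @param samples character vector of designed sequences, equal length.
#' @param truth ground-truth sequence of the same length.
#' @param structure the target [backbone()], same length.
#' @return An object of class `design_eval`: a data.frame with one row per
#'   class (`core`, `intermediate`, `surface`, `all`) and columns
#'   `n_positions`, `recovery`, `diversity` (NA where the class is empty
#'   or there are fewer than 2 samples).
#' @export
per_class_report <- function(samples, truth, structure) {
  stopifnot(length(samples) >= 1L, inherits(structure, "backbone"))
  L <- nchar(truth)
  if (length(structure) != L)
    stop("structure length must equal sequence length")
  if (any(nchar(samples) != L)) stop("samples must match the truth length")
  cls <- as.character(neighbor_density_class(structure)$class)
  Ms <- do.call(rbind, strsplit(samples, ""))
  tv <- strsplit(truth, "")[[1]]
  one <- function(pos) {
    if (length(pos) == 0L)
      return(c(n_positions = 0, recovery = NA_real_, diversity = NA_real_))
    rec <- mean(vapply(seq_len(nrow(Ms)), function(i)
      100 * mean(Ms[i, pos] == tv[pos]), numeric(1)))
    div <- if (nrow(Ms) < 2L) NA_real_ else {
      n <- nrow(Ms); tot <- 0
      for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
          tot <- tot + mean(Ms[i, pos] == Ms[j, pos])
      100 - 100 * tot / (n * (n - 1L) / 2L)
    }
    c(n_positions = length(pos), recovery = rec, diversity = div)
  }
  classes <- c("core", "intermediate", "surface")
  rows <- lapply(classes, function(cl) one(which(cls == cl)))
  rows <- c(rows, list(one(seq_len(L))))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(class = c(classes, "all"), out)
  class(out) <- c("design_eval", "data.frame")
  out
}

#' @export
print.design_eval <- function(x, ...) {
  cat("Per-class design evaluation (recovery / diversity, %):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Percent gain over a baseline
#'
#' `100 * (x - baseline) / baseline` — the format used to report recovery
#' and diversity gains of a regularized model over its unregularized
#' baseline.
#'
#' @param x,baseline numeric values (baseline non-zero).
#' @export
percent_gain <- function(x, baseline) {
  stopifnot(all(baseline != 0))
  100 * (x - baseline) / baseline
}
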