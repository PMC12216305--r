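#' Score discretization over (0, 1)
#'
#' The distillation targets (TM/pTM scalars, per-residue lDDT/pLDDT) live in
#' the open interval (0, 1) and are discretized into `n_bins` equal-width
#' classes — 50 by default, matching the classifier vocabulary. Bins are
#' half-open `[edge, edge + width)` with the final bin closed, so
#' discretization is total and deterministic. Class labels are 0-based
#' (`0 .. n_bins - 1`), matching the bin arithmetic
#' `label = floor((x - lo) / width)`; note this differs from R's usual
#' 1-based indexing.
#'
#' @param n_bins number of bins (>= 2), default 50.
#' @param lo,hi interval bounds, default (0, 1).
#' @return An object of class `score_binning`.
#' @examples
#' b <- score_binning()
#' discretize_score(0.511, b)  # 25
#' bin_center(49, b)           # 0.99
#' @export
score_binning <- function(n_bins = 50L, lo = 0, hi = 1) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L, hi > lo)
  structure(list(n_bins = n_bins, lo = lo, hi = hi,
                 width = (hi - lo) / n_bins),
            class = "score_binning")
}

#' @export
print.score_binning <- function(x, ...) {
  cat(sprintf("<score_binning> %d bins over (%g, %g), width %g\n",
              x$n_bins, x$lo, x$hi, x$width))
  invisible(x)
}

#' @rdname score_binning
#' @param x score(s) in `[lo, hi]`; values exactly at the bounds are clamped
#'   into the open interval by one machine epsilon before discretization.
#' @param binning a [score_binning()].
#' @export
discretize_score <- function(x, binning = score_binning()) {
  stopifnot(inherits(binning, "score_binning"))
  if (any(!is.finite(x)) || any(x < binning$lo) || any(x > binning$hi))
    stop("score outside [", binning$lo, ", ", binning$hi, "]")
  eps <- .Machine$double.eps
  x <- pmin(pmax(x, binning$lo + eps), binning$hi - eps)
  lab <- floor((x - binning$lo) / binning$width)
  as.integer(pmin(pmax(lab, 0), binning$n_bins - 1L))
}

#' @rdname score_binning
#' @param label 0-based class label(s) in `[0, n_bins)`.
#' @export
bin_center <- function(label, binning = score_binning()) {
  stopifnot(inherits(binning, "score_binning"))
  if (any(label < 0L) || any(label >= binning$n_bins))
    stop("label outside [0, ", binning$n_bins, ")")
  binning$lo + (label + 0.5) * binning$width
}

#' @rdname score_binning
#' @description `bin_centers()` returns all `n_bins` centers in order.
#' @export
bin_centers <- function(binning = score_binning()) {
  bin_center(seq_len(binning$n_bins) - 1L, binning)
}
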