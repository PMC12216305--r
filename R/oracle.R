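#' Synthetic sequence-to-score oracle
#'
#' A deterministic stand-in for folding-model confidence labels at desk
#' scale. Per-residue scores are a logistic function of the local
#' amino-acid composition: fixed random per-letter coefficients `w` are
#' drawn once from the seed, and residue i scores
#' `plogis(gain * sum_a w_a x_ia + bias)` where `x_i` is the composition of
#' the window of half-width `half_width` around i. The scalar score is the
#' unweighted mean of the per-residue track (the same way mean-pLDDT
#' summarizes a per-residue confidence track). Outputs are strictly inside
#' (0, 1) and depend only on the sequence.
#'
#' @param seed integer seed fixing the coefficients.
#' @param half_width feature window half-width (window size `2h + 1`).
#' @param gain,bias logistic link parameters; the defaults spread scalar
#'   scores of random sequences over a wide band of the 50-bin vocabulary.
#' @return An object of class `sc_oracle`; score sequences with
#'   [predict.sc_oracle()].
#' @examples
#' orc <- make_oracle(seed = 7)
#' predict(orc, "ACDEFGHIKLMNPQRSTVWY")$scalar
#' @export
make_oracle <- function(seed = 1L, half_width = 4L, gain = 1, bias = 0) {
  w <- with_seed(seed, stats::rnorm(20L, sd = 3))
  coef <- c(w, 0)   # X contributes nothing
  structure(list(coef = coef, half_width = as.integer(half_width),
                 gain = gain, bias = bias, seed = as.integer(seed)),
            class = "sc_oracle")
}

#' @export
print.sc_oracle <- function(x, ...) {
  cat(sprintf(
    "<sc_oracle> logistic of %d-wide windowed composition (seed %d)\n",
    2L * x$half_width + 1L, x$seed))
  invisible(x)
}

#' @rdname make_oracle
#' @param object an `sc_oracle`.
#' @param sequence amino-acid string.
#' @param ... unused.
#' @return `predict()` returns `list(scalar = <mean score>, residue =
#'   <per-residue scores>)`.
#' @export
predict.sc_oracle <- function(object, sequence, ...) {
  P <- tokens_onehot(seq_to_tokens(sequence))
  X <- window_features(P, object$half_width)
  eta <- object$gain * as.vector(X %*% object$coef) + object$bias
  res <- stats::plogis(eta)
  eps <- 1e-9   # keep strictly inside (0, 1)
  res <- pmin(pmax(res, eps), 1 - eps)
  list(scalar = mean(res), residue = res)
}

#' Turn an oracle (or distill model) into a plain scoring function
#'
#' @param object an `sc_oracle` or `sc_distill` fit.
#' @param type `"both"`, `"scalar"` or `"residue"`.
#' @return A function `sequence -> list(scalar, residue)` (or a bare
#'   numeric for `"scalar"`), suitable for [generate_synthetic_scored()].
#' @export
as_scorer <- function(object, type = c("both", "scalar", "residue")) {
  type <- match.arg(type)
  function(sequence) {
    p <- predict(object, sequence)
    switch(type,
           both = p,
           scalar = p$scalar,
           residue = list(residue = p$residue))
  }
}
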