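#' Structure-consistency loss
#'
#' `sum_i (1 - SC_i)` over per-sample structure-consistency scores — the
#' regularization term added to a design model's reconstruction loss.
#' Differentiable (linear) in the scores. Scores must lie in `[0, 1]`; the
#' interior is the operating regime, the closed bounds are the loss's
#' limits (0 when every score is 1, N when every score is 0).
#'
#' @param sc_scores numeric vector of SC scores in `[0, 1]`, length >= 1.
#' @return Non-negative loss.
#' @examples
#' sc_loss(c(0.8, 0.6))  # 0.6
#' @export
sc_loss <- function(sc_scores) {
  if (length(sc_scores) == 0L) stop("sc_scores must be non-empty")
  if (any(!is.finite(sc_scores)) || any(sc_scores < 0) || any(sc_scores > 1))
    stop("SC scores must lie in [0, 1]")
  sum(1 - sc_scores)
}

#' Combined reconstruction + structure-consistency objective
#'
#' Assembles `total = ce + alpha * sc_loss(sc_scores)` exactly, the
#' regularized training objective: the downstream task's cross-entropy plus
#' the weighted structure-consistency term. `alpha = 1` is the reference
#' setting; `alpha = 0` switches the regularizer off (total equals `ce`
#' bit-for-bit).
#'
#' @param ce non-negative reconstruction (cross-entropy) loss.
#' @param sc_scores per-sample SC scores in `[0, 1]`.
#' @param alpha non-negative weight of the SC term (default 1).
#' @return An object of class `sc_loss_term` with fields `ce_loss`,
#'   `sc_loss`, `alpha`, `total` and `sc_scores`.
#' @examples
#' combined_loss(2, c(0.5), alpha = 1)$total  # 2.5
#' @export
combined_loss <- function(ce, sc_scores, alpha = 1) {
  stopifnot(length(ce) == 1L, is.finite(ce), ce >= 0)
  if (alpha < 0) stop("alpha must be non-negative")
  sc <- if (alpha == 0 && length(sc_scores) == 0L) 0 else sc_loss(sc_scores)
  structure(list(ce_loss = ce, sc_loss = sc, alpha = alpha,
                 total = ce + alpha * sc, sc_scores = sc_scores),
            class = "sc_loss_term")
}

#' @export
print.sc_loss_term <- function(x, ...) {
  cat(sprintf(
    "<sc_loss_term> total %.6g = ce %.6g + alpha %.3g * sc %.6g (N = %d)\n",
    x$total, x$ce_loss, x$alpha, x$sc_loss, length(x$sc_scores)))
  invisible(x)
}

# Soft forward through the distill model from an L x 20 row-stochastic
# matrix; returns the scalar SC score and (optionally) its gradient w.r.t.
# the input probabilities. Per-residue models are reduced to a scalar by
# the unweighted mean of the per-position expected scores.
distill_soft_score <- function(model, probs, gradient = FALSE,
                               validate = TRUE) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 20L)
    stop("soft input must have 20 columns (amino-acid probabilities)")
  if (validate && any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  L <- nrow(probs)
  P21 <- cbind(probs, 0)   # X channel carries no mass
  X <- window_features(P21, model$config$half_width)
  fw <- distill_forward(model$weights, X, rep(1L, L), L)
  cen <- bin_centers(model$binning)
  if (model$target == "scalar") {
    p <- softmax(as.vector(fw$Zs))
    score <- sum(p * cen)
    if (!gradient) return(list(score = score))
    dZs <- p * (cen - score)                      # de/dz for expectation
    dHbar <- as.vector(model$weights$Ws %*% dZs)
    dH <- matrix(dHbar, L, length(dHbar), byrow = TRUE) / L
  } else {
    Pm <- softmax_rows(fw$Zr)
    e <- as.vector(Pm %*% cen)
    score <- mean(e)
    if (!gradient) return(list(score = score))
    dZr <- Pm * (matrix(cen, L, length(cen), byrow = TRUE) - e) / L
    dH <- dZr %*% t(model$weights$Wr)
  }
  dA <- dH * (1 - fw$H^2)
  dX <- dA %*% t(model$weights$W1)
  dP21 <- window_features_adjoint(dX, model$config$half_width)
  list(score = score, grad = dP21[, 1:20, drop = FALSE])
}

# Unvalidated scalar readout, used by finite-difference checks where a
# single perturbed entry breaks row-stochasticity.
distill_soft_score_raw <- function(model, probs)
  distill_soft_score(model, probs, validate = FALSE)$score

#' Structure-consistency scores for generated sequences
#'
#' Feeds candidate designs through a frozen distill model and returns one
#' SC score per sample (per-residue models are averaged to a scalar).
#' `mode = "hard"` embeds discrete sequences (no gradient path to the
#' generator); `mode = "soft"` feeds per-position probability vectors over
#' the 20-letter alphabet through the model, so the score is smooth in the
#' generator's distributions — at one-hot inputs the two modes agree. With
#' `gradient = TRUE` (soft mode) each score carries its analytic gradient
#' with respect to the input probability matrix as attribute `gradients`.
#'
#' @param distill_model a trained [sc_distill] fit (kept frozen).
#' @param generated list of amino-acid strings (hard mode) or of L x 20
#'   row-stochastic matrices with columns ordered as `ACDEFGHIKLMNPQRSTVWY`
#'   (soft mode).
#' @param mode `"soft"` or `"hard"`.
#' @param gradient logical; attach per-sample gradients (soft mode only).
#' @return Numeric vector of SC scores in (0, 1), one per sample; with
#'   `gradient = TRUE`, attribute `gradients` is a list of L x 20 matrices.
#' @export
score_generated <- function(distill_model, generated,
                            mode = c("soft", "hard"), gradient = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(distill_model, "sc_distill"))
  if (!is.list(generated)) generated <- list(generated)
  if (length(generated) == 0L) stop("generated must be non-empty")
  if (mode == "hard") {
    scores <- vapply(generated, function(s) {
      p <- predict(distill_model, s)
      if (distill_model$target == "scalar") p$scalar else mean(p$residue)
    }, numeric(1))
    return(scores)
  }
  out <- lapply(generated, function(P)
    distill_soft_score(distill_model, P, gradient = gradient))
  scores <- vapply(out, `[[`, numeric(1), "score")
  if (gradient) attr(scores, "gradients") <- lapply(out, `[[`, "grad")
  scores
}
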