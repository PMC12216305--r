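# Windowed-composition features shared by the distill model and the
# synthetic oracle.

# One-hot matrix (L x 21) for a token vector over AAX.
tokens_onehot <- function(tokens) {
  P <- matrix(0, length(tokens), length(AAX))
  P[cbind(seq_along(tokens), tokens)] <- 1
  P
}

# Row i of the result is the mean of rows max(1, i-h) .. min(L, i+h) of P:
# the local amino-acid composition in a window of half-width h. P may be
# one-hot (hard sequences) or row-stochastic (soft distributions).
window_features <- function(P, half_width = 4L) {
  L <- nrow(P)
  cs <- rbind(0, apply(P, 2L, cumsum))
  lo <- pmax(1L, seq_len(L) - half_width)
  hi <- pmin(L, seq_len(L) + half_width)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# Adjoint of window_features: given dX (L x K), return dP such that
# <dX, window_features(P)> = <dP, P>. Needed for gradients through soft
# sequence distributions.
window_features_adjoint <- function(dX, half_width = 4L) {
  L <- nrow(dX)
  lo <- pmax(1L, seq_len(L) - half_width)
  hi <- pmin(L, seq_len(L) + half_width)
  W <- dX / (hi - lo + 1L)
  # dP[j, ] = sum over i with lo_i <= j <= hi_i of W[i, ]
  cs <- apply(W, 2L, cumsum)
  cs <- rbind(0, cs)
  # position j is inside window of i iff i in [j - h, j + h] (clipped)
  jlo <- pmax(1L, seq_len(L) - half_width)
  jhi <- pmin(L, seq_len(L) + half_width)
  cs[jhi + 1L, , drop = FALSE] - cs[jlo, , drop = FALSE]
}
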