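#' Generate a toy Cα backbone
#'
#' Three generators used throughout the test fixtures and the toy design
#' task: `helix` places residues on ideal alpha-helix Cα geometry (rise
#' ~1.5 Å per residue, ~3.6 residues per turn, radius 2.3 Å, consecutive
#' Cα-Cα distance ~3.8 Å); `extended` spaces residues 3.5 Å apart along an
#' axis with a slight zig-zag; `random_coil` runs a self-avoiding random
#' walk with 3.8 Å steps (minimum non-consecutive separation 3.6 Å).
#'
#' @param length number of residues (>= 2).
#' @param kind one of `"helix"`, `"extended"`, `"random_coil"`.
#' @param seed optional integer seed (used by `random_coil`).
#' @param max_retries bounded retries for self-avoiding placement.
#' @return A [backbone()] object.
#' @examples
#' bb <- make_backbone(20, "helix")
#' range(sqrt(rowSums(diff(bb$ca_coords)^2)))
#' @export
make_backbone <- function(length, kind = c("helix", "extended", "random_coil"),
                          seed = NULL, max_retries = 200L) {
  kind <- match.arg(kind)
  stopifnot(length >= 2L)
  coords <- switch(kind,
    helix = {
      i <- seq_len(length) - 1L
      theta <- i * 2 * pi / 3.6
      cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    },
    extended = {
      i <- seq_len(length) - 1L
      cbind(3.5 * i, 0.6 * (i %% 2L), 0)
    },
    random_coil = with_seed(seed, {
      p <- matrix(0, length, 3)
      for (i in 2:length) {
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          u <- stats::rnorm(3)
          step <- 3.8 * u / sqrt(sum(u^2))
          cand <- p[i - 1L, ] + step
          prior <- p[seq_len(max(1L, i - 2L)), , drop = FALSE]
          if (i == 2L ||
              min(sqrt(rowSums(sweep(prior, 2L, cand)^2))) > 3.6) {
            p[i, ] <- cand; placed <- TRUE; break
          }
        }
        if (!placed)
          stop("self-avoiding walk failed after ", max_retries, " retries")
      }
      p
    })
  )
  backbone(coords)
}

#' Displace every residue by an exact distance, orthogonal to rigid motions
#'
#' Builds a model structure in which every Cα is moved by exactly `delta` Å
#' from the reference, along directions chosen so the displacement field is
#' orthogonal to all six rigid-body modes (net translation and infinitesimal
#' rotations about the centroid). The identity superposition is then
#' stationary — and, for isotropically spread directions, optimal — so every
#' aligned pair sits at distance `delta` under the best superposition. With
#' `delta = tm_d0(L)` this realizes the analytic case TM = 0.5.
#'
#' Stationarity at the identity does not by itself guarantee optimality
#' (a draw can be a saddle, or a better superposition can exist in a far
#' basin), so each candidate is certified with the full superposition
#' search and redrawn until no superposition beats the identity.
#'
#' @param structure a [backbone()] object (the reference).
#' @param delta displacement per residue in Å.
#' @param seed integer seed for the initial random directions.
#' @param tol residual tolerance for the alternating projection.
#' @param max_draws bounded retries over direction draws.
#' @return A displaced [backbone()].
#' @examples
#' bb <- make_backbone(40, "random_coil", seed = 1)
#' tm_score(displace_backbone_exact(bb, tm_d0(40), seed = 2), bb)  # 0.5
#' @export
displace_backbone_exact <- function(structure, delta, seed = 1, tol = 1e-12,
                                    max_draws = 25L) {
  stopifnot(inherits(structure, "backbone"), delta >= 0)
  X <- structure$ca_coords
  n <- nrow(X)
  if (n < 7L) stop("need at least 7 residues to escape the rigid modes")
  Xc <- sweep(X, 2L, colMeans(X))
  # 3N-dimensional basis of rigid displacement fields
  G <- matrix(0, 3L * n, 6L)
  for (a in 1:3) G[seq(a, 3L * n, by = 3L), a] <- 1
  for (a in 1:3) {
    w <- numeric(3); w[a] <- 1
    for (i in seq_len(n))
      G[(3L * i - 2L):(3L * i), 3L + a] <-
        c(w[2] * Xc[i, 3] - w[3] * Xc[i, 2],
          w[3] * Xc[i, 1] - w[1] * Xc[i, 3],
          w[1] * Xc[i, 2] - w[2] * Xc[i, 1])
  }
  Q <- qr.Q(qr(G))
  # certification: the full superposition search must not beat the
  # identity (whose TM is exactly 1 / (1 + (delta/d0)^2) by construction);
  # draws where it does (a saddle or a better far basin) are rejected
  tm_at_identity <- 1 / (1 + (delta / tm_d0(n))^2)
  globally_optimal <- function(cand) {
    tm <- as.numeric(tm_score(backbone(cand), structure))
    tm <= tm_at_identity + 1e-9
  }
  for (draw in seq_len(max_draws)) {
    E <- with_seed(child_seed(seed, draw - 1L),
                   matrix(stats::rnorm(3L * n), n, 3L))
    res <- Inf
    for (it in 1:1000) {  # alternate: project out rigid modes, renormalize
      v <- as.vector(t(E))
      v <- v - Q %*% crossprod(Q, v)
      E <- matrix(v, n, 3L, byrow = TRUE)
      E <- E / sqrt(rowSums(E^2))
      res <- sqrt(sum(crossprod(Q, as.vector(t(E)))^2))
      if (res < tol) break
    }
    if (res >= tol) next
    cand <- X + delta * E
    if (delta == 0 || globally_optimal(cand))
      return(backbone(cand, residue_ids = structure$residue_ids,
                      sequence = structure$sequence))
  }
  stop("no direction draw with the identity superposition optimal after ",
       max_draws, " attempts")
}

#' Perturb a backbone with Gaussian coordinate noise
#'
#' Adds independent isotropic Gaussian displacement of standard deviation
#' `magnitude` (Å, per coordinate axis) to every Cα. Magnitude 0 returns the
#' structure unchanged, and larger magnitudes yield structure pairs of
#' progressively lower TM-score and lDDT against the original — the graded
#' pairs used to exercise the structure metrics.
#'
#' @param structure a [backbone()] object.
#' @param magnitude displacement scale in Å (>= 0).
#' @param seed optional integer seed.
#' @return A perturbed [backbone()].
#' @export
perturb_backbone <- function(structure, magnitude, seed = NULL) {
  stopifnot(inherits(structure, "backbone"), magnitude >= 0)
  if (magnitude == 0) return(structure)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(3L * length(structure), sd = magnitude),
                    ncol = 3L)
    backbone(structure$ca_coords + noise,
             residue_ids = structure$residue_ids,
             sequence = structure$sequence)
  })
}
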