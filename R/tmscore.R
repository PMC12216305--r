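#' Length-dependent TM-score distance scale d0
#'
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, clamped below at 0.5 Å (the formula
#' is small or negative for L <= 21, which would blow up the score on toy
#' inputs).
#'
#' @param l_ref reference (normalization) length, a positive integer.
#' @return d0 in Å.
#' @examples
#' tm_d0(100)  # 1.24 * 85^(1/3) - 1.8
#' @export
tm_d0 <- function(l_ref) {
  stopifnot(l_ref >= 1)
  if (l_ref <= 15) return(0.5)
  max(0.5, 1.24 * (l_ref - 15)^(1 / 3) - 1.8)
}

# TM sum for given model coords under a transform, against reference coords.
tm_under_transform <- function(mod, ref, rotation, translation, d0, l_ref) {
  moved <- apply_transform(mod, rotation, translation)
  d2 <- rowSums((moved - ref)^2)
  sum(1 / (1 + d2 / d0^2)) / l_ref
}

# Deterministic canonical frame: center at the origin, principal axes of
# the coordinate covariance as the basis, with a sign convention and a
# proper-rotation guarantee. Searching from canonicalized inputs makes the
# whole superposition search invariant to the frames the structures arrive
# in. Returns the rotation/translation taking original to canonical coords.
canonical_frame <- function(coords) {
  ctr <- colMeans(coords)
  X <- sweep(coords, 2L, ctr)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  V <- ev$vectors
  for (a in 1:3) {   # sign convention: largest-|.| component positive
    j <- which.max(abs(V[, a]))
    if (V[j, a] < 0) V[, a] <- -V[, a]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  R <- t(V)
  list(coords = X %*% V, rotation = R, translation = -as.vector(R %*% ctr))
}

# Octahedral-group rotation starts (24 proper rotations of the cube),
# generated deterministically.
octahedral_rotations <- function() {
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rots <- list(diag(3))
  for (a in 1:3) for (k in 1:3)
    rots <- c(rots, list(rotvec_to_mat(axes[a, ] * (k * pi / 2))))
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1))
    rots <- c(rots, list(rotvec_to_mat(c(s1, s2, s3) / sqrt(3) * (2 * pi / 3))))
  for (v in list(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                 c(1, 0, -1), c(0, 1, 1), c(0, 1, -1)))
    rots <- c(rots, list(rotvec_to_mat(v / sqrt(2) * pi)))
  rots
}

#' TM-score between two backbones
#'
#' Template-modelling score: `TM = (1/L_ref) * sum_i 1 / (1 + (d_i/d0)^2)`
#' over corresponded Cα pairs, maximized over rigid superpositions, with the
#' length-dependent scale [tm_d0()]. Normalization length is the reference
#' length (configurable via `l_norm`). The optimization is deterministic:
#' Kabsch superposition seeded from the full correspondence and its halves,
#' iterative reselection of pairs under distance cutoffs 8, 6 and 4 Å, and a
#' final Nelder-Mead polish of the best superposition found.
#'
#' @param model,reference [backbone()] objects (or n x 3 coordinate
#'   matrices).
#' @param correspondence two-column integer matrix of paired residue indices
#'   (model, reference), 1-based; default pairs residues positionally.
#' @param l_norm normalization length; defaults to the reference length.
#' @param polish logical; run the final numerical polish (default TRUE).
#' @return TM-score in (0, 1], with attributes `superposition` (the best
#'   transform) and `d0`.
#' @examples
#' bb <- make_backbone(30, kind = "helix", seed = 1)
#' tm_score(bb, bb)  # 1
#' @export
tm_score <- function(model, reference, correspondence = NULL, l_norm = NULL,
                     polish = TRUE) {
  mc <- if (inherits(model, "backbone")) model$ca_coords else as.matrix(model)
  rc <- if (inherits(reference, "backbone")) reference$ca_coords else
    as.matrix(reference)
  if (is.null(correspondence)) {
    if (nrow(mc) != nrow(rc))
      stop("structures differ in length; supply an explicit correspondence")
    correspondence <- cbind(seq_len(nrow(mc)), seq_len(nrow(rc)))
  }
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) == 0L) stop("empty correspondence")
  if (max(correspondence[, 1L]) > nrow(mc) ||
      max(correspondence[, 2L]) > nrow(rc) || min(correspondence) < 1L)
    stop("correspondence indices out of range")
  n <- nrow(correspondence)
  if (n < 3L) stop("need at least 3 corresponded pairs")
  l_ref <- l_norm %||% nrow(rc)
  d0 <- tm_d0(l_ref)

  # canonicalize both frames so the search is rigid-motion invariant
  cm <- canonical_frame(mc[correspondence[, 1L], , drop = FALSE])
  cr <- canonical_frame(rc[correspondence[, 2L], , drop = FALSE])
  mod <- cm$coords
  ref <- cr$coords

  best <- list(tm = -Inf, rotation = diag(3), translation = numeric(3))
  # top candidate pool for the final polish stage (distinct local optima)
  pool <- list()
  pool_k <- 10L
  consider <- function(rot, tr) {
    tm <- tm_under_transform(mod, ref, rot, tr, d0, l_ref)
    if (tm > best$tm)
      best <<- list(tm = tm, rotation = rot, translation = tr)
    if (length(pool) < pool_k ||
        tm > min(vapply(pool, `[[`, numeric(1), "tm"))) {
      keep <- TRUE
      for (p in pool)   # drop near-duplicates of an existing candidate
        if (abs(p$tm - tm) < 1e-4 &&
            sum((p$translation - tr)^2) < 1e-2) { keep <- FALSE; break }
      if (keep) {
        pool[[length(pool) + 1L]] <<- list(tm = tm, rotation = rot,
                                           translation = tr)
        if (length(pool) > pool_k) {
          o <- order(vapply(pool, `[[`, numeric(1), "tm"),
                     decreasing = TRUE)
          pool <<- pool[o[seq_len(pool_k)]]
        }
      }
    }
    tm
  }
  refine <- function(rot, tr) {   # iterative close-pair reselection
    for (cutoff in c(8, 6, 4)) {
      prev <- integer(0)
      for (iter in 1:20) {
        d <- sqrt(rowSums((apply_transform(mod, rot, tr) - ref)^2))
        sel <- which(d < cutoff)
        if (length(sel) < 3L) sel <- order(d)[1:3]
        if (identical(sel, prev)) break
        prev <- sel
        sp <- suppressWarnings(kabsch_superpose(mod[sel, , drop = FALSE],
                                                ref[sel, , drop = FALSE]))
        rot <- sp$rotation; tr <- sp$translation
        consider(rot, tr)
      }
    }
  }
  # gapless fragment seeds: full chain, halves and quarters at offsets
  seeds <- list(seq_len(n))
  for (flen in unique(pmax(4L, c(n %/% 2L, n %/% 4L)))) {
    if (flen >= n) next
    offs <- unique(c(seq(1L, n - flen + 1L, by = max(1L, n %/% 4L)),
                     n - flen + 1L))
    for (o in offs) seeds <- c(seeds, list(o:(o + flen - 1L)))
  }
  # small chains have spiky TM landscapes (d0 clamped at 0.5): enumerate
  # every residue triple as an additional superposition seed
  if (n <= 20L)
    seeds <- c(seeds, utils::combn(n, 3L, simplify = FALSE))
  for (seed in seeds) {
    if (length(seed) < 3L) next
    s <- suppressWarnings(kabsch_superpose(mod[seed, , drop = FALSE],
                                           ref[seed, , drop = FALSE]))
    consider(s$rotation, s$translation)
    refine(s$rotation, s$translation)
  }
  if (polish) {
    # deterministic global restarts over the octahedral rotation group,
    # then a tight final polish of the best transform found
    nm <- function(par, rot0, maxit, reltol) {
      obj <- function(p)
        -tm_under_transform(mod, ref, rotvec_to_mat(p[1:3]) %*% rot0,
                            p[4:6], d0, l_ref)
      op <- stats::optim(par, obj, method = "Nelder-Mead",
                         control = list(reltol = reltol, maxit = maxit))
      list(tm = -op$value,
           rotation = rotvec_to_mat(op$par[1:3]) %*% rot0,
           translation = op$par[4:6])
    }
    for (R0 in octahedral_rotations()) {
      r <- nm(numeric(6), R0, maxit = 400L, reltol = 1e-8)
      consider(r$rotation, r$translation)
      refine(r$rotation, r$translation)
    }
    # tight-polish every distinct candidate in the pool, then the winner
    for (p in pool) {
      r <- nm(c(numeric(3), p$translation), p$rotation,
              maxit = 3000L, reltol = 1e-13)
      consider(r$rotation, r$translation)
    }
    r <- nm(c(numeric(3), best$translation), best$rotation,
            maxit = 6000L, reltol = 1e-15)
    consider(r$rotation, r$translation)
  }
  # map the transform back to the original frames:
  # ref_orig = Rr^-1 (R (Rm x + tm) + t - tr)
  Rr <- cr$rotation; Rm <- cm$rotation
  rot_full <- t(Rr) %*% best$rotation %*% Rm
  tr_full <- as.vector(t(Rr) %*%
                         (best$rotation %*% cm$translation +
                            best$translation - cr$translation))
  structure(best$tm,
            superposition = structure(
              list(rotation = rot_full, translation = tr_full,
                   rmsd = NA_real_), class = "superposition"),
            d0 = d0)
}
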