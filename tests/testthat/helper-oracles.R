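# Independent brute-force oracles, deliberately naive implementations kept
# separate from the package's vectorized code paths.

# lDDT by exhaustive double loop over residue pairs.
brute_lddt <- function(model, reference, radius = 15,
                       tolerances = c(0.5, 1, 2, 4)) {
  xm <- model$ca_coords; xr <- reference$ca_coords
  n <- nrow(xr)
  per <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    kept <- 0L; tot <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      dr <- sqrt(sum((xr[i, ] - xr[j, ])^2))
      if (dr > radius) next
      dm <- sqrt(sum((xm[i, ] - xm[j, ])^2))
      for (t in tolerances) {
        tot <- tot + 1L
        if (abs(dm - dr) < t) kept <- kept + 1L
      }
    }
    if (tot > 0L) per[i] <- kept / tot
  }
  list(global = mean(per, na.rm = TRUE), per_residue = per)
}

# Horn's closed-form absolute orientation (quaternion eigen-decomposition)
# -- an algorithm independent of the package's SVD Kabsch.
horn_superpose <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2L, cm); B <- sweep(fixed, 2L, cf)
  S <- crossprod(A, B)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  list(rotation = R, translation = cf - as.vector(R %*% cm))
}

# Restricted brute-force TM-score: every residue triple defines a seed
# superposition (Horn), each refined by close-pair reselection under
# cutoffs 8/6/4 A, plus random-rotation Nelder-Mead restarts; the best
# transform gets a tight final polish. Independent implementation of the
# same bounded search family as the package.
brute_tm <- function(model, reference, n_random = 24L) {
  mod <- model$ca_coords; ref <- reference$ca_coords
  n <- nrow(ref); l_ref <- n
  d0 <- scdistill::tm_d0(l_ref)
  rotvec <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  tmval <- function(R, tr) {
    moved <- sweep(mod %*% t(R), 2L, tr, "+")
    sum(1 / (1 + rowSums((moved - ref)^2) / d0^2)) / l_ref
  }
  best <- list(tm = -Inf, R = diag(3), tr = numeric(3))
  pool <- list()
  note <- function(R, tr) {
    v <- tmval(R, tr)
    if (v > best$tm) best <<- list(tm = v, R = R, tr = tr)
    if (length(pool) < 10L || v > min(vapply(pool, `[[`, numeric(1), "tm"))) {
      dup <- FALSE
      for (p in pool)
        if (abs(p$tm - v) < 1e-4 && sum((p$tr - tr)^2) < 1e-2) {
          dup <- TRUE; break
        }
      if (!dup) {
        pool[[length(pool) + 1L]] <<- list(tm = v, R = R, tr = tr)
        if (length(pool) > 10L) {
          o <- order(vapply(pool, `[[`, numeric(1), "tm"),
                     decreasing = TRUE)
          pool <<- pool[o[1:10]]
        }
      }
    }
  }
  refine <- function(R, tr) {
    for (cut in c(8, 6, 4)) {
      prev <- NULL
      for (it in 1:25) {
        d <- sqrt(rowSums((sweep(mod %*% t(R), 2L, tr, "+") - ref)^2))
        sel <- which(d < cut)
        if (length(sel) < 3L) sel <- order(d)[1:3]
        if (identical(sel, prev)) break
        prev <- sel
        h <- horn_superpose(mod[sel, , drop = FALSE], ref[sel, , drop = FALSE])
        R <- h$rotation; tr <- h$translation
        note(R, tr)
      }
    }
  }
  for (tri in utils::combn(n, 3L, simplify = FALSE)) {
    h <- horn_superpose(mod[tri, , drop = FALSE], ref[tri, , drop = FALSE])
    note(h$rotation, h$translation)
    refine(h$rotation, h$translation)
  }
  obj <- function(par) -tmval(rotvec(par[1:3]), par[4:6])
  t0 <- colMeans(ref) - colMeans(mod)
  set.seed(1234)
  for (s in seq_len(n_random)) {
    op <- stats::optim(c(stats::runif(3, -pi, pi), t0), obj,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-9, maxit = 600))
    note(rotvec(op$par[1:3]), op$par[4:6])
    refine(rotvec(op$par[1:3]), op$par[4:6])
  }
  # tight polish of every pooled candidate, then around the winner
  pol <- function(R0, tr0, maxit, reltol) {
    obj2 <- function(p) -tmval(rotvec(p[1:3]) %*% R0, tr0 + p[4:6])
    op <- stats::optim(numeric(6), obj2, method = "Nelder-Mead",
                       control = list(reltol = reltol, maxit = maxit))
    list(tm = -op$value, R = rotvec(op$par[1:3]) %*% R0,
         tr = tr0 + op$par[4:6])
  }
  for (p in pool) {
    r <- pol(p$R, p$tr, 3000L, 1e-13)
    if (r$tm > best$tm) best <- r
  }
  r <- pol(best$R, best$tr, 6000L, 1e-15)
  max(best$tm, r$tm)
}

# Minimum RMSD over proper rotations by numerical optimization.
brute_min_rmsd <- function(moving, fixed, n_starts = 12L) {
  rotvec <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(par) {
    moved <- sweep(moving %*% t(rotvec(par[1:3])), 2L, par[4:6], "+")
    sqrt(mean(rowSums((moved - fixed)^2)))
  }
  t0 <- colMeans(fixed) - colMeans(moving)
  best <- Inf
  set.seed(4321)
  for (s in seq_len(n_starts)) {
    st <- c(stats::runif(3, -pi, pi), t0)
    op <- stats::optim(st, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-15, maxit = 5000))
    op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-15, maxit = 5000))
    best <- min(best, op$value)
  }
  best
}

# Global Needleman-Wunsch identity (match 1, mismatch 0, gap 0) by explicit
# dynamic programming, normalized by the query length, in percent.
brute_nw_identity <- function(query, subject) {
  a <- strsplit(query, "")[[1]]; b <- strsplit(subject, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n))
    for (j in seq_len(m))
      D[i + 1L, j + 1L] <- max(D[i, j] + (a[i] == b[j]),
                               D[i, j + 1L], D[i + 1L, j])
  100 * D[n + 1L, m + 1L] / n
}

# Random scored records for curation tests.
random_records <- function(n, seed, len = c(20L, 40L), scores = NULL) {
  scdistill::generate_synthetic_scored(
    n, function(s) if (is.null(scores)) stats::runif(1, 0.05, 0.95)
    else sample(scores, 1L),
    length_range = len, seed = seed)
}
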