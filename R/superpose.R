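#' Kabsch superposition
#'
#' Finds the proper rotation (determinant +1; reflections are never
#' returned) and translation minimizing the RMSD between two paired point
#' sets, by SVD of the cross-covariance matrix.
#'
#' The transform maps the moving set onto the fixed set as
#' `moved = moving %*% t(rotation) + translation` (rows are points).
#' Collinear (rank-deficient) configurations are accepted: the minimizing
#' transform is still returned, but the rotation about the degenerate axis
#' is not unique; a warning is raised.
#'
#' @param moving,fixed numeric matrices of identical dimension n x 3, n >= 3.
#' @return A list of class `superposition` with elements `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Å).
#' @examples
#' p <- matrix(rnorm(24), 8, 3)
#' s <- kabsch_superpose(p + 5, p)
#' s$rmsd  # ~0
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("coordinates must be finite")
  if (nrow(moving) != nrow(fixed) || ncol(moving) != 3L || ncol(fixed) != 3L)
    stop("point sets must be matched n x 3 matrices")
  n <- nrow(moving)
  if (n < 3L) stop("at least 3 points are required for superposition")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  Pm <- sweep(moving, 2L, cm); Pf <- sweep(fixed, 2L, cf)
  H <- crossprod(Pm, Pf)                 # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1))
    warning("degenerate (collinear) point configuration: rotation not unique")
  tr <- cf - as.vector(R %*% cm)
  moved <- Pm %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Pf)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A, det(R) = %.3f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

# Apply a rotation/translation pair to an n x 3 coordinate matrix.
apply_transform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2L, translation, "+")
}

# Rodrigues: rotation vector (axis * angle) -> 3x3 rotation matrix.
rotvec_to_mat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
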