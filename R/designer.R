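#' Designer training configuration
#'
#' @param hidden hidden width of the position-wise network.
#' @param lr Adam learning rate.
#' @param iters number of minibatch steps.
#' @param batch_size sequences per minibatch.
#' @param test_fraction held-out fraction of the task's structures.
#' @param sc_mode gradient path for the SC term: `"soft"`
#'   (probability-weighted embeddings, smooth) or `"straight_through"`
#'   (hard forward on sampled sequences, soft backward).
#' @return A list of class `designer_config`.
#' @export
designer_config <- function(hidden = 32L, lr = 0.02, iters = 300L,
                            batch_size = 32L, test_fraction = 0.2,
                            sc_mode = c("soft", "straight_through")) {
  sc_mode <- match.arg(sc_mode)
  stopifnot(hidden >= 1L, lr > 0, iters >= 1L, batch_size >= 1L,
            test_fraction >= 0, test_fraction < 1)
  structure(as.list(environment()), class = "designer_config")
}

#' Train a toy structure-conditioned sequence designer
#'
#' Fits a position-wise network (structure features -> tanh hidden ->
#' 20-way residue logits) to a [make_design_task()] task by minibatch Adam
#' on the combined objective `mean_i [ CE_i + alpha * (1 - SC_i) ]`, where
#' `CE_i` is the per-sequence reconstruction cross-entropy (summed over
#' positions, the standard sequence loss) and `SC_i` is the
#' structure-consistency score of the
#' designer's soft output distributions under a frozen distill model
#' ([score_generated()], soft mode). `alpha = 0` — or no distill model —
#' trains the plain unregularized designer through an identical code path,
#' so the `alpha = 0` trajectory is bit-for-bit independent of the
#' presence of the distill model.
#'
#' @param task a [make_design_task()] task.
#' @param distill_model optional frozen [sc_distill] fit providing the SC
#'   score.
#' @param alpha non-negative SC weight (default 0; the reference
#'   regularized setting is 1).
#' @param config a [designer_config()].
#' @param seed integer seed (split, init, minibatches).
#' @return An object of class `designer_fit` with `weights`, `scaler`,
#'   `trajectory` (per-step total loss), `train_idx`, `test_idx`, `alpha`.
#' @export
train_designer <- function(task, distill_model = NULL, alpha = 0,
                           config = designer_config(), seed = 1L) {
  stopifnot(inherits(task, "design_task"), alpha >= 0)
  use_sc <- alpha > 0 && !is.null(distill_model)
  if (alpha > 0 && is.null(distill_model))
    stop("alpha > 0 requires a distill_model")
  n <- length(task$records)
  idx <- with_seed(child_seed(seed, 1L), sample.int(n))
  n_test <- floor(config$test_fraction * n)
  test_idx <- if (n_test > 0L) sort(idx[seq_len(n_test)]) else integer(0)
  train_idx <- sort(setdiff(idx, test_idx))
  if (length(train_idx) == 0L) stop("no training structures")

  d <- ncol(task$records[[1L]]$features)
  Ftr <- do.call(rbind, lapply(task$records[train_idx], `[[`, "features"))
  scaler <- list(center = colMeans(Ftr),
                 scale = pmax(apply(Ftr, 2L, stats::sd), 1e-8))
  feats <- lapply(task$records, function(r)
    sweep(sweep(r$features, 2L, scaler$center), 2L, scaler$scale, "/"))
  toks <- lapply(task$records, function(r) {
    t <- seq_to_tokens(r$sequence)
    if (any(t > 20L)) stop("task sequences must use the 20-letter alphabet")
    t
  })
  lens <- vapply(feats, nrow, integer(1))

  h <- config$hidden
  weights <- with_seed(child_seed(seed, 2L), list(
    W1 = matrix(stats::rnorm(d * h, sd = 0.5), d, h), b1 = numeric(h),
    W2 = matrix(stats::rnorm(h * 20L, sd = 0.1), h, 20L), b2 = numeric(20L)
  ))
  adam <- lapply(weights, function(w) list(m = w * 0, v = w * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
  trajectory <- numeric(config$iters)

  with_seed(child_seed(seed, 3L), {
    for (it in seq_len(config$iters)) {
      b <- sample(train_idx, min(config$batch_size, length(train_idx)),
                  replace = TRUE)
      B <- length(b)
      Xb <- do.call(rbind, feats[b])
      groups <- rep(seq_along(b), lens[b])
      H <- tanh(sweep(Xb %*% weights$W1, 2L, weights$b1, "+"))
      Z <- sweep(H %*% weights$W2, 2L, weights$b2, "+")
      P <- softmax_rows(Z)
      labs <- unlist(toks[b])
      rows <- seq_len(nrow(P))
      pt <- pmax(P[cbind(rows, labs)], 1e-12)
      # per-sequence CE is the sum of per-position CE (the standard
      # sequence reconstruction loss); the batch objective is the mean
      # over sequences of CE_i + alpha * (1 - SC_i)
      rw <- rep(1 / B, length(groups))
      ce <- sum(rw * -log(pt))
      dZ <- P * rw
      dZ[cbind(rows, labs)] <- dZ[cbind(rows, labs)] - rw
      loss <- ce
      if (use_sc) {
        sc_vals <- numeric(B)
        for (k in seq_len(B)) {
          rws <- which(groups == k)
          Pk <- P[rws, , drop = FALSE]
          if (config$sc_mode == "soft") {
            s <- distill_soft_score(distill_model, Pk, gradient = TRUE)
            sc_vals[k] <- s$score
            gP <- -(alpha / B) * s$grad       # d total / d Pk
          } else {
            # straight-through: hard forward on the sampled sequence,
            # gradient taken at the soft distributions
            samp <- apply(Pk, 1L, function(p) sample.int(20L, 1L, prob = p))
            hard <- tokens_onehot(samp)[, 1:20, drop = FALSE]
            sc_vals[k] <- distill_soft_score(distill_model, hard)$score
            gP <- -(alpha / B) *
              distill_soft_score(distill_model, Pk, gradient = TRUE)$grad
          }
          # back through the row softmax: dz = p * (g - sum(g * p))
          inner <- rowSums(gP * Pk)
          dZ[rws, ] <- dZ[rws, ] + Pk * (gP - inner)
        }
        loss <- loss + (alpha / B) * sum(1 - sc_vals)
      }
      dW2 <- crossprod(H, dZ); db2 <- colSums(dZ)
      dH <- dZ %*% t(weights$W2)
      dA <- dH * (1 - H^2)
      grad <- list(W1 = crossprod(Xb, dA), b1 = colSums(dA),
                   W2 = dW2, b2 = db2)
      step <- step + 1L
      for (nm in names(weights)) {
        g <- grad[[nm]]
        adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * g
        adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * g^2
        mh <- adam[[nm]]$m / (1 - beta1^step)
        vh <- adam[[nm]]$v / (1 - beta2^step)
        weights[[nm]] <- weights[[nm]] - config$lr * mh / (sqrt(vh) + eps)
      }
      trajectory[it] <- loss
    }
  })

  structure(list(weights = weights, scaler = scaler, config = config,
                 alpha = alpha, used_sc = use_sc,
                 trajectory = trajectory,
                 train_idx = train_idx, test_idx = test_idx,
                 seed = as.integer(seed)),
            class = "designer_fit")
}

#' @export
print.designer_fit <- function(x, ...) {
  cat(sprintf(
    "<designer_fit> alpha = %g%s, %d steps, final loss %.4f\n",
    x$alpha, if (x$used_sc) " (SC-regularized)" else "",
    length(x$trajectory), utils::tail(x$trajectory, 1L)))
  invisible(x)
}

#' @export
plot.designer_fit <- function(x, ...) {
  graphics::plot(x$trajectory, type = "l", xlab = "step",
                 ylab = "total loss", ...)
  invisible(x)
}

# Per-position residue distributions for one task record.
designer_probs <- function(object, record) {
  F <- sweep(sweep(record$features, 2L, object$scaler$center), 2L,
             object$scaler$scale, "/")
  H <- tanh(sweep(F %*% object$weights$W1, 2L, object$weights$b1, "+"))
  softmax_rows(sweep(H %*% object$weights$W2, 2L, object$weights$b2, "+"))
}

#' Predict residue distributions or decoded sequences for task records
#'
#' @param object a `designer_fit`.
#' @param records list of task records (e.g. `task$records[fit$test_idx]`).
#' @param type `"probs"` (list of L x 20 matrices) or `"decode"` (greedy
#'   argmax sequences).
#' @param ... unused.
#' @export
predict.designer_fit <- function(object, records,
                                 type = c("probs", "decode"), ...) {
  type <- match.arg(type)
  if (!is.null(records$features)) records <- list(records)
  probs <- lapply(records, function(r) designer_probs(object, r))
  if (type == "probs") return(probs)
  vapply(probs, function(P)
    paste(AA20[max.col(P, ties.method = "first")], collapse = ""),
    character(1))
}

#' Sample sequence decodes from a designer
#'
#' Draws `nsim` independent sequences per record from the designer's
#' per-position distributions — the decode set whose recovery and
#' diversity the evaluation module measures.
#'
#' @param object a `designer_fit`.
#' @param nsim samples per record (default 16).
#' @param seed integer seed.
#' @param records list of task records.
#' @param ... unused.
#' @return A list (one element per record) of character vectors of length
#'   `nsim`.
#' @export
#' @method simulate designer_fit
simulate.designer_fit <- function(object, nsim = 16L, seed = 1L,
                                  records = NULL, ...) {
  stopifnot(!is.null(records))
  if (!is.null(records$features)) records <- list(records)
  with_seed(seed, lapply(records, function(r) {
    P <- designer_probs(object, r)
    vapply(seq_len(nsim), function(k)
      paste(AA20[apply(P, 1L, function(p) sample.int(20L, 1L, prob = p))],
            collapse = ""), character(1))
  }))
}
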