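#' Focal loss for binned score classification
#'
#' `loss = -(1 - p_t)^gamma * log(p_t)` where `p_t` is the predicted
#' probability of the true class. `gamma = 0` recovers plain cross-entropy;
#' larger `gamma` down-weights well-classified examples, countering the
#' class imbalance of skewed score distributions. `p_t = 0` is clamped at
#' 1e-12 before the logarithm.
#'
#' @param class_probs probability vector (sums to 1 within 1e-6).
#' @param true_label 0-based class label.
#' @param gamma focusing parameter, >= 0 (default 2).
#' @return Non-negative loss.
#' @examples
#' focal_loss(c(0.5, 0.5), 0, gamma = 2)  # 0.25 * log(2)
#' @export
focal_loss <- function(class_probs, true_label, gamma = 2) {
  stopifnot(gamma >= 0, true_label >= 0, true_label < length(class_probs))
  if (abs(sum(class_probs) - 1) > 1e-6)
    stop("class_probs must sum to 1")
  p_t <- max(class_probs[true_label + 1L], 1e-12)
  -(1 - p_t)^gamma * log(p_t)
}

# Gradient of the focal loss w.r.t. the logits, given probs p (vector or
# matrix of rows) and 0-based labels. Returns same shape as p.
focal_grad_logits <- function(p, labels, gamma) {
  if (is.vector(p)) p <- matrix(p, 1L)
  idx <- cbind(seq_len(nrow(p)), labels + 1L)
  pt <- pmax(p[idx], 1e-12)
  om <- 1 - pt
  a <- if (gamma == 0) rep(-1, length(pt)) else
    gamma * pt * om^(gamma - 1) * log(pt) - om^gamma
  G <- -a * p
  G[idx] <- G[idx] + a
  G
}

#' Differentiable scalar readout from bin logits
#'
#' Softmax over the bin vocabulary followed by the probability-weighted
#' mean of bin centers: a smooth function of the logits, bounded inside the
#' binning interval and invariant to adding a constant to all logits. The
#' hard alternative (`readout = "argmax"`) returns the center of the
#' most probable bin.
#'
#' @param logits numeric vector over `n_bins` (or a matrix with one row per
#'   position).
#' @param binning a [score_binning()].
#' @param readout `"expectation"` (default) or `"argmax"`.
#' @return Score(s) in `(lo, hi)`.
#' @examples
#' expected_score(rep(0, 50))  # 0.5
#' @export
expected_score <- function(logits, binning = score_binning(),
                           readout = c("expectation", "argmax")) {
  readout <- match.arg(readout)
  if (is.vector(logits)) logits <- matrix(logits, 1L)
  stopifnot(all(is.finite(logits)), ncol(logits) == binning$n_bins)
  cen <- bin_centers(binning)
  out <- if (readout == "expectation") {
    as.vector(softmax_rows(logits) %*% cen)
  } else {
    cen[max.col(logits, ties.method = "first")]
  }
  out
}

#' Training configuration for the distill model
#'
#' @param n_bins classification vocabulary size (default 50).
#' @param focal_gamma focal-loss focusing parameter (default 2).
#' @param hidden width of the position-wise hidden layer.
#' @param half_width composition window half-width (window `2h + 1`).
#' @param lr Adam learning rate.
#' @param epochs,batch_size optimization schedule.
#' @param val_fraction held-out fraction for per-epoch validation CE.
#' @param weighted_sampling draw minibatches with inverse-bin-frequency
#'   weights ([sampling_weights()]).
#' @return A list of class `distill_config`.
#' @export
distill_config <- function(n_bins = 50L, focal_gamma = 2, hidden = 24L,
                           half_width = 4L, lr = 0.02, epochs = 20L,
                           batch_size = 32L, val_fraction = 0.1,
                           weighted_sampling = TRUE) {
  stopifnot(n_bins >= 2L, focal_gamma >= 0, hidden >= 1L, lr > 0,
            epochs >= 1L, batch_size >= 1L,
            val_fraction >= 0, val_fraction < 1)
  structure(as.list(environment()), class = "distill_config")
}

distill_init_weights <- function(config, seed) {
  h <- config$hidden; nb <- config$n_bins; k <- length(AAX)
  with_seed(seed, list(
    W1 = matrix(stats::rnorm(k * h, sd = 0.5), k, h),
    b1 = numeric(h),
    Wr = matrix(stats::rnorm(h * nb, sd = 0.1), h, nb),
    br = numeric(nb),
    Ws = matrix(stats::rnorm(h * nb, sd = 0.1), h, nb),
    bs = numeric(nb)
  ))
}

# Forward pass over a stacked feature matrix Xb (rows = positions of all
# sequences in the batch). Returns hidden activations and both heads.
distill_forward <- function(weights, Xb, groups, lens) {
  H <- tanh(sweep(Xb %*% weights$W1, 2L, weights$b1, "+"))
  Zr <- sweep(H %*% weights$Wr, 2L, weights$br, "+")
  Hbar <- rowsum(H, groups) / lens
  Zs <- sweep(Hbar %*% weights$Ws, 2L, weights$bs, "+")
  list(H = H, Zr = Zr, Hbar = Hbar, Zs = Zs)
}

#' Fit a sequence-to-score distill model
#'
#' Trains a small sequence model to predict binned structure-confidence
#' scores from amino-acid sequence alone. The reference architecture is a
#' position-wise network over windowed-composition features: a tanh hidden
#' layer shared across positions, a per-position head emitting logits over
#' the bin vocabulary (the per-residue pLDDT-style track), and a
#' sequence-level head reading the mean-pooled hidden state (the scalar
#' pTM-style score). Training minimizes the focal loss over discretized
#' labels with Adam, drawing minibatches with inverse-bin-frequency
#' sampling weights; a held-out split is evaluated with plain
#' cross-entropy after each epoch and the best-epoch weights are kept.
#' The whole run is deterministic given `seed`.
#'
#' @param data a `scored_dataset` or list of [scored_seq()] records carrying
#'   targets matching `target`.
#' @param target `"scalar"` (train the sequence-level head on
#'   `scalar_score`) or `"per_residue"` (train the per-position head on
#'   `residue_scores`).
#' @param config a [distill_config()].
#' @param seed integer seed for initialization, splitting and sampling.
#' @return An object of class `sc_distill` with components `weights`,
#'   `config`, `binning`, `target`, `report` (per-epoch data.frame with
#'   train focal loss and validation CE), `best_epoch` and `seed`.
#' @seealso [predict.sc_distill()], [score_generated()]
#' @export
sc_distill <- function(data, target = c("scalar", "per_residue"),
                       config = distill_config(), seed = 1L) {
  target <- match.arg(target)
  records <- if (inherits(data, "scored_dataset")) data$records else data
  if (length(records) == 0L) stop("empty dataset")
  has <- vapply(records, function(r) {
    if (target == "scalar") !is.null(r$scalar_score)
    else !is.null(r$residue_scores)
  }, logical(1))
  if (!all(has))
    stop("dataset records lack ", target, " targets required by config")
  binning <- score_binning(config$n_bins)

  # precompute features and labels once
  feats <- lapply(records, function(r)
    window_features(tokens_onehot(seq_to_tokens(r$sequence)),
                    config$half_width))
  labels <- lapply(records, function(r) {
    if (target == "scalar") discretize_score(r$scalar_score, binning)
    else discretize_score(r$residue_scores, binning)
  })
  lens <- vapply(feats, nrow, integer(1))

  n <- length(records)
  n_val <- floor(config$val_fraction * n)
  idx <- with_seed(child_seed(seed, 1L), sample.int(n))
  val <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
  train <- setdiff(idx, val)
  if (length(train) == 0L) stop("no training records after validation split")

  w_sample <- if (config$weighted_sampling && length(train) > 1L)
    sampling_weights(records[train], binning) else NULL

  weights <- distill_init_weights(config, child_seed(seed, 2L))
  adam <- lapply(weights, function(w) list(m = w * 0, v = w * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L

  n_iter <- max(1L, ceiling(length(train) / config$batch_size))
  report <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_ce = numeric(0))
  best <- list(ce = Inf, weights = weights, epoch = 0L)

  eval_ce <- function(ids) {
    if (length(ids) == 0L) return(NA_real_)
    tot <- 0
    for (i in ids) {
      fw <- distill_forward(weights, feats[[i]],
                            rep(1L, lens[i]), lens[i])
      if (target == "scalar") {
        p <- softmax(as.vector(fw$Zs))
        tot <- tot + focal_loss(p, labels[[i]], gamma = 0)
      } else {
        P <- softmax_rows(fw$Zr)
        pt <- pmax(P[cbind(seq_len(lens[i]), labels[[i]] + 1L)], 1e-12)
        tot <- tot + mean(-log(pt))
      }
    }
    tot / length(ids)
  }

  rng_seed <- child_seed(seed, 3L)
  with_seed(rng_seed, {
    for (epoch in seq_len(config$epochs)) {
      ep_loss <- 0
      for (it in seq_len(n_iter)) {
        b <- sample(train, min(config$batch_size, length(train)),
                    replace = TRUE, prob = w_sample)
        Xb <- do.call(rbind, feats[b])
        groups <- rep(seq_along(b), lens[b])
        fw <- distill_forward(weights, Xb, groups, lens[b])
        B <- length(b)
        if (target == "scalar") {
          P <- softmax_rows(fw$Zs)
          labs <- unlist(labels[b])
          pt <- pmax(P[cbind(seq_len(B), labs + 1L)], 1e-12)
          ep_loss <- ep_loss + mean(-(1 - pt)^config$focal_gamma * log(pt))
          dZs <- focal_grad_logits(P, labs, config$focal_gamma) / B
          dWs <- crossprod(fw$Hbar, dZs); dbs <- colSums(dZs)
          dHbar <- dZs %*% t(weights$Ws)
          dH <- dHbar[groups, , drop = FALSE] / lens[b][groups]
          dWr <- weights$Wr * 0; dbr <- weights$br * 0
        } else {
          P <- softmax_rows(fw$Zr)
          labs <- unlist(labels[b])
          pt <- pmax(P[cbind(seq_len(nrow(P)), labs + 1L)], 1e-12)
          rw <- 1 / (lens[b][groups] * B)   # mean over positions, then batch
          ep_loss <- ep_loss +
            sum(rw * -(1 - pt)^config$focal_gamma * log(pt))
          dZr <- focal_grad_logits(P, labs, config$focal_gamma) * rw
          dWr <- crossprod(fw$H, dZr); dbr <- colSums(dZr)
          dH <- dZr %*% t(weights$Wr)
          dWs <- weights$Ws * 0; dbs <- weights$bs * 0
        }
        dA <- dH * (1 - fw$H^2)
        grad <- list(W1 = crossprod(Xb, dA), b1 = colSums(dA),
                     Wr = dWr, br = dbr, Ws = dWs, bs = dbs)
        step <- step + 1L
        for (nm in names(weights)) {
          g <- grad[[nm]]
          adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * g
          adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * g^2
          mh <- adam[[nm]]$m / (1 - beta1^step)
          vh <- adam[[nm]]$v / (1 - beta2^step)
          weights[[nm]] <- weights[[nm]] - config$lr * mh / (sqrt(vh) + eps)
        }
      }
      vce <- eval_ce(val)
      report <- rbind(report, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n_iter,
                                         val_ce = vce))
      track <- if (is.na(vce)) ep_loss / n_iter else vce
      if (track < best$ce)
        best <- list(ce = track, weights = weights, epoch = epoch)
    }
  })

  structure(list(weights = best$weights, config = config, binning = binning,
                 target = target, report = report,
                 best_epoch = best$epoch, seed = as.integer(seed),
                 n_train = length(train), n_val = length(val)),
            class = "sc_distill")
}

#' Number of trainable parameters of a distill fit
#' @param object an `sc_distill` fit.
#' @param ... unused.
#' @export
#' @method coef sc_distill
coef.sc_distill <- function(object, ...) object$weights

parameter_count <- function(weights) sum(vapply(weights, length, integer(1)))

#' @export
print.sc_distill <- function(x, ...) {
  cat(sprintf(
    "<sc_distill> %s model, %d bins, %d parameters, best epoch %d (val CE %.4f)\n",
    x$target, x$config$n_bins, parameter_count(x$weights), x$best_epoch,
    min(x$report$val_ce, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.sc_distill <- function(object, ...) {
  cat(sprintf("Distilled structure-confidence model (%s target)\n",
              object$target))
  cat(sprintf("  vocabulary: %d bins over (0,1); focal gamma %.1f\n",
              object$config$n_bins, object$config$focal_gamma))
  cat(sprintf("  parameters: %d; window half-width %d; hidden %d\n",
              parameter_count(object$weights), object$config$half_width,
              object$config$hidden))
  cat(sprintf("  training: %d records, validation: %d; best epoch %d\n",
              object$n_train, object$n_val, object$best_epoch))
  print(utils::tail(object$report, 5L))
  invisible(object)
}

#' @export
plot.sc_distill <- function(x, ...) {
  graphics::matplot(x$report$epoch,
                    cbind(x$report$train_loss, x$report$val_ce),
                    type = "l", lty = 1:2, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train (focal)", "validation (CE)"),
                   lty = 1:2, col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Predict confidence scores for sequences
#'
#' @param object an `sc_distill` fit.
#' @param sequences character vector of amino-acid sequences (or a single
#'   sequence).
#' @param type `"both"` (list with `scalar` and `residue`, for a single
#'   sequence), `"ptm"` (scalar per sequence) or `"plddt"` (list of
#'   per-residue vectors).
#' @param readout `"expectation"` or `"argmax"` bin readout.
#' @param ... unused.
#' @return See `type`.
#' @export
predict.sc_distill <- function(object, sequences,
                               type = c("both", "ptm", "plddt"),
                               readout = "expectation", ...) {
  type <- match.arg(type)
  one <- function(s) {
    X <- window_features(tokens_onehot(seq_to_tokens(s)),
                         object$config$half_width)
    fw <- distill_forward(object$weights, X, rep(1L, nrow(X)), nrow(X))
    list(scalar = expected_score(as.vector(fw$Zs), object$binning,
                                 readout = readout),
         residue = expected_score(fw$Zr, object$binning, readout = readout))
  }
  if (type == "both") {
    if (length(sequences) != 1L)
      stop('type = "both" expects a single sequence')
    return(one(sequences))
  }
  out <- lapply(sequences, one)
  if (type == "ptm") vapply(out, `[[`, numeric(1), "scalar")
  else lapply(out, `[[`, "residue")
}

#' @rdname predict.sc_distill
#' @description `predict_ptm()` and `predict_plddt()` are thin conveniences
#'   for the scalar and per-residue tracks.
#' @param model an `sc_distill` fit.
#' @param sequence a single amino-acid sequence.
#' @export
predict_ptm <- function(model, sequence)
  predict(model, sequence, type = "ptm")

#' @rdname predict.sc_distill
#' @export
predict_plddt <- function(model, sequence)
  predict(model, sequence, type = "plddt")[[1L]]

#' Residuals of a distill fit on a dataset
#'
#' Predicted minus observed scalar (or mean-residue) scores.
#'
#' @param object an `sc_distill` fit.
#' @param data a `scored_dataset` or record list; required.
#' @param ... unused.
#' @export
#' @method residuals sc_distill
residuals.sc_distill <- function(object, data, ...) {
  records <- if (inherits(data, "scored_dataset")) data$records else data
  pred <- vapply(records, function(r) {
    p <- predict(object, r$sequence)
    if (object$target == "scalar") p$scalar else mean(p$residue)
  }, numeric(1))
  obs <- vapply(records, record_mean_score, numeric(1))
  pred - obs
}

#' Simulate scored sequences from a distill fit
#'
#' Draws uniform-random sequences and scores them with the fitted model —
#' the mechanism used to build synthetic lower-score training corpora.
#'
#' @param object an `sc_distill` fit.
#' @param nsim number of sequences.
#' @param seed integer seed.
#' @param length_range sequence length bounds.
#' @param ... unused.
#' @return A list of [scored_seq()] records with provenance `"synthetic"`.
#' @export
#' @method simulate sc_distill
simulate.sc_distill <- function(object, nsim = 1L, seed = 1L,
                                length_range = c(30L, 80L), ...) {
  scorer <- if (object$target == "scalar")
    function(s) predict(object, s)$scalar
  else
    function(s) list(residue = predict(object, s)$residue)
  generate_synthetic_scored(nsim, scorer, length_range = length_range,
                            seed = seed)
}

#' Save / load a distill model as JSON
#'
#' Plain-text checkpoint holding weights, configuration and binning.
#'
#' @param model an `sc_distill` fit.
#' @param path file path.
#' @export
save_distill <- function(model, path) {
  stopifnot(inherits(model, "sc_distill"))
  obj <- list(
    target = model$target,
    config = unclass(model$config),
    seed = model$seed, best_epoch = model$best_epoch,
    weights = lapply(model$weights, function(w)
      if (is.matrix(w)) list(dim = dim(w), data = as.vector(w))
      else list(dim = NULL, data = as.vector(w)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_distill
#' @export
load_distill <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(distill_config, o$config[names(o$config) %in%
                                            names(formals(distill_config))])
  weights <- lapply(o$weights, function(w) {
    if (!is.null(w$dim) && length(w$dim)) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  structure(list(weights = weights, config = cfg,
                 binning = score_binning(cfg$n_bins),
                 target = o$target,
                 report = data.frame(), best_epoch = o$best_epoch %||% NA,
                 seed = o$seed %||% NA, n_train = NA, n_val = NA),
            class = "sc_distill")
}
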