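test_that("focal loss matches its closed forms and limits", {
  expect_equal(focal_loss(c(0.5, 0.5), 0L, gamma = 2), 0.25 * log(2))
  expect_equal(focal_loss(c(1, 0), 0L, gamma = 3), 0)
  expect_error(focal_loss(c(0.7, 0.7), 0L), "sum")

  # gamma = 0 recovers cross-entropy over many random distributions
  set.seed(2)
  for (k in 1:200) {
    p <- softmax_ <- exp(rnorm(10)); p <- p / sum(p)
    lab <- sample(0:9, 1)
    expect_equal(focal_loss(p, lab, gamma = 0), -log(p[lab + 1]),
                 tolerance = 1e-10)
  }

  # monotone non-increasing in p_t for fixed gamma
  pt <- seq(0.05, 0.95, by = 0.05)
  for (g in c(0, 0.5, 2, 5)) {
    losses <- vapply(pt, function(p)
      focal_loss(c(p, 1 - p), 0L, gamma = g), numeric(1))
    expect_true(all(diff(losses) <= 1e-12))
  }
})

test_that("expected_score reads out the bin expectation", {
  b <- score_binning()
  one_hot <- rep(-1e3, 50); one_hot[26] <- 1e3   # bin 25
  expect_equal(expected_score(one_hot, b), 0.51)
  expect_equal(expected_score(rep(0, 50), b), 0.5)
  two <- rep(-1e3, 50); two[c(1, 50)] <- 100
  expect_equal(expected_score(two, b), 0.5)   # mean of 0.01 and 0.99
  # invariant to constant logit shifts; bounded inside (0, 1)
  set.seed(3)
  for (k in 1:50) {
    z <- rnorm(50, sd = 3)
    e <- expected_score(z, b)
    expect_equal(expected_score(z + 17.3, b), e, tolerance = 1e-12)
    expect_gt(e, 0); expect_lt(e, 1)
  }
  expect_equal(expected_score(one_hot, b, readout = "argmax"), 0.51)
})

test_that("distill training gradients match finite differences", {
  # tiny model, tiny batch: compare analytic dW1 against numeric gradient
  cfg <- distill_config(n_bins = 5L, hidden = 3L, half_width = 1L)
  w <- scdistill:::distill_init_weights(cfg, seed = 9)
  X <- scdistill:::window_features(
    scdistill:::tokens_onehot(scdistill:::seq_to_tokens("ACDEF")), 1L)
  lab <- 3L
  softmax_vec <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  loss_of <- function(weights) {
    fw <- scdistill:::distill_forward(weights, X, rep(1L, 5L), 5L)
    focal_loss(softmax_vec(as.vector(fw$Zs)), lab, gamma = 2)
  }
  fw <- scdistill:::distill_forward(w, X, rep(1L, 5L), 5L)
  P <- softmax_vec(as.vector(fw$Zs))
  dZs <- scdistill:::focal_grad_logits(P, lab, gamma = 2)
  dHbar <- dZs %*% t(w$Ws)
  dH <- matrix(dHbar, 5L, 3L, byrow = TRUE) / 5L
  dA <- dH * (1 - fw$H^2)
  dW1 <- crossprod(X, dA)
  h <- 1e-6
  for (idx in list(c(1, 1), c(5, 2), c(21, 3))) {
    wp <- w; wp$W1[idx[1], idx[2]] <- wp$W1[idx[1], idx[2]] + h
    wm <- w; wm$W1[idx[1], idx[2]] <- wm$W1[idx[1], idx[2]] - h
    num <- (loss_of(wp) - loss_of(wm)) / (2 * h)
    expect_equal(dW1[idx[1], idx[2]], num, tolerance = 1e-5)
  }
})

test_that("training runs, is deterministic, and reports per-epoch losses", {
  recs <- list(scored_seq("a", "ACDEFGHIKL", scalar_score = 0.3),
               scored_seq("b", "MNPQRSTVWY", scalar_score = 0.7))
  cfg <- distill_config(epochs = 1L, hidden = 4L, val_fraction = 0)
  fit <- sc_distill(recs, target = "scalar", config = cfg, seed = 5)
  expect_s3_class(fit, "sc_distill")
  expect_equal(nrow(fit$report), 1L)
  expect_true(is.finite(fit$report$train_loss))

  fit2 <- sc_distill(recs, target = "scalar", config = cfg, seed = 5)
  expect_identical(fit$report, fit2$report)
  expect_identical(fit$weights, fit2$weights)

  expect_error(sc_distill(list(), target = "scalar"), "empty")
  expect_error(sc_distill(recs, target = "per_residue", config = cfg),
               "lack")
})

test_that("prediction contracts: untrained model, lengths, bad input", {
  cfg <- distill_config(hidden = 4L)
  w <- scdistill:::distill_init_weights(cfg, seed = 1)
  w$W1[] <- 0; w$Wr[] <- 0; w$Ws[] <- 0   # constant-logit model
  m <- structure(list(weights = w, config = cfg,
                      binning = score_binning(), target = "scalar",
                      report = data.frame(), best_epoch = 0L, seed = 1L),
                 class = "sc_distill")
  expect_equal(predict_ptm(m, "ACDEFGH"), 0.5)
  pl <- predict_plddt(m, "ACDEFGH")
  expect_equal(pl, rep(0.5, 7))
  expect_error(predict_ptm(m, "ACB!DE"), "position")
  p1 <- predict_ptm(m, "ACDEFGH")
  expect_identical(p1, predict_ptm(m, "ACDEFGH"))
})

test_that("a small model recovers the synthetic oracle", {
  orc <- make_oracle(seed = 7)
  ds <- generate_synthetic_scored(600, as_scorer(orc), seed = 11)
  cfg <- distill_config(epochs = 8L)
  fit <- sc_distill(scored_dataset(ds), target = "scalar", config = cfg,
                    seed = 1)
  expect_lt(scdistill:::parameter_count(fit$weights), 1e5)
  test <- generate_synthetic_scored(150, as_scorer(orc), seed = 99)
  pred <- predict(fit, vapply(test, `[[`, character(1), "sequence"),
                  type = "ptm")
  truth <- vapply(test, `[[`, numeric(1), "scalar_score")
  expect_gt(cor(pred, truth), 0.9)
  expect_lt(mean(abs(predict_ptm(fit, test[[1]]$sequence) -
                       test[[1]]$scalar_score)), 0.1)
})

test_that("checkpoints round-trip through JSON", {
  recs <- generate_synthetic_scored(30, as_scorer(make_oracle(3)), seed = 2)
  cfg <- distill_config(epochs = 2L, hidden = 6L)
  fit <- sc_distill(recs, target = "per_residue", config = cfg, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  save_distill(fit, f)
  back <- load_distill(f)
  s <- "ACDEFGHIKLMNP"
  expect_equal(predict_plddt(back, s), predict_plddt(fit, s),
               tolerance = 1e-12)
  expect_identical(back$target, "per_residue")
})

test_that("weighted sampling exposes rare bins during training", {
  # two-bin 90/10 dataset: empirical exposure within 5% of uniform
  recs <- c(
    lapply(1:90, function(i) scored_seq(paste0("a", i), "ACDEF",
                                        scalar_score = 0.15)),
    lapply(1:10, function(i) scored_seq(paste0("b", i), "ACDEF",
                                        scalar_score = 0.85)))
  w <- sampling_weights(recs)
  set.seed(10)
  draws <- sample(100, 5e4, replace = TRUE, prob = w)
  expect_lt(abs(mean(draws <= 90) - 0.5), 0.05)
})
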