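test_that("discretization maps scores to 0-based labels and back", {
  b <- score_binning()
  expect_identical(discretize_score(0.001, b), 0L)
  expect_identical(discretize_score(0.999, b), 49L)
  expect_identical(discretize_score(0.511, b), 25L)
  # boundary values are clamped into the open interval
  expect_identical(discretize_score(0, b), 0L)
  expect_identical(discretize_score(1, b), 49L)
  expect_error(discretize_score(1.2, b), "outside")
  expect_error(discretize_score(-0.1, b), "outside")

  expect_equal(bin_center(0L, b), 0.01)
  expect_equal(bin_center(49L, b), 0.99)
  expect_error(bin_center(50L, b), "outside")
  expect_error(bin_center(-1L, b), "outside")
})

test_that("discretize/bin_center round-trip error is at most half a bin", {
  set.seed(5)
  for (nb in c(10L, 50L, 97L)) {
    b <- score_binning(nb)
    x <- runif(1000)
    err <- abs(bin_center(discretize_score(x, b), b) - x)
    expect_lte(max(err), 0.5 / nb + 1e-12)
  }
  # full label range reachable
  x <- runif(10000)
  expect_identical(sort(unique(discretize_score(x))), 0:49)
})

test_that("scored_seq enforces its invariants", {
  expect_error(scored_seq("a", "ACDE"), "at least one")
  expect_error(scored_seq("a", "ACDE", scalar_score = 1.2), "inside")
  expect_error(scored_seq("a", "ACDE", residue_scores = c(0.5, 0.5)),
               "length")
  expect_error(scored_seq("a", "AC1E", scalar_score = 0.5), "illegal")
  r <- scored_seq("a", "ACDE", residue_scores = rep(0.25, 4))
  expect_equal(scdistill:::record_mean_score(r), 0.25)
})

test_that("JSONL and CSV round-trips preserve records", {
  recs <- list(
    scored_seq("a", "ACDEFGHIK", scalar_score = 0.7),
    scored_seq("b", "MNPQR", residue_scores = c(0.1, 0.2, 0.3, 0.4, 0.5),
               provenance = "synthetic"))
  ds <- scored_dataset(recs)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl_dataset(ds, f)
  back <- read_jsonl_dataset(f)
  expect_equal(length(back), 2L)
  expect_equal(back$records[[1]]$scalar_score, 0.7)
  expect_equal(back$records[[2]]$residue_scores, c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(back$records[[2]]$provenance, "synthetic")
  expect_equal(sum(back$bin_histogram), 2L)

  fc <- withr::local_tempfile(fileext = ".csv")
  write_csv_dataset(ds, fc)
  got <- utils::read.csv(fc)
  expect_equal(got$sequence, c("ACDEFGHIK", "MNPQR"))

  fm <- withr::local_tempfile(fileext = ".json")
  write_manifest(ds, fm)
  man <- jsonlite::fromJSON(fm)
  expect_equal(man$n_records, 2L)
  expect_equal(sum(man$bin_histogram), 2L)
})

test_that("similarity filtering removes near-duplicates of the holdout", {
  hold <- c("ACDEFGHIKLMNPQRSTVWY")
  cand <- list(
    scored_seq("dup", "ACDEFGHIKLMNPQRSTVWY", scalar_score = 0.5),
    scored_seq("novel", "WWWHHHWWWHHHWWWHHHWW", scalar_score = 0.5))
  kept <- filter_by_similarity(cand, hold, threshold = 100)
  expect_equal(vapply(kept, `[[`, character(1), "id"), "novel")
  kept40 <- filter_by_similarity(cand, hold, threshold = 40)
  expect_equal(vapply(kept40, `[[`, character(1), "id"), "novel")
  expect_identical(filter_by_similarity(list(), hold), list())
})

test_that("identity similarity matches the brute-force NW oracle", {
  set.seed(31)
  for (k in 1:10) {
    a <- paste(sample(scdistill:::AA20, sample(8:20, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(scdistill:::AA20, sample(8:20, 1), replace = TRUE),
               collapse = "")
    expect_equal(seq_similarity(a, b, method = "identity"),
                 brute_nw_identity(a, b), tolerance = 1e-12)
  }
  # half the positions substituted into a disjoint alphabet: the filtering
  # decision agrees with the brute-force identity at threshold 40
  a <- "ACDEACDEACDEACDEACDE"
  ch <- strsplit(a, "")[[1]]
  ch[seq(1, 20, by = 2)] <- "W"
  b <- paste(ch, collapse = "")
  sim <- brute_nw_identity(b, a)
  rec <- scored_seq("x", b, scalar_score = 0.5)
  kept <- filter_by_similarity(list(rec), a, threshold = 40,
                               method = "identity")
  expect_identical(length(kept) == 1L, sim < 40)
})

test_that("cropping takes an aligned contiguous window, deterministically", {
  r <- scored_seq("long", paste(rep("ACDEFGHIKL", 60), collapse = ""),
                  residue_scores = stats::plogis(seq_len(600) / 100 - 3))
  out <- crop_sequence(r, 500L, seed = 3)
  expect_equal(nchar(out$sequence), 500L)
  expect_equal(length(out$residue_scores), 500L)
  # window alignment: scores follow the same window as the letters
  out2 <- crop_sequence(r, 500L, seed = 3)
  expect_identical(out$sequence, out2$sequence)
  expect_identical(out$residue_scores, out2$residue_scores)
  idx <- regexpr(out$sequence, r$sequence, fixed = TRUE)
  expect_gte(idx, 1L)
  expect_equal(out$residue_scores,
               r$residue_scores[idx:(idx + 499L)])
  # short records pass through untouched
  s <- scored_seq("short", "ACDEF", scalar_score = 0.4)
  expect_identical(crop_sequence(s, 500L), s)
})

test_that("augmentation perturbs in place and strips the score", {
  r <- scored_seq("r", "ACDEFG", scalar_score = 0.9)
  p <- augment_perturb(r, "segment_permute", intensity = 1, seed = 2)
  expect_null(p$scalar_score)
  expect_equal(p$provenance, "augmented")
  expect_identical(sort(strsplit(p$sequence, "")[[1]]),
                   sort(strsplit(r$sequence, "")[[1]]))
  expect_error(augment_perturb(r, intensity = 0), "intensity")

  # Hamming distance bounded by the segment length over many draws
  long <- scored_seq("l", paste(rep("ACDEFGHIKL", 5), collapse = ""),
                     scalar_score = 0.5)
  for (k in 1:100) {
    q <- augment_perturb(long, "segment_replace", intensity = 0.3,
                         seed = k)
    hd <- sum(strsplit(q$sequence, "")[[1]] !=
                strsplit(long$sequence, "")[[1]])
    expect_lte(hd, ceiling(0.3 * 50))
    expect_equal(nchar(q$sequence), 50L)
  }
  one <- scored_seq("one", "A", scalar_score = 0.5)
  expect_warning(augment_perturb(one, "segment_permute", intensity = 0.5),
                 "short")
})

test_that("balance filtering keeps the low range and thins the high range", {
  low <- lapply(1:20, function(i)
    scored_seq(paste0("lo", i), "ACDEFG", scalar_score = 0.3))
  high <- lapply(1:80, function(i)
    scored_seq(paste0("hi", i), "ACDEFG", scalar_score = 0.9))
  all0 <- balance_filter(low, keep_below = 0.8, keep_fraction_above = 0.5,
                         seed = 1)
  expect_equal(length(all0), 20L)

  none <- balance_filter(c(low, high), keep_below = 0.8,
                         keep_fraction_above = 0, seed = 1)
  expect_true(all(grepl("^lo", vapply(none, `[[`, character(1), "id"))))

  # choosing keep_fraction to equalize mass above/below: 20 below, 80 above
  fr <- vapply(1:10, function(s) {
    out <- balance_filter(c(low, high), keep_below = 0.8,
                          keep_fraction_above = 0.25, seed = s)
    ms <- vapply(out, scdistill:::record_mean_score, numeric(1))
    mean(ms >= 0.8)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.05)
  h <- attr(balance_filter(c(low, high), 0.8, 0.25, seed = 2),
            "hist_before")
  expect_equal(sum(h), 100L)
})

test_that("inverse-frequency weights equalize bin exposure", {
  recs <- c(
    lapply(1:90, function(i) scored_seq(paste0("a", i), "ACD",
                                        scalar_score = 0.15)),
    lapply(1:10, function(i) scored_seq(paste0("b", i), "ACD",
                                        scalar_score = 0.85)))
  w <- sampling_weights(recs)
  expect_equal(sum(w), 1)
  expect_equal(w[1] / w[91], 1 / 9, tolerance = 1e-12)
  expect_true(all(w > 0))
  # all in one bin: uniform
  wu <- sampling_weights(recs[1:90])
  expect_equal(wu, rep(1 / 90, 90))

  # empirical exposure under weighted draws approaches 50/50
  set.seed(8)
  draws <- sample(100, 2e4, replace = TRUE, prob = w)
  expect_lt(abs(mean(draws <= 90) - 0.5), 0.03)
})

test_that("synthetic scored generation is seeded and validated", {
  const <- function(s) 0.3
  g <- generate_synthetic_scored(5, const, seed = 4)
  expect_equal(vapply(g, `[[`, numeric(1), "scalar_score"), rep(0.3, 5))
  expect_equal(vapply(g, `[[`, character(1), "provenance"),
               rep("synthetic", 5))
  g2 <- generate_synthetic_scored(5, const, seed = 4)
  expect_identical(vapply(g, `[[`, character(1), "sequence"),
                   vapply(g2, `[[`, character(1), "sequence"))
  expect_error(generate_synthetic_scored(2, function(s) 1.5, seed = 1),
               "outside")

  # the oracle spreads random sequences over many bins
  orc <- make_oracle(seed = 7)
  ds <- generate_synthetic_scored(1000, as_scorer(orc, "scalar"), seed = 5)
  labs <- vapply(ds, function(r) discretize_score(r$scalar_score),
                 integer(1))
  expect_gte(length(unique(labs)), 10L)
})

test_that("FASTA round-trip preserves names and sequences", {
  seqs <- c(s1 = "ACDEFGHIK", s2 = "MNPQRSTVWY")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})
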