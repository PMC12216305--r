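test_that("PDB round-trip preserves coordinates and degenerate files error", {
  bb <- make_backbone(3L, "extended")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(bb, f)
  got <- read_pdb(f)
  expect_s3_class(got, "backbone")
  expect_equal(length(got), 3L)
  expect_equal(got$ca_coords, bb$ca_coords, tolerance = 1e-3,
               ignore_attr = TRUE)

  # re-write and re-read: coordinates stable to PDB precision
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(got, f2)
  expect_equal(read_pdb(f2)$ca_coords, got$ca_coords, tolerance = 1e-3)

  # HETATM-only file
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("HETATM    1  O   HOH A   1    ",
                      "   0.000   0.000   0.000  1.00  0.00"), "END"), f3)
  expect_error(read_pdb(f3), "ATOM")
  # residue without CA
  f4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("ATOM      1  CB  ALA A   1    ",
                      "   0.000   0.000   0.000  1.00  0.00"), "END"), f4)
  expect_error(read_pdb(f4), "CA")
})

test_that("backbone invariants are enforced", {
  m <- matrix(0, 3, 3); m[, 1] <- c(0, 3.8, 7.6)
  expect_error(backbone(m, residue_ids = c(1, 3, 2)), "increasing")
  m2 <- m; m2[2, 2] <- NA
  expect_error(backbone(m2), "finite")
  expect_error(backbone(m, sequence = "AC"), "length")
})

test_that("Kabsch recovers exact transforms and matches brute-force RMSD", {
  set.seed(71)
  p <- matrix(rnorm(24), 8, 3)
  s0 <- kabsch_superpose(p, p)
  expect_lt(s0$rmsd, 1e-12)

  # pure translation
  s1 <- kabsch_superpose(p, sweep(p, 2, c(5, -2, 7), "+"))
  expect_lt(s1$rmsd, 1e-12)
  expect_equal(s1$translation, c(5, -2, 7), tolerance = 1e-9)
  expect_equal(s1$rotation, diag(3), tolerance = 1e-9)

  # two unrelated point sets vs numerical minimizer; rotation stays proper
  for (k in 1:3) {
    set.seed(100 + k)
    a <- matrix(rnorm(24, sd = 3), 8, 3)
    b <- matrix(rnorm(24, sd = 3), 8, 3)
    s <- kabsch_superpose(a, b)
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
    expect_equal(s$rmsd, brute_min_rmsd(a, b), tolerance = 1e-6)
  }

  expect_error(kabsch_superpose(p[1:2, ], p[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch_superpose(line, line), "collinear")
})

test_that("TM-score analytic cases: identity, d0 displacement, d0 formula", {
  bb <- make_backbone(40, "random_coil", seed = 11)
  expect_equal(as.numeric(tm_score(bb, bb)), 1, tolerance = 1e-12)

  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8)
  expect_equal(tm_d0(10), 0.5)   # clamped for short chains
  expect_equal(tm_d0(21), 0.5)

  # every pair displaced by exactly d0 under the optimal superposition
  mod <- displace_backbone_exact(bb, tm_d0(40), seed = 2)
  expect_equal(as.numeric(tm_score(mod, bb)), 0.5, tolerance = 1e-6)
})

test_that("TM-score matches brute-force superposition search on toys", {
  for (k in 1:6) {
    bb <- make_backbone(12 + (k %% 3), "random_coil", seed = 300 + k)
    mod <- perturb_backbone(bb, magnitude = 0.5 + 0.2 * k, seed = 400 + k)
    tm <- as.numeric(tm_score(mod, bb))
    expect_equal(tm, brute_tm(mod, bb), tolerance = 1e-6)
  }
})

test_that("TM-score is rigid-motion invariant and swap-symmetric", {
  bb <- make_backbone(30, "random_coil", seed = 21)
  mod <- perturb_backbone(bb, 1.5, seed = 22)
  tm0 <- as.numeric(tm_score(mod, bb))
  set.seed(23)
  ang <- rnorm(3)
  th <- sqrt(sum(ang^2)); k <- ang / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  moved <- backbone(sweep(mod$ca_coords %*% t(R), 2, c(10, -4, 2), "+"))
  expect_equal(as.numeric(tm_score(moved, bb)), tm0, tolerance = 1e-9)
  # equal lengths + full correspondence: normalization identical under swap
  expect_equal(as.numeric(tm_score(bb, mod)), tm0, tolerance = 1e-7)
})

test_that("TM-score input validation", {
  bb <- make_backbone(20, "helix")
  expect_error(tm_score(bb, bb, correspondence = matrix(0L, 0, 2)), "empty")
  expect_error(tm_score(bb, bb, correspondence = cbind(1:3, 19:21)),
               "out of range")
  expect_error(tm_score(make_backbone(10, "helix"), bb), "length")
})

test_that("lDDT analytic cases and error handling", {
  bb <- make_backbone(20, "helix")
  r <- lddt(bb, bb)
  expect_equal(r$lddt_global, 1)
  expect_equal(r$lddt_per_residue, rep(1, 20))

  # uniform +1.5 A pair-distance perturbation: fails 0.5/1, passes 2/4
  dr <- as.matrix(dist(bb$ca_coords))
  dm <- dr + 1.5
  r2 <- lddt_from_dist(dm, dr)
  expect_equal(r2$lddt_global, 0.5)
  expect_equal(r2$lddt_per_residue, rep(0.5, 20))

  expect_error(lddt(backbone(matrix(0, 1, 3)), backbone(matrix(0, 1, 3))),
               "2 residues")
  expect_error(lddt(make_backbone(5, "helix"), make_backbone(6, "helix")),
               "length")

  # residues with no pair in the radius are excluded with a message
  far <- backbone(rbind(c(0, 0, 0), c(3.8, 0, 0), c(100, 0, 0)))
  expect_message(r3 <- lddt(far, far), "excluded")
  expect_true(is.na(r3$lddt_per_residue[3]))
  expect_equal(r3$lddt_global, 1)
})

test_that("lDDT equals the brute-force all-pairs oracle on random pairs", {
  for (k in 1:8) {
    n <- sample(5:30, 1)
    bb <- make_backbone(n, "random_coil", seed = 500 + k)
    mod <- perturb_backbone(bb, runif(1, 0.3, 3), seed = 600 + k)
    got <- suppressMessages(lddt(mod, bb))
    want <- brute_lddt(mod, bb)
    expect_equal(got$lddt_global, want$global, tolerance = 1e-12)
    expect_equal(got$lddt_per_residue, want$per_residue, tolerance = 1e-12)
  }
})

test_that("lDDT is superposition-free (rigid-motion invariant)", {
  bb <- make_backbone(25, "random_coil", seed = 31)
  mod <- perturb_backbone(bb, 1, seed = 32)
  base <- lddt(mod, bb)$lddt_global
  th <- 1.1; K <- matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  moved <- backbone(sweep(mod$ca_coords %*% t(R), 2, c(-3, 8, 1), "+"))
  expect_equal(lddt(moved, bb)$lddt_global, base, tolerance = 1e-9)
})

test_that("per-residue lDDT mean equals the global score", {
  bb <- make_backbone(18, "random_coil", seed = 41)
  mod <- perturb_backbone(bb, 2, seed = 42)
  r <- suppressMessages(lddt(mod, bb))
  expect_identical(r$lddt_global, mean(r$lddt_per_residue, na.rm = TRUE))
})

test_that("neighbor density classes follow the count thresholds", {
  # isolated pair: 0-1 neighbors -> surface
  iso <- backbone(rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0)))
  nd <- neighbor_density_class(iso)
  expect_equal(as.character(nd$class), rep("surface", 3))
  expect_equal(nd$neighbors, c(0L, 0L, 0L))

  # 30 residues packed inside a 10 A ball: every residue core
  set.seed(9)
  pts <- matrix(rnorm(90), 30, 3)
  pts <- 4 * pts / sqrt(rowSums(pts^2)) * runif(30)^(1 / 3)
  dense <- backbone(pts)
  ndc <- neighbor_density_class(dense)
  expect_true(all(ndc$neighbors >= 24))
  expect_equal(as.character(ndc$class), rep("core", 30))

  # exactly 20 neighbors within radius -> intermediate
  center <- c(0, 0, 0)
  inside <- t(vapply(1:20, function(i) {
    u <- c(cos(i), sin(i), cos(2 * i)); 5 * u / sqrt(sum(u^2))
  }, numeric(3)))
  outside <- t(vapply(1:5, function(i) {
    u <- c(sin(3 * i), cos(2 * i), sin(i)); 30 * u / sqrt(sum(u^2))
  }, numeric(3)))
  bb20 <- backbone(rbind(center, inside, outside))
  nd20 <- neighbor_density_class(bb20, index = 1)
  expect_equal(nd20$neighbors, 20L)
  expect_equal(as.character(nd20$class), "intermediate")

  expect_error(neighbor_density_class(iso, index = 9), "out of range")
})

test_that("all-atom lDDT uses atom_records and matches Ca-only on Ca data", {
  n <- 8L
  base <- make_backbone(n, "helix")
  recs <- lapply(seq_len(n), function(i) list(
    list(atom = "CA", xyz = base$ca_coords[i, ]),
    list(atom = "CB", xyz = base$ca_coords[i, ] + c(0.8, 0.4, -0.2))))
  bb <- backbone(base$ca_coords, atom_records = recs)
  r <- lddt(bb, bb, all_atom = TRUE)
  expect_equal(r$lddt_global, 1)
  expect_length(r$lddt_per_residue, n)

  # perturbing one CB changes the all-atom score but not the Ca-only one
  recs2 <- recs
  recs2[[3]][[2]]$xyz <- recs2[[3]][[2]]$xyz + c(3, 0, 0)
  bb2 <- backbone(base$ca_coords, atom_records = recs2)
  expect_lt(lddt(bb2, bb, all_atom = TRUE)$lddt_global, 1)
  expect_equal(lddt(bb2, bb)$lddt_global, 1)

  expect_error(lddt(base, base, all_atom = TRUE), "atom_records")
})

test_that("cli accepts a YAML config with flag precedence", {
  skip_if_not_installed("yaml")
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(n = 3, seed = 5), cfgf)
  expect_identical(cli_main(c("fixtures", "--out", dir, "--config", cfgf)),
                   0L)
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 5L)
  ds <- read_jsonl_dataset(file.path(dir, "scored.jsonl"))
  expect_equal(length(ds), 3L)
})
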