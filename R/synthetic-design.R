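# Toy structure-conditioned sequence design task with a planted,
# recoverable structure -> residue rule.

# Rotation-invariant per-residue structure features: neighbor counts at
# three radii, local chain geometry, and position along the chain.
backbone_features <- function(bb) {
  X <- bb$ca_coords
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  cl <- function(i) pmin(pmax(i, 1L), n)
  span <- d[cbind(seq_len(n), cl(seq_len(n) + 2L))] +
    d[cbind(seq_len(n), cl(seq_len(n) - 2L))]
  F <- cbind(
    n6 = rowSums(d <= 6) - 1L,
    n8 = rowSums(d <= 8) - 1L,
    n10 = rowSums(d <= 10) - 1L,
    span = span,
    meank = apply(d, 1L, function(r) mean(sort(r)[2:min(6L, n)])),
    pos = seq_len(n) / n
  )
  F
}

# The planted rule: 8 classes from neighbor density (4 levels of the 8 A
# count) crossed with local compactness (span threshold), each mapped to
# one fixed amino acid.
RULE_AA <- c("A", "G", "L", "V", "S", "T", "E", "K")

rule_class <- function(features) {
  n8 <- features[, "n8"]
  dens <- findInterval(n8, c(4, 6, 8)) + 1L      # 1..4
  compact <- as.integer(features[, "span"] < 13) # 0/1
  dens + 4L * compact                            # 1..8
}

rule_sequence <- function(features) {
  paste(RULE_AA[rule_class(features)], collapse = "")
}

#' Generate a toy structure-conditioned design task
#'
#' Emits `n` paired (backbone, features, sequence) records with a planted
#' structure-to-residue rule: each residue's class — neighbor density at
#' 8 Å crossed with local chain compactness — maps deterministically to one
#' of eight amino acids, and each position is then corrupted to a uniform
#' random residue with probability `noise`. Because the rule is a function
#' of rotation-invariant features, a small model trained on the features
#' can recover it (noise 0 is perfectly recoverable; noise 1 is chance).
#' Each record also carries a contiguous masked span for the infilling
#' variant of the task.
#'
#' @param n number of structures (>= 1).
#' @param lengths integer range of chain lengths.
#' @param noise per-position corruption rate in `[0, 1]`.
#' @param mask_fraction length fraction of the contiguous masked span.
#' @param kind backbone generator mix passed to [make_backbone()].
#' @param seed integer seed.
#' @return An object of class `design_task`: list with `records` (each
#'   `list(backbone, features, sequence, mask)`), `noise`, `seed` and
#'   `feature_names`.
#' @export
make_design_task <- function(n, lengths = c(30L, 60L), noise = 0.2,
                             mask_fraction = 0.25,
                             kind = c("random_coil", "helix"), seed = 1L) {
  stopifnot(n >= 1L, noise >= 0, noise <= 1)
  kinds <- rep(match.arg(kind, several.ok = TRUE), length.out = n)
  records <- with_seed(seed, lapply(seq_len(n), function(i) {
    L <- sample(lengths[1L]:lengths[2L], 1L)
    bb <- make_backbone(L, kinds[i],
                        seed = NULL)  # inherits the task RNG stream
    F <- backbone_features(bb)
    truth <- strsplit(rule_sequence(F), "")[[1]]
    corrupt <- stats::runif(L) < noise
    truth[corrupt] <- sample(AA20, sum(corrupt), replace = TRUE)
    mlen <- max(1L, round(mask_fraction * L))
    mstart <- sample.int(L - mlen + 1L, 1L)
    list(backbone = bb, features = F,
         sequence = paste(truth, collapse = ""),
         mask = c(mstart, mstart + mlen - 1L))
  }))
  structure(list(records = records, noise = noise, seed = as.integer(seed),
                 feature_names = colnames(records[[1L]]$features)),
            class = "design_task")
}

#' @export
print.design_task <- function(x, ...) {
  cat(sprintf("<design_task> %d structures, noise %.2f, seed %d\n",
              length(x$records), x$noise, x$seed))
  invisible(x)
}

#' Rule-lookup baseline for the toy design task
#'
#' Applies the planted structure-to-residue rule directly: the ceiling
#' "model" for the task (recovery 100 at noise 0, chance at noise 1).
#'
#' @param record a record of a [make_design_task()] task.
#' @return The rule's sequence for the record's structure.
#' @export
rule_lookup <- function(record) rule_sequence(record$features)
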