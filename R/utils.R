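# Shared internals: alphabet, seeding, numeric helpers.

# 20 standard amino acids, one-letter codes, plus X for unknown.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AAX <- c(AA20, "X")

aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

aa1to3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. seed = NULL runs code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed, staying within 32-bit integer range.
child_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12289L) %% 2147483587L
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Row-wise softmax for a matrix of logits.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

seq_to_tokens <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  ch <- strsplit(toupper(sequence), "")[[1]]
  tok <- match(ch, AAX)
  if (anyNA(tok)) {
    bad <- which(is.na(tok))[1L]
    stop(sprintf("illegal residue character '%s' at position %d", ch[bad], bad))
  }
  tok
}

tokens_to_seq <- function(tokens) paste(AAX[tokens], collapse = "")

random_sequence <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
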