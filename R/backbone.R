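#' Backbone structure objects
#'
#' A `backbone` holds an ordered protein chain at alpha-carbon resolution:
#' residue numbers, Cα coordinates in Ångström, and optionally the one-letter
#' sequence and full per-residue atom records (for all-atom lDDT).
#'
#' @param ca_coords numeric matrix, one row per residue, columns x/y/z (Å).
#' @param residue_ids integer vector of residue numbers, strictly increasing
#'   in file/chain order. Defaults to `1:nrow(ca_coords)`.
#' @param sequence optional one-letter amino-acid string of the same length.
#' @param atom_records optional list (one element per residue) of named lists
#'   `list(atom = "CB", xyz = c(x, y, z))` holding additional atoms.
#'
#' @return An object of class `backbone`.
#' @examples
#' bb <- backbone(matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE))
#' length(bb)
#' @export
backbone <- function(ca_coords, residue_ids = NULL, sequence = NULL,
                     atom_records = NULL) {
  ca_coords <- as.matrix(ca_coords)
  if (ncol(ca_coords) != 3L)
    stop("ca_coords must have 3 columns (x, y, z)")
  storage.mode(ca_coords) <- "double"
  n <- nrow(ca_coords)
  if (n < 1L) stop("backbone needs at least one residue")
  if (!all(is.finite(ca_coords))) stop("all coordinates must be finite")
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n)
    stop("residue_ids length must match number of residues")
  if (n > 1L && any(diff(residue_ids) <= 0L))
    stop("residue_ids must be strictly increasing")
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (nchar(sequence) != n)
      stop("sequence length must match number of residues")
  }
  if (!is.null(atom_records) && length(atom_records) != n)
    stop("atom_records must have one entry per residue")
  dimnames(ca_coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(residue_ids = residue_ids, sequence = sequence,
         ca_coords = ca_coords, atom_records = atom_records),
    class = "backbone"
  )
}

#' @export
length.backbone <- function(x) nrow(x$ca_coords)

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %d residues (ids %d..%d)%s\n",
              length(x), x$residue_ids[1L],
              x$residue_ids[length(x)],
              if (is.null(x$sequence)) "" else ", with sequence"))
  invisible(x)
}

#' Read a backbone from a PDB file
#'
#' Parses ATOM records (via \pkg{bio3d}) and extracts one residue per CA
#' atom, in file order; insertion codes are preserved in the ordering.
#' HETATM records are ignored. Non-CA atoms of each residue are retained in
#' `atom_records` for all-atom lDDT.
#'
#' @param path path to a PDB file.
#' @param chain optional chain identifier to select; default takes the first
#'   chain in the file.
#' @param keep_atoms logical; retain non-CA atoms in `atom_records`.
#' @return A [backbone()] object.
#' @export
read_pdb <- function(path, chain = NULL, keep_atoms = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no ATOM records in '", path, "' (HETATM-only or empty file)")
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[is.na(at$chain) | at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain '", chain, "'")
  ins <- ifelse(is.na(at$insert), "", at$insert)
  rkey <- paste(at$resno, ins, sep = "|")
  ukey <- unique(rkey)   # file order
  ca_idx <- integer(0)
  atom_records <- if (keep_atoms) vector("list", length(ukey)) else NULL
  for (i in seq_along(ukey)) {
    rows <- which(rkey == ukey[i])
    ca <- rows[at$elety[rows] == "CA"]
    if (length(ca) == 0L)
      stop(sprintf("residue %s %s has no CA atom", at$resid[rows[1L]], ukey[i]))
    ca_idx[i] <- ca[1L]
    if (keep_atoms) {
      atom_records[[i]] <- lapply(rows, function(r)
        list(atom = at$elety[r], xyz = c(at$x[r], at$y[r], at$z[r])))
    }
  }
  coords <- cbind(at$x[ca_idx], at$y[ca_idx], at$z[ca_idx])
  seq1 <- aa3to1[at$resid[ca_idx]]
  seq1[is.na(seq1)] <- "X"
  backbone(coords,
           residue_ids = seq_along(ukey),
           sequence = paste(seq1, collapse = ""),
           atom_records = atom_records)
}

#' Write a backbone to a PDB file
#'
#' Emits one CA ATOM record per residue (plus any extra atoms stored in
#' `atom_records`), suitable for round-tripping through [read_pdb()].
#'
#' @param x a [backbone()] object.
#' @param path output file path.
#' @param chain chain identifier to write (single character).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, chain = "A") {
  stopifnot(inherits(x, "backbone"))
  n <- length(x)
  seq1 <- if (is.null(x$sequence)) rep("A", n) else strsplit(x$sequence, "")[[1]]
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    res3 <- aa1to3[seq1[i]]
    if (is.na(res3)) res3 <- "UNK"
    atoms <- if (!is.null(x$atom_records)) x$atom_records[[i]] else
      list(list(atom = "CA", xyz = x$ca_coords[i, ]))
    if (is.null(x$atom_records))
      atoms <- list(list(atom = "CA", xyz = x$ca_coords[i, ]))
    for (a in atoms) {
      serial <- serial + 1L
      nm <- a$atom
      # PDB atom-name column convention: 1-3 char names start in column 14
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, nm_fmt, res3, chain, x$residue_ids[i],
        a$xyz[1L], a$xyz[2L], a$xyz[3L]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
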