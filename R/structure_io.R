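# Coordinate data model and PDB/FASTA I/O.
#
# A `protein_structure` holds one chain: per-residue coordinates for the five
# atoms {N, CA, C, O, CB}, a presence mask, the one-letter sequence and
# 0-based residue ids. Decoys from mixed sources have inconsistent PDB
# numbering, so residues are re-indexed on read and metrics align by order.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

#' Construct a single-chain protein structure
#'
#' The container every other module consumes: per-residue coordinates for the
#' backbone atoms N, CA, C, O plus C-beta, with a per-atom presence mask.
#' Coordinates of absent atoms are `NA` and are never read by metrics.
#'
#' @param coords Numeric array `c(L, 5, 3)`; second dimension ordered
#'   N, CA, C, O, CB. Entries for absent atoms may be `NA`.
#' @param sequence Single string of length-L one-letter amino-acid codes
#'   (20 standard letters plus `"X"` for non-standard residues).
#' @param atom_mask Logical `L x 5` matrix, `TRUE` where the atom is present.
#'   Defaults to "present wherever coordinates are finite".
#' @param residue_ids Strictly increasing integer labels; default `0:(L-1)`.
#' @param chain_id Single-character chain identifier.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(coords, sequence, atom_mask = NULL,
                              residue_ids = NULL, chain_id = "A") {
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 5L || dim(coords)[3L] != 3L)
    stop("coords must be an L x 5 x 3 array", call. = FALSE)
  n <- dim(coords)[1L]
  dimnames(coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  if (is.null(atom_mask))
    atom_mask <- apply(coords, c(1L, 2L), function(v) all(is.finite(v)))
  dimnames(atom_mask) <- list(NULL, BACKBONE_ATOMS)
  if (is.null(residue_ids)) residue_ids <- seq_len(n) - 1L
  x <- structure(
    list(coords = coords, sequence = sequence,
         atom_mask = atom_mask, residue_ids = as.integer(residue_ids),
         chain_id = chain_id),
    class = "protein_structure")
  validate_structure(x)
  x
}

#' @export
length.protein_structure <- function(x) dim(x$coords)[1L]

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> chain %s, %d residues\n",
              x$chain_id, length(x)))
  cat(sprintf("  sequence: %s\n",
              if (nchar(x$sequence) > 60)
                paste0(substr(x$sequence, 1, 57), "...") else x$sequence))
  cat(sprintf("  atoms present: %d / %d\n",
              sum(x$atom_mask), length(x$atom_mask)))
  invisible(x)
}

validate_structure <- function(x) {
  n <- dim(x$coords)[1L]
  if (nchar(x$sequence) != n)
    stop("sequence length does not match number of residues", call. = FALSE)
  if (!identical(dim(x$atom_mask), c(n, 5L)) && !identical(dim(x$atom_mask), as.integer(c(n, 5))))
    stop("atom_mask must be L x 5", call. = FALSE)
  if (length(x$residue_ids) != n || (n > 1L && any(diff(x$residue_ids) <= 0L)))
    stop("residue_ids must be strictly increasing with one id per residue",
         call. = FALSE)
  present <- which(x$atom_mask)
  for (k in 1:3) {
    slab <- x$coords[, , k]
    if (any(!is.finite(slab[present])))
      stop("present atoms must have finite coordinates", call. = FALSE)
  }
  invisible(x)
}

# n x 3 matrix of one atom's coordinates (NA rows where absent).
atom_coords <- function(structure, atom) {
  m <- structure$coords[, atom, , drop = FALSE]
  dim(m) <- c(dim(structure$coords)[1L], 3L)
  m
}

get_atom <- function(structure, i, atom) structure$coords[i, atom, ]

seq_chars <- function(structure) strsplit(structure$sequence, "")[[1L]]

#' Read a single chain from a PDB file or text
#'
#' Parses ATOM records for one chain, keeping only the atoms
#' N, CA, C, O, CB. Alternate locations are resolved to the highest
#' occupancy (ties: first seen); insertion-coded residues are folded into
#' sequential order; only the first MODEL of a multi-model file is read.
#' Non-standard residues keep their backbone atoms and map to `"X"`.
#'
#' @param path Path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline or of length > 1 is treated as text).
#' @param chain Chain identifier to read; `NULL` (default) takes the first
#'   chain encountered.
#' @return A [protein_structure()].
#' @export
read_pdb <- function(path, chain = NULL) {
  lines <- if (length(path) > 1L || grepl("\n", path[1L], fixed = TRUE)) {
    unlist(strsplit(path, "\n", fixed = TRUE))
  } else readLines(path, warn = FALSE)

  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L] - 1L)]
  atom_lines <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom_lines) == 0L)
    stop("no parsable ATOM records in input", call. = FALSE)

  fx <- function(l, a, b) substr(l, a, b)
  rec <- data.frame(
    atom    = trimws(fx(atom_lines, 13, 16)),
    altloc  = fx(atom_lines, 17, 17),
    resname = trimws(fx(atom_lines, 18, 20)),
    chain   = fx(atom_lines, 22, 22),
    resseq  = as.integer(fx(atom_lines, 23, 26)),
    icode   = fx(atom_lines, 27, 27),
    x = as.numeric(fx(atom_lines, 31, 38)),
    y = as.numeric(fx(atom_lines, 39, 46)),
    z = as.numeric(fx(atom_lines, 47, 54)),
    occ = suppressWarnings(as.numeric(fx(atom_lines, 55, 60))),
    stringsAsFactors = FALSE)
  rec$occ[is.na(rec$occ)] <- 1

  chains <- unique(rec$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains)
    stop(sprintf("chain '%s' not present (chains: %s)",
                 chain, paste(chains, collapse = ", ")), call. = FALSE)
  rec <- rec[rec$chain == chain & rec$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  if (!any(rec$atom == "CA"))
    stop(sprintf("chain '%s' has no CA atoms", chain), call. = FALSE)

  reskey <- paste(rec$resseq, rec$icode, sep = "|")
  resorder <- unique(reskey)
  n <- length(resorder)
  coords <- array(NA_real_, c(n, 5L, 3L))
  mask <- matrix(FALSE, n, 5L)
  seqv <- character(n)
  for (i in seq_len(n)) {
    sub <- rec[reskey == resorder[i], , drop = FALSE]
    aa <- AA3TO1[sub$resname[1L]]
    seqv[i] <- if (is.na(aa)) "X" else aa
    for (a in seq_along(BACKBONE_ATOMS)) {
      hit <- sub[sub$atom == BACKBONE_ATOMS[a], , drop = FALSE]
      if (nrow(hit) == 0L) next
      # altloc: highest occupancy wins, first seen breaks ties
      hit <- hit[order(-hit$occ), , drop = FALSE]
      coords[i, a, ] <- c(hit$x[1L], hit$y[1L], hit$z[1L])
      mask[i, a] <- TRUE
    }
  }
  protein_structure(coords, paste(seqv, collapse = ""), mask,
                    residue_ids = seq_len(n) - 1L, chain_id = chain)
}

AA1TO3 <- c(stats::setNames(names(AA3TO1)[1:20], unname(AA3TO1)[1:20]), X = "UNK")

#' Write a structure as PDB text
#'
#' Emits fixed-width ATOM records (occupancy 1.00) for present atoms only,
#' followed by TER/END. Serial numbers and residue numbers are regenerated;
#' the B-factor column can carry a per-residue confidence value.
#'
#' @param structure A [protein_structure()].
#' @param path Optional output file; when `NULL` the text is returned.
#' @param bfactor Optional numeric per-residue value (e.g. pLDDT) written to
#'   the B-factor column of every atom of that residue; default 0.
#' @return The PDB text, invisibly when written to `path`.
#' @export
write_pdb <- function(structure, path = NULL, bfactor = NULL) {
  validate_structure(structure)
  n <- length(structure)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  stopifnot(length(bfactor) == n)
  sq <- seq_chars(structure)
  elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    res3 <- AA1TO3[sq[i]]
    if (is.na(res3)) res3 <- "UNK"
    for (a in seq_along(BACKBONE_ATOMS)) {
      if (!structure$atom_mask[i, a]) next
      serial <- serial + 1L
      nm <- BACKBONE_ATOMS[a]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, res3, structure$chain_id, structure$residue_ids[i] + 1L,
        structure$coords[i, a, 1L], structure$coords[i, a, 2L],
        structure$coords[i, a, 3L], 1, bfactor[i], elements[nm]))
    }
  }
  lines <- c(lines,
             sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                     AA1TO3[sq[n]], structure$chain_id,
                     structure$residue_ids[n] + 1L),
             "END")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

#' Read target sequences from a FASTA file
#'
#' @param path FASTA file with one or more records.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(recs, as.character, "")), names(recs))
}
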