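# Template featurization: encode a decoy backbone as the sequence-free
# template a structure predictor consumes — one-hot token rows over a
# 22-letter alphabet (20 amino acids + unknown + gap), a C-beta distance
# matrix, backbone dihedrals as (sin, cos) pairs, and validity masks.
#
# The 22-token alphabet order is fixed HERE and nowhere else; adapters for
# real predictors translate from this order.

#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @export
TOKEN_ALPHABET <- c(AA_ALPHABET, "X", "-")

GAP_INDEX <- 22L
UNKNOWN_INDEX <- 21L

# Ideal virtual C-beta internal coordinates (conventional values); the
# dihedral is torsion(C, N, CA, CB) for L-amino-acid chirality.
CB_BOND <- 1.522
CB_ANGLE <- 110.4 * pi / 180
CB_DIHEDRAL <- 122.5 * pi / 180

#' Ideal virtual C-beta position from the backbone frame
#'
#' Constructs the tetrahedral C-beta implied by the N, CA, C frame with bond
#' length 1.522 A, N-CA-CB angle 110.4 degrees and the dihedral that places
#' CB with L-amino-acid chirality. Used to give glycine a C-beta and to fill
#' unresolved C-beta atoms, so every residue contributes to the distance
#' matrix.
#'
#' @param n_pos,ca_pos,c_pos Positions of the residue's N, CA and C atoms.
#' @return Length-3 numeric position of the virtual C-beta.
#' @export
virtual_cbeta <- function(n_pos, ca_pos, c_pos) {
  if (any(!is.finite(c(n_pos, ca_pos, c_pos))))
    stop("backbone positions must be finite", call. = FALSE)
  v1 <- n_pos - ca_pos
  v2 <- c_pos - ca_pos
  if (vec_norm(v1) < 1e-6 || vec_norm(v2) < 1e-6 ||
      vec_norm(cross3(v1, v2)) < 1e-6)
    stop("degenerate backbone frame (collinear or coincident atoms)",
         call. = FALSE)
  place_atom(c_pos, n_pos, ca_pos, CB_BOND, CB_ANGLE, CB_DIHEDRAL)
}

#' Reduce a structure to the template backbone representation
#'
#' Keeps only {N, CA, C, O, CB} (the container already enforces this) and
#' fills every missing C-beta — glycines included — with [virtual_cbeta()]
#' wherever N, CA and C are present. Residues lacking a complete backbone
#' frame keep their C-beta absent. Experimentally observed C-beta atoms are
#' never overwritten.
#'
#' @param structure A [protein_structure()].
#' @return A [protein_structure()] with the C-beta slots filled where
#'   possible and `atom_mask` updated.
#' @export
mask_to_backbone <- function(structure) {
  validate_structure(structure)
  coords <- structure$coords
  mask <- structure$atom_mask
  for (i in seq_len(length(structure))) {
    if (mask[i, "CB"]) next
    if (mask[i, "N"] && mask[i, "CA"] && mask[i, "C"]) {
      coords[i, "CB", ] <- virtual_cbeta(coords[i, "N", ], coords[i, "CA", ],
                                         coords[i, "C", ])
      mask[i, "CB"] <- TRUE
    }
  }
  protein_structure(coords, structure$sequence, mask,
                    structure$residue_ids, structure$chain_id)
}

#' One-hot gap-token sequence
#'
#' The encoding that hides the template's amino-acid identity from the
#' predictor: every row is one-hot at the gap token ("missing amino acid").
#'
#' @param length Number of residues, >= 1.
#' @return `length x 22` one-hot matrix with columns named by
#'   [TOKEN_ALPHABET].
#' @export
gap_sequence <- function(length) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  m <- matrix(0, length, 22L, dimnames = list(NULL, TOKEN_ALPHABET))
  m[, GAP_INDEX] <- 1
  m
}

onehot_sequence <- function(sequence) {
  chars <- strsplit(sequence, "")[[1L]]
  idx <- match(chars, TOKEN_ALPHABET)
  idx[is.na(idx)] <- UNKNOWN_INDEX
  m <- matrix(0, length(chars), 22L, dimnames = list(NULL, TOKEN_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

decode_onehot <- function(onehot) {
  paste(TOKEN_ALPHABET[max.col(onehot)], collapse = "")
}

# Backbone dihedrals phi, psi, omega with termini masked. Omega is assigned
# to the peptide bond preceding each residue (first residue masked).
backbone_torsions <- function(structure) {
  n <- length(structure)
  ang <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("phi", "psi", "omega")))
  mask <- matrix(FALSE, n, 3L, dimnames = list(NULL, c("phi", "psi", "omega")))
  m <- structure$atom_mask
  cd <- structure$coords
  for (i in seq_len(n)) {
    if (i > 1L && m[i - 1L, "C"] && all(m[i, c("N", "CA", "C")])) {
      ang[i, "phi"] <- dihedral_angle(cd[i - 1L, "C", ], cd[i, "N", ],
                                      cd[i, "CA", ], cd[i, "C", ])
      mask[i, "phi"] <- TRUE
    }
    if (i < n && all(m[i, c("N", "CA", "C")]) && m[i + 1L, "N"]) {
      ang[i, "psi"] <- dihedral_angle(cd[i, "N", ], cd[i, "CA", ],
                                      cd[i, "C", ], cd[i + 1L, "N", ])
      mask[i, "psi"] <- TRUE
    }
    if (i > 1L && all(m[i - 1L, c("CA", "C")]) && all(m[i, c("N", "CA")])) {
      ang[i, "omega"] <- dihedral_angle(cd[i - 1L, "CA", ], cd[i - 1L, "C", ],
                                        cd[i, "N", ], cd[i, "CA", ])
      mask[i, "omega"] <- TRUE
    }
  }
  list(angles = ang, mask = mask)
}

#' Featurize a structure as a predictor template
#'
#' Builds the full template encoding from a backbone-reduced structure:
#' the C-beta distance matrix (virtual C-beta where needed), backbone
#' dihedrals phi/psi/omega as (sin, cos) pairs with undefined termini
#' masked, atom masks, and the one-hot token sequence — all gap tokens by
#' default, so no amino-acid identity leaks to the predictor. Side-chain
#' torsion channels are flagged invalid rather than zeroed (side chains
#' were removed). `sequence_mode = "native"` reproduces the overconfidence
#' control in which the decoy's real sequence is supplied instead.
#'
#' @param structure A [protein_structure()], ideally already processed by
#'   [mask_to_backbone()] (applied defensively otherwise).
#' @param sequence_mode `"gap"` (default) or `"native"`.
#' @param ca_fallback If `TRUE`, pairs whose C-beta cannot be virtualized
#'   fall back to CA distances instead of being flagged invalid.
#' @return An object of class `template_features`: list with
#'   `aatype_onehot` (L x 22), `cbeta_distance_matrix` (L x L, Angstrom),
#'   `pair_valid` (L x L logical), `torsions` (L x 3 x 2 sin/cos),
#'   `torsion_mask` (L x 3), `sidechain_torsion_mask` (L x 4, all `FALSE`),
#'   `atom_mask` (L x 5) and `sequence_mode`. The source backbone is
#'   attached as attribute `"structure"` for mock predictors.
#' @export
featurize_template <- function(structure, sequence_mode = c("gap", "native"),
                               ca_fallback = FALSE) {
  sequence_mode <- match.arg(sequence_mode)
  structure <- mask_to_backbone(structure)
  n <- length(structure)
  pos <- atom_coords(structure, "CB")
  has <- structure$atom_mask[, "CB"]
  if (ca_fallback) {
    fb <- !has & structure$atom_mask[, "CA"]
    pos[fb, ] <- atom_coords(structure, "CA")[fb, , drop = FALSE]
    has <- has | fb
  }
  if (sum(has) < 2L)
    stop("need at least 2 residues with a usable C-beta/CA position",
         call. = FALSE)
  dmat <- matrix(NA_real_, n, n)
  dmat[has, has] <- pairwise_dist(pos[has, , drop = FALSE])
  pair_valid <- outer(has, has, `&`)
  diag(dmat) <- ifelse(has, 0, NA_real_)

  tor <- backbone_torsions(structure)
  torsions <- array(0, c(n, 3L, 2L),
                    dimnames = list(NULL, c("phi", "psi", "omega"),
                                    c("sin", "cos")))
  torsions[, , "sin"] <- sin(tor$angles)
  torsions[, , "cos"] <- cos(tor$angles)
  torsions[is.na(torsions)] <- 0

  aatype <- if (sequence_mode == "gap") gap_sequence(n)
            else onehot_sequence(structure$sequence)

  out <- structure(
    list(aatype_onehot = aatype,
         cbeta_distance_matrix = dmat,
         pair_valid = pair_valid,
         torsions = torsions,
         torsion_mask = tor$mask,
         sidechain_torsion_mask = matrix(FALSE, n, 4L),
         atom_mask = structure$atom_mask,
         sequence_mode = sequence_mode),
    class = "template_features")
  attr(out, "structure") <- structure
  out
}

#' @export
print.template_features <- function(x, ...) {
  cat(sprintf("<template_features> %d residues, sequence_mode = %s\n",
              nrow(x$aatype_onehot), x$sequence_mode))
  cat(sprintf("  valid distance pairs: %d / %d\n",
              sum(x$pair_valid), length(x$pair_valid)))
  invisible(x)
}

#' Serialize template features to a directory
#'
#' Writes each array field as a plain CSV plus a JSON manifest recording the
#' field shapes, alphabet and sequence mode, so adapters and tests can diff
#' encodings bit-exactly.
#'
#' @param features A `template_features` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_template_features <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, name) utils::write.table(
    m, file.path(dir, paste0(name, ".csv")), sep = ",",
    row.names = FALSE, col.names = FALSE)
  wr(features$aatype_onehot, "aatype_onehot")
  wr(features$cbeta_distance_matrix, "cbeta_distance_matrix")
  wr(features$pair_valid * 1L, "pair_valid")
  wr(cbind(features$torsions[, , "sin"], features$torsions[, , "cos"]),
     "torsions_sincos")
  wr(features$torsion_mask * 1L, "torsion_mask")
  wr(features$atom_mask * 1L, "atom_mask")
  manifest <- list(
    n_residues = nrow(features$aatype_onehot),
    alphabet = TOKEN_ALPHABET,
    gap_index = GAP_INDEX,
    sequence_mode = features$sequence_mode,
    fields = c("aatype_onehot", "cbeta_distance_matrix", "pair_valid",
               "torsions_sincos", "torsion_mask", "atom_mask"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read serialized template features
#'
#' @param dir Directory written by [write_template_features()].
#' @return A `template_features` object (without the attached backbone).
#' @export
read_template_features <- function(dir) {
  rd <- function(name) as.matrix(utils::read.table(
    file.path(dir, paste0(name, ".csv")), sep = ",", header = FALSE))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  n <- manifest$n_residues
  sc <- rd("torsions_sincos")
  torsions <- array(0, c(n, 3L, 2L),
                    dimnames = list(NULL, c("phi", "psi", "omega"),
                                    c("sin", "cos")))
  torsions[, , "sin"] <- sc[, 1:3]
  torsions[, , "cos"] <- sc[, 4:6]
  aat <- rd("aatype_onehot")
  dimnames(aat) <- list(NULL, TOKEN_ALPHABET)
  structure(
    list(aatype_onehot = aat,
         cbeta_distance_matrix = unname(rd("cbeta_distance_matrix")),
         pair_valid = unname(rd("pair_valid")) > 0,
         torsions = torsions,
         torsion_mask = unname(rd("torsion_mask")) > 0,
         sidechain_torsion_mask = matrix(FALSE, n, 4L),
         atom_mask = unname(rd("atom_mask")) > 0,
         sequence_mode = manifest$sequence_mode),
    class = "template_features")
}
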