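# Synthetic natives and decoy ladders with known quality.
#
# Toy natives are built in torsion space with ideal bond geometry; decoys
# are graded perturbations of a native, so the true quality of every decoy
# is computable and ladders span a known quality range. This emulates the
# one property of real decoy sets the ranking statistics need — a wide,
# graded spread of accuracy around a single native — not the physics of
# fragment assembly.

# Ideal backbone internal coordinates (Engh-Huber-like values).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2 * pi / 180
ANGLE_CA_C_N <- 116.2 * pi / 180
ANGLE_C_N_CA <- 121.7 * pi / 180
ANGLE_CA_C_O <- 120.1 * pi / 180

deg <- function(x) x * pi / 180

#' Build a backbone from torsion angles
#'
#' Chains residues with ideal bond lengths and angles from phi/psi/omega
#' torsions (degrees), places carbonyl O atoms in the peptide plane, and
#' fills every C-beta with [virtual_cbeta()].
#'
#' @param phi,psi,omega Numeric vectors of length L (degrees). `phi[1]` and
#'   `omega[1]` are unused (undefined at the N-terminus).
#' @param sequence Optional sequence string (default poly-alanine).
#' @return A [protein_structure()].
#' @export
build_backbone <- function(phi, psi, omega = NULL, sequence = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  coords <- array(NA_real_, c(n, 5L, 3L),
                  dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
  # first residue in a canonical frame
  coords[1L, "N", ] <- c(0, 0, 0)
  coords[1L, "CA", ] <- c(BOND_N_CA, 0, 0)
  coords[1L, "C", ] <- coords[1L, "CA", ] +
    BOND_CA_C * c(cos(pi - ANGLE_N_CA_C), sin(pi - ANGLE_N_CA_C), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      coords[i, "N", ] <- place_atom(coords[i - 1L, "N", ],
                                     coords[i - 1L, "CA", ],
                                     coords[i - 1L, "C", ],
                                     BOND_C_N, ANGLE_CA_C_N, deg(psi[i - 1L]))
      coords[i, "CA", ] <- place_atom(coords[i - 1L, "CA", ],
                                      coords[i - 1L, "C", ],
                                      coords[i, "N", ],
                                      BOND_N_CA, ANGLE_C_N_CA, deg(omega[i]))
      coords[i, "C", ] <- place_atom(coords[i - 1L, "C", ],
                                     coords[i, "N", ],
                                     coords[i, "CA", ],
                                     BOND_CA_C, ANGLE_N_CA_C, deg(phi[i]))
    }
    # carbonyl O opposite the next N in the peptide plane
    o_torsion <- if (i < n) deg(psi[i]) + pi else pi
    coords[i, "O", ] <- place_atom(coords[i, "N", ], coords[i, "CA", ],
                                   coords[i, "C", ],
                                   BOND_C_O, ANGLE_CA_C_O, o_torsion)
    coords[i, "CB", ] <- virtual_cbeta(coords[i, "N", ], coords[i, "CA", ],
                                       coords[i, "C", ])
  }
  protein_structure(coords, sequence)
}

HELIX_PHI <- -57
HELIX_PSI <- -47

# Smallest CA-CA distance over pairs with |i - j| > 2, Inf if none.
min_nonneighbor_ca <- function(structure) {
  ca <- atom_coords(structure, "CA")
  d <- pairwise_dist(ca)
  sep <- abs(outer(seq_len(nrow(ca)), seq_len(nrow(ca)), `-`))
  v <- d[sep > 2L]
  if (length(v)) min(v) else Inf
}

#' Generate a toy native structure
#'
#' Idealized backbones for testing: `"helix"` (phi = -57, psi = -47,
#' omega = 180 throughout), `"helix_hairpin"` (two helices joined by a
#' four-residue turn), or `"random_compact"` (per-residue torsions sampled
#' from helix/sheet/polyproline basins with whole-chain rejection of CA
#' clashes under 3.5 A). Deterministic for a given seed.
#'
#' @param length Number of residues, >= 8.
#' @param topology `"helix"`, `"helix_hairpin"` or `"random_compact"`.
#' @param seed Integer seed (used by `"random_compact"` and to draw the
#'   sequence).
#' @param max_tries Resampling budget for the self-avoidance rejection.
#' @return A [protein_structure()].
#' @export
make_toy_native <- function(length, topology = c("helix", "helix_hairpin",
                                                 "random_compact"),
                            seed = 1L, max_tries = 200L) {
  topology <- match.arg(topology)
  if (length < 8L) stop("length must be >= 8", call. = FALSE)
  sequence <- with_seed(stable_hash(seed, 7L), paste(
    sample(AA_ALPHABET, length, replace = TRUE), collapse = ""))
  if (topology == "helix") {
    return(build_backbone(rep(HELIX_PHI, length), rep(HELIX_PSI, length),
                          sequence = sequence))
  }
  if (topology == "helix_hairpin") {
    n1 <- (length - 4L) %/% 2L
    n2 <- length - 4L - n1
    # turn torsions chosen so the helices pack without CA clashes at any
    # tested chain length
    phi <- c(rep(HELIX_PHI, n1), c(149, 92, 47, 106), rep(HELIX_PHI, n2))
    psi <- c(rep(HELIX_PSI, n1), c(152, -121, -111, -145),
             rep(HELIX_PSI, n2))
    return(build_backbone(phi, psi, sequence = sequence))
  }
  # random_compact: basin-sampled torsions + clash rejection
  for (try in seq_len(max_tries)) {
    st <- with_seed(stable_hash(seed, try), {
      basin <- sample(3L, length, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      phi <- c(-57, -120, -75)[basin] + stats::rnorm(length, 0, c(10, 15, 15)[basin])
      psi <- c(-47, 130, 150)[basin] + stats::rnorm(length, 0, c(10, 15, 15)[basin])
      build_backbone(phi, psi, sequence = sequence)
    })
    if (min_nonneighbor_ca(st) >= 3.5) return(st)
  }
  stop("could not generate a self-avoiding chain within the retry budget",
       call. = FALSE)
}

#' Perturb a structure to a target noise scale
#'
#' Two graded degradation modes. `"cartesian_smooth"` draws i.i.d. Gaussian
#' residue displacements, smooths them along the chain with a window-5
#' moving average and rescales to root-mean-square `sigma` per coordinate;
#' whole residues move rigidly, so local bond geometry degrades gracefully
#' the way real decoys do. `"torsion"` jitters phi/psi by
#' `N(0, sigma degrees)` and rebuilds the chain with ideal geometry.
#' C-beta atoms are re-virtualized from the perturbed backbone. The result
#' is deterministic for a given seed.
#'
#' @param structure A [protein_structure()].
#' @param sigma Noise scale: Angstrom for `"cartesian_smooth"`, degrees for
#'   `"torsion"`; 0 returns the input coordinates (C-beta still
#'   re-virtualized).
#' @param mode `"cartesian_smooth"` (default) or `"torsion"`.
#' @param seed Integer seed.
#' @return A perturbed [protein_structure()].
#' @export
perturb_structure <- function(structure, sigma,
                              mode = c("cartesian_smooth", "torsion"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  n <- length(structure)
  if (mode == "cartesian_smooth") {
    coords <- structure$coords
    if (sigma > 0) {
      noise <- with_seed(seed, matrix(stats::rnorm(n * 3L), n, 3L))
      # centered moving average, window 5 (shorter at the ends)
      sm <- apply(noise, 2L, function(col) {
        vapply(seq_len(n), function(i) {
          w <- max(1L, i - 2L):min(n, i + 2L)
          mean(col[w])
        }, 0)
      })
      sm <- matrix(sm, n, 3L)
      rms <- sqrt(mean(sm^2))
      if (rms > 0) sm <- sm * (sigma / rms)
      for (a in seq_len(5L)) coords[, a, ] <- coords[, a, ] + sm
    }
    out <- protein_structure(coords, structure$sequence, structure$atom_mask,
                             structure$residue_ids, structure$chain_id)
    # re-virtualize C-beta from the perturbed frame
    out$atom_mask[, "CB"] <- FALSE
    out$coords[, "CB", ] <- NA_real_
    return(mask_to_backbone(out))
  }
  tor <- backbone_torsions(structure)
  ang <- tor$angles * 180 / pi
  phi <- ifelse(is.na(ang[, "phi"]), HELIX_PHI, ang[, "phi"])
  psi <- ifelse(is.na(ang[, "psi"]), HELIX_PSI, ang[, "psi"])
  if (sigma > 0) {
    jit <- with_seed(seed, matrix(stats::rnorm(2L * n, 0, sigma), n, 2L))
    phi <- phi + jit[, 1L]
    psi <- psi + jit[, 2L]
  }
  build_backbone(phi, psi, sequence = structure$sequence)
}

#' Specification of a synthetic decoy ladder
#'
#' @param native_length Residue count of the generated native.
#' @param topology Passed to [make_toy_native()].
#' @param sigmas Strictly increasing noise scales, one rung each; include 0
#'   to add the unperturbed native as a rung.
#' @param n_per_sigma Decoys per rung (>= 1).
#' @param mode Perturbation mode, see [perturb_structure()].
#' @param seed Master seed; every decoy derives a distinct sub-seed from a
#'   stable hash of (seed, rung, index).
#' @return An object of class `decoy_ladder_spec`.
#' @export
decoy_ladder_spec <- function(native_length = 60L, topology = "helix_hairpin",
                              sigmas = c(0.25, 0.5, 1, 2, 4),
                              n_per_sigma = 10L,
                              mode = "cartesian_smooth", seed = 1L) {
  if (any(diff(sigmas) <= 0) || any(sigmas < 0))
    stop("sigmas must be strictly increasing and >= 0", call. = FALSE)
  if (n_per_sigma < 1L) stop("n_per_sigma must be >= 1", call. = FALSE)
  structure(list(native_length = as.integer(native_length),
                 topology = topology, sigmas = sigmas,
                 n_per_sigma = as.integer(n_per_sigma), mode = mode,
                 seed = as.integer(seed)),
            class = "decoy_ladder_spec")
}

#' Generate a decoy ladder
#'
#' Builds the native and `n_per_sigma` perturbed decoys per noise rung, each
#' from an independent, stably hashed sub-seed so regeneration is
#' byte-identical.
#'
#' @param spec A [decoy_ladder_spec()].
#' @return List with `native`, `decoys` (named list of structures) and
#'   `manifest` (data.frame: `decoy_id`, `sigma`, `rung`, `seed`).
#' @export
make_decoy_ladder <- function(spec) {
  stopifnot(inherits(spec, "decoy_ladder_spec"))
  native <- make_toy_native(spec$native_length, spec$topology,
                            seed = spec$seed)
  decoys <- list()
  manifest <- NULL
  for (r in seq_along(spec$sigmas)) {
    for (k in seq_len(spec$n_per_sigma)) {
      sub_seed <- stable_hash(spec$seed, r, k)
      id <- sprintf("s%02d_%03d", r, k)
      decoys[[id]] <- perturb_structure(native, spec$sigmas[r], spec$mode,
                                        seed = sub_seed)
      manifest <- rbind(manifest, data.frame(
        decoy_id = id, sigma = spec$sigmas[r], rung = r, seed = sub_seed,
        stringsAsFactors = FALSE))
    }
  }
  list(native = native, decoys = decoys, manifest = manifest)
}
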