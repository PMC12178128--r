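# The structure-predictor contract and deterministic mock implementations.
#
# A predictor is an S3 object with a `fun(target_sequence, template, num_recycles,
# seed)` slot returning a predictor_output. Real adapters (e.g. an AlphaFold
# wrapper translating the template encoding into network features) plug in
# behind the same contract; the shipped mocks make every downstream protocol
# runnable and testable without model weights:
#
#   * geometry_mock():   confidence from backbone-geometry plausibility.
#   * oracle_mock():     confidence from true similarity to a hidden native —
#                        a pipeline-correctness oracle, not a simulation.
#   * sequence_match_mock(), planted_generator_mock(): planted-signal mocks
#                        for the design and search optimizers.
#
# Mocks return the template backbone as their output structure (no
# refinement); the TM(decoy, output) factor of the composite score is then
# exactly 1, which the test-suite accounts for.

#' Distogram bin layout
#'
#' Default layout: 64 bins whose 63 inner edges run from 2.3125 to
#' 21.6875 Angstrom in 0.3125 steps; the first bin is below the first edge
#' and the final bin is open-ended. This mirrors the distance-head layout of
#' published structure predictors and is configurable.
#'
#' @param n_bins Number of bins (>= 2).
#' @param first_edge,last_edge First and last inner edge (Angstrom).
#' @return List with `edges` (length `n_bins - 1`), `centers`
#'   (length `n_bins`; outer bins use edge +/- half-step) and `n_bins`.
#' @export
distogram_bins <- function(n_bins = 64L, first_edge = 2.3125,
                           last_edge = 21.6875) {
  edges <- seq(first_edge, last_edge, length.out = n_bins - 1L)
  step <- edges[2L] - edges[1L]
  centers <- c(edges[1L] - step / 2,
               (edges[-1L] + edges[-length(edges)]) / 2,
               edges[length(edges)] + step / 2)
  list(edges = edges, centers = centers, n_bins = as.integer(n_bins))
}

# Bin index of each distance (final bin catches >= last edge).
distance_to_bin <- function(d, bins) findInterval(d, bins$edges) + 1L

#' Construct a predictor object
#'
#' @param name Predictor name (used in reports and CLI selection).
#' @param fun Function `(target_sequence, template, num_recycles, seed)`
#'   returning a [predictor_output()].
#' @param requires_template Does the implementation refuse template-free
#'   calls?
#' @param capabilities Character vector of optional capability tags (e.g.
#'   `"distogram"`, `"gradient"`).
#' @return An object of class `predictor`.
#' @export
new_predictor <- function(name, fun, requires_template = FALSE,
                          capabilities = "distogram") {
  structure(list(name = name, fun = fun,
                 requires_template = requires_template,
                 capabilities = capabilities),
            class = "predictor")
}

#' @export
print.predictor <- function(x, ...) {
  cat(sprintf("<predictor> %s (capabilities: %s)\n", x$name,
              paste(x$capabilities, collapse = ", ")))
  invisible(x)
}

#' Assemble and validate a predictor output
#'
#' @param structure Predicted [protein_structure()].
#' @param plddt Per-residue predicted lDDT in [0, 100].
#' @param ptm Predicted TM-score in [0, 1].
#' @param distogram `L x L x B` array of per-pair bin probabilities; every
#'   pair's vector must sum to 1.
#' @param num_recycles_used Integer recycle count.
#' @param bins The [distogram_bins()] layout of `distogram`.
#' @return An object of class `predictor_output`.
#' @export
predictor_output <- function(structure, plddt, ptm, distogram,
                             num_recycles_used = 1L,
                             bins = distogram_bins()) {
  out <- structure(
    list(structure = structure, plddt = plddt, ptm = ptm,
         distogram = distogram, num_recycles_used = as.integer(num_recycles_used),
         bins = bins),
    class = "predictor_output")
  validate_predictor_output(out)
  out
}

#' @export
print.predictor_output <- function(x, ...) {
  cat(sprintf("<predictor_output> %d residues, mean pLDDT %.1f, pTM %.3f\n",
              length(x$structure), mean(x$plddt), x$ptm))
  invisible(x)
}

validate_predictor_output <- function(out) {
  n <- length(out$structure)
  if (length(out$plddt) != n)
    stop("pLDDT must have one value per residue", call. = FALSE)
  if (any(out$plddt < 0 | out$plddt > 100))
    stop("pLDDT values must lie in [0, 100]", call. = FALSE)
  if (out$ptm < 0 || out$ptm > 1)
    stop("pTM must lie in [0, 1]", call. = FALSE)
  dd <- dim(out$distogram)
  if (length(dd) != 3L || dd[1L] != n || dd[2L] != n)
    stop("distogram must be L x L x B", call. = FALSE)
  sums <- rowSums(matrix(out$distogram, dd[1L] * dd[2L], dd[3L]))
  if (any(abs(sums - 1) > 1e-6))
    stop("distogram rows must each sum to 1", call. = FALSE)
  invisible(out)
}

#' Run a predictor under the contract
#'
#' Validates the inputs (sequence alphabet, template/sequence length match,
#' template requirement), dispatches to the implementation and validates the
#' output invariants, including length preservation.
#'
#' @param predictor A [new_predictor()] object.
#' @param target_sequence Target amino-acid sequence (20 letters + X).
#' @param template Optional `template_features` for the decoy backbone.
#' @param num_recycles Number of recycling iterations (default 1).
#' @param seed Integer seed; implementations must be deterministic given
#'   (inputs, seed).
#' @return A validated `predictor_output`.
#' @export
predict_structure <- function(predictor, target_sequence, template = NULL,
                              num_recycles = 1L, seed = 1L) {
  stopifnot(inherits(predictor, "predictor"))
  chars <- strsplit(target_sequence, "")[[1L]]
  if (!all(chars %in% c(AA_ALPHABET, "X")))
    stop("target sequence may only use the 20 amino-acid letters plus X",
         call. = FALSE)
  if (!is.null(template) && nrow(template$aatype_onehot) != length(chars))
    stop("template length must equal target sequence length", call. = FALSE)
  if (is.null(template) && isTRUE(predictor$requires_template))
    stop(sprintf("predictor '%s' requires a template", predictor$name),
         call. = FALSE)
  out <- predictor$fun(target_sequence, template, num_recycles, seed)
  validate_predictor_output(out)
  if (length(out$structure) != length(chars))
    stop("predicted structure length must equal target sequence length",
         call. = FALSE)
  out
}

# Gaussian distogram centered on a distance matrix; rows always normalize.
# Invalid pairs get a uniform distribution.
soft_distogram <- function(dmat, valid, bins, sd) {
  n <- nrow(dmat)
  b <- bins$n_bins
  dist <- matrix(1 / b, n * n, b)
  flat <- which(valid)
  if (length(flat)) {
    w <- exp(-0.5 * (outer(dmat[flat], bins$centers, `-`) / sd)^2) + 1e-12
    dist[flat, ] <- w / rowSums(w)
  }
  array(dist, c(n, n, b))
}

onehot_distogram <- function(dmat, valid, bins) {
  n <- nrow(dmat)
  b <- bins$n_bins
  dist <- matrix(1 / b, n * n, b)
  flat <- which(valid)
  if (length(flat)) {
    dist[flat, ] <- 0
    dist[cbind(flat, distance_to_bin(dmat[flat], bins))] <- 1
  }
  array(dist, c(n, n, b))
}

#' Geometry-plausibility confidence of a backbone
#'
#' The scoring rule of [geometry_mock()]: per-residue plausibility
#' `p_i = 100 exp(-(e_i / 0.5)^2)` where `e_i` is the mean absolute
#' deviation of the residue's virtual CA-CA bonds from 3.8 A, multiplied by
#' a clash penalty `1 - f_clash` with `f_clash` the fraction of non-neighbor
#' CA pairs (|i - j| > 2) closer than 3.5 A. pTM is a logistic of the mean
#' plausibility rescaled so 0 maps to 0 and 100 maps to 1.
#'
#' @param structure A [protein_structure()] with CA coordinates.
#' @return List with `plddt` (per residue, [0, 100]) and `ptm` ([0, 1]).
#' @export
geometry_mock_confidence <- function(structure) {
  ca <- atom_coords(structure, "CA")
  ok <- structure$atom_mask[, "CA"]
  n <- nrow(ca)
  dev <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    devs <- c()
    if (i > 1L && ok[i] && ok[i - 1L])
      devs <- c(devs, abs(vec_norm(ca[i, ] - ca[i - 1L, ]) - 3.8))
    if (i < n && ok[i] && ok[i + 1L])
      devs <- c(devs, abs(vec_norm(ca[i + 1L, ] - ca[i, ]) - 3.8))
    if (length(devs)) dev[i] <- mean(devs)
  }
  p <- 100 * exp(-(dev / 0.5)^2)
  p[is.na(p)] <- 50  # isolated residue: no geometric evidence either way

  d <- pairwise_dist(ca[ok, , drop = FALSE])
  sep <- abs(outer(which(ok), which(ok), `-`))
  nonneigh <- sep > 2L & upper.tri(d)
  f_clash <- if (any(nonneigh)) mean(d[nonneigh] < 3.5) else 0
  p <- p * (1 - f_clash)

  m <- mean(p) / 100
  logistic <- function(z) 1 / (1 + exp(-10 * (z - 0.5)))
  ptm <- (logistic(m) - logistic(0)) / (logistic(1) - logistic(0))
  list(plddt = p, ptm = ptm)
}

#' Geometry-based mock predictor
#'
#' Scores the template by local backbone plausibility (CA-CA virtual bond
#' geometry and steric clashes) with no knowledge of any native structure.
#' The output structure is the template backbone itself; the distogram is a
#' Gaussian around the template's C-beta distances whose width grows as
#' confidence falls. Without a template it emits an ideal helix for the
#' target sequence.
#'
#' @param bins Distogram layout, default [distogram_bins()].
#' @return A [new_predictor()] object.
#' @export
geometry_mock <- function(bins = distogram_bins()) {
  new_predictor("geometry-mock", function(target_sequence, template,
                                          num_recycles, seed) {
    if (is.null(template)) {
      st <- make_toy_native(nchar(target_sequence), "helix", seed = 1L)
      st$sequence <- target_sequence
      template <- featurize_template(st, "gap")
    }
    st <- attr(template, "structure")
    conf <- geometry_mock_confidence(st)
    sd <- 0.5 + 4 * (1 - mean(conf$plddt) / 100)
    dist <- soft_distogram(template$cbeta_distance_matrix,
                           template$pair_valid, bins, sd)
    predictor_output(st, conf$plddt, conf$ptm, dist,
                     num_recycles_used = num_recycles, bins = bins)
  })
}

#' Oracle mock predictor with a hidden native
#'
#' A pipeline-correctness oracle: confidences are the true quality of the
#' template measured against a native structure hidden at construction —
#' per-residue pLDDT is `100 x lDDT(template, native)`, pTM is
#' `TM(template, native)`, and the distogram is one-hot at the bin of each
#' native C-beta distance. Refuses template-free calls.
#'
#' @param hidden_native The native [protein_structure()]; never exposed
#'   downstream.
#' @param bins Distogram layout.
#' @return A [new_predictor()] object.
#' @export
oracle_mock <- function(hidden_native, bins = distogram_bins()) {
  native_bb <- mask_to_backbone(hidden_native)
  native_cb <- atom_coords(native_bb, "CB")
  has_cb <- native_bb$atom_mask[, "CB"]
  ncb <- matrix(NA_real_, length(native_bb), length(native_bb))
  ncb[has_cb, has_cb] <- pairwise_dist(native_cb[has_cb, , drop = FALSE])
  valid <- outer(has_cb, has_cb, `&`)
  dist <- onehot_distogram(ncb, valid, bins)  # input-independent: precompute
  new_predictor("oracle-mock", function(target_sequence, template,
                                        num_recycles, seed) {
    st <- attr(template, "structure")
    ld <- lddt(st, native_bb)
    plddt <- 100 * ld$per_residue
    plddt[is.na(plddt)] <- 100 * ld$global
    ptm <- tm_score(st, native_bb)
    predictor_output(st, plddt, ptm, dist,
                     num_recycles_used = num_recycles, bins = bins)
  }, requires_template = TRUE)
}

# Fraction of positions at which two equal-length sequences agree.
seq_match_fraction <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  mean(av == bv)
}

#' Planted-signal mock for sequence design
#'
#' A mock whose distogram sharpens as the query sequence approaches a hidden
#' target sequence: each valid pair's distribution is a mixture
#' `w x one-hot(native bin) + (1 - w) x uniform` with
#' `w = w_min + (w_max - w_min) x match`, `match` the identity between the
#' query and the hidden sequence. The distogram cross-entropy against the
#' native distances is then strictly decreasing in `match`, giving the
#' hill-climb designer a recoverable planted signal.
#'
#' @param native Backbone whose C-beta distances anchor the distogram.
#' @param hidden_sequence The planted sequence (same length as `native`).
#' @param w_min,w_max Mixture weights at 0% and 100% identity.
#' @param bins Distogram layout.
#' @return A [new_predictor()] object.
#' @export
sequence_match_mock <- function(native, hidden_sequence, w_min = 0.02,
                                w_max = 0.98, bins = distogram_bins()) {
  native_bb <- mask_to_backbone(native)
  feats <- featurize_template(native_bb, "gap")
  onehot <- onehot_distogram(feats$cbeta_distance_matrix, feats$pair_valid,
                             bins)
  b <- bins$n_bins
  new_predictor("sequence-match-mock", function(target_sequence, template,
                                                num_recycles, seed) {
    m <- seq_match_fraction(target_sequence, hidden_sequence)
    w <- w_min + (w_max - w_min) * m
    dist <- w * onehot + (1 - w) / b
    plddt <- rep(100 * w, length(native_bb))
    predictor_output(native_bb, plddt, w, dist,
                     num_recycles_used = num_recycles, bins = bins)
  })
}

#' Planted-signal mock generator for structure search
#'
#' Emits a noised copy of a hidden native whose noise scale shrinks as the
#' input sequence approaches a planted key:
#' `sigma = sigma_max - (sigma_max - sigma_min) x match`. The perturbation
#' seed is a stable hash of the input sequence, so the generator is a
#' deterministic function of its input and the best-so-far search objective
#' is well defined.
#'
#' @param native Hidden native backbone.
#' @param key_sequence Planted key (same length as the generator input).
#' @param sigma_max,sigma_min Noise scales (Angstrom) at 0% and 100% match.
#' @param bins Distogram layout.
#' @return A [new_predictor()] object.
#' @export
planted_generator_mock <- function(native, key_sequence, sigma_max = 2,
                                   sigma_min = 0.25, bins = distogram_bins()) {
  native_bb <- mask_to_backbone(native)
  new_predictor("planted-generator-mock", function(target_sequence, template,
                                                   num_recycles, seed) {
    m <- seq_match_fraction(target_sequence, key_sequence)
    sigma <- sigma_max - (sigma_max - sigma_min) * m
    sub_seed <- stable_hash(seed, utf8ToInt(target_sequence))
    st <- perturb_structure(native_bb, sigma, "cartesian_smooth",
                            seed = sub_seed)
    conf <- geometry_mock_confidence(st)
    feats <- featurize_template(st, "gap")
    dist <- soft_distogram(feats$cbeta_distance_matrix, feats$pair_valid,
                           bins, sd = 1)
    predictor_output(st, conf$plddt, conf$ptm, dist,
                     num_recycles_used = num_recycles, bins = bins)
  })
}

#' Look up a shipped predictor by name
#'
#' @param name One of `"geometry-mock"` or `"oracle-mock"`.
#' @param native Native structure, required for `"oracle-mock"`.
#' @return A [new_predictor()] object.
#' @export
get_predictor <- function(name, native = NULL) {
  switch(name,
    "geometry-mock" = geometry_mock(),
    "oracle-mock" = {
      if (is.null(native))
        stop("oracle-mock requires a native structure", call. = FALSE)
      oracle_mock(native)
    },
    stop(sprintf("unknown predictor '%s'", name), call. = FALSE))
}
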