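# Application protocols built on the predictor contract:
#   * design_sequence(): fixed-backbone sequence design, minimizing the
#     categorical cross-entropy between the predictor's distogram and the
#     target backbone's C-beta distances — the differentiable surrogate for
#     the composite confidence score (low predictor confidence widens the
#     predicted distance distributions and raises the cross-entropy, so the
#     surrogate also tracks confidence).
#   * fold_by_search(): structure prediction by a generator-discriminator
#     loop — a generator predictor proposes a candidate structure from a
#     mutable input sequence, the candidate is injected into a discriminator
#     as a gap-token template, and the discriminator's composite confidence
#     is the search objective.
# Both use a pluggable proposal engine; the shipped engine is a greedy
# discrete hill-climb (gradient ascent is an adapter-level capability of
# predictors that can differentiate through their network).

#' Distogram cross-entropy against target distances
#'
#' Mean over scored pairs of `-log p(bin of the target distance)`, with
#' predicted probabilities floored at 1e-12. The final bin is open-ended,
#' so any distance at or beyond the last edge maps into it.
#'
#' @param distogram `L x L x B` probability array (rows normalized).
#' @param target_distances `L x L` matrix of target C-beta distances
#'   (Angstrom).
#' @param pair_mask Logical `L x L`; default scores every pair with
#'   `|i - j| >= 1` and a finite target distance (no short-range
#'   exclusion — near-diagonal pairs keep the loss sensitive to local
#'   geometry).
#' @param bins [distogram_bins()] layout of the distogram.
#' @return Non-negative scalar loss; 0 iff every scored pair is one-hot on
#'   the target bin (up to the probability floor).
#' @export
distogram_cross_entropy <- function(distogram, target_distances,
                                    pair_mask = NULL,
                                    bins = distogram_bins(dim(distogram)[3L])) {
  n <- nrow(target_distances)
  if (is.null(pair_mask)) {
    sep <- abs(outer(seq_len(n), seq_len(n), `-`))
    pair_mask <- sep >= 1L & is.finite(target_distances)
  }
  idx <- which(pair_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no valid pairs to score", call. = FALSE)
  bin <- distance_to_bin(target_distances[pair_mask], bins)
  p <- distogram[cbind(idx[, 1L], idx[, 2L], bin)]
  mean(-log(pmax(p, 1e-12)))
}

random_sequence <- function(length, seed) {
  with_seed(seed, paste(sample(AA_ALPHABET, length, replace = TRUE),
                        collapse = ""))
}

mutate_sequence <- function(sequence, k = 1L) {
  chars <- strsplit(sequence, "")[[1L]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    choices <- setdiff(AA_ALPHABET, chars[p])
    chars[p] <- sample(choices, 1L)
  }
  paste(chars, collapse = "")
}

#' Fixed-backbone sequence design by distogram cross-entropy
#'
#' Featurizes the target backbone once as a gap-token template with side
#' chains masked, then searches sequence space: each step proposes `k`
#' point mutations, queries the predictor with the proposal and the fixed
#' template, evaluates the cross-entropy between the predicted distogram
#' and the template's C-beta distances, and accepts on strict improvement.
#' A flat landscape (no proposal changes the loss within the patience
#' window) is detected and reported rather than searched further.
#'
#' @param predictor A [new_predictor()] exposing a distogram.
#' @param target_backbone The backbone to design for (a
#'   [protein_structure()]; at least 90% of residues must have N, CA, C).
#' @param config List of knobs: `steps` (default 1000), `k` mutations per
#'   step (default 1), `seed` (default 1), `init_sequence` (default: random
#'   over the 20 amino acids), `flat_patience` (default 100),
#'   `num_recycles` (default 1).
#' @return List with `best_sequence`, `best_loss`, `initial_loss`,
#'   `trajectory` (data.frame: step, proposal loss, best-so-far loss,
#'   accepted), `flat_landscape` and `steps_run`.
#' @export
design_sequence <- function(predictor, target_backbone, config = list()) {
  steps <- config$steps %||% 1000L
  k <- config$k %||% 1L
  seed <- config$seed %||% 1L
  flat_patience <- config$flat_patience %||% 100L
  num_recycles <- config$num_recycles %||% 1L

  frame_ok <- rowSums(target_backbone$atom_mask[, c("N", "CA", "C"),
                                                drop = FALSE]) == 3L
  if (mean(frame_ok) < 0.9)
    stop("target backbone must have N, CA, C for at least 90% of residues",
         call. = FALSE)
  if (!"distogram" %in% predictor$capabilities)
    stop(sprintf("predictor '%s' exposes no distogram", predictor$name),
         call. = FALSE)

  bb <- mask_to_backbone(target_backbone)
  template <- featurize_template(bb, "gap")
  target_d <- template$cbeta_distance_matrix
  n <- length(bb)
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  pair_mask <- sep >= 1L & template$pair_valid

  loss_of <- function(sequence) {
    out <- predict_structure(predictor, sequence, template,
                             num_recycles = num_recycles, seed = seed)
    distogram_cross_entropy(out$distogram, target_d, pair_mask, out$bins)
  }

  best_seq <- config$init_sequence %||% random_sequence(n, stable_hash(seed, 11L))
  best_loss <- loss_of(best_seq)
  initial_loss <- best_loss
  traj <- data.frame(step = 0L, loss = best_loss, best_loss = best_loss,
                     accepted = TRUE)
  flat <- FALSE
  with_seed(stable_hash(seed, 13L), {
    unchanged <- 0L
    any_accept <- FALSE
    for (s in seq_len(steps)) {
      prop <- mutate_sequence(best_seq, k)
      l <- loss_of(prop)
      acc <- l < best_loss - 1e-12
      if (acc) {
        best_seq <- prop
        best_loss <- l
        any_accept <- TRUE
      }
      if (abs(l - initial_loss) < 1e-12 && !any_accept) {
        unchanged <- unchanged + 1L
      }
      traj <- rbind(traj, data.frame(step = s, loss = l,
                                     best_loss = best_loss, accepted = acc))
      if (unchanged >= flat_patience) {
        flat <- TRUE
        break
      }
    }
  })
  list(best_sequence = best_seq, best_loss = best_loss,
       initial_loss = initial_loss, trajectory = traj,
       flat_landscape = flat, steps_run = max(traj$step))
}

#' Structure prediction by generator-discriminator search
#'
#' Maintains a mutable generator input sequence (initialized to the target
#' sequence). Each step the generator predicts a candidate structure for
#' the current input (no template), the candidate is featurized as a
#' gap-token template and injected into the discriminator together with the
#' target sequence, and the discriminator's composite confidence score is
#' the objective. Point mutations to the generator input are accepted on
#' strict improvement; the best-so-far objective is therefore non-
#' decreasing along the trajectory. `steps = 0` returns the baseline
#' single-pass prediction.
#'
#' @param generator,discriminator [new_predictor()] objects.
#' @param target_sequence The sequence whose structure is sought.
#' @param config List of knobs: `steps` (default 200), `k` (default 1),
#'   `seed` (default 1), `num_recycles` (default 1).
#' @return List with `best_structure`, `best_objective`,
#'   `baseline_objective` (step-0 value), `best_sequence` (the generator
#'   input that produced the best candidate) and `trajectory` (data.frame:
#'   step, objective, best-so-far, accepted).
#' @export
fold_by_search <- function(generator, discriminator, target_sequence,
                           config = list()) {
  steps <- config$steps %||% 200L
  k <- config$k %||% 1L
  seed <- config$seed %||% 1L
  num_recycles <- config$num_recycles %||% 1L

  evaluate <- function(gen_seq) {
    gen_out <- tryCatch(
      predict_structure(generator, gen_seq, NULL,
                        num_recycles = num_recycles, seed = seed),
      error = function(e) stop("generator: ", conditionMessage(e),
                               call. = FALSE))
    cand <- mask_to_backbone(gen_out$structure)
    feats <- featurize_template(cand, "gap")
    disc_out <- predict_structure(discriminator, target_sequence, feats,
                                  num_recycles = num_recycles, seed = seed)
    list(objective = as.numeric(composite_score(disc_out, cand)),
         structure = cand)
  }

  cur_seq <- target_sequence
  base <- evaluate(cur_seq)
  best <- base
  best_seq <- cur_seq
  traj <- data.frame(step = 0L, objective = base$objective,
                     best_objective = base$objective, accepted = TRUE)
  if (steps > 0L) {
    with_seed(stable_hash(seed, 17L), {
      for (s in seq_len(steps)) {
        prop_seq <- mutate_sequence(best_seq, k)
        res <- tryCatch(evaluate(prop_seq), error = function(e)
          stop(sprintf("step %d: %s", s, conditionMessage(e)), call. = FALSE))
        acc <- res$objective > best$objective + 1e-12
        if (acc) {
          best <- res
          best_seq <- prop_seq
        }
        traj <- rbind(traj, data.frame(step = s, objective = res$objective,
                                       best_objective = best$objective,
                                       accepted = acc))
      }
    })
  }
  list(best_structure = best$structure, best_objective = best$objective,
       baseline_objective = base$objective, best_sequence = best_seq,
       trajectory = traj)
}
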