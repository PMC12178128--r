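# The composite confidence score and the per-decoy scoring pipeline:
# featurize the decoy as a sequence-free template, query the predictor with
# the target sequence, and multiply mean pLDDT, pTM and the TM-score between
# the decoy and the predictor's output structure. The last factor adjusts
# for the output drifting away from the injected decoy: the confidences
# describe the output, while the decoy is what is being ranked.

#' Composite confidence score of a decoy
#'
#' `(mean pLDDT / 100) x pTM x TM(decoy, output)`, with the TM-score
#' normalized by the decoy length. All three factors are attached as the
#' `"factors"` attribute.
#'
#' @param output A `predictor_output`.
#' @param decoy The decoy [protein_structure()] that was injected as the
#'   template.
#' @param plddt_aggregate How to collapse per-residue pLDDT: `"mean"`
#'   (default, community convention) or `"median"`.
#' @return Score in [0, 1] with attribute `factors =
#'   c(plddt_mean, ptm, tm_decoy_vs_output)`.
#' @export
composite_score <- function(output, decoy, plddt_aggregate = c("mean", "median")) {
  plddt_aggregate <- match.arg(plddt_aggregate)
  if (length(output$structure) != length(decoy))
    stop("decoy and predictor output must have the same length", call. = FALSE)
  plddt_sum <- if (plddt_aggregate == "mean") mean(output$plddt)
               else stats::median(output$plddt)
  tm <- tm_score(decoy, output$structure, normalize_length = length(decoy))
  score <- (plddt_sum / 100) * output$ptm * tm
  attr(score, "factors") <- c(plddt_mean = plddt_sum, ptm = output$ptm,
                              tm_decoy_vs_output = tm)
  score
}

#' Score one decoy against a target sequence
#'
#' The full template-injection protocol for a single decoy: reduce the decoy
#' to its backbone with virtual C-beta atoms, featurize it as a gap-token
#' template (or with its native sequence, for the overconfidence control),
#' run the predictor, and compute the composite confidence score. When the
#' native structure is known, the decoy's true TM-score and GDT_TS are
#' recorded alongside.
#'
#' @param predictor A [new_predictor()] object.
#' @param target_sequence The target amino-acid sequence.
#' @param decoy Candidate [protein_structure()], same length as the
#'   sequence.
#' @param native Optional native [protein_structure()] for truth columns.
#' @param decoy_id Identifier used in reports and error messages.
#' @param config List of knobs: `sequence_mode` ("gap"/"native", default
#'   "gap"), `num_recycles` (default 1), `seed` (default 1),
#'   `plddt_aggregate` ("mean"/"median").
#' @return A `decoy_record`: one-row data.frame with columns `decoy_id`,
#'   `composite`, `plddt_mean`, `ptm`, `tm_decoy_vs_output` and (if `native`
#'   is given) `true_tm`, `true_gdt_ts`.
#' @export
score_decoy <- function(predictor, target_sequence, decoy, native = NULL,
                        decoy_id = "decoy", config = list()) {
  sequence_mode <- config$sequence_mode %||% "gap"
  num_recycles <- config$num_recycles %||% 1L
  seed <- config$seed %||% 1L
  plddt_aggregate <- config$plddt_aggregate %||% "mean"
  if (nchar(target_sequence) != length(decoy))
    stop(sprintf("[%s] decoy length %d != target sequence length %d",
                 decoy_id, length(decoy), nchar(target_sequence)),
         call. = FALSE)
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) stop(
      sprintf("[%s] %s: %s", decoy_id, stage, conditionMessage(e)),
      call. = FALSE))
  }
  bb <- wrap("mask_to_backbone", mask_to_backbone(decoy))
  feats <- wrap("featurize_template",
                featurize_template(bb, sequence_mode = sequence_mode))
  out <- wrap("predict", predict_structure(predictor, target_sequence, feats,
                                           num_recycles = num_recycles,
                                           seed = seed))
  score <- wrap("composite_score",
                composite_score(out, bb, plddt_aggregate = plddt_aggregate))
  f <- attr(score, "factors")
  rec <- data.frame(decoy_id = decoy_id, composite = as.numeric(score),
                    plddt_mean = f[["plddt_mean"]], ptm = f[["ptm"]],
                    tm_decoy_vs_output = f[["tm_decoy_vs_output"]],
                    stringsAsFactors = FALSE)
  if (!is.null(native)) {
    rec$true_tm <- wrap("true_tm", tm_score(decoy, native))
    rec$true_gdt_ts <- wrap("true_gdt_ts", gdt_ts(decoy, native))
  }
  class(rec) <- c("decoy_record", class(rec))
  rec
}

#' Score a set of decoys for one target
#'
#' @inheritParams score_decoy
#' @param decoys Named list of decoy structures (names become `decoy_id`s).
#' @return A data.frame with one [score_decoy()] row per decoy.
#' @export
score_decoy_set <- function(predictor, target_sequence, decoys, native = NULL,
                            config = list()) {
  ids <- names(decoys)
  if (is.null(ids)) ids <- sprintf("decoy_%03d", seq_along(decoys))
  rows <- lapply(seq_along(decoys), function(i)
    score_decoy(predictor, target_sequence, decoys[[i]], native = native,
                decoy_id = ids[i], config = config))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
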