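# Per-target decoy ranking and the evaluation statistics of the estimation-
# of-model-accuracy (EMA) task: Spearman correlation between score and true
# quality, top-1 selection, top-1 GDT_TS loss, and across-method Z-scores
# with the "best decoy over 0.4 GDT_TS" target filter.

#' Rank decoys by composite score
#'
#' @param records Data.frame of [score_decoy()] rows.
#' @param by Column to rank on (default `"composite"`; any logged factor
#'   may be chosen).
#' @return Character vector of `decoy_id`s in descending score order; ties
#'   break lexicographically by id, so the order is deterministic.
#' @export
rank_decoys <- function(records, by = "composite") {
  if (NROW(records) < 1L) stop("no records to rank", call. = FALSE)
  ord <- order(-records[[by]], records$decoy_id, method = "radix")
  records$decoy_id[ord]
}

#' Evaluate decoy ranking for one target
#'
#' Computes the per-target report: Spearman rank correlation between the
#' composite score and true TM-score, the top-ranked decoy and its true
#' quality, and the top-1 GDT_TS loss (best achievable GDT_TS minus the
#' GDT_TS of the decoy the score actually picked).
#'
#' @param records Data.frame of [score_decoy()] rows including the truth
#'   columns `true_tm` and `true_gdt_ts`.
#' @param target_id Label for the report.
#' @param by Score column to rank on (default `"composite"`).
#' @return A `ranking_report`: one-row data.frame with columns `target_id`,
#'   `spearman_composite_vs_tm`, `top1_decoy_id`, `top1_true_tm`,
#'   `top1_gdt_loss`, `n_decoys`.
#' @export
evaluate_target <- function(records, target_id = "target", by = "composite") {
  if (is.null(records$true_tm) || is.null(records$true_gdt_ts) ||
      anyNA(records$true_tm) || anyNA(records$true_gdt_ts))
    stop("records must carry true_tm and true_gdt_ts for every decoy",
         call. = FALSE)
  top1 <- rank_decoys(records, by = by)[1L]
  i <- match(top1, records$decoy_id)
  rep <- data.frame(
    target_id = target_id,
    spearman_composite_vs_tm = spearman_rho(records[[by]], records$true_tm),
    top1_decoy_id = top1,
    top1_true_tm = records$true_tm[i],
    top1_gdt_loss = max(records$true_gdt_ts) - records$true_gdt_ts[i],
    n_decoys = NROW(records),
    stringsAsFactors = FALSE)
  class(rep) <- c("ranking_report", class(rep))
  rep
}

#' Across-method EMA comparison with Z-scores
#'
#' Reproduces the assessor-style comparison: drop targets whose best decoy
#' has GDT_TS of 0.4 or less, then per surviving target convert each
#' method's top-1 GDT_TS loss to a Z-score over methods —
#' `(mean(loss) - loss_m) / sd(loss)` with the sample (n-1) standard
#' deviation, signed so a lower loss gives a higher Z — and average per
#' method.
#'
#' @param loss Numeric matrix of top-1 GDT_TS losses, methods x targets
#'   (dimnames used in the output).
#' @param best_gdt Numeric vector, one per target: the best decoy GDT_TS.
#' @return List with `mean_loss` and `mean_z` (named per method) and
#'   `targets_kept`.
#' @export
ema_evaluation <- function(loss, best_gdt) {
  loss <- as.matrix(loss)
  if (ncol(loss) != length(best_gdt))
    stop("best_gdt must have one entry per loss column", call. = FALSE)
  keep <- best_gdt > 0.4
  if (!any(keep))
    stop("no target passes the best-GDT_TS > 0.4 filter", call. = FALSE)
  loss <- loss[, keep, drop = FALSE]
  if (nrow(loss) < 2L)
    stop("Z-scores need at least 2 methods", call. = FALSE)
  z <- apply(loss, 2L, function(col) {
    s <- stats::sd(col)
    if (s == 0)
      stop("Z-score degenerate: all methods tie on a surviving target",
           call. = FALSE)
    (mean(col) - col) / s
  })
  z <- matrix(z, nrow = nrow(loss), dimnames = dimnames(loss))
  list(mean_loss = rowMeans(loss), mean_z = rowMeans(z),
       targets_kept = which(keep))
}

#' Percentile bootstrap confidence interval of a mean
#'
#' @param x Numeric vector.
#' @param conf Confidence level (default 0.95).
#' @param n_boot Number of resamples (default 10000).
#' @param seed RNG seed (default 1).
#' @return Named vector `c(mean, lower, upper)`.
#' @export
bootstrap_ci <- function(x, conf = 0.95, n_boot = 10000L, seed = 1L) {
  means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(x, length(x), replace = TRUE)), 0)
  })
  alpha <- (1 - conf) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(mean = mean(x), lower = q[1L], upper = q[2L])
}
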