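#' Protein-centric CAFA-style evaluation
#'
#' For each score threshold h, a protein's predicted term set is
#' P_j(h) = terms scoring >= h; precision is |P  intersect  T| / |P| (0 when
#' no term is predicted) and recall |P intersect T| / |T|.  Precision and
#' recall are averaged over ALL proteins at each h, and Fmax is the
#' maximum harmonic mean over the threshold grid 0.01 ... 1.00 (step
#' 0.01).  A coverage mode averaging precision only over proteins with at
#' least one prediction (the canonical CAFA convention) is available.
#' ROC-AUC is the micro-averaged rank statistic over all (protein, term)
#' pairs with half-credit for ties.
#'
#' @name metrics
NULL

default_grid <- function() seq(0.01, 1, by = 0.01)

#' Per-protein precision and recall at one threshold
#'
#' @param scores protein x term matrix in \[0, 1\]
#' @param truth binary matrix, every row with >= 1 positive
#' @param h threshold; predicted set = scores >= h
#' @return list(precision, recall), numeric vectors over proteins
#' @export
protein_precision_recall <- function(scores, truth, h) {
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  if (!all(dim(scores) == dim(truth)))
    stop_data("scores and truth shapes differ")
  if (any(rowSums(truth) == 0))
    stop_data("every protein needs at least one true term")
  pred <- scores >= h
  tp <- rowSums(pred & truth == 1)
  npred <- rowSums(pred)
  precision <- ifelse(npred > 0, tp / npred, 0)
  recall <- tp / rowSums(truth)
  list(precision = precision, recall = recall)
}

#' Threshold sweep of averaged precision/recall
#'
#' @inheritParams protein_precision_recall
#' @param grid increasing threshold grid in (0, 1]
#' @param coverage average precision only over proteins with >= 1
#'   prediction at h (CAFA coverage convention) instead of all proteins
#' @return data.frame(threshold, precision, recall, f)
#' @export
threshold_sweep <- function(scores, truth, grid = default_grid(),
                            coverage = FALSE) {
  rows <- lapply(grid, function(h) {
    pr <- protein_precision_recall(scores, truth, h)
    prec <- if (coverage) {
      covered <- rowSums(as.matrix(scores) >= h) > 0
      if (any(covered)) mean(pr$precision[covered]) else 0
    } else mean(pr$precision)
    rec <- mean(pr$recall)
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(threshold = h, precision = prec, recall = rec, f = f)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Maximum protein-centric F-measure
#'
#' @inheritParams threshold_sweep
#' @return list(fmax, threshold) — ties resolved to the smallest h
#' @export
fmax <- function(scores, truth, grid = default_grid(), coverage = FALSE) {
  sweep <- threshold_sweep(scores, truth, grid, coverage)
  i <- which.max(sweep$f)    # which.max returns the first (smallest h)
  list(fmax = sweep$f[i], threshold = sweep$threshold[i])
}

#' Rank-based ROC-AUC
#'
#' Micro averaging pools all (protein, term) pairs; macro averages
#' per-term AUCs, skipping single-class terms (their count is reported as
#' an attribute).  Ties get half credit (Mann-Whitney convention).
#' Returns NA when only one class is present.
#'
#' @param scores numeric matrix or vector
#' @param truth binary matrix or vector of the same shape
#' @param averaging `"micro"` (default) or `"macro"`
#' @export
roc_auc <- function(scores, truth, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  auc1 <- function(s, y) {
    pos <- y == 1
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(s)                       # average ranks = tie half-credit
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (averaging == "micro" || is.null(dim(scores)))
    return(auc1(as.numeric(scores), as.numeric(truth)))
  per_term <- vapply(seq_len(ncol(scores)), function(j)
    auc1(scores[, j], truth[, j]), 0)
  skipped <- sum(is.na(per_term))
  out <- mean(per_term, na.rm = TRUE)
  attr(out, "skipped_terms") <- skipped
  out
}

#' Full evaluation report
#'
#' @inheritParams threshold_sweep
#' @return list(fmax, threshold, auc, sweep)
#' @export
evaluate_predictions <- function(scores, truth, grid = default_grid(),
                                 coverage = FALSE) {
  sweep <- threshold_sweep(scores, truth, grid, coverage)
  i <- which.max(sweep$f)
  list(fmax = sweep$f[i], threshold = sweep$threshold[i],
       precision = sweep$precision[i], recall = sweep$recall[i],
       auc = roc_auc(scores, truth), sweep = sweep)
}

#' Write an evaluation report (JSON summary + TSV sweep table)
#'
#' @param report from [evaluate_predictions()]
#' @param path base path; writes `<path>.json` and `<path>_sweep.tsv`
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(report[c("fmax", "threshold", "precision",
                                "recall", "auc")],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(report$sweep, paste0(path, "_sweep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
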