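# Multiclass AUC over hard ordinal labels (Hand-Till construction).

# Tie-corrected Mann-Whitney AUC: probability that a positive's score
# exceeds a negative's, ties counting one half. Rank formulation.
rank_auc <- function(scores_neg, scores_pos) {
  n0 <- length(scores_neg); n1 <- length(scores_pos)
  if (n0 == 0L || n1 == 0L) return(NA_real_)
  r <- rank(c(scores_neg, scores_pos), ties.method = "average")
  (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Multiclass AUC from hard stage labels
#'
#' Hand-Till style measure for an ordinal classifier emitting hard labels:
#' the unweighted mean, over all unordered pairs of classes present in the
#' reference, of the pairwise AUC obtained by restricting to observations
#' whose reference lies in the pair and scoring the predicted label with the
#' tie-corrected Mann-Whitney statistic (higher predicted stage = more
#' severe). When the predicted labels are binary within a pair, the pairwise
#' AUC equals the hard-label binary AUC (sensitivity + specificity)/2 of the
#' corresponding 2x2 table.
#'
#' @param reference,test Equal-length integer stage vectors (e.g. 0-3).
#' @return AUC as a proportion in `[0, 1]`.
#' @examples
#' multiclass_auc(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 2, 0))
#' @export
multiclass_auc <- function(reference, test) {
  if (length(reference) != length(test)) {
    abort("`reference` and `test` must have equal length.")
  }
  ref <- as.integer(reference); tst <- as.integer(test)
  if (anyNA(ref) || anyNA(tst)) abort("stage labels must be non-missing integers.")
  classes <- sort(unique(ref))
  if (length(classes) < 2L) {
    abort("reference must contain at least two classes.",
          class = "perioprp_config_error")
  }
  pairs <- utils::combn(classes, 2L)
  aucs <- apply(pairs, 2L, function(p) {
    rank_auc(tst[ref == p[1]], tst[ref == p[2]])
  })
  mean(aucs)
}
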