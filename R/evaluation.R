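## Evaluation: confusion counts, accuracy/coverage, and top-L/k reports.
##
## Acc = TP / (TP + FP), Cov = TP / (TP + FN). Per-chain evaluation ranks
## all long-range pairs by score and keeps the K = max(1, floor(L * frac))
## most contact-like at each level frac in {2, 1, 1/2, 1/5, 1/10, 1/20}.

#' Confusion counts
#'
#' @param predicted,truth Equal-length 0/1 vectors.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop_gac("predicted and truth must have equal length")
  c(TP = sum(predicted == 1 & truth == 1),
    FP = sum(predicted == 1 & truth == 0),
    FN = sum(predicted == 0 & truth == 1),
    TN = sum(predicted == 0 & truth == 0))
}

#' Accuracy and coverage
#'
#' `Acc = TP/(TP+FP)`, `Cov = TP/(TP+FN)`; a 0/0 ratio is reported as
#' `NA` (undefined), never as 0.
#'
#' @param cc Output of [confusion_counts()].
#' @return Named numeric vector `c(Acc, Cov)`.
#' @export
accuracy_coverage <- function(cc) {
  acc <- if (cc[["TP"]] + cc[["FP"]] > 0) cc[["TP"]] / (cc[["TP"]] + cc[["FP"]]) else NA_real_
  cov <- if (cc[["TP"]] + cc[["FN"]] > 0) cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]) else NA_real_
  c(Acc = acc, Cov = cov)
}

#' Select the top-K most contact-like pairs
#'
#' K = max(1, floor(L * fraction)); pairs are ranked by ascending score
#' (lower = more contact-like) with ties broken by (i, j) lexicographic
#' order, so the selection is a total function of the scores.
#'
#' @param scored Data frame with columns `i`, `j`, `score`.
#' @param L Chain length.
#' @param fraction Level as a fraction of L (e.g. 0.2 for L/5).
#' @return The selected rows; attribute `short` is `TRUE` when fewer than
#'   K pairs were available and all were taken.
#' @export
select_top_k <- function(scored, L, fraction) {
  k <- max(1L, floor(L * fraction))
  ord <- order(scored$score, scored$i, scored$j)
  short <- nrow(scored) < k
  take <- ord[seq_len(min(k, nrow(scored)))]
  out <- scored[take, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "short") <- short
  out
}

#' Top-L/k accuracy report for one chain
#'
#' @param scored Data frame with columns `i`, `j`, `score` covering all
#'   long-range pairs of the chain.
#' @param cm The chain's `contact_map` (truth).
#' @param fractions Levels as fractions of L; defaults to
#'   2L, L, L/2, L/5, L/10, L/20.
#' @return Data frame of class `topk_report` with columns `fraction`, `K`,
#'   `TP` and `accuracy`, plus attributes `chain_id` and `L`.
#' @export
topk_accuracy_levels <- function(scored, cm,
                                 fractions = c(2, 1, 0.5, 0.2, 0.1, 0.05)) {
  L <- cm$L
  ckey <- if (nrow(cm$contact_pairs) > 0)
    cm$contact_pairs[, 1] * (L + 1) + cm$contact_pairs[, 2] else numeric()
  rows <- lapply(fractions, function(f) {
    top <- select_top_k(scored, L, f)
    key <- top$i * (L + 1) + top$j
    tp <- sum(key %in% ckey)
    data.frame(fraction = f, K = nrow(top), TP = tp, accuracy = tp / nrow(top))
  })
  out <- do.call(rbind, rows)
  attr(out, "chain_id") <- cm$chain_id
  attr(out, "L") <- L
  class(out) <- c("topk_report", "data.frame")
  out
}

#' Per-group mean top-K accuracies
#'
#' Averages per-chain accuracies within user-supplied group labels (for
#' example structural classes). Undefined (NA) accuracies are skipped and
#' counted.
#'
#' @param reports Named list of `topk_report` data frames.
#' @param groups Named character vector of group labels, one per chain.
#' @return Data frame with columns `group`, `fraction`, `mean_accuracy`,
#'   `n_chains`, `n_skipped`.
#' @export
grouped_summary <- function(reports, groups) {
  miss <- setdiff(names(reports), names(groups))
  if (length(miss) > 0)
    stop_gac("missing group label for chain(s): %s", paste(miss, collapse = ", "))
  long <- do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(group = groups[[id]], fraction = r$fraction,
               accuracy = r$accuracy)
  }))
  agg <- do.call(rbind, lapply(split(long, list(long$group, long$fraction), drop = TRUE),
    function(d) data.frame(group = d$group[1], fraction = d$fraction[1],
                           mean_accuracy = mean(d$accuracy, na.rm = TRUE),
                           n_chains = sum(!is.na(d$accuracy)),
                           n_skipped = sum(is.na(d$accuracy)))))
  rownames(agg) <- NULL
  agg[order(agg$group, -agg$fraction), ]
}

#' Evaluate an RR prediction file against a contact map
#'
#' Makes the module a standalone scorer for external predictors: reads an
#' RR file, scores its ranking against the truth contact map.
#'
#' @param rr_path Path to a CASP RR file.
#' @param cm Truth `contact_map`.
#' @param fractions Top-K levels.
#' @return A `topk_report`.
#' @export
evaluate_rr <- function(rr_path, cm, fractions = c(2, 1, 0.5, 0.2, 0.1, 0.05)) {
  ps <- read_rr(rr_path)
  if (nrow(ps$records) > 0 && max(ps$records$j) > cm$L)
    stop_gac("chain length mismatch: RR has residue %d, map has L=%d",
             max(ps$records$j), cm$L)
  topk_accuracy_levels(ps$records, cm, fractions)
}
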