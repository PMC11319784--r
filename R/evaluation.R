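#' Overlap length of two spans
#'
#' Number of character positions covered by both spans (0-based inclusive
#' convention): `max(0, min(a_end, b_end) - max(a_start, b_start) + 1)`.
#'
#' @param a,b Spans: lists or vectors with elements `start` and `end`.
#' @return A non-negative integer.
#' @examples
#' span_overlap(list(start = 0, end = 9), list(start = 5, end = 14))  # 5
#' @export
span_overlap <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  max(0L, as.integer(min(a$end, b$end) - max(a$start, b$start) + 1L))
}

#' Directional span evaluation
#'
#' For each section `S1` in `L1`, finds `S2'`, the `L2` section overlapping
#' `S1` the most (ties broken by earliest-starting `S2`, then `L2` order),
#' and computes the match ratio `r = overlap(S1, S2') / |S1|`. `S1` counts
#' as correct when the overlap is strictly positive and the labels agree.
#' Accuracy is the fraction of correct `L1` sections; the match ratio is
#' the mean of the `r` values. With `L1` as predictions and `L2` as gold
#' this yields precision; swapped, recall.
#'
#' @param L1,L2 [section_spans()] data frames over the same note.
#' @return An `eval_outcome`: list with `n_correct`, `ratios` (one `r` per
#'   `L1` section), `accuracy`, `match_ratio`, and `degenerate` (`TRUE`
#'   when `L1` is empty, in which case accuracy and match ratio are 0).
#' @export
evaluate_directional <- function(L1, L2) {
  n1 <- nrow(L1)
  if (n1 == 0L)
    return(structure(list(n_correct = 0L, ratios = numeric(0),
                          accuracy = 0, match_ratio = 0, degenerate = TRUE),
                     class = "eval_outcome"))
  n2 <- nrow(L2)
  ratios <- numeric(n1)
  n_correct <- 0L
  for (i in seq_len(n1)) {
    len1 <- L1$end[i] - L1$start[i] + 1L
    if (n2 == 0L) next  # ratios[i] stays 0
    ov <- pmax(0L, pmin(L1$end[i], L2$end) - pmax(L1$start[i], L2$start) + 1L)
    best <- max(ov)
    cand <- which(ov == best)
    j <- cand[order(L2$start[cand], cand)][1]
    ratios[i] <- ov[j] / len1
    if (ov[j] > 0L && L2$label[j] == L1$label[i])
      n_correct <- n_correct + 1L
  }
  structure(list(n_correct = n_correct, ratios = ratios,
                 accuracy = n_correct / n1, match_ratio = mean(ratios),
                 degenerate = FALSE),
            class = "eval_outcome")
}

f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

metrics_from_directions <- function(pd, td, n_pred, n_gold) {
  precision <- if (n_pred > 0L) pd$n_correct / n_pred else 0
  recall <- if (n_gold > 0L) td$n_correct / n_gold else 0
  pmr <- if (length(pd$ratios)) mean(pd$ratios) else 0
  tmr <- if (length(td$ratios)) mean(td$ratios) else 0
  structure(list(precision = precision, recall = recall,
                 f1 = f1_score(precision, recall),
                 prediction_match_ratio = pmr, target_match_ratio = tmr,
                 match_ratio = (pmr + tmr) / 2,
                 n_pred = n_pred, n_gold = n_gold,
                 n_correct_pred = pd$n_correct,
                 n_correct_gold = td$n_correct),
            class = "metrics_report")
}

#' Span-based metrics for one note
#'
#' Precision and prediction match ratio come from
#' `evaluate_directional(pred, gold)`; recall and target match ratio from
#' `evaluate_directional(gold, pred)`. `F1` is the harmonic mean of
#' precision and recall (0 when both are 0), and the combined match ratio
#' is the mean of the two directional match ratios.
#'
#' @param pred,gold [section_spans()] data frames for the same note.
#' @return A `metrics_report` list: `precision`, `recall`, `f1`,
#'   `prediction_match_ratio`, `target_match_ratio`, `match_ratio`, plus
#'   the underlying counts.
#' @export
compute_metrics <- function(pred, gold) {
  metrics_from_directions(evaluate_directional(pred, gold),
                          evaluate_directional(gold, pred),
                          nrow(pred), nrow(gold))
}

pool_directional <- function(outcomes) {
  list(n_correct = sum(vapply(outcomes, `[[`, integer(1), "n_correct")),
       ratios = unlist(lapply(outcomes, `[[`, "ratios")))
}

#' Micro-aggregated metrics over a corpus
#'
#' Pools correct-match counts and section counts across notes (micro
#' averaging, appropriate when section types are unevenly distributed) and
#' pools the per-section match ratios across notes for each directional
#' match ratio.
#'
#' @param per_note Non-empty list of pairs; each element is a list with
#'   components `pred` and `gold` ([section_spans()] data frames).
#' @param per_type Also compute pooled per-type rows (see
#'   [per_type_report()])?
#' @return A `metrics_report`; when `per_type = TRUE` it carries a
#'   `per_type` data frame component.
#' @export
micro_aggregate <- function(per_note, per_type = FALSE) {
  if (!is.list(per_note) || !length(per_note))
    stop("per_note must be a non-empty list of (pred, gold) pairs",
         call. = FALSE)
  pd <- pool_directional(lapply(per_note, function(p)
    evaluate_directional(p$pred, p$gold)))
  td <- pool_directional(lapply(per_note, function(p)
    evaluate_directional(p$gold, p$pred)))
  n_pred <- sum(vapply(per_note, function(p) nrow(p$pred), integer(1)))
  n_gold <- sum(vapply(per_note, function(p) nrow(p$gold), integer(1)))
  rep <- metrics_from_directions(pd, td, n_pred, n_gold)
  if (per_type) rep$per_type <- per_type_rows(per_note)
  rep
}

restrict_label <- function(df, lab) df[df$label == lab, , drop = FALSE]

per_type_rows <- function(per_note) {
  labs <- sort(unique(unlist(lapply(per_note, function(p)
    c(p$pred$label, p$gold$label)))))
  rows <- lapply(labs, function(lab) {
    pd <- pool_directional(lapply(per_note, function(p)
      evaluate_directional(restrict_label(p$pred, lab), p$gold)))
    td <- pool_directional(lapply(per_note, function(p)
      evaluate_directional(restrict_label(p$gold, lab), p$pred)))
    n_pred <- sum(vapply(per_note, function(p)
      nrow(restrict_label(p$pred, lab)), integer(1)))
    n_gold <- sum(vapply(per_note, function(p)
      nrow(restrict_label(p$gold, lab)), integer(1)))
    m <- metrics_from_directions(pd, td, n_pred, n_gold)
    data.frame(label = lab, precision = m$precision, recall = m$recall,
               f1 = m$f1, prediction_count = n_pred,
               prediction_match_ratio = m$prediction_match_ratio,
               target_count = n_gold,
               target_match_ratio = m$target_match_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$f1, out$label), , drop = FALSE]
}

#' Per-section-type report
#'
#' One row per section type occurring in the predictions or the gold:
#' precision restricted to predictions of that type (a correct match must
#' carry the same type), recall restricted to gold sections of that type,
#' counts, and the correspondingly restricted match ratios. Rows are sorted
#' by F1, descending.
#'
#' @param pred,gold [section_spans()] data frames for the same note.
#' @return A data frame with columns `label`, `precision`, `recall`, `f1`,
#'   `prediction_count`, `prediction_match_ratio`, `target_count`,
#'   `target_match_ratio`.
#' @export
per_type_report <- function(pred, gold) {
  per_type_rows(list(list(pred = pred, gold = gold)))
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    paste0("<metrics_report> precision %.*f  recall %.*f  F1 %.*f\n",
           "  match ratio %.*f (prediction %.*f / target %.*f)\n",
           "  %d predicted / %d gold sections\n"),
    digits, x$precision, digits, x$recall, digits, x$f1,
    digits, x$match_ratio, digits, x$prediction_match_ratio,
    digits, x$target_match_ratio, x$n_pred, x$n_gold))
  if (!is.null(x$per_type)) {
    cat("  per-type rows: ", nrow(x$per_type), "\n", sep = "")
  }
  invisible(x)
}
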