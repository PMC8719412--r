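#' F-measure: harmonic mean of precision and recall
#'
#' `2 * R * P / (R + P)`, defined as 0 when both are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F-measure in `[0, 1]`.
#' @export
fmeasure <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * recall * precision / (recall + precision)
}

mention_keys <- function(mentions) {
  if (!length(mentions)) return(character(0))
  vapply(mentions, function(m)
    paste(m$etype, m$start, m$end, sep = "\r"), character(1))
}

count_matches <- function(gold_keys, pred_keys) {
  # multiset intersection per sentence
  sum(pmin(table(factor(pred_keys, levels = unique(c(gold_keys, pred_keys)))),
           table(factor(gold_keys, levels = unique(c(gold_keys, pred_keys))))))
}

as_mention_sets <- function(x) {
  if (inherits(x, "ner_corpus")) corpus_mentions(x) else x
}

prf_cell <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(precision = p, recall = r, fmeasure = fmeasure(p, r),
       tp = tp, fp = fp, fn = fn, support = tp + fn)
}

#' Entity-level precision/recall/F evaluation
#'
#' A predicted mention counts as a true positive only when its
#' `(type, start, end)` triple exactly matches a gold mention of the same
#' sentence (strict span matching). Cells with an empty denominator are
#' reported as 0. Besides the overall (micro) scores, per-type scores are
#' reported together with their macro and micro averages.
#'
#' @param gold,pred Aligned per-sentence mention sets: either
#'   [ner_corpus()] objects or lists (one element per sentence) of lists of
#'   [entity_mention()]s.
#' @return An object of class `eval_report`: `overall` (precision, recall,
#'   fmeasure, tp/fp/fn, support), `per_type` (data frame, one row per type
#'   plus `macro_average` and `micro_average` rows).
#' @export
entity_prf <- function(gold, pred) {
  gold <- as_mention_sets(gold); pred <- as_mention_sets(pred)
  if (length(gold) != length(pred))
    stop(sprintf("entity_prf: gold has %d sentences but pred has %d",
                 length(gold), length(pred)))
  types <- sort(unique(unlist(c(
    lapply(gold, function(ms) vapply(ms, `[[`, character(1), "etype")),
    lapply(pred, function(ms) vapply(ms, `[[`, character(1), "etype"))))))
  tp <- fp <- fn <- stats::setNames(rep(0L, length(types)), types)
  for (k in seq_along(gold)) {
    gk <- mention_keys(gold[[k]]); pk <- mention_keys(pred[[k]])
    for (ty in types) {
      g <- gk[startsWith(gk, paste0(ty, "\r"))]
      p <- pk[startsWith(pk, paste0(ty, "\r"))]
      m <- count_matches(g, p)
      tp[ty] <- tp[ty] + m
      fp[ty] <- fp[ty] + length(p) - m
      fn[ty] <- fn[ty] + length(g) - m
    }
  }
  overall <- prf_cell(sum(tp), sum(fp), sum(fn))
  rows <- lapply(types, function(ty) {
    cell <- prf_cell(tp[[ty]], fp[[ty]], fn[[ty]])
    data.frame(type = ty, precision = cell$precision, recall = cell$recall,
               fmeasure = cell$fmeasure, support = cell$support)
  })
  per_type <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(per_type))
    per_type <- data.frame(type = character(0), precision = numeric(0),
                           recall = numeric(0), fmeasure = numeric(0),
                           support = integer(0))
  if (nrow(per_type)) {
    macro <- data.frame(type = "macro_average",
                        precision = mean(per_type$precision),
                        recall = mean(per_type$recall),
                        fmeasure = mean(per_type$fmeasure),
                        support = sum(per_type$support))
    micro <- data.frame(type = "micro_average",
                        precision = overall$precision,
                        recall = overall$recall,
                        fmeasure = overall$fmeasure,
                        support = overall$support)
    per_type <- rbind(per_type, macro, micro)
  }
  structure(list(overall = overall, per_type = per_type),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<eval_report> P %.2f%%  R %.2f%%  F %.2f%%  (TP %d, FP %d, FN %d)\n",
              100 * o$precision, 100 * o$recall, 100 * o$fmeasure,
              o$tp, o$fp, o$fn))
  if (nrow(x$per_type)) {
    df <- x$per_type
    df$precision <- sprintf("%.2f", 100 * df$precision)
    df$recall <- sprintf("%.2f", 100 * df$recall)
    df$fmeasure <- sprintf("%.2f", 100 * df$fmeasure)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Count gold-mention occurrences per (surface, type) pair
#'
#' The rarity key is the typed surface: the same string annotated with two
#' types counts separately.
#'
#' @param train A [ner_corpus()] (the training set).
#' @return Named integer vector; names are `<surface>\r<type>`.
#' @export
occurrence_counts <- function(train) {
  mentions <- unlist(corpus_mentions(train), recursive = FALSE)
  if (!length(mentions)) return(stats::setNames(integer(0), character(0)))
  keys <- vapply(mentions, function(m)
    paste(m$surface, m$etype, sep = "\r"), character(1))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

#' Recall stratified by training-set rarity
#'
#' Each gold test mention is assigned the bucket equal to its training-set
#' occurrence count (0, 1, 2 or 3); mentions occurring 4 or more times in
#' training are excluded. Bucket 0 is the unseen entities. Recall within a
#' bucket uses the strict `(type, start, end)` match criterion.
#'
#' @param counts Occurrence map from [occurrence_counts()] on the training
#'   corpus.
#' @param gold,pred Aligned per-sentence mention sets of the test corpus
#'   ([ner_corpus()] or lists of mention lists). Gold mentions must carry
#'   surfaces.
#' @return Data frame with columns `bucket` (0:3), `recall`, `tp`, `support`;
#'   buckets with no gold mentions have support 0 and recall `NA`.
#' @export
stratified_rare_recall <- function(counts, gold, pred) {
  gold <- as_mention_sets(gold); pred <- as_mention_sets(pred)
  if (length(gold) != length(pred))
    stop("stratified_rare_recall: gold and pred must align by sentence")
  tp <- support <- stats::setNames(rep(0L, 4L), as.character(0:3))
  for (k in seq_along(gold)) {
    pk <- mention_keys(pred[[k]])
    for (m in gold[[k]]) {
      if (is.na(m$surface))
        stop("stratified_rare_recall: gold mentions must carry surfaces")
      cnt <- counts[paste(m$surface, m$etype, sep = "\r")]
      cnt <- if (is.na(cnt)) 0L else as.integer(cnt)
      if (cnt > 3L) next
      b <- as.character(cnt)
      support[b] <- support[b] + 1L
      if (paste(m$etype, m$start, m$end, sep = "\r") %in% pk)
        tp[b] <- tp[b] + 1L
    }
  }
  data.frame(bucket = 0:3,
             recall = ifelse(support > 0, tp / pmax(support, 1L), NA_real_),
             tp = as.integer(tp), support = as.integer(support))
}
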