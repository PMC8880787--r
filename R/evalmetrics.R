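# Span-level evaluation. A predicted span is correct iff a gold span with
# the identical (doc, sentence, channel, start, end) exists: exact boundary,
# exact channel, no partial credit. Precision = correct / predicted,
# recall = correct / gold, F1 = harmonic mean.

#' Score predicted spans against gold spans
#'
#' Duplicates within either collection are collapsed before counting.
#' Zero-denominator conventions: no predictions gives precision 0, no gold
#' gives recall 0, and F1 is 0 when P + R = 0; each such case is flagged in
#' `$undefined` rather than reported as NA.
#'
#' @param gold,pred Span data frames (`tag_id`, `sentence_id`, `start`,
#'   `end`, optional `doc_id`).
#' @return A `span_score` list: `aggregate` (micro counts and P/R/F1),
#'   `per_channel` (one row per tag id present in either set), `macro`
#'   (unweighted means of per-channel P/R/F1), `undefined` (logical flags
#'   for the zero-denominator conventions).
#' @examples
#' gold <- data.frame(tag_id = "ergativity.middle", sentence_id = 1,
#'                    start = 0, end = 1)
#' score_spans(gold, gold)$aggregate$f1   # 1
#' @export
score_spans <- function(gold, pred) {
  gold <- as_spans(normalize_eval_spans(gold))
  pred <- as_spans(normalize_eval_spans(pred))
  gk <- unique(span_keys(gold))
  pk <- unique(span_keys(pred))
  agg <- prf(n_gold = length(gk), n_pred = length(pk),
             n_correct = length(intersect(gk, pk)))

  tags <- sort(unique(c(gold$tag_id, pred$tag_id)))
  per <- do.call(rbind, lapply(tags, function(tg) {
    g <- unique(span_keys(gold[gold$tag_id == tg, , drop = FALSE]))
    p <- unique(span_keys(pred[pred$tag_id == tg, , drop = FALSE]))
    r <- prf(length(g), length(p), length(intersect(g, p)))
    data.frame(tag_id = tg, n_gold = r$n_gold, n_pred = r$n_pred,
               n_correct = r$n_correct, precision = r$precision,
               recall = r$recall, f1 = r$f1, stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(tag_id = character(), n_gold = integer(),
                      n_pred = integer(), n_correct = integer(),
                      precision = numeric(), recall = numeric(),
                      f1 = numeric(), stringsAsFactors = FALSE)
  }
  macro <- if (nrow(per) > 0) {
    list(precision = mean(per$precision), recall = mean(per$recall),
         f1 = mean(per$f1))
  } else {
    list(precision = 0, recall = 0, f1 = 0)
  }
  structure(list(
    aggregate = agg,
    per_channel = per,
    macro = macro,
    undefined = c(precision = agg$n_pred == 0L, recall = agg$n_gold == 0L,
                  f1 = agg$n_pred == 0L && agg$n_gold == 0L)
  ), class = "span_score")
}

normalize_eval_spans <- function(spans) {
  if (is.null(spans)) return(empty_spans())
  spans <- as.data.frame(spans)
  if (nrow(spans) > 0 && any(spans$start >= spans$end)) {
    stop_input("malformed span: start must be < end")
  }
  spans
}

span_keys <- function(spans) {
  if (nrow(spans) == 0) return(character())
  paste(spans$doc_id, spans$sentence_id, spans$tag_id, spans$start, spans$end,
        sep = "\r")
}

prf <- function(n_gold, n_pred, n_correct) {
  p <- if (n_pred > 0) n_correct / n_pred else 0
  r <- if (n_gold > 0) n_correct / n_gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(n_gold = as.integer(n_gold), n_pred = as.integer(n_pred),
       n_correct = as.integer(n_correct), precision = p, recall = r, f1 = f)
}

#' @export
print.span_score <- function(x, digits = 2, ...) {
  a <- x$aggregate
  # two-decimal display mirrors the convention of truncating 2/3 to 0.66
  tr <- function(v) formatC(trunc(v * 10^digits) / 10^digits,
                            format = "f", digits = digits)
  cat(sprintf("spans: gold=%d pred=%d correct=%d\n", a$n_gold, a$n_pred,
              a$n_correct))
  cat(sprintf("precision %s  recall %s  F1 %s\n",
              tr(a$precision), tr(a$recall), tr(a$f1)))
  invisible(x)
}

#' Write an evaluation report
#'
#' JSON with full-precision aggregate, macro, and per-channel metrics.
#'
#' @param score A `span_score`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_score <- function(score, path) {
  stopifnot(inherits(score, "span_score"))
  jsonlite::write_json(
    list(aggregate = score$aggregate, macro = score$macro,
         per_channel = score$per_channel,
         undefined = as.list(score$undefined)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
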