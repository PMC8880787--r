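# Span-annotation tables. A span set is a plain data frame with columns
#   doc_id, sentence_id, tag_id, start, end, source, verified
# using 0-based, half-open [start, end) morpheme coordinates per sentence.
# 'source' is one of dictionary/model/manual; 'verified' mirrors the manual
# check flag of the annotation workflow.

SPAN_COLS <- c("doc_id", "sentence_id", "tag_id", "start", "end",
               "source", "verified")

empty_spans <- function() {
  data.frame(doc_id = character(), sentence_id = integer(),
             tag_id = character(), start = integer(), end = integer(),
             source = character(), verified = logical(),
             stringsAsFactors = FALSE)
}

as_spans <- function(df) {
  if (is.null(df)) return(empty_spans())
  if (!"doc_id" %in% colnames(df)) df$doc_id <- ""
  if (!"source" %in% colnames(df)) df$source <- "manual"
  if (!"verified" %in% colnames(df)) df$verified <- FALSE
  missing <- setdiff(SPAN_COLS, colnames(df))
  if (length(missing) > 0) {
    stop_input(sprintf("span table lacks column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  df <- df[, SPAN_COLS]
  df$sentence_id <- as.integer(df$sentence_id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$verified <- as.logical(df$verified)
  if (nrow(df) > 0 && any(df$start >= df$end)) {
    stop_input("malformed span: start must be < end")
  }
  rownames(df) <- NULL
  df
}

sort_spans <- function(spans) {
  spans[order(spans$tag_id, spans$doc_id, spans$sentence_id, spans$start), ,
        drop = FALSE]
}

#' Read / write span-annotation TSV
#'
#' Columns: `doc_id`, `sentence_id`, `tag_id`, `start`, `end`, `source`,
#' `verified` (`true`/`false`). The `verified` column is the file
#' counterpart of the annotation tool's manual check flag and may be edited
#' in place.
#'
#' @param path File path.
#' @return `read_spans()`: a span data frame; `write_spans()`: `path`,
#'   invisibly.
#' @export
read_spans <- function(path) {
  df <- read_tsv_utf8(path)
  df$verified <- tolower(df$verified) %in% c("true", "1", "yes")
  as_spans(df)
}

#' @param spans A span data frame.
#' @rdname read_spans
#' @export
write_spans <- function(spans, path) {
  spans <- as_spans(spans)
  spans$verified <- ifelse(spans$verified, "true", "false")
  write_tsv_utf8(spans, path)
}

#' Attach span annotations to a corpus
#'
#' @param corpus A `pragma_corpus`.
#' @param spans Span data frame whose `doc_id`s all occur in the corpus.
#' @return The corpus with `$spans` set.
#' @export
set_spans <- function(corpus, spans) {
  stopifnot(inherits(corpus, "pragma_corpus"))
  spans <- as_spans(spans)
  ids <- vapply(corpus$documents, function(d) d$doc_id, character(1))
  unknown <- setdiff(unique(spans$doc_id), ids)
  if (length(unknown) > 0) {
    stop_reference(sprintf("spans reference unknown doc_id(s): %s",
                           paste(unknown, collapse = ", ")))
  }
  corpus$spans <- spans
  corpus
}
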