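# Multi-channel IOB2 label matrices.
#
# A label matrix is the C x T view of one sentence's annotation: one row per
# channel (tag type), one column per morpheme, cells in {O, B, I}. B opens a
# span, I continues it, O is outside. Channels are independent rows, so
# cross-channel overlap is representable while within-channel overlap is
# structurally impossible.

#' Encode spans as a C x T IOB2 label matrix
#'
#' @param spans Span data frame (needs `tag_id`, `start`, `end`) for one
#'   sentence; within-channel spans must not overlap.
#' @param T Token count of the sentence.
#' @param channels Ordered character vector of tag ids (the matrix rows).
#'   Spans whose tag is not listed raise a reference error.
#' @return Character matrix with `rownames = channels`, entries O/B/I.
#' @export
encode_spans <- function(spans, T, channels) {
  T <- as.integer(T)
  m <- matrix("O", nrow = length(channels), ncol = T,
              dimnames = list(channels, NULL))
  if (is.null(spans) || nrow(spans) == 0) return(m)
  unknown <- setdiff(unique(spans$tag_id), channels)
  if (length(unknown) > 0) {
    stop_reference(sprintf("span tag(s) not in channel list: %s",
                           paste(unknown, collapse = ", ")))
  }
  if (any(spans$start < 0L | spans$end > T | spans$start >= spans$end)) {
    stop_bounds(sprintf("span out of range for T=%d", T))
  }
  for (ch in unique(spans$tag_id)) {
    s <- spans[spans$tag_id == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop_input(sprintf("overlapping spans within channel '%s'", ch))
    }
    for (i in seq_len(nrow(s))) {
      m[ch, s$start[i] + 1L] <- "B"
      if (s$end[i] - s$start[i] > 1L) {
        m[ch, (s$start[i] + 2L):s$end[i]] <- "I"
      }
    }
  }
  m
}

#' Decode an IOB2 label matrix to spans
#'
#' Accepts any matrix, including invalid model output: an orphan I (an I not
#' preceded by B or I in its channel) is repaired by promoting it to B, and
#' each repair is reported. Maximal B I* runs become spans.
#'
#' @param matrix Character matrix as produced by [encode_spans()].
#' @return List with `spans` (data frame `tag_id`, `start`, `end`) and
#'   `repairs` (data frame `tag_id`, `pos` of each promoted orphan I,
#'   0-based).
#' @export
decode_matrix <- function(matrix) {
  channels <- rownames(matrix)
  spans <- list()
  repairs <- list()
  for (ci in seq_len(nrow(matrix))) {
    row <- matrix[ci, ]
    T_ <- length(row)
    start <- NA_integer_
    for (t in seq_len(T_)) {
      lab <- row[t]
      if (lab == "I" && is.na(start)) {
        repairs[[length(repairs) + 1]] <- data.frame(
          tag_id = channels[ci], pos = t - 1L, stringsAsFactors = FALSE)
        lab <- "B"
      }
      if (lab == "B") {
        if (!is.na(start)) {
          spans[[length(spans) + 1]] <- data.frame(
            tag_id = channels[ci], start = start, end = t - 1L,
            stringsAsFactors = FALSE)
        }
        start <- t - 1L
      } else if (lab == "O") {
        if (!is.na(start)) {
          spans[[length(spans) + 1]] <- data.frame(
            tag_id = channels[ci], start = start, end = t - 1L,
            stringsAsFactors = FALSE)
          start <- NA_integer_
        }
      }
    }
    if (!is.na(start)) {
      spans[[length(spans) + 1]] <- data.frame(
        tag_id = channels[ci], start = start, end = T_,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(tag_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  list(
    spans = if (length(spans) > 0) do.call(rbind, spans) else empty,
    repairs = if (length(repairs) > 0) do.call(rbind, repairs) else
      data.frame(tag_id = character(), pos = integer(), stringsAsFactors = FALSE)
  )
}

#' Validate an IOB2 label matrix
#'
#' @param matrix Character matrix with rows = channels.
#' @return Data frame of violations (`tag_id`, `pos` of each orphan I,
#'   0-based); zero rows iff the matrix is valid.
#' @export
validate_matrix <- function(matrix) {
  channels <- rownames(matrix)
  out <- list()
  for (ci in seq_len(nrow(matrix))) {
    row <- matrix[ci, ]
    prev_in_span <- FALSE
    for (t in seq_along(row)) {
      if (row[t] == "I" && !prev_in_span) {
        out[[length(out) + 1]] <- data.frame(tag_id = channels[ci],
                                             pos = t - 1L,
                                             stringsAsFactors = FALSE)
      }
      prev_in_span <- row[t] %in% c("B", "I")
    }
  }
  if (length(out) > 0) do.call(rbind, out) else
    data.frame(tag_id = character(), pos = integer(), stringsAsFactors = FALSE)
}

#' Export label matrices as TSV
#'
#' One line per token, one column per channel, cells `O|B|I`; a header row
#' carries the channel ids and `#doc=`/`#sentence=` comment lines separate
#' sentences when several matrices are written.
#'
#' @param matrices Named list (or single matrix); names are used as
#'   `doc:sentence` labels in the separators.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_label_matrices <- function(matrices, path) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  lines <- character()
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    label <- names(matrices)[i]
    lines <- c(lines,
               sprintf("#sentence=%s", if (is.null(label) || !nzchar(label)) i else label),
               paste(rownames(m), collapse = "\t"),
               if (ncol(m) > 0) apply(t(m), 1, paste, collapse = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
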