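# Annotation dictionaries and dictionary-based span tagging.
#
# A lexicon entry pairs a tag_id with a contiguous sequence of morpheme
# patterns; each pattern constrains any subset of {surface, lemma, pos} by
# exact equality (after NFKC normalization). Matching per channel is
# leftmost-longest: scan left to right, take the longest entry matching at
# the current position, resume at its end. Channels are matched
# independently, so spans may overlap across channels but never within one.

PATTERN_FIELDS <- c("surface", "lemma", "pos")

parse_pattern <- function(str, where = "") {
  if (!nzchar(str)) stop_format(sprintf("%sempty pattern", where))
  cons <- strsplit(str, ";", fixed = TRUE)[[1]]
  lapply(cons, function(con) {
    if (!nzchar(con)) stop_format(sprintf("%spattern has an empty constraint", where))
    parts <- strsplit(con, "&", fixed = TRUE)[[1]]
    kv <- lapply(parts, function(p) {
      eq <- regexpr("=", p, fixed = TRUE)
      if (eq < 0) stop_format(sprintf("%sbad constraint '%s' (expected field=value)", where, p))
      c(substr(p, 1, eq - 1), substr(p, eq + 1, nchar(p)))
    })
    keys <- vapply(kv, `[`, character(1), 1)
    vals <- vapply(kv, `[`, character(1), 2)
    bad <- setdiff(keys, PATTERN_FIELDS)
    if (length(bad) > 0) {
      stop_format(sprintf("%sunknown pattern field(s): %s", where,
                          paste(bad, collapse = ", ")))
    }
    if (length(keys) == 0) stop_format(sprintf("%sconstraint with zero fields", where))
    setNames(nfkc(vals), keys)
  })
}

format_pattern <- function(pattern) {
  paste(vapply(pattern, function(con) {
    paste(names(con), con, sep = "=", collapse = "&")
  }, character(1)), collapse = ";")
}

new_entry <- function(tag_id, pattern) {
  if (is.character(pattern) && is.null(names(pattern))) {
    # convenience: plain character vector means surface-sequence pattern
    pattern <- lapply(pattern, function(s) c(surface = nfkc(s)))
  }
  if (!is.list(pattern) || length(pattern) == 0) {
    stop_format("pattern must be a non-empty list of constraints")
  }
  pattern <- lapply(pattern, function(con) {
    if (is.null(names(con)) || any(!names(con) %in% PATTERN_FIELDS) ||
        length(con) == 0) {
      stop_format("each constraint must name at least one of surface/lemma/pos")
    }
    setNames(nfkc(as.character(con)), names(con))
  })
  list(tag_id = tag_id, pattern = pattern, key = paste(tag_id, format_pattern(pattern)))
}

#' Create a lexicon
#'
#' @param entries List of entries; each entry is a list with `tag_id` and
#'   `pattern` (list of named character vectors constraining `surface`,
#'   `lemma` and/or `pos`), or is created from a plain character vector of
#'   surface forms.
#' @param scheme Optional `annotation_scheme`; when given, every `tag_id`
#'   must resolve in it.
#' @return A `pragma_lexicon`.
#' @export
new_lexicon <- function(entries = list(), scheme = NULL) {
  entries <- lapply(entries, function(e) new_entry(e$tag_id, e$pattern))
  keys <- vapply(entries, `[[`, character(1), "key")
  if (anyDuplicated(keys)) {
    stop_duplicate(sprintf("duplicate lexicon entries: %s",
                           paste(unique(keys[duplicated(keys)]), collapse = "; ")))
  }
  if (!is.null(scheme)) {
    unknown <- setdiff(vapply(entries, `[[`, character(1), "tag_id"),
                       scheme$tags$tag_id)
    if (length(unknown) > 0) {
      stop_reference(sprintf("lexicon references unknown tag_id(s): %s",
                             paste(unknown, collapse = ", ")))
    }
  }
  structure(list(entries = entries), class = "pragma_lexicon")
}

#' Load a lexicon
#'
#' Reads lexicon TSVs (`tag_id<TAB>pattern`; pattern constraints `;`-joined,
#' each `field=value(&field=value)*`). `path` may be one file or a directory
#' of dictionary files read in lexicographic order.
#'
#' @param path Lexicon file or directory. Defaults to the bundled
#'   dictionaries.
#' @param scheme `annotation_scheme` governing tag ids.
#' @return A `pragma_lexicon`; entry order follows file order.
#' @export
load_lexicon <- function(path = bundled_lexicon_path(), scheme = load_scheme()) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  } else {
    if (!file.exists(path)) stop_input(sprintf("lexicon path not found: %s", path))
    path
  }
  entries <- list()
  keys <- character()
  key_lines <- character()
  for (f in files) {
    df <- read_tsv_utf8(f)
    if (!identical(colnames(df), c("tag_id", "pattern"))) {
      stop_format(sprintf("%s: lexicon header must be 'tag_id<TAB>pattern'", f))
    }
    for (i in seq_len(nrow(df))) {
      where <- sprintf("%s line %d: ", basename(f), i + 1L)
      e <- new_entry(df$tag_id[i], parse_pattern(df$pattern[i], where))
      if (e$key %in% keys) {
        stop_duplicate(sprintf("%sduplicate of entry at %s", where,
                               key_lines[match(e$key, keys)]))
      }
      keys <- c(keys, e$key)
      key_lines <- c(key_lines, sprintf("%s line %d", basename(f), i + 1L))
      entries[[length(entries) + 1]] <- e
    }
  }
  lex <- new_lexicon(list(), scheme = NULL)
  lex$entries <- entries
  unknown <- setdiff(vapply(entries, `[[`, character(1), "tag_id"),
                     scheme$tags$tag_id)
  if (length(unknown) > 0) {
    stop_reference(sprintf("lexicon references unknown tag_id(s): %s",
                           paste(unknown, collapse = ", ")))
  }
  lex
}

#' Add an entry to a lexicon
#'
#' Mirrors the annotation tool's "add new item by surface form, basic form,
#' and part-of-speech".
#'
#' @param lexicon A `pragma_lexicon`.
#' @param tag_id Tag the entry annotates.
#' @param pattern Pattern as in [new_lexicon()].
#' @param scheme Optional scheme to validate `tag_id` against.
#' @return The updated lexicon (entry appended).
#' @export
add_entry <- function(lexicon, tag_id, pattern, scheme = NULL) {
  stopifnot(inherits(lexicon, "pragma_lexicon"))
  e <- new_entry(tag_id, pattern)
  if (!is.null(scheme) && !tag_id %in% scheme$tags$tag_id) {
    stop_reference(sprintf("unknown tag_id '%s'", tag_id))
  }
  if (e$key %in% vapply(lexicon$entries, `[[`, character(1), "key")) {
    stop_duplicate(sprintf("entry already present: %s", e$key))
  }
  lexicon$entries <- c(lexicon$entries, list(e))
  lexicon
}

#' Write a lexicon TSV
#'
#' @param lexicon A `pragma_lexicon`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "pragma_lexicon"))
  df <- data.frame(
    tag_id = vapply(lexicon$entries, `[[`, character(1), "tag_id"),
    pattern = vapply(lexicon$entries, function(e) format_pattern(e$pattern),
                     character(1)),
    stringsAsFactors = FALSE)
  write_tsv_utf8(df, path)
  invisible(path)
}

#' @export
print.pragma_lexicon <- function(x, ...) {
  cat(sprintf("<pragma_lexicon> %d entries, %d channels\n",
              length(x$entries),
              length(unique(vapply(x$entries, `[[`, character(1), "tag_id")))))
  invisible(x)
}

# Does entry pattern match the token stream at position t (1-based)?
# norm: list with surface/lemma/pos character vectors, NFKC-normalized.
pattern_matches_at <- function(pattern, norm, t) {
  L <- length(pattern)
  if (t + L - 1L > length(norm$surface)) return(FALSE)
  for (j in seq_len(L)) {
    con <- pattern[[j]]
    k <- t + j - 1L
    for (f in names(con)) {
      if (norm[[f]][k] != con[[f]]) return(FALSE)
    }
  }
  TRUE
}

#' Annotate a document against a lexicon
#'
#' Scans every sentence once per channel (tag type). Policy is
#' leftmost-longest: at each position the longest matching entry of the
#' channel wins and scanning resumes at its end, so spans within one channel
#' never overlap; different channels are independent and may overlap freely.
#'
#' @param doc A `pragma_document`.
#' @param lexicon A `pragma_lexicon`.
#' @return Span data frame (`source = "dictionary"`, `verified = FALSE`),
#'   sorted by channel, sentence, start. Empty when nothing matches.
#' @export
annotate_document <- function(doc, lexicon) {
  stopifnot(inherits(doc, "pragma_document"), inherits(lexicon, "pragma_lexicon"))
  tags <- vapply(lexicon$entries, `[[`, character(1), "tag_id")
  by_tag <- split(lexicon$entries, factor(tags, levels = unique(tags)))
  out <- list()
  tok <- doc$tokens
  for (sid in unique(tok$sentence_id)) {
    s <- tok[tok$sentence_id == sid, ]
    norm <- list(surface = nfkc(s$surface), lemma = nfkc(s$lemma),
                 pos = nfkc(s$pos))
    T_ <- nrow(s)
    for (tag in names(by_tag)) {
      entries <- by_tag[[tag]]
      lens <- vapply(entries, function(e) length(e$pattern), integer(1))
      ord <- order(-lens)           # try longest first at each position
      t <- 1L
      while (t <= T_) {
        hit <- 0L
        for (ei in ord) {
          if (pattern_matches_at(entries[[ei]]$pattern, norm, t)) { hit <- ei; break }
        }
        if (hit > 0L) {
          L <- lens[hit]
          out[[length(out) + 1]] <- data.frame(
            doc_id = doc$doc_id, sentence_id = sid, tag_id = tag,
            start = t - 1L, end = t - 1L + L,
            source = "dictionary", verified = FALSE,
            stringsAsFactors = FALSE)
          t <- t + L
        } else {
          t <- t + 1L
        }
      }
    }
  }
  spans <- if (length(out) > 0) do.call(rbind, out) else empty_spans()
  sort_spans(as_spans(spans))
}

#' Annotate a whole corpus
#'
#' @param corpus A `pragma_corpus`.
#' @param lexicon A `pragma_lexicon`.
#' @return The corpus with dictionary spans attached as `$spans`.
#' @export
annotate_corpus <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "pragma_corpus"))
  spans <- do.call(rbind, c(list(empty_spans()),
                            lapply(corpus$documents, annotate_document,
                                   lexicon = lexicon)))
  set_spans(corpus, sort_spans(spans))
}
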