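#' Load an annotation scheme
#'
#' Reads a scheme TSV describing the tag-type inventory used by every other
#' stage: one row per tag type, with columns `metafunction`, `heading_id`,
#' `heading_name`, `tag_id`, `tag_name`, `notes`. Only the ideational and
#' interpersonal metafunctions are admitted; the textual metafunction is
#' rejected at load (it is outside the scope of the scheme).
#'
#' Heading ids that differ only by a trailing variant marker (`_ic`, `_ben`)
#' denote scheme-level variants of one annotation dictionary; the loader
#' strips the marker to derive `dictionary_name`, so the bundled scheme has
#' 16 headings backed by 15 dictionaries.
#'
#' @param path Path to a UTF-8 scheme TSV. Defaults to the bundled
#'   159-tag systemic-functional scheme.
#' @return An object of class `annotation_scheme`: a list with data frames
#'   `headings` (`heading_id`, `heading_name`, `metafunction`,
#'   `dictionary_name`) and `tags` (`tag_id`, `heading_id`, `tag_name`,
#'   `notes`), both in file order.
#' @examples
#' sch <- load_scheme()
#' nrow(sch$tags)            # 159
#' summarize_scheme(sch)
#' @export
load_scheme <- function(path = bundled_scheme_path()) {
  if (!file.exists(path)) stop_input(sprintf("scheme file not found: %s", path))
  df <- read_tsv_utf8(path)
  want <- c("metafunction", "heading_id", "heading_name", "tag_id",
            "tag_name", "notes")
  if (!identical(colnames(df), want)) {
    stop_schema(sprintf("scheme header must be exactly: %s",
                        paste(want, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    return(new_scheme(
      headings = data.frame(heading_id = character(), heading_name = character(),
                            metafunction = character(), dictionary_name = character(),
                            stringsAsFactors = FALSE),
      tags = data.frame(tag_id = character(), heading_id = character(),
                        tag_name = character(), notes = character(),
                        stringsAsFactors = FALSE)))
  }
  bad_mf <- setdiff(unique(df$metafunction), c("ideational", "interpersonal"))
  if (length(bad_mf) > 0) {
    stop_schema(sprintf("unknown metafunction label(s): %s (only 'ideational' and 'interpersonal' are in scope)",
                        paste(bad_mf, collapse = ", ")))
  }
  dup <- df$tag_id[duplicated(df$tag_id)]
  if (length(dup) > 0) {
    stop_schema(sprintf("duplicate tag_id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(df$tag_id)) || any(!nzchar(df$heading_id))) {
    stop_schema("tag_id and heading_id must be non-empty")
  }
  # headings in order of first appearance; name/metafunction must be stable
  first <- !duplicated(df$heading_id)
  headings <- data.frame(
    heading_id = df$heading_id[first],
    heading_name = df$heading_name[first],
    metafunction = df$metafunction[first],
    stringsAsFactors = FALSE
  )
  for (h in headings$heading_id) {
    sel <- df$heading_id == h
    if (length(unique(df$heading_name[sel])) > 1 ||
        length(unique(df$metafunction[sel])) > 1) {
      stop_schema(sprintf("heading '%s' has inconsistent name or metafunction across rows", h))
    }
  }
  headings$dictionary_name <- sub("_(ic|ben)$", "", headings$heading_id)
  tags <- df[, c("tag_id", "heading_id", "tag_name", "notes")]
  rownames(tags) <- NULL
  new_scheme(headings = headings, tags = tags)
}

new_scheme <- function(headings, tags) {
  structure(list(headings = headings, tags = tags),
            class = "annotation_scheme")
}

#' Path to the bundled 159-tag scheme
#'
#' @return File path of the packaged scheme TSV.
#' @export
bundled_scheme_path <- function() {
  system.file("extdata", "scheme_sfl159.tsv", package = "pragmap",
              mustWork = TRUE)
}

#' Path to the bundled dictionary directory
#'
#' One TSV per annotation dictionary (15 files). The filler and negotiating
#' particle dictionaries carry the scheme's enumerated lexis; the remaining
#' dictionaries hold small fixture entries, since the full production lexis
#' is not distributable.
#'
#' @return Directory path containing the packaged lexicon TSVs.
#' @export
bundled_lexicon_path <- function() {
  system.file("extdata", "lexicon", package = "pragmap", mustWork = TRUE)
}

#' Summarize a scheme by heading
#'
#' @param scheme An `annotation_scheme`.
#' @return A data frame with one row per heading: `heading_id`,
#'   `heading_name`, `metafunction`, `dictionary_name`, `n_tags`. Tag counts
#'   sum to the scheme's total tag-type count.
#' @export
summarize_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "annotation_scheme"))
  h <- scheme$headings
  if (nrow(h) == 0) {
    return(cbind(h, data.frame(n_tags = integer())))
  }
  h$n_tags <- as.integer(table(factor(scheme$tags$heading_id,
                                      levels = h$heading_id)))
  rownames(h) <- NULL
  h
}

#' Write a scheme TSV
#'
#' Inverse of [load_scheme()]: `load_scheme(write_scheme(s, f))` preserves
#' the scheme's content and row order.
#'
#' @param scheme An `annotation_scheme`.
#' @param path Output path (UTF-8, LF).
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "annotation_scheme"))
  tg <- scheme$tags
  hmap <- scheme$headings
  idx <- match(tg$heading_id, hmap$heading_id)
  out <- data.frame(
    metafunction = hmap$metafunction[idx],
    heading_id = tg$heading_id,
    heading_name = hmap$heading_name[idx],
    tag_id = tg$tag_id,
    tag_name = tg$tag_name,
    notes = tg$notes,
    stringsAsFactors = FALSE
  )
  write_tsv_utf8(out, path)
  invisible(path)
}

#' @export
print.annotation_scheme <- function(x, ...) {
  cat(sprintf("<annotation_scheme> %d tag types, %d headings, %d dictionaries\n",
              nrow(x$tags), nrow(x$headings),
              length(unique(x$headings$dictionary_name))))
  invisible(x)
}

# ---- shared TSV helpers (UTF-8, LF, no quoting) ----

read_tsv_utf8 <- function(path) {
  txt <- tryCatch(
    readLines(path, encoding = "UTF-8", warn = FALSE),
    error = function(e) stop_format(sprintf("cannot read %s: %s", path, conditionMessage(e)))
  )
  if (any(!validUTF8(txt))) stop_format(sprintf("%s is not valid UTF-8", path))
  if (length(txt) == 0) stop_format(sprintf("%s is empty (missing header row)", path))
  header <- strsplit(txt[1], "\t", fixed = TRUE)[[1]]
  body <- txt[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    df <- as.data.frame(setNames(replicate(length(header), character(),
                                           simplify = FALSE), header),
                        stringsAsFactors = FALSE)
    return(df)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  n <- length(header)
  m <- t(vapply(parts, function(p) {
    length(p) <- n
    p
  }, character(n)))
  m[is.na(m)] <- ""
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  colnames(df) <- header
  df
}

write_tsv_utf8 <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(colnames(df), collapse = "\t"),
             if (nrow(df) > 0) do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
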