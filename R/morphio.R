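# Transcript I/O: the PRAGMA-TSV dialect.
#
# A file holds one or more documents. Each document is a '#key=value' header
# block (keys: doc_id, subject_id, group, age, task) followed by sentence
# blocks; sentences are separated by one blank line; each morpheme line is
#   surface \t lemma \t pos \t pos_detail \t speaker
# Lines starting '##' are format comments. Canonical serialization sorts
# header keys and terminates every sentence with exactly one blank line, so
# write_corpus(read_corpus(f)) is byte-stable.

GROUPS <- c("ASD-1", "ASD-2", "TD")
TASKS  <- c("A", "E", "D", "DG", "P", "CT", "SM", "H", "I", "B", "C", "G")
SPEAKERS <- c("subject", "examiner")
META_KEYS <- c("age", "doc_id", "group", "subject_id", "task")
FORMAT_COMMENT <- "## pragma-tsv 1"

#' Construct a document
#'
#' @param doc_id,subject_id Identifiers (non-empty strings).
#' @param group Diagnostic group: one of `"ASD-1"`, `"ASD-2"`, `"TD"`.
#' @param age Age in whole years, `>= 0`.
#' @param task Task code, one of `A,E,D,DG,P,CT,SM,H,I,B,C,G`.
#' @param tokens Data frame with columns `sentence_id` (1-based integer),
#'   `index` (0-based position within sentence), `surface`, `lemma`, `pos`,
#'   `pos_detail`, `speaker` (`"subject"` or `"examiner"`).
#' @return A `pragma_document`.
#' @export
new_document <- function(doc_id, subject_id, group, age, task, tokens) {
  if (!nzchar(doc_id)) stop_format("doc_id must be non-empty")
  if (!group %in% GROUPS) {
    stop_format(sprintf("unknown group '%s' for key 'group' (expected %s)",
                        group, paste(GROUPS, collapse = "/")))
  }
  if (!task %in% TASKS) {
    stop_format(sprintf("unknown task '%s' for key 'task' (expected %s)",
                        task, paste(TASKS, collapse = "/")))
  }
  age <- suppressWarnings(as.integer(age))
  if (is.na(age) || age < 0) stop_format("key 'age' must be an integer >= 0")
  tokens <- validate_tokens(tokens, doc_id)
  structure(list(doc_id = doc_id, subject_id = subject_id, group = group,
                 age = age, task = task, tokens = tokens),
            class = "pragma_document")
}

validate_tokens <- function(tokens, doc_id) {
  need <- c("sentence_id", "index", "surface", "lemma", "pos",
            "pos_detail", "speaker")
  missing <- setdiff(need, colnames(tokens))
  if (length(missing) > 0) {
    stop_format(sprintf("document '%s': token table lacks column(s) %s",
                        doc_id, paste(missing, collapse = ", ")))
  }
  tokens <- tokens[, need]
  tokens$sentence_id <- as.integer(tokens$sentence_id)
  tokens$index <- as.integer(tokens$index)
  if (any(!nzchar(tokens$surface))) {
    stop_format(sprintf("document '%s': empty surface form", doc_id))
  }
  bad_sp <- setdiff(unique(tokens$speaker), SPEAKERS)
  if (length(bad_sp) > 0) {
    stop_format(sprintf("document '%s': unknown speaker(s) %s",
                        doc_id, paste(bad_sp, collapse = ", ")))
  }
  # morpheme indices must be 0..T-1 contiguous per sentence
  for (sid in unique(tokens$sentence_id)) {
    idx <- tokens$index[tokens$sentence_id == sid]
    if (!identical(idx, seq.int(0L, length(idx) - 1L))) {
      stop_format(sprintf("document '%s' sentence %d: morpheme indices not contiguous from 0",
                          doc_id, sid))
    }
  }
  rownames(tokens) <- NULL
  tokens
}

#' Construct a corpus
#'
#' @param documents List of [new_document()] objects with unique `doc_id`s.
#' @param spans Optional span-annotation data frame (see [annotate_corpus()]).
#' @return A `pragma_corpus`.
#' @export
new_corpus <- function(documents = list(), spans = NULL) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop_format(sprintf("duplicate doc_id(s): %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(list(documents = documents, spans = spans),
            class = "pragma_corpus")
}

#' Read a PRAGMA-TSV corpus
#'
#' @param path A transcript file, or a directory whose `*.tsv` files are read
#'   in lexicographic order.
#' @return A `pragma_corpus`; document order follows file order.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    docs <- unlist(lapply(files, parse_pragma_file), recursive = FALSE)
    return(new_corpus(docs))
  }
  if (!file.exists(path)) stop_input(sprintf("corpus path not found: %s", path))
  new_corpus(parse_pragma_file(path))
}

parse_pragma_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (any(!validUTF8(lines))) stop_format(sprintf("%s is not valid UTF-8", path))
  docs <- list()
  meta <- list()
  sentences <- list()      # list of lists of token-line fields
  cur <- list()
  seen_tokens <- FALSE

  flush_sentence <- function() {
    if (length(cur) > 0) {
      sentences[[length(sentences) + 1]] <<- cur
      cur <<- list()
    }
  }
  flush_doc <- function() {
    flush_sentence()
    if (length(meta) == 0 && length(sentences) == 0) return()
    missing <- setdiff(META_KEYS, names(meta))
    if (length(missing) > 0) {
      stop_format(sprintf("%s: document header missing required key(s): %s",
                          path, paste(missing, collapse = ", ")))
    }
    tok <- do.call(rbind, unlist(lapply(seq_along(sentences), function(si) {
      lapply(seq_along(sentences[[si]]), function(ti) {
        f <- sentences[[si]][[ti]]
        data.frame(sentence_id = si, index = ti - 1L,
                   surface = f[1], lemma = f[2], pos = f[3],
                   pos_detail = f[4], speaker = f[5],
                   stringsAsFactors = FALSE)
      })
    }), recursive = FALSE))
    if (is.null(tok)) {
      tok <- data.frame(sentence_id = integer(), index = integer(),
                        surface = character(), lemma = character(),
                        pos = character(), pos_detail = character(),
                        speaker = character(), stringsAsFactors = FALSE)
    }
    docs[[length(docs) + 1]] <<- new_document(
      doc_id = meta$doc_id, subject_id = meta$subject_id, group = meta$group,
      age = meta$age, task = meta$task, tokens = tok)
    meta <<- list(); sentences <<- list(); seen_tokens <<- FALSE
  }

  for (ln in lines) {
    if (startsWith(ln, "##")) next
    if (startsWith(ln, "#")) {
      if (seen_tokens) flush_doc()
      kv <- sub("^#", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) stop_format(sprintf("%s: malformed header line '%s'", path, ln))
      key <- substr(kv, 1, eq - 1)
      meta[[key]] <- substr(kv, eq + 1, nchar(kv))
      next
    }
    if (!nzchar(ln)) { flush_sentence(); next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 5) {
      stop_format(sprintf("%s: morpheme line must have 5 tab-separated fields, got %d: '%s'",
                          path, length(f), ln))
    }
    cur[[length(cur) + 1]] <- f
    seen_tokens <- TRUE
  }
  flush_doc()
  docs
}

#' Write a corpus in canonical PRAGMA-TSV
#'
#' Inverse of [read_corpus()] on canonical form: header keys sorted, one
#' blank line after every sentence, a single format comment at the top.
#'
#' @param corpus A `pragma_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "pragma_corpus"))
  out <- c(FORMAT_COMMENT)
  for (d in corpus$documents) {
    meta <- c(age = as.character(d$age), doc_id = d$doc_id, group = d$group,
              subject_id = d$subject_id, task = d$task)
    meta <- meta[sort(names(meta))]
    out <- c(out, paste0("#", names(meta), "=", meta))
    tok <- d$tokens
    for (sid in unique(tok$sentence_id)) {
      s <- tok[tok$sentence_id == sid, ]
      out <- c(out,
               paste(s$surface, s$lemma, s$pos, s$pos_detail, s$speaker,
                     sep = "\t"),
               "")
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(out), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Summarize a corpus
#'
#' Morpheme totals count subject-speaker morphemes only: examiner turns are
#' kept for concordance context but never enter analysis denominators.
#'
#' @param corpus A `pragma_corpus`.
#' @return A list: `n_documents`, `n_subjects`, `subjects_per_group` (named
#'   integer vector over groups present), `n_morphemes_subject`,
#'   `n_morphemes_total`.
#' @export
corpus_summary <- function(corpus) {
  stopifnot(inherits(corpus, "pragma_corpus"))
  docs <- corpus$documents
  subj <- vapply(docs, function(d) d$subject_id, character(1))
  grp  <- vapply(docs, function(d) d$group, character(1))
  n_subj_tok <- sum(vapply(docs, function(d) sum(d$tokens$speaker == "subject"), integer(1)))
  n_tok <- sum(vapply(docs, function(d) nrow(d$tokens), integer(1)))
  per_group <- if (length(docs) > 0) {
    vapply(split(subj, grp), function(s) length(unique(s)), integer(1))
  } else {
    setNames(integer(0), character(0))
  }
  list(
    n_documents = length(docs),
    n_subjects = length(unique(subj)),
    subjects_per_group = per_group,
    n_morphemes_subject = n_subj_tok,
    n_morphemes_total = n_tok
  )
}

#' @export
print.pragma_corpus <- function(x, ...) {
  s <- corpus_summary(x)
  cat(sprintf("<pragma_corpus> %d documents, %d subjects, %d subject morphemes%s\n",
              s$n_documents, s$n_subjects, s$n_morphemes_subject,
              if (!is.null(x$spans)) sprintf(", %d spans", nrow(x$spans)) else ""))
  invisible(x)
}

#' Convert raw morphological-analyzer output to a document
#'
#' Accepts analyzer lines of the form `surface\tfeature1,feature2,...` with
#' `EOS` terminating each sentence (the UniDic/MeCab output convention).
#' Feature field 1 is taken as the coarse part-of-speech, field 2 as
#' `pos_detail`, and field 8 (when present) as the lemma; otherwise the
#' surface form doubles as lemma. Segmentation is treated as reviewed input;
#' no re-analysis is attempted.
#'
#' @param lines Character vector of analyzer output lines.
#' @param doc_id,subject_id,group,age,task Document metadata.
#' @param speaker Speaker attributed to all morphemes (default "subject").
#' @return A `pragma_document`.
#' @export
mecab_to_document <- function(lines, doc_id, subject_id, group, age, task,
                              speaker = "subject") {
  rows <- list()
  sid <- 1L
  idx <- 0L
  any_in_sentence <- FALSE
  for (ln in lines) {
    if (ln == "EOS") {
      if (any_in_sentence) { sid <- sid + 1L; idx <- 0L; any_in_sentence <- FALSE }
      next
    }
    if (!nzchar(ln)) next
    tabpos <- regexpr("\t", ln, fixed = TRUE)
    if (tabpos < 0) stop_format(sprintf("malformed analyzer line: '%s'", ln))
    surface <- substr(ln, 1, tabpos - 1)
    feats <- strsplit(substr(ln, tabpos + 1, nchar(ln)), ",", fixed = TRUE)[[1]]
    rows[[length(rows) + 1]] <- data.frame(
      sentence_id = sid, index = idx, surface = surface,
      lemma = if (length(feats) >= 8 && nzchar(feats[8])) feats[8] else surface,
      pos = if (length(feats) >= 1) feats[1] else "",
      pos_detail = if (length(feats) >= 2) feats[2] else "",
      speaker = speaker, stringsAsFactors = FALSE)
    idx <- idx + 1L
    any_in_sentence <- TRUE
  }
  tok <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sentence_id = integer(), index = integer(), surface = character(),
               lemma = character(), pos = character(), pos_detail = character(),
               speaker = character(), stringsAsFactors = FALSE)
  new_document(doc_id, subject_id, group, age, task, tok)
}

# Subset a corpus by document index or doc_id, keeping matching spans.
corpus_subset <- function(corpus, which) {
  docs <- corpus$documents
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  keep <- if (is.character(which)) ids %in% which else seq_along(docs) %in% which
  spans <- corpus$spans
  if (!is.null(spans)) spans <- spans[spans$doc_id %in% ids[keep], , drop = FALSE]
  new_corpus(docs[keep], spans = spans)
}
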