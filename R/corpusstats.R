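# Corpus-viewer computations: occurrence rates, Welch's t-test group
# comparison, KWIC concordance, frequency tables.
#
# The unit of analysis is the subject: one pooled per-morpheme rate per
# subject per tag, with the denominator the subject-speaker morpheme count
# of the filtered documents. Group comparisons use Welch's unequal-variance
# t with Welch-Satterthwaite degrees of freedom and a two-sided p.

# Expand a group selector: "ASD" covers both ASD subgroups.
expand_group <- function(g) {
  if (identical(g, "ASD")) c("ASD-1", "ASD-2") else g
}

filter_documents <- function(corpus, group = NULL, task = NULL,
                             min_age = NULL, max_age = NULL) {
  keep <- vapply(corpus$documents, function(d) {
    (is.null(group) || d$group %in% unlist(lapply(group, expand_group))) &&
      (is.null(task) || d$task %in% task) &&
      (is.null(min_age) || d$age >= min_age) &&
      (is.null(max_age) || d$age <= max_age)
  }, logical(1))
  which(keep)
}

#' Per-subject occurrence rates
#'
#' For each subject in the filtered documents and each requested tag:
#' `count` spans of that tag across the subject's documents, `morphemes` the
#' subject-speaker morpheme total of those documents, and
#' `rate = count / morphemes`. Examiner morphemes never enter the
#' denominator.
#'
#' @param corpus Annotated `pragma_corpus` (spans in `$spans`).
#' @param tags Character vector of tag ids.
#' @param group,task Optional filters (group `"ASD"` covers `ASD-1` and
#'   `ASD-2`).
#' @param min_age,max_age Optional age bounds (inclusive, years).
#' @return Data frame: `subject_id`, `group`, `tag_id`, `count`,
#'   `morphemes`, `rate`. A filter matching no documents returns zero rows
#'   with a warning.
#' @export
occurrence_rates <- function(corpus, tags, group = NULL, task = NULL,
                             min_age = NULL, max_age = NULL) {
  stopifnot(inherits(corpus, "pragma_corpus"))
  if (is.null(corpus$spans)) stop_input("corpus carries no span annotations")
  idx <- filter_documents(corpus, group, task, min_age, max_age)
  if (length(idx) == 0) {
    pm_warn("filter matches no documents")
    return(data.frame(subject_id = character(), group = character(),
                      tag_id = character(), count = integer(),
                      morphemes = integer(), rate = numeric(),
                      stringsAsFactors = FALSE))
  }
  docs <- corpus$documents[idx]
  doc_ids <- vapply(docs, function(d) d$doc_id, character(1))
  subj <- vapply(docs, function(d) d$subject_id, character(1))
  grp <- vapply(docs, function(d) d$group, character(1))
  mor <- vapply(docs, function(d) sum(d$tokens$speaker == "subject"), integer(1))
  subjects <- unique(subj)
  sub_grp <- grp[match(subjects, subj)]
  sub_mor <- vapply(subjects, function(s) sum(mor[subj == s]), integer(1))
  spans <- corpus$spans
  spans <- spans[spans$doc_id %in% doc_ids & spans$tag_id %in% tags, ,
                 drop = FALSE]
  spans$subject_id <- subj[match(spans$doc_id, doc_ids)]
  out <- expand.grid(subject_id = subjects, tag_id = tags,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cnt <- table(factor(spans$subject_id, levels = subjects),
               factor(spans$tag_id, levels = tags))
  out$group <- sub_grp[match(out$subject_id, subjects)]
  out$count <- as.integer(cnt[cbind(match(out$subject_id, subjects),
                                    match(out$tag_id, tags))])
  out$morphemes <- sub_mor[match(out$subject_id, subjects)]
  if (any(out$morphemes <= 0)) {
    stop_input("subject with zero subject-speaker morphemes in filtered documents")
  }
  out$rate <- out$count / out$morphemes
  out[, c("subject_id", "group", "tag_id", "count", "morphemes", "rate")]
}

#' Welch's two-sample t-test from samples
#'
#' `t = (mean(x) - mean(y)) / sqrt(s_x^2/n_x + s_y^2/n_y)` with sample
#' (n-1) variances, Welch-Satterthwaite degrees of freedom, and a two-sided
#' p from the t distribution. No equal-variance assumption.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return List: `t`, `df`, `p`.
#' @export
welch_from_samples <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop_input("each sample needs at least 2 values")
  }
  welch_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Welch's two-sample t-test from summary statistics
#'
#' Same formulas as [welch_from_samples()] applied to printed summaries
#' (group means, standard deviations, sizes) — the reproduction path when
#' only a results table is available.
#'
#' @param mean_a,sd_a,n_a First group summary (sd >= 0, n >= 2).
#' @param mean_b,sd_b,n_b Second group summary.
#' @return List: `t`, `df`, `p`.
#' @export
welch_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop_input("each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0) stop_input("standard deviations must be >= 0")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (va + vb == 0) {
    stop_degenerate("both group variances are zero; Welch statistic undefined")
  }
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Compare tag occurrence rates between two groups
#'
#' One row per requested tag, in input order: per-subject rates are pooled
#' within each group and compared with Welch's t-test. Sign convention is
#' group A minus group B (defaults put TD first, so positive t means the
#' comparison group uses the tag more). Degenerate tags (both group
#' variances zero) are listed in the `"exclusions"` attribute and emitted
#' with missing t/df/p.
#'
#' @param corpus Annotated `pragma_corpus`.
#' @param tags Tag ids to compare (order preserved in the output).
#' @param group_a,group_b Group selectors; `"ASD"` covers both subgroups.
#' @param task,min_age,max_age Document filters as in [occurrence_rates()].
#' @param holm If `TRUE`, append a Holm-adjusted p column (`p_holm`);
#'   default off — raw per-tag p-values are the primary report.
#' @return Data frame: `tag_id`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`,
#'   `n_b`, `t`, `df`, `p` (and `p_holm` when requested).
#' @export
compare_groups <- function(corpus, tags, group_a = "TD", group_b = "ASD",
                           task = NULL, min_age = NULL, max_age = NULL,
                           holm = FALSE) {
  ra <- occurrence_rates(corpus, tags, group = group_a, task = task,
                         min_age = min_age, max_age = max_age)
  rb <- occurrence_rates(corpus, tags, group = group_b, task = task,
                         min_age = min_age, max_age = max_age)
  if (length(unique(ra$subject_id)) < 2 || length(unique(rb$subject_id)) < 2) {
    stop_input("both groups need at least 2 subjects after filtering")
  }
  exclusions <- character()
  rows <- lapply(tags, function(tg) {
    xa <- ra$rate[ra$tag_id == tg]
    xb <- rb$rate[rb$tag_id == tg]
    base <- data.frame(tag_id = tg, mean_a = mean(xa), sd_a = sd(xa),
                       n_a = length(xa), mean_b = mean(xb), sd_b = sd(xb),
                       n_b = length(xb), stringsAsFactors = FALSE)
    w <- tryCatch(welch_from_samples(xa, xb),
                  pragmap_degenerate_error = function(e) NULL)
    if (is.null(w)) {
      exclusions <<- c(exclusions, tg)
      cbind(base, data.frame(t = NA_real_, df = NA_real_, p = NA_real_))
    } else {
      cbind(base, data.frame(t = w$t, df = w$df, p = w$p))
    }
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  attr(out, "exclusions") <- exclusions
  out
}

#' Write a group-comparison table
#'
#' TSV in the layout `tag  mean_<A>  SD_<A>  mean_<B>  SD_<B>  t  p` plus
#' `df`, with group names substituted into the column headers.
#'
#' @param comparison Output of [compare_groups()].
#' @param path Output file.
#' @param group_a,group_b Names used in the column headers.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path, group_a = "TD",
                             group_b = "ASD") {
  df <- data.frame(
    tag = comparison$tag_id,
    a_mean = formatC(comparison$mean_a, format = "f", digits = 6),
    a_sd = formatC(comparison$sd_a, format = "f", digits = 6),
    b_mean = formatC(comparison$mean_b, format = "f", digits = 6),
    b_sd = formatC(comparison$sd_b, format = "f", digits = 6),
    t = formatC(comparison$t, format = "f", digits = 3),
    p = formatC(comparison$p, format = "f", digits = 3),
    df = formatC(comparison$df, format = "f", digits = 2),
    stringsAsFactors = FALSE)
  colnames(df) <- c("tag", sprintf("mean_%s", group_a), sprintf("SD_%s", group_a),
                    sprintf("mean_%s", group_b), sprintf("SD_%s", group_b),
                    "t", "p", "df")
  if ("p_holm" %in% colnames(comparison)) {
    df$p_holm <- formatC(comparison$p_holm, format = "f", digits = 3)
  }
  write_tsv_utf8(df, path)
  invisible(path)
}

#' KWIC concordance
#'
#' Key Word In Context: one hit per matching annotated span (query by tag
#' id, recognized by a `.` in the query) or per surface-form occurrence.
#' Context windows are morpheme surfaces truncated at sentence bounds.
#'
#' @param corpus A `pragma_corpus`; tag queries require `$spans`.
#' @param query A tag id (contains `.`) or a surface form.
#' @param window Context size in morphemes on each side (default 5).
#' @return Data frame ordered by (doc, sentence, start): `doc_id`,
#'   `sentence_id`, `start`, `end`, `left_context`, `keyword`,
#'   `right_context` (space-joined surfaces).
#' @export
kwic <- function(corpus, query, window = 5L) {
  stopifnot(inherits(corpus, "pragma_corpus"))
  window <- as.integer(window)
  is_tag <- grepl(".", query, fixed = TRUE)
  hits <- if (is_tag) {
    spans <- corpus$spans
    if (is.null(spans)) stop_input("tag query requires an annotated corpus")
    if (!query %in% spans$tag_id) {
      sch_tags <- tryCatch(load_scheme()$tags$tag_id, error = function(e) character())
      if (!query %in% sch_tags) {
        stop_reference(sprintf("unknown tag_id '%s'", query))
      }
      spans[0, , drop = FALSE]
    } else {
      spans[spans$tag_id == query, , drop = FALSE]
    }
  } else {
    out <- list()
    for (d in corpus$documents) {
      tok <- d$tokens
      m <- which(tok$surface == query)
      if (length(m) > 0) {
        out[[length(out) + 1]] <- data.frame(
          doc_id = d$doc_id, sentence_id = tok$sentence_id[m],
          start = tok$index[m], end = tok$index[m] + 1L,
          stringsAsFactors = FALSE)
      }
    }
    if (length(out) > 0) do.call(rbind, out) else
      data.frame(doc_id = character(), sentence_id = integer(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE)
  }
  if (nrow(hits) == 0) {
    return(data.frame(doc_id = character(), sentence_id = integer(),
                      start = integer(), end = integer(),
                      left_context = character(), keyword = character(),
                      right_context = character(), stringsAsFactors = FALSE))
  }
  doc_ids <- vapply(corpus$documents, function(d) d$doc_id, character(1))
  res <- lapply(seq_len(nrow(hits)), function(i) {
    d <- corpus$documents[[match(hits$doc_id[i], doc_ids)]]
    s <- d$tokens[d$tokens$sentence_id == hits$sentence_id[i], ]
    a <- hits$start[i]; b <- hits$end[i]
    left <- s$surface[seq_len(a)][seq_len(a) > a - window]
    right_idx <- seq.int(b + 1L, length.out = min(window, nrow(s) - b))
    right <- if (nrow(s) > b && window > 0) s$surface[right_idx] else character()
    data.frame(doc_id = hits$doc_id[i], sentence_id = hits$sentence_id[i],
               start = a, end = b,
               left_context = paste(left, collapse = " "),
               keyword = paste(s$surface[(a + 1L):b], collapse = " "),
               right_context = paste(right, collapse = " "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$doc_id, out$sentence_id, out$start), , drop = FALSE]
}

#' Tag frequency table
#'
#' Span counts and per-morpheme rates aggregated by diagnostic group, task,
#' or scheme heading. Cell counts always sum to the corpus-wide span count
#' (conservation), whatever the grouping.
#'
#' @param corpus Annotated `pragma_corpus`.
#' @param by One of `"group"`, `"task"`, `"heading"`.
#' @param scheme `annotation_scheme`, required for `by = "heading"`.
#' @return Data frame: `cell`, `count`, `morphemes`, `rate`. For heading
#'   grouping, `morphemes` is the whole-corpus subject-morpheme total.
#' @export
freq_table <- function(corpus, by = c("group", "task", "heading"),
                       scheme = NULL) {
  stopifnot(inherits(corpus, "pragma_corpus"))
  by <- match.arg(by)
  spans <- corpus$spans
  if (is.null(spans)) stop_input("corpus carries no span annotations")
  docs <- corpus$documents
  doc_ids <- vapply(docs, function(d) d$doc_id, character(1))
  doc_mor <- vapply(docs, function(d) sum(d$tokens$speaker == "subject"), integer(1))
  if (by %in% c("group", "task")) {
    doc_cell <- vapply(docs, function(d) d[[if (by == "group") "group" else "task"]],
                       character(1))
    cells <- sort(unique(doc_cell))
    span_cell <- doc_cell[match(spans$doc_id, doc_ids)]
    cnt <- as.integer(table(factor(span_cell, levels = cells)))
    mor <- vapply(cells, function(cl) sum(doc_mor[doc_cell == cl]), integer(1))
  } else {
    if (is.null(scheme)) stop_input("heading grouping requires a scheme")
    heading <- scheme$tags$heading_id[match(spans$tag_id, scheme$tags$tag_id)]
    if (anyNA(heading)) {
      stop_reference("spans carry tag ids not present in the scheme")
    }
    cells <- sort(unique(heading))
    cnt <- as.integer(table(factor(heading, levels = cells)))
    mor <- rep(sum(doc_mor), length(cells))
  }
  data.frame(cell = cells, count = cnt, morphemes = mor,
             rate = ifelse(mor > 0, cnt / mor, 0), stringsAsFactors = FALSE,
             row.names = NULL)
}
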