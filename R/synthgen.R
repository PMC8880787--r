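# Synthetic annotated corpora with planted group-specific tag rates.
#
# The generator emulates the statistical shape of the clinical corpus — a TD
# and an ASD group of interview transcripts whose tag-bearing morpheme
# sequences occur at group-specific per-morpheme rates — not Japanese
# grammar. Each document is a shuffled stream of distractor morphemes and
# tag-bearing sequences; gold spans are recorded exactly where sequences
# land, and the emitted lexicon contains exactly those sequences, so
# dictionary annotation reproduces the gold spans by construction.

#' Default planted rates
#'
#' Per-morpheme occurrence rates of the six sentence-final negotiating
#' particles for the TD and ASD groups, at the magnitudes a task-A
#' interview corpus exhibits (order 1e-5 to 1e-2).
#'
#' @return Data frame: `group` ("TD"/"ASD"), `tag_id`, `rate`.
#' @export
default_tag_rates <- function() {
  tags <- paste0("negparticle.", c("kana", "kane", "sa", "ne", "yo", "yona"))
  td  <- c(0.003071, 0.002423, 0.000000, 0.010057, 0.001900, 0.000045)
  asd <- c(0.003423, 0.001179, 0.000017, 0.005572, 0.000839, 0.000026)
  data.frame(group = rep(c("TD", "ASD"), each = length(tags)),
             tag_id = rep(tags, 2), rate = c(td, asd),
             stringsAsFactors = FALSE)
}

default_sequences <- function(tags) {
  setNames(lapply(tags, function(tg) sub("^[^.]*\\.", "", tg)), tags)
}

#' Specification for a synthetic corpus
#'
#' Defaults state the emulated study shape: 57 TD and 50 ASD subjects, one
#' task-A interview document each, mean length 1000 morphemes
#' (negative-binomial, dispersion `size = 20`), ages 16-45, and planted
#' per-morpheme rates from [default_tag_rates()].
#'
#' @param n_subjects Named counts per group (names from
#'   `ASD-1`/`ASD-2`/`TD`).
#' @param doc_length_mean,doc_length_dispersion Negative-binomial mean and
#'   `size` for per-document morpheme counts (minimum length 50 enforced).
#' @param tag_rates Data frame `group` ("TD"/"ASD"), `tag_id`, `rate`;
#'   rates must lie in [0, 0.2].
#' @param sequences Named list tag_id -> character vector of surface forms
#'   (the tag-bearing morpheme sequence); must be unique and disjoint from
#'   the distractor vocabulary.
#' @param distractors Character vector of filler surface forms.
#' @param task Task code given to every document.
#' @param age_range Inclusive integer bounds for subject ages.
#' @param sentence_mean_len Mean sentence length in morphemes.
#' @param seed Default seed used by [generate_corpus()].
#' @return A `synth_spec`.
#' @export
synth_spec <- function(n_subjects = c("TD" = 57L, "ASD-1" = 50L),
                       doc_length_mean = 1000, doc_length_dispersion = 20,
                       tag_rates = default_tag_rates(),
                       sequences = default_sequences(unique(tag_rates$tag_id)),
                       distractors = sprintf("w%03d", 1:400),
                       task = "A", age_range = c(16L, 45L),
                       sentence_mean_len = 12, seed = 1L) {
  if (any(!names(n_subjects) %in% GROUPS)) {
    stop_spec(sprintf("n_subjects names must be among %s",
                      paste(GROUPS, collapse = "/")))
  }
  if (any(tag_rates$rate < 0 | tag_rates$rate > 0.2)) {
    stop_spec("tag rates must lie in [0, 0.2]")
  }
  tags <- unique(tag_rates$tag_id)
  if (!setequal(names(sequences), tags)) {
    stop_spec("sequences must be given for exactly the tags in tag_rates")
  }
  seq_keys <- vapply(sequences, paste, character(1), collapse = "\r")
  if (anyDuplicated(seq_keys)) stop_spec("tag-bearing sequences must be unique")
  if (length(intersect(unlist(sequences), distractors)) > 0) {
    stop_spec("tag-bearing sequences must be disjoint from the distractor vocabulary")
  }
  # feasibility: expected inserted morphemes per final morpheme must stay < 1
  lens <- vapply(sequences, length, integer(1))
  for (g in unique(tag_rates$group)) {
    r <- tag_rates$rate[tag_rates$group == g]
    l <- lens[tag_rates$tag_id[tag_rates$group == g]]
    if (sum(r * l) >= 1) {
      stop_spec(sprintf("group %s: planted rates imply more inserted morphemes than document length", g))
    }
  }
  structure(list(n_subjects = n_subjects, doc_length_mean = doc_length_mean,
                 doc_length_dispersion = doc_length_dispersion,
                 tag_rates = tag_rates, sequences = sequences,
                 distractors = distractors, task = task,
                 age_range = as.integer(age_range),
                 sentence_mean_len = sentence_mean_len,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

rate_group <- function(group) sub("-.*$", "", group)  # ASD-1/ASD-2 -> ASD

#' Generate a synthetic annotated corpus
#'
#' Per subject, one document: total length drawn from the spec's length
#' distribution; each tag's occurrence count is Binomial(T, rate), and the
#' corresponding sequences are shuffled uniformly among the distractor
#' morphemes (so the realized expected per-morpheme rate equals the planted
#' rate and spans can never overlap within a channel). Gold spans carry
#' `source = "manual"`, `verified = TRUE`. Deterministic given `seed`.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return List: `corpus` (a `pragma_corpus` with gold `$spans`), `lexicon`
#'   (a `pragma_lexicon` containing exactly the tag-bearing sequences),
#'   `spec`.
#' @export
generate_corpus <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  tags <- unique(spec$tag_rates$tag_id)
  lens <- vapply(spec$sequences, length, integer(1))[tags]
  with_seed(seed, {
    docs <- list()
    spans <- list()
    for (g in names(spec$n_subjects)) {
      rg <- rate_group(g)
      rates <- vapply(tags, function(tg) {
        r <- spec$tag_rates$rate[spec$tag_rates$group == rg &
                                   spec$tag_rates$tag_id == tg]
        if (length(r) == 0) 0 else r[1]
      }, numeric(1))
      for (i in seq_len(spec$n_subjects[[g]])) {
        subject_id <- sprintf("%s_s%03d", gsub("-", "", g), i)
        doc_id <- paste0(subject_id, "_", spec$task)
        age <- sample(spec$age_range[1]:spec$age_range[2], 1)
        T_ <- max(50L, rnbinom(1, size = spec$doc_length_dispersion,
                               mu = spec$doc_length_mean))
        k <- rbinom(length(tags), T_, rates)
        inserted <- sum(k * lens)
        if (inserted > T_) {
          stop_spec("planted rates infeasible for drawn document length")
        }
        n_distract <- T_ - inserted
        # unit stream: 0 = one distractor morpheme, j = sequence of tag j
        units <- sample(rep.int(c(0L, seq_along(tags)), c(n_distract, k)))
        gen <- build_doc(units, tags, lens, spec, doc_id, subject_id,
                         g, age)
        docs[[length(docs) + 1]] <- gen$doc
        if (nrow(gen$spans) > 0) spans[[length(spans) + 1]] <- gen$spans
      }
    }
    spans <- if (length(spans) > 0) do.call(rbind, spans) else empty_spans()
    corpus <- set_spans(new_corpus(docs), sort_spans(as_spans(spans)))
    lex <- new_lexicon(lapply(tags, function(tg) {
      list(tag_id = tg, pattern = spec$sequences[[tg]])
    }))
    list(corpus = corpus, lexicon = lex, spec = spec)
  })
}

build_doc <- function(units, tags, lens, spec, doc_id, subject_id, group, age) {
  n_units <- length(units)
  unit_len <- rep(1L, n_units)
  unit_len[units != 0L] <- lens[units[units != 0L]]
  # chop the unit stream into sentences
  sent_units <- integer(0)
  done <- 0L
  while (done < n_units) {
    L <- 1L + rpois(1, spec$sentence_mean_len - 1)
    sent_units <- c(sent_units, min(L, n_units - done))
    done <- done + min(L, n_units - done)
  }
  unit_sent <- rep(seq_along(sent_units), sent_units)
  sent_f <- factor(unit_sent, levels = seq_along(sent_units))
  # morpheme start index of each unit within its sentence (0-based)
  unit_start <- unlist(lapply(split(unit_len, sent_f), function(l) {
    cumsum(c(0L, l))[seq_along(l)]
  }), use.names = FALSE)
  n_dis <- sum(units == 0L)
  dis_surf <- sample(spec$distractors, n_dis, replace = TRUE)
  surfaces <- vector("list", n_units)
  di <- 1L
  for (u in seq_len(n_units)) {
    if (units[u] == 0L) {
      surfaces[[u]] <- dis_surf[di]; di <- di + 1L
    } else {
      surfaces[[u]] <- spec$sequences[[tags[units[u]]]]
    }
  }
  surf <- unlist(surfaces, use.names = FALSE)
  tok <- data.frame(
    sentence_id = rep(unit_sent, unit_len),
    index = unlist(lapply(split(unit_len, sent_f), function(l)
      seq.int(0L, sum(l) - 1L)), use.names = FALSE),
    surface = surf, lemma = surf,
    pos = rep(ifelse(units == 0L, "noun", "particle"), unit_len),
    pos_detail = "", speaker = "subject", stringsAsFactors = FALSE)
  doc <- new_document(doc_id, subject_id, group, age, spec$task, tok)
  tagged <- which(units != 0L)
  spans <- if (length(tagged) > 0) {
    data.frame(doc_id = doc_id, sentence_id = unit_sent[tagged],
               tag_id = tags[units[tagged]], start = unit_start[tagged],
               end = unit_start[tagged] + unit_len[tagged],
               source = "manual", verified = TRUE, stringsAsFactors = FALSE)
  } else empty_spans()
  list(doc = doc, spans = spans)
}

#' Rate-recovery and test-calibration report
#'
#' Regenerates the spec'd world `replicates` times, runs the
#' [occurrence_rates()] / [compare_groups()] pipeline on each replicate's
#' gold spans, and reports, per tag: the planted group rates, the mean
#' estimated rates, their bias, and the fraction of replicates with
#' p < 0.05.
#'
#' @param spec A [synth_spec()].
#' @param replicates Number of replicates (>= 2).
#' @param seed Base seed; replicate r uses a seed derived from it.
#' @param group_a,group_b Group selectors passed to [compare_groups()].
#' @return Data frame: `tag_id`, `rate_a`, `rate_b`, `est_a`, `est_b`,
#'   `bias_a`, `bias_b`, `reject_rate`.
#' @export
recovery_report <- function(spec, replicates, seed = spec$seed,
                            group_a = "TD", group_b = "ASD") {
  stopifnot(inherits(spec, "synth_spec"))
  if (replicates < 2) stop_input("replicates must be >= 2")
  tags <- unique(spec$tag_rates$tag_id)
  est_a <- matrix(NA_real_, replicates, length(tags))
  est_b <- matrix(NA_real_, replicates, length(tags))
  pmat <- matrix(NA_real_, replicates, length(tags))
  for (r in seq_len(replicates)) {
    rep_seed <- (as.integer(seed) * 1009L + r) %% 2147483647L
    gen <- generate_corpus(spec, seed = rep_seed)
    cmp <- compare_groups(gen$corpus, tags, group_a = group_a,
                          group_b = group_b)
    est_a[r, ] <- cmp$mean_a
    est_b[r, ] <- cmp$mean_b
    pmat[r, ] <- cmp$p
  }
  truth <- function(g, tg) {
    r <- spec$tag_rates$rate[spec$tag_rates$group == g &
                               spec$tag_rates$tag_id == tg]
    if (length(r) == 0) 0 else r[1]
  }
  ra <- vapply(tags, truth, numeric(1), g = rate_group(group_a))
  rb <- vapply(tags, truth, numeric(1), g = rate_group(group_b))
  data.frame(
    tag_id = tags, rate_a = ra, rate_b = rb,
    est_a = colMeans(est_a), est_b = colMeans(est_b),
    bias_a = colMeans(est_a) - ra, bias_b = colMeans(est_b) - rb,
    reject_rate = colMeans(pmat < 0.05, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a synthetic-corpus spec from JSON
#'
#' Accepts a JSON object with any subset of the [synth_spec()] fields
#' (`n_subjects` as an object of group counts, `tag_rates` as an array of
#' `{group, tag_id, rate}` records, `sequences` as an object of arrays).
#' Omitted fields take the defaults.
#'
#' @param path JSON file path.
#' @return A `synth_spec`.
#' @export
synth_spec_from_json <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("spec file not found: %s", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(js$n_subjects)) args$n_subjects <- unlist(js$n_subjects)
  for (f in c("doc_length_mean", "doc_length_dispersion", "task",
              "sentence_mean_len", "seed")) {
    if (!is.null(js[[f]])) args[[f]] <- js[[f]]
  }
  if (!is.null(js$age_range)) args$age_range <- unlist(js$age_range)
  if (!is.null(js$tag_rates)) args$tag_rates <- as.data.frame(js$tag_rates)
  if (!is.null(js$sequences)) args$sequences <- lapply(js$sequences, unlist)
  if (!is.null(js$distractors)) args$distractors <- unlist(js$distractors)
  if (!is.null(js$tag_rates) && is.null(js$sequences)) {
    args$sequences <- default_sequences(unique(args$tag_rates$tag_id))
  }
  do.call(synth_spec, args)
}
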