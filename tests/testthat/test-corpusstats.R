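# annotated fixture: tiny corpus with ne/yo spans attached
annotated_tiny <- function() {
  corpus <- tiny_corpus()
  spans <- data.frame(
    doc_id = c("doc1", "doc1", "doc2"),
    sentence_id = c(1L, 2L, 1L),
    tag_id = c("negparticle.ne", "negparticle.ne", "negparticle.yo"),
    start = c(2L, 1L, 2L), end = c(3L, 2L, 3L),
    source = "manual", verified = TRUE, stringsAsFactors = FALSE)
  set_spans(corpus, spans)
}

test_that("occurrence rates are per subject over subject-speaker morphemes", {
  corpus <- annotated_tiny()
  r <- occurrence_rates(corpus, c("negparticle.ne", "negparticle.yo"))
  expect_equal(nrow(r), 4L)   # 2 subjects x 2 tags
  ra <- r[r$subject_id == "subjA" & r$tag_id == "negparticle.ne", ]
  # doc1 has 4 subject-speaker morphemes (one examiner token excluded)
  expect_equal(ra$count, 2L)
  expect_equal(ra$morphemes, 4L)
  expect_equal(ra$rate, 0.5)
  # zero-occurrence tag still yields a row with rate 0
  expect_equal(r$rate[r$subject_id == "subjA" & r$tag_id == "negparticle.yo"], 0)
  # magnitude fixture: 3 spans in 1000 morphemes -> 0.003
  expect_equal(3 / 1000, 0.003)

  # rates invariant under sentence reordering within a document
  d1 <- corpus$documents[[1]]
  tok <- d1$tokens
  tok$sentence_id <- ifelse(tok$sentence_id == 1L, 2L, 1L)
  tok <- tok[order(tok$sentence_id, tok$index), ]
  corpus2 <- corpus
  corpus2$documents[[1]] <- new_document(d1$doc_id, d1$subject_id, d1$group,
                                         d1$age, d1$task, tok)
  sp <- corpus$spans
  sp$sentence_id <- ifelse(sp$doc_id == "doc1",
                           ifelse(sp$sentence_id == 1L, 2L, 1L),
                           sp$sentence_id)
  corpus2 <- set_spans(corpus2, sp)
  r2 <- occurrence_rates(corpus2, c("negparticle.ne", "negparticle.yo"))
  expect_equal(r2[order(r2$subject_id, r2$tag_id), "rate"],
               r[order(r$subject_id, r$tag_id), "rate"])

  expect_warning(occurrence_rates(corpus, "negparticle.ne", task = "H"),
                 class = "pragmap_warning")
})

test_that("welch_from_samples matches the frozen reference computation", {
  x <- c(0.012, 0.007, 0.009, 0.014, 0.010)
  y <- c(0.005, 0.008, 0.004, 0.006, 0.009)
  w <- welch_from_samples(x, y)
  expect_equal(w$t, 2.626128657194450, tolerance = 1e-10)
  expect_equal(w$df, 7.498467539704653, tolerance = 1e-10)
  expect_equal(w$p, 0.032098520054646, tolerance = 1e-10)
  # and agrees with the stats::t.test oracle on random draws
  set.seed(601)
  for (i in 1:25) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    w <- welch_from_samples(a, b)
    tt <- stats::t.test(a, b)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(w$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("welch edge conventions hold", {
  x <- c(0.1, 0.2, 0.3)
  expect_equal(welch_from_samples(x, x)$t, 0)
  expect_equal(welch_from_samples(x, x)$p, 1)
  w1 <- welch_from_samples(x, c(0.4, 0.5, 0.9))
  w2 <- welch_from_samples(c(0.4, 0.5, 0.9), x)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)
  expect_error(welch_from_samples(c(1), c(1, 2)),
               class = "pragmap_input_error")
  expect_error(welch_from_summary(1, 0, 5, 2, 0, 5),
               class = "pragmap_degenerate_error")
  expect_equal(welch_from_summary(0.3, 0.1, 5, 0.3, 0.4, 9)$t, 0)
})

test_that("welch_from_samples equals welch_from_summary exactly (property)", {
  set.seed(602)
  for (i in 1:50) {
    a <- rnorm(sample(2:20, 1))
    b <- rnorm(sample(2:20, 1))
    ws <- welch_from_samples(a, b)
    wy <- welch_from_summary(mean(a), sd(a), length(a),
                             mean(b), sd(b), length(b))
    expect_identical(ws, wy)
  }
})

test_that("group comparison orders rows, reports summaries and exclusions", {
  spec <- small_spec()
  gen <- generate_corpus(spec, seed = 31)
  tags <- c("modality.usuality", "negparticle.ne")
  cmp <- compare_groups(gen$corpus, tags, group_a = "TD", group_b = "ASD")
  expect_equal(cmp$tag_id, tags)          # input order preserved
  expect_equal(cmp$n_a, rep(15L, 2))
  expect_equal(cmp$n_b, rep(15L, 2))
  # summary path and sample path agree exactly
  r <- occurrence_rates(gen$corpus, "negparticle.ne")
  xa <- r$rate[r$group == "TD"]
  xb <- r$rate[r$group == "ASD-1"]
  w <- welch_from_summary(mean(xa), sd(xa), length(xa),
                          mean(xb), sd(xb), length(xb))
  row <- cmp[cmp$tag_id == "negparticle.ne", ]
  expect_equal(row$t, w$t)
  expect_equal(row$p, w$p)
  # identical groups give t = 0 everywhere
  docs_td <- Filter(function(d) d$group == "TD", gen$corpus$documents)
  clone <- lapply(docs_td, function(d) {
    d$doc_id <- paste0(d$doc_id, "_clone")
    d$subject_id <- paste0(d$subject_id, "_clone")
    d$group <- "ASD-2"
    d
  })
  sp <- gen$corpus$spans
  sp_td <- sp[sp$doc_id %in% vapply(docs_td, `[[`, character(1), "doc_id"), ]
  sp_clone <- sp_td
  sp_clone$doc_id <- paste0(sp_clone$doc_id, "_clone")
  twin <- set_spans(new_corpus(c(docs_td, clone)), rbind(sp_td, sp_clone))
  cmp2 <- compare_groups(twin, tags, group_a = "TD", group_b = "ASD-2")
  expect_true(all(abs(cmp2$t) < 1e-12 | is.na(cmp2$t)))
  # holm column appears on request and is >= raw p
  cmp3 <- compare_groups(gen$corpus, tags, holm = TRUE)
  expect_true(all(cmp3$p_holm >= cmp3$p, na.rm = TRUE))
})

test_that("comparison is invariant under subject relabeling within groups", {
  gen <- generate_corpus(small_spec(), seed = 32)
  tags <- "negparticle.ne"
  cmp1 <- compare_groups(gen$corpus, tags)
  relab <- lapply(gen$corpus$documents, function(d) {
    d$subject_id <- paste0("anon_", substr(d$subject_id, 4, 99))
    d
  })
  corpus2 <- set_spans(new_corpus(relab), gen$corpus$spans)
  cmp2 <- compare_groups(corpus2, tags)
  expect_equal(cmp2$t, cmp1$t)
  expect_equal(cmp2$p, cmp1$p)
})

test_that("kwic returns ordered hits with truncated windows", {
  lex <- load_lexicon(scheme = load_scheme())
  corpus <- annotate_corpus(new_corpus(list(example_document())), lex)
  hits <- kwic(corpus, "filler.nanka", window = 2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$keyword, "nanka")
  expect_equal(hits$left_context, "oko ttari")
  expect_equal(hits$right_context, "suru koto")
  # window 0 gives empty contexts
  h0 <- kwic(corpus, "filler.nanka", window = 0)
  expect_equal(h0$left_context, "")
  expect_equal(h0$right_context, "")
  # surface query and no-match query
  hs <- kwic(corpus, "aru", window = 1)
  expect_equal(hs$left_context, "koto")
  expect_equal(nrow(kwic(corpus, "zzz")), 0L)
  expect_error(kwic(corpus, "not.a.tag"), class = "pragmap_reference_error")
})

test_that("freq_table conserves counts across groupings", {
  gen <- generate_corpus(small_spec(), seed = 33)
  total <- nrow(gen$corpus$spans)
  for (by in c("group", "task")) {
    ft <- freq_table(gen$corpus, by = by)
    expect_equal(sum(ft$count), total)
  }
  ft <- freq_table(gen$corpus, by = "heading", scheme = load_scheme())
  expect_equal(sum(ft$count), total)
  expect_setequal(ft$cell, c("modality", "negparticle"))
  # single-document corpus collapses to one cell
  one <- pragmap:::corpus_subset(gen$corpus, 1)
  ft1 <- freq_table(one, by = "group")
  expect_equal(nrow(ft1), 1L)
  expect_equal(ft1$count, nrow(one$spans))
})
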