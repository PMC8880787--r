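test_that("spec validation catches infeasible and malformed worlds", {
  expect_error(synth_spec(tag_rates = data.frame(
    group = "TD", tag_id = "negparticle.ne", rate = 0.3)),
    class = "pragmap_spec_error")
  expect_error(synth_spec(
    tag_rates = data.frame(group = "TD", tag_id = "negparticle.ne",
                           rate = 0.01),
    sequences = list(negparticle.ne = "w001")),   # collides with distractors
    class = "pragmap_spec_error")
  expect_error(synth_spec(
    tag_rates = data.frame(group = c("TD", "TD"),
                           tag_id = c("a.x", "a.y"), rate = c(0.15, 0.15)),
    sequences = list(a.x = c("p", "q", "r", "s"), a.y = c("u", "v", "w", "z"))),
    class = "pragmap_spec_error")   # 2 * 0.15 * 4 morphemes > 1
  expect_error(synth_spec(n_subjects = c(XX = 5L)),
               class = "pragmap_spec_error")
})

test_that("generation is seed-deterministic and respects the stated world", {
  spec <- small_spec()
  g1 <- generate_corpus(spec, seed = 41)
  g2 <- generate_corpus(spec, seed = 41)
  f1 <- tempfile(); f2 <- tempfile()
  write_corpus(g1$corpus, f1); write_corpus(g2$corpus, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$corpus$spans, g2$corpus$spans)
  g3 <- generate_corpus(spec, seed = 42)
  expect_false(identical(readLines(f1),
                         { f3 <- tempfile(); write_corpus(g3$corpus, f3)
                           readLines(f3) }))
  s <- corpus_summary(g1$corpus)
  expect_equal(s$n_documents, 30L)
  expect_equal(s$subjects_per_group[["TD"]], 15L)
  expect_equal(s$subjects_per_group[["ASD-1"]], 15L)
  expect_true(all(vapply(g1$corpus$documents, `[[`, integer(1), "age") >= 13))
})

test_that("all-zero rates give an empty gold span set", {
  spec <- synth_spec(n_subjects = c(TD = 2L, "ASD-1" = 2L),
                     doc_length_mean = 100, doc_length_dispersion = 10,
                     tag_rates = data.frame(
                       group = c("TD", "ASD"), tag_id = "negparticle.ne",
                       rate = c(0, 0)))
  gen <- generate_corpus(spec, seed = 5)
  expect_equal(nrow(gen$corpus$spans), 0L)
})

test_that("closure: dictionary annotation reproduces gold spans exactly", {
  gen <- generate_corpus(small_spec(), seed = 43)
  ann <- annotate_corpus(gen$corpus, gen$lexicon)
  sc <- score_spans(gen$corpus$spans, ann$spans)
  expect_equal(sc$aggregate$precision, 1)
  expect_equal(sc$aggregate$recall, 1)
  expect_equal(sc$aggregate$f1, 1)
  # emitted lexicon contains exactly the tag-bearing sequences
  expect_setequal(vapply(gen$lexicon$entries, `[[`, character(1), "tag_id"),
                  unique(gen$spec$tag_rates$tag_id))
})

test_that("realized rate concentrates on the planted rate (binomial SE)", {
  rate <- 0.005
  spec <- synth_spec(n_subjects = c(TD = 60L, "ASD-1" = 60L),
                     doc_length_mean = 1000, doc_length_dispersion = 20,
                     tag_rates = data.frame(group = c("TD", "ASD"),
                                            tag_id = "negparticle.ne",
                                            rate = rate))
  gen <- generate_corpus(spec, seed = 44)
  n_mor <- corpus_summary(gen$corpus)$n_morphemes_subject
  expect_gte(n_mor, 1e5)
  realized <- nrow(gen$corpus$spans) / n_mor
  se <- sqrt(rate * (1 - rate) / n_mor)
  expect_lt(abs(realized - rate), 3 * se)
})

test_that("recovery report estimates rates with shrinking bias", {
  spec <- small_spec()
  rep1 <- recovery_report(spec, replicates = 5, seed = 45)
  expect_equal(nrow(rep1), 2L)
  expect_true(all(abs(rep1$bias_a) < rep1$rate_a + 0.01))
  # consistency: bias magnitude shrinks as the corpus grows (3 size tiers)
  tiers <- c(100, 400, 1600)
  bias <- vapply(tiers, function(mu) {
    sp <- synth_spec(n_subjects = c(TD = 10L, "ASD-1" = 10L),
                     doc_length_mean = mu, doc_length_dispersion = 20,
                     tag_rates = data.frame(group = c("TD", "ASD"),
                                            tag_id = "negparticle.ne",
                                            rate = c(0.01, 0.005)))
    r <- recovery_report(sp, replicates = 8, seed = 46)
    abs(r$bias_a)
  }, numeric(1))
  expect_true(bias[3] <= bias[1])
})

test_that("spec JSON round-trips through synth_spec_from_json", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    n_subjects = list(TD = 4, `ASD-1` = 4),
    doc_length_mean = 150, doc_length_dispersion = 10,
    tag_rates = data.frame(group = c("TD", "ASD"),
                           tag_id = "negparticle.yo", rate = c(0.01, 0.002)),
    seed = 9), f, auto_unbox = TRUE)
  spec <- synth_spec_from_json(f)
  expect_s3_class(spec, "synth_spec")
  expect_equal(spec$n_subjects[["TD"]], 4)
  expect_equal(spec$sequences$negparticle.yo, "yo")
  gen <- generate_corpus(spec)
  expect_equal(length(gen$corpus$documents), 8L)
})
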