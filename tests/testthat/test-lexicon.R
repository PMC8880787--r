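test_that("bundled filler dictionary has the eight enumerated entries", {
  sch <- load_scheme()
  lex <- load_lexicon(file.path(bundled_lexicon_path(), "filler.tsv"), sch)
  expect_equal(length(lex$entries), 8L)
  expect_true(all(vapply(lex$entries, function(e) length(e$pattern),
                         integer(1)) == 1L))
  surfs <- vapply(lex$entries, function(e) e$pattern[[1]][["surface"]],
                  character(1))
  expect_setequal(surfs, c("maa", "nanka", "ano", "unto", "eeto", "sono",
                           "kono", "kou"))
})

test_that("lexicon loader rejects bad references, empty patterns, duplicates", {
  sch <- load_scheme()
  f <- tempfile(fileext = ".tsv")
  writeLines(c("tag_id\tpattern", "nonexistent.tag\tsurface=x"), f)
  expect_error(load_lexicon(f, sch), class = "pragmap_reference_error")

  writeLines(c("tag_id\tpattern", "filler.maa\t"), f)
  expect_error(load_lexicon(f, sch), class = "pragmap_format_error")

  writeLines(c("tag_id\tpattern", "filler.maa\tbogus=x"), f)
  expect_error(load_lexicon(f, sch), class = "pragmap_format_error")

  writeLines(c("tag_id\tpattern", "filler.maa\tsurface=maa",
               "filler.maa\tsurface=maa"), f)
  expect_error(load_lexicon(f, sch), "line",
               class = "pragmap_duplicate_error")
})

test_that("add_entry appends, rejects duplicates, and matches by lemma", {
  sch <- load_scheme()
  lex <- new_lexicon()
  lex <- add_entry(lex, "filler.maa", list(c(surface = "maaa")), scheme = sch)
  expect_equal(length(lex$entries), 1L)
  expect_error(add_entry(lex, "filler.maa", list(c(surface = "maaa"))),
               class = "pragmap_duplicate_error")
  expect_error(add_entry(lex, "no.such", list(c(surface = "x")), scheme = sch),
               class = "pragmap_reference_error")

  # lemma+pos entry matches two inflected surfaces sharing the lemma
  lex <- add_entry(lex, "proctype.verbal",
                   list(c(lemma = "iu", pos = "verb")))
  tok <- data.frame(sentence_id = 1L, index = 0:1,
                    surface = c("itta", "iimasu"), lemma = "iu",
                    pos = "verb", pos_detail = "", speaker = "subject",
                    stringsAsFactors = FALSE)
  doc <- new_document("d", "s", "TD", 20L, "A", tok)
  sp <- annotate_document(doc, lex)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$start, c(0L, 1L))

  # writer round-trips the grown lexicon
  f <- tempfile(fileext = ".tsv")
  write_lexicon(lex, f)
  back <- load_lexicon(f, sch)
  expect_equal(vapply(back$entries, `[[`, character(1), "key"),
               vapply(lex$entries, `[[`, character(1), "key"))
})

test_that("worked-example sentence is annotated with overlapping channels", {
  lex <- load_lexicon(scheme = load_scheme())
  sp <- annotate_document(example_document(), lex)
  sp <- sp[sp$tag_id %in% c("ergativity.middle", "modality.usuality",
                            "filler.nanka"), ]
  expect_equal(nrow(sp), 4L)
  mid <- sp[sp$tag_id == "ergativity.middle", ]
  expect_equal(mid$start, c(0L, 4L))
  expect_equal(mid$end, c(1L, 6L))
  usu <- sp[sp$tag_id == "modality.usuality", ]
  expect_equal(usu$start, 3L)
  expect_equal(usu$end, 6L)
  nk <- sp[sp$tag_id == "filler.nanka", ]
  expect_equal(c(nk$start, nk$end), c(2L, 3L))
  expect_true(all(sp$source == "dictionary"))
  expect_false(any(sp$verified))
})

test_that("empty lexicon annotates nothing; output is deterministic", {
  doc <- example_document()
  expect_equal(nrow(annotate_document(doc, new_lexicon())), 0L)
  lex <- load_lexicon(scheme = load_scheme())
  expect_identical(annotate_document(doc, lex), annotate_document(doc, lex))
})

test_that("matcher equals the brute-force leftmost-longest oracle", {
  set.seed(401)
  sch_tags <- c("filler.maa", "filler.ano", "modality.usuality",
                "negparticle.ne")
  for (case in 1:250) {
    T_ <- sample(1:8, 1)
    alph <- c("a", "b")
    tok <- data.frame(
      sentence_id = 1L, index = seq_len(T_) - 1L,
      surface = sample(alph, T_, replace = TRUE),
      lemma = sample(alph, T_, replace = TRUE),
      pos = sample(c("p", "q"), T_, replace = TRUE),
      pos_detail = "", speaker = "subject", stringsAsFactors = FALSE)
    n_entries <- sample(1:4, 1)
    entries <- list()
    for (i in seq_len(n_entries)) {
      len <- sample(1:3, 1)
      pat <- lapply(seq_len(len), function(j) {
        fields <- sample(c("surface", "lemma", "pos"), sample(1:2, 1))
        vals <- vapply(fields, function(f)
          sample(if (f == "pos") c("p", "q") else alph, 1), character(1))
        setNames(vals, fields)
      })
      entries[[i]] <- list(tag_id = "filler.maa", pattern = pat)
    }
    # dedupe so the lexicon constructor accepts them; channel per test is one
    keys <- vapply(entries, function(e)
      paste(vapply(e$pattern, function(p) paste(names(p), p, collapse = ","),
                   character(1)), collapse = ";"), character(1))
    entries <- entries[!duplicated(keys)]
    lex <- new_lexicon(entries)
    doc <- new_document("d", "s", "TD", 20L, "A", tok)
    got <- annotate_document(doc, lex)
    want <- oracle_leftmost_longest(tok, lex$entries)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("within-channel spans never overlap (property)", {
  set.seed(402)
  lex <- new_lexicon(list(
    list(tag_id = "filler.maa", pattern = list(c(surface = "a"))),
    list(tag_id = "filler.maa", pattern = list(c(surface = "a"), c(surface = "b"))),
    list(tag_id = "filler.maa", pattern = list(c(surface = "b"), c(surface = "a")))))
  for (case in 1:50) {
    T_ <- sample(2:12, 1)
    tok <- data.frame(sentence_id = 1L, index = seq_len(T_) - 1L,
                      surface = sample(c("a", "b"), T_, replace = TRUE),
                      lemma = "x", pos = "p", pos_detail = "",
                      speaker = "subject", stringsAsFactors = FALSE)
    sp <- annotate_document(new_document("d", "s", "TD", 20L, "A", tok), lex)
    if (nrow(sp) > 1) {
      sp <- sp[order(sp$start), ]
      expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
    }
  }
})
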