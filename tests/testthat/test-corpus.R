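# Corpus model: reading, containment, breath-group segmentation, summaries.

test_that("a TSV fixture with three phonemes in one word builds the full hierarchy", {
  path <- write_tsv_fixture(tiny_tokens())
  h <- read_alignment(path, dialect = "tsv")
  expect_s3_class(h, "corpus_hierarchy")
  expect_equal(nrow(tokens_at(h, "phoneme")), 3L)
  expect_equal(nrow(tokens_at(h, "word")), 1L)
  expect_equal(nrow(tokens_at(h, "breath_group")), 1L)
  # containment checked by hand: all three phonemes belong to the one word
  ph <- tokens_at(h, "phoneme")
  w <- tokens_at(h, "word")
  expect_true(all(ph$parent == w$id))
  expect_equal(w$parent, tokens_at(h, "breath_group")$id)
  expect_true(validate_hierarchy(h))
})

test_that("degenerate inputs are refused, not silently emptied", {
  empty <- tiny_tokens()[0, ]
  path <- write_tsv_fixture(empty)
  expect_error(read_alignment(path, dialect = "tsv"), "no tokens")
  # an all-silence file is equally empty
  sil <- tiny_tokens()
  sil$label <- "sil"
  expect_error(corpus_hierarchy(sil), "no non-silence tokens")
  expect_error(read_alignment(tempfile("nope"), dialect = "tsv"), "not found")
})

test_that("a phoneme straddling two words is reported as an orphan", {
  tok <- data.frame(
    speaker = "s",
    level = c("word", "word", "phoneme"),
    label = c("un", "dos", "x"),
    start = c(0.0, 0.2, 0.15),
    end = c(0.2, 0.4, 0.25),
    stringsAsFactors = FALSE
  )
  expect_error(corpus_hierarchy(tok), "orphan|not contained")
})

test_that("malformed TSV and overlapping intervals raise named parse/validation errors", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("speaker\tlevel\tlabel\tstart\tend",
               "s\tword\thola\tzero\t0.5"), bad)
  expect_error(read_alignment(bad, "tsv"), "non-numeric 'start' at data line 1")
  nohdr <- tempfile(fileext = ".tsv")
  writeLines("a\tb\tc", nohdr)
  expect_error(read_alignment(nohdr, "tsv"), "header")
  ovl <- data.frame(speaker = "s", level = "word",
                    label = c("a", "b"), start = c(0, 0.1),
                    end = c(0.3, 0.4), stringsAsFactors = FALSE)
  expect_error(corpus_hierarchy(ovl), "overlap")
})

test_that("breath groups split at pauses and never span speakers", {
  # 5 contiguous words, no gaps -> one BG
  w5 <- data.frame(speaker = "s", level = "word",
                   label = letters[1:5],
                   start = seq(0, 0.8, by = 0.2),
                   end = seq(0.2, 1.0, by = 0.2),
                   stringsAsFactors = FALSE)
  h <- corpus_hierarchy(w5, pause_threshold = 0.3)
  expect_equal(nrow(tokens_at(h, "breath_group")), 1L)
  expect_equal(nrow(tokens_at(h, "word")), 5L)

  # one 0.5 s gap with threshold 0.3 s -> two BGs
  w5b <- w5
  w5b$start[4:5] <- w5b$start[4:5] + 0.5
  w5b$end[4:5] <- w5b$end[4:5] + 0.5
  h2 <- corpus_hierarchy(w5b, pause_threshold = 0.3)
  bg <- tokens_at(h2, "breath_group")
  expect_equal(nrow(bg), 2L)
  words <- tokens_at(h2, "word")
  expect_equal(as.integer(table(words$parent)), c(3L, 2L))
  # BG spans its words
  expect_equal(sort(bg$start), c(0.0, 1.1))
  expect_equal(sort(bg$end), c(0.6, 1.5))

  # interleaved speakers: BGs never span speakers
  h3 <- corpus_hierarchy(two_speaker_tokens(), pause_threshold = 0.3)
  bg3 <- tokens_at(h3, "breath_group")
  w3 <- tokens_at(h3, "word")
  sp_of_bg <- split(w3$speaker, w3$parent)
  expect_true(all(vapply(sp_of_bg, function(s) length(unique(s)) == 1L, TRUE)))
  expect_equal(nrow(bg3), 3L)  # speaker a splits at its 0.5 s pause
})

test_that("segmentation is idempotent and validates its input", {
  h <- corpus_hierarchy(two_speaker_tokens(), pause_threshold = 0.3)
  h2 <- segment_breath_groups(h, pause_threshold = 0.3)
  expect_equal(summary(h2), summary(h))
  expect_equal(tokens_at(h2, "word")[, c("label", "start", "end")],
               tokens_at(h, "word")[, c("label", "start", "end")],
               ignore_attr = TRUE)
  expect_error(segment_breath_groups(h, pause_threshold = -1), "positive")
  neg <- data.frame(speaker = "s", level = "word", label = c("a", "b"),
                    start = c(0, 0.25), end = c(0.3, 0.5),
                    stringsAsFactors = FALSE)
  expect_error(corpus_hierarchy(neg), "overlap")
})

test_that("summaries count tokens, case-folded types and median durations", {
  tok <- data.frame(speaker = "s", level = "word",
                    label = c("el", "El", "mar"),
                    start = c(0, 0.1, 0.3), end = c(0.1, 0.3, 1.2),
                    stringsAsFactors = FALSE)
  s <- summary(corpus_hierarchy(tok))
  w <- s[s$level == "word", ]
  expect_equal(w$n_tokens, 3L)
  expect_equal(w$n_types, 2L)          # "el" and "mar", case-folded
  expect_equal(w$median_duration, 0.2) # durations {0.1, 0.2, 0.9}
})

test_that("generated corpora match the generator's bookkeeping", {
  spec <- synth_spec(vocab_size = 200, seed = 7)
  h <- generate_corpus(spec, 10000)
  s <- summary(h)
  expect_equal(s$n_tokens[s$level == "word"], 10000L)
  truth <- attr(h, "synth")
  expect_lte(s$n_types[s$level == "word"], spec$vocab_size)
  # containment is a partition at both nestings
  tk <- h$tokens
  expect_equal(sum(tk$level == "phoneme"),
               sum(table(tk$parent[tk$level == "phoneme"])))
  expect_equal(as.integer(sum(table(tk$parent[tk$level == "word"]))),
               10000L)
  expect_true(validate_hierarchy(h))
})

test_that("the canonical TSV dialect round-trips a hierarchy exactly", {
  h <- generate_corpus(synth_spec(vocab_size = 50, seed = 3), 500)
  path <- tempfile(fileext = ".tsv")
  write_alignment(h, path)
  h2 <- read_alignment(path, dialect = "tsv")
  for (lv in c("phoneme", "word", "breath_group")) {
    a <- tokens_at(h, lv); b <- tokens_at(h2, lv)
    expect_equal(b$label, a$label)
    expect_equal(b$start, a$start, tolerance = 1e-6)
    expect_equal(b$end, a$end, tolerance = 1e-6)
  }
})

test_that("TextGrid files round-trip through writer and reader", {
  tok <- tiny_tokens()
  h <- corpus_hierarchy(tok)
  tg <- tempfile(fileext = ".TextGrid")
  write_textgrid(h, tg)
  h2 <- read_alignment(tg, dialect = "textgrid", speaker = "spk1")
  expect_equal(tokens_at(h2, "phoneme")$label,
               tokens_at(h, "phoneme")$label)
  expect_equal(tokens_at(h2, "word")$start, tokens_at(h, "word")$start,
               tolerance = 1e-5)
  # tier mapping by custom names
  h3 <- read_alignment(tg, dialect = "textgrid",
                       tier_map = c(phoneme = "PHONEME", word = "Word"),
                       speaker = "x")
  expect_equal(nrow(tokens_at(h3, "phoneme")), 3L)
  expect_error(
    read_alignment(tg, dialect = "textgrid", tier_map = c(word = "ORT")),
    "no tier matches")
  broken <- tempfile(fileext = ".TextGrid")
  writeLines("not a textgrid", broken)
  expect_error(read_alignment(broken, "textgrid"), "ooTextFile")
})
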