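# In-code fixtures: a tiny hand-built aligned corpus and writers for the
# canonical TSV dialect. All numbers chosen so containment can be checked by
# hand.

# one speaker, one word "mar" of three phonemes, contiguous
tiny_tokens <- function() {
  data.frame(
    speaker = "spk1",
    level = c("word", "phoneme", "phoneme", "phoneme"),
    label = c("mar", "m", "a", "r"),
    start = c(0.00, 0.00, 0.08, 0.17),
    end   = c(0.30, 0.08, 0.17, 0.30),
    stringsAsFactors = FALSE
  )
}

# two speakers, several words with a long pause splitting speaker 1
two_speaker_tokens <- function() {
  data.frame(
    speaker = c(rep("a", 3), rep("b", 2)),
    level = "word",
    label = c("el", "mar", "el", "la", "nit"),
    start = c(0.0, 0.2, 1.0, 0.1, 0.35),
    end   = c(0.2, 0.5, 1.3, 0.3, 0.6),
    stringsAsFactors = FALSE
  )
}

write_tsv_fixture <- function(tokens, path = tempfile(fileext = ".tsv")) {
  out <- tokens
  out$start <- sprintf("%.6f", out$start)
  out$end <- sprintf("%.6f", out$end)
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(paste(c("speaker", "level", "label", "start", "end"),
                   collapse = "\t"), con)
  writeLines(do.call(paste,
                     c(unname(out[c("speaker", "level", "label",
                                    "start", "end")]), sep = "\t")), con)
  close(con)
  path
}

# small coupled synthetic corpus shared by law tests
law_test_corpus <- function() {
  spec <- synth_spec(zipf_alpha = 1.42, brevity_lambda = 23.8,
                     vocab_size = 500, seed = 401)
  generate_corpus(spec, 20000)
}
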