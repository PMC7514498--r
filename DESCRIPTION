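Package: speechlaws
Title: Linguistic Laws in Time-Aligned Speech Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of linguistic laws in oral corpora across
    three nested levels (phonemes, words, breath groups). Reads time-aligned
    annotations (Praat TextGrid or a canonical TSV dialect), segments breath
    groups at speech pauses, and fits six laws in both physical (time
    duration) and symbolic (phoneme/character count) units: the lognormality
    law of unit durations with a rescaling-collapse diagnostic, Zipf's
    rank-frequency law by discrete power-law maximum likelihood with
    Clauset-style xmin selection, a two-parameter Yule family for phoneme
    frequencies, Herdan-Heaps vocabulary growth under speaker-order
    permutation, the exponential brevity law with an optimal-coding exponent,
    the size-rank law, and the Menzerath-Altmann law by nonlinear least
    squares. Includes a seeded generator of synthetic corpora with the joint
    statistical structure the laws assume (lognormal phoneme durations, words
    as phoneme concatenations, Zipf-distributed tokens with frequency-size
    coupling) and a coarsening operator emulating finite annotation precision
    and a minimum detectable duration, used to study resolution artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
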