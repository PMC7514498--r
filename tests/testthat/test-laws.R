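# Law analyses over corpus hierarchies, mostly on a shared coupled synthetic
# corpus (500 word types, 20k tokens).

h_law <- law_test_corpus()

test_that("lognormality analysis recovers the generating phoneme parameters", {
  # uncoupled corpus: phoneme durations are i.i.d. lognormal(-3, 2)
  spec <- synth_spec(mu = -3, sigma = 2, coupling = "none",
                     vocab_size = 300, seed = 51)
  h <- generate_corpus(spec, 20000)
  res <- analyze_lognormality(h)
  expect_lt(abs(res$fits$phoneme$mu + 3), 0.02)
  expect_lt(abs(res$fits$phoneme$sigma - 2), 0.03)
  # coarsening strictly degrades the phoneme-level Gaussian collapse
  res2 <- analyze_lognormality(h, coarsen_precision = 0.01,
                               coarsen_tau = 0.03)
  expect_gt(res2$coarsened$phoneme$ks_to_gaussian,
            res2$fits$phoneme$ks_to_gaussian)
})

test_that("levels that cannot be fitted are reported without aborting the others", {
  w <- data.frame(speaker = "s", level = "word",
                  label = sprintf("w%02d", 1:12),
                  start = 0:11 / 5, end = 0:11 / 5 + 0.1 + (0:11) / 100,
                  stringsAsFactors = FALSE)
  h <- corpus_hierarchy(w)
  res <- analyze_lognormality(h)
  expect_s3_class(res$fits$word, "lognormal_fit")
  expect_null(res$fits$phoneme)
  # a degenerate level (all durations identical) is carried as an error
  # object while the other levels still report
  w2 <- w; w2$start <- as.numeric(1:12); w2$end <- w2$start + 0.5
  res2 <- analyze_lognormality(corpus_hierarchy(w2))
  expect_s3_class(res2$fits$word, "fit_error")
})

test_that("Zipf rank tables are order-free and tie-stable", {
  z <- analyze_zipf(h_law)
  expect_true(all(diff(z$words$freq) <= 0))
  expect_equal(sum(z$words$freq), 20000L)
  expect_s3_class(z$word_fit, "power_law_fit")
  expect_s3_class(z$phoneme_fit, "yule_fit")
  # permuting token order leaves the rank-frequency table unchanged
  h2 <- h_law
  set.seed(61)
  h2$tokens <- h2$tokens[sample(nrow(h2$tokens)), ]
  z2 <- analyze_zipf(h2)
  expect_equal(z2$words, z$words)
})

test_that("Herdan growth curves are bounded, monotone, and saturate at beta = 1 for all-new types", {
  # every token a new type: V(L) = L exactly
  w <- data.frame(speaker = rep(c("a", "b"), each = 50), level = "word",
                  label = sprintf("t%03d", 1:100),
                  start = rep(0:49 / 5, 2), end = rep(0:49 / 5 + 0.15, 2),
                  stringsAsFactors = FALSE)
  res <- analyze_herdan(corpus_hierarchy(w), n_permutations = 2, seed = 1,
                        min_tokens = 5)
  expect_equal(res$beta, 1, tolerance = 1e-10)
  expect_true(all(res$curve$V <= res$curve$L))
  expect_true(all(diff(res$curve$V) >= 0))

  # deterministic under a fixed seed
  r1 <- analyze_herdan(h_law, n_permutations = 1, seed = 3)
  r2 <- analyze_herdan(h_law, n_permutations = 1, seed = 3)
  expect_identical(r1$beta, r2$beta)

  # Zipf corpus: sublinear growth in both symbolic and physical units
  r <- analyze_herdan(h_law, n_permutations = 5, seed = 5)
  expect_gt(r$beta, 0); expect_lt(r$beta, 1)
  expect_gt(r$gamma, 0); expect_lt(r$gamma, 1)
  expect_lt(abs(r$beta - r$gamma), 0.03)
})

test_that("brevity analysis couples frequency and size in every unit system", {
  b <- analyze_brevity(h_law, "word")
  expect_equal(sum(b$p_i), 1)
  expect_setequal(names(b$fits), c("duration", "phonemes", "characters"))
  # generated with lambda = 23.8: recovered from raw per-type data
  expect_lt(abs(b$fits$duration$lambda_rate - 23.8) / 23.8, 0.1)
  expect_lt(b$fits$duration$spearman_rho, -0.5)
  expect_false(b$uninformative)
  for (u in c("phonemes", "characters")) {
    expect_gt(b$lambda_D[[u]]$lambda_D, 0)
    expect_lte(b$lambda_D[[u]]$lambda_D, 1)
    expect_gte(b$lambda_D[[u]]$D, 2)
  }
  # uniform type frequencies: no association, flagged uninformative
  w <- data.frame(speaker = "s", level = "word",
                  label = rep(sprintf("w%02d", 1:12), each = 2),
                  start = 0:23 / 2, end = 0:23 / 2 + 0.1 + rep(1:12 / 50, each = 2),
                  stringsAsFactors = FALSE)
  bu <- analyze_brevity(corpus_hierarchy(w), "word")
  expect_true(bu$uninformative)
})

test_that("size-rank law recovers the generator's theta and the alpha/lambda prediction", {
  z <- analyze_zipf(h_law)
  b <- analyze_brevity(h_law, "word")
  sr <- analyze_size_rank(h_law, z, b)
  truth <- attr(h_law, "synth")$spec
  theta_gen <- truth$zipf_alpha / truth$brevity_lambda
  expect_lt(abs(sr$theta - theta_gen) / theta_gen, 0.1)
  expect_equal(sr$theta_predicted, z$word_fit$alpha /
                 b$fits$duration$lambda_rate)
  # unit consistency: fitted theta within 15% of alpha/lambda
  expect_lt(abs(sr$theta - sr$theta_predicted) / sr$theta, 0.15)
  expect_gt(sr$r2, 0.5)
})

test_that("Menzerath analysis fits raw construct-level points at both scale pairs", {
  m <- analyze_menzerath(h_law, "bg_words")
  expect_setequal(names(m$fits), c("duration", "phonemes", "characters"))
  expect_gte(min(m$constructs$n), 1)
  expect_true(all(m$constructs$y_duration > 0))
  mw <- analyze_menzerath(h_law, "word_phonemes")
  expect_s3_class(mw$fits$duration, "menzerath_fit")
  expect_lte(mw$fits$duration$r2, 1)
  # at least 4 distinct construct sizes required
  small <- corpus_hierarchy(data.frame(
    speaker = "s", level = "word", label = c("a", "b"),
    start = c(0, 0.2), end = c(0.2, 0.4), stringsAsFactors = FALSE))
  expect_error(analyze_menzerath(small, "word_phonemes"), "phoneme")
})
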