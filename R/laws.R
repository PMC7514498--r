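# The six per-law analyses over a corpus hierarchy. Each returns a result
# object wrapping the underlying fit(s) plus the per-type or per-construct
# tables they were computed from, so every reported number is traceable.

# per-type table at a level: type key, label, frequency, mean/median token
# duration, phoneme count, character count
.type_table <- function(h, level = "word", size_stat = "mean") {
  tk <- tokens_at(h, level)
  if (nrow(tk) == 0L) stop("no tokens at level ", level)
  key <- .type_key(tk$label)
  agg_fun <- if (size_stat == "median") stats::median else mean
  freq <- as.integer(table(key)[unique(key)])
  names(freq) <- unique(key)
  dur <- tapply(tk$t, key, agg_fun)[names(freq)]
  out <- data.frame(key = names(freq), freq = as.integer(freq),
                    duration = as.numeric(dur), stringsAsFactors = FALSE)
  if (level == "word" && any(h$tokens$level == "phoneme")) {
    nph <- table(h$tokens$parent[h$tokens$level == "phoneme"])
    per_tok <- as.integer(nph[as.character(tk$id)])
    per_tok[is.na(per_tok)] <- 0L
    med <- tapply(per_tok, key, stats::median)[names(freq)]
    out$n_phonemes <- as.numeric(med)
  }
  out$n_characters <- nchar(gsub("[[:punct:][:space:]]", "", out$key))
  out
}

#' Lognormality analysis with collapse diagnostics
#'
#' Fits the lognormal duration model at every level present and reports the
#' Kolmogorov-Smirnov distance of each rescaled (standardized log) sample to
#' N(0,1): if durations are lognormal, rescaled samples at all levels
#' collapse onto the standard Gaussian. Levels with too few tokens (or other
#' fitter errors) are reported as errors without aborting the other levels.
#'
#' @param h a `corpus_hierarchy`
#' @param coarsen_precision,coarsen_tau if both non-`NULL`, the analysis is
#'   repeated on durations degraded by [coarsen()] and reported under
#'   `$coarsened`, a resolution-sensitivity diagnostic
#' @return object of class `lognormality_result`: per-level `lognormal_fit`s
#'   (or error messages) under `$fits`, optionally `$coarsened`
#' @export
analyze_lognormality <- function(h, coarsen_precision = NULL,
                                 coarsen_tau = NULL) {
  stopifnot(inherits(h, "corpus_hierarchy"))
  one_pass <- function(transform) {
    fits <- list()
    for (lv in intersect(.levels, unique(h$tokens$level))) {
      t <- transform(h$tokens$t[h$tokens$level == lv])
      fits[[lv]] <- tryCatch(fit_lognormal(t), error = function(e)
        structure(list(message = conditionMessage(e)), class = "fit_error"))
    }
    fits
  }
  out <- list(fits = one_pass(identity))
  if (!is.null(coarsen_precision) && !is.null(coarsen_tau))
    out$coarsened <- one_pass(function(t)
      coarsen(t, coarsen_precision, coarsen_tau))
  structure(out, class = "lognormality_result")
}

#' Zipf analysis: power law for words, Yule family for phonemes
#'
#' Builds rank-frequency tables at the word and phoneme levels (types keyed
#' by case-folded label; rank ties broken by first occurrence in the sorted
#' count order) and fits the discrete power law to word frequencies and the
#' two-parameter Yule family to phoneme frequencies.
#'
#' @param h a `corpus_hierarchy`
#' @return object of class `zipf_result`: `words`/`phonemes` rank-frequency
#'   data.frames (`rank`, `key`, `freq`), `word_fit` (`power_law_fit`),
#'   `phoneme_fit` (`yule_fit`); fitter errors are surfaced with level
#'   context
#' @export
analyze_zipf <- function(h) {
  stopifnot(inherits(h, "corpus_hierarchy"))
  rank_table <- function(level) {
    tt <- .type_table(h, level)
    tt <- tt[order(-tt$freq, tt$key), , drop = FALSE]
    data.frame(rank = seq_len(nrow(tt)), key = tt$key, freq = tt$freq,
               stringsAsFactors = FALSE)
  }
  with_ctx <- function(expr, what) {
    tryCatch(expr, error = function(e)
      stop("Zipf analysis failed for ", what, ": ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list()
  if (any(h$tokens$level == "word")) {
    out$words <- with_ctx(rank_table("word"), "words")
    out$word_fit <- with_ctx(fit_power_law(out$words$freq), "words")
  }
  if (any(h$tokens$level == "phoneme")) {
    out$phonemes <- with_ctx(rank_table("phoneme"), "phonemes")
    out$phoneme_fit <- with_ctx(fit_yule(out$phonemes$freq), "phonemes")
  }
  if (length(out) == 0L) stop("corpus has neither word nor phoneme tokens")
  structure(out, class = "zipf_result")
}

#' Herdan-Heaps vocabulary growth under speaker-order permutation
#'
#' For each permutation of the speaker concatenation order, walks the word
#' tokens accumulating the token count `L`, the elapsed spoken time `T`
#' (summed word durations) and the vocabulary size `V`, then estimates the
#' scaling exponents of `V(L) ~ L^beta` and `V(T) ~ T^gamma` by least
#' squares on log-log axes. `beta` and `gamma` are means over permutations.
#'
#' @param h a `corpus_hierarchy`
#' @param n_permutations number of speaker-order permutations; default
#'   `min(100, factorial(number of speakers))`
#' @param seed integer seed for the permutation draws
#' @param min_tokens smallest `L` entering the slope fit (the initial
#'   transient is excluded); default 10
#' @param n_eval number of log-spaced curve points used in each slope fit
#' @return object of class `herdan_result`: `beta`, `gamma`, per-permutation
#'   `fits_L`/`fits_T` (`loglog_fit`s) and the first permutation's growth
#'   curve under `$curve` (`L`, `T`, `V`)
#' @export
analyze_herdan <- function(h, n_permutations = NULL, seed = NULL,
                           min_tokens = 10, n_eval = 200) {
  stopifnot(inherits(h, "corpus_hierarchy"))
  words <- tokens_at(h, "word")
  if (nrow(words) == 0L) stop("empty corpus: no word tokens")
  speakers <- unique(words$speaker)
  S <- length(speakers)
  if (is.null(n_permutations))
    n_permutations <- if (S > 5L) 100L else min(100L, factorial(S))
  stopifnot(n_permutations >= 1)

  by_sp <- split(seq_len(nrow(words)), words$speaker)
  keys <- .type_key(words$label)

  .with_seed(seed, {
    fits_L <- vector("list", n_permutations)
    fits_T <- vector("list", n_permutations)
    curve1 <- NULL
    for (pm in seq_len(n_permutations)) {
      ord <- unlist(by_sp[sample(S)], use.names = FALSE)
      k <- keys[ord]
      L <- seq_along(k)
      V <- cumsum(!duplicated(k))
      Tm <- cumsum(words$t[ord])
      idx <- unique(round(exp(seq(log(max(min_tokens, 1)), log(length(k)),
                                  length.out = n_eval))))
      idx <- idx[idx >= 1 & idx <= length(k)]
      fits_L[[pm]] <- fit_loglog(L[idx], V[idx])
      fits_T[[pm]] <- fit_loglog(Tm[idx], V[idx])
      if (pm == 1L) curve1 <- data.frame(L = L[idx], T = Tm[idx], V = V[idx])
    }
    structure(list(
      beta = mean(vapply(fits_L, `[[`, 0, "slope")),
      gamma = mean(vapply(fits_T, `[[`, 0, "slope")),
      fits_L = fits_L, fits_T = fits_T,
      n_permutations = n_permutations, curve = curve1
    ), class = "herdan_result")
  })
}

#' Brevity-law analysis
#'
#' Per type, computes the frequency and the size in every available unit
#' system (mean token duration in seconds; phoneme count; character count of
#' the case-folded label) and fits the exponential brevity law
#' `f ~ exp(-lambda * l)` on the raw per-type data for each unit. For
#' symbolic units it additionally estimates the optimal-coding exponent
#' `lambda_D` by regressing the size `l_i` on the optimal code length
#' `-log_D(p_i)`, where `p_i` is the type probability and `D` the number of
#' distinct symbols of that unit; `lambda_D` in (0, 1] means the sizes sit
#' within a constant factor of optimal non-singular coding (1 = optimal). A
#' value outside the bound is reported with a warning, not censored.
#'
#' @param h a `corpus_hierarchy`
#' @param level `"word"` or `"phoneme"`
#' @param size_stat `"mean"` (default) or `"median"` token duration per type
#' @return object of class `brevity_result`: `types` (per-type table),
#'   `fits` (named list of `exponential_fit` per unit system), `lambda_D`
#'   (named list per symbolic unit: `lambda_D`, `D`, `slope`), and
#'   `uninformative` flag (no frequency variation or no significant
#'   frequency-size association)
#' @export
analyze_brevity <- function(h, level = c("word", "phoneme"),
                            size_stat = c("mean", "median")) {
  stopifnot(inherits(h, "corpus_hierarchy"))
  level <- match.arg(level)
  size_stat <- match.arg(size_stat)
  tt <- .type_table(h, level, size_stat)
  if (nrow(tt) < 10L) stop("fewer than 10 types at level ", level)

  units <- c(duration = "duration")
  if (level == "word") {
    if ("n_phonemes" %in% names(tt) && any(tt$n_phonemes > 0))
      units <- c(units, phonemes = "n_phonemes")
    if (any(tt$n_characters > 0)) {
      units <- c(units, characters = "n_characters")
    } else {
      warning("no orthographic labels: character units disabled")
    }
  }

  fits <- lapply(units, function(col) fit_exponential(tt[[col]], tt$freq))
  names(fits) <- names(units)

  p_i <- tt$freq / sum(tt$freq)
  lamD <- list()
  for (u in setdiff(names(units), "duration")) {
    D <- if (u == "phonemes") {
      length(unique(.type_key(tokens_at(h, "phoneme")$label)))
    } else {
      length(unique(strsplit(paste(tt$key, collapse = ""), "")[[1L]]))
    }
    lstar <- -log(p_i) / log(D)
    sl <- unname(stats::coef(stats::lm(tt[[units[[u]]]] ~ lstar))[2L])
    ld <- 1 / sl
    if (!is.na(ld) && (ld <= 0 || ld > 1))
      warning(sprintf("lambda_D = %.3f for %s units outside (0, 1]", ld, u))
    lamD[[u]] <- list(lambda_D = ld, D = D, slope = sl)
  }

  uninf <- length(unique(tt$freq)) == 1L ||
    is.na(fits$duration$spearman_p) || fits$duration$spearman_p >= 0.05
  structure(list(level = level, types = tt, fits = fits, lambda_D = lamD,
                 p_i = p_i, uninformative = uninf),
            class = "brevity_result")
}

#' Size-rank analysis
#'
#' Fits the size-rank law `l ~ theta * log(r)` on raw per-type data, with
#' ranks from the Zipf analysis (frequency ties broken by descending size,
#' then label) and sizes from the brevity analysis, and compares the fitted
#' `theta` with the value `alpha / lambda` predicted from the Zipf and
#' brevity exponents. The prediction uses the ratio `alpha / lambda`: with
#' the law written `f ~ exp(-lambda l)` and `f ~ r^-alpha`, eliminating `f`
#' gives `l = const + (alpha/lambda) log r`, and published exponent tables
#' are numerically consistent with the ratio.
#'
#' @param h a `corpus_hierarchy`
#' @param zipf a `zipf_result` computed on `h`
#' @param brevity a `brevity_result` computed on `h` at the same level
#' @param unit unit system of `brevity` used for sizes (default
#'   `"duration"`)
#' @return object of class `size_rank_result`: `theta` (fitted slope),
#'   `intercept`, `r2`, `theta_predicted` (`alpha/lambda`), `agreement`
#'   (absolute difference), `table` (per-type rank/size)
#' @export
analyze_size_rank <- function(h, zipf, brevity, unit = "duration") {
  stopifnot(inherits(zipf, "zipf_result"), inherits(brevity, "brevity_result"))
  if (brevity$level != "word")
    stop("size-rank analysis is defined for the word level here")
  col <- switch(unit, duration = "duration", phonemes = "n_phonemes",
                characters = "n_characters",
                stop("unknown unit: ", unit))
  tt <- brevity$types
  tt <- tt[order(-tt$freq, -tt[[col]], tt$key), , drop = FALSE]
  tt$rank <- seq_len(nrow(tt))
  fit <- stats::lm(tt[[col]] ~ log(tt$rank))
  theta <- unname(stats::coef(fit)[2L])
  lam <- brevity$fits[[unit]]$lambda_rate
  pred <- zipf$word_fit$alpha / lam
  structure(list(
    unit = unit, theta = theta,
    intercept = unname(stats::coef(fit)[1L]),
    r2 = .r_squared(fit),
    alpha = zipf$word_fit$alpha, lambda = lam,
    theta_predicted = pred,
    agreement = abs(theta - pred),
    table = tt[, c("rank", "key", "freq", col)]
  ), class = "size_rank_result")
}

#' Menzerath-Altmann analysis
#'
#' For `scale_pair = "bg_words"`: each breath group is a construct of size
#' `n` = its word count, and `y` is the mean size of those words (averaged
#' over tokens) in seconds, phonemes or characters. For
#' `scale_pair = "word_phonemes"`: each word token is a construct of size
#' `n` = its phoneme count and `y` is the mean phoneme duration within it.
#' The law `y(n) = a n^b exp(-c n)` is fitted on the raw construct-level
#' points for each unit system.
#'
#' @param h a `corpus_hierarchy`
#' @param scale_pair `"bg_words"` or `"word_phonemes"`
#' @return object of class `menzerath_result`: `constructs` (raw per-
#'   construct table), `fits` (named list of `menzerath_fit` per unit)
#' @export
analyze_menzerath <- function(h, scale_pair = c("bg_words", "word_phonemes")) {
  stopifnot(inherits(h, "corpus_hierarchy"))
  scale_pair <- match.arg(scale_pair)
  tk <- h$tokens
  if (scale_pair == "bg_words") {
    words <- tk[tk$level == "word", , drop = FALSE]
    if (nrow(words) == 0L || !any(tk$level == "breath_group"))
      stop("bg_words analysis needs word and breath-group levels")
    grp <- words$parent
    n <- as.integer(table(grp))
    ids <- as.integer(names(table(grp)))
    y_dur <- as.numeric(tapply(words$t, grp, mean))
    cons <- data.frame(construct = ids, n = n, y_duration = y_dur)
    if (any(tk$level == "phoneme")) {
      nph <- table(tk$parent[tk$level == "phoneme"])
      per_word <- as.integer(nph[as.character(words$id)])
      per_word[is.na(per_word)] <- 0L
      cons$y_phonemes <- as.numeric(tapply(per_word, grp, mean))
    }
    cons$y_characters <- as.numeric(
      tapply(nchar(gsub("[[:punct:][:space:]]", "", .type_key(words$label))),
             grp, mean))
  } else {
    ph <- tk[tk$level == "phoneme", , drop = FALSE]
    if (nrow(ph) == 0L) stop("word_phonemes analysis needs a phoneme level")
    grp <- ph$parent
    cons <- data.frame(
      construct = as.integer(names(table(grp))),
      n = as.integer(table(grp)),
      y_duration = as.numeric(tapply(ph$t, grp, mean))
    )
  }
  ycols <- grep("^y_", names(cons), value = TRUE)
  fits <- list()
  for (yc in ycols) {
    ok <- cons[[yc]] > 0
    fits[[sub("^y_", "", yc)]] <-
      tryCatch(fit_menzerath(cons$n[ok], cons[[yc]][ok]),
               error = function(e)
                 structure(list(message = conditionMessage(e)),
                           class = "fit_error"))
  }
  structure(list(scale_pair = scale_pair, constructs = cons, fits = fits),
            class = "menzerath_result")
}
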