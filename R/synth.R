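# Seeded generator of synthetic speech corpora carrying the joint statistical
# structure the law analyses assume: lognormal phoneme durations, words as
# concatenations of n phonemes, Zipf-distributed word tokens whose mean
# durations follow the size-rank coupling (hence the brevity law), and
# pause-delimited breath groups. A coarsening operator emulates the finite
# precision and minimum detectable duration of real annotation pipelines.

# evaluate expr under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Truncated geometric distribution on 1..kmax
#'
#' Probability vector proportional to `(1-p)^(k-1) p` on `k = 1..kmax`, with
#' `p` solved so the mean equals `mean`.
#'
#' @param mean target mean (must lie in `(1, (1+kmax)/2)`)
#' @param kmax upper support bound
#' @return numeric probability vector of length `kmax`
#' @export
trunc_geom <- function(mean, kmax) {
  stopifnot(mean > 1, mean < (1 + kmax) / 2)
  m <- function(logit_p) {
    p <- stats::plogis(logit_p)
    w <- (1 - p)^(0:(kmax - 1)) * p
    sum(seq_len(kmax) * w) / sum(w)
  }
  root <- stats::uniroot(function(z) m(z) - mean, c(-20, 20))$root
  p <- stats::plogis(root)
  w <- (1 - p)^(0:(kmax - 1)) * p
  w / sum(w)
}

#' Specify a synthetic corpus
#'
#' Collects the parameters of the generative model. Defaults follow the
#' stochastic duration model used in the resolution study (`mu = -3`,
#' `sigma = 2` for the log-duration Gaussian) and Catalan-like corpus
#' structure elsewhere: Zipf exponent 1.42, brevity rate 23.8 per second,
#' 5000 word types, about 3.75 phonemes per word and 4 words per breath
#' group.
#'
#' @param mu location of the log-duration Gaussian (log-seconds)
#' @param sigma scale of the log-duration Gaussian (> 0)
#' @param n_dist probability vector over phonemes-per-word `n = 1..K`
#'   (used when composing words without frequency-size coupling)
#' @param zipf_alpha Zipf rank-frequency exponent for token sampling
#' @param brevity_lambda frequency-size coupling rate, per second
#' @param vocab_size number of word types (>= 1)
#' @param l_min mean duration of the rank-1 word type, seconds; type mean
#'   durations follow `l_min + (zipf_alpha/brevity_lambda) * log(rank)`
#' @param phon_scale nominal mean phoneme duration (seconds) used to convert
#'   a type's target duration into its phoneme count
#' @param duration_jitter coefficient of variation of a type's token
#'   durations around its mean (lognormal multiplicative noise)
#' @param alphabet_size number of phoneme types (symbol alphabet)
#' @param bg_len_dist probability vector over words-per-breath-group
#' @param n_speakers number of (opaque) speaker labels
#' @param coupling `"size_rank"` imposes the frequency-size coupling through
#'   the size-rank form so Zipf, brevity and size-rank are jointly
#'   consistent; `"none"` composes every word directly from `n_dist` and
#'   i.i.d. lognormal phonemes (exact phoneme-level lognormality, no brevity)
#' @param precision rounding grain for [coarsen()], seconds
#' @param tau minimum detectable duration for [coarsen()], seconds
#' @param coarsen_durations if `TRUE`, [generate_corpus()] coarsens phoneme
#'   durations (then sums), so resolution artifacts propagate to words
#' @param seed integer seed; mandatory for corpus generation
#' @return an object of class `synth_spec`
#' @export
synth_spec <- function(mu = -3, sigma = 2,
                       n_dist = trunc_geom(3.75, 8),
                       zipf_alpha = 1.42, brevity_lambda = 23.8,
                       vocab_size = 5000, l_min = 0.1,
                       phon_scale = 0.08, duration_jitter = 0.05,
                       alphabet_size = 32,
                       bg_len_dist = trunc_geom(4, 20),
                       n_speakers = 4,
                       coupling = c("size_rank", "none"),
                       precision = 0.01, tau = 0.03,
                       coarsen_durations = FALSE,
                       seed = NULL) {
  coupling <- match.arg(coupling)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (vocab_size < 1) stop("vocab_size must be >= 1")
  if (precision <= 0) stop("precision must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  for (nm in c("n_dist", "bg_len_dist")) {
    d <- get(nm)
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8)
      stop(nm, " must be a probability vector over 1..K")
  }
  if (n_dist[1L] < 0 || length(n_dist) < 1L) stop("invalid n_dist")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(
    mu = mu, sigma = sigma, n_dist = n_dist, zipf_alpha = zipf_alpha,
    brevity_lambda = brevity_lambda, vocab_size = as.integer(vocab_size),
    l_min = l_min, phon_scale = phon_scale,
    duration_jitter = duration_jitter,
    alphabet_size = as.integer(alphabet_size),
    bg_len_dist = bg_len_dist, n_speakers = as.integer(n_speakers),
    coupling = coupling, precision = precision, tau = tau,
    coarsen_durations = coarsen_durations, seed = seed
  ), class = "synth_spec")
}

#' Sample phoneme durations
#'
#' I.i.d. draws of `Y = exp(X)` with `X ~ N(mu, sigma^2)`: the lognormal
#' phoneme-duration model.
#'
#' @param spec a [synth_spec()]
#' @param count number of draws (>= 1)
#' @return numeric vector of durations in seconds
#' @export
sample_phonemes <- function(spec, count) {
  stopifnot(inherits(spec, "synth_spec"), count >= 1)
  .with_seed(spec$seed, stats::rlnorm(count, spec$mu, spec$sigma))
}

#' Compose word durations from phoneme parts
#'
#' For each word, draws a phoneme count `n` from `spec$n_dist`, then `n`
#' i.i.d. lognormal phoneme durations; the word duration is their sum
#' `Z = sum(Y_i)`.
#'
#' @param spec a [synth_spec()]
#' @param count number of words (>= 1)
#' @return list with `duration` (numeric, word durations), `n` (integer,
#'   phonemes per word) and `parts` (data.frame `word`, `t` of the phoneme
#'   durations)
#' @export
compose_words <- function(spec, count) {
  stopifnot(inherits(spec, "synth_spec"), count >= 1)
  .with_seed(spec$seed, {
    n <- sample.int(length(spec$n_dist), count, replace = TRUE,
                    prob = spec$n_dist)
    y <- stats::rlnorm(sum(n), spec$mu, spec$sigma)
    idx <- rep(seq_len(count), n)
    z <- as.numeric(rowsum(y, idx))
    list(duration = z, n = n,
         parts = data.frame(word = idx, t = y))
  })
}

#' Coarsen durations to a finite resolution
#'
#' Emulates an annotation pipeline with finite precision and a minimum
#' detectable duration: each value is rounded to the nearest multiple of
#' `precision`, then values below `tau` are raised to `tau`. Idempotent when
#' `tau` is a multiple of `precision`; order preserving.
#'
#' @param durations numeric vector, seconds
#' @param precision rounding grain, seconds (> 0)
#' @param tau duration floor, seconds (>= 0)
#' @return coarsened durations
#' @export
coarsen <- function(durations, precision = 0.01, tau = 0.03) {
  stopifnot(precision > 0, tau >= 0)
  x <- round(durations / precision) * precision
  x[x < tau] <- tau
  x
}

# symbol alphabet for synthetic phoneme labels; symbols must stay distinct
# under case folding since analysis keys types by case-folded label
.synth_alphabet <- function(size) {
  pool <- c(letters, as.character(0:9))
  if (size > length(pool)) stop("alphabet_size too large (max 36)")
  pool[seq_len(size)]
}

#' Generate a full synthetic corpus
#'
#' Builds a vocabulary of `vocab_size` word types with token probabilities
#' `p(r)` proportional to `r^-zipf_alpha` and, under the default
#' `"size_rank"` coupling, type mean durations
#' `l_r = l_min + (zipf_alpha/brevity_lambda) * log(r)` -- the size-rank
#' form, which makes Zipf's law, the brevity law and the size-rank law hold
#' jointly by construction. Each type's phoneme count is `l_r / phon_scale`
#' (rounded, at least 1) and its label is a concatenation of symbols from a
#' power-law-weighted alphabet. Tokens are sampled i.i.d., realized as
#' phoneme concatenations, grouped into breath groups with sizes from
#' `bg_len_dist`, and laid out on a synthetic timeline whose inter-group
#' pauses (0.5 s) exceed the default segmentation threshold.
#'
#' @param spec a [synth_spec()]; `spec$seed` must be set
#' @param n_word_tokens number of word tokens (>= 1)
#' @return a `corpus_hierarchy`; the generating ground truth (type table and
#'   spec) is attached as attribute `"synth"`
#' @export
generate_corpus <- function(spec, n_word_tokens) {
  stopifnot(inherits(spec, "synth_spec"), n_word_tokens >= 1)
  if (is.null(spec$seed)) stop("spec$seed is mandatory for generate_corpus")
  .with_seed(spec$seed, .generate_corpus_impl(spec, as.integer(n_word_tokens)))
}

.generate_corpus_impl <- function(spec, n_tok) {
  V <- spec$vocab_size
  r <- seq_len(V)
  p <- r^(-spec$zipf_alpha); p <- p / sum(p)
  theta <- spec$zipf_alpha / spec$brevity_lambda
  ell <- spec$l_min + theta * log(r)

  if (spec$coupling == "size_rank") {
    n_phon <- pmax(1L, as.integer(round(ell / spec$phon_scale)))
  } else {
    n_phon <- sample.int(length(spec$n_dist), V, replace = TRUE,
                         prob = spec$n_dist)
  }

  # labels: per-type symbol sequences from a power-law-weighted alphabet
  ab <- .synth_alphabet(spec$alphabet_size)
  w_ab <- seq_along(ab)^-1; w_ab <- w_ab / sum(w_ab)
  syms <- lapply(n_phon, function(k) sample(ab, k, replace = TRUE,
                                            prob = w_ab))
  labels <- vapply(syms, paste, "", collapse = "")
  while (anyDuplicated(labels)) {
    dup <- which(duplicated(labels))
    extra <- sample(ab, length(dup), replace = TRUE, prob = w_ab)
    syms[dup] <- Map(c, syms[dup], extra)
    labels[dup] <- vapply(syms[dup], paste, "", collapse = "")
  }
  n_phon <- lengths(syms)

  # token stream
  tok_r <- sample.int(V, n_tok, replace = TRUE, prob = p)
  tok_n <- n_phon[tok_r]
  m <- sum(tok_n)
  parts <- stats::rlnorm(m, spec$mu, spec$sigma)
  tok_id <- rep(seq_len(n_tok), tok_n)
  if (spec$coupling == "size_rank") {
    jit <- spec$duration_jitter
    total <- ell[tok_r] *
      stats::rlnorm(n_tok, -jit^2 / 2, jit)
    raw_sum <- as.numeric(rowsum(parts, tok_id))
    parts <- parts * (total / raw_sum)[tok_id]
  }
  if (spec$coarsen_durations)
    parts <- coarsen(parts, spec$precision, spec$tau)
  total <- as.numeric(rowsum(parts, tok_id))

  # breath-group sizes covering the token stream
  bg_len <- integer(0)
  while (sum(bg_len) < n_tok) {
    draw <- sample.int(length(spec$bg_len_dist),
                       max(64L, ceiling(n_tok / 2)), replace = TRUE,
                       prob = spec$bg_len_dist)
    bg_len <- c(bg_len, draw)
  }
  bg_len <- bg_len[seq_len(which(cumsum(bg_len) >= n_tok)[1L])]
  bg_len[length(bg_len)] <- n_tok - sum(bg_len[-length(bg_len)])
  n_bg <- length(bg_len)
  tok_bg <- rep(seq_len(n_bg), bg_len)
  bg_speaker <- sprintf("spk%02d", (seq_len(n_bg) - 1L) %% spec$n_speakers + 1L)

  # timeline: per speaker cumulative clock, 0.5 s pause between BGs
  pause <- 0.5
  tok_start <- numeric(n_tok); tok_end <- numeric(n_tok)
  bg_start <- numeric(n_bg); bg_end <- numeric(n_bg)
  clock <- numeric(0)
  pos <- 1L
  for (g in seq_len(n_bg)) {
    sp <- bg_speaker[g]
    t0 <- if (sp %in% names(clock)) clock[[sp]] else 0
    idx <- pos:(pos + bg_len[g] - 1L)
    durs <- total[idx]
    ends <- t0 + cumsum(durs)
    tok_start[idx] <- ends - durs
    tok_end[idx] <- ends
    bg_start[g] <- t0
    bg_end[g] <- ends[length(ends)]
    clock[sp] <- ends[length(ends)] + pause
    pos <- pos + bg_len[g]
  }

  # phoneme timestamps inside each token
  ph_end_rel <- stats::ave(parts, tok_id, FUN = cumsum)
  ph_start <- tok_start[tok_id] + ph_end_rel - parts
  ph_end <- tok_start[tok_id] + ph_end_rel
  ph_lab <- unlist(syms[tok_r], use.names = FALSE)
  tok_speaker <- bg_speaker[tok_bg]

  tokens <- rbind(
    data.frame(speaker = bg_speaker, level = "breath_group", label = "",
               start = bg_start, end = bg_end, stringsAsFactors = FALSE),
    data.frame(speaker = tok_speaker, level = "word", label = labels[tok_r],
               start = tok_start, end = tok_end, stringsAsFactors = FALSE),
    data.frame(speaker = tok_speaker[tok_id], level = "phoneme",
               label = ph_lab, start = ph_start, end = ph_end,
               stringsAsFactors = FALSE)
  )
  h <- corpus_hierarchy(tokens, tol = 1e-6)
  attr(h, "synth") <- list(
    spec = spec,
    types = data.frame(rank = r, label = labels, n_phon = n_phon,
                       ell = ell, p = p, stringsAsFactors = FALSE)
  )
  h
}

#' Write a synth spec as a flat key-value config file
#'
#' One `key = value` pair per line; probability vectors are comma-separated
#' over support `1..K`. The seed is mandatory.
#'
#' @param spec a [synth_spec()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_synth_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(spec$seed)) stop("seed is mandatory in a serialized synth_spec")
  fmt <- function(v) {
    if (is.character(v)) v
    else paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
               collapse = ",")
  }
  lines <- vapply(names(spec), function(k) sprintf("%s = %s", k,
                                                   fmt(spec[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a synth spec config file
#'
#' @param path path to a file written by [write_synth_spec()]
#' @return a `synth_spec`
#' @export
read_synth_spec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*[#;]", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$",
                                  lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L)
    stop("config parse error at line ", bad[1L], ": ", lines[bad[1L]])
  vals <- stats::setNames(lapply(kv, function(m) m[3L]),
                          vapply(kv, `[`, "", 2L))
  num <- function(x) as.numeric(strsplit(x, ",")[[1L]])
  args <- list()
  for (k in names(vals)) {
    v <- trimws(vals[[k]])
    args[[k]] <- if (k == "coupling") v
      else if (grepl("^(TRUE|FALSE)$", v)) as.logical(v)
      else num(v)
  }
  if (is.null(args$seed) || anyNA(args$seed))
    stop("seed is mandatory in a synth_spec config")
  args$vocab_size <- as.integer(args$vocab_size)
  args$alphabet_size <- as.integer(args$alphabet_size)
  args$n_speakers <- as.integer(args$n_speakers)
  args$seed <- as.integer(args$seed)
  args$coarsen_durations <- as.logical(args$coarsen_durations)
  do.call(synth_spec, args)
}
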