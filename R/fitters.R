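# Estimation machinery shared by the law analyses: log-rescaling, lognormal
# MLE, discrete power-law MLE with Clauset-style xmin selection, a
# two-parameter Yule family, exponential (brevity) least squares, nonlinear
# Menzerath-Altmann least squares, log-log slope fits and logarithmic
# binning. All fitters are deterministic given identical inputs.

#' Standardize log-durations
#'
#' `t' = (log t - <log t>) / sd(log t)`. If the sample is lognormal the
#' result is standard Gaussian, which is the collapse diagnostic used across
#' linguistic levels.
#'
#' @param sample positive durations
#' @return object of class `rescaled_sample`: list with `values`
#'   (standardized natural-log durations) and `n`
#' @export
rescale_log <- function(sample) {
  if (length(sample) < 2L) stop("need at least 2 values")
  if (any(!is.finite(sample)) || any(sample <= 0))
    stop("all values must be positive and finite")
  lx <- log(sample)
  s <- stats::sd(lx)
  if (s == 0) stop("zero variance in log sample (degenerate)")
  structure(list(values = (lx - mean(lx)) / s, n = length(sample)),
            class = "rescaled_sample")
}

# exact KS statistic of a sample against the standard normal; computed
# directly so tied values (e.g. after coarsening) are handled without noise
.ks_gaussian <- function(x) {
  x <- sort(x)
  n <- length(x)
  cdf <- stats::pnorm(x)
  max(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf))
}

#' Fit a lognormal duration distribution by maximum likelihood
#'
#' Closed-form MLE: `mu` is the mean of the natural logs and `sigma` their
#' standard deviation (maximum-likelihood, i.e. divisor `n`). Also reports
#' the Kolmogorov-Smirnov distance between the rescaled sample and N(0,1)
#' as a lognormality diagnostic.
#'
#' @param sample positive durations (n >= 10)
#' @return object of class `lognormal_fit`: `mu`, `sigma`, `n`,
#'   `ks_to_gaussian`
#' @export
fit_lognormal <- function(sample) {
  if (length(sample) < 10L) stop("need at least 10 values")
  rs <- rescale_log(sample)
  lx <- log(sample)
  n <- length(lx)
  structure(list(
    mu = mean(lx),
    sigma = sqrt(sum((lx - mean(lx))^2) / n),
    n = n,
    ks_to_gaussian = .ks_gaussian(rs$values)
  ), class = "lognormal_fit")
}

# -- discrete power law (Zipf) ----------------------------------------------

# negative log-likelihood of the truncated discrete power law r^-alpha / H
# on support xmin..xmax, for observations `x` with multiplicities `w`
.plaw_negll <- function(alpha, x, w, xmin, xmax) {
  H <- sum(seq.int(xmin, xmax)^(-alpha))
  alpha * sum(w * log(x)) + sum(w) * log(H)
}

.plaw_cdf <- function(alpha, xmin, xmax) {
  p <- seq.int(xmin, xmax)^(-alpha)
  cumsum(p) / sum(p)
}

#' Fit a discrete power law to rank-frequency data by MLE
#'
#' Data are per-type token counts; each type contributes its frequency rank
#' (1 = most frequent) with multiplicity equal to its count, and the model is
#' the discrete power law `p(r) proportional to r^-alpha` on the observed
#' rank support `xmin..max(rank)`. Following Clauset-style model selection,
#' `xmin` is chosen to minimize the Kolmogorov-Smirnov distance between the
#' fitted tail and the data, with the MLE for `alpha` recomputed at each
#' candidate `xmin`.
#'
#' @param freqs positive integer counts per type (>= 10 distinct types)
#' @param xmin_candidates candidate `xmin` ranks scanned (default `1:100`,
#'   clipped so the tail keeps at least 10 distinct ranks)
#' @param fmin minimum count for a rank to enter the fitted support
#'   (default 2). In the region where types occur once or twice, sorting by
#'   count decouples the observed rank from the underlying one (ties are
#'   ordered arbitrarily), which flattens the empirical curve and biases the
#'   exponent downward; those ranks are excluded and the model is truncated
#'   to the retained support. Set `fmin = 1` to fit every observed rank.
#' @return object of class `power_law_fit`: `alpha`, `xmin`, `ks` (KS
#'   distance on the fitted tail), `n_tail` (observations used), `n_types`,
#'   `rmax` (largest rank in the fitted support)
#' @export
fit_power_law <- function(freqs, xmin_candidates = 1:100, fmin = 2) {
  freqs <- as.numeric(freqs)
  if (any(freqs <= 0) || any(freqs != round(freqs)))
    stop("freqs must be positive integer counts")
  if (length(freqs) < 10L) stop("need at least 10 types")
  if (length(unique(freqs)) == 1L)
    stop("all counts equal: no tail to fit")
  f <- sort(freqs, decreasing = TRUE)
  n_types <- length(f)
  rmax <- if (any(f >= fmin)) max(which(f >= fmin)) else 0L
  if (rmax < 10L) rmax <- n_types   # too few multi-token ranks: keep all
  f <- f[seq_len(rmax)]
  r <- seq_len(rmax)
  xmin_candidates <- xmin_candidates[xmin_candidates <= rmax - 10L]
  if (length(xmin_candidates) == 0L) xmin_candidates <- 1L

  cand <- lapply(xmin_candidates, function(xm) {
    keep <- r >= xm
    x <- r[keep]; w <- f[keep]
    opt <- stats::optimize(.plaw_negll, c(1.000001, 20), x = x, w = w,
                           xmin = xm, xmax = rmax, tol = 1e-6)
    emp <- cumsum(w) / sum(w)
    ks <- max(abs(emp - .plaw_cdf(opt$minimum, xm, rmax)))
    list(alpha = opt$minimum, xmin = xm, ks = ks, n_tail = sum(w))
  })
  # parsimony rule: among candidates whose KS is within the KS statistic's
  # own sampling noise (~ n^-1/2) of the minimum, keep the smallest xmin --
  # discarding head ranks is only warranted by a real misfit, not by KS
  # fluctuations of that order
  ks_all <- vapply(cand, `[[`, 0, "ks")
  tol_ks <- 1 / sqrt(cand[[which.min(ks_all)]]$n_tail)
  best <- cand[[which(ks_all <= min(ks_all) + tol_ks)[1L]]]
  structure(c(best, list(n_types = n_types, rmax = rmax)),
            class = "power_law_fit")
}

# -- two-parameter Yule family ----------------------------------------------

# Rank-frequency Yule family used in quantitative linguistics:
#   p(r; a, b) = C(a, b) * b^r * r^-a,   r = 1..rmax,  0 < b <= 1
# normalized over the observed rank support. For b = 1 it degenerates to the
# discrete power law; a = 0 gives a geometric decay.
.yule_negll <- function(par, x, w, rmax) {
  a <- par[1L]
  b <- stats::plogis(par[2L])
  r <- seq_len(rmax)
  logp <- r * log(b) - a * log(r)
  logC <- -log(sum(exp(logp - max(logp)))) - max(logp)
  -(sum(w * (x * log(b) - a * log(x))) + sum(w) * logC)
}

#' Fit the two-parameter Yule family to rank-frequency data by MLE
#'
#' The family is `p(r; a, b)` proportional to `b^r * r^-a` over the observed
#' ranks, a geometric-power ("Yule") rank-frequency form with power exponent
#' `a` (real) and geometric damping `b` in (0, 1]; the same form is printed
#' in every serialized report. Data enter as per-type counts, exactly as in
#' [fit_power_law()]. Estimated numerically (Nelder-Mead on a transformed
#' scale).
#'
#' @param freqs positive integer counts per type (>= 10 distinct types)
#' @return object of class `yule_fit`: `a`, `b`, `loglik`, `n`, `n_types`,
#'   `convergence` (0 = converged)
#' @export
fit_yule <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (any(freqs <= 0) || any(freqs != round(freqs)))
    stop("freqs must be positive integer counts")
  if (length(freqs) < 10L) stop("need at least 10 types")
  if (length(unique(freqs)) == 1L) stop("degenerate sample: all counts equal")
  f <- sort(freqs, decreasing = TRUE)
  x <- seq_along(f)
  rmax <- length(f)
  opt <- stats::optim(c(1, stats::qlogis(0.95)), .yule_negll, x = x, w = f,
                      rmax = rmax, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("Yule MLE did not converge (optim code ", opt$convergence,
         ", ", opt$counts[1L], " evaluations)")
  structure(list(
    a = opt$par[1L], b = stats::plogis(opt$par[2L]),
    loglik = -opt$value, n = sum(f), n_types = rmax,
    convergence = opt$convergence,
    family = "p(r) ~ b^r * r^-a, r = 1..n_types"
  ), class = "yule_fit")
}

#' Yule family log-likelihood at given parameters
#'
#' Evaluates the log-likelihood of the family fitted by [fit_yule()] at
#' arbitrary `(a, b)`, for optimality probes and oracles.
#'
#' @param freqs positive integer counts per type
#' @param a power exponent
#' @param b geometric damping in (0, 1)
#' @return log-likelihood value
#' @export
yule_loglik <- function(freqs, a, b) {
  f <- sort(as.numeric(freqs), decreasing = TRUE)
  -.yule_negll(c(a, stats::qlogis(b)), x = seq_along(f), w = f,
               rmax = length(f))
}


# R^2 on the raw points of a linear fit, without summary.lm's perfect-fit
# warnings on exact data
.r_squared <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  if (ss_tot == 0) {
    if (ss_res <= 1e-20) 1 else NA_real_
  } else 1 - ss_res / ss_tot
}

# -- exponential (brevity) fit ----------------------------------------------

#' Fit the exponential brevity law
#'
#' Least squares of `log f` against size `l` on the raw per-type data:
#' `f ~ prefactor * exp(-lambda * l)`. Types with zero frequency are dropped
#' with a warning. Also reports the Spearman rank correlation between
#' frequency and size (average ranks for ties).
#'
#' @param sizes per-type sizes (seconds, phonemes or characters); >= 0
#' @param freqs per-type frequencies
#' @return object of class `exponential_fit`: `lambda_rate`, `prefactor`,
#'   `r2`, `spearman_rho`, `spearman_p`, `n`
#' @export
fit_exponential <- function(sizes, freqs) {
  if (length(sizes) != length(freqs)) stop("sizes and freqs differ in length")
  if (any(sizes < 0)) stop("sizes must be non-negative")
  drop <- freqs <= 0
  if (any(drop)) {
    warning(sum(drop), " type(s) with zero frequency excluded")
    sizes <- sizes[!drop]; freqs <- freqs[!drop]
  }
  if (length(sizes) < 3L) stop("fewer than 3 usable points")
  fit <- stats::lm(log(freqs) ~ sizes)
  ct <- suppressWarnings(
    stats::cor.test(freqs, sizes, method = "spearman", exact = FALSE))
  structure(list(
    lambda_rate = -unname(stats::coef(fit)[2L]),
    prefactor = exp(unname(stats::coef(fit)[1L])),
    r2 = .r_squared(fit),
    spearman_rho = unname(ct$estimate),
    spearman_p = ct$p.value,
    n = length(sizes)
  ), class = "exponential_fit")
}

# -- Menzerath-Altmann fit ---------------------------------------------------

#' Fit the Menzerath-Altmann law by nonlinear least squares
#'
#' Model `y(n) = a * n^b * exp(-c * n)` fitted to raw `(n, y)` points with
#' the Levenberg-Marquardt algorithm. The default start is
#' `(a, b, c) = (median(y), -0.1, -0.01)`; on non-convergence up to 20
#' seeded jittered restarts are attempted. `r2` is computed against the raw
#' points used in the fit; for an exactly constant `y` reproduced exactly by
#' the model, `r2` is reported as 1 by convention.
#'
#' @param n_values construct sizes (e.g. words per breath group)
#' @param y_values mean constituent sizes (> 0)
#' @return object of class `menzerath_fit`: `a`, `b`, `c`, `r2`,
#'   `inversion_n` (extremum location `b/c`), `n`
#' @export
fit_menzerath <- function(n_values, y_values) {
  if (length(n_values) != length(y_values)) stop("n and y differ in length")
  if (length(unique(n_values)) < 4L) stop("need >= 4 distinct construct sizes")
  if (any(y_values <= 0)) stop("y values must be positive")
  df <- data.frame(n = as.numeric(n_values), y = as.numeric(y_values))
  start <- list(a = stats::median(df$y), b = -0.1, c = -0.01)
  fit <- NULL; tried <- 0L
  starts_log <- sprintf("(a=%.4g, b=%.3g, c=%.3g)", start$a, start$b, start$c)
  repeat {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * n^b * exp(-c * n), data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) || tried >= 20L) break
    tried <- tried + 1L
    jit <- .with_seed(tried, stats::rnorm(3, 0, c(0.5, 0.2, 0.02)))
    start <- list(a = abs(stats::median(df$y) * exp(jit[1L])),
                  b = -0.1 + jit[2L], c = -0.01 + jit[3L])
  }
  if (is.null(fit))
    stop("Menzerath fit did not converge after ", tried,
         " restarts; start points tried from ", starts_log)
  cf <- stats::coef(fit)
  res <- df$y - stats::predict(fit)
  ss_tot <- sum((df$y - mean(df$y))^2)
  ss_res <- sum(res^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res <= 1e-10 * sum(df$y^2)) 1 else NA_real_
  } else 1 - ss_res / ss_tot
  structure(list(
    a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
    r2 = r2,
    inversion_n = if (cf["c"] != 0) unname(cf["b"] / cf["c"]) else NA_real_,
    n = nrow(df)
  ), class = "menzerath_fit")
}

# -- log-log slope fit -------------------------------------------------------

#' Ordinary least squares on log-log axes
#'
#' Fits `log y = intercept + slope * log x`; the scaling-exponent estimator
#' used for vocabulary-growth (Herdan-Heaps) curves.
#'
#' @param x positive values
#' @param y positive values
#' @return object of class `loglog_fit`: `slope`, `intercept`, `r2`, `n`
#' @export
fit_loglog <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(x <= 0) || any(y <= 0)) stop("values must be positive")
  fit <- stats::lm(log(y) ~ log(x))
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = .r_squared(fit),
    n = length(x)
  ), class = "loglog_fit")
}

#' Logarithmic binning
#'
#' Logarithmically spaced bins over the range of `x`; per-bin means of `x`
#' and `y`. Empty bins are dropped. A visualization/diagnostic aid: law fits
#' are always performed on raw data, not on bins.
#'
#' @param x positive values
#' @param y values to average per bin
#' @param n_bins number of bins (>= 2... a single bin returns the overall
#'   mean)
#' @return data.frame with `x` (bin mean of x), `y` (bin mean of y), `n`
#'   (points in bin)
#' @export
bin_log <- function(x, y, n_bins = 20) {
  stopifnot(length(x) == length(y), n_bins >= 1)
  if (any(x <= 0)) stop("x must be positive for logarithmic binning")
  if (n_bins == 1L)
    return(data.frame(x = mean(x), y = mean(y), n = length(x)))
  br <- exp(seq(log(min(x)), log(max(x)), length.out = n_bins + 1L))
  br[1L] <- br[1L] * (1 - 1e-12); br[length(br)] <- br[length(br)] * (1 + 1e-12)
  bin <- cut(x, br, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(x = mean(x[i]), y = mean(y[i]), n = sum(i))
  }))
  rownames(out) <- NULL
  out
}

# -- printing ----------------------------------------------------------------

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Lognormal fit: mu = %.4f, sigma = %.4f (n = %d, KS vs N(0,1) = %.4f)\n",
              x$mu, x$sigma, x$n, x$ks_to_gaussian))
  invisible(x)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Discrete power law: alpha = %.4f (xmin = %d, KS = %.4f, tail n = %d)\n",
              x$alpha, x$xmin, x$ks, x$n_tail))
  invisible(x)
}

#' @export
print.yule_fit <- function(x, ...) {
  cat(sprintf("Yule family %s: a = %.4f, b = %.4f (loglik = %.1f)\n",
              x$family, x$a, x$b, x$loglik))
  invisible(x)
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential law: lambda = %.4f (r2 = %.3f, Spearman rho = %.3f, p = %.2g)\n",
              x$lambda_rate, x$r2, x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' @export
print.menzerath_fit <- function(x, ...) {
  cat(sprintf("Menzerath-Altmann: a = %.4g, b = %.4g, c = %.4g (r2 = %.3f, inversion at n = %.1f)\n",
              x$a, x$b, x$c, x$r2, x$inversion_n))
  invisible(x)
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("Log-log fit: slope = %.4f (r2 = %.3f, n = %d)\n",
              x$slope, x$r2, x$n))
  invisible(x)
}

#' Flatten a fit object to a serializable record
#'
#' @param fit any fit object produced by the package
#' @param law law name
#' @param level linguistic level
#' @param unit unit system
#' @return named list of scalars suitable for JSON serialization
#' @export
as_fit_record <- function(fit, law = NA_character_, level = NA_character_,
                          unit = NA_character_) {
  rec <- c(list(law = law, level = level, unit = unit),
           fit[vapply(fit, function(v) is.numeric(v) || is.character(v),
                      TRUE)])
  rec
}
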