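# Estimation machinery. Oracles: closed forms where they exist, brute-force
# grid searches and Monte Carlo elsewhere.

test_that("rescale_log is exact affine standardization", {
  rs <- rescale_log(c(1, exp(1), exp(2)))
  expect_equal(rs$values, c(-1, 0, 1))
  expect_error(rescale_log(rep(2, 5)), "zero variance")
  expect_error(rescale_log(c(1, -1, 2)), "positive")
  # property: any valid sample standardizes exactly
  set.seed(31)
  for (i in 1:5) {
    v <- rescale_log(rlnorm(50 + i, runif(1, -3, 0), runif(1, 0.2, 2)))$values
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(sd(v) - 1), 1e-10)
  }
})

test_that("lognormal MLE has the closed-form invariances and shrinking error", {
  set.seed(17)
  x <- rlnorm(2000, -1.5, 0.7)
  f <- fit_lognormal(x)
  # scaling the sample by k shifts mu by log k, leaves sigma unchanged
  fk <- fit_lognormal(3 * x)
  expect_equal(fk$mu, f$mu + log(3))
  expect_equal(fk$sigma, f$sigma)
  expect_error(fit_lognormal(rep(exp(1), 12)), "zero variance")
  expect_error(fit_lognormal(c(1, 2)), "at least 10")
  # recovery error shrinks as n grows (3-sigma bands of the closed form)
  for (n in c(1e3, 1e4, 1e5)) {
    xs <- rlnorm(n, -1.62, 0.66)
    fn <- fit_lognormal(xs)
    expect_lt(abs(fn$mu + 1.62), 3 * 0.66 / sqrt(n))
    expect_lt(abs(fn$sigma - 0.66), 3 * 0.66 / sqrt(2 * n))
  }
})

test_that("power-law MLE matches a brute-force likelihood grid on a toy corpus", {
  # 30-type toy corpus sampled from a Zipf distribution
  set.seed(23)
  V <- 30
  p <- (1:V)^-1.6; p <- p / sum(p)
  counts <- tabulate(sample.int(V, 2000, TRUE, prob = p), V)
  counts <- counts[counts > 0]
  fit <- fit_power_law(counts, xmin_candidates = 1L)
  # oracle: direct grid search over the truncated Zipf likelihood, on the
  # same support rule (ranks with at least 2 tokens)
  f <- sort(counts, decreasing = TRUE)
  R0 <- max(which(f >= 2)); if (R0 < 10) R0 <- length(f)
  f <- f[1:R0]; r <- 1:R0
  grid <- seq(1.01, 4, by = 1e-3)
  ll <- vapply(grid, function(a)
    -a * sum(f * log(r)) - sum(f) * log(sum(r^-a)), 0)
  expect_lt(abs(fit$alpha - grid[which.max(ll)]), 1e-3)
  expect_equal(fit$n_tail, sum(f))
})

test_that("power-law MLE refuses degenerate inputs", {
  expect_error(fit_power_law(rep(5, 20)), "no tail")
  expect_error(fit_power_law(1:5), "at least 10")
  expect_error(fit_power_law(c(2.5, 1:10)), "integer")
})

test_that("Yule-family MLE is self-consistent and locally optimal", {
  # sample from the fitted family with known parameters, then refit
  set.seed(29)
  rmax <- 30
  a0 <- 0.6; b0 <- 0.85
  p <- b0^(1:rmax) * (1:rmax)^-a0; p <- p / sum(p)
  counts <- tabulate(sample.int(rmax, 5e4, TRUE, prob = p), rmax)
  fit <- fit_yule(counts)
  expect_lt(abs(fit$a - a0), 0.15)
  expect_lt(abs(fit$b - b0), 0.03)
  # local optimality probe: MLE beats perturbed parameters
  for (d in list(c(0.05, 0), c(-0.05, 0), c(0, 0.02), c(0, -0.02))) {
    expect_gte(fit$loglik,
               yule_loglik(counts, fit$a + d[1], min(fit$b + d[2], 0.999)))
  }
  expect_error(fit_yule(rep(3, 15)), "degenerate")
})

test_that("exponential brevity fit is exact on exact data", {
  f <- fit_exponential(1:3, exp(-(1:3)))
  expect_equal(f$lambda_rate, 1)
  expect_equal(f$prefactor, 1)
  expect_equal(f$r2, 1)
  # strictly decreasing frequency in size: perfect anti-correlation
  f2 <- fit_exponential(c(0.1, 0.5, 0.7, 1.2), c(40, 22, 17, 3))
  expect_equal(f2$spearman_rho, -1)
  expect_warning(f3 <- fit_exponential(1:4, c(8, 3, 0, 1)), "zero frequency")
  expect_equal(f3$n, 3L)
  suppressWarnings(expect_error(fit_exponential(1:3, c(1, 0, 0)),
                                "fewer than 3"))
  expect_error(fit_exponential(c(-1, 1, 2), c(3, 2, 1)), "non-negative")
})

test_that("Menzerath fit recovers noiseless curves and honours the extremum calculus", {
  n <- 1:40
  y <- 0.3 * n^-0.25 * exp(0.02 * n)
  fit <- fit_menzerath(n, y)
  expect_equal(fit$a, 0.3, tolerance = 1e-6)
  expect_equal(fit$b, -0.25, tolerance = 1e-6)
  expect_equal(fit$c, -0.02, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # analytic extremum b/c matches the numeric extremum of the fitted curve
  grid <- seq(1, 40, by = 0.01)
  curve <- fit$a * grid^fit$b * exp(-fit$c * grid)
  expect_lt(abs(grid[which.min(curve)] - fit$inversion_n), 0.011)
  # constant y: b and c vanish, exact fit reported as r2 = 1
  fc <- fit_menzerath(1:10, rep(0.4, 10))
  expect_equal(fc$b, 0, tolerance = 1e-6)
  expect_equal(fc$c, 0, tolerance = 1e-6)
  expect_equal(fc$r2, 1)
  expect_error(fit_menzerath(1:3, c(1, 2, 3)), "4 distinct")
  expect_error(fit_menzerath(1:5, c(1, 2, -1, 1, 2)), "positive")
})

test_that("log-log slope fit recovers exact power laws and is scale invariant", {
  x <- 10^seq(0, 3, length.out = 40)
  f <- fit_loglog(x, x^0.63)
  expect_equal(f$slope, 0.63)
  expect_equal(f$r2, 1)
  expect_equal(fit_loglog(x, rep(2, 40))$slope, 0)
  f2 <- fit_loglog(x * 7, x^0.63)
  expect_equal(f2$slope, f$slope)
  expect_error(fit_loglog(c(-1, 1, 2), c(1, 2, 3)), "positive")
})

test_that("logarithmic binning averages per bin and preserves monotone order", {
  x <- c(1, 2, 4, 8); y <- c(1, 3, 5, 7)
  expect_equal(bin_log(x, y, 1), data.frame(x = 3.75, y = 4, n = 4L))
  # hand-computed two-bin case: breaks at sqrt(8) ~ 2.83
  b2 <- bin_log(x, y, 2)
  expect_equal(b2$y, c(mean(c(1, 3)), mean(c(5, 7))))
  expect_equal(b2$n, c(2L, 2L))
  # monotone y gives monotone binned means; empty bins are dropped
  set.seed(41)
  xs <- sort(rlnorm(100, 0, 1.5)); ys <- sort(runif(100))
  bb <- bin_log(xs, ys, 12)
  expect_true(all(diff(bb$y) >= 0))
  expect_true(all(bb$n >= 1))
  expect_equal(sum(bb$n), 100L)
  # oracle: recompute bin means with an independent loop
  br <- exp(seq(log(min(xs)), log(max(xs)), length.out = 13))
  br[1] <- br[1] * (1 - 1e-12); br[13] <- br[13] * (1 + 1e-12)
  man <- sapply(seq_len(12), function(k) {
    i <- xs > br[k] & xs <= br[k + 1]
    if (any(i)) mean(ys[i]) else NA
  })
  expect_equal(bb$y, man[!is.na(man)])
})
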