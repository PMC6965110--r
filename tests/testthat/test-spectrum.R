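test_that("the occurrence density is exponential with rate alpha", {
  d <- effect_distribution(1 / 30)
  expect_equal(d$alpha, 30)
  expect_equal(effect_pdf(0, d), 30)  # density at 0 equals the rate
  expect_equal(integrate(function(s) effect_pdf(s, d), 0, Inf)$value, 1,
               tolerance = 1e-8)
  expect_equal(integrate(function(s) s * effect_pdf(s, d), 0, Inf)$value,
               1 / 30, tolerance = 1e-8)
  expect_error(effect_pdf(-0.1, d), ">= 0")
  expect_error(effect_distribution(0))
})

test_that("the improvement normalisation makes CDF(0) exactly zero", {
  # hand evaluation: 1/30 - 1/32 + 1/(1500*1531)
  expect_equal(improvement_beta(30, 1500),
               1 / 30 - 1 / 32 + 1 / (1500 * 1531), tolerance = 1e-15)
  expect_equal(improvement_beta(30, Inf), 1 / 30 - 1 / 32)
  for (alpha in c(10, 30, 60)) {
    for (N in c(100, 1500, 15000, Inf)) {
      d <- improvement_distribution(alpha, N)
      expect_equal(improvement_cdf(0, d), 0)
      expect_gt(improvement_cdf(10, d), 0.999)
      s <- seq(0, 2, length.out = 200)
      expect_true(all(diff(improvement_cdf(s, d)) >= 0))
    }
  }
})

test_that("the improvement density is the derivative of the closed-form CDF", {
  d <- improvement_distribution(30, 1500)
  s <- seq(0.005, 0.5, length.out = 40)
  h <- 1e-6
  fd <- (improvement_cdf(s + h, d) - improvement_cdf(s - h, d)) / (2 * h)
  expect_equal(improvement_pdf(s, d), fd, tolerance = 1e-5)
  expect_true(all(improvement_pdf(s, d) >= 0))
  expect_equal(integrate(function(x) improvement_pdf(x, d), 0, Inf)$value, 1,
               tolerance = 1e-6)
})

test_that("the closed-form CDF approximates the occurrence-times-fixation product", {
  d <- improvement_distribution(30, 1500)
  s <- c(0.01, 0.05, 0.1, 0.2, 0.4, 0.7, 1)
  gap <- abs(improvement_cdf(s, d) - product_density_cdf(s, 30, 1500))
  expect_lt(max(gap), 0.02)   # the approximation is in fact ~5e-4 here
})

test_that("inverse-CDF sampling reproduces the closed-form distribution", {
  d <- improvement_distribution(30, 1500)
  q <- improvement_quantile(c(0, 0.25, 0.5, 0.99), d)
  expect_equal(improvement_cdf(q, d), c(0, 0.25, 0.5, 0.99), tolerance = 1e-8)
  set.seed(71)
  x <- sample_improvement(1e5, d)
  expect_true(all(x > 0))
  ks <- suppressWarnings(
    ks.test(x, function(s) improvement_cdf(s, d))$statistic)
  expect_lt(ks, 0.01)
  # mean against the independently integrated product density
  dens <- function(x)
    30 * exp(-30 * x) * vapply(x, function(si)
      fixation_probability_closed(1 / 3000, si, 1500), 0)
  Z <- integrate(dens, 0, Inf, rel.tol = 1e-10)$value
  mu <- integrate(function(x) x * dens(x), 0, Inf, rel.tol = 1e-10)$value / Z
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
})

test_that("the exponential MLE is the sample mean, with flagged degenerate SE", {
  f <- fit_exponential_mle(effect_sample(c(0.1, 0.3)))
  expect_equal(f$e_delta1, 0.2)
  set.seed(81)
  eff <- rexp(500, 30)
  f2 <- fit_exponential_mle(effect_sample(eff))
  expect_identical(f2$e_delta1, mean(eff))  # exact identity, not approximate
  f1 <- fit_exponential_mle(effect_sample(0.5))
  expect_equal(f1$e_delta1, 0.5)
  expect_true(is.na(attr(f1, "se")))
  expect_error(fit_exponential_mle(effect_sample(numeric())), "empty")
  expect_error(fit_exponential_mle(effect_sample(0.2, kind = "preobserved")),
               "random")
})

test_that("least-squares fitting recovers the rate from exact bins", {
  alpha <- 37
  edges <- seq(0, 0.4, by = 0.05)
  prob <- exp(-alpha * edges[-length(edges)]) - exp(-alpha * edges[-1])
  bins <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                     count = round(1e7 * prob))
  sample <- effect_sample(0.01, bins = bins)
  f <- fit_exponential_lsq(sample)
  expect_equal(f$alpha, 37, tolerance = 1e-3)
  fd <- fit_exponential_lsq(sample, target = "density")
  expect_equal(fd$alpha, 37, tolerance = 0.05)  # midpoint approximation
  too_few <- effect_sample(0.01, bins = bins[1:2, ])
  expect_error(fit_exponential_lsq(too_few), "3 bins")
})
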