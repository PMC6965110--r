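test_that("generators are pure functions of (spec, seed)", {
  spec <- synthetic_spec(n_random = 100, n_preobserved = 100, N = 1500,
                         seed = 4242)
  a <- generate_random_effects(spec)
  b <- generate_random_effects(spec)
  expect_identical(a, b)
  expect_identical(generate_preobserved_effects(spec),
                   generate_preobserved_effects(spec))
  # the caller's RNG stream is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_random_effects(spec)); x2 <- runif(1)
  expect_identical(x1, x2)
  # empty samples
  empty <- synthetic_spec(n_random = 0, n_preobserved = 0, seed = 1)
  expect_length(generate_random_effects(empty)$effects, 0)
  expect_length(generate_preobserved_effects(empty)$effects, 0)
})

test_that("random effects have the requested exponential mean", {
  spec <- synthetic_spec(e_delta1 = 1 / 30, n_random = 1e5, seed = 7)
  eff <- generate_random_effects(spec)$effects
  se <- sd(eff) / sqrt(length(eff))
  expect_lt(abs(mean(eff) - 1 / 30), 3 * se)
})

test_that("preobserved effects follow the improvement distribution", {
  spec <- synthetic_spec(e_delta1 = 1 / 30, n_random = 1e5,
                         n_preobserved = 1e5, N = 1500, seed = 8)
  pre <- generate_preobserved_effects(spec)$effects
  d <- improvement_distribution(30, 1500)
  ks <- suppressWarnings(
    ks.test(pre, function(s) improvement_cdf(s, d))$statistic)
  expect_lt(ks, 0.01)
  # fixation filters for larger effects
  rnd <- generate_random_effects(spec)$effects
  expect_gt(mean(pre), mean(rnd))
})

test_that("binning preserves counts and places effects correctly", {
  s <- bin_effects(effect_sample(0.15), c(0, 0.1, 0.2))
  expect_equal(s$bins$count, c(0, 1))
  set.seed(9)
  big <- effect_sample(rexp(5000, 30))
  binned <- bin_effects(big, seq(0, 1, by = 0.02), overflow = "extend")
  expect_equal(sum(binned$bins$count), 5000)
  expect_error(bin_effects(big, c(0, 0.2, 0.1)), "increasing")
  expect_error(bin_effects(effect_sample(c(0.05, 0.5)), c(0, 0.1)), "outside")
  ext <- bin_effects(effect_sample(c(0.05, 0.5)), c(0, 0.1),
                     overflow = "extend")
  expect_equal(sum(ext$bins$count), 2)
  expect_equal(ext$bins$upper[nrow(ext$bins)], Inf)
})

test_that("binned-then-fit recovers the rate on dense zero-noise samples", {
  # quantile-spaced pseudo-sample: empirical bins match exponential bins
  alpha <- 30
  eff <- qexp(ppoints(20000), rate = alpha)
  binned <- bin_effects(effect_sample(eff), seq(0, 0.3, by = 0.03),
                        overflow = "extend")
  f <- fit_exponential_lsq(binned)
  expect_equal(f$alpha, alpha, tolerance = 0.01)
})

test_that("effects tables round-trip through the delimited format", {
  spec <- synthetic_spec(n_random = 50, seed = 10)
  s <- generate_random_effects(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_effects_table(s, path)
  back <- read_effects_table(path)
  expect_equal(back$effects, s$effects, tolerance = 1e-12)
  expect_equal(back$kind, "random")
  # counts expand to repeated observations
  writeLines(c("# comment line", "effect,count", "0.1,2", "0.3,1"), path)
  expect_equal(read_effects_table(path)$effects, c(0.1, 0.1, 0.3))
  # malformed input is reported with its data line
  writeLines(c("effect", "0.2", "-0.1"), path)
  expect_error(read_effects_table(path), "line 2")
  writeLines(c("size", "0.2"), path)
  expect_error(read_effects_table(path), "'effect' column")
})

test_that("MLE recovery attains nominal 3-SE coverage on synthetic samples", {
  hits <- vapply(seq_len(100), function(i) {
    spec <- synthetic_spec(e_delta1 = 1 / 30, n_random = 1000, seed = 1000 + i)
    f <- fit_exponential_mle(generate_random_effects(spec))
    abs(f$e_delta1 - 1 / 30) <= 3 * attr(f, "se")
  }, TRUE)
  expect_gte(sum(hits), 93)
})
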