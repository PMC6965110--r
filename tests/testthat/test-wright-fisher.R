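test_that("boundary frequencies are absorbing", {
  set.seed(11)
  expect_equal(wf_next_frequency(rep(0, 50), scheme_dominant(0.5), 100),
               rep(0, 50))
  expect_equal(wf_next_frequency(rep(1, 50), scheme_dominant(0.5), 100),
               rep(1, 50))
  r1 <- wf_run_to_absorption(1, scheme_dominant(0.5), population(100))
  expect_true(r1$fixed)
  expect_equal(r1$generations, 0L)
  r0 <- wf_run_to_absorption(0, scheme_dominant(0.5), population(100))
  expect_false(r0$fixed)
  expect_equal(r0$generations, 0L)
})

test_that("the selection-weighted expected frequency has the right semantics", {
  # neutrality: expected next frequency equals p exactly
  p <- c(0.1, 0.35, 0.8)
  expect_equal(wf_expected_frequency(p, scheme_neutral()), p)
  # full dominance with s = 1 at low p: carriers contribute ~twice per capita
  p <- 1e-4
  ps <- wf_expected_frequency(p, scheme_dominant(1))
  expect_equal((ps / p) / ((1 - ps) / (1 - p)), 2, tolerance = 1e-3)
  expect_error(wf_expected_frequency(0.5, selection_scheme(s_het = -1, s_hom = -1)),
               NA)  # fitness exactly 0 is allowed
})

test_that("neutral one-generation transitions form a martingale", {
  set.seed(21)
  N <- 50
  p <- 0.3
  reps <- 1e5
  nxt <- wf_next_frequency(rep(p, reps), scheme_neutral(), N)
  se <- sqrt(p * (1 - p) / (2 * N)) / sqrt(reps)
  expect_lt(abs(mean(nxt) - p), 3 * se)
})

test_that("identical seeds yield identical runs and estimates", {
  sch <- scheme_semidominant(0.1)
  pop <- population(50)
  set.seed(99)
  a <- wf_run_to_absorption(1 / 100, sch, pop, keep_trajectory = TRUE)
  set.seed(99)
  b <- wf_run_to_absorption(1 / 100, sch, pop, keep_trajectory = TRUE)
  expect_identical(a, b)
  set.seed(5)
  e1 <- wf_fixation_stats(1 / 100, sch, pop, replicates = 500)
  set.seed(5)
  e2 <- wf_fixation_stats(1 / 100, sch, pop, replicates = 500)
  expect_identical(e1, e2)
})

test_that("runs hitting the generation cap are censored, not counted as losses", {
  set.seed(3)
  r <- wf_run_to_absorption(0.5, scheme_neutral(), population(5000),
                            max_generations = 3)
  expect_true(r$censored)
  expect_false(r$fixed)
  set.seed(3)
  est <- wf_fixation_stats(0.5, scheme_neutral(), population(2000),
                           replicates = 200, max_generations = 5)
  expect_equal(est$n_censored, 200L)
  expect_true(is.na(est$p_fix))
})

test_that("censoring is negligible at the default 100N generation cap", {
  set.seed(31)
  est <- wf_fixation_stats(1 / 100, scheme_neutral(), population(50),
                           replicates = 1e5)
  expect_lt(est$n_censored / est$replicates, 0.001)
  # neutral fixation probability equals p0
  expect_lt(abs(est$p_fix - 0.01), 3 * est$p_fix_se)
})

test_that("simulated fixation statistics match the exact chain oracle", {
  set.seed(41)
  N <- 50
  sch <- scheme_semidominant(0.05)
  ch <- exact_wf_chain(N, sch)$single
  est <- wf_fixation_stats(1 / (2 * N), sch, population(N), replicates = 4e4)
  expect_lt(abs(est$p_fix - ch$u), 3 * est$p_fix_se)
  expect_lt(abs(est$t_fix_mean - ch$t_cond), 3 * est$t_fix_se)
})

test_that("neutral fixation from p0 = 1/2 is symmetric", {
  set.seed(51)
  est <- wf_fixation_stats(0.5, scheme_neutral(), population(50),
                           replicates = 2e4)
  expect_lt(abs(est$p_fix - 0.5), 3 * est$p_fix_se)
})

test_that("time estimates are flagged unavailable when no run fixes", {
  set.seed(61)
  est <- wf_fixation_stats(1 / 100, scheme_dominant(-0.8), population(50),
                           replicates = 300)
  expect_equal(est$n_fixed, 0L)
  expect_true(is.na(est$t_fix_mean))
  expect_equal(est$p_fix, 0)
})

test_that("p0 must sit on the allele-count lattice", {
  expect_error(wf_run_to_absorption(0.123, scheme_neutral(), population(100)),
               "multiple of 1/\\(2N\\)")
})
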