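test_that("drift and variance terms match hand-evaluated values", {
  # haploid pair
  expect_equal(mean_change_haploid(0.5, 1), 1 / 6)
  expect_equal(mean_change_haploid(c(0, 1), 0.7), c(0, 0))
  expect_equal(variance_haploid(c(0, 1), 0.3, 100), c(0, 0))
  expect_equal(variance_haploid(0.5, 0, 1500), 1 / 6000)
  expect_equal(variance_haploid(0.5, 1, 1500), (0.25 / 3000) * (3 / 1.5))
  # Kimura pair
  expect_equal(mean_change_kimura(0.5, scheme_semidominant(0.1)), 0.025)
  expect_equal(mean_change_kimura(0.5, scheme_recessive(0.2)), 0.025)
  expect_equal(mean_change_kimura(c(0, 1), scheme_dominant(0.4)), c(0, 0))
  expect_equal(variance_kimura(0.5, 1500), 1 / 12000)
  expect_equal(variance_kimura(0.3, 777), variance_kimura(0.7, 777))
  # domain errors
  expect_error(mean_change_haploid(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(variance_kimura(1.2, 100), "\\[0, 1\\]")
})

test_that("closed-form fixation probability handles limits and known values", {
  expect_equal(fixation_probability_closed(0.3, 0, 1500), 0.3)
  expect_equal(fixation_probability_closed(0.3, 1e-15, 1500), 0.3)
  expect_equal(fixation_probability_closed(1, 0.5, 100), 1)
  expect_equal(fixation_probability_closed(0, 0.5, 100), 0)
  # hand evaluation: N = 1500, s = 1, p0 = 1/(2N):
  # (1 - exp(-2/3)) / (1 - exp(-2000)) = 0.4865829...
  expect_equal(fixation_probability_closed(1 / 3000, 1, 1500),
               -expm1(-2 / 3), tolerance = 1e-12)
  expect_error(fixation_probability_closed(0.5, -1, 100), "> -1")
})

test_that("every fixation-probability route returns p0 under neutrality", {
  pop <- population(400)
  for (p0 in c(0.25, single_mutant_p0(pop))) {
    expect_equal(fixation_probability_closed(p0, 0, pop$N), p0)
    expect_equal(fixation_probability_quadrature(p0, scheme_neutral(), pop,
                                                 model = "kimura"), p0)
    expect_equal(fixation_probability_quadrature(p0, scheme_neutral(), pop,
                                                 model = "haploid"), p0)
    expect_equal(fixation_probability_frequency_dependent(p0, 0, 0, pop), p0)
  }
})

test_that("closed form and haploid-route quadrature agree on a parameter grid", {
  for (N in c(100, 1500, 15000)) {
    pop <- population(N)
    p0 <- single_mutant_p0(pop)
    for (s in c(0.01, 0.1, 0.5, 1)) {
      closed <- fixation_probability_closed(p0, s, N)
      quad <- fixation_probability_quadrature(p0, scheme_semidominant(s), pop,
                                              model = "auto")
      expect_lt(abs(quad / closed - 1), 0.01,
                label = sprintf("relative gap at N=%d, s=%g", N, s))
    }
  }
})

test_that("Kimura-route quadrature matches the exact Wright-Fisher chain", {
  # deterministic oracle: dense absorbing-chain solve, no MC noise. The
  # diffusion bias shrinks with N, so the frequency-dependent cell (whose
  # effective selection is strongest) uses the larger population.
  cells <- list(list(N = 50, sch = scheme_semidominant(0.02)),
                list(N = 50, sch = scheme_dominant(0.02)),
                list(N = 50, sch = scheme_recessive(0.5)),
                list(N = 100, sch = scheme_frequency_dependent(1)))
  for (cell in cells) {
    pop <- population(cell$N)
    u_chain <- exact_wf_chain(cell$N, cell$sch)$single$u
    u_quad <- fixation_probability_quadrature(single_mutant_p0(pop), cell$sch,
                                              pop, model = "kimura")
    expect_lt(abs(u_quad / u_chain - 1), 0.03, label = cell$sch$label)
  }
})

test_that("fixation probability is monotone in p0 and in s", {
  pop <- population(300)
  p0s <- c(0.001, 0.01, 0.1, 0.3, 0.7, 1)
  u <- fixation_probability_quadrature(p0s, scheme_semidominant(0.1), pop)
  expect_true(all(diff(u) >= -1e-12))
  p0 <- single_mutant_p0(pop)
  us <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.5), function(s)
    fixation_probability_quadrature(p0, scheme_dominant(s), pop,
                                    model = "kimura"), 0)
  expect_true(all(diff(us) > 0))
})

test_that("dominance ordering holds at equal homozygote advantage", {
  pop <- population(500)
  p0 <- single_mutant_p0(pop)
  s_hom <- 0.2
  u_rec <- fixation_probability_quadrature(p0, scheme_recessive(s_hom), pop,
                                           model = "kimura")
  u_semi <- fixation_probability_quadrature(p0, scheme_semidominant(s_hom / 2),
                                            pop, model = "kimura")
  u_dom <- fixation_probability_quadrature(
    p0, selection_scheme(s_het = s_hom, s_hom = s_hom), pop, model = "kimura")
  expect_lt(u_rec, u_semi)
  expect_lt(u_semi, u_dom)
})

test_that("frequency-dependent selection strongly suppresses fixation", {
  pop <- population(1500)
  p0 <- single_mutant_p0(pop)
  u_fd <- fixation_probability_frequency_dependent(p0, 0.5, 1.0, pop)
  u_const <- fixation_probability_quadrature(p0, scheme_semidominant(0.5), pop,
                                             model = "kimura")
  expect_lt(u_fd, u_const)
  expect_lt(u_fd / u_const, 0.5)  # "much lower", not marginally lower
})
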