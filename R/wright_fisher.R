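#' One generation of diploid Wright-Fisher sampling
#'
#' Under Hardy-Weinberg random mating at mutant allele frequency `p`, the
#' selection-weighted expected frequency in the next generation is
#' \deqn{p^* = \frac{p^2 (1+s_{hom}) + p(1-p)(1+s_{het})}
#'                  {p^2 (1+s_{hom}) + 2 p (1-p)(1+s_{het}) + (1-p)^2},}
#' and the next allele count is drawn binomially from `2N` trials with
#' success probability `p*`. Frequency-dependent coefficients are evaluated
#' at the current `p`. Frequencies 0 and 1 are absorbing.
#'
#' @param p Current allele frequency (vectorised; each a multiple of
#'   `1/(2N)` in a faithful simulation, though any value in `[0,1]` is
#'   accepted).
#' @param scheme A [selection_scheme()].
#' @param N Population size in diploid individuals.
#' @return Next-generation allele frequency (same length as `p`). Uses the
#'   current R random number stream; call [set.seed()] for reproducibility.
#' @export
wf_next_frequency <- function(p, scheme, N) {
  stopifnot(N >= 2, N == round(N))
  ps <- wf_expected_frequency(p, scheme)
  stats::rbinom(length(p), 2L * N, ps) / (2 * N)
}

#' @rdname wf_next_frequency
#' @export
wf_expected_frequency <- function(p, scheme) {
  check_frequency(p)
  co <- scheme_coefficients(scheme, p)
  w_het <- 1 + co$s_het
  w_hom <- 1 + co$s_hom
  if (any(w_het < 0) || any(w_hom < 0))
    stop("genotype fitnesses 1 + s must be nonnegative")
  num <- p^2 * w_hom + p * (1 - p) * w_het
  den <- p^2 * w_hom + 2 * p * (1 - p) * w_het + (1 - p)^2
  out <- num / den
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

#' Run one Wright-Fisher lineage to absorption
#'
#' Iterates [wf_next_frequency()] from `p0` until the mutant allele is lost
#' (`p = 0`) or fixed (`p = 1`), or until `max_generations` is reached, in
#' which case the run is flagged as censored rather than counted as a loss.
#'
#' @param p0 Initial frequency, a multiple of `1/(2N)`.
#' @param scheme A [selection_scheme()].
#' @param pop A [population()] (census size `N` drives the sampling).
#' @param max_generations Cap on simulated generations (default `100 * N`).
#' @param keep_trajectory If `TRUE`, record the full frequency path.
#' @return An object of class `"wf_run"` with fields `fixed` (logical),
#'   `generations` (integer), `censored` (logical) and optionally
#'   `trajectory`.
#' @export
#' @examples
#' set.seed(1)
#' wf_run_to_absorption(1 / 200, scheme_dominant(0.5), population(100))
wf_run_to_absorption <- function(p0, scheme, pop,
                                 max_generations = 100L * pop$N,
                                 keep_trajectory = FALSE) {
  stopifnot(inherits(pop, "population"), length(p0) == 1L,
            max_generations >= 1)
  check_frequency(p0, "p0")
  count0 <- p0 * 2 * pop$N
  if (abs(count0 - round(count0)) > 1e-9)
    stop("p0 must be a multiple of 1/(2N)")
  p <- p0
  gen <- 0L
  traj <- if (keep_trajectory) p0 else NULL
  while (p > 0 && p < 1 && gen < max_generations) {
    p <- wf_next_frequency(p, scheme, pop$N)
    gen <- gen + 1L
    if (keep_trajectory) traj <- c(traj, p)
  }
  structure(list(fixed = p == 1, censored = p > 0 && p < 1,
                 generations = gen, final_frequency = p, trajectory = traj),
            class = "wf_run")
}

#' @export
print.wf_run <- function(x, ...) {
  cat(sprintf("Wright-Fisher run: %s after %d generations%s\n",
              if (x$censored) "censored" else if (x$fixed) "fixed" else "lost",
              x$generations, if (x$censored) " (cap reached)" else ""))
  invisible(x)
}

#' Monte-Carlo fixation statistics from replicate Wright-Fisher runs
#'
#' Runs `replicates` independent lineages (vectorised across replicates) and
#' aggregates the fixation fraction with its binomial standard error and the
#' mean absorption time of fixed runs with its standard error. Censored runs
#' (cap reached) are excluded from both numerator and denominator of the
#' fixation fraction and reported separately.
#'
#' @inheritParams wf_run_to_absorption
#' @param replicates Number of independent lineages (`>= 100`).
#' @return An object of class `"wf_estimate"`: `p_fix`, `p_fix_se`,
#'   `n_fixed`, `t_fix_mean`, `t_fix_se` (both `NA` when no run fixed),
#'   `n_censored`, `replicates`.
#' @export
#' @examples
#' set.seed(1)
#' wf_fixation_stats(1 / 100, scheme_semidominant(0.05), population(50),
#'                   replicates = 1000)
wf_fixation_stats <- function(p0 = single_mutant_p0(pop), scheme, pop,
                              replicates = 1e5,
                              max_generations = 100L * pop$N) {
  stopifnot(inherits(pop, "population"), replicates >= 100)
  check_frequency(p0, "p0")
  count0 <- p0 * 2 * pop$N
  if (abs(count0 - round(count0)) > 1e-9)
    stop("p0 must be a multiple of 1/(2N)")
  n2 <- 2L * pop$N
  p <- rep.int(p0, replicates)
  active <- rep.int(TRUE, replicates)
  gen_absorbed <- integer(replicates)
  gen <- 0L
  while (any(active) && gen < max_generations) {
    idx <- which(active)
    p[idx] <- wf_next_frequency(p[idx], scheme, pop$N)
    gen <- gen + 1L
    done <- idx[p[idx] == 0 | p[idx] == 1]
    gen_absorbed[done] <- gen
    active[done] <- FALSE
  }
  censored <- active
  fixed <- !censored & p == 1
  lost <- !censored & p == 0
  n_obs <- sum(fixed) + sum(lost)
  pf <- if (n_obs > 0) sum(fixed) / n_obs else NA_real_
  pf_se <- if (n_obs > 0) sqrt(pf * (1 - pf) / n_obs) else NA_real_
  tf <- gen_absorbed[fixed]
  structure(list(
    p_fix = pf, p_fix_se = pf_se, n_fixed = sum(fixed),
    t_fix_mean = if (length(tf) > 0) mean(tf) else NA_real_,
    t_fix_se = if (length(tf) > 1)
      stats::sd(tf) / sqrt(length(tf)) else NA_real_,
    n_censored = sum(censored), replicates = replicates,
    scheme = scheme, pop = pop, p0 = p0),
    class = "wf_estimate")
}

#' @export
print.wf_estimate <- function(x, ...) {
  cat(sprintf("Wright-Fisher estimate (%d replicates, scheme %s, N = %d):\n",
              x$replicates, x$scheme$label, x$pop$N))
  cat(sprintf("  p_fix = %.5g +/- %.3g (binomial SE), %d fixed runs\n",
              x$p_fix, x$p_fix_se, x$n_fixed))
  if (!is.na(x$t_fix_mean))
    cat(sprintf("  mean fixation time (fixed runs) = %.5g +/- %.3g generations\n",
                x$t_fix_mean, if (is.na(x$t_fix_se)) 0 else x$t_fix_se))
  else
    cat("  mean fixation time unavailable (no fixed runs)\n")
  if (x$n_censored > 0)
    cat(sprintf("  %d censored runs (generation cap reached)\n", x$n_censored))
  invisible(x)
}

#' Realised per-capita offspring ratio of carriers to wild type
#'
#' Measures the semantics of the selection coefficient directly in the
#' simulator: from a fixed starting allele count, many one-generation
#' transitions are drawn and the mean per-allele offspring number of mutant
#' carriers is divided by that of wild-type alleles. At `s = 1` (full
#' dominance) and low frequency this ratio converges to 2 - carriers leave
#' on average twice the offspring of the wild type.
#'
#' @param scheme A [selection_scheme()].
#' @param N Population size in diploid individuals.
#' @param p Frequency at which the ratio is probed (low; default `1/(2N)`
#'   times 10 for a stable denominator).
#' @param transitions Number of independent one-generation transitions.
#' @return A list with `ratio`, its Monte-Carlo standard error `se`, the
#'   expected ratio under the sampling kernel, and inputs.
#' @export
wf_fitness_ratio <- function(scheme, N, p = min(10 / (2 * N), 0.05),
                             transitions = 1e5) {
  stopifnot(N >= 2, transitions >= 100)
  check_frequency(p)
  x0 <- round(p * 2 * N)
  if (x0 < 1 || x0 >= 2 * N) stop("probe frequency must give 1 <= count < 2N")
  p <- x0 / (2 * N)
  ps <- wf_expected_frequency(p, scheme)
  k <- stats::rbinom(transitions, 2L * N, ps)
  mut_offspring <- k / x0
  wt_offspring <- (2 * N - k) / (2 * N - x0)
  ratios <- mut_offspring / wt_offspring
  list(ratio = mean(ratios),
       se = stats::sd(ratios) / sqrt(transitions),
       expected = (ps / p) / ((1 - ps) / (1 - p)),
       p = p, N = N, transitions = transitions)
}
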