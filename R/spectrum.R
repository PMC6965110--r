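#' Exponential distribution of beneficial fitness effects
#'
#' Extreme value theory predicts that when the wild type already ranks near
#' the top of the fitness landscape, the fitness effects `s` of beneficial
#' mutations are exponentially distributed,
#' \deqn{p(s) = \alpha\, e^{-\alpha s}, \qquad \alpha = 1 / E[\Delta_1],}
#' where `E[Delta_1]` is the expected fitness gap between the best and the
#' second-best possible mutant genotype.
#'
#' @param e_delta1 Expected gap `E[Delta_1]` (`> 0`). `1/30` is a reasonable
#'   working value for highly adapted organisms, bracketed by viral
#'   estimates between about `1/53` and `1/37`.
#' @return An object of class `"effect_distribution"` with fields
#'   `e_delta1` and `alpha = 1/e_delta1`.
#' @export
#' @examples
#' effect_distribution(1 / 30)
effect_distribution <- function(e_delta1) {
  stopifnot(is.numeric(e_delta1), length(e_delta1) == 1L,
            is.finite(e_delta1), e_delta1 > 0)
  structure(list(e_delta1 = e_delta1, alpha = 1 / e_delta1),
            class = "effect_distribution")
}

#' @export
print.effect_distribution <- function(x, ...) {
  cat(sprintf("Exponential beneficial-effect distribution: E[Delta1] = %.5g (alpha = %.5g)\n",
              x$e_delta1, x$alpha))
  se <- attr(x, "se")
  if (!is.null(se))
    cat(sprintf("  fitted by %s from n = %d effects; SE(E[Delta1]) = %s\n",
                attr(x, "method"), attr(x, "n"),
                if (is.na(se)) "unavailable" else sprintf("%.3g", se)))
  invisible(x)
}

#' Density of beneficial-effect sizes
#'
#' @param s Effect size (`>= 0`, vectorised).
#' @param dist An [effect_distribution()].
#' @return `alpha * exp(-alpha * s)`.
#' @export
effect_pdf <- function(s, dist) {
  stopifnot(inherits(dist, "effect_distribution"))
  if (!is.numeric(s) || anyNA(s) || any(s < 0))
    stop("effect sizes s must be >= 0")
  stats::dexp(s, rate = dist$alpha)
}

#' Normalisation constant of the improvement distribution
#'
#' The improvement density is proportional to the product of the occurrence
#' density `alpha exp(-alpha s)` and the fixation probability of a single
#' new mutant of effect `s`. The closed-form CDF requires the scaling factor
#' `beta` that makes `CDF(0) = 0`:
#' \deqn{\beta = \frac{1}{\alpha} - \frac{1}{2+\alpha}
#'              + \frac{1}{N(N+\alpha+1)}.}
#' In the large-population mode (`N = Inf`) the last term vanishes.
#'
#' @param alpha Exponential rate of the occurrence density (`> 0`).
#' @param N Population size (`>= 2`), or `Inf` to drop the finite-size term.
#' @return The scalar `beta`.
#' @export
#' @examples
#' improvement_beta(30, 1500)  # ~0.002084
improvement_beta <- function(alpha, N) {
  stopifnot(is.numeric(alpha), alpha > 0, is.numeric(N), N >= 2)
  1 / alpha - 1 / (2 + alpha) + if (is.finite(N)) 1 / (N * (N + alpha + 1)) else 0
}

#' Distribution of improvements (mutations that occur and fix)
#'
#' An *improvement* is the compound event of a beneficial mutation occurring
#' and subsequently going to fixation; its size is the mutation's fitness
#' effect. The closed-form cumulative distribution is
#' \deqn{CDF(s) = 1 - \frac{e^{-\alpha s}}{\beta}\left[\frac{1}{\alpha}
#'   - \frac{e^{-2s}}{2+\alpha}
#'   + \frac{e^{-(N+1)s}}{N(N+\alpha+1)}\right],}
#' a tight approximation to the normalised integral of the
#' occurrence-times-fixation product density.
#'
#' @param alpha Exponential rate `1/E[Delta_1]` of the occurrence density.
#' @param N Population size entering the fixation filter, or `Inf` for the
#'   large-population mode in which the `N` term is dropped.
#' @return An object of class `"improvement_distribution"` with fields
#'   `alpha`, `N` and `beta`.
#' @export
#' @examples
#' improvement_distribution(alpha = 30, N = 1500)
improvement_distribution <- function(alpha, N = Inf) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha > 0,
            is.numeric(N), length(N) == 1L, N >= 2)
  structure(list(alpha = alpha, N = N, beta = improvement_beta(alpha, N)),
            class = "improvement_distribution")
}

#' @export
print.improvement_distribution <- function(x, ...) {
  cat(sprintf("Improvement distribution: alpha = %g, N = %s, beta = %.6g\n",
              x$alpha, if (is.finite(x$N)) format(x$N) else "Inf (term dropped)",
              x$beta))
  invisible(x)
}

#' @rdname improvement_distribution
#' @param s Improvement size (`>= 0`, vectorised).
#' @param dist An `"improvement_distribution"`.
#' @return `improvement_cdf()`: cumulative probability in `[0, 1]`.
#' @export
improvement_cdf <- function(s, dist) {
  stopifnot(inherits(dist, "improvement_distribution"))
  if (!is.numeric(s) || anyNA(s) || any(s < 0))
    stop("improvement sizes s must be >= 0")
  a <- dist$alpha; N <- dist$N
  tailN <- if (is.finite(N)) exp(-(N + 1) * s) / (N * (N + a + 1)) else 0
  val <- 1 - exp(-a * s) / dist$beta *
    (1 / a - exp(-2 * s) / (2 + a) + tailN)
  pmin(pmax(val, 0), 1)
}

#' @rdname improvement_distribution
#' @return `improvement_pdf()`: the density (derivative of the CDF).
#' @export
improvement_pdf <- function(s, dist) {
  stopifnot(inherits(dist, "improvement_distribution"))
  if (!is.numeric(s) || anyNA(s) || any(s < 0))
    stop("improvement sizes s must be >= 0")
  a <- dist$alpha; N <- dist$N
  cN <- if (is.finite(N)) (a + N + 1) / (N * (N + a + 1)) else 0
  exp(-a * s) / dist$beta * (1 - exp(-2 * s) + cN * exp(-(N + 1) * s))
}

#' @rdname improvement_distribution
#' @param q Cumulative probabilities in `[0, 1)` (vectorised).
#' @return `improvement_quantile()`: sizes `s` with `CDF(s) = q`, found by
#'   inverse-CDF root finding (bracketed bisection start, Newton polish).
#' @export
improvement_quantile <- function(q, dist) {
  stopifnot(inherits(dist, "improvement_distribution"))
  if (!is.numeric(q) || anyNA(q) || any(q < 0) || any(q >= 1))
    stop("q must lie in [0, 1)")
  if (length(q) == 0L) return(numeric())
  # bracket: exponential tail dominates, so quantile of Exp(alpha) shifted
  upper <- stats::qexp(max(q), rate = dist$alpha) + 20 / dist$alpha + 5
  # initial guess by monotone interpolation of the closed-form CDF
  grid <- seq(0, upper, length.out = 512L)
  cg <- improvement_cdf(grid, dist)
  keep <- !duplicated(cg)
  s <- stats::approx(cg[keep], grid[keep], xout = q, rule = 2)$y
  # Newton iterations on the closed form (density is strictly positive)
  for (it in 1:50) {
    f <- improvement_cdf(s, dist) - q
    d <- improvement_pdf(s, dist)
    step <- f / pmax(d, 1e-300)
    s <- pmax(s - step, 0)
    if (max(abs(step)) < 1e-12) break
  }
  if (max(abs(improvement_cdf(s, dist) - q)) > 1e-8)
    stop("improvement quantile root finding did not converge")
  s
}

#' Draw improvement sizes
#'
#' Samples from the improvement distribution by inverting the closed-form
#' CDF at uniform variates. Uses the current R random number stream.
#'
#' @param n Number of draws.
#' @param dist An [improvement_distribution()].
#' @return `n` positive improvement sizes.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_improvement(1000, improvement_distribution(30, 1500)))
sample_improvement <- function(n, dist) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n))
  improvement_quantile(stats::runif(n), dist)
}

#' A sample of beneficial-effect observations
#'
#' @param effects Numeric vector of positive effect sizes.
#' @param kind `"random"` (effects as they occur - the data needed to
#'   estimate `E[Delta_1]`) or `"preobserved"` (effects that occurred *and*
#'   fixed, i.e. filtered by fixation).
#' @param bins Optional binning as a data frame with columns `lower`,
#'   `upper`, `count` (see [bin_effects()]).
#' @return An object of class `"effect_sample"`.
#' @export
effect_sample <- function(effects, kind = c("random", "preobserved"),
                          bins = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(effects))
  if (anyNA(effects) || any(effects <= 0))
    stop("all effect sizes must be positive")
  if (!is.null(bins)) {
    stopifnot(is.data.frame(bins),
              all(c("lower", "upper", "count") %in% names(bins)))
    if (any(bins$count < 0)) stop("bin counts must be nonnegative")
    if (any(diff(c(bins$lower[1], bins$upper)) <= 0) ||
        any(bins$lower[-1] != bins$upper[-nrow(bins)]))
      stop("bin edges must be strictly increasing and contiguous")
  }
  structure(list(effects = as.numeric(effects), kind = kind, bins = bins),
            class = "effect_sample")
}

#' @export
print.effect_sample <- function(x, ...) {
  cat(sprintf("Effect sample (%s): n = %d, mean = %.4g%s\n", x$kind,
              length(x$effects),
              if (length(x$effects)) mean(x$effects) else NA,
              if (is.null(x$bins)) "" else
                sprintf(", %d bins", nrow(x$bins))))
  invisible(x)
}

#' Maximum-likelihood fit of the exponential effect distribution
#'
#' The MLE of `E[Delta_1]` for an exponential sample is the sample mean; the
#' large-sample standard error is `mean / sqrt(n)`. Intended for "random"
#' effects (as they occur); fitting fixation-filtered effects would conflate
#' occurrence with fixation and is refused.
#'
#' @param sample An [effect_sample()] with `kind = "random"`.
#' @return An [effect_distribution()] with attributes `se`, `n` and
#'   `method = "mle"`. A single observation yields `se = NA` (flagged, not
#'   zero).
#' @export
#' @examples
#' fit_exponential_mle(effect_sample(c(0.1, 0.3)))  # E[Delta1] = 0.2
fit_exponential_mle <- function(sample) {
  stopifnot(inherits(sample, "effect_sample"))
  if (sample$kind != "random")
    stop("MLE of E[Delta_1] requires 'random' (unfiltered) effects")
  n <- length(sample$effects)
  if (n == 0L) stop("cannot fit an empty sample")
  m <- mean(sample$effects)
  out <- effect_distribution(m)
  attr(out, "se") <- if (n >= 2) m / sqrt(n) else NA_real_
  attr(out, "n") <- n
  attr(out, "method") <- "mle"
  out
}

#' Least-squares fit of the exponential effect distribution to binned data
#'
#' Minimises the sum of squared differences between observed bin frequencies
#' (counts normalised by the total) and the exponential model's bin
#' probabilities `exp(-alpha * lower) - exp(-alpha * upper)`, over the rate
#' `alpha`. With `target = "density"` the fit instead matches empirical bin
#' densities (frequency / width) against the model density at bin midpoints.
#'
#' @param sample An [effect_sample()] carrying `bins` (at least 3).
#' @param target `"frequency"` (default) or `"density"`.
#' @param interval Search interval for `alpha`.
#' @return An [effect_distribution()] with attributes `se` (`NA`; use a
#'   bootstrap for uncertainty), `n`, `method = "lsq"`, and `objective` (the
#'   minimised sum of squares).
#' @export
fit_exponential_lsq <- function(sample, target = c("frequency", "density"),
                                interval = c(1e-3, 1e4)) {
  stopifnot(inherits(sample, "effect_sample"))
  target <- match.arg(target)
  if (is.null(sample$bins) || nrow(sample$bins) < 3L)
    stop("least-squares fitting needs binned data with at least 3 bins")
  b <- sample$bins
  total <- sum(b$count)
  if (total <= 0) stop("bin counts are all zero")
  freq <- b$count / total
  obj <- if (target == "frequency") {
    function(a) {
      pr <- exp(-a * b$lower) - exp(-a * b$upper)
      sum((freq - pr)^2)
    }
  } else {
    mid <- (b$lower + b$upper) / 2
    width <- b$upper - b$lower
    dens <- freq / width
    function(a) sum((dens - a * exp(-a * mid))^2)
  }
  # the objective is flat for large alpha; bracket the basin on a log grid
  # before the local golden-section refinement
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 400L))
  vals <- vapply(grid, obj, 0)
  if (!all(is.finite(vals)))
    stop("least-squares optimisation failed (non-finite objective)")
  i <- which.min(vals)
  bracket <- c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))])
  opt <- stats::optimize(obj, interval = bracket, tol = 1e-10)
  if (i == 1L || i == length(grid))
    warning("fitted alpha lies at the boundary of the search interval")
  out <- effect_distribution(1 / opt$minimum)
  attr(out, "se") <- NA_real_
  attr(out, "n") <- total
  attr(out, "method") <- "lsq"
  attr(out, "objective") <- opt$objective
  out
}
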