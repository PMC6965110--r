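#' Per-generation drift and variance terms of the diffusion approximation
#'
#' The allele-frequency diffusion is characterised by the mean change
#' `M(p)` in mutant frequency per generation and its variance `V(p)`.
#' Two standard approximations are provided. The *haploid* pair treats the
#' population as if carriers were haploid with advantage `s_het`:
#' \deqn{M(p) = p(1-p)\, s / (1 + s p), \qquad
#'       V(p) = \frac{p(1-p)}{2N}\,\frac{2+s}{1+s p}.}
#' The *Kimura* diploid pair keeps both genotype coefficients:
#' \deqn{M(p) = p(1-p)\,(s_{het} + (s_{hom} - 2 s_{het})\,p), \qquad
#'       V(p) = p(1-p) / (2 N_e).}
#'
#' @param p Allele frequency (vectorised, in `[0, 1]`).
#' @param s_het Heterozygote selection coefficient.
#' @param N Population size in diploid individuals.
#' @name diffusion_terms
NULL

#' @rdname diffusion_terms
#' @export
mean_change_haploid <- function(p, s_het) {
  check_frequency(p)
  if (any(1 + s_het * p <= 0)) stop("mean fitness 1 + s_het * p must be positive")
  p * (1 - p) * s_het / (1 + s_het * p)
}

#' @rdname diffusion_terms
#' @export
variance_haploid <- function(p, s_het, N) {
  check_frequency(p)
  stopifnot(N >= 2)
  if (any(1 + s_het * p <= 0)) stop("mean fitness 1 + s_het * p must be positive")
  p * (1 - p) / (2 * N) * (2 + s_het) / (1 + s_het * p)
}

#' @rdname diffusion_terms
#' @param scheme A [selection_scheme()]; frequency-dependent coefficients are
#'   evaluated at `p`.
#' @export
mean_change_kimura <- function(p, scheme) {
  check_frequency(p)
  co <- scheme_coefficients(scheme, p)
  p * (1 - p) * (co$s_het + (co$s_hom - 2 * co$s_het) * p)
}

#' @rdname diffusion_terms
#' @param Ne Effective population size in diploid individuals.
#' @export
variance_kimura <- function(p, Ne) {
  check_frequency(p)
  stopifnot(Ne >= 2)
  p * (1 - p) / (2 * Ne)
}

# 2 M(p) / V(p) with the shared p(1-p) factor cancelled analytically, so the
# ratio is smooth on [0, 1] and free of 0/0 at the absorbing boundaries.
drift_variance_ratio <- function(scheme, pop, model = c("kimura", "haploid")) {
  model <- match.arg(model)
  force(scheme); force(pop)
  if (model == "kimura") {
    function(p) {
      co <- scheme_coefficients(scheme, p)
      4 * pop$Ne * (co$s_het + (co$s_hom - 2 * co$s_het) * p)
    }
  } else {
    function(p) {
      s <- scheme_coefficients(scheme, p)$s_het
      4 * pop$N * s / (2 + s)
    }
  }
}

# Cumulative integral of exp(-H(x)) on a sorted mesh covering [0, 1], where
# H(x) = int_0^x phi(y) dy and phi = 2M/V. Each mesh interval uses the
# exponential-fitted rule exact for locally constant phi, so steep selection
# boundary layers are resolved without overflow: only differences of H enter.
# Returns the cumulative integral at every mesh point (0 at the first).
cumulative_G_integral <- function(mesh, phi) {
  h <- diff(mesh)
  left <- mesh[-length(mesh)]
  right <- mesh[-1]
  dH <- h / 6 * (phi(left) + 4 * phi(left + h / 2) + phi(right))  # Simpson
  Hleft <- c(0, cumsum(dH))
  Hleft <- Hleft - min(Hleft)  # shift so exp() never overflows
  w <- ifelse(abs(dH) < 1e-12, h, h * (-expm1(-dH)) / dH)
  c(0, cumsum(exp(-Hleft[-length(Hleft)]) * w))
}

# u(p) at requested points for a given scheme/population/model, via the
# stationary solution u(p) = int_0^p G / int_0^1 G, G = exp(-int 2M/V).
# Mesh is refined (doubled) until successive answers agree to rel_tol.
fixation_profile <- function(points, scheme, pop,
                             model = c("kimura", "haploid"),
                             rel_tol = 1e-8, n_base = 2048L,
                             max_points = 2^18) {
  model <- match.arg(model)
  check_frequency(points, "p0")
  phi <- drift_variance_ratio(scheme, pop, model)
  n <- as.integer(n_base)
  prev <- NULL
  repeat {
    mesh <- sort(unique(c(seq(0, 1, length.out = n + 1L), points)))
    S <- cumulative_G_integral(mesh, phi)
    u <- S[match(points, mesh)] / S[length(S)]
    if (!is.null(prev)) {
      err <- max(abs(u - prev) / pmax(abs(u), 1e-300))
      if (err <= rel_tol || n >= max_points) {
        if (err > rel_tol * 100 && n >= max_points)
          stop(sprintf(paste0("fixation-probability quadrature did not converge: ",
                              "relative change %.3g at %d mesh intervals"),
                       err, n))
        break
      }
    }
    prev <- u
    n <- n * 2L
  }
  pmin(pmax(u, 0), 1)
}

#' Closed-form fixation probability (haploid/semidominant approximation)
#'
#' Fixation probability of a mutant lineage at initial frequency `p0` under
#' the haploid diffusion terms, which admit the closed form
#' \deqn{p_{fix}(p_0) = \frac{1 - e^{-4N \frac{s}{2+s} p_0}}
#'                           {1 - e^{-4N \frac{s}{2+s}}}.}
#' The neutral limit `s = 0` returns `p0` analytically.
#'
#' @param p0 Initial mutant allele frequency in `[0, 1]`.
#' @param s_het Heterozygote selection coefficient (`> -1`).
#' @param N Population size in diploid individuals.
#' @return Fixation probability in `[0, 1]` (vectorised over `p0`).
#' @export
#' @examples
#' fixation_probability_closed(1 / 3000, s_het = 1, N = 1500)  # ~0.487
fixation_probability_closed <- function(p0, s_het, N) {
  check_frequency(p0, "p0")
  stopifnot(length(s_het) == 1L, is.finite(s_het), N >= 2)
  if (s_het <= -1) stop("s_het must be > -1")
  if (abs(s_het) < 1e-12) return(p0)  # neutral limit, not 0/0
  r <- 4 * N * s_het / (2 + s_het)
  if (r > 0) expm1(-r * p0) / expm1(-r)
  else exp(r * (1 - p0)) * expm1(r * p0) / expm1(r)  # avoids overflow for s < 0
}

#' Fixation probability by quadrature of the stationary diffusion equation
#'
#' Computes \eqn{u(p_0) = \int_0^{p_0} G(x) dx / \int_0^1 G(x) dx} with
#' \eqn{G(x) = \exp(-\int_0^x 2M(y)/V(y)\, dy)}, the stationary
#' (absorption-probability) solution of the allele-frequency Fokker-Planck
#' equation. Works for any [selection_scheme()], including recessive and
#' frequency-dependent selection, where no closed form exists.
#'
#' @param p0 Initial frequency; defaults to a single heterozygous mutant,
#'   `1/(2N)`.
#' @param scheme A [selection_scheme()].
#' @param pop A [population()].
#' @param model Which drift/variance pair to integrate: `"kimura"` (diploid,
#'   both genotype coefficients; matches forward Wright-Fisher simulation),
#'   `"haploid"` (reproduces [fixation_probability_closed()] exactly for
#'   constant coefficients), or `"auto"` (haploid for constant semidominant
#'   schemes, Kimura otherwise).
#' @param rel_tol Relative tolerance of the mesh-refinement quadrature.
#' @return Fixation probability in `[0, 1]` (vectorised over `p0`).
#' @export
#' @examples
#' pop <- population(1500)
#' fixation_probability_quadrature(1 / 3000, scheme_semidominant(0.1), pop)
fixation_probability_quadrature <- function(p0 = single_mutant_p0(pop), scheme, pop,
                                            model = c("auto", "kimura", "haploid"),
                                            rel_tol = 1e-8) {
  model <- match.arg(model)
  if (model == "auto")
    model <- if (scheme$mode == "constant" && is_semidominant(scheme))
      "haploid" else "kimura"
  if (is_neutral_scheme(scheme)) return(check_frequency(p0, "p0"))
  fixation_profile(p0, scheme, pop, model = model, rel_tol = rel_tol)
}

#' Fixation probability under linearly frequency-dependent selection
#'
#' Substitutes `s_het(p) = k_het * p` and `s_hom(p) = k_hom * p` into the
#' Kimura drift term and evaluates the stationary fixation probability by
#' quadrature. With positive slopes the advantage vanishes while the mutant
#' is rare, so fixation probabilities fall far below the constant-coefficient
#' case with the same maximal advantage.
#'
#' @inheritParams fixation_probability_quadrature
#' @param k_het,k_hom Nonnegative slopes of the frequency-dependent
#'   heterozygote/homozygote coefficients.
#' @export
fixation_probability_frequency_dependent <- function(p0 = single_mutant_p0(pop),
                                                     k_het, k_hom, pop,
                                                     model = c("kimura", "haploid"),
                                                     rel_tol = 1e-8) {
  model <- match.arg(model)
  scheme <- scheme_frequency_dependent(k_het, k_hom)
  if (is_neutral_scheme(scheme)) return(check_frequency(p0, "p0"))
  fixation_profile(p0, scheme, pop, model = model, rel_tol = rel_tol)
}
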