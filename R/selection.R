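#' Selection scheme for a diploid mutant allele
#'
#' Describes the fitness of mutant genotypes relative to the wild type
#' (fitness 1). Heterozygote carriers have fitness `1 + s_het`, homozygote
#' carriers `1 + s_hom`. In `frequency_dependent` mode the coefficients grow
#' linearly with the mutant allele frequency `p`:
#' `s_het(p) = k_het * p`, `s_hom(p) = k_hom * p`, modelling an advantage
#' (e.g. communication) that only materialises once carriers are common.
#'
#' @param s_het Selection coefficient of the heterozygote (dimensionless,
#'   `>= -1` so that fitness is nonnegative). Ignored in
#'   `frequency_dependent` mode.
#' @param s_hom Selection coefficient of the homozygote; defaults to `s_het`
#'   (full dominance).
#' @param mode `"constant"` (frequency-independent selection) or
#'   `"frequency_dependent"`.
#' @param k_het,k_hom Nonnegative slopes of the frequency-dependent
#'   coefficients (used only in `frequency_dependent` mode).
#' @param label Optional human-readable label carried into result tables.
#'
#' @details Coefficients above 1 are permitted but trigger a warning: `s = 1`
#'   already corresponds to carriers leaving on average twice the offspring
#'   of the wild type, an extreme value for a vertebrate population.
#'
#' @return An object of class `"selection_scheme"`.
#' @seealso [scheme_dominant()], [scheme_semidominant()],
#'   [scheme_recessive()], [scheme_frequency_dependent()]
#' @export
#' @examples
#' selection_scheme(s_het = 0.1, s_hom = 0.2)           # semidominant
#' selection_scheme(mode = "frequency_dependent", k_het = 0.5, k_hom = 1)
selection_scheme <- function(s_het = 0, s_hom = s_het,
                             mode = c("constant", "frequency_dependent"),
                             k_het = 0, k_hom = 0, label = NULL) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    stopifnot(is.numeric(s_het), length(s_het) == 1L, is.finite(s_het),
              is.numeric(s_hom), length(s_hom) == 1L, is.finite(s_hom))
    if (s_het < -1 || s_hom < -1)
      stop("selection coefficients must be >= -1 (fitness 1 + s nonnegative)")
    if (s_het > 1)
      warning("s_het > 1: carriers would leave more than twice the offspring ",
              "of the wild type; results extrapolate beyond plausible values",
              call. = FALSE)
    k_het <- k_hom <- 0
  } else {
    stopifnot(is.numeric(k_het), length(k_het) == 1L, is.finite(k_het),
              is.numeric(k_hom), length(k_hom) == 1L, is.finite(k_hom))
    if (k_het < 0 || k_hom < 0)
      stop("frequency-dependent slopes k_het, k_hom must be >= 0")
    if (k_het > 1)
      warning("k_het > 1: effective s_het exceeds 1 at high frequency",
              call. = FALSE)
    s_het <- s_hom <- 0
  }
  structure(
    list(mode = mode, s_het = s_het, s_hom = s_hom,
         k_het = k_het, k_hom = k_hom,
         label = label %||% default_scheme_label(mode, s_het, s_hom, k_het, k_hom)),
    class = "selection_scheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_scheme_label <- function(mode, s_het, s_hom, k_het, k_hom) {
  if (mode == "frequency_dependent")
    return(sprintf("freq-dep (k_het=%g, k_hom=%g)", k_het, k_hom))
  if (s_het == 0 && s_hom == 0) return("neutral")
  if (s_het == s_hom) return(sprintf("dominant (s=%g)", s_het))
  if (isTRUE(all.equal(s_hom, 2 * s_het))) return(sprintf("semidominant (s_het=%g)", s_het))
  if (s_het == 0) return(sprintf("recessive (s_hom=%g)", s_hom))
  sprintf("constant (s_het=%g, s_hom=%g)", s_het, s_hom)
}

#' Convenience constructors for standard dominance patterns
#'
#' `scheme_dominant()` gives heterozygote and homozygote the same advantage
#' (`s_hom = s_het`), the case of a fully dominant mutation whose phenotype
#' is present with a single copy. `scheme_semidominant()` sets
#' `s_hom = 2 * s_het` (no dominance; mathematically equivalent to a haploid
#' model). `scheme_recessive()` sets `s_het = 0`, so carriers gain nothing
#' until homozygotes appear. `scheme_neutral()` is the zero-selection scheme.
#'
#' @param s Selection coefficient of the heterozygote (for
#'   `scheme_recessive()`, of the homozygote).
#' @return A [selection_scheme()].
#' @export
scheme_dominant <- function(s) selection_scheme(s_het = s, s_hom = s)

#' @rdname scheme_dominant
#' @export
scheme_semidominant <- function(s) selection_scheme(s_het = s, s_hom = 2 * s)

#' @rdname scheme_dominant
#' @export
scheme_recessive <- function(s) selection_scheme(s_het = 0, s_hom = s)

#' @rdname scheme_dominant
#' @export
scheme_neutral <- function() selection_scheme(s_het = 0, s_hom = 0)

#' Linearly frequency-dependent selection scheme
#'
#' @param k_het Slope of the heterozygote coefficient: `s_het(p) = k_het * p`.
#' @param k_hom Slope of the homozygote coefficient; defaults to
#'   `2 * k_het`, the closest analogue of the semidominant constant case.
#' @return A [selection_scheme()] in `frequency_dependent` mode.
#' @export
scheme_frequency_dependent <- function(k_het, k_hom = 2 * k_het) {
  selection_scheme(mode = "frequency_dependent", k_het = k_het, k_hom = k_hom)
}

#' Effective selection coefficients at a given allele frequency
#'
#' @param scheme A [selection_scheme()].
#' @param p Allele frequency (vectorised, each in `[0, 1]`).
#' @return A list with vectors `s_het` and `s_hom`, recycled to `length(p)`.
#' @export
scheme_coefficients <- function(scheme, p) {
  stopifnot(inherits(scheme, "selection_scheme"))
  check_frequency(p)
  if (scheme$mode == "constant") {
    list(s_het = rep_len(scheme$s_het, length(p)),
         s_hom = rep_len(scheme$s_hom, length(p)))
  } else {
    list(s_het = scheme$k_het * p, s_hom = scheme$k_hom * p)
  }
}

is_semidominant <- function(scheme) {
  scheme$mode == "constant" && isTRUE(all.equal(scheme$s_hom, 2 * scheme$s_het))
}

is_neutral_scheme <- function(scheme) {
  if (scheme$mode == "constant") scheme$s_het == 0 && scheme$s_hom == 0
  else scheme$k_het == 0 && scheme$k_hom == 0
}

#' @export
print.selection_scheme <- function(x, ...) {
  cat("Selection scheme:", x$label, "\n")
  if (x$mode == "constant")
    cat(sprintf("  s_het = %g, s_hom = %g (constant)\n", x$s_het, x$s_hom))
  else
    cat(sprintf("  s_het(p) = %g p, s_hom(p) = %g p (frequency dependent)\n",
                x$k_het, x$k_hom))
  invisible(x)
}

#' Diploid population description
#'
#' @param N Census size in diploid individuals (`>= 2`); the number of
#'   alleles at the locus is `2N` and a single heterozygous mutant starts at
#'   frequency `1/(2N)`.
#' @param Ne Effective population size (defaults to `N`): the size of an
#'   idealised randomly mating population with the same drift variance.
#' @return An object of class `"population"`.
#' @export
#' @examples
#' population(1500)
population <- function(N, Ne = N) {
  stopifnot(is.numeric(N), length(N) == 1L, is.finite(N),
            is.numeric(Ne), length(Ne) == 1L, is.finite(Ne))
  if (N < 2 || N != round(N)) stop("N must be an integer >= 2")
  if (Ne < 2 || Ne != round(Ne)) stop("Ne must be an integer >= 2")
  structure(list(N = as.integer(N), Ne = as.integer(Ne)), class = "population")
}

#' Initial frequency of a single heterozygous mutant
#'
#' @param pop A [population()].
#' @return `1 / (2 N)`.
#' @export
single_mutant_p0 <- function(pop) {
  stopifnot(inherits(pop, "population"))
  1 / (2 * pop$N)
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population: N = %d diploid individuals (Ne = %d, 2N = %d alleles)\n",
              x$N, x$Ne, 2L * x$N))
  invisible(x)
}

check_frequency <- function(p, name = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop(sprintf("%s must be an allele frequency in [0, 1]", name))
  invisible(p)
}

#' Fixation result container
#'
#' Bundles the fixation probability of a mutant lineage with its mean
#' fixation-time summaries. `theta` is the product of fixation probability
#' and mean time to fixation; `t_conditional = theta / p_fix` is the mean
#' number of generations to fixation among lineages that do fix.
#'
#' @param p_fix Fixation probability in `[0, 1]`.
#' @param theta Product quantity (probability times generations, `>= 0`).
#' @param t_conditional Mean generations to fixation given fixation.
#' @param method One of `"closed_form"`, `"quadrature"`, `"bvp"`,
#'   `"monte_carlo"`.
#' @param scheme,pop,p0 Provenance of the result (optional but recommended).
#' @return An object of class `"fixation_result"`.
#' @export
fixation_result <- function(p_fix, theta = NA_real_, t_conditional = NA_real_,
                            method = c("closed_form", "quadrature", "bvp",
                                       "monte_carlo"),
                            scheme = NULL, pop = NULL, p0 = NA_real_) {
  method <- match.arg(method)
  stopifnot(is.numeric(p_fix), length(p_fix) == 1L)
  if (!is.na(p_fix) && (p_fix < -1e-12 || p_fix > 1 + 1e-12))
    stop("p_fix must lie in [0, 1]")
  p_fix <- min(max(p_fix, 0), 1)
  if (!is.na(theta) && theta < -1e-9) stop("theta must be >= 0")
  if (!is.na(t_conditional) && t_conditional < -1e-9)
    stop("t_conditional must be >= 0")
  if (!is.na(theta) && !is.na(t_conditional) && p_fix > 0) {
    if (abs(theta - p_fix * t_conditional) >
        1e-6 * max(1, abs(theta)))
      stop("inconsistent fixation result: theta != p_fix * t_conditional")
  }
  structure(list(p_fix = p_fix, theta = theta, t_conditional = t_conditional,
                 method = method, scheme = scheme, pop = pop, p0 = p0),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("Fixation result (%s):\n", x$method))
  if (!is.null(x$scheme)) cat("  scheme:", x$scheme$label, "\n")
  if (!is.null(x$pop)) cat(sprintf("  N = %d, Ne = %d\n", x$pop$N, x$pop$Ne))
  if (!is.na(x$p0)) cat(sprintf("  p0 = %g\n", x$p0))
  cat(sprintf("  p_fix = %.6g\n", x$p_fix))
  if (!is.na(x$theta)) cat(sprintf("  theta = %.6g probability*generations\n", x$theta))
  if (!is.na(x$t_conditional))
    cat(sprintf("  mean time to fixation (given fixation) = %.6g generations\n",
                x$t_conditional))
  invisible(x)
}
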