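#' Fixation probabilities over a parameter grid
#'
#' Evaluates fixation probabilities for each combination of population size
#' and selection strength under one or more dominance patterns, starting
#' from a single heterozygous mutant (`p0 = 1/(2N)` unless overridden).
#' Constant-coefficient schemes use `s` as the heterozygote coefficient
#' (homozygote per the pattern); `"frequency_dependent"` uses slope
#' `k_het = s`, `k_hom = 2 s`.
#'
#' @param N Vector of population sizes.
#' @param s Vector of selection strengths (or slopes).
#' @param schemes Character vector from `c("dominant", "semidominant",
#'   "recessive", "frequency_dependent")`.
#' @param p0 Initial frequency, or `NULL` for `1/(2N)`.
#' @param model Passed to [fixation_probability_quadrature()].
#' @return A data frame with columns `N`, `s`, `scheme`, `mode`, `s_het`,
#'   `s_hom`, `p0`, `p_fix`.
#' @export
#' @examples
#' fixation_probability_table(N = c(100, 1500), s = c(0.1, 0.5),
#'                            schemes = c("dominant", "recessive"))
fixation_probability_table <- function(N, s,
                                       schemes = c("dominant", "semidominant",
                                                   "recessive",
                                                   "frequency_dependent"),
                                       p0 = NULL, model = "auto") {
  schemes <- match.arg(schemes, several.ok = TRUE)
  grid <- expand.grid(N = N, s = s, scheme = schemes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sch <- make_scheme(g$scheme, g$s)
    pop <- population(g$N)
    q0 <- if (is.null(p0)) single_mutant_p0(pop) else p0
    pf <- fixation_probability_quadrature(q0, sch, pop, model = model)
    data.frame(N = g$N, s = g$s, scheme = g$scheme, mode = sch$mode,
               s_het = sch$s_het, s_hom = sch$s_hom, p0 = q0, p_fix = pf)
  })
  do.call(rbind, rows)
}

make_scheme <- function(scheme, s) {
  switch(scheme,
         dominant = scheme_dominant(s),
         semidominant = scheme_semidominant(s),
         recessive = scheme_recessive(s),
         frequency_dependent = scheme_frequency_dependent(s),
         stop("unknown scheme: ", scheme))
}

#' Mean fixation times over a parameter grid
#'
#' Solves the fixation-time boundary-value problem for each `(N, s)` cell
#' and reports the mean time to fixation of lineages that fix, in
#' generations and in years at the low and high generation times of
#' `config$generation_years`. Solver failures are reported per cell
#' (`NA` entries plus a `note` column), not fatally.
#'
#' @inheritParams fixation_probability_table
#' @param scheme_type One dominance pattern (see
#'   [fixation_probability_table()]).
#' @param config A [time_solver_config()].
#' @return A data frame with columns `N`, `s_het`, `s_hom`, `mode`,
#'   `p_fix`, `theta`, `t_conditional`, `years_low`, `years_high`, `note`.
#' @export
fixation_time_table <- function(N, s, scheme_type = "dominant",
                                config = time_solver_config()) {
  grid <- expand.grid(N = N, s = s)
  gy <- range(config$generation_years)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sch <- make_scheme(scheme_type, g$s)
    pop <- population(g$N)
    res <- tryCatch(conditional_fixation_time(sch, pop, config = config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(N = g$N, s_het = sch$s_het, s_hom = sch$s_hom,
                 mode = sch$mode, p_fix = NA_real_, theta = NA_real_,
                 t_conditional = NA_real_, years_low = NA_real_,
                 years_high = NA_real_, note = conditionMessage(res))
    } else {
      data.frame(N = g$N, s_het = sch$s_het, s_hom = sch$s_hom,
                 mode = sch$mode, p_fix = res$p_fix, theta = res$theta,
                 t_conditional = res$t_conditional,
                 years_low = generations_to_years(res$t_conditional, gy[1]),
                 years_high = generations_to_years(res$t_conditional, gy[2]),
                 note = "")
    }
  })
  do.call(rbind, rows)
}

#' Fit the beneficial-effect distribution and predict the fixation filter
#'
#' Fits `E[Delta_1]` to a sample of "random" beneficial effects by maximum
#' likelihood and (after binning) by least squares, then overlays the
#' predicted distribution of "preobserved" effects - the improvement CDF at
#' the least-squares rate - for comparison with fixation-filtered
#' observations.
#'
#' @param sample An [effect_sample()] with `kind = "random"`, or a path to
#'   a delimited effects table (see [read_effects_table()]).
#' @param N Population size of the fixation filter for the predicted curve
#'   (default `Inf`, dropping the finite-size term as appropriate when the
#'   effective population is very large).
#' @param bin_edges Bin edges for the least-squares fit; default covers
#'   `[0, 0.4]` in steps of 0.05 with an open overflow bin.
#' @param curve_points Number of points of the predicted CDF curve.
#' @return A list with `mle` and `lsq` fits ([effect_distribution()]s),
#'   the binned sample, and `predicted` (data frame `s`,
#'   `cdf_random`, `cdf_preobserved`).
#' @export
fit_effects_report <- function(sample, N = Inf,
                               bin_edges = seq(0, 0.4, by = 0.05),
                               curve_points = 101L) {
  if (is.character(sample)) sample <- read_effects_table(sample)
  stopifnot(inherits(sample, "effect_sample"))
  mle <- fit_exponential_mle(sample)
  binned <- bin_effects(sample, bin_edges, overflow = "extend")
  lsq <- fit_exponential_lsq(binned)
  dist <- improvement_distribution(alpha = lsq$alpha, N = N)
  smax <- max(bin_edges[is.finite(bin_edges)])
  sgrid <- seq(0, smax, length.out = curve_points)
  predicted <- data.frame(
    s = sgrid,
    cdf_random = stats::pexp(sgrid, rate = lsq$alpha),
    cdf_preobserved = improvement_cdf(sgrid, dist))
  list(mle = mle, lsq = lsq, binned = binned, improvement = dist,
       predicted = predicted)
}

#' Write an analysis table with a JSON metadata sidecar
#'
#' Writes `x` as a comma-separated table with a header row, plus
#' `<path>.meta.json` recording the parameters (always including any seed)
#' so that every output is reproducible from its metadata alone.
#'
#' @param x A data frame.
#' @param path Output CSV path.
#' @param metadata Named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, metadata = list()) {
  stopifnot(is.data.frame(x))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
  meta <- c(metadata, list(rows = nrow(x), written = format(Sys.time(), "%Y-%m-%d")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
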