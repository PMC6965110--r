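#' Specification for synthetic beneficial-effect data
#'
#' Describes a synthetic data set with the statistical structure assumed by
#' the fitting and accumulation stages: "random" effects are drawn from the
#' exponential occurrence distribution; "preobserved" effects (those that
#' occurred *and* went to fixation) follow the improvement distribution,
#' i.e. the occurrence density filtered by the fixation probability. This
#' emulates measured viral fitness-effect data sets in which both kinds of
#' observation appear.
#'
#' @param e_delta1 True `E[Delta_1]` of the occurrence distribution
#'   (default `1/30`).
#' @param n_random Number of "random" draws.
#' @param n_preobserved Number of "preobserved" draws.
#' @param N Population size of the fixation filter; `Inf` (the default
#'   matches fitting against pooled viral data, where the population is
#'   effectively very large) drops the finite-size term.
#' @param bin_edges Optional bin edges for [bin_effects()].
#' @param seed Optional integer seed; generators are pure functions of
#'   `(spec, seed)`.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(e_delta1 = 1 / 30, n_random = 0L,
                           n_preobserved = 0L, N = Inf, bin_edges = NULL,
                           seed = NULL) {
  stopifnot(is.numeric(e_delta1), e_delta1 > 0,
            n_random >= 0, n_random == round(n_random),
            n_preobserved >= 0, n_preobserved == round(n_preobserved),
            is.numeric(N), N >= 2)
  if (!is.null(bin_edges)) {
    stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2)
    if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  }
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(e_delta1 = e_delta1, n_random = as.integer(n_random),
                 n_preobserved = as.integer(n_preobserved), N = N,
                 bin_edges = bin_edges, seed = seed),
            class = "synthetic_spec")
}

#' Generate "random" beneficial effects (as they occur)
#'
#' I.i.d. exponential draws with mean `e_delta1` - the occurrence
#' distribution before any fixation filtering.
#'
#' @param spec A [synthetic_spec()].
#' @return An [effect_sample()] with `kind = "random"`.
#' @export
#' @examples
#' s <- generate_random_effects(synthetic_spec(n_random = 500, seed = 1))
#' mean(s$effects)  # ~ 1/30
generate_random_effects <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  eff <- with_seed(spec$seed,
                   stats::rexp(spec$n_random, rate = 1 / spec$e_delta1))
  effect_sample(eff, kind = "random")
}

#' Generate "preobserved" effects (occurred and fixed)
#'
#' Draws from the improvement distribution at `alpha = 1/e_delta1` and the
#' spec's `N`, reusing the production sampler ([sample_improvement()]).
#' Because fixation filters for larger effects, the preobserved sample mean
#' exceeds the random sample mean at equal `e_delta1`.
#'
#' @param spec A [synthetic_spec()].
#' @return An [effect_sample()] with `kind = "preobserved"`.
#' @export
generate_preobserved_effects <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dist <- improvement_distribution(alpha = 1 / spec$e_delta1, N = spec$N)
  eff <- with_seed(spec$seed, sample_improvement(spec$n_preobserved, dist))
  effect_sample(eff, kind = "preobserved")
}

#' Bin an effect sample
#'
#' Counts effects per bin over strictly increasing edges. Effects outside
#' the edges are an error unless `overflow = "extend"`, which appends an
#' open-ended final bin (and a leading bin down to 0 if needed).
#'
#' @param sample An [effect_sample()].
#' @param bin_edges Strictly increasing numeric edges.
#' @param overflow `"error"` (default) or `"extend"`.
#' @return The sample with a `bins` data frame (`lower`, `upper`, `count`);
#'   counts sum to the sample size.
#' @export
#' @examples
#' bin_effects(effect_sample(0.15), c(0, 0.1, 0.2))$bins
bin_effects <- function(sample, bin_edges, overflow = c("error", "extend")) {
  stopifnot(inherits(sample, "effect_sample"), is.numeric(bin_edges),
            length(bin_edges) >= 2)
  overflow <- match.arg(overflow)
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  eff <- sample$effects
  lo <- min(bin_edges); hi <- max(bin_edges)
  out_of_range <- eff < lo | eff > hi
  if (any(out_of_range)) {
    if (overflow == "error")
      stop(sum(out_of_range), " effects fall outside the bin edges; ",
           "use overflow = \"extend\" to add open bins")
    if (any(eff < lo)) bin_edges <- c(0, bin_edges)
    if (any(eff > hi)) bin_edges <- c(bin_edges, Inf)
  }
  k <- length(bin_edges) - 1L
  idx <- findInterval(eff, bin_edges, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[eff == bin_edges[1]] <- 1L  # include the lower boundary
  counts <- tabulate(idx, nbins = k)
  effect_sample(sample$effects, kind = sample$kind,
                bins = data.frame(lower = bin_edges[-length(bin_edges)],
                                  upper = bin_edges[-1],
                                  count = counts))
}

#' Read and write delimited effects tables
#'
#' The on-disk format is delimited text with a header row, a mandatory
#' `effect` column (positive floats) and an optional `count` column
#' (nonnegative integers; a row with count `k` stands for `k` identical
#' observations). Comment lines begin with `#`.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @param kind Sample kind recorded on the returned [effect_sample()].
#' @return `read_effects_table()`: an [effect_sample()].
#' @export
read_effects_table <- function(path, sep = ",",
                               kind = c("random", "preobserved")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("effects table not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      strip.white = TRUE),
    error = function(e) stop("failed to parse effects table ", path, ": ",
                             conditionMessage(e)))
  if (!"effect" %in% names(tab))
    stop("effects table must have an 'effect' column (header row required)")
  bad <- which(!is.finite(tab$effect) | tab$effect <= 0)
  if (length(bad))
    stop("non-positive or missing effect at data line ", bad[1],
         " of ", path)
  eff <- tab$effect
  if ("count" %in% names(tab)) {
    if (any(!is.finite(tab$count) | tab$count < 0 |
            tab$count != round(tab$count)))
      stop("'count' column must contain nonnegative integers")
    eff <- rep(tab$effect, times = tab$count)
  }
  effect_sample(eff, kind = kind)
}

#' @rdname read_effects_table
#' @param sample An [effect_sample()] to write (one row per observation,
#'   `count = 1`).
#' @return `write_effects_table()`: the path, invisibly.
#' @export
write_effects_table <- function(sample, path, sep = ",") {
  stopifnot(inherits(sample, "effect_sample"))
  df <- data.frame(effect = sample$effects, count = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beneficial-effect sample (kind = %s), n = %d",
                     sample$kind, length(sample$effects)), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
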