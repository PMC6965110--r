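#' Accumulate improvements until a target total fitness gain
#'
#' Repeatedly draws improvement sizes from `dist` until their running sum
#' reaches the target `m`, modelling an adaptive walk in which beneficial
#' mutations occur and fix one after another. Because improvements come in
#' discrete steps, the final total generally overshoots `m` slightly, which
#' is why the expected number of steps exceeds `m` divided by the mean
#' improvement size.
#'
#' @param m Target total improvement (`>= 0`). `m = 0` returns an empty run.
#' @param dist An [improvement_distribution()].
#' @return An object of class `"accumulation_run"` with fields `steps`
#'   (ordered improvement sizes), `n_steps`, `max_step` and `total`. Uses
#'   the current R random number stream.
#' @export
#' @examples
#' set.seed(1)
#' accumulate(1, improvement_distribution(30, 1500))
accumulate <- function(m, dist) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m >= 0,
            inherits(dist, "improvement_distribution"))
  steps <- numeric()
  total <- 0
  block <- 16L  # expected walk length is ~m/mean-step; draw in blocks
  while (total < m) {
    draw <- sample_improvement(block, dist)
    cum <- total + cumsum(draw)
    hit <- which(cum >= m)
    if (length(hit)) {
      steps <- c(steps, draw[seq_len(hit[1])])
      total <- cum[hit[1]]
      break
    }
    steps <- c(steps, draw)
    total <- cum[block]
  }
  structure(list(steps = steps, n_steps = length(steps),
                 max_step = if (length(steps)) max(steps) else NA_real_,
                 total = total, m = m),
            class = "accumulation_run")
}

#' @export
print.accumulation_run <- function(x, ...) {
  cat(sprintf("Accumulation run: %d steps to total %.4g (target m = %g), max step %.4g\n",
              x$n_steps, x$total, x$m,
              if (is.na(x$max_step)) 0 else x$max_step))
  invisible(x)
}

#' Replicate accumulation runs
#'
#' @inheritParams accumulate
#' @param replicates Number of independent runs (`>= 1`).
#' @return A list of [accumulate()] results (class
#'   `"accumulation_runs"`).
#' @export
accumulate_many <- function(replicates, m, dist) {
  stopifnot(replicates >= 1, replicates == round(replicates))
  structure(lapply(seq_len(replicates), function(i) accumulate(m, dist)),
            class = "accumulation_runs")
}

#' Summarise a collection of accumulation runs
#'
#' Builds histograms of the number of steps per run (unit-width integer
#' bins) and of the largest step in each run (default width-0.05 bins on
#' `[0, 1]`, extended as needed), plus means and quantiles.
#'
#' @param runs A list of `"accumulation_run"` objects
#'   (e.g. from [accumulate_many()]).
#' @param max_step_breaks Bin edges for the largest-step histogram.
#' @param params Optional named list of experiment parameters (m, alpha, N,
#'   seed, ...) recorded verbatim in the summary.
#' @return An object of class `"accumulation_summary"`.
#' @export
summarize_runs <- function(runs, max_step_breaks = seq(0, 1, by = 0.05),
                           params = NULL) {
  if (length(runs) == 0L) stop("no runs to summarise")
  stopifnot(all(vapply(runs, inherits, TRUE, "accumulation_run")))
  n_steps <- vapply(runs, `[[`, 0, "n_steps")
  max_step <- vapply(runs, `[[`, 0, "max_step")
  n_breaks <- seq(-0.5, max(n_steps) + 0.5, by = 1)
  n_hist <- graphics::hist(n_steps, breaks = n_breaks, plot = FALSE)
  if (max(max_step, na.rm = TRUE) > max(max_step_breaks))
    max_step_breaks <- c(max_step_breaks,
                         seq(max(max_step_breaks),
                             max(max_step, na.rm = TRUE) + 0.05, by = 0.05)[-1])
  m_hist <- graphics::hist(max_step[!is.na(max_step)],
                           breaks = max_step_breaks, plot = FALSE)
  structure(list(
    replicates = length(runs),
    n_steps = list(mean = mean(n_steps),
                   quantiles = stats::quantile(n_steps, c(0.025, 0.25, 0.5,
                                                          0.75, 0.975)),
                   breaks = n_hist$breaks, counts = n_hist$counts),
    max_step = list(mean = mean(max_step, na.rm = TRUE),
                    quantiles = stats::quantile(max_step,
                                                c(0.025, 0.25, 0.5, 0.75, 0.975),
                                                na.rm = TRUE),
                    breaks = m_hist$breaks, counts = m_hist$counts),
    single_step_fraction = mean(n_steps == 1),
    params = params),
    class = "accumulation_summary")
}

#' @export
print.accumulation_summary <- function(x, ...) {
  cat(sprintf("Accumulation summary over %d runs:\n", x$replicates))
  if (!is.null(x$params))
    cat("  parameters:",
        paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
        "\n")
  cat(sprintf("  steps per run: mean %.3g, median %g\n",
              x$n_steps$mean, x$n_steps$quantiles[["50%"]]))
  cat(sprintf("  largest step: mean %.3g, median %.3g\n",
              x$max_step$mean, x$max_step$quantiles[["50%"]]))
  cat(sprintf("  fraction of single-step runs: %.4g\n", x$single_step_fraction))
  invisible(x)
}

#' Run the accumulation experiment with recorded metadata
#'
#' Seeds the random number generator, draws `replicates` accumulation runs
#' to total gain `m` from the improvement distribution with parameters
#' `alpha` and `N`, and returns the summary with full parameter metadata -
#' the headline Monte-Carlo experiment contrasting one macro-mutation with
#' a walk of smaller adaptive steps.
#'
#' @param m Target total improvement (default 1).
#' @param alpha Exponential rate of the occurrence density (default 30).
#' @param N Population size in the fixation filter (default 1500; `Inf`
#'   drops the finite-size term).
#' @param replicates Number of Monte-Carlo runs (default 10000).
#' @param seed Integer seed recorded in the output metadata; `NULL` leaves
#'   the random number stream untouched.
#' @return A list with elements `summary` (an
#'   [summarize_runs()] result), `runs` and `metadata`.
#' @export
#' @examples
#' res <- accumulation_experiment(replicates = 200, seed = 1)
#' res$summary
accumulation_experiment <- function(m = 1, alpha = 30, N = 1500,
                                    replicates = 10000, seed = NULL) {
  dist <- improvement_distribution(alpha = alpha, N = N)
  runs <- with_seed(seed, accumulate_many(replicates, m, dist))
  params <- list(m = m, alpha = alpha, N = N, replicates = replicates,
                 seed = if (is.null(seed)) NA else seed)
  list(summary = summarize_runs(runs, params = params),
       runs = runs, metadata = params)
}

# Evaluate expr with a temporarily seeded RNG; restores the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
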