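#' Configuration for the fixation-time boundary-value solver
#'
#' @param grid_points Number of interior mesh nodes on `(0, 1)`
#'   (`>= 100`; default 2000). The mesh is uniform; evaluation points are
#'   inserted as extra nodes, so very small initial frequencies are
#'   represented exactly.
#' @param tolerance Relative tolerance used for the fixation-probability
#'   quadrature supplying the right-hand side.
#' @param generation_years Years per generation used when converting
#'   generations to calendar time; length-1 or length-2 (low, high). The
#'   default `c(25, 30)` spans typical human generation-time estimates.
#' @return An object of class `"time_solver_config"`.
#' @export
time_solver_config <- function(grid_points = 2000L, tolerance = 1e-8,
                               generation_years = c(25, 30)) {
  stopifnot(is.numeric(grid_points), length(grid_points) == 1L,
            grid_points >= 100, grid_points == round(grid_points),
            is.numeric(tolerance), tolerance > 0,
            is.numeric(generation_years),
            length(generation_years) %in% 1:2,
            all(generation_years >= 1), all(generation_years <= 100))
  structure(list(grid_points = as.integer(grid_points), tolerance = tolerance,
                 generation_years = generation_years),
            class = "time_solver_config")
}

# Kimura drift/variance callables for a scheme (optionally the haploid pair).
scheme_MV <- function(scheme, pop, model = c("kimura", "haploid")) {
  model <- match.arg(model)
  if (model == "kimura")
    list(M = function(p) mean_change_kimura(p, scheme),
         V = function(p) variance_kimura(p, pop$Ne))
  else
    list(M = function(p) mean_change_haploid(p, scheme_coefficients(scheme, p)$s_het),
         V = function(p) variance_haploid(p, scheme_coefficients(scheme, p)$s_het,
                                          pop$N))
}

#' Solve for the fixation-probability-weighted mean fixation time
#'
#' Solves the ordinary boundary-value problem
#' \deqn{M(p)\,\vartheta'(p) + \tfrac{1}{2} V(p)\,\vartheta''(p) = -p_{fix}(p),
#'       \qquad \vartheta(0) = \vartheta(1) = 0,}
#' where \eqn{\vartheta(p)} is the product of the fixation probability and the
#' mean time to fixation from initial frequency `p`, and `p_fix(p)` is the
#' stationary fixation probability from the same drift/variance pair.
#' Discretisation is second-order finite differences on a (by default
#' uniform) mesh excluding the singular absorbing endpoints, where the
#' boundary values are imposed exactly.
#'
#' @param scheme A [selection_scheme()].
#' @param pop A [population()].
#' @param config A [time_solver_config()].
#' @param extra_points Numeric vector of frequencies inserted into the mesh
#'   (e.g. the initial frequency `1/(2N)`, typically far below the uniform
#'   spacing).
#' @param model Drift/variance pair; `"kimura"` (default) keeps both
#'   genotype coefficients, which matters for fixation times.
#' @param boundary_refine Add a geometric cascade of mesh nodes near the
#'   absorbing boundaries (default `TRUE`); without it, strong selection
#'   (`N*s` in the thousands) leaves the boundary layer unresolved on a
#'   uniform mesh.
#' @return An object of class `"theta_solution"`: mesh `p` (including 0 and
#'   1), `theta`, `p_fix` on the mesh, plus the inputs.
#' @export
#' @examples
#' sol <- solve_theta(scheme_neutral(), population(200),
#'                    time_solver_config(grid_points = 500))
#' theta_at(sol, 1 / 400) / 0.0025  # ~ 4N = 800 generations
solve_theta <- function(scheme, pop, config = time_solver_config(),
                        extra_points = numeric(), model = c("kimura", "haploid"),
                        boundary_refine = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(pop, "population"), inherits(config, "time_solver_config"))
  check_frequency(extra_points, "extra_points")
  mesh <- c(seq(0, 1, length.out = config$grid_points + 2L), extra_points)
  if (boundary_refine) {
    # under strong selection theta varies on the scale 1/(4 N s) next to the
    # absorbing boundaries; a geometric cascade of nodes from below the
    # single-mutant frequency up to the uniform spacing resolves it
    h <- 1 / (config$grid_points + 1)
    p_start <- max(min(c(extra_points[extra_points > 0],
                         single_mutant_p0(pop))) / 4, 1e-9)
    if (p_start < h) {
      geom <- p_start * 2^seq(0, ceiling(log2(h / p_start)))
      mesh <- c(mesh, geom, 1 - geom)
    }
  }
  mesh <- sort(unique(mesh[mesh >= 0 & mesh <= 1]))
  x <- mesh[c(-1L, -length(mesh))]          # interior nodes
  n <- length(x)
  hm <- x - mesh[seq_len(n)]                # spacing to left neighbour
  hp <- mesh[seq_len(n) + 2L] - x           # spacing to right neighbour

  mv <- scheme_MV(scheme, pop, model)
  Mi <- mv$M(x)
  Vi <- mv$V(x)
  if (any(Vi <= 0)) stop("variance term must be positive on the interior mesh")
  pfix <- if (is_neutral_scheme(scheme)) x else
    fixation_profile(x, scheme, pop, model = model, rel_tol = config$tolerance)

  # second-order nonuniform central differences:
  # theta'' ~ 2 [ th_{i-1}/(hm(hm+hp)) - th_i/(hm hp) + th_{i+1}/(hp(hm+hp)) ]
  # theta'  ~ [ -hp/hm th_{i-1} + (hp/hm - hm/hp) th_i + hm/hp th_{i+1} ] / (hm+hp)
  lo <- Vi / (hm * (hm + hp)) - Mi * hp / (hm * (hm + hp))
  di <- -Vi / (hm * hp) + Mi * (hp - hm) / (hm * hp) / 1
  up <- Vi / (hp * (hm + hp)) + Mi * hm / (hp * (hm + hp))
  # note: with theta(0) = theta(1) = 0 the boundary columns drop out
  A <- Matrix::bandSparse(n, n, k = -1:1,
                          diagonals = list(lo[-1L], di, up[-n]))
  theta_int <- tryCatch(as.numeric(Matrix::solve(A, -pfix)),
                        error = function(e)
                          stop("fixation-time solver failed on a mesh of ", n,
                               " interior nodes: ", conditionMessage(e)))
  theta <- c(0, theta_int, 0)
  if (min(theta) < -1e-6 * max(abs(theta)))
    warning("theta has negative entries beyond rounding; mesh may be too coarse")
  theta <- pmax(theta, 0)
  structure(list(p = mesh, theta = theta,
                 p_fix = c(0, pfix, 1),
                 scheme = scheme, pop = pop, config = config, model = model),
            class = "theta_solution")
}

#' Evaluate a fixation-time solution at given frequencies
#'
#' @param sol A `"theta_solution"` from [solve_theta()].
#' @param p Frequencies at which to evaluate (interpolated linearly between
#'   mesh nodes; exact at nodes).
#' @return `theta(p)`.
#' @export
theta_at <- function(sol, p) {
  stopifnot(inherits(sol, "theta_solution"))
  check_frequency(p)
  stats::approx(sol$p, sol$theta, xout = p, rule = 2)$y
}

#' Mean time to fixation of lineages that fix
#'
#' Computes \eqn{\tau(p_0) = \vartheta(p_0) / p_{fix}(p_0)}, the mean number
#' of generations to fixation among lineages that do reach fixation, by
#' solving the boundary-value problem of [solve_theta()] with `p0` inserted
#' into the mesh.
#'
#' @inheritParams solve_theta
#' @param p0 Initial frequency; defaults to a single heterozygous mutant.
#' @return A [fixation_result()] with `method = "bvp"`.
#' @export
#' @examples
#' conditional_fixation_time(scheme_dominant(1e-6), population(1500))
conditional_fixation_time <- function(scheme, pop, p0 = single_mutant_p0(pop),
                                      config = time_solver_config(),
                                      model = c("kimura", "haploid")) {
  model <- match.arg(model)
  stopifnot(length(p0) == 1L)
  check_frequency(p0, "p0")
  sol <- solve_theta(scheme, pop, config, extra_points = p0, model = model)
  i <- match(p0, sol$p)
  pf <- sol$p_fix[i]
  if (!is.finite(pf) || pf <= config$tolerance)
    stop("fixation probability at p0 is zero within tolerance; ",
         "mean time given fixation is undefined")
  th <- sol$theta[i]
  if (th <= 0 && p0 > 0 && p0 < 1)
    stop("theta(p0) was not resolved on this mesh (strong selection ",
         "boundary layer); increase grid_points")
  fixation_result(p_fix = pf, theta = th, t_conditional = th / pf,
                  method = "bvp", scheme = scheme, pop = pop, p0 = p0)
}

#' Convert generations to calendar years
#'
#' @param t Time in generations (`>= 0`, vectorised).
#' @param generation_years Years per generation (vectorised).
#' @return `t * generation_years`.
#' @export
#' @examples
#' generations_to_years(6000, 25)  # 150000 years
generations_to_years <- function(t, generation_years) {
  stopifnot(is.numeric(t), all(t >= 0), is.numeric(generation_years),
            all(generation_years > 0))
  t * generation_years
}

#' @export
print.theta_solution <- function(x, ...) {
  cat(sprintf("theta(p) solution (%s terms): %d mesh nodes, scheme %s, N = %d\n",
              x$model, length(x$p), x$scheme$label, x$pop$N))
  invisible(x)
}
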