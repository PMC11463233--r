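# Homogeneous groups: closed-form equilibrium, collectively optimal target
# weighting, best response and ESS.
#
# Every agent updates its estimate of a target at 0 on the real line as
#   kappa_{t+1} = w z + ((1-w)/n) sum_j (kappa_j + nu_j),
# with z ~ N(0, 1) the private environmental signal and nu ~ N(0, gamma^2)
# the interaction noise on each social observation. At the variance
# equilibrium the target error sigma = sd(kappa) and the inter-agent estimate
# correlation rho have the closed forms implemented here.

#' Equilibrium correlation between agents' estimates
#'
#' At the variance equilibrium of a homogeneous group, the correlation
#' between two distinct agents' target estimates depends only on the target
#' weighting `w` and the group size `n`:
#' \deqn{\rho = \frac{(1-w)^2}{n - (1-w)^2 (n-1)}.}
#' Interaction noise does not enter: it inflates every agent's variance but
#' contributes no shared component.
#'
#' @param w Target weighting in `(0, 1]`; the weight an agent places on its
#'   private environmental signal. `w = 0` is rejected: with no environmental
#'   input the equilibrium degenerates (`rho -> 1`, no finite target error).
#' @param n Group size, an integer `>= 2`.
#' @return The equilibrium correlation, a number in `[0, 1)`.
#' @seealso [equilibrium_sigma()] for the corresponding target error.
#' @examples
#' equilibrium_rho(0.5, 10)   # 0.25 / 7.75
#' equilibrium_rho(1, 10)     # independent estimates
#' @export
equilibrium_rho <- function(w, n) {
  n <- check_count(n, "n", lower = 2L)
  check_w_positive(w)
  q <- (1 - w)^2
  q / (n - q * (n - 1))
}

#' Equilibrium target error of a homogeneous group
#'
#' Solves the equilibrium variance relation for a group of `n` identical
#' agents with target weighting `w` and interaction noise `gamma`:
#' \deqn{\sigma^2 = \frac{n w^2 + (1-w)^2 \gamma^2}
#'                      {n - (1-w)^2 (1 + (n-1)\rho)},}
#' with \eqn{\rho} from [equilibrium_rho()]. The environmental signal has
#' unit variance, which sets the scale of `sigma` and `gamma`.
#'
#' @inheritParams equilibrium_rho
#' @param gamma Interaction-noise standard deviation, `>= 0`.
#' @return An object of class `"collnav_equilibrium"`: a list with elements
#'   `sigma` (equilibrium target error) and `rho` (equilibrium inter-agent
#'   correlation).
#' @examples
#' equilibrium_sigma(1, 10, 5)        # sigma = 1 whatever gamma
#' equilibrium_sigma(0.5, 10, 1)      # sigma ~= 0.533
#' @export
equilibrium_sigma <- function(w, n, gamma) {
  n <- check_count(n, "n", lower = 2L)
  check_w_positive(w)
  check_scalar(gamma, "gamma", lower = 0)
  rho <- equilibrium_rho(w, n)
  q <- (1 - w)^2
  sigma2 <- (n * w^2 + q * gamma^2) / (n - q * (1 + (n - 1) * rho))
  structure(list(sigma = sqrt(sigma2), rho = rho),
            class = "collnav_equilibrium")
}

#' @export
print.collnav_equilibrium <- function(x, ...) {
  cat(sprintf("Homogeneous-group equilibrium: sigma = %.6g, rho = %.6g\n",
              x$sigma, x$rho))
  invisible(x)
}

#' Collectively optimal target weighting
#'
#' Finds the target weighting `w*` in `(0, 1]` minimising the equilibrium
#' target error of [equilibrium_sigma()]. The error surface is smooth with a
#' unique interior minimum, so a coarse grid scan (step `grid_step`) is
#' followed by bounded scalar minimisation on the bracketing interval. `w*`
#' increases with `gamma` (approaching 1 as `gamma -> Inf`, 0 as
#' `gamma -> 0`) and decreases with group size.
#'
#' @inheritParams equilibrium_sigma
#' @param grid_step Spacing of the bracketing grid over `(0, 1]`.
#' @param tol Absolute tolerance on `w*` passed to the polishing minimiser.
#' @return A list with `w_star`, and `sigma`, `rho` at the optimum.
#' @examples
#' collective_optimal_w(10, 0.5)
#' @export
collective_optimal_w <- function(n, gamma, grid_step = 1e-3, tol = 1e-7) {
  n <- check_count(n, "n", lower = 2L)
  check_scalar(gamma, "gamma", lower = 0)
  f <- function(w) equilibrium_sigma(w, n, gamma)$sigma
  ws <- seq(grid_step, 1, by = grid_step)
  vals <- vapply(ws, f, numeric(1))
  i <- which.min(vals)
  lo <- max(grid_step / 2, ws[i] - grid_step)
  hi <- min(1, ws[i] + grid_step)
  opt <- stats::optimize(f, lower = lo, upper = hi, tol = tol)
  # optimize() never lands exactly on a boundary; keep whichever of the
  # polished point and the boundary w = 1 is truly lower.
  w_star <- opt$minimum
  if (f(1) < opt$objective) w_star <- 1
  if (!is.finite(opt$objective))
    stop("collective_optimal_w: minimisation failed to converge", call. = FALSE)
  eq <- equilibrium_sigma(w_star, n, gamma)
  list(w_star = w_star, sigma = eq$sigma, rho = eq$rho)
}

#' Best-response target weighting of a focal agent
#'
#' Given a population in which every other agent uses the target weighting
#' `w_pop`, the weighting minimising the focal agent's own equilibrium target
#' error has the closed form
#' \deqn{w' = \frac{\sigma^2 (1 + (n-1)\rho) + \gamma^2}
#'                 {n + \sigma^2 (1 + (n-1)\rho) + \gamma^2},}
#' where \eqn{\sigma, \rho} are the population equilibrium values at `w_pop`.
#'
#' @param w_pop Target weighting used by the rest of the population, `(0, 1]`.
#' @inheritParams equilibrium_sigma
#' @return The best-response weighting, a number in `(0, 1)`.
#' @examples
#' best_response_w(1, 10, 1)   # 2/12
#' @export
best_response_w <- function(w_pop, n, gamma) {
  n <- check_count(n, "n", lower = 2L)
  check_scalar(gamma, "gamma", lower = 0)
  eq <- equilibrium_sigma(w_pop, n, gamma)
  s <- eq$sigma^2 * (1 + (n - 1) * eq$rho) + gamma^2
  s / (n + s)
}

#' Evolutionarily stable target weighting
#'
#' Iterates [best_response_w()] from `w0 = 1` to its fixed point: the target
#' weighting at which no single agent can reduce its own target error by
#' deviating. Plain best-response iteration is used, with a damping factor of
#' 0.5 applied when oscillation is detected. The ESS weighting is always
#' below the collectively optimal weighting and yields a larger target error:
#' rational agents over-use social information relative to the group optimum.
#'
#' @inheritParams equilibrium_sigma
#' @param tol Absolute convergence tolerance on `w`.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A list with `w_ess`, the equilibrium `sigma` and `rho` at the ESS,
#'   and `iterations` used.
#' @examples
#' ess_w(10, 1)
#' @export
ess_w <- function(n, gamma, tol = 1e-8, max_iter = 1e4) {
  n <- check_count(n, "n", lower = 2L)
  check_scalar(gamma, "gamma", lower = 0, allow_lower = FALSE)
  w <- 1
  prev_step <- 0
  for (it in seq_len(max_iter)) {
    w_new <- best_response_w(w, n, gamma)
    step <- w_new - w
    # oscillation: consecutive steps of opposite sign; damp towards w_new
    if (prev_step * step < 0) w_new <- w + 0.5 * step
    if (abs(w_new - w) <= tol) {
      eq <- equilibrium_sigma(w_new, n, gamma)
      return(list(w_ess = w_new, sigma = eq$sigma, rho = eq$rho,
                  iterations = it))
    }
    prev_step <- w_new - w
    w <- w_new
  }
  stop(sprintf(
    "ess_w: best-response iteration did not converge in %d iterations (last w = %.10g, step = %.3g)",
    as.integer(max_iter), w, prev_step), call. = FALSE)
}
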