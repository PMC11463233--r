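# Two-type (expert/naive) groups. Type A agents receive environmental
# signals with unit variance, type B agents with variance epsilon^2
# (epsilon >= 1). Every agent splits its social attention between the two
# types: alpha is the relative weight on following type-A agents. The
# interaction noise gamma is uniform across all agents.
#
# The equilibrium is a 5-variable fixed point (sigmaA, sigmaB, rhoAA, rhoBB,
# rhoAB) of the coupled variance/correlation update equations, solved by
# fixed-point iteration from the purely-environmental initial state.

#' Parameters of a two-type (expert/naive) group
#'
#' @param nA,nB Number of type-A (expert) and type-B (naive) agents, each
#'   `>= 1`.
#' @param epsilon Environmental-noise standard deviation of type-B agents
#'   (type A is fixed at 1). Must be `>= 1`; `epsilon = 1` is the symmetric
#'   boundary case, useful for consistency checks against the homogeneous
#'   model although the expert/naive distinction is then vacuous.
#' @param gamma Interaction-noise standard deviation, uniform across agents.
#' @param wA,wB Target weightings of each type, in `[0, 1]`.
#' @param alphaA,alphaB Relative attention paid by each type to type-A agents
#'   (versus type-B agents), in `[0, 1]`.
#' @return An object of class `"mixed_params"`.
#' @examples
#' mixed_params(1, 9, epsilon = 4, gamma = 0.5, wA = 0.8, wB = 0.1)
#' @export
mixed_params <- function(nA, nB, epsilon, gamma,
                         wA = 1, wB = 1, alphaA = 0.5, alphaB = 0.5) {
  nA <- check_count(nA, "nA", lower = 1L)
  nB <- check_count(nB, "nB", lower = 1L)
  check_scalar(epsilon, "epsilon", lower = 1)
  check_scalar(gamma, "gamma", lower = 0)
  check_scalar(wA, "wA", lower = 0, upper = 1)
  check_scalar(wB, "wB", lower = 0, upper = 1)
  check_scalar(alphaA, "alphaA", lower = 0, upper = 1)
  check_scalar(alphaB, "alphaB", lower = 0, upper = 1)
  structure(list(nA = nA, nB = nB, epsilon = epsilon, gamma = gamma,
                 wA = wA, wB = wB, alphaA = alphaA, alphaB = alphaB),
            class = "mixed_params")
}

#' @export
print.mixed_params <- function(x, ...) {
  cat(sprintf(
    "Two-type group: nA = %d, nB = %d, epsilon = %.4g, gamma = %.4g\n",
    x$nA, x$nB, x$epsilon, x$gamma))
  cat(sprintf("  strategy: wA = %.6g, wB = %.6g, alphaA = %.6g, alphaB = %.6g\n",
              x$wA, x$wB, x$alphaA, x$alphaB))
  invisible(x)
}

# Variance of the alpha-weighted social term used by an agent with attention
# split `alpha`, given the state moments a = sigmaA^2 (1 + (nA-1) rhoAA),
# b = sigmaB^2 (1 + (nB-1) rhoBB), c = sigmaA sigmaB rhoAB. `noise = TRUE`
# includes the per-observation interaction noise (independent across
# observers, so it appears in variances but never in cross-covariances).
social_var <- function(alpha, a, b, c, nA, nB, gamma2, noise = TRUE) {
  v <- alpha^2 / nA * a + (1 - alpha)^2 / nB * b + 2 * alpha * (1 - alpha) * c
  if (noise) v <- v + (alpha^2 / nA + (1 - alpha)^2 / nB) * gamma2
  v
}

#' Equilibrium of a two-type group
#'
#' Solves the coupled equilibrium equations for the target errors and
#' estimate correlations of a two-type group by fixed-point iteration,
#' starting from the purely environmental state `sigmaA = 1`,
#' `sigmaB = epsilon`, all correlations 0.
#'
#' @param params A [mixed_params()] object.
#' @param tol Convergence tolerance: maximum absolute change of any state
#'   variable between successive iterations.
#' @param max_iter Iteration cap.
#' @return An object of class `"mixed_equilibrium"`: a list with `sigmaA`,
#'   `sigmaB`, `rhoAA`, `rhoBB`, `rhoAB`, plus `iterations` and `residual`
#'   (the maximum absolute violation of the equilibrium equations at the
#'   returned state).
#' @examples
#' p <- mixed_params(1, 9, epsilon = 4, gamma = 0.5, wA = 0.8, wB = 0.1)
#' mixed_equilibrium(p)
#' @export
mixed_equilibrium <- function(params, tol = 1e-10, max_iter = 1e5) {
  stopifnot(inherits(params, "mixed_params"))
  if (params$wA == 0 && params$wB == 0 && params$gamma > 0)
    stop("degenerate parameters: wA = wB = 0 admits no finite equilibrium",
         call. = FALSE)
  nA <- params$nA; nB <- params$nB
  e2 <- params$epsilon^2; g2 <- params$gamma^2
  wA <- params$wA; wB <- params$wB; aA <- params$alphaA; aB <- params$alphaB

  step <- function(st) {
    a <- st[1]^2 * (1 + (nA - 1) * st[3])
    b <- st[2]^2 * (1 + (nB - 1) * st[4])
    c <- st[1] * st[2] * st[5]
    sA2 <- wA^2 + (1 - wA)^2 * social_var(aA, a, b, c, nA, nB, g2)
    sB2 <- e2 * wB^2 + (1 - wB)^2 * social_var(aB, a, b, c, nA, nB, g2)
    # shared (noise-free) components give the new covariances
    covAA <- (1 - wA)^2 * social_var(aA, a, b, c, nA, nB, g2, noise = FALSE)
    covBB <- (1 - wB)^2 * social_var(aB, a, b, c, nA, nB, g2, noise = FALSE)
    covAB <- (1 - wA) * (1 - wB) *
      (aA * aB / nA * a + (1 - aA) * (1 - aB) / nB * b +
         (aA * (1 - aB) + aB * (1 - aA)) * c)
    sA <- sqrt(sA2); sB <- sqrt(sB2)
    c(sA, sB,
      if (nA > 1) covAA / sA2 else 0,
      if (nB > 1) covBB / sB2 else 0,
      covAB / (sA * sB))
  }

  st <- c(1, params$epsilon, 0, 0, 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st_new <- step(st)
    if (!all(is.finite(st_new)))
      stop("mixed_equilibrium: iteration diverged (non-finite state)",
           call. = FALSE)
    if (max(abs(st_new - st)) <= tol) { st <- st_new; converged <- TRUE; break }
    st <- st_new
  }
  residual <- max(abs(step(st) - st))
  if (!converged)
    stop(sprintf(
      "mixed_equilibrium: no convergence in %d iterations (residual %.3g)",
      as.integer(max_iter), residual), call. = FALSE)
  structure(list(sigmaA = st[1], sigmaB = st[2],
                 rhoAA = st[3], rhoBB = st[4], rhoAB = st[5],
                 iterations = it, residual = residual),
            class = "mixed_equilibrium")
}

#' @export
print.mixed_equilibrium <- function(x, ...) {
  cat(sprintf(
    "Two-type equilibrium: sigmaA = %.6g, sigmaB = %.6g\n  rhoAA = %.6g, rhoBB = %.6g, rhoAB = %.6g  (%d iterations)\n",
    x$sigmaA, x$sigmaB, x$rhoAA, x$rhoBB, x$rhoAB, x$iterations))
  invisible(x)
}

#' Collective target error of a two-type group
#'
#' The root-mean-square target error across all agents,
#' \deqn{\sqrt{(n_A \sigma_A^2 + n_B \sigma_B^2) / (n_A + n_B)},}
#' the group-level objective minimised by [collective_optimum()].
#'
#' @param eq A [mixed_equilibrium()] object (or any list with `sigmaA`,
#'   `sigmaB`).
#' @param nA,nB Type counts.
#' @return The collective target error (scalar).
#' @export
collective_error <- function(eq, nA, nB) {
  nA <- check_count(nA, "nA", lower = 1L)
  nB <- check_count(nB, "nB", lower = 1L)
  sqrt((nA * eq$sigmaA^2 + nB * eq$sigmaB^2) / (nA + nB))
}

#' Best-response strategy of focal agents in a two-type group
#'
#' Given the population strategy in `params` and its equilibrium `eq`,
#' returns the strategy minimising a focal agent's own equilibrium target
#' error while all other agents hold their strategy fixed. The attention
#' split has the closed form
#' \deqn{\alpha' = \zeta_B / (\zeta_A + \zeta_B), \qquad
#'   \zeta_X = \frac{\sigma_X^2 (1 + (n_X - 1)\rho_{XX}) + \gamma^2}{n_X}
#'             - \sigma_A \sigma_B \rho_{AB},}
#' identical for focal agents of both types (the private-signal variance does
#' not involve `alpha`), and the target weightings follow as
#' \eqn{w_A' = \psi/(1+\psi)}, \eqn{w_B' = \psi/(\epsilon^2+\psi)} with
#' \eqn{\psi} the social-term variance at \eqn{\alpha'}. These are the exact
#' stationarity conditions of the focal error; tests verify them against
#' direct numerical minimisation.
#'
#' @param params A [mixed_params()] object (the population strategy).
#' @param eq The equilibrium for `params`, from [mixed_equilibrium()].
#' @return A list with `wA`, `wB`, `alphaA`, `alphaB` (the last two equal by
#'   construction).
#' @export
mixed_best_response <- function(params, eq) {
  stopifnot(inherits(params, "mixed_params"))
  nA <- params$nA; nB <- params$nB; g2 <- params$gamma^2
  a <- eq$sigmaA^2 * (1 + (nA - 1) * eq$rhoAA)
  b <- eq$sigmaB^2 * (1 + (nB - 1) * eq$rhoBB)
  c <- eq$sigmaA * eq$sigmaB * eq$rhoAB
  zA <- (a + g2) / nA - c
  zB <- (b + g2) / nB - c
  if (zA + zB == 0)
    stop("mixed_best_response: zetaA + zetaB = 0, attention split undefined",
         call. = FALSE)
  alpha <- zB / (zA + zB)
  # the unconstrained stationary point can only be a minimum when
  # zA + zB > 0; otherwise, or outside [0,1], the constrained optimum is at
  # a boundary of the admissible attention range
  if (zA + zB > 0) {
    alpha <- min(1, max(0, alpha))
  } else {
    f <- function(al) social_var(al, a, b, c, nA, nB, g2)
    alpha <- if (f(0) <= f(1)) 0 else 1
  }
  psi <- social_var(alpha, a, b, c, nA, nB, g2)
  list(wA = psi / (1 + psi),
       wB = psi / (params$epsilon^2 + psi),
       alphaA = alpha, alphaB = alpha)
}

#' Evolutionarily stable strategy of a two-type group
#'
#' Alternates [mixed_equilibrium()] (full re-solve of the five state
#' variables) with [mixed_best_response()] until the four strategy parameters
#' reach a fixed point: the strategy from which no single agent of either
#' type can reduce its own target error by deviating. Iteration starts from
#' `wA = wB = 1`, `alphaA = alphaB = 1/2` (agents initially attend only to
#' their private signal), with a damping factor of 0.5 applied to oscillating
#' components.
#'
#' @param nA,nB Type counts.
#' @param epsilon,gamma Noise parameters as in [mixed_params()].
#' @param tol Absolute convergence tolerance on each strategy parameter.
#' @param max_iter Iteration cap.
#' @return A list with `params` (the ESS strategy, a [mixed_params()]
#'   object), `equilibrium` (its [mixed_equilibrium()]), and `iterations`.
#' @examples
#' mixed_ess(1, 9, epsilon = 4, gamma = 0.5)
#' @export
mixed_ess <- function(nA, nB, epsilon, gamma, tol = 1e-8, max_iter = 1e4) {
  par <- mixed_params(nA, nB, epsilon, gamma,
                      wA = 1, wB = 1, alphaA = 0.5, alphaB = 0.5)
  prev_step <- rep(0, 4)
  for (it in seq_len(max_iter)) {
    eq <- mixed_equilibrium(par)
    br <- mixed_best_response(par, eq)
    cur <- c(par$wA, par$wB, par$alphaA, par$alphaB)
    new <- c(br$wA, br$wB, br$alphaA, br$alphaB)
    step <- new - cur
    damp <- prev_step * step < 0
    new[damp] <- cur[damp] + 0.5 * step[damp]
    if (max(abs(new - cur)) <= tol) {
      par <- mixed_params(nA, nB, epsilon, gamma,
                          wA = new[1], wB = new[2],
                          alphaA = new[3], alphaB = new[4])
      return(list(params = par, equilibrium = mixed_equilibrium(par),
                  iterations = it))
    }
    prev_step <- new - cur
    par <- mixed_params(nA, nB, epsilon, gamma,
                        wA = new[1], wB = new[2],
                        alphaA = new[3], alphaB = new[4])
  }
  stop(sprintf(
    "mixed_ess: best-response alternation did not converge in %d iterations (last strategy: wA = %.8g, wB = %.8g, alpha = %.8g)",
    as.integer(max_iter), par$wA, par$wB, par$alphaA), call. = FALSE)
}

#' Collectively optimal strategy of a two-type group
#'
#' Minimises the collective (root-mean-square) target error
#' [collective_error()] over the four strategy parameters
#' `(wA, wB, alphaA, alphaB)` in `[0, 1]^4`, using Nelder--Mead in a
#' logit-transformed space so the parameters remain strictly inside the unit
#' box. Multiple restarts guard against local minima: the ESS strategy, the
#' symmetric strategy, and `restarts - 2` random draws.
#'
#' @inheritParams mixed_ess
#' @param restarts Number of Nelder--Mead restarts (`>= 2`; default 5).
#' @param seed Optional integer seed for the random restart points.
#' @return A list with `params` (optimal strategy), `equilibrium`,
#'   `collective_error` (the minimised objective), and `convergence` (0 for
#'   a clean Nelder--Mead exit at the best restart).
#' @examples
#' \donttest{collective_optimum(1, 9, epsilon = 4, gamma = 0.5)}
#' @export
collective_optimum <- function(nA, nB, epsilon, gamma, restarts = 5,
                               seed = NULL) {
  restarts <- check_count(restarts, "restarts", lower = 2L)
  if (!is.null(seed)) set.seed(seed)
  objective <- function(theta) {
    p <- inv_logit(theta)
    par <- mixed_params(nA, nB, epsilon, gamma,
                        wA = p[1], wB = p[2], alphaA = p[3], alphaB = p[4])
    eq <- tryCatch(mixed_equilibrium(par), error = function(e) NULL)
    if (is.null(eq)) return(1e10)
    collective_error(eq, nA, nB)
  }
  ess <- tryCatch(mixed_ess(nA, nB, epsilon, gamma), error = function(e) NULL)
  starts <- list()
  if (!is.null(ess))
    starts <- c(starts, list(logit(pmin(1 - 1e-9, pmax(1e-9, c(
      ess$params$wA, ess$params$wB, ess$params$alphaA, ess$params$alphaB))))))
  starts <- c(starts, list(rep(0, 4)))  # symmetric point (all parameters 1/2)
  while (length(starts) < restarts)
    starts <- c(starts, list(stats::runif(4, -2, 2)))

  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("collective_optimum: all restarts failed to converge", call. = FALSE)
  p <- inv_logit(best$par)
  par <- mixed_params(nA, nB, epsilon, gamma,
                      wA = p[1], wB = p[2], alphaA = p[3], alphaB = p[4])
  eq <- mixed_equilibrium(par)
  list(params = par, equilibrium = eq,
       collective_error = collective_error(eq, nA, nB),
       convergence = best$convergence)
}
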