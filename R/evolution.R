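# Evolution of navigational strategies under costly information.
#
# Each agent carries a genome (w, epsilon, gamma): its target weighting and
# the standard deviations of its private environmental noise and of the
# noise on its social observations. Precision is costly: fitness is
#   F_i = -sigma_i - epsilon_i^(-k) - gamma_i^(-k),
# with sigma_i the agent's equilibrium target error and k the information
# cost exponent. Agents trial local mutations one at a time and keep those
# that raise their own fitness; below a critical k this reliably produces
# divergent leader (high w, low epsilon, high gamma) and follower (low w,
# high epsilon, low gamma) phenotypes.

#' Per-agent genomes
#'
#' Bundles per-agent parameter vectors into a validated data frame used by
#' [equilibrium_covariance()], [agent_fitness()] and
#' [simulate_heterogeneous()].
#'
#' @param w Target weightings, in `[0, 1]`.
#' @param epsilon Environmental-noise standard deviations, `> 0`.
#' @param gamma Interaction-noise standard deviations, `> 0`.
#' @return A data frame of class `"agent_genomes"` with one row per agent.
#' @examples
#' agent_genomes(w = c(1, 0), epsilon = c(0.5, 3), gamma = c(3, 0.5))
#' @export
agent_genomes <- function(w, epsilon, gamma) {
  if (length(w) != length(epsilon) || length(w) != length(gamma))
    stop("'w', 'epsilon' and 'gamma' must have equal length", call. = FALSE)
  if (length(w) < 1L)
    stop("at least one agent is required", call. = FALSE)
  if (!all(is.finite(w)) || any(w < 0) || any(w > 1))
    stop("all 'w' must lie in [0, 1]", call. = FALSE)
  if (!all(is.finite(epsilon)) || any(epsilon <= 0))
    stop("all 'epsilon' must be > 0", call. = FALSE)
  if (!all(is.finite(gamma)) || any(gamma <= 0))
    stop("all 'gamma' must be > 0", call. = FALSE)
  structure(data.frame(w = w, epsilon = epsilon, gamma = gamma),
            class = c("agent_genomes", "data.frame"))
}

#' Equilibrium covariance of heterogeneous agents' estimates
#'
#' Iterates the covariance recursion of the heterogeneous update rule from
#' the zero matrix to its fixed point. Off-diagonal elements are
#' `(1 - w_k)(1 - w_l) V`, with `V` the variance of the group's average
#' estimate; diagonal elements add the private-signal and observation-noise
#' terms `w_k^2 eps_k^2 + (1 - w_k)^2 gam_k^2 / n`.
#'
#' @param genomes An [agent_genomes()] data frame.
#' @param tol Convergence tolerance on the maximum absolute elementwise
#'   change.
#' @param max_iter Iteration cap.
#' @return A list with `cov` (the `n x n` equilibrium covariance matrix),
#'   `sigma` (per-agent equilibrium target errors, the square roots of the
#'   diagonal) and `iterations`.
#' @examples
#' g <- agent_genomes(w = c(0.5, 0.5), epsilon = c(1, 1), gamma = c(1, 1))
#' equilibrium_covariance(g)$sigma   # matches equilibrium_sigma(0.5, 2, 1)
#' @export
equilibrium_covariance <- function(genomes, tol = 1e-10, max_iter = 1e5) {
  stopifnot(inherits(genomes, "agent_genomes"))
  n <- nrow(genomes)
  w <- genomes$w; e <- genomes$epsilon; g <- genomes$gamma
  if (all(w == 0))
    stop("degenerate genomes: all target weightings are zero, no finite equilibrium",
         call. = FALSE)
  u <- 1 - w
  own <- w^2 * e^2 + u^2 * g^2 / n  # per-agent private + observation noise
  C <- matrix(0, n, n)
  for (it in seq_len(max_iter)) {
    V <- sum(C) / n^2
    C_new <- outer(u, u) * V
    diag(C_new) <- diag(C_new) + own
    if (max(abs(C_new - C)) <= tol) {
      C <- C_new
      return(list(cov = C, sigma = sqrt(diag(C)), iterations = it))
    }
    C <- C_new
  }
  stop(sprintf(
    "equilibrium_covariance: no convergence in %d iterations",
    as.integer(max_iter)), call. = FALSE)
}

#' Fitness of one agent under costly information
#'
#' \deqn{F_i = -\sigma_i - \epsilon_i^{-k} - \gamma_i^{-k},}
#' where \eqn{\sigma_i} is the agent's equilibrium target error given the
#' whole group's genomes. Smaller noise parameters buy accuracy but cost
#' fitness directly; `k` tunes how steeply precision is priced.
#'
#' @param i Agent index (1-based).
#' @param genomes An [agent_genomes()] data frame.
#' @param k Information-cost exponent, `> 0`.
#' @return The fitness value (a negative number).
#' @export
agent_fitness <- function(i, genomes, k) {
  stopifnot(inherits(genomes, "agent_genomes"))
  i <- check_count(i, "i", lower = 1L)
  if (i > nrow(genomes)) stop("agent index out of range", call. = FALSE)
  check_scalar(k, "k", lower = 0, allow_lower = FALSE)
  sig <- equilibrium_covariance(genomes)$sigma[i]
  -sig - genomes$epsilon[i]^(-k) - genomes$gamma[i]^(-k)
}

#' Propose a local mutation of one genome
#'
#' `w` is perturbed additively (`N(w, sd^2)`, clipped to `[0, 1]`);
#' `epsilon` and `gamma` are perturbed multiplicatively on the log scale
#' (`log x' ~ N(log x, sd^2)`), so they stay positive. Draws use R's global
#' RNG stream.
#'
#' @param genome A one-row [agent_genomes()] data frame, or a list with
#'   `w`, `epsilon`, `gamma`.
#' @param sd Standard deviation of all three proposal perturbations.
#' @return A list with the mutated `w`, `epsilon`, `gamma`.
#' @export
propose_mutation <- function(genome, sd = 0.01) {
  check_scalar(sd, "sd", lower = 0)
  list(w = min(1, max(0, stats::rnorm(1, genome$w, sd))),
       epsilon = genome$epsilon * exp(stats::rnorm(1, 0, sd)),
       gamma = genome$gamma * exp(stats::rnorm(1, 0, sd)))
}

#' Classify the outcome of an evolutionary run
#'
#' A run counts as divergent (`"leader_follower"`) when the spread of final
#' target weightings exceeds `threshold`: the leader keeps attending to the
#' environment (`w` near 1) while followers stop (`w` near 0). Otherwise the
#' agents share a `"common_strategy"`.
#'
#' @param w Final target weightings (or an [agent_genomes()] data frame).
#' @param threshold Divergence threshold on `max(w) - min(w)`.
#' @return `"leader_follower"` or `"common_strategy"`.
#' @export
classify_outcome <- function(w, threshold = 0.5) {
  if (is.data.frame(w)) w <- w$w
  check_scalar(threshold, "threshold", lower = 0, upper = 1)
  if (max(w) - min(w) > threshold) "leader_follower" else "common_strategy"
}

#' Mutation-selection dynamics of navigational strategies
#'
#' Initialises `n` agents with `w ~ U(0,1)`, `epsilon ~ Exp(1)`,
#' `gamma ~ Exp(1)`, then for `steps` time steps picks one agent uniformly at
#' random, proposes a local mutation of its genome ([propose_mutation()])
#' and accepts it iff the agent's own fitness ([agent_fitness()]), evaluated
#' at the group's covariance equilibrium with all other agents fixed,
#' strictly increases. The inner loop runs in compiled code using the
#' closed-form covariance fixed point, so full-length runs are cheap; it
#' draws from R's RNG stream, so runs are exactly reproducible via `seed`.
#'
#' @param n Group size, `>= 2`.
#' @param k Information-cost exponent, `> 0`.
#' @param steps Number of mutation-trial steps (default `50000 * n`).
#' @param mutation_sd Proposal standard deviation (default 0.01).
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @param thin Interval between recorded genome snapshots.
#' @param criterion `"fitness"` (default) accepts on the full costly-
#'   information fitness; `"sigma"` accepts on target error alone, a variant
#'   under which the cost terms are inert and precision evolves without
#'   bound.
#' @param init Optional [agent_genomes()] data frame to start from instead
#'   of random initialisation.
#' @return An object of class `"evolution_trace"`: a list with `snapshots`
#'   (long data frame: `step`, `agent`, `w`, `epsilon`, `gamma`), `accepted`
#'   (per-step logical), `agent` (per-step acting agent), `final` (an
#'   [agent_genomes()] data frame), `outcome` (via [classify_outcome()]),
#'   `failures` (proposals rejected because they admitted no finite
#'   equilibrium) and the configuration used.
#' @examples
#' tr <- evolve(n = 2, k = 1, steps = 2000, seed = 1)
#' tr$outcome
#' @export
evolve <- function(n, k, steps = 50000 * n, mutation_sd = 0.01, seed = NULL,
                   thin = max(1L, steps %/% 500L),
                   criterion = c("fitness", "sigma"), init = NULL) {
  n <- check_count(n, "n", lower = 2L)
  check_scalar(k, "k", lower = 0, allow_lower = FALSE)
  steps <- check_count(steps, "steps", lower = 1L)
  check_scalar(mutation_sd, "mutation_sd", lower = 0, allow_lower = FALSE)
  thin <- check_count(thin, "thin", lower = 1L)
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(init)) {
    init <- agent_genomes(w = stats::runif(n),
                          epsilon = stats::rexp(n, 1),
                          gamma = stats::rexp(n, 1))
  } else {
    stopifnot(inherits(init, "agent_genomes"), nrow(init) == n)
  }

  res <- evolve_cpp(n, k, steps, mutation_sd, thin,
                    criterion == "sigma",
                    init$w, init$epsilon, init$gamma)
  if (res$failures > 0)
    warning(sprintf(
      "evolve: %d proposals admitted no finite equilibrium and were rejected",
      res$failures))

  n_snap <- length(res$snap_step)
  snapshots <- data.frame(
    step = rep(res$snap_step, times = n),
    agent = rep(seq_len(n), each = n_snap),
    w = as.vector(res$snap_w),
    epsilon = as.vector(res$snap_epsilon),
    gamma = as.vector(res$snap_gamma))
  final <- agent_genomes(res$final_w, res$final_epsilon, res$final_gamma)
  structure(list(snapshots = snapshots,
                 accepted = res$accepted,
                 agent = res$agent,
                 final = final,
                 outcome = classify_outcome(final),
                 failures = res$failures,
                 config = list(n = n, k = k, steps = steps,
                               mutation_sd = mutation_sd, seed = seed,
                               thin = thin, criterion = criterion)),
            class = "evolution_trace")
}

#' @export
print.evolution_trace <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Evolutionary run: n = %d, k = %.3g, %d steps (%.1f%% accepted)\n",
    cfg$n, cfg$k, cfg$steps, 100 * mean(x$accepted)))
  cat(sprintf("Outcome: %s\n", x$outcome))
  cat("Final genomes:\n")
  print(format(as.data.frame(x$final), digits = 4))
  invisible(x)
}

#' Bifurcation scan over the information-cost exponent
#'
#' Runs `replicates` independent evolutionary simulations ([evolve()]) at
#' each value of `k_grid` and classifies each outcome. The critical cost
#' exponent separating divergent (leader/follower) from common-strategy
#' populations is estimated as the midpoint between the largest `k` whose
#' replicates are majority-divergent and the smallest `k` whose replicates
#' are majority-common.
#'
#' @param k_grid Increasing vector of cost exponents to scan.
#' @param n Group size.
#' @param replicates Independent runs per grid value.
#' @param steps Steps per run (default `50000 * n`).
#' @param seed Optional integer seed set once before the scan.
#' @param mutation_sd,threshold Passed to [evolve()] and
#'   [classify_outcome()].
#' @return A list with `results` (one row per run and agent: `k`,
#'   `replicate`, `agent`, `final_w`, `final_epsilon`, `final_gamma`,
#'   `outcome`), `summary` (per-`k` proportion divergent), `critical_k`
#'   (estimated switch point, `NA` if the scan never switches) and
#'   `failures` (runs that errored, recorded but not fatal).
#' @examples
#' \donttest{bifurcation_scan(c(0.5, 2.5), n = 2, replicates = 3,
#'                            steps = 20000, seed = 1)}
#' @export
bifurcation_scan <- function(k_grid, n = 2, replicates = 10,
                             steps = 50000 * n, seed = NULL,
                             mutation_sd = 0.01, threshold = 0.5) {
  stopifnot(is.numeric(k_grid), length(k_grid) >= 1, !is.unsorted(k_grid))
  replicates <- check_count(replicates, "replicates", lower = 1L)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  failed <- data.frame(k = numeric(0), replicate = integer(0),
                       message = character(0))
  for (k in k_grid) {
    for (r in seq_len(replicates)) {
      tr <- tryCatch(
        evolve(n = n, k = k, steps = steps, mutation_sd = mutation_sd,
               thin = steps),
        error = function(e) e)
      if (inherits(tr, "error")) {
        failed <- rbind(failed, data.frame(k = k, replicate = r,
                                           message = conditionMessage(tr)))
        next
      }
      out <- classify_outcome(tr$final, threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, replicate = r, agent = seq_len(n),
        final_w = tr$final$w, final_epsilon = tr$final$epsilon,
        final_gamma = tr$final$gamma, outcome = out)
    }
  }
  results <- do.call(rbind, rows)
  per_run <- unique(results[, c("k", "replicate", "outcome")])
  summary <- stats::aggregate(outcome ~ k, data = per_run,
                              FUN = function(o) mean(o == "leader_follower"))
  names(summary)[2] <- "prop_divergent"
  div <- summary$k[summary$prop_divergent > 0.5]
  com <- summary$k[summary$prop_divergent <= 0.5]
  critical_k <- NA_real_
  if (length(div) && length(com)) {
    above <- com[com > max(div)]
    if (length(above)) critical_k <- (max(div) + min(above)) / 2
  }
  list(results = results, summary = summary, critical_k = critical_k,
       failures = failed)
}
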