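# Direct stochastic simulation of the heading-update rules. Serves as the
# independent check on every analytic equilibrium in the package: the
# simulators never call the closed-form/fixed-point code.
#
# Replicate trick: an agent's social term needs only the *sum* of its n
# observation errors, which is a single N(0, n gamma^2) draw, so each time
# step costs two R x n Gaussian matrices regardless of group size.

new_sim_summary <- function(x) structure(x, class = "collnav_sim")

#' @export
print.collnav_sim <- function(x, ...) {
  cat(sprintf("Monte Carlo summary: %d replicates x %d steps (burn-in %d)\n",
              x$config$replicates, x$config$steps, x$config$burn_in))
  if (!is.null(x$sigma_hat) && length(x$sigma_hat) == 1L)
    cat(sprintf("  sigma_hat = %.5g (se %.2g), rho_hat = %.5g (se %.2g)\n",
                x$sigma_hat, x$sigma_se, x$rho_hat, x$rho_se))
  invisible(x)
}

# pooled post-burn-in second moments with replicate-level standard errors;
# K_accum: R x n matrix accumulators filled by the caller
sim_moments <- function(ms_rep, pp_rep, n_post) {
  ms <- ms_rep / n_post   # per-replicate mean square (over agents, steps)
  pp <- pp_rep / n_post   # per-replicate mean pairwise product
  R <- length(ms)
  sigma2 <- mean(ms)
  sigma_hat <- sqrt(sigma2)
  sigma2_se <- stats::sd(ms) / sqrt(R)
  rho_rep <- pp / sigma2
  list(sigma_hat = sigma_hat,
       sigma_se = sigma2_se / (2 * sigma_hat),  # delta method for the sqrt
       rho_hat = mean(pp) / sigma2,
       rho_se = stats::sd(rho_rep) / sqrt(R))
}

#' Monte Carlo simulation of a homogeneous group
#'
#' Simulates `replicates` independent groups of `n` agents for `steps`
#' discrete time steps under the homogeneous update rule: each agent blends
#' a fresh unit-variance environmental signal (weight `w`) with the mean of
#' its noisy observations of all current estimates. Initial estimates are
#' purely environmental (`N(0, 1)`). Empirical target error and inter-agent
#' correlation are reported per step and pooled after the burn-in.
#'
#' @inheritParams equilibrium_sigma
#' @param steps Number of time steps (`>= 1`).
#' @param replicates Number of independent groups.
#' @param seed Optional integer seed.
#' @param burn_in Steps discarded before pooling equilibrium summaries
#'   (default `steps / 2`).
#' @return An object of class `"collnav_sim"`: per-step `sigma_t`, `rho_t`
#'   (length `steps`), pooled `sigma_hat`, `rho_hat` with replicate-based
#'   standard errors `sigma_se`, `rho_se`, the post-burn-in grand mean
#'   `mean_hat` with `mean_se`, and the configuration.
#' @examples
#' s <- simulate_homogeneous(0.5, 10, 1, steps = 50, replicates = 200, seed = 1)
#' s$sigma_hat
#' @export
simulate_homogeneous <- function(w, n, gamma, steps = 200, replicates = 2000,
                                 seed = NULL, burn_in = steps %/% 2) {
  n <- check_count(n, "n", lower = 2L)
  check_scalar(w, "w", lower = 0, upper = 1)
  check_scalar(gamma, "gamma", lower = 0)
  steps <- check_count(steps, "steps", lower = 1L)
  replicates <- check_count(replicates, "replicates", lower = 1L)
  burn_in <- check_count(burn_in, "burn_in", lower = 0L)
  if (burn_in >= steps) stop("'burn_in' must be < 'steps'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  R <- replicates
  K <- matrix(stats::rnorm(R * n), R, n)
  sigma_t <- rho_t <- numeric(steps)
  ms_rep <- pp_rep <- mean_rep <- numeric(R)
  n_post <- 0L

  for (t in seq_len(steps)) {
    Z <- matrix(stats::rnorm(R * n), R, n)
    Vsum <- matrix(stats::rnorm(R * n, 0, sqrt(n) * gamma), R, n)
    K <- w * Z + (1 - w) / n * (rowSums(K) + Vsum)

    rs <- rowSums(K); rq <- rowSums(K^2)
    sigma2 <- mean(rq) / n
    pairprod <- (rs^2 - rq) / (n * (n - 1))
    sigma_t[t] <- sqrt(sigma2)
    rho_t[t] <- mean(pairprod) / sigma2
    if (t > burn_in) {
      ms_rep <- ms_rep + rq / n
      pp_rep <- pp_rep + pairprod
      mean_rep <- mean_rep + rs / n
      n_post <- n_post + 1L
    }
  }

  mo <- sim_moments(ms_rep, pp_rep, n_post)
  mean_rep <- mean_rep / n_post
  new_sim_summary(c(
    list(sigma_t = sigma_t, rho_t = rho_t,
         mean_hat = mean(mean_rep),
         mean_se = stats::sd(mean_rep) / sqrt(R)),
    mo,
    list(config = list(w = w, n = n, gamma = gamma, steps = steps,
                       replicates = replicates, seed = seed,
                       burn_in = burn_in))))
}

#' Monte Carlo simulation of heterogeneous agents
#'
#' Simulates agents with per-agent genomes `(w, epsilon, gamma)` under the
#' heterogeneous update rule (each agent averages over all current
#' estimates, with its own observation noise), or -- when `params` is given
#' -- the two-type expert/naive rule in which each agent splits its social
#' attention between the types via `alpha`. Initial estimates are purely
#' environmental (`N(0, epsilon_i^2)`).
#'
#' @param genomes An [agent_genomes()] data frame (ignored when `params` is
#'   supplied).
#' @param params Optional [mixed_params()] object selecting the two-type
#'   layout: agents 1..nA are type A (`epsilon = 1`), the rest type B.
#' @inheritParams simulate_homogeneous
#' @return An object of class `"collnav_sim"` with per-agent pooled errors
#'   `sigma_hat` (vector), the pooled empirical covariance matrix `cov_hat`
#'   with elementwise standard errors `cov_se`, per-step pooled `sigma_t`,
#'   and -- in the two-type layout -- per-type summaries `sigmaA_hat`,
#'   `sigmaB_hat`, `rhoAA_hat`, `rhoBB_hat`, `rhoAB_hat`.
#' @examples
#' g <- agent_genomes(w = c(0.8, 0.2), epsilon = c(1, 2), gamma = c(0.5, 0.5))
#' simulate_heterogeneous(g, steps = 50, replicates = 200, seed = 1)$sigma_hat
#' @export
simulate_heterogeneous <- function(genomes = NULL, steps = 200,
                                   replicates = 2000, seed = NULL,
                                   burn_in = steps %/% 2, params = NULL) {
  steps <- check_count(steps, "steps", lower = 1L)
  replicates <- check_count(replicates, "replicates", lower = 1L)
  burn_in <- check_count(burn_in, "burn_in", lower = 0L)
  if (burn_in >= steps) stop("'burn_in' must be < 'steps'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  two_type <- !is.null(params)
  if (two_type) {
    stopifnot(inherits(params, "mixed_params"))
    nA <- params$nA; nB <- params$nB; n <- nA + nB
    eps <- c(rep(1, nA), rep(params$epsilon, nB))
    wv <- c(rep(params$wA, nA), rep(params$wB, nB))
    alpha <- c(rep(params$alphaA, nA), rep(params$alphaB, nB))
    gam <- rep(params$gamma, n)
    idxA <- seq_len(nA); idxB <- nA + seq_len(nB)
  } else {
    stopifnot(inherits(genomes, "agent_genomes"))
    n <- nrow(genomes)
    if (n < 2L) stop("at least 2 agents are required", call. = FALSE)
    wv <- genomes$w; eps <- genomes$epsilon; gam <- genomes$gamma
  }

  R <- replicates
  K <- matrix(stats::rnorm(R * n, 0, rep(eps, each = R)), R, n)
  sigma_t <- matrix(0, steps, n)
  # replicate-level accumulators for all unordered pairs incl. self-pairs
  pair_i <- sequence(seq_len(n))
  pair_j <- rep(seq_len(n), times = seq_len(n))
  # (pair_i, pair_j) enumerate i <= j column-wise
  PP <- matrix(0, R, length(pair_i))
  mean_rep <- numeric(R)
  n_post <- 0L

  for (t in seq_len(steps)) {
    Z <- matrix(stats::rnorm(R * n, 0, rep(eps, each = R)), R, n)
    if (two_type) {
      sA <- rowSums(K[, idxA, drop = FALSE]); sB <- rowSums(K[, idxB, drop = FALSE])
      NA_sum <- matrix(stats::rnorm(R * n, 0, sqrt(nA) * rep(gam, each = R)), R, n)
      NB_sum <- matrix(stats::rnorm(R * n, 0, sqrt(nB) * rep(gam, each = R)), R, n)
      soc <- sweep(sA + NA_sum, 2, alpha / nA, "*") +
        sweep(sB + NB_sum, 2, (1 - alpha) / nB, "*")
      K <- sweep(Z, 2, wv, "*") + sweep(soc, 2, 1 - wv, "*")
    } else {
      Vsum <- matrix(stats::rnorm(R * n, 0, sqrt(n) * rep(gam, each = R)), R, n)
      soc <- (rowSums(K) + Vsum) / n
      K <- sweep(Z, 2, wv, "*") + sweep(soc, 2, 1 - wv, "*")
    }
    sigma_t[t, ] <- sqrt(colMeans(K^2))
    if (t > burn_in) {
      PP <- PP + K[, pair_i] * K[, pair_j]
      mean_rep <- mean_rep + rowMeans(K)
      n_post <- n_post + 1L
    }
  }

  PP <- PP / n_post
  mean_rep <- mean_rep / n_post
  cov_hat <- matrix(0, n, n)
  cov_se <- matrix(0, n, n)
  m <- colMeans(PP)
  se <- apply(PP, 2, stats::sd) / sqrt(R)
  for (p in seq_along(pair_i)) {
    i <- pair_i[p]; j <- pair_j[p]
    cov_hat[i, j] <- cov_hat[j, i] <- m[p]
    cov_se[i, j] <- cov_se[j, i] <- se[p]
  }

  out <- list(sigma_t = sigma_t,
              sigma_hat = sqrt(diag(cov_hat)),
              cov_hat = cov_hat, cov_se = cov_se,
              mean_hat = mean(mean_rep),
              mean_se = stats::sd(mean_rep) / sqrt(R),
              config = list(steps = steps, replicates = replicates,
                            seed = seed, burn_in = burn_in,
                            two_type = two_type))
  if (two_type) {
    off_mean <- function(M, idx, idy) {
      S <- M[idx, idy, drop = FALSE]
      if (identical(idx, idy)) {
        if (length(idx) < 2L) return(NA_real_)
        mean(S[row(S) != col(S)])
      } else mean(S)
    }
    sA2 <- mean(diag(cov_hat)[idxA]); sB2 <- mean(diag(cov_hat)[idxB])
    out$sigmaA_hat <- sqrt(sA2)
    out$sigmaB_hat <- sqrt(sB2)
    out$rhoAA_hat <- off_mean(cov_hat, idxA, idxA) / sA2
    out$rhoBB_hat <- off_mean(cov_hat, idxB, idxB) / sB2
    out$rhoAB_hat <- off_mean(cov_hat, idxA, idxB) / sqrt(sA2 * sB2)
  }
  new_sim_summary(out)
}
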