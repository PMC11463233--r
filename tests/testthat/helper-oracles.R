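# Independent oracles, written directly from the model's dynamic update
# rules. They never call the package's equilibrium or best-response code, so
# agreement is a genuine two-route check.

# Fixed point of the homogeneous variance/correlation recursion, iterated
# dynamically from the purely environmental state (sigma0 = 1, rho0 = 0).
oracle_homog_fixed_point <- function(w, n, gamma, tol = 1e-12,
                                     max_iter = 1e6) {
  s2 <- 1; rho <- 0
  for (i in seq_len(max_iter)) {
    s2_new <- w^2 + (1 - w)^2 / n * (s2 * (1 + (n - 1) * rho)) +
      (1 - w)^2 / n * gamma^2
    rho_new <- (s2 / s2_new) * (1 + (n - 1) * rho) * (1 - w)^2 / n
    if (abs(s2_new - s2) < tol && abs(rho_new - rho) < tol) {
      return(list(sigma = sqrt(s2_new), rho = rho_new))
    }
    s2 <- s2_new; rho <- rho_new
  }
  stop("oracle did not converge")
}

# Best-response weighting by direct numerical minimisation of the focal
# agent's error variance, given population equilibrium statistics.
oracle_best_response <- function(w_pop, n, gamma) {
  pop <- oracle_homog_fixed_point(w_pop, n, gamma)
  s2 <- pop$sigma^2; rho <- pop$rho
  f <- function(wp) {
    wp^2 + (1 - wp)^2 / n * (s2 * (1 + (n - 1) * rho)) +
      (1 - wp)^2 / n * gamma^2
  }
  # coarse grid bracket, then golden-section polish
  ws <- seq(0.001, 0.999, by = 0.001)
  i <- which.min(vapply(ws, f, numeric(1)))
  stats::optimize(f, lower = max(1e-6, ws[i] - 0.001),
                  upper = min(1 - 1e-6, ws[i] + 0.001), tol = 1e-10)$minimum
}

# Error variance of a focal agent of the given type deviating to strategy
# (wp, alpha) against a two-type population at equilibrium `eq`. Built
# straight from the two-type update rule's variance algebra.
oracle_mixed_focal_var <- function(wp, alpha, type, params, eq) {
  nA <- params$nA; nB <- params$nB; g2 <- params$gamma^2
  a <- eq$sigmaA^2 * (1 + (nA - 1) * eq$rhoAA)
  b <- eq$sigmaB^2 * (1 + (nB - 1) * eq$rhoBB)
  cc <- eq$sigmaA * eq$sigmaB * eq$rhoAB
  soc <- alpha^2 / nA * a + (1 - alpha)^2 / nB * b +
    2 * alpha * (1 - alpha) * cc +
    (alpha^2 / nA + (1 - alpha)^2 / nB) * g2
  env <- if (type == "A") 1 else params$epsilon^2
  wp^2 * env + (1 - wp)^2 * soc
}

# 2-D grid minimiser of the focal error over (w', alpha').
oracle_mixed_best_response <- function(type, params, eq, grid = 401) {
  ws <- seq(0, 1, length.out = grid)
  als <- seq(0, 1, length.out = grid)
  best <- c(Inf, NA, NA)
  for (al in als) {
    v <- oracle_mixed_focal_var(ws, al, type, params, eq)
    i <- which.min(v)
    if (v[i] < best[1]) best <- c(v[i], ws[i], al)
  }
  list(var = best[1], w = best[2], alpha = best[3])
}
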