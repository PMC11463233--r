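test_that("closed-form equilibrium matches the dynamic recursion fixed point", {
  # frozen spot values first
  expect_equal(equilibrium_rho(0.5, 10), 0.25 / 7.75, tolerance = 1e-12)
  expect_equal(equilibrium_rho(1, 10), 0)
  expect_equal(equilibrium_rho(0.999, 2), 1e-6 / (2 - 1e-6), tolerance = 1e-9)
  eq <- equilibrium_sigma(0.5, 10, 1)
  expect_equal(eq$sigma^2, 2.75 / (10 - 0.25 * (1 + 9 * 0.25 / 7.75)),
               tolerance = 1e-12)
  expect_equal(equilibrium_sigma(1, 10, 7)$sigma, 1)

  # oracle equivalence over a parameter grid
  for (w in c(0.05, 0.3, 0.7, 1)) {
    for (n in c(2, 5, 25)) {
      for (gamma in c(0, 0.5, 2)) {
        fp <- oracle_homog_fixed_point(w, n, gamma)
        eq <- equilibrium_sigma(w, n, gamma)
        expect_equal(eq$sigma, fp$sigma, tolerance = 1e-8,
                     label = sprintf("sigma at (w=%g,n=%d,gamma=%g)", w, n, gamma))
        expect_equal(eq$rho, fp$rho, tolerance = 1e-8,
                     label = sprintf("rho at (w=%g,n=%d,gamma=%g)", w, n, gamma))
      }
    }
  }
})

test_that("degenerate and invalid parameters are rejected", {
  expect_error(equilibrium_rho(0, 10), "degenerate")
  expect_error(equilibrium_sigma(0, 10, 1), "degenerate")
  expect_error(equilibrium_rho(1.2, 10), "admissible range")
  expect_error(equilibrium_rho(0.5, 1), "integer >= 2")
  expect_error(equilibrium_sigma(0.5, 10, -1), "admissible range")
})

test_that("optimal target weighting tracks noise and group size", {
  # gamma -> Inf: social channel useless, w* -> 1 and sigma -> 1
  hi <- collective_optimal_w(10, 1e3)
  expect_lt(abs(hi$w_star - 1), 1e-2)
  expect_lt(abs(hi$sigma - 1), 1e-3)
  # gamma -> 0: w* -> 0
  expect_lt(collective_optimal_w(10, 1e-3)$w_star, 0.05)
  # monotone decreasing in n at fixed gamma
  ws <- vapply(c(2, 10, 50), function(n) collective_optimal_w(n, 0.5)$w_star,
               numeric(1))
  expect_true(all(diff(ws) < 0))
  # monotone increasing in gamma at fixed n
  wg <- vapply(c(0.1, 0.5, 1, 2, 5), function(g) collective_optimal_w(10, g)$w_star,
               numeric(1))
  expect_true(all(diff(wg) > 0))
  # sigma at the optimum decreases with group size
  sg <- vapply(c(2, 10, 50), function(n) collective_optimal_w(n, 0.5)$sigma,
               numeric(1))
  expect_true(all(diff(sg) < 0))
})

test_that("best response matches direct numerical minimisation", {
  expect_equal(best_response_w(1, 10, 1), 2 / 12, tolerance = 1e-12)
  # gamma huge: best response stays at the environmental extreme
  expect_gt(best_response_w(1, 10, 1e4), 0.999)
  for (w_pop in c(0.2, 0.6, 1)) {
    for (gamma in c(0.3, 1, 3)) {
      expect_equal(best_response_w(w_pop, 10, gamma),
                   oracle_best_response(w_pop, 10, gamma), tolerance = 1e-5,
                   label = sprintf("best response at (w=%g, gamma=%g)", w_pop, gamma))
    }
  }
  # the best response is a minimum of the focal error, not just a stationary
  # point: nudging w' either way can only increase the error
  pop <- equilibrium_sigma(0.6, 10, 1)
  s2 <- pop$sigma^2 * (1 + 9 * pop$rho)
  f <- function(wp) wp^2 + (1 - wp)^2 / 10 * s2 + (1 - wp)^2 / 10
  wb <- best_response_w(0.6, 10, 1)
  expect_lte(f(wb), f(wb + 0.01))
  expect_lte(f(wb), f(wb - 0.01))
})

test_that("the ESS is a best-response fixed point dominated by the optimum", {
  ess <- ess_w(10, 1)
  expect_lt(abs(best_response_w(ess$w_ess, 10, 1) - ess$w_ess), 1e-7)
  opt <- collective_optimal_w(10, 1)
  expect_lt(ess$w_ess, opt$w_star)
  expect_gt(ess$sigma, opt$sigma)
  # near-useless social channel: ESS collapses to the environmental signal
  expect_lt(abs(ess_w(2, 1e3)$w_ess - 1), 1e-2)
})
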