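test_that("the two-type equilibrium collapses to the homogeneous one under symmetry", {
  p <- mixed_params(5, 5, 1, 1, wA = 0.5, wB = 0.5, alphaA = 0.5, alphaB = 0.5)
  eq <- mixed_equilibrium(p)
  expect_equal(eq$sigmaA, eq$sigmaB, tolerance = 1e-9)
  expect_equal(eq$rhoAA, eq$rhoBB, tolerance = 1e-9)
  expect_equal(eq$rhoAA, eq$rhoAB, tolerance = 1e-9)
  # with attention split matching the group proportions, the two-type update
  # is algebraically the homogeneous update for n = nA + nB
  hom <- equilibrium_sigma(0.5, 10, 1)
  expect_equal(eq$sigmaA, hom$sigma, tolerance = 1e-8)
  expect_equal(eq$rhoAB, hom$rho, tolerance = 1e-8)
  expect_lte(eq$residual, 1e-8)
})

test_that("the two-type equilibrium matches Monte Carlo simulation", {
  p <- mixed_params(1, 9, 4, 0.5, wA = 0.8, wB = 0.1,
                    alphaA = 0.5, alphaB = 0.5)
  eq <- mixed_equilibrium(p)
  s <- simulate_heterogeneous(params = p, steps = 200, replicates = 2000,
                              seed = 421)
  # pooled empirical moments carry sampling error; 3 standard errors on the
  # variances translated to the sigma scale
  expect_lt(abs(s$sigmaA_hat - eq$sigmaA), 3 * s$cov_se[1, 1] / (2 * eq$sigmaA))
  sB_se <- mean(diag(s$cov_se)[-1]) / (2 * eq$sigmaB)  # conservative: no pooling gain
  expect_lt(abs(s$sigmaB_hat - eq$sigmaB), 3 * sB_se)
  expect_lt(abs(s$rhoAB_hat - eq$rhoAB), 0.02)
  expect_lt(abs(s$rhoBB_hat - eq$rhoBB), 0.02)
})

test_that("degenerate two-type parameters are rejected", {
  expect_error(mixed_params(1, 9, 0.5, 1), "admissible range")
  p <- mixed_params(1, 9, 4, 1, wA = 0, wB = 0)
  expect_error(mixed_equilibrium(p), "degenerate")
})

test_that("closed-form best responses minimise the focal error (oracle grid)", {
  cases <- list(
    mixed_params(1, 9, 4, 0.5, wA = 1, wB = 1, alphaA = 0.5, alphaB = 0.5),
    mixed_params(1, 9, 4, 0.5, wA = 0.6, wB = 0.2, alphaA = 0.3, alphaB = 0.3),
    mixed_params(3, 7, 2, 1, wA = 0.4, wB = 0.4, alphaA = 0.6, alphaB = 0.4))
  for (p in cases) {
    eq <- mixed_equilibrium(p)
    br <- mixed_best_response(p, eq)
    # identical attention split for both types, by construction
    expect_identical(br$alphaA, br$alphaB)
    for (type in c("A", "B")) {
      o <- oracle_mixed_best_response(type, p, eq)
      wb <- if (type == "A") br$wA else br$wB
      # the grid oracle resolves the minimiser only to its spacing (1/400)
      expect_lt(abs(wb - o$w), 5e-3,
                label = sprintf("w' for type %s", type))
      expect_lt(abs(br$alphaA - o$alpha), 5e-3,
                label = sprintf("alpha' for type %s", type))
      # and the closed form is at least as good as the grid winner
      expect_lte(oracle_mixed_focal_var(wb, br$alphaA, type, p, eq),
                 o$var + 1e-10)
    }
  }
  # full symmetry: equal attention to both halves of the group
  ps <- mixed_params(5, 5, 1, 1, wA = 0.5, wB = 0.5)
  brs <- mixed_best_response(ps, mixed_equilibrium(ps))
  expect_equal(brs$alphaA, 0.5, tolerance = 1e-9)
})

test_that("collective error is the RMS of per-agent errors", {
  mk <- function(sa, sb) list(sigmaA = sa, sigmaB = sb)
  expect_equal(collective_error(mk(3, 3), 4, 6), 3)
  expect_equal(collective_error(mk(1, 2), 1, 9), sqrt(3.7))
  expect_equal(collective_error(mk(0, 2), 5, 5), 2 / sqrt(2))
})

test_that("the symmetric ESS coincides with the homogeneous ESS", {
  es <- mixed_ess(5, 5, 1, 1)
  expect_equal(es$params$wA, es$params$wB, tolerance = 1e-7)
  expect_equal(es$params$alphaA, 0.5, tolerance = 1e-6)
  expect_equal(es$params$wA, ess_w(10, 1)$w_ess, tolerance = 1e-6)
})

test_that("expert/naive ESS and optimum behave as expected across epsilon", {
  ess <- lapply(c(1, 4, 16), function(e) mixed_ess(1, 9, e, 0.5))
  wB <- vapply(ess, function(x) x$params$wB, numeric(1))
  al <- vapply(ess, function(x) x$params$alphaA, numeric(1))
  expect_true(all(diff(wB) < 0))        # naive agents abandon their signal
  expect_true(all(diff(al) > 0))        # attention shifts towards the expert
  expect_true(all(al < 1))              # but naive headings stay informative
  e16 <- ess[[3]]
  expect_gt(e16$equilibrium$sigmaB, e16$equilibrium$sigmaA)
  expect_identical(e16$params$alphaA, e16$params$alphaB)

  opt <- collective_optimum(1, 9, 16, 0.5, seed = 99)
  expect_gt(opt$params$wA, e16$params$wA)     # optimum demands a more
  expect_gt(opt$params$alphaA, e16$params$alphaA)  # environment-focused expert
  expect_lte(opt$collective_error,
             collective_error(e16$equilibrium, 1, 9) + 1e-9)
})

test_that("the symmetric collective optimum is symmetric", {
  opt <- collective_optimum(5, 5, 1, 1, seed = 7)
  expect_equal(opt$params$wA, opt$params$wB, tolerance = 1e-3)
  expect_equal(opt$params$alphaA, 0.5, tolerance = 5e-3)
  # and matches the homogeneous optimum for n = 10
  expect_equal(opt$collective_error, collective_optimal_w(10, 1)$sigma,
               tolerance = 1e-5)
})
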