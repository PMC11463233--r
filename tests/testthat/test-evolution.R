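test_that("the covariance fixed point reproduces known equilibria", {
  # no social coupling: estimates are fresh private signals
  g <- agent_genomes(w = c(1, 1), epsilon = c(0.5, 3), gamma = c(1, 1))
  ec <- equilibrium_covariance(g)
  expect_equal(ec$cov, diag(c(0.25, 9)), tolerance = 1e-9)
  expect_equal(ec$sigma, c(0.5, 3), tolerance = 1e-9)

  # homogeneous genomes recover the homogeneous closed form exactly
  for (w in c(0.2, 0.7)) {
    for (gamma in c(0.5, 2)) {
      gh <- agent_genomes(w = rep(w, 2), epsilon = c(1, 1),
                          gamma = rep(gamma, 2))
      expect_equal(equilibrium_covariance(gh)$sigma,
                   rep(equilibrium_sigma(w, 2, gamma)$sigma, 2),
                   tolerance = 1e-8,
                   label = sprintf("sigma at (w=%g, gamma=%g)", w, gamma))
    }
  }

  # any valid fixed point is a symmetric PSD covariance
  set.seed(3)
  for (i in 1:5) {
    gr <- agent_genomes(w = runif(4), epsilon = rexp(4) + 0.1,
                        gamma = rexp(4) + 0.1)
    C <- equilibrium_covariance(gr)$cov
    expect_equal(C, t(C))
    expect_gte(min(eigen(C, symmetric = TRUE)$values), -1e-10)
  }

  expect_error(
    equilibrium_covariance(agent_genomes(c(0, 0), c(1, 1), c(1, 1))),
    "degenerate")
})

test_that("the covariance fixed point matches Monte Carlo simulation", {
  g <- agent_genomes(w = c(0.9, 0.3, 0.5), epsilon = c(0.8, 2, 1),
                     gamma = c(0.4, 1, 0.7))
  ec <- equilibrium_covariance(g)
  s <- simulate_heterogeneous(g, steps = 200, replicates = 2000, seed = 37)
  expect_true(all(abs(ec$cov - s$cov_hat) <= 3 * s$cov_se))
})

test_that("fitness combines equilibrium error with information costs", {
  g <- agent_genomes(w = c(1, 1), epsilon = c(1, 1), gamma = c(1, 1))
  expect_equal(agent_fitness(1, g, 1), -3, tolerance = 1e-9)
  expect_equal(agent_fitness(1, g, 2), -3, tolerance = 1e-9)  # unit costs
  # cheapening social precision (larger gamma) raises fitness when w = 1
  g2 <- agent_genomes(w = c(1, 1), epsilon = c(1, 1), gamma = c(10, 1))
  expect_gt(agent_fitness(1, g2, 1), agent_fitness(1, g, 1))
})

test_that("mutation proposals have the stated law and respect bounds", {
  base <- list(w = 0.5, epsilon = 1, gamma = 1)
  # zero spread leaves the genome unchanged
  expect_equal(propose_mutation(base, sd = 0), base)
  set.seed(12)
  props <- replicate(1e4, unlist(propose_mutation(base, sd = 0.01)))
  expect_equal(sd(props["w", ]), 0.01, tolerance = 0.05)
  expect_equal(sd(log(props["epsilon", ])), 0.01, tolerance = 0.05)
  expect_equal(sd(log(props["gamma", ])), 0.01, tolerance = 0.05)
  # clipping keeps w inside the unit interval
  set.seed(13)
  hi <- replicate(500, propose_mutation(list(w = 1, epsilon = 1, gamma = 1))$w)
  expect_true(all(hi <= 1))
})

test_that("evolution runs are reproducible and fitness-monotone for the actor", {
  tr1 <- evolve(n = 2, k = 1, steps = 3000, seed = 5, thin = 1)
  tr2 <- evolve(n = 2, k = 1, steps = 3000, seed = 5, thin = 1)
  expect_identical(tr1$snapshots, tr2$snapshots)
  expect_identical(tr1$accepted, tr2$accepted)

  # replay a short window: every accepted step must strictly raise the
  # acting agent's fitness, recomputed independently in R
  snap <- tr1$snapshots
  at <- function(step) {
    s <- snap[snap$step == step, ]
    agent_genomes(s$w[order(s$agent)], s$epsilon[order(s$agent)],
                  s$gamma[order(s$agent)])
  }
  for (t in 1:300) {
    if (tr1$accepted[t]) {
      a <- tr1$agent[t]
      expect_gt(agent_fitness(a, at(t), 1), agent_fitness(a, at(t - 1), 1))
    } else {
      expect_identical(at(t), at(t - 1))
    }
  }

  # snapshot bookkeeping
  expect_equal(length(unique(tr1$snapshots$step)), 3000 + 1)
  tr3 <- evolve(n = 2, k = 1, steps = 1000, seed = 5, thin = 300)
  expect_equal(sort(unique(tr3$snapshots$step)), c(0, 300, 600, 900))
})

test_that("divergent runs pair a leading with a following phenotype", {
  n_div <- 0
  for (s in 1:20) {
    tr <- evolve(n = 2, k = 1, steps = 20000, seed = 400 + s)
    if (tr$outcome == "leader_follower") {
      n_div <- n_div + 1
      lead <- which.max(tr$final$w)
      expect_equal(which.min(tr$final$epsilon), lead)
      expect_equal(which.max(tr$final$gamma), lead)
    }
  }
  expect_gt(n_div, 5)  # divergence is the typical outcome at k = 1
})

test_that("outcomes are classified by the spread of final target weightings", {
  expect_equal(classify_outcome(c(0.95, 0.03)), "leader_follower")
  expect_equal(classify_outcome(c(0.9, 0.88)), "common_strategy")
  expect_equal(classify_outcome(c(0.5, 0.5)), "common_strategy")
  expect_equal(classify_outcome(c(0.9, 0.2), threshold = 0.6),
               "leader_follower")
})

test_that("the bifurcation scan locates the divergence/convergence switch", {
  sc <- bifurcation_scan(c(0.5, 1, 2, 2.5), n = 2, replicates = 5,
                         steps = 20000, seed = 77)
  expect_equal(nrow(sc$results), 4 * 5 * 2)
  expect_named(sc$results, c("k", "replicate", "agent", "final_w",
                             "final_epsilon", "final_gamma", "outcome"))
  expect_gt(sc$summary$prop_divergent[1], 0.5)   # cheap information: diverge
  expect_lt(sc$summary$prop_divergent[4], 0.5)   # dear information: converge
  expect_true(sc$critical_k > 0.5 && sc$critical_k < 2.5)
})
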