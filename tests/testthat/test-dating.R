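# Tip dating: priors, coalescent density, clock, MCMC behaviour, and
# posterior summaries.

test_that("two contemporaneous tips give the closed-form coalescent density", {
  topo <- ape::read.tree(text = "(A:1,B:1);")
  for (t in c(0.3, 1, 4)) {
    for (ne in c(0.5, 2)) {
      dt <- dated_tree(topo, c(0, 0, t))
      expect_equal(coalescent_logprior(dt, ne), -log(ne) - t / ne,
                   tolerance = 1e-12)
    }
  }
})

test_that("a serial three-tip tree matches the hand-computed density", {
  # tips at 0, 0, 0.5; coalescences at 0.3 (the two contemporaneous
  # tips) and 1.2. Intervals: [0,0.3) k=2; [0.3,0.5) k=1; [0.5,1.2) k=2.
  topo <- ape::read.tree(text = "((A:0.3,B:0.3):0.9,C:0.7);")
  dt <- dated_tree(topo, c(0, 0, 0.5, 1.2, 0.3))
  ne <- 0.8
  hand <- -2 * log(ne) - (1 / ne) * (0.3 + 0 + 0.7)
  expect_equal(coalescent_logprior(dt, ne), hand, tolerance = 1e-12)
})

test_that("the two-tip coalescent density integrates to one", {
  ne <- 0.7
  dens <- function(t) sapply(t, function(ti)
    exp(coalescent_logprior(list(tip_ages = c(0, 0), node_ages = ti), ne)))
  total <- stats::integrate(dens, 0, Inf)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("impossible serial configurations have zero density", {
  # both coalescences before the late sample arrives
  expect_identical(
    coalescent_logprior(list(tip_ages = c(0, 0, 5),
                             node_ages = c(1, 2)), 1), -Inf)
})

test_that("the ULN clock prior is additive and matches the lognormal pdf", {
  r <- c(0.01, 0.02, 0.05)
  ml <- log(0.02); sl <- 0.4
  expect_equal(uln_clock_logprior(r, ml, sl),
               sum(sapply(r, uln_clock_logprior, meanlog = ml, sdlog = sl)))
  expect_equal(uln_clock_logprior(0.02, ml, sl),
               stats::dlnorm(0.02, ml, sl, log = TRUE))
  # tightening sigma around the mode concentrates the density
  expect_gt(uln_clock_logprior(exp(ml), ml, 0.01),
            uln_clock_logprior(exp(ml), ml, 1))
})

test_that("HPD intervals are the shortest windows at the stated mass", {
  x <- 1:100
  h <- hpd_interval(x)
  expect_equal(h[2] - h[1], 94)
  expect_identical(hpd_interval(rep(3.5, 50)), c(3.5, 3.5))
  skewed <- c(rep(1, 90), seq(10, 100, length.out = 10))
  h2 <- hpd_interval(skewed)
  expect_identical(h2[1], 1)
  expect_lt(h2[2], 100)
})

test_that("posterior summaries report median, HPD, and ESS per parameter", {
  tr <- data.frame(gen = 1:100, a = 1:100, b = rep(2, 100))
  s <- summarize_posterior(tr, burn_in_frac = 0)
  expect_equal(s$median[s$param == "a"], 50.5)
  expect_equal(s$hpd_upper[s$param == "b"], 2)
  expect_equal(s$hpd_lower[s$param == "b"], 2)
  expect_true(all(s$hpd_lower <= s$median & s$median <= s$hpd_upper))
  # invariant to sample order
  perm <- tr[sample(100), ]
  s2 <- summarize_posterior(perm, burn_in_frac = 0)
  expect_equal(s2$median, s$median)
  expect_equal(s2$hpd_lower, s$hpd_lower)
  # burn-in removal
  s3 <- summarize_posterior(tr, burn_in_frac = 0.5)
  expect_equal(s3$median[s3$param == "a"], 75.5)
  expect_error(summarize_posterior(tr[0, ], 0), "no samples|empty")
})

test_that("the sampling interval must divide the chain length", {
  expect_error(mcmc_config(n_gen = 1000, thin = 300), "divide")
  expect_silent(mcmc_config(n_gen = 1000, thin = 200))
})

test_that("identical seeds give identical traces, different seeds differ", {
  topo <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  sim <- evolve_sequences(dated_tree(topo, c(0.1, 0, 0, 1, 0.5),
                                     rates = 0.02),
                          jc_model(), length = 1000, seed = 1)
  priors <- prior_set(tip_ages = list(A = list(mean = 0.1, sd = 0.05)),
                      root = list(mean = 1, sd = 0.3))
  cfg <- mcmc_config(n_gen = 4000, thin = 20, seed = 7,
                     estimate_subst = FALSE)
  r1 <- mcmc_run(sim$seqs[c("A", "B", "C")], topo, priors, cfg,
                 models = jc_model())
  r2 <- mcmc_run(sim$seqs[c("A", "B", "C")], topo, priors, cfg,
                 models = jc_model())
  expect_identical(r1$traces, r2$traces)
  cfg3 <- mcmc_config(n_gen = 4000, thin = 20, seed = 8,
                      estimate_subst = FALSE)
  r3 <- mcmc_run(sim$seqs[c("A", "B", "C")], topo, priors, cfg3,
                 models = jc_model())
  expect_false(identical(r1$traces, r3$traces))
})

test_that("calibration-mode marginals track their stated priors", {
  # two-tip configuration: the root is the only internal node, so every
  # marginal equals its prior exactly (likelihood and coalescent off)
  topo <- ape::read.tree(text = "(A:1,B:1);")
  priors <- prior_set(
    tip_ages = list(A = list(mean = 0.3, sd = 0.1),
                    B = list(fixed = 0)),
    root = list(mean = 5, sd = 1),
    clock = list(estimate = FALSE, mu = log(0.02), sigma = 0.4))
  cfg <- mcmc_config(n_gen = 150000, thin = 50, seed = 3,
                     mode = "calibration", estimate_subst = FALSE)
  run <- mcmc_run(NULL, topo, priors, cfg)
  tr <- run$traces[-(1:600), ]
  lp <- paleomito:::lnorm_params_real(5, 1)
  expect_lt(abs(mean(tr$age_n3) - 5), 0.08)
  expect_lt(abs(sd(tr$age_n3) - 1), 0.08)
  # truncated normal tip: moments of N(0.3, 0.1) truncated at 0 are
  # essentially untruncated here
  expect_lt(abs(mean(tr$tip_A) - 0.3), 0.01)
  expect_lt(abs(sd(tr$tip_A) - 0.1), 0.01)
})

test_that("prior mode leaves the posterior equal to the joint prior mass", {
  # with the likelihood off the recorded lnlik stays zero
  topo <- ape::read.tree(text = "(A:1,B:1);")
  priors <- prior_set(tip_ages = list(A = list(mean = 0.3, sd = 0.1)),
                      root = list(mean = 5, sd = 1))
  cfg <- mcmc_config(n_gen = 2000, thin = 20, seed = 1, mode = "prior",
                     estimate_subst = FALSE)
  run <- mcmc_run(NULL, topo, priors, cfg)
  expect_true(all(run$traces$lnlik == 0))
  expect_true(all(is.finite(run$traces$lnpost)))
})

test_that("longer alignments shrink the focal-age HPD", {
  rs <- recovery_study()
  cfg <- mcmc_config(n_gen = 20000, thin = 40, burnin_frac = 0.25,
                     estimate_subst = FALSE)
  widths <- sapply(c(1000, 20000), function(n) {
    rec <- recovery_experiment(rs$dt, rs$model, nsites = n,
                               priors = rs$priors, config = cfg,
                               focal = rs$focal, n_replicates = 2,
                               seed = 77)
    mean(rec$table$hpd_upper - rec$table$hpd_lower)
  })
  expect_lt(widths[2], widths[1])
})
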