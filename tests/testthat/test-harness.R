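# Robustness harness: pipeline plumbing, series bookkeeping, stability
# verdicts. Statistical behaviour at the full study scale is exercised
# in the acceptance tests; here a reduced study checks the mechanics.

mini_study <- function(seed = 1) {
  synthetic_validation_study(
    seed = seed, n_templates = 250L, genome_length = 3000L,
    mcmc = mcmc_config(n_gen = 10000L, thin = 50L, burnin_frac = 0.25,
                       estimate_subst = FALSE))
}

test_that("one pipeline run produces a coherent focal posterior", {
  study <- mini_study(1)
  res <- suppressMessages(run_ancestral_dating_pipeline(
    study$reads_by_taxon, study$genomes, study$gene_table, study$cfg,
    seed = 5))
  expect_true(res$hpd_lower <= res$median & res$median <= res$hpd_upper)
  expect_gt(res$median, 0.05)
  expect_lt(res$median, 2)
  expect_gt(res$consensus$F1$covered_frac, 0.9)
  expect_identical(nchar(res$ancestral_masked), ncol(res$supermatrix$matrix))
})

test_that("pipeline runs are deterministic given the seed", {
  study <- mini_study(2)
  r1 <- suppressMessages(run_ancestral_dating_pipeline(
    study$reads_by_taxon, study$genomes, study$gene_table, study$cfg,
    seed = 9))
  r2 <- suppressMessages(run_ancestral_dating_pipeline(
    study$reads_by_taxon, study$genomes, study$gene_table, study$cfg,
    seed = 9))
  expect_identical(r1$median, r2$median)
  expect_identical(r1$summary, r2$summary)
})

test_that("the error-injection zero-rate path reproduces the baseline", {
  study <- mini_study(3)
  base <- suppressMessages(run_ancestral_dating_pipeline(
    study$reads_by_taxon, study$genomes, study$gene_table, study$cfg,
    seed = 4))
  zero <- suppressMessages(run_ancestral_dating_pipeline(
    study$reads_by_taxon, study$genomes, study$gene_table, study$cfg,
    seed = 4, inject_read_rate = 0, inject_consensus_rate = 0))
  expect_identical(base$median, zero$median)
})

test_that("series tables have one row per condition and seed", {
  study <- mini_study(4)
  tab <- suppressMessages(downsampling_series(
    study$reads_by_taxon, study$genomes, study$gene_table, study$cfg,
    levels = c("all", 100), seeds = 1:2))
  expect_identical(nrow(tab), 4L)
  expect_identical(sort(unique(tab$condition)), c("100", "all"))
  expect_true(all(tab$hpd_lower <= tab$median & tab$median <= tab$hpd_upper))

  eis <- suppressMessages(error_injection_series(
    study$reads_by_taxon, study$genomes, study$gene_table, study$cfg,
    rate = 0.01, seeds = 1L))
  expect_setequal(eis$condition, c("baseline", "consensus", "raw_reads"))
  # baseline in the error series equals the "all" down-sampling row
  expect_identical(eis$median[eis$condition == "baseline" & eis$seed == 1],
                   tab$median[tab$condition == "all" & tab$seed == 1])
})

test_that("a level above the available reads degrades to the full set", {
  study <- mini_study(5)
  expect_message(
    res <- run_ancestral_dating_pipeline(
      study$reads_by_taxon, study$genomes, study$gene_table, study$cfg,
      seed = 2, downsample_n = 10000000L),
    "using all")
})

test_that("stability verdicts flag only deviations beyond the tolerance", {
  tab <- structure(data.frame(
    condition = c("all", "all", "300", "300", "100", "100"),
    seed = c(1, 2, 1, 2, 1, 2),
    median = c(0.4, 0.42, 0.41, 0.43, 0.4, 0.6),
    hpd_lower = 0.2, hpd_upper = 0.7, ess = 100),
    class = c("stability_table", "data.frame"))
  rep <- stability_report(tab, tolerance = 0.15)
  v <- rep$verdicts
  expect_true(all(v$stable[v$condition == "300"]))
  expect_false(v$stable[v$condition == "100" & v$seed == 2])
  expect_true(any(grepl("UNSTABLE", rep$summary)))
  # verdicts invariant to row order
  perm <- tab[sample(nrow(tab)), ]
  class(perm) <- class(tab)
  v2 <- stability_report(perm, tolerance = 0.15)$verdicts
  key <- function(d) d[order(d$condition, d$seed),
                       c("condition", "seed", "stable")]
  expect_identical(key(v2), key(v))
  # all medians equal baseline: everything stable
  flat <- tab; flat$median <- 0.4
  expect_true(all(stability_report(flat)$verdicts$stable))
  expect_error(stability_report(tab[tab$condition != "all", ]),
               "missing baseline")
})

test_that("recovery experiments aggregate bias, RMSE and coverage", {
  rs <- recovery_study()
  rec <- recovery_experiment(
    rs$dt, rs$model, nsites = 2000, priors = rs$priors,
    config = mcmc_config(n_gen = 8000, thin = 40, burnin_frac = 0.25,
                         estimate_subst = FALSE),
    focal = rs$focal, n_replicates = 2, seed = 3)
  expect_identical(nrow(rec$table), 2L)
  agg <- rec$aggregate$tips
  expect_true(is.finite(agg$bias) && is.finite(agg$rmse))
  expect_gte(agg$bias_mcse, 0)
  expect_identical(rec$true_age, 1.0)
})

test_that("ancestor-based dating beats tip-based dating under terminal errors", {
  # terminal substitution noise of ~0.35% confined to the two focal tips
  # inflates their branches; dating from the reconstructed, masked
  # ancestor should sit closer to the true divergence on average
  topo_full <- ape::read.tree(text = "((((F1,F2)A,SIC)B,OUT1)C,OUT2)R;")
  topo_dating <- ape::read.tree(text = "(((ancestor,SIC)B,OUT1)C,OUT2)R;")
  ages <- c(F1 = 0.117, F2 = 0.117, SIC = 0.1125, OUT1 = 0.233,
            OUT2 = 0, R = 5.0, C = 1.0, B = 0.4, A = 0.2)
  dt <- dated_tree(topo_full, ages[c(topo_full$tip.label,
                                     c("R", "C", "B", "A"))],
                   rates = 0.02)
  model <- hky_model(8, freq = c(0.33, 0.26, 0.13, 0.28), alpha = 0.5)
  priors <- prior_set(
    tip_ages = list(
      F1 = list(mean = 0.117, sd = 0.05),
      F2 = list(mean = 0.117, sd = 0.05),
      ancestor = list(mean = 0.2, sd = 0.1, lower = 0.05, upper = 0.43),
      SIC = list(mean = 0.1125, sd = 0.05),
      OUT1 = list(mean = 0.233, sd = 0.05),
      OUT2 = list(fixed = 0)),
    node_calibrations = list(list(taxa = c("F1", "F2"), mean = 0.2,
                                  sd = 0.1, lower = 0.05, upper = 0.43)),
    root = list(mean = 5, sd = 1),
    clock = list(mu_mean = log(0.02), mu_sd = 2))
  cfg <- mcmc_config(n_gen = 20000, thin = 40, burnin_frac = 0.25,
                     estimate_subst = FALSE)
  rec <- recovery_experiment(dt, model, nsites = 4000, priors = priors,
                             config = cfg, focal = c("F1", "SIC"),
                             n_replicates = 8, seed = 11,
                             method = "both",
                             terminal_error_rate = 0.0035,
                             collapse = c("F1", "F2"), sister = "SIC",
                             topo_dating = topo_dating)
  tab <- rec$table
  err_by <- tapply(abs(tab$err), tab$method, mean)
  expect_lte(err_by[["ancestor"]], err_by[["tips"]])
})
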