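#!/usr/bin/env Rscript
# Step 6 - Bayesian tip dating of the reconstructed ancestor.
#
# Replaces the focal clade by the masked ancestral sequence and dates the
# fixed topology under per-partition HKY+Gamma, an uncorrelated lognormal
# relaxed clock, a constant-size serial coalescent prior, truncated-normal
# tip calibrations and a lognormal root prior. Writes the trace, the
# posterior summary, and the dated tree under results/dating/.

library(paleomito)

out <- "results/dating"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read_tsv("results/data/genes.tsv")
genomes <- read_fasta("results/data/genomes_true.fasta")
anc <- read_fasta("results/ancestral/ancestor_masked.fasta")
topo_dating <- read_newick("results/data/topology_dating.nwk")

# dating matrix: outgroups from their genomes, ancestor from step 5.
# the ancestor row is already in supermatrix coordinates, so the
# outgroups are run through the same column extraction.
keep <- c("SIC", "OUT1", "OUT2")
sm <- build_supermatrix(stats::setNames(genomes$seq[match(keep, genomes$id)],
                                        keep), genes)
dmat <- rbind(sm$matrix,
              matrix(strsplit(anc$seq, "")[[1]], 1,
                     dimnames = list("ancestor", NULL)))

priors <- prior_set(
  tip_ages = list(
    ancestor = list(mean = 0.2, sd = 0.1, lower = 0.05, upper = 0.43),
    SIC = list(mean = 0.1125, sd = 0.05),
    OUT1 = list(mean = 0.233, sd = 0.05),
    OUT2 = list(fixed = 0)),
  root = list(mean = 5, sd = 1),
  clock = list(mu_mean = log(0.02), mu_sd = 2))
models <- stats::setNames(rep(list(hky_model(8, alpha = 0.5)),
                              length(sm$partitions)),
                          names(sm$partitions))
config <- mcmc_config(n_gen = 200000L, thin = 100L, burnin_frac = 0.25,
                      seed = 20260906)
run <- mcmc_run(dmat, topo_dating, priors, config, models = models,
                partitions = sm$partitions)
write_tsv(run$traces, file.path(out, "trace.tsv"))
summ <- summarize_posterior(run$traces, config$burnin_frac)
write_tsv(summ, file.path(out, "summary.tsv"))

col <- mrca_age_column(topo_dating, c("ancestor", "SIC"))
focal <- summ[summ$param == col, ]
cat(sprintf(
  "focal divergence (ancestor vs sister): median %.3f Ma, 95%% HPD [%.3f, %.3f], ESS %.0f\n",
  focal$median, focal$hpd_lower, focal$hpd_upper, focal$ess))

# dated tree at posterior-median ages
ages <- numeric(length(topo_dating$tip.label) + topo_dating$Nnode)
ntip <- length(topo_dating$tip.label)
for (i in seq_len(ntip)) {
  cn <- paste0("tip_", topo_dating$tip.label[i])
  ages[i] <- if (cn %in% summ$param) summ$median[summ$param == cn] else 0
}
for (n in (ntip + 1):(ntip + topo_dating$Nnode))
  ages[n] <- summ$median[summ$param == paste0("age_n", n)]
write_dated_tree(dated_tree(topo_dating, ages),
                 file.path(out, "dated_tree.nwk"))
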