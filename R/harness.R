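# Robustness harness: the ancestral-node dating pipeline (reads ->
# clusters -> consensus -> supermatrix -> reconstruction + mask ->
# tip dating), the down-sampling and error-injection series, stability
# verdicts, and truth-known parameter-recovery experiments.

#' Pipeline configuration for ancestral-node dating
#'
#' Bundles every module's parameters for one end-to-end run. Defaults
#' follow the read-processing chain used throughout: 30 bp length
#' filter, dereplication, greedy clustering at 93% identity on both
#' strands, 3 bp end-trimming of cluster centroids, majority consensus,
#' five-partition supermatrix, marginal ancestral reconstruction with
#' descendant-missingness masking, and tip dating of the reconstructed
#' ancestor.
#'
#' @param topo_full rooted `phylo` over all taxa including the focal
#'   tips.
#' @param topo_dating rooted `phylo` in which the focal clade is replaced
#'   by the single `ancestor_label` tip.
#' @param focal_tips the two focal tip labels.
#' @param sister taxon label whose MRCA with the ancestor is the focal
#'   divergence.
#' @param reference taxon whose (true) genome is the mapping reference.
#' @param priors a [prior_set] for the dating run.
#' @param mcmc an [mcmc_config] template (its seed is replaced per run).
#' @param recon_model substitution model template for branch-length
#'   fitting and ancestral reconstruction (applied to every partition).
#' @param dating_model substitution model template for the dating
#'   likelihood (applied to every partition).
#' @param ancestor_label tip name given to the reconstructed ancestor.
#' @param min_len,trim_k,id_threshold,strand_both,map_k,max_mismatch_frac,
#'   min_depth,majority_frac,overlap_mode,downsample_stage module
#'   parameters (see the respective functions).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(topo_full, topo_dating, focal_tips, sister,
                            reference, priors, mcmc,
                            recon_model = hky_model(8, alpha = 0.5),
                            dating_model = hky_model(8, alpha = 0.5),
                            ancestor_label = "ancestor",
                            min_len = 30L, trim_k = 3L,
                            id_threshold = 0.93, strand_both = TRUE,
                            map_k = 16L, max_mismatch_frac = 0.1,
                            min_depth = 1L, majority_frac = 0.5,
                            overlap_mode = "dedup",
                            downsample_stage = c("reads", "clusters")) {
  downsample_stage <- match.arg(downsample_stage)
  structure(list(topo_full = topo_full, topo_dating = topo_dating,
                 focal_tips = focal_tips, sister = sister,
                 reference = reference, priors = priors, mcmc = mcmc,
                 recon_model = recon_model, dating_model = dating_model,
                 ancestor_label = ancestor_label, min_len = min_len,
                 trim_k = trim_k, id_threshold = id_threshold,
                 strand_both = strand_both, map_k = map_k,
                 max_mismatch_frac = max_mismatch_frac,
                 min_depth = min_depth, majority_frac = majority_frac,
                 overlap_mode = overlap_mode,
                 downsample_stage = downsample_stage),
            class = "pipeline_config")
}

# Read chain for one focal specimen: filter -> (downsample) ->
# (error-inject) -> dereplicate -> cluster -> trim -> map -> pileup ->
# consensus. Returns the consensus plus bookkeeping.
consensus_from_reads <- function(reads, ref_seq, cfg, seed,
                                 downsample_n = NULL,
                                 inject_read_rate = 0) {
  seeds <- derive_seeds(seed, 3L)
  r <- filter_reads(reads, cfg$min_len)
  if (!is.null(downsample_n) && cfg$downsample_stage == "reads") {
    if (downsample_n >= nrow(r))
      message("down-sampling level >= available reads; using all")
    r <- downsample(r, downsample_n, seed = seeds[1])
  }
  if (inject_read_rate > 0)
    r$seq <- inject_errors(r$seq, inject_read_rate, seed = seeds[2])
  d <- dereplicate(r)
  cl <- suppressWarnings(
    cluster_greedy(d, cfg$id_threshold, cfg$strand_both))
  cent <- cl$centroids
  if (!is.null(downsample_n) && cfg$downsample_stage == "clusters")
    cent <- downsample(cent, downsample_n, seed = seeds[3])
  trimmed <- suppressWarnings(trim_cluster_ends(cent$seq, cfg$trim_k))
  keep <- !is.na(trimmed)
  cent <- cent[keep, , drop = FALSE]
  cent$seq <- trimmed[keep]
  pl <- map_to_reference(cent, ref_seq, k = cfg$map_k,
                         max_mismatch_frac = cfg$max_mismatch_frac)
  pile <- build_pileup(pl, cent, ref_seq)
  cons <- call_consensus(pile, cfg$min_depth, cfg$majority_frac)
  list(consensus = cons, n_reads = nrow(r), n_clusters = nrow(cl$centroids),
       n_mapped = sum(pl$mapped),
       covered_frac = mean(pileup_depth(pile) > 0),
       placements = pl, centroids = cent)
}

#' Run the full ancestral-node dating pipeline once
#'
#' @param reads_by_taxon named list of read tables for the focal taxa.
#' @param genomes named character vector of true genome sequences for the
#'   non-focal taxa (shared coordinate frame with the gene table).
#' @param gene_table annotation table driving the supermatrix.
#' @param cfg a [pipeline_config].
#' @param seed integer seed for this run.
#' @param downsample_n optional per-specimen read count (down-sampling
#'   condition).
#' @param inject_read_rate substitution-error rate injected into raw
#'   reads before consensus calling.
#' @param inject_consensus_rate substitution-error rate injected into the
#'   finished consensus sequences before reconstruction.
#' @return a list with the focal-divergence posterior (`median`,
#'   `hpd_lower`, `hpd_upper`, `ess`), the per-specimen consensus
#'   bookkeeping, the supermatrix, and the dating summary table.
#' @export
run_ancestral_dating_pipeline <- function(reads_by_taxon, genomes,
                                          gene_table, cfg, seed = 1L,
                                          downsample_n = NULL,
                                          inject_read_rate = 0,
                                          inject_consensus_rate = 0) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seeds <- derive_seeds(seed, length(reads_by_taxon) + 2L)
  ref_seq <- genomes[[cfg$reference]]
  cons <- list()
  for (i in seq_along(cfg$focal_tips)) {
    t <- cfg$focal_tips[i]
    cons[[t]] <- consensus_from_reads(reads_by_taxon[[t]], ref_seq, cfg,
                                      seed = seeds[i],
                                      downsample_n = downsample_n,
                                      inject_read_rate = inject_read_rate)
  }
  focal_seqs <- vapply(cons, function(x) x$consensus, "")
  if (inject_consensus_rate > 0)
    focal_seqs <- stats::setNames(
      inject_errors(focal_seqs, inject_consensus_rate,
                    seed = seeds[length(seeds) - 1L]),
      names(focal_seqs))
  all_seqs <- c(focal_seqs, genomes)
  sm <- build_supermatrix(all_seqs, gene_table,
                          overlap_mode = cfg$overlap_mode)

  nparts <- length(sm$partitions)
  recon_models <- stats::setNames(rep(list(cfg$recon_model), nparts),
                                  names(sm$partitions))
  fit <- suppressWarnings(
    optimize_branch_lengths(sm, cfg$topo_full, recon_models))
  anc_node <- ape::getMRCA(cfg$topo_full, cfg$focal_tips)
  rec <- marginal_ancestral(sm, fit$tree, recon_models, sm$partitions,
                            node = anc_node)
  masked <- mask_missing(rec$map,
                         apply(sm$matrix[cfg$focal_tips, , drop = FALSE],
                               1L, paste, collapse = ""))

  dmat <- sm$matrix[setdiff(rownames(sm$matrix), cfg$focal_tips), ,
                    drop = FALSE]
  dmat <- rbind(dmat,
                matrix(strsplit(masked, "", fixed = TRUE)[[1]], 1L,
                       dimnames = list(cfg$ancestor_label, NULL)))
  dating_models <- stats::setNames(rep(list(cfg$dating_model), nparts),
                                   names(sm$partitions))
  config <- cfg$mcmc
  config$seed <- seeds[length(seeds)]
  run <- mcmc_run(dmat, cfg$topo_dating, cfg$priors, config,
                  models = dating_models, partitions = sm$partitions)
  summ <- summarize_posterior(run$traces, config$burnin_frac)
  col <- mrca_age_column(cfg$topo_dating,
                         c(cfg$ancestor_label, cfg$sister))
  row <- summ[summ$param == col, ]
  list(median = row$median, hpd_lower = row$hpd_lower,
       hpd_upper = row$hpd_upper, ess = row$ess,
       consensus = cons, supermatrix = sm, summary = summ,
       ancestral_masked = masked)
}

#' Down-sampling stability series
#'
#' Runs the full pipeline at each down-sampling level for each seed and
#' records the focal-divergence posterior. A level exceeding the
#' available reads degrades to `"all"` (noted by the pipeline).
#'
#' @inheritParams run_ancestral_dating_pipeline
#' @param levels down-sampling levels; `"all"` means no down-sampling.
#' @param seeds integer seeds (one series per seed).
#' @return a `stability_table` data frame: `condition`, `seed`,
#'   `median`, `hpd_lower`, `hpd_upper`, `ess`.
#' @export
downsampling_series <- function(reads_by_taxon, genomes, gene_table, cfg,
                                levels = c("all", 1000, 500, 300, 100),
                                seeds = 1:5) {
  rows <- list()
  for (sd in seeds) {
    for (lv in levels) {
      n <- if (identical(lv, "all")) NULL else as.integer(lv)
      res <- run_ancestral_dating_pipeline(reads_by_taxon, genomes,
                                           gene_table, cfg, seed = sd,
                                           downsample_n = n)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = as.character(lv), seed = sd,
                   median = res$median, hpd_lower = res$hpd_lower,
                   hpd_upper = res$hpd_upper, ess = res$ess,
                   stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("stability_table", "data.frame"))
}

#' Error-injection stability series
#'
#' For each seed: a baseline run, a run with errors injected into the
#' finished consensus sequences, and a run with errors injected into the
#' raw reads before consensus calling.
#'
#' @inheritParams downsampling_series
#' @param rate substitution-error rate (default 1%).
#' @param modes which injection modes to run.
#' @param include_baseline also run the unperturbed baseline per seed
#'   (set `FALSE` when baseline rows are supplied from a down-sampling
#'   series run with the same seeds, whose `"all"` rows are identical).
#' @return a `stability_table` with conditions `baseline`, `consensus`,
#'   `raw_reads`.
#' @export
error_injection_series <- function(reads_by_taxon, genomes, gene_table,
                                   cfg, rate = 0.01,
                                   modes = c("consensus", "raw_reads"),
                                   seeds = 1:5,
                                   include_baseline = TRUE) {
  stopifnot(rate >= 0, rate <= 1)
  rows <- list()
  conds <- if (include_baseline) c("baseline", modes) else modes
  for (sd in seeds) {
    for (mode in conds) {
      res <- switch(mode,
        baseline = run_ancestral_dating_pipeline(
          reads_by_taxon, genomes, gene_table, cfg, seed = sd),
        consensus = run_ancestral_dating_pipeline(
          reads_by_taxon, genomes, gene_table, cfg, seed = sd,
          inject_consensus_rate = rate),
        raw_reads = run_ancestral_dating_pipeline(
          reads_by_taxon, genomes, gene_table, cfg, seed = sd,
          inject_read_rate = rate))
      rows[[length(rows) + 1L]] <-
        data.frame(condition = mode, seed = sd, median = res$median,
                   hpd_lower = res$hpd_lower, hpd_upper = res$hpd_upper,
                   ess = res$ess, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("stability_table", "data.frame"))
}

#' Stability verdicts against the baseline condition
#'
#' A condition is stable when its posterior median lies within
#' `tolerance` (relative) of the same-seed baseline median. The
#' tolerance is always printed with the verdicts.
#'
#' @param table a `stability_table`.
#' @param tolerance relative tolerance band (default 0.15 of the baseline
#'   median).
#' @param baseline condition label providing the baseline rows.
#' @return a list with `verdicts` (per-row data frame adding
#'   `baseline_median`, `rel_dev`, `stable`) and `summary` (text lines).
#' @export
stability_report <- function(table, tolerance = 0.15,
                             baseline = c("all", "baseline")) {
  base <- table[table$condition %in% baseline, , drop = FALSE]
  if (!nrow(base)) stop("missing baseline condition in stability table")
  bmed <- stats::setNames(base$median, base$seed)
  v <- table[!table$condition %in% baseline, , drop = FALSE]
  v$baseline_median <- unname(bmed[as.character(v$seed)])
  v$rel_dev <- abs(v$median - v$baseline_median) / v$baseline_median
  v$stable <- v$rel_dev <= tolerance
  per_cond <- split(v, v$condition)
  lines <- c(sprintf("stability tolerance: %.0f%% of baseline median",
                     100 * tolerance),
             vapply(per_cond, function(d)
               sprintf("condition %s: %d/%d seeds stable (max dev %.1f%%)",
                       d$condition[1], sum(d$stable), nrow(d),
                       100 * max(d$rel_dev)), ""))
  unstable <- v[!v$stable, , drop = FALSE]
  if (nrow(unstable))
    lines <- c(lines, sprintf("UNSTABLE: %s (seed %d, dev %.1f%%)",
                              unstable$condition, unstable$seed,
                              100 * unstable$rel_dev))
  list(verdicts = v, summary = lines)
}

#' Truth-known parameter-recovery experiment
#'
#' Simulates alignments on a known chronogram, dates them, and scores
#' the focal-node age estimator: bias (with Monte-Carlo standard error),
#' RMSE, and 95% HPD coverage. With `method = "ancestor"` (or
#' `"both"`) the two `collapse` tips are first collapsed to their
#' reconstructed, masked ancestor before dating, optionally after
#' injecting terminal errors into those tip sequences - the
#' ancestor-versus-tip comparison that motivates ancestral-node dating.
#'
#' @param dt a [dated_tree] with rates (or supply a scalar `rate`).
#' @param model simulation [subst_model] (also used for analysis).
#' @param nsites alignment length.
#' @param priors a [prior_set] for the dating run.
#' @param config an [mcmc_config] template.
#' @param focal tip labels whose MRCA is the scored node.
#' @param n_replicates number of simulated replicates.
#' @param seed master seed.
#' @param rate scalar clock rate when `dt` carries none.
#' @param method `"tips"`, `"ancestor"`, or `"both"`.
#' @param terminal_error_rate substitution rate injected into the
#'   `collapse` tip sequences before analysis (emulates damage-inflated
#'   terminals).
#' @param collapse the two tips replaced by their reconstructed ancestor
#'   (required for ancestor-based dating).
#' @param sister taxon whose MRCA with the ancestor is the scored node in
#'   ancestor-based dating.
#' @param topo_dating dating topology with the `ancestor` tip (required
#'   for ancestor-based dating).
#' @return a list with `table` (one row per replicate x method) and
#'   `aggregate` (bias, `bias_mcse`, `rmse`, `coverage` per method).
#' @export
recovery_experiment <- function(dt, model, nsites, priors, config, focal,
                                n_replicates = 20L, seed = 1L,
                                rate = NULL,
                                method = c("tips", "ancestor", "both"),
                                terminal_error_rate = 0,
                                collapse = NULL, sister = NULL,
                                topo_dating = NULL) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 1)
  topo <- dt$topo
  focal_node <- ape::getMRCA(topo, focal)
  true_age <- dt$ages[focal_node]
  methods <- if (method == "both") c("tips", "ancestor") else method
  if ("ancestor" %in% methods &&
      (is.null(collapse) || is.null(sister) || is.null(topo_dating)))
    stop("ancestor-based dating needs `collapse`, `sister` and `topo_dating`")
  seeds <- derive_seeds(seed, n_replicates)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    sub_seeds <- derive_seeds(seeds[r], 4L)
    sim <- evolve_sequences(dt, model, length = nsites,
                            seed = sub_seeds[1], rate = rate)
    tipseqs <- sim$seqs[topo$tip.label]
    if (terminal_error_rate > 0 && !is.null(collapse))
      tipseqs[collapse] <- inject_errors(tipseqs[collapse],
                                         terminal_error_rate,
                                         seed = sub_seeds[2])
    for (m in methods) {
      est <- tryCatch({
        if (m == "tips") {
          cfgr <- config; cfgr$seed <- sub_seeds[3]
          run <- mcmc_run(tipseqs, topo, priors, cfgr, models = model)
          summ <- summarize_posterior(run$traces, cfgr$burnin_frac)
          col <- mrca_age_column(topo, focal)
          summ[summ$param == col, ]
        } else {
          anc_node <- ape::getMRCA(topo, collapse)
          fit <- suppressWarnings(optimize_branch_lengths(
            tipseqs, topo, model))
          rec <- marginal_ancestral(tipseqs, fit$tree, model,
                                    node = anc_node)
          anc <- mask_missing(rec$map, tipseqs[collapse])
          dseqs <- c(tipseqs[setdiff(topo$tip.label, collapse)],
                     ancestor = anc)
          cfgr <- config; cfgr$seed <- sub_seeds[4]
          run <- mcmc_run(dseqs, topo_dating, priors, cfgr,
                          models = model)
          summ <- summarize_posterior(run$traces, cfgr$burnin_frac)
          col <- mrca_age_column(topo_dating, c("ancestor", sister))
          summ[summ$param == col, ]
        }
      }, error = function(e) {
        warning("replicate ", r, " (", m, ") failed: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(est) || !nrow(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, seed = seeds[r], method = m, true_age = true_age,
        median = est$median, hpd_lower = est$hpd_lower,
        hpd_upper = est$hpd_upper,
        covered = est$hpd_lower <= true_age & true_age <= est$hpd_upper,
        err = est$median - true_age, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- lapply(split(tab, tab$method), function(d)
    list(bias = mean(d$err),
         bias_mcse = stats::sd(d$err) / sqrt(nrow(d)),
         rmse = sqrt(mean(d$err^2)),
         coverage = mean(d$covered), n = nrow(d)))
  list(table = tab, aggregate = agg, true_age = true_age)
}

# ---------------------------------------------------------------------------
# Study-condition constructors (the desk-scale synthetic analogs; see the
# methods vignette for the rationale behind each value)

#' Desk-scale synthetic validation study
#'
#' The scaled analog of the down-sampling / error-injection validation
#' design: an 8 kb annotated mitogenome evolved on a serial chronogram
#' with two recent focal specimens (ages 0.117 Ma, splitting 0.2 Ma ago),
#' a dated sister lineage (0.1125 Ma) with the focal divergence at
#' 0.4 Ma, an older dated outgroup and a modern outgroup, under a
#' 0.02 subst/site/Ma clock; damaged, duplicate-inflated read sets of
#' about 5,000 reads per focal specimen.
#'
#' @param seed master seed for genome evolution and read simulation.
#' @param n_templates template molecules per focal specimen (default
#'   1250; mean PCR multiplicity 4 gives ~5,000 reads).
#' @param genome_length synthetic mitogenome length (bp).
#' @param mcmc an [mcmc_config] template for the dating runs.
#' @param dm damage model applied to the focal libraries.
#' @return a list with `reads_by_taxon`, `genomes` (true sequences of
#'   the non-focal taxa), `gene_table`, `cfg` (a [pipeline_config]),
#'   `truth` (true focal divergence and all node ages), and `sim`
#'   (full simulation output including true focal genomes).
#' @export
synthetic_validation_study <- function(seed = 1L, n_templates = 1250L,
                                       genome_length = 8000L,
                                       mcmc = NULL,
                                       dm = damage_model()) {
  topo_full <- ape::read.tree(
    text = "((((F1,F2)A,SIC)B,OUT1)C,OUT2)R;")
  topo_dating <- ape::read.tree(
    text = "(((ancestor,SIC)B,OUT1)C,OUT2)R;")
  ages <- c(F1 = 0.117, F2 = 0.117, SIC = 0.1125, OUT1 = 0.233,
            OUT2 = 0, R = 5.0, C = 1.0, B = 0.4, A = 0.2)
  dt <- dated_tree(topo_full,
                   ages[c(topo_full$tip.label,
                          c("R", "C", "B", "A"))],
                   rates = 0.02)
  gene_table <- synthetic_gene_table(genome_length)
  model <- hky_model(8, freq = c(0.33, 0.26, 0.13, 0.28), alpha = 0.5,
                     ncat = 4L)
  seeds <- derive_seeds(seed, 3L)
  sim <- evolve_sequences(dt, model, length = genome_length,
                          seed = seeds[1])
  genomes <- sim$seqs[c("SIC", "OUT1", "OUT2")]
  reads_by_taxon <- list(
    F1 = simulate_read_set(sim$seqs[["F1"]], n_templates, dm = dm,
                           seed = seeds[2]),
    F2 = simulate_read_set(sim$seqs[["F2"]], n_templates, dm = dm,
                           seed = seeds[3]))
  priors <- prior_set(
    tip_ages = list(
      ancestor = list(mean = 0.2, sd = 0.1, lower = 0.05, upper = 0.43),
      SIC = list(mean = 0.1125, sd = 0.05),
      OUT1 = list(mean = 0.233, sd = 0.05),
      OUT2 = list(fixed = 0)),
    root = list(mean = 5, sd = 1),
    clock = list(mu_mean = log(0.02), mu_sd = 2))
  if (is.null(mcmc))
    mcmc <- mcmc_config(n_gen = 60000L, thin = 60L, burnin_frac = 0.25,
                        estimate_subst = TRUE)
  cfg <- pipeline_config(topo_full = topo_full, topo_dating = topo_dating,
                         focal_tips = c("F1", "F2"), sister = "SIC",
                         reference = "SIC", priors = priors, mcmc = mcmc)
  list(reads_by_taxon = reads_by_taxon, genomes = genomes,
       gene_table = gene_table, cfg = cfg,
       truth = list(focal_divergence = 0.4, ages = ages), sim = sim,
       model = model)
}

#' Desk-scale recovery study (6-taxon chronogram)
#'
#' Strict-clock chronogram with the focal split at 1.0 time units used
#' for parameter-recovery calibration: three dated tips (normal priors
#' at their true ages), three contemporaneous tips, a lognormal root
#' prior at the true root age, HKY+Gamma sequences.
#'
#' @param rate strict clock rate (substitutions/site per time unit).
#' @return a list with `dt` (the [dated_tree]), `model`, `priors`,
#'   `focal` tips, and `true_focal_age`.
#' @export
recovery_study <- function(rate = 0.02) {
  topo <- ape::read.tree(
    text = "(((A,B)nAB,(C,D)nCD)nF,(E,F6)nEF)root;")
  ages <- c(A = 0, B = 0.1, C = 0, D = 0.15, E = 0, F6 = 0.1,
            root = 2.0, nF = 1.0, nAB = 0.4, nCD = 0.5, nEF = 0.8)
  dt <- dated_tree(topo, ages[c(topo$tip.label,
                                c("root", "nF", "nAB", "nCD", "nEF"))],
                   rates = rate)
  model <- hky_model(8, freq = c(0.33, 0.26, 0.13, 0.28), alpha = 0.5)
  priors <- prior_set(
    tip_ages = list(B = list(mean = 0.1, sd = 0.05),
                    D = list(mean = 0.15, sd = 0.05),
                    F6 = list(mean = 0.1, sd = 0.05)),
    root = list(mean = 2, sd = 0.5),
    clock = list(mu_mean = log(rate), mu_sd = 2))
  list(dt = dt, model = model, priors = priors, focal = c("A", "C"),
       true_focal_age = 1.0)
}
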