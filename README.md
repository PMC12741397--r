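# paleomito

Divergence dating for low-coverage, damage-prone ancient mitochondrial
genomes.

Ancient mitochondrial DNA survives as short fragments (typically
30–80 bp) carrying post-mortem cytosine deamination — C→T
misincorporations near 5′ fragment ends and complementary G→A near 3′
ends — and sequencing libraries built from a handful of surviving
template molecules are inflated by PCR duplicates. Both artefacts
lengthen the terminal branches of the affected specimens in a phylogeny
and bias divergence-time estimates that depend on those branches.

`paleomito` implements an ancestral-node dating workflow that sidesteps
the inflated terminals, together with the simulation and robustness
machinery needed to validate it:

1. **Read processing** — 30 bp length filter, exact dereplication,
   greedy centroid clustering at 93% identity on both strands (PCR
   duplicate removal), and a minimal seed-and-extend mapper.
2. **Consensus** — 3 bp end-trimmed majority consensus from pileups,
   with `N` at ties and under-covered sites; damage misincorporation
   profiles by read-end offset; 1 kb windowed depth.
3. **Supermatrix** — five partitions (codon positions 1/2/3, RNAs,
   control region) from annotated mitogenomes, with start/stop codons
   stripped, overlapping gene regions kept once, and light-strand genes
   reverse-complemented.
4. **Reconstruction** — partitioned GTR/HKY(+I)+Γ pruning likelihood
   (compiled kernel), ML branch lengths on a fixed topology, marginal
   ancestral state posteriors `P(x_v = s | D) ∝ π_s L_v(s) O_v(s)` at
   the focal ancestor, and masking of every site missing in either
   descendant.
5. **Tip dating** — Bayesian MCMC on a chronogram: per-partition
   HKY(+I)+Γ likelihood with branch lengths `(t_parent − t_child) × r`,
   an uncorrelated lognormal relaxed clock, a constant-size serial
   coalescent tree prior, truncated-normal tip/tMRCA calibrations and a
   lognormal root prior; posterior medians with shortest-interval 95%
   HPDs and ESS.
6. **Robustness harness** — read down-sampling series, 1%
   error-injection series, stability verdicts against a stated tolerance
   band, and truth-known parameter-recovery experiments.
7. **Simulator** — sequences evolved along dated trees, lognormal
   fragment lengths truncated to [30, 76] bp (mean ≈ 38.9), exponential
   end-decay deamination `δ·e^(−λ(i−1))`, zero-truncated-geometric PCR
   duplication, and seeded substitution-error injection.

The methods vignette (`vignettes/ancestral-node-dating.Rmd`) documents
the models, priors, operators, numerical conventions and the deliberate
approximations.

## Worked example

Simulate a damaged, duplicate-inflated library from a known genome,
deduplicate and cluster it, call an end-trimmed consensus, and profile
the damage:

```r
library(paleomito)

genome <- with_seed(1, paste(sample(c("A","C","G","T"), 4000,
                                    replace = TRUE), collapse = ""))
reads <- simulate_read_set(genome, n_templates = 1000, seed = 1)
nrow(reads); mean(nchar(reads$seq))
#> [1] 3951
#> [1] 39.1306

cl <- cluster_greedy(dereplicate(filter_reads(reads)))
cl
#> read_clusters: 976 clusters from 996 members (total size 3951)

cent <- cl$centroids
cent$seq <- trim_cluster_ends(cent$seq, 3)
pl <- map_to_reference(cent, genome)
cons <- call_consensus(build_pileup(pl, cent, genome))
mean(strsplit(cons, "")[[1]] == strsplit(genome, "")[[1]])
#> [1] 0.9995

prof <- damage_profile(map_to_reference(cl$centroids, genome),
                       cl$centroids, genome)
round(prof$freq_ct_5p[1:5], 3)
#> [1] 0.331 0.228 0.164 0.112 0.112
```

The ~4,000 reads (mean 39.1 bp) collapse to 976 clusters — essentially
one per surviving template; after 3 bp end-trimming the majority
consensus recovers the source genome at 99.95% identity even though the
terminal C→T rate is 30%, and the observed misincorporation frequencies
(0.331, 0.228, 0.164, …) track the simulated `0.3·e^(−0.3(i−1))` decay
(0.300, 0.222, 0.165, …) within counting noise.

The full analysis — simulation, read processing, consensus, supermatrix,
ancestral reconstruction, tip dating, and the down-sampling/error
robustness sweep — is laid out as numbered drivers under `analysis/`
(`01_simulate.R` … `07_validate.R`), each a thin script over the package
functions that writes its tables under `results/`.

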