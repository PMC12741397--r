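---
title: "Ancestral-node divergence dating for low-coverage ancient mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral-node divergence dating for low-coverage ancient mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomito)
```

## The problem

Ancient mitochondrial DNA from subfossil material arrives as very short
fragments (tens of base pairs) carrying post-mortem cytosine deamination,
which shows up as C&rarr;T misincorporations near 5&prime; fragment ends
and, on the complementary strand, G&rarr;A near 3&prime; ends. Library
preparation adds a second pathology: PCR over-amplification of the few
surviving template molecules, so a low-complexity library can look deeply
sequenced while carrying little independent information. Both effects
inflate the terminal branches of the sequenced specimens in a phylogeny,
and any divergence-time estimate that leans on those terminal branch
lengths inherits the bias.

`paleomito` implements the dating strategy that works around this: build
per-specimen consensus mitogenomes from deduplicated, end-trimmed read
clusters; reconstruct the marginal maximum-likelihood ancestral sequence
at the most recent common ancestor (MRCA) of the error-bearing specimens;
mask every site at which either specimen lacks data; and estimate the
divergence of that *ancestral node* from its sister lineage by Bayesian
tip dating. Because the reconstruction integrates over the terminal
branches, sequence errors confined to those branches largely cancel. The
package also implements the accompanying validation design: re-running
the whole chain under read down-sampling and under 1% artificial
substitution errors, and checking that the focal divergence estimate
stays put.

## Pipeline overview

1. **Simulation** (`evolve_sequences`, `fragmentize`, `apply_damage`,
   `amplify_and_sequence`, `inject_errors`): truth-known inputs with the
   statistical structure the analysis assumes.
2. **Read processing** (`filter_reads`, `dereplicate`, `cluster_greedy`,
   `map_to_reference`, `downsample`): a 30 bp length filter, exact
   dereplication, greedy centroid clustering at 93% identity on both
   strands, and a minimal seed-and-extend mapper.
3. **Consensus and profiles** (`trim_cluster_ends`, `build_pileup`,
   `call_consensus`, `damage_profile`, `windowed_depth`): 3 bp
   end-trimmed majority consensus with `N` at unresolved sites; damage
   misincorporation curves by read-end offset; 1 kb windowed depth.
4. **Supermatrix** (`build_supermatrix`): five partitions &mdash; codon
   positions 1/2/3 of the concatenated protein-coding genes, the RNAs,
   and the control region (D-loop) &mdash; with start/stop codons
   stripped, the shared columns of the overlapping CDS pairs
   (ATP8/ATP6, ND4L/ND4, ND5/ND6) kept exactly once, and light-strand
   genes reverse-complemented.
5. **Reconstruction** (`optimize_branch_lengths`, `marginal_ancestral`,
   `mask_missing`): ML branch lengths on the fixed topology, per-site
   marginal posteriors at the focal MRCA, MAP sequence, missing-data
   masking.
6. **Tip dating** (`mcmc_run`, `summarize_posterior`): partitioned
   HKY(+I)+&Gamma; likelihood on a chronogram, uncorrelated lognormal
   relaxed clock, constant-size serial coalescent prior, truncated-normal
   tip/node calibrations, lognormal root prior.
7. **Robustness** (`downsampling_series`, `error_injection_series`,
   `stability_report`, `recovery_experiment`): the validation design.

## Models

### Substitution models and likelihood

`subst_model` builds a general time-reversible (GTR) rate matrix
\(q_{ij} = s_{ij}\pi_j\) satisfying detailed balance
\(\pi_i q_{ij} = \pi_j q_{ji}\), scaled so the mean substitution rate at
stationarity is 1; branch lengths are therefore expected substitutions
per site. Transition probabilities \(P(t) = e^{Qt}\) come from the
symmetric eigendecomposition of
\(\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)\). Among-site
rate variation uses the discrete-gamma approximation with four
equal-probability categories at their category means (the default
everywhere), plus an optional invariant-sites class with proportion
\(p_{inv}\). `pruning_loglik` computes the Felsenstein pruning
likelihood over compressed site patterns in compiled code; `N` and `-`
are fully ambiguous (partial likelihood 1 for every state), so an
all-missing column contributes exactly zero log-likelihood.

### Marginal ancestral reconstruction

For an internal node \(v\), the per-site posterior over states is

\[ P(x_v = s \mid D) \propto \pi_s \, L_v(s)\, O_v(s), \]

where \(L_v\) is the conditional likelihood of the data below \(v\) and
\(O_v\) of the data above it (computed by a down&ndash;up pass), mixed
over gamma categories and the invariant class. The MAP state is reported
per site; exact posterior ties emit `N` rather than an arbitrary base.
This is the *marginal* (empirical Bayes) reconstruction; joint
reconstruction is out of scope. Codon-position-partitioned nucleotide
models stand in for a codon substitution model for coding sequence
&mdash; a deliberate approximation: each codon position gets its own
GTR/HKY+&Gamma; model, which captures the dominant rate and composition
differences among positions but not codon-level dependence.

`mask_missing` then replaces with `N` every site at which any designated
descendant is missing, so the reconstruction never asserts states where
the focal individuals carried no data. This mirrors the missing-data
rule of the dating design and is what keeps the down-sampled conditions
honest: less coverage means a shorter, not a more imaginative, ancestor.

### Tip dating

The dating model works in units of Ma, with rates in
substitutions/site/Ma and per-branch effective lengths
\((t_{parent}-t_{child}) \times r_{branch}\):

* **Serial coalescent prior.** With lineage count \(k\) through each
  inter-event interval of length \(\Delta t\), the constant-size
  coalescent contributes \(e^{-\binom{k}{2}\Delta t/N_e}\) per interval
  and \(1/N_e\) per coalescence, with lineage counts updated at both
  sampling (tip) and coalescent events.
* **Uncorrelated lognormal (ULN) relaxed clock.** Branch rates are
  i.i.d. lognormal; in the sampler the state is the per-branch log rate
  with a \(\mathcal N(\mu, \sigma)\) prior, \(\mu\) given a diffuse
  normal hyperprior and \(\sigma\) an exponential hyperprior (these can
  be fixed for strict-clock-style analyses).
* **Calibrations.** Dated tips get truncated-normal age priors; clade
  ages (tMRCAs) can be calibrated the same way; the root takes a
  lognormal prior parameterised by its *real-space* mean and sd (the
  parameterisation is a documented package choice; the conversion to
  log-space parameters is internal).
* **Population size.** \(N_e\) (in Ma of coalescent time) gets a diffuse
  lognormal hyperprior.

The sampler is Metropolis-Hastings with: uniform-in-bracket node-age
moves (the bracket of a node does not depend on its own age, so the move
is symmetric), random-walk root and tip-age moves, per-branch log-rate
walks, a Gibbs update for \(\mu\), multiplicative walks for \(\sigma\)
and the HKY parameters, and three likelihood-invariant joint operators:
an **age&ndash;rate** move that slides a node age while rescaling the
adjacent branch rates so every adjacent branch *length* is unchanged; a
**subtree translate** that shifts every age in a clade by a common
offset, rescaling only the stem-edge rate; and a global
**rate&ndash;time rescale** that multiplies every free age by a factor
\(c\) while shifting every branch's log rate to keep all branch
lengths fixed (Jacobian \(c^{n}\) over the \(n\) scaled ages). All
three leave the likelihood untouched (unit Jacobian in log-rate space
for the deterministic rate shifts) and are what let the chain traverse
the rate&ndash;time ridge that otherwise dominates the autocorrelation
of node-age traces. Proposal scales are
tuned toward 30% acceptance during burn-in only, so the post-burn-in
chain is a fixed Markov kernel. Identical seeds and configurations give
byte-identical traces.

When a reconstructed ancestor replaces its two descendants in the dating
alignment, its own age is a free parameter bounded by the tMRCA
calibration of the pair (here: the prior that would have applied to
their MRCA). The alternative &mdash; fixing the ancestor's age &mdash;
would understate uncertainty and is not used.

`summarize_posterior` reports medians, shortest-interval 95% HPDs
(the shortest contiguous window containing \(\lceil 0.95 n\rceil\)
sorted samples; a constant trace yields a zero-width interval), and an
ESS from Geyer's initial-positive-sequence estimate of the integrated
autocorrelation time.

### Validating the sampler against its priors

With the likelihood off, the marginal of a calibrated *node* age is
still not its calibration density, because the coalescent term and the
uniform node moves couple all ages. `mcmc_run` therefore exposes
`mode = "calibration"` (likelihood *and* coalescent off). On a two-tip
topology the root is the only internal node and every sampled quantity's
marginal equals its stated prior exactly; this is the configuration used
for the Kolmogorov&ndash;Smirnov prior-recovery checks. `mode = "prior"`
keeps the coalescent for prior-predictive work.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed and
documented here, not tuned per experiment.

* **Fragment lengths**: discretised lognormal (meanlog \( = \log 34\),
  sdlog \(0.25\)) truncated to \([30, 76]\) bp, giving a mean of
  38.9 bp after the 30 bp filter &mdash; the short-fragment regime of
  captured ancient mitochondrial libraries. The genome is circular;
  fragments may span the origin.
* **Damage**: a `C` at 5&prime; offset \(i\) deaminates with probability
  \(\delta_5 e^{-\lambda (i-1)}\) and a `G` at 3&prime; offset \(j\)
  with \(\delta_3 e^{-\lambda (j-1)}\) &mdash; the standard exponential
  end-decay parameterisation of ancient-DNA damage &mdash; with defaults
  \(\delta_5 = \delta_3 = 0.3\), \(\lambda = 0.3\), plus an independent
  background error rate \(\varepsilon = 0.001\). Deamination is applied
  before background errors and error injection is independent of damage,
  so an injected substitution may hit an already-damaged site.
* **Amplification**: zero-truncated geometric duplicate multiplicities
  (default success probability 0.25, mean 4 copies per template),
  emulating over-amplified low-complexity libraries; duplicates share
  their template's true coordinates.
* **Error injection**: each `A/C/G/T` site flips to a uniformly chosen
  different base with the given probability; `N` and gaps are never
  touched and never produced.

What the generator does **not** emulate: indels (all coordinates are
ungapped and alignment-free), base-quality scores, capture-bait bias,
and non-target (contaminant) reads. Passing tests therefore demonstrate
correctness of the statistical machinery under the generator's
assumptions; they do not certify behaviour on real libraries with
structural artefacts the generator omits.

## The desk-scale study conditions

The stability analog (`synthetic_validation_study`) mirrors the
validation design at reduced size, chosen once:

* an 8,000 bp annotated "mitogenome" with a scaled gene table (eight CDS
  including the three named overlapping pairs and a light-strand gene,
  four RNAs, a terminal control region);
* a serial chronogram with two focal specimens at 0.117 Ma whose lineage
  split 0.2 Ma ago, a dated sister at 0.1125 Ma with the focal
  divergence at **0.4 Ma**, a dated outgroup at 0.233 Ma (split 1.0 Ma),
  a modern outgroup, and a root at 5 Ma;
* a strict 0.02 substitutions/site/Ma generating clock (mammalian
  mitogenome scale), HKY (&kappa; = 8) with mitochondrial-like base
  composition and &Gamma;(0.5) rate variation;
* 1,250 template molecules per focal specimen (about 5,000 reads at
  mean multiplicity 4), damage on.

Priors mirror the structure of the real analysis: truncated-normal tip
ages (sd 0.05 Ma), a normal(0.2, 0.1) tMRCA prior truncated to
[0.05, 0.43] Ma applied to the reconstructed ancestor's age, and a
lognormal root prior at the true root age.

The dating model in the harness default is per-partition HKY+&Gamma;
with &kappa; and &alpha; estimated in-chain. The invariant-sites class
is available (`hky_model(..., pinv = )`, estimated in-chain when
positive) but is off in the harness default: the generator has no
invariant class, and \(p_{inv}\) mixes very slowly against &alpha; on
desk-scale chains (the well-known ridge between the two), which would
spend most of the chain on a nuisance parameter.

Problem sizes for the routine checks are package choices: the stability
series runs 150,000-generation chains thinned to 100 (the `mcmc_config`
default of \(2\times10^6\) generations, thin 200, suits one-off
analyses; the real study's \(10^8\) generations is config-reachable),
the recovery experiment uses 15 kb alignments with 40,000-generation
chains, and the prior-recovery check retains 5,000 samples. The
down-sampling levels (1,000 / 500 / 300 / 100 reads), the 1% injection
rate, the 93% identity threshold, the 30 bp filter and the 3 bp trim are
the study's fixed conditions.

## Numerical choices and degenerate inputs

* Branch lengths are bounded below at \(10^{-9}\) to avoid degenerate
  transition matrices; branch-length optimisation is coordinate-wise
  golden-section with a boundary snap, and the log-likelihood is
  non-decreasing across sweeps.
* Pruning partials rescale per pattern when the maximum drops below
  \(10^{-120}\); an all-scaled-free fast path avoids per-category
  logarithms on shallow trees.
* Consensus ties, MAP ties, and sub-threshold majorities all produce
  `N`, never an arbitrary base; downstream masking expects honest
  ambiguity.
* The damage profile is computed before end-trimming and the consensus
  after it, mirroring the damage-observed-then-trim order of the
  read-processing design.
* Sequences with length \(\le 2k\) are rejected by the end-trimmer (no
  interior sequence remains); reads above 50% `N` are dropped before
  clustering with a warning.
* Cluster identity is fixed as matching columns of the left-aligned
  ungapped comparison divided by the longer length, `N` never matching;
  greedy order is abundance desc, length desc, then id &mdash; the exact
  semantics of tool-specific identity definitions vary, so this one is
  pinned and tested.
* The final partial depth window is averaged over its own length, not
  the nominal window.
* Overlap columns of the named CDS pairs are kept once via the first
  gene (`overlap_mode = "dedup"`); a strict mode drops them from both
  genes, matching the literal reading of "excluded". Codon positions are
  assigned in each gene's own frame *before* overlap removal, so
  removal never shifts frame labels.
* Down-sampling applies to filtered reads before dereplication and
  clustering by default (`downsample_stage = "reads"`); a
  post-clustering stage is available since the design is ambiguous on
  this point.

## Known limitations

* No gapped alignment anywhere: real data must be pre-aligned per gene;
  the simulator is indel-free by construction.
* The mapper is a minimal exact-seed/ungapped-extend placement tool; it
  is not a replacement for a production aligner on divergent or
  structurally variant data.
* The codon-position approximation for coding-sequence reconstruction
  (above).
* Stability verdicts compare posterior medians with a 15% relative
  tolerance band; the band is an explicit package convention (always
  printed with the verdicts), standing in for a qualitative "~" in the
  validation design it reproduces. Under damage-on, low-coverage
  conditions the 300-read level retains only ~30&ndash;65% of sites in
  the masked ancestor, and individual read-subsample draws can move the
  focal median near or past that band even when the estimator is
  unbiased on average.
* MCMC quality is the user's responsibility: check the reported ESS and
  widen chains for final analyses.
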