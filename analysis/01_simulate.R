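#!/usr/bin/env Rscript
# Step 1 - simulate the study data.
#
# Evolves an 8 kb annotated mitogenome along a serial chronogram (two
# recent focal specimens whose lineage split from the sister lineage
# 0.4 Ma ago), then turns the two focal genomes into damaged,
# PCR-duplicate-inflated short-read libraries of ~5,000 reads each.
# Writes reads, true genomes, the gene table, topologies and truth
# tables under results/data/.

library(paleomito)

seed <- 20260906
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- synthetic_validation_study(seed = seed)

for (t in names(study$reads_by_taxon))
  write_fasta(study$reads_by_taxon[[t]],
              file.path(out, paste0("reads_", t, ".fasta")))
write_fasta(c(study$genomes,
              F1 = study$sim$seqs[["F1"]], F2 = study$sim$seqs[["F2"]]),
            file.path(out, "genomes_true.fasta"))
write_tsv(study$gene_table, file.path(out, "genes.tsv"))
write_newick(study$cfg$topo_full, file.path(out, "topology_full.nwk"))
write_newick(study$cfg$topo_dating, file.path(out, "topology_dating.nwk"))

# truth tables: template coordinates per read
for (t in names(study$reads_by_taxon)) {
  r <- study$reads_by_taxon[[t]]
  write_tsv(r[, c("id", "template", "start", "len", "strand")],
            file.path(out, paste0("truth_", t, ".tsv")))
}
write_manifest(out,
               list(seed = seed, genome_length = 8000,
                    n_templates = 1250, clock_rate = 0.02,
                    focal_divergence_ma = study$truth$focal_divergence),
               seeds = seed)

cat(sprintf("wrote %d + %d reads (mean length %.1f bp) and %d genomes to %s\n",
            nrow(study$reads_by_taxon$F1), nrow(study$reads_by_taxon$F2),
            mean(nchar(study$reads_by_taxon$F1$seq)),
            length(study$genomes) + 2, out))
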