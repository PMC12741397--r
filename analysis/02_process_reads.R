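#!/usr/bin/env Rscript
# Step 2 - read processing.
#
# For each focal specimen: 30 bp length filter, exact dereplication,
# greedy clustering at 93% identity (both strands), 3 bp end-trimming of
# centroids, and placement on the sister taxon's genome with the minimal
# seed-and-extend mapper. Writes centroid FASTA (";size=" abundances),
# cluster membership tables and minimal SAM under results/processed/.

library(paleomito)

data_dir <- "results/data"
out <- "results/processed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genomes <- read_fasta(file.path(data_dir, "genomes_true.fasta"))
ref <- genomes$seq[genomes$id == "SIC"]

for (t in c("F1", "F2")) {
  reads <- read_fasta(file.path(data_dir, paste0("reads_", t, ".fasta")))
  filt <- filter_reads(reads, 30)
  dered <- dereplicate(filt)
  cl <- suppressWarnings(cluster_greedy(dered, 0.93, strand_both = TRUE))
  trimmed <- suppressWarnings(trim_cluster_ends(cl$centroids$seq, 3))
  keep <- !is.na(trimmed)
  cent <- cl$centroids[keep, , drop = FALSE]
  cent$seq <- trimmed[keep]
  pl <- map_to_reference(cent, ref)

  write_fasta(cl$centroids, file.path(out, paste0(t, "_centroids.fasta")))
  write_tsv(cl$members, file.path(out, paste0(t, "_members.tsv")))
  write_sam(pl, cent, "SIC", nchar(ref),
            file.path(out, paste0(t, "_placements.sam")))
  cat(sprintf(
    "%s: %d reads -> %d unique -> %d clusters; %d/%d centroids mapped\n",
    t, nrow(reads), nrow(dered), nrow(cl$centroids), sum(pl$mapped),
    nrow(cent)))
}
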