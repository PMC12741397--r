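# Standard-format readers/writers: FASTA/FASTQ (abundance annotations in
# headers), Newick (with node ages for dated trees), minimal SAM, flat
# key-value run configs, tab-separated tables, and run manifests. All
# file outputs are deterministic given config + seed; run metadata lives
# in the manifest, never inside data files.

#' Read FASTA/FASTQ into a read table
#'
#' Parses `;size=N;` abundance annotations in headers into the `size`
#' column. FASTQ qualities are ignored (FASTA is canonical internally).
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`.
#' @return a read table (`id`, `seq`, `size`).
#' @export
read_fasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ss <- Biostrings::readDNAStringSet(path, format = format)
  ids <- names(ss) %||% character(length(ss))
  size <- rep(1L, length(ss))
  has <- grepl(";size=\\d+;?", ids)
  size[has] <- as.integer(sub(".*;size=(\\d+);?.*", "\\1", ids[has]))
  ids <- sub(";size=\\d+;?", "", ids)
  ids <- sub("\\s.*$", "", ids)
  data.frame(id = ids, seq = as.character(ss), size = size,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table (or named sequences) as FASTA/FASTQ
#'
#' Abundances `> 1` are annotated as `;size=N;` in the header. FASTQ
#' output uses a uniform quality character.
#'
#' @param x read table or named character vector of sequences.
#' @param path output file.
#' @param width line wrap width for FASTA.
#' @param format `"fasta"` or `"fastq"`.
#' @param quality_char uniform FASTQ quality symbol.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L,
                        format = c("fasta", "fastq"),
                        quality_char = "I") {
  format <- match.arg(format)
  x <- as_reads(x)
  ids <- ifelse(x$size > 1L, paste0(x$id, ";size=", x$size, ";"), x$id)
  ss <- Biostrings::DNAStringSet(x$seq)
  names(ss) <- ids
  if (format == "fasta") {
    Biostrings::writeXStringSet(ss, path, width = width)
  } else {
    q <- Biostrings::BStringSet(strrep(quality_char, nchar(x$seq)))
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape preserving topology, branch lengths and labels.
#'
#' @param path file path.
#' @return `read_newick`: a `phylo`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse a tree from ", path)
  tr
}

#' @rdname read_newick
#' @param tree a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read a dated tree with node ages
#'
#' Newick with branch lengths equal to durations (Ma) and node labels
#' carrying node ages (`age=<x>`); tips' ages are recoverable from the
#' root age minus root-to-tip path lengths, so the round trip restores
#' the full age vector.
#'
#' @param dt a [dated_tree].
#' @param path file path.
#' @export
write_dated_tree <- function(dt, path) {
  tr <- dt$topo
  ntip <- length(tr$tip.label)
  tr$edge.length <- dt$ages[tr$edge[, 1]] - dt$ages[tr$edge[, 2]]
  tr$node.label <- sprintf("age=%.10g", dt$ages[(ntip + 1L):length(dt$ages)])
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' @rdname write_dated_tree
#' @export
read_dated_tree <- function(path) {
  tr <- ape::read.tree(path)
  ntip <- length(tr$tip.label)
  node_ages <- as.numeric(sub("^age=", "", tr$node.label))
  if (anyNA(node_ages)) stop("node labels do not carry ages")
  # tip age = parent age - branch duration
  ages <- numeric(ntip + tr$Nnode)
  ages[(ntip + 1L):(ntip + tr$Nnode)] <- node_ages
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip)
      ages[ch] <- ages[tr$edge[e, 1]] - tr$edge.length[e]
  }
  ages[abs(ages) < 1e-12] <- 0
  tr$node.label <- NULL
  dated_tree(tr, ages)
}

#' Write placements as minimal SAM
#'
#' Header plus the 11 mandatory fields with an ungapped (`<len>M`) CIGAR;
#' unmapped reads are emitted with flag 4. Coordinates convert to SAM's
#' 1-based convention at this boundary.
#'
#' @param placements placement table from [map_to_reference].
#' @param reads the read table.
#' @param ref_name reference sequence name.
#' @param ref_length reference length.
#' @param path output file.
#' @export
write_sam <- function(placements, reads, ref_name, ref_length, path) {
  reads <- as_reads(reads)
  seqs <- reads$seq[match(placements$id, reads$id)]
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_length))
  flag <- ifelse(!placements$mapped, 4L,
                 ifelse(placements$strand == "-", 16L, 0L))
  out_seq <- ifelse(placements$mapped & placements$strand == "-",
                    rev_comp(seqs), seqs)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  placements$id, flag,
                  ifelse(placements$mapped, ref_name, "*"),
                  ifelse(placements$mapped, placements$pos + 1L, 0L),
                  ifelse(placements$mapped, 255L, 0L),
                  ifelse(placements$mapped,
                         paste0(placements$alen, "M"), "*"),
                  out_seq,
                  ifelse(placements$mapped, placements$mismatches, 0L))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write / read tab-separated tables
#'
#' @param x data frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Flat key-value run configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' parsed as logical, numeric, or comma-separated vectors where they
#' look like one, else kept as strings.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  parse1 <- function(v) {
    if (grepl(",", v, fixed = TRUE))
      return(unlist(lapply(trimws(strsplit(v, ",")[[1]]), parse1)))
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) return(n)
    v
  }
  stats::setNames(lapply(vals, parse1), keys)
}

#' @rdname read_run_config
#' @param config named list of scalar or vector values.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Provenance record for a harness run: config hash (MD5 of the written
#' config), seeds, and the package version. Kept separate from data
#' files so those stay byte-identical across re-runs.
#'
#' @param dir run directory.
#' @param config named configuration list.
#' @param seeds integer seeds used.
#' @export
write_manifest <- function(dir, config, seeds) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.txt")
  write_run_config(config, cfg_path)
  man <- c(paste0("config_md5 = ", unname(tools::md5sum(cfg_path))),
           paste0("seeds = ", paste(seeds, collapse = ",")),
           paste0("package_version = ",
                  as.character(utils::packageVersion("paleomito"))))
  writeLines(man, file.path(dir, "manifest.txt"))
  invisible(file.path(dir, "manifest.txt"))
}

#' Write a supermatrix and its partition file
#'
#' FASTA matrix plus a partition file in the common
#' `name = start-end[, ...]` range-list format (1-based inclusive).
#'
#' @param sm a `supermatrix`.
#' @param fasta_path,partition_path output files.
#' @export
write_supermatrix <- function(sm, fasta_path, partition_path) {
  seqs <- matrix_to_seqs(sm$matrix)
  write_fasta(seqs, fasta_path)
  ranges <- vapply(sm$partitions, function(idx) {
    if (!length(idx)) return("")
    d <- which(diff(idx) != 1L)
    starts <- idx[c(1L, d + 1L)]
    ends <- idx[c(d, length(idx))]
    paste(sprintf("%d-%d", starts, ends), collapse = ", ")
  }, "")
  writeLines(sprintf("%s = %s", names(sm$partitions), ranges),
             partition_path)
  invisible(partition_path)
}
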