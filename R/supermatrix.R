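# Partitioned supermatrix assembly from annotated mitogenomes: start/stop
# codon stripping, removal of the named overlapping CDS regions, L-strand
# reverse complementation, and the five-partition map (codon positions
# 1/2/3, RNAs, D-loop). Inputs are per-gene homologous columns (pre-aligned
# or indel-free); no multiple alignment is performed here.

#' Annotated genome
#'
#' A genome sequence with its gene table: `name`, `start`, `end` (0-based
#' half-open), `strand` (`H` heavy / `L` light), `class`
#' (`CDS`, `tRNA`, `rRNA`, `D-loop`).
#'
#' @param id taxon identifier.
#' @param seq genome sequence string.
#' @param genes gene table data frame.
#' @return an object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, seq, genes) {
  validate_gene_table(genes, nchar(seq))
  structure(list(id = id, seq = toupper(seq), genes = genes),
            class = "annotated_genome")
}

validate_gene_table <- function(genes, seq_len = Inf) {
  need <- c("name", "start", "end", "strand", "class")
  stopifnot(is.data.frame(genes), all(need %in% names(genes)))
  if (any(genes$start < 0 | genes$end <= genes$start))
    stop("gene intervals must be non-empty and non-negative")
  if (any(genes$end > seq_len))
    stop("gene interval beyond sequence bounds")
  if (!all(genes$strand %in% c("H", "L")))
    stop("strand must be 'H' or 'L'")
  if (!all(genes$class %in% c("CDS", "tRNA", "rRNA", "D-loop")))
    stop("class must be CDS, tRNA, rRNA or D-loop")
  invisible(genes)
}

# The named overlapping CDS pairs whose shared columns are excluded from
# duplication (dedup mode keeps one copy via the first member; strict mode
# drops the shared columns from both).
OVERLAP_PAIRS <- list(c("ATP8", "ATP6"), c("ND4L", "ND4"), c("ND5", "ND6"))

#' Build a partitioned supermatrix from annotated genomes
#'
#' Per CDS the first and last codon are stripped; shared columns of the
#' named overlapping pairs (ATP8/ATP6, ND4L/ND4, ND5/ND6) are removed
#' from the second member (`overlap_mode = "dedup"`, retaining one copy)
#' or from both (`"strict"`); light-strand genes are reverse-complemented;
#' blocks are concatenated as CDS genes (gene-table order), RNAs, then
#' D-loop. Codon positions are assigned in each gene's own reading frame
#' before overlap removal, so removal never shifts the frame labels.
#'
#' @param genomes a list of [annotated_genome] objects, or a named
#'   character vector of genome sequences with `gene_table` supplied.
#'   All genomes must share the gene table's coordinate frame; a taxon
#'   whose sequence is shorter than a gene interval is filled with `N`
#'   there (with a message).
#' @param gene_table shared gene table when `genomes` is a character
#'   vector.
#' @param overlap_mode `"dedup"` (default) or `"strict"`.
#' @param strip_codons strip the first and last codon of every CDS
#'   (default `TRUE`; disable to study overlap handling in isolation).
#' @return an object of class `supermatrix`: list with `matrix`
#'   (taxon x site character matrix), `partitions` (named site-index
#'   list: pos1, pos2, pos3, RNA, Dloop), `blocks` (CDS/RNA/D-loop
#'   lengths), and `column_info` (gene, 0-based genome position, codon
#'   position).
#' @export
build_supermatrix <- function(genomes, gene_table = NULL,
                              overlap_mode = c("dedup", "strict"),
                              strip_codons = TRUE) {
  overlap_mode <- match.arg(overlap_mode)
  if (is.list(genomes) && inherits(genomes[[1]], "annotated_genome")) {
    gene_table <- genomes[[1]]$genes
    seqs <- stats::setNames(vapply(genomes, function(g) g$seq, ""),
                            vapply(genomes, function(g) g$id, ""))
  } else {
    stopifnot(!is.null(gene_table), !is.null(names(genomes)))
    seqs <- toupper(genomes)
  }
  validate_gene_table(gene_table)

  cds <- gene_table[gene_table$class == "CDS", , drop = FALSE]
  rna <- gene_table[gene_table$class %in% c("tRNA", "rRNA"), , drop = FALSE]
  dlp <- gene_table[gene_table$class == "D-loop", , drop = FALSE]

  # per-gene retained genome columns (1-based) + codon positions, in the
  # gene's own 5'->3' order
  gene_cols <- list()
  gene_cpos <- list()
  for (i in seq_len(nrow(cds))) {
    g <- cds[i, ]
    cols <- (g$start + 1L):g$end
    if (g$strand == "L") cols <- rev(cols)
    if (length(cols) %% 3L != 0L)
      stop("CDS not divisible by 3: ", g$name)
    if (strip_codons)
      cols <- cols[-c(1:3, (length(cols) - 2L):length(cols))]
    if (length(cols) %% 3L != 0L)
      stop("CDS not divisible by 3 after exclusions: ", g$name)
    gene_cols[[g$name]] <- cols
    gene_cpos[[g$name]] <- rep_len(1:3, length(cols))
  }
  for (pair in OVERLAP_PAIRS) {
    if (!all(pair %in% names(gene_cols))) next
    a <- gene_table[match(pair[1], gene_table$name), ]
    b <- gene_table[match(pair[2], gene_table$name), ]
    ov_lo <- max(a$start, b$start); ov_hi <- min(a$end, b$end)
    if (ov_lo >= ov_hi) next
    ov <- (ov_lo + 1L):ov_hi
    drop_from <- if (overlap_mode == "dedup") pair[2] else pair
    for (nm in drop_from) {
      keep <- !(gene_cols[[nm]] %in% ov)
      gene_cols[[nm]] <- gene_cols[[nm]][keep]
      gene_cpos[[nm]] <- gene_cpos[[nm]][keep]
    }
  }

  rna_cols <- unlist(lapply(seq_len(nrow(rna)), function(i) {
    cols <- (rna$start[i] + 1L):rna$end[i]
    if (rna$strand[i] == "L") rev(cols) else cols
  }))
  dlp_cols <- if (nrow(dlp)) unlist(lapply(seq_len(nrow(dlp)), function(i)
    (dlp$start[i] + 1L):dlp$end[i])) else integer()

  cds_order <- cds$name
  all_cols <- c(unlist(gene_cols[cds_order], use.names = FALSE),
                rna_cols, dlp_cols)
  all_cpos <- c(unlist(gene_cpos[cds_order], use.names = FALSE),
                rep(NA_integer_, length(rna_cols) + length(dlp_cols)))
  gene_of <- c(rep.int(cds_order,
                       vapply(gene_cols[cds_order], length, 1L)),
               rep.int(rna$name, rna$end - rna$start),
               rep.int(dlp$name, dlp$end - dlp$start))
  # complement flag per column (L-strand genes contribute complements)
  comp_flag <- c(unlist(lapply(cds_order, function(nm)
    rep(cds$strand[match(nm, cds$name)] == "L",
        length(gene_cols[[nm]])))),
    unlist(lapply(seq_len(nrow(rna)), function(i)
      rep(rna$strand[i] == "L", rna$end[i] - rna$start[i]))),
    rep(FALSE, length(dlp_cols)))

  nsites <- length(all_cols)
  taxa <- names(seqs)
  mat <- matrix("N", length(taxa), nsites, dimnames = list(taxa, NULL))
  comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  for (t in taxa) {
    ch <- strsplit(seqs[[t]], "", fixed = TRUE)[[1]]
    if (length(ch) < max(all_cols)) {
      message("taxon ", t, " shorter than the gene table; missing ",
              "positions filled with N")
      ch <- c(ch, rep("N", max(all_cols) - length(ch)))
    }
    row <- ch[all_cols]
    row[comp_flag] <- comp_map[row[comp_flag]]
    row[is.na(row) | !(row %in% c(BASES, "N", "-"))] <- "N"
    mat[t, ] <- row
  }

  ncds <- sum(vapply(gene_cols[cds_order], length, 1L))
  nrna <- length(rna_cols)
  partitions <- list(pos1 = which(all_cpos == 1L),
                     pos2 = which(all_cpos == 2L),
                     pos3 = which(all_cpos == 3L),
                     RNA = if (nrna) ncds + seq_len(nrna) else integer(),
                     Dloop = if (length(dlp_cols))
                       ncds + nrna + seq_along(dlp_cols) else integer())
  structure(list(matrix = mat, partitions = partitions,
                 blocks = c(CDS = ncds, RNA = nrna,
                            Dloop = length(dlp_cols)),
                 column_info = data.frame(gene = gene_of,
                                          genome_pos = all_cols - 1L,
                                          codon_pos = all_cpos)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf(
    "supermatrix: %d taxa x %d sites (CDS %d, RNA %d, D-loop %d)\n",
    nrow(x$matrix), ncol(x$matrix), x$blocks["CDS"], x$blocks["RNA"],
    x$blocks["Dloop"]))
  cat("partitions:",
      paste(sprintf("%s=%d", names(x$partitions),
                    lengths(x$partitions)), collapse = ", "), "\n")
  invisible(x)
}

#' Count unambiguous bases in an alignment row
#'
#' @param row a sequence string, character vector of strings, or a
#'   `supermatrix` (counted per taxon).
#' @return integer count(s) of characters in `{A, C, G, T}`.
#' @export
count_unambiguous <- function(row) {
  if (inherits(row, "supermatrix"))
    return(apply(row$matrix, 1L, function(r) sum(r %in% BASES)))
  vapply(strsplit(toupper(row), "", fixed = TRUE),
         function(ch) sum(ch %in% BASES), 1L)
}

#' Synthetic scaled mitogenome gene table
#'
#' A compact annotation emulating the organisation of a mammalian
#' mitogenome at reduced size: CDS genes laid end to end including the
#' three named overlapping pairs (ATP8/ATP6, ND4L/ND4, ND5/ND6) with an
#' L-strand ND6, a block of RNAs, and a terminal D-loop (control region)
#' filling the remainder of the genome.
#'
#' @param genome_length total genome length in bp (default 8000, a
#'   scaled-down mitogenome).
#' @return a gene table data frame (0-based half-open coordinates).
#' @export
synthetic_gene_table <- function(genome_length = 8000L) {
  # gene lengths scale with the genome; CDS lengths stay divisible by 3;
  # overlaps are fixed and deliberately not multiples of 3
  s <- genome_length / 8000
  cds_len <- function(l) max(30L, as.integer(3 * round(l * s / 3)))
  rna_len <- function(l) max(40L, as.integer(round(l * s)))
  g <- list()
  add <- function(name, len, strand = "H", class = "CDS", overlap = 0L) {
    start <- if (length(g)) g[[length(g)]]$end - overlap else 0L
    g[[length(g) + 1L]] <<- data.frame(name = name, start = start,
                                       end = start + len, strand = strand,
                                       class = class,
                                       stringsAsFactors = FALSE)
  }
  add("ND1", cds_len(900))
  add("COX1", cds_len(1200))
  add("ATP8", cds_len(204))
  add("ATP6", cds_len(630), overlap = 10L)
  add("ND4L", cds_len(288))
  add("ND4", cds_len(1140), overlap = 7L)
  add("ND5", cds_len(1500))
  add("ND6", cds_len(498), strand = "L", overlap = 4L)
  add("rrnS", rna_len(500), class = "rRNA")
  add("rrnL", rna_len(800), class = "rRNA")
  add("trnF", rna_len(70), class = "tRNA")
  add("trnV", rna_len(70), class = "tRNA")
  genes <- do.call(rbind, g)
  if (genes$end[nrow(genes)] >= genome_length)
    stop("genome_length too small for the synthetic gene table")
  rbind(genes,
        data.frame(name = "D-loop", start = genes$end[nrow(genes)],
                   end = genome_length, strand = "H", class = "D-loop",
                   stringsAsFactors = FALSE))
}
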