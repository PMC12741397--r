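# Pileups, end-trimmed majority consensus, damage-misincorporation
# profiles, and windowed depth of coverage.

#' Trim fixed-length ends off cluster sequences
#'
#' Removes the first and last `k` characters of each sequence, discarding
#' (with a warning) sequences of length `<= 2k`, which carry no interior
#' sequence. Trimming suppresses terminal deamination artefacts before
#' consensus calling.
#'
#' @param x character vector of sequences.
#' @param k bases to trim from each end (`>= 0`).
#' @return character vector with `NA` for rejected sequences.
#' @export
trim_cluster_ends <- function(x, k = 3L) {
  stopifnot(k >= 0)
  if (k == 0) return(x)
  lens <- nchar(x)
  out <- ifelse(lens > 2 * k, substr(x, k + 1L, lens - k), NA_character_)
  nrej <- sum(is.na(out) & !is.na(x))
  if (nrej > 0)
    warning(nrej, " sequence(s) of length <= ", 2 * k,
            " rejected by end-trimming")
  out
}

# Reference-oriented bases and positions contributed by mapped placements.
placement_bases <- function(placements, reads, reference, circular = TRUE) {
  reads <- as_reads(reads)
  L <- nchar(reference)
  pl <- placements[placements$mapped, , drop = FALSE]
  if (!nrow(pl))
    return(list(pos = integer(), code = integer(), L = L))
  seqs <- reads$seq[match(pl$id, reads$id)]
  if (anyNA(seqs)) stop("placement refers to unknown read id")
  bad <- pl$pos < 0 | (!circular & (pl$pos + pl$alen > L))
  if (any(bad))
    stop("placement out of bounds for read ", pl$id[which(bad)[1]])
  seqs[pl$strand == "-"] <- rev_comp(seqs[pl$strand == "-"])
  lens <- nchar(seqs)
  ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  posl <- unlist(lapply(seq_len(nrow(pl)), function(i)
    pl$pos[i] + 0:(lens[i] - 1L)), use.names = FALSE)
  posl <- posl %% L
  code <- match(ch, c(BASES, "N"))
  code[is.na(code)] <- 5L
  list(pos = posl, code = code, L = L)
}

#' Build a pileup from placements
#'
#' Per reference position counts of A, C, G, T (reference-strand
#' oriented; reverse-strand reads contribute complemented bases) and N.
#'
#' @param placements placement table from [map_to_reference].
#' @param reads the read table the placements refer to.
#' @param reference reference DNA string.
#' @param circular treat the reference as circular.
#' @return an object of class `pileup`: a 5 x L integer count matrix
#'   (rows A, C, G, T, N) with a `depth()` given by column sums.
#' @export
build_pileup <- function(placements, reads, reference, circular = TRUE) {
  pb <- placement_bases(placements, reads, reference, circular)
  counts <- matrix(tabulate(pb$pos * 5L + pb$code, nbins = 5L * pb$L),
                   nrow = 5L, dimnames = list(c(BASES, "N"), NULL))
  structure(list(counts = counts, length = pb$L), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  d <- colSums(x$counts)
  cat(sprintf("pileup over %d positions: mean depth %.2f, %.1f%% covered\n",
              x$length, mean(d), 100 * mean(d > 0)))
  invisible(x)
}

#' Depth per position of a pileup
#' @param pileup a [build_pileup] result.
#' @return integer vector of per-position depths (base counts + N).
#' @export
pileup_depth <- function(pileup) colSums(pileup$counts)

#' Call a majority consensus from a pileup
#'
#' At each position the base with a strict plurality and fraction
#' `> majority_frac` of the non-N observations is called when the non-N
#' depth is `>= min_depth`; otherwise `N`. Ties always produce `N`.
#'
#' @param pileup a [build_pileup] result.
#' @param min_depth minimum non-N depth to call a base.
#' @param majority_frac required fraction (strict) of non-N observations.
#' @return consensus sequence string with `N` at unresolved sites.
#' @export
call_consensus <- function(pileup, min_depth = 1L, majority_frac = 0.5) {
  stopifnot(min_depth >= 1, majority_frac >= 0, majority_frac < 1)
  cnt <- pileup$counts[1:4, , drop = FALSE]
  depth <- colSums(cnt)
  mx <- apply(cnt, 2L, max)
  nmax <- colSums(cnt == rep(mx, each = 4L)) # ties counted at max
  idx <- max.col(t(cnt), ties.method = "first")
  call <- BASES[idx]
  ok <- depth >= min_depth & mx > majority_frac * depth & nmax == 1L &
    mx > 0
  call[!ok] <- "N"
  paste(call, collapse = "")
}

#' Damage misincorporation profile by read-end offset
#'
#' For offsets 1..L from each read end, the frequency of read-versus-
#' reference mismatches of type C-to-T (5' end) and G-to-A (3' end),
#' computed on reference-C (respectively -G) sites only, in molecule
#' orientation (reverse-strand placements are compared against the
#' reverse-complemented reference). The opposite-type substitutions at
#' each end are reported as background.
#'
#' @param placements placement table (non-empty mapped set).
#' @param reads the read table.
#' @param reference reference DNA string.
#' @param L maximum offset from each end.
#' @param circular treat the reference as circular.
#' @return a data frame of class `damage_table` with per-offset
#'   frequencies (`NA` when a reference-base count is 0) and observation
#'   counts.
#' @export
damage_profile <- function(placements, reads, reference, L = 25L,
                           circular = TRUE) {
  reads <- as_reads(reads)
  pl <- placements[placements$mapped, , drop = FALSE]
  if (!nrow(pl)) stop("no mapped placements")
  Lref <- nchar(reference)
  ext <- paste0(reference, substr(reference, 1L, max(pl$alen)))
  seqs <- reads$seq[match(pl$id, reads$id)]
  refsub <- substring(ext, pl$pos + 1L, pl$pos + pl$alen)
  rev <- pl$strand == "-"
  refsub[rev] <- rev_comp(refsub[rev])   # molecule orientation

  lens <- pl$alen
  rch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  fch <- unlist(strsplit(refsub, "", fixed = TRUE), use.names = FALSE)
  off5 <- sequence(lens)
  off3 <- rep.int(lens, lens) - off5 + 1L

  count2 <- function(off, refb, readb) {
    sel <- off <= L & fch == refb
    n <- tabulate(off[sel], nbins = L)
    hit <- tabulate(off[sel & rch == readb], nbins = L)
    list(n = n, freq = ifelse(n > 0, hit / n, NA_real_))
  }
  ct5 <- count2(off5, "C", "T")
  ga3 <- count2(off3, "G", "A")
  ga5 <- count2(off5, "G", "A")
  ct3 <- count2(off3, "C", "T")
  structure(data.frame(offset = seq_len(L),
                       freq_ct_5p = ct5$freq, n_c_5p = ct5$n,
                       freq_ga_3p = ga3$freq, n_g_3p = ga3$n,
                       freq_ga_5p = ga5$freq, n_g_5p = ga5$n,
                       freq_ct_3p = ct3$freq, n_c_3p = ct3$n),
            class = c("damage_table", "data.frame"))
}

#' Windowed depth of coverage
#'
#' Mean per-base depth within consecutive windows; the final partial
#' window is averaged over its own length, not the nominal window size.
#'
#' @param placements placement table.
#' @param reference_length reference length in bp.
#' @param window window size in bp (`>= 1`).
#' @return a list with `windows` (data frame: `window`, `start`, `end`
#'   0-based half-open, `mean_depth`) and `mean_depth` (overall mean
#'   per-base depth).
#' @export
windowed_depth <- function(placements, reference_length, window = 1000L) {
  stopifnot(window >= 1)
  L <- reference_length
  pl <- placements[placements$mapped, , drop = FALSE]
  depth <- numeric(L)
  if (nrow(pl)) {
    posl <- unlist(lapply(seq_len(nrow(pl)), function(i)
      pl$pos[i] + 0:(pl$alen[i] - 1L)), use.names = FALSE) %% L
    depth <- tabulate(posl + 1L, nbins = L)
  }
  nw <- ceiling(L / window)
  start <- (seq_len(nw) - 1L) * window
  end <- pmin(start + window, L)
  mean_depth <- vapply(seq_len(nw), function(i)
    mean(depth[(start[i] + 1L):end[i]]), 0)
  list(windows = data.frame(window = seq_len(nw), start = start, end = end,
                            mean_depth = mean_depth),
       mean_depth = sum(depth) / L)
}
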