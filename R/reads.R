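# Read processing: length filtering, exact dereplication, greedy identity
# clustering (abundance-ordered centroids, both strands), a minimal
# seed-and-extend mapper, and seeded down-sampling.

#' Coerce to a read table
#'
#' Reads are plain data frames with columns `id`, `seq` and `size`
#' (abundance, default 1); simulation metadata columns are carried along.
#'
#' @param x a character vector of sequences (ids generated), a named
#'   character vector (names become ids), or a data frame with at least
#'   `id` and `seq`.
#' @return a read data frame.
#' @export
as_reads <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    if (is.null(x$size)) x$size <- 1L
    return(x)
  }
  ids <- names(x) %||% sprintf("r%06d", seq_along(x))
  data.frame(id = ids, seq = toupper(unname(x)), size = 1L,
             stringsAsFactors = FALSE)
}

#' Filter reads by minimum length
#'
#' Keeps exactly the reads with `nchar(seq) >= min_len`, preserving order.
#' Idempotent.
#'
#' @param reads a read table (see [as_reads]).
#' @param min_len minimum retained length in bp (`>= 1`).
#' @return the filtered read table.
#' @export
filter_reads <- function(reads, min_len = 30L) {
  stopifnot(min_len >= 1)
  reads <- as_reads(reads)
  reads[nchar(reads$seq) >= min_len, , drop = FALSE]
}

#' Dereplicate identical reads
#'
#' Groups reads by exact full-length string equality and sums their
#' abundances. Output is sorted by abundance descending, then length
#' descending, then lexicographic id; each record keeps the
#' lexicographically smallest member id.
#'
#' @param reads a read table.
#' @return a dereplicated read table with summed `size`.
#' @export
dereplicate <- function(reads) {
  reads <- as_reads(reads)
  if (!nrow(reads)) return(reads)
  grp <- match(reads$seq, unique(reads$seq))
  size <- as.integer(rowsum(as.numeric(reads$size), grp))
  id <- vapply(split(reads$id, grp), function(v) sort(v)[1], "")
  seq <- unique(reads$seq)
  out <- data.frame(id = id, seq = seq, size = size,
                    stringsAsFactors = FALSE)
  out[order(-out$size, -nchar(out$seq), out$id), , drop = FALSE]
}

#' Pairwise ungapped identity
#'
#' Identity of two sequences under the fixed definition used throughout:
#' matching columns of the left-aligned (equal-offset) ungapped comparison
#' divided by the length of the longer sequence; `N` never matches.
#'
#' @param a,b DNA strings.
#' @param strand_both also try the reverse complement of `b` and return
#'   the larger identity.
#' @return identity in `[0, 1]`.
#' @export
pair_identity <- function(a, b, strand_both = FALSE) {
  ident1 <- function(x, y) {
    cx <- strsplit(x, "", fixed = TRUE)[[1]]
    cy <- strsplit(y, "", fixed = TRUE)[[1]]
    l <- min(length(cx), length(cy))
    m <- sum(cx[seq_len(l)] == cy[seq_len(l)] & cx[seq_len(l)] != "N")
    m / max(length(cx), length(cy))
  }
  i <- ident1(a, b)
  if (strand_both) i <- max(i, ident1(a, rev_comp(b)))
  i
}

#' Greedy centroid clustering at an identity threshold
#'
#' Abundance-ordered greedy clustering: reads are processed by abundance
#' descending (ties: length descending, then id); each read joins the
#' first existing centroid it matches at `>= id_threshold` identity (on
#' either strand when `strand_both`), else founds a new cluster. Reads
#' with more than 50% `N` are dropped with a warning.
#'
#' @param reads a read table (dereplication recommended first).
#' @param id_threshold identity threshold in `(0, 1]`.
#' @param strand_both compare both strands.
#' @return an object of class `read_clusters`: a list with `centroids`
#'   (id, seq, size = summed member abundance) and `members` (id,
#'   centroid, strand).
#' @export
cluster_greedy <- function(reads, id_threshold = 0.93, strand_both = TRUE) {
  stopifnot(id_threshold > 0, id_threshold <= 1)
  reads <- as_reads(reads)
  nfrac <- vapply(strsplit(reads$seq, "", fixed = TRUE),
                  function(ch) mean(ch == "N"), 0)
  if (any(nfrac > 0.5)) {
    warning(sum(nfrac > 0.5), " read(s) with > 50% N dropped before clustering")
    reads <- reads[nfrac <= 0.5, , drop = FALSE]
  }
  if (!nrow(reads)) {
    return(structure(list(
      centroids = data.frame(id = character(), seq = character(),
                             size = integer(), stringsAsFactors = FALSE),
      members = data.frame(id = character(), centroid = character(),
                           strand = character(), stringsAsFactors = FALSE)),
      class = "read_clusters"))
  }
  ord <- order(-reads$size, -nchar(reads$seq), reads$id)
  reads <- reads[ord, , drop = FALSE]
  rcs <- if (strand_both) rev_comp(reads$seq) else character()
  res <- greedy_cluster_cpp(reads$seq, rcs, id_threshold)
  cidx <- res$centroid
  csize <- as.integer(rowsum(as.numeric(reads$size), cidx))
  cpos <- sort(unique(cidx))
  centroids <- data.frame(id = reads$id[cpos], seq = reads$seq[cpos],
                          size = csize[match(cpos, sort(unique(cidx)))],
                          stringsAsFactors = FALSE)
  members <- data.frame(id = reads$id, centroid = reads$id[cidx],
                        strand = res$strand, stringsAsFactors = FALSE)
  structure(list(centroids = centroids, members = members),
            class = "read_clusters")
}

#' @export
print.read_clusters <- function(x, ...) {
  cat(sprintf("read_clusters: %d clusters from %d members (total size %d)\n",
              nrow(x$centroids), nrow(x$members), sum(x$centroids$size)))
  invisible(x)
}

#' Minimal seed-and-extend read mapper
#'
#' Exact k-mer seeding with ungapped extension on both strands against a
#' (circular) reference. The best placement minimises the mismatch count;
#' ties break to the lowest reference coordinate, then the forward
#' strand. `N` never counts as a match. Reads whose best placement
#' exceeds `max_mismatch_frac * length` mismatches are flagged unplaced.
#'
#' @param reads a read table.
#' @param reference reference DNA string (length `>= k`).
#' @param k seed length.
#' @param max_mismatch_frac maximum tolerated mismatch fraction.
#' @param seed_step spacing of seed offsets tried along the read.
#' @param circular treat the reference as circular.
#' @return a placement data frame: `id`, `pos` (0-based leftmost on the
#'   forward reference), `strand`, `mismatches`, `alen`, `mapped`.
#' @export
map_to_reference <- function(reads, reference, k = 16L,
                             max_mismatch_frac = 0.1, seed_step = 4L,
                             circular = TRUE) {
  reads <- as_reads(reads)
  reference <- toupper(reference)
  L <- nchar(reference)
  if (L < k) stop("reference length must be >= k")
  if (!grepl("[ACGT]", reference))
    stop("degenerate reference (no unambiguous bases)")
  maxlen <- max(nchar(reads$seq), k)
  ext <- if (circular) paste0(reference, substr(reference, 1L, maxlen))
         else reference
  Lext <- nchar(ext)
  refcode <- utf8ToInt(ext)
  ncode <- utf8ToInt("N")

  starts <- seq_len(L)
  kmers <- substring(ext, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE) & nchar(kmers) == k
  kmap <- split(starts[keep], kmers[keep])

  n <- nrow(reads)
  pos <- rep(NA_integer_, n); strand <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n); alen <- rep(NA_integer_, n)
  mapped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    len <- nchar(s)
    if (len < k) next
    offs <- unique(c(seq.int(1L, len - k + 1L, by = seed_step), len - k + 1L))
    best <- NULL
    for (st in c("+", "-")) {
      q <- if (st == "+") s else rev_comp(s)
      qcode <- utf8ToInt(q)
      cand <- integer()
      for (off in offs) {
        hits <- kmap[[substr(q, off, off + k - 1L)]]
        if (!is.null(hits)) cand <- c(cand, hits - off + 1L)
      }
      cand <- unique(cand[cand >= 1L & cand <= L & cand + len - 1L <= Lext])
      for (p in cand) {
        rsub <- refcode[p:(p + len - 1L)]
        nmm <- sum(rsub != qcode | qcode == ncode)
        if (is.null(best) || nmm < best$mm ||
            (nmm == best$mm && (p - 1L) < best$pos) ||
            (nmm == best$mm && (p - 1L) == best$pos && st == "+" &&
             best$strand == "-")) {
          best <- list(pos = p - 1L, strand = st, mm = nmm)
        }
      }
      if (!is.null(best) && best$mm == 0L) break
    }
    if (!is.null(best) && best$mm <= floor(max_mismatch_frac * len)) {
      pos[i] <- best$pos; strand[i] <- best$strand
      mm[i] <- best$mm; alen[i] <- len; mapped[i] <- TRUE
    }
  }
  data.frame(id = reads$id, pos = pos, strand = strand, mismatches = mm,
             alen = alen, mapped = mapped, stringsAsFactors = FALSE)
}

#' Down-sample reads without replacement
#'
#' Uniform sample of `min(n, nrow(reads))` reads, reproducible given the
#' seed; sampled reads keep their original order.
#'
#' @param reads a read table.
#' @param n target number of reads (`>= 0`).
#' @param seed integer seed.
#' @return the sampled read table.
#' @export
downsample <- function(reads, n, seed = 1L) {
  stopifnot(n >= 0)
  reads <- as_reads(reads)
  if (n >= nrow(reads)) return(reads)
  with_seed(seed, {
    keep <- sort(sample.int(nrow(reads), n))
    reads[keep, , drop = FALSE]
  })
}
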