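# Internal helpers shared across modules. Coordinates are 0-based half-open
# internally; conversions to 1-based happen only at I/O boundaries.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over `A,C,G,T,N` (other characters are
#' preserved, `-` stays `-`).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
rev_comp <- function(x) {
  y <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(y, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

# Encode a DNA string as integer codes 1..4 (A,C,G,T); anything else
# (N, gaps, IUPAC ambiguity) becomes 5 = fully ambiguous.
encode_seq <- function(s) {
  i <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES)
  i[is.na(i)] <- 5L
  i
}

decode_seq <- function(codes) {
  paste(c(BASES, "N")[codes], collapse = "")
}

# Character matrix (rows = taxa) from equal-length strings.
seqs_to_matrix <- function(seqs) {
  n <- nchar(seqs)
  if (length(unique(n)) != 1L)
    stop("sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

matrix_to_seqs <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards. Every stochastic operation in the package
#' funnels its `seed` argument through this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
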