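# Synthetic-data generators: mitogenome evolution along dated trees,
# fragmentation into short ancient-DNA-like reads, terminal deamination
# damage, PCR over-amplification, and controlled substitution-error
# injection. All randomness flows from a single integer seed per call.

#' Dated tree (chronogram with possibly non-contemporaneous tips)
#'
#' A rooted binary topology with node ages in Ma (tips may be non-zero:
#' serial sampling) and optional per-branch substitution rates
#' (substitutions/site/Ma). Every parent must be strictly older than each
#' child.
#'
#' @param topo rooted `phylo`.
#' @param ages numeric vector of node ages in ape node order
#'   (`1..ntip` tips then internals), or a named vector over tip labels
#'   and internal node labels.
#' @param rates optional per-branch rates (length `nrow(topo$edge)`) or a
#'   single rate recycled to all branches.
#' @return an object of class `dated_tree`.
#' @export
dated_tree <- function(topo, ages, rates = NULL) {
  stopifnot(inherits(topo, "phylo"))
  if (!ape::is.rooted(topo)) stop("topology must be rooted")
  ntot <- length(topo$tip.label) + topo$Nnode
  if (!is.null(names(ages))) {
    labs <- c(topo$tip.label, topo$node.label %||% paste0("n", length(topo$tip.label) + seq_len(topo$Nnode)))
    if (!all(labs %in% names(ages)))
      stop("named ages must cover all tips and internal node labels")
    ages <- unname(ages[labs])
  }
  stopifnot(length(ages) == ntot)
  if (any(ages[seq_len(length(topo$tip.label))] < 0))
    stop("tip ages must be >= 0")
  dur <- ages[topo$edge[, 1]] - ages[topo$edge[, 2]]
  if (any(dur <= 0))
    stop("every parent age must be strictly greater than each child age")
  if (!is.null(rates)) {
    if (length(rates) == 1L) rates <- rep(rates, nrow(topo$edge))
    stopifnot(length(rates) == nrow(topo$edge), all(rates > 0))
  }
  structure(list(topo = topo, ages = as.numeric(ages), rates = rates),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("dated_tree: %d tips, root age %.4g Ma%s\n",
              length(x$topo$tip.label),
              x$ages[length(x$topo$tip.label) + 1L],
              if (is.null(x$rates)) "" else ", per-branch rates set"))
  invisible(x)
}

#' Branch durations and substitution branch lengths of a dated tree
#'
#' @param dt a [dated_tree].
#' @param rate per-branch rates or a scalar; defaults to `dt$rates`.
#' @return a `phylo` with `edge.length` in expected substitutions/site.
#' @export
dated_tree_phylo <- function(dt, rate = NULL) {
  stopifnot(inherits(dt, "dated_tree"))
  rate <- rate %||% dt$rates
  if (is.null(rate)) stop("no rates supplied")
  if (length(rate) == 1L) rate <- rep(rate, nrow(dt$topo$edge))
  tr <- dt$topo
  tr$edge.length <- (dt$ages[tr$edge[, 1]] - dt$ages[tr$edge[, 2]]) * rate
  tr
}

#' Evolve sequences along a tree
#'
#' Simulates nucleotide sequences at every node of a rooted tree under
#' (partitioned) GTR(+I)+Gamma models, sites i.i.d. given their partition
#' and rate category. True internal-node sequences are retained so
#' ancestral-reconstruction accuracy can be scored.
#'
#' @param tree a [dated_tree] (with rates, or supply `rate`) or a `phylo`
#'   whose `edge.length` is already in substitutions/site.
#' @param models a single [subst_model] or named list of models per
#'   partition.
#' @param partition integer vector assigning each site to a partition
#'   (names must match `models`), or a named vector of partition lengths;
#'   `NULL` with a single model simulates `length` i.i.d. sites.
#' @param length number of sites when `partition` is `NULL`.
#' @param seed integer seed.
#' @param rate clock rate(s) used to convert a [dated_tree] to
#'   substitutions/site.
#' @return a list with `seqs` (named character vector: tips by label,
#'   internal nodes `"n<k>"`), `site_partition`, and `tree` (the `phylo`
#'   used, branch lengths in substitutions/site).
#' @export
evolve_sequences <- function(tree, models, partition = NULL, length = NULL,
                             seed = 1L, rate = NULL) {
  if (inherits(tree, "dated_tree")) tree <- dated_tree_phylo(tree, rate)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (inherits(models, "subst_model")) models <- list(all = models)
  if (is.null(partition)) {
    if (is.null(length)) stop("supply `partition` or `length`")
    partition <- rep(names(models)[1], length)
  } else if (is.numeric(partition) && !is.null(names(partition))) {
    # named block lengths
    partition <- rep(names(partition), times = partition)
  }
  partition <- as.character(partition)
  stopifnot(all(partition %in% names(models)))
  nsites <- length(partition)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  with_seed(seed, {
    states <- matrix(0L, nnode, nsites)
    sitecat <- integer(nsites)   # 0 = invariant class
    for (pn in names(models)) {
      m <- models[[pn]]
      idx <- which(partition == pn)
      cats <- ifelse(stats::runif(length(idx)) < m$pinv, 0L,
                     sample.int(m$ncat, length(idx), replace = TRUE))
      sitecat[idx] <- cats
      states[root, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                      prob = m$freq)
    }
    tr <- ape::reorder.phylo(tree, "postorder")
    for (e in rev(seq_len(nrow(tr$edge)))) {    # preorder
      pa <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      states[ch, ] <- states[pa, ]
      bl <- tr$edge.length[e]
      if (bl <= 0) next
      for (pn in names(models)) {
        m <- models[[pn]]
        for (c in seq_len(m$ncat)) {
          idx <- which(partition == pn & sitecat == c)
          if (!length(idx)) next
          P <- transition_matrix(m, bl, m$cat_rates[c])
          px <- states[pa, idx]
          for (x in 1:4) {
            sel <- idx[px == x]
            if (length(sel))
              states[ch, sel] <- sample.int(4L, length(sel),
                                            replace = TRUE, prob = P[x, ])
          }
        }
      }
    }
    labs <- c(tree$tip.label, paste0("n", (ntip + 1L):nnode))
    seqs <- stats::setNames(
      apply(states, 1L, function(r) paste(BASES[r], collapse = "")), labs)
    list(seqs = seqs, site_partition = partition, tree = tree)
  })
}

#' Fragment length model
#'
#' Discretised lognormal fragment-length distribution truncated to
#' `[min, max]`. Defaults emulate short ancient mitochondrial libraries:
#' post-filter lengths in `[30, 76]` bp with a mean near 39 bp.
#'
#' @param meanlog,sdlog lognormal parameters on the bp scale.
#' @param min,max hard length bounds (bp).
#' @return an object of class `fragment_model` carrying the exact pmf on
#'   `min:max` and its mean.
#' @export
fragment_model <- function(meanlog = log(34), sdlog = 0.25,
                           min = 30L, max = 76L) {
  stopifnot(min >= 1, max >= min, sdlog > 0)
  support <- seq.int(min, max)
  p <- stats::plnorm(support + 0.5, meanlog, sdlog) -
    stats::plnorm(support - 0.5, meanlog, sdlog)
  if (sum(p) <= 0) stop("degenerate length distribution on [min, max]")
  p <- p / sum(p)
  structure(list(meanlog = meanlog, sdlog = sdlog, min = as.integer(min),
                 max = as.integer(max), support = support, pmf = p,
                 mean = sum(support * p)),
            class = "fragment_model")
}

#' @rdname fragment_model
#' @param fm a `fragment_model`.
#' @export
fragment_length_mean <- function(fm) fm$mean

#' Fragment a (circular) genome into template molecules
#'
#' Draws `n_templates` fragments with uniform start positions and lengths
#' from the fragment model. The genome is treated as circular by default;
#' fragments spanning the origin wrap, and their recorded start is the
#' 0-based leftmost position of the fragment on the forward strand.
#'
#' @param genome a DNA string.
#' @param fm a [fragment_model].
#' @param n_templates number of template molecules (`>= 0`).
#' @param seed integer seed.
#' @param circular treat the genome as circular.
#' @return a data frame with columns `template`, `start` (0-based),
#'   `len`, `strand`, `seq` (fragment sequence in molecule orientation).
#' @export
fragmentize <- function(genome, fm, n_templates, seed = 1L,
                        circular = TRUE) {
  stopifnot(inherits(fm, "fragment_model"), n_templates >= 0)
  L <- nchar(genome)
  if (fm$min > L) stop("minimum fragment length exceeds genome length")
  if (n_templates == 0)
    return(data.frame(template = character(), start = integer(),
                      len = integer(), strand = character(),
                      seq = character(), stringsAsFactors = FALSE))
  with_seed(seed, {
    len <- sample(fm$support, n_templates, replace = TRUE, prob = fm$pmf)
    if (!circular) len <- pmin(len, L)
    start <- if (circular) sample.int(L, n_templates, replace = TRUE) - 1L
             else vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L,
                         1L)
    strand <- sample(c("+", "-"), n_templates, replace = TRUE)
    ext <- paste0(genome, substr(genome, 1L, fm$max))
    seqs <- substring(ext, start + 1L, start + len)
    seqs[strand == "-"] <- rev_comp(seqs[strand == "-"])
    data.frame(template = sprintf("t%06d", seq_len(n_templates)),
               start = start, len = len, strand = strand, seq = seqs,
               stringsAsFactors = FALSE)
  })
}

#' Post-mortem damage model
#'
#' Terminal cytosine-deamination damage with exponential decay from each
#' molecule end: a `C` at 5' offset `i` becomes `T` with probability
#' `delta5 * exp(-lambda * (i - 1))`; a `G` at 3' offset `j` becomes `A`
#' with probability `delta3 * exp(-lambda * (j - 1))`. Independent
#' background substitution errors occur at rate `epsilon`.
#'
#' @param delta5,delta3 terminal damage amplitudes in `[0, 1]`.
#' @param lambda per-position exponential decay rate (`>= 0`).
#' @param epsilon background substitution error rate in `[0, 1]`.
#' @return an object of class `damage_model`.
#' @export
damage_model <- function(delta5 = 0.3, delta3 = 0.3, lambda = 0.3,
                         epsilon = 0.001) {
  stopifnot(delta5 >= 0, delta5 <= 1, delta3 >= 0, delta3 <= 1,
            lambda >= 0, epsilon >= 0, epsilon <= 1)
  structure(list(delta5 = delta5, delta3 = delta3, lambda = lambda,
                 epsilon = epsilon),
            class = "damage_model")
}

#' Apply post-mortem damage to fragments
#'
#' Damage acts in molecule orientation (the stored fragment sequence).
#' Deamination is applied first, then background errors; the two are
#' independent, so a background error may hit an already-damaged site.
#'
#' @param fragments a data frame with a `seq` column (as from
#'   [fragmentize]) or a character vector of sequences.
#' @param dm a [damage_model].
#' @param seed integer seed.
#' @return same shape as the input with damaged sequences.
#' @export
apply_damage <- function(fragments, dm, seed = 1L) {
  stopifnot(inherits(dm, "damage_model"))
  seqs <- if (is.data.frame(fragments)) fragments$seq else fragments
  if (!length(seqs)) return(fragments)
  with_seed(seed, {
    lens <- nchar(seqs)
    ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    grp <- rep.int(seq_along(seqs), lens)
    off5 <- sequence(lens)
    off3 <- rep.int(lens, lens) - off5 + 1L

    isC <- ch == "C"
    if (dm$delta5 > 0 && any(isC)) {
      p <- dm$delta5 * exp(-dm$lambda * (off5[isC] - 1))
      hit <- stats::runif(sum(isC)) < p
      ch[which(isC)[hit]] <- "T"
    }
    isG <- ch == "G"
    if (dm$delta3 > 0 && any(isG)) {
      p <- dm$delta3 * exp(-dm$lambda * (off3[isG] - 1))
      hit <- stats::runif(sum(isG)) < p
      ch[which(isG)[hit]] <- "A"
    }
    if (dm$epsilon > 0) {
      elig <- which(ch %in% BASES)
      hit <- elig[stats::runif(length(elig)) < dm$epsilon]
      if (length(hit)) {
        cur <- match(ch[hit], BASES)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        ch[hit] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
      }
    }
    out <- vapply(split(ch, grp), paste, "", collapse = "",
                  USE.NAMES = FALSE)
    if (is.data.frame(fragments)) {
      fragments$seq <- out
      fragments
    } else out
  })
}

#' PCR amplification model
#'
#' Duplicate-multiplicity distribution with support on the positive
#' integers. The default zero-truncated geometric emulates
#' over-amplification of a few template molecules in low-complexity
#' libraries; `family = "constant"` emits exactly `size` copies.
#'
#' @param family `"ztgeom"` or `"constant"`.
#' @param prob success probability of the zero-truncated geometric
#'   (mean multiplicity `1/prob`).
#' @param size fixed multiplicity for `family = "constant"`.
#' @param per_dup_error optional per-duplicate substitution error rate
#'   (polymerase errors).
#' @return an object of class `amplification_model`.
#' @export
amplification_model <- function(family = c("ztgeom", "constant"),
                                prob = 0.25, size = 1L,
                                per_dup_error = 0) {
  family <- match.arg(family)
  stopifnot(prob > 0, prob <= 1, size >= 1,
            per_dup_error >= 0, per_dup_error <= 1)
  structure(list(family = family, prob = prob, size = as.integer(size),
                 per_dup_error = per_dup_error),
            class = "amplification_model")
}

#' Amplify fragments into a read multiset
#'
#' Each template fragment is emitted `m >= 1` times; duplicates share the
#' template's true coordinates. Optional per-duplicate errors are applied
#' independently to each copy.
#'
#' @param fragments data frame from [fragmentize] (damaged or not).
#' @param am an [amplification_model].
#' @param seed integer seed.
#' @return a read data frame with columns `id`, `template`, `start`,
#'   `len`, `strand`, `seq`, `size` (always 1 for raw reads).
#' @export
amplify_and_sequence <- function(fragments, am, seed = 1L) {
  stopifnot(inherits(am, "amplification_model"))
  n <- nrow(fragments)
  if (n == 0)
    return(data.frame(id = character(), template = character(),
                      start = integer(), len = integer(),
                      strand = character(), seq = character(),
                      size = integer(), stringsAsFactors = FALSE))
  with_seed(seed, {
    m <- switch(am$family,
                ztgeom = stats::rgeom(n, am$prob) + 1L,
                constant = rep(am$size, n))
    idx <- rep.int(seq_len(n), m)
    dup <- sequence(m)
    reads <- data.frame(
      id = paste0(fragments$template[idx], ".", dup),
      template = fragments$template[idx],
      start = fragments$start[idx], len = fragments$len[idx],
      strand = fragments$strand[idx], seq = fragments$seq[idx],
      size = 1L, stringsAsFactors = FALSE)
    if (am$per_dup_error > 0)
      reads$seq <- inject_errors(reads$seq, am$per_dup_error,
                                 seed = sample.int(.Machine$integer.max, 1))
    reads
  })
}

#' Inject random substitution errors
#'
#' Each `A/C/G/T` site is substituted to a uniformly chosen different base
#' with probability `rate`. `N` and gap characters are never touched and
#' no site is ever converted to `N`.
#'
#' @param x character vector of sequences (or a single string).
#' @param rate substitution probability per site, in `[0, 1]`.
#' @param seed integer seed.
#' @return perturbed copy of `x`.
#' @export
inject_errors <- function(x, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || !length(x)) return(x)
  with_seed(seed, {
    lens <- nchar(x)
    ch <- unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)
    grp <- rep.int(seq_along(x), lens)
    elig <- which(ch %in% BASES)
    hit <- elig[stats::runif(length(elig)) < rate]
    if (length(hit)) {
      cur <- match(ch[hit], BASES)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      ch[hit] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    vapply(split(ch, grp), paste, "", collapse = "", USE.NAMES = FALSE)
  })
}

#' Simulate an ancient-DNA read set for one specimen
#'
#' Convenience chain: [fragmentize] then [apply_damage] then
#' [amplify_and_sequence], with sub-seeds derived from one master seed.
#'
#' @param genome DNA string (the specimen's true mitogenome).
#' @param n_templates number of template molecules.
#' @param fm,dm,am fragment, damage, and amplification models (defaults
#'   emulate a damaged, duplicate-inflated capture library).
#' @param seed integer seed.
#' @return a read data frame (see [amplify_and_sequence]).
#' @export
simulate_read_set <- function(genome, n_templates,
                              fm = fragment_model(),
                              dm = damage_model(),
                              am = amplification_model(),
                              seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  frags <- fragmentize(genome, fm, n_templates, seed = seeds[1])
  frags <- apply_damage(frags, dm, seed = seeds[2])
  amplify_and_sequence(frags, am, seed = seeds[3])
}
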