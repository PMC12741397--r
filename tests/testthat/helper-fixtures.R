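# Shared fixtures: tiny trees, toy genomes and an exhaustive-enumeration
# likelihood oracle, all built in code.

# Random rooted binary tree with ntip tips and exponential branch lengths.
random_tree <- function(ntip, mean_bl = 0.1) {
  tr <- ape::rtree(ntip, rooted = TRUE, br = NULL)
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_bl)
  tr
}

random_model <- function(pinv = NULL, alpha = NULL) {
  f <- stats::runif(4, 0.1, 1)
  subst_model(stats::runif(6, 0.3, 3), f / sum(f),
              pinv = pinv %||% stats::runif(1, 0, 0.4),
              alpha = alpha %||% stats::runif(1, 0.3, 2), ncat = 4L)
}

random_alignment <- function(taxa, nsites, n_frac = 0.05) {
  m <- matrix(sample(c("A", "C", "G", "T"), length(taxa) * nsites,
                     replace = TRUE), length(taxa), nsites,
              dimnames = list(taxa, NULL))
  if (n_frac > 0) {
    nn <- round(n_frac * length(m))
    m[sample(length(m), nn)] <- "N"
  }
  m
}

# Exhaustive-enumeration log-likelihood: sums over all internal-state
# assignments at every site, independent of the pruning implementation.
enumeration_loglik <- function(aln, tree, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  codes <- apply(aln[tr$tip.label, , drop = FALSE], c(1, 2), function(ch) {
    i <- match(ch, c("A", "C", "G", "T"))
    if (is.na(i)) 5L else i
  })
  internals <- (ntip + 1L):(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  total <- 0
  for (s in seq_len(ncol(codes))) {
    site_var <- 0
    for (c in seq_len(model$ncat)) {
      P <- lapply(seq_len(nrow(tr$edge)), function(e)
        transition_matrix(model, tr$edge.length[e], model$cat_rates[c]))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        asgn <- grid[g, ]
        state_of <- function(n) if (n <= ntip) codes[n, s] else
          asgn[n - ntip]
        p <- unname(model$freq[asgn[1]])  # root = ntip + 1 is first internal
        for (e in seq_len(nrow(tr$edge))) {
          pa <- state_of(tr$edge[e, 1])
          ch <- state_of(tr$edge[e, 2])
          p <- p * (if (ch == 5L) 1 else P[[e]][pa, ch])
        }
        lik <- lik + p
      }
      site_var <- site_var + model$cat_weights[c] * lik
    }
    inv <- 0
    for (s4 in 1:4)
      if (all(codes[, s] == s4 | codes[, s] == 5L))
        inv <- inv + model$freq[s4]
    total <- total + log(model$pinv * inv + (1 - model$pinv) * site_var)
  }
  unname(total)
}

# Toy annotated genome shared by supermatrix tests: two CDS overlapping by
# 7 columns, an L-strand CDS, one RNA, a D-loop.
toy_gene_table <- function() {
  data.frame(
    name = c("ATP8", "ATP6", "ND6", "rrnS", "D-loop"),
    start = c(0L, 23L, 60L, 90L, 120L),
    end = c(30L, 53L, 90L, 120L, 150L),
    strand = c("H", "H", "L", "H", "H"),
    class = c("CDS", "CDS", "CDS", "rRNA", "D-loop"),
    stringsAsFactors = FALSE)
}

random_genome <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                          replace = TRUE), collapse = "")
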