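# Partitioned phylogenetic likelihood by Felsenstein pruning. The compiled
# kernel works on site patterns; N and gaps are fully ambiguous states
# (partial likelihood 1 for every nucleotide).

# Integer-code matrix (taxa x sites) from a supermatrix, a character
# matrix, or a named character vector of aligned sequences.
alignment_codes <- function(x) {
  if (inherits(x, "supermatrix")) x <- x$matrix
  if (is.character(x) && is.null(dim(x))) x <- seqs_to_matrix(x)
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  codes <- matrix(match(toupper(x), BASES), nrow(x), ncol(x))
  codes[is.na(codes)] <- 5L
  rownames(codes) <- rownames(x)
  codes
}

# Site-pattern compression: unique columns with multiplicities.
compress_patterns <- function(codes) {
  key <- apply(codes, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  list(tip = codes[, first, drop = FALSE],
       wts = as.numeric(table(key)[key[first]]))
}

# Per-pattern compatibility with each constant state s: every taxon shows
# s or an ambiguity. 4 x npat 0/1 matrix, fixed for a given alignment.
invariant_compat <- function(tip) {
  t(vapply(1:4, function(s)
    as.numeric(colSums(tip == s | tip == 5L) == nrow(tip)),
    numeric(ncol(tip))))
}

# Stationary mass of constant states compatible with each pattern (for
# the invariant-sites class).
invariant_weights <- function(tip, pi, compat = NULL) {
  if (is.null(compat)) compat <- invariant_compat(tip)
  as.vector(pi %*% compat)
}

prep_partition <- function(codes, model) {
  cp <- compress_patterns(codes)
  compat <- invariant_compat(cp$tip)
  list(tip = cp$tip, wts = cp$wts,
       U = model$eig$U, V = model$eig$V, lambda = model$eig$lambda,
       pi = unname(model$freq),
       catrate = model$cat_rates, catw = model$cat_weights,
       pinv = model$pinv, compat = compat,
       invw = invariant_weights(cp$tip, unname(model$freq), compat))
}

# Normalise the (models, partitions) pair: single model for the whole
# alignment, or a named list of models parallel to a named list of site
# index vectors.
resolve_partitions <- function(nsites, models, partitions) {
  if (inherits(models, "subst_model")) {
    if (is.null(partitions)) partitions <- list(all = seq_len(nsites))
    models <- stats::setNames(rep(list(models), length(partitions)),
                              names(partitions))
  }
  stopifnot(is.list(models), length(models) == length(partitions))
  if (is.null(names(models))) names(models) <- names(partitions)
  list(models = models[names(partitions)], partitions = partitions)
}

check_taxa <- function(aln_taxa, tip_labels) {
  miss <- setdiff(tip_labels, aln_taxa)
  extra <- setdiff(aln_taxa, tip_labels)
  if (length(miss) || length(extra))
    stop("taxon mismatch between alignment and tree; missing from alignment: ",
         paste(miss, collapse = ", "), "; absent from tree: ",
         paste(extra, collapse = ", "))
}

# Postorder edge matrix and branch lengths from an ape phylo.
postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, blens = tr$edge.length, tree = tr)
}

#' Partitioned pruning log-likelihood
#'
#' Total log-likelihood of an alignment on a rooted tree with branch
#' lengths in substitutions/site, by Felsenstein pruning with
#' discrete-gamma mixing and an invariant-sites class per partition.
#' `N` and `-` are treated as fully ambiguous.
#'
#' @param x alignment: a `supermatrix`, a character matrix with taxon
#'   rownames, or a named character vector of equal-length sequences.
#' @param tree rooted `phylo` with `edge.length` in substitutions/site.
#' @param models a single [subst_model] or a named list of models, one per
#'   partition.
#' @param partitions named list of site index vectors (jointly exhaustive);
#'   `NULL` treats the alignment as one partition. A `supermatrix` supplies
#'   its own partitions when `partitions` is `NULL`.
#' @return the total log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(x, tree, models, partitions = NULL) {
  if (inherits(x, "supermatrix") && is.null(partitions))
    partitions <- x$partitions
  codes <- alignment_codes(x)
  check_taxa(rownames(codes), tree$tip.label)
  codes <- codes[tree$tip.label, , drop = FALSE]
  rp <- resolve_partitions(ncol(codes), models, partitions)
  po <- postorder_edges(tree)
  total <- 0
  for (p in seq_along(rp$partitions)) {
    part <- prep_partition(codes[, rp$partitions[[p]], drop = FALSE],
                           rp$models[[p]])
    ll <- peel_part_cpp(po$edge, length(tree$tip.label), part, po$blens)
    total <- total + sum(part$wts * ll)
  }
  total
}

# Fast path for repeated evaluation (MCMC / branch-length optimisation):
# pre-encode partitions once, then evaluate for new branch lengths.
prep_likelihood <- function(x, tree, models, partitions = NULL) {
  if (inherits(x, "supermatrix") && is.null(partitions))
    partitions <- x$partitions
  codes <- alignment_codes(x)
  check_taxa(rownames(codes), tree$tip.label)
  codes <- codes[tree$tip.label, , drop = FALSE]
  rp <- resolve_partitions(ncol(codes), models, partitions)
  po <- postorder_edges(tree)
  parts <- lapply(seq_along(rp$partitions), function(p)
    prep_partition(codes[, rp$partitions[[p]], drop = FALSE],
                   rp$models[[p]]))
  list(edge = po$edge, ntip = length(tree$tip.label), parts = parts,
       tree = po$tree)
}

eval_likelihood <- function(prep, blens) {
  peel_total_cpp(prep$edge, prep$ntip, prep$parts, blens)
}

# Swap new substitution-model parameters into a prepared partition.
update_part_model <- function(part, model) {
  part$U <- model$eig$U; part$V <- model$eig$V
  part$lambda <- model$eig$lambda
  part$pi <- unname(model$freq)
  part$catrate <- model$cat_rates; part$catw <- model$cat_weights
  part$pinv <- model$pinv
  part$invw <- invariant_weights(part$tip, part$pi, part$compat)
  part
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate-wise univariate optimisation of each branch length, swept
#' until the log-likelihood improvement falls below `tol`. The
#' log-likelihood is non-decreasing across sweeps.
#'
#' @inheritParams pruning_loglik
#' @param tol convergence tolerance on the total log-likelihood.
#' @param max_sweeps maximum number of passes over all branches.
#' @param min_bl,max_bl box constraints on branch lengths
#'   (substitutions/site); the lower bound avoids degenerate matrices.
#' @return a list with `tree` (branch lengths replaced by their MLEs,
#'   postorder), `loglik`, and `converged`.
#' @export
optimize_branch_lengths <- function(x, tree, models, partitions = NULL,
                                    tol = 1e-4, max_sweeps = 20L,
                                    min_bl = 1e-9, max_bl = 10) {
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.05, nrow(tree$edge))
  prep <- prep_likelihood(x, tree, models, partitions)
  blens <- pmax(prep$tree$edge.length, min_bl)
  ll <- eval_likelihood(prep, blens)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    ll0 <- ll
    for (e in seq_along(blens)) {
      f <- function(b) {
        blens[e] <- b
        eval_likelihood(prep, blens)
      }
      op <- stats::optimize(f, c(min_bl, max_bl), maximum = TRUE,
                            tol = 1e-8)
      if (op$objective >= ll) {
        blens[e] <- op$maximum
        ll <- op$objective
      }
      # snap to the lower bound when it is at least as good
      if (f(min_bl) >= ll - 1e-12) {
        blens[e] <- min_bl
        ll <- f(min_bl)
      }
    }
    if (ll - ll0 < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("branch-length optimisation did not converge after ",
            max_sweeps, " sweeps (last improvement ",
            signif(ll - ll0, 3), ")")
  out <- prep$tree
  out$edge.length <- blens
  list(tree = out, loglik = ll, converged = converged)
}
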