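# Marginal (empirical Bayes) ancestral sequence reconstruction: per-site
# posterior state distributions at internal nodes, integrating over all
# other nodes, with model parameters fixed at their estimates.

# Down (subtree) and up (rest-of-tree) conditional likelihoods for one
# partition and one rate category, as 4 x nsites matrices per node.
updown_partials <- function(codes, tree, P_by_edge) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nsites <- ncol(codes)
  edge <- tree$edge

  L <- vector("list", nnode)
  sL <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    M <- matrix(0, 4, nsites)
    amb <- codes[i, ] == 5L
    M[, amb] <- 1
    ok <- which(!amb)
    M[cbind(codes[i, ok], ok)] <- 1
    L[[i]] <- M
    sL[[i]] <- numeric(nsites)
  }
  # edge is assumed to be in postorder (children before parents)
  for (e in seq_len(nrow(edge))) {
    pa <- edge[e, 1]; ch <- edge[e, 2]
    if (is.null(L[[pa]])) {
      L[[pa]] <- matrix(1, 4, nsites)
      sL[[pa]] <- numeric(nsites)
    }
    contrib <- P_by_edge[[e]] %*% L[[ch]]
    L[[pa]] <- L[[pa]] * contrib
    sL[[pa]] <- sL[[pa]] + sL[[ch]]
    mx <- pmax(L[[pa]][1, ], L[[pa]][2, ], L[[pa]][3, ], L[[pa]][4, ])
    small <- mx < 1e-120 & mx > 0
    if (any(small)) {
      L[[pa]][, small] <- sweep(L[[pa]][, small, drop = FALSE], 2L,
                                mx[small], "/")
      sL[[pa]][small] <- sL[[pa]][small] + log(mx[small])
    }
  }

  root <- ntip + 1L
  O <- vector("list", nnode)
  sO <- vector("list", nnode)
  O[[root]] <- matrix(1, 4, nsites)
  sO[[root]] <- numeric(nsites)
  for (e in rev(seq_len(nrow(edge)))) {       # preorder on reversed postorder
    pa <- edge[e, 1]; ch <- edge[e, 2]
    sibs <- which(edge[, 1] == pa & edge[, 2] != ch)
    S <- matrix(1, 4, nsites)
    sS <- numeric(nsites)
    for (se in sibs) {
      S <- S * (P_by_edge[[se]] %*% L[[edge[se, 2]]])
      sS <- sS + sL[[edge[se, 2]]]
    }
    O[[ch]] <- crossprod(P_by_edge[[e]], O[[pa]] * S)
    sO[[ch]] <- sO[[pa]] + sS
    mx <- pmax(O[[ch]][1, ], O[[ch]][2, ], O[[ch]][3, ], O[[ch]][4, ])
    small <- mx < 1e-120 & mx > 0
    if (any(small)) {
      O[[ch]][, small] <- sweep(O[[ch]][, small, drop = FALSE], 2L,
                                mx[small], "/")
      sO[[ch]][small] <- sO[[ch]][small] + log(mx[small])
    }
  }
  list(L = L, sL = sL, O = O, sO = sO)
}

#' Marginal ancestral state posteriors and MAP sequence
#'
#' Per-site marginal posterior distributions over (A, C, G, T) at internal
#' nodes, proportional to the stationary-frequency-weighted product of the
#' conditional likelihoods of the data below and above the node, mixed
#' over gamma categories and the invariant class. The MAP state is
#' reported per site; exact posterior ties emit `N`.
#'
#' @inheritParams pruning_loglik
#' @param node internal node number (ape numbering, `ntip + 1` is the
#'   root), or `NULL` for all internal nodes.
#' @return for a single node, a list with `prob` (nsites x 4 posterior
#'   matrix), `map` (MAP sequence string), and `node`; for `node = NULL`,
#'   a named list of such objects (`"n<k>"`).
#' @export
marginal_ancestral <- function(x, tree, models, partitions = NULL,
                               node = NULL) {
  if (inherits(x, "supermatrix") && is.null(partitions))
    partitions <- x$partitions
  codes <- alignment_codes(x)
  check_taxa(rownames(codes), tree$tip.label)
  codes <- codes[tree$tip.label, , drop = FALSE]
  rp <- resolve_partitions(ncol(codes), models, partitions)
  po <- postorder_edges(tree)
  tr <- po$tree
  ntip <- length(tr$tip.label)
  nodes <- if (is.null(node)) (ntip + 1L):(ntip + tr$Nnode) else as.integer(node)
  if (any(nodes <= ntip)) stop("node must be internal")
  nsites <- ncol(codes)

  # accumulate per-node unnormalised posterior mass across partitions
  post <- lapply(nodes, function(n) matrix(0, nsites, 4,
                                           dimnames = list(NULL, BASES)))
  names(post) <- paste0("n", nodes)

  for (p in seq_along(rp$partitions)) {
    sites <- rp$partitions[[p]]
    m <- rp$models[[p]]
    sub <- codes[, sites, drop = FALSE]
    ncat <- m$ncat
    # per-category contributions in log space, combined per state
    acc <- lapply(seq_along(nodes), function(i)
      matrix(-Inf, length(sites), 4))
    for (c in seq_len(ncat)) {
      P_by_edge <- lapply(seq_len(nrow(tr$edge)), function(e)
        transition_matrix(m, tr$edge.length[e], m$cat_rates[c]))
      ud <- updown_partials(sub, tr, P_by_edge)
      for (i in seq_along(nodes)) {
        n <- nodes[i]
        v <- m$freq * ud$L[[n]] * ud$O[[n]]           # 4 x nsites
        lv <- t(log(v) + rep(ud$sL[[n]] + ud$sO[[n]], each = 4)) +
          log((1 - m$pinv) * m$cat_weights[c])
        acc[[i]] <- log_add(acc[[i]], lv)
      }
    }
    if (m$pinv > 0) {
      # invariant class: node state must equal the shared constant state
      for (s in 1:4) {
        compat <- colSums(sub == s | sub == 5L) == nrow(sub)
        if (any(compat)) {
          li <- log(m$pinv * m$freq[s])
          for (i in seq_along(nodes)) {
            acc[[i]][compat, s] <- log_add_scalar(acc[[i]][compat, s], li)
          }
        }
      }
    }
    for (i in seq_along(nodes)) {
      mx <- pmax(acc[[i]][, 1], acc[[i]][, 2], acc[[i]][, 3], acc[[i]][, 4])
      pr <- exp(acc[[i]] - mx)
      pr <- pr / rowSums(pr)
      post[[i]][sites, ] <- pr
    }
  }

  res <- lapply(seq_along(nodes), function(i) {
    pr <- post[[i]]
    map <- map_states(pr)
    list(prob = pr, map = map, node = nodes[i])
  })
  names(res) <- names(post)
  if (!is.null(node) && length(node) == 1L) res[[1]] else res
}

log_add <- function(a, b) {
  mx <- pmax(a, b)
  out <- mx + log(exp(a - mx) + exp(b - mx))
  out[a == -Inf & b == -Inf] <- -Inf
  out
}

log_add_scalar <- function(a, b) log_add(a, rep(b, length(a)))

# MAP state per row with exact ties reported as N.
map_states <- function(prob) {
  mx <- apply(prob, 1L, max)
  nmax <- rowSums(prob == mx)
  idx <- max.col(prob, ties.method = "first")
  out <- BASES[idx]
  out[nmax > 1L] <- "N"
  paste(out, collapse = "")
}

#' Mask a reconstructed ancestral sequence by descendant missingness
#'
#' Sites that are missing (`N` or `-`) in any designated descendant are
#' set to `N` in the reconstruction; all other sites are untouched. This
#' prevents the reconstruction from asserting states where the focal
#' individuals carried no data.
#'
#' @param ancestral a sequence string (the reconstruction).
#' @param descendants character vector of sequences in the same coordinate
#'   frame (e.g. the supermatrix rows of the focal individuals).
#' @return the masked sequence string.
#' @export
mask_missing <- function(ancestral, descendants) {
  n <- nchar(ancestral)
  if (any(nchar(descendants) != n))
    stop("length mismatch between ancestral sequence and descendants")
  a <- strsplit(ancestral, "", fixed = TRUE)[[1]]
  miss <- rep(FALSE, n)
  for (d in descendants) {
    ch <- strsplit(toupper(d), "", fixed = TRUE)[[1]]
    miss <- miss | !(ch %in% BASES)
  }
  a[miss] <- "N"
  paste(a, collapse = "")
}
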