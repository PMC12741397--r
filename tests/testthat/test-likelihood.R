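# Pruning likelihood: oracles, conventions, and branch-length estimation.

test_that("single-taxon likelihood is the sum of log stationary frequencies", {
  m <- random_model()
  tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                       edge.length = 0.3, Nnode = 1L,
                       tip.label = "A"), class = "phylo")
  # one tip joined to the root by a single branch: lnL is still
  # sum(log pi) because the model is stationary
  seqs <- c(A = "ACGT")
  ll <- pruning_loglik(seqs, tr, subst_model(m$rates, m$freq))
  expect_equal(ll, sum(log(m$freq)), tolerance = 1e-10)
})

test_that("a site that is N in every taxon contributes zero log-likelihood", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.1,C:0.3);")
  m <- jc_model(pinv = 0.2, alpha = 0.5)
  l1 <- pruning_loglik(c(A = "ACGT", B = "ACGA", C = "TCGT"), tr, m)
  l2 <- pruning_loglik(c(A = "ACGTN", B = "ACGAN", C = "TCGTN"), tr, m)
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration on small random instances", {
  set.seed(42)
  for (i in 1:10) {
    ntip <- sample(3:5, 1)
    tr <- random_tree(ntip)
    m <- random_model()
    aln <- random_alignment(tr$tip.label, 12)
    expect_equal(pruning_loglik(aln, tr, m),
                 enumeration_loglik(aln, tr, m), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to root placement for reversible models", {
  set.seed(5)
  tr <- ape::unroot(random_tree(5))
  m <- random_model()
  aln <- random_alignment(tr$tip.label, 50)
  lls <- sapply(1:3, function(i) {
    rt <- ape::root(tr, outgroup = tr$tip.label[i], resolve.root = TRUE)
    pruning_loglik(aln, rt, m)
  })
  expect_lt(max(lls) - min(lls), 1e-8)
})

test_that("pruning agrees with an independent likelihood implementation", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  tr <- random_tree(6)
  aln <- random_alignment(tr$tip.label, 200, n_frac = 0)
  # JC
  ll <- pruning_loglik(aln, tr, jc_model())
  pd <- phangorn::phyDat(aln)
  fit <- phangorn::pml(ape::unroot(tr), pd)
  expect_equal(ll, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
  # GTR with unequal frequencies, no rate variation
  f <- c(0.35, 0.25, 0.15, 0.25)
  rates <- c(1.2, 3.1, 0.7, 1.1, 4.0, 1)
  ll2 <- pruning_loglik(aln, tr, subst_model(rates, f))
  fit2 <- phangorn::pml(ape::unroot(tr), pd, bf = f, Q = rates)
  expect_equal(ll2, as.numeric(stats::logLik(fit2)), tolerance = 1e-6)
})

test_that("taxon mismatches are reported with the offending names", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,C:0.1);")
  expect_error(pruning_loglik(c(A = "A", B = "C", D = "G"), tr, jc_model()),
               "taxon mismatch.*C.*D")
})

test_that("two identical sequences give a zero MLE branch length", {
  seqs <- c(A = strrep("ACGT", 50), B = strrep("ACGT", 50))
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  fit <- optimize_branch_lengths(seqs, tr, jc_model())
  expect_lt(sum(fit$tree$edge.length), 1e-6)
})

test_that("two-taxon JC MLE path length matches the closed-form distance", {
  set.seed(8)
  sim <- evolve_sequences(ape::read.tree(text = "(A:0.12,B:0.08);"),
                          jc_model(), length = 20000, seed = 31)
  seqs <- sim$seqs[c("A", "B")]
  p <- mean(strsplit(seqs[1], "")[[1]] != strsplit(seqs[2], "")[[1]])
  d_hat <- -0.75 * log(1 - 4 * p / 3)
  fit <- optimize_branch_lengths(seqs, ape::read.tree(text = "(A:0.1,B:0.1);"),
                                 jc_model())
  expect_equal(sum(fit$tree$edge.length), d_hat, tolerance = 1e-4)
})

test_that("branch-length optimisation never decreases the log-likelihood", {
  set.seed(13)
  tr <- random_tree(5)
  m <- jc_model(alpha = 0.8)
  sim <- evolve_sequences(tr, m, length = 500, seed = 99)
  aln <- sim$seqs[tr$tip.label]
  start <- tr
  start$edge.length <- rep(0.2, nrow(tr$edge))
  ll0 <- pruning_loglik(aln, start, m)
  fit <- suppressWarnings(optimize_branch_lengths(aln, start, m))
  expect_gte(fit$loglik, ll0)
})
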