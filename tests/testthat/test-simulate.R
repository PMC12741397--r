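# Synthetic-data generators: sequence evolution, fragmentation, damage,
# amplification, and error injection.

test_that("a zero-duration branch copies the parent sequence", {
  tr <- ape::read.tree(text = "(A:0,B:0.2);")
  sim <- evolve_sequences(tr, jc_model(), length = 500, seed = 1)
  expect_identical(sim$seqs[["A"]], sim$seqs[["n3"]])
})

test_that("two-taxon JC divergence matches the closed form", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  sim <- evolve_sequences(tr, jc_model(), length = 10000, seed = 7)
  p <- mean(strsplit(sim$seqs[["A"]], "")[[1]] !=
              strsplit(sim$seqs[["B"]], "")[[1]])
  expected <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / 10000))
})

test_that("JC pairwise identity approaches 1/4 at large divergence", {
  tr <- ape::read.tree(text = "(A:8,B:8);")
  sim <- evolve_sequences(tr, jc_model(), length = 10000, seed = 3)
  ident <- mean(strsplit(sim$seqs[["A"]], "")[[1]] ==
                  strsplit(sim$seqs[["B"]], "")[[1]])
  expect_lt(abs(ident - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("evolution respects partition-specific models", {
  tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
  models <- list(slow = jc_model(), fast = jc_model())
  sim <- evolve_sequences(tr, models,
                          partition = c(slow = 500, fast = 500), seed = 5)
  expect_equal(nchar(sim$seqs[["A"]]), 1000L)
  expect_equal(sim$site_partition[1], "slow")
  expect_equal(sim$site_partition[1000], "fast")
})

test_that("dated trees validate age monotonicity and expose durations", {
  topo <- ape::read.tree(text = "((A,B)n5,C)n4;")
  # node 4 is the root, node 5 the (A,B) ancestor
  expect_error(dated_tree(topo, c(0, 0, 0, 0.4, 0.5)), "strictly greater")
  dt <- dated_tree(topo, c(0, 0.1, 0, 1.2, 0.5), rates = 0.02)
  ph <- dated_tree_phylo(dt)
  expect_true(all(ph$edge.length > 0))
  expect_equal(sum(ph$edge.length),
               0.02 * sum(c(1.2 - 0.5, 0.5, 0.5 - 0.1, 1.2)))
})

test_that("fragmentation respects hard bounds and the model mean", {
  fm <- fragment_model()
  g <- random_genome(5000)
  frags <- fragmentize(g, fm, 10000, seed = 2)
  expect_true(all(frags$len >= fm$min & frags$len <= fm$max))
  expect_true(all(nchar(frags$seq) == frags$len))
  se <- sd(frags$len) / sqrt(nrow(frags))
  expect_lt(abs(mean(frags$len) - fragment_length_mean(fm)), 4 * se)
  # the calibrated default emulates short ancient mitochondrial reads
  expect_equal(fragment_length_mean(fm), 38.9, tolerance = 0.01)
  expect_identical(nrow(fragmentize(g, fm, 0, seed = 1)), 0L)
  expect_error(fragmentize(strrep("A", 10), fm, 5), "exceeds genome length")
})

test_that("fragments agree with their recorded coordinates (circular)", {
  g <- random_genome(300)
  frags <- fragmentize(g, fragment_model(min = 30, max = 76), 500, seed = 4)
  ext <- paste0(g, g)
  fwd <- substring(ext, frags$start + 1, frags$start + frags$len)
  expect_identical(frags$seq[frags$strand == "+"], fwd[frags$strand == "+"])
  expect_identical(frags$seq[frags$strand == "-"],
                   rev_comp(fwd[frags$strand == "-"]))
})

test_that("damage leaves sequences untouched when all rates are zero", {
  dm <- damage_model(0, 0, 0.3, 0)
  seqs <- replicate(20, random_genome(50))
  expect_identical(apply_damage(seqs, dm, seed = 1), seqs)
})

test_that("saturating 5' damage deaminates exactly the terminal cytosine", {
  dm <- damage_model(delta5 = 1, delta3 = 0, lambda = 1e9, epsilon = 0)
  out <- apply_damage(c("CCCC", "ACCC"), dm, seed = 1)
  expect_identical(out, c("TCCC", "ACCC"))
})

test_that("observed terminal damage frequency matches the model curve", {
  dm <- damage_model(delta5 = 0.3, delta3 = 0, lambda = 0.3, epsilon = 0)
  seqs <- replicate(20000, paste(sample(c("A", "C", "G", "T"), 30,
                                        replace = TRUE), collapse = ""))
  out <- apply_damage(seqs, dm, seed = 6)
  first_in <- substr(seqs, 1, 1)
  first_out <- substr(out, 1, 1)
  cidx <- first_in == "C"
  freq <- mean(first_out[cidx] == "T")
  n <- sum(cidx)
  expect_lt(abs(freq - 0.3), 4 * sqrt(0.3 * 0.7 / n))
  # decay: offset 5 frequency should be near 0.3 * exp(-0.3*4)
  p5 <- 0.3 * exp(-0.3 * 4)
  in5 <- substr(seqs, 5, 5); out5 <- substr(out, 5, 5)
  c5 <- in5 == "C"
  expect_lt(abs(mean(out5[c5] == "T") - p5), 4 * sqrt(p5 * (1 - p5) / sum(c5)))
})

test_that("amplification preserves template bookkeeping", {
  g <- random_genome(1000)
  frags <- fragmentize(g, fragment_model(), 500, seed = 1)
  am <- amplification_model(prob = 0.25)
  reads <- amplify_and_sequence(frags, am, seed = 2)
  # duplicates of a template report identical true coordinates
  sp <- split(reads, reads$template)
  expect_true(all(vapply(sp, function(d)
    length(unique(d$start)) == 1 && length(unique(d$strand)) == 1, TRUE)))
  # expected read count = n_templates * E[multiplicity]
  expect_lt(abs(nrow(reads) - 500 / 0.25), 4 * sqrt(500 * 0.75 / 0.25^2))
  # degenerate multiplicity: reads = fragments
  one <- amplify_and_sequence(frags, amplification_model("constant", size = 1),
                              seed = 3)
  expect_identical(one$seq, frags$seq)
})

test_that("error injection follows the binomial law and respects N sites", {
  s <- random_genome(13000)
  expect_identical(inject_errors(s, 0, seed = 1), s)
  all_changed <- inject_errors(s, 1, seed = 1)
  expect_true(all(strsplit(all_changed, "")[[1]] != strsplit(s, "")[[1]]))
  counts <- sapply(1:5, function(sd) {
    out <- inject_errors(s, 0.01, seed = sd)
    sum(strsplit(out, "")[[1]] != strsplit(s, "")[[1]])
  })
  expect_true(all(abs(counts - 130) < 3 * sqrt(13000 * 0.01 * 0.99)))
  # N and gaps untouched, never introduced
  sn <- "ANG-TNCC"
  out <- inject_errors(sn, 1, seed = 2)
  ch <- strsplit(out, "")[[1]]
  expect_identical(ch[c(2, 4, 6)], c("N", "-", "N"))
  expect_false(any(ch[c(1, 3, 5, 7, 8)] == "N"))
})

test_that("identical seeds give byte-identical simulator output", {
  g <- random_genome(2000)
  r1 <- simulate_read_set(g, 200, seed = 99)
  r2 <- simulate_read_set(g, 200, seed = 99)
  expect_identical(r1, r2)
  r3 <- simulate_read_set(g, 200, seed = 100)
  expect_false(identical(r1$seq, r3$seq))
})

test_that("undamaged single-copy reads reconstruct the genome where covered", {
  g <- random_genome(1500)
  frags <- fragmentize(g, fragment_model(), 1500, seed = 11)
  reads <- amplify_and_sequence(frags, amplification_model("constant",
                                                           size = 1),
                                seed = 1)
  pl <- map_to_reference(reads, g)
  pile <- build_pileup(pl, reads, g)
  cons <- call_consensus(pile)
  covered <- pileup_depth(pile) > 0
  expect_true(all(covered))
  expect_identical(cons, g)
})
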