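# Read processing: filtering, dereplication, clustering, mapping,
# down-sampling.

test_that("length filtering keeps exactly the reads at or above the cutoff", {
  reads <- as_reads(c(r1 = strrep("A", 29), r2 = strrep("C", 30),
                      r3 = strrep("G", 45)))
  out <- filter_reads(reads, 30)
  expect_identical(out$id, c("r2", "r3"))
  expect_identical(filter_reads(out, 30), out)          # idempotent
  empty <- filter_reads(reads[0, ], 30)
  expect_identical(nrow(empty), 0L)
})

test_that("dereplication groups exact duplicates and conserves abundance", {
  reads <- as_reads(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGA"))
  out <- dereplicate(reads)
  expect_identical(nrow(out), 2L)
  expect_identical(out$size, c(3L, 1L))
  expect_identical(out$id[1], "a")      # lexicographically smallest member
  expect_equal(sum(out$size), 4)
  distinct <- as_reads(c(x = "AAAA", y = "CCCC"))
  expect_identical(nrow(dereplicate(distinct)), 2L)
})

test_that("pairwise identity uses matching columns over the longer length", {
  a <- strrep("ACGTG", 10)                  # 50-mer
  b <- paste0(substr(a, 1, 45), "GAAAA")    # differs at 5 trailing sites
  expect_equal(pair_identity(a, b), 0.90)
  expect_equal(pair_identity(a, a), 1)
  expect_equal(pair_identity("ANGT", "AAGT"), 0.75)  # N never matches
  expect_equal(pair_identity("ACGT", rev_comp("ACGT"), strand_both = TRUE), 1)
})

test_that("greedy clustering honours the identity threshold", {
  n <- 8
  reads <- as_reads(setNames(rep("ACGTACGTACGTACGTACGTACGTACGTACGT", n),
                             paste0("r", 1:n)))
  cl <- cluster_greedy(dereplicate(reads))
  expect_identical(nrow(cl$centroids), 1L)
  expect_equal(cl$centroids$size, n)

  a <- strrep("ACGTG", 10)
  b <- paste0(substr(a, 1, 45), "GAAAA")    # identity 0.90 < 0.93
  cl2 <- cluster_greedy(as_reads(c(x = a, y = b)), id_threshold = 0.93)
  expect_identical(nrow(cl2$centroids), 2L)

  # a read equal to a centroid's reverse complement joins on strand both
  cl3 <- cluster_greedy(as_reads(c(x = a, y = rev_comp(a))),
                        strand_both = TRUE)
  expect_identical(nrow(cl3$centroids), 1L)
  expect_identical(cl3$members$strand, c("+", "-"))
  cl4 <- cluster_greedy(as_reads(c(x = a, y = rev_comp(a))),
                        strand_both = FALSE)
  expect_identical(nrow(cl4$centroids), 2L)
})

test_that("clustering partitions the reads and is recheckable post hoc", {
  set.seed(31)
  g <- random_genome(400)
  reads <- simulate_read_set(g, 150, dm = damage_model(), seed = 12)
  d <- dereplicate(reads)
  cl <- suppressWarnings(cluster_greedy(d))
  expect_setequal(cl$members$id, d$id)
  expect_identical(anyDuplicated(cl$members$id), 0L)
  expect_equal(sum(cl$centroids$size), sum(d$size))
  # member-to-centroid identity respects the threshold on its strand
  for (i in seq_len(nrow(cl$members))) {
    mem <- cl$members[i, ]
    q <- d$seq[d$id == mem$id]
    cent <- cl$centroids$seq[cl$centroids$id == mem$centroid]
    if (mem$strand == "-") q <- rev_comp(q)
    expect_gte(pair_identity(q, cent), 0.93)
  }
})

test_that("clustering at threshold 1 without strands equals dereplication", {
  set.seed(5)
  reads <- as_reads(replicate(60, random_genome(35)))
  d <- dereplicate(reads)
  cl <- cluster_greedy(d, id_threshold = 1, strand_both = FALSE)
  expect_identical(sort(cl$centroids$seq), sort(d$seq))
})

test_that("duplicate-inflated libraries cluster back to template counts", {
  set.seed(77)
  g <- random_genome(3000)
  frags <- fragmentize(g, fragment_model(), 120, seed = 3)
  reads <- amplify_and_sequence(frags, amplification_model(prob = 0.2),
                                seed = 4)        # mean multiplicity 5
  cl <- cluster_greedy(dereplicate(reads))
  # no damage: clusters = distinct templates (distinct fragment strings)
  expect_identical(nrow(cl$centroids), length(unique(frags$seq)))
})

test_that("the minimal mapper places exact and near-exact reads correctly", {
  set.seed(19)
  ref <- random_genome(2000)
  read <- substr(ref, 501, 540)
  pl <- map_to_reference(as_reads(c(r = read)), ref)
  expect_true(pl$mapped)
  expect_identical(pl$pos, 500L)
  expect_identical(pl$mismatches, 0L)
  expect_identical(pl$strand, "+")

  mm <- read
  substr(mm, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                substr(read, 20, 20))[1]
  pl2 <- map_to_reference(as_reads(c(r = mm)), ref)
  expect_identical(pl2$pos, 500L)
  expect_identical(pl2$mismatches, 1L)

  rc <- rev_comp(read)
  pl3 <- map_to_reference(as_reads(c(r = rc)), ref)
  expect_identical(pl3$pos, 500L)
  expect_identical(pl3$strand, "-")

  rnd <- as_reads(c(r = random_genome(30)))
  pl4 <- map_to_reference(rnd, ref)
  expect_false(pl4$mapped)

  expect_error(map_to_reference(rnd, strrep("N", 100)), "degenerate")
})

test_that("placements recover true coordinates on simulated reads", {
  set.seed(23)
  g <- random_genome(4000)
  frags <- fragmentize(g, fragment_model(), 400, seed = 8)
  # mild substitution noise below the mismatch allowance
  frags$seq <- inject_errors(frags$seq, 0.02, seed = 9)
  pl <- map_to_reference(frags[, c("template", "seq")] |>
                           (\(d) data.frame(id = d$template, seq = d$seq,
                                            size = 1))(), g)
  ok <- pl$mapped
  expect_gt(mean(ok), 0.95)
  agree <- pl$pos[ok] == frags$start[ok] & pl$strand[ok] == frags$strand[ok]
  expect_gte(mean(agree), 0.99)
})

test_that("down-sampling is uniform, exact and seed-reproducible", {
  reads <- as_reads(replicate(500, random_genome(30)))
  expect_identical(downsample(reads, 1000, seed = 1), reads)
  s1 <- downsample(reads, 300, seed = 42)
  s2 <- downsample(reads, 300, seed = 42)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 300L)
  expect_identical(anyDuplicated(s1$id), 0L)
  expect_false(identical(s1, downsample(reads, 300, seed = 43)))
})
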