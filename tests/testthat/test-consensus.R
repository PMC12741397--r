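# Pileups, consensus calling, damage profiles, windowed depth.

test_that("end-trimming removes exactly k bases from each end", {
  s <- strrep("ACGTAC", 6)                       # 36-mer
  out <- trim_cluster_ends(s, 3)
  expect_identical(out, substr(s, 4, 33))
  expect_identical(nchar(out), 30L)
  expect_identical(trim_cluster_ends(s, 0), s)
  expect_warning(short <- trim_cluster_ends("ACGTAC", 3), "rejected")
  expect_true(is.na(short))
})

test_that("pileups accumulate hand-computed counts on both strands", {
  ref <- strrep("T", 10)
  reads <- as_reads(c(f = "ACG"))
  pl <- data.frame(id = "f", pos = 0L, strand = "+", mismatches = 3L,
                   alen = 3L, mapped = TRUE)
  pile <- build_pileup(pl, reads, ref)
  expect_equal(unname(pile$counts["A", 1]), 1L)
  expect_equal(unname(pile$counts["C", 2]), 1L)
  expect_equal(unname(pile$counts["G", 3]), 1L)
  expect_equal(sum(pile$counts), 3L)
  expect_equal(unname(pileup_depth(pile)[4]), 0)        # uncovered

  # a reverse-strand read stored as CGT contributes its complement
  # re-oriented: ACG at positions 0..2
  reads2 <- as_reads(c(r = "CGT"))
  pl2 <- data.frame(id = "r", pos = 0L, strand = "-", mismatches = 3L,
                    alen = 3L, mapped = TRUE)
  pile2 <- build_pileup(pl2, reads2, ref)
  expect_equal(unname(pile2$counts["A", 1]), 1L)
  expect_equal(unname(pile2$counts["C", 2]), 1L)
  expect_equal(unname(pile2$counts["G", 3]), 1L)

  bad <- data.frame(id = "f", pos = -1L, strand = "+", mismatches = 0L,
                    alen = 3L, mapped = TRUE)
  expect_error(build_pileup(bad, reads, ref), "out of bounds.*f")
})

test_that("consensus calls follow depth, plurality and tie rules", {
  mk <- function(counts) {
    m <- matrix(0L, 5, ncol(counts), dimnames = list(c("A", "C", "G", "T",
                                                       "N"), NULL))
    m[rownames(counts), ] <- counts
    structure(list(counts = m, length = ncol(counts)), class = "pileup")
  }
  p <- mk(matrix(c(5L, 0L), 2, 1, dimnames = list(c("A", "T"), NULL)))
  expect_identical(call_consensus(p), "A")
  tie <- mk(matrix(c(2L, 2L), 2, 1, dimnames = list(c("A", "T"), NULL)))
  expect_identical(call_consensus(tie), "N")
  zero <- mk(matrix(c(0L, 0L), 2, 1, dimnames = list(c("A", "T"), NULL)))
  expect_identical(call_consensus(zero), "N")
  deep <- mk(matrix(c(3L, 1L), 2, 1, dimnames = list(c("A", "T"), NULL)))
  expect_identical(call_consensus(deep, min_depth = 5), "N")
  expect_identical(call_consensus(deep, min_depth = 1), "A")
})

test_that("damage profiles recover simulated deamination within MC error", {
  set.seed(55)
  g <- random_genome(3000)
  frags <- fragmentize(g, fragment_model(), 8000, seed = 1)
  dm <- damage_model(delta5 = 0.3, delta3 = 0.3, lambda = 0.3, epsilon = 0)
  damaged <- apply_damage(frags, dm, seed = 2)
  reads <- data.frame(id = damaged$template, seq = damaged$seq, size = 1)
  pl <- data.frame(id = damaged$template, pos = damaged$start,
                   strand = damaged$strand, mismatches = 0L,
                   alen = damaged$len, mapped = TRUE)
  prof <- damage_profile(pl, reads, g, L = 25)
  p1 <- prof$freq_ct_5p[1]
  expect_lt(abs(p1 - 0.3), 4 * sqrt(0.3 * 0.7 / prof$n_c_5p[1]))
  # decay with offset
  expect_lt(prof$freq_ct_5p[10], prof$freq_ct_5p[1])
  expect_lt(abs(prof$freq_ct_5p[5] - 0.3 * exp(-0.3 * 4)),
            4 * sqrt(0.3 * 0.7 / prof$n_c_5p[5]))
  # symmetric amplitudes: the 3' G->A curve mirrors the 5' C->T curve
  expect_lt(abs(prof$freq_ga_3p[1] - prof$freq_ct_5p[1]),
            4 * sqrt(0.3 * 0.7 / min(prof$n_g_3p[1], prof$n_c_5p[1])))
  # background substitutions stay near zero
  expect_lt(max(prof$freq_ga_5p, na.rm = TRUE), 0.02)

  # undamaged reads: all frequencies at background
  clean <- data.frame(id = frags$template, seq = frags$seq, size = 1)
  prof0 <- damage_profile(pl, clean, g, L = 25)
  expect_lt(max(prof0$freq_ct_5p, na.rm = TRUE), 0.01)
})

test_that("windowed depth averages partial windows over their own length", {
  pl <- data.frame(id = "r", pos = 0L, strand = "+", mismatches = 0L,
                   alen = 30L, mapped = TRUE)
  wd <- windowed_depth(pl, reference_length = 1000L, window = 1000L)
  expect_equal(wd$windows$mean_depth, 0.03)
  expect_equal(wd$mean_depth, 0.03)

  none <- windowed_depth(pl[0, ], 5000L, 1000L)
  expect_true(all(none$windows$mean_depth == 0))

  wd2 <- windowed_depth(pl, reference_length = 16800L, window = 1000L)
  expect_identical(nrow(wd2$windows), 17L)
  expect_identical(wd2$windows$end[17] - wd2$windows$start[17], 800L)
  # sum over windows of mean x length equals total aligned bases
  tot <- with(wd2$windows, sum(mean_depth * (end - start)))
  expect_equal(tot, 30)
})
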