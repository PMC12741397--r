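# Supermatrix assembly: exclusions, strand handling, partitions.

test_that("overlapping CDS columns appear exactly once in dedup mode", {
  gt <- toy_gene_table()
  g <- random_genome(150)
  sm <- build_supermatrix(c(t1 = g), gt, strip_codons = FALSE)
  # ATP8/ATP6 overlap = genome columns 24..30 (1-based), 7 columns
  ov <- 24:30
  hits <- sm$column_info$genome_pos %in% (ov - 1)
  expect_identical(sum(hits), 7L)
  expect_true(all(sm$column_info$gene[hits] == "ATP8"))

  strict <- build_supermatrix(c(t1 = g), gt, overlap_mode = "strict",
                              strip_codons = FALSE)
  expect_identical(sum(strict$column_info$genome_pos %in% (ov - 1)), 0L)
  expect_identical(ncol(strict$matrix), ncol(sm$matrix) - 7L)
})

test_that("light-strand genes enter the matrix reverse-complemented", {
  gt <- toy_gene_table()
  g <- random_genome(150)
  sm <- build_supermatrix(c(t1 = g), gt, strip_codons = FALSE)
  nd6 <- sm$column_info$gene == "ND6"
  got <- paste(sm$matrix["t1", nd6], collapse = "")
  expect_identical(got, rev_comp(substr(g, 61, 90)))
})

test_that("start and stop codons are stripped and frames preserved", {
  gt <- toy_gene_table()
  g <- random_genome(150)
  sm <- build_supermatrix(c(t1 = g), gt)
  atp8 <- sm$column_info[sm$column_info$gene == "ATP8", ]
  # 30 bp minus start and stop codon; the shared ATP6 columns stay in ATP8
  expect_identical(nrow(atp8), 24L)        # 0-based positions 3..26
  expect_identical(atp8$codon_pos[1:6], c(1L, 2L, 3L, 1L, 2L, 3L))
  expect_identical(min(atp8$genome_pos), 3L)
})

test_that("matrix length equals the sum of blocks and of partitions", {
  gt <- toy_gene_table()
  g <- random_genome(150)
  sm <- build_supermatrix(c(t1 = g, t2 = random_genome(150)), gt)
  expect_identical(ncol(sm$matrix), as.integer(sum(sm$blocks)))
  expect_identical(ncol(sm$matrix), length(unlist(sm$partitions)))
  expect_identical(anyDuplicated(unlist(sm$partitions)), 0L)
  expect_identical(nrow(sm$matrix), 2L)
})

test_that("rebuilding from the same inputs is byte-identical", {
  gt <- synthetic_gene_table(8000)
  seqs <- c(a = random_genome(8000), b = random_genome(8000))
  s1 <- build_supermatrix(seqs, gt)
  s2 <- build_supermatrix(seqs, gt)
  expect_identical(s1, s2)
})

test_that("tip rows reproduce the simulator's genomes column-for-column", {
  gt <- synthetic_gene_table(8000)
  topo <- ape::read.tree(text = "(A:0.05,B:0.05);")
  sim <- evolve_sequences(topo, hky_model(4), length = 8000, seed = 3)
  sm <- build_supermatrix(sim$seqs[c("A", "B")], gt)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (t in c("A", "B")) {
    ch <- strsplit(sim$seqs[[t]], "")[[1]]
    expected <- ch[sm$column_info$genome_pos + 1L]
    # L-strand columns are complements
    l_genes <- gt$name[gt$strand == "L"]
    lcols <- sm$column_info$gene %in% l_genes
    expected[lcols] <- comp[expected[lcols]]
    expect_identical(unname(sm$matrix[t, ]), unname(expected))
  }
})

test_that("gene-table violations are reported by name", {
  gt <- toy_gene_table()
  gt$end[1] <- 29L            # ATP8 length 29, not divisible by 3
  expect_error(build_supermatrix(c(t1 = random_genome(150)), gt),
               "divisible by 3.*ATP8")
  short <- c(t1 = random_genome(100))    # shorter than the table span
  expect_message(sm <- build_supermatrix(short, toy_gene_table()),
                 "filled with N")
  expect_true(any(sm$matrix == "N"))
})

test_that("unambiguous-base counts ignore N and gaps", {
  expect_identical(count_unambiguous("ACGTN-"), 4L)
  expect_identical(count_unambiguous(strrep("N", 10)), 0L)
  row <- "ACGTNNACGT--"
  # count = row length - (#N + #gap)
  expect_identical(count_unambiguous(row), nchar(row) - 2L - 2L)
  gt <- toy_gene_table()
  sm <- build_supermatrix(c(t1 = random_genome(150)), gt)
  expect_identical(unname(count_unambiguous(sm)["t1"]),
                   ncol(sm$matrix))
})
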