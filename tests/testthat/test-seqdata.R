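test_that("FASTA reading parses, normalizes case and validates lengths", {
  p <- write_fasta_fixture(c("a", "b"), c("ACGT", "ACGA"))
  a <- read_locus_fasta(p, "toy")
  expect_s3_class(a, "locus_alignment")
  expect_equal(length(a$haplotypes), 2L)
  expect_equal(a$length, 4L)
  expect_equal(a$haplotypes[[1]]$label, "a")

  p2 <- write_fasta_fixture("x", "acgt")
  expect_error(read_locus_fasta(p2), "at least 2")
  p3 <- write_fasta_fixture(c("a", "b"), c("acgt", "acgt"))
  expect_equal(read_locus_fasta(p3)$haplotypes[[1]]$sequence, "ACGT")

  expect_error(locus_alignment("x", c("a", "b"), c("ACGT", "ACGTA")),
               "alignment error")
  p4 <- tempfile(fileext = ".fa")
  file.create(p4)
  expect_error(read_locus_fasta(p4), "empty FASTA|format")
})

test_that("FASTA round-trip preserves sequences, labels and outgroup", {
  a <- locus_alignment("rt", c("s1", "s2", "s3"),
                       c("ACGTNACG-T", "ACGTAACGTT", "ACCTAACGTT"),
                       outgroup = "ACGTAACGTT")
  p <- tempfile(fileext = ".fa")
  write_locus_fasta(a, p)
  b <- read_locus_fasta(p, "rt")
  expect_equal(vapply(b$haplotypes, `[[`, character(1), "sequence"),
               vapply(a$haplotypes, `[[`, character(1), "sequence"),
               ignore_attr = TRUE)
  expect_equal(vapply(b$haplotypes, `[[`, character(1), "label"),
               c("s1", "s2", "s3"), ignore_attr = TRUE)
  expect_equal(b$outgroup, a$outgroup)
})

test_that("population map reading validates columns and duplicates", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tisland",
               "s1\tp1\ti1", "s2\tp1\ti1", "s3\tp2\ti2", "s4\tp2\ti2"), p)
  m <- read_population_map(p)
  expect_s3_class(m, "population_map")
  expect_equal(length(unique(m$assignments)), 2L)
  expect_equal(unname(m$islands["p2"]), "i2")

  writeLines(c("sample\tpopulation\tisland", "s1\tp1\ti1", "s1\tp2\ti1"), p)
  expect_error(read_population_map(p), "duplicate")

  writeLines(c("sample\tpopulation\tisland",
               "s1\tp1\ti1", "s2\tp1\ti1"), p)
  a <- locus_alignment("x", c("s1", "sX"), c("ACGT", "ACGA"))
  expect_error(attach_population_map(list(a), p), "sX")
  a2 <- locus_alignment("x", c("s1", "s2"), c("ACGT", "ACGA"))
  expect_silent(attach_population_map(list(a2), p))
})

test_that("site matrix extraction applies the column filtering rules", {
  # identical sequences: no variation, L = full length
  a <- locus_alignment("m", paste0("s", 1:4), rep("ACGTACGT", 4))
  m <- extract_site_matrix(a)
  expect_equal(m$S, 0L)
  expect_equal(m$L, 8)

  # column with ingroup gap/N dropped entirely (complete deletion)
  a <- locus_alignment("m", paste0("s", 1:3), c("AC-T", "ACGT", "NCGT"))
  m <- extract_site_matrix(a)
  expect_equal(m$L, 2)   # columns 1 and 3 removed
  expect_equal(m$S, 0L)

  # triallelic column excluded from the matrix but retained in L
  a <- locus_alignment("m", paste0("s", 1:3), c("AAAT", "ACAT", "AGAA"))
  m <- extract_site_matrix(a)
  expect_equal(m$S, 1L)  # only the final biallelic T/A column
  expect_equal(m$L, 4)
  expect_equal(m$n_multiallelic, 1L)

  # outgroup polarization: T/A column with outgroup T -> T coded 0
  a <- locus_alignment("m", c("s1", "s2"), c("ACGT", "ACGA"),
                       outgroup = "ACGT")
  m <- extract_site_matrix(a, use_outgroup = TRUE)
  expect_true(m$polarized)
  expect_equal(unname(m$mat[, 1L]), c(0L, 1L))
  expect_equal(m$positions, 3)

  # outgroup gap: column kept, flagged unpolarized
  a <- locus_alignment("m", c("s1", "s2", "s3"), c("ACGT", "ACGA", "ACGA"),
                       outgroup = "ACG-")
  m <- extract_site_matrix(a, use_outgroup = TRUE)
  expect_equal(m$S, 1L)
  expect_false(m$col_polarized[1L])
  # major-allele fallback: A is major -> coded 0
  expect_equal(unname(m$mat[, 1L]), c(1L, 0L, 0L))
})

test_that("extraction is invariant to row order up to row permutation", {
  set.seed(5)
  seqs <- c("ACGTAA", "ACGTAT", "AAGTCT", "ACGACT")
  a1 <- locus_alignment("m", paste0("s", 1:4), seqs)
  perm <- c(3L, 1L, 4L, 2L)
  a2 <- locus_alignment("m", paste0("s", perm), seqs[perm])
  m1 <- extract_site_matrix(a1)
  m2 <- extract_site_matrix(a2)
  expect_equal(m1$positions, m2$positions)
  # the induced pairwise-difference structure is row-order invariant
  # (0/1 coding itself may flip at 50/50 columns under the first-row rule)
  dist_of <- function(m) {
    d <- as.matrix(dist(m$mat, method = "manhattan"))
    dimnames(d) <- list(m$sample_labels, m$sample_labels)
    d
  }
  d1 <- dist_of(m1)
  d2 <- dist_of(m2)
  expect_equal(d1[rownames(d2), colnames(d2)], d2)
})

test_that("site mask drops the masked columns from S and L", {
  a <- locus_alignment("m", c("s1", "s2"), c("ACGTACGT", "ATGTACGA"))
  mask <- data.frame(locus = "m", start = 0L, end = 2L)
  m <- extract_site_matrix(a, mask = mask)
  expect_equal(m$L, 6)
  expect_equal(m$S, 1L)       # the T/A column at position 7 only
  expect_equal(m$positions, 7)
})

test_that("tie-breaking of 0/1 coding is deterministic (first-row rule)", {
  a <- locus_alignment("m", c("s1", "s2"), c("ACGT", "ACGA"))
  m1 <- extract_site_matrix(a)
  m2 <- extract_site_matrix(a)
  expect_identical(m1$mat, m2$mat)
  expect_equal(unname(m1$mat[, 1L]), c(0L, 1L))  # first row carries the 0
})
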