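test_that("segregating sites and haplotype counts", {
  m0 <- sm(c("", ""), positions = numeric(0), L = 10)
  expect_equal(segregating_sites(m0), 0L)
  expect_equal(haplotype_count(m0), 1L)
  m <- sm(c("000", "001", "001", "111"))
  expect_equal(segregating_sites(m), 3L)
  expect_equal(haplotype_count(m), 3L)
})

test_that("pairwise diversity matches hand-enumerated pair differences", {
  m <- sm(c("000", "001", "011", "111"), L = 3)
  # all 6 pairs: 1+2+3+1+2+1 = 10 differences -> k-bar = 5/3
  expect_equal(pairwise_diversity(m)$pi_total, 5 / 3)
  m2 <- sm(c("1", "0"), L = 100)
  expect_equal(pairwise_diversity(m2)$pi_total, 1)
  expect_equal(pairwise_diversity(m2)$pi_site, 0.01)
  m3 <- sm(c("", "", "", ""), positions = numeric(0), L = 50)
  expect_equal(pairwise_diversity(m3)$pi_total, 0)
})

test_that("Watterson's theta follows S / (a_n L)", {
  expect_equal(watterson_theta(3, 2, 100), 0.03)
  expect_equal(watterson_theta(0, 8, 100), 0)
  expect_equal(watterson_theta(11, 4, 100), 11 / ((1 + 1/2 + 1/3) * 100))
  expect_error(watterson_theta(3, 1, 100), "n >= 2")
})

test_that("Tajima's D agrees with a direct evaluation of the 1989 formulas", {
  set.seed(31)
  for (r in 1:20) {
    n <- sample(4:10, 1)
    S <- sample(2:12, 1)
    mat <- matrix(0L, n, S)
    for (j in seq_len(S)) {
      k <- sample(seq_len(n - 1L), 1)
      mat[sample(n, k), j] <- 1L
    }
    m <- site_matrix(mat, seq_len(S) - 1, L = S)
    expect_equal(tajimas_d(m), direct_tajima_d(mat), tolerance = 1e-12)
  }
  # zero numerator: k-bar = S/a1 exactly (n = 4, a1 = 11/6, S = 11)
  expect_equal(coaldemog:::tajima_d_from(6, 11, 4), 0)
  # undefined at S = 0, reported NA and never 0
  m0 <- sm(c("", ""), positions = numeric(0), L = 10)
  expect_true(is.na(tajimas_d(m0)))
})

test_that("Fay and Wu's H matches hand evaluation and handles polarity", {
  # n = 4, one derived singleton: theta_pi = 0.5, theta_H = 1/6, H = 1/3
  m <- sm(c("1", "0", "0", "0"), L = 10, polarized = TRUE)
  expect_equal(as.numeric(fay_wu_h(m)), 1 / 3, tolerance = 1e-12)
  # n = 4, 3 derived copies: theta_pi = 0.5, theta_H = 1.5, H = -1
  m <- sm(c("1", "1", "1", "0"), L = 10, polarized = TRUE)
  expect_equal(as.numeric(fay_wu_h(m)), -1, tolerance = 1e-12)
  expect_equal(as.numeric(fay_wu_h(m)),
               direct_fay_wu_h(3L, 4L), tolerance = 1e-12)
  # no segregating sites -> 0
  m0 <- sm(c("", "", "", ""), positions = numeric(0), L = 10)
  expect_equal(fay_wu_h(m0), 0)
  # no polarized column -> undefined, with excluded count attached
  mu <- sm(c("1", "0", "0", "0"), L = 10, polarized = FALSE)
  expect_true(is.na(fay_wu_h(mu)))
  expect_equal(attr(fay_wu_h(mu), "n_unpolarized"), 1L)
})

test_that("column relabeling changes theta_H but not theta_pi", {
  set.seed(8)
  mat <- matrix(rbinom(6 * 5, 1, 0.4), 6, 5)
  mat[1, colSums(mat) == 0] <- 1L
  mat[1, colSums(mat) == 6] <- 0L
  m <- site_matrix(mat, 0:4, L = 5, polarized = TRUE)
  mf <- site_matrix(1L - mat, 0:4, L = 5, polarized = TRUE)
  expect_equal(pairwise_diversity(m)$pi_total,
               pairwise_diversity(mf)$pi_total)
  c1 <- colSums(mat)
  expect_false(isTRUE(all.equal(as.numeric(fay_wu_h(m)),
                                as.numeric(fay_wu_h(mf)))) &&
                 any(c1 != 6 - c1))
})

test_that("four-gamete R_M equals exhaustive brute force on random matrices", {
  # the canonical pair: all four gametes across two columns
  m <- sm(c("00", "01", "10", "11"))
  expect_equal(min_recombination_rm(m)$rm, 1L)
  m2 <- sm(c("00", "01", "11"))
  expect_equal(min_recombination_rm(m2)$rm, 0L)
  set.seed(99)
  for (r in 1:60) {
    n <- sample(4:8, 1)
    S <- sample(2:12, 1)
    mat <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
    ok <- colSums(mat) > 0 & colSums(mat) < n
    mat <- mat[, ok, drop = FALSE]
    if (ncol(mat) == 0L) next
    m <- site_matrix(mat, seq_len(ncol(mat)) - 1, L = ncol(mat))
    expect_equal(min_recombination_rm(m)$rm, brute_force_rm(mat),
                 info = paste("replicate", r))
  }
})

test_that("largest non-recombining block uses midpoint boundaries", {
  # no violation anywhere: full alignment length
  m <- sm(c("00", "01", "11"), positions = c(3, 8), L = 100)
  expect_equal(largest_nonrecombining_block(m, 100), 100)
  # S = 0: full length
  m0 <- sm(c("", ""), positions = numeric(0), L = 100)
  expect_equal(largest_nonrecombining_block(m0, 100), 100)
  # single incompatible pair at positions 10 and 30 in a 100 bp locus:
  # left block [0, 20) = 20 bp, right block [20, 100) = 80 bp
  m1 <- sm(c("00", "01", "10", "11"), positions = c(10, 30), L = 100)
  expect_equal(largest_nonrecombining_block(m1, 100), 80)
})

test_that("Dxy averages between-population pair differences", {
  # 3 identical vs 1 sequence differing at 2 of 100 sites
  m <- sm(c("00", "00", "00", "11"), L = 100)
  expect_equal(dxy(m, 1:3, 4)$dxy_site, 0.02)
  # symmetry
  set.seed(4)
  mat <- matrix(rbinom(6 * 4, 1, 0.5), 6, 4)
  mat[1, colSums(mat) == 0] <- 1L
  mat[1, colSums(mat) == 6] <- 0L
  m2 <- site_matrix(mat, 0:3, L = 10)
  expect_equal(dxy(m2, 1:3, 4:6), dxy(m2, 4:6, 1:3))
  # 2v2 toy: mean of the 4 between-pair distances
  m3 <- sm(c("000", "011", "001", "111"), L = 3)
  d12 <- sum(m3$mat[1, ] != m3$mat[3, ]) # A1-B1
  d <- mean(c(sum(m3$mat[1, ] != m3$mat[3, ]), sum(m3$mat[1, ] != m3$mat[4, ]),
              sum(m3$mat[2, ] != m3$mat[3, ]), sum(m3$mat[2, ] != m3$mat[4, ])))
  expect_equal(dxy(m3, 1:2, 3:4)$dxy_total, d)
  expect_error(dxy(m3, 1:2, 2:3), "disjoint")
})

test_that("statistics are invariant under row permutation", {
  set.seed(12)
  mat <- matrix(rbinom(8 * 6, 1, 0.5), 8, 6)
  ok <- colSums(mat) > 0 & colSums(mat) < 8
  mat <- mat[, ok, drop = FALSE]
  m <- site_matrix(mat, seq_len(ncol(mat)) - 1, L = 10, polarized = TRUE)
  perm <- sample(8)
  mp <- site_matrix(mat[perm, ], seq_len(ncol(mat)) - 1, L = 10,
                    polarized = TRUE)
  expect_equal(pairwise_diversity(m), pairwise_diversity(mp))
  expect_equal(tajimas_d(m), tajimas_d(mp))
  expect_equal(fay_wu_h(m), fay_wu_h(mp))
  expect_equal(min_recombination_rm(m)$rm, min_recombination_rm(mp)$rm)
  expect_equal(haplotype_count(m), haplotype_count(mp))
})

test_that("pooled population summary concatenates analyzed sites", {
  map_p <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tisland",
               paste0("s", 1:4, "\tp1\ti1")), map_p)
  map <- read_population_map(map_p)
  # two loci; pooled pi = (k1 + k2) / (L1 + L2)
  a1 <- locus_alignment("l1", paste0("s", 1:4),
                        c("AAAA", "AAAT", "AAAT", "AAAT"))
  a2 <- locus_alignment("l2", paste0("s", 1:4),
                        c("CCCCCC", "CCCCCC", "CCCCCC", "CCCCCC"))
  ps <- population_summary(list(l1 = a1, l2 = a2), map, "p1")
  k1 <- pairwise_diversity(extract_site_matrix(a1))$pi_total
  expect_equal(ps$pi_site, k1 / 10)
  expect_equal(ps$theta_w_site, 1 / (sum(1 / (1:3)) * 10))
  # monomorphic population: zeros, D undefined
  a3 <- locus_alignment("l1", paste0("s", 1:4), rep("GGGG", 4))
  ps0 <- population_summary(list(l1 = a3), map, "p1")
  expect_equal(ps0$pi_site, 0)
  expect_equal(ps0$theta_w_site, 0)
  expect_true(is.na(ps0$tajima_d))
  expect_error(population_summary(list(l1 = a1), map, "nope"), "unknown")
})

test_that("invariants hold on simulated matrices", {
  set.seed(77)
  d <- demography("SNM", theta0 = 4)
  for (r in 1:25) {
    g <- sample_genealogy(8, d)
    m <- drop_mutations(g, 4, L = 500)
    pd <- pairwise_diversity(m)
    expect_lte(pd$pi_total, m$S)
    if (m$S >= 1) {
      expect_lte(min_recombination_rm(m)$rm, m$S - 1)
      dd <- tajimas_d(m)
      expect_equal(sign(dd),
                   sign(pd$pi_total - m$S / sum(1 / (1:(m$n - 1)))))
    }
    blk <- largest_nonrecombining_block(m, 500)
    no_conflict <- min_recombination_rm(m)$rm == 0
    expect_equal(blk == 500, no_conflict)
  }
})
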