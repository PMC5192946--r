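test_that("demography validates parameters per model", {
  expect_error(demography("SNM"), "theta0")
  expect_error(demography("BOT", theta0 = 1, severity = 0), "severity")
  expect_error(demography("IM2", theta1 = 1, theta2 = 1), "thetaA|t_split")
  expect_error(demography("IM2", theta1 = 1, theta2 = 1, thetaA = 1,
                          t_split = -1), "t_split")
  d <- demography("IM2", theta1 = 2, theta2 = 1, thetaA = 3, t_split = 0.5)
  expect_equal(d$theta0, 2)  # deme-1 theta is the reference
})

test_that("standard neutral expectations: TMRCA and total length", {
  set.seed(21)
  d <- demography("SNM", theta0 = 1)
  t2 <- replicate(4000, sample_genealogy(2, d)$tmrca)
  expect_equal(mean(t2), 0.5, tolerance = 4 * sd(t2) / sqrt(4000) / 0.5)
  tl <- replicate(3000, sample_genealogy(10, d)$total_length)
  expect_equal(mean(tl), sum(1 / (1:9)),
               tolerance = 4 * sd(tl) / sqrt(3000) / sum(1 / (1:9)))
})

test_that("mutation dropping is Poisson in the branch length", {
  set.seed(22)
  d <- demography("SNM", theta0 = 5)
  s2 <- replicate(4000, {
    g <- sample_genealogy(2, d)
    drop_mutations(g, 5, L = 100)$S
  })
  expect_equal(mean(s2), 5, tolerance = 4 * sd(s2) / sqrt(4000) / 5)
  # fixed-S conditioning: every replicate has exactly S sites
  g <- sample_genealogy(6, d)
  expect_true(all(replicate(50, drop_mutations(g, 5, fixed_s = 7L)$S) == 7L))
  # theta -> 0 limit: no mutations
  expect_equal(drop_mutations(sample_genealogy(4, d), 1e-9, L = 10)$S, 0L)
})

test_that("model identities collapse to the standard neutral model", {
  set.seed(23)
  n_rep <- 3000
  snm <- sim_s_tmrca_cpp(8L, 0L, 0, 0, 1, 3, n_rep)
  exp0 <- sim_s_tmrca_cpp(8L, 1L, 0, 0, 1, 3, n_rep)
  bot1 <- sim_s_tmrca_cpp(8L, 2L, 0, 0.3, 1, 3, n_rep)
  expect_gt(ks.test(snm[, 2], exp0[, 2])$p.value, 0.01)
  expect_gt(ks.test(snm[, 2], bot1[, 2])$p.value, 0.01)
  expect_gt(wilcox.test(snm[, 1], exp0[, 1])$p.value, 0.01)
  expect_gt(wilcox.test(snm[, 1], bot1[, 1])$p.value, 0.01)
})

test_that("IM2 with t_split = 0 is panmictic at the ancestral size", {
  set.seed(24)
  d <- demography("IM2", theta1 = 1, theta2 = 1, thetaA = 2, t_split = 0)
  tm <- replicate(3000, sample_genealogy(c(1, 1), d)$tmrca)
  # relative size 2 -> pair coalescent rate 1 -> mean TMRCA 1
  expect_equal(mean(tm), 1, tolerance = 4 * sd(tm) / sqrt(3000))
})

test_that("IM2 without migration and a deep split keeps demes separated", {
  set.seed(25)
  d <- demography("IM2", theta1 = 1, theta2 = 1, thetaA = 1, t_split = 3)
  tm <- replicate(2000, sample_genealogy(c(1, 1), d)$tmrca)
  # the two lineages cannot coalesce before t_split
  expect_true(all(tm >= 3))
  expect_equal(mean(tm), 3.5, tolerance = 4 * sd(tm) / sqrt(2000) / 3.5)
})

test_that("growth and bottleneck models push Tajima's D in known directions", {
  set.seed(26)
  loci <- data.frame(locus_id = "l", L = 500)
  mean_d <- function(d) {
    mean(replicate(400, {
      m <- simulate_dataset(d, 16, loci)[[1]]
      v <- tajimas_d(m)
      if (is.na(v)) 0 else v
    }))
  }
  d_exp <- mean_d(demography("EXP", theta0 = 5, g = 40))
  d_bot <- mean_d(demography("BOT", theta0 = 5, t_b = 0.1, severity = 0.05))
  expect_lt(d_exp, -0.3)   # star-like genealogies
  expect_gt(d_bot, 0.3)    # excess intermediate-frequency variation
})

test_that("simulation is reproducible from the master seed", {
  loci <- default_loci()
  d <- demography("SNM", theta0 = 4)
  set.seed(500)
  x1 <- simulate_dataset(d, 16, loci)
  set.seed(500)
  x2 <- simulate_dataset(d, 16, loci)
  expect_identical(x1, x2)
})

test_that("ms-format writer emits the standard block structure", {
  set.seed(27)
  d <- demography("SNM", theta0 = 3)
  mats <- simulate_dataset(d, 4, data.frame(locus_id = c("a", "b"),
                                            L = c(100, 100)))
  p <- tempfile()
  write_ms(mats, p)
  lines <- readLines(p)
  expect_equal(sum(lines == "//"), 2L)
  expect_true(any(grepl("^segsites:", lines)))
  if (mats[[1]]$S > 0) {
    expect_true(any(grepl("^positions:", lines)))
    rows <- lines[grep("^[01]+$", lines)]
    expect_equal(nchar(rows[1]), mats[[1]]$S)
  }
})
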