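test_that("prior sampling respects bounds and distributions", {
  expect_error(prior_uniform(1, 1), "lower < upper")
  expect_error(prior_loguniform(0, 1), "lower > 0")
  set.seed(41)
  u <- sample_prior(prior_uniform(0, 1), 10000)
  expect_equal(mean(u), 0.5, tolerance = 3 * sd(u) / sqrt(10000) / 0.5)
  lu <- sample_prior(prior_loguniform(0.1, 10), 10000)
  expect_true(all(lu >= 0.1 & lu <= 10))
  expect_equal(median(lu), 1, tolerance = 0.1)   # analytic log-uniform median
  m <- sample_prior(list(a = prior_uniform(0, 1),
                         b = prior_loguniform(1, 2)), 50)
  expect_equal(dim(m), c(50L, 2L))
  expect_equal(colnames(m), c("a", "b"))
})

test_that("reference tables are reproducible and match analytic means", {
  design <- list(n = 8, loci = data.frame(locus_id = c("a", "b"),
                                          L = c(400, 400)))
  pr <- list(theta0 = prior_uniform(3, 3 + 1e-9))  # effectively fixed theta
  set.seed(42)
  tab <- build_reference_table("SNM", pr, design, 300)
  expect_s3_class(tab, "reference_table")
  expect_equal(tab$n_sims, 300L)
  expect_equal(colnames(tab$params), "theta0")
  a8 <- sum(1 / (1:7))
  # E[S] = theta * a_n, E[pi_total] = theta
  expect_equal(mean(tab$summaries[, "mean_S"]), 3 * a8, tolerance = 0.08)
  expect_equal(mean(tab$summaries[, "mean_pi"]), 3, tolerance = 0.08)
  set.seed(42)
  tab2 <- build_reference_table("SNM", pr, design, 300)
  expect_identical(tab$summaries, tab2$summaries)
})

test_that("rejection at tolerance 1 returns the prior", {
  design <- list(n = 6, loci = data.frame(locus_id = "a", L = 300))
  set.seed(43)
  tabs <- lapply(c("SNM", "EXP"), function(m) {
    build_reference_table(m, default_model_priors()[[m]], design, 400)
  })
  obs <- tabs[[1]]$summaries[1, ]
  fit <- abc_reject(obs, tabs, tolerance = 1)
  expect_equal(unname(fit$model_posteriors), c(0.5, 0.5))
  expect_equal(sum(fit$model_posteriors), 1, tolerance = 1e-12)
  # parameter posterior at tolerance 1 is the prior itself
  expect_equal(mean(fit$accepted$SNM[, "theta0"]),
               mean(tabs[[1]]$params[, "theta0"]))
})

test_that("rejection with minimal tolerance picks the matching row", {
  design <- list(n = 6, loci = data.frame(locus_id = "a", L = 300))
  set.seed(44)
  tab <- build_reference_table("SNM", default_model_priors()$SNM, design, 200)
  obs <- tab$summaries[57, ]
  fit <- abc_reject(obs, list(tab), tolerance = 1 / 200)
  expect_equal(unname(fit$accepted$SNM[1, "theta0"]),
               unname(tab$params[57, "theta0"]))
  expect_error(abc_reject(obs, list(tab), tolerance = 0), "tolerance")
})

test_that("posterior mode finds known density peaks", {
  expect_error(posterior_mode(1:10), "at least 50")
  expect_equal(posterior_mode(rep(3.7, 60)), 3.7)
  set.seed(45)
  x <- runif(50000) + runif(50000)   # triangular, peak at 1
  expect_equal(posterior_mode(x), 1, tolerance = 0.05)
})

test_that("HPD interval equals the brute-force window scan", {
  expect_error(hpd_interval(1:10), "at least 50")
  x <- 1:100
  h <- hpd_interval(x, 0.95)
  expect_equal(unname(h[2] - h[1]), 94)
  expect_equal(unname(hpd_interval(rep(2, 80))), c(2, 2))
  set.seed(46)
  for (r in 1:40) {
    x <- switch(1 + r %% 3,
                rnorm(sample(50:400, 1)),
                exp(rnorm(sample(50:400, 1))),
                c(rnorm(100), rnorm(60, 6)))
    lev <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    expect_equal(unname(hpd_interval(x, lev)), brute_force_hpd(x, lev))
    # shortest-interval property: never wider than the central interval
    ci <- quantile(x, c((1 - lev) / 2, 1 - (1 - lev) / 2))
    expect_lte(diff(unname(hpd_interval(x, lev))), unname(diff(ci)) + 1e-12)
  }
})

test_that("posterior predictive checks are calibrated and deterministic", {
  design <- list(n = 8, loci = data.frame(locus_id = c("a", "b"),
                                          L = c(400, 400)))
  set.seed(47)
  truth <- demography("SNM", theta0 = 4)
  obs <- dataset_summary(simulate_dataset(truth, 8, design$loci))
  tab <- build_reference_table("SNM", default_model_priors()$SNM, design, 600)
  fit <- abc_reject(obs, list(tab), tolerance = 0.1)
  expect_error(posterior_predictive_check(fit, "SNM", design, n_rep = 0),
               "n_rep")
  set.seed(48)
  q1 <- posterior_predictive_check(fit, "SNM", design, n_rep = 100)
  set.seed(48)
  q2 <- posterior_predictive_check(fit, "SNM", design, n_rep = 100)
  expect_identical(q1, q2)
  # data generated from the fitted model: central quantiles dominate
  expect_gt(mean(q1 > 0.01 & q1 < 0.99), 0.7)
})

test_that("scaling identities hold exactly", {
  # population migration rate 2NM = 0.5 * theta * m
  expect_equal(population_migration_rate(1, 2), 1)
  expect_equal(population_migration_rate(0.8, 0.5), 0.2)
  # t = T * mu  =>  T = t / mu
  ts <- time_scale(1e-6, theta_ref = 1)
  expect_equal(years_from_scaled(0.01, ts), 10000)
  expect_equal(coal_units_from_scaled(0.05, ts), 0.05)
  # the published pairing t = 0.043 ~ 69 kya back-computes mu = t / T
  mu <- 0.043 / 69000
  expect_equal(years_from_scaled(0.043, time_scale(mu)), 69000)
  expect_error(time_scale(0), "mu")
})

test_that("IM2 fit recovers parameters and reports derived rates", {
  set.seed(49)
  loci <- data.frame(locus_id = paste0("L", 1:4), L = rep(400, 4))
  design <- list(n = c(8, 8), loci = loci)
  truth <- demography("IM2", theta1 = 4, theta2 = 4, thetaA = 4,
                      t_split = 0.8, m12 = 0, m21 = 0)
  obs <- simulate_dataset(truth, c(8, 8), loci)
  fit <- fit_im2(obs, design, n_sims = 1200, tolerance = 0.05)
  expect_s3_class(fit, "im2_fit")
  est <- fit$estimates$IM2
  expect_true(est["t_split", "lo"] <= 0.8 && est["t_split", "hi"] >= 0.8)
  expect_equal(sum(fit$model_posteriors), 1)
  expect_true(all(rownames(fit$derived) == c("2NM_12", "2NM_21")))
  expect_error(fit_im2(obs, list(n = 8, loci = loci)), "two populations")
})
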