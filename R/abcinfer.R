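#' Prior specifications
#'
#' Uniform and log-uniform priors for ABC parameter draws.
#'
#' @param lower,upper bounds; `lower < upper`, and `lower > 0` for the
#'   log-uniform.
#' @return object of class `prior_spec`.
#' @export
prior_uniform <- function(lower, upper) {
  if (!(lower < upper)) stop_input("prior bounds must satisfy lower < upper")
  structure(list(kind = "uniform", lower = lower, upper = upper),
            class = "prior_spec")
}

#' @rdname prior_uniform
#' @export
prior_loguniform <- function(lower, upper) {
  if (!(lower < upper)) stop_input("prior bounds must satisfy lower < upper")
  if (lower <= 0) stop_input("log-uniform prior requires lower > 0")
  structure(list(kind = "loguniform", lower = lower, upper = upper),
            class = "prior_spec")
}

#' Draw from a prior
#'
#' @param p a `prior_spec`, or a named list of them (one per parameter).
#' @param n number of draws.
#' @return numeric vector, or an `n` x p matrix for a list of priors.
#' @export
sample_prior <- function(p, n) {
  if (n < 1L) stop_input("n must be >= 1")
  if (inherits(p, "prior_spec")) {
    return(switch(p$kind,
      uniform = runif(n, p$lower, p$upper),
      loguniform = exp(runif(n, log(p$lower), log(p$upper)))))
  }
  stopifnot(is.list(p), length(p) >= 1L, !is.null(names(p)))
  out <- vapply(p, sample_prior, numeric(n), n = n)
  if (n == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(p)))
  out
}

#' Default model priors
#'
#' Config-extensible defaults for the four single-population models and the
#' two-population IM model. `theta0` is per locus.
#'
#' @return named list of named lists of [prior_uniform()] /
#'   [prior_loguniform()] specs.
#' @export
default_model_priors <- function() {
  list(
    SNM = list(theta0 = prior_loguniform(0.5, 20)),
    EXP = list(theta0 = prior_loguniform(0.5, 20),
               g = prior_uniform(0, 50)),
    BOT = list(theta0 = prior_loguniform(0.5, 20),
               t_b = prior_uniform(0.05, 0.5),
               severity = prior_loguniform(0.02, 1)),
    BOT_EXP = list(theta0 = prior_loguniform(0.5, 20),
                   g = prior_uniform(0, 50),
                   t_b = prior_uniform(0.05, 0.5),
                   severity = prior_loguniform(0.02, 1)),
    IM2 = list(theta1 = prior_loguniform(0.5, 20),
               theta2 = prior_loguniform(0.5, 20),
               thetaA = prior_loguniform(0.5, 20),
               t_split = prior_uniform(0.01, 2),
               m12 = prior_uniform(0, 2),
               m21 = prior_uniform(0, 2))
  )
}

#' Build a demography from a named parameter vector
#'
#' Maps a row of an ABC parameter draw (as produced by [sample_prior()])
#' onto a [demography()] object for the given model.
#'
#' @param model model id.
#' @param par named vector or list of the model's parameters.
#' @return a [demography()].
#' @export
demography_from_params <- function(model, par) {
  par <- as.list(par)
  switch(model,
    SNM = demography("SNM", theta0 = par$theta0),
    EXP = demography("EXP", theta0 = par$theta0, g = par$g),
    BOT = demography("BOT", theta0 = par$theta0, t_b = par$t_b,
                     severity = par$severity),
    BOT_EXP = demography("BOT_EXP", theta0 = par$theta0, g = par$g,
                         t_b = par$t_b, severity = par$severity),
    IM2 = demography("IM2", theta1 = par$theta1, theta2 = par$theta2,
                     thetaA = par$thetaA, t_split = par$t_split,
                     m12 = par$m12, m21 = par$m21),
    stop_input("unknown model: ", model))
}

#' Build an ABC reference table
#'
#' Draws `n_sims` parameter vectors from the prior, simulates a dataset
#' matched to the observed design for each, and records the multilocus
#' summary vector ([dataset_summary()], or [dataset_summary_im2()] for IM2).
#'
#' @param model_id one of `"SNM"`, `"EXP"`, `"BOT"`, `"BOT_EXP"`, `"IM2"`.
#' @param prior named list of `prior_spec`s for the model's parameters.
#' @param design list with `n` (haplotypes sampled; length-2 for IM2) and
#'   `loci` (data.frame with `locus_id`, `L`, optional `theta_scale`),
#'   matching the observed dataset.
#' @param n_sims number of simulations.
#' @return object of class `reference_table`.
#' @export
build_reference_table <- function(model_id, prior, design, n_sims) {
  stopifnot(n_sims >= 1L, is.list(design), !is.null(design$n),
            is.data.frame(design$loci))
  params <- sample_prior(prior, n_sims)
  summarise <- if (model_id == "IM2") dataset_summary_im2 else dataset_summary
  summaries <- matrix(NA_real_, nrow = n_sims, ncol = 0L)
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    d <- demography_from_params(model_id, params[i, ])
    rows[[i]] <- summarise(simulate_dataset(d, design$n, design$loci))
  }
  summaries <- do.call(rbind, rows)
  ok <- apply(is.finite(summaries), 1L, all)
  structure(
    list(model = model_id, params = params[ok, , drop = FALSE],
         summaries = summaries[ok, , drop = FALSE],
         n_sims = sum(ok), summary_names = colnames(summaries),
         design = design),
    class = "reference_table"
  )
}

#' @export
print.reference_table <- function(x, ...) {
  cat("reference_table:", x$model, "-", x$n_sims, "simulations,",
      ncol(x$params), "parameters,", length(x$summary_names), "summaries\n")
  invisible(x)
}

# robust per-summary scale pooled across tables; zero scales fall back to
# sd, then to 1, so constant summaries cannot dominate the distance
pooled_robust_scale <- function(summaries) {
  s <- apply(summaries, 2L, stats::mad)
  zero <- s == 0
  if (any(zero)) s[zero] <- apply(summaries[, zero, drop = FALSE], 2L, sd)
  s[s == 0 | !is.finite(s)] <- 1
  s
}

#' Rejection-ABC model choice and parameter posteriors
#'
#' Centers and scales every summary by its robust scale (median absolute
#' deviation pooled across models), computes Euclidean distances from the
#' observed vector, and accepts the `tolerance` fraction of nearest rows
#' pooled across models. Model posterior probabilities are the per-model
#' shares of the accepted set; per-parameter posteriors come from each
#' model's accepted draws.
#'
#' @param observed named summary vector (same names as the tables).
#' @param tables list of [build_reference_table()] results with equal
#'   `n_sims` and identical summary names.
#' @param tolerance accepted fraction of pooled simulations, in (0, 1].
#' @return object of class `abc_fit`.
#' @export
abc_reject <- function(observed, tables, tolerance = 0.005) {
  if (!(tolerance > 0 && tolerance <= 1)) {
    stop_input("tolerance must be in (0, 1]")
  }
  if (inherits(tables, "reference_table")) tables <- list(tables)
  nms <- lapply(tables, `[[`, "summary_names")
  if (length(unique(vapply(nms, paste, character(1), collapse = "|"))) != 1L) {
    stop_input("all reference tables must share the same summary set")
  }
  ns <- vapply(tables, `[[`, numeric(1), "n_sims")
  if (length(unique(ns)) != 1L) {
    stop_input("reference tables must have equal n_sims")
  }
  observed <- observed[nms[[1L]]]
  if (anyNA(observed)) stop_input("observed summaries missing entries")
  pooled <- do.call(rbind, lapply(tables, `[[`, "summaries"))
  model_of <- rep(vapply(tables, `[[`, character(1), "model"), ns)
  scale <- pooled_robust_scale(pooled)
  z <- sweep(pooled, 2L, observed, `-`)
  z <- sweep(z, 2L, scale, `/`)
  dist <- sqrt(rowSums(z^2))
  n_accept <- max(1L, ceiling(tolerance * nrow(pooled)))
  acc_idx <- order(dist)[seq_len(n_accept)]
  acc_model <- model_of[acc_idx]
  models <- vapply(tables, `[[`, character(1), "model")
  post <- vapply(models, function(m) mean(acc_model == m), numeric(1))
  accepted <- list()
  offsets <- c(0L, cumsum(ns))
  for (i in seq_along(tables)) {
    local_idx <- acc_idx[acc_idx > offsets[i] & acc_idx <= offsets[i + 1L]] -
      offsets[i]
    accepted[[models[i]]] <- tables[[i]]$params[local_idx, , drop = FALSE]
  }
  estimates <- lapply(accepted, function(p) {
    if (nrow(p) < 50L) return(NULL)
    t(apply(p, 2L, function(x) {
      c(mode = posterior_mode(x), hpd_interval(x, 0.95))
    }))
  })
  structure(
    list(model_posteriors = post, accepted = accepted,
         estimates = estimates, tolerance = tolerance,
         n_accept = n_accept, observed = observed, scale = scale,
         summary_names = nms[[1L]]),
    class = "abc_fit"
  )
}

#' Fit the four single-population demographic models by ABC
#'
#' Convenience wrapper: builds one reference table per model from the given
#' priors and design, then calls [abc_reject()].
#'
#' @param observed list of [site_matrix()] objects (one per locus) or an
#'   already-computed named summary vector.
#' @param design see [build_reference_table()].
#' @param priors named list of per-model priors; defaults to
#'   [default_model_priors()].
#' @param models models to compare.
#' @param n_sims simulations per model.
#' @param tolerance accepted fraction.
#' @return an `abc_fit`.
#' @export
abc_model_choice <- function(observed, design,
                             priors = default_model_priors(),
                             models = c("SNM", "EXP", "BOT", "BOT_EXP"),
                             n_sims = 10000, tolerance = 0.005) {
  if (is.list(observed) && is_site_matrix(observed[[1L]])) {
    observed <- dataset_summary(observed)
  }
  tables <- lapply(models, function(m) {
    build_reference_table(m, priors[[m]], design, n_sims)
  })
  abc_reject(observed, tables, tolerance)
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("rejection-ABC fit:", x$n_accept, "accepted draws (tolerance",
      x$tolerance, ")\n")
  cat("model posterior probabilities:\n")
  print(round(x$model_posteriors, 3))
  invisible(x)
}

#' @export
summary.abc_fit <- function(object, ...) {
  cat("rejection-ABC fit\n")
  cat("  accepted:", object$n_accept, "draws at tolerance",
      object$tolerance, "\n\nmodel posteriors:\n")
  print(round(object$model_posteriors, 3))
  for (m in names(object$estimates)) {
    if (is.null(object$estimates[[m]])) next
    cat("\n", m, "parameter posteriors (mode, 95% HPD):\n")
    print(round(object$estimates[[m]], 4))
  }
  invisible(object)
}

#' @export
coef.abc_fit <- function(object, model = NULL, ...) {
  model <- model %||% names(which.max(object$model_posteriors))
  est <- object$estimates[[model]]
  if (is.null(est)) {
    stop_input("too few accepted draws under model ", model,
               " for point estimates")
  }
  setNames(est[, "mode"], rownames(est))
}

#' @export
plot.abc_fit <- function(x, model = NULL, ...) {
  model <- model %||% names(which.max(x$model_posteriors))
  p <- x$accepted[[model]]
  if (is.null(p) || nrow(p) < 2L) {
    stop_input("no accepted draws to plot for model ", model)
  }
  np <- ncol(p)
  old <- graphics::par(mfrow = c(1L, np))
  on.exit(graphics::par(old))
  for (j in seq_len(np)) {
    dd <- density(p[, j])
    plot(dd, main = paste(model, colnames(p)[j]), xlab = colnames(p)[j], ...)
  }
  invisible(x)
}

#' Posterior mode from accepted draws
#'
#' Argmax of a Gaussian-kernel density (Silverman bandwidth) evaluated on a
#' 512-point grid spanning the sample range. A tie between equal density
#' maxima returns the lower value.
#'
#' @param samples numeric vector of at least 50 draws.
#' @return the mode.
#' @export
posterior_mode <- function(samples) {
  if (length(samples) < 50L) {
    stop_input("posterior_mode needs at least 50 samples")
  }
  if (diff(range(samples)) == 0) return(samples[1L])
  d <- density(samples, bw = "nrd0", n = 512,
               from = min(samples), to = max(samples))
  d$x[which.max(d$y)]  # which.max takes the first (lower) grid point on ties
}

#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(level * n)` of the sorted samples.
#'
#' @param samples numeric vector of at least 50 draws.
#' @param level coverage level.
#' @return named vector `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  n <- length(samples)
  if (n < 50L) stop_input("hpd_interval needs at least 50 samples")
  s <- sort(samples)
  m <- ceiling(level * n)
  if (m >= n) return(c(lo = s[1L], hi = s[n]))
  i <- seq_len(n - m + 1L)
  w <- s[i + m - 1L] - s[i]
  j <- which.min(w)
  c(lo = s[j], hi = s[j + m - 1L])
}

#' Posterior predictive check
#'
#' Resamples accepted parameter vectors of one model, simulates datasets of
#' the observed design, and reports each observed summary's quantile within
#' its posterior predictive distribution. Quantiles near 0 or 1 flag
#' summaries the fitted model fails to reproduce.
#'
#' @param fit an `abc_fit`.
#' @param model_id which model's accepted draws to use.
#' @param design the observed design (see [build_reference_table()]).
#' @param n_rep number of predictive simulations (>= 1).
#' @return named vector of predictive quantiles, one per summary.
#' @export
posterior_predictive_check <- function(fit, model_id, design, n_rep = 500) {
  stopifnot(inherits(fit, "abc_fit"))
  if (n_rep < 1L) stop_input("n_rep must be >= 1")
  p <- fit$accepted[[model_id]]
  if (is.null(p) || nrow(p) == 0L) {
    stop_input("no accepted draws for model ", model_id)
  }
  summarise <- if (model_id == "IM2") dataset_summary_im2 else dataset_summary
  idx <- sample.int(nrow(p), n_rep, replace = TRUE)
  sims <- matrix(NA_real_, n_rep, length(fit$summary_names),
                 dimnames = list(NULL, fit$summary_names))
  for (r in seq_len(n_rep)) {
    d <- demography_from_params(model_id, p[idx[r], ])
    sims[r, ] <- summarise(simulate_dataset(d, design$n, design$loci))
  }
  obs <- fit$observed
  setNames(vapply(seq_along(obs), function(j) mean(sims[, j] <= obs[j]),
                  numeric(1)), names(obs))
}

#' Fit the two-population isolation-with-migration model by ABC
#'
#' Joint rejection-ABC posterior over (theta1, theta2, thetaA, t_split,
#' m12, m21) from two-population summaries including Dxy. Derived
#' reportables use the population migration rate identity `2NM = 0.5 *
#' theta * m`; in place of likelihood-ratio tests of nested zero-migration
#' models, the fit reports the posterior mass below a migration threshold.
#'
#' @param observed list of [site_matrix()] objects carrying a `pop`
#'   attribute (or a named summary vector from [dataset_summary_im2()]).
#' @param design list with `n = c(n1, n2)` and `loci`.
#' @param prior named list of priors for the six IM2 parameters.
#' @param n_sims,tolerance rejection settings.
#' @param zero_mig_threshold migration rate below which a draw counts as
#'   effectively zero migration.
#' @return object of class `im2_fit` (inherits `abc_fit`) with additional
#'   `derived` (posterior mode and 95% HPD of 2NM in both directions) and
#'   `zero_migration` (posterior mass below the threshold per direction).
#' @export
fit_im2 <- function(observed, design, prior = default_model_priors()$IM2,
                    n_sims = 10000, tolerance = 0.005,
                    zero_mig_threshold = 0.05) {
  if (length(design$n) != 2L) {
    stop_input("fit_im2 requires exactly two populations: design$n = c(n1, n2)")
  }
  if (is.list(observed) && is_site_matrix(observed[[1L]])) {
    observed <- dataset_summary_im2(observed)
  }
  tab <- build_reference_table("IM2", prior, design, n_sims)
  fit <- abc_reject(observed, list(tab), tolerance)
  p <- fit$accepted$IM2
  nm12 <- 0.5 * p[, "theta1"] * p[, "m12"]
  nm21 <- 0.5 * p[, "theta2"] * p[, "m21"]
  derived <- NULL
  if (nrow(p) >= 50L) {
    derived <- rbind(
      `2NM_12` = c(mode = posterior_mode(nm12), hpd_interval(nm12)),
      `2NM_21` = c(mode = posterior_mode(nm21), hpd_interval(nm21)))
  }
  fit$derived <- derived
  fit$zero_migration <- c(m12 = mean(p[, "m12"] < zero_mig_threshold),
                          m21 = mean(p[, "m21"] < zero_mig_threshold))
  class(fit) <- c("im2_fit", "abc_fit")
  fit
}

#' @export
print.im2_fit <- function(x, ...) {
  cat("isolation-with-migration (IM2) rejection-ABC fit:", x$n_accept,
      "accepted draws\n")
  est <- x$estimates$IM2
  if (!is.null(est)) {
    cat("parameter posteriors (mode, 95% HPD):\n")
    print(round(est, 4))
  }
  if (!is.null(x$derived)) {
    cat("derived population migration rates (2NM = 0.5 theta m):\n")
    print(round(x$derived, 4))
  }
  cat("posterior mass at effectively zero migration:\n")
  print(round(x$zero_migration, 3))
  invisible(x)
}

#' Population migration rate identity
#'
#' `2NM = 0.5 * theta * m`, the product form linking the mutation-scaled
#' migration rate m = M/mu and theta = 4*N*mu.
#'
#' @param theta population mutation parameter.
#' @param m mutation-scaled migration rate.
#' @return 2NM.
#' @export
population_migration_rate <- function(theta, m) 0.5 * theta * m

#' Time-scale constants
#'
#' Converts mutation-scaled times `t = T * mu` to absolute years
#' (`T = t / mu`) and to coalescent units (`t / theta_ref`).
#'
#' @param mu_per_locus_year mutation rate per locus per year (> 0).
#' @param theta_ref reference theta for coalescent-unit conversion.
#' @param generation_years generation time metadata in years.
#' @return object of class `time_scale`.
#' @export
time_scale <- function(mu_per_locus_year, theta_ref = NULL,
                       generation_years = 1) {
  if (is.null(mu_per_locus_year) || mu_per_locus_year <= 0) {
    stop_input("mutation rate mu must be > 0")
  }
  if (!is.null(theta_ref) && theta_ref <= 0) {
    stop_input("theta_ref must be > 0")
  }
  structure(list(mu_per_locus_year = mu_per_locus_year,
                 theta_ref = theta_ref,
                 generation_years = generation_years),
            class = "time_scale")
}

#' Convert a mutation-scaled time to years
#'
#' @param t_mut mutation-scaled time (t = T * mu).
#' @param ts a [time_scale()].
#' @return time in years.
#' @export
years_from_scaled <- function(t_mut, ts) {
  stopifnot(inherits(ts, "time_scale"))
  t_mut / ts$mu_per_locus_year
}

#' Convert a mutation-scaled time to coalescent units
#'
#' @param t_mut mutation-scaled time.
#' @param ts a [time_scale()] with `theta_ref` set.
#' @return time in units of 4*N0 generations.
#' @export
coal_units_from_scaled <- function(t_mut, ts) {
  stopifnot(inherits(ts, "time_scale"))
  if (is.null(ts$theta_ref)) stop_input("time_scale has no theta_ref")
  t_mut / ts$theta_ref
}
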