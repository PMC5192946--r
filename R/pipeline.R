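# Shared plumbing for the run_* commands: fixed output layout
# (stats/, abc/, im/, neutrality/, logs/), config echo with seed, and
# refusal to overwrite existing results without force = TRUE.

prepare_outdir <- function(out_dir, sub, force) {
  target <- file.path(out_dir, sub)
  if (dir.exists(target) && length(list.files(target)) > 0L && !force) {
    stop_input("output directory ", target,
               " already has results; use force = TRUE to overwrite")
  }
  dir.create(target, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "logs"), recursive = TRUE,
             showWarnings = FALSE)
  target
}

write_run_log <- function(out_dir, command, config) {
  log <- c(list(command = command, timestamp = format(Sys.time())), config)
  jsonlite::write_json(log,
                       file.path(out_dir, "logs", paste0(command, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_study <- function(fasta_paths, map_path) {
  alignments <- lapply(fasta_paths, read_locus_fasta)
  names(alignments) <- vapply(alignments, `[[`, character(1), "locus_id")
  attach_population_map(alignments, map_path)
}

#' Per-locus and per-population diversity reports
#'
#' Computes the per-locus table (alignment length, largest non-recombining
#' block, n, S, h, R_M, pi, Tajima's D, Fay and Wu's H over all sampled
#' haplotypes) and the per-population table (n, pooled pi, Watterson's
#' theta, Tajima's D over all loci) and writes both as TSV under
#' `out_dir/stats/`.
#'
#' @param fasta_paths per-locus FASTA files.
#' @param map_path population map TSV.
#' @param out_dir output directory.
#' @param use_outgroup polarize against outgroup records for H.
#' @param mask optional site mask from [read_site_mask()].
#' @param force overwrite existing outputs.
#' @return invisibly, list with the two data.frames and file paths.
#' @export
run_stats <- function(fasta_paths, map_path, out_dir, use_outgroup = TRUE,
                      mask = NULL, force = FALSE) {
  target <- prepare_outdir(out_dir, "stats", force)
  study <- read_study(fasta_paths, map_path)
  locus_tab <- do.call(rbind, lapply(study$alignments, function(a) {
    m <- extract_site_matrix(a, use_outgroup = use_outgroup &&
                               length(a$outgroup) > 0, mask = mask)
    locus_summary(m, a$locus_id, alignment_length = a$length)
  }))
  pops <- unique(unname(study$map$assignments))
  pop_tab <- do.call(rbind, lapply(pops, function(p) {
    ps <- population_summary(study$alignments, study$map, p)
    data.frame(population = p, island = study$map$islands[[p]],
               n = ps$n, L_total = ps$L_total, pi = ps$pi_site,
               theta_w = ps$theta_w_site, tajima_d = ps$tajima_d,
               stringsAsFactors = FALSE)
  }))
  files <- c(locus = write_tsv(locus_tab, file.path(target, "locus_stats.tsv")),
             population = write_tsv(pop_tab,
                                    file.path(target, "population_stats.tsv")))
  write_run_log(out_dir, "stats",
                list(fasta = fasta_paths, map = map_path,
                     use_outgroup = use_outgroup))
  invisible(list(locus = locus_tab, population = pop_tab, files = files))
}

#' Per-locus neutrality test report
#'
#' Tajima's D and (with outgroup data) Fay and Wu's H with coalescent
#' simulation p-values, plus the multilocus HKA test when a
#' polymorphism/divergence table is supplied.
#'
#' @param fasta_paths per-locus FASTA files.
#' @param map_path population map TSV.
#' @param out_dir output directory.
#' @param n_reps coalescent simulations per test (default 10,000).
#' @param hka_table optional path to an HKA input TSV (see
#'   [read_hka_table()]).
#' @param seed RNG seed for the simulation tests.
#' @param force overwrite existing outputs.
#' @return invisibly, list with the per-locus test data.frame and the HKA
#'   `htest` (or NULL).
#' @export
run_neutrality <- function(fasta_paths, map_path, out_dir, n_reps = 10000,
                           hka_table = NULL, seed = NULL, force = FALSE) {
  target <- prepare_outdir(out_dir, "neutrality", force)
  if (!is.null(seed)) set.seed(seed)
  study <- read_study(fasta_paths, map_path)
  rows <- lapply(study$alignments, function(a) {
    has_og <- length(a$outgroup) > 0
    m <- extract_site_matrix(a, use_outgroup = has_og)
    d <- tajimas_d(m)
    d_p <- if (!is.na(d) && m$S >= 1L) {
      tajima_d_test(d, m$n, m$S, n_reps)$p.value
    } else NA_real_
    h <- if (has_og) as.numeric(fay_wu_h(m)) else NA_real_
    h_p <- if (!is.na(h) && m$S >= 1L) {
      fay_wu_h_test(h, m$n, m$S, n_reps)$p.value
    } else NA_real_
    data.frame(locus = a$locus_id, n = m$n, S = m$S, tajima_d = d,
               tajima_d_p = d_p, fay_wu_h = h, fay_wu_h_p = h_p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write_tsv(tab, file.path(target, "locus_tests.tsv"))
  hka <- NULL
  if (!is.null(hka_table)) {
    hka <- hka_test(read_hka_table(hka_table))
    jsonlite::write_json(
      list(x_squared = unname(hka$statistic), df = unname(hka$parameter),
           p_value = hka$p.value, T = unname(hka$estimate["T"]),
           f = unname(hka$estimate["f"])),
      file.path(target, "hka.json"), auto_unbox = TRUE, digits = NA)
  }
  write_run_log(out_dir, "neutrality",
                list(fasta = fasta_paths, map = map_path, n_reps = n_reps,
                     seed = seed))
  invisible(list(locus_tests = tab, hka = hka))
}

# theta(t) backwards trajectory for one accepted single-population draw
theta_trajectory <- function(model, par, t_grid) {
  par <- as.list(par)
  th <- switch(model,
    SNM = rep(par$theta0, length(t_grid)),
    EXP = par$theta0 * exp(-par$g * t_grid),
    BOT = ifelse(t_grid < par$t_b, par$theta0, par$theta0 / par$severity),
    BOT_EXP = ifelse(t_grid < par$t_b, par$theta0 * exp(-par$g * t_grid),
                     par$theta0 / par$severity))
  th
}

#' Per-population demographic model choice by ABC
#'
#' For every requested population: extracts its multilocus summaries, runs
#' [abc_model_choice()] against the four single-population models, writes a
#' JSON result (posterior model probabilities, parameter modes and 95% HPD
#' intervals, tolerance, seed), a posterior predictive check report, and a
#' theta-trajectory table (posterior quantiles of theta(t) on a time grid).
#'
#' @param fasta_paths,map_path input data.
#' @param out_dir output directory.
#' @param populations populations to fit (default: all in the map).
#' @param priors,n_sims,tolerance see [abc_model_choice()].
#' @param n_predictive posterior predictive simulations per population.
#' @param t_grid time grid (4*N0 units) for the trajectory table.
#' @param seed RNG seed.
#' @param force overwrite existing outputs.
#' @return invisibly, named list of `abc_fit` objects.
#' @export
run_model_choice <- function(fasta_paths, map_path, out_dir,
                             populations = NULL,
                             priors = default_model_priors(),
                             n_sims = 10000, tolerance = 0.005,
                             n_predictive = 200,
                             t_grid = seq(0, 1, by = 0.05),
                             seed = NULL, force = FALSE) {
  target <- prepare_outdir(out_dir, "abc", force)
  if (!is.null(seed)) set.seed(seed)
  study <- read_study(fasta_paths, map_path)
  populations <- populations %||% unique(unname(study$map$assignments))
  fits <- list()
  for (p in populations) {
    samples <- names(study$map$assignments)[study$map$assignments == p]
    mats <- lapply(study$alignments, function(a) {
      keep <- vapply(a$haplotypes, function(h) h$label %in% samples,
                     logical(1))
      sub <- locus_alignment(
        a$locus_id,
        labels = vapply(a$haplotypes[keep], `[[`, character(1), "label"),
        sequences = vapply(a$haplotypes[keep], `[[`, character(1),
                           "sequence"))
      extract_site_matrix(sub)
    })
    design <- list(n = mats[[1L]]$n,
                   loci = data.frame(
                     locus_id = names(mats),
                     L = vapply(mats, `[[`, numeric(1), "L")))
    fit <- abc_model_choice(mats, design, priors = priors,
                            n_sims = n_sims, tolerance = tolerance)
    best <- names(which.max(fit$model_posteriors))
    ppc <- posterior_predictive_check(fit, best, design,
                                      n_rep = n_predictive)
    acc <- fit$accepted[[best]]
    traj <- t(apply(
      apply(acc, 1L, function(r) theta_trajectory(best, r, t_grid)),
      1L, quantile, probs = c(0.025, 0.5, 0.975)))
    traj_tab <- data.frame(t = t_grid, q025 = traj[, 1L], q50 = traj[, 2L],
                           q975 = traj[, 3L])
    write_tsv(traj_tab, file.path(target, paste0(p, "_trajectory.tsv")))
    jsonlite::write_json(
      list(population = p, seed = seed, tolerance = tolerance,
           n_sims = n_sims,
           model_posteriors = as.list(fit$model_posteriors),
           best_model = best,
           estimates = lapply(fit$estimates, function(e) {
             if (is.null(e)) NULL else
               as.data.frame(cbind(parameter = rownames(e), round(e, 6)))
           }),
           predictive_quantiles = as.list(round(ppc, 4))),
      file.path(target, paste0(p, "_abc.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fits[[p]] <- fit
  }
  write_run_log(out_dir, "model-choice",
                list(fasta = fasta_paths, map = map_path, n_sims = n_sims,
                     tolerance = tolerance, seed = seed,
                     populations = populations))
  invisible(fits)
}

#' Pairwise isolation-with-migration fit with time conversion
#'
#' Fits the two-population IM model by ABC for one population pair and
#' writes a JSON report with mutation-scaled and year-converted divergence
#' time estimates (mode and 95% HPD).
#'
#' @param fasta_paths,map_path input data.
#' @param out_dir output directory.
#' @param pair character vector of exactly two population ids.
#' @param mu mutation rate per locus per year (required for the year
#'   conversion).
#' @param theta_ref reference per-locus theta converting coalescent-unit
#'   split times to mutation-scaled times (t_mut = t_coal * theta_ref);
#'   defaults to the posterior mode of theta1.
#' @param prior,n_sims,tolerance see [fit_im2()].
#' @param seed RNG seed.
#' @param force overwrite existing outputs.
#' @return invisibly, the `im2_fit`.
#' @export
run_im <- function(fasta_paths, map_path, out_dir, pair, mu,
                   theta_ref = NULL, prior = default_model_priors()$IM2,
                   n_sims = 10000, tolerance = 0.005, seed = NULL,
                   force = FALSE) {
  if (length(pair) != 2L) stop_input("pair must name exactly 2 populations")
  if (missing(mu) || is.null(mu)) {
    stop_input("config error: mutation rate mu is required for run_im")
  }
  target <- prepare_outdir(out_dir, "im", force)
  if (!is.null(seed)) set.seed(seed)
  study <- read_study(fasta_paths, map_path)
  keep_samples <- names(study$map$assignments)[
    study$map$assignments %in% pair]
  mats <- lapply(study$alignments, function(a) {
    keep <- vapply(a$haplotypes, function(h) h$label %in% keep_samples,
                   logical(1))
    labs <- vapply(a$haplotypes[keep], `[[`, character(1), "label")
    sub <- locus_alignment(
      a$locus_id, labels = labs,
      sequences = vapply(a$haplotypes[keep], `[[`, character(1),
                         "sequence"))
    m <- extract_site_matrix(sub)
    attr(m, "pop") <- ifelse(study$map$assignments[labs] == pair[1L], 1L, 2L)
    m
  })
  pop_vec <- attr(mats[[1L]], "pop")
  design <- list(n = c(sum(pop_vec == 1L), sum(pop_vec == 2L)),
                 loci = data.frame(
                   locus_id = names(mats),
                   L = vapply(mats, `[[`, numeric(1), "L")))
  fit <- fit_im2(mats, design, prior = prior, n_sims = n_sims,
                 tolerance = tolerance)
  est <- fit$estimates$IM2
  if (is.null(est)) {
    stop_input("too few accepted draws for IM2 point estimates; ",
               "increase n_sims or tolerance")
  }
  theta_ref <- theta_ref %||% unname(est["theta1", "mode"])
  ts <- time_scale(mu, theta_ref = theta_ref)
  t_coal <- est["t_split", c("mode", "lo", "hi")]
  t_mut <- t_coal * theta_ref
  t_years <- years_from_scaled(t_mut, ts)
  report <- list(
    pair = pair, seed = seed, n_sims = n_sims, tolerance = tolerance,
    mu = mu, theta_ref = theta_ref,
    estimates = as.data.frame(cbind(parameter = rownames(est),
                                    round(est, 6))),
    t_split_coalescent = as.list(round(t_coal, 6)),
    t_split_mutation_scaled = as.list(round(t_mut, 6)),
    T_years = as.list(round(t_years, 1)),
    population_migration_2NM = if (is.null(fit$derived)) NULL else
      as.data.frame(cbind(direction = rownames(fit$derived),
                          round(fit$derived, 6))),
    zero_migration_mass = as.list(round(fit$zero_migration, 4)))
  jsonlite::write_json(report,
                       file.path(target,
                                 paste0(pair[1L], "_", pair[2L], "_im.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_log(out_dir, "im",
                list(fasta = fasta_paths, map = map_path, pair = pair,
                     mu = mu, n_sims = n_sims, tolerance = tolerance,
                     seed = seed))
  invisible(fit)
}
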