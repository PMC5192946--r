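#' Default island-study configuration
#'
#' A study-shaped design: 8 nuclear loci of 339-470 bp and 18 populations on
#' 8 islands with 14-16 phased haplotypes per population per locus, a
#' per-site theta of 0.004 under the standard neutral model for every
#' population, and one outgroup sequence per locus at 10x the within-species
#' diversity so polarization is unambiguous in expectation.
#'
#' @param theta_site per-site theta for every population.
#' @param model single-population demographic model for every population
#'   (per-population overrides can be edited into the returned list).
#' @return configuration list for [generate_island_study()].
#' @export
default_island_config <- function(theta_site = 0.004, model = "SNM") {
  loci <- data.frame(
    locus_id = paste0("locus", 1:8),
    L = c(461, 387, 387, 470, 407, 425, 464, 339))
  islands <- rep(paste0("island", 1:8), c(2, 1, 1, 1, 4, 5, 1, 3))
  n <- rep(16L, 18L)
  n[c(10L, 17L)] <- 14L  # two populations sampled at 14 haplotypes
  pops <- lapply(seq_len(18L), function(i) {
    list(island = islands[i], n = n[i], model = model,
         theta_site = theta_site, g = 0, t_b = 0, severity = 1)
  })
  names(pops) <- sprintf("pop%02d", seq_len(18L))
  list(loci = loci, populations = pops,
       outgroup_divergence = 10 * theta_site, n_outgroup = 1L,
       allow_mispolarization = FALSE)
}

pop_demography <- function(p, theta_locus) {
  demography(p$model, theta0 = theta_locus, g = p$g %||% 0,
             t_b = p$t_b %||% 0, severity = p$severity %||% 1)
}

random_reference <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         character(1))
}

#' Generate a study-shaped synthetic dataset
#'
#' Simulates every population independently under its configured demographic
#' model, threads the resulting site matrices onto a random per-locus
#' reference sequence (one substitution per segregating column at unique
#' alignment positions), adds outgroup sequences diverged from the ancestral
#' sequence, and writes the exact formats the readers consume: one FASTA per
#' locus, a population map TSV, and a truth-record JSON that fully
#' determines the dataset at the stored seed.
#'
#' @param config configuration from [default_island_config()] (possibly
#'   edited).
#' @param dir output directory (created).
#' @param seed master seed; stored in the truth record.
#' @return invisibly, a list with `fasta` (named file paths), `map` (path),
#'   `truth` (path), and `truth_record`.
#' @export
generate_island_study <- function(config = default_island_config(), dir,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- config$loci
  pops <- config$populations
  if (is.null(names(pops))) stop_input("config$populations must be named")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # per population x locus site matrices
  mats <- lapply(names(pops), function(pn) {
    p <- pops[[pn]]
    lapply(seq_len(nrow(loci)), function(l) {
      d <- pop_demography(p, p$theta_site * loci$L[l])
      g <- sample_genealogy(p$n, d)
      drop_mutations(g, d$theta0, L = loci$L[l])
    })
  })
  names(mats) <- names(pops)

  fasta_paths <- character(nrow(loci))
  names(fasta_paths) <- loci$locus_id
  for (l in seq_len(nrow(loci))) {
    L <- loci$L[l]
    ref <- strsplit(random_reference(L), "")[[1L]]
    available <- seq_len(L)
    labels <- character(0)
    seqs <- character(0)
    for (pn in names(pops)) {
      m <- mats[[pn]][[l]]
      if (m$S > length(available)) {
        stop_input("config error: locus ", loci$locus_id[l],
                   " too short for the simulated variation")
      }
      cols <- sort(sample(available, m$S))
      available <- setdiff(available, cols)
      derived <- other_base(ref[cols])
      for (i in seq_len(m$n)) {
        s <- ref
        hit <- m$mat[i, ] == 1L
        s[cols[hit]] <- derived[hit]
        seqs <- c(seqs, paste(s, collapse = ""))
      }
      labels <- c(labels, paste0(pn, "_h", seq_len(m$n)))
    }
    # outgroup: ancestral sequence mutated outside the segregating columns
    og <- character(config$n_outgroup %||% 1L)
    n_div <- rpois(1L, config$outgroup_divergence * L)
    pool <- if (isTRUE(config$allow_mispolarization)) seq_len(L) else available
    og_cols <- sample(pool, min(n_div, length(pool)))
    og_seq <- ref
    og_seq[og_cols] <- other_base(ref[og_cols])
    og[] <- paste(og_seq, collapse = "")
    aln <- locus_alignment(loci$locus_id[l], labels, seqs, outgroup = og)
    fasta_paths[l] <- file.path(dir, paste0(loci$locus_id[l], ".fa"))
    write_locus_fasta(aln, fasta_paths[l])
  }

  map_path <- file.path(dir, "population_map.tsv")
  map_df <- do.call(rbind, lapply(names(pops), function(pn) {
    data.frame(sample = paste0(pn, "_h", seq_len(pops[[pn]]$n)),
               population = pn, island = pops[[pn]]$island,
               stringsAsFactors = FALSE)
  }))
  write.table(map_df, map_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    seed = seed,
    loci = loci,
    populations = lapply(pops, function(p) {
      p[c("island", "n", "model", "theta_site", "g", "t_b", "severity")]
    }),
    outgroup_divergence = config$outgroup_divergence,
    manifest = c(unname(fasta_paths), map_path))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(fasta = fasta_paths, map = map_path, truth = truth_path,
                 truth_record = truth, matrices = mats))
}

#' Labeled model panel for recovery benchmarking
#'
#' Balanced panel of in-memory datasets with known generating model and
#' parameters, for model-choice benchmarking. Parameters are drawn from
#' well-separated regimes: exponential growth with clearly nonzero rates and
#' bottlenecks restricted to severe size reductions.
#'
#' @param design list with `n` and `loci` (see [build_reference_table()]).
#' @param n_each datasets per model.
#' @param models models to include.
#' @param priors per-model truth-generating priors; defaults to the
#'   inference priors with growth restricted to g in (5, 50) and severity to
#'   (0.02, 0.1).
#' @return list of items `list(model, params, matrices)`.
#' @export
generate_model_panel <- function(design, n_each = 25,
                                 models = c("SNM", "EXP", "BOT", "BOT_EXP"),
                                 priors = NULL) {
  if (is.null(priors)) {
    priors <- default_model_priors()
    for (m in intersect(c("EXP", "BOT_EXP"), models)) {
      priors[[m]]$g <- prior_uniform(5, 50)
    }
    for (m in intersect(c("BOT", "BOT_EXP"), models)) {
      priors[[m]]$severity <- prior_loguniform(0.02, 0.1)
    }
  }
  out <- list()
  for (m in models) {
    for (r in seq_len(n_each)) {
      par <- drop(sample_prior(priors[[m]], 1L))
      d <- demography_from_params(m, par)
      out[[length(out) + 1L]] <- list(
        model = m, params = par,
        matrices = simulate_dataset(d, design$n, design$loci))
    }
  }
  out
}
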