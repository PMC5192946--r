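#' Demographic model specification
#'
#' Bundles the parameters of one of the five demographic models driving the
#' coalescent simulator. Time is measured in units of 4*N0 generations and
#' theta = 4*N*mu is per locus (ms conventions).
#'
#' Models:
#' * `SNM` — standard neutral model of constant size `theta0`.
#' * `EXP` — exponential growth toward the present: looking backwards the
#'   relative size declines as `exp(-g * t)` from `theta0`.
#' * `BOT` — instantaneous size reduction (forward in time) at `t_b`:
#'   backwards, size jumps from `theta0` to the ancestral
#'   `theta0 / severity`, so `severity = theta0 / theta_A` < 1 means the
#'   present population is the smaller one.
#' * `BOT_EXP` — exponential growth since the reduction: backwards,
#'   `exp(-g*t)` until `t_b`, then the constant ancestral size.
#' * `IM2` — two populations of sizes `theta1` (the reference, so
#'   `theta0 = theta1`), `theta2`, splitting from an ancestor of size
#'   `thetaA` at `t_split`, with per-lineage (backwards) migration rates
#'   `m12` (deme 1 to 2) and `m21`, scaled as 4*N0*M.
#'
#' @param model one of `"SNM"`, `"EXP"`, `"BOT"`, `"BOT_EXP"`, `"IM2"`.
#' @param theta0 present-day per-locus population mutation parameter
#'   (reference size for the time scale). For IM2 it is taken from `theta1`.
#' @param g exponential rate per 4*N0 generations (EXP, BOT_EXP).
#' @param t_b size-change time in 4*N0 units (BOT, BOT_EXP).
#' @param severity ratio theta0 / theta_ancestral at `t_b` (BOT, BOT_EXP).
#' @param theta1,theta2,thetaA,t_split,m12,m21 IM2 block, see above.
#' @return an object of class `demography`.
#' @export
demography <- function(model = c("SNM", "EXP", "BOT", "BOT_EXP", "IM2"),
                       theta0 = NULL, g = 0, t_b = 0, severity = 1,
                       theta1 = NULL, theta2 = NULL, thetaA = NULL,
                       t_split = NULL, m12 = 0, m21 = 0) {
  model <- match.arg(model)
  if (model == "IM2") {
    for (nm in c("theta1", "theta2", "thetaA", "t_split")) {
      if (is.null(get(nm))) stop_input("IM2 requires ", nm)
    }
    if (theta1 <= 0 || theta2 <= 0 || thetaA <= 0) {
      stop_input("all IM2 theta parameters must be > 0")
    }
    if (t_split < 0 || m12 < 0 || m21 < 0) {
      stop_input("t_split and migration rates must be >= 0")
    }
    theta0 <- theta1
  } else {
    if (is.null(theta0) || theta0 <= 0) stop_input("theta0 must be > 0")
    if (model %in% c("BOT", "BOT_EXP")) {
      if (t_b < 0) stop_input("t_b must be >= 0")
      if (severity <= 0) stop_input("severity must be > 0")
    }
    if (model %in% c("EXP", "BOT_EXP") && g < 0) {
      stop_input("g must be >= 0 (growth toward the present)")
    }
  }
  structure(
    list(model = model, theta0 = theta0, g = g, t_b = t_b,
         severity = severity, theta1 = theta1, theta2 = theta2,
         thetaA = thetaA, t_split = t_split, m12 = m12, m21 = m21),
    class = "demography"
  )
}

#' @export
print.demography <- function(x, ...) {
  cat("demography:", x$model, "\n")
  p <- switch(x$model,
    SNM = c(theta0 = x$theta0),
    EXP = c(theta0 = x$theta0, g = x$g),
    BOT = c(theta0 = x$theta0, t_b = x$t_b, severity = x$severity),
    BOT_EXP = c(theta0 = x$theta0, g = x$g, t_b = x$t_b,
                severity = x$severity),
    IM2 = c(theta1 = x$theta1, theta2 = x$theta2, thetaA = x$thetaA,
            t_split = x$t_split, m12 = x$m12, m21 = x$m21))
  print(round(p, 6))
  invisible(x)
}

model_code <- function(model) {
  match(model, c("SNM", "EXP", "BOT", "BOT_EXP", "IM2")) - 1L
}

#' Sample one coalescent genealogy
#'
#' Simulates a genealogy of `sum(n)` lineages under a demographic model.
#' Coalescence among k lineages in a deme of relative size rho occurs at
#' total rate `k*(k-1)/rho` per unit of 4*N0 generations, so for n = 2 under
#' the standard neutral model the expected TMRCA is 0.5.
#'
#' @param n number of sampled haplotypes; for IM2 a length-2 vector
#'   `c(n1, n2)`.
#' @param d a [demography()] object.
#' @return an object of class `genealogy`: parent pointers over `2n-1` nodes
#'   (0-based, root = -1), node times in 4*N0 units, `total_length` and
#'   `tmrca`.
#' @export
sample_genealogy <- function(n, d) {
  stopifnot(inherits(d, "demography"))
  if (d$model == "IM2") {
    if (length(n) != 2L) stop_input("IM2 needs n = c(n1, n2)")
    n1 <- as.integer(n[1]); n2 <- as.integer(n[2])
  } else {
    if (length(n) != 1L) stop_input("single-population models need scalar n")
    n1 <- as.integer(n); n2 <- 0L
  }
  if (n1 + n2 < 2L) stop_input("need at least 2 sampled lineages")
  res <- sim_genealogy_cpp(
    n1, n2, model_code(d$model), d$g, d$t_b, d$severity,
    rho2 = if (d$model == "IM2") d$theta2 / d$theta1 else 1,
    rhoA = if (d$model == "IM2") d$thetaA / d$theta1 else 1,
    t_split = d$t_split %||% 0, m12 = d$m12, m21 = d$m21)
  res$pop <- if (d$model == "IM2") rep(1:2, c(n1, n2)) else rep(1L, n1)
  class(res) <- "genealogy"
  res
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy:", x$n, "leaves, TMRCA =", signif(x$tmrca, 4),
      ", total length =", signif(x$total_length, 4), "(4N0 units)\n")
  invisible(x)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Mutation count is Poisson with mean `theta * total_length` (or exactly
#' `fixed_s` when given); each mutation falls on a branch with probability
#' proportional to its length and receives a unique position in (0,1). The
#' returned matrix is polarized: 1 is the derived allele.
#'
#' @param g a [sample_genealogy()] result.
#' @param theta per-locus population mutation parameter.
#' @param L analyzed length in bp carried along for per-site statistics.
#' @param fixed_s optionally condition on exactly this many segregating
#'   sites instead of drawing from the Poisson.
#' @return a [site_matrix()].
#' @export
drop_mutations <- function(g, theta, L = 1, fixed_s = NULL) {
  stopifnot(inherits(g, "genealogy"))
  if (is.null(fixed_s)) {
    if (theta <= 0) stop_input("theta must be > 0")
    fs <- -1L
  } else {
    fs <- as.integer(fixed_s)
    if (fs < 0) stop_input("fixed_s must be >= 0")
  }
  res <- drop_mutations_cpp(g$parent, g$time, g$n, theta, fs)
  site_matrix(res$matrix, res$positions, L = L, polarized = TRUE)
}

#' Simulate a multilocus dataset under one demographic model
#'
#' One independent genealogy per locus; the per-locus mutation parameter is
#' `d$theta0 * theta_scale`, with `theta_scale` defaulting to length
#' proportionality (`L / mean(L)`).
#'
#' @param d a [demography()] object.
#' @param n sampled haplotypes (length-2 for IM2).
#' @param loci data.frame with columns `locus_id`, `L`, and optionally
#'   `theta_scale`.
#' @return named list of [site_matrix()] objects, one per locus. For IM2
#'   each carries a `pop` attribute giving the deme of every row.
#' @export
simulate_dataset <- function(d, n, loci) {
  stopifnot(is.data.frame(loci), nrow(loci) >= 1L,
            all(c("locus_id", "L") %in% names(loci)))
  scale <- loci$theta_scale %||% (loci$L / mean(loci$L))
  out <- vector("list", nrow(loci))
  names(out) <- loci$locus_id
  for (i in seq_len(nrow(loci))) {
    gen <- sample_genealogy(n, d)
    m <- drop_mutations(gen, d$theta0 * scale[i], L = loci$L[i])
    if (d$model == "IM2") attr(m, "pop") <- gen$pop
    out[[i]] <- m
  }
  out
}

#' Write simulated loci in ms output format
#'
#' Emits the `//` / `segsites:` / `positions:` blocks of Hudson's ms so
#' simulations can be cross-checked against external coalescent tooling.
#'
#' @param matrices list of [site_matrix()] objects.
#' @param path output file.
#' @param cmd header line to print (defaults to a package tag).
#' @export
write_ms <- function(matrices, path, cmd = "coaldemog") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(cmd, ""), con)
  for (m in matrices) {
    writeLines("//", con)
    writeLines(paste("segsites:", m$S), con)
    if (m$S > 0L) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", m$positions), collapse = " ")),
                 con)
      writeLines(apply(m$mat, 1L, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
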