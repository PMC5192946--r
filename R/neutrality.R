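empirical_p <- function(null, obs, tail) {
  nr <- length(null)
  p_le <- (1 + sum(null <= obs)) / (nr + 1)
  p_ge <- (1 + sum(null >= obs)) / (nr + 1)
  switch(tail,
         low = p_le,
         high = p_ge,
         two = min(1, 2 * min(p_le, p_ge)))
}

# null (pi_total, theta_H) replicates under the standard neutral model,
# conditioned on exactly S segregating sites (fixed-S convention) or on a
# fixed theta with monomorphic replicates discarded
neutral_null <- function(n, S, n_reps, mode, theta) {
  if (mode == "fixed_s") {
    return(fixed_s_null_cpp(n, S, n_reps))
  }
  if (is.null(theta) || theta <= 0) {
    stop_input("fixed-theta mode requires theta > 0")
  }
  out <- matrix(NA_real_, n_reps, 3L)
  r <- 0L
  while (r < n_reps) {
    g <- sim_genealogy_cpp(n, 0L, 0L, 0, 0, 1, 1, 1, 0, 0, 0)
    dm <- drop_mutations_cpp(g$parent, g$time, n, theta, -1L)
    S_r <- ncol(dm$matrix)
    if (S_r == 0L) next
    counts <- colSums(dm$matrix)
    r <- r + 1L
    out[r, ] <- c(sum(2 * counts * (n - counts)),
                  sum(2 * counts^2), S_r)
  }
  cbind(out[, 1L] / (n * (n - 1)), out[, 2L] / (n * (n - 1)), out[, 3L])
}

#' Simulation p-value for Tajima's D
#'
#' Null distribution from standard-neutral coalescent simulations
#' conditioned on the observed number of segregating sites (fixed-S
#' convention; a fixed-theta mode is available). Two-tailed empirical
#' p-value `2 * min(P(<= obs), P(>= obs))` capped at 1, with the add-one
#' correction `(1 + count) / (n_reps + 1)`.
#'
#' @param observed_d observed Tajima's D.
#' @param n number of haplotypes.
#' @param S observed segregating sites (>= 1).
#' @param n_reps number of coalescent simulations.
#' @param mode `"fixed_s"` (default) or `"fixed_theta"`.
#' @param theta per-locus theta for fixed-theta mode.
#' @return an object of class `htest`.
#' @export
tajima_d_test <- function(observed_d, n, S, n_reps = 10000,
                          mode = c("fixed_s", "fixed_theta"), theta = NULL) {
  mode <- match.arg(mode)
  if (S < 1L) stop_input("Tajima's D is undefined at S = 0")
  if (is.na(observed_d)) stop_input("observed D is undefined")
  if (n_reps < 1000L) stop_input("n_reps must be >= 1000")
  null <- neutral_null(n, S, n_reps, mode, theta)
  d_null <- if (mode == "fixed_s") {
    tajima_d_from(null[, 1L], S, n)
  } else {
    cc <- tajima_constants(n)
    (null[, 1L] - null[, 3L] / cc$a1) /
      sqrt(cc$e1 * null[, 3L] + cc$e2 * null[, 3L] * (null[, 3L] - 1))
  }
  structure(
    list(statistic = c(D = observed_d),
         parameter = c(n = n, S = S, n_reps = n_reps),
         p.value = empirical_p(d_null, observed_d, "two"),
         method = paste0("Tajima's D coalescent test (",
                         sub("_", "-", mode), ", two-tailed)"),
         data.name = sprintf("n = %d haplotypes, S = %d", n, S)),
    class = "htest"
  )
}

#' Simulation p-value for Fay and Wu's H
#'
#' Null distribution from standard-neutral fixed-S simulations with
#' perfectly known ancestral states; one-tailed toward low H (the excess of
#' high-frequency derived alleles the statistic targets) by default,
#' two-tailed by flag. Default replicate count is 10,000 simulations.
#'
#' @param observed_h observed unnormalized H (requires outgroup-polarized
#'   data; an NA observed value is an input error).
#' @param n number of haplotypes.
#' @param S observed segregating sites (>= 1).
#' @param n_reps number of coalescent simulations.
#' @param tail `"low"` (default) or `"two"`.
#' @return an object of class `htest`.
#' @export
fay_wu_h_test <- function(observed_h, n, S, n_reps = 10000,
                          tail = c("low", "two")) {
  tail <- match.arg(tail)
  if (S < 1L) stop_input("Fay and Wu's H test is undefined at S = 0")
  if (is.na(observed_h)) {
    stop_input("observed H is undefined: input data are not polarized")
  }
  if (n_reps < 1000L) stop_input("n_reps must be >= 1000")
  null <- fixed_s_null_cpp(n, S, n_reps)
  h_null <- null[, 1L] - null[, 2L]
  structure(
    list(statistic = c(H = observed_h),
         parameter = c(n = n, S = S, n_reps = n_reps),
         p.value = empirical_p(h_null, observed_h, tail),
         method = paste0("Fay and Wu's H coalescent test (fixed-S, ",
                         if (tail == "low") "one-tailed low" else "two-tailed",
                         ")"),
         data.name = sprintf("n = %d haplotypes, S = %d", n, S)),
    class = "htest"
  )
}

hka_moments <- function(input, T_div, f, variant) {
  aA <- vapply(input$n_A, harmonic_a, numeric(1))
  bA <- vapply(input$n_A, harmonic_b, numeric(1))
  if (variant == "two_species") {
    aB <- vapply(input$n_B, harmonic_a, numeric(1))
    bB <- vapply(input$n_B, harmonic_b, numeric(1))
    tot <- input$S_A + input$S_B + input$D_AB
    denom <- aA + f * aB + T_div + (1 + f) / 2
  } else {
    aB <- bB <- rep(0, nrow(input))
    tot <- input$S_A + input$D_AB
    denom <- aA + T_div + 1
  }
  theta <- tot / denom
  list(theta = theta, aA = aA, bA = bA, aB = aB, bB = bB)
}

#' Multilocus HKA test
#'
#' Hudson-Kreitman-Aguade (1987) goodness-of-fit test of proportionality
#' between within-species polymorphism and between-species divergence across
#' loci. Per-locus thetas, the scaled divergence time T (in 2N generations)
#' and, in the two-species variant, the population-size ratio f are obtained
#' from the moment equations (per-locus totals plus polymorphism column
#' sums); the statistic is `X^2 = sum (obs - exp)^2 / var` over all cells
#' with the 1987 variance formulas including the theta^2 terms. Degrees of
#' freedom: `L - 1` (one species) or `2L - 2` (two species); p from the
#' chi-squared distribution.
#'
#' @param input data.frame with columns `locus`, `L`, `S_A`, `n_A`,
#'   `D_AB`, and for the two-species variant also `S_B`, `n_B`.
#' @param variant `"two_species"` (default) or `"one_species"`.
#' @return an object of class `htest` with the fitted `T`, `f` and
#'   per-locus thetas attached.
#' @export
hka_test <- function(input, variant = c("two_species", "one_species")) {
  variant <- match.arg(variant)
  input <- as.data.frame(input)
  L <- nrow(input)
  if (L < 2L) stop_input("HKA test needs at least 2 loci")
  need <- c("S_A", "n_A", "D_AB")
  if (variant == "two_species") need <- c(need, "S_B", "n_B")
  if (!all(need %in% names(input))) {
    stop_input("HKA input needs columns: ", paste(need, collapse = ", "))
  }
  if (any(input$S_A < 0) || any(input$D_AB < 0)) {
    stop_input("counts must be >= 0")
  }
  SA_tot <- sum(input$S_A)
  if (SA_tot == 0) stop_input("no polymorphism in species A; theta not estimable")

  if (variant == "one_species") {
    g <- function(T_div) {
      mm <- hka_moments(input, T_div, 1, variant)
      sum(mm$theta * mm$aA) - SA_tot
    }
    # g is decreasing in T; bracket then root-find to tolerance 1e-10
    hi <- 1
    while (g(hi) > 0 && hi < 1e9) hi <- hi * 10
    T_hat <- if (g(1e-12) <= 0) 0 else
      uniroot(g, c(1e-12, hi), tol = 1e-10)$root
    f_hat <- 1
  } else {
    SB_tot <- sum(input$S_B)
    if (SB_tot == 0) stop_input("no polymorphism in species B; f not estimable")
    resid <- function(x) {
      T_div <- exp(x[1L]); f <- exp(x[2L])
      mm <- hka_moments(input, T_div, f, variant)
      c(sum(mm$theta * mm$aA) - SA_tot,
        sum(mm$theta * f * mm$aB) - SB_tot)
    }
    obj <- function(x) sum(resid(x)^2)
    fit <- nlminb(c(0, 0), obj, control = list(abs.tol = 1e-20,
                                               rel.tol = 1e-14,
                                               iter.max = 500))
    # polish from a second start if needed
    if (sqrt(fit$objective) > 1e-6 * (SA_tot + SB_tot)) {
      fit2 <- nlminb(c(log(1 + sum(input$D_AB) / SA_tot), log(SB_tot / SA_tot)),
                     obj, control = list(abs.tol = 1e-20, rel.tol = 1e-14,
                                         iter.max = 500))
      if (fit2$objective < fit$objective) fit <- fit2
    }
    if (sqrt(fit$objective) > 1e-6 * (SA_tot + SB_tot)) {
      stop_input("HKA moment solver did not converge; residual norm = ",
                 signif(sqrt(fit$objective), 4))
    }
    T_hat <- exp(fit$par[1L]); f_hat <- exp(fit$par[2L])
  }

  mm <- hka_moments(input, T_hat, f_hat, variant)
  theta <- mm$theta
  e_SA <- theta * mm$aA
  v_SA <- e_SA + theta^2 * mm$bA
  if (variant == "two_species") {
    e_D <- theta * (T_hat + (1 + f_hat) / 2)
    v_D <- e_D + (theta * (1 + f_hat) / 2)^2
    e_SB <- theta * f_hat * mm$aB
    v_SB <- e_SB + (theta * f_hat)^2 * mm$bB
    x2 <- sum((input$S_A - e_SA)^2 / v_SA) +
      sum((input$S_B - e_SB)^2 / v_SB) +
      sum((input$D_AB - e_D)^2 / v_D)
    df <- 2L * L - 2L
  } else {
    e_D <- theta * (T_hat + 1)
    v_D <- e_D + theta^2
    x2 <- sum((input$S_A - e_SA)^2 / v_SA) +
      sum((input$D_AB - e_D)^2 / v_D)
    df <- L - 1L
  }
  structure(
    list(statistic = c(`X-squared` = x2),
         parameter = c(df = df),
         p.value = pchisq(x2, df, lower.tail = FALSE),
         estimate = c(T = T_hat, f = f_hat),
         theta = setNames(theta, input$locus),
         method = paste0("HKA test (", sub("_", " ", variant), ")"),
         data.name = paste(L, "loci")),
    class = "htest"
  )
}

#' Read an HKA input table
#'
#' TSV with header columns `locus`, `L`, `S_A`, `n_A`, `S_B`, `n_B`,
#' `D_AB` (species-B columns optional for the one-species variant).
#'
#' @param path TSV file.
#' @return data.frame suitable for [hka_test()].
#' @export
read_hka_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Simulate data under the HKA null model
#'
#' Generates per-locus polymorphism counts from standard-neutral coalescent
#' genealogies and divergence counts from the Poisson-exponential mixture
#' implied by the model (shared divergence time T in 2N generations,
#' locus-specific thetas, size ratio f), for calibration studies of
#' [hka_test()].
#'
#' @param theta per-locus thetas.
#' @param T_div divergence time in 2N generations.
#' @param f population-size ratio (species B / species A).
#' @param n_A,n_B sample sizes (scalars or per-locus vectors).
#' @param variant `"two_species"` or `"one_species"`.
#' @return data.frame suitable for [hka_test()].
#' @export
simulate_hka_data <- function(theta, T_div, f = 1, n_A = 16, n_B = 16,
                              variant = c("two_species", "one_species")) {
  variant <- match.arg(variant)
  L <- length(theta)
  n_A <- rep_len(n_A, L)
  n_B <- rep_len(n_B, L)
  S_A <- S_B <- D_AB <- numeric(L)
  for (i in seq_len(L)) {
    S_A[i] <- sim_s_tmrca_cpp(n_A[i], 0L, 0, 0, 1, theta[i], 1L)[1L, 1L]
    anc <- if (variant == "two_species") (1 + f) / 2 else 1
    D_AB[i] <- rpois(1L, theta[i] * T_div +
                       theta[i] * anc * stats::rexp(1L))
    if (variant == "two_species") {
      S_B[i] <- sim_s_tmrca_cpp(n_B[i], 0L, 0, 0, 1,
                                theta[i] * f, 1L)[1L, 1L]
    }
  }
  out <- data.frame(locus = paste0("L", seq_len(L)), L = NA_integer_,
                    S_A = S_A, n_A = n_A, D_AB = D_AB)
  if (variant == "two_species") {
    out$S_B <- S_B
    out$n_B <- n_B
  }
  out
}
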