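#' Number of segregating sites
#'
#' @param m a [site_matrix()].
#' @return integer count S.
#' @export
segregating_sites <- function(m) {
  stopifnot(is_site_matrix(m))
  m$S
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences over all unordered haplotype pairs
#' (Nei's per-locus k-bar), and its per-site value k-bar / L.
#'
#' @param m a [site_matrix()].
#' @return list with `pi_total` and `pi_site`.
#' @export
pairwise_diversity <- function(m) {
  stopifnot(is_site_matrix(m))
  if (m$n < 2L) stop_input("pi needs at least 2 haplotypes")
  pi_total <- pi_total_from_counts(colSums(m$mat), m$n)
  list(pi_total = pi_total, pi_site = pi_total / m$L)
}

# k-bar from per-column derived/alternate allele counts
pi_total_from_counts <- function(counts, n) {
  if (length(counts) == 0L) return(0)
  sum(2 * counts * (n - counts)) / (n * (n - 1))
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a_n * L)` with `a_n = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites.
#' @param n number of haplotypes.
#' @param L analyzed length in bp.
#' @return theta_W per site.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2L) stop_input("Watterson's theta needs n >= 2")
  if (L < 1) stop_input("L must be >= 1")
  S / (harmonic_a(n) * L)
}

# Tajima (1989) variance constants
tajima_constants <- function(n) {
  a1 <- harmonic_a(n)
  a2 <- harmonic_b(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_from <- function(k_bar, S, n) {
  if (S < 1L) return(NA_real_)
  cc <- tajima_constants(n)
  (k_bar - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Standardized difference between the pairwise-diversity and
#' segregating-sites estimators of theta, with the Tajima (1989) variance
#' constants. Undefined (NA) when S = 0; never reported as 0 in that case.
#'
#' @param m a [site_matrix()].
#' @return D, or NA when S = 0.
#' @export
tajimas_d <- function(m) {
  stopifnot(is_site_matrix(m))
  tajima_d_from(pairwise_diversity(m)$pi_total, m$S, m$n)
}

#' Fay and Wu's H (unnormalized)
#'
#' `H = theta_pi - theta_H` computed over the polarized columns only, with
#' `theta_H = sum_i 2 * S_i * i^2 / (n (n-1))` where `S_i` counts sites whose
#' derived allele is carried by i haplotypes. Columns lacking outgroup
#' polarity are excluded (their number is attached as attribute
#' `n_unpolarized`); with no polarized column the statistic is undefined.
#'
#' @param m a [site_matrix()].
#' @return per-locus H (0 when there is no segregating site; NA when no
#'   column is polarized).
#' @export
fay_wu_h <- function(m) {
  stopifnot(is_site_matrix(m))
  if (m$S == 0L) return(0)
  pol <- which(m$col_polarized)
  n_excl <- m$S - length(pol)
  if (length(pol) == 0L) {
    return(structure(NA_real_, n_unpolarized = n_excl))
  }
  counts <- colSums(m$mat[, pol, drop = FALSE])
  n <- m$n
  theta_pi <- sum(2 * counts * (n - counts)) / (n * (n - 1))
  theta_h <- sum(2 * counts^2) / (n * (n - 1))
  structure(theta_pi - theta_h, n_unpolarized = n_excl)
}

# logical S x S matrix: TRUE where a column pair shows all four gametes
four_gamete_incompatibility <- function(mat) {
  S <- ncol(mat)
  if (S < 2L) return(matrix(FALSE, S, S))
  m1 <- mat
  m0 <- 1L - mat
  n11 <- crossprod(m1) > 0
  n10 <- crossprod(m1, m0) > 0
  n01 <- crossprod(m0, m1) > 0
  n00 <- crossprod(m0) > 0
  inc <- n11 & n10 & n01 & n00
  diag(inc) <- FALSE
  inc
}

#' Minimum number of recombination events (R_M)
#'
#' Four-gamete test on all column pairs followed by the Hudson-Kaplan
#' interval reduction: R_M is the maximum number of pairwise-disjoint
#' incompatible intervals, found by the greedy right-endpoint scan.
#'
#' @param m a [site_matrix()].
#' @return list with `rm` and `incompatible` (2-column matrix of column
#'   index pairs failing the four-gamete test).
#' @export
min_recombination_rm <- function(m) {
  stopifnot(is_site_matrix(m))
  inc <- four_gamete_incompatibility(m$mat)
  idx <- which(inc & upper.tri(inc), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(rm = 0L, incompatible = idx))
  }
  ord <- order(idx[, 2L], idx[, 1L])
  idx <- idx[ord, , drop = FALSE]
  rm_count <- 0L
  last_right <- -1L
  for (r in seq_len(nrow(idx))) {
    if (idx[r, 1L] >= last_right) {
      rm_count <- rm_count + 1L
      last_right <- idx[r, 2L]
    }
  }
  list(rm = rm_count, incompatible = unname(idx))
}

#' Largest non-recombining block (bp)
#'
#' Longest contiguous alignment interval whose contained segregating sites
#' jointly pass all pairwise four-gamete tests. A block spanning columns
#' j..k is measured from the midpoint between columns j-1 and j to the
#' midpoint between k and k+1, clamped to the alignment bounds, so a locus
#' with no four-gamete violation returns the full alignment length.
#'
#' @param m a [site_matrix()].
#' @param alignment_length alignment length in bp (defaults to `m$L`).
#' @return block length in bp.
#' @export
largest_nonrecombining_block <- function(m, alignment_length = m$L) {
  stopifnot(is_site_matrix(m))
  S <- m$S
  if (S == 0L) return(alignment_length)
  pos <- m$positions
  fractional <- any(pos != floor(pos))
  if (fractional) pos <- pos * alignment_length
  inc <- four_gamete_incompatibility(m$mat)
  lo <- 1L
  best <- 0
  for (k in seq_len(S)) {
    if (k > 1L) {
      bad <- which(inc[seq_len(k - 1L), k])
      if (length(bad)) lo <- max(lo, max(bad) + 1L)
    }
    start <- if (lo == 1L) 0 else (pos[lo - 1L] + pos[lo]) / 2
    end <- if (k == S) alignment_length else (pos[k] + pos[k + 1L]) / 2
    best <- max(best, end - start)
  }
  min(best, alignment_length)
}

#' Number of distinct haplotypes
#'
#' @param m a [site_matrix()].
#' @return count of distinct rows (1 when S = 0).
#' @export
haplotype_count <- function(m) {
  stopifnot(is_site_matrix(m))
  if (m$S == 0L) return(1L)
  nrow(unique(m$mat))
}

#' Average pairwise divergence between two populations (Dxy)
#'
#' Mean number of per-site nucleotide differences over all between-population
#' haplotype pairs.
#'
#' @param m a [site_matrix()].
#' @param rows_a,rows_b row indices of the two populations; non-empty and
#'   disjoint.
#' @return list with `dxy_total` (mean pairwise differences per locus) and
#'   `dxy_site`.
#' @export
dxy <- function(m, rows_a, rows_b) {
  stopifnot(is_site_matrix(m))
  if (length(rows_a) == 0L || length(rows_b) == 0L) {
    stop_input("both row sets must be non-empty")
  }
  if (length(intersect(rows_a, rows_b))) {
    stop_input("row sets must be disjoint")
  }
  na <- length(rows_a)
  nb <- length(rows_b)
  if (m$S == 0L) return(list(dxy_total = 0, dxy_site = 0))
  ca <- colSums(m$mat[rows_a, , drop = FALSE])
  cb <- colSums(m$mat[rows_b, , drop = FALSE])
  total <- sum(ca * (nb - cb) + (na - ca) * cb)
  list(dxy_total = total / (na * nb), dxy_site = total / (na * nb) / m$L)
}

#' Per-locus summary statistics
#'
#' All Table-2-shaped statistics for one locus: S, haplotype count, pi,
#' Watterson's theta, Tajima's D, Fay and Wu's H, R_M and the largest
#' non-recombining block.
#'
#' @param m a [site_matrix()].
#' @param locus_id optional label.
#' @param alignment_length alignment length in bp for the block statistic
#'   (defaults to `m$L`).
#' @return one-row data.frame.
#' @export
locus_summary <- function(m, locus_id = "locus", alignment_length = m$L) {
  stopifnot(is_site_matrix(m))
  pd <- pairwise_diversity(m)
  h_val <- fay_wu_h(m)
  data.frame(
    locus = locus_id,
    L = m$L,
    block_bp = largest_nonrecombining_block(m, alignment_length),
    n = m$n,
    S = m$S,
    h = haplotype_count(m),
    rm = min_recombination_rm(m)$rm,
    pi_site = pd$pi_site,
    pi_total = pd$pi_total,
    theta_w_site = watterson_theta(m$S, m$n, m$L),
    tajima_d = tajimas_d(m),
    fay_wu_h = as.numeric(h_val),
    stringsAsFactors = FALSE
  )
}

#' Multilocus summary for one dataset
#'
#' Reduces a list of per-locus site matrices to the summary space used for
#' ABC: means and variances across loci of S, pi (per-locus totals),
#' Watterson's theta (per-locus total S / a_n), Tajima's D and the haplotype
#' count, plus the number of monomorphic loci. Undefined D values
#' (monomorphic loci) enter as 0, with the monomorphic count carrying the
#' information instead (dropping such loci would bias toward high-theta
#' parameter draws).
#'
#' @param matrices list of [site_matrix()] objects.
#' @return named numeric vector.
#' @export
dataset_summary <- function(matrices) {
  S <- vapply(matrices, segregating_sites, numeric(1))
  pi_t <- vapply(matrices, function(m) pairwise_diversity(m)$pi_total,
                 numeric(1))
  thw <- vapply(matrices, function(m) m$S / harmonic_a(m$n), numeric(1))
  D <- vapply(matrices, tajimas_d, numeric(1))
  D[is.na(D)] <- 0
  h <- vapply(matrices, haplotype_count, numeric(1))
  v <- function(x) if (length(x) > 1L) var(x) else 0
  c(mean_S = mean(S), var_S = v(S),
    mean_pi = mean(pi_t), var_pi = v(pi_t),
    mean_thw = mean(thw), var_thw = v(thw),
    mean_D = mean(D), var_D = v(D),
    mean_h = mean(h), var_h = v(h),
    n_mono = sum(S == 0L))
}

#' Two-population multilocus summary (IM analyses)
#'
#' Per-deme means across loci of S, pi, Tajima's D and haplotype count plus
#' the mean and variance across loci of per-locus Dxy totals.
#'
#' @param matrices list of [site_matrix()] objects whose rows carry a `pop`
#'   attribute (1/2), as produced by [simulate_dataset()] under IM2, or an
#'   explicit `pop` vector via the `pop` argument.
#' @param pop optional integer vector of deme labels for the rows.
#' @return named numeric vector.
#' @export
dataset_summary_im2 <- function(matrices, pop = NULL) {
  per_locus <- lapply(matrices, function(m) {
    p <- pop %||% attr(m, "pop")
    if (is.null(p)) stop_input("matrices must carry a pop attribute")
    r1 <- which(p == 1L)
    r2 <- which(p == 2L)
    sub <- function(rows) subset_site_matrix(m, rows)
    m1 <- sub(r1)
    m2 <- sub(r2)
    d1 <- tajimas_d(m1)
    d2 <- tajimas_d(m2)
    c(S1 = m1$S, pi1 = pairwise_diversity(m1)$pi_total,
      D1 = if (is.na(d1)) 0 else d1, h1 = haplotype_count(m1),
      S2 = m2$S, pi2 = pairwise_diversity(m2)$pi_total,
      D2 = if (is.na(d2)) 0 else d2, h2 = haplotype_count(m2),
      dxy = dxy(m, r1, r2)$dxy_total)
  })
  tab <- do.call(rbind, per_locus)
  out <- colMeans(tab)
  names(out) <- paste0("mean_", colnames(tab))
  c(out, var_dxy = if (nrow(tab) > 1L) var(tab[, "dxy"]) else 0)
}

# restrict a site matrix to a subset of rows, re-filtering segregation
subset_site_matrix <- function(m, rows) {
  sub <- m$mat[rows, , drop = FALSE]
  cs <- colSums(sub)
  keep <- cs > 0L & cs < length(rows)
  site_matrix(sub[, keep, drop = FALSE], m$positions[keep], L = m$L,
              sample_labels = m$sample_labels[rows],
              polarized = m$polarized,
              col_polarized = m$col_polarized[keep])
}

#' Per-population pooled summary
#'
#' Per-locus statistics for one population plus pooled pi, Watterson's theta
#' and Tajima's D computed on concatenated analyzed sites: total pairwise
#' differences over total L, total S over `a_n * total L`, and D from the
#' pooled totals. When the per-locus sample size varies, the population's
#' minimum n supplies the harmonic constants (exact whenever n is constant
#' across loci).
#'
#' @param alignments named list of `locus_alignment` objects.
#' @param pop_map a population map from [read_population_map()].
#' @param population_id population to summarize.
#' @param use_outgroup passed to [extract_site_matrix()].
#' @return list of class `population_summary` with `per_locus` (data.frame)
#'   and pooled `pi_site`, `theta_w_site`, `tajima_d`, `n`, `L_total`.
#' @export
population_summary <- function(alignments, pop_map, population_id,
                               use_outgroup = FALSE) {
  stopifnot(inherits(pop_map, "population_map"))
  samples <- names(pop_map$assignments)[pop_map$assignments == population_id]
  if (length(samples) == 0L) {
    stop_input("unknown population: ", population_id)
  }
  mats <- lapply(alignments, function(a) {
    keep <- vapply(a$haplotypes, function(h) h$label %in% samples,
                   logical(1))
    if (sum(keep) < 2L) return(NULL)
    sub <- locus_alignment(a$locus_id,
                           labels = vapply(a$haplotypes[keep],
                                           `[[`, character(1), "label"),
                           sequences = vapply(a$haplotypes[keep],
                                              `[[`, character(1), "sequence"),
                           outgroup = a$outgroup)
    extract_site_matrix(sub, use_outgroup = use_outgroup)
  })
  mats <- Filter(Negate(is.null), mats)
  if (length(mats) == 0L) {
    stop_input("population ", population_id,
               " has fewer than 2 haplotypes at every locus")
  }
  per_locus <- do.call(rbind, Map(locus_summary, mats, names(mats)))
  n_min <- min(per_locus$n)
  S_tot <- sum(per_locus$S)
  L_tot <- sum(per_locus$L)
  k_tot <- sum(per_locus$pi_total)
  list_out <- list(
    population = population_id,
    per_locus = per_locus,
    n = n_min,
    L_total = L_tot,
    pi_site = k_tot / L_tot,
    theta_w_site = if (S_tot > 0) S_tot / (harmonic_a(n_min) * L_tot) else 0,
    tajima_d = tajima_d_from(k_tot, S_tot, n_min)
  )
  class(list_out) <- "population_summary"
  list_out
}

#' @export
print.population_summary <- function(x, ...) {
  cat("population", x$population, "- n =", x$n, ", total L =", x$L_total,
      "bp\n")
  cat(sprintf("  pooled pi = %.4f  theta_W = %.4f  Tajima's D = %s\n",
              x$pi_site, x$theta_w_site,
              ifelse(is.na(x$tajima_d), "undefined",
                     sprintf("%.3f", x$tajima_d))))
  invisible(x)
}
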