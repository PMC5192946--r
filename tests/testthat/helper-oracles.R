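# Independent oracles and small fixture builders used across the suite.

# site matrix from haplotype strings like c("0010", "0110"), optionally
# with explicit positions and analyzed length
sm <- function(rows, positions = NULL, L = NULL, ...) {
  mat <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  S <- ncol(mat)
  site_matrix(mat, positions %||% (seq_len(S) - 1), L = L %||% max(S, 1), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force minimum recombination count: maximum set of pairwise-disjoint
# incompatible intervals found by exhaustive dynamic programming
brute_force_rm <- function(mat) {
  S <- ncol(mat)
  if (S < 2L) return(0L)
  pairs <- list()
  for (i in seq_len(S - 1L)) {
    for (j in (i + 1L):S) {
      a <- mat[, i]
      b <- mat[, j]
      gam <- unique(paste0(a, b))
      if (all(c("00", "01", "10", "11") %in% gam)) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(pairs) == 0L) return(0L)
  iv <- do.call(rbind, pairs)
  iv <- iv[order(iv[, 2L], iv[, 1L]), , drop = FALSE]
  k <- nrow(iv)
  dp <- rep(1L, k)
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      if (j < i && iv[j, 2L] <= iv[i, 1L]) dp[i] <- max(dp[i], dp[j] + 1L)
    }
  }
  max(dp)
}

# brute-force shortest interval containing ceiling(level * n) sorted samples
brute_force_hpd <- function(x, level = 0.95) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(level * n)
  best <- c(s[1L], s[n])
  for (i in seq_len(n - m + 1L)) {
    if (s[i + m - 1L] - s[i] < best[2L] - best[1L]) {
      best <- c(s[i], s[i + m - 1L])
    }
  }
  best
}

# direct spreadsheet-style evaluation of Tajima's (1989) D from an explicit
# pair loop, independent of the package's vectorized implementation
direct_tajima_d <- function(mat) {
  n <- nrow(mat)
  S <- ncol(mat)
  k_bar <- 0
  np <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k_bar <- k_bar + sum(mat[i, ] != mat[j, ])
      np <- np + 1L
    }
  }
  k_bar <- k_bar / np
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# direct evaluation of unnormalized H = theta_pi - theta_H from derived
# allele counts
direct_fay_wu_h <- function(counts, n) {
  theta_pi <- sum(2 * counts * (n - counts)) / (n * (n - 1))
  theta_h <- sum(2 * counts^2) / (n * (n - 1))
  theta_pi - theta_h
}

# closed-form HKA moment solution for the equal-sample-size two-species
# case, derived independently of the package's numeric solver
closed_form_hka_fit <- function(input) {
  aA <- sum(1 / seq_len(input$n_A[1L] - 1))
  aB <- sum(1 / seq_len(input$n_B[1L] - 1))
  SA <- sum(input$S_A)
  SB <- sum(input$S_B)
  tot <- sum(input$S_A + input$S_B + input$D_AB)
  f <- SB * aA / (SA * aB)
  W <- SA / aA                       # = sum of theta_i
  T_div <- tot / W - aA - f * aB - (1 + f) / 2
  list(T = T_div, f = f)
}

# write a small FASTA fixture
write_fasta_fixture <- function(labels, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", labels, "\n", seqs), path)
  path
}

default_loci <- function() {
  data.frame(locus_id = paste0("L", 1:8),
             L = c(461, 387, 387, 470, 407, 425, 464, 339))
}
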