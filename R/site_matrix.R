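#' Haplotype-by-segregating-site matrix
#'
#' The common substrate of all summary statistics: a binary matrix with one
#' row per haplotype and one column per strictly segregating biallelic site.
#' `0` codes the reference (major or ancestral) allele and `1` the alternate
#' (or derived, when the column is polarized against an outgroup).
#'
#' @param mat integer 0/1 matrix, `n` haplotypes by `S` sites. Every column
#'   must contain at least one 0 and one 1.
#' @param positions column coordinates, strictly increasing. 0-based
#'   alignment indices for sequence-derived matrices; real numbers in (0,1)
#'   for simulated loci.
#' @param L analyzed length in bp (sites surviving filters); per-site
#'   statistics divide by `L`.
#' @param sample_labels optional row labels, unique, length `n`.
#' @param polarized logical: `TRUE` when every retained column is oriented so
#'   that 1 means the derived allele.
#' @param col_polarized optional logical vector (length `S`) flagging which
#'   individual columns carry outgroup-derived polarity; defaults to
#'   `rep(polarized, S)`.
#' @param n_multiallelic number of ingroup columns excluded because they
#'   carried more than two alleles (retained in `L`, reported separately).
#' @return an object of class `site_matrix` with fields `mat`, `positions`,
#'   `n`, `S`, `L`, `sample_labels`, `polarized`, `col_polarized`,
#'   `n_multiallelic`.
#' @export
site_matrix <- function(mat, positions, L, sample_labels = NULL,
                        polarized = FALSE, col_polarized = NULL,
                        n_multiallelic = 0L) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  n <- nrow(mat)
  S <- ncol(mat)
  if (n < 2L) stop_input("a site_matrix needs at least 2 haplotypes")
  if (length(positions) != S) {
    stop_input("positions must have one entry per matrix column")
  }
  if (S > 1L && any(diff(positions) <= 0)) {
    stop_input("positions must be strictly increasing")
  }
  if (S > 0L) {
    cs <- colSums(mat)
    if (any(cs == 0L) || any(cs == n)) {
      stop_input("every column must be strictly segregating (>=1 zero and >=1 one)")
    }
  }
  if (L < 1) stop_input("L must be a positive number of base pairs")
  integer_pos <- S == 0L || all(positions == floor(positions))
  if (integer_pos && L < S) {
    stop_input("analyzed length L cannot be smaller than the number of sites S")
  }
  if (is.null(sample_labels)) {
    sample_labels <- paste0("hap", seq_len(n))
  }
  if (anyDuplicated(sample_labels)) stop_input("sample labels must be unique")
  if (is.null(col_polarized)) col_polarized <- rep(isTRUE(polarized), S)
  structure(
    list(mat = mat, positions = as.numeric(positions), n = n, S = S,
         L = as.numeric(L), sample_labels = as.character(sample_labels),
         polarized = isTRUE(polarized) || (S > 0L && all(col_polarized)),
         col_polarized = as.logical(col_polarized),
         n_multiallelic = as.integer(n_multiallelic)),
    class = "site_matrix"
  )
}

#' @export
print.site_matrix <- function(x, ...) {
  cat("site_matrix:", x$n, "haplotypes x", x$S, "segregating sites,",
      "L =", x$L, "bp",
      if (x$polarized) "(polarized)" else "(unpolarized)", "\n")
  if (x$n_multiallelic > 0L) {
    cat("  multiallelic ingroup columns excluded:", x$n_multiallelic, "\n")
  }
  invisible(x)
}

is_site_matrix <- function(x) inherits(x, "site_matrix")
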