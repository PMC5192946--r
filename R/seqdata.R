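#' Phased haplotype alignment for one locus
#'
#' @param locus_id locus label.
#' @param labels haplotype sample labels, unique.
#' @param sequences character vector of aligned sequences over
#'   `{A,C,G,T,N,-}` (upper-cased on construction), equal lengths.
#' @param outgroup optional character vector of outgroup sequences of the
#'   same alignment length.
#' @return object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_id, labels, sequences, outgroup = NULL) {
  sequences <- toupper(sequences)
  if (!is.null(outgroup)) outgroup <- toupper(outgroup)
  if (length(labels) != length(sequences)) {
    stop_input("labels and sequences must have equal length")
  }
  if (length(sequences) < 2L) {
    stop_input("a locus alignment needs at least 2 ingroup haplotypes")
  }
  if (anyDuplicated(labels)) {
    stop_input("sample labels must be unique within a locus")
  }
  len <- unname(nchar(sequences[1L]))
  if (any(nchar(sequences) != len) ||
      (!is.null(outgroup) && any(nchar(outgroup) != len))) {
    stop_input("alignment error: sequences have unequal lengths in locus ",
               locus_id)
  }
  structure(
    list(locus_id = locus_id,
         haplotypes = Map(function(l, s) list(label = l, sequence = s),
                          as.character(labels), sequences),
         length = len,
         outgroup = outgroup),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment", x$locus_id, ":", length(x$haplotypes),
      "haplotypes x", x$length, "bp",
      if (length(x$outgroup)) paste0("(+", length(x$outgroup), " outgroup)")
      else "", "\n")
  invisible(x)
}

#' Read a per-locus FASTA alignment
#'
#' Records whose name starts with `OUTGROUP|` are collected as outgroup
#' sequences; everything else is an ingroup haplotype. Sequences are
#' upper-cased and record order is preserved.
#'
#' @param path FASTA file.
#' @param locus_id locus label; defaults to the file name without extension.
#' @return a [locus_alignment()].
#' @export
read_locus_fasta <- function(path, locus_id = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (length(dna) == 0L) stop_input("format error: empty FASTA file ", path)
  seqs <- toupper(vapply(as.character(dna), paste, character(1),
                         collapse = ""))
  labs <- names(dna)
  og <- grepl("^OUTGROUP\\|", labs)
  locus_alignment(
    locus_id %||% sub("\\.(fa|fasta|fna)$", "", basename(path),
                      ignore.case = TRUE),
    labels = labs[!og], sequences = seqs[!og],
    outgroup = if (any(og)) unname(seqs[og]) else NULL)
}

#' Write a per-locus FASTA alignment
#'
#' Inverse of [read_locus_fasta()]; outgroup records are prefixed
#' `OUTGROUP|`.
#'
#' @param a a [locus_alignment()].
#' @param path output file.
#' @export
write_locus_fasta <- function(a, path) {
  stopifnot(inherits(a, "locus_alignment"))
  labs <- vapply(a$haplotypes, `[[`, character(1), "label")
  seqs <- vapply(a$haplotypes, `[[`, character(1), "sequence")
  if (length(a$outgroup)) {
    labs <- c(labs, paste0("OUTGROUP|og", seq_along(a$outgroup)))
    seqs <- c(seqs, a$outgroup)
  }
  dna <- ape::as.DNAbin(lapply(setNames(seqs, labs),
                               function(s) strsplit(tolower(s), "")[[1L]]))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Three-column TSV (`sample`, `population`, `island`) with a header row.
#'
#' @param path TSV file.
#' @return object of class `population_map` with `assignments` (named
#'   vector sample -> population) and `islands` (named vector
#'   population -> island).
#' @export
read_population_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "island")
  if (!all(need %in% names(tab))) {
    stop_input("population map needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$sample)) {
    stop_input("duplicate sample rows in population map: ",
               paste(unique(tab$sample[duplicated(tab$sample)]),
                     collapse = ", "))
  }
  isl <- tapply(tab$island, tab$population, function(x) unique(x)[1L])
  structure(
    list(assignments = setNames(tab$population, tab$sample),
         islands = setNames(as.character(isl), names(isl))),
    class = "population_map"
  )
}

#' @export
print.population_map <- function(x, ...) {
  cat("population_map:", length(x$assignments), "samples,",
      length(x$islands), "populations,",
      length(unique(x$islands)), "islands\n")
  invisible(x)
}

#' Reconcile alignments with a population map
#'
#' Checks that every ingroup haplotype label in every alignment is present
#' in the map; unresolved labels raise an error that lists the offenders.
#'
#' @param alignments list of [locus_alignment()] objects.
#' @param map_path path to the population map TSV, or an already-read
#'   `population_map`.
#' @return list with `alignments` and `map`.
#' @export
attach_population_map <- function(alignments, map_path) {
  map <- if (inherits(map_path, "population_map")) map_path
         else read_population_map(map_path)
  labs <- unique(unlist(lapply(alignments, function(a) {
    vapply(a$haplotypes, `[[`, character(1), "label")
  })))
  missing <- setdiff(labs, names(map$assignments))
  if (length(missing)) {
    stop_input("haplotype labels absent from population map: ",
               paste(missing, collapse = ", "))
  }
  list(alignments = alignments, map = map)
}

#' Read a column mask
#'
#' BED-like 3-column TSV (`locus`, `start`, `end`; 0-based half-open) of
#' alignment columns to drop before analysis, e.g. mononucleotide-repeat
#' regions masked during upstream data preparation.
#'
#' @param path TSV file.
#' @return data.frame with columns `locus`, `start`, `end`.
#' @export
read_site_mask <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "start", "end")
  if (!all(need %in% names(tab))) {
    stop_input("site mask needs columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Reduce an alignment to a binary site matrix
#'
#' Filtering rules (complete deletion):
#' * masked columns and columns containing `-` or `N` in any ingroup
#'   sequence are removed entirely and do not count toward `L`;
#' * ingroup columns with more than two alleles are excluded from the
#'   matrix (infinite-sites statistics assume biallelic sites) but retained
#'   in `L` and counted in `n_multiallelic`;
#' * only strictly segregating biallelic ingroup columns enter the matrix.
#'
#' Coding: without an outgroup, 0 is the major allele (ties broken by the
#' allele of the first haplotype row). With `use_outgroup = TRUE`, a column
#' is polarized (0 = ancestral) only when all outgroup sequences agree,
#' carry no gap/N, and match one ingroup allele; otherwise the column stays
#' in the matrix under major-allele coding and is flagged unpolarized
#' (excluded from Fay and Wu's H but not from S, pi, theta_W or D).
#'
#' @param a a [locus_alignment()].
#' @param use_outgroup polarize columns against the outgroup.
#' @param mask optional mask data.frame from [read_site_mask()] (rows for
#'   other loci are ignored).
#' @return a [site_matrix()] with 0-based alignment positions.
#' @export
extract_site_matrix <- function(a, use_outgroup = FALSE, mask = NULL) {
  stopifnot(inherits(a, "locus_alignment"))
  if (use_outgroup && !length(a$outgroup)) {
    stop_input("use_outgroup = TRUE but alignment has no outgroup sequences")
  }
  seqs <- vapply(a$haplotypes, `[[`, character(1), "sequence")
  labs <- vapply(a$haplotypes, `[[`, character(1), "label")
  chars <- do.call(rbind, strsplit(seqs, ""))
  og <- if (length(a$outgroup)) do.call(rbind, strsplit(a$outgroup, ""))
        else NULL
  n <- nrow(chars)
  keep <- rep(TRUE, ncol(chars))
  if (!is.null(mask)) {
    mask <- mask[mask$locus == a$locus_id, , drop = FALSE]
    for (r in seq_len(nrow(mask))) {
      cols <- seq.int(mask$start[r] + 1L, mask$end[r])
      keep[cols[cols >= 1L & cols <= ncol(chars)]] <- FALSE
    }
  }
  has_missing <- apply(chars, 2L, function(col) any(col %in% c("-", "N")))
  keep <- keep & !has_missing
  cols <- which(keep)
  L <- length(cols)
  if (L == 0L) stop_input("no analyzable columns remain in locus ", a$locus_id)

  mat_cols <- list()
  positions <- integer(0)
  col_pol <- logical(0)
  n_multi <- 0L
  for (j in cols) {
    col <- chars[, j]
    alleles <- unique(col)
    if (length(alleles) == 1L) next
    if (length(alleles) > 2L) {
      n_multi <- n_multi + 1L
      next
    }
    zero_allele <- NA_character_
    polarized <- FALSE
    if (use_outgroup) {
      ogc <- og[, j]
      if (length(unique(ogc)) == 1L && !(ogc[1L] %in% c("-", "N")) &&
          ogc[1L] %in% alleles) {
        zero_allele <- ogc[1L]
        polarized <- TRUE
      }
    }
    if (!polarized) {
      counts <- c(sum(col == alleles[1L]), sum(col == alleles[2L]))
      zero_allele <- if (counts[1L] != counts[2L]) {
        alleles[which.max(counts)]
      } else {
        col[1L]  # tie: allele of the first haplotype row
      }
    }
    mat_cols[[length(mat_cols) + 1L]] <- as.integer(col != zero_allele)
    positions <- c(positions, j - 1L)  # 0-based alignment coordinate
    col_pol <- c(col_pol, polarized)
  }
  S <- length(mat_cols)
  mat <- if (S > 0L) do.call(cbind, mat_cols) else
    matrix(integer(0), nrow = n, ncol = 0L)
  site_matrix(mat, positions, L = L, sample_labels = labs,
              polarized = S > 0L && all(col_pol), col_polarized = col_pol,
              n_multiallelic = n_multi)
}
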