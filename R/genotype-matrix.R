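#' Construct a genotype matrix
#'
#' The central genotype container: a samples x markers matrix of biallelic
#' allele dosages (0, 1, 2 copies of the alternate allele, `NA` = missing)
#' together with a marker map giving chromosome, 1-based bp position and
#' ref/alt alleles per marker.
#'
#' @param dosage numeric matrix, samples in rows, markers in columns; entries
#'   in `{0, 1, 2, NA}`. Row names are sample ids, column names marker ids
#'   (generated if absent).
#' @param map data.frame with one row per marker and columns `marker_id`,
#'   `chrom`, `pos` (1-based bp), `ref`, `alt`. Positions must be strictly
#'   increasing within a chromosome.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (integer-valued matrix) and `map`.
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0, 1, 2, 1), 2, 2, dimnames = list(c("s1", "s2"), NULL)),
#'   data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G")
#' )
#' n_markers(g)
#' @export
genotype_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("sample_%03d", seq_len(nrow(dosage)))
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (is.null(map$marker_id)) {
    map$marker_id <- sprintf("snp_%05d", seq_len(nrow(map)))
  }
  if (is.null(map$ref)) map$ref <- "A"
  if (is.null(map$alt)) map$alt <- "G"
  map <- map[, c("marker_id", "chrom", "pos", "ref", "alt")]
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  rownames(map) <- NULL
  if (nrow(map) != ncol(dosage)) {
    stop("map has ", nrow(map), " markers but dosage has ", ncol(dosage),
         " columns")
  }
  colnames(dosage) <- map$marker_id
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(rownames(dosage))) stop("duplicate sample ids")
  if (anyDuplicated(map$marker_id)) stop("duplicate marker ids")
  if (any(!is.finite(map$pos)) || any(map$pos <= 0L)) {
    stop("marker positions must be positive integers")
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`
#' @export
n_markers <- function(g) ncol(g$dosage)

#' @rdname genotype_matrix
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(g) rownames(g$dosage)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`
#' @param i sample index (ids, logical or integer)
#' @param j marker index
#' @param ... ignored
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  d <- x$dosage[i, j, drop = FALSE]
  structure(list(dosage = d, map = x$map[j, , drop = FALSE]),
            class = "genotype_matrix")
}

#' Observed alternate-allele frequencies
#'
#' Computed on non-missing genotypes only: freq = mean(dosage) / 2 per marker.
#' Markers with no observed genotypes get `NA`.
#'
#' @param g a `genotype_matrix`
#' @param samples optional subset of sample ids or indices
#' @return numeric vector, one frequency per marker
#' @export
allele_freq <- function(g, samples = NULL) {
  d <- g$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Marker QC filter
#'
#' Drops markers failing a per-marker call-rate or minor-allele-frequency
#' threshold. MAF is computed on observed (non-missing) alleles. Filtering is
#' idempotent: applying the same thresholds twice changes nothing.
#'
#' @param g a `genotype_matrix`
#' @param min_call_rate markers with a lower fraction of non-missing genotypes
#'   are removed; in `[0, 1]`
#' @param min_maf markers with a lower minor allele frequency are removed; in
#'   `[0, 0.5]`
#' @return the filtered `genotype_matrix`, with an attribute `qc_report`
#'   (list: `n_in`, `n_removed_call_rate`, `n_removed_maf`, `n_out`)
#' @examples
#' g <- genotype_matrix(matrix(c(0, 0, 0, 1), 2),
#'                      data.frame(chrom = "1", pos = c(1L, 5L)))
#' qc_filter(g, min_maf = 0.3)
#' @export
qc_filter <- function(g, min_call_rate = 0, min_maf = 0) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  call_rate <- colMeans(!is.na(g$dosage))
  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  fail_cr <- call_rate < min_call_rate
  # markers with zero observed genotypes have undefined MAF; they only ever
  # fail the call-rate filter
  fail_maf <- !is.na(maf) & maf < min_maf & !fail_cr
  keep <- !(fail_cr | (!is.na(maf) & maf < min_maf))
  keep[is.na(maf) & !fail_cr] <- TRUE
  out <- g[, keep]
  attr(out, "qc_report") <- list(
    n_in = n_markers(g),
    n_removed_call_rate = sum(fail_cr),
    n_removed_maf = sum(fail_maf),
    n_out = n_markers(out)
  )
  out
}
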