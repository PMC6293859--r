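#' VanRaden realized genomic relationship matrix
#'
#' Computes the method-1 VanRaden GRM `K = W W' / (2 * sum_j p_j (1 - p_j))`
#' where `W` is the dosage matrix with column `j` centered by `2 p_j` and
#' `p_j` the observed alternate-allele frequency at marker `j`, estimated
#' from all samples pooled. Missing dosages are mean-imputed per marker
#' before centering. Monomorphic markers contribute nothing and are excluded
#' from both the numerator and the scaling denominator, so `K` is invariant
#' to adding them.
#'
#' @param g a [genotype_matrix]
#' @param tol eigenvalues below `-tol` raise an error; values in `(-tol, 0)`
#'   are accepted as numerical noise
#' @return list of class `grm` with elements `K` (n x n symmetric matrix with
#'   sample-id dimnames), `n_markers` (markers used), `freq` (frequencies
#'   used for centering)
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2), 3, 1,
#'                      dimnames = list(c("a", "b", "c"), NULL)),
#'                      data.frame(chrom = "1", pos = 1L))
#' vanraden_grm(g)$K
#' @export
vanraden_grm <- function(g, tol = 1e-8) {
  d <- g$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  # mean-impute missing dosages per marker
  if (anyNA(d)) {
    for (j in which(colSums(is.na(d)) > 0)) {
      d[is.na(d[, j]), j] <- 2 * p[j]
    }
  }
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("zero denominator: all markers are monomorphic")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(d, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  structure(list(K = K, n_markers = sum(poly), freq = p), class = "grm")
}

#' @method print grm
#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$K), "samples,", x$n_markers, "markers\n")
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.3f\n",
              mean(diag(x$K)),
              mean(x$K[upper.tri(x$K)])))
  invisible(x)
}

#' Genotype principal component analysis
#'
#' Eigendecomposition of the sample covariance of column-standardized
#' dosages (each marker centered by `2p` and scaled by `sqrt(2p(1-p))`),
#' which is the standard population-structure PCA and equals the
#' eigendecomposition of a scaled GRM. Missing dosages are mean-imputed;
#' monomorphic markers are dropped. Scores for component `k` are
#' `u_k * sqrt(lambda_k)`, so score variance reflects the eigenvalue.
#'
#' @param g a [genotype_matrix]
#' @param n_components number of leading components to return; truncated
#'   with a warning if it exceeds `n_samples - 1`
#' @return list of class `genotype_pca` with `scores` (n x k matrix),
#'   `eigenvalues` (length k, non-increasing) and `prop_var` (fraction of
#'   total variance per component)
#' @export
genotype_pca <- function(g, n_components = 2) {
  n <- n_samples(g)
  stopifnot(n >= 2)
  kmax <- n - 1L
  if (n_components > kmax) {
    warning("n_components truncated to n_samples - 1 = ", kmax)
    n_components <- kmax
  }
  d <- g$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  if (anyNA(d)) {
    for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * p[j]
  }
  poly <- !is.na(p) & p > 0 & p < 1
  scores <- matrix(0, n, n_components,
                   dimnames = list(sample_ids(g),
                                   paste0("PC", seq_len(n_components))))
  if (!any(poly)) {
    return(structure(list(scores = scores,
                          eigenvalues = rep(0, n_components),
                          prop_var = rep(0, n_components)),
                     class = "genotype_pca"))
  }
  Ws <- sweep(d[, poly, drop = FALSE], 2, 2 * p[poly])
  Ws <- sweep(Ws, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  B <- tcrossprod(Ws) / sum(poly)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  k <- n_components
  scores[, ] <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  structure(list(scores = scores,
                 eigenvalues = ev[seq_len(k)],
                 prop_var = if (sum(ev) > 0) ev[seq_len(k)] / sum(ev)
                            else rep(0, k)),
            class = "genotype_pca")
}

#' @method print genotype_pca
#' @export
print.genotype_pca <- function(x, ...) {
  cat("genotype_pca:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n")
  cat("  proportion of variance:",
      paste(sprintf("%.3f", x$prop_var), collapse = ", "), "\n")
  invisible(x)
}

#' Write a GRM or PCA scores to TSV
#'
#' @param x a `grm` or `genotype_pca`
#' @param path output TSV path
#' @param samples optional sample table; if given, PCA scores gain a `line`
#'   column
#' @return `path`, invisibly
#' @export
write_grm <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$K), x$K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
write_pca_scores <- function(x, path, samples = NULL) {
  df <- data.frame(sample_id = rownames(x$scores), x$scores,
                   check.names = FALSE)
  if (!is.null(samples)) {
    df$line <- samples$line[match(df$sample_id, samples$sample_id)]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
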