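#' Per-site Weir-Cockerham Fst between two groups
#'
#' Computes, for every SNP, the Weir & Cockerham (1984) variance components
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals, from observed heterozygosity), and the per-site
#' estimate `Fst = a / (a + b + c)`, between the selection and control
#' lines. Negative estimates are retained; sites where the denominator is
#' zero (e.g. both groups monomorphic for the same allele) have `fst = NA`
#' and are flagged `defined = FALSE`.
#'
#' @param g a [genotype_matrix]
#' @param samples sample table with `sample_id` and `line` columns; every
#'   genotyped sample must appear
#' @param group_col column of `samples` defining the two groups
#'   (default `"line"`)
#' @return data.frame of class `site_stats`, one row per marker: `marker_id`,
#'   `chrom`, `pos`, `a`, `d` (= a + b + c), `fst`, `defined`, per-group
#'   allele frequencies `p_<group>`, per-group per-site diversity
#'   `pi_<group>`
#' @examples
#' g <- genotype_matrix(matrix(c(2, 2, 0, 0), 4, 1,
#'        dimnames = list(paste0("s", 1:4), NULL)),
#'        data.frame(chrom = "1", pos = 1L))
#' s <- data.frame(sample_id = paste0("s", 1:4),
#'                 line = c("selection", "selection", "control", "control"))
#' wc_fst_site(g, s)$fst   # fixed difference: exactly 1
#' @export
wc_fst_site <- function(g, samples, group_col = "line") {
  grp <- samples[[group_col]][match(sample_ids(g), samples$sample_id)]
  if (anyNA(grp)) stop("samples table does not cover all genotyped samples")
  lev <- sort(unique(grp))
  if (length(lev) != 2) stop("exactly two non-empty groups are required")
  d1 <- g$dosage[grp == lev[1], , drop = FALSE]
  d2 <- g$dosage[grp == lev[2], , drop = FALSE]
  n1 <- colSums(!is.na(d1))
  n2 <- colSums(!is.na(d2))
  if (all(n1 == 0) || all(n2 == 0)) {
    stop("a group has zero genotyped samples at every site")
  }
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1, na.rm = TRUE)
  h2 <- colMeans(d2 == 1, na.rm = TRUE)

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  # sites unusable for the estimator: a group with no data, or n = 1
  usable <- n1 > 0 & n2 > 0 & nbar > 1
  defined <- usable & is.finite(denom) & abs(denom) > 1e-300 & denom != 0
  fst <- ifelse(defined, a / denom, NA_real_)
  a[!usable] <- NA_real_
  denom[!usable] <- NA_real_

  out <- data.frame(
    marker_id = g$map$marker_id, chrom = g$map$chrom, pos = g$map$pos,
    a = a, d = denom, fst = fst, defined = defined,
    stringsAsFactors = FALSE
  )
  out[[paste0("p_", lev[1])]] <- p1
  out[[paste0("p_", lev[2])]] <- p2
  out[[paste0("pi_", lev[1])]] <- pi_from_counts(round(2 * n1 * p1), 2 * n1)
  out[[paste0("pi_", lev[2])]] <- pi_from_counts(round(2 * n2 * p2), 2 * n2)
  class(out) <- c("site_stats", "data.frame")
  out
}

# pi from alternate-allele count k out of n observed alleles:
# 2 * k * (n - k) / (n * (n - 1)); 0 for monomorphic, NA when n < 2
pi_from_counts <- function(k, n) {
  ifelse(n >= 2, 2 * k * (n - k) / (n * (n - 1)), NA_real_)
}

#' Per-site nucleotide diversity
#'
#' For a biallelic site with observed allele counts `n_A` and `n_a`
#' (`n = n_A + n_a` sampled chromosomes), `pi = 2 n_A n_a / (n (n - 1))`:
#' the proportion of pairwise chromosome comparisons that differ.
#' Monomorphic sites give 0; sites with fewer than two observed alleles give
#' `NA`.
#'
#' @param g a [genotype_matrix]
#' @param samples optional subset of sample ids/indices to compute over
#' @return numeric vector of per-site pi
#' @examples
#' g <- genotype_matrix(matrix(c(2, 1, 0, 0), 2, 2,
#'        dimnames = list(c("a", "b"), NULL)),
#'        data.frame(chrom = "1", pos = c(1L, 2L)))
#' pi_site(g)   # 3 alt + 1 ref -> 0.5; monomorphic ref -> 0
#' @export
pi_site <- function(g, samples = NULL) {
  d <- g$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  n <- 2 * colSums(!is.na(d))
  k <- colSums(d, na.rm = TRUE)
  pi_from_counts(k, n)
}

#' Aggregate per-site statistics in non-overlapping windows
#'
#' Tiles each chromosome with half-open windows `[start, start + size)`
#' beginning at position 1 and aggregates the per-SNP statistics from
#' [wc_fst_site()]: unweighted mean Fst over defined sites, the ratio
#' estimate `weighted_fst = sum(a) / sum(a + b + c)`, the 95% quantile of
#' per-SNP Fst (linear interpolation between order statistics, R quantile
#' type 7), and per-line nucleotide diversity per bp
#' (`sum of per-site pi / window size`). Windows are flagged
#' `elevated_mean` when `mean_fst > mean_threshold` and `elevated_q95` when
#' `q95_fst > q95_threshold`.
#'
#' @param sites a `site_stats` data.frame from [wc_fst_site()]
#' @param window_size_bp window width in bp (> 0); 1 Mb is the usual choice
#'   for elevated-window calling, 2 Mb for diversity reporting and 100 kb
#'   for Manhattan-style export
#' @param mean_threshold flag threshold on the window mean Fst
#' @param q95_threshold flag threshold on the window 95% Fst quantile
#' @param chrom_lengths optional named vector of chromosome lengths; windows
#'   are tiled to at least the last marker position otherwise
#' @param q probability for the upper quantile column (default 0.95)
#' @return data.frame of class `window_stats`: `chrom`, `start`, `end`
#'   (half-open), `n_snps`, `mean_fst`, `weighted_fst`, `q95_fst`, one
#'   `pi_<group>_bp` column per line, `elevated_mean`, `elevated_q95`
#' @export
window_stats <- function(sites, window_size_bp = 1e6,
                         mean_threshold = 0.05, q95_threshold = 0.25,
                         chrom_lengths = NULL, q = 0.95) {
  stopifnot(window_size_bp > 0)
  pi_cols <- grep("^pi_", names(sites), value = TRUE)
  rows <- list()
  for (ch in unique(sites$chrom)) {
    sc <- sites[sites$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(sc$pos)
    }
    starts <- seq(1, len, by = window_size_bp)
    win_of <- (sc$pos - 1) %/% window_size_bp + 1
    for (w in seq_along(starts)) {
      in_w <- win_of == w
      f <- sc$fst[in_w & sc$defined]
      row <- data.frame(
        chrom = ch, start = starts[w],
        end = starts[w] + window_size_bp,
        n_snps = sum(in_w),
        mean_fst = if (length(f)) mean(f) else NA_real_,
        weighted_fst = {
          aa <- sc$a[in_w & sc$defined]
          dd <- sc$d[in_w & sc$defined]
          if (length(aa) && sum(dd) != 0) sum(aa) / sum(dd) else NA_real_
        },
        q95_fst = if (length(f)) stats::quantile(f, q, names = FALSE, type = 7)
                  else NA_real_,
        stringsAsFactors = FALSE
      )
      for (pc in pi_cols) {
        v <- sc[[pc]][in_w]
        row[[paste0(pc, "_bp")]] <- sum(v, na.rm = TRUE) / window_size_bp
      }
      row$elevated_mean <- isTRUE(row$mean_fst > mean_threshold)
      row$elevated_q95 <- isTRUE(row$q95_fst > q95_threshold)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window_size_bp") <- window_size_bp
  attr(out, "thresholds") <- c(mean = mean_threshold, q95 = q95_threshold)
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Call selection-signature loci from the top Fst quantile
#'
#' The threshold is the `(1 - quantile)` quantile (linear interpolation) of
#' all defined per-SNP Fst values; every locus with `fst >= threshold` is
#' returned, ranked by descending Fst. Ties at the threshold are all
#' included.
#'
#' @param sites a `site_stats` data.frame from [wc_fst_site()]
#' @param quantile upper tail mass, default 0.01 (top 1% of Fst values)
#' @return data.frame: `marker_id`, `chrom`, `pos`, `fst`, `rank`,
#'   `threshold`
#' @export
top_quantile_loci <- function(sites, quantile = 0.01) {
  f <- sites$fst[sites$defined]
  if (!length(f)) stop("no defined Fst values")
  thr <- stats::quantile(f, 1 - quantile, names = FALSE, type = 7)
  sel <- sites$defined & sites$fst >= thr
  out <- sites[sel, c("marker_id", "chrom", "pos", "fst")]
  out <- out[order(-out$fst, out$chrom, out$pos), ]
  out$rank <- seq_len(nrow(out))
  out$threshold <- thr
  rownames(out) <- NULL
  out
}
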