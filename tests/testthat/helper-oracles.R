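# Independent oracles used to cross-check the implementation.
# These are deliberately naive, scalar transcriptions kept separate from the
# package's vectorized code paths.

# Weir & Cockerham (1984) variance components for ONE biallelic site and two
# populations, written directly from the published formulas (r = 2, no
# vectorization shared with the package implementation).
wc_oracle_site <- function(geno1, geno2) {
  g1 <- geno1[!is.na(geno1)]
  g2 <- geno2[!is.na(geno2)]
  n_i <- c(length(g1), length(g2))
  if (any(n_i == 0)) return(list(a = NA, b = NA, c = NA, fst = NA))
  p_i <- c(sum(g1) / (2 * n_i[1]), sum(g2) / (2 * n_i[2]))
  h_i <- c(sum(g1 == 1) / n_i[1], sum(g2 == 1) / n_i[2])
  r <- 2
  nbar <- sum(n_i) / r
  if (nbar <= 1) return(list(a = NA, b = NA, c = NA, fst = NA))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       fst = if (is.finite(denom) && denom != 0) a / denom else NA_real_)
}

# nucleotide diversity by brute-force enumeration of all chromosome pairs
pi_oracle_site <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  alleles <- unlist(lapply(d, function(x) c(rep(1L, x), rep(0L, 2L - x))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff_sum <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diff_sum <- diff_sum + (alleles[i] != alleles[j])
  }
  diff_sum / choose(n, 2)
}

# generalized least squares + BLUP via direct inversion of
# V = sigma_c^2 SS' + sigma_g^2 K + sigma_e^2 I
gls_oracle <- function(y, X, W, v, S = NULL, K = NULL) {
  n <- length(y)
  V <- v$residual * diag(n)
  if (!is.null(S) && v$cage > 0) V <- V + v$cage * tcrossprod(S)
  if (!is.null(K) && v$polygenic > 0) V <- V + v$polygenic * K
  Vi <- solve(V)
  Xs <- cbind(X, W)
  beta <- solve(t(Xs) %*% Vi %*% Xs, t(Xs) %*% Vi %*% y)
  r <- y - Xs %*% beta
  c_hat <- if (!is.null(S) && v$cage > 0)
    v$cage * as.vector(t(S) %*% Vi %*% r) else numeric(0)
  g_hat <- if (!is.null(K) && v$polygenic > 0)
    v$polygenic * as.vector(K %*% Vi %*% r) else numeric(0)
  p <- ncol(X)
  list(b = as.vector(beta)[seq_len(p)],
       q = if (!is.null(W) && NCOL(W) > 0)
         as.vector(beta)[p + seq_len(ncol(W))] else numeric(0),
       c = c_hat, g = g_hat)
}

# random small genotype fixture with ids and a valid map
rand_genotypes <- function(n, m, seed, missing_rate = 0) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  d <- matrix(d, n, m)
  if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA
  rownames(d) <- sprintf("s%03d", seq_len(n))
  genotype_matrix(d, data.frame(chrom = "chr01",
                                pos = sort(sample(1e6, m)),
                                ref = "A", alt = "G"))
}

two_group_table <- function(g, n1) {
  ids <- sample_ids(g)
  data.frame(sample_id = ids,
             line = rep(c("selection", "control"),
                        c(n1, length(ids) - n1)),
             stringsAsFactors = FALSE)
}
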