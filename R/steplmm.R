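#' Fit the stepwise mixed linear model for a growth trait
#'
#' Fits `y = Xb + Sc + Zg + Wq + e`: a fixed population mean and selection
#' line effect (`b`), random cage effects (`c ~ N(0, I sigma_c^2)`, one cage
#' per family), random polygenic effects (`g ~ N(0, K sigma_g^2)` with `K`
#' the VanRaden genomic relationship matrix) and, optionally, fixed major-QTL
#' allele-substitution effects (`q`) chosen by a stepwise genome scan.
#'
#' Variance components are estimated by restricted maximum likelihood
#' ([reml_varcomp()]). The genome scan tests each candidate marker one at a
#' time as an extra fixed column with the variance components held at their
#' current estimates (re-estimated whenever a marker enters the model), and
#' forward selection adds the most significant marker while its p-value
#' clears a Bonferroni threshold `alpha / n_markers_tested`; after each
#' addition a backward pass drops any included marker whose conditional
#' p-value has risen above the threshold, and markers within
#' `min_distance_bp` of an accepted QTL are excluded from later rounds.
#'
#' @param formula model formula, e.g. `Bwt8m ~ line`; the left side names
#'   the trait column of `data`, the right side the fixed effects (an
#'   intercept is always included)
#' @param data sample table with the trait, fixed-effect and `cage_id`
#'   columns plus `sample_id` matching the genotype rows; samples with a
#'   missing trait value are dropped (complete-case per trait)
#' @param genotypes a [genotype_matrix] covering the samples
#' @param K optional precomputed [vanraden_grm()] (or bare matrix with
#'   sample-id dimnames); computed from `genotypes` when `NULL`
#' @param cage name of the cage column, or `NULL` to omit the cage term
#' @param scan run the stepwise genome scan (`FALSE` fits the polygenic
#'   model only)
#' @param alpha genome-wide type-I error for the Bonferroni inclusion
#'   threshold
#' @param max_qtl maximum number of QTL to accept
#' @param min_distance_bp exclusion radius around accepted QTL
#' @param ridge ridge added to `K`'s diagonal if it is numerically singular
#' @return an object of class `steplmm`; see Details. Key components:
#'   `varcomp` (fitted [varcomp()], including the post-hoc QTL variance
#'   `sigma_q^2 = var(W q-hat)`), `h2`, `qtl` (data.frame of accepted QTL
#'   with effects, Wald p-values and contributions `cp`), `gebv`
#'   (`Z g-hat + W q-hat` per sample), `effects` (`b`, `q`, `c`, `g`),
#'   `scan` (per-marker statistics of the final null scan), `loglik`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_families = 6, n_markers = 200,
#'                                       n_selection_families = 4, seed = 3))
#' fit <- steplmm(Bwt8m ~ line, data = cohort$samples,
#'                genotypes = cohort$genotypes, scan = FALSE)
#' fit$h2
#' @seealso [scan_markers()], [reml_varcomp()], [assemble_mme()]
#' @export
steplmm <- function(formula, data, genotypes, K = NULL, cage = "cage_id",
                    scan = TRUE, alpha = 0.05, max_qtl = 10,
                    min_distance_bp = 1e6, ridge = 0) {
  cl <- match.call()
  trait <- all.vars(formula[[2]])
  if (!trait %in% names(data)) stop("trait column '", trait, "' not in data")
  keep <- !is.na(data[[trait]])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  if (n < 3) stop("too few phenotyped samples")
  idx <- match(data$sample_id, sample_ids(genotypes))
  if (anyNA(idx)) stop("phenotyped samples missing from the genotype matrix")

  y <- data[[trait]]
  X <- stats::model.matrix(stats::delete.response(stats::terms(formula)),
                           data = data)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design X is rank deficient")
  S <- NULL
  if (!is.null(cage) && cage %in% names(data)) {
    cages <- unique(data[[cage]])
    if (length(cages) > 1) S <- outer(data[[cage]], cages, "==") * 1
  }
  if (is.null(K)) K <- vanraden_grm(genotypes)
  Kmat <- if (inherits(K, "grm")) K$K else as.matrix(K)
  Kmat <- Kmat[idx, idx, drop = FALSE]
  if (ridge > 0) Kmat <- Kmat + ridge * diag(n)

  G <- genotypes$dosage[idx, , drop = FALSE]
  map <- genotypes$map

  # --- stepwise selection -------------------------------------------------
  selected <- integer(0)
  excluded <- rep(FALSE, ncol(G))
  fit0 <- reml_varcomp(y, X, S = S, K = Kmat)
  scan_tab <- NULL
  if (scan) {
    repeat {
      Wsel <- if (length(selected)) G[, selected, drop = FALSE] else NULL
      Xfull <- if (is.null(Wsel)) X else cbind(X, Wsel)
      fit0 <- reml_varcomp(y, Xfull, S = S, K = Kmat)
      sc <- scan_markers(y, X, G, fit0$varcomp, S = S, K = Kmat,
                         W = Wsel, map = map)
      if (is.null(scan_tab)) scan_tab <- sc
      cand <- which(!sc$skipped & !excluded)
      cand <- setdiff(cand, selected)
      m_tested <- length(cand)
      if (m_tested == 0 || length(selected) >= max_qtl) break
      thr <- if (alpha > 0) alpha / m_tested else 0
      best <- cand[which.min(sc$p[cand])]
      if (alpha <= 0 || !is.finite(sc$p[best]) || sc$p[best] >= thr) break
      selected <- c(selected, best)
      excluded <- excluded | (map$chrom == map$chrom[best] &
                                abs(map$pos - map$pos[best]) <= min_distance_bp)
      # backward check on the joint fit
      repeat {
        Wsel <- G[, selected, drop = FALSE]
        fit_j <- reml_varcomp(y, cbind(X, Wsel), S = S, K = Kmat)
        cond <- conditional_wald(y, X, Wsel, fit_j$varcomp, S = S, K = Kmat)
        worst <- which.max(cond$p)
        if (length(selected) > 0 && cond$p[worst] > thr) {
          selected <- selected[-worst]
          if (!length(selected)) break
        } else break
      }
      if (length(selected) >= max_qtl) break
    }
    # refresh the null scan table for reporting
    Wsel <- if (length(selected)) G[, selected, drop = FALSE] else NULL
    Xfull <- if (is.null(Wsel)) X else cbind(X, Wsel)
    fit0 <- reml_varcomp(y, Xfull, S = S, K = Kmat)
  }

  # --- final effect solve (GLS + BLUP identities) -------------------------
  v <- fit0$varcomp
  W <- if (length(selected)) G[, selected, drop = FALSE] else
    matrix(0, n, 0)
  sol <- solve_effects(y, X, W, v, S = S, K = Kmat)
  gebv <- as.vector(if (ncol(W)) W %*% sol$q else rep(0, n)) + sol$g_term
  sigma_q2 <- if (ncol(W)) stats::var(as.vector(W %*% sol$q)) else 0
  v <- varcomp(cage = v$cage, polygenic = v$polygenic,
               residual = v$residual, qtl = sigma_q2)
  h2 <- heritability(v)
  vp_hat <- v$qtl + v$polygenic + v$cage + v$residual

  qtl <- if (length(selected)) {
    cond <- conditional_wald(y, X, W, fit0$varcomp, S = S, K = Kmat)
    data.frame(
      trait = trait,
      marker_id = map$marker_id[selected],
      chrom = map$chrom[selected],
      pos = map$pos[selected],
      effect = sol$q,
      statistic = cond$t,
      p = cond$p,
      cp = vapply(seq_along(selected), function(k) {
        stats::var(W[, k] * sol$q[k]) / vp_hat
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(trait = character(), marker_id = character(),
               chrom = character(), pos = integer(), effect = numeric(),
               statistic = numeric(), p = numeric(), cp = numeric())
  }

  fitted <- as.vector(X %*% sol$b) +
    (if (ncol(W)) as.vector(W %*% sol$q) else 0) + sol$c_term + sol$g_term

  structure(list(
    call = cl, trait = trait, n = n, sample_id = data$sample_id,
    varcomp = v, h2 = h2, loglik = fit0$loglik, reml_trace = fit0$trace,
    qtl = qtl, scan = scan_tab,
    effects = list(b = stats::setNames(sol$b, colnames(X)), q = sol$q,
                   c = sol$c, g = sol$g),
    gebv = stats::setNames(gebv, data$sample_id),
    fitted = fitted, residuals = y - fitted, y = y,
    alpha = alpha, min_distance_bp = min_distance_bp
  ), class = "steplmm")
}

# GLS fixed effects and BLUPs via direct V-based identities:
#   V = sigma_c^2 SS' + sigma_g^2 K + sigma_e^2 I  (Z = I)
#   beta-hat = (X*' V^-1 X*)^-1 X*' V^-1 y,  X* = [X W]
#   c-hat = sigma_c^2 S' V^-1 (y - X* beta),  g-hat = sigma_g^2 K V^-1 (...)
solve_effects <- function(y, X, W, v, S = NULL, K = NULL) {
  n <- length(y)
  V <- diag(n) * v$residual
  if (!is.null(S) && v$cage > 0) V <- V + v$cage * tcrossprod(S)
  if (!is.null(K) && v$polygenic > 0) V <- V + v$polygenic * K
  Xs <- cbind(X, W)
  Vi_X <- solve(V, Xs)
  Vi_y <- solve(V, y)
  beta <- solve(crossprod(Xs, Vi_X), crossprod(Xs, Vi_y))
  r <- y - Xs %*% beta
  Vi_r <- solve(V, r)
  c_hat <- if (!is.null(S) && v$cage > 0) {
    v$cage * as.vector(crossprod(S, Vi_r))
  } else numeric(0)
  g_hat <- if (!is.null(K) && v$polygenic > 0) {
    v$polygenic * as.vector(K %*% Vi_r)
  } else numeric(0)
  p <- ncol(X)
  list(
    b = as.vector(beta)[seq_len(p)],
    q = if (ncol(W)) as.vector(beta)[p + seq_len(ncol(W))] else numeric(0),
    c = c_hat,
    g = g_hat,
    c_term = if (length(c_hat)) as.vector(S %*% c_hat) else rep(0, n),
    g_term = if (length(g_hat)) g_hat else rep(0, n)
  )
}

# Wald statistics for the QTL columns of the joint GLS fit
conditional_wald <- function(y, X, W, v, S = NULL, K = NULL) {
  n <- length(y)
  V <- diag(n) * v$residual
  if (!is.null(S) && v$cage > 0) V <- V + v$cage * tcrossprod(S)
  if (!is.null(K) && v$polygenic > 0) V <- V + v$polygenic * K
  Xs <- cbind(X, W)
  Vi_X <- solve(V, Xs)
  A <- solve(crossprod(Xs, Vi_X))
  beta <- A %*% crossprod(Xs, solve(V, y))
  p <- ncol(X)
  jq <- p + seq_len(ncol(W))
  se <- sqrt(diag(A)[jq])
  t <- as.vector(beta[jq]) / se
  df <- n - ncol(Xs)
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Single-marker association scan at fixed variance components
#'
#' Tests each candidate marker one at a time as an extra fixed
#' allele-substitution column, holding the variance components at their
#' current REML estimates (the standard approximation that makes a
#' genome-wide scan a set of generalized-least-squares slope tests). Markers
#' that are monomorphic, or collinear with the fixed part (including any
#' already-selected QTL columns in `W`), are skipped with a flag.
#'
#' @param y response vector
#' @param X base fixed-effect design (mean + line)
#' @param G dosage matrix over the phenotyped samples (samples x markers)
#' @param v current [varcomp()] estimates
#' @param S cage incidence or `NULL`
#' @param K relationship matrix or `NULL`
#' @param W dosage columns of already-selected QTL (absorbed into the fixed
#'   part), or `NULL`
#' @param map optional marker map carried through to the result
#' @return data.frame: `marker_id`, `chrom`, `pos` (if `map` given),
#'   `beta` (allele substitution effect), `se`, `t`, `p`, `skipped`
#' @export
scan_markers <- function(y, X, G, v, S = NULL, K = NULL, W = NULL,
                         map = NULL) {
  n <- length(y)
  H <- diag(n)
  if (!is.null(S) && v$cage > 0 && v$residual > 0) {
    H <- H + (v$cage / v$residual) * tcrossprod(S)
  }
  if (!is.null(K) && v$polygenic > 0 && v$residual > 0) {
    H <- H + (v$polygenic / v$residual) * K
  }
  L <- chol(H)
  Xs <- cbind(X, W)
  yt <- backsolve(L, y, transpose = TRUE)
  Xt <- backsolve(L, Xs, transpose = TRUE)
  Gt <- backsolve(L, G, transpose = TRUE)
  XtXi <- solve(crossprod(Xt))
  # residualize y and every marker on the transformed fixed part
  py <- yt - Xt %*% (XtXi %*% crossprod(Xt, yt))
  PG <- Gt - Xt %*% (XtXi %*% crossprod(Xt, Gt))
  ss_w <- colSums(PG^2)
  p_fixed <- ncol(Xs)
  df <- n - p_fixed - 1
  skipped <- ss_w < 1e-10 * n
  beta <- ifelse(skipped, NA_real_, colSums(PG * as.vector(py)) / ss_w)
  rss <- sum(py^2) - ifelse(skipped, 0, beta^2 * ss_w)
  sigma2 <- rss / df
  se <- ifelse(skipped, NA_real_, sqrt(sigma2 / ss_w))
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), df)
  out <- data.frame(beta = beta, se = se, t = t, p = p, skipped = skipped)
  if (!is.null(map)) {
    out <- cbind(map[, c("marker_id", "chrom", "pos")], out)
  }
  rownames(out) <- NULL
  out
}

#' Per-QTL contribution to phenotypic variance
#'
#' `Cp = var(w q-hat) / Vp-hat`, the sample variance of a QTL's fitted term
#' over the phenotyped samples, as a fraction of the fitted phenotypic
#' variance `Vp-hat = sigma_q^2 + sigma_g^2 + sigma_c^2 + sigma_e^2`.
#'
#' @param w marker dosage vector over the phenotyped samples
#' @param effect fitted allele substitution effect `q-hat`
#' @param v fitted [varcomp()] (with `qtl` filled in)
#' @return Cp in `[0, 1]`
#' @export
qtl_contribution <- function(w, effect, v) {
  vp <- v$qtl + v$polygenic + v$cage + v$residual
  if (vp <= 0) stop("fitted phenotypic variance is zero")
  stats::var(w * effect) / vp
}
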