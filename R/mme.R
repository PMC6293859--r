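#' Assemble the mixed model equations
#'
#' Builds Henderson's mixed model equations for the growth-trait model
#' `y = Xb + Sc + Zg + Wq + e` with fixed mean/line effects `b`, fixed
#' major-QTL allele-substitution effects `q`, random cage effects
#' `c ~ N(0, I sigma_c^2)` and random polygenic effects
#' `g ~ N(0, K sigma_g^2)`. The symmetric block system, with blocks ordered
#' `(b, q, c, g)`, is
#' \deqn{\begin{bmatrix} X'X & X'W & X'S & X'Z \\ W'X & W'W & W'S & W'Z \\
#'   S'X & S'W & S'S + \lambda_1 I & S'Z \\
#'   Z'X & Z'W & Z'S & Z'Z + \lambda_2 K^{-1} \end{bmatrix}
#'   \begin{bmatrix}\hat b\\ \hat q\\ \hat c\\ \hat g\end{bmatrix} =
#'   \begin{bmatrix} X'y \\ W'y \\ S'y \\ Z'y \end{bmatrix}}
#' with `lambda1 = sigma_e^2/sigma_c^2` and `lambda2 = sigma_e^2/sigma_g^2`.
#' A zero cage or polygenic variance (infinite lambda) drops that block.
#'
#' @param y numeric response vector
#' @param X fixed-effect design (mean + line), full column rank
#' @param v a [varcomp()] with the current variance components
#' @param W optional fixed-QTL dosage columns (may be `NULL` / 0 columns)
#' @param S optional cage incidence matrix (`NULL` or zero cage variance
#'   drops the cage block)
#' @param K polygenic relationship matrix (required when
#'   `v$polygenic > 0`); inverted inside, after an optional ridge
#' @param Z polygenic incidence, default identity over records
#' @param ridge ridge `delta` added to `diag(K)` before inversion when `K`
#'   is numerically singular; `0` means no repair
#' @return list of class `mme_system`: `C` (coefficient matrix), `rhs`,
#'   `blocks` (index list per block), plus the inputs needed by
#'   [solve_mme()]
#' @examples
#' y <- c(1, 2, 3, 2, 1, 2)
#' X <- cbind(1, rep(0:1, each = 3))
#' sys <- assemble_mme(y, X, varcomp(polygenic = 1, residual = 1),
#'                     K = diag(6))
#' solve_mme(sys)$b
#' @export
assemble_mme <- function(y, X, v, W = NULL, S = NULL, K = NULL,
                         Z = NULL, ridge = 0) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  use_q <- !is.null(W) && NCOL(W) > 0
  use_c <- !is.null(S) && v$cage > 0
  use_g <- v$polygenic > 0
  if (use_q) W <- as.matrix(W)
  if (use_c) S <- as.matrix(S)
  lam <- lambda_ratios(v)
  if (use_g) {
    if (is.null(K)) stop("K is required when the polygenic variance is > 0")
    if (is.null(Z)) Z <- diag(n)
    Kinv <- safe_k_inverse(K, ridge)
  } else {
    Z <- NULL
  }
  des <- list(b = X,
              q = if (use_q) W else NULL,
              c = if (use_c) S else NULL,
              g = if (use_g) Z else NULL)
  des <- des[!vapply(des, is.null, logical(1))]
  nm <- names(des)
  sizes <- vapply(des, ncol, integer(1))
  off <- cumsum(c(0, sizes))
  p <- sum(sizes)
  C <- matrix(0, p, p)
  rhs <- numeric(p)
  blocks <- list()
  for (i in seq_along(des)) {
    idx_i <- off[i] + seq_len(sizes[i])
    blocks[[nm[i]]] <- idx_i
    rhs[idx_i] <- crossprod(des[[i]], y)
    for (j in seq_along(des)) {
      idx_j <- off[j] + seq_len(sizes[j])
      C[idx_i, idx_j] <- crossprod(des[[i]], des[[j]])
    }
  }
  if (use_c) {
    ic <- blocks$c
    C[ic, ic] <- C[ic, ic] + lam$lambda1 * diag(length(ic))
  }
  if (use_g) {
    ig <- blocks$g
    C[ig, ig] <- C[ig, ig] + lam$lambda2 * Kinv
  }
  structure(list(C = C, rhs = rhs, blocks = blocks, design = des,
                 varcomp = v, n = n),
            class = "mme_system")
}

# Invert K, with PSD check: eigenvalues below -1e-8 are an error, small
# negatives are clipped; singular K without a ridge is an error advising one.
safe_k_inverse <- function(K, ridge = 0) {
  K <- (K + t(K)) / 2
  if (ridge > 0) K <- K + ridge * diag(nrow(K))
  e <- eigen(K, symmetric = TRUE)
  if (any(e$values < -1e-8)) {
    stop("K is not positive semi-definite (eigenvalue ",
         format(min(e$values)), ")")
  }
  ev <- pmax(e$values, 0)
  if (min(ev) < 1e-10 * max(ev)) {
    stop("K is numerically singular; supply a ridge delta > 0 ",
         "(e.g. ridge = 1e-6)")
  }
  e$vectors %*% ((1 / ev) * t(e$vectors))
}

#' Solve an assembled mixed-model system
#'
#' Solves the symmetric block system from [assemble_mme()] and returns the
#' estimated effects by block, together with the genomic estimated breeding
#' values `GEBV = Z g-hat + W q-hat`.
#'
#' @param system an `mme_system` from [assemble_mme()]
#' @return list with `b` (fixed effects), `q` (QTL effects, possibly empty),
#'   `c` (cage BLUPs), `g` (polygenic BLUPs), `gebv`, and `solution` (the
#'   full stacked vector)
#' @export
solve_mme <- function(system) {
  if (any(!is.finite(system$C)) || any(!is.finite(system$rhs))) {
    stop("non-finite entries in the mixed model equations")
  }
  sol <- solve(system$C, system$rhs)
  get <- function(nm) {
    if (nm %in% names(system$blocks)) sol[system$blocks[[nm]]] else numeric(0)
  }
  b <- get("b"); q <- get("q"); cc <- get("c"); g <- get("g")
  gebv <- numeric(system$n)
  if (length(g)) gebv <- gebv + as.vector(system$design$g %*% g)
  if (length(q)) gebv <- gebv + as.vector(system$design$q %*% q)
  list(b = b, q = q, c = cc, g = g, gebv = gebv, solution = sol)
}
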