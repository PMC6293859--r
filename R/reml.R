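# Restricted-likelihood machinery for the growth-trait mixed model.
#
# The covariance of y (up to sigma_e^2) is H = I + gamma_c SS' + gamma_g K
# with gamma_c = sigma_c^2/sigma_e^2 and gamma_g = sigma_g^2/sigma_e^2.
# Both beta and sigma_e^2 are profiled out of the restricted likelihood, so
# the optimization runs over the log variance ratios only.

# profiled restricted log-likelihood at variance ratios gamma (named vector
# possibly containing "cage" and "polygenic"); returns loglik plus the
# profiled sigma_e^2 and GLS beta
reml_profile <- function(log_gamma, y, X, SSt = NULL, K = NULL) {
  n <- length(y)
  p <- ncol(X)
  H <- diag(n)
  if (!is.null(SSt) && "cage" %in% names(log_gamma)) {
    H <- H + exp(log_gamma[["cage"]]) * SSt
  }
  if (!is.null(K) && "polygenic" %in% names(log_gamma)) {
    H <- H + exp(log_gamma[["polygenic"]]) * K
  }
  L <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(L)) return(list(loglik = -Inf))
  # chol() returns upper triangular: H = t(L) %*% L
  yt <- backsolve(L, y, transpose = TRUE)
  Xt <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(Xt)
  ch2 <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch2)) return(list(loglik = -Inf))
  beta <- backsolve(ch2, backsolve(ch2, crossprod(Xt, yt), transpose = TRUE))
  r <- yt - Xt %*% beta
  quad <- sum(r^2)
  if (quad <= 0) quad <- .Machine$double.eps
  sigma_e2 <- quad / (n - p)
  logdet_H <- 2 * sum(log(diag(L)))
  logdet_XtX <- 2 * sum(log(diag(ch2)))
  ll <- -0.5 * ((n - p) * log(sigma_e2) + logdet_H + logdet_XtX +
                  (n - p) * (1 + log(2 * pi)))
  list(loglik = ll, sigma_e2 = sigma_e2, beta = as.vector(beta))
}

#' Estimate variance components by restricted maximum likelihood
#'
#' Maximizes the restricted likelihood of the model `y = Xb (+ Wq) + Sc +
#' Zg + e` over the cage and polygenic variance ratios, with any
#' currently-selected QTL columns absorbed into the fixed part. `beta` and
#' `sigma_e^2` are profiled out analytically, leaving a 0-, 1- or
#' 2-dimensional derivative-free search over log variance ratios
#' (Nelder-Mead with multiple starts; golden-section for one ratio).
#' Zero-boundary estimates are allowed: a ratio below `boundary_tol` is
#' reported as variance 0.
#'
#' @param y response vector (no missing values)
#' @param X fixed-effect design including the intercept, line effect and any
#'   fixed QTL dosage columns
#' @param S cage incidence matrix, or `NULL` to omit the cage term
#' @param K polygenic relationship matrix, or `NULL` to omit the polygenic
#'   term
#' @param tol convergence tolerance on the restricted log-likelihood
#' @param max_iter maximum optimizer iterations per start
#' @param boundary_tol variance ratios below this are reported as exact
#'   zeros
#' @return list of class `reml_fit`: `varcomp` (a [varcomp()]), `loglik`,
#'   `beta` (GLS fixed effects at the optimum), `trace` (best-so-far
#'   restricted log-likelihood per evaluation, non-decreasing), and
#'   `gamma` (fitted variance ratios)
#' @export
reml_varcomp <- function(y, X, S = NULL, K = NULL, tol = 1e-6,
                         max_iter = 500, boundary_tol = 1e-5) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) stop("need at least ", p + 2, " records for REML")
  SSt <- if (!is.null(S)) tcrossprod(as.matrix(S)) else NULL
  terms <- c(if (!is.null(SSt)) "cage", if (!is.null(K)) "polygenic")

  trace_env <- new.env()
  trace_env$best <- -Inf
  trace_env$trace <- numeric(0)
  objective <- function(lg) {
    lg <- pmin(pmax(lg, -16), 16)
    names(lg) <- terms
    res <- reml_profile(lg, y, X, SSt, K)
    if (is.finite(res$loglik) && res$loglik > trace_env$best) {
      trace_env$best <- res$loglik
    }
    trace_env$trace <- c(trace_env$trace, trace_env$best)
    -res$loglik
  }

  if (length(terms) == 0) {
    opt_lg <- numeric(0)
  } else if (length(terms) == 1) {
    op <- stats::optimize(objective, interval = c(-16, 16), tol = tol)
    opt_lg <- op$minimum
  } else {
    starts <- expand.grid(c(-2, 1), c(-2, 1))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      op <- stats::optim(as.numeric(starts[s, ]), objective,
                         method = "Nelder-Mead",
                         control = list(maxit = max_iter,
                                        reltol = tol * 1e-2))
      if (op$convergence != 0) {
        stop("REML did not converge from start ", s,
             " (code ", op$convergence, "); trace length ",
             length(trace_env$trace))
      }
      if (is.null(best) || op$value < best$value) best <- op
    }
    opt_lg <- best$par
  }
  opt_lg <- pmin(pmax(opt_lg, -16), 16)
  names(opt_lg) <- terms
  final <- reml_profile(opt_lg, y, X, SSt, K)
  gamma <- exp(opt_lg)
  gamma[gamma < boundary_tol] <- 0
  v <- varcomp(
    cage = if ("cage" %in% terms) gamma[["cage"]] * final$sigma_e2 else 0,
    polygenic = if ("polygenic" %in% terms)
      gamma[["polygenic"]] * final$sigma_e2 else 0,
    residual = final$sigma_e2
  )
  structure(list(varcomp = v, loglik = final$loglik, beta = final$beta,
                 trace = trace_env$trace, gamma = gamma),
            class = "reml_fit")
}
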