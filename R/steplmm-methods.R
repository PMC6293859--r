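#' @method print steplmm
#' @export
print.steplmm <- function(x, digits = 3, ...) {
  cat("Stepwise mixed linear model fit, trait:", x$trait, "\n")
  cat("  samples:", x$n, "  restricted log-likelihood:",
      format(x$loglik, digits = 6), "\n")
  v <- x$varcomp
  cat(sprintf("  variance components: cage %.3g, polygenic %.3g, QTL %.3g, residual %.3g\n",
              v$cage, v$polygenic, v$qtl, v$residual))
  cat(sprintf("  heritability h^2 = %.*f\n", digits, x$h2))
  if (nrow(x$qtl)) {
    cat("  QTL (", nrow(x$qtl), "):\n", sep = "")
    print(x$qtl[, c("marker_id", "chrom", "pos", "effect", "p", "cp")],
          digits = digits, row.names = FALSE)
  } else {
    cat("  no QTL accepted\n")
  }
  invisible(x)
}

#' @export
summary.steplmm <- function(object, ...) {
  structure(list(fit = object), class = "summary.steplmm")
}

#' @method print summary.steplmm
#' @export
print.summary.steplmm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nFixed effects:\n")
  print(f$effects$b, digits = 4)
  cat("\nGEBV summary:\n")
  print(summary(f$gebv))
  invisible(x)
}

#' @export
coef.steplmm <- function(object, ...) {
  c(object$effects$b,
    if (length(object$effects$q)) {
      stats::setNames(object$effects$q, object$qtl$marker_id)
    })
}

#' @export
fitted.steplmm <- function(object, ...) {
  stats::setNames(object$fitted, object$sample_id)
}

#' @export
residuals.steplmm <- function(object, ...) {
  stats::setNames(object$residuals, object$sample_id)
}

#' Genomic estimated breeding values from a fitted model
#'
#' Returns `GEBV = Z g-hat + W q-hat` for the phenotyped samples.
#'
#' @param object a fitted [steplmm()] model
#' @param ... ignored
#' @return named numeric vector of GEBVs
#' @export
predict.steplmm <- function(object, ...) {
  object$gebv
}

#' Manhattan plot of the genome scan
#'
#' Plots `-log10(p)` of the single-marker scan by genomic position, marking
#' accepted QTL.
#'
#' @param x a fitted [steplmm()] model with a scan table
#' @param ... passed to [graphics::plot()]
#' @method plot steplmm
#' @export
plot.steplmm <- function(x, ...) {
  sc <- x$scan
  if (is.null(sc)) stop("model was fitted with scan = FALSE")
  sc <- sc[!sc$skipped, ]
  chroms <- unique(sc$chrom)
  offset <- stats::setNames(
    c(0, cumsum(tapply(sc$pos, factor(sc$chrom, levels = chroms), max)))[
      seq_along(chroms)],
    chroms)
  xpos <- sc$pos + offset[sc$chrom]
  col <- (match(sc$chrom, chroms) %% 2) + 1
  graphics::plot(xpos, -log10(sc$p), pch = 16, cex = 0.4,
                 col = c("grey40", "steelblue")[col],
                 xlab = "genome position", ylab = expression(-log[10](p)),
                 main = paste("Scan:", x$trait), ...)
  if (nrow(x$qtl)) {
    hit <- x$qtl
    graphics::points(hit$pos + offset[hit$chrom],
                     -log10(sc$p[match(hit$marker_id, sc$marker_id)]),
                     col = "red", pch = 1, cex = 1.4)
  }
  invisible(x)
}

#' Simulate new phenotypes from a fitted model
#'
#' Draws `nsim` new response vectors from the fitted decomposition: fixed
#' part held at its estimates, new cage effects, polygenic effects
#' (`MVN(0, K sigma_g^2)` is approximated by resampling the fitted BLUP
#' covariance structure via `K`), and residuals.
#'
#' @param object a fitted [steplmm()] model
#' @param nsim number of replicates
#' @param seed optional seed
#' @param K the relationship matrix over the phenotyped samples (required if
#'   the fitted polygenic variance is positive)
#' @param S cage incidence over the phenotyped samples (required if the
#'   fitted cage variance is positive)
#' @param ... ignored
#' @return data.frame with `nsim` columns of simulated responses
#' @export
simulate.steplmm <- function(object, nsim = 1, seed = NULL, K = NULL,
                             S = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  v <- object$varcomp
  # fixed + QTL part only: strip the fitted random-effect realizations
  mean_part <- object$fitted -
    (if (length(object$effects$g)) object$effects$g else 0) -
    (if (length(object$effects$c) && !is.null(S))
       as.vector(S %*% object$effects$c) else 0)
  Ksqrt <- NULL
  if (v$polygenic > 0) {
    if (is.null(K)) stop("K is required to simulate the polygenic term")
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    Ksqrt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  out <- matrix(0, n, nsim)
  for (r in seq_len(nsim)) {
    y <- mean_part + stats::rnorm(n, 0, sqrt(v$residual))
    if (!is.null(Ksqrt)) {
      y <- y + sqrt(v$polygenic) * as.vector(Ksqrt %*% stats::rnorm(n))
    }
    if (v$cage > 0 && !is.null(S)) {
      y <- y + as.vector(S %*% stats::rnorm(ncol(S), 0, sqrt(v$cage)))
    }
    out[, r] <- y
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
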