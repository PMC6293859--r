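#' Specify a simulated full-sib-family cohort
#'
#' A `cohort_spec` captures the design of a two-line breeding cohort: a set
#' of full-sib families (two parents plus a fixed number of offspring, one
#' cage per family) split between a selection line and a control line,
#' genotyped at biallelic SNPs spread uniformly over a set of chromosomes. A
#' chosen fraction of markers is given line-divergent founder allele
#' frequencies via the Balding-Nichols model, and major QTL with fixed
#' allele-substitution effects can be planted at named markers. The defaults
#' mirror a medium-scale aquaculture selection experiment: 25 families (19
#' selection, 6 control) of 8 offspring + 2 parents each, 5,000 markers on
#' 10 chromosomes of 2 Mb.
#'
#' @param n_families number of full-sib families
#' @param offspring_per_family offspring per family (each family also has 2
#'   parents)
#' @param n_selection_families how many families belong to the selection
#'   line; the rest are control
#' @param n_markers total number of SNPs
#' @param n_chromosomes number of chromosomes; markers are spread evenly
#' @param chromosome_length chromosome length in bp
#' @param divergent_fraction fraction of markers whose founder frequencies
#'   differ between lines
#' @param divergence_fst Balding-Nichols differentiation parameter for the
#'   divergent markers
#' @param divergent_markers optional explicit marker indices to make
#'   divergent (overrides random placement; its length must then be
#'   consistent with `divergent_fraction` only loosely -- the explicit set
#'   wins)
#' @param founder_overrides optional data.frame (`marker`, `p_selection`,
#'   `p_control`) pinning exact founder frequencies at chosen markers after
#'   the random draws. A block of neighbouring markers pinned to strongly
#'   different line frequencies emulates the hitchhiking footprint of a
#'   selective sweep, the regional signal that elevated-window calling is
#'   designed to detect; single-marker Balding-Nichols draws do not produce
#'   such regional signals because markers here are unlinked.
#' @param qtl_list list of planted QTL; each element a list/vector with
#'   `trait`, `marker` (index) and either `effect` (allele substitution
#'   effect on the trait scale) or `cp` (target contribution to phenotypic
#'   variance, converted to an effect from the realized dosage variance)
#' @param varcomp_true [varcomp()] holding the simulation-truth cage,
#'   polygenic and residual variances
#' @param line_effect fixed trait difference added to the selection line
#' @param traits character vector of trait names to simulate
#' @param missing_rate fraction of genotypes set missing at random
#' @param seed integer seed; every simulation step derives its randomness
#'   from it
#' @return an object of class `cohort_spec`
#' @examples
#' spec <- cohort_spec(n_families = 4, n_markers = 50, seed = 1)
#' cohort <- simulate_cohort(spec)
#' dim(cohort$genotypes$dosage)
#' @export
cohort_spec <- function(n_families = 25,
                        offspring_per_family = 8,
                        n_selection_families = 19,
                        n_markers = 5000,
                        n_chromosomes = 10,
                        chromosome_length = 2e6,
                        divergent_fraction = 0.01,
                        divergence_fst = 0.4,
                        divergent_markers = NULL,
                        founder_overrides = NULL,
                        qtl_list = list(),
                        varcomp_true = varcomp(cage = 0.25, polygenic = 1,
                                               residual = 0.75),
                        line_effect = 1,
                        traits = c("iBwt", "iBlen", "Bwt8m", "Blen8m",
                                   "Bdp8m", "Bwd8m"),
                        missing_rate = 0,
                        seed = 1L) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    stopifnot(
      n_families >= 1, offspring_per_family >= 0,
      n_selection_families >= 0, n_selection_families <= n_families,
      n_markers >= 1, n_chromosomes >= 1, chromosome_length > 0,
      divergent_fraction >= 0, divergent_fraction <= 1,
      divergence_fst >= 0, divergence_fst < 1,
      missing_rate >= 0, missing_rate < 1
    )
    stopifnot(varcomp_true$cage >= 0, varcomp_true$polygenic >= 0,
              varcomp_true$residual >= 0)
    for (q in qtl_list) {
      q <- as.list(q)
      if (is.null(q$trait) || is.null(q$marker)) {
        stop("each planted QTL needs a trait and a marker index")
      }
      if (as.integer(q$marker) < 1 || as.integer(q$marker) > n_markers) {
        stop("planted QTL marker index ", q$marker, " out of range 1..",
             n_markers)
      }
      if (is.null(q$effect) && is.null(q$cp)) {
        stop("each planted QTL needs an effect or a target cp")
      }
    }
    if (!is.null(founder_overrides)) {
      stopifnot(all(c("marker", "p_selection", "p_control") %in%
                      names(founder_overrides)),
                all(founder_overrides$marker >= 1),
                all(founder_overrides$marker <= n_markers),
                all(founder_overrides$p_selection >= 0),
                all(founder_overrides$p_selection <= 1),
                all(founder_overrides$p_control >= 0),
                all(founder_overrides$p_control <= 1))
    }
  })
  invisible(spec)
}

#' @method print cohort_spec
#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec:", x$n_families, "families (",
      x$n_selection_families, "selection /",
      x$n_families - x$n_selection_families, "control ),",
      2 + x$offspring_per_family, "samples each\n")
  cat("  markers:", x$n_markers, "on", x$n_chromosomes,
      "chromosomes of", format(x$chromosome_length, big.mark = ","), "bp\n")
  cat("  divergent fraction:", x$divergent_fraction,
      " (Balding-Nichols Fst ", x$divergence_fst, ")\n")
  cat("  planted QTL:", length(x$qtl_list), " seed:", x$seed, "\n")
  invisible(x)
}

#' Variance components of the growth-trait mixed model
#'
#' Holds the cage, polygenic and residual variances of the phenotype model
#' `y = Xb + Sc + Zg + Wq + e`, plus the post-hoc QTL variance (the sample
#' variance of the fitted fixed-QTL term `W q-hat`). The variance ratios
#' `lambda1 = residual/cage` and `lambda2 = residual/polygenic` enter the
#' mixed model equations; a zero variance corresponds to an infinite ratio
#' and is handled by dropping the effect.
#'
#' @param cage cage variance (sigma_c^2)
#' @param polygenic polygenic variance (sigma_g^2)
#' @param residual residual variance (sigma_e^2)
#' @param qtl variance explained by the fixed major QTL (sigma_q^2)
#' @return an object of class `varcomp`
#' @examples
#' varcomp(cage = 0, polygenic = 1, residual = 1)
#' @export
varcomp <- function(cage = 0, polygenic = 0, residual = 1, qtl = 0) {
  stopifnot(cage >= 0, polygenic >= 0, residual >= 0, qtl >= 0)
  structure(list(cage = cage, polygenic = polygenic, residual = residual,
                 qtl = qtl),
            class = "varcomp")
}

#' @method print varcomp
#' @export
print.varcomp <- function(x, digits = 4, ...) {
  cat("variance components:\n")
  cat(sprintf("  cage      (sigma_c^2): %.*g\n", digits, x$cage))
  cat(sprintf("  polygenic (sigma_g^2): %.*g\n", digits, x$polygenic))
  cat(sprintf("  QTL       (sigma_q^2): %.*g\n", digits, x$qtl))
  cat(sprintf("  residual  (sigma_e^2): %.*g\n", digits, x$residual))
  cat(sprintf("  h^2: %.3f\n", heritability(x)))
  invisible(x)
}

#' Variance ratios entering the mixed model equations
#'
#' `lambda1 = sigma_e^2 / sigma_c^2`, `lambda2 = sigma_e^2 / sigma_g^2`.
#' Ratios are `Inf` when the corresponding variance is zero (the effect is
#' then dropped from the model).
#'
#' @param v a [varcomp()]
#' @return named list with `lambda1` and `lambda2`
#' @export
lambda_ratios <- function(v) {
  list(
    lambda1 = if (v$cage > 0) v$residual / v$cage else Inf,
    lambda2 = if (v$polygenic > 0) v$residual / v$polygenic else Inf
  )
}

#' Narrow-sense heritability with fixed major QTL
#'
#' `h^2 = (sigma_q^2 + sigma_g^2) / (sigma_q^2 + sigma_g^2 + sigma_c^2 +
#' sigma_e^2)`: the genetic fraction of phenotypic variance, counting both
#' the polygenic variance and the variance captured by the fixed major-QTL
#' term.
#'
#' @param v a [varcomp()], or the QTL variance `sigma_q^2` if the remaining
#'   components are passed individually
#' @param polygenic,cage,residual individual components when `v` is numeric
#' @return heritability in `[0, 1]`
#' @examples
#' heritability(varcomp(polygenic = 1, residual = 1))      # 0.5
#' heritability(15.58, polygenic = 0, cage = 0, residual = 11.68)
#' @export
heritability <- function(v, polygenic = 0, cage = 0, residual = 0) {
  if (is.numeric(v)) {
    v <- varcomp(cage = cage, polygenic = polygenic, residual = residual,
                 qtl = v)
  }
  total <- v$qtl + v$polygenic + v$cage + v$residual
  if (total <= 0) stop("total phenotypic variance is zero")
  (v$qtl + v$polygenic) / total
}
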