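#' Simulate the pedigree and housing of a two-line cohort
#'
#' Builds the sample table for a cohort of full-sib families: each family has
#' two parents and `offspring_per_family` offspring, lives in its own cage,
#' and belongs to either the selection or the control line (the first
#' `n_selection_families` families are the selection line).
#'
#' @param spec a [cohort_spec()]
#' @return data.frame with columns `sample_id`, `family_id`, `line`,
#'   `cage_id`, `role`
#' @examples
#' ped <- simulate_pedigree(cohort_spec(n_families = 2, offspring_per_family = 3,
#'                                      n_selection_families = 1))
#' table(ped$line, ped$role)
#' @export
simulate_pedigree <- function(spec) {
  validate_cohort_spec(spec)
  fam <- sprintf("fam_%02d", seq_len(spec$n_families))
  line <- ifelse(seq_len(spec$n_families) <= spec$n_selection_families,
                 "selection", "control")
  per_fam <- 2 + spec$offspring_per_family
  rows <- lapply(seq_len(spec$n_families), function(i) {
    role <- c("parent", "parent",
              rep("offspring", spec$offspring_per_family))
    data.frame(
      sample_id = sprintf("%s_%s%d", fam[i],
                          c("p", "p", rep("o", spec$offspring_per_family)),
                          c(1, 2, seq_len(spec$offspring_per_family))),
      family_id = fam[i],
      line = line[i],
      cage_id = sprintf("cage_%02d", i),
      role = role,
      stringsAsFactors = FALSE
    )
  })
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  stopifnot(nrow(ped) == spec$n_families * per_fam)
  ped
}

#' Simulate founder allele frequencies with line divergence
#'
#' Baseline alternate-allele frequencies are drawn uniformly on
#' `[0.05, 0.95]` per marker. For the divergent subset of markers the two
#' line-specific frequencies are drawn independently from a Balding-Nichols
#' beta distribution `Beta(p (1-F)/F, (1-p)(1-F)/F)` with mean equal to the
#' baseline `p` and differentiation parameter `F = divergence_fst`;
#' non-divergent markers share the baseline frequency in both lines. Any
#' `founder_overrides` in the spec are applied last, pinning exact line
#' frequencies (and the divergent flag) at the listed markers.
#'
#' @param spec a [cohort_spec()]
#' @return data.frame with columns `marker`, `p_selection`, `p_control`,
#'   `divergent`
#' @export
simulate_founder_frequencies <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  m <- spec$n_markers
  p0 <- stats::runif(m, 0.05, 0.95)
  divergent <- rep(FALSE, m)
  if (!is.null(spec$divergent_markers)) {
    divergent[spec$divergent_markers] <- TRUE
  } else if (spec$divergent_fraction > 0) {
    n_div <- round(spec$divergent_fraction * m)
    divergent[sample.int(m, n_div)] <- TRUE
  }
  p_sel <- p0
  p_con <- p0
  f <- spec$divergence_fst
  if (f > 0 && any(divergent)) {
    nd <- sum(divergent)
    shape_scale <- (1 - f) / f
    a <- p0[divergent] * shape_scale
    b <- (1 - p0[divergent]) * shape_scale
    p_sel[divergent] <- stats::rbeta(nd, a, b)
    p_con[divergent] <- stats::rbeta(nd, a, b)
  }
  if (!is.null(spec$founder_overrides)) {
    ov <- spec$founder_overrides
    j <- as.integer(ov$marker)
    p_sel[j] <- ov$p_selection
    p_con[j] <- ov$p_control
    divergent[j] <- ov$p_selection != ov$p_control
  }
  data.frame(marker = seq_len(m), p_selection = p_sel, p_control = p_con,
             divergent = divergent)
}

#' Simulate genotypes down a one-generation pedigree
#'
#' Parents receive binomial(2, p_line) dosages at each marker; each offspring
#' receives one allele sampled from each parent per marker (Mendelian
#' transmission: a heterozygous parent transmits the alternate allele with
#' probability 1/2). Markers are placed at evenly spaced positions along the
#' chromosomes. A `missing_rate > 0` masks genotypes completely at random.
#'
#' @param pedigree sample table from [simulate_pedigree()]
#' @param freqs founder frequencies from [simulate_founder_frequencies()]
#' @param spec the [cohort_spec()] (marker layout, missingness, seed)
#' @return a [genotype_matrix]
#' @export
simulate_genotypes <- function(pedigree, freqs, spec) {
  set.seed(spec$seed + 1L)
  m <- spec$n_markers
  stopifnot(nrow(freqs) == m)
  fams <- unique(pedigree$family_id)
  n <- nrow(pedigree)
  dosage <- matrix(NA_real_, n, m, dimnames = list(pedigree$sample_id, NULL))
  for (fi in fams) {
    idx <- which(pedigree$family_id == fi)
    ln <- pedigree$line[idx[1]]
    p <- if (ln == "selection") freqs$p_selection else freqs$p_control
    par_idx <- idx[pedigree$role[idx] == "parent"]
    off_idx <- idx[pedigree$role[idx] == "offspring"]
    for (pi in par_idx) dosage[pi, ] <- stats::rbinom(m, 2, p)
    if (length(off_idx)) {
      # per-parent transmission probability of the alt allele: dosage/2
      t1 <- dosage[par_idx[1], ] / 2
      t2 <- dosage[par_idx[2], ] / 2
      for (oi in off_idx) {
        dosage[oi, ] <- stats::rbinom(m, 1, t1) + stats::rbinom(m, 1, t2)
      }
    }
  }
  if (spec$missing_rate > 0) {
    mask <- stats::runif(length(dosage)) < spec$missing_rate
    dosage[mask] <- NA_real_
  }
  map <- marker_map_for_spec(spec)
  genotype_matrix(dosage, map)
}

# Even marker placement: markers are split as evenly as possible across
# chromosomes and placed at regular positions along each.
marker_map_for_spec <- function(spec) {
  m <- spec$n_markers
  chrom_of <- rep(seq_len(spec$n_chromosomes), length.out = m)
  chrom_of <- sort(chrom_of)
  pos <- integer(m)
  for (ch in seq_len(spec$n_chromosomes)) {
    k <- sum(chrom_of == ch)
    if (k > 0) {
      pos[chrom_of == ch] <-
        as.integer(round(seq(1, spec$chromosome_length, length.out = k + 1)[-1]))
    }
  }
  data.frame(marker_id = sprintf("snp_%05d", seq_len(m)),
             chrom = sprintf("chr%02d", chrom_of), pos = pos,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Simulate growth-trait phenotypes from the mixed model
#'
#' Phenotypes follow `y = Xb + Sc + Zg + Wq + e`: a fixed mean and line
#' effect, a random cage effect `c ~ N(0, sigma_c^2)` (one cage per family),
#' a polygenic effect `g ~ MVN(0, K sigma_g^2)` with `K` the VanRaden
#' relationship matrix realized from the simulated genotypes, fixed planted
#' QTL effects applied to centered QTL dosages, and i.i.d. residuals. A
#' planted QTL given as a target contribution `cp` is converted to an allele
#' substitution effect `sqrt(cp/(1-cp) * (sigma_c^2+sigma_g^2+sigma_e^2) /
#' var(w))` using the realized dosage variance `var(w)`.
#'
#' @param genotypes a [genotype_matrix] (no missing values)
#' @param pedigree sample table from [simulate_pedigree()]
#' @param spec the [cohort_spec()]
#' @return the sample table with one numeric column per trait appended; the
#'   simulated component realizations are attached as attribute
#'   `components` (list per trait: `cage`, `polygenic`, `qtl`, `residual`
#'   vectors over samples)
#' @export
simulate_phenotypes <- function(genotypes, pedigree, spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed + 2L)
  n <- nrow(pedigree)
  stopifnot(n == n_samples(genotypes))
  vt <- spec$varcomp_true
  cages <- unique(pedigree$cage_id)
  S <- outer(pedigree$cage_id, cages, "==") * 1

  # one polygenic draw per trait from the realized-K normal
  K <- vanraden_grm(genotypes)$K
  ek <- eigen(K, symmetric = TRUE)
  ev <- pmax(ek$values, 0)
  Ksqrt <- ek$vectors %*% (sqrt(ev) * t(ek$vectors))

  out <- pedigree
  comps <- list()
  for (tr in spec$traits) {
    mu <- 0
    line_x <- as.numeric(pedigree$line == "selection")
    y <- mu + spec$line_effect * line_x
    c_eff <- stats::rnorm(length(cages), 0, sqrt(vt$cage))
    cage_term <- as.vector(S %*% c_eff)
    g <- as.vector(Ksqrt %*% stats::rnorm(n)) * sqrt(vt$polygenic)
    qtl_term <- rep(0, n)
    for (q in spec$qtl_list) {
      q <- as.list(q)
      if (q$trait != tr) next
      w <- genotypes$dosage[, as.integer(q$marker)]
      w <- w - mean(w)
      vw <- stats::var(w)
      eff <- if (!is.null(q$effect)) {
        q$effect
      } else {
        cp <- q$cp
        if (vw <= 0) stop("planted QTL marker is monomorphic; cannot hit cp")
        sqrt(cp / (1 - cp) * (vt$cage + vt$polygenic + vt$residual) / vw)
      }
      qtl_term <- qtl_term + w * eff
    }
    e <- stats::rnorm(n, 0, sqrt(vt$residual))
    out[[tr]] <- y + cage_term + g + qtl_term + e
    comps[[tr]] <- list(cage = cage_term, polygenic = g, qtl = qtl_term,
                        residual = e)
  }
  attr(out, "components") <- comps
  out
}

#' Simulate a complete cohort
#'
#' Runs [simulate_pedigree()], [simulate_founder_frequencies()],
#' [simulate_genotypes()] and [simulate_phenotypes()] in order. Identical
#' specs (including the seed) give bit-identical cohorts.
#'
#' @param spec a [cohort_spec()]
#' @return list with elements `pedigree` (sample table without traits),
#'   `founder_freqs`, `genotypes` ([genotype_matrix]), `samples` (sample
#'   table with trait columns) and `spec`
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_families = 3, n_markers = 40, seed = 7))
#' head(cohort$samples)
#' @export
simulate_cohort <- function(spec) {
  ped <- simulate_pedigree(spec)
  freqs <- simulate_founder_frequencies(spec)
  geno <- simulate_genotypes(ped, freqs, spec)
  samples <- simulate_phenotypes(geno, ped, spec)
  list(pedigree = ped, founder_freqs = freqs, genotypes = geno,
       samples = samples, spec = spec)
}

#' Write a simulated cohort to disk
#'
#' Writes `genotypes.vcf`, `samples.tsv` and `phenotypes.tsv` under `dir`.
#'
#' @param cohort result of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return named vector of written paths, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    samples = file.path(dir, "samples.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv")
  )
  write_vcf(cohort$genotypes, paths[["vcf"]],
            contig_lengths = stats::setNames(
              rep(cohort$spec$chromosome_length,
                  cohort$spec$n_chromosomes),
              sprintf("chr%02d", seq_len(cohort$spec$n_chromosomes))))
  write_sample_table(cohort$pedigree, paths[["samples"]])
  traits <- cohort$spec$traits
  write_sample_table(cohort$samples[, c("sample_id", traits)],
                     paths[["phenotypes"]])
  invisible(paths)
}
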