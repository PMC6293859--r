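test_that("pedigree matches the two-line full-sib design", {
  ped <- simulate_pedigree(cohort_spec(n_families = 25,
                                       offspring_per_family = 8,
                                       n_selection_families = 19))
  expect_equal(nrow(ped), 250)
  expect_equal(sum(ped$line == "selection"), 190)
  expect_equal(sum(ped$line == "control"), 60)
  expect_equal(sum(ped$role == "parent"), 50)
  # one cage per family
  expect_equal(unname(table(ped$cage_id, ped$family_id) > 0),
               diag(25) > 0, ignore_attr = TRUE)

  tiny <- simulate_pedigree(cohort_spec(n_families = 1,
                                        offspring_per_family = 0,
                                        n_selection_families = 1))
  expect_equal(nrow(tiny), 2)
  expect_true(all(tiny$role == "parent"))

  two <- simulate_pedigree(cohort_spec(n_families = 2,
                                       offspring_per_family = 3,
                                       n_selection_families = 1))
  expect_equal(nrow(two), 10)
  expect_equal(length(unique(two$cage_id)), 2)
  expect_equal(as.vector(table(two$family_id)), c(5L, 5L))
})

test_that("founder frequencies respect divergence settings", {
  sp0 <- cohort_spec(n_markers = 500, divergence_fst = 0,
                     divergent_fraction = 0.2, seed = 4)
  fr0 <- simulate_founder_frequencies(sp0)
  expect_equal(fr0$p_selection, fr0$p_control)

  spn <- cohort_spec(n_markers = 500, divergent_fraction = 0, seed = 4)
  frn <- simulate_founder_frequencies(spn)
  expect_false(any(frn$divergent))
  expect_equal(frn$p_selection, frn$p_control)

  sp <- cohort_spec(n_markers = 2000, divergent_fraction = 0.1,
                    divergence_fst = 0.3, seed = 5)
  fr <- simulate_founder_frequencies(sp)
  expect_equal(sum(fr$divergent), 200)
  expect_true(all(fr$p_selection >= 0 & fr$p_selection <= 1))
  nondiv <- !fr$divergent
  expect_equal(fr$p_selection[nondiv], fr$p_control[nondiv])

  ov <- data.frame(marker = c(3, 9), p_selection = c(0.9, 0.5),
                   p_control = c(0.1, 0.5))
  spo <- cohort_spec(n_markers = 20, divergent_fraction = 0, seed = 1,
                     founder_overrides = ov)
  fro <- simulate_founder_frequencies(spo)
  expect_equal(fro$p_selection[3], 0.9)
  expect_equal(fro$p_control[3], 0.1)
  expect_true(fro$divergent[3])
  expect_false(fro$divergent[9])
})

test_that("realized divergent-marker Fst tracks the Balding-Nichols draw", {
  # independent MC oracle: mean per-site WC Fst between two lines whose
  # frequencies are independent Balding-Nichols draws at F = 0.3 around a
  # uniform baseline, at the cohort's sample sizes. Computed once with the
  # scalar oracle; the skewed per-site ratio distribution puts the mean well
  # below F (approx. 0.22), and the spec-level tolerance of +/-0.1 around F
  # brackets it.
  sp <- cohort_spec(n_markers = 4000, divergent_fraction = 0.25,
                    divergence_fst = 0.3, seed = 42)
  co <- simulate_cohort(sp)
  sites <- wc_fst_site(co$genotypes, co$samples)
  div <- co$founder_freqs$divergent
  m_div <- mean(sites$fst[div], na.rm = TRUE)
  expect_gt(m_div, 0.3 - 0.1)
  expect_lt(m_div, 0.3 + 0.1)
  # planted divergent markers beat the non-divergent background
  expect_gt(m_div, mean(sites$fst[!div], na.rm = TRUE))
  # the weighted (ratio-of-sums) estimand matches the parameter itself
  wfst <- sum(sites$a[div], na.rm = TRUE) / sum(sites$d[div], na.rm = TRUE)
  expect_lt(abs(wfst - 0.3), 0.05)
})

test_that("genotype transmission is Mendelian", {
  sp <- cohort_spec(n_families = 4, offspring_per_family = 8,
                    n_selection_families = 2, n_markers = 8000, seed = 9)
  co <- simulate_cohort(sp)
  d <- co$genotypes$dosage
  ped <- co$pedigree
  for (fam in unique(ped$family_id)) {
    par <- which(ped$family_id == fam & ped$role == "parent")
    off <- which(ped$family_id == fam & ped$role == "offspring")
    p1 <- d[par[1], ]; p2 <- d[par[2], ]
    o <- d[off, , drop = FALSE]
    # homozygous x homozygous crosses are deterministic
    both0 <- p1 == 0 & p2 == 0
    expect_true(all(o[, both0] == 0))
    cross20 <- (p1 == 2 & p2 == 0) | (p1 == 0 & p2 == 2)
    expect_true(all(o[, cross20] == 1))
    # het x het segregates 1/4 : 1/2 : 1/4 in the long run
    hh <- p1 == 1 & p2 == 1
    draws <- as.vector(o[, hh])
    expect_gt(length(draws), 5000)
    props <- tabulate(draws + 1, 3) / length(draws)
    expect_lt(max(abs(props - c(0.25, 0.5, 0.25))), 0.04)
  }
})

test_that("realized founder allele frequencies stay within sampling error", {
  sp <- cohort_spec(n_markers = 2000, seed = 13, divergent_fraction = 0)
  co <- simulate_cohort(sp)
  par_sel <- co$pedigree$sample_id[co$pedigree$role == "parent" &
                                     co$pedigree$line == "selection"]
  phat <- allele_freq(co$genotypes, par_sel)
  p <- co$founder_freqs$p_selection
  se <- sqrt(p * (1 - p) / (2 * length(par_sel)))
  expect_gt(mean(abs(phat - p) <= 3.5 * se), 0.985)
})

test_that("phenotype decomposition follows the mixed model", {
  # degenerate: no variance anywhere -> constant phenotype
  sp0 <- cohort_spec(n_families = 4, n_markers = 60, n_selection_families = 2,
                     varcomp_true = varcomp(cage = 0, polygenic = 0,
                                            residual = 0),
                     line_effect = 0, seed = 2)
  co0 <- simulate_cohort(sp0)
  expect_equal(stats::sd(co0$samples$Bwt8m), 0)

  # residual-only: phenotype variance near 1
  sp1 <- cohort_spec(varcomp_true = varcomp(residual = 1), line_effect = 0,
                     n_markers = 300, seed = 3)
  co1 <- simulate_cohort(sp1)
  expect_equal(stats::var(co1$samples$Bwt8m), 1, tolerance = 0.2)

  # component bookkeeping at large n
  spb <- cohort_spec(n_families = 60, n_selection_families = 45,
                     n_markers = 600,
                     varcomp_true = varcomp(cage = 1, polygenic = 2,
                                            residual = 1.5),
                     seed = 8)
  cob <- simulate_cohort(spb)
  comp <- attr(cob$samples, "components")$Bwt8m
  cage_draws <- tapply(comp$cage, cob$pedigree$cage_id, unique)
  expect_lt(abs(stats::var(as.numeric(cage_draws)) - 1), 0.25)
  expect_lt(abs(stats::var(comp$residual) - 1.5), 0.25 * 1.5)
  expect_lt(abs(stats::var(comp$polygenic) - 2), 0.25 * 2)

  # out-of-range planted QTL marker fails
  expect_error(
    cohort_spec(n_markers = 10,
                qtl_list = list(list(trait = "Bwt8m", marker = 11,
                                     effect = 1))),
    "out of range")
})

test_that("offspring-on-mid-parent regression recovers h2 = 0.5", {
  slopes <- numeric(12)
  for (r in seq_along(slopes)) {
    sp <- cohort_spec(n_markers = 800, line_effect = 0,
                      varcomp_true = varcomp(cage = 0, polygenic = 2,
                                             residual = 2),
                      seed = 300 + r)
    co <- simulate_cohort(sp)
    ped <- co$pedigree
    y <- co$samples$Bwt8m
    mid <- tapply(y[ped$role == "parent"],
                  ped$family_id[ped$role == "parent"], mean)
    off <- y[ped$role == "offspring"]
    mp <- mid[ped$family_id[ped$role == "offspring"]]
    slopes[r] <- stats::coef(stats::lm(off ~ mp))[2]
  }
  expect_lt(abs(mean(slopes) - 0.5), 0.15)
})

test_that("identical spec and seed reproduce the cohort bit for bit", {
  sp <- cohort_spec(n_families = 5, n_markers = 120,
                    n_selection_families = 3, seed = 77,
                    qtl_list = list(list(trait = "iBwt", marker = 50,
                                         cp = 0.1)))
  a <- simulate_cohort(sp)
  b <- simulate_cohort(sp)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$samples, b$samples)
  expect_identical(a$founder_freqs, b$founder_freqs)
})
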