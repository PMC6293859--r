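test_that("MME blocks reduce correctly when terms are absent", {
  set.seed(101)
  n <- 8
  y <- rnorm(n)
  X <- cbind(1, rep(0:1, each = 4))
  K <- diag(n)
  # no QTL, no cage: standard GBLUP system (b, g blocks only)
  sys <- assemble_mme(y, X, varcomp(polygenic = 1, residual = 1), K = K)
  expect_named(sys$blocks, c("b", "g"))
  expect_equal(dim(sys$C), c(n + 2, n + 2))

  # very large lambda2 shrinks g to zero and b to OLS
  sys2 <- assemble_mme(y, X, varcomp(polygenic = 1e-10, residual = 1), K = K)
  sol2 <- solve_mme(sys2)
  expect_lt(max(abs(sol2$g)), 1e-6)
  expect_equal(sol2$b, unname(stats::coef(stats::lm(y ~ X - 1))),
               tolerance = 1e-6)
})

test_that("MME solutions equal direct-V GLS on a K = I toy and random cases", {
  set.seed(102)
  # n = 6 toy with K = I
  n <- 6
  y <- rnorm(n)
  X <- cbind(1, rep(0:1, each = 3))
  W <- matrix(rbinom(n, 2, 0.5), n, 1)
  S <- diag(n)[, rep(1:2, each = 3)] * 1
  v <- varcomp(cage = 0.5, polygenic = 1.5, residual = 1)
  sys <- assemble_mme(y, X, v, W = W, S = S, K = diag(n))
  sol <- solve_mme(sys)
  or <- gls_oracle(y, X, W, v, S = S, K = diag(n))
  expect_equal(sol$b, or$b, tolerance = 1e-8)
  expect_equal(sol$q, or$q, tolerance = 1e-8)
  expect_equal(sol$c, or$c, tolerance = 1e-8)
  expect_equal(sol$g, or$g, tolerance = 1e-8)

  # 30 random instances, n <= 50 (more in the acceptance suite)
  for (rep in 1:30) {
    n <- sample(6:50, 1)
    y <- rnorm(n)
    X <- cbind(1, rnorm(n))
    W <- if (rep %% 2) matrix(rbinom(n * 2, 2, 0.4), n, 2) else NULL
    S <- if (rep %% 3) {
      nc <- sample(2:4, 1)
      outer(sample(nc, n, TRUE), seq_len(nc), "==") * 1
    } else NULL
    A <- matrix(rnorm(n * n), n)
    K <- crossprod(A) / n + diag(n)   # well-conditioned PSD
    v <- varcomp(cage = if (is.null(S)) 0 else runif(1, 0.2, 2),
                 polygenic = runif(1, 0.2, 2), residual = runif(1, 0.5, 2))
    sol <- solve_mme(assemble_mme(y, X, v, W = W, S = S, K = K))
    or <- gls_oracle(y, X, W, v, S = S, K = K)
    expect_equal(sol$b, or$b, tolerance = 1e-8)
    if (!is.null(W)) expect_equal(sol$q, or$q, tolerance = 1e-8)
    expect_equal(sol$g, or$g, tolerance = 1e-8)
    if (!is.null(S)) expect_equal(sol$c, or$c, tolerance = 1e-8)
    # repeated solves are reproducible
    sol2 <- solve_mme(assemble_mme(y, X, v, W = W, S = S, K = K))
    expect_equal(sol$solution, sol2$solution, tolerance = 1e-10)
  }
})

test_that("singular K demands a ridge and PSD violations are caught", {
  n <- 5
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  Ks <- matrix(1, n, n)                 # rank 1
  v <- varcomp(polygenic = 1, residual = 1)
  expect_error(assemble_mme(y, X, v, K = Ks), "ridge")
  sys <- assemble_mme(y, X, v, K = Ks, ridge = 1e-4)
  expect_true(all(is.finite(solve_mme(sys)$solution)))
  Kneg <- diag(n); Kneg[1, 1] <- -1
  expect_error(assemble_mme(y, X, v, K = Kneg), "positive semi-definite")
})

test_that("REML recovers the residual variance on pure-noise data", {
  set.seed(111)
  n <- 250
  y <- rnorm(n, sd = sqrt(2))
  X <- cbind(1, rbinom(n, 1, 0.5))
  fit <- reml_varcomp(y, X, K = diag(n))
  total <- fit$varcomp$residual + fit$varcomp$polygenic
  expect_lt(abs(total - 2), 0.3 * 2)
  # with K = I the polygenic and residual parts are exchangeable; their sum
  # is the identified quantity, and the trace must be monotone
  expect_true(all(diff(fit$trace) >= 0))
})

test_that("REML pushes the polygenic variance to zero when there is none", {
  hits <- 0
  for (r in 1:10) {
    co <- simulate_cohort(cohort_spec(
      n_families = 15, n_markers = 400, n_selection_families = 10,
      varcomp_true = varcomp(cage = 0, polygenic = 0, residual = 1),
      seed = 400 + r))
    fit <- steplmm(Bwt8m ~ line, data = co$samples,
                   genotypes = co$genotypes, scan = FALSE)
    hits <- hits + (fit$varcomp$polygenic <= 0.05 * fit$varcomp$residual)
  }
  expect_gte(hits, 8)
})

test_that("heritability follows the variance-component formula", {
  expect_equal(round(heritability(15.58, polygenic = 0, cage = 0,
                                  residual = 11.68), 2), 0.57)
  expect_equal(round(heritability(26.19, polygenic = 0, cage = 0,
                                  residual = 44.28), 2), 0.37)
  expect_equal(heritability(varcomp(cage = 1, residual = 1)), 0)
  expect_equal(heritability(varcomp(polygenic = 3, residual = 0)), 1)
  expect_error(heritability(varcomp(residual = 0)), "zero")
  # always in [0, 1]
  set.seed(121)
  for (i in 1:50) {
    v <- varcomp(cage = runif(1, 0, 5), polygenic = runif(1, 0, 5),
                 residual = runif(1, 0.01, 5), qtl = runif(1, 0, 5))
    expect_true(heritability(v) >= 0 && heritability(v) <= 1)
  }
})

test_that("fitted model satisfies the GEBV identity and variance bound", {
  co <- simulate_cohort(cohort_spec(
    n_families = 8, n_markers = 500, n_selection_families = 5, seed = 131,
    qtl_list = list(list(trait = "Bwt8m", marker = 250, cp = 0.25))))
  fit <- steplmm(Bwt8m ~ line, data = co$samples, genotypes = co$genotypes,
                 scan = TRUE, alpha = 0.2)
  idx <- match(fit$sample_id, sample_ids(co$genotypes))
  gebv_manual <- rep(0, fit$n)
  if (length(fit$effects$g)) gebv_manual <- gebv_manual + fit$effects$g
  if (nrow(fit$qtl)) {
    W <- co$genotypes$dosage[idx, match(fit$qtl$marker_id,
                                        co$genotypes$map$marker_id),
                             drop = FALSE]
    gebv_manual <- gebv_manual + as.vector(W %*% fit$effects$q)
  }
  expect_equal(unname(fit$gebv), gebv_manual)
  # residual decomposition is exact
  expect_equal(fit$fitted + fit$residuals, fit$y)
  # contributions plus the polygenic share stay below 1
  v <- fit$varcomp
  vp <- v$qtl + v$polygenic + v$cage + v$residual
  expect_lte(sum(fit$qtl$cp) + v$polygenic / vp, 1 + 1e-8)
  expect_true(all(fit$qtl$cp >= 0 & fit$qtl$cp <= 1))
  # qtl_contribution agrees with the reported cp
  if (nrow(fit$qtl)) {
    w <- co$genotypes$dosage[idx, match(fit$qtl$marker_id[1],
                                        co$genotypes$map$marker_id)]
    expect_equal(qtl_contribution(w, fit$effects$q[1], v), fit$qtl$cp[1])
  }
})

test_that("scan skips collinear markers and is invariant to sample order", {
  co <- simulate_cohort(cohort_spec(n_families = 6, n_markers = 120,
                                    n_selection_families = 4, seed = 141))
  y <- co$samples$Bwt8m
  X <- cbind(1, as.numeric(co$samples$line == "selection"))
  K <- vanraden_grm(co$genotypes)$K
  fit <- reml_varcomp(y, X, K = K)
  G <- co$genotypes$dosage
  # a marker duplicating an existing fixed column is skipped
  Gdup <- cbind(G, dupline = X[, 2] * 2)
  sc <- scan_markers(y, X, Gdup, fit$varcomp, K = K)
  expect_true(sc$skipped[ncol(Gdup)])
  # monomorphic marker skipped
  Gm <- cbind(G, mono = 2)
  expect_true(scan_markers(y, X, Gm, fit$varcomp, K = K)$skipped[ncol(Gm)])
  # permutation of samples leaves p-values unchanged
  perm <- sample(nrow(G))
  sc1 <- scan_markers(y, X, G, fit$varcomp, K = K)
  sc2 <- scan_markers(y[perm], X[perm, ], G[perm, ], fit$varcomp,
                      K = K[perm, perm])
  expect_equal(sc1$p, sc2$p, tolerance = 1e-9)
})

test_that("stepwise selection respects alpha = 0 and finds planted QTL", {
  co <- simulate_cohort(cohort_spec(
    n_families = 12, n_markers = 600, n_selection_families = 8, seed = 151,
    qtl_list = list(list(trait = "Bwt8m", marker = 300, cp = 0.3))))
  fit0 <- steplmm(Bwt8m ~ line, data = co$samples,
                  genotypes = co$genotypes, alpha = 0)
  expect_equal(nrow(fit0$qtl), 0)
  fit <- steplmm(Bwt8m ~ line, data = co$samples, genotypes = co$genotypes,
                 alpha = 0.05)
  expect_gte(nrow(fit$qtl), 1)
  expect_true("snp_00300" %in% fit$qtl$marker_id)
})

test_that("complete-case handling drops samples with missing traits", {
  co <- simulate_cohort(cohort_spec(n_families = 6, n_markers = 150,
                                    n_selection_families = 4, seed = 161))
  co$samples$Bwt8m[1:5] <- NA
  fit <- steplmm(Bwt8m ~ line, data = co$samples, genotypes = co$genotypes,
                 scan = FALSE)
  expect_equal(fit$n, nrow(co$samples) - 5)
  expect_false(any(co$samples$sample_id[1:5] %in% fit$sample_id))
})

test_that("steplmm methods print, predict and simulate coherently", {
  co <- simulate_cohort(cohort_spec(n_families = 6, n_markers = 150,
                                    n_selection_families = 4, seed = 171))
  fit <- steplmm(Bwt8m ~ line, data = co$samples, genotypes = co$genotypes,
                 scan = FALSE)
  expect_output(print(fit), "heritability")
  expect_output(print(summary(fit)), "Fixed effects")
  expect_named(coef(fit), c("(Intercept)", "lineselection"))
  expect_equal(unname(predict(fit)), unname(fit$gebv))
  expect_length(residuals(fit), fit$n)
  idx <- match(fit$sample_id, sample_ids(co$genotypes))
  K <- vanraden_grm(co$genotypes)$K[idx, idx]
  S <- outer(co$samples$cage_id, unique(co$samples$cage_id), "==") * 1
  sims <- simulate(fit, nsim = 3, seed = 1, K = K, S = S)
  expect_equal(dim(sims), c(fit$n, 3))
  expect_true(all(is.finite(as.matrix(sims))))
})
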