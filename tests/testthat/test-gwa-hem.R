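test_that("MAF filter is strict at the boundary and matches recomputation", {
  # 10 accessions: column means 0.1, 0.2, 0.3 -> maf 0.1, 0.2, 0.3
  Z <- matrix(0L, 10, 3,
              dimnames = list(sprintf("a%02d", 1:10), c("s1", "s2", "s3")))
  Z[1, 1] <- 1L; Z[1:2, 2] <- 1L; Z[1:3, 3] <- 1L
  panel <- genotype_panel(Z, data.frame(snp_id = colnames(Z),
                                        chrom = "chr1",
                                        pos = c(5L, 10L, 15L)))
  kept <- maf_filter(panel, 0.2)
  expect_identical(kept$map$snp_id, "s3")   # 0.1 and exactly 0.2 removed
  expect_error(maf_filter(panel, 0.45), "every SNP")
  # random panel: retained set equals brute-force frequency filter
  set.seed(1)
  Zr <- matrix(rbinom(200 * 40, 1, runif(40, 0.05, 0.5)[rep(1:40, each = 200)]),
               200, 40, byrow = FALSE)
  rownames(Zr) <- sprintf("a%03d", 1:200)
  colnames(Zr) <- sprintf("s%02d", 1:40)
  pr <- genotype_panel(Zr, data.frame(snp_id = colnames(Zr), chrom = "chr1",
                                      pos = seq_len(40) * 3L))
  f <- colMeans(Zr)
  expect_identical(maf_filter(pr, 0.2)$map$snp_id,
                   colnames(Zr)[pmin(f, 1 - f) > 0.2])
})

test_that("SNP-BLUP matches closed-form ridge, including the two-line toy", {
  # toy: y = (1, -1), single SNP column (1, 0) centers to (0.5, -0.5);
  # scaled to the classic (1, -1) column via two copies of each accession
  Z <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("hi", "lo"), "s1"))
  panel <- toy_panel(Z)
  fit <- fit_snp_blup(c(hi = 1, lo = -1), panel, lambda = 1)
  # centered column is (0.5, -0.5): u = z'y / (z'z + lambda) = 1 / 1.5
  expect_equal(unname(fit$u_hat), 2 / 3, tolerance = 1e-12)
  expect_equal(fit$mu, 0, tolerance = 1e-12)
  # infinite shrinkage
  set.seed(2)
  Zr <- matrix(rbinom(20 * 50, 1, 0.4), 20, 50)
  y <- rnorm(20)
  pr <- toy_panel(Zr)
  fit_big <- fit_snp_blup(y, pr, lambda = 1e9)
  expect_lt(max(abs(fit_big$u_hat)), 1e-6)
  # dual-form equals primal closed form, fixed and REML-estimated lambda
  for (lam in list(0.7, 30, NULL)) {
    fit_i <- fit_snp_blup(y, pr, lambda = lam)
    oracle <- bf_ridge(Zr, y, fit_i$lambda)
    expect_equal(unname(fit_i$u_hat), oracle$u, tolerance = 1e-8)
    expect_equal(fit_i$mu, oracle$mu, tolerance = 1e-8)
  }
  # missing phenotypes drop accessions with a warning
  y_na <- y; y_na[3] <- NA
  expect_warning(fit_na <- fit_snp_blup(y_na, pr), "missing")
  expect_length(fit_na$u_hat, 50L)
  expect_error(fit_snp_blup(rep(1, 20), pr), "zero phenotypic variance")
})

test_that("shrinkage is monotone in lambda", {
  set.seed(3)
  Z <- matrix(rbinom(25 * 40, 1, 0.3), 25, 40)
  y <- rnorm(25)
  panel <- toy_panel(Z)
  norms <- vapply(c(0.1, 1, 10, 100, 1000), function(lam) {
    sqrt(sum(fit_snp_blup(y, panel, lambda = lam)$u_hat^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("HEM effects equal a brute-force weighted ridge and preserve zeros", {
  set.seed(4)
  Z <- matrix(rbinom(15 * 30, 1, 0.5), 15, 30)
  Z[, 7] <- 1L              # constant column: centered to zero, u_hat = 0
  y <- rnorm(15)
  panel <- toy_panel(Z)
  fit <- fit_snp_blup(y, panel)
  expect_equal(unname(fit$u_hat[7]), 0)
  hem <- hem_update(fit)
  expect_equal(unname(hem$u_hem[7]), 0)   # zero stays exactly zero
  expect_true(all(hem$h >= 0 & hem$h < 1))
  # independent primal weighted solve
  oracle <- bf_weighted_ridge(Z, y, unname(hem$w), fit$sigma_e2)
  expect_equal(unname(hem$u_hem), oracle, tolerance = 1e-8)
  # hat values equal diag((Z'Z + lambda I)^-1 Z'Z)
  Zc <- scale(Z, scale = FALSE)
  h_bf <- diag(solve(crossprod(Zc) + fit$lambda * diag(30), crossprod(Zc)))
  expect_equal(unname(hem$h), h_bf, tolerance = 1e-8)
})

test_that("HEM preserves effect ordering in the exchangeable-column case", {
  # orthogonal equal-norm columns: equal u_hat and equal hat values, so the
  # re-weighted solve must be proportional to the first stage
  Z <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1)) + 0
  rownames(Z) <- sprintf("a%d", 1:4)
  colnames(Z) <- c("s1", "s2")
  panel <- genotype_panel((Z + 1) / 2,
                          data.frame(snp_id = colnames(Z), chrom = "chr1",
                                     pos = c(10L, 20L)))
  y <- c(2, 0, 0, -2)   # equal projection on both columns
  fit <- fit_snp_blup(y, panel, lambda = 2)
  expect_equal(fit$u_hat[["s1"]], fit$u_hat[["s2"]], tolerance = 1e-12)
  hem <- hem_update(fit)
  expect_equal(hem$h[["s1"]], hem$h[["s2"]], tolerance = 1e-12)
  expect_gt(abs(hem$u_hem[["s1"]]), 0)
  expect_equal(hem$u_hem[["s1"]] / fit$u_hat[["s1"]],
               hem$u_hem[["s2"]] / fit$u_hat[["s2"]], tolerance = 1e-10)
})

test_that("permutation thresholds are reproducible and degenerate-safe", {
  set.seed(6)
  Z <- matrix(rbinom(20 * 60, 1, 0.4), 20, 60)
  y <- rnorm(20)
  panel <- toy_panel(Z)
  thr1 <- permutation_threshold(y, panel, q = 0.99, B = 30, seed = 42)
  thr2 <- permutation_threshold(y, panel, q = 0.99, B = 30, seed = 42)
  expect_identical(thr1$tau, thr2$tau)
  thr3 <- permutation_threshold(y, panel, q = 0.99, B = 30, seed = 43)
  expect_false(identical(thr1$tau, thr3$tau))
  # quantile level is monotone up to the maximum of the pooled effects
  thr_max <- permutation_threshold(y, panel, q = 1, B = 30, seed = 42)
  expect_gte(thr_max$tau, thr1$tau)
  # constant phenotype: flagged degenerate with zero threshold
  thr0 <- permutation_threshold(rep(3, 20), panel, B = 10, seed = 1)
  expect_true(thr0$degenerate)
  expect_identical(thr0$tau, 0)
  # per-permutation-max pooling gives a no-smaller threshold
  thr_fw <- permutation_threshold(y, panel, q = 0.99, B = 30, seed = 42,
                                  pool = "per_perm_max")
  expect_gte(thr_fw$tau, thr1$tau)
})

test_that("significance calls are invariant under affine phenotype transforms", {
  cfg <- sim_config(n_accessions = 40, n_snps = 300, n_genes = 30,
                    n_causal_genes = 2, n_response_genes = 1,
                    causal_effect_size = 0.5, seed = 21)
  panel <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg, panel)
  sim <- simulate_phenotypes(cfg, panel, ann)
  tt <- build_trait_table(sim$pheno)
  tm <- build_trait_matrix(tt, "biomass_mg")
  g1 <- run_gwa(tm, panel, traits = "biomass_mg", B = 40, seed = 5)
  tm2 <- tm
  tm2$biomass_mg <- -3.2 * tm2$biomass_mg + 40
  g2 <- run_gwa(tm2, panel, traits = "biomass_mg", B = 40, seed = 5)
  for (cond in names(g1$results$biomass_mg)) {
    expect_identical(g1$results$biomass_mg[[cond]]$sig_calls,
                     g2$results$biomass_mg[[cond]]$sig_calls)
    # effects scale by |a| (sign flips with the transform)
    expect_equal(g2$results$biomass_mg[[cond]]$u_hem,
                 -3.2 * g1$results$biomass_mg[[cond]]$u_hem,
                 tolerance = 1e-6)
  }
})

test_that("run_gwa skips degenerate traits and reports why", {
  cfg <- sim_config(n_accessions = 20, n_snps = 100, n_genes = 10,
                    n_causal_genes = 0, seed = 8)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(cfg, panel, simulate_annotation(cfg, panel))
  tm <- build_trait_matrix(build_trait_table(sim$pheno), "biomass_mg")
  tm$flatline <- 1
  expect_message(
    g <- run_gwa(tm, panel, traits = c("biomass_mg", "flatline"),
                 B = 10, seed = 1),
    "zero variance")
  expect_true(all(g$skipped$trait == "flatline"))
  expect_length(g$results$biomass_mg, 2L)
  expect_null(g$results$flatline$MS)
})
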