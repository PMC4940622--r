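test_that("genotype panels are deterministic, respect the MAF floor, and store true frequencies", {
  cfg <- sim_config(n_accessions = 96, n_snps = 800, n_genes = 80, seed = 1)
  panel <- simulate_genotypes(cfg)
  expect_equal(dim(panel$alleles), c(96L, 800L))
  expect_true(all(panel$alleles %in% c(0L, 1L)))  # no heterozygous codes
  expect_true(min(panel$map$maf) >= 0.2)
  # stored maf matches column-wise recomputation
  p <- colMeans(panel$alleles)
  expect_equal(panel$map$maf, unname(pmin(p, 1 - p)))
  # positions strictly increasing within chromosomes
  for (ch in unique(panel$map$chrom)) {
    expect_true(all(diff(panel$map$pos[panel$map$chrom == ch]) > 0))
  }
  # byte-identical rerun
  panel2 <- simulate_genotypes(cfg)
  expect_identical(panel$alleles, panel2$alleles)
  expect_identical(panel$map, panel2$map)
  # near-degenerate MAF floor, verified by recomputing frequencies
  cfg49 <- sim_config(n_accessions = 96, n_snps = 100, n_genes = 10,
                      maf_min = 0.49, seed = 2)
  panel49 <- simulate_genotypes(cfg49)
  f <- colMeans(panel49$alleles)
  expect_true(all(pmin(f, 1 - f) >= 0.49))
  expect_true(all(pmin(f, 1 - f) <= 0.5))
  # too few SNPs for gene-level calling is rejected up front
  expect_error(sim_config(n_snps = 30, n_genes = 20), "2 \\* `n_genes`")
})

test_that("gene annotations tile chromosomes, hold >= 2 SNPs per gene, and round-trip GFF3", {
  cfg <- sim_config(n_accessions = 24, n_snps = 500, n_genes = 60, seed = 7)
  panel <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg, panel)
  expect_equal(nrow(ann), 60L)
  expect_false(anyDuplicated(ann$gene_id) > 0)
  expect_true(all(ann$start <= ann$end))
  # non-overlap within chromosome
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1) expect_true(all(a$start[-1] > a$end[-nrow(a)]))
  }
  # every gene contains >= 2 SNPs; counts by brute-force containment
  all_snps <- cbind(panel$map, significant = TRUE)
  counts <- bf_gene_counts(all_snps, ann)
  expect_true(all(counts >= 2))
  expect_lte(sum(counts), cfg$n_snps)
  # GFF3 round trip preserves intervals exactly
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, path)
  back <- read_annotation_gff3(path)
  back <- back[match(ann$gene_id, back$gene_id), ]
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$chrom, ann$chrom)
  expect_equal(back$strand, ann$strand)
})

test_that("phenotype generator honours its construction invariants", {
  cfg <- quick_cfg(11)
  panel <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg, panel)
  sim <- simulate_phenotypes(cfg, panel, ann)
  ph <- sim$pheno
  expect_equal(nrow(ph), 96L * 2L * 5L)
  expect_setequal(unique(ph$treatment), c("MS", "MS+Allyl"))
  comp <- as.matrix(ph[, compound_catalog()$abbreviation])
  expect_true(all(comp >= 0))
  # AOP2-null accessions have *exactly* zero allyl in the control arm
  null_ms <- ph[!ph$aop2_functional & ph$treatment == "MS", ]
  expect_true(nrow(null_ms) > 0)
  expect_true(all(null_ms$Allyl == 0))
  # and strictly positive allyl (uptake) under treatment
  null_tr <- ph[!ph$aop2_functional & ph$treatment == "MS+Allyl", ]
  expect_true(all(null_tr$Allyl > 0))
  # causal-gene ground truth recorded
  expect_length(sim$truth$causal_genes, cfg$n_causal_genes)
  expect_true(all(sim$truth$causal_genes %in% ann$gene_id))
  # determinism
  sim2 <- simulate_phenotypes(cfg, panel, ann)
  expect_identical(sim$pheno, sim2$pheno)
})

test_that("zero heritability target yields near-zero estimated heritability", {
  h2 <- vapply(1:20, function(s) {
    cfg <- sim_config(n_accessions = 40, n_snps = 120, n_genes = 12,
                      n_causal_genes = 0, target_h2_biomass = 0, seed = s)
    panel <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(cfg, panel, simulate_annotation(cfg, panel))
    suppressMessages(broad_sense_h2(sim$pheno, "biomass_mg")$H2)
  }, numeric(1))
  expect_lt(mean(h2), 0.05)
})

test_that("expression fold-changes are deterministic and enriched only when requested", {
  cfg <- sim_config(n_accessions = 12, n_snps = 400, n_genes = 100,
                    seed = 5)
  panel <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg, panel)
  causal <- ann$gene_id[1:10]
  fc1 <- simulate_expression_response(cfg, ann, causal)
  fc2 <- simulate_expression_response(cfg, ann, causal)
  expect_identical(fc1, fc2)
  # enrichment > 0: causal |log2fc| exceeds non-causal (pooled over seeds)
  pool <- lapply(1:50, function(s) {
    cfgs <- sim_config(n_accessions = 12, n_snps = 400, n_genes = 100,
                       expression_enrichment = 1.5, seed = 100 + s)
    fc <- simulate_expression_response(cfgs, ann, causal)
    split(abs(fc$log2fc), fc$gene_id %in% causal)
  })
  x_causal <- unlist(lapply(pool, `[[`, "TRUE"))
  x_other <- unlist(lapply(pool, `[[`, "FALSE"))
  tt <- t.test(x_causal, x_other, alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
  # enrichment == 0: distributions coincide
  pool0 <- lapply(1:50, function(s) {
    cfg0 <- sim_config(n_accessions = 12, n_snps = 400, n_genes = 100,
                       expression_enrichment = 0, seed = 300 + s)
    fc <- simulate_expression_response(cfg0, ann, causal)
    split(abs(fc$log2fc), fc$gene_id %in% causal)
  })
  tt0 <- t.test(unlist(lapply(pool0, `[[`, "TRUE")),
                unlist(lapply(pool0, `[[`, "FALSE")))
  expect_gt(tt0$p.value, 1e-3)
})

test_that("study serialization round-trips genotypes, phenotypes and VCF", {
  cfg <- sim_config(n_accessions = 12, n_snps = 60, n_genes = 6,
                    n_causal_genes = 1, seed = 9)
  dir <- withr::local_tempdir()
  study <- simulate_study(cfg, dir, vcf = TRUE)
  expect_true(all(file.exists(unlist(study[c("genotype", "annotation",
                                             "phenotype", "fold_change",
                                             "truth_json", "vcf")]))))
  panel2 <- read_genotype_tsv(study$genotype)
  expect_identical(panel2$alleles, study$panel$alleles)
  expect_equal(panel2$map, study$panel$map)
  ph2 <- read_phenotype_tsv(study$phenotype)
  expect_equal(names(ph2), names(study$pheno))
  expect_equal(as.data.frame(ph2), as.data.frame(study$pheno),
               tolerance = 1e-12)
  # VCF parses with an independent reader and preserves the calls
  v <- vcfR::read.vcfR(study$vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  expect_equal(dim(gt), c(60L, 12L))
  expect_identical(unname(t(gt) == "1"), unname(study$panel$alleles == 1L))
})
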