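#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the synthetic analogue of the experimental design: 96 inbred
# accessions genotyped at 3000 common SNPs (MAF >= 0.2) over 300 genes,
# phenotyped in quintuplicate under control medium (MS) and medium with
# 50 uM allyl glucosinolate (MS+Allyl). Five causal genes are planted for
# biomass (three acting in both arms, two treatment-specific), and half
# the panel is AOP2-null (no endogenous allyl, so treated-arm allyl is
# pure uptake). All downstream stages read only the files written here.

suppressPackageStartupMessages(library(allylgwa))

seed <- 1L
out_dir <- "results/sim"

cfg <- sim_config(n_accessions = 96, n_snps = 3000, n_genes = 300,
                  n_causal_genes = 5, n_response_genes = 2,
                  causal_effect_size = 0.25, seed = seed)
print(cfg)

study <- simulate_study(cfg, out_dir, vcf = TRUE)
cat("\nwrote:\n")
for (f in c("genotype", "annotation", "phenotype", "fold_change",
            "truth_json", "vcf")) {
  cat(sprintf("  %s\n", study[[f]]))
}
cat(sprintf("\npanel: %d accessions x %d SNPs, realized MAF in [%.3f, %.3f]\n",
            nrow(study$panel$alleles), ncol(study$panel$alleles),
            min(study$panel$map$maf), max(study$panel$map$maf)))
cat(sprintf("AOP2-null accessions: %d of %d\n",
            sum(!study$truth$aop2_functional), cfg$n_accessions))
cat("causal genes:", paste(study$truth$causal_genes, collapse = ", "), "\n")
cat("treatment-specific:", paste(study$truth$response_genes,
                                 collapse = ", "), "\n")
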