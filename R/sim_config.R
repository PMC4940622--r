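#' Configuration for the synthetic study generator
#'
#' Collects every knob of the synthetic-cohort generator in one validated
#' object. The defaults describe the design this package emulates: a panel of
#' 96 inbred accessions phenotyped in quintuplicate under a control medium
#' (`MS`) and the same medium supplemented with 50 uM allyl glucosinolate
#' (`MS+Allyl`), genotyped at common SNPs (minor-allele frequency at least
#' 0.2), with roughly half the panel carrying a natural AOP2 knockout and
#' therefore no endogenous allyl GSL.
#'
#' @param n_accessions Number of inbred accessions in the panel.
#' @param n_snps Number of simulated SNPs (must be at least `2 * n_genes`
#'   so that every gene can contain two SNPs).
#' @param n_genes Number of annotated genes.
#' @param maf_min Lower bound for the realized minor-allele frequency of
#'   every emitted SNP; must lie in `[0, 0.5)`.
#' @param reps_per_treatment Seedlings measured per accession per treatment.
#' @param n_blocks Number of experimental blocks; replicates are rotated
#'   through blocks.
#' @param n_causal_genes Number of genes given causal effects on biomass.
#' @param n_response_genes How many of the causal genes are
#'   treatment-specific ("response" genes whose effects are expressed only
#'   under allyl feeding, driving the accession-by-treatment interaction).
#'   Defaults to half of `n_causal_genes`.
#' @param snps_per_causal_gene Causal SNPs placed in each causal gene
#'   (at least 2 so gene-level calling can recover them).
#' @param causal_effect_size Per-SNP allele substitution effect, in units of
#'   the phenotypic standard deviation.
#' @param target_h2_biomass Broad-sense heritability the biomass generator
#'   aims at (fraction of phenotypic variance between accessions).
#' @param target_h2_uptake Broad-sense heritability of foliar allyl
#'   accumulation among AOP2-null accessions under treatment.
#' @param uptake_mean Grand mean of foliar allyl accumulation from uptake,
#'   umol per g fresh weight.
#' @param uptake_cv Coefficient of variation of accession-level uptake
#'   means (lognormal across accessions).
#' @param frac_aop2_null Fraction of accessions lacking a functional AOP2
#'   (zero endogenous allyl).
#' @param expression_enrichment How much larger (multiplicatively) the
#'   log2 fold-change spread of causal genes is relative to non-causal
#'   genes in the simulated transcript-response table; 0 means identical
#'   distributions.
#' @param treatment_label Label of the treated condition.
#' @param dose_label Dose annotation carried through to output metadata.
#' @param n_chromosomes Chromosomes the SNPs are spread across.
#' @param seed Integer seed making every generator call reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_snps = 500, n_genes = 60, seed = 1)
#' cfg$n_accessions
#' @export
sim_config <- function(n_accessions = 96L,
                       n_snps = 3000L,
                       n_genes = 300L,
                       maf_min = 0.2,
                       reps_per_treatment = 5L,
                       n_blocks = 5L,
                       n_causal_genes = 5L,
                       n_response_genes = NULL,
                       snps_per_causal_gene = 2L,
                       causal_effect_size = 0.25,
                       target_h2_biomass = 0.88,
                       target_h2_uptake = 0.70,
                       uptake_mean = 0.34,
                       uptake_cv = 0.45,
                       frac_aop2_null = 0.5,
                       expression_enrichment = 1.5,
                       treatment_label = "MS+Allyl",
                       dose_label = "50 uM",
                       n_chromosomes = 5L,
                       seed = 1L) {
  if (is.null(n_response_genes)) {
    n_response_genes <- as.integer(ceiling(n_causal_genes / 2))
  }
  cfg <- list(
    n_accessions = as.integer(n_accessions),
    n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes),
    maf_min = maf_min,
    reps_per_treatment = as.integer(reps_per_treatment),
    n_blocks = as.integer(n_blocks),
    n_causal_genes = as.integer(n_causal_genes),
    n_response_genes = as.integer(n_response_genes),
    snps_per_causal_gene = as.integer(snps_per_causal_gene),
    causal_effect_size = causal_effect_size,
    target_h2_biomass = target_h2_biomass,
    target_h2_uptake = target_h2_uptake,
    uptake_mean = uptake_mean,
    uptake_cv = uptake_cv,
    frac_aop2_null = frac_aop2_null,
    expression_enrichment = expression_enrichment,
    treatment_label = treatment_label,
    dose_label = dose_label,
    n_chromosomes = as.integer(n_chromosomes),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_accessions >= 2L,
    cfg$n_snps >= 1L,
    cfg$n_genes >= 1L,
    cfg$reps_per_treatment >= 1L,
    cfg$n_blocks >= 1L,
    cfg$n_chromosomes >= 1L,
    cfg$snps_per_causal_gene >= 2L,
    cfg$causal_effect_size >= 0,
    cfg$uptake_mean > 0,
    cfg$uptake_cv >= 0
  )
  if (cfg$maf_min < 0 || cfg$maf_min >= 0.5) {
    stop("`maf_min` must lie in [0, 0.5)", call. = FALSE)
  }
  for (f in c("target_h2_biomass", "target_h2_uptake", "frac_aop2_null")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", f), call. = FALSE)
    }
  }
  if (cfg$target_h2_biomass >= 1) {
    stop("`target_h2_biomass` >= 1 is unattainable", call. = FALSE)
  }
  if (cfg$target_h2_uptake >= 1) {
    stop("`target_h2_uptake` >= 1 is unattainable", call. = FALSE)
  }
  if (cfg$n_causal_genes > cfg$n_genes) {
    stop("`n_causal_genes` cannot exceed `n_genes`", call. = FALSE)
  }
  if (cfg$n_response_genes > cfg$n_causal_genes) {
    stop("`n_response_genes` cannot exceed `n_causal_genes`", call. = FALSE)
  }
  if (cfg$n_snps < 2L * cfg$n_genes) {
    stop("`n_snps` must be at least 2 * `n_genes` ",
         "(every gene needs room for two SNPs)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d accessions x %d SNPs (MAF >= %.2f), %d genes on %d chromosomes\n",
              x$n_accessions, x$n_snps, x$maf_min, x$n_genes, x$n_chromosomes))
  cat(sprintf("  %d reps x 2 treatments (MS vs %s, %s), %d blocks\n",
              x$reps_per_treatment, x$treatment_label, x$dose_label, x$n_blocks))
  cat(sprintf("  %d causal genes (%d treatment-specific), effect %.2f SD/allele\n",
              x$n_causal_genes, x$n_response_genes, x$causal_effect_size))
  cat(sprintf("  target H2: biomass %.2f, uptake %.2f; AOP2-null fraction %.2f; seed %d\n",
              x$target_h2_biomass, x$target_h2_uptake, x$frac_aop2_null, x$seed))
  invisible(x)
}
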