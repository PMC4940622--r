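#' Simulate replicate-level biomass and glucosinolate phenotypes
#'
#' Generates a long-format phenotype table for a two-treatment randomized
#' block experiment over the accessions of `panel`:
#'
#' * **Biomass** (`biomass_mg`, mg/plant) is built as grand mean +
#'   accession genetic value + treatment main effect + accession-by-
#'   treatment interaction + block effect + residual. The genetic value is
#'   the sum of causal-SNP allele effects (from `cfg$n_causal_genes` genes
#'   chosen in `ann`, `cfg$snps_per_causal_gene` SNPs each) plus an
#'   unlinked polygenic term; treatment-specific ("response") causal genes
#'   act only under allyl feeding and drive the interaction. Component
#'   variances are rescaled so the realized accession-level variance
#'   fraction equals `cfg$target_h2_biomass` under the expected-mean-square
#'   estimator of [broad_sense_h2()].
#' * **Compound abundances** (umol/g fresh weight, one column per compound
#'   of [compound_catalog()]) follow a multiplicative model: compound base
#'   level x accession effect x treatment response x accession-by-treatment
#'   response x block x replicate noise, which keeps every abundance
#'   non-negative. Aliphatic compounds tend to rise and indolic compounds
#'   to fall under treatment.
#' * **Allyl** is special-cased: accessions without a functional AOP2 have
#'   *exactly zero* endogenous allyl, so their allyl content under
#'   treatment is pure uptake. Accession uptake means are lognormal with
#'   mean `cfg$uptake_mean` and CV `cfg$uptake_cv`; replicate noise is
#'   calibrated so the uptake heritability equals `cfg$target_h2_uptake`.
#'
#' @param cfg A [sim_config()].
#' @param panel A [genotype_panel()] consistent with `ann`.
#' @param ann Gene annotation from [simulate_annotation()].
#' @return A list with elements
#'   * `pheno`: tibble with columns `accession`, `treatment`
#'     (`"MS"` / `cfg$treatment_label`), `block`, `plant_id`,
#'     `aop2_functional`, `biomass_mg`, and the 17 compound columns;
#'   * `truth`: ground-truth list (causal/response gene ids and their SNPs,
#'     variance components, accession genetic values, uptake means, seed).
#' @examples
#' cfg <- sim_config(n_accessions = 12, n_snps = 120, n_genes = 12,
#'                   n_causal_genes = 2, seed = 3)
#' panel <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(cfg, panel, simulate_annotation(cfg, panel))
#' head(sim$pheno[, 1:7])
#' @export
simulate_phenotypes <- function(cfg, panel, ann) {
  validate_sim_config(cfg)
  if (!all(ann$chrom %in% panel$map$chrom)) {
    stop("annotation and panel disagree on chromosome names", call. = FALSE)
  }
  set.seed(derive_seed(cfg$seed, 3L))

  n <- cfg$n_accessions
  acc <- rownames(panel$alleles)
  stopifnot(length(acc) == n)
  treatments <- c("MS", cfg$treatment_label)
  r <- cfg$reps_per_treatment

  ## ---- causal architecture for biomass --------------------------------
  biomass_mean <- 15    # mg/plant, 15-day-old rosettes
  biomass_sd <- 3.5     # phenotypic SD scale (Vp = biomass_sd^2)
  h2 <- cfg$target_h2_biomass
  Vp <- biomass_sd^2
  ce <- cfg$causal_effect_size

  n_resp <- cfg$n_response_genes
  n_main <- cfg$n_causal_genes - n_resp
  causal_genes <- character(0)
  if (cfg$n_causal_genes > 0) {
    causal_genes <- sample(ann$gene_id, cfg$n_causal_genes)
  }
  main_genes <- head(causal_genes, n_main)
  resp_genes <- setdiff(causal_genes, main_genes)

  pick_snps <- function(genes) {
    if (length(genes) == 0) return(character(0))
    unlist(lapply(genes, function(g) {
      row <- ann[ann$gene_id == g, ]
      inside <- panel$map$snp_id[panel$map$chrom == row$chrom &
                                   panel$map$pos >= row$start &
                                   panel$map$pos <= row$end]
      sample(inside, min(cfg$snps_per_causal_gene, length(inside)))
    }))
  }
  main_snps <- pick_snps(main_genes)
  resp_snps <- pick_snps(resp_genes)

  # variance bookkeeping (in units of Vp): each causal SNP contributes
  # ce^2; response effects act in one arm only, so their contribution to
  # the accession-level variance is a quarter of their raw variance
  v_main_raw <- length(main_snps) * ce^2
  v_resp_raw <- length(resp_snps) * ce^2
  v_causal <- v_main_raw + v_resp_raw / 4
  shrink <- 1
  if (v_causal > h2 && v_causal > 0) {
    shrink <- h2 / v_causal
    message(sprintf(
      "causal-SNP variance (%.3f Vp) exceeds the genetic budget h2 = %.3f; scaling effects down",
      v_causal, h2))
    v_main_raw <- v_main_raw * shrink
    v_resp_raw <- v_resp_raw * shrink
  }
  v_poly <- max(0, h2 - v_main_raw - v_resp_raw / 4)

  snp_score <- function(snps, v_target) {
    if (length(snps) == 0 || v_target <= 0) return(rep(0, n))
    Z <- panel$alleles[, snps, drop = FALSE]
    beta <- sample(c(-1, 1), length(snps), replace = TRUE)
    scale_to_var(as.numeric(Z %*% beta), v_target * Vp)
  }
  g_main <- snp_score(main_snps, v_main_raw) +
    scale_to_var(rnorm(n), v_poly * Vp)
  g_resp <- snp_score(resp_snps, v_resp_raw)
  sigma_e2 <- (1 - h2) * Vp

  treat_effect <- c(0, -0.07 * biomass_mean)  # allyl feeding lowers biomass
  names(treat_effect) <- treatments
  block_sd_biomass <- 0.01 * biomass_sd       # block was a minor nuisance term
  block_eff <- rnorm(cfg$n_blocks, 0, block_sd_biomass)

  ## ---- AOP2 status and allyl uptake -----------------------------------
  n_null <- round(cfg$frac_aop2_null * n)
  aop2_functional <- rep(TRUE, n)
  if (n_null > 0) aop2_functional[sample.int(n, n_null)] <- FALSE
  names(aop2_functional) <- acc

  # accession uptake means: lognormal, log-standardised so the geometric
  # mean/CV are exact for every cohort
  sdlog_u <- sqrt(log(1 + cfg$uptake_cv^2))
  meanlog_u <- log(cfg$uptake_mean) - sdlog_u^2 / 2
  zu <- rnorm(n)
  zu <- if (n > 1 && sd(zu) > 0) (zu - mean(zu)) / sd(zu) else rep(0, n)
  uptake <- exp(meanlog_u + sdlog_u * zu)
  names(uptake) <- acc
  # replicate noise calibrated so Var(between)/(Var(between)+Var(within))
  # equals target_h2_uptake; within-variance of m * exp(N(-s^2/2, s^2)) is
  # m^2 (e^{s^2}-1), so calibrate s against the realized accession moments
  sg2_u <- if (n > 1) stats::var(uptake) else 0
  h2u <- cfg$target_h2_uptake
  se2_u <- if (h2u > 0) sg2_u * (1 - h2u) / h2u else sg2_u * 1e4 + 1e-4
  em2 <- mean(uptake^2)
  s_up <- sqrt(log(1 + se2_u / em2))

  ## ---- compound profile model -----------------------------------------
  catalog <- compound_catalog()
  compounds <- catalog$abbreviation
  base_abund <- c(
    "3OHP" = 0.8, "3MSP" = 0.3, "2-OH-butenyl" = 0.4, "4OHB" = 0.05,
    "4MSB" = 1.2, "Allyl" = 1.2, "5MSP" = 0.05, "But-3-enyl" = 0.6,
    "3MTP" = 0.1, "7MSH" = 0.15, "4MTB" = 0.5, "8MSO" = 0.6,
    "7MTH" = 0.1, "8MTO" = 0.4, "I3M" = 0.9, "4MI3M" = 0.15, "MI3M" = 0.3
  )
  stopifnot(setequal(names(base_abund), compounds))
  treat_mult <- ifelse(catalog$class == "aliphatic", 1.25, 0.8)
  names(treat_mult) <- compounds
  acc_sdlog <- 0.6     # accession spread of compound levels
  int_sdlog <- 0.25    # accession x treatment response spread
  rep_sdlog <- 0.3     # replicate noise
  block_sdlog <- 0.02

  acc_mult <- matrix(exp(rnorm(n * length(compounds), 0, acc_sdlog)),
                     n, length(compounds),
                     dimnames = list(acc, compounds))
  int_mult <- matrix(lnorm_mult(n * length(compounds), int_sdlog),
                     n, length(compounds),
                     dimnames = list(acc, compounds))
  block_mult <- matrix(lnorm_mult(cfg$n_blocks * length(compounds),
                                  block_sdlog),
                       cfg$n_blocks, length(compounds),
                       dimnames = list(NULL, compounds))

  ## ---- assemble the replicate-level table -----------------------------
  design <- expand.grid(rep = seq_len(r), treatment = treatments,
                        accession = acc, stringsAsFactors = FALSE)
  design$block <- ((design$rep - 1L) %% cfg$n_blocks) + 1L
  nrows <- nrow(design)
  ai <- match(design$accession, acc)
  ti <- match(design$treatment, treatments)

  biomass <- biomass_mean + g_main[ai] +
    ifelse(ti == 2L, g_resp[ai], 0) +
    treat_effect[ti] + block_eff[design$block] +
    rnorm(nrows, 0, sqrt(sigma_e2))
  biomass <- pmax(biomass, 0.1)

  comp_mat <- matrix(0, nrows, length(compounds),
                     dimnames = list(NULL, compounds))
  for (cix in seq_along(compounds)) {
    cmp <- compounds[cix]
    mult <- ifelse(ti == 2L, treat_mult[cmp] * int_mult[ai, cix], 1)
    comp_mat[, cix] <- base_abund[cmp] * acc_mult[ai, cix] * mult *
      block_mult[design$block, cix] * lnorm_mult(nrows, rep_sdlog)
  }

  # allyl: endogenous (AOP2-functional only) + uptake in the treated arm
  endo <- base_abund["Allyl"] * acc_mult[, "Allyl"]
  endo[!aop2_functional] <- 0
  allyl_endo <- endo[ai] *
    ifelse(ti == 2L, treat_mult["Allyl"] * int_mult[ai, "Allyl"], 1) *
    lnorm_mult(nrows, rep_sdlog)
  allyl_endo[!aop2_functional[ai]] <- 0   # exact zero, not just small
  uptake_part <- ifelse(ti == 2L,
                        uptake[ai] * lnorm_mult(nrows, s_up) *
                          block_mult[design$block, "Allyl"],
                        0)
  comp_mat[, "Allyl"] <- allyl_endo + uptake_part

  pheno <- tibble(
    accession = design$accession,
    treatment = design$treatment,
    block = as.integer(design$block),
    plant_id = sprintf("%s_%s_r%d", design$accession,
                       ifelse(ti == 2L, "allyl", "ms"), design$rep),
    aop2_functional = aop2_functional[ai],
    biomass_mg = as.numeric(biomass)
  )
  pheno <- cbind(pheno, as_tibble(comp_mat))
  pheno <- as_tibble(pheno)

  truth <- list(
    seed = cfg$seed,
    causal_genes = causal_genes,
    main_genes = main_genes,
    response_genes = resp_genes,
    main_snps = main_snps,
    response_snps = resp_snps,
    effect_scale = shrink,
    variance_components = list(
      Vp = Vp, h2_biomass = h2,
      v_main = v_main_raw * Vp, v_response = v_resp_raw * Vp,
      v_polygenic = v_poly * Vp, sigma_e2 = sigma_e2,
      uptake_sigma_g2 = sg2_u, uptake_sigma_e2 = se2_u
    ),
    genetic_values = list(main = g_main, response = g_resp),
    uptake_means = uptake,
    aop2_functional = aop2_functional
  )
  list(pheno = pheno, truth = truth)
}

#' Simulate a transcript fold-change response table
#'
#' One signed log2 fold-change per annotated gene, emulating a transcript
#' response profile to allyl feeding. Non-causal genes draw from
#' `N(0, 0.5^2)`; genes named in `causal_genes` draw from the same
#' distribution inflated by `1 + cfg$expression_enrichment`, so with
#' enrichment 0 the two distributions coincide.
#'
#' @param cfg A [sim_config()].
#' @param ann Gene annotation.
#' @param causal_genes Character vector of gene ids to enrich (typically
#'   `truth$causal_genes` from [simulate_phenotypes()]); may be empty.
#' @return Tibble with columns `gene_id`, `log2fc`.
#' @export
simulate_expression_response <- function(cfg, ann, causal_genes = character(0)) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, 4L))
  base_sd <- 0.5
  lfc <- rnorm(nrow(ann), 0, base_sd)
  hit <- ann$gene_id %in% causal_genes
  lfc[hit] <- lfc[hit] * (1 + cfg$expression_enrichment)
  tibble(gene_id = ann$gene_id, log2fc = lfc)
}
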