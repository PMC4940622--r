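#' Genome-wide association over traits and conditions
#'
#' Runs the SNP-BLUP + HEM + permutation-threshold pipeline for every
#' requested trait within every treatment condition of a trait matrix of
#' accession LS-means. By default the traits are those measurable in all
#' accessions: biomass plus the five glucosinolate summaries (short-chain,
#' long-chain, total aliphatic, total indolic, total GSL). Per-trait
#' failures (e.g. zero variance) are reported and skipped without
#' aborting the batch.
#'
#' @param trait_matrix Tibble from [build_trait_matrix()]: `accession`,
#'   `treatment`, one column per trait.
#' @param panel A [genotype_panel()]; [maf_filter()] is applied with
#'   `maf_min`.
#' @param traits Trait columns to map; default the standard six.
#' @param maf_min MAF filter threshold (strict), default 0.2.
#' @param q Permutation quantile for the significance threshold.
#' @param B Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @param pool Threshold pooling rule, see [permutation_threshold()].
#' @return Object of class `gwa_result`: list with
#'   * `results`: nested list `results[[trait]][[condition]]`, each a
#'     `hem_result` with `tau`, `q`, `B` and logical `sig_calls` filled;
#'   * `effects`: long tibble (trait, condition, chrom, pos, snp_id,
#'     u_hem, abs_effect, significant) ready for Manhattan plotting;
#'   * `skipped`: tibble of skipped trait x condition with reasons.
#' @export
run_gwa <- function(trait_matrix, panel,
                    traits = default_gwa_traits(),
                    maf_min = 0.2, q = 0.99, B = 1000L, seed = 1L,
                    pool = "pooled") {
  stopifnot(all(c("accession", "treatment") %in% names(trait_matrix)))
  missing <- setdiff(traits, names(trait_matrix))
  if (length(missing) > 0) {
    stop("trait matrix lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  panel_f <- maf_filter(panel, maf_min)
  engine <- gwa_engine(panel_f$alleles)
  conditions <- unique(trait_matrix$treatment)
  results <- list()
  skipped <- list()
  eff_rows <- list()
  for (tr in traits) {
    results[[tr]] <- list()
    for (cond in conditions) {
      rows <- trait_matrix$treatment == cond
      y <- trait_matrix[[tr]][rows]
      names(y) <- trait_matrix$accession[rows]
      y <- y[rownames(panel_f$alleles)]
      res <- tryCatch({
        if (anyNA(y)) stop("missing LS-means for some accessions")
        if (stats::var(y) == 0) stop("trait has zero variance")
        fit <- fit_ridge_engine(engine, as.numeric(y))
        hem_raw <- hem_engine(engine, fit, as.numeric(y))
        thr <- permutation_threshold(as.numeric(y), panel_f, q = q, B = B,
                                     seed = derive_seed(seed, match(cond, conditions)),
                                     pool = pool, engine = engine)
        hem <- structure(list(
          u_hem = stats::setNames(hem_raw$u_hem, engine$snp_ids),
          h = stats::setNames(hem_raw$h, engine$snp_ids),
          w = stats::setNames(hem_raw$w, engine$snp_ids),
          lambda = fit$lambda, sigma_u2 = fit$sigma_u2,
          sigma_e2 = fit$sigma_e2, mu = fit$mu,
          tau = thr$tau, q = q, B = as.integer(B),
          sig_calls = abs(hem_raw$u_hem) > thr$tau
        ), class = "hem_result")
        hem
      }, error = function(e) e)
      if (inherits(res, "error")) {
        message(sprintf("skipping %s / %s: %s", tr, cond,
                        conditionMessage(res)))
        skipped[[length(skipped) + 1L]] <- tibble(trait = tr,
                                                  condition = cond,
                                                  reason = conditionMessage(res))
        next
      }
      results[[tr]][[cond]] <- res
      eff_rows[[length(eff_rows) + 1L]] <- tibble(
        trait = tr, condition = cond,
        chrom = panel_f$map$chrom, pos = panel_f$map$pos,
        snp_id = panel_f$map$snp_id,
        u_hem = as.numeric(res$u_hem),
        abs_effect = abs(as.numeric(res$u_hem)),
        significant = as.integer(res$sig_calls)
      )
    }
  }
  structure(list(
    results = results,
    effects = if (length(eff_rows)) do.call(rbind, eff_rows) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    settings = list(maf_min = maf_min, q = q, B = as.integer(B),
                    seed = as.integer(seed), pool = pool)
  ), class = "gwa_result")
}

#' Default traits used for association mapping
#'
#' Biomass plus the five glucosinolate summaries present in all
#' accessions.
#' @return Character vector of six trait names.
#' @export
default_gwa_traits <- function() {
  c("biomass_mg", "Short chain GSL", "Long chain GSL",
    "Total aliphatics", "Total indolics", "Total GSL")
}
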