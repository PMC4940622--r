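backtick <- function(x) paste0("`", x, "`")

# default model terms given the columns present in the data
default_terms <- function(data) {
  terms <- "accession"
  if ("treatment" %in% names(data) &&
      length(unique(data$treatment)) > 1L) {
    terms <- c(terms, "treatment", "accession:treatment")
  }
  if ("block" %in% names(data) && length(unique(data$block)) > 1L) {
    terms <- c(terms, "block")
  }
  terms
}

prep_factors <- function(data) {
  for (f in intersect(c("accession", "treatment", "block", "genotype"),
                      names(data))) {
    data[[f]] <- factor(data[[f]])
  }
  data
}

#' Sequential ANOVA for a replicate-level trait
#'
#' Fits the fixed-effects linear model implied by `terms` (default:
#' accession, treatment, their interaction, and an additive block term —
#' block is treated as a fixed nuisance term) and returns the Type-I
#' (sequential) ANOVA table. For the complete crossed design the degrees
#' of freedom are fixed by the design shape: `a - 1` for accession, 1 for
#' treatment, `a - 1` for the interaction and `n_blocks - 1` for block.
#'
#' @param data Replicate-level table with the factor columns named in
#'   `terms` and a numeric trait column.
#' @param trait Name of the trait column.
#' @param terms Character vector of model terms in the order they enter
#'   the sequential decomposition; default derived from the columns
#'   present.
#' @return Tibble with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`; the last row is the residual (`Error`) line.
#' @examples
#' cfg <- sim_config(n_accessions = 8, n_snps = 60, n_genes = 6,
#'                   n_causal_genes = 0, seed = 2)
#' panel <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(cfg, panel, simulate_annotation(cfg, panel))
#' fit_anova(sim$pheno, "biomass_mg")
#' @export
fit_anova <- function(data, trait, terms = NULL) {
  if (!trait %in% names(data)) stop("trait column not found", call. = FALSE)
  if (!is.numeric(data[[trait]])) stop("trait must be numeric", call. = FALSE)
  data <- prep_factors(as.data.frame(data))
  if (is.null(terms)) terms <- default_terms(data)
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in vars) {
    if (!v %in% names(data)) stop("missing factor column: ", v, call. = FALSE)
    if (length(unique(data[[v]])) < 2L) {
      stop("factor '", v, "' needs at least two levels", call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste(backtick(trait), "~",
                                 paste(terms, collapse = " + ")))
  # keep.order preserves the declared sequential order (lm would move
  # interactions after all main effects)
  fit <- stats::lm(stats::terms(fml, keep.order = TRUE), data = data)
  if (stats::df.residual(fit) < 1L) {
    stop("zero residual degrees of freedom", call. = FALSE)
  }
  tab <- stats::anova(fit)
  tibble(
    term = ifelse(trimws(rownames(tab)) == "Residuals", "Error",
                  trimws(rownames(tab))),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
}

#' Least-square means per accession-by-treatment cell
#'
#' Marginal means from the additive-block model
#' `trait ~ accession * treatment + block`: predictions on the full
#' accession x treatment x block grid averaged over block levels. For a
#' balanced design this equals the arithmetic cell mean; under mild
#' unbalance it is the model-adjusted mean. Cells whose interaction
#' coefficient is not estimable (entirely missing) propagate `NA`.
#'
#' @param data Replicate-level table with `accession`, a numeric trait
#'   column, and optionally `treatment` and `block`.
#' @param trait Trait column name.
#' @return Tibble `accession`, `treatment` (if present), `lsmean`.
#' @export
ls_means <- function(data, trait) {
  data <- prep_factors(as.data.frame(data))
  has_trt <- "treatment" %in% names(data) &&
    nlevels(data$treatment) > 1L
  has_block <- "block" %in% names(data) && nlevels(data$block) > 1L
  rhs <- "accession"
  if (has_trt) rhs <- "accession * treatment"
  if (has_block) rhs <- paste(rhs, "+ block")
  fml <- stats::as.formula(paste(backtick(trait), "~", rhs))
  fit <- stats::lm(fml, data = data)
  beta <- stats::coef(fit)

  grid_vars <- list(accession = levels(data$accession))
  if (has_trt) grid_vars$treatment <- levels(data$treatment)
  if (has_block) grid_vars$block <- levels(data$block)
  grid <- expand.grid(grid_vars, stringsAsFactors = TRUE)
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
  bad <- is.na(beta)
  pred <- as.numeric(mm[, !bad, drop = FALSE] %*% beta[!bad])
  # a prediction touching a dropped (inestimable) coefficient is NA
  if (any(bad)) {
    touched <- rowSums(abs(mm[, bad, drop = FALSE])) > 0
    pred[touched] <- NA_real_
  }
  grid$.pred <- pred
  by_vars <- c("accession", if (has_trt) "treatment")
  agg <- stats::aggregate(grid$.pred, grid[by_vars], FUN = mean)
  names(agg)[ncol(agg)] <- "lsmean"
  out <- as_tibble(agg)
  out$accession <- as.character(out$accession)
  if (has_trt) out$treatment <- as.character(out$treatment)
  out[order(out$accession), , drop = FALSE]
}

#' Accession-by-treatment trait matrix of LS-means
#'
#' Computes [ls_means()] for each requested trait and assembles the wide
#' response matrix used for association mapping: one row per accession x
#' treatment, one column per trait.
#'
#' @param trait_table Replicate-level trait table (e.g. from
#'   [build_trait_table()]).
#' @param traits Character vector of trait column names.
#' @return Tibble `accession`, `treatment`, then one column per trait.
#' @export
build_trait_matrix <- function(trait_table, traits) {
  out <- NULL
  for (tr in traits) {
    lsm <- ls_means(trait_table, tr)
    names(lsm)[names(lsm) == "lsmean"] <- tr
    out <- if (is.null(out)) lsm else merge(out, lsm,
                                            by = intersect(names(out),
                                                           c("accession",
                                                             "treatment")))
  }
  as_tibble(out)
}

#' Broad-sense heritability from expected mean squares
#'
#' Estimates the accession-level genetic variance from the sequential
#' ANOVA of [fit_anova()] as
#' `sigma_g2 = max(0, (MS_accession - MS_error) / r_bar)` with `r_bar` the
#' harmonic mean number of observations per accession, and reports
#' `H2 = sigma_g2 / (sigma_g2 + sigma_e2)` clamped to `[0, 1]`
#' (`sigma_e2` = residual mean square). With treatment in the model the
#' interaction term must be included so the residual is pure error; the
#' estimate then measures the variance of accession means across both
#' arms.
#'
#' @param data Replicate-level table.
#' @param trait Trait column name.
#' @param terms Model terms passed to [fit_anova()]; default as there.
#' @return List of class `heritability_result`: `sigma_g2`, `sigma_e2`,
#'   `sigma_p2`, `H2`, `r_bar`.
#' @examples
#' cfg <- sim_config(n_accessions = 24, n_snps = 60, n_genes = 6,
#'                   n_causal_genes = 0, seed = 5)
#' panel <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(cfg, panel, simulate_annotation(cfg, panel))
#' broad_sense_h2(sim$pheno, "biomass_mg")$H2
#' @export
broad_sense_h2 <- function(data, trait, terms = NULL) {
  counts <- table(data$accession)
  if (length(counts) < 2L || sum(counts >= 2L) < 2L) {
    stop("need at least two accessions with two or more replicates",
         call. = FALSE)
  }
  if (all(counts < 2L)) {
    stop("residual variance is not estimable with one replicate per accession",
         call. = FALSE)
  }
  tab <- fit_anova(data, trait, terms)
  ms_a <- tab$meansq[tab$term == "accession"]
  ms_e <- tab$meansq[tab$term == "Error"]
  r_bar <- length(counts) / sum(1 / as.numeric(counts))  # harmonic mean
  sigma_g2 <- max(0, (ms_a - ms_e) / r_bar)
  sigma_p2 <- sigma_g2 + ms_e
  h2 <- if (sigma_p2 > 0) sigma_g2 / sigma_p2 else 0
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = ms_e,
                 sigma_p2 = sigma_p2, H2 = min(max(h2, 0), 1),
                 r_bar = r_bar),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("H2 = %.3f (sigma_g2 = %.4g, sigma_e2 = %.4g, r_bar = %.2f)\n",
              x$H2, x$sigma_g2, x$sigma_e2, x$r_bar))
  invisible(x)
}

#' Mutant-versus-wild-type treatment response test
#'
#' Two-way genotype-by-treatment ANOVA for a single mutant line against
#' the wild type: the genotype x treatment interaction P-value tests
#' whether the mutant's response to the treatment differs from the wild
#' type's. The grouping label reduces the post-hoc comparison to the
#' binary call reported for validation panels: `"b"` (response differs
#' from WT) iff the interaction P <= `alpha`, else `"a"`.
#'
#' @param data Replicate-level table with columns `genotype`, `treatment`,
#'   the trait, and optionally `block` (added as an additive term).
#' @param trait Trait column name.
#' @param alpha Significance level for the interaction (default 0.05).
#' @return List: `p_interaction`, `label` (`"a"`/`"b"`), `anova` (the
#'   sequential table).
#' @export
mutant_response_test <- function(data, trait, alpha = 0.05) {
  data <- prep_factors(as.data.frame(data))
  if (!"genotype" %in% names(data) || nlevels(data$genotype) != 2L) {
    stop("need exactly two genotypes (mutant and wild type)", call. = FALSE)
  }
  if (!"treatment" %in% names(data) || nlevels(data$treatment) != 2L) {
    stop("need both treatment arms", call. = FALSE)
  }
  terms <- c("genotype", "treatment", "genotype:treatment")
  if ("block" %in% names(data) && nlevels(data$block) > 1L) {
    terms <- c(terms, "block")
  }
  tab <- fit_anova(data, trait, terms)
  p_int <- tab$p.value[tab$term == "genotype:treatment"]
  list(p_interaction = p_int,
       label = if (!is.na(p_int) && p_int <= alpha) "b" else "a",
       anova = tab)
}
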