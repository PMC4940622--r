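#' Catalog of measured glucosinolate compounds
#'
#' The 17 foliar glucosinolates the analysis expects: 14 aliphatic
#' (methionine-derived) and 3 indolic (tryptophan-derived) compounds,
#' identified by the standard short-hand nomenclature (e.g. `4MSB` =
#' 4-methylsulfinylbutyl, `4MTB` = 4-methylthiobutyl, `Allyl` = 2-propenyl
#' / sinigrin). `chain_length` is the side-chain carbon number (NA for
#' indolics) and `side_chain` the chemical class of the side chain:
#' methylsulfinyl (`MS`), methylthio (`MT`), alkenyl, hydroxylated, or
#' indole.
#'
#' @return Tibble with columns `abbreviation`, `class`, `chain_length`,
#'   `side_chain` (17 rows).
#' @examples
#' table(compound_catalog()$class)
#' @export
compound_catalog <- function() {
  tibble(
    abbreviation = c("3OHP", "3MSP", "2-OH-butenyl", "4OHB", "4MSB",
                     "Allyl", "5MSP", "But-3-enyl", "3MTP", "7MSH",
                     "4MTB", "8MSO", "7MTH", "8MTO",
                     "I3M", "4MI3M", "MI3M"),
    class = c(rep("aliphatic", 14), rep("indolic", 3)),
    chain_length = c(3L, 3L, 4L, 4L, 4L, 3L, 5L, 4L, 3L, 7L, 4L, 8L, 7L,
                     8L, NA, NA, NA),
    side_chain = c("hydroxy", "MS", "alkenyl", "hydroxy", "MS",
                   "alkenyl", "MS", "alkenyl", "MT", "MS",
                   "MT", "MS", "MT", "MT",
                   "indole", "indole", "indole")
  )
}

#' Default derived-trait definitions
#'
#' The 15 derived summation and ratio traits that, together with the 17
#' individual compounds, make the 32-trait table. Summations group
#' compounds by chain length, side-chain chemistry and biosynthetic class;
#' the three ratio traits use the bounded form `a / (a + b)`. Memberships
#' are reconstructed from the nomenclature and are overridable (pass your
#' own list of the same shape to [build_trait_table()]).
#'
#' Each element is a list with `type = "sum"` and `members`, or
#' `type = "ratio"` with `num` and `den` (both compound/trait member
#' vectors; the ratio is `sum(num) / (sum(num) + sum(den))`).
#'
#' @return Named list of 15 trait definitions.
#' @export
default_trait_definitions <- function() {
  sum_def <- function(members) list(type = "sum", members = members)
  ratio_def <- function(num, den) list(type = "ratio", num = num, den = den)
  c3 <- c("3OHP", "3MSP", "3MTP", "Allyl")
  c4 <- c("4OHB", "4MSB", "4MTB", "But-3-enyl", "2-OH-butenyl")
  c7 <- c("7MSH", "7MTH")
  c8 <- c("8MSO", "8MTO")
  short <- c(c3, c4, "5MSP")
  long <- c(c7, c8)
  ms <- c("3MSP", "4MSB", "5MSP", "7MSH", "8MSO")
  mt <- c("3MTP", "4MTB", "7MTH", "8MTO")
  indolic <- c("I3M", "4MI3M", "MI3M")
  list(
    "Total 3C GSL" = sum_def(c3),
    "Total 4C GSL" = sum_def(c4),
    "Total 7C GSL" = sum_def(c7),
    "Total 8C GSL" = sum_def(c8),
    "Short chain GSL" = sum_def(short),
    "Long chain GSL" = sum_def(long),
    "Short vs. Long" = ratio_def(short, long),
    "Total alkyl" = sum_def(c("Allyl", "But-3-enyl", "2-OH-butenyl")),
    "Total MT" = sum_def(mt),
    "Total MS" = sum_def(ms),
    "Total aliphatics" = sum_def(c(short, long)),
    "Total indolics" = sum_def(indolic),
    "Total GSL" = sum_def(c(short, long, indolic)),
    "Aliphatics vs. indolics" = ratio_def(c(short, long), indolic),
    "MS/MT ratio" = ratio_def(ms, mt)
  )
}

#' Build the 32-trait glucosinolate table
#'
#' Applies the derived-trait definitions to a replicate-level phenotype
#' table holding the 17 compound columns (already normalized to umol/g
#' fresh weight) and returns the same rows with 32 trait columns: the 17
#' compounds passed through plus the 15 derived summations and ratios.
#' Ratio traits are `NA` where numerator and denominator are both zero.
#'
#' @param pheno Data frame containing all 17 compound columns (plus any id
#'   columns, which are carried through).
#' @param defs Derived-trait definitions, default
#'   [default_trait_definitions()].
#' @return Tibble: the non-compound id columns of `pheno`, then the 32
#'   trait columns.
#' @examples
#' cfg <- sim_config(n_accessions = 6, n_snps = 40, n_genes = 4,
#'                   n_causal_genes = 0, seed = 1)
#' panel <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(cfg, panel, simulate_annotation(cfg, panel))
#' traits <- build_trait_table(sim$pheno)
#' ncol(traits) - (ncol(sim$pheno) - 17)  # 32 trait columns
#' @export
build_trait_table <- function(pheno, defs = default_trait_definitions()) {
  compounds <- compound_catalog()$abbreviation
  missing <- setdiff(compounds, names(pheno))
  if (length(missing) > 0) {
    stop("missing compound column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  comp <- as.matrix(pheno[, compounds])
  if (any(comp < 0, na.rm = TRUE)) {
    stop("compound abundances must be non-negative", call. = FALSE)
  }
  id_cols <- setdiff(names(pheno), compounds)
  out <- as_tibble(pheno[, c(id_cols, compounds), drop = FALSE])
  for (nm in names(defs)) {
    d <- defs[[nm]]
    if (identical(d$type, "sum")) {
      out[[nm]] <- rowSums(comp[, d$members, drop = FALSE])
    } else if (identical(d$type, "ratio")) {
      num <- rowSums(comp[, d$num, drop = FALSE])
      den <- num + rowSums(comp[, d$den, drop = FALSE])
      out[[nm]] <- ifelse(den > 0, num / den, NA_real_)
    } else {
      stop("unknown trait definition type for '", nm, "'", call. = FALSE)
    }
  }
  out
}

#' Names of the 32 glucosinolate trait columns
#'
#' @param defs Derived-trait definitions.
#' @return Character vector: 17 compounds then the derived trait names.
#' @export
gsl_trait_names <- function(defs = default_trait_definitions()) {
  c(compound_catalog()$abbreviation, names(defs))
}

#' Relative-difference response statistic
#'
#' The bounded treatment-response statistic
#' `(treated - control) / (0.5 * (treated + control))`. For non-negative
#' inputs it lives in `[-2, 2]`: +2 when the trait is present only under
#' treatment, -2 when present only in the control, 0 for no change.
#' Undefined (NA) when both values are zero.
#'
#' @param treated,control Non-negative trait values (vectorized).
#' @return Numeric vector of signed relative differences.
#' @examples
#' relative_difference(1.5, 0.5)  # 1
#' relative_difference(3, 0)      # 2
#' @export
relative_difference <- function(treated, control) {
  s <- 0.5 * (treated + control)
  ifelse(s == 0, NA_real_, (treated - control) / s)
}

#' Side-chain oxidation ratio of the 4-carbon glucosinolates
#'
#' `4MSB / (4MSB + 4MTB)`: the methylsulfinyl share of the 4C pool, in
#' `[0, 1]`. NA when both abundances are zero.
#'
#' @param msb 4MSB abundance(s), non-negative.
#' @param mtb 4MTB abundance(s), non-negative.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' oxidation_ratio(2, 2)  # 0.5
#' oxidation_ratio(1, 3)  # 0.25
#' @export
oxidation_ratio <- function(msb, mtb) {
  if (any(msb < 0, na.rm = TRUE) || any(mtb < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  s <- msb + mtb
  ifelse(s == 0, NA_real_, msb / s)
}
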