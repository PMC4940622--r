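#' Genotype panel of inbred accessions
#'
#' Container for an accession-by-SNP matrix of homozygous allele calls
#' (coded 0/1 — accessions are fully inbred, so no heterozygous code
#' exists), together with a SNP map (chromosome, 1-based position) and the
#' per-SNP minor-allele frequency recomputed from the matrix.
#'
#' @param alleles Integer matrix, accessions in rows and SNPs in columns,
#'   entries in `{0, 1}`, with row and column names.
#' @param map Data frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   one row per column of `alleles`, positions strictly increasing within
#'   each chromosome.
#' @return An object of class `genotype_panel`: a list with elements
#'   `alleles` (the matrix) and `map` (a tibble with an added `maf` column).
#' @examples
#' m <- matrix(c(0L, 1L, 1L, 0L, 1L, 0L), nrow = 3,
#'             dimnames = list(paste0("acc", 1:3), c("s1", "s2")))
#' panel <- genotype_panel(m, data.frame(snp_id = c("s1", "s2"),
#'                                       chrom = "chr1", pos = c(10L, 20L)))
#' panel$map$maf
#' @export
genotype_panel <- function(alleles, map) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L))) {
    stop("alleles must be coded 0/1 (inbred homozygous calls)", call. = FALSE)
  }
  map <- as_tibble(map)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)),
            nrow(map) == ncol(alleles))
  if (anyDuplicated(map$snp_id)) stop("duplicated snp ids", call. = FALSE)
  if (is.null(rownames(alleles)) || is.null(colnames(alleles))) {
    stop("alleles must carry accession rownames and SNP colnames",
         call. = FALSE)
  }
  if (!identical(colnames(alleles), as.character(map$snp_id))) {
    stop("alleles columns and map rows must agree (same SNPs, same order)",
         call. = FALSE)
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within a chromosome",
           call. = FALSE)
    }
  }
  map$maf <- compute_maf(alleles)
  structure(list(alleles = alleles, map = map), class = "genotype_panel")
}

#' Minor-allele frequencies of a 0/1 allele matrix
#'
#' @param alleles Accession-by-SNP 0/1 matrix.
#' @return Numeric vector `min(p, 1 - p)` per column.
#' @export
compute_maf <- function(alleles) {
  p <- colMeans(alleles)
  unname(pmin(p, 1 - p))
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d accessions x %d SNPs on %d chromosome(s); MAF in [%.3f, %.3f]\n",
              nrow(x$alleles), ncol(x$alleles), length(unique(x$map$chrom)),
              min(x$map$maf), max(x$map$maf)))
  invisible(x)
}

#' Simulate an inbred genotype panel
#'
#' Draws a panel of homozygous 0/1 genotypes whose realized minor-allele
#' frequency is guaranteed to be at least `cfg$maf_min` for every SNP:
#' for each SNP a minor-allele *count* is sampled uniformly over the
#' feasible counts `{k : min(k, n - k)/n >= maf_min}` and the carriers are
#' a uniform random subset of accessions. SNPs are spread across
#' `cfg$n_chromosomes` chromosomes at strictly increasing positions chosen
#' to leave room for the gene annotation produced by
#' [simulate_annotation()]. SNPs are independent: no linkage-disequilibrium
#' structure is imposed.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_panel()].
#' @examples
#' panel <- simulate_genotypes(sim_config(n_snps = 200, n_genes = 20, seed = 1))
#' min(panel$map$maf) >= 0.2
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_accessions
  p <- cfg$n_snps

  k_lo <- ceiling(n * cfg$maf_min)
  k_hi <- floor(n * (1 - cfg$maf_min))
  feasible <- k_lo:k_hi
  feasible <- feasible[pmin(feasible, n - feasible) / n >= cfg$maf_min]
  if (length(feasible) == 0L) {
    stop("no allele count satisfies the requested `maf_min` at this panel size",
         call. = FALSE)
  }

  acc_ids <- sprintf("acc%03d", seq_len(n))
  counts <- feasible[sample.int(length(feasible), p, replace = TRUE)]
  alleles <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    alleles[sample.int(n, counts[j]), j] <- 1L
  }

  # even split across chromosomes, sorted unique positions with ~50 bp mean
  # spacing so genes (SNP-bounded intervals) stay compact
  chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), p))
  map_list <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
    m <- sum(chrom_of == ch)
    if (m == 0L) return(NULL)
    pos <- sort(sample.int(max(50L * m, m + 1L), m))
    data.frame(chrom = sprintf("chr%d", ch), pos = pos)
  })
  map <- do.call(rbind, map_list)
  map$snp_id <- sprintf("snp%05d", seq_len(p))
  rownames(alleles) <- acc_ids
  colnames(alleles) <- map$snp_id
  genotype_panel(alleles, map[, c("snp_id", "chrom", "pos")])
}
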