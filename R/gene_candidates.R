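#' Count significant SNPs per gene
#'
#' Assigns each significant SNP to *every* gene whose `[start, end]`
#' interval (1-based, inclusive) contains its position, using
#' `GenomicRanges` overlap machinery, and returns per-gene significant-SNP
#' counts. SNPs falling in no gene are tallied in the `n_unassigned`
#' attribute.
#'
#' @param snps Data frame with columns `chrom`, `pos`, `snp_id`,
#'   `significant` (logical or 0/1) — e.g. one trait x condition slice of
#'   the `effects` table of [run_gwa()].
#' @param ann Gene annotation tibble (see [gene_annotation()]). Every
#'   chromosome present in `snps` must appear in `ann`, otherwise a hard
#'   error lists the offenders.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `n_sig_snps`, with
#'   attribute `n_unassigned` (significant SNPs outside every gene).
#' @export
assign_snps_to_genes <- function(snps, ann) {
  ann <- gene_annotation(ann)
  stopifnot(all(c("chrom", "pos", "significant") %in% names(snps)))
  bad <- setdiff(unique(snps$chrom), unique(ann$chrom))
  if (length(bad) > 0) {
    stop("chromosome(s) in SNP table absent from annotation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sig <- snps[as.logical(snps$significant), , drop = FALSE]
  counts <- integer(nrow(ann))
  unassigned <- 0L
  if (nrow(sig) > 0) {
    gr_snp <- GenomicRanges::GRanges(sig$chrom,
                                     IRanges::IRanges(sig$pos, sig$pos))
    gr_gene <- GenomicRanges::GRanges(ann$chrom,
                                      IRanges::IRanges(ann$start, ann$end))
    hits <- GenomicRanges::findOverlaps(gr_snp, gr_gene, type = "within")
    counts <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(ann))
    unassigned <- sum(!seq_len(nrow(sig)) %in% S4Vectors::queryHits(hits))
  }
  out <- tibble(gene_id = ann$gene_id, chrom = ann$chrom,
                start = ann$start, end = ann$end,
                n_sig_snps = as.integer(counts))
  attr(out, "n_unassigned") <- as.integer(unassigned)
  out
}

#' Call gene-level candidates from significant-SNP counts
#'
#' A gene is a candidate iff it holds at least `min_snps` significant
#' SNPs (default 2). Monotone: raising `min_snps` never adds candidates.
#'
#' @param counts Output of [assign_snps_to_genes()].
#' @param min_snps Minimum significant SNPs per gene.
#' @param trait,condition Optional labels carried into the result.
#' @return Object of class `candidate_set`: tibble `gene_id`,
#'   `n_sig_snps`, `candidate`, with `trait`/`condition`/`min_snps`
#'   attributes.
#' @export
call_candidates <- function(counts, min_snps = 2L, trait = NA_character_,
                            condition = NA_character_) {
  stopifnot(min_snps >= 1L)
  out <- tibble(gene_id = counts$gene_id,
                n_sig_snps = counts$n_sig_snps,
                candidate = counts$n_sig_snps >= min_snps)
  attr(out, "trait") <- trait
  attr(out, "condition") <- condition
  attr(out, "min_snps") <- as.integer(min_snps)
  class(out) <- c("candidate_set", class(out))
  out
}

candidate_genes <- function(set) set$gene_id[set$candidate]

#' Overlap of candidate sets between two conditions
#'
#' Partitions the control and treated candidate gene sets into
#' unique-to-control, unique-to-treatment and shared, with counts.
#'
#' @param control,treated `candidate_set`s for the same trait.
#' @return List of class `overlap_report`: `unique_control`,
#'   `unique_treated`, `shared` (character vectors) and `counts` (named
#'   integer vector, including the input set sizes).
#' @export
compare_conditions <- function(control, treated) {
  cg <- candidate_genes(control)
  tg <- candidate_genes(treated)
  shared <- intersect(cg, tg)
  out <- list(
    unique_control = setdiff(cg, tg),
    unique_treated = setdiff(tg, cg),
    shared = shared,
    counts = c(control = length(cg), treated = length(tg),
               unique_control = length(setdiff(cg, tg)),
               unique_treated = length(setdiff(tg, cg)),
               shared = length(shared))
  )
  structure(out, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("candidate overlap: %d control / %d treated; %d unique-control, %d unique-treated, %d shared\n",
              x$counts["control"], x$counts["treated"],
              x$counts["unique_control"], x$counts["unique_treated"],
              x$counts["shared"]))
  invisible(x)
}

#' Prioritize condition-unique candidates by transcript response
#'
#' Drops genes that were candidates under both conditions, ranks the
#' remaining condition-unique candidates by absolute log2 fold-change of
#' their transcript response (descending, ties broken by gene id), and
#' returns the top `top_k`.
#'
#' @param report An `overlap_report` from [compare_conditions()].
#' @param fc Fold-change table with columns `gene_id`, `log2fc`. Queried
#'   genes missing from `fc` are dropped with a warning.
#' @param top_k Number of genes to return (default 13). If fewer remain,
#'   the full ranked list is returned.
#' @return Tibble `gene_id`, `log2fc`, `abs_log2fc`, `source`
#'   (`"control"`/`"treated"`), `rank`.
#' @export
prioritize_candidates <- function(report, fc, top_k = 13L) {
  stopifnot(inherits(report, "overlap_report"),
            all(c("gene_id", "log2fc") %in% names(fc)))
  pool <- tibble(
    gene_id = c(report$unique_control, report$unique_treated),
    source = c(rep("control", length(report$unique_control)),
               rep("treated", length(report$unique_treated)))
  )
  if (nrow(pool) == 0) {
    message("no condition-unique candidates to prioritize")
    return(tibble(gene_id = character(0), log2fc = numeric(0),
                  abs_log2fc = numeric(0), source = character(0),
                  rank = integer(0)))
  }
  idx <- match(pool$gene_id, fc$gene_id)
  if (anyNA(idx)) {
    warning(sprintf("%d candidate gene(s) missing from the fold-change table; dropped",
                    sum(is.na(idx))))
    pool <- pool[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  pool$log2fc <- fc$log2fc[idx]
  pool$abs_log2fc <- abs(pool$log2fc)
  ord <- order(-pool$abs_log2fc, pool$gene_id)
  pool <- pool[ord, , drop = FALSE]
  pool <- head(pool, top_k)
  pool$rank <- seq_len(nrow(pool))
  pool[, c("gene_id", "log2fc", "abs_log2fc", "source", "rank")]
}
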