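write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE,
                              stringsAsFactors = FALSE))
}

#' Genotype panel TSV serialization
#'
#' The genotype TSV has one row per SNP: `chrom`, `pos`, `snp_id`, then
#' one 0/1 column per accession.
#'
#' @param panel A [genotype_panel()].
#' @param path File path.
#' @return `write_genotype_tsv()`: the path, invisibly.
#'   `read_genotype_tsv()`: a [genotype_panel()].
#' @export
write_genotype_tsv <- function(panel, path) {
  out <- cbind(panel$map[, c("chrom", "pos", "snp_id")],
               as.data.frame(t(panel$alleles)))
  write_tsv_plain(out, path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  tab <- read_tsv_plain(path)
  acc_cols <- setdiff(names(tab), c("chrom", "pos", "snp_id"))
  alleles <- t(as.matrix(tab[, acc_cols]))
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- acc_cols
  colnames(alleles) <- tab$snp_id
  genotype_panel(alleles, tab[, c("snp_id", "chrom", "pos")])
}

#' Export a genotype panel as a haploid-style VCF
#'
#' Minimal VCF 4.2 with one sample column per accession and haploid GT
#' calls (`0` reference-like, `1` alternate-like), matching the inbred
#' 0/1 coding of the panel.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path (uncompressed `.vcf`).
#' @return The path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=allylgwa",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(panel$alleles)), collapse = "\t")
  ), con)
  gt <- t(panel$alleles)  # SNP x accession
  body <- paste(panel$map$chrom, panel$map$pos, panel$map$snp_id,
                "A", "T", ".", "PASS", ".", "GT",
                sep = "\t")
  gt_txt <- apply(gt, 1L, paste, collapse = "\t")
  writeLines(paste(body, gt_txt, sep = "\t"), con)
  invisible(path)
}

#' Phenotype / trait table TSV serialization
#'
#' @param x Data frame (replicate-level phenotype or trait table).
#' @param path File path.
#' @return `write_phenotype_tsv()`: the path, invisibly;
#'   `read_phenotype_tsv()`: a tibble (column names, which may include
#'   compound abbreviations like `2-OH-butenyl`, are preserved verbatim).
#' @export
write_phenotype_tsv <- function(x, path) write_tsv_plain(x, path)

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) read_tsv_plain(path)

#' Write the ground-truth record of a simulated study
#'
#' @param truth Truth list from [simulate_phenotypes()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a complete study and write all its artifacts
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_annotation()], [simulate_phenotypes()] and
#' [simulate_expression_response()] and serializing genotypes (TSV),
#' annotation (GFF3), replicate phenotypes (TSV), fold-changes (TSV) and
#' the ground truth (JSON) into `out_dir`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param vcf Also write a VCF copy of the panel?
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects (`panel`, `ann`, `pheno`, `truth`, `fc`).
#' @export
simulate_study <- function(cfg, out_dir, vcf = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg, panel)
  sim <- simulate_phenotypes(cfg, panel, ann)
  fc <- simulate_expression_response(cfg, ann, sim$truth$causal_genes)
  paths <- list(
    genotype = file.path(out_dir, "genotypes.tsv"),
    annotation = file.path(out_dir, "genes.gff3"),
    phenotype = file.path(out_dir, "phenotypes.tsv"),
    fold_change = file.path(out_dir, "fold_changes.tsv"),
    truth_json = file.path(out_dir, "truth.json")
  )
  write_genotype_tsv(panel, paths$genotype)
  write_annotation_gff3(ann, paths$annotation)
  write_phenotype_tsv(sim$pheno, paths$phenotype)
  write_tsv_plain(fc, paths$fold_change)
  write_truth_json(sim$truth, paths$truth_json)
  if (vcf) {
    paths$vcf <- file.path(out_dir, "genotypes.vcf")
    write_panel_vcf(panel, paths$vcf)
  }
  invisible(c(paths, list(panel = panel, ann = ann, pheno = sim$pheno,
                          truth = sim$truth, fc = fc)))
}
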