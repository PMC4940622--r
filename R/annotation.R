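#' Validate a gene annotation table
#'
#' @param ann Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based, inclusive) and `strand`.
#' @return The annotation as a tibble, invisibly checked.
#' @export
gene_annotation <- function(ann) {
  ann <- as_tibble(ann)
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(ann)))
  if (anyDuplicated(ann$gene_id)) stop("gene ids must be unique", call. = FALSE)
  if (any(ann$start > ann$end)) stop("gene start must be <= end", call. = FALSE)
  if (any(ann$start < 1L)) stop("coordinates are 1-based", call. = FALSE)
  ann
}

#' Simulate a gene annotation over a genotype panel
#'
#' Tiles each chromosome with non-overlapping `gene` intervals such that
#' every gene contains at least two SNP positions of `panel`. Genes are
#' built by partitioning the ordered SNPs of a chromosome into contiguous
#' groups (a random share of SNPs is left intergenic); a gene spans from
#' its first to its last member SNP, so containment is guaranteed and
#' neighbouring genes never overlap.
#'
#' @param cfg A [sim_config()].
#' @param panel A [genotype_panel()], typically from [simulate_genotypes()].
#' @return A gene annotation tibble (see [gene_annotation()]).
#' @examples
#' cfg <- sim_config(n_snps = 200, n_genes = 20, seed = 1)
#' ann <- simulate_annotation(cfg, simulate_genotypes(cfg))
#' nrow(ann)
#' @export
simulate_annotation <- function(cfg, panel) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, 2L))
  map <- panel$map
  chroms <- unique(map$chrom)
  snp_per_chrom <- table(factor(map$chrom, levels = chroms))

  # genes per chromosome, proportional to SNP counts (largest remainder)
  raw <- as.numeric(snp_per_chrom) / sum(snp_per_chrom) * cfg$n_genes
  g_per_chrom <- floor(raw)
  rem <- cfg$n_genes - sum(g_per_chrom)
  if (rem > 0) {
    bump <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
    g_per_chrom[bump] <- g_per_chrom[bump] + 1
  }
  if (any(2 * g_per_chrom > as.numeric(snp_per_chrom))) {
    stop("infeasible tiling: too few SNPs on some chromosome to give every ",
         "gene two SNPs", call. = FALSE)
  }

  out <- vector("list", length(chroms))
  gid <- 0L
  for (ci in seq_along(chroms)) {
    g <- g_per_chrom[ci]
    if (g == 0L) next
    pos <- map$pos[map$chrom == chroms[ci]]
    m <- length(pos)
    genic_target <- max(2L * g, round(0.7 * m))
    genic_target <- min(genic_target, m)
    extra <- genic_target - 2L * g
    sizes <- rep(2L, g)
    if (extra > 0L) {
      add <- tabulate(sample.int(g, extra, replace = TRUE), nbins = g)
      sizes <- sizes + add
    }
    # distribute intergenic SNPs into the g + 1 gaps
    leftover <- m - sum(sizes)
    gaps <- tabulate(sample.int(g + 1L, leftover, replace = TRUE),
                     nbins = g + 1L)
    cursor <- gaps[1L]
    rows <- vector("list", g)
    for (k in seq_len(g)) {
      idx <- cursor + seq_len(sizes[k])
      gid <- gid + 1L
      rows[[k]] <- data.frame(
        gene_id = sprintf("GENE%04d", gid),
        chrom = chroms[ci],
        start = pos[idx[1L]],
        end = pos[idx[length(idx)]],
        strand = sample(c("+", "-"), 1L)
      )
      cursor <- cursor + sizes[k] + gaps[k + 1L]
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  gene_annotation(do.call(rbind, out))
}

#' Write / read a gene annotation as GFF3
#'
#' Serialisation goes through `rtracklayer`, emitting a GFF3 file with one
#' `gene` feature per row (1-based inclusive coordinates, `ID` and `Name`
#' set to the gene id).
#'
#' @param ann Gene annotation tibble.
#' @param path Output (or input) file path.
#' @return `write_annotation_gff3()` returns `path` invisibly;
#'   `read_annotation_gff3()` returns the annotation tibble.
#' @export
write_annotation_gff3 <- function(ann, path) {
  ann <- gene_annotation(ann)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$ID <- ann$gene_id
  S4Vectors::mcols(gr)$Name <- ann$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "allylgwa"
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "gene"]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  gene_annotation(tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ))
}
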