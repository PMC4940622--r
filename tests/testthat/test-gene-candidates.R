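toy_ann <- function() {
  gene_annotation(data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 300L, 50L),
    end = c(200L, 400L, 90L),
    strand = "+"
  ))
}

test_that("SNP-to-gene assignment honours inclusive 1-based boundaries", {
  snps <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(150L, 100L, 200L, 201L, 90L),
    snp_id = sprintf("s%d", 1:5),
    significant = TRUE
  )
  counts <- assign_snps_to_genes(snps, toy_ann())
  expect_equal(counts$n_sig_snps[counts$gene_id == "gA"], 3L)  # 100,150,200
  expect_equal(counts$n_sig_snps[counts$gene_id == "gB"], 0L)  # 201 excluded
  expect_equal(counts$n_sig_snps[counts$gene_id == "gC"], 1L)  # end inclusive
  expect_equal(attr(counts, "n_unassigned"), 1L)
  # non-significant SNPs never count
  snps$significant <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(assign_snps_to_genes(snps, toy_ann())$n_sig_snps,
               c(1L, 0L, 0L))
  # chromosome name mismatch is a hard error naming the offender
  bad <- snps; bad$chrom[1] <- "Chr1"
  expect_error(assign_snps_to_genes(bad, toy_ann()), "Chr1")
})

test_that("random layouts match brute-force containment, including overlapping genes", {
  set.seed(11)
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:20),
    chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
    start = s <- sample.int(900, 20),
    end = s + sample.int(150, 20),
    strand = "+"
  ))
  snps <- data.frame(
    chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
    pos = sample.int(1100, 300, replace = TRUE),
    snp_id = sprintf("s%03d", 1:300),
    significant = runif(300) < 0.3
  )
  counts <- assign_snps_to_genes(snps, ann)
  expect_equal(counts$n_sig_snps, unname(bf_gene_counts(snps, ann)))
})

test_that("candidate calling applies the >= 2 SNP rule monotonically", {
  set.seed(12)
  counts <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                           n_sig_snps = rpois(30, 1.2))
  set2 <- call_candidates(counts, 2)
  expect_identical(set2$candidate, counts$n_sig_snps >= 2)
  # a gene with exactly 2 significant SNPs is a candidate; with 1 it is not
  expect_true(call_candidates(tibble::tibble(gene_id = "g", n_sig_snps = 2L),
                              2)$candidate)
  expect_false(call_candidates(tibble::tibble(gene_id = "g", n_sig_snps = 1L),
                               2)$candidate)
  # monotonicity: raising min_snps never adds candidates
  for (k in 1:4) {
    lo <- call_candidates(counts, k)
    hi <- call_candidates(counts, k + 1)
    expect_true(all(lo$candidate[hi$candidate]))
  }
})

test_that("condition overlaps partition the candidate sets exactly", {
  mk <- function(genes, all_genes = sprintf("g%02d", 1:20)) {
    call_candidates(tibble::tibble(
      gene_id = all_genes,
      n_sig_snps = ifelse(all_genes %in% genes, 2L, 0L)), 2)
  }
  rep1 <- compare_conditions(mk(c("g01", "g02")), mk(c("g02", "g03")))
  expect_identical(rep1$unique_control, "g01")
  expect_identical(rep1$unique_treated, "g03")
  expect_identical(rep1$shared, "g02")
  # identical sets: everything shared
  rep2 <- compare_conditions(mk(c("g04", "g05")), mk(c("g04", "g05")))
  expect_length(rep2$shared, 2L)
  expect_length(rep2$unique_control, 0L)
  # random sets: partition identities hold
  set.seed(13)
  for (i in 1:10) {
    a <- sample(sprintf("g%02d", 1:20), sample(0:10, 1))
    b <- sample(sprintf("g%02d", 1:20), sample(0:10, 1))
    rp <- compare_conditions(mk(a), mk(b))
    expect_equal(rp$counts[["unique_control"]] + rp$counts[["shared"]],
                 length(a))
    expect_equal(rp$counts[["unique_treated"]] + rp$counts[["shared"]],
                 length(b))
    expect_length(intersect(rp$unique_control, rp$shared), 0L)
    expect_setequal(c(rp$unique_control, rp$shared), a)
  }
})

test_that("prioritization drops shared genes, ranks by |log2fc| and breaks ties by id", {
  mk <- function(genes, all_genes = sprintf("g%02d", 1:10)) {
    call_candidates(tibble::tibble(
      gene_id = all_genes,
      n_sig_snps = ifelse(all_genes %in% genes, 2L, 0L)), 2)
  }
  rep_ <- compare_conditions(mk(c("g01", "g02", "g03")),
                             mk(c("g01", "g04", "g05")))
  fc <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                       log2fc = c(9, 2, -3, 1, -1, 0, 0, 0, 0, 0))
  top2 <- prioritize_candidates(rep_, fc, top_k = 2)
  expect_identical(top2$gene_id, c("g03", "g02"))  # g01 shared, dropped
  expect_identical(top2$rank, 1:2)
  # top_k larger than the list returns the full ranked list
  full <- prioritize_candidates(rep_, fc, top_k = 50)
  expect_identical(full$gene_id, c("g03", "g02", "g04", "g05"))
  # ties broken lexicographically
  fc_tie <- fc; fc_tie$log2fc <- c(9, 1, 1, -1, 1, 0, 0, 0, 0, 0)
  tie <- prioritize_candidates(rep_, fc_tie, top_k = 4)
  expect_identical(tie$gene_id, c("g02", "g03", "g04", "g05"))
  # genes missing from the fold-change table are dropped with a warning
  expect_warning(pr <- prioritize_candidates(rep_, fc[-3, ], top_k = 5),
                 "missing")
  expect_false("g03" %in% pr$gene_id)
  # empty candidate list: empty output with a notice
  rep_empty <- compare_conditions(mk(character(0)), mk(character(0)))
  expect_message(out <- prioritize_candidates(rep_empty, fc), "no condition")
  expect_equal(nrow(out), 0L)
})
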