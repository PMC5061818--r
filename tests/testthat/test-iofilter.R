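make_test_genes <- function() {
  # three genes on one A chromosome, one on a C chromosome
  data.frame(
    gene_id = c("gA1", "gA2", "gA3", "gC1"),
    chrom = c("A01", "A01", "A01", "C01"),
    start = c(0L, 700L, 1400L, 0L),
    end = c(200L, 900L, 1600L, 300L),
    strand = c("+", "-", "+", "+"),
    length = c(200L, 200L, 200L, 300L),
    subgenome = c("A", "A", "A", "C"),
    partner_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

test_that("GFF3 and BED coordinates normalize to 0-based half-open", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    "A01\ttest\tgene\t101\t200\t.\t+\t.\tID=g1;subgenome=A"
  ), gff)
  g <- read_annotation(gff)
  expect_identical(g$start, 100L)
  expect_identical(g$end, 200L)
  expect_identical(g$length, 100L)
  expect_identical(g$subgenome, "A")

  bed <- file.path(dir, "g.bed")
  writeLines("A01\t100\t200\tg1\t0\t+", bed)
  gb <- read_annotation(bed)
  expect_identical(gb$start, 100L)
  expect_identical(gb$end, 200L)
})

test_that("BED and GFF3 writers agree and round-trip the intervals", {
  genes <- make_test_genes()
  dir <- withr::local_tempdir()
  write_annotation(genes, bed_path = file.path(dir, "g.bed"),
                   gff3_path = file.path(dir, "g.gff3"))
  from_bed <- read_annotation(file.path(dir, "g.bed"))
  from_gff <- read_annotation(file.path(dir, "g.gff3"))
  key <- function(g) g[order(g$gene_id), c("gene_id", "chrom", "start",
                                           "end", "strand", "subgenome")]
  expect_identical(key(from_bed), key(from_gff))
  expect_identical(key(from_bed), key(genes))
})

test_that("pair links validate symmetry and the cross-subgenome rule", {
  genes <- make_test_genes()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "pairs.tsv")

  # both orientations of the same link collapse to one undirected pair
  writeLines(c("a_gene_id\tc_gene_id", "gA1\tgC1", "gC1\tgA1"), p)
  pairs <- read_pairs(p, genes)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$a_gene_id, "gA1")
  expect_identical(pairs$c_gene_id, "gC1")

  writeLines(c("a_gene_id\tc_gene_id", "gA1\tgA2"), p)
  expect_error(read_pairs(p, genes), "cross-subgenome")

  writeLines(c("a_gene_id\tc_gene_id", "gA1\tgC1", "gA2\tgC1"), p)
  expect_error(read_pairs(p, genes), "more than one")

  writeLines(c("a_gene_id\tc_gene_id", "gA1\tnope"), p)
  expect_error(read_pairs(p, genes), "unknown")
})

test_that("count reader validates shape, sign and declared depths", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "c.tsv")
  writeLines("gene_id\tsample\treplicate\tcount", f)
  expect_identical(nrow(read_counts(f)), 0L)

  writeLines(c("gene_id\tsample\treplicate\tcount", "g1\tAA1\t1\t-1"), f)
  expect_error(read_counts(f), "non-negative")

  writeLines(c("#library_size\tAA1\t1\t5",
               "gene_id\tsample\treplicate\tcount",
               "g1\tAA1\t1\t10"), f)
  expect_error(read_counts(f), "library sizes")
})

test_that("hand-built SAM exercises each acceptance and rejection rule", {
  genes <- make_test_genes()
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "t.sam")
  rec <- function(qname, flag, pos, mapq = 60, cigar = "50M", pnext = 1) {
    paste(qname, flag, "A01", pos, mapq, cigar, "=", pnext, 0,
          strrep("A", 50), strrep("I", 50), sep = "\t")
  }
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:A01\tLN:3000",
    "@SQ\tSN:C01\tLN:1000",
    rec("rule2", 99, 1, pnext = 101), rec("rule2", 147, 101, pnext = 1),
    rec("rule3", 99, 151, pnext = 701), rec("rule3", 147, 701, pnext = 151),
    rec("samestrand", 65, 1401, pnext = 1501),
    rec("samestrand", 129, 1501, pnext = 1401),
    rec("singleend", 99, 1, pnext = 401), rec("singleend", 147, 401, pnext = 1),
    rec("nonadj", 99, 1, pnext = 1401), rec("nonadj", 147, 1401, pnext = 1)
  ), sam)
  res <- filter_and_count(sam, genes)
  expect_equal(unname(res$counts[c("gA1", "gA2", "gA3", "gC1")]),
               c(1.5, 0.5, 0, 0))
  expect_identical(res$log$rule2, 1L)
  expect_identical(res$log$rule3, 1L)
  expect_identical(res$log$total_pairs, 5L)
  expect_identical(res$log$accepted +
                     sum(res$log$rejected), res$log$total_pairs)
  expect_identical(unname(res$log$rejected["incoherent_orientation"]), 1L)
  expect_identical(unname(res$log$rejected["single_end_on_gene"]), 1L)
  expect_identical(unname(res$log$rejected["non_adjacent"]), 1L)
  expect_equal(res$library_size, sum(res$counts))
})

test_that("counting a generated SAM reproduces the planted counts exactly", {
  cfg <- sim_config(n_genes = 40, seed = 9, mean_expression = 4,
                    lib_sizes = 5000, frac_paired = 0.5,
                    effect_fold = 4)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "aa1.sam")
  expected <- write_sam(ds, "AA1", 1L, sam)
  res <- filter_and_count(sam, ds$genes)
  expect_equal(res$counts, expected$counts)
  expect_identical(res$log$rule2, expected$rule2)
  expect_identical(res$log$rule3, expected$rule3)
  expect_identical(res$log$total_pairs, expected$total_pairs)
  expect_equal(res$log$rejected[sort(names(expected$rejected))],
               expected$rejected[sort(names(expected$rejected))])
  expect_identical(res$log$accepted + sum(res$log$rejected),
                   res$log$total_pairs)
})
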