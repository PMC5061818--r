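test_that("configuration validation rejects impossible designs", {
  bad_mix <- class_mix_one("additive_equal")
  bad_mix["silent"] <- 0.1
  expect_error(sim_config(class_mix = bad_mix), "sum to 1")
  expect_error(sim_config(lib_sizes = 0), "library sizes")
  expect_error(sim_config(effect_fold = 1), "effect_fold")
  expect_error(sim_config(nb_dispersion = -0.1), "nb_dispersion")
  expect_error(sim_config(n_genes = -5), "n_genes")
  expect_error(
    sim_config(class_mix = c(class_mix_one("additive_equal"), bogus = 0)),
    "named")
  # planted mass cannot exceed the declared sequencing depth
  expect_error(
    generate_dataset(sim_config(n_genes = 1000, mean_expression = 1e5,
                                lib_sizes = 1e4)),
    "depth")
})

test_that("a zero-gene configuration yields empty, well-formed tables", {
  ds <- generate_dataset(sim_config(n_genes = 0))
  expect_identical(nrow(ds$counts), 0L)
  expect_identical(nrow(ds$genes), 0L)
  expect_identical(nrow(ds$truth), 0L)
  expect_identical(nrow(ds$pairs), 0L)
})

test_that("identical configurations give identical datasets and fixtures", {
  cfg <- sim_config(n_genes = 120, seed = 11)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$genes, ds2$genes)
  expect_identical(ds1$truth, ds2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture(ds1, d1, sam = "AA1:1")
  p2 <- write_fixture(ds2, d2, sam = "AA1:1")
  for (f in c("counts", "bed", "gff3", "pairs", "truth", "sam_AA1:1")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
})

test_that("simulated counts realize the planted per-class mean structure", {
  cfg <- sim_config(n_genes = 3000, seed = 3, mean_expression = 150,
                    effect_fold = 4)
  ds <- generate_dataset(cfg)
  reps <- cfg$n_replicates
  totals <- tapply(ds$counts$count,
                   list(ds$counts$gene_id, ds$counts$sample), sum)
  totals <- totals[rownames(ds$means), colnames(ds$means)]
  # Poisson totals: |observed - expected| within 3 SE per planted class
  for (cl in setdiff(SIM_CLASSES, "silent")) {
    g <- ds$truth$gene_id[ds$truth$true_class == cl]
    if (length(g) < 50) next
    expected <- sum(ds$means[g, ]) * reps
    observed <- sum(totals[g, ])
    expect_lt(abs(observed - expected), 3 * sqrt(expected),
              label = sprintf("class %s total", cl))
  }
})

test_that("dispersion zero gives Poisson noise, positive dispersion inflates it", {
  cfg0 <- null_config(n_genes = 2000, seed = 5, mean_expression = 200)
  v0 <- with(generate_dataset(cfg0), {
    m <- pool_counts(counts)
    stats::var(m[, "AA1"] / 2)  # per-replicate scale
  })
  cfg1 <- null_config(n_genes = 2000, seed = 5, mean_expression = 200,
                      nb_dispersion = 0.2)
  v1 <- with(generate_dataset(cfg1), {
    m <- pool_counts(counts)
    stats::var(m[, "AA1"] / 2)
  })
  expect_gt(v1, 2 * v0)
})

test_that("truth table is one row per gene with pair-aware bias labels", {
  ds <- generate_dataset(sim_config(n_genes = 500, seed = 2))
  expect_identical(sort(ds$truth$gene_id), sort(ds$genes$gene_id))
  expect_false(anyDuplicated(ds$truth$gene_id) > 0)
  paired <- c(ds$pairs$a_gene_id, ds$pairs$c_gene_id)
  unpaired_bias <- ds$truth$true_bias[!ds$truth$gene_id %in% paired]
  expect_true(all(unpaired_bias == "none"))
  # pair links are symmetric and cross-subgenome
  sub <- setNames(ds$genes$subgenome, ds$genes$gene_id)
  expect_true(all(sub[ds$pairs$a_gene_id] == "A"))
  expect_true(all(sub[ds$pairs$c_gene_id] == "C"))
  # silent truth label if and only if no fragment was ever sampled
  tot <- tapply(ds$counts$count, ds$counts$gene_id, sum)[ds$truth$gene_id]
  expect_identical(as.vector(tot == 0), ds$truth$true_class == "silent")
})

test_that("fixture round-trips through the readers", {
  ds <- generate_dataset(sim_config(n_genes = 10, seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_fixture(ds, dir)
  expect_identical(length(readLines(paths$counts)) - 1L -
                     sum(startsWith(readLines(paths$counts), "#")),
                   nrow(ds$counts))
  back <- read_counts(paths$counts)
  expect_equal(back$count, ds$counts$count)
  expect_equal(attr(back, "library_sizes"),
               attr(ds$counts, "library_sizes"))
  genes <- read_annotation(paths$bed, pairs_path = paths$pairs)
  expect_setequal(genes$gene_id, ds$genes$gene_id)
  i <- match(ds$genes$gene_id, genes$gene_id)
  expect_identical(genes$start[i], ds$genes$start)
  expect_identical(genes$end[i], ds$genes$end)
  expect_identical(genes$partner_id[i], ds$genes$partner_id)
})
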