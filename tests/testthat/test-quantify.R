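test_that("fpkm implements the count/length/depth normalization", {
  expect_identical(fpkm(0, 1000, 1e6), 0)
  expect_identical(fpkm(10, 1000, 1e6), 10)
  # inverse scaling with library size, invariance to gene relabeling
  expect_equal(fpkm(10, 1000, 2e6), 5)
  expect_equal(fpkm(c(3, 7), c(500, 2000), 1e6),
               c(3 * 2, 7 / 2))
  expect_error(fpkm(1, 0, 1e6), "length")
  expect_error(fpkm(1, 1000, 0), "library")
  expect_error(fpkm(-1, 1000, 1e6), ">= 0")
})

test_that("two-sided Fisher test matches exhaustive fixed-margin enumeration", {
  expect_identical(fisher_exact_two_sided(0, 10, 0, 10), 1)
  # row swap leaves the two-sided p unchanged
  expect_equal(fisher_exact_two_sided(3, 10, 1, 10),
               fisher_exact_two_sided(1, 10, 3, 10))
  expect_error(fisher_exact_two_sided(-1, 10, 0, 10), ">= 0")
  expect_error(fisher_exact_two_sided(11, 10, 0, 10), "exceed")

  # exhaustive over all small tables
  for (n1 in 1:8) for (n2 in 1:8) for (c1 in 0:n1) for (c2 in 0:n2) {
    expect_equal(fisher_exact_two_sided(c1, n1, c2, n2),
                 fet_oracle(c1, n1, c2, n2), tolerance = 1e-12,
                 label = sprintf("table %d/%d vs %d/%d", c1, n1, c2, n2))
  }

  # randomized tables up to margin total 200, including the example size
  set.seed(42)
  for (i in 1:300) {
    n1 <- sample(1:199, 1)
    n2 <- sample(1:(200 - n1), 1)
    c1 <- sample(0:n1, 1)
    c2 <- sample(0:n2, 1)
    expect_equal(fisher_exact_two_sided(c1, n1, c2, n2),
                 fet_oracle(c1, n1, c2, n2), tolerance = 1e-12)
  }
  # agreement with the standard implementation on a handful of tables
  for (tab in list(c(3, 10, 1, 10), c(40, 100, 10, 60), c(0, 5, 4, 7))) {
    m <- matrix(c(tab[1], tab[2] - tab[1], tab[3], tab[4] - tab[3]),
                nrow = 2, byrow = TRUE)
    expect_equal(fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4]),
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment equals the direct step-up formula", {
  expect_identical(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("null contrast yields no signs; planted folds are recovered with direction", {
  # identical pooled counts and library sizes -> all signs 0
  counts <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), 2),
    sample = rep(c("S1", "S2"), each = 3),
    replicate = 1L,
    count = c(5, 9, 0, 5, 9, 0)
  )
  d <- differential_contrast(counts, "S1", "S2")
  expect_identical(nrow(d), 2L)  # g3 expressed in neither sample
  expect_true(all(d$sign == 0L))

  mix <- setNames(rep(0, length(SIM_CLASSES)), SIM_CLASSES)
  mix[c("eld_A_up", "eld_A_down")] <- 0.1
  mix["additive_equal"] <- 0.8
  cfg <- sim_config(n_genes = 2000, seed = 21, mean_expression = 500,
                    effect_fold = 8, lib_sizes = 4e7, class_mix = mix)
  ds <- generate_dataset(cfg)
  d <- differential_contrast(ds$counts, "AA1", "CC")
  sgn <- setNames(d$sign, d$gene_id)
  up <- ds$truth$gene_id[ds$truth$true_class == "eld_A_up"]
  dn <- ds$truth$gene_id[ds$truth$true_class == "eld_A_down"]
  expect_gt(mean(sgn[up] == 1L), 0.9)
  expect_gt(mean(sgn[dn] == -1L), 0.9)
  # sign invariant: non-zero iff q below alpha
  expect_identical(d$sign != 0L, d$q < 0.05)
})

test_that("MPV pseudo-sample averages depth-normalized parental counts", {
  mp <- mpv_pseudo(c(100, 0), 1e6, c(300, 0), 3e6)
  # L* = 2e6; normalized counts 200 and 200 -> mpv 200; zeros stay zero
  expect_identical(mp$lib, 2e6)
  expect_identical(mp$count, c(200, 0))
  # half-up rounding of the average
  mp2 <- mpv_pseudo(3, 100, 4, 100)
  expect_identical(mp2$count, 4)  # (3 + 4)/2 = 3.5 -> 4
})

test_that("expression profile flags expressed genes exactly when counts are non-zero", {
  ds <- generate_dataset(sim_config(n_genes = 200, seed = 6))
  prof <- expression_profile(ds$counts, ds$genes)
  expect_identical(prof$expressed, prof$fpkm > 0)
  mat <- pool_counts(ds$counts)
  expect_identical(unname(prof$expressed), unname(mat > 0))
})
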