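test_that("exactly 19 sign triples are interval-realizable, matching the case analysis", {
  adm <- admissible_triples()
  expect_identical(nrow(adm), 19L)
  expect_identical(nrow(unique(adm)), 19L)

  all27 <- expand.grid(s_ha = c(-1, 0, 1), s_hc = c(-1, 0, 1),
                       s_pc = c(-1, 0, 1))
  oracle <- mapply(triple_admissible, all27$s_ha, all27$s_hc, all27$s_pc)
  expect_identical(sum(oracle), 19L)
  key <- function(d) paste(d$s_ha, d$s_hc, d$s_pc)
  expect_setequal(key(adm), key(all27[oracle, ]))
})

test_that("pattern assignment is a bijection on admissible triples, INCONSISTENT otherwise", {
  all27 <- expand.grid(s_ha = c(-1L, 0L, 1L), s_hc = c(-1L, 0L, 1L),
                       s_pc = c(-1L, 0L, 1L))
  pat <- assign_pattern(all27$s_ha, all27$s_hc, all27$s_pc)
  expect_identical(sum(pat == "INCONSISTENT"), 8L)
  valid <- pat[pat != "INCONSISTENT"]
  expect_identical(sort(valid), sort(alloexpr:::ROMAN_PATTERNS))
  adm <- admissible_triples()
  expect_false(any(assign_pattern(adm$s_ha, adm$s_hc, adm$s_pc) ==
                     "INCONSISTENT"))

  # pinned anchor patterns: equal-to-both, the four ELD forms, the
  # hybrid-above-A/below-C impossibility
  expect_identical(assign_pattern(0L, 0L, 0L), "XI")
  expect_identical(assign_pattern(0L, 1L, 1L), "XII")    # mimics A, A > C
  expect_identical(assign_pattern(-1L, 0L, 1L), "XIII")  # mimics C, down
  expect_identical(assign_pattern(1L, 0L, -1L), "XVIII") # mimics C, up
  expect_identical(assign_pattern(0L, -1L, -1L), "XIX")  # mimics A, down
  expect_identical(assign_pattern(1L, -1L, 1L), "INCONSISTENT")
  expect_identical(assign_pattern(1L, 1L, 0L), "IX")     # transgressive up
  expect_identical(assign_pattern(-1L, -1L, 0L), "X")    # transgressive down
  expect_error(assign_pattern(2L, 0L, 0L), "s_ha")
})

test_that("category grid maps (hybrid vs MPV, parent vs parent) to letters", {
  expect_identical(assign_category(0L, 0L), "a")
  expect_identical(assign_category(0L, 1L), "b")
  expect_identical(assign_category(0L, -1L), "c")
  expect_identical(assign_category(1L, 0L), "d")
  expect_identical(assign_category(1L, 1L), "e")
  expect_identical(assign_category(1L, -1L), "f")
  expect_identical(assign_category(-1L, 0L), "g")
  expect_identical(assign_category(-1L, 1L), "h")
  expect_identical(assign_category(-1L, -1L), "i")
  expect_error(assign_category(3L, 0L), "s_h_mpv")
})

test_that("null simulation lands almost entirely in the equal-to-both patterns", {
  ds <- generate_dataset(null_config(n_genes = 2000, seed = 31))
  cls <- classify_all(ds$counts, a = "AA1", c = "CC", h = "AC1")
  frac_equal <- sum(cls$summary$pattern_counts[c("VII", "XI", "XVII")]) /
    cls$summary$n_genes
  expect_gt(frac_equal, 0.95)
  # partition invariants
  expect_identical(sum(cls$summary$pattern_counts),
                   as.integer(cls$summary$n_genes))
  expect_identical(sum(cls$summary$category_counts),
                   as.integer(cls$summary$n_genes))
})

test_that("planted ELD and transgressive classes are recovered with their form", {
  ds <- generate_dataset(recovery_config(n_genes = 3000, seed = 33))
  cls <- classify_all(ds$counts, a = "AA1", c = "CC", h = "AC1")
  a <- cls$assignments
  expect_gt(recovery_rate(ds$truth, a, "eld_A_up",
                          function(m) m$eld_form == "A_up"), 0.9)
  expect_gt(recovery_rate(ds$truth, a, "eld_A_down",
                          function(m) m$eld_form == "A_down"), 0.9)
  expect_gt(recovery_rate(ds$truth, a, "eld_C_up",
                          function(m) m$eld_form == "C_up"), 0.9)
  expect_gt(recovery_rate(ds$truth, a, "eld_C_down",
                          function(m) m$eld_form == "C_down"), 0.9)
  expect_gt(recovery_rate(ds$truth, a, "transgressive_up",
                          function(m) m$transgressive == "up"), 0.9)
  expect_gt(recovery_rate(ds$truth, a, "transgressive_down",
                          function(m) m$transgressive == "down"), 0.9)
  # ELD only among parent-differential genes, hybrid tracking the sign
  eld <- a[a$eld_form != "none", ]
  expect_true(all(eld$s_pc != 0L))
  expect_true(all(eld$pattern %in% c("XII", "XIII", "XVIII", "XIX")))
  # category letters track the additivity call
  expect_identical(a$category %in% c("a", "b", "c"),
                   a$additive_vs_mpv == "additive")
  expect_identical(a$category %in% c("d", "e", "f"),
                   a$additive_vs_mpv == "up")
})

test_that("cross-comparison partitions shared genes and is diagonal on itself", {
  ds <- generate_dataset(recovery_config(n_genes = 1000, seed = 35))
  cls <- classify_all(ds$counts, a = "AA1", c = "CC", h = "AC1")
  self <- cross_compare(cls$assignments, cls$assignments)
  expect_identical(self$changed, 0L)
  expect_identical(self$opposite, 0L)
  off_diag <- sum(self$eld_table) - sum(diag(self$eld_table))
  expect_identical(off_diag, 0L)

  cls2 <- classify_all(ds$counts, a = "AA2", c = "CC", h = "AC2")
  cmp <- cross_compare(cls$assignments, cls2$assignments)
  expect_identical(cmp$both_additive + cmp$both_nonadditive_same +
                     cmp$changed + cmp$opposite, cmp$n_shared)
})
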