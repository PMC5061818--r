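# Classification of every gene by its three pairwise significance signs
# (hybrid vs A parent, hybrid vs C parent, A parent vs C parent) into the
# 19 realizable expression patterns (roman numerals), and by (hybrid vs
# MPV, A vs C) into the 9 expression categories (letters a-i). Patterns
# XII/XIII/XVIII/XIX are the four forms of expression-level dominance;
# I/IX/XV and II/X/XVI are transgressive up/down.

ROMAN_PATTERNS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                    "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI",
                    "XVII", "XVIII", "XIX")

# canonical triple -> numeral table; column order (s_ha, s_hc, s_pc)
.pattern_table <- function() {
  t <- rbind(
    c( 1,  1,  1), c(-1, -1,  1), c( 1,  0,  0), c( 0,  1,  0),
    c(-1,  0,  0), c( 0, -1,  0), c( 0,  0,  1), c( 1, -1, -1),
    c( 1,  1,  0), c(-1, -1,  0), c( 0,  0,  0), c( 0,  1,  1),
    c(-1,  0,  1), c(-1,  1,  1), c( 1,  1, -1), c(-1, -1, -1),
    c( 0,  0, -1), c( 1,  0, -1), c( 0, -1, -1)
  )
  data.frame(s_ha = t[, 1], s_hc = t[, 2], s_pc = t[, 3],
             pattern = ROMAN_PATTERNS, stringsAsFactors = FALSE)
}

.pattern_group_map <- c(
  I = "transgressive_up", IX = "transgressive_up", XV = "transgressive_up",
  II = "transgressive_down", X = "transgressive_down",
  XVI = "transgressive_down",
  VII = "equal_both", XI = "equal_both", XVII = "equal_both",
  III = "equal_one_parent", IV = "equal_one_parent",
  V = "equal_one_parent", VI = "equal_one_parent",
  XII = "equal_one_parent", XIII = "equal_one_parent",
  XVIII = "equal_one_parent", XIX = "equal_one_parent",
  VIII = "intermediate", XIV = "intermediate",
  INCONSISTENT = "inconsistent"
)

.eld_form_map <- c(XII = "A_up", XIX = "A_down", XVIII = "C_up",
                   XIII = "C_down")

#' Sign triples realizable by three confidence intervals
#'
#' Enumerates the triples `(s_ha, s_hc, s_pc)` of pairwise comparison
#' signs (hybrid vs A, hybrid vs C, A vs C) that can be realized by three
#' real intervals, where a directed sign means disjoint intervals in that
#' order and 0 means overlap. Computed by brute-force enumeration over a
#' finite endpoint grid (six distinct endpoints suffice to realize any
#' ordering of three disjoint intervals). Exactly 19 of the 27 formal
#' triples are realizable.
#'
#' @return data frame of the admissible triples with columns `s_ha`,
#'   `s_hc`, `s_pc` (integers in -1/0/+1), one row per triple.
#' @export
admissible_triples <- function() {
  iv <- t(utils::combn(1:6, 2))
  colnames(iv) <- c("lo", "hi")
  cmp <- function(i, j) {  # sign of interval i vs interval j
    ifelse(iv[i, "lo"] > iv[j, "hi"], 1L,
           ifelse(iv[i, "hi"] < iv[j, "lo"], -1L, 0L))
  }
  n <- nrow(iv)
  grid <- expand.grid(h = seq_len(n), a = seq_len(n), c = seq_len(n))
  trip <- data.frame(
    s_ha = cmp(grid$h, grid$a),
    s_hc = cmp(grid$h, grid$c),
    s_pc = cmp(grid$a, grid$c)
  )
  out <- unique(trip)
  out <- out[order(out$s_ha, out$s_hc, out$s_pc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the roman-numeral expression pattern
#'
#' Maps sign triples to the 19 patterns; the 8 triples not realizable by
#' three confidence intervals map to `"INCONSISTENT"`.
#'
#' @param s_ha,s_hc,s_pc integer signs in -1/0/+1 for hybrid vs A parent,
#'   hybrid vs C parent, and A parent vs C parent (recycled to a common
#'   length).
#' @return character vector of numerals `I`..`XIX` or `INCONSISTENT`.
#' @export
assign_pattern <- function(s_ha, s_hc, s_pc) {
  n <- max(length(s_ha), length(s_hc), length(s_pc))
  s_ha <- .check_sign(rep_len(s_ha, n), "s_ha")
  s_hc <- .check_sign(rep_len(s_hc, n), "s_hc")
  s_pc <- .check_sign(rep_len(s_pc, n), "s_pc")
  tab <- .pattern_table()
  key <- paste(s_ha, s_hc, s_pc)
  hit <- match(key, paste(tab$s_ha, tab$s_hc, tab$s_pc))
  out <- tab$pattern[hit]
  out[is.na(hit)] <- "INCONSISTENT"
  out
}

#' Assign the letter expression category
#'
#' Nine categories from the hybrid-vs-MPV sign (rows) and the
#' parent-vs-parent sign (columns): additive genes are `a`/`b`/`c`
#' (for A = C, A > C, A < C), up-regulated `d`/`e`/`f`, down-regulated
#' `g`/`h`/`i`.
#'
#' @param s_h_mpv,s_pc integer signs in -1/0/+1 (recycled).
#' @return character vector of letters `a`..`i`.
#' @export
assign_category <- function(s_h_mpv, s_pc) {
  n <- max(length(s_h_mpv), length(s_pc))
  s_h_mpv <- .check_sign(rep_len(s_h_mpv, n), "s_h_mpv")
  s_pc <- .check_sign(rep_len(s_pc, n), "s_pc")
  grid <- matrix(c("a", "b", "c",
                   "d", "e", "f",
                   "g", "h", "i"), nrow = 3, byrow = TRUE)
  row <- c(`0` = 1L, `1` = 2L, `-1` = 3L)[as.character(s_h_mpv)]
  col <- c(`0` = 1L, `1` = 2L, `-1` = 3L)[as.character(s_pc)]
  grid[cbind(row, col)]
}

#' Classify all genes of a parents/hybrid trio
#'
#' Runs the four contrasts (A vs C, hybrid vs A, hybrid vs C, hybrid vs
#' MPV) over the genes expressed in the trio, BH-adjusted within each
#' contrast, and assigns each gene its pattern, category,
#' expression-level-dominance form, transgressive status and additivity
#' call.
#'
#' @param counts long count data frame or pooled matrix.
#' @param a,c,h sample names of the A parent, C parent and hybrid.
#' @param alpha significance level on BH-adjusted p-values.
#' @param expressed_in `"any"` (default) keeps genes expressed in at
#'   least one of the three samples, zeros included in the tests;
#'   `"all"` restricts to genes expressed in all three.
#' @return list with `assignments` (one row per gene: signs, pattern,
#'   category, eld_form, transgressive, additive_vs_mpv) and `summary`
#'   (pattern/category counts, ELD forms and dominance totals,
#'   transgressive totals, exact-binomial balance p-values, sample names
#'   and universe size).
#' @export
classify_all <- function(counts, a, c, h, alpha = 0.05,
                         expressed_in = c("any", "all")) {
  expressed_in <- match.arg(expressed_in)
  mat <- pool_counts(counts)
  missing <- setdiff(c(a, c, h), colnames(mat))
  if (length(missing)) {
    stop("missing samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  libs <- attr(mat, "lib_sizes")
  sub <- mat[, c(a, c, h), drop = FALSE]
  u <- if (expressed_in == "any") rowSums(sub > 0) > 0 else
    rowSums(sub > 0) == 3L
  u <- rownames(mat)[u]
  if (length(u) == 0L) stop("no expressed genes in the trio", call. = FALSE)

  ca <- mat[u, a]; cc <- mat[u, c]; ch <- mat[u, h]
  pc <- .contrast_signs(ca, libs[[a]], cc, libs[[c]], alpha)
  ha <- .contrast_signs(ch, libs[[h]], ca, libs[[a]], alpha)
  hc <- .contrast_signs(ch, libs[[h]], cc, libs[[c]], alpha)
  mp <- mpv_pseudo(ca, libs[[a]], cc, libs[[c]])
  hm <- .contrast_signs(ch, libs[[h]], mp$count, mp$lib, alpha)

  pattern <- assign_pattern(ha$sign, hc$sign, pc$sign)
  category <- assign_category(hm$sign, pc$sign)
  eld_form <- unname(.eld_form_map[pattern])
  eld_form[is.na(eld_form)] <- "none"
  transgressive <- unname(.pattern_group_map[pattern])
  transgressive[!transgressive %in%
                  c("transgressive_up", "transgressive_down")] <- "none"
  transgressive <- sub("transgressive_", "", transgressive)
  additive_vs_mpv <- c(`0` = "additive", `1` = "up",
                       `-1` = "down")[as.character(hm$sign)]

  assignments <- data.frame(
    gene_id = u,
    s_pc = pc$sign, s_ha = ha$sign, s_hc = hc$sign, s_h_mpv = hm$sign,
    pattern = pattern, category = category, eld_form = eld_form,
    transgressive = transgressive,
    additive_vs_mpv = unname(additive_vs_mpv),
    stringsAsFactors = FALSE, row.names = NULL
  )

  as_counts <- function(x, levels) {
    t <- table(factor(x, levels = levels))
    stats::setNames(as.integer(t), names(t))
  }
  pat_counts <- as_counts(pattern, c(ROMAN_PATTERNS, "INCONSISTENT"))
  cat_counts <- as_counts(category, letters[1:9])
  eld_counts <- as_counts(eld_form,
                          c("A_up", "A_down", "C_up", "C_down", "none"))
  n_a_dom <- sum(eld_counts[c("A_up", "A_down")])
  n_c_dom <- sum(eld_counts[c("C_up", "C_down")])
  n_up <- sum(transgressive == "up")
  n_down <- sum(transgressive == "down")
  balance <- function(k, n) {
    if (n == 0) return(NA_real_)
    stats::binom.test(k, n, p = 0.5)$p.value
  }

  summary <- list(
    samples = c(A = a, C = c, H = h),
    alpha = alpha,
    n_genes = length(u),
    pattern_counts = pat_counts,
    category_counts = cat_counts,
    eld_forms = eld_counts[c("A_up", "A_down", "C_up", "C_down")],
    eld_total = n_a_dom + n_c_dom,
    a_dominance = n_a_dom,
    c_dominance = n_c_dom,
    eld_balance_p = balance(n_a_dom, n_a_dom + n_c_dom),
    transgressive_up = n_up,
    transgressive_down = n_down,
    transgressive_balance_p = balance(n_up, n_up + n_down),
    n_additive = sum(additive_vs_mpv == "additive"),
    n_nonadditive = sum(additive_vs_mpv != "additive")
  )
  list(assignments = assignments, summary = summary)
}

#' Compare pattern assignments between two hybrids
#'
#' Contingency of additivity and of the four expression-level-dominance
#' forms between two hybrids over their commonly classified genes.
#'
#' @param assignments_h1,assignments_h2 assignment data frames from
#'   [classify_all()].
#' @param decimals decimals for reported percentages.
#' @return list: `n_shared`, additivity sharing counts (`both_additive`,
#'   `both_nonadditive_same`, `changed`, `opposite`) with percentages,
#'   and `eld_table` (5x5 contingency over the ELD forms and `none`)
#'   with `eld_same`, the genes keeping the same ELD form.
#' @export
cross_compare <- function(assignments_h1, assignments_h2, decimals = 1) {
  m <- merge(assignments_h1, assignments_h2, by = "gene_id",
             suffixes = c("_1", "_2"))
  if (nrow(m) == 0L) {
    stop("the two assignment sets share no genes", call. = FALSE)
  }
  n <- nrow(m)
  add1 <- m$additive_vs_mpv_1 == "additive"
  add2 <- m$additive_vs_mpv_2 == "additive"
  both_add <- sum(add1 & add2)
  both_non_same <- sum(!add1 & !add2 &
                         m$additive_vs_mpv_1 == m$additive_vs_mpv_2)
  opposite <- sum(!add1 & !add2 &
                    m$additive_vs_mpv_1 != m$additive_vs_mpv_2)
  changed <- sum(xor(add1, add2))
  lev <- c("A_up", "A_down", "C_up", "C_down", "none")
  eld_tab <- table(factor(m$eld_form_1, lev), factor(m$eld_form_2, lev))
  eld_same <- sum(diag(eld_tab[1:4, 1:4]))
  list(
    n_shared = n,
    both_additive = both_add,
    both_additive_pct = percent(both_add, n, decimals),
    both_nonadditive_same = both_non_same,
    changed = changed,
    opposite = opposite,
    eld_table = eld_tab,
    eld_same = eld_same
  )
}
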