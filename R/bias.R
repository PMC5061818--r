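# Homoeolog expression bias. Each A/C gene pair is tested twice: between
# the parents (A copy in the A parent vs C copy in the C parent, each
# with its own library size) and within the hybrid (both copies in one
# library). Counts are length-adjusted to the pair's mean length before
# the exact test so that homoeolog length differences cancel. The two
# signs place the pair in one of nine categories describing parental
# legacy (maintained / lost / novel / reversed bias).

#' The nine homoeolog-bias categories
#'
#' Row labels of the bias summary table, by parental legacy: bias
#' maintained from the parents, lost in the hybrid, novel in the hybrid,
#' or reversed between parents and hybrid.
#' @export
BIAS_CATEGORIES <- c(
  "maintained_equal", "maintained_A", "maintained_C",
  "lost_A", "lost_C",
  "novel_A", "novel_C", "reversed_A_to_C", "reversed_C_to_A"
)

#' Length-adjusted homoeolog contrast
#'
#' Adjusts each copy's count to the pair's mean length
#' (`c' = round_half_up(c * mean_len / len)`), tests the adjusted counts
#' against their libraries with [fisher_exact_two_sided()], adjusts the
#' whole family of pairs with BH, and signs by the normalized difference
#' (+1 = A copy higher). Pairs with both adjusted counts zero get sign 0.
#'
#' @param count_a,count_c pooled counts of the A and C copies (vectors
#'   over pairs).
#' @param len_a,len_c copy lengths in bp.
#' @param lib_a,lib_c library sizes (scalars; within a hybrid both are
#'   the same library total).
#' @param alpha significance level on adjusted p-values.
#' @return data frame with `p`, `q`, `sign`.
#' @export
homoeolog_contrast <- function(count_a, len_a, lib_a,
                               count_c, len_c, lib_c, alpha = 0.05) {
  if (any(len_a <= 0) || any(len_c <= 0)) {
    stop("gene lengths must be > 0", call. = FALSE)
  }
  .stopifnot_scalar_number(lib_a, "lib_a", positive = TRUE)
  .stopifnot_scalar_number(lib_c, "lib_c", positive = TRUE)
  mean_len <- (len_a + len_c) / 2
  ca <- pmin(round_half_up(count_a * mean_len / len_a), lib_a)
  cc <- pmin(round_half_up(count_c * mean_len / len_c), lib_c)
  p <- fisher_exact_two_sided(ca, lib_a, cc, lib_c)
  q <- bh_adjust(p)
  s <- ifelse(q < alpha, sign(ca / lib_a - cc / lib_c), 0)
  data.frame(p = p, q = q, sign = as.integer(s))
}

#' Nine-way bias category from the two pair signs
#'
#' @param parent_sign sign of the parental contrast (+1 = A copy higher
#'   in its parent).
#' @param hybrid_sign sign of the within-hybrid contrast.
#' @return character vector over [BIAS_CATEGORIES].
#' @export
classify_pair <- function(parent_sign, hybrid_sign) {
  n <- max(length(parent_sign), length(hybrid_sign))
  p <- .check_sign(rep_len(parent_sign, n), "parent_sign")
  h <- .check_sign(rep_len(hybrid_sign, n), "hybrid_sign")
  key <- paste(p, h)
  map <- c(
    "0 0" = "maintained_equal",
    "1 1" = "maintained_A", "-1 -1" = "maintained_C",
    "1 0" = "lost_A", "-1 0" = "lost_C",
    "0 1" = "novel_A", "0 -1" = "novel_C",
    "1 -1" = "reversed_A_to_C", "-1 1" = "reversed_C_to_A"
  )
  unname(map[key])
}

.bias_legacy <- c(
  maintained_equal = "none",
  maintained_A = "maintained", maintained_C = "maintained",
  lost_A = "lost", lost_C = "lost",
  novel_A = "novel", novel_C = "novel",
  reversed_A_to_C = "reversed", reversed_C_to_A = "reversed"
)

#' Classify homoeolog pairs of one parents/hybrid contrast
#'
#' Restricts to the commonly expressed pair universe, runs the parental
#' and within-hybrid length-adjusted contrasts (BH within each family),
#' and assigns each pair its nine-way category and parental-legacy
#' label.
#'
#' @param counts long count data frame or pooled matrix.
#' @param genes gene-model data frame (lengths).
#' @param pairs data frame `a_gene_id`, `c_gene_id`.
#' @param a,c,h sample names of A parent, C parent and hybrid.
#' @param alpha significance level.
#' @param universe `"either"` (default): each copy expressed in its
#'   parent or in the hybrid; `"all_samples"`: each copy expressed both
#'   in its parent and in the hybrid.
#' @return data frame: a_gene_id, c_gene_id, parent_sign, hybrid_sign,
#'   category, legacy.
#' @export
classify_homoeolog_bias <- function(counts, genes, pairs, a, c, h,
                                    alpha = 0.05,
                                    universe = c("either", "all_samples")) {
  universe <- match.arg(universe)
  mat <- pool_counts(counts)
  libs <- attr(mat, "lib_sizes")
  ia <- match(pairs$a_gene_id, rownames(mat))
  ic <- match(pairs$c_gene_id, rownames(mat))
  keep <- !is.na(ia) & !is.na(ic)
  pairs <- pairs[keep, , drop = FALSE]
  ia <- ia[keep]; ic <- ic[keep]
  a_par <- mat[ia, a]; a_hyb <- mat[ia, h]
  c_par <- mat[ic, c]; c_hyb <- mat[ic, h]
  expr <- if (universe == "either") {
    (a_par + a_hyb) > 0 & (c_par + c_hyb) > 0
  } else {
    a_par > 0 & a_hyb > 0 & c_par > 0 & c_hyb > 0
  }
  if (!any(expr)) stop("no commonly expressed homoeolog pairs", call. = FALSE)
  pairs <- pairs[expr, , drop = FALSE]
  len_a <- genes$length[match(pairs$a_gene_id, genes$gene_id)]
  len_c <- genes$length[match(pairs$c_gene_id, genes$gene_id)]
  if (anyNA(len_a) || anyNA(len_c)) {
    stop("pairs reference genes absent from the annotation", call. = FALSE)
  }
  par <- homoeolog_contrast(a_par[expr], len_a, libs[[a]],
                            c_par[expr], len_c, libs[[c]], alpha)
  hyb <- homoeolog_contrast(a_hyb[expr], len_a, libs[[h]],
                            c_hyb[expr], len_c, libs[[h]], alpha)
  category <- classify_pair(par$sign, hyb$sign)
  data.frame(
    a_gene_id = pairs$a_gene_id, c_gene_id = pairs$c_gene_id,
    parent_sign = par$sign, hybrid_sign = hyb$sign,
    category = category, legacy = unname(.bias_legacy[category]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Summarize homoeolog-bias calls into the nine-category table
#'
#' Counts and one-decimal percentages per category (denominator = pairs
#' in the contrast), overall A- and C-bias totals (pairs whose hybrid
#' sign favors that subgenome), and a chi-square goodness-of-fit test of
#' the A:C bias totals against 1:1. When a second hybrid's calls are
#' supplied, a `common` column counts pairs in the same category in both.
#'
#' @param calls pair-call data frame from [classify_homoeolog_bias()].
#' @param calls2 optional second hybrid's calls over the same pairs.
#' @param decimals decimals for percentages.
#' @return list: `table` (category, n, pct, optionally common),
#'   `overall_A`, `overall_A_pct`, `overall_C`, `overall_C_pct`,
#'   `total`, `balance_chisq_p`.
#' @export
summarize_bias <- function(calls, calls2 = NULL, decimals = 1) {
  if (nrow(calls) == 0L) stop("empty pair-call set", call. = FALSE)
  total <- nrow(calls)
  n <- table(factor(calls$category, levels = BIAS_CATEGORIES))
  tab <- data.frame(
    category = BIAS_CATEGORIES,
    n = as.integer(n),
    pct = percent(as.integer(n), total, decimals),
    stringsAsFactors = FALSE
  )
  if (!is.null(calls2)) {
    m <- merge(calls[, c("a_gene_id", "category")],
               calls2[, c("a_gene_id", "category")],
               by = "a_gene_id")
    shared <- table(factor(m$category.x[m$category.x == m$category.y],
                           levels = BIAS_CATEGORIES))
    tab$common <- as.integer(shared)
  }
  n_a <- sum(calls$hybrid_sign == 1L)
  n_c <- sum(calls$hybrid_sign == -1L)
  chisq_p <- if (n_a + n_c > 0) {
    # small-count approximation warnings are expected for near-balanced
    # tables with few biased pairs; the statistic is still reported
    suppressWarnings(
      stats::chisq.test(c(n_a, n_c), p = c(0.5, 0.5))$p.value)
  } else NA_real_
  list(
    table = tab,
    overall_A = n_a, overall_A_pct = percent(n_a, total, decimals),
    overall_C = n_c, overall_C_pct = percent(n_c, total, decimals),
    total = total,
    balance_chisq_p = chisq_p
  )
}
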