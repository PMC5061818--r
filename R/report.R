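# Whole-experiment orchestration and the small reporting arithmetic used
# throughout the summary tables (one-decimal half-up percentages, floored
# integer means).

#' Percentage with half-up rounding
#'
#' @param numerator,denominator counts; `denominator > 0`.
#' @param decimals decimal places (default 1, the reporting convention).
#' @return `100 * numerator / denominator`, rounded half-up.
#' @examples
#' percent(16962, 22836) # 74.3
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  round_half_up(100 * numerator / denominator, decimals)
}

#' Floored integer mean
#'
#' Integer part of the arithmetic mean, as used for reporting average
#' read counts.
#'
#' @param values non-empty vector of non-negative numbers.
#' @return integer-valued floor of the mean.
#' @export
mean_integer <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  floor(mean(values))
}

#' Run the full expression analysis over a two-hybrid experiment
#'
#' Orchestrates, deterministically, every stage over a count table:
#' pairwise differential contrasts (each hybrid vs its parents, the
#' parents vs each other, hybrid vs hybrid), pattern/category
#' classification with ELD and transgressive extraction for each hybrid,
#' cross-hybrid sharing, and the homoeolog-bias tables. Every percentage
#' in the report is recomputed from the stored counts at the configured
#' rounding.
#'
#' @param counts long count data frame or pooled matrix.
#' @param genes gene-model data frame.
#' @param pairs homoeolog pair links (may have zero rows).
#' @param roles named list of sample names:
#'   `list(A1 = , A2 = , C = , H1 = , H2 = )`; hybrid 1 is classified
#'   against parent `A1` + `C`, hybrid 2 against `A2` + `C`.
#' @param alpha significance level on BH-adjusted p-values.
#' @param decimals decimals for percentages.
#' @return nested list: `expressed` (per-sample expressed-gene counts),
#'   `de` (per-contrast DE counts over the expressed union),
#'   `classification` (per-hybrid [classify_all()] summaries),
#'   `sharing` ([cross_compare()] output), `bias` (per-hybrid
#'   [summarize_bias()] tables), plus `alpha`.
#' @export
run_experiment <- function(counts, genes, pairs,
                           roles = list(A1 = "AA1", A2 = "AA2", C = "CC",
                                        H1 = "AC1", H2 = "AC2"),
                           alpha = 0.05, decimals = 1) {
  mat <- pool_counts(counts)
  expressed <- colSums(mat > 0)

  contrasts <- list(
    c(roles$A1, roles$C), c(roles$A2, roles$C),
    c(roles$H1, roles$A1), c(roles$H1, roles$C),
    c(roles$H2, roles$A2), c(roles$H2, roles$C),
    c(roles$H1, roles$H2), c(roles$A1, roles$A2)
  )
  de <- lapply(contrasts, function(xy) {
    d <- differential_contrast(mat, xy[1], xy[2], alpha = alpha)
    n_univ <- nrow(d)
    n_up <- sum(d$sign == 1L)
    n_down <- sum(d$sign == -1L)
    list(x = xy[1], y = xy[2], n_universe = n_univ,
         n_de = n_up + n_down, n_up = n_up, n_down = n_down,
         pct_de = percent(n_up + n_down, n_univ, decimals),
         pct_up = percent(n_up, n_univ, decimals),
         pct_down = percent(n_down, n_univ, decimals))
  })
  names(de) <- vapply(contrasts, function(xy)
    paste(xy, collapse = "_vs_"), character(1))

  cls1 <- classify_all(mat, a = roles$A1, c = roles$C, h = roles$H1,
                       alpha = alpha)
  cls2 <- classify_all(mat, a = roles$A2, c = roles$C, h = roles$H2,
                       alpha = alpha)
  sharing <- cross_compare(cls1$assignments, cls2$assignments, decimals)

  bias <- NULL
  if (nrow(pairs) > 0) {
    calls1 <- classify_homoeolog_bias(mat, genes, pairs, a = roles$A1,
                                      c = roles$C, h = roles$H1,
                                      alpha = alpha)
    calls2 <- classify_homoeolog_bias(mat, genes, pairs, a = roles$A2,
                                      c = roles$C, h = roles$H2,
                                      alpha = alpha)
    bias <- list(
      H1 = summarize_bias(calls1, calls2, decimals),
      H2 = summarize_bias(calls2, calls1, decimals),
      calls = list(H1 = calls1, H2 = calls2)
    )
  }

  list(
    alpha = alpha,
    expressed = expressed,
    de = de,
    classification = list(H1 = cls1, H2 = cls2),
    sharing = sharing,
    bias = bias
  )
}
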