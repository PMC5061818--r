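# FPKM quantification and DEGseq-style per-gene differential testing:
# replicates are pooled by summation and each gene is tested with a
# two-sided Fisher's exact test of its count against the remainder of the
# library, followed by Benjamini-Hochberg adjustment within the contrast.

#' Fragments per kilobase per million mapped fragments
#'
#' `count * 1e9 / (library_size * gene_length_bp)`. A gene is "expressed"
#' in a sample iff its FPKM is greater than zero, i.e. iff its pooled
#' count is non-zero.
#'
#' @param count fragment count(s).
#' @param gene_length_bp gene length(s) in bp, > 0.
#' @param library_size total mapped fragments in the library, > 0.
#' @return numeric FPKM values.
#' @export
fpkm <- function(count, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) stop("gene length must be > 0", call. = FALSE)
  if (any(library_size <= 0)) stop("library size must be > 0", call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  count * 1e9 / (library_size * gene_length_bp)
}

#' Two-sided Fisher's exact test for a 2x2 count table
#'
#' Tests the table `[[c1, n1 - c1], [c2, n2 - c2]]` by summing all
#' hypergeometric probabilities not exceeding that of the observed table
#' (with a relative tie tolerance of 1e-7, the convention of
#' `stats::fisher.test`). Implemented directly on `dhyper` so that tens of
#' thousands of per-gene tests with library-sized margins are cheap.
#'
#' @param c1,c2 focal counts, `0 <= c <= n`.
#' @param n1,n2 library totals, > 0. All four arguments are recycled.
#' @return vector of two-sided p-values in (0, 1].
#' @export
fisher_exact_two_sided <- function(c1, n1, c2, n2) {
  args <- cbind(c1 = c1, n1 = n1, c2 = c2, n2 = n2)
  if (any(args < 0)) stop("counts and totals must be >= 0", call. = FALSE)
  if (any(args[, "n1"] <= 0) || any(args[, "n2"] <= 0)) {
    stop("library totals must be > 0", call. = FALSE)
  }
  if (any(args[, "c1"] > args[, "n1"]) || any(args[, "c2"] > args[, "n2"])) {
    stop("counts cannot exceed their library totals", call. = FALSE)
  }
  rel_err <- 1 + 1e-7
  vapply(seq_len(nrow(args)), function(i) {
    c1i <- args[i, "c1"]; n1i <- args[i, "n1"]
    c2i <- args[i, "c2"]; n2i <- args[i, "n2"]
    k <- c1i + c2i
    lo <- max(0, k - n2i)
    hi <- min(n1i, k)
    support <- lo:hi
    d <- stats::dhyper(support, k, n1i + n2i - k, n1i)
    d0 <- stats::dhyper(c1i, k, n1i + n2i - k, n1i)
    min(1, sum(d[d <= d0 * rel_err]))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return BH-adjusted q-values (monotone, `q >= p`, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

.contrast_signs <- function(cx, nx, cy, ny, alpha) {
  cx <- round_half_up(cx)
  cy <- round_half_up(cy)
  p <- fisher_exact_two_sided(cx, nx, cy, ny)
  q <- bh_adjust(p)
  s <- ifelse(q < alpha, sign(cx / nx - cy / ny), 0)
  list(p = p, q = q, sign = as.integer(s))
}

#' Differential expression between two samples
#'
#' Pools replicates by summation, restricts to genes expressed (pooled
#' count > 0) in at least one of the two samples, and tests each gene's
#' count against the remaining library with [fisher_exact_two_sided()].
#' Signs are +1 when `x` is significantly higher than `y` at BH-adjusted
#' `q < alpha`, -1 when lower, 0 otherwise.
#'
#' @param counts long count data frame or pooled matrix (see
#'   [pool_counts()]).
#' @param x,y sample names to contrast (`x` vs `y`).
#' @param alpha significance level on adjusted p-values.
#' @param genes optional character vector fixing the gene universe
#'   (e.g. the three-sample universe used by [classify_all()]); the
#'   default is the union of genes expressed in `x` or `y`.
#' @return data frame: gene_id, count_x, count_y, p, q, sign.
#' @export
differential_contrast <- function(counts, x, y, alpha = 0.05,
                                  genes = NULL) {
  mat <- pool_counts(counts)
  if (!all(c(x, y) %in% colnames(mat))) {
    stop("samples not found in count table: ",
         paste(setdiff(c(x, y), colnames(mat)), collapse = ", "),
         call. = FALSE)
  }
  libs <- attr(mat, "lib_sizes")
  if (is.null(genes)) {
    keep <- rownames(mat)[mat[, x] > 0 | mat[, y] > 0]
  } else {
    keep <- intersect(genes, rownames(mat))
  }
  if (length(keep) == 0L) {
    stop("no expressed genes in contrast ", x, " vs ", y, call. = FALSE)
  }
  cs <- .contrast_signs(mat[keep, x], libs[[x]], mat[keep, y], libs[[y]],
                        alpha)
  data.frame(
    gene_id = keep,
    count_x = unname(mat[keep, x]),
    count_y = unname(mat[keep, y]),
    p = cs$p, q = cs$q, sign = cs$sign,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Mid-parent pseudo-sample for additivity testing
#'
#' The mid-parent value (MPV) is the average of the two parents'
#' expression levels. For exact-test comparison against the hybrid it is
#' materialized as an integer pseudo-count: each parent's pooled count is
#' normalized to the common reference depth `L* = (lib_a + lib_c) / 2`,
#' the two normalized counts are averaged, and the result is rounded
#' half-up; the pseudo-library size is `L*`.
#'
#' @param count_a,count_c pooled parental counts (vectors).
#' @param lib_a,lib_c parental library sizes.
#' @return list with `count` (integer pseudo-counts) and `lib` (scalar
#'   pseudo-library size).
#' @export
mpv_pseudo <- function(count_a, lib_a, count_c, lib_c) {
  .stopifnot_scalar_number(lib_a, "lib_a", positive = TRUE)
  .stopifnot_scalar_number(lib_c, "lib_c", positive = TRUE)
  l_star <- (lib_a + lib_c) / 2
  ca <- round_half_up(count_a * l_star / lib_a)
  cc <- round_half_up(count_c * l_star / lib_c)
  list(count = round_half_up((ca + cc) / 2), lib = round_half_up(l_star))
}

#' Expression profile (FPKM and expressed flags)
#'
#' @param counts long count data frame or pooled matrix.
#' @param genes gene-model data frame supplying lengths.
#' @return list with matrices `fpkm` and `expressed` (genes x samples),
#'   plus `lib_sizes`.
#' @export
expression_profile <- function(counts, genes) {
  mat <- pool_counts(counts)
  libs <- attr(mat, "lib_sizes")
  len <- genes$length[match(rownames(mat), genes$gene_id)]
  if (anyNA(len)) {
    stop("count table contains genes absent from the annotation",
         call. = FALSE)
  }
  fp <- sweep(mat, 2, libs, function(cnt, l) cnt / l) * 1e9 / len
  list(fpkm = fp, expressed = mat > 0, lib_sizes = libs)
}
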