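# Count-table interchange. The long format (gene_id, sample, replicate,
# count) matches the on-disk TSV; analysis functions pool replicates into
# a genes x samples matrix whose column sums are the library sizes.

# A count table may declare per-(sample, replicate) library sizes: the
# total sequencing depth of the library, of which the annotated genes
# capture a part. Declared sizes travel as the "library_sizes" attribute
# (a data frame sample/replicate/library_size) and as '#library_size'
# comment lines in the TSV. Without a declaration, the library size of a
# sample is the column sum of its counts (the accepted-fragment total,
# the convention for SAM-derived tables).

#' Read a count table
#'
#' @param path TSV with header `gene_id`, `sample`, `replicate`, `count`;
#'   optional leading comment lines
#'   `#library_size<TAB>sample<TAB>replicate<TAB>total` declare sequencing
#'   depths, which are checked against the recomputed column sums.
#' @return long-format count data frame (attribute `library_sizes` when
#'   declared).
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  libs <- NULL
  decl <- lines[is_comment & startsWith(lines, "#library_size")]
  if (length(decl)) {
    parts <- strsplit(decl, "\t", fixed = TRUE)
    libs <- data.frame(
      sample = vapply(parts, `[`, character(1), 2),
      replicate = as.integer(vapply(parts, `[`, character(1), 3)),
      library_size = as.numeric(vapply(parts, `[`, character(1), 4)),
      stringsAsFactors = FALSE
    )
  }
  x <- utils::read.delim(text = paste(lines[!is_comment], collapse = "\n"),
                         header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "sample", "replicate", "count")
  if (!all(need %in% names(x))) {
    stop("counts file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, need]
  if (nrow(x) && (any(!is.finite(x$count)) || any(x$count < 0))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(libs)) {
    obs <- stats::aggregate(count ~ sample + replicate, x, sum)
    m <- merge(obs, libs, by = c("sample", "replicate"))
    if (any(m$count > m$library_size)) {
      stop("declared library sizes are smaller than the assigned counts",
           call. = FALSE)
    }
    attr(x, "library_sizes") <- libs
  }
  x
}

#' Write a count table
#'
#' @param counts long-format count data frame; a `library_sizes`
#'   attribute, if present, is written as comment lines.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  libs <- attr(counts, "library_sizes")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(libs)) {
    writeLines(sprintf("#library_size\t%s\t%d\t%.0f", libs$sample,
                       libs$replicate, libs$library_size), con)
  }
  utils::write.table(counts[, c("gene_id", "sample", "replicate", "count")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool replicates into a genes x samples count matrix
#'
#' Replicates of a sample are summed. Library sizes are the summed
#' declared sequencing depths when the table declares them, otherwise
#' the column sums of the pooled matrix (total accepted fragment mass).
#'
#' @param counts long-format count data frame, or an already-pooled
#'   matrix (returned unchanged).
#' @return numeric matrix with rownames `gene_id` and an attribute
#'   `lib_sizes` (named per-sample totals).
#' @export
pool_counts <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(attr(counts, "lib_sizes"))) {
      attr(counts, "lib_sizes") <- colSums(counts)
    }
    return(counts)
  }
  genes <- unique(counts$gene_id)
  samples <- unique(counts$sample)
  mat <- tapply(counts$count,
                list(factor(counts$gene_id, levels = genes),
                     factor(counts$sample, levels = samples)),
                sum)
  mat[is.na(mat)] <- 0
  mat <- matrix(as.numeric(mat), nrow = length(genes),
                dimnames = list(genes, samples))
  decl <- attr(counts, "library_sizes")
  if (!is.null(decl)) {
    pooled <- tapply(decl$library_size, factor(decl$sample, samples), sum)
    if (anyNA(pooled)) {
      stop("declared library sizes do not cover every sample",
           call. = FALSE)
    }
    attr(mat, "lib_sizes") <- stats::setNames(as.numeric(pooled), samples)
  } else {
    attr(mat, "lib_sizes") <- colSums(mat)
  }
  mat
}
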