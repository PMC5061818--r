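# Gene-model I/O. Internally every interval is 0-based half-open; BED is
# native to that convention, GFF3 is 1-based closed and converted on the
# way in/out. Subgenome labels come from a `subgenome` GFF3 attribute when
# present, otherwise from the chromosome-name prefix (A.../C...).

.as_gene_df <- function(gr, gene_id, subgenome) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    subgenome = subgenome,
    partner_id = NA_character_,
    stringsAsFactors = FALSE
  )
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df$length <- df$end - df$start
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(df$gene_id[dup]), collapse = ", "), call. = FALSE)
  }
  df[, c("gene_id", "chrom", "start", "end", "strand", "length",
         "subgenome", "partner_id")]
}

.subgenome_from_chrom <- function(chrom) {
  pre <- toupper(substr(chrom, 1, 1))
  ifelse(pre %in% c("A", "C"), pre, NA_character_)
}

#' Read a gene annotation (BED6 or GFF3)
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param pairs_path optional two-column TSV (`a_gene_id`, `c_gene_id`)
#'   of homoeolog pairs; links are validated symmetric and
#'   cross-subgenome and stored in `partner_id`.
#' @return data frame of gene models with 0-based half-open `start`/`end`,
#'   `strand`, `length`, `subgenome` and `partner_id`.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3"),
                            pairs_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if (!is.null(mc$type)) {
      keep <- as.character(mc$type) == "gene"
      if (any(keep)) { gr <- gr[keep]; mc <- S4Vectors::mcols(gr) }
    }
    gene_id <- if (!is.null(mc$ID)) as.character(mc$ID) else
      if (!is.null(mc$Name)) as.character(mc$Name) else
        stop("GFF3 gene records need an ID attribute", call. = FALSE)
    subg <- if (!is.null(mc$subgenome)) as.character(mc$subgenome) else
      .subgenome_from_chrom(as.character(GenomicRanges::seqnames(gr)))
  } else {
    if (is.null(mc$name)) stop("BED needs a name column", call. = FALSE)
    gene_id <- as.character(mc$name)
    subg <- .subgenome_from_chrom(as.character(GenomicRanges::seqnames(gr)))
  }
  genes <- .as_gene_df(gr, gene_id, subg)
  if (!is.null(pairs_path)) {
    pairs <- read_pairs(pairs_path, genes)
    genes$partner_id[match(pairs$a_gene_id, genes$gene_id)] <- pairs$c_gene_id
    genes$partner_id[match(pairs$c_gene_id, genes$gene_id)] <- pairs$a_gene_id
  }
  genes
}

#' Read and validate homoeolog pair links
#'
#' Accepts links in either orientation (and redundantly in both); each
#' undirected pair must connect one A-subgenome gene to one C-subgenome
#' gene, and no gene may belong to two different pairs.
#'
#' @param path two-column TSV with header `a_gene_id`, `c_gene_id`.
#' @param genes gene-model data frame (for id and subgenome validation).
#' @return data frame with columns `a_gene_id`, `c_gene_id` (A copy first).
#' @export
read_pairs <- function(path, genes) {
  p <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(p) < 2L) stop("pairs file needs two columns", call. = FALSE)
  p <- p[, 1:2]
  names(p) <- c("a_gene_id", "c_gene_id")
  if (nrow(p) == 0L) return(p)
  unknown <- setdiff(c(p$a_gene_id, p$c_gene_id), genes$gene_id)
  if (length(unknown)) {
    stop("pairs reference unknown genes: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  sub <- stats::setNames(genes$subgenome, genes$gene_id)
  s1 <- sub[p$a_gene_id]
  s2 <- sub[p$c_gene_id]
  if (any(is.na(s1) | is.na(s2) | s1 == s2)) {
    bad <- which(is.na(s1) | is.na(s2) | s1 == s2)[1]
    stop(sprintf("pair %s - %s is not cross-subgenome (A-C)",
                 p$a_gene_id[bad], p$c_gene_id[bad]), call. = FALSE)
  }
  # normalize orientation: A copy first, then collapse duplicates
  flip <- s1 == "C"
  tmp <- p$a_gene_id[flip]
  p$a_gene_id[flip] <- p$c_gene_id[flip]
  p$c_gene_id[flip] <- tmp
  p <- unique(p)
  if (anyDuplicated(p$a_gene_id) || anyDuplicated(p$c_gene_id)) {
    stop("a gene participates in more than one homoeolog pair",
         call. = FALSE)
  }
  rownames(p) <- NULL
  p
}

.genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
}

#' Write a gene annotation as BED6 and/or GFF3
#'
#' The two writers describe identical intervals in their native
#' conventions (BED 0-based half-open, GFF3 1-based closed).
#'
#' @param genes gene-model data frame.
#' @param bed_path,gff3_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_annotation <- function(genes, bed_path = NULL, gff3_path = NULL) {
  gr <- .genes_granges(genes)
  written <- character(0)
  if (!is.null(bed_path)) {
    grb <- gr
    S4Vectors::mcols(grb) <- S4Vectors::DataFrame(
      name = genes$gene_id, score = 0L)
    rtracklayer::export(grb, bed_path, format = "bed")
    written <- c(written, bed_path)
  }
  if (!is.null(gff3_path)) {
    grg <- gr
    S4Vectors::mcols(grg) <- S4Vectors::DataFrame(
      source = "alloexpr", type = "gene", ID = genes$gene_id,
      subgenome = genes$subgenome)
    rtracklayer::export(grg, gff3_path, format = "gff3")
    written <- c(written, gff3_path)
  }
  invisible(written)
}

#' Write homoeolog pair links
#'
#' @param pairs data frame with `a_gene_id`, `c_gene_id`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("a_gene_id", "c_gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
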