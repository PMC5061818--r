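# On-disk fixtures for a simulated dataset: counts TSV, BED + GFF3
# annotation, pair links, truth table, and optionally a synthetic SAM per
# sample/replicate whose accepted read pairs reproduce the planted counts
# exactly (the counting-rule oracle).

#' Write a simulated dataset to a directory
#'
#' Writes `counts.tsv`, `genes.bed`, `genes.gff3`, `pairs.tsv`,
#' `truth.tsv`, and, if requested, `reads_<sample>_<rep>.sam` files built
#' with [write_sam()].
#'
#' @param dataset a dataset from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @param sam optional character vector of `"sample:replicate"` columns
#'   for which to emit a synthetic SAM, e.g. `"AA1:1"`.
#' @return invisibly, a named list of written paths; SAM entries carry the
#'   expected acceptance log as attribute `"expected"`.
#' @export
write_fixture <- function(dataset, dir, sam = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create ", dir, call. = FALSE)
  }
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    bed = file.path(dir, "genes.bed"),
    gff3 = file.path(dir, "genes.gff3"),
    pairs = file.path(dir, "pairs.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_counts(dataset$counts, paths$counts)
  if (nrow(dataset$genes)) {
    write_annotation(dataset$genes, bed_path = paths$bed,
                     gff3_path = paths$gff3)
  } else {
    file.create(paths$bed, paths$gff3)
  }
  write_pairs(dataset$pairs, paths$pairs)
  utils::write.table(dataset$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (col in sam) {
    sp <- strsplit(col, ":", fixed = TRUE)[[1]]
    p <- file.path(dir, sprintf("reads_%s_%s.sam", sp[1], sp[2]))
    exp_log <- write_sam(dataset, sample = sp[1],
                         replicate = as.integer(sp[2]), path = p)
    attr(p, "expected") <- exp_log
    paths[[paste0("sam_", col)]] <- p
  }
  invisible(paths)
}

.sam_record <- function(qname, flag, chrom, pos, mapq = 60L,
                        cigar = "50M", rnext = "=", pnext = 0L,
                        tlen = 0L, seq = strrep("A", 50), extra = NULL) {
  fields <- c(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen,
              seq, strrep("I", nchar(seq)))
  if (!is.null(extra)) fields <- c(fields, extra)
  paste(fields, collapse = "\t")
}

.sam_pair <- function(qname, chrom1, pos1, chrom2, pos2,
                      flag1 = 99L, flag2 = 147L, mapq = c(60L, 60L),
                      extra1 = NULL, extra2 = NULL, rlen = 50L) {
  tlen <- if (chrom1 == chrom2) (pos2 + rlen) - pos1 else 0L
  c(
    .sam_record(qname, flag1, chrom1, pos1, mapq[1], pnext = pos2,
                tlen = tlen, rnext = if (chrom1 == chrom2) "=" else chrom2,
                extra = extra1),
    .sam_record(qname, flag2, chrom2, pos2, mapq[2], pnext = pos1,
                tlen = -tlen, rnext = if (chrom1 == chrom2) "=" else chrom1,
                extra = extra2)
  )
}

#' Write a synthetic SAM reproducing one count column
#'
#' Emits a valid headered SAM for one `(sample, replicate)` column of a
#' simulated dataset. Every planted count is realized as accepted read
#' pairs: most as same-gene opposite-strand pairs (rule 2), and, when
#' `rule3 = TRUE`, some as pairs of fragments bridging adjacent genes
#' (rule 3, two bridging pairs per selected adjacency so each gene still
#' gains an integer count). With `distractors = TRUE` a fixed set of
#' rejectable pairs (unmapped mate, low mapping quality, alternative-hit
#' tag, intergenic mates, non-adjacent genes, same-strand mates,
#' secondary-only alignments) is appended to exercise every rejection
#' reason of [filter_and_count()].
#'
#' @param dataset a dataset from [generate_dataset()] (counts must be
#'   integers, as produced by the generator).
#' @param sample,replicate which count column to realize.
#' @param path output SAM path.
#' @param rule3 plant adjacent-gene ("rule 3") pairs.
#' @param distractors plant rejectable pairs.
#' @return invisibly, the expected acceptance log: `counts` (named planted
#'   counts), `total_pairs`, `rule2`, `rule3`, `rejected` (named vector by
#'   reason).
#' @export
write_sam <- function(dataset, sample, replicate, path,
                      rule3 = TRUE, distractors = TRUE) {
  genes <- dataset$genes
  cc <- dataset$counts
  sel <- cc$sample == sample & cc$replicate == replicate
  if (!any(sel)) stop("no counts for ", sample, ":", replicate, call. = FALSE)
  cnt <- stats::setNames(cc$count[sel], cc$gene_id[sel])[genes$gene_id]
  if (any(cnt != floor(cnt))) {
    stop("write_sam requires integer planted counts", call. = FALSE)
  }
  cnt <- as.integer(cnt)
  names(cnt) <- genes$gene_id

  chroms <- sort(unique(genes$chrom))
  chrom_len <- vapply(chroms, function(ch)
    max(genes$end[genes$chrom == ch]) + 1000L, integer(1))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, chrom_len))

  start1b <- genes$start + 1L      # SAM is 1-based
  end1b <- genes$end               # last covered base, 1-based closed
  recs <- character(0)
  remaining <- cnt
  n_rule3 <- 0L

  if (rule3) {
    for (ch in chroms) {
      gi <- which(genes$chrom == ch)
      gi <- gi[order(genes$start[gi])]
      i <- 1L
      while (i < length(gi)) {
        g1 <- gi[i]; g2 <- gi[i + 1L]
        if (remaining[g1] >= 1L && remaining[g2] >= 1L) {
          for (j in 1:2) {
            recs <- c(recs, .sam_pair(
              sprintf("r3_%s_%d_%d", ch, i, j),
              ch, end1b[g1] - 49L - (j - 1L) * 5L,
              ch, start1b[g2] + (j - 1L) * 5L))
          }
          remaining[g1] <- remaining[g1] - 1L
          remaining[g2] <- remaining[g2] - 1L
          n_rule3 <- n_rule3 + 2L
          i <- i + 2L
        } else {
          i <- i + 1L
        }
      }
    }
  }

  for (g in which(remaining > 0L)) {
    len <- genes$length[g]
    span <- max(1L, len - 120L)
    for (j in seq_len(remaining[g])) {
      p1 <- start1b[g] + ((j - 1L) * 7L) %% span
      recs <- c(recs, .sam_pair(sprintf("r2_%s_%d", genes$gene_id[g], j),
                                genes$chrom[g], p1, genes$chrom[g], p1 + 60L))
    }
  }
  n_rule2 <- sum(remaining)

  rejected <- integer(0)
  if (distractors) {
    # need a chromosome carrying at least three genes
    tab <- table(genes$chrom)
    ch <- names(tab)[tab >= 3L][1]
    if (!is.na(ch)) {
      gi <- which(genes$chrom == ch)
      gi <- gi[order(genes$start[gi])]
      g1 <- gi[1]; g2 <- gi[2]; g3 <- gi[3]
      gap1 <- end1b[g1] + 100L  # intergenic: 500 bp gaps in simulated layout
      d <- list()
      d$mate_unmapped <- c(
        .sam_record("dx_unmapped", 73L, genes$chrom[g1], start1b[g1],
                    pnext = start1b[g1]),
        .sam_record("dx_unmapped", 133L, genes$chrom[g1], start1b[g1],
                    mapq = 0L, cigar = "*", pnext = start1b[g1]))
      d$low_mapq <- .sam_pair("dx_mapq", ch, start1b[g1], ch,
                              start1b[g1] + 60L, mapq = c(0L, 0L))
      d$alt_hits <- .sam_pair("dx_xa", ch, start1b[g1], ch,
                              start1b[g1] + 60L,
                              extra1 = sprintf("XA:Z:%s,+%d,50M,1;",
                                               ch, gap1))
      d$intergenic <- .sam_pair("dx_intergenic", ch, gap1, ch, gap1 + 60L)
      d$single_end <- .sam_pair("dx_single", ch, start1b[g1], ch, gap1)
      d$non_adjacent <- .sam_pair("dx_nonadj", ch, start1b[g1], ch,
                                  start1b[g3])
      d$same_strand <- .sam_pair("dx_strand", ch, start1b[g2], ch,
                                 start1b[g2] + 60L, flag1 = 65L,
                                 flag2 = 129L)
      d$secondary <- .sam_pair("dx_secondary", ch, start1b[g2], ch,
                               start1b[g2] + 60L, flag1 = 355L,
                               flag2 = 403L)
      recs <- c(recs, unlist(d, use.names = FALSE))
      rejected <- c(
        mate_unmapped = 1L, not_best_unique = 2L, no_gene_overlap = 1L,
        single_end_on_gene = 1L, non_adjacent = 1L,
        incoherent_orientation = 1L, mate_missing = 1L
      )
    }
  }

  writeLines(c(header, recs), path)
  invisible(list(
    counts = stats::setNames(as.numeric(cnt), genes$gene_id),
    total_pairs = n_rule2 + n_rule3 + sum(rejected),
    rule2 = n_rule2,
    rule3 = n_rule3,
    rejected = rejected
  ))
}
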