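# Paired-read acceptance counting. A fragment (read pair) contributes to
# gene counts only if both mates are best-unique alignments and either
# (rule 2) both overlap the same gene on opposite strands (+1 to that
# gene) or (rule 3) they overlap two genes that are consecutive in start
# order on one chromosome (+0.5 to each). Everything else is rejected and
# logged by reason.

.cigar_ref_width <- function(cigar) {
  out <- rep(NA_integer_, length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (!any(ok)) return(out)
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar[ok])
  out[ok] <- vapply(regmatches(cigar[ok], m), function(ops) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
  out
}

# best gene per alignment record: >=1 bp overlap, ties broken by larger
# overlap then lexicographic gene_id
.best_gene <- function(chrom, start, end, genes) {
  gi <- rep(NA_integer_, length(chrom))
  mapped <- !is.na(start)
  if (!any(mapped)) return(gi)
  q <- GenomicRanges::GRanges(chrom[mapped],
                              IRanges::IRanges(start[mapped], end[mapped]))
  s <- .genes_granges(genes)
  GenomicRanges::strand(s) <- "*"
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(q[qh], s[sh]))
    ord <- order(qh, -ov, genes$gene_id[sh])
    first <- !duplicated(qh[ord])
    gi[which(mapped)[qh[ord][first]]] <- sh[ord][first]
  }
  gi
}

#' Count fragments per gene from a SAM file
#'
#' Reads a (headered) SAM, joins mates by read name, applies the
#' paired-read acceptance rules and returns per-gene fragment counts plus
#' an acceptance log. "Best unique" means: mapped, primary (not
#' secondary/supplementary), mapping quality at least `min_mapq`, and no
#' `XA` alternative-hit tag. Counts may be fractional in multiples of 0.5
#' because adjacent-gene fragments are split between the two genes.
#'
#' @param sam_path SAM file with `@SQ` header lines.
#' @param genes gene-model data frame (see [read_annotation()]).
#' @param min_mapq minimum mapping quality for a best-unique mate.
#' @return list with `counts` (named numeric over all genes),
#'   `library_size` (total assigned fragment mass) and `log` (list:
#'   `total_pairs`, `accepted`, `rule2`, `rule3`, `rejected` named by
#'   reason).
#' @export
filter_and_count <- function(sam_path, genes, min_mapq = 1) {
  bam <- Rsamtools::asBam(sam_path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "XA")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]

  counts <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  empty_log <- list(total_pairs = 0L, accepted = 0L, rule2 = 0L,
                    rule3 = 0L, rejected = integer(0))
  if (length(x$qname) == 0L) {
    return(list(counts = counts, library_size = 0, log = empty_log))
  }

  flag <- x$flag
  xa <- x$tag$XA
  if (is.null(xa)) xa <- rep(NA_character_, length(flag))
  rec <- data.frame(
    qname = x$qname, flag = flag,
    chrom = as.character(x$rname), pos = x$pos,
    mapq = x$mapq, cigar = x$cigar,
    xa = as.character(xa),
    stringsAsFactors = FALSE
  )
  rec$unmapped <- bitwAnd(rec$flag, 0x4) > 0L
  rec$end <- rec$pos + .cigar_ref_width(rec$cigar) - 1L
  rec$rev <- bitwAnd(rec$flag, 0x10) > 0L
  rec$first <- bitwAnd(rec$flag, 0x40) > 0L
  primary <- bitwAnd(rec$flag, 0x100) == 0L & bitwAnd(rec$flag, 0x800) == 0L

  all_qnames <- unique(rec$qname)
  total_pairs <- length(all_qnames)

  prim <- rec[primary, , drop = FALSE]
  nfirst <- tapply(prim$first, prim$qname, sum)
  nrec <- tapply(prim$first, prim$qname, length)
  paired_q <- names(nrec)[nrec == 2L & nfirst == 1L]
  n_mate_missing <- total_pairs - length(paired_q)

  reasons <- character(0)
  if (length(paired_q)) {
    prim <- prim[prim$qname %in% paired_q, , drop = FALSE]
    prim <- prim[order(prim$qname, !prim$first), , drop = FALSE]
    m1 <- prim[prim$first, , drop = FALSE]
    m2 <- prim[!prim$first, , drop = FALSE]

    gene_of <- function(m) {
      st <- ifelse(m$unmapped, NA_integer_, m$pos)
      .best_gene(m$chrom, st, m$end, genes)
    }
    g1 <- gene_of(m1)
    g2 <- gene_of(m2)

    rank_in_chrom <- integer(nrow(genes))
    for (ch in unique(genes$chrom)) {
      i <- which(genes$chrom == ch)
      rank_in_chrom[i] <- rank(genes$start[i], ties.method = "first")
    }

    np <- nrow(m1)
    reasons <- rep(NA_character_, np)
    best_unique <- function(m) {
      !m$unmapped & m$mapq >= min_mapq & is.na(m$xa)
    }
    bu1 <- best_unique(m1)
    bu2 <- best_unique(m2)
    any_unmapped <- m1$unmapped | m2$unmapped
    reasons[any_unmapped] <- "mate_unmapped"
    nbu <- is.na(reasons) & (!bu1 | !bu2)
    reasons[nbu] <- "not_best_unique"

    open <- is.na(reasons)
    no1 <- is.na(g1)
    no2 <- is.na(g2)
    reasons[open & no1 & no2] <- "no_gene_overlap"
    reasons[open & xor(no1, no2)] <- "single_end_on_gene"

    same <- open & !no1 & !no2 & g1 == g2
    coherent <- m1$rev != m2$rev
    reasons[same & !coherent] <- "incoherent_orientation"
    rule2_idx <- which(same & coherent)

    diff <- open & !no1 & !no2 & g1 != g2
    same_chrom <- diff & genes$chrom[g1] == genes$chrom[g2]
    adjacent <- same_chrom &
      abs(rank_in_chrom[g1] - rank_in_chrom[g2]) == 1L
    reasons[diff & !adjacent] <- "non_adjacent"
    rule3_idx <- which(adjacent)

    if (length(rule2_idx)) {
      t2 <- table(g1[rule2_idx])
      counts[as.integer(names(t2))] <- counts[as.integer(names(t2))] +
        as.numeric(t2)
    }
    if (length(rule3_idx)) {
      t3 <- table(c(g1[rule3_idx], g2[rule3_idx]))
      counts[as.integer(names(t3))] <- counts[as.integer(names(t3))] +
        0.5 * as.numeric(t3)
    }
    n_rule2 <- length(rule2_idx)
    n_rule3 <- length(rule3_idx)
  } else {
    n_rule2 <- n_rule3 <- 0L
  }

  rej <- table(reasons[!is.na(reasons)])
  rejected <- stats::setNames(as.integer(rej), names(rej))
  if (n_mate_missing > 0L) {
    rejected["mate_missing"] <-
      (if ("mate_missing" %in% names(rejected))
         rejected[["mate_missing"]] else 0L) + n_mate_missing
  }

  list(
    counts = counts,
    library_size = sum(counts),
    log = list(
      total_pairs = total_pairs,
      accepted = n_rule2 + n_rule3,
      rule2 = n_rule2,
      rule3 = n_rule3,
      rejected = rejected
    )
  )
}
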