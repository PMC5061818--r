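#' Truth classes planted by the count simulator
#'
#' Character vector of the ten class labels a simulated gene can carry.
#' @export
SIM_CLASSES <- c(
  "additive_equal", "additive_parentdiff",
  "eld_A_up", "eld_A_down", "eld_C_up", "eld_C_down",
  "transgressive_up", "transgressive_down",
  "novel_bias", "silent"
)

.default_class_mix <- function() {
  c(
    additive_equal      = 0.26,
    additive_parentdiff = 0.10,
    eld_A_up            = 0.015,
    eld_A_down          = 0.015,
    eld_C_up            = 0.015,
    eld_C_down          = 0.015,
    transgressive_up    = 0.010,
    transgressive_down  = 0.005,
    novel_bias          = 0.025,
    silent              = 0.540
  )
}

#' Simulation configuration
#'
#' Describes a five-library experiment emulating an allopolyploidization
#' design: two A-genome parents (`AA1`, `AA2`), one shared C-genome parent
#' (`CC`), and the two derived hybrids (`AC1`, `AC2`), each sequenced with
#' `n_replicates` biological replicates. Counts are gamma-Poisson
#' (negative binomial); `nb_dispersion = 0` degrades to Poisson, which is
#' the default because the downstream Fisher-exact machinery models
#' counting noise only and replicates of a sample share their gene-level
#' mean.
#'
#' @param n_genes number of gene models to simulate.
#' @param frac_paired fraction of genes organized as A/C homoeolog pairs
#'   (each pair contributes two genes).
#' @param lib_sizes sequencing depth per replicate library, a single
#'   number or a named vector over `AA1, AA2, CC, AC1, AC2` (fragments).
#'   The simulated genes are a subset of the transcriptome each library
#'   samples, so planted mean counts scale with depth relative to the
#'   mean depth and the depths are recorded as the count table's declared
#'   library sizes.
#' @param mean_expression baseline mean fragment count per gene at the
#'   reference (mean) library size.
#' @param nb_dispersion negative-binomial dispersion; variance is
#'   `mu + mu^2 * nb_dispersion`.
#' @param class_mix named proportions over [SIM_CLASSES], summing to 1.
#' @param effect_fold fold change (> 1) applied to planted parent/hybrid
#'   differences.
#' @param n_replicates biological replicates per sample.
#' @param seed integer RNG seed; identical configurations produce
#'   identical datasets.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000,
                       frac_paired = 0.5,
                       lib_sizes = 5e6,
                       mean_expression = 100,
                       nb_dispersion = 0,
                       class_mix = NULL,
                       effect_fold = 4,
                       n_replicates = 2,
                       seed = 1) {
  samples <- c("AA1", "AA2", "CC", "AC1", "AC2")
  if (is.null(class_mix)) class_mix <- .default_class_mix()
  if (length(lib_sizes) == 1L) {
    lib_sizes <- stats::setNames(rep(lib_sizes, 5L), samples)
  }
  if (!all(samples %in% names(lib_sizes))) {
    stop("lib_sizes must cover samples ", paste(samples, collapse = ", "),
         call. = FALSE)
  }
  lib_sizes <- lib_sizes[samples]

  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 0 ||
      n_genes != floor(n_genes)) {
    stop("n_genes must be a non-negative integer", call. = FALSE)
  }
  if (frac_paired < 0 || frac_paired > 1) {
    stop("frac_paired must be in [0, 1]", call. = FALSE)
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  .stopifnot_scalar_number(mean_expression, "mean_expression", positive = TRUE)
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (effect_fold <= 1) stop("effect_fold must be > 1", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (!setequal(names(class_mix), SIM_CLASSES)) {
    stop("class_mix must be named by exactly the classes in SIM_CLASSES",
         call. = FALSE)
  }
  class_mix <- class_mix[SIM_CLASSES]
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }

  structure(
    list(
      n_genes = as.integer(n_genes), frac_paired = frac_paired,
      lib_sizes = lib_sizes, mean_expression = mean_expression,
      nb_dispersion = nb_dispersion, class_mix = class_mix,
      effect_fold = effect_fold, n_replicates = as.integer(n_replicates),
      seed = as.integer(seed), samples = samples
    ),
    class = "sim_config"
  )
}

# Per-unit planted means in copy terms. a/c: expression of the A/C locus in
# its own parent; hA/hC: expression of each homoeolog in the hybrid. An
# unpaired gene uses hA (== hC for every class it can receive).
.class_means <- function(class, dir_a, m, f) {
  a <- c <- hA <- hC <- numeric(length(class))
  mid <- function(a, c) (a + c) / 2
  for (i in seq_along(class)) {
    cl <- class[i]
    if (cl == "additive_equal") {
      a[i] <- c[i] <- hA[i] <- hC[i] <- m
    } else if (cl == "additive_parentdiff") {
      if (dir_a[i]) { a[i] <- m * f; c[i] <- m } else { a[i] <- m; c[i] <- m * f }
      hA[i] <- hC[i] <- mid(a[i], c[i])
    } else if (cl == "eld_A_up") {
      a[i] <- m * f; c[i] <- m; hA[i] <- hC[i] <- a[i]
    } else if (cl == "eld_A_down") {
      a[i] <- m; c[i] <- m * f; hA[i] <- hC[i] <- a[i]
    } else if (cl == "eld_C_up") {
      a[i] <- m; c[i] <- m * f; hA[i] <- hC[i] <- c[i]
    } else if (cl == "eld_C_down") {
      a[i] <- m * f; c[i] <- m; hA[i] <- hC[i] <- c[i]
    } else if (cl == "transgressive_up") {
      a[i] <- c[i] <- m; hA[i] <- hC[i] <- m * f
    } else if (cl == "transgressive_down") {
      a[i] <- c[i] <- m; hA[i] <- hC[i] <- m / f
    } else if (cl == "novel_bias") {
      a[i] <- c[i] <- m
      if (dir_a[i]) { hA[i] <- m * f; hC[i] <- m } else { hA[i] <- m; hC[i] <- m * f }
    } else if (cl == "silent") {
      a[i] <- c[i] <- hA[i] <- hC[i] <- 0
    } else {
      stop("unknown class: ", cl)
    }
  }
  list(a = a, c = c, hA = hA, hC = hC)
}

.class_group <- function(class) {
  switch(class,
    additive_equal      = "equal_both",
    additive_parentdiff = "intermediate",
    eld_A_up            = ,
    eld_A_down          = ,
    eld_C_up            = ,
    eld_C_down          = "equal_one_parent",
    transgressive_up    = "transgressive_up",
    transgressive_down  = "transgressive_down",
    novel_bias          = "equal_both",  # overridden per copy
    silent              = "equal_both"
  )
}

.empty_dataset <- function(config) {
  list(
    counts = data.frame(gene_id = character(), sample = character(),
                        replicate = integer(), count = numeric()),
    genes = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), length = integer(),
                       subgenome = character(), partner_id = character(),
                       stringsAsFactors = FALSE),
    pairs = data.frame(a_gene_id = character(), c_gene_id = character()),
    truth = data.frame(gene_id = character(), true_class = character(),
                       true_pattern_group = character(),
                       true_bias = character()),
    means = matrix(numeric(0), nrow = 0, ncol = 5,
                   dimnames = list(NULL,
                                   c("AA1", "AA2", "CC", "AC1", "AC2"))),
    config = config
  )
}

#' Generate a parental/hybrid count dataset with known truth
#'
#' Produces per-gene fragment counts for the five samples of the design
#' together with a gene annotation (two subgenomes A/C laid out on
#' chromosomes A01-A10 and C01-C09), homoeolog pair links, and a truth
#' table recording the planted class of every gene. Planted hybrids are
#' additive (mid-parent) except for the expression-level-dominance,
#' transgressive and novel-bias classes, which deviate by `effect_fold` in
#' the configured direction. Genes whose sampled counts are zero in every
#' library are relabeled `silent` post hoc.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (long data frame: gene_id, sample,
#'   replicate, count, with declared library sizes attached), `genes`
#'   (annotation with 0-based half-open coordinates), `pairs` (a_gene_id,
#'   c_gene_id), `truth`, `means` (expected per-replicate counts, genes x
#'   samples), `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  if (n == 0L) return(.empty_dataset(config))

  n_pairs <- floor(n * config$frac_paired / 2)
  n_unpaired <- n - 2L * n_pairs
  n_units <- n_pairs + n_unpaired
  paired_unit <- c(rep(TRUE, n_pairs), rep(FALSE, n_unpaired))

  mix <- config$class_mix
  unit_class <- sample(SIM_CLASSES, n_units, replace = TRUE, prob = mix)
  # novel homoeolog bias is only defined for pairs; unpaired draws of it
  # fold into the additive-equal background
  unit_class[!paired_unit & unit_class == "novel_bias"] <- "additive_equal"
  dir_a <- stats::runif(n_units) < 0.5

  m <- config$mean_expression
  f <- config$effect_fold
  mu_unit <- .class_means(unit_class, dir_a, m, f)

  # gene-level bookkeeping: pairs contribute an A and a C copy
  a_chroms <- sprintf("A%02d", 1:10)
  c_chroms <- sprintf("C%02d", 1:9)
  gene_id <- character(n)
  subgenome <- character(n)
  chrom <- character(n)
  unit_of <- integer(n)
  copy <- character(n)   # "A", "C" (pair copies) or "U" side tag
  k <- 0L
  if (n_pairs > 0) {
    idx <- seq_len(n_pairs)
    gene_id[2 * idx - 1] <- sprintf("BnaA.g%05d", idx)
    gene_id[2 * idx]     <- sprintf("BnaC.g%05d", idx)
    subgenome[2 * idx - 1] <- "A"
    subgenome[2 * idx]     <- "C"
    chrom[2 * idx - 1] <- a_chroms[(idx - 1L) %% 10L + 1L]
    chrom[2 * idx]     <- c_chroms[(idx - 1L) %% 9L + 1L]
    unit_of[2 * idx - 1] <- idx
    unit_of[2 * idx]     <- idx
    copy[2 * idx - 1] <- "A"
    copy[2 * idx]     <- "C"
    k <- 2L * n_pairs
  }
  if (n_unpaired > 0) {
    idx <- seq_len(n_unpaired)
    sub <- ifelse(idx %% 2L == 1L, "A", "C")
    gene_id[k + idx] <- ifelse(sub == "A",
                               sprintf("BnaA.s%05d", idx),
                               sprintf("BnaC.s%05d", idx))
    subgenome[k + idx] <- sub
    chrom[k + idx] <- ifelse(sub == "A",
                             a_chroms[(idx - 1L) %% 10L + 1L],
                             c_chroms[(idx - 1L) %% 9L + 1L])
    unit_of[k + idx] <- n_pairs + idx
    copy[k + idx] <- sub
  }

  len <- as.integer(pmin(pmax(round(stats::rlnorm(n, log(1200), 0.35)),
                              300), 4000))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(c(0L, len[i][-length(i)] + 500L))
  }
  genes <- data.frame(
    gene_id = gene_id, chrom = chrom, start = start, end = start + len,
    strand = strand, length = len, subgenome = subgenome,
    partner_id = NA_character_, stringsAsFactors = FALSE
  )
  pairs <- data.frame(a_gene_id = character(0), c_gene_id = character(0))
  if (n_pairs > 0) {
    idx <- seq_len(n_pairs)
    pairs <- data.frame(a_gene_id = sprintf("BnaA.g%05d", idx),
                        c_gene_id = sprintf("BnaC.g%05d", idx),
                        stringsAsFactors = FALSE)
    genes$partner_id[match(pairs$a_gene_id, genes$gene_id)] <- pairs$c_gene_id
    genes$partner_id[match(pairs$c_gene_id, genes$gene_id)] <- pairs$a_gene_id
  }

  # per-gene expression level in each sample: a parent library reports the
  # level of whichever locus it carries (homoeologous reads align to the
  # model), the hybrid resolves the two copies
  u <- unit_of
  hyb <- ifelse(copy == "C", mu_unit$hC[u], mu_unit$hA[u])
  mu <- cbind(AA1 = mu_unit$a[u], AA2 = mu_unit$a[u], CC = mu_unit$c[u],
              AC1 = hyb, AC2 = hyb)
  # fragment counts accrue with gene length (FPKM logic): a gene of the
  # reference length (1200 bp) at expression level mean_expression yields
  # mean_expression fragments at the reference depth
  len_ref <- 1200
  mu <- mu * (len / len_ref)

  libs <- config$lib_sizes
  l_ref <- mean(libs)
  # the simulated genes are a subset of the transcriptome the library
  # samples; their planted mass must fit inside the declared depth
  if (max(colSums(mu)) > l_ref) {
    stop("planted mean mass exceeds the declared sequencing depth; ",
         "increase lib_sizes or lower mean_expression/n_genes",
         call. = FALSE)
  }
  disp <- config$nb_dispersion
  reps <- config$n_replicates
  blocks <- vector("list", length(config$samples) * reps)
  bi <- 0L
  for (s in config$samples) {
    lam <- mu[, s] * libs[[s]] / l_ref
    for (r in seq_len(reps)) {
      cnt <- if (disp == 0) stats::rpois(n, lam) else
        stats::rnbinom(n, mu = lam, size = 1 / disp)
      bi <- bi + 1L
      blocks[[bi]] <- data.frame(gene_id = gene_id, sample = s,
                                 replicate = r, count = as.numeric(cnt),
                                 stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, blocks)
  rownames(counts) <- NULL
  attr(counts, "library_sizes") <- data.frame(
    sample = rep(config$samples, each = reps),
    replicate = rep(seq_len(reps), times = length(config$samples)),
    library_size = rep(unname(libs), each = reps),
    stringsAsFactors = FALSE
  )

  group <- vapply(unit_class[u], .class_group, character(1))
  nb <- unit_class[u] == "novel_bias"
  biased_copy <- ifelse(dir_a[u], "A", "C")
  group[nb & copy == biased_copy] <- "transgressive_up"
  group[nb & copy != biased_copy] <- "equal_both"
  true_bias <- rep("none", n)
  # novel_bias only occurs on paired units by construction
  true_bias[nb] <- ifelse(dir_a[u[nb]], "A_bias", "C_bias")

  truth <- data.frame(
    gene_id = gene_id,
    true_class = unit_class[u],
    true_pattern_group = unname(group),
    true_bias = true_bias,
    stringsAsFactors = FALSE
  )

  # post-hoc relabel of genes that never produced a fragment
  tot <- tapply(counts$count, counts$gene_id, sum)[gene_id]
  all_zero <- !is.na(tot) & tot == 0
  truth$true_class[all_zero] <- "silent"
  truth$true_pattern_group[all_zero] <- "equal_both"
  truth$true_bias[all_zero] <- "none"

  means <- sweep(mu, 2, unname(libs[colnames(mu)]) / l_ref, `*`)
  rownames(means) <- gene_id

  structure(
    list(counts = counts, genes = genes, pairs = pairs, truth = truth,
         means = means, config = config),
    class = "alloexpr_sim"
  )
}

#' @export
print.alloexpr_sim <- function(x, ...) {
  cat(sprintf(
    "alloexpr simulated dataset: %d genes (%d homoeolog pairs), %d samples x %d replicates\n",
    nrow(x$genes), nrow(x$pairs), length(x$config$samples),
    x$config$n_replicates))
  invisible(x)
}
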