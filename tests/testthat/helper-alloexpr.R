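# Independent oracles and small configuration builders shared by the
# suite. The oracles deliberately avoid the code paths they check.

# two-sided Fisher p by direct enumeration over the fixed-margin tables,
# using binomial coefficients (not dhyper)
fet_oracle <- function(c1, n1, c2, n2) {
  k <- c1 + c2
  xs <- max(0, k - n2):min(n1, k)
  logp <- lchoose(n1, xs) + lchoose(n2, k - xs) - lchoose(n1 + n2, k)
  p <- exp(logp)
  p0 <- exp(lchoose(n1, c1) + lchoose(n2, k - c1) - lchoose(n1 + n2, k))
  min(1, sum(p[p <= p0 * (1 + 1e-7)]))
}

# BH by the step-up formula written out directly
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# admissibility of a sign triple by the confidence-interval logic,
# case by case (independent of the package's grid enumeration)
triple_admissible <- function(ha, hc, pc) {
  if (ha == 1 && hc == -1) return(pc == -1)
  if (ha == -1 && hc == 1) return(pc == 1)
  if (ha == 1 && hc == 0) return(pc %in% c(0, -1))
  if (ha == 0 && hc == 1) return(pc %in% c(1, 0))
  if (ha == -1 && hc == 0) return(pc %in% c(1, 0))
  if (ha == 0 && hc == -1) return(pc %in% c(0, -1))
  TRUE  # (+,+), (-,-), (0,0) admit any parental sign
}

class_mix_one <- function(class) {
  mix <- setNames(rep(0, length(SIM_CLASSES)), SIM_CLASSES)
  mix[class] <- 1
  mix
}

null_config <- function(n_genes = 2000, seed = 1, mean_expression = 100,
                        ...) {
  sim_config(n_genes = n_genes, seed = seed,
             mean_expression = mean_expression,
             class_mix = class_mix_one("additive_equal"), ...)
}

# one planted unit class per tenth of the genes; the regime used for
# parameter-recovery checks (strong effects, high counts)
recovery_config <- function(n_genes = 10000, seed = 1) {
  mix <- setNames(rep(0.1, length(SIM_CLASSES)), SIM_CLASSES)
  sim_config(n_genes = n_genes, seed = seed, mean_expression = 500,
             effect_fold = 8, lib_sizes = 5e7, class_mix = mix)
}

# fraction of truth-class genes whose assignment satisfies a predicate
recovery_rate <- function(truth, assignments, class, pred) {
  m <- merge(truth[truth$true_class == class, "gene_id", drop = FALSE],
             assignments, by = "gene_id")
  mean(pred(m))
}
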