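# Shared in-code fixtures: tiny variant/sample constructors used across the
# suite. All randomness in tests is seeded where used.

variant_rec <- function(sample_id = "S1", chrom = "X", pos = 1000L,
                        ref = "A", alt = "G", gene = "G1",
                        consequence = "missense", depth = 60L, vaf = 0.95,
                        call_quality = 50, pop_af = 0.5, genotype = "hem") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, consequence = consequence,
             depth = depth, vaf = vaf, call_quality = call_quality,
             pop_af = pop_af, genotype = genotype, stringsAsFactors = FALSE)
}

blank_samples <- function(ids, group = "TS_monosomy") {
  s <- data.frame(sample_id = ids,
                  group = rep(group, length.out = length(ids)),
                  stringsAsFactors = FALSE)
  for (cond in phenotype_conditions())
    s[[cond]] <- rep(NA_integer_, nrow(s))
  s
}

# hemizygous carrier records for a set of samples at one variant
hemi_recs <- function(ids, gene = "G1", pos = 5000000L, chrom = "X",
                      ref = "C", alt = "T", pop_af = 0.5, genotype = "hem") {
  if (!length(ids)) return(NULL)
  variant_rec(sample_id = ids, chrom = chrom, pos = pos, ref = ref,
              alt = alt, gene = gene, pop_af = pop_af, genotype = genotype)
}

# cohort with n1 with-condition samples (a carriers of one X gene) and n2
# without (cc carriers); used to reconstruct published carrier tables
carrier_cohort <- function(a, n1, cc, n2, condition = "hypertension",
                           gene = "GENE1") {
  ids_w <- sprintf("W%03d", seq_len(n1))
  ids_o <- sprintf("O%03d", seq_len(n2))
  s <- blank_samples(c(ids_w, ids_o))
  s[[condition]] <- c(rep(1L, n1), rep(0L, n2))
  v <- rbind(hemi_recs(ids_w[seq_len(a)], gene),
             hemi_recs(ids_o[seq_len(cc)], gene))
  cohort_table(v, s)
}

# random toy cohort for brute-force oracle comparisons
random_toy_cohort <- function(seed, n_samples = 12L, n_genes = 4L,
                              condition = "diabetes") {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n_samples))
  s <- blank_samples(ids)
  s[[condition]] <- sample(c(0L, 1L, NA), n_samples, replace = TRUE,
                           prob = c(0.45, 0.45, 0.1))
  rows <- list()
  for (g in seq_len(n_genes)) {
    for (v in 1:2) {
      carriers <- ids[runif(n_samples) < 0.4]
      if (!length(carriers)) next
      rows[[length(rows) + 1L]] <- hemi_recs(
        carriers, gene = sprintf("G%02d", g),
        pos = as.integer(3e6 + g * 1e5 + v * 50),
        pop_af = runif(1, 0.05, 0.95))
    }
  }
  cohort_table(do.call(rbind, rows), s)
}

# independent full-enumeration two-sided Fisher oracle (lchoose-based,
# no dhyper) using the point-probability rule
fisher_enum_oracle <- function(a, b, cc, d) {
  n1 <- a + b; n2 <- cc + d; k <- a + cc; N <- n1 + n2
  if (n1 == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  supp <- max(0, k - n2):min(k, n1)
  lp <- lchoose(n1, supp) + lchoose(n2, k - supp) - lchoose(N, k)
  p <- exp(lp)
  min(1, sum(p[p <= p[supp == a] * (1 + 1e-7)]))
}

# independent CMLE oracle: direct maximisation of the conditional
# log-likelihood over log-odds-ratio (not the score-equation root)
cmle_grid_oracle <- function(a, b, cc, d) {
  n1 <- a + b; n2 <- cc + d; k <- a + cc
  supp <- max(0, k - n2):min(k, n1)
  lw <- lchoose(n1, supp) + lchoose(n2, k - supp)
  loglik <- function(theta) {
    lp <- lw + supp * theta
    (lw[supp == a] + a * theta) - (max(lp) + log(sum(exp(lp - max(lp)))))
  }
  exp(stats::optimize(loglik, c(-25, 25), maximum = TRUE,
                      tol = 1e-10)$maximum)
}
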