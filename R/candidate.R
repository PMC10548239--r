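## Autosomal candidate-gene replication: allele-frequency comparison of
## common variants in one gene between phenotype groups (the TIMP3-style
## analysis; reusable for any autosomal candidate such as CRELD1).
##
## Unlike the hemizygous X analysis, autosomal loci are diploid: each
## participating individual contributes two alleles, a heterozygote one
## alternate allele and a homozygote-alt two. "MAF" here means the
## alternate-allele frequency as tabulated (no minor-allele folding:
## published comparisons report alt frequencies, which can exceed 0.5).

#' Per-variant allele-count comparison for a candidate gene
#'
#' For every variant observed in `gene`, counts alternate alleles in the
#' with- and without-condition groups (het = 1, hom = 2), with totals of
#' two alleles per participating individual. Individuals with a record at
#' the variant but unknown genotype class are excluded from both allele
#' totals for that variant; individuals with no record count as two
#' reference alleles. The Fisher p comes from the shared exact test on the
#' (alt, ref) x (with, without) allele table and is invariant to which
#' allele is called "minor".
#'
#' @param cohort A `cohort_table`.
#' @param gene Gene symbol; must be autosomal in the data.
#' @param groups A [phenotype_groups()] object (built with the relevant
#'   karyotype set, e.g. all Turner-syndrome groups).
#' @return A data.frame of class `allele_count_comparison` with one row
#'   per variant: `variant_key`, `alt_with`, `total_with`, `alt_without`,
#'   `total_without`, `maf_with`, `maf_without`, `p_fisher`,
#'   `reference_af`.
#' @export
candidate_allele_counts <- function(cohort, gene, groups) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(groups, "phenotype_groups"))
  if (length(intersect(groups$with_ids, groups$without_ids)))
    stop("with/without sample sets overlap")
  v <- cohort$variants
  v <- v[!is.na(v$gene) & v$gene == gene, , drop = FALSE]
  if (nrow(v) && any(v$chrom %in% c("X", "Y")))
    stop("candidate gene '", gene, "' has sex-chromosome records; ",
         "the allele-count comparison assumes an autosomal diploid locus")
  part <- c(groups$with_ids, groups$without_ids)
  v <- v[v$sample_id %in% part, , drop = FALSE]
  keys <- if (nrow(v))
    unique(sprintf("%s:%d:%s-%s", v$chrom, v$pos, v$ref, v$alt))
  else character()

  rows <- lapply(keys, function(k) {
    vk <- v[sprintf("%s:%d:%s-%s", v$chrom, v$pos, v$ref, v$alt) == k, ,
            drop = FALSE]
    dose <- setNames(rep(0L, length(part)), part)
    excl <- character()
    for (i in seq_len(nrow(vk))) {
      g <- vk$genotype[i]
      if (is.na(g)) excl <- c(excl, vk$sample_id[i])
      else dose[vk$sample_id[i]] <- switch(g, het = 1L, hom = 2L, hem = 1L, 0L)
    }
    use_with <- setdiff(groups$with_ids, excl)
    use_without <- setdiff(groups$without_ids, excl)
    alt_w <- sum(dose[use_with]); alt_o <- sum(dose[use_without])
    tot_w <- 2L * length(use_with); tot_o <- 2L * length(use_without)
    data.frame(variant_key = k,
               alt_with = alt_w, total_with = tot_w,
               alt_without = alt_o, total_without = tot_o,
               maf_with = if (tot_w) alt_w / tot_w else NA_real_,
               maf_without = if (tot_o) alt_o / tot_o else NA_real_,
               p_fisher = fisher_exact_two_sided(alt_w, tot_w - alt_w,
                                                 alt_o, tot_o - alt_o),
               reference_af = suppressWarnings(mean(vk$pop_af, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_key = character(), alt_with = integer(),
               total_with = integer(), alt_without = integer(),
               total_without = integer(), maf_with = numeric(),
               maf_without = numeric(), p_fisher = numeric(),
               reference_af = numeric(), stringsAsFactors = FALSE)
  out$reference_af[is.nan(out$reference_af)] <- NA_real_
  rownames(out) <- NULL
  structure(out, class = c("allele_count_comparison", "data.frame"),
            gene = gene, condition = groups$condition,
            n_with = length(groups$with_ids),
            n_without = length(groups$without_ids))
}

#' @export
print.allele_count_comparison <- function(x, ...) {
  cat(sprintf("Candidate-gene allele comparison: %s vs '%s' (%d/%d individuals)\n",
              attr(x, "gene"), attr(x, "condition"),
              attr(x, "n_with"), attr(x, "n_without")))
  if (nrow(x))
    print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
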