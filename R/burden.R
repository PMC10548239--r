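## Hemizygous X-chromosome burden testing.
##
## The core analysis: within a karyotype-restricted analysis set (by
## default the monosomy-X cohort, where every X call is hemizygous and
## carrier status is binary), common X variants (population allele
## frequency in a window, default 0.1-0.9) are collapsed to carrier
## indicators per gene or per variant and compared between samples with
## and without a clinical condition: effect size = difference in carrier
## proportions, exact conditional test, conditional-MLE odds ratio, and a
## stringent Bonferroni correction over every unit with data.

#' Split an analysis set into with/without-condition sample sets
#'
#' Samples with unknown (NA) status for the condition are excluded, never
#' imputed. The analysis set is restricted to the requested karyotype
#' groups (default: monosomy X only).
#'
#' @param samples A sample data.frame (see [read_sample_metadata()]).
#' @param condition One of [phenotype_conditions()].
#' @param karyotypes Character vector of [cohort_groups()] defining the
#'   analysis set.
#' @return An object of class `phenotype_groups`: list with `condition`,
#'   `with_ids`, `without_ids`.
#' @export
phenotype_groups <- function(samples, condition,
                             karyotypes = "TS_monosomy") {
  condition <- match.arg(condition, phenotype_conditions())
  stopifnot(all(karyotypes %in% cohort_groups()))
  s <- samples[samples$group %in% karyotypes, , drop = FALSE]
  flag <- s[[condition]]
  structure(list(condition = condition,
                 with_ids = s$sample_id[!is.na(flag) & flag == 1L],
                 without_ids = s$sample_id[!is.na(flag) & flag == 0L]),
            class = "phenotype_groups")
}

#' @export
print.phenotype_groups <- function(x, ...) {
  cat(sprintf("Phenotype groups for '%s': %d with, %d without\n",
              x$condition, length(x$with_ids), length(x$without_ids)))
  invisible(x)
}

#' Common-variant population allele-frequency window
#'
#' Keeps records whose population allele frequency is present and inside
#' `[low, high]` (inclusive). Records with missing `pop_af` are dropped
#' and counted (attribute `n_missing_af`). The window targets *common*
#' variants: only around a mid-range population frequency can carrier
#' proportions differ by a sizeable effect in both directions.
#'
#' @param records A variant-record data.frame.
#' @param low,high Inclusive window bounds (defaults 0.1 and 0.9).
#' @param quiet Suppress the dropped-record message.
#' @return The kept records, order preserved.
#' @export
common_af_window <- function(records, low = 0.1, high = 0.9, quiet = FALSE) {
  v <- .records_of(records)
  stopifnot(low >= 0, high <= 1, low <= high)
  missing_af <- is.na(v$pop_af)
  if (!quiet && any(missing_af))
    message(sum(missing_af), " record(s) dropped for missing pop_af")
  keep <- !missing_af & v$pop_af >= low & v$pop_af <= high
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_af") <- sum(missing_af)
  out
}

# shared carrier-table builder; `unit` is a character vector parallel to
# the records (gene symbol or variant key)
.carrier_tables <- function(v, unit, groups) {
  n_with <- length(groups$with_ids)
  n_without <- length(groups$without_ids)
  if (length(intersect(groups$with_ids, groups$without_ids)))
    stop("with/without sample sets overlap")
  in_with <- v$sample_id %in% groups$with_ids
  in_without <- v$sample_id %in% groups$without_ids
  keep <- (in_with | in_without) & !is.na(unit) & nzchar(unit)
  v <- v[keep, , drop = FALSE]; unit <- unit[keep]
  in_with <- in_with[keep]
  if (!nrow(v))
    return(data.frame(unit_id = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), stringsAsFactors = FALSE))
  # unique individuals per unit ("a sample carrying 3 variants counts once")
  uw <- unique(data.frame(unit = unit, sample = v$sample_id,
                          w = in_with, stringsAsFactors = FALSE))
  a <- tapply(uw$w, uw$unit, sum)
  cc <- tapply(!uw$w, uw$unit, sum)
  units <- names(a)
  data.frame(unit_id = units,
             a = as.integer(a), b = n_with - as.integer(a),
             c = as.integer(cc), d = n_without - as.integer(cc),
             stringsAsFactors = FALSE)
}

#' Per-gene and per-variant carrier contingency tables
#'
#' `gene_level_carriers()` counts, per gene, the number of unique
#' individuals in each phenotype group carrying at least one qualifying
#' variant in that gene; `variant_level_carriers()` does the same keyed on
#' the individual variant (`chrom:pos:REF-ALT`). Non-carriers within the
#' participating samples form the complements, so samples with zero
#' qualifying variants still contribute to denominators. Records with an
#' empty gene symbol are ignored by the gene-level count (and tallied in
#' attribute `n_no_gene`).
#'
#' @param records Variant records, already passed through
#'   [common_af_window()] and restricted to the relevant chromosome.
#' @param groups A [phenotype_groups()] object.
#' @param quiet Suppress the no-gene message.
#' @return A data.frame with columns `unit_id`, `a`, `b`, `c`, `d` (the
#'   2x2 carrier/condition cells).
#' @export
gene_level_carriers <- function(records, groups, quiet = FALSE) {
  v <- .records_of(records)
  no_gene <- is.na(v$gene) | !nzchar(v$gene)
  if (!quiet && any(no_gene))
    message(sum(no_gene), " record(s) without gene symbol ignored")
  out <- .carrier_tables(v, ifelse(no_gene, NA_character_, v$gene), groups)
  attr(out, "n_no_gene") <- sum(no_gene)
  out
}

#' @rdname gene_level_carriers
#' @export
variant_level_carriers <- function(records, groups, quiet = FALSE) {
  v <- .records_of(records)
  key <- sprintf("%s:%d:%s-%s", v$chrom, v$pos, v$ref, v$alt)
  .carrier_tables(v, key, groups)
}

#' Run a burden scan
#'
#' End-to-end gene- or variant-level burden analysis of common hemizygous
#' X-chromosome variants for one clinical condition: restrict to the
#' analysis karyotypes and chromosome X (optionally to subregions such as
#' [par_regions()]), apply the population-frequency window, build carrier
#' tables, and compute for every unit the carrier proportions, effect
#' size (difference in proportions), exact Fisher p, conditional-MLE odds
#' ratio with exact 95% CI, and Bonferroni-adjusted p over the number of
#' units tested. Units are flagged `risk` when the effect size strictly
#' exceeds `+effect_threshold` and `protective` when strictly below
#' `-effect_threshold`.
#'
#' The odds ratio is always oriented as carriers-with-condition versus
#' carriers-without-condition, so its sign (relative to 1) agrees with the
#' effect size.
#'
#' @param cohort A `cohort_table` (normally standard-filtered).
#' @param condition One of [phenotype_conditions()].
#' @param level `"gene"` or `"variant"`.
#' @param af_low,af_high Population allele-frequency window.
#' @param effect_threshold Strict flagging threshold on |effect size|.
#' @param karyotypes Analysis-set karyotype groups (default monosomy X;
#'   supply several TS groups for the extended PAR-wide analysis).
#' @param region Optional data.frame with columns `chrom`, `start`, `end`
#'   (1-based closed) restricting the scan, e.g. `par_regions()`.
#' @param compute_or Compute conditional-MLE odds ratios (TRUE by
#'   default; skipping them speeds up large simulation studies).
#' @return An object of classes `burden_scan` and `data.frame`, one row
#'   per unit, sorted by decreasing |effect size|, with attributes
#'   `condition`, `level`, `m_tests`, `n_with`, `n_without`.
#' @export
run_burden <- function(cohort, condition, level = c("gene", "variant"),
                       af_low = 0.1, af_high = 0.9, effect_threshold = 0.35,
                       karyotypes = "TS_monosomy", region = NULL,
                       compute_or = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  level <- match.arg(level)
  groups <- phenotype_groups(cohort$samples, condition, karyotypes)
  n_with <- length(groups$with_ids); n_without <- length(groups$without_ids)
  if (n_with == 0L || n_without == 0L)
    stop("empty analysis set: condition '", condition,
         "' has with/without sizes ", n_with, "/", n_without)

  v <- cohort$variants
  v <- v[v$chrom == "X", , drop = FALSE]
  if (!is.null(region)) {
    keep <- rep(FALSE, nrow(v))
    for (i in seq_len(nrow(region)))
      keep <- keep | (v$chrom == .normalize_chrom(region$chrom[i]) &
                        v$pos >= region$start[i] & v$pos <= region$end[i])
    v <- v[keep, , drop = FALSE]
  }
  v <- common_af_window(v, af_low, af_high, quiet = TRUE)
  tabs <- if (level == "gene") gene_level_carriers(v, groups, quiet = TRUE)
          else variant_level_carriers(v, groups)

  m <- nrow(tabs)
  res <- data.frame(unit_id = tabs$unit_id, level = level,
                    condition = condition,
                    a = tabs$a, b = tabs$b, c = tabs$c, d = tabs$d,
                    prop_with = tabs$a / n_with,
                    prop_without = tabs$c / n_without,
                    stringsAsFactors = FALSE)
  res$effect_size <- res$prop_with - res$prop_without
  res$or_cmle <- NA_real_; res$ci_low <- NA_real_; res$ci_high <- NA_real_
  res$p_fisher <- NA_real_
  if (m) {
    for (i in seq_len(m)) {
      res$p_fisher[i] <- fisher_exact_two_sided(tabs$a[i], tabs$b[i],
                                                tabs$c[i], tabs$d[i])
      if (compute_or) {
        orci <- cmle_odds_ratio(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
        res$or_cmle[i] <- orci$or
        res$ci_low[i] <- orci$ci[1L]; res$ci_high[i] <- orci$ci[2L]
      }
    }
  }
  res$p_adj <- if (m) bonferroni(res$p_fisher, m) else numeric(0)
  res$m_tests <- m
  res$flag <- ifelse(res$effect_size > effect_threshold, "risk",
                     ifelse(res$effect_size < -effect_threshold,
                            "protective", "none"))
  res <- res[order(-abs(res$effect_size), res$unit_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("burden_scan", "data.frame"),
            condition = condition, level = level, m_tests = m,
            n_with = n_with, n_without = n_without)
}

#' @export
print.burden_scan <- function(x, n = 10L, ...) {
  cat(sprintf("Burden scan (%s level) for '%s': %d with vs %d without; %d unit(s) tested\n",
              attr(x, "level"), attr(x, "condition"),
              attr(x, "n_with"), attr(x, "n_without"), attr(x, "m_tests")))
  if (nrow(x)) {
    show <- head(as.data.frame(x)[, c("unit_id", "prop_with", "prop_without",
                                      "effect_size", "or_cmle", "p_fisher",
                                      "p_adj", "flag")], n)
    print(show, row.names = FALSE, digits = 3)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more unit(s)\n")
  }
  invisible(x)
}

#' @export
summary.burden_scan <- function(object, ...) {
  flagged <- sum(object$flag != "none")
  sig_raw <- sum(object$p_fisher < 0.05, na.rm = TRUE)
  sig_adj <- sum(object$p_adj < 0.05, na.rm = TRUE)
  cat(sprintf(
    "Burden scan for '%s' (%s level): %d units; %d flagged (|effect| > threshold);\n%d with raw p < 0.05; %d Bonferroni-significant (m = %d)\n",
    attr(object, "condition"), attr(object, "level"), nrow(object), flagged,
    sig_raw, sig_adj, attr(object, "m_tests")))
  invisible(list(n_units = nrow(object), n_flagged = flagged,
                 n_sig_raw = sig_raw, n_sig_adj = sig_adj,
                 m_tests = attr(object, "m_tests")))
}

#' Scatterplot of carrier proportions for a burden scan
#'
#' Proportion of carriers among without-condition samples against the
#' proportion among with-condition samples, with the identity line and the
#' effect-size flagging band; flagged units are labelled.
#'
#' @param x A `burden_scan`.
#' @param effect_threshold Band half-width (matches the scan default).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.burden_scan <- function(x, effect_threshold = 0.35, ...) {
  graphics::plot(x$prop_without, x$prop_with, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "carrier proportion, without condition",
                 ylab = "carrier proportion, with condition",
                 pch = 19, col = "#00000055",
                 main = sprintf("%s burden (%s level)",
                                attr(x, "condition"), attr(x, "level")), ...)
  graphics::abline(0, 1, col = "grey40")
  graphics::abline(effect_threshold, 1, lty = 2, col = "grey60")
  graphics::abline(-effect_threshold, 1, lty = 2, col = "grey60")
  lab <- x$flag != "none"
  if (any(lab))
    graphics::text(x$prop_without[lab], x$prop_with[lab],
                   labels = x$unit_id[lab], pos = 3, cex = 0.7, col = "red3")
  invisible(x)
}
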