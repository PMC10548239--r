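## Exome variability profiling: per-sample variant counts by chromosome
## class and predicted translational impact, and rank-based group
## comparison (Kruskal-Wallis, with Dunn-style post-hoc contrasts).

#' Per-sample variant counts by chromosome class and consequence
#'
#' Counts one vector per (sample, chromosome class), where the classes are
#' `autosomal` (chromosomes 1-22) and `X`. Y and mitochondrial records are
#' excluded from both classes; their counts are attached as attribute
#' `n_excluded` and reported. Every sample in the cohort metadata gets a
#' row for both classes (zero counts included), so downstream group
#' comparisons see genuinely variant-free samples.
#'
#' @param cohort A `cohort_table`, already restricted to the records of
#'   one filtering pipeline.
#' @param pipeline Label for the pipeline the cohort was filtered with
#'   (`"standard"` or `"somatic"`); carried through to the output.
#' @param quiet Suppress the excluded-record message.
#' @return A data.frame with columns `sample_id`, `pipeline`,
#'   `chrom_class`, one column per consequence class, and `total`.
#' @export
count_by_consequence <- function(cohort, pipeline = c("standard", "somatic"),
                                 quiet = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  pipeline <- match.arg(pipeline)
  v <- cohort$variants
  excl <- v$chrom %in% c("Y", "MT")
  if (!quiet && any(excl))
    message(sum(excl), " Y/MT record(s) excluded from chromosome classes")
  v <- v[!excl, , drop = FALSE]
  v$chrom_class <- ifelse(v$chrom == "X", "X", "autosomal")

  classes <- c("autosomal", "X")
  cons <- consequence_classes()
  grid <- expand.grid(sample_id = cohort$samples$sample_id,
                      chrom_class = classes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow(grid), length(cons),
                   dimnames = list(NULL, cons))
  if (nrow(v)) {
    tab <- table(factor(v$sample_id, levels = cohort$samples$sample_id),
                 factor(v$chrom_class, levels = classes),
                 factor(v$consequence, levels = cons))
    for (k in seq_along(cons))
      counts[, k] <- as.integer(as.vector(tab[, , k]))
  }
  out <- cbind(data.frame(sample_id = grid$sample_id,
                          pipeline = rep(pipeline, nrow(grid)),
                          chrom_class = grid$chrom_class,
                          stringsAsFactors = FALSE),
               as.data.frame(counts))
  out$total <- as.integer(rowSums(counts))
  attr(out, "n_excluded") <- sum(excl)
  out
}

#' Rank-based comparison of a quantity across cohort groups
#'
#' Kruskal-Wallis one-way analysis of variance on ranks (midranks for
#' ties, with the standard tie-correction factor, via
#' [stats::kruskal.test()]), with per-group medians and quartiles for
#' box-plot style reporting, and optional Dunn-style pairwise post-hoc
#' contrasts with Bonferroni correction. If all values are identical the
#' test is degenerate and p = 1 is returned.
#'
#' @param values Numeric vector (e.g. per-sample variant totals).
#' @param groups Grouping vector of the same length.
#' @param posthoc Compute pairwise Dunn contrasts (default TRUE when there
#'   are more than two groups).
#' @return An object of class `group_comparison`: a list with `statistic`
#'   (the tie-corrected H), `df`, `p.value`, `group_summary` and `posthoc`.
#' @export
compare_groups <- function(values, groups, posthoc = NULL) {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab == 0L)) stop("empty group")
  if (is.null(posthoc)) posthoc <- length(tab) > 2L

  gs <- do.call(rbind, lapply(names(tab), function(g) {
    x <- values[groups == g]
    data.frame(group = g, n = length(x), median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))

  if (length(unique(values)) == 1L) {
    res <- list(statistic = 0, df = length(tab) - 1L, p.value = 1,
                group_summary = gs, posthoc = NULL, degenerate = TRUE)
    return(structure(res, class = "group_comparison"))
  }
  kw <- kruskal.test(values, factor(groups))
  ph <- if (posthoc) .dunn_posthoc(values, groups) else NULL
  structure(list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p.value = kw$p.value, group_summary = gs, posthoc = ph,
                 degenerate = FALSE),
            class = "group_comparison")
}

# Dunn's pairwise rank comparison with tie correction and Bonferroni
.dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2L)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    z = NA_real_, p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    g1 <- groups == pairs[1L, i]; g2 <- groups == pairs[2L, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sum(g1) + 1 / sum(g2)))
    z <- (mean(r[g1]) - mean(r[g2])) / se
    out$z[i] <- z
    out$p[i] <- 2 * pnorm(-abs(z))
  }
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis rank comparison: H = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  if (isTRUE(x$degenerate)) cat("  (all values identical; degenerate)\n")
  print(x$group_summary, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("Pairwise Dunn contrasts (Bonferroni-adjusted):\n")
    print(x$posthoc, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
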