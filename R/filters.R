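## Parallel variant-filtering pipelines.
##
## Two filters run side by side on the merged cohort: a "standard" filter
## for germline / early-somatic calls, and a "somatic" filter that targets
## low-allele-fraction mosaic events. The somatic thresholds (>= 40x
## coverage, VAF in [0.05, 0.25], both bounds inclusive) balance
## sensitivity against read-sampling noise at the low end and genuine
## heterozygous calls at the high end. The standard pipeline's thresholds
## are configuration-driven; the shipped defaults (quality >= 20, depth >=
## 10, VAF >= 0.25) are deliberately conservative placeholders, since no
## single canonical choice exists.

#' Filter configuration
#'
#' @param min_depth_somatic Minimum read depth for the somatic-mosaic
#'   filter (default 40; "at least", i.e. inclusive).
#' @param vaf_low,vaf_high Inclusive VAF window for the somatic-mosaic
#'   filter (defaults 0.05 and 0.25).
#' @param min_quality_standard Minimum call quality for the standard
#'   filter (default 20).
#' @param min_depth_standard Minimum depth for the standard filter
#'   (default 10).
#' @param vaf_min_standard Minimum VAF for the standard filter
#'   (default 0.25).
#' @param min_quality_somatic Optional quality floor for the somatic
#'   filter; `NULL` (the default) applies none.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth_somatic = 40L, vaf_low = 0.05,
                          vaf_high = 0.25, min_quality_standard = 20,
                          min_depth_standard = 10L, vaf_min_standard = 0.25,
                          min_quality_somatic = NULL) {
  stopifnot(vaf_low >= 0, vaf_low < vaf_high, vaf_high <= 1,
            min_depth_somatic >= 0, min_depth_standard >= 0,
            vaf_min_standard >= 0, vaf_min_standard <= 1)
  structure(list(min_depth_somatic = as.integer(min_depth_somatic),
                 vaf_low = vaf_low, vaf_high = vaf_high,
                 min_quality_standard = min_quality_standard,
                 min_depth_standard = as.integer(min_depth_standard),
                 vaf_min_standard = vaf_min_standard,
                 min_quality_somatic = min_quality_somatic),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Filter configuration\n",
      sprintf("  somatic : depth >= %d, %.3g <= vaf <= %.3g%s\n",
              x$min_depth_somatic, x$vaf_low, x$vaf_high,
              if (is.null(x$min_quality_somatic)) "" else
                sprintf(", quality >= %.3g", x$min_quality_somatic)),
      sprintf("  standard: quality >= %.3g, depth >= %d, vaf >= %.3g\n",
              x$min_quality_standard, x$min_depth_standard,
              x$vaf_min_standard), sep = "")
  invisible(x)
}

.apply_filter <- function(x, keep_fun) {
  if (inherits(x, "cohort_table")) {
    v <- x$variants
    kept <- v[keep_fun(v), , drop = FALSE]
    rownames(kept) <- NULL
    cohort_table(kept, x$samples)
  } else {
    v <- .records_of(x)
    kept <- v[keep_fun(v), , drop = FALSE]
    rownames(kept) <- NULL
    kept
  }
}

#' Somatic-mosaic variant filter
#'
#' Keeps records with `depth >= min_depth_somatic` and
#' `vaf_low <= vaf <= vaf_high` (bounds inclusive), plus the optional
#' somatic quality floor if configured. Input order is preserved.
#'
#' @param x A variant-record data.frame or a `cohort_table` (in which case
#'   a filtered `cohort_table` is returned).
#' @param cfg A [filter_config()].
#' @return Same container type as `x`, restricted to the kept records.
#' @export
somatic_filter <- function(x, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  .apply_filter(x, function(v) {
    keep <- v$depth >= cfg$min_depth_somatic &
      v$vaf >= cfg$vaf_low & v$vaf <= cfg$vaf_high
    if (!is.null(cfg$min_quality_somatic))
      keep <- keep & v$call_quality >= cfg$min_quality_somatic
    keep & !is.na(keep)
  })
}

#' Standard (germline / early-somatic) variant filter
#'
#' Keeps records with `call_quality >= min_quality_standard`,
#' `depth >= min_depth_standard` and `vaf >= vaf_min_standard`. Behaviour
#' is fully driven by the configuration. Input order is preserved.
#'
#' @inheritParams somatic_filter
#' @return Same container type as `x`, restricted to the kept records.
#' @export
standard_filter <- function(x, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  .apply_filter(x, function(v) {
    keep <- v$call_quality >= cfg$min_quality_standard &
      v$depth >= cfg$min_depth_standard & v$vaf >= cfg$vaf_min_standard
    keep & !is.na(keep)
  })
}
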