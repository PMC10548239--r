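## SNP-array mosaicism: estimate the fraction of a second cell line from
## B-allele frequencies (BAF) and log R ratios (LRR) under a two-population
## copy-number mixture.
##
## In a mixture of cell line 1 (copy number c1, alt copies a1 at a marker)
## and cell line 2 (c2, a2) with fraction f of line-2 cells,
##   E[BAF] = ((1-f)*a1 + f*a2) / ((1-f)*c1 + f*c2)
##   E[LRR] = log2(((1-f)*c1 + f*c2) / 2)
## Heterozygous-like markers form off-centre BAF bands whose position
## encodes f; average signal intensity encodes the mixture copy number.
## Presets: "ring" = 45,X vs 46,X,r(X) (1 vs 2 copies); "isoXq" = 45,X vs
## 46,X,i(Xq) on the q arm (1 vs 3 copies, the isochromosome carrying two
## identical q-arm alleles).

#' Two-population copy-number mixture model
#'
#' @param c1,c2 Copy number at the locus in cell lines 1 and 2.
#' @param a1,a2 Alternate (B) allele copies in each line at an informative
#'   marker; `0 <= a <= c` and the marker must be informative
#'   (`(c1, a1) != (c2, a2)` with differing allelic ratios).
#' @param f Fraction of cells belonging to line 2, in \[0, 1\].
#' @return An object of class `copy_mixture_model`.
#' @export
copy_mixture_model <- function(c1, a1, c2, a2, f) {
  stopifnot(c1 >= 1, c2 >= 0, a1 >= 0, a1 <= c1, a2 >= 0, a2 <= c2,
            f >= 0, f <= 1)
  if (c1 == c2 && a1 == a2)
    stop("non-informative model: both lines identical at the marker")
  structure(list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, f = f),
            class = "copy_mixture_model")
}

#' Expected BAF and LRR under a copy-number mixture
#'
#' @param model A [copy_mixture_model()].
#' @return `expected_baf()` the mixture B-allele frequency;
#'   `expected_lrr()` the mixture log2 intensity ratio relative to two
#'   copies.
#' @examples
#' expected_baf(copy_mixture_model(1, 0, 2, 1, f = 0.5))  # 1/3
#' @export
expected_baf <- function(model) {
  stopifnot(inherits(model, "copy_mixture_model"))
  f <- model$f
  ((1 - f) * model$a1 + f * model$a2) /
    ((1 - f) * model$c1 + f * model$c2)
}

#' @rdname expected_baf
#' @export
expected_lrr <- function(model) {
  stopifnot(inherits(model, "copy_mixture_model"))
  f <- model$f
  log2(((1 - f) * model$c1 + f * model$c2) / 2)
}

.mixture_presets <- list(
  ring  = list(c1 = 1, a1 = 0, c2 = 2, a2 = 1),
  isoXq = list(c1 = 1, a1 = 0, c2 = 3, a2 = 2)
)

.resolve_shape <- function(shape) {
  if (is.character(shape)) {
    shape <- match.arg(shape, names(.mixture_presets))
    .mixture_presets[[shape]]
  } else {
    stopifnot(is.list(shape), all(c("c1", "a1", "c2", "a2") %in% names(shape)))
    shape
  }
}

# invert E[BAF] = b for f given the shape; closed form of the mixture ratio
.invert_baf <- function(b, s) {
  num <- s$a1 - b * s$c1
  den <- (s$a1 - b * s$c1) - (s$a2 - b * s$c2)
  if (den == 0) return(NA_real_)
  min(1, max(0, num / den))
}

#' SNP-array marker profile
#'
#' @param markers A data.frame with columns `chrom`, `pos` (1-based),
#'   `baf` in \[0, 1\] and `lrr`; sorted by position on construction.
#' @param region Optional `(chrom, start, end)` list restricting later
#'   estimation; 1-based fully closed.
#' @return An object of class `snp_profile`.
#' @export
snp_profile <- function(markers, region = NULL) {
  need <- c("chrom", "pos", "baf", "lrr")
  missing <- setdiff(need, names(markers))
  if (length(missing))
    stop("marker table missing columns: ", paste(missing, collapse = ", "))
  m <- markers[need]
  m$chrom <- .normalize_chrom(m$chrom)
  m$pos <- as.integer(m$pos)
  if (any(m$baf < 0 | m$baf > 1, na.rm = TRUE)) stop("baf must lie in [0, 1]")
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(markers = m, region = region), class = "snp_profile")
}

#' Read a GenomeStudio-style marker table
#'
#' Tab-delimited with columns `chrom`, `pos`, `baf`, `lrr`.
#'
#' @param path File path.
#' @param region Optional region list passed to [snp_profile()].
#' @return An `snp_profile`.
#' @export
read_marker_table <- function(path, region = NULL) {
  snp_profile(read.delim(path, stringsAsFactors = FALSE), region)
}

.region_markers <- function(profile) {
  m <- profile$markers
  r <- profile$region
  if (!is.null(r))
    m <- m[m$chrom == .normalize_chrom(r$chrom) &
             m$pos >= r$start & m$pos <= r$end, , drop = FALSE]
  m
}

#' Estimate the mosaic cell-line fraction from BAF bands
#'
#' Markers with `baf < hom_low` or `baf > hom_high` are treated as
#' homozygous and excluded. The remaining heterozygous-like markers are
#' folded about 0.5 (`min(baf, 1 - baf)`; band positions are symmetric
#' under allele relabelling) and the band position `b` is the folded
#' median, robustified by a second pass that drops points further than
#' `max(3 * mad, 0.05)` from the first-pass centre (this removes
#' homozygous markers whose noise leaked past the exclusion threshold).
#' The mixture formula is then inverted for `f`. For the ring shape
#' (1 copy vs 2) this is `f = b / (1 - b)`. For shapes whose band can
#' cross 0.5 (e.g. isochromosome, 1 vs 3), folding leaves two candidate
#' solutions; the one whose expected LRR is closer to the observed median
#' LRR is chosen. Bands closer to the exclusion threshold than 0.01 are
#' indistinguishable from homozygous noise: the estimate is then 0 with
#' flag `"no heterozygous band"` (the practical detection limit of the
#' band method).
#'
#' @param profile An [snp_profile()].
#' @param shape `"ring"`, `"isoXq"`, or a list with `c1`, `a1`, `c2`,
#'   `a2` giving the informative-marker configuration (line-1 alt copies /
#'   copy number vs line 2).
#' @param hom_low,hom_high Homozygous-band exclusion thresholds.
#' @param min_markers Minimum markers required in the region.
#' @return An object of class `mosaic_estimate`: list with `f_hat`,
#'   `method`, `n_markers`, `band_positions`, `residual`, `flag`.
#' @export
estimate_fraction_from_baf <- function(profile, shape = "ring",
                                       hom_low = 0.05, hom_high = 0.95,
                                       min_markers = 30L) {
  stopifnot(inherits(profile, "snp_profile"))
  s <- .resolve_shape(shape)
  m <- .region_markers(profile)
  if (nrow(m) < min_markers)
    stop("fewer than ", min_markers, " markers in region (", nrow(m), ")")
  mid <- m$baf[m$baf > hom_low & m$baf < hom_high & !is.na(m$baf)]

  no_band <- function() structure(
    list(f_hat = 0, method = "baf", n_markers = nrow(m),
         band_positions = numeric(), residual = NA_real_,
         flag = "no heterozygous band"),
    class = "mosaic_estimate")

  if (length(mid) < 10L) return(no_band())
  folded <- pmin(mid, 1 - mid)
  b0 <- median(folded)
  keep <- abs(folded - b0) <= max(3 * mad(folded), 0.05)
  b <- median(folded[keep])
  if (b <= hom_low + 0.01) return(no_band())

  cands <- unique(c(.invert_baf(b, s), .invert_baf(1 - b, s)))
  cands <- cands[!is.na(cands)]
  # candidates whose expected band actually folds to b
  valid <- vapply(cands, function(f) {
    eb <- expected_baf(copy_mixture_model(s$c1, s$a1, s$c2, s$a2, f))
    abs(min(eb, 1 - eb) - b) < 1e-6
  }, logical(1L))
  cands <- cands[valid]
  if (!length(cands)) return(no_band())
  f_hat <- if (length(cands) == 1L) cands else {
    med_lrr <- median(m$lrr, na.rm = TRUE)
    lrr_dist <- vapply(cands, function(f)
      abs(expected_lrr(copy_mixture_model(s$c1, s$a1, s$c2, s$a2, f)) -
            med_lrr), numeric(1L))
    cands[which.min(lrr_dist)]
  }
  structure(list(f_hat = f_hat, method = "baf", n_markers = nrow(m),
                 band_positions = sort(c(b, 1 - b)),
                 residual = mad(folded[keep] - b),
                 flag = "ok"),
            class = "mosaic_estimate")
}

#' Estimate the mosaic cell-line fraction from median LRR
#'
#' Inverts the mixture copy number implied by the median log R ratio:
#' `f = (2^(median(lrr) + 1) - c1) / (c2 - c1)`, clamped to \[0, 1\].
#'
#' @param profile An [snp_profile()].
#' @param c1,c2 Copy numbers of the two cell lines (`c1 != c2`).
#' @param min_markers Minimum markers required in the region.
#' @return A `mosaic_estimate`.
#' @export
estimate_fraction_from_lrr <- function(profile, c1 = 1, c2 = 2,
                                       min_markers = 30L) {
  stopifnot(inherits(profile, "snp_profile"))
  if (c1 == c2) stop("c1 and c2 must differ")
  m <- .region_markers(profile)
  if (nrow(m) < min_markers)
    stop("fewer than ", min_markers, " markers in region (", nrow(m), ")")
  med <- median(m$lrr, na.rm = TRUE)
  f <- (2^(med + 1) - c1) / (c2 - c1)
  structure(list(f_hat = min(1, max(0, f)), method = "lrr",
                 n_markers = nrow(m), band_positions = numeric(),
                 residual = mad(m$lrr, na.rm = TRUE), flag = "ok"),
            class = "mosaic_estimate")
}

#' Combined mosaic-fraction estimate
#'
#' BAF-band estimation is preferred (band positions are a sharper signal
#' than intensity); when no heterozygous band is detectable the LRR
#' estimate is used as fallback.
#'
#' @inheritParams estimate_fraction_from_baf
#' @param method `"combined"` (default), `"baf"` or `"lrr"`.
#' @return A `mosaic_estimate` (with `method` recording the estimator
#'   actually used; `"combined"` falls back from `"baf"` to `"lrr"`).
#' @export
estimate_mosaic_fraction <- function(profile, shape = "ring",
                                     method = c("combined", "baf", "lrr"),
                                     hom_low = 0.05, hom_high = 0.95,
                                     min_markers = 30L) {
  method <- match.arg(method)
  s <- .resolve_shape(shape)
  if (method == "lrr")
    return(estimate_fraction_from_lrr(profile, s$c1, s$c2, min_markers))
  est <- estimate_fraction_from_baf(profile, s, hom_low, hom_high,
                                    min_markers)
  if (method == "combined" && est$flag == "no heterozygous band") {
    lrr <- estimate_fraction_from_lrr(profile, s$c1, s$c2, min_markers)
    # a genuinely pure line-1 sample has both no band and line-1 intensity
    if (lrr$f_hat > 0.05) return(lrr)
  }
  est
}

#' @export
print.mosaic_estimate <- function(x, ...) {
  cat(sprintf("Mosaic fraction estimate: f = %.3f (%s method, %d markers)\n",
              x$f_hat, x$method, x$n_markers))
  if (length(x$band_positions))
    cat("  BAF bands at", paste(sprintf("%.3f", x$band_positions),
                                collapse = ", "), "\n")
  if (!identical(x$flag, "ok")) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Wilcoxon matched-pairs signed-rank comparison of mosaicism values
#'
#' Two-sided paired signed-rank test, e.g. comparing original
#' karyotype-derived mosaic percentages against array-derived ones in the
#' same individuals. Zero differences are dropped (the standard
#' convention). The exact distribution is used for up to 25 non-zero
#' pairs when there are no ties in the absolute differences; otherwise
#' the normal approximation with tie handling and continuity correction.
#' If all differences are zero the test is degenerate and p = 1.
#'
#' @param original,new Numeric vectors of equal length (>= 5 pairs).
#' @return A list with `statistic` (V, the positive-rank sum), `p.value`,
#'   `n_nonzero` and `method`.
#' @export
paired_signed_rank <- function(original, new) {
  stopifnot(length(original) == length(new), length(original) >= 5L)
  d <- new - original
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (!length(nz))
    return(list(statistic = 0, p.value = 1, n_nonzero = 0L,
                method = "degenerate (all differences zero)"))
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    wilcox.test(nz, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_nonzero = length(nz),
       method = if (exact) "exact" else "normal approximation")
}
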