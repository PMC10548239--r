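## Cohort I/O: variant tables, sample metadata, merging.
##
## A "variant record" is one annotated variant call in one sample, held as a
## row of a plain data.frame with columns
##   sample_id, chrom, pos, ref, alt, gene, consequence, depth, vaf,
##   call_quality, pop_af, genotype
## Coordinates are 1-based fully closed (VCF convention, GRCh38 labels);
## chromosome names are normalised by stripping any "chr" prefix.
## `genotype` is one of "het", "hom", "hem" (hemizygous) or NA; it is only
## needed by the autosomal candidate-gene analysis.

.variant_cols <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                   "consequence", "depth", "vaf", "call_quality", "pop_af",
                   "genotype")

# fixed annotation -> consequence-class mapping; anything unmapped -> "other"
.consequence_map <- c(
  "missense"              = "missense",
  "missense variant"      = "missense",
  "synonymous"            = "synonymous",
  "synonymous variant"    = "synonymous",
  "frameshift"            = "frameshift",
  "frameshift variant"    = "frameshift",
  "frameshift deletion"   = "frameshift",
  "frameshift insertion"  = "frameshift",
  "inframe"               = "inframe",
  "in frame"              = "inframe",
  "inframe deletion"      = "inframe",
  "inframe insertion"     = "inframe",
  "inframe indel"         = "inframe",
  "stop gain"             = "stop_gain",
  "stop gained"           = "stop_gain",
  "stopgain"              = "stop_gain",
  "nonsense"              = "stop_gain"
)

#' Map annotation strings to consequence classes
#'
#' Every input annotation maps to exactly one of
#' `consequence_classes()`; strings not in the shipped mapping table map to
#' `"other"` (annotation platforms never publish their full vocabulary, so
#' the mapping is total by construction). Case, hyphens and underscores are
#' ignored. The number of unmapped strings is attached as attribute
#' `n_unmapped` and reported via `message()`.
#'
#' @param x Character vector of annotation strings.
#' @param quiet Suppress the unmapped-count message.
#' @return Character vector of consequence classes.
#' @export
normalize_consequence <- function(x, quiet = FALSE) {
  key <- tolower(gsub("[_\\-]+", " ", trimws(as.character(x))))
  key <- gsub("  +", " ", key)
  out <- unname(.consequence_map[key])
  unmapped <- is.na(out) & !is.na(key) & !(key %in% consequence_classes())
  out[is.na(out) & key %in% consequence_classes()] <-
    key[is.na(out) & key %in% consequence_classes()]
  out[is.na(out)] <- "other"
  if (!quiet && any(unmapped))
    message(sum(unmapped), " annotation string(s) not in the mapping table; ",
            "classed as 'other'")
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

.validate_variants <- function(v) {
  missing <- setdiff(.variant_cols, names(v))
  if (length(missing))
    stop("variant table is missing columns: ", paste(missing, collapse = ", "))
  v <- v[.variant_cols]
  v$chrom <- .normalize_chrom(v$chrom)
  v$pos <- as.integer(v$pos)
  v$depth <- as.integer(v$depth)
  if (nrow(v)) {
    if (any(v$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
    if (any(v$ref == v$alt, na.rm = TRUE)) stop("ref and alt must differ")
    if (any(v$vaf < 0 | v$vaf > 1, na.rm = TRUE)) stop("vaf must lie in [0, 1]")
    if (any(v$depth < 0L, na.rm = TRUE)) stop("depth must be non-negative")
    bad_af <- !is.na(v$pop_af) & (v$pop_af < 0 | v$pop_af > 1)
    if (any(bad_af)) stop("pop_af must lie in [0, 1] or be missing")
  }
  rownames(v) <- NULL
  v
}

.variant_key <- function(v) {
  paste(v$sample_id, v$chrom, v$pos, v$ref, v$alt, sep = "\r")
}

#' Read variant records from a VCF file
#'
#' Parses a VCF (v4.x) with `vcfR` and returns one variant record per
#' sample-allele: multiallelic sites are decomposed into one record per ALT
#' allele. Depth comes from FORMAT `DP`. VAF precedence: an explicit
#' per-allele FORMAT `AF` field is used when present, otherwise VAF is
#' derived from `AD` as `AD_alt / sum(AD)`. Gene symbol, consequence
#' annotation and population allele frequency are read from the INFO keys
#' `GENE`, `CSQ` and `POPAF` when present (the annotated-export dialect of
#' this package). Records whose depth or VAF cannot be derived are skipped;
#' the skip count is attached as attribute `n_skipped` and reported.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample identifier to stamp on the records. The first
#'   genotype column of the VCF is read.
#' @param quiet Suppress the skipped-record message.
#' @return A variant-record data.frame (possibly 0-row).
#' @export
read_vcf <- function(path, sample_id, quiet = FALSE) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("unparsable VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0L) return(.validate_variants(.empty_variants()))

  gt_field <- function(el) {
    m <- tryCatch(vcfR::extract.gt(vcf, element = el, as.numeric = FALSE),
                  error = function(e) NULL)
    if (is.null(m)) rep(NA_character_, n) else as.character(m[, 1L])
  }
  dp <- suppressWarnings(as.numeric(gt_field("DP")))
  ad <- gt_field("AD")
  af <- gt_field("AF")
  gt <- gt_field("GT")

  info_key <- function(key) {
    val <- vcfR::extract.info(vcf, element = key)
    if (is.null(val)) rep(NA_character_, n) else as.character(val)
  }
  gene <- info_key("GENE")
  csq  <- info_key("CSQ")
  paf  <- suppressWarnings(as.numeric(info_key("POPAF")))

  out <- vector("list", n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    alts <- alts[!is.na(alts) & alts != "." & nzchar(alts)]
    if (!length(alts) || is.na(fix$POS[i])) { n_skipped <- n_skipped + 1L; next }
    ad_i <- suppressWarnings(as.numeric(strsplit(
      ifelse(is.na(ad[i]), "", ad[i]), ",", fixed = TRUE)[[1L]]))
    af_i <- suppressWarnings(as.numeric(strsplit(
      ifelse(is.na(af[i]), "", af[i]), ",", fixed = TRUE)[[1L]]))
    depth_i <- dp[i]
    if (is.na(depth_i) && length(ad_i) && !anyNA(ad_i)) depth_i <- sum(ad_i)

    vafs <- rep(NA_real_, length(alts))
    for (j in seq_along(alts)) {
      if (length(af_i) >= j && !is.na(af_i[j])) {
        vafs[j] <- af_i[j]
      } else if (length(ad_i) >= j + 1L && !anyNA(ad_i) && sum(ad_i) > 0) {
        vafs[j] <- ad_i[j + 1L] / sum(ad_i)
      }
    }
    if (is.na(depth_i) || anyNA(vafs)) { n_skipped <- n_skipped + 1L; next }

    # genotype class for the j-th alt allele from GT
    geno <- rep(NA_character_, length(alts))
    if (!is.na(gt[i])) {
      alleles <- strsplit(gt[i], "[/|]")[[1L]]
      for (j in seq_along(alts)) {
        nalt <- sum(alleles == as.character(j))
        geno[j] <- if (length(alleles) == 1L && nalt == 1L) "hem"
          else if (nalt >= 2L) "hom"
          else if (nalt == 1L) "het"
          else NA_character_
      }
    }
    out[[i]] <- data.frame(
      sample_id = sample_id, chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts,
      gene = ifelse(is.na(gene[i]), "", gene[i]),
      consequence = as.vector(normalize_consequence(
        ifelse(is.na(csq[i]), "other", csq[i]), quiet = TRUE)),
      depth = as.integer(round(depth_i)), vaf = vafs,
      call_quality = suppressWarnings(as.numeric(fix$QUAL[i])),
      pop_af = paf[i], genotype = geno, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res)) res <- .empty_variants()
  res$call_quality[is.na(res$call_quality)] <- 0
  if (!quiet && n_skipped > 0L)
    message(n_skipped, " VCF record(s) skipped (missing DP/AD or malformed)")
  res <- .validate_variants(res)
  attr(res, "n_skipped") <- n_skipped
  res
}

.empty_variants <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene = character(),
             consequence = character(), depth = integer(), vaf = numeric(),
             call_quality = numeric(), pop_af = numeric(),
             genotype = character(), stringsAsFactors = FALSE)
}

#' Read and write the annotated-export variant dialect
#'
#' A UTF-8 comma-delimited flat export with one row per sample-variant and
#' a header carrying exactly the variant-record columns (`sample_id, chrom,
#' pos, ref, alt, gene, consequence, depth, vaf, call_quality, pop_af,
#' genotype`), emulating the merged CSV exports of clinical annotation
#' platforms. An empty `pop_af` cell reads as missing. Consequence strings
#' are mapped through [normalize_consequence()].
#'
#' @param path File path.
#' @return `read_annotated_export()` returns a variant-record data.frame;
#'   `write_annotated_export()` returns `path` invisibly.
#' @export
read_annotated_export <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(.variant_cols, names(df))
  if (length(missing))
    stop("annotated export header mismatch; missing columns: ",
         paste(missing, collapse = ", "))
  df$consequence <- as.vector(normalize_consequence(df$consequence,
                                                    quiet = TRUE))
  df$gene[is.na(df$gene)] <- ""
  df$pop_af <- suppressWarnings(as.numeric(df$pop_af))
  .validate_variants(df)
}

#' @rdname read_annotated_export
#' @param records A variant-record data.frame.
#' @export
write_annotated_export <- function(records, path) {
  records <- .validate_variants(records)
  write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-delimited, columns `sample_id`, `group` (one of [cohort_groups()])
#' and one 0/1/NA column per condition in [phenotype_conditions()]. NA
#' means the phenotype is unknown; such samples are excluded from that
#' condition's burden analysis, never imputed.
#'
#' @param path File path.
#' @return A sample data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  .validate_samples(df)
}

.validate_samples <- function(df) {
  need <- c("sample_id", "group", phenotype_conditions())
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sample table is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample table")
  bad <- setdiff(unique(df$group), cohort_groups())
  if (length(bad))
    stop("unknown cohort group(s): ", paste(bad, collapse = ", "))
  for (cond in phenotype_conditions()) {
    v <- df[[cond]]
    if (!all(v %in% c(0L, 1L, NA)))
      stop("condition column '", cond, "' must be 0/1/NA")
    df[[cond]] <- as.integer(v)
  }
  rownames(df) <- NULL
  df[need]
}

#' Merge per-sample variant tables into a cohort table
#'
#' Binds per-sample variant-record tables, checks every record's sample
#' against the metadata, and deduplicates on (sample_id, chrom, pos, ref,
#' alt) keeping the record with the higher call quality (ties keep the
#' first by input order; tie collisions are reported). The result is
#' canonically sorted, so merging is order-independent.
#'
#' @param tables A list of variant-record data.frames (or a single one).
#' @param samples A sample data.frame (see [read_sample_metadata()]).
#' @param quiet Suppress collision messages.
#' @return A `cohort_table` object.
#' @export
merge_cohort <- function(tables, samples, quiet = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  samples <- .validate_samples(samples)
  v <- do.call(rbind, lapply(tables, .validate_variants))
  if (is.null(v)) v <- .empty_variants()
  unknown <- setdiff(unique(v$sample_id), samples$sample_id)
  if (length(unknown))
    stop("variant records reference unknown sample_id(s): ",
         paste(unknown, collapse = ", "))
  if (nrow(v)) {
    key <- .variant_key(v)
    ord <- order(key, -v$call_quality, seq_len(nrow(v)))
    v <- v[ord, , drop = FALSE]
    key <- key[ord]
    dup <- duplicated(key)
    # collisions where a discarded duplicate had equal quality to the kept one
    kept_q <- v$call_quality[match(key, key)]
    n_tie <- sum(dup & v$call_quality == kept_q)
    if (!quiet && any(dup))
      message(sum(dup), " duplicate (sample, variant) record(s) removed (",
              n_tie, " equal-quality collision(s))")
    v <- v[!dup, , drop = FALSE]
    v <- v[order(v$sample_id, match(v$chrom, .chrom_levels()), v$pos,
                 v$ref, v$alt), , drop = FALSE]
    rownames(v) <- NULL
  }
  cohort_table(v, samples)
}

#' Construct a cohort table
#'
#' Bundles a variant-record table with sample metadata and enforces the
#' cohort invariants: every variant's sample appears in the metadata and
#' (sample_id, chrom, pos, ref, alt) is unique.
#'
#' @param variants A variant-record data.frame.
#' @param samples A sample data.frame.
#' @return An object of class `cohort_table`: a list with elements
#'   `variants` and `samples`.
#' @export
cohort_table <- function(variants, samples) {
  variants <- .validate_variants(variants)
  samples <- .validate_samples(samples)
  unknown <- setdiff(unique(variants$sample_id), samples$sample_id)
  if (length(unknown))
    stop("variants reference unknown sample_id(s): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(.variant_key(variants)))
    stop("(sample_id, chrom, pos, ref, alt) must be unique")
  structure(list(variants = variants, samples = samples),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x$samples), "samples,",
      nrow(x$variants), "variant records\n")
  tab <- table(factor(x$samples$group, levels = cohort_groups()))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

.records_of <- function(x) {
  if (inherits(x, "cohort_table")) x$variants else .validate_variants(x)
}
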