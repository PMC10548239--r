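## Synthetic cohort generator: fully simulated inputs carrying the
## statistical structure the analysis assumes, so every pipeline stage is
## testable without access to restricted human data.
##
## The defaults emulate the study conditions: seven cohorts of sizes
## (75, 20, 5, 34, 23, 101, 11); with/without counts per clinical
## condition in the monosomy group of (25/24, 19/53, 24/28, 32/43, 16/36,
## 17/35, 14/33) with the remainder unknown; ~650 X-chromosome genes with
## variant data (a small number of them pseudoautosomal); population
## allele frequencies uniform on (0.05, 0.95) so the 0.1-0.9 common-
## variant window is exercised on both sides; and per-karyotype X-variant
## intensity proportional to the amount of X material (one X-copy
## equivalent for 45,X and 46,XY, two for 46,XX, intermediate for ring /
## complex / isochromosome karyotypes).

.default_group_sizes <- function() {
  c(TS_monosomy = 75L, TS_ring = 20L, TS_complex = 5L,
    TS_isochromosome = 34L, XX_control = 23L, XX_POI = 101L,
    XY_control = 11L)
}

.default_condition_counts <- function() {
  # with/without counts in the monosomy-X group; remainder unknown
  list(diabetes = c(25L, 24L), obesity = c(19L, 53L),
       autoimmunity = c(24L, 28L), hypothyroidism = c(32L, 43L),
       hypertension = c(16L, 36L), cca = c(17L, 35L),
       hearing_loss = c(14L, 33L))
}

.default_x_copies <- function() {
  c(TS_monosomy = 1, TS_ring = 1.3, TS_complex = 1.5,
    TS_isochromosome = 1.7, XX_control = 2, XX_POI = 2, XY_control = 1)
}

#' Simulation configuration
#'
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param group_sizes Named integer vector over [cohort_groups()]
#'   (defaults to the study cohort sizes; subsets are allowed, e.g. only
#'   `TS_monosomy` for burden simulation studies).
#' @param condition_counts Named list of `c(with, without)` counts for the
#'   monosomy group; other Turner groups are assigned proportionally
#'   scaled counts, control groups are left unknown.
#' @param n_x_genes Number of X-chromosome genes with variant data
#'   (default 650), of which `n_par_genes` are placed in PAR1/PAR2.
#' @param n_par_genes Number of pseudoautosomal genes (default 25).
#' @param n_auto_genes Number of autosomal genes (default 300).
#' @param variants_per_gene Common variants simulated per gene
#'   (default 2).
#' @param af_dist Function `n -> n` population allele frequencies
#'   (default uniform on (0.05, 0.95)).
#' @param planted_effects Optional data.frame with columns `gene`,
#'   `condition`, `delta`: the named gene's first variant gets its carrier
#'   probability shifted by `delta` in with-condition samples. Gene names
#'   are `XG0001 ... XG<n_x_genes>` (X) and `AG0001 ...` (autosomal).
#' @param x_copies Named numeric vector of X-copy equivalents per group,
#'   driving the per-karyotype X-variant intensity.
#' @param somatic_fraction Fraction of records drawn with a low VAF in
#'   (0, 0.3), emulating somatic-mosaic events (default 0.08).
#' @param depth_mu,depth_size Negative-binomial read-depth parameters
#'   (mean 60, size 6: substantial mass on both sides of 40x).
#' @param baf_noise_sd,lrr_noise_sd Marker noise for
#'   [simulate_baf_profile()] defaults.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              group_sizes = .default_group_sizes(),
                              condition_counts = .default_condition_counts(),
                              n_x_genes = 650L, n_par_genes = 25L,
                              n_auto_genes = 300L, variants_per_gene = 2L,
                              af_dist = function(n) runif(n, 0.05, 0.95),
                              planted_effects = NULL,
                              x_copies = .default_x_copies(),
                              somatic_fraction = 0.08,
                              depth_mu = 60, depth_size = 6,
                              baf_noise_sd = 0.03, lrr_noise_sd = 0.15) {
  # accept YAML-style nested lists as well as named vectors
  group_sizes <- unlist(group_sizes)
  x_copies <- unlist(x_copies)
  condition_counts <- lapply(condition_counts, unlist)
  if (is.list(planted_effects) && !is.data.frame(planted_effects))
    planted_effects <- as.data.frame(planted_effects,
                                     stringsAsFactors = FALSE)
  if (length(group_sizes) && is.null(names(group_sizes)))
    stop("group_sizes must be a named vector over cohort_groups()")
  stopifnot(all(names(group_sizes) %in% cohort_groups()),
            all(group_sizes >= 0), n_x_genes >= 1,
            n_par_genes >= 0, n_par_genes <= n_x_genes,
            n_auto_genes >= 0, variants_per_gene >= 1,
            somatic_fraction >= 0, somatic_fraction <= 1)
  for (cond in names(condition_counts)) {
    stopifnot(cond %in% phenotype_conditions(),
              length(condition_counts[[cond]]) == 2L)
  }
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("gene", "condition", "delta") %in%
                    names(planted_effects)))
    bad <- abs(planted_effects$delta) >= 0.9
    if (any(bad))
      stop("infeasible planted effect(s): ",
           paste(sprintf("%s/%s delta=%.2f",
                         planted_effects$gene[bad],
                         planted_effects$condition[bad],
                         planted_effects$delta[bad]), collapse = "; "))
  }
  structure(list(seed = as.integer(seed), group_sizes = group_sizes,
                 condition_counts = condition_counts,
                 n_x_genes = as.integer(n_x_genes),
                 n_par_genes = as.integer(n_par_genes),
                 n_auto_genes = as.integer(n_auto_genes),
                 variants_per_gene = as.integer(variants_per_gene),
                 af_dist = af_dist, planted_effects = planted_effects,
                 x_copies = x_copies, somatic_fraction = somatic_fraction,
                 depth_mu = depth_mu, depth_size = depth_size,
                 baf_noise_sd = baf_noise_sd, lrr_noise_sd = lrr_noise_sd),
            class = "simulation_config")
}

# deterministic phenotype allocation: exact counts in the monosomy group,
# proportionally scaled counts in the other TS groups, unknown in controls
.assign_phenotypes <- function(samples, cfg) {
  mono_n <- 75  # reference size the condition counts are expressed against
  for (cond in phenotype_conditions()) {
    cc <- cfg$condition_counts[[cond]]
    flag <- rep(NA_integer_, nrow(samples))
    for (g in unique(samples$group)) {
      idx <- which(samples$group == g)
      if (!g %in% c("TS_monosomy", "TS_ring", "TS_complex",
                    "TS_isochromosome") || is.null(cc)) next
      if (g == "TS_monosomy" && length(idx) == 75L) {
        n_with <- cc[1L]; n_without <- cc[2L]
      } else {
        n_with <- round(length(idx) * cc[1L] / mono_n)
        n_without <- round(length(idx) * cc[2L] / mono_n)
        if (n_with + n_without > length(idx))
          n_without <- length(idx) - n_with
      }
      v <- c(rep(1L, n_with), rep(0L, n_without),
             rep(NA_integer_, length(idx) - n_with - n_without))
      flag[idx] <- sample(v)
    }
    samples[[cond]] <- flag
  }
  samples
}

#' Simulate a synthetic cohort
#'
#' Generates sample metadata and a variant-record table with the
#' structure the burden analysis assumes. Per sample, condition flags
#' follow the configured with/without counts; per variant, carrier status
#' is Bernoulli with probability `1 - (1 - af)^xc` where `xc` is the
#' group's X-copy equivalent (autosomal loci use diploid `xc = 2` and
#' receive het/hom genotype classes), shifted by `delta` for planted
#' (gene, condition) pairs in with-condition samples. Germline VAFs sit
#' near 1 for hemizygous calls and near 0.5/1 for het/hom; a configured
#' fraction of records instead draws a low VAF in (0, 0.3) emulating
#' somatic mosaicism. Read depth is negative-binomial with mass on both
#' sides of the 40x somatic threshold. Output is deterministic given the
#' seed.
#'
#' @param cfg A [simulation_config()].
#' @return A `cohort_table`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)

  ## samples ----------------------------------------------------------------
  sizes <- cfg$group_sizes[cfg$group_sizes > 0]
  groups <- rep(names(sizes), times = sizes)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_along(groups)),
    group = groups, stringsAsFactors = FALSE)
  for (cond in phenotype_conditions()) samples[[cond]] <- NA_integer_
  samples <- .assign_phenotypes(samples, cfg)
  samples <- .validate_samples(samples)

  ## gene / variant scaffold ------------------------------------------------
  vpg <- cfg$variants_per_gene
  par <- par_regions()
  n_par1 <- min(cfg$n_par_genes, 20L); n_par2 <- cfg$n_par_genes - n_par1
  x_gene_pos <- c(
    if (n_par1) round(seq(par$start[1] + 5e4, par$end[1] - 5e4,
                          length.out = n_par1)),
    if (cfg$n_x_genes - cfg$n_par_genes > 0)
      round(seq(3e6, 155e6, length.out = cfg$n_x_genes - cfg$n_par_genes)),
    if (n_par2) round(seq(par$start[2] + 5e3, par$end[2] - 5e3,
                          length.out = n_par2)))
  x_gene_pos <- sort(x_gene_pos)
  genes <- data.frame(
    gene = c(sprintf("XG%04d", seq_len(cfg$n_x_genes)),
             if (cfg$n_auto_genes)
               sprintf("AG%04d", seq_len(cfg$n_auto_genes))),
    chrom = c(rep("X", cfg$n_x_genes),
              if (cfg$n_auto_genes)
                as.character(1 + (seq_len(cfg$n_auto_genes) - 1) %% 22)),
    gpos = c(x_gene_pos,
             if (cfg$n_auto_genes)
               round(seq(1e6, 2e8, length.out = cfg$n_auto_genes))),
    stringsAsFactors = FALSE)

  nv <- nrow(genes) * vpg
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  variants <- data.frame(
    gene = rep(genes$gene, each = vpg),
    chrom = rep(genes$chrom, each = vpg),
    pos = rep(genes$gpos, each = vpg) + rep(seq_len(vpg) * 97L, nrow(genes)),
    ref = ref, alt = alt,
    pop_af = cfg$af_dist(nv),
    consequence = sample(consequence_classes(), nv, replace = TRUE,
                         prob = c(0.45, 0.35, 0.04, 0.03, 0.02, 0.11)),
    stringsAsFactors = FALSE)

  ## planted effects: force a feasible, mid-window baseline frequency
  planted_idx <- integer(0); planted_delta <- numeric(0)
  planted_cond <- character(0)
  if (!is.null(cfg$planted_effects)) {
    pe <- cfg$planted_effects
    for (i in seq_len(nrow(pe))) {
      j <- which(variants$gene == pe$gene[i])[1L]
      if (is.na(j)) stop("planted gene not in scaffold: ", pe$gene[i])
      lo <- max(0.15, 0.05 - pe$delta[i]); hi <- min(0.85, 0.95 - pe$delta[i])
      if (lo >= hi) stop("infeasible planted effect: ", pe$gene[i])
      variants$pop_af[j] <- runif(1L, lo, min(hi, 0.5 + max(0, -pe$delta[i])))
      planted_idx <- c(planted_idx, j)
      planted_delta <- c(planted_delta, pe$delta[i])
      planted_cond <- c(planted_cond, pe$condition[i])
    }
  }

  ## carrier draws ----------------------------------------------------------
  ns <- nrow(samples)
  xc <- unname(cfg$x_copies[samples$group])
  is_x <- variants$chrom == "X"
  # carrier probability per (variant, sample): 1 - (1 - af)^copies
  copies <- matrix(rep(2, nv * ns), nv, ns)
  copies[is_x, ] <- matrix(xc, sum(is_x), ns, byrow = TRUE)
  p <- 1 - (1 - variants$pop_af)^copies
  for (k in seq_along(planted_idx)) {
    flag <- samples[[planted_cond[k]]]
    shift <- which(!is.na(flag) & flag == 1L)
    p[planted_idx[k], shift] <-
      pmin(1, pmax(0, p[planted_idx[k], shift] + planted_delta[k]))
  }
  hit <- which(matrix(runif(nv * ns), nv, ns) < p)
  vi <- ((hit - 1L) %% nv) + 1L          # variant index of each carrier call
  si <- ((hit - 1L) %/% nv) + 1L         # sample index
  # genotype class: diploid loci split carriers into het/hom by HWE;
  # single-copy-equivalent loci are hemizygous
  af_i <- variants$pop_af[vi]
  dip <- copies[hit] >= 2
  hom_p <- ifelse(dip, af_i^2 / (1 - (1 - af_i)^2), 0)
  geno <- ifelse(runif(length(hit)) < hom_p, "hom",
                 ifelse(dip, "het", "hem"))
  v <- data.frame(
    sample_id = samples$sample_id[si],
    chrom = variants$chrom[vi], pos = variants$pos[vi],
    ref = variants$ref[vi], alt = variants$alt[vi],
    gene = variants$gene[vi], consequence = variants$consequence[vi],
    genotype = geno, pop_af = af_i, stringsAsFactors = FALSE)

  ## per-record sequencing fields -------------------------------------------
  n <- nrow(v)
  v$depth <- rnbinom(n, mu = cfg$depth_mu, size = cfg$depth_size) + 1L
  germ_vaf <- ifelse(v$genotype == "het", rbeta(n, 50, 50), rbeta(n, 80, 4))
  somatic <- runif(n) < cfg$somatic_fraction
  v$vaf <- ifelse(somatic, runif(n, 0.005, 0.3), germ_vaf)
  # common germline calls at ~60x are high-confidence; the standard
  # filter's quality floor mainly guards pathological calls
  v$call_quality <- round(rgamma(n, shape = 16, scale = 3.125), 1)
  v <- v[.variant_cols]

  merge_cohort(v, samples, quiet = TRUE)
}

#' Simulate an SNP-array BAF/LRR profile
#'
#' Forward model for the mosaic-fraction estimators: markers are
#' heterozygous-informative with probability `het_fraction` (taking the
#' model's band position or its allele-relabelled mirror with equal
#' probability) and homozygous otherwise (BAF 0 or 1); Gaussian noise is
#' added and BAF truncated to \[0, 1\]; LRR sits at the mixture's expected
#' log2 ratio plus noise.
#'
#' @param model A [copy_mixture_model()] (its `f` is the simulated truth).
#' @param n_markers Number of markers.
#' @param het_fraction Fraction of informative markers.
#' @param baf_noise_sd,lrr_noise_sd Noise standard deviations.
#' @param seed Optional seed.
#' @param chrom,start,end Region the markers are placed on.
#' @return An `snp_profile` with the simulated region attached.
#' @export
simulate_baf_profile <- function(model, n_markers = 500L,
                                 het_fraction = 0.5, baf_noise_sd = 0.03,
                                 lrr_noise_sd = 0.15, seed = NULL,
                                 chrom = "X", start = 1L, end = 155000000L) {
  stopifnot(inherits(model, "copy_mixture_model"), n_markers >= 1)
  if (!is.null(seed)) set.seed(seed)
  eb <- expected_baf(model)
  el <- expected_lrr(model)
  het <- runif(n_markers) < het_fraction
  mirror <- runif(n_markers) < 0.5
  baf0 <- ifelse(het, ifelse(mirror, 1 - eb, eb),
                 ifelse(mirror, 1, 0))
  baf <- pmin(1, pmax(0, baf0 + rnorm(n_markers, 0, baf_noise_sd)))
  lrr <- el + rnorm(n_markers, 0, lrr_noise_sd)
  pos <- sort(sample.int(end - start + 1L, n_markers, replace = FALSE) +
                start - 1L)
  snp_profile(data.frame(chrom = chrom, pos = pos, baf = baf, lrr = lrr,
                         stringsAsFactors = FALSE),
              region = list(chrom = chrom, start = start, end = end))
}
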