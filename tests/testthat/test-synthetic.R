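# The synthetic cohort generator: determinism, study-structure defaults,
# planted effects and the array-profile forward model.

test_that("default configuration reproduces the study cohort structure", {
  co <- simulate_cohort(simulation_config(seed = 5))
  expect_equal(nrow(co$samples), 269L)
  tab <- table(factor(co$samples$group, levels = cohort_groups()))
  expect_equal(unname(as.integer(tab)), c(75L, 20L, 5L, 34L, 23L, 101L, 11L))
  # exact with/without counts in the monosomy group
  mono <- co$samples[co$samples$group == "TS_monosomy", ]
  expected <- list(diabetes = c(25L, 24L), obesity = c(19L, 53L),
                   autoimmunity = c(24L, 28L), hypothyroidism = c(32L, 43L),
                   hypertension = c(16L, 36L), cca = c(17L, 35L),
                   hearing_loss = c(14L, 33L))
  for (cond in names(expected)) {
    expect_equal(sum(mono[[cond]] == 1L, na.rm = TRUE), expected[[cond]][1])
    expect_equal(sum(mono[[cond]] == 0L, na.rm = TRUE), expected[[cond]][2])
  }
  # controls carry no phenotype labels
  ctrl <- co$samples[co$samples$group == "XX_control", ]
  expect_true(all(is.na(ctrl$diabetes)))
})

test_that("the same seed reproduces the cohort exactly and seeds differ", {
  cfg <- simulation_config(seed = 9, group_sizes = c(TS_monosomy = 30L),
                           n_x_genes = 60L, n_auto_genes = 10L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_cohort(simulation_config(seed = 10,
                                          group_sizes = c(TS_monosomy = 30L),
                                          n_x_genes = 60L,
                                          n_auto_genes = 10L))
  expect_false(identical(a$variants, c2$variants))
})

test_that("X-variant intensity tracks the amount of X material", {
  co <- simulate_cohort(simulation_config(seed = 12))
  cts <- count_by_consequence(co, "standard", quiet = TRUE)
  x <- cts[cts$chrom_class == "X", ]
  g <- co$samples$group[match(x$sample_id, co$samples$sample_id)]
  mu <- tapply(x$total, g, mean)
  expect_lt(mu[["TS_monosomy"]], mu[["TS_isochromosome"]])
  expect_lt(mu[["TS_isochromosome"]], mu[["XX_control"]])
  expect_lt(mu[["XY_control"]], mu[["TS_isochromosome"]])
  # monosomy and XY have the same single-X intensity
  expect_lt(abs(mu[["TS_monosomy"]] - mu[["XY_control"]]) /
              mu[["TS_monosomy"]], 0.15)
})

test_that("planted effects shift the empirical carrier-proportion difference", {
  deltas <- numeric(100)
  for (s in 1:100) {
    cfg <- simulation_config(
      seed = s, group_sizes = c(TS_monosomy = 75L), n_x_genes = 80L,
      n_auto_genes = 0L, variants_per_gene = 1L,
      planted_effects = data.frame(gene = "XG0007",
                                   condition = "hypertension",
                                   delta = 0.45))
    co <- simulate_cohort(cfg)
    groups <- phenotype_groups(co$samples, "hypertension")
    carriers <- unique(co$variants$sample_id[co$variants$gene == "XG0007"])
    deltas[s] <- mean(groups$with_ids %in% carriers) -
      mean(groups$without_ids %in% carriers)
  }
  expect_lt(abs(mean(deltas) - 0.45), 0.15)
})

test_that("infeasible planted deltas are rejected with the offending entry", {
  expect_error(simulation_config(
    planted_effects = data.frame(gene = "XG0001", condition = "diabetes",
                                 delta = 0.95)),
    "infeasible.*XG0001")
})

test_that("null burden p-values are uniform or super-uniform", {
  pooled <- c()
  for (s in 1:3) {
    co <- simulate_cohort(simulation_config(
      seed = 400 + s, group_sizes = c(TS_monosomy = 75L),
      n_x_genes = 200L, n_auto_genes = 0L, variants_per_gene = 1L))
    b <- run_burden(standard_filter(co), "hypertension", compute_or = FALSE)
    pooled <- c(pooled, b$p_fisher)
  }
  for (t in c(0.05, 0.1, 0.2, 0.5))
    expect_lte(mean(pooled <= t), t + 0.03)
})

test_that("simulated cohorts satisfy the cohort-table invariants", {
  co <- simulate_cohort(simulation_config(
    seed = 77, group_sizes = c(TS_monosomy = 20L, XX_control = 5L),
    n_x_genes = 40L, n_auto_genes = 10L))
  expect_s3_class(co, "cohort_table")  # constructor enforces the invariants
  expect_true(all(co$variants$sample_id %in% co$samples$sample_id))
  expect_true(all(co$variants$vaf >= 0 & co$variants$vaf <= 1))
  expect_true(all(co$variants$depth >= 0))
  # somatic-like fraction: some records fall inside the somatic VAF window
  expect_gt(mean(co$variants$vaf <= 0.3), 0.02)
})

test_that("the BAF profile forward model hits its noise-free anchors", {
  m0 <- copy_mixture_model(1, 0, 2, 1, 0)
  p0 <- simulate_baf_profile(m0, 100, baf_noise_sd = 0, seed = 1)
  expect_true(all(p0$markers$baf %in% c(0, 1)))
  m1 <- copy_mixture_model(1, 0, 2, 1, 1)
  p1 <- simulate_baf_profile(m1, 100, het_fraction = 1, baf_noise_sd = 0,
                             seed = 2)
  expect_true(all(p1$markers$baf == 0.5))
  # determinism
  pa <- simulate_baf_profile(m1, 50, seed = 3)
  pb <- simulate_baf_profile(m1, 50, seed = 3)
  expect_identical(pa$markers, pb$markers)
})
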