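# Hemizygous X-chromosome burden testing: the frequency window, carrier
# collapsing, and the end-to-end scan.

test_that("the common-variant window is inclusive and drops missing frequencies", {
  v <- variant_rec(sample_id = sprintf("S%d", 1:4), pos = 1:4,
                   pop_af = c(0.09, 0.10, 0.90, NA))
  kept <- suppressMessages(common_af_window(v))
  expect_equal(kept$pop_af, c(0.10, 0.90))
  expect_equal(attr(kept, "n_missing_af"), 1L)
  grid <- variant_rec(sample_id = sprintf("G%02d", 1:21), pos = 1:21,
                      pop_af = seq(0, 1, 0.05))
  expect_equal(common_af_window(grid, quiet = TRUE)$pop_af,
               grid$pop_af[grid$pop_af >= 0.1 & grid$pop_af <= 0.9])
})

test_that("gene-level carrier tables count unique individuals", {
  co <- carrier_cohort(10, 16, 5, 36)
  groups <- phenotype_groups(co$samples, "hypertension")
  tab <- gene_level_carriers(co$variants, groups, quiet = TRUE)
  expect_equal(unlist(tab[, c("a", "b", "c", "d")], use.names = FALSE),
               c(10L, 6L, 5L, 31L))
  # a sample carrying three variants in one gene still counts once
  extra <- rbind(hemi_recs("W001", "GENE1", pos = 5000100L),
                 hemi_recs("W001", "GENE1", pos = 5000200L))
  co2 <- cohort_table(rbind(co$variants, extra), co$samples)
  tab2 <- gene_level_carriers(co2$variants, groups, quiet = TRUE)
  expect_equal(tab2$a, 10L)
})

test_that("carrier tables equal a brute-force per-sample membership scan", {
  for (seed in c(21, 22, 23)) {
    co <- random_toy_cohort(seed)
    groups <- phenotype_groups(co$samples, "diabetes")
    v <- common_af_window(co$variants, quiet = TRUE)
    tab <- gene_level_carriers(v, groups, quiet = TRUE)
    for (i in seq_len(nrow(tab))) {
      gvar <- v[v$gene == tab$unit_id[i], ]
      a_bf <- sum(vapply(groups$with_ids,
                         function(s) s %in% gvar$sample_id, logical(1)))
      c_bf <- sum(vapply(groups$without_ids,
                         function(s) s %in% gvar$sample_id, logical(1)))
      expect_equal(tab$a[i], a_bf)
      expect_equal(tab$c[i], c_bf)
      expect_equal(tab$a[i] + tab$b[i], length(groups$with_ids))
      expect_equal(tab$c[i] + tab$d[i], length(groups$without_ids))
    }
    vt <- variant_level_carriers(v, groups)
    key <- sprintf("%s:%d:%s-%s", v$chrom, v$pos, v$ref, v$alt)
    for (i in seq_len(nrow(vt))) {
      carr <- unique(v$sample_id[key == vt$unit_id[i]])
      expect_equal(vt$a[i], length(intersect(carr, groups$with_ids)))
      expect_equal(vt$c[i], length(intersect(carr, groups$without_ids)))
    }
  }
})

test_that("variant-level proportions reproduce the pseudoautosomal splicing-gene example", {
  # carriers 18/24 with-condition vs 11/28 without -> 0.75 and 0.39
  ids_w <- sprintf("W%02d", 1:24); ids_o <- sprintf("O%02d", 1:28)
  s <- blank_samples(c(ids_w, ids_o))
  s$autoimmunity <- c(rep(1L, 24), rep(0L, 28))
  v <- rbind(hemi_recs(ids_w[1:18], "AKAP17A", pos = 1601004L, ref = "C",
                       alt = "G", pop_af = 0.54),
             hemi_recs(ids_o[1:11], "AKAP17A", pos = 1601004L, ref = "C",
                       alt = "G", pop_af = 0.54))
  b <- run_burden(cohort_table(v, s), "autoimmunity", level = "variant")
  expect_equal(b$unit_id, "X:1601004:C-G")
  expect_equal(round(b$prop_with, 2), 0.75)
  expect_equal(round(b$prop_without, 2), 0.39)
})

test_that("a variant present in no grouped sample is absent from the output", {
  co <- carrier_cohort(3, 5, 2, 6)
  ghost <- blank_samples("GHOST")
  s <- rbind(co$samples, ghost)  # sample with unknown phenotype
  v <- rbind(co$variants, hemi_recs("GHOST", "GENE9", pos = 7e6))
  b <- run_burden(cohort_table(v, s), "hypertension")
  expect_false("GENE9" %in% b$unit_id)
})

test_that("the scan composes its parts and honours its invariants", {
  co <- random_toy_cohort(31, n_samples = 20L, n_genes = 6L)
  b <- run_burden(co, "diabetes")
  groups <- phenotype_groups(co$samples, "diabetes")
  # stepwise pipeline: window -> carriers -> test -> adjust
  v <- co$variants[co$variants$chrom == "X", ]
  v <- common_af_window(v, quiet = TRUE)
  tabs <- gene_level_carriers(v, groups, quiet = TRUE)
  expect_equal(sort(b$unit_id), sort(tabs$unit_id))
  expect_equal(unique(b$m_tests), nrow(tabs))
  i <- match(b$unit_id[1], tabs$unit_id)
  expect_equal(b$p_fisher[1],
               fisher_exact_two_sided(tabs$a[i], tabs$b[i], tabs$c[i],
                                      tabs$d[i]))
  expect_equal(b$p_adj, bonferroni(b$p_fisher, nrow(tabs)))
  expect_equal(b$effect_size, b$prop_with - b$prop_without)
  expect_true(all(diff(abs(b$effect_size)) <= 1e-12))  # sorted by |effect|
  expect_true(all(b$p_adj >= b$p_fisher))
  defined <- is.finite(b$or_cmle) & b$or_cmle > 0 & abs(b$effect_size) > 1e-12
  expect_true(all((b$effect_size[defined] > 0) == (b$or_cmle[defined] > 1)))
})

test_that("flagging is strictly greater than the threshold", {
  # effect exactly 0.35: 17/20 vs 10/20
  co <- carrier_cohort(17, 20, 10, 20)
  b <- run_burden(co, "hypertension")
  expect_equal(round(b$effect_size, 10), 0.35)
  expect_equal(b$flag, "none")
  co2 <- carrier_cohort(18, 20, 10, 20)  # 0.40
  expect_equal(run_burden(co2, "hypertension")$flag, "risk")
})

test_that("samples with unknown phenotype are excluded, never imputed", {
  co <- carrier_cohort(4, 8, 2, 9)
  s <- co$samples
  s$hypertension[1] <- NA  # a with-condition carrier becomes unknown
  b <- run_burden(cohort_table(co$variants, s), "hypertension")
  expect_equal(attr(b, "n_with"), 7L)
  expect_equal(b$a, 3L)
})

test_that("region restriction keeps only pseudoautosomal variants when asked", {
  ids <- sprintf("S%02d", 1:12)
  s <- blank_samples(ids)
  s$diabetes <- rep(c(1L, 0L), 6)
  v <- rbind(hemi_recs(ids[1:5], "PARG1", pos = 500000L),     # PAR1
             hemi_recs(ids[2:7], "NONPAR", pos = 50000000L))  # X proper
  b <- run_burden(cohort_table(v, s), "diabetes", region = par_regions())
  expect_equal(b$unit_id, "PARG1")
  expect_equal(unique(b$m_tests), 1L)
})

test_that("multi-karyotype analysis sets widen the denominator", {
  ids_m <- sprintf("M%02d", 1:6); ids_r <- sprintf("R%02d", 1:6)
  s <- rbind(blank_samples(ids_m, "TS_monosomy"),
             blank_samples(ids_r, "TS_ring"))
  s$cca <- rep(c(1L, 0L), 6)
  v <- hemi_recs(c(ids_m[1:3], ids_r[1:3]), "PARG1", pos = 500000L)
  b_mono <- run_burden(cohort_table(v, s), "cca")
  b_wide <- run_burden(cohort_table(v, s), "cca",
                       karyotypes = c("TS_monosomy", "TS_ring"))
  expect_equal(attr(b_mono, "n_with") + attr(b_mono, "n_without"), 6L)
  expect_equal(attr(b_wide, "n_with") + attr(b_wide, "n_without"), 12L)
})

test_that("an empty analysis set is fatal", {
  co <- carrier_cohort(3, 5, 2, 6, condition = "hypertension")
  expect_error(run_burden(co, "obesity"), "empty analysis set")
})
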