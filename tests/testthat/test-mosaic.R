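# Copy-number mixture model, BAF/LRR mosaic-fraction estimation, and the
# paired signed-rank comparison.

test_that("expected BAF follows the mixture formula", {
  expect_equal(expected_baf(copy_mixture_model(1, 0, 2, 1, f = 1)), 0.5)
  expect_equal(expected_baf(copy_mixture_model(1, 0, 2, 1, f = 0)), 0)
  expect_equal(expected_baf(copy_mixture_model(1, 0, 2, 1, f = 0.5)), 1 / 3)
  # oracle: simulate allele copies cell by cell at f = 0.5
  set.seed(8)
  line2 <- runif(2e5) < 0.5
  baf_sim <- sum(ifelse(line2, 1, 0)) / sum(ifelse(line2, 2, 1))
  expect_equal(baf_sim, 1 / 3, tolerance = 0.01)
  expect_error(copy_mixture_model(1, 1, 1, 1, 0.3), "non-informative")
})

test_that("expected BAF is monotone in f and symmetric under allele relabelling", {
  fs <- seq(0, 1, 0.05)
  b <- vapply(fs, function(f)
    expected_baf(copy_mixture_model(1, 0, 2, 1, f)), numeric(1))
  expect_true(all(diff(b) > 0))
  for (f in c(0.2, 0.5, 0.8)) {
    m <- copy_mixture_model(1, 0, 3, 2, f)
    m_rel <- copy_mixture_model(1, 1, 3, 1, f)  # a -> c - a on both lines
    expect_equal(expected_baf(m_rel), 1 - expected_baf(m))
  }
})

test_that("expected LRR encodes the mixture copy number", {
  expect_equal(expected_lrr(copy_mixture_model(1, 0, 2, 1, f = 1)), 0)
  expect_equal(expected_lrr(copy_mixture_model(1, 0, 2, 1, f = 0)), -1)
})

test_that("noise-free profiles give the trivial estimates", {
  m0 <- copy_mixture_model(1, 0, 2, 1, f = 0)
  p0 <- simulate_baf_profile(m0, 200, baf_noise_sd = 0, lrr_noise_sd = 0,
                             seed = 1)
  expect_true(all(p0$markers$baf %in% c(0, 1)))
  e0 <- estimate_fraction_from_baf(p0, "ring")
  expect_equal(e0$f_hat, 0)
  expect_equal(e0$flag, "no heterozygous band")

  m1 <- copy_mixture_model(1, 0, 2, 1, f = 1)
  p1 <- simulate_baf_profile(m1, 200, baf_noise_sd = 0, lrr_noise_sd = 0,
                             seed = 2)
  e1 <- estimate_fraction_from_baf(p1, "ring")
  expect_equal(e1$f_hat, 1)
  expect_true(0.5 %in% e1$band_positions)
})

test_that("BAF estimation recovers a simulated ring fraction", {
  prof <- simulate_baf_profile(copy_mixture_model(1, 0, 2, 1, 0.4), 500,
                               baf_noise_sd = 0.03, seed = 33)
  est <- estimate_fraction_from_baf(prof, "ring")
  expect_lt(abs(est$f_hat - 0.4), 0.03)
  expect_equal(sort(est$band_positions), sort(c(est$band_positions)))
  # allele-relabel symmetry: flipping every BAF leaves the estimate unchanged
  flipped <- prof
  flipped$markers$baf <- 1 - flipped$markers$baf
  est_f <- estimate_fraction_from_baf(flipped, "ring")
  expect_equal(est_f$f_hat, est$f_hat)
})

test_that("the isochromosome preset resolves the folded-band ambiguity via LRR", {
  for (f in c(0.3, 0.7)) {
    prof <- simulate_baf_profile(copy_mixture_model(1, 0, 3, 2, f), 800,
                                 baf_noise_sd = 0.02, lrr_noise_sd = 0.1,
                                 seed = round(100 * f))
    est <- estimate_mosaic_fraction(prof, "isoXq")
    expect_lt(abs(est$f_hat - f), 0.05)
  }
})

test_that("LRR estimation inverts the intensity ratio", {
  mk <- function(lrr) snp_profile(data.frame(
    chrom = "X", pos = 1:50, baf = 0.5, lrr = lrr))
  expect_equal(estimate_fraction_from_lrr(mk(rep(0, 50)), 1, 2)$f_hat, 1)
  expect_equal(estimate_fraction_from_lrr(mk(rep(-1, 50)), 1, 2)$f_hat, 0)
  prof <- simulate_baf_profile(copy_mixture_model(1, 0, 2, 1, 0.6), 500,
                               lrr_noise_sd = 0.15, seed = 44)
  expect_lt(abs(estimate_fraction_from_lrr(prof, 1, 2)$f_hat - 0.6), 0.05)
  expect_error(estimate_fraction_from_lrr(mk(rep(0, 50)), 2, 2), "differ")
})

test_that("estimators demand a minimum marker count", {
  small <- snp_profile(data.frame(chrom = "X", pos = 1:10, baf = 0.3,
                                  lrr = 0))
  expect_error(estimate_fraction_from_baf(small, "ring"), "fewer than")
  expect_error(estimate_fraction_from_lrr(small, 1, 2), "fewer than")
})

test_that("round-trip recovery holds across the mosaic-fraction range", {
  for (f in c(0.2, 0.5, 0.8)) {
    prof <- simulate_baf_profile(copy_mixture_model(1, 0, 2, 1, f), 500,
                                 baf_noise_sd = 0.03,
                                 seed = 500 + round(10 * f))
    expect_lt(abs(estimate_fraction_from_baf(prof, "ring")$f_hat - f), 0.03)
  }
})

test_that("paired signed-rank test matches a full sign-enumeration oracle", {
  enum_oracle <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
  }
  set.seed(71)
  for (i in 1:6) {
    n <- sample(6:12, 1)
    x <- round(rnorm(n), 3); y <- round(rnorm(n) + 0.4, 3)
    if (any(duplicated(abs(y - x))) || any(y == x)) next
    res <- paired_signed_rank(x, y)
    expect_equal(res$p.value, enum_oracle(y - x), tolerance = 1e-12)
    expect_equal(res$method, "exact")
  }
})

test_that("identical vectors are degenerate and shifts are detected", {
  x <- c(0.2, 0.3, 0.5, 0.7, 0.9)
  res <- paired_signed_rank(x, x)
  expect_equal(res$p.value, 1)
  expect_equal(res$n_nonzero, 0L)
  # consistent downward shift in the second measurement, n = 40
  set.seed(72)
  detected <- 0L
  for (i in 1:100) {
    orig <- runif(40, 0.2, 0.9)
    new <- pmax(0, orig - 0.15 + rnorm(40, 0, 0.05))
    if (paired_signed_rank(orig, new)$p.value < 0.001) detected <- detected + 1L
  }
  expect_gte(detected / 100, 0.95)
})
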