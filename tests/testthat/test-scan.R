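test_that("scan LOD matches the explicit least-squares oracle", {
  ap <- scan_fixture()
  y <- c(10.2, 14.1, 8.3, 12.7, 11.9)
  lm_ <- tibble::tibble(line = ap$lines, mean = y)
  scan <- genome_scan(lm_, ap)
  for (g in 1:3) {
    expect_equal(
      scan$lod[g],
      oracle_lod(y, cbind(1, ap$probs[, , g])),
      tolerance = 1e-10
    )
  }
  expect_equal(attr(scan, "n"), 5)
})

test_that("LOD is invariant under affine phenotype transforms", {
  ap <- scan_fixture()
  y <- c(10.2, 14.1, 8.3, 12.7, 11.9)
  s1 <- genome_scan(tibble::tibble(line = ap$lines, mean = y), ap)
  s2 <- genome_scan(tibble::tibble(line = ap$lines, mean = -3.7 * y + 100), ap)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-10)
})

test_that("variance explained obeys the LOD identity and the R-squared increment", {
  ap <- scan_fixture()
  y <- c(10.2, 14.1, 8.3, 12.7, 11.9)
  scan <- genome_scan(tibble::tibble(line = ap$lines, mean = y), ap)
  expect_equal(scan$varexp, 1 - 10^(-2 * scan$lod / 5), tolerance = 1e-12)
  # identity with the full-over-null R2 increment at each position
  for (g in 1:3) {
    fit <- lm(y ~ ap$probs[, , g])
    expect_equal(scan$varexp[g], summary(fit)$r.squared, tolerance = 1e-10)
  }
})

test_that("a perfectly predictive position is guarded and still ranks first", {
  ap <- scan_fixture()
  y_exact <- 7 * ap$probs[, 1, 1] + 2 # noise-free signal at position 1
  s <- genome_scan(tibble::tibble(line = ap$lines, mean = y_exact), ap)
  expect_true(all(is.finite(s$lod)))
  expect_equal(which.max(s$lod), 1L)
  # constant phenotype: LOD defined as zero everywhere
  s0 <- genome_scan(tibble::tibble(line = ap$lines, mean = rep(3, 5)), ap)
  expect_equal(s0$lod, rep(0, 3))
})

test_that("a covariate equal to the fitted values absorbs the signal", {
  ap <- scan_fixture()
  y <- c(10.2, 14.1, 8.3, 12.7, 11.9)
  fitted1 <- fitted(lm(y ~ ap$probs[, , 1]))
  s <- genome_scan(
    tibble::tibble(line = ap$lines, mean = y), ap,
    covariates = tibble::tibble(line = ap$lines, f = fitted1)
  )
  expect_lt(s$lod[1], 1e-8)
})

test_that("permutation thresholds are deterministic and hit quantile edges", {
  sim <- quick_sim(60, seed = 41)
  ph <- simulate_phenotypes(sim, NULL, sim_config(seed = 42))
  lm_ <- line_means(ph)
  ap <- true_additive(sim, grid_step = 2)
  p1 <- permutation_threshold(lm_, ap, n_perm = 30, seed = 7)
  p2 <- permutation_threshold(lm_, ap, n_perm = 30, seed = 7)
  expect_identical(p1$threshold, p2$threshold)
  pa <- permutation_threshold(lm_, ap, n_perm = 30, alpha = 1, seed = 7)
  expect_equal(pa$threshold, min(pa$max_lod))
  expect_warning(permutation_threshold(lm_, ap, n_perm = 10, seed = 1),
    "unstable")
})

test_that("peak calling recovers a triangular profile and merges overlaps", {
  # triangular LOD peaking at 10 around cm 25
  cm <- seq(0, 50, by = 1)
  lod <- pmax(10 - abs(cm - 25) * 0.8, 0)
  scan <- structure(
    tibble::tibble(chrom = "1", cm = cm, bp = cm * 1e5 + 1,
      lod = lod, varexp = 0),
    class = c("qtl_scan", class(tibble::tibble()))
  )
  pk <- peaks_and_intervals(scan, threshold = 5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_cm, 25)
  # interval = region with LOD > 8, closed at grid points
  expect_equal(pk$ci_lo_cm, 23)
  expect_equal(pk$ci_hi_cm, 27)

  # two peaks with overlapping 2-LOD intervals merge to the higher one
  lod2 <- pmax(10 - abs(cm - 25) * 0.4, 9 - abs(cm - 30) * 0.4, 0)
  scan$lod <- lod2
  pk2 <- peaks_and_intervals(scan, threshold = 5)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$peak_cm, 25)
  # nothing above threshold: empty result
  expect_equal(nrow(peaks_and_intervals(scan, threshold = 50)), 0)
})

test_that("founder means at a strong QTL rank-correlate with injected effects", {
  sim <- quick_sim(300, seed = 51)
  eff <- c(0, 5, 10, 15, 20, 25, 30, 35)
  ph <- simulate_phenotypes(sim, qtl_spec("2", 25, effects = list(eff)),
    sim_config(line_sd = 14, seed = 52))
  lm_ <- line_means(ph)
  hc <- ancestry_at(sim$mosaics, "2", 25) # truth = ideal confident calls
  fe <- founder_effects(lm_, hc)
  j <- dplyr::inner_join(fe,
    tibble::tibble(founder = sim$panel$founders, eff = eff), by = "founder")
  expect_gte(stats::cor(j$mean, j$eff, method = "spearman"), 0.9)

  # reporting rule: founders with fewer than 5 lines are suppressed
  fe2 <- founder_effects(lm_[1:12, ], hc[lm_$line[1:12]])
  expect_true(all(!fe2$reported[fe2$n < 5]))
  expect_true(all(fe2$reported[fe2$n >= 5]))
  expect_warning(
    founder_effects(lm_, setNames(rep(NA_character_, nrow(lm_)), lm_$line)),
    "confident"
  )
})

test_that("interval intersection and gene counting follow closed-bound rules", {
  a <- tibble::tibble(chrom = "2R", ci_lo_bp = 8.21e6, ci_hi_bp = 8.49e6)
  b <- tibble::tibble(chrom = "2R", ci_lo_bp = 8.43e6, ci_hi_bp = 8.74e6)
  ov <- cross_panel_overlap(a, b)
  expect_equal(ov$width_kb, 60, tolerance = 1e-9)
  expect_null(cross_panel_overlap(a,
    tibble::tibble(chrom = "3R", ci_lo_bp = 8.43e6, ci_hi_bp = 8.74e6)))
  expect_null(cross_panel_overlap(a,
    tibble::tibble(chrom = "2R", ci_lo_bp = 9e6, ci_hi_bp = 9.5e6)))

  set.seed(61)
  starts <- sort(sample.int(1e6, 100))
  ann <- tibble::tibble(chrom = "2R", start = starts, end = starts + 5000,
    gene = sprintf("g%03d", 1:100), protein_coding = TRUE)
  lo <- starts[20]; hi <- starts[56] # covers genes 20..56 by direct enumeration
  direct <- sum(ann$start <= hi & ann$end >= lo)
  expect_equal(count_genes(ann, "2R", lo, hi)$n, direct)
  # gene starting exactly at the interval end is counted (inclusive bounds)
  expect_equal(count_genes(ann, "2R", starts[10] - 1, starts[10])$n,
    sum(ann$start <= starts[10] & ann$end >= starts[10] - 1))
  # non-coding genes are excluded; empty annotation counts zero
  ann$protein_coding[20] <- FALSE
  expect_equal(count_genes(ann, "2R", lo, hi)$n, direct - 1)
  expect_equal(count_genes(ann[0, ], "2R", lo, hi)$n, 0)
})

test_that("LOD is invariant to permutation of founder probability columns", {
  ap <- scan_fixture()
  y <- c(10.2, 14.1, 8.3, 12.7, 11.9)
  perm <- c(3, 1, 2)
  ap2 <- ap
  ap2$probs <- ap$probs[, perm, ]
  s1 <- genome_scan(tibble::tibble(line = ap$lines, mean = y), ap)
  s2 <- genome_scan(tibble::tibble(line = ap$lines, mean = y), ap2)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-10)
})
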