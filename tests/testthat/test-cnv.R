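test_that("CNV imputation propagates founder genotypes through hard calls", {
  founder_cnv <- c(A1 = 0L, A2 = 0L, A3 = 0L, A4 = 0L, A5 = 0L, A6 = 0L,
    A7 = 1L, AB8 = 1L)
  calls <- tibble::tibble(
    line = c("r1", "r2", "r3", "r4"),
    founder = c("A7", "A2", NA, "AB8")
  )
  st <- impute_ril_cnv(calls, founder_cnv)
  expect_equal(st$status, c(1L, 0L, NA_integer_, 1L))
  expect_error(
    impute_ril_cnv(tibble::tibble(line = "x", founder = "Z9"), founder_cnv),
    "Z9"
  )
  # NA fraction equals the fraction of sub-threshold hard calls
  expect_equal(mean(is.na(st$status)), mean(is.na(calls$founder)))
})

test_that("imputed status matches simulation truth at every confident call", {
  map <- sim_marker_map(chrom = "2", length_cm = 40, length_bp = 1.6e7,
    spacing_cm = 0.4)
  sim <- simulate_panel(60, map, breakpoint_rate = 0.15, error_rate = 0,
    seed = 81)
  dup <- c("A2", "A5", "A7", "AB8")
  founder_cnv <- setNames(as.integer(sim$panel$founders %in% dup),
    sim$panel$founders)
  ap <- infer_additive(sim$markers, sim$panel,
    hmm_params(error_rate = 0.005, recomb_scale = 0.15), grid_step = 1)
  locus <- which.min(abs(ap$map$cm - 20))
  hc <- tibble::tibble(line = ap$lines,
    founder = hard_call(ap$probs[, , locus]))
  st <- impute_ril_cnv(hc, founder_cnv)
  truth_f <- ancestry_at(sim$mosaics, "2", ap$map$cm[locus])
  truth <- as.integer(truth_f[st$line] %in% dup)
  conf <- !is.na(st$status)
  expect_gt(sum(conf), 0)
  expect_equal(st$status[conf], truth[conf])
})

test_that("a purely CNV-driven peak is removed by adjustment while others persist", {
  map <- sim_marker_map(chrom = c("2", "3"), length_cm = c(50, 50),
    length_bp = c(2e7, 2e7), spacing_cm = 0.5)
  sim <- simulate_panel(400, map, seed = 82)
  dup <- c("A1", "A4", "A6", "AB8")
  q <- qtl_spec(
    "3", 25, effects = list(c(6, 6, 6, 6, -6, -6, -6, -6)),
    cnv = list(chrom = "2", cm = 25, dup_founders = dup, effect = 14)
  )
  ph <- simulate_phenotypes(sim, q, sim_config(seed = 83))
  lm_ <- line_means(ph)
  ap <- true_additive(sim, grid_step = 1)
  thr <- permutation_threshold(lm_, ap, n_perm = 100, seed = 84)$threshold

  scan0 <- genome_scan(lm_, ap)
  pk0 <- peaks_and_intervals(scan0, thr)
  expect_true(any(pk0$chrom == "2" & abs(pk0$peak_cm - 25) < 10))
  expect_true(any(pk0$chrom == "3" & abs(pk0$peak_cm - 25) < 10))

  truth_f <- ancestry_at(sim$mosaics, "2", 25)
  status <- tibble::tibble(line = lm_$line,
    status = as.integer(truth_f[lm_$line] %in% dup))
  scan1 <- covariate_adjusted_scan(lm_, ap, status)
  cnv_region <- scan1$chrom == "2" & abs(scan1$cm - 25) < 5
  expect_lt(max(scan1$lod[cnv_region]), thr)
  pk1 <- peaks_and_intervals(scan1, thr)
  expect_true(any(pk1$chrom == "3" & abs(pk1$peak_cm - 25) < 10))

  # NA lines are dropped and the reduced n reported
  status_na <- status
  status_na$status[1:50] <- NA
  scan2 <- covariate_adjusted_scan(lm_, ap, status_na)
  expect_equal(attr(scan2, "n"), attr(scan0, "n") - 50)

  # constant covariate: adjusted scan equals the unadjusted scan
  scan3 <- covariate_adjusted_scan(lm_, ap,
    dplyr::mutate(status, status = 1L))
  expect_equal(scan3$lod, scan0$lod, tolerance = 1e-10)
})

test_that("LOD is invariant to affine recoding of the CNV covariate", {
  sim <- quick_sim(120, seed = 85)
  dup <- c("A3", "A5")
  q <- qtl_spec(character(), numeric(), list(),
    cnv = list(chrom = "2", cm = 30, dup_founders = dup, effect = 8))
  ph <- simulate_phenotypes(sim, q, sim_config(seed = 86))
  lm_ <- line_means(ph)
  ap <- true_additive(sim, grid_step = 1)
  truth_f <- ancestry_at(sim$mosaics, "2", 30)
  st01 <- tibble::tibble(line = lm_$line,
    status = as.integer(truth_f[lm_$line] %in% dup))
  s01 <- covariate_adjusted_scan(lm_, ap, st01)
  centered <- dplyr::mutate(st01, status = status - mean(status))
  s_c <- genome_scan(lm_, ap,
    covariates = dplyr::transmute(centered, line, cnv = status))
  expect_equal(s01$lod, s_c$lod, tolerance = 1e-9)
})

test_that("the line-level CNV effect test reproduces the summary-statistic Welch form", {
  lm_ <- tibble::tibble(line = sprintf("L%03d", 1:151),
    mean = c(rnorm(119, 57.6, 20.88), rnorm(32, 65.4, 20.67)))
  st <- tibble::tibble(line = lm_$line, status = rep(c(0L, 1L), c(119, 32)))
  res <- cnv_effect_test(lm_, st)
  g <- res$groups
  ref <- welch_from_summary(g$mean[g$status == 0], g$sd[g$status == 0],
    g$n[g$status == 0], g$mean[g$status == 1], g$sd[g$status == 1],
    g$n[g$status == 1])
  expect_equal(res$test$p, ref$p, tolerance = 1e-12)
  expect_error(
    cnv_effect_test(lm_, dplyr::mutate(st, status = 0L)),
    "empty"
  )
})

test_that("a simulated duplication effect is detected with high power", {
  hits <- 0
  for (r in 1:5) {
    sim <- quick_sim(800, seed = 90 + r)
    dup <- c("A2", "A7", "AB8")
    q <- qtl_spec(character(), numeric(), list(),
      cnv = list(chrom = "2", cm = 25, dup_founders = dup, effect = 8))
    ph <- simulate_phenotypes(sim, q, sim_config(seed = 190 + r))
    lm_ <- line_means(ph)
    truth_f <- ancestry_at(sim$mosaics, "2", 25)
    st <- tibble::tibble(line = lm_$line,
      status = as.integer(truth_f[lm_$line] %in% dup))
    hits <- hits + (cnv_effect_test(lm_, st)$test$p < 1e-4)
  }
  expect_gte(hits, 4)
})
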