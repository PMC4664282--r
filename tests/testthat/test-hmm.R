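test_that("the diplotype state space has k(k+1)/2 unordered states", {
  expect_equal(nrow(diplotype_states(8)), 36)
  expect_equal(nrow(diplotype_states(2)), 3)
  expect_equal(nrow(diplotype_states(3)), 6)
  s <- diplotype_states(c("A1", "A2", "A3"))
  expect_true(all(s$f1 <= s$f2))
  expect_error(diplotype_states(0), "at least one")
})

test_that("forward-backward equals exhaustive path enumeration on small fixtures", {
  fixtures <- list(
    list(cm = c(0, 1), alleles = cbind(c(0, 1), c(1, 0)),
      obs = c(0, 1), eps = 0.05, scale = 0.3),
    list(cm = c(0, 2, 3), alleles = cbind(c(0, 1, 0), c(1, 0, 0), c(1, 1, 1)),
      obs = c(0, 1, NA), eps = 0.05, scale = 0.2),
    list(cm = c(0, 0.5, 2, 4),
      alleles = cbind(c(0, 1, 0, 1), c(1, 0, 0, 1), c(0, 0, 1, 1)),
      obs = c(0, 0, 1, 1), eps = 0.1, scale = 0.5),
    list(cm = c(0, 1, 2, 3),
      alleles = cbind(c(0, 0, 0, 0), c(1, 1, 1, 1), c(0, 1, 0, 1)),
      obs = c(1, NA, 0, 1), eps = 0.01, scale = 0.15)
  )
  for (fx in fixtures) {
    panel <- toy_panel(fx$cm, fx$alleles)
    params <- hmm_params(error_rate = fx$eps, recomb_scale = fx$scale)
    dec <- posterior_decode(fx$obs, panel, params)
    oracle <- oracle_posterior(fx$obs, panel, params)
    expect_lt(max(abs(dec$posterior - oracle)), 1e-10)
    expect_equal(rowSums(dec$posterior), rep(1, nrow(oracle)), tolerance = 1e-9)
  }
})

test_that("an uninformative marker returns the prior", {
  panel <- toy_panel(0, matrix(c(1, 1, 1), 1)) # all founders share the allele
  dec <- posterior_decode(1, panel, hmm_params(error_rate = 0.05))
  expect_equal(unname(dec$posterior[1, ]), rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("a founder-private allele run with zero error pins the posterior", {
  # founder 1 carries a private allele at every marker
  alleles <- cbind(rep(1, 5), rep(0, 5), rep(0, 5))
  panel <- toy_panel(seq(0, 4), alleles)
  dec <- posterior_decode(rep(1, 5), panel, hmm_params(error_rate = 1e-12))
  hom1 <- which(dec$states$f1 == 1 & dec$states$f2 == 1)
  expect_true(all(dec$posterior[dec$map$observed, hom1] > 1 - 1e-6))
})

test_that("additive collapse matches its direct summation formula", {
  states <- diplotype_states(8)
  p <- rep(0, 36); p[which(states$f1 == 1 & states$f2 == 1)] <- 1
  expect_equal(unname(collapse_additive(p)), c(1, rep(0, 7)))
  p <- rep(0, 36); p[which(states$f1 == 1 & states$f2 == 2)] <- 1
  expect_equal(unname(collapse_additive(p)), c(0.5, 0.5, rep(0, 6)))

  set.seed(1)
  for (i in 1:10) {
    p <- runif(36); p <- p / sum(p)
    # direct summation: homozygous mass + half of every het state touching f
    direct <- vapply(1:8, function(f) {
      het <- states$f1 != states$f2 & (states$f1 == f | states$f2 == f)
      sum(p[states$f1 == f & states$f2 == f]) + 0.5 * sum(p[het])
    }, numeric(1))
    expect_equal(unname(collapse_additive(p)), direct, tolerance = 1e-12)
    expect_equal(sum(collapse_additive(p)), 1, tolerance = 1e-12)
  }
  expect_error(collapse_additive(rep(0.1, 36)), "sum to 1")
})

test_that("hard calls honour the confident-call threshold", {
  a <- c(A1 = 0.01, A2 = 0.97, A3 = 0.02)
  expect_equal(hard_call(a), "A2")
  a <- c(A1 = 0.03, A2 = 0.94, A3 = 0.03)
  expect_true(is.na(hard_call(a))) # 0.94 is not > 0.95
  expect_true(is.na(hard_call(rep(1 / 8, 8))))
  expect_error(hard_call(a, threshold = 0.4), "0.5")
})

test_that("hard calls match true ancestry on a dense synthetic panel", {
  map <- sim_marker_map(chrom = "2", length_cm = 40, length_bp = 1.6e7,
    spacing_cm = 0.5)
  sim <- simulate_panel(25, map, breakpoint_rate = 0.15, error_rate = 0.003,
    seed = 31)
  params <- hmm_params(error_rate = 0.005, recomb_scale = 0.15)
  correct <- 0L; called <- 0L
  for (i in seq_len(10)) {
    dec <- posterior_decode(sim$markers[i, ], sim$panel, params)
    hc <- hard_call(dec)
    truth <- vapply(dec$map$cm, function(x) {
      ancestry_at(sim$mosaics, "2", x)[[sim$lines$ril[i]]]
    }, character(1))
    called <- called + sum(!is.na(hc))
    correct <- correct + sum(hc == truth, na.rm = TRUE)
  }
  expect_gt(called, 0)
  expect_gte(correct / called, 0.98)
})

test_that("posterior mass on the true state does not decrease as error shrinks", {
  alleles <- cbind(c(1, 1, 0, 1), c(0, 0, 1, 0), c(0, 1, 1, 1))
  panel <- toy_panel(c(0, 1, 2, 3), alleles)
  obs <- alleles[, 1] # noise-free observation of founder 1
  hom1 <- which(diplotype_states(3)$f1 == 1 & diplotype_states(3)$f2 == 1)
  mass <- vapply(c(0.2, 0.1, 0.05, 0.01, 0.001), function(eps) {
    mean(posterior_decode(obs, panel, hmm_params(error_rate = eps))$posterior[, hom1])
  }, numeric(1))
  expect_true(all(diff(mass) >= -1e-12))
})

test_that("homozygous-only mode agrees with the mosaic truth and runs faster state spaces", {
  map <- sim_marker_map(chrom = "2", length_cm = 20, length_bp = 8e6,
    spacing_cm = 0.5)
  sim <- simulate_panel(5, map, error_rate = 0, seed = 8)
  dec <- posterior_decode(sim$markers[1, ], sim$panel,
    hmm_params(error_rate = 0.001, homozygous_only = TRUE))
  expect_equal(ncol(dec$posterior), 8)
  expect_equal(rowSums(dec$posterior), rep(1, nrow(dec$map)), tolerance = 1e-9)
  hc <- hard_call(dec)
  truth <- vapply(dec$map$cm, function(x) {
    ancestry_at(sim$mosaics, "2", x)[[sim$lines$ril[1]]]
  }, character(1))
  expect_gte(mean(hc == truth, na.rm = TRUE), 0.95)
})

test_that("grid evaluation interleaves unobserved positions exactly", {
  map <- sim_marker_map(chrom = "2", length_cm = 10, length_bp = 4e6,
    spacing_cm = 1)
  sim <- simulate_panel(3, map, error_rate = 0, seed = 12)
  ap <- infer_additive(sim$markers, sim$panel,
    hmm_params(error_rate = 0.001), grid_step = 0.5)
  expect_equal(dim(ap$probs), c(3, 8, 21))
  sums <- apply(ap$probs, c(1, 3), sum)
  expect_equal(unname(sums), matrix(1, 3, 21), tolerance = 1e-9)
})
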