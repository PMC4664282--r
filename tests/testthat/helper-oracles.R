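# Independent oracles and tiny fixture builders shared across tests.

# A hand-built founder panel on a single chromosome: marker positions in cM,
# founder alleles given column-wise.
toy_panel <- function(cm, alleles, chrom = "2L", panel = "pT") {
  map <- tibble::tibble(chrom = chrom, cm = cm,
    bp = as.integer(round(1 + cm * 1e5)))
  founder_panel(map, alleles, panel = panel)
}

# Brute-force diplotype posterior by exhaustive enumeration over all ordered
# pairs of founder haplotype paths (single chromosome). Kept deliberately
# independent of the forward-backward implementation: joint probabilities
# are accumulated path by path.
oracle_posterior <- function(markers, panel, params) {
  k <- length(panel$founders)
  M <- nrow(panel$map)
  states <- diplotype_states(panel$founders)
  S <- nrow(states)
  prior <- params$prior
  if (is.null(prior)) prior <- rep(1 / S, S)
  # ordered-pair initial probabilities: heterozygous state mass split over
  # its two orderings
  prior_ord <- matrix(0, k, k)
  for (s in seq_len(S)) {
    a <- states$f1[s]; b <- states$f2[s]
    if (a == b) prior_ord[a, a] <- prior[s] else {
      prior_ord[a, b] <- prior[s] / 2
      prior_ord[b, a] <- prior[s] / 2
    }
  }
  d <- diff(panel$map$cm)
  trans <- lapply(d, function(dd) {
    r <- 1 - exp(-params$recomb_scale * dd)
    m <- matrix(r / (k - 1), k, k); diag(m) <- 1 - r; m
  })
  eps <- params$error_rate
  agree <- function(f, m) {
    if (is.na(markers[m])) 1 else if (panel$alleles[m, f] == markers[m]) 1 - eps else eps
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), M)))
  post <- matrix(0, M, S)
  state_of <- matrix(0L, k, k)
  for (s in seq_len(S)) {
    state_of[states$f1[s], states$f2[s]] <- s
    state_of[states$f2[s], states$f1[s]] <- s
  }
  for (i in seq_len(nrow(paths))) {
    for (j in seq_len(nrow(paths))) {
      p1 <- paths[i, ]; p2 <- paths[j, ]
      w <- prior_ord[p1[1], p2[1]]
      if (w == 0) next
      for (m in seq_len(M)) {
        w <- w * agree(p1[m], m) * agree(p2[m], m)
        if (m < M) w <- w * trans[[m]][p1[m], p1[m + 1]] * trans[[m]][p2[m], p2[m + 1]]
      }
      for (m in seq_len(M)) {
        s <- state_of[p1[m], p2[m]]
        post[m, s] <- post[m, s] + w
      }
    }
  }
  post / rowSums(post)
}

# Least-squares LOD oracle: explicit normal-equations solution with a
# pseudoinverse (rank-deficient designs allowed).
oracle_lod <- function(y, X, X0 = matrix(1, length(y))) {
  rss <- function(x) {
    xtx <- crossprod(x)
    beta <- MASS::ginv(xtx) %*% crossprod(x, y)
    sum((y - x %*% beta)^2)
  }
  (length(y) / 2) * log10(rss(X0) / rss(X))
}

# Small single-chromosome panel simulation used by several scan tests.
quick_sim <- function(n_rils, length_cm = 50, seed = 1, ...) {
  simulate_panel(
    n_rils,
    sim_marker_map(chrom = "2", length_cm = length_cm,
      length_bp = length_cm * 4e5, spacing_cm = 0.5),
    seed = seed, ...
  )
}

# Hand-built 5-line, 3-founder additive-probability fixture on 3 positions.
scan_fixture <- function() {
  probs <- array(0, dim = c(5, 3, 3))
  probs[, , 1] <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.5, 0.5, 0), c(0.2, 0.3, 0.5))
  probs[, , 2] <- rbind(
    c(0.9, 0.1, 0), c(0.1, 0.8, 0.1), c(0, 0.2, 0.8), c(0.4, 0.4, 0.2),
    c(1 / 3, 1 / 3, 1 / 3))
  probs[, , 3] <- rbind(
    c(0, 1, 0), c(0, 1, 0), c(1, 0, 0), c(0, 0, 1), c(0.5, 0, 0.5))
  lines <- paste0("L", 1:5)
  dimnames(probs) <- list(lines, paste0("F", 1:3), NULL)
  mppscan:::additive_probs_(
    tibble::tibble(chrom = "1", cm = c(0, 5, 10), bp = c(1, 5e5, 1e6)),
    probs, lines, paste0("F", 1:3)
  )
}

published_qtl <- function() {
  readr::read_tsv(system.file("extdata", "qtl_summary_table.tsv",
    package = "mppscan"), show_col_types = FALSE)
}
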