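# Shared machinery: match line means to an additive-probability object,
# optionally with per-line covariates, and precompute per-position
# orthonormal bases so that scans (and phenotype permutations) reduce to
# cross-products. The design at each position contains an intercept, any
# covariates, and the k additive probabilities; since the probabilities sum
# to one the design is rank-deficient, which the rank-revealing QR absorbs
# (the residual sum of squares depends only on the column space, so the fit
# is invariant to which redundant direction is dropped).
scan_prepare_ <- function(line_means, probs, covariates = NULL) {
  if (!inherits(probs, "additive_probs")) {
    abort("`probs` must be an `additive_probs` object.")
  }
  if (!all(c("line", "mean") %in% names(line_means))) {
    abort("`line_means` needs columns `line` and `mean`.")
  }
  dat <- tibble(line = probs$lines) |>
    dplyr::inner_join(line_means[, c("line", "mean")], by = "line")
  covnames <- character()
  if (!is.null(covariates)) {
    if (!"line" %in% names(covariates)) abort("`covariates` needs a `line` column.")
    dat <- dplyr::left_join(dat, covariates, by = "line")
    covnames <- setdiff(names(covariates), "line")
    dat <- dat[stats::complete.cases(dat[covnames]), ]
  }
  if (nrow(dat) == 0) abort("No lines shared between phenotypes and probabilities.")
  keep <- match(dat$line, probs$lines)
  n <- nrow(dat)
  covmat <- if (length(covnames)) as.matrix(dat[covnames]) else NULL
  x0 <- cbind(`(Intercept)` = rep(1, n), covmat)
  if (n <= ncol(x0) + 1L) abort("Fewer lines than model parameters.")
  G <- dim(probs$probs)[3]
  q0 <- qr_basis_(x0)
  qs <- lapply(seq_len(G), function(g) {
    qr_basis_(cbind(x0, probs$probs[keep, , g]))
  })
  list(y = dat$mean, lines = dat$line, n = n, map = probs$map,
    q0 = q0, qs = qs, covnames = covnames)
}

qr_basis_ <- function(x) {
  qx <- qr(x)
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}

# LOD matrix (positions x phenotype-columns) for a phenotype matrix Y.
scan_lod_ <- function(prep, Y) {
  Y <- as.matrix(Y)
  n <- prep$n
  tot <- colSums(Y^2)
  rss0 <- pmax(tot - colSums(crossprod(prep$q0, Y)^2), 0)
  lod <- matrix(0, length(prep$qs), ncol(Y))
  for (g in seq_along(prep$qs)) {
    rss1 <- pmax(tot - colSums(crossprod(prep$qs[[g]], Y)^2), 0)
    ok <- rss0 > n * .Machine$double.eps * pmax(tot, 1)
    l <- numeric(ncol(Y))
    l[ok] <- (n / 2) * log10(rss0[ok] / pmax(rss1[ok], .Machine$double.eps * rss0[ok]))
    lod[g, ] <- pmax(l, 0)
  }
  lod
}

#' Haplotype-regression genome scan
#'
#' At every evaluation position, regresses the line-mean phenotype on the k
#' additive founder probabilities (plus any covariates) and contrasts that
#' fit against the null model of intercept + covariates alone:
#' `LOD = (n/2) * log10(RSS_null / RSS_full)`. The variance explained at a
#' position follows the identity `VE = 1 - 10^(-2*LOD/n)`. Lines with a
#' missing covariate are dropped and the reduced n reported.
#'
#' @param line_means Tibble with columns `line` and `mean` (e.g. from
#'   [line_means()] or [summarize_lines()]).
#' @param probs An `additive_probs` object ([infer_additive()] or
#'   [true_additive()]).
#' @param covariates Optional tibble: `line` plus one or more numeric
#'   covariate columns (e.g. CNV status, subpopulation indicator).
#' @return A tibble of class `qtl_scan`: `chrom`, `cm`, `bp`, `lod`,
#'   `varexp`, with attributes `n` (lines used) and `covariates`.
#' @export
genome_scan <- function(line_means, probs, covariates = NULL) {
  prep <- scan_prepare_(line_means, probs, covariates)
  lod <- scan_lod_(prep, matrix(prep$y, ncol = 1))[, 1]
  out <- dplyr::mutate(prep$map,
    lod = lod, varexp = 1 - 10^(-2 * lod / prep$n)
  )
  structure(out,
    class = c("qtl_scan", class(tibble())),
    n = prep$n,
    covariates = if (length(prep$covnames)) prep$covnames else "none"
  )
}

#' Genomewide significance threshold by phenotype permutation
#'
#' Permutes the line-mean phenotype across lines (genotypes and covariates
#' fixed), rescans the genome for each permutation with one shared
#' permutation across all positions (preserving the linkage structure of
#' the null), and takes the empirical `1 - alpha` quantile of the
#' per-permutation genomewide maximum LOD.
#'
#' @inheritParams genome_scan
#' @param n_perm Number of permutations (the conventional choice is 1,000).
#' @param alpha Genomewide significance level.
#' @param seed Optional integer seed for the permutation stream.
#' @return A `perm_null` object: list with `max_lod` (one genomewide max
#'   per permutation), `threshold`, `alpha`, `n_perm`, `seed`.
#' @export
permutation_threshold <- function(line_means, probs, covariates = NULL,
                                  n_perm = 1000, alpha = 0.05, seed = NULL) {
  stopifnot_scalar_prob(alpha, "alpha", 0, 1)
  if (n_perm < 20) warn("Fewer than 20 permutations: the threshold quantile is unstable.")
  prep <- scan_prepare_(line_means, probs, covariates)
  with_seed_(seed, {
    Y <- vapply(seq_len(n_perm), function(j) prep$y[sample.int(prep$n)],
      numeric(prep$n))
    max_lod <- apply(scan_lod_(prep, Y), 2, max)
    structure(
      list(max_lod = max_lod,
        threshold = unname(quantile(max_lod, 1 - alpha)),
        alpha = alpha, n_perm = n_perm, seed = seed),
      class = "perm_null"
    )
  })
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "<perm_null> %d permutations: genomewide %g%% threshold LOD = %.3f\n",
    x$n_perm, 100 * x$alpha, x$threshold
  ))
  invisible(x)
}

#' @export
#' @method tidy perm_null
tidy.perm_null <- function(x, ...) {
  tibble(permutation = seq_along(x$max_lod), max_lod = x$max_lod)
}

#' @export
#' @method glance perm_null
glance.perm_null <- function(x, ...) {
  tibble(n_perm = x$n_perm, alpha = x$alpha, threshold = x$threshold)
}

#' Call QTL peaks and 2-LOD support intervals
#'
#' Finds, per chromosome, local maxima exceeding the significance
#' threshold. Each peak's support interval is the contiguous run of
#' positions around it with LOD within 2 units of the peak; peaks whose
#' intervals overlap are merged, keeping the higher peak. At flat peaks the
#' leftmost maximal position is reported; intervals are closed.
#'
#' @param scan A `qtl_scan` tibble.
#' @param threshold LOD threshold (e.g. from [permutation_threshold()]).
#' @param drop Support-interval drop in LOD units (default 2).
#' @return Tibble of peaks: `chrom`, `peak_cm`, `peak_bp`, `lod`,
#'   `ci_lo_cm`, `ci_hi_cm`, `ci_lo_bp`, `ci_hi_bp`. Empty when nothing
#'   exceeds the threshold.
#' @export
peaks_and_intervals <- function(scan, threshold, drop = 2) {
  thr <- if (inherits(threshold, "perm_null")) threshold$threshold else threshold
  res <- purrr::map_dfr(unique(scan$chrom), function(ch) {
    s <- scan[scan$chrom == ch, ]
    lod <- s$lod
    peaks <- list()
    # local maxima above threshold (leftmost position of any flat run)
    is_max <- vapply(seq_along(lod), function(i) {
      left <- if (i > 1) lod[i - 1] else -Inf
      right <- if (i < length(lod)) lod[i + 1] else -Inf
      lod[i] > thr && lod[i] >= right && lod[i] > left
    }, logical(1))
    if (length(lod) > 0 && lod[1] > thr &&
      (length(lod) == 1 || lod[1] >= lod[2])) is_max[1] <- TRUE
    for (i in which(is_max)) {
      lo <- i; while (lo > 1 && lod[lo - 1] > lod[i] - drop) lo <- lo - 1
      hi <- i; while (hi < length(lod) && lod[hi + 1] > lod[i] - drop) hi <- hi + 1
      peaks[[length(peaks) + 1]] <- tibble(
        chrom = ch, peak_cm = s$cm[i], peak_bp = s$bp[i], lod = lod[i],
        ci_lo_cm = s$cm[lo], ci_hi_cm = s$cm[hi],
        ci_lo_bp = s$bp[lo], ci_hi_bp = s$bp[hi]
      )
    }
    pk <- dplyr::bind_rows(peaks)
    if (nrow(pk) <= 1) return(pk)
    # merge overlapping support intervals, keeping the higher peak
    pk <- pk[order(-pk$lod), ]
    kept <- pk[1, ]
    for (r in seq_len(nrow(pk))[-1]) {
      ov <- kept$ci_lo_cm <= pk$ci_hi_cm[r] & kept$ci_hi_cm >= pk$ci_lo_cm[r]
      if (!any(ov)) kept <- dplyr::bind_rows(kept, pk[r, ])
    }
    dplyr::arrange(kept, .data$peak_cm)
  })
  res
}

#' Variance explained and percent of heritability for a QTL
#'
#' Converts a LOD score from an n-line haplotype regression into the
#' fraction of line-mean phenotypic variance the locus explains,
#' `VE = 1 - 10^(-2*LOD/n)`, and expresses it as a percentage of the
#' broad-sense heritability of the line means.
#'
#' @param lod LOD score(s), non-negative.
#' @param n Number of lines in the scan.
#' @param h2_mean Broad-sense heritability of the line means, in (0, 1].
#' @return Tibble with columns `varexp` and `pct_h2`.
#' @examples
#' variance_explained_pct(27.2, 853, 0.95) # pct_h2 ~ 14.4
#' @export
variance_explained_pct <- function(lod, n, h2_mean) {
  if (any(lod < 0)) abort("`lod` must be non-negative.")
  if (n < 2) abort("`n` must be at least 2.")
  stopifnot_scalar_prob(h2_mean, "h2_mean", 1e-12, 1)
  ve <- 1 - 10^(-2 * lod / n)
  tibble(varexp = ve, pct_h2 = 100 * ve / h2_mean)
}
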