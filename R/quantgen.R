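#' Variance components and broad-sense heritability
#'
#' Decomposes per-fly phenotypes into among-line (genetic) and within-line
#' (environmental) variance with a one-way random-effects model, fitted by
#' REML (\pkg{lme4}) or by method-of-moments on the one-way ANOVA expected
#' mean squares with the unbalanced-design correction
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)`. The per-observation broad-sense
#' heritability is `sG2 / (sG2 + sE2)`. For the heritability of line means
#' two conventions are available: shrinking the environmental term by the
#' average replication (`sG2 / (sG2 + sE2/nbar)`, the default) or dividing
#' the genetic component by the observed variance of the line means
#' (`line_h2 = "var_line_means"`); the two differ slightly under unbalanced
#' replication.
#'
#' @param phenotypes Per-fly tibble with `Genotype` and
#'   `CaffeineResistance` columns (the standard phenotype layout), or any
#'   tibble via `line_col`/`value_col`.
#' @param method `"reml"` (default) or `"moments"`.
#' @param line_h2 `"replication"` (default) or `"var_line_means"`.
#' @param line_col,value_col Column names holding the line label and the
#'   trait value.
#' @return A `variance_components` list: `sigma_g2`, `sigma_e2`, `nbar`,
#'   `n_lines`, `h2_obs`, `h2_line`, `method`.
#' @export
variance_components_h2 <- function(phenotypes, method = c("reml", "moments"),
                                   line_h2 = c("replication", "var_line_means"),
                                   line_col = "Genotype",
                                   value_col = "CaffeineResistance") {
  method <- match.arg(method)
  line_h2 <- match.arg(line_h2)
  line <- factor(phenotypes[[line_col]])
  y <- phenotypes[[value_col]]
  ni <- table(line)
  if (length(ni) < 2) abort("Need at least two lines.")
  if (sum(ni >= 2) < 2) {
    abort("Within-line variance is unidentifiable: need at least two lines with two or more replicates.")
  }
  N <- length(y); a <- length(ni)

  if (method == "reml") {
    fit <- lme4::lmer(y ~ 1 + (1 | line), REML = TRUE,
      data = data.frame(y = y, line = line))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sg2 <- vc$vcov[vc$grp == "line"]
    se2 <- vc$vcov[vc$grp == "Residual"]
  } else {
    gm <- mean(y)
    mi <- tapply(y, line, mean)
    ssa <- sum(ni * (mi - gm)^2)
    ssw <- sum((y - mi[line])^2)
    msa <- ssa / (a - 1)
    msw <- ssw / (N - a)
    n0 <- (N - sum(ni^2) / N) / (a - 1)
    sg2 <- max((msa - msw) / n0, 0)
    se2 <- msw
  }

  nbar <- mean(ni)
  h2_obs <- sg2 / (sg2 + se2)
  h2_line <- if (line_h2 == "replication") {
    sg2 / (sg2 + se2 / nbar)
  } else {
    min(sg2 / var(tapply(y, line, mean)), 1)
  }
  structure(
    list(sigma_g2 = sg2, sigma_e2 = se2, nbar = nbar, n_lines = a,
      h2_obs = h2_obs, h2_line = h2_line, method = method),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> (%s) sG2 = %.3f, sE2 = %.3f (%d lines, nbar = %.1f)\n  H2 of observations = %.3f, H2 of line means = %.3f\n",
    x$method, x$sigma_g2, x$sigma_e2, x$n_lines, x$nbar, x$h2_obs, x$h2_line
  ))
  invisible(x)
}

#' @export
#' @method tidy variance_components
tidy.variance_components <- function(x, ...) {
  tibble(
    component = c("among_line", "within_line"),
    variance = c(x$sigma_g2, x$sigma_e2)
  )
}

#' @export
#' @method glance variance_components
glance.variance_components <- function(x, ...) {
  tibble(h2_obs = x$h2_obs, h2_line = x$h2_line, nbar = x$nbar,
    n_lines = x$n_lines)
}

#' Heritability of line means from the per-observation ratio
#'
#' Pure accounting helper: with per-observation heritability `h2` and an
#' average of `nbar` replicates per line, line means carry heritability
#' `h2 / (h2 + (1 - h2)/nbar)`.
#'
#' @param h2 Per-observation broad-sense heritability, in (0, 1].
#' @param nbar Average replicates per line.
#' @return Heritability of the line means.
#' @examples
#' h2_of_line_means(0.53, 16.5) # ~0.95
#' @export
h2_of_line_means <- function(h2, nbar) {
  stopifnot_scalar_prob(h2, "h2", 1e-12, 1)
  if (nbar < 1) abort("`nbar` must be at least 1.")
  h2 / (h2 + (1 - h2) / nbar)
}

#' Welch's t-test from summary statistics
#'
#' Two-sample mean comparison without assuming equal variances, computed
#' from group means, SDs and sizes:
#' `t = (m2 - m1) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return Tibble `t`, `df`, `p`.
#' @examples
#' welch_from_summary(57.6, 20.88, 119, 65.4, 20.67, 32) # p ~ 0.065
#' @export
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) abort("Both groups need at least 2 observations.")
  if (s1 < 0 || s2 < 0) abort("SDs must be non-negative.")
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) return(tibble(t = 0, df = n1 + n2 - 2, p = 1))
    abort("Both SDs are zero but the means differ: no sampling variance to test against.")
  }
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m2 - m1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Power of a line-based single-variant association test
#'
#' Power of the 1-df association test of a biallelic site against line
#' means, for a site explaining a fraction `r2` of the among-line variance,
#' via the noncentral distribution with noncentrality
#' `lambda = n * r2 / (1 - r2)`. The default uses the finite-sample
#' noncentral-F form (df2 = n - 2); `method = "chisq"` gives the
#' large-sample chi-square limit. With `polymorphic_adjust = TRUE` the MAF
#' enters through binomial genotype-count sampling: power is averaged over
#' the probability that the site is actually polymorphic among the sampled
#' lines (elsewhere the MAF is absorbed into `r2`).
#'
#' @param n_lines Number of lines.
#' @param r2 Fraction of among-line variance explained by the site, (0, 1).
#' @param alpha Significance level.
#' @param maf Minor allele frequency, (0, 0.5].
#' @param method `"f"` (default) or `"chisq"`.
#' @param polymorphic_adjust Multiply by the probability the site
#'   segregates in the sample (default FALSE).
#' @return Power (probability of detection).
#' @examples
#' assoc_power(158, r2 = 0.10, alpha = 2e-4) # ~0.62-0.65
#' @export
assoc_power <- function(n_lines, r2, alpha, maf = 0.4,
                        method = c("f", "chisq"),
                        polymorphic_adjust = FALSE) {
  method <- match.arg(method)
  if (maf <= 0 || maf > 0.5) abort("`maf` must be in (0, 0.5].")
  if (r2 <= 0 || r2 >= 1) abort("`r2` must be in (0, 1).")
  stopifnot_scalar_prob(alpha, "alpha", 1e-300, 1)
  if (alpha == 1) return(1)
  lambda <- n_lines * r2 / (1 - r2)
  pow <- if (method == "f") {
    df2 <- n_lines - 2
    1 - pf(qf(1 - alpha, 1, df2), 1, df2, ncp = lambda)
  } else {
    1 - pchisq(qchisq(1 - alpha, 1), 1, ncp = lambda)
  }
  if (polymorphic_adjust) {
    p_mono <- maf^n_lines + (1 - maf)^n_lines
    pow <- pow * (1 - p_mono)
  }
  pow
}
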