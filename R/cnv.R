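#' Impute RIL copy-number status from founder genotypes
#'
#' Propagates founder duplication genotypes (0 = single copy, 1 =
#' duplicated) to RILs through the haplotype mosaic: a RIL confidently
#' assigned founder f at the CNV locus (hard call at the 0.95 threshold)
#' inherits f's duplication status; RILs without a confident call are NA.
#'
#' @param hard_calls Tibble `line`, `founder` (NA where unassigned), or a
#'   named character vector, from [hard_call()] at the CNV locus.
#' @param founder_cnv Named 0/1 vector of founder duplication genotypes.
#' @return Tibble `line`, `status` (integer 0/1/NA).
#' @export
impute_ril_cnv <- function(hard_calls, founder_cnv) {
  if (!is.data.frame(hard_calls)) {
    hard_calls <- tibble(line = names(hard_calls), founder = unname(hard_calls))
  }
  called <- unique(hard_calls$founder[!is.na(hard_calls$founder)])
  missing <- setdiff(called, names(founder_cnv))
  if (length(missing)) {
    abort(paste0("Founder(s) without a CNV genotype: ",
      paste(missing, collapse = ", ")))
  }
  if (!all(founder_cnv %in% c(0L, 1L))) abort("`founder_cnv` must be coded 0/1.")
  tibble(
    line = hard_calls$line,
    status = ifelse(is.na(hard_calls$founder), NA_integer_,
      as.integer(founder_cnv[hard_calls$founder]))
  )
}

#' Test the phenotypic effect of a CNV across lines
#'
#' Compares line-mean phenotypes of duplicated (status 1) against
#' single-copy (status 0) lines with Welch's t-test; NA-status lines are
#' dropped.
#'
#' @param line_means Tibble `line`, `mean`.
#' @param status Tibble `line`, `status` from [impute_ril_cnv()].
#' @return List of class `cnv_test` with `groups` (per-status mean/SD/n)
#'   and `test` (tibble `t`, `df`, `p`).
#' @export
cnv_effect_test <- function(line_means, status) {
  dat <- dplyr::inner_join(line_means, status, by = "line") |>
    dplyr::filter(!is.na(.data$status))
  groups <- dat |>
    dplyr::group_by(.data$status) |>
    dplyr::summarise(sd = sd(.data$mean), mean = mean(.data$mean),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::select("status", "mean", "sd", "n")
  if (!all(c(0L, 1L) %in% groups$status)) {
    abort("One CNV status group is empty; need both single-copy and duplicated lines.")
  }
  g0 <- groups[groups$status == 0L, ]
  g1 <- groups[groups$status == 1L, ]
  structure(
    list(groups = groups,
      test = welch_from_summary(g0$mean, g0$sd, g0$n, g1$mean, g1$sd, g1$n)),
    class = "cnv_test"
  )
}

#' @export
print.cnv_test <- function(x, ...) {
  cat(sprintf(
    "<cnv_test> single-copy %.1f (n=%d) vs duplicated %.1f (n=%d): t = %.2f, p = %.3g\n",
    x$groups$mean[x$groups$status == 0], x$groups$n[x$groups$status == 0],
    x$groups$mean[x$groups$status == 1], x$groups$n[x$groups$status == 1],
    x$test$t, x$test$p
  ))
  invisible(x)
}

#' Genome scan adjusted for CNV status
#'
#' Reruns [genome_scan()] with the CNV status as a covariate, restricted to
#' the lines whose status is confidently known (NA-status lines are dropped
#' from both the null and the full model, and the reduced n is recorded on
#' the result). A QTL whose effect is entirely mediated by the CNV
#' disappears from the adjusted scan; independent QTL persist.
#'
#' @inheritParams genome_scan
#' @param status Tibble `line`, `status` (0/1/NA) from [impute_ril_cnv()].
#' @return A `qtl_scan` tibble (attribute `n` reflects the confident
#'   subset).
#' @export
covariate_adjusted_scan <- function(line_means, probs, status) {
  st <- dplyr::filter(status, !is.na(.data$status))
  if (nrow(st) < 3) abort("Too few lines with known CNV status.")
  genome_scan(
    dplyr::semi_join(line_means, st, by = "line"),
    probs,
    covariates = dplyr::transmute(st, line = .data$line,
      cnv = as.numeric(.data$status))
  )
}
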