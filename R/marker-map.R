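#' Build a synthetic marker map
#'
#' Creates a marker map covering one or more chromosomes, with evenly spaced
#' markers on the genetic (cM) scale and physical positions (bp) assigned at
#' a constant bp-per-cM expansion within each chromosome. The default genome
#' mimics a compact fly-like genome: three chromosomes totalling ~280 cM and
#' ~120 Mb.
#'
#' @param chrom Character vector of chromosome labels.
#' @param length_cm Numeric vector, genetic length of each chromosome (cM).
#' @param length_bp Numeric vector, physical length of each chromosome (bp).
#' @param spacing_cm Marker spacing in cM (single value, applied everywhere).
#' @return A tibble with columns `chrom`, `cm`, `bp`, one row per marker.
#'   Genetic positions are non-decreasing and physical positions strictly
#'   increasing within each chromosome.
#' @examples
#' sim_marker_map(chrom = "2L", length_cm = 55, length_bp = 23e6)
#' @export
sim_marker_map <- function(chrom = c("X", "2", "3"),
                           length_cm = c(66, 107, 110),
                           length_bp = c(22.4e6, 44.8e6, 52.3e6),
                           spacing_cm = 0.5) {
  if (length(chrom) == 0) abort("`chrom` must name at least one chromosome.")
  if (length(length_cm) != length(chrom) || length(length_bp) != length(chrom)) {
    abort("`length_cm` and `length_bp` must match `chrom` in length.")
  }
  if (spacing_cm <= 0) abort("`spacing_cm` must be positive.")
  purrr::pmap_dfr(
    list(chrom, length_cm, length_bp),
    function(ch, lcm, lbp) {
      cm <- seq(0, lcm, by = spacing_cm)
      tibble(chrom = ch, cm = cm, bp = as.integer(round(1 + cm / lcm * (lbp - 1))))
    }
  )
}

validate_marker_map <- function(map) {
  req <- c("chrom", "cm", "bp")
  if (!all(req %in% names(map))) {
    abort("A marker map needs columns `chrom`, `cm`, `bp`.")
  }
  if (nrow(map) == 0) abort("Marker map is empty.")
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      ok = all(diff(.data$cm) >= 0) && all(diff(.data$bp) > 0) &&
        !anyDuplicated(.data$bp) && all(.data$bp > 0) && all(.data$cm >= 0),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Marker map violates ordering/uniqueness on chromosome(s): ",
      paste(bad$chrom, collapse = ", ")
    ))
  }
  invisible(map)
}

# Monotone linear interpolation between the genetic and physical scales of
# one chromosome of a marker map (rule = 2: clamped at the chromosome ends).
cm_to_bp <- function(map, chrom, cm) {
  m <- map[map$chrom == chrom, ]
  if (nrow(m) == 0) abort(sprintf("Chromosome '%s' not in marker map.", chrom))
  if (nrow(m) == 1) return(rep(m$bp, length(cm)))
  approx(m$cm, m$bp, xout = cm, rule = 2, ties = "ordered")$y
}

bp_to_cm <- function(map, chrom, bp) {
  m <- map[map$chrom == chrom, ]
  if (nrow(m) == 0) abort(sprintf("Chromosome '%s' not in marker map.", chrom))
  if (nrow(m) == 1) return(rep(m$cm, length(bp)))
  approx(m$bp, m$cm, xout = bp, rule = 2, ties = "ordered")$y
}
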