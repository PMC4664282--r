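#' Founder panel container
#'
#' Bundles a marker map with the founder allele matrix for one mapping panel.
#' A panel has `k` founders (8 in the DSPR-like default); markers are
#' biallelic with alleles coded 0/1. Markers at which all founders carry the
#' same allele are retained but flagged uninformative.
#'
#' @param map Marker map tibble (`chrom`, `cm`, `bp`).
#' @param alleles Integer matrix, markers x founders, entries in \{0, 1\}.
#' @param founders Character vector of founder labels (columns of `alleles`).
#' @param panel Panel label, e.g. `"pA"`.
#' @return An object of class `founder_panel`.
#' @export
founder_panel <- function(map, alleles, founders = colnames(alleles), panel = "pA") {
  validate_marker_map(map)
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != nrow(map)) {
    abort("`alleles` must have one row per marker in `map`.")
  }
  if (!all(alleles %in% c(0L, 1L))) abort("Founder alleles must be coded 0/1.")
  if (is.null(founders)) founders <- paste0("F", seq_len(ncol(alleles)))
  colnames(alleles) <- founders
  structure(
    list(
      map = dplyr::mutate(as_tibble(map),
        informative = apply(alleles, 1, function(a) length(unique(a)) > 1L)
      ),
      alleles = alleles,
      founders = founders,
      panel = panel
    ),
    class = "founder_panel"
  )
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf(
    "<founder_panel> %s: %d founders, %d markers on %d chromosome(s)\n",
    x$panel, length(x$founders), nrow(x$map), length(unique(x$map$chrom))
  ))
  invisible(x)
}

default_founder_labels <- function(panel) {
  prefix <- if (identical(panel, "pB")) "B" else "A"
  c(paste0(prefix, 1:7), "AB8")
}

#' Simulate a multiparent RIL panel
#'
#' Generates a complete synthetic mapping panel: random biallelic founder
#' haplotypes, mosaic RIL genomes, and observed RIL marker calls. RILs are
#' fully inbred, so each genome is a single mosaic of founder segments.
#' Ancestry breakpoints are laid down as a Poisson process on the genetic
#' map (`breakpoint_rate` expected breakpoints per cM), with each switch
#' moving to one of the other founders uniformly; this emulates the dense
#' mosaic structure that many generations of intercrossing produce, without
#' simulating the pedigree itself. Observed marker calls equal the ancestral
#' founder's allele, flipped independently with probability `error_rate`.
#'
#' @param n_rils Number of RILs to simulate.
#' @param map Marker map tibble; defaults to [sim_marker_map()].
#' @param breakpoint_rate Expected ancestry breakpoints per cM (>= 0).
#'   The default 0.15/cM gives mean segment lengths of ~6.7 cM, a dense,
#'   DSPR-like mosaic.
#' @param error_rate Per-marker genotyping error probability.
#' @param panel Panel label (`"pA"` or `"pB"`); founder labels follow the
#'   A1..A7/B1..B7 + shared AB8 convention.
#' @param n_founders Number of founders (default 8).
#' @param n_subpop Number of replicate subpopulations RILs are assigned to.
#' @param seed Optional integer seed; when given the simulation is fully
#'   reproducible and the caller's RNG state is untouched.
#' @return A list of class `panel_sim` with elements `panel`
#'   ([founder_panel]), `mosaics` (tibble of ancestry segments: `ril`,
#'   `chrom`, `founder`, `start_cm`, `end_cm`, `start_bp`, `end_bp`),
#'   `lines` (tibble `ril`, `panel`, `subpop`), and `markers` (RIL x marker
#'   matrix of observed 0/1 calls).
#' @examples
#' sim <- simulate_panel(20, sim_marker_map("2L", 50, 2e7), seed = 1)
#' head(sim$mosaics)
#' @export
simulate_panel <- function(n_rils, map = sim_marker_map(),
                           breakpoint_rate = 0.15, error_rate = 0.005,
                           panel = "pA", n_founders = 8, n_subpop = 2,
                           seed = NULL) {
  if (n_rils < 1) abort("`n_rils` must be at least 1.")
  if (breakpoint_rate < 0) abort("`breakpoint_rate` must be non-negative.")
  stopifnot_scalar_prob(error_rate, "error_rate")
  validate_marker_map(map)

  with_seed_(seed, {
    founders <- if (n_founders == 8) default_founder_labels(panel) else
      paste0(substr(panel, 2, 2), seq_len(n_founders))
    alleles <- matrix(rbinom(nrow(map) * n_founders, 1L, 0.5),
      nrow = nrow(map), dimnames = list(NULL, founders)
    )
    fp <- founder_panel(map, alleles, founders, panel)

    rils <- sprintf("%s_%04d", panel, seq_len(n_rils))
    chroms <- unique(map$chrom)
    spans <- lapply(chroms, function(ch) range(map$cm[map$chrom == ch]))
    names(spans) <- chroms

    seg_list <- vector("list", n_rils * length(chroms))
    k <- 0L
    nf <- length(founders)
    for (i in seq_len(n_rils)) {
      # one starting founder per RIL: with no recombination the whole
      # genome is a single founder, as for a RIL fixed without crossover
      f_start <- sample.int(nf, 1L)
      for (ch in chroms) {
        lo <- spans[[ch]][1]; hi <- spans[[ch]][2]
        len <- hi - lo
        n_bk <- if (len > 0) rpois(1, breakpoint_rate * len) else 0L
        bks <- sort(runif(n_bk, lo, hi))
        f <- integer(n_bk + 1L)
        f[1] <- f_start
        if (n_bk > 0) {
          for (j in seq_len(n_bk)) {
            f[j + 1L] <- sample.int(nf - 1L, 1L)
            if (f[j + 1L] >= f[j]) f[j + 1L] <- f[j + 1L] + 1L
          }
        }
        starts <- c(lo, bks); ends <- c(bks, hi)
        k <- k + 1L
        seg_list[[k]] <- tibble(
          ril = rils[i], chrom = ch, founder = founders[f],
          start_cm = starts, end_cm = ends
        )
      }
    }
    mosaics <- dplyr::bind_rows(seg_list)
    mosaics <- mosaics |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(
        start_bp = cm_to_bp(map, .data$chrom[1], .data$start_cm),
        end_bp = cm_to_bp(map, .data$chrom[1], .data$end_cm)
      ) |>
      dplyr::ungroup()

    # observed marker calls: segment-wise founder allele + error flips
    markers <- matrix(NA_integer_, n_rils, nrow(map),
      dimnames = list(rils, NULL)
    )
    for (i in seq_len(n_rils)) {
      anc <- ancestry_index_(mosaics[mosaics$ril == rils[i], ], map, founders)
      true_allele <- alleles[cbind(seq_len(nrow(map)), anc)]
      if (error_rate > 0) {
        flip <- rbinom(nrow(map), 1L, error_rate) == 1L
        true_allele[flip] <- 1L - true_allele[flip]
      }
      markers[i, ] <- true_allele
    }

    lines <- tibble(
      ril = rils, panel = panel,
      subpop = paste0(panel, ((seq_len(n_rils) - 1L) %% n_subpop) + 1L)
    )
    structure(
      list(panel = fp, mosaics = mosaics, lines = lines, markers = markers),
      class = "panel_sim"
    )
  })
}

#' @export
print.panel_sim <- function(x, ...) {
  cat(sprintf(
    "<panel_sim> %s: %d RILs, %d markers, %d ancestry segments\n",
    x$panel$panel, nrow(x$lines), ncol(x$markers), nrow(x$mosaics)
  ))
  invisible(x)
}

# Founder index (1..k) of one RIL's mosaic at every marker position.
ancestry_index_ <- function(segs, map, founders) {
  out <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    sc <- segs[segs$chrom == ch, ]
    sc <- sc[order(sc$start_cm), ]
    pos <- map$cm[map$chrom == ch]
    idx <- findInterval(pos, sc$start_cm, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    out[map$chrom == ch] <- match(sc$founder[idx], founders)
  }
  out
}

#' Look up true founder ancestry at genome positions
#'
#' @param mosaics Mosaic segment tibble from [simulate_panel()].
#' @param chrom,cm Position to query.
#' @param founders Optional founder label vector (fixes factor order).
#' @return Named character vector: founder label per RIL at the position.
#' @export
ancestry_at <- function(mosaics, chrom, cm, founders = NULL) {
  segs <- mosaics[mosaics$chrom == chrom &
    mosaics$start_cm <= cm & mosaics$end_cm >= cm, ]
  segs <- segs[order(segs$ril, segs$start_cm), ]
  segs <- segs[!duplicated(segs$ril), ] # boundary positions: keep left segment
  setNames(segs$founder, segs$ril)
}

#' True additive founder probabilities from simulated mosaics
#'
#' Builds the additive-probability object the genome scan consumes directly
#' from the (known) mosaic ancestry: probability 1 on the ancestral founder
#' at every position. Useful for testing the scan machinery independently of
#' haplotype inference, and as the noise-free limit of [infer_additive()].
#'
#' @param sim A `panel_sim` object.
#' @param grid_step Evaluation grid step in cM.
#' @return An `additive_probs` object (see [infer_additive()]).
#' @export
true_additive <- function(sim, grid_step = 0.5) {
  map <- sim$panel$map
  founders <- sim$panel$founders
  grid <- scan_grid_(map, grid_step)
  n <- nrow(sim$lines)
  probs <- array(0, dim = c(n, length(founders), nrow(grid)),
    dimnames = list(sim$lines$ril, founders, NULL)
  )
  for (i in seq_len(n)) {
    segs <- sim$mosaics[sim$mosaics$ril == sim$lines$ril[i], ]
    for (ch in unique(grid$chrom)) {
      sc <- segs[segs$chrom == ch, ]
      sc <- sc[order(sc$start_cm), ]
      gi <- which(grid$chrom == ch)
      idx <- findInterval(grid$cm[gi], sc$start_cm)
      idx[idx < 1L] <- 1L
      f <- match(sc$founder[idx], founders)
      probs[cbind(i, f, gi)] <- 1
    }
  }
  additive_probs_(grid, probs, sim$lines$ril, founders)
}

scan_grid_ <- function(map, grid_step) {
  purrr::map_dfr(unique(map$chrom), function(ch) {
    r <- range(map$cm[map$chrom == ch])
    cm <- seq(r[1], r[2], by = grid_step)
    tibble(chrom = ch, cm = cm, bp = cm_to_bp(map, ch, cm))
  })
}

#' Specify QTL and CNV effects for phenotype simulation
#'
#' @param chrom,cm Position of each effect locus (vectors, one entry per QTL).
#' @param effects List of numeric vectors, one per QTL, giving the additive
#'   phenotypic effect (trait units, here hours) of each founder haplotype.
#' @param cnv Optional CNV locus: a list with elements `chrom`, `cm`,
#'   `dup_founders` (character vector of founders carrying the duplication),
#'   and `effect` (additive effect in trait units of carrying it).
#' @return A `qtl_spec` object.
#' @examples
#' qtl_spec("2", 30, effects = list(c(5, 5, -5, -5, 5, -5, 5, -5)))
#' @export
qtl_spec <- function(chrom = character(), cm = numeric(),
                     effects = list(), cnv = NULL) {
  if (length(chrom) != length(cm) || length(cm) != length(effects)) {
    abort("`chrom`, `cm` and `effects` must have one entry per QTL.")
  }
  if (!is.null(cnv) &&
    !all(c("chrom", "cm", "dup_founders", "effect") %in% names(cnv))) {
    abort("`cnv` needs elements chrom, cm, dup_founders, effect.")
  }
  structure(list(chrom = chrom, cm = cm, effects = effects, cnv = cnv),
    class = "qtl_spec"
  )
}

#' Phenotype simulation settings
#'
#' Defaults reproduce the scale of an adult-survival assay on toxic media:
#' grand mean 37.3 h with among-line SD 17.82 h, per-observation broad-sense
#' heritability 0.53, and replicate counts per line drawn as a rounded
#' normal with mean 16.5 and SD 3.62, bounded to 9..32 flies.
#'
#' @param mean Grand mean of the trait (hours).
#' @param h2 Target per-observation broad-sense heritability, in (0, 1].
#' @param line_sd Target among-line SD (hours).
#' @param reps_mean,reps_sd,reps_range Replicate-count distribution per line.
#' @param seed Optional integer seed.
#' @return A `sim_phenotype_config` list.
#' @export
sim_config <- function(mean = 37.3, h2 = 0.53, line_sd = 17.82,
                       reps_mean = 16.5, reps_sd = 3.62,
                       reps_range = c(9, 32), seed = NULL) {
  if (h2 <= 0 || h2 > 1) abort("`h2` must be in (0, 1].")
  if (line_sd < 0) abort("`line_sd` must be non-negative.")
  if (reps_range[1] < 1) abort("Replicate counts must be >= 1.")
  structure(
    list(mean = mean, h2 = h2, line_sd = line_sd, reps_mean = reps_mean,
      reps_sd = reps_sd, reps_range = reps_range, seed = seed),
    class = "sim_phenotype_config"
  )
}

#' Simulate per-fly phenotypes over a RIL panel
#'
#' Each fly's value is grand mean + founder effect at every QTL (given the
#' line's true ancestry) + CNV effect if the line carries the duplication +
#' a line-level deviation + within-line noise, truncated at 0 hours. The
#' line-level deviation variance is chosen so the total among-line variance
#' hits `config$line_sd^2` (QTL effects included), and the within-line
#' variance so the per-observation heritability equals `config$h2` in
#' expectation.
#'
#' @param sim A `panel_sim` object from [simulate_panel()].
#' @param qtl A [qtl_spec()]; `NULL` for a purely polygenic/null trait.
#' @param config A [sim_config()].
#' @return A tibble of per-fly records in the standard phenotype layout:
#'   `MappingPanel`, `Popn`, `PopnRep`, `Genotype`, `RepVial`,
#'   `CaffeineResistance` (hours). The per-line genetic values are attached
#'   as attribute `"genetic_values"`.
#' @export
simulate_phenotypes <- function(sim, qtl = NULL, config = sim_config()) {
  map <- sim$panel$map
  founders <- sim$panel$founders
  lines <- sim$lines
  n <- nrow(lines)

  g <- rep(0, n)
  names(g) <- lines$ril
  cnv_status <- NULL
  if (!is.null(qtl)) {
    for (q in seq_along(qtl$chrom)) {
      r <- range(map$cm[map$chrom == qtl$chrom[q]])
      if (length(r) == 0 || qtl$cm[q] < r[1] || qtl$cm[q] > r[2]) {
        abort(sprintf("QTL position %s:%g is off the marker map.",
          qtl$chrom[q], qtl$cm[q]))
      }
      eff <- qtl$effects[[q]]
      if (length(eff) != length(founders)) {
        abort("Each QTL effect vector must have one entry per founder.")
      }
      anc <- ancestry_at(sim$mosaics, qtl$chrom[q], qtl$cm[q])
      g <- g + setNames(eff, founders)[anc[lines$ril]]
    }
    if (!is.null(qtl$cnv)) {
      anc <- ancestry_at(sim$mosaics, qtl$cnv$chrom, qtl$cnv$cm)
      cnv_status <- as.integer(anc[lines$ril] %in% qtl$cnv$dup_founders)
      g <- g + qtl$cnv$effect * cnv_status
    }
  }

  with_seed_(config$seed, {
    var_qtl <- if (n > 1) var(g) else 0
    var_line <- max(config$line_sd^2 - var_qtl, 0)
    if (var_qtl > config$line_sd^2) {
      inform("QTL effects alone exceed the among-line variance target; line-level deviation set to 0.")
    }
    v_g <- var_qtl + var_line
    sigma_e <- if (config$h2 == 1) 0 else sqrt(v_g * (1 - config$h2) / config$h2)

    line_dev <- rnorm(n, 0, sqrt(var_line))
    reps <- pmin(pmax(round(rnorm(n, config$reps_mean, config$reps_sd)),
      config$reps_range[1]), config$reps_range[2])

    out <- tibble(
      MappingPanel = "DSPR",
      Popn = rep(lines$panel, reps),
      PopnRep = rep(lines$subpop, reps),
      Genotype = rep(lines$ril, reps),
      RepVial = 1L,
      CaffeineResistance = pmax(
        config$mean + rep(g + line_dev, reps) + rnorm(sum(reps), 0, sigma_e),
        0
      )
    )
    attr(out, "genetic_values") <- g
    attr(out, "cnv_status") <- cnv_status
    out
  })
}

#' Per-line means from a per-fly phenotype table
#'
#' @param phenotypes Tibble in the layout produced by
#'   [simulate_phenotypes()] (or read from a phenotype CSV): one row per fly
#'   with `Genotype` and `CaffeineResistance` columns.
#' @return Tibble with columns `line`, `mean`, `sd`, `n`.
#' @export
line_means <- function(phenotypes) {
  phenotypes |>
    dplyr::group_by(line = .data$Genotype) |>
    dplyr::summarise(
      mean = mean(.data$CaffeineResistance),
      sd = sd(.data$CaffeineResistance),
      n = dplyr::n(), .groups = "drop"
    )
}
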