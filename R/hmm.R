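#' Diplotype state space over k founders
#'
#' The diplotype of a line at a position is the unordered pair of founder
#' ancestries of its two haplotypes: k homozygous states plus k(k-1)/2
#' heterozygous states, k(k+1)/2 in all (36 for 8 founders).
#'
#' @param founders Founder labels, or a single integer k (labels F1..Fk).
#' @return Tibble with columns `state` (label), `f1`, `f2` (founder indices,
#'   `f1 <= f2`), in canonical lexicographic order.
#' @examples
#' nrow(diplotype_states(8)) # 36
#' @export
diplotype_states <- function(founders = 8) {
  if (is.numeric(founders)) {
    if (founders < 1) abort("Need at least one founder.")
    founders <- paste0("F", seq_len(founders))
  }
  k <- length(founders)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble(
    state = ifelse(idx[, 1] == idx[, 2], founders[idx[, 1]],
      paste0(founders[idx[, 1]], "/", founders[idx[, 2]])),
    f1 = unname(idx[, 1]), f2 = unname(idx[, 2])
  )
}

#' HMM parameters for founder-haplotype inference
#'
#' @param error_rate Genotyping error probability per marker, in [0, 0.5).
#' @param recomb_scale Expected ancestry switches per cM per haplotype
#'   (> 0). The per-interval switch probability over d cM is
#'   `1 - exp(-recomb_scale * d)`, distributed uniformly over the other
#'   founders; the two haplotypes of a diplotype switch independently.
#' @param prior Stationary prior over diplotype states (defaults to
#'   uniform); must sum to 1.
#' @param homozygous_only Restrict the state space to the k homozygous
#'   states (appropriate for fully inbred lines); default keeps the full
#'   diplotype space.
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(error_rate = 0.005, recomb_scale = 0.15,
                       prior = NULL, homozygous_only = FALSE) {
  if (error_rate < 0 || error_rate >= 0.5) abort("`error_rate` must be in [0, 0.5).")
  if (recomb_scale <= 0) abort("`recomb_scale` must be positive.")
  if (!is.null(prior) && abs(sum(prior) - 1) > 1e-8) abort("`prior` must sum to 1.")
  structure(
    list(error_rate = error_rate, recomb_scale = recomb_scale,
      prior = prior, homozygous_only = homozygous_only),
    class = "hmm_params"
  )
}

# Per-haplotype founder transition matrix over a map distance of d cM.
hap_transition_ <- function(d, scale, k) {
  r <- 1 - exp(-scale * d)
  m <- matrix(r / (k - 1), k, k)
  diag(m) <- 1 - r
  m
}

# Diplotype transition matrix: haplotypes switch independently, and
# probabilities into a heterozygous (unordered) target state sum over its
# two orderings. Symmetric construction, so lumping ordered pairs into
# unordered states is exact.
diplo_transition_ <- function(d, scale, k, states) {
  t1 <- hap_transition_(d, scale, k)
  a <- states$f1; b <- states$f2
  u <- t1[a, a, drop = FALSE] * t1[b, b, drop = FALSE] # T[a_s,c_t]*T[b_s,d_t]
  het <- which(states$f1 != states$f2)
  if (length(het)) {
    u2 <- t1[a, b, drop = FALSE] * t1[b, a, drop = FALSE]
    u[, het] <- u[, het] + u2[, het]
  }
  u
}

#' Posterior diplotype probabilities for one line
#'
#' Runs forward-backward over the diplotype state space. The emission for a
#' state is the product over its two founders of per-allele agreement with
#' the observed marker call (`1 - error_rate` on agreement, `error_rate` on
#' disagreement); missing calls emit uniformly. Transitions follow the
#' distance-dependent switch model of [hmm_params()]. Chromosomes are
#' decoded independently; per-position renormalization guards against
#' underflow. Extra (unobserved) query positions can be interleaved with
#' the markers, yielding exact posteriors on an arbitrary grid.
#'
#' @param markers Numeric vector of observed 0/1 marker calls (NA allowed),
#'   aligned to the rows of `panel$map`.
#' @param panel A [founder_panel()].
#' @param params An [hmm_params()].
#' @param positions Optional tibble (`chrom`, `cm`) of additional positions
#'   at which to evaluate the posterior.
#' @return A `diplotype_posterior` object: list with `map` (positions,
#'   including an `observed` flag), `states`, `posterior` (positions x
#'   states), and `additive` (positions x founders; see
#'   [collapse_additive()]).
#' @export
posterior_decode <- function(markers, panel, params = hmm_params(),
                             positions = NULL) {
  map <- panel$map
  if (length(markers) != nrow(map)) {
    abort("`markers` length must equal the number of markers in the panel map.")
  }
  k <- length(panel$founders)
  states <- if (params$homozygous_only) {
    s <- diplotype_states(panel$founders); s[s$f1 == s$f2, ]
  } else {
    diplotype_states(panel$founders)
  }
  S <- nrow(states)
  prior <- params$prior %||% rep(1 / S, S)
  if (length(prior) != S) abort("`prior` length must match the state count.")

  pos <- tibble(chrom = map$chrom, cm = map$cm, obs = seq_along(markers))
  if (!is.null(positions)) {
    pos <- dplyr::bind_rows(pos,
      tibble(chrom = positions$chrom, cm = positions$cm, obs = NA_integer_))
  }
  pos <- pos[order(match(pos$chrom, unique(map$chrom)), pos$cm,
    is.na(pos$obs)), ]

  eps <- params$error_rate
  post <- matrix(NA_real_, nrow(pos), S)
  for (ch in unique(pos$chrom)) {
    rows <- which(pos$chrom == ch)
    G <- length(rows)
    # emissions
    emis <- matrix(1, G, S)
    for (gi in seq_len(G)) {
      ob <- pos$obs[rows[gi]]
      if (!is.na(ob) && !is.na(markers[ob])) {
        agree <- ifelse(panel$alleles[ob, ] == markers[ob], 1 - eps, eps)
        emis[gi, ] <- agree[states$f1] * agree[states$f2]
      }
    }
    # transitions, cached by interval length
    d <- diff(pos$cm[rows])
    dk <- as.character(signif(d, 12))
    trans <- lapply(unique(dk), function(key) {
      diplo_transition_(d[match(key, dk)], params$recomb_scale, k, states)
    })
    names(trans) <- unique(dk)

    fwd <- matrix(0, G, S)
    scl <- numeric(G)
    f <- prior * emis[1, ]
    scl[1] <- sum(f); fwd[1, ] <- f / scl[1]
    if (G > 1) for (gi in 2:G) {
      f <- as.vector(fwd[gi - 1, ] %*% trans[[dk[gi - 1]]]) * emis[gi, ]
      scl[gi] <- sum(f)
      if (scl[gi] == 0) abort("All diplotype states inconsistent with the data; check `error_rate`.")
      fwd[gi, ] <- f / scl[gi]
    }
    bwd <- matrix(0, G, S)
    bwd[G, ] <- 1
    if (G > 1) for (gi in (G - 1):1) {
      b <- trans[[dk[gi]]] %*% (emis[gi + 1, ] * bwd[gi + 1, ])
      bwd[gi, ] <- b / max(b)
    }
    p <- fwd * bwd
    post[rows, ] <- p / rowSums(p)
  }

  out_map <- tibble(
    chrom = pos$chrom, cm = pos$cm,
    bp = purrr::map2_dbl(pos$chrom, pos$cm, ~ cm_to_bp(map, .x, .y)),
    observed = !is.na(pos$obs)
  )
  structure(
    list(map = out_map, states = states, posterior = post,
      additive = collapse_additive(post, states, k = k,
        founders = panel$founders)),
    class = "diplotype_posterior"
  )
}

#' Collapse diplotype posteriors to additive founder probabilities
#'
#' Heterozygous states are treated as intermediate between their two
#' homozygous states: each founder receives the full mass of its homozygous
#' state plus half the mass of every heterozygous state it participates in,
#' i.e. `additive(f) = P(f,f) + 0.5 * sum_g P(f,g)`. The result sums to 1.
#'
#' @param posterior A probability vector over the diplotype states, a
#'   positions x states matrix, or a `diplotype_posterior` object.
#' @param states Optional state table (inferred from the canonical
#'   [diplotype_states()] order when omitted).
#' @param k Number of founders (inferred from the state count when omitted).
#' @param founders Optional founder labels for the result columns.
#' @param tol Tolerance for the sum-to-one check on the input.
#' @return A length-k vector or positions x k matrix of additive founder
#'   probabilities.
#' @export
collapse_additive <- function(posterior, states = NULL, k = NULL,
                              founders = NULL, tol = 1e-6) {
  if (inherits(posterior, "diplotype_posterior")) {
    return(posterior$additive)
  }
  vec <- is.null(dim(posterior))
  p <- if (vec) matrix(posterior, 1) else as.matrix(posterior)
  S <- ncol(p)
  if (is.null(states)) {
    k <- k %||% (sqrt(8 * S + 1) - 1) / 2
    if (abs(k - round(k)) > 1e-9) abort("State count is not k(k+1)/2 for any k.")
    k <- as.integer(round(k))
    states <- diplotype_states(founders %||% k)
    if (nrow(states) != S) states <- states[states$f1 == states$f2, ]
  }
  k <- k %||% max(states$f2)
  if (any(abs(rowSums(p) - 1) > tol)) {
    abort("Diplotype posterior rows must sum to 1 (beyond tolerance).")
  }
  A <- matrix(0, nrow(states), k)
  A[cbind(seq_len(nrow(states)), states$f1)] <-
    A[cbind(seq_len(nrow(states)), states$f1)] + 0.5
  A[cbind(seq_len(nrow(states)), states$f2)] <-
    A[cbind(seq_len(nrow(states)), states$f2)] + 0.5
  out <- p %*% A
  colnames(out) <- founders %||% paste0("F", seq_len(k))
  if (vec) out[1, ] else out
}

#' Hard founder calls from additive probabilities
#'
#' Assigns founder `f` wherever `additive(f) > threshold`, `NA` otherwise.
#' The default threshold 0.95 is the conventional confident-call rule for
#' reporting founder means and imputing founder genotypes.
#'
#' @param additive A length-k additive probability vector, a positions x k
#'   matrix, or a `diplotype_posterior` object.
#' @param threshold Call threshold, in (0.5, 1].
#' @return Character vector of founder labels (NA where no founder exceeds
#'   the threshold).
#' @export
hard_call <- function(additive, threshold = 0.95) {
  if (threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must be in (0.5, 1].")
  }
  if (inherits(additive, "diplotype_posterior")) additive <- additive$additive
  m <- if (is.null(dim(additive))) matrix(additive, 1,
    dimnames = list(NULL, names(additive))) else as.matrix(additive)
  labels <- colnames(m) %||% paste0("F", seq_len(ncol(m)))
  best <- max.col(m, ties.method = "first")
  val <- m[cbind(seq_len(nrow(m)), best)]
  out <- ifelse(val > threshold, labels[best], NA_character_)
  if (is.null(dim(additive))) out[1] else out
}

additive_probs_ <- function(map, probs, lines, founders) {
  structure(
    list(map = as_tibble(map), probs = probs, lines = lines,
      founders = founders),
    class = "additive_probs"
  )
}

#' @export
print.additive_probs <- function(x, ...) {
  cat(sprintf(
    "<additive_probs> %d lines x %d founders x %d positions\n",
    dim(x$probs)[1], dim(x$probs)[2], dim(x$probs)[3]
  ))
  invisible(x)
}

#' Infer additive founder probabilities for a RIL panel
#'
#' Runs [posterior_decode()] for every RIL and assembles the per-position
#' additive probabilities on a regular evaluation grid (markers plus a
#' `grid_step` lattice per chromosome), the form consumed by
#' [genome_scan()].
#'
#' @param markers RIL x marker matrix of observed 0/1 calls (NA allowed);
#'   rownames identify the lines.
#' @param panel A [founder_panel()].
#' @param params An [hmm_params()].
#' @param grid_step Evaluation grid step in cM (default 0.2).
#' @return An `additive_probs` object: `map` (grid positions), `probs`
#'   (lines x founders x positions array), `lines`, `founders`.
#' @export
infer_additive <- function(markers, panel, params = hmm_params(),
                           grid_step = 0.2) {
  markers <- as.matrix(markers)
  lines <- rownames(markers) %||% sprintf("ril_%04d", seq_len(nrow(markers)))
  grid <- scan_grid_(panel$map, grid_step)
  probs <- array(NA_real_,
    dim = c(nrow(markers), length(panel$founders), nrow(grid)),
    dimnames = list(lines, panel$founders, NULL)
  )
  for (i in seq_len(nrow(markers))) {
    dec <- posterior_decode(markers[i, ], panel, params, positions = grid)
    # match decoded rows back onto the grid (marker rows interleaved)
    key_dec <- paste(dec$map$chrom, signif(dec$map$cm, 12))
    key_grid <- paste(grid$chrom, signif(grid$cm, 12))
    idx <- match(key_grid, key_dec)
    probs[i, , ] <- t(dec$additive[idx, , drop = FALSE])
  }
  additive_probs_(grid, probs, lines, panel$founders)
}
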