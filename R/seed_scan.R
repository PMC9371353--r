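#' Bilateral seed indicator vector
#'
#' Initial condition for epicentre scanning: 1 at both members of a
#' homologous region pair, 0 elsewhere. Midline regions (possible in
#' non-default atlases) yield a single nonzero with a message. Pearson
#' correlation makes the seed magnitude consequence-free, so the value 1 is
#' used unnormalized.
#'
#' @param regions region table (or `ndm_connectome`)
#' @param seed region label, 1-based matrix index, or a `pair_label` from
#'   [homologue_pairs()]
#' @return length-N numeric seed vector
#' @export
bilateral_seed_vector <- function(regions, seed) {
  rt <- if (inherits(regions, "ndm_connectome")) regions$regions else regions
  n <- nrow(rt)
  if (is.numeric(seed)) {
    if (length(seed) != 1L || seed < 1 || seed > n)
      stop("seed index out of range: ", seed)
    i <- as.integer(seed)
  } else {
    i <- match(seed, rt$label)
    if (is.na(i)) {
      pairs <- homologue_pairs(rt)
      k <- match(seed, pairs$pair_label)
      if (is.na(k)) stop("unknown region: ", seed)
      i <- pairs$left[k]
    }
  }
  f0 <- numeric(n)
  f0[i] <- 1
  h <- rt$homologue_id[i]
  if (is.na(h)) {
    message("region '", rt$label[i],
            "' is midline: unilateral seed (single nonzero)")
  } else {
    f0[h + 1L] <- 1
  }
  f0
}

#' Seed-excluded correlation of a diffusion trajectory with measured atrophy
#'
#' For each model time, the Pearson correlation between the predicted
#' pattern `f(t)` and the measured atrophy t-map over the non-seed regions.
#' Excluding the seeds guarantees the correlation is not driven by atrophy
#' at the seed itself. Time points where either vector has zero variance
#' over the retained regions (always the case at `t = 0`, where the
#' non-seed prediction is identically zero) are recorded as `NA`, never
#' as 0.
#'
#' @param traj `ndm_trajectory`
#' @param atrophy `atrophy_map` on the same region ordering
#' @param exclude integer indices (1-based) of the seed regions to drop
#' @return numeric vector of Pearson r, one per time point (`NA` where
#'   undefined)
#' @export
correlation_trace <- function(traj, atrophy, exclude = integer(0)) {
  stopifnot(inherits(traj, "ndm_trajectory"), inherits(atrophy, "atrophy_map"))
  if (nrow(atrophy) != ncol(traj$values))
    stop("atrophy map has ", nrow(atrophy), " regions but trajectory has ",
         ncol(traj$values))
  tl <- colnames(traj$values)
  if (!is.null(tl) && !identical(tl, atrophy$region_label))
    stop("trajectory and atrophy map are on different region orderings")
  keep <- setdiff(seq_len(nrow(atrophy)), exclude)
  y <- atrophy$t[keep]
  if (stats::sd(y) == 0)
    return(rep(NA_real_, length(traj$times)))
  apply(traj$values[, keep, drop = FALSE], 1L, function(f) {
    if (stats::sd(f) == 0) NA_real_ else stats::cor(f, y)
  })
}

#' Scan all bilateral seeds and rank candidate epicentres
#'
#' The repeated-seeding engine: diffusion is initiated from every bilateral
#' homologue pair in turn, evolved over the model-time grid, and each
#' trajectory is correlated (seed-excluded Pearson) with the measured
#' atrophy map at every time point. Each seed is scored by its maximum
#' correlation over valid times; seeds are ranked by that maximum. With the
#' default 82-region bilateral atlas this produces 41 initial conditions,
#' 80-region correlations and a 41 x 51 correlation-time surface.
#'
#' @param c `ndm_connectome`
#' @param atrophy `atrophy_map` on the connectome's regions (same order)
#' @param dec optional precomputed `ndm_laplacian` for `c`
#' @param times model-time grid (default 0..50 in unit steps)
#' @param alpha diffusivity constant (default 1)
#' @param correction family-wise error correction across seeds:
#'   `"bonferroni"` (default) or `"holm"`
#' @return object of class `seed_scan`: list with `seeds` (data.frame
#'   `seed_label`, `max_r`, `t_star`, `p`, `p_fwe`, ranked by `max_r`
#'   descending, ties broken by region-table order), `corr_matrix`
#'   (S x T surface, seeds in region-table order), `times`, `n_used`
#'   (regions per correlation), `alpha`, `correction`
#' @export
repeated_seed_scan <- function(c, atrophy, dec = NULL, times = 0:50,
                               alpha = 1, correction = c("bonferroni", "holm")) {
  stopifnot(inherits(c, "ndm_connectome"), inherits(atrophy, "atrophy_map"))
  correction <- match.arg(correction)
  if (!identical(atrophy$region_label, c$regions$label))
    stop("atrophy map regions do not match the connectome (same order required)")
  if (stats::sd(atrophy$t) == 0)
    stop("degenerate atrophy map: all t-values equal; correlations undefined")
  if (is.null(dec)) dec <- build_laplacian(c)

  pairs <- homologue_pairs(c)
  s <- nrow(pairs)
  corr <- matrix(NA_real_, s, length(times),
                 dimnames = list(pairs$pair_label, times))
  n_used <- integer(s)
  for (k in seq_len(s)) {
    ex <- c(pairs$left[k], pairs$right[k])
    ex <- ex[!is.na(ex)]
    f0 <- numeric(nrow(c$regions))
    f0[ex] <- 1
    traj <- propagate(dec, f0, times = times, alpha = alpha)
    corr[k, ] <- correlation_trace(traj, atrophy, exclude = ex)
    n_used[k] <- nrow(atrophy) - length(ex)
  }

  max_r <- numeric(s); t_star <- numeric(s)
  for (k in seq_len(s)) {
    valid <- which(!is.na(corr[k, ]))
    if (!length(valid))
      stop("all correlations undefined for seed '", pairs$pair_label[k], "'")
    m <- max(corr[k, valid])
    hit <- valid[corr[k, valid] == m]
    if (length(hit) > 1L)
      message("seed '", pairs$pair_label[k], "': argmax time tied at t = ",
              paste(times[hit], collapse = ", "), "; smallest kept")
    max_r[k] <- m
    t_star[k] <- times[hit[1L]]
  }

  p <- correlation_p(max_r, n_used)
  p_fwe <- fwe_adjust(p, correction)
  seeds <- data.frame(seed_label = pairs$pair_label, max_r = max_r,
                      t_star = t_star, p = p, p_fwe = p_fwe,
                      stringsAsFactors = FALSE)
  seeds <- seeds[order(-seeds$max_r, seq_len(s)), ]
  rownames(seeds) <- NULL
  structure(list(seeds = seeds, corr_matrix = corr, times = times,
                 n_used = n_used, alpha = alpha, correction = correction),
            class = "seed_scan")
}

# Two-sided p-value of a Pearson r via the t transform with df = n - 2.
correlation_p <- function(r, n) {
  df <- n - 2
  tstat <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  # keep p strictly positive even when r underflows the t transform
  pmax(2 * stats::pt(tstat, df, lower.tail = FALSE), .Machine$double.xmin)
}

fwe_adjust <- function(p, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}

#' Re-apply (or change) the family-wise correction of a seed scan
#'
#' Bonferroni over the S seed hypotheses (`p_fwe = min(1, S p)`) by default;
#' Holm's step-down as the less conservative alternative.
#'
#' @param result `seed_scan`
#' @param correction `"bonferroni"` or `"holm"`
#' @return `seed_scan` with updated `p_fwe`
#' @export
fwe_correct <- function(result, correction = c("bonferroni", "holm")) {
  stopifnot(inherits(result, "seed_scan"))
  correction <- match.arg(correction)
  result$seeds$p_fwe <- fwe_adjust(result$seeds$p, correction)
  result$correction <- correction
  result
}

#' Write seed-scan results as TSV
#'
#' Per-seed summary `seed_label  max_r  t_star  p  p_fwe`; optionally the
#' full correlation surface in long format (`seed_label  time  r`).
#'
#' @param result `seed_scan`
#' @param path summary TSV path
#' @param surface_path optional long-format surface TSV path
#' @export
write_seed_scan <- function(result, path, surface_path = NULL) {
  stopifnot(inherits(result, "seed_scan"))
  utils::write.table(result$seeds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(surface_path)) {
    long <- data.frame(
      seed_label = rep(rownames(result$corr_matrix),
                       times = ncol(result$corr_matrix)),
      time = rep(result$times, each = nrow(result$corr_matrix)),
      r = as.vector(result$corr_matrix))
    utils::write.table(long, surface_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(result)
}

#' @export
print.seed_scan <- function(x, ...) {
  cat("seed_scan: ", nrow(x$corr_matrix), " seeds x ", ncol(x$corr_matrix),
      " time points (alpha = ", x$alpha, ", ", x$correction,
      " FWE over seeds)\nTop seeds:\n", sep = "")
  print.data.frame(utils::head(x$seeds, 5L), row.names = FALSE, digits = 3)
  invisible(x)
}
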