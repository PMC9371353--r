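#' Specification for the synthetic study generator
#'
#' Defines the stated world for a simulated atrophy study: a bilateral,
#' spatially embedded connectome; a planted bilateral diffusion seed at a
#' planted model time; and group volume tables whose patient-vs-control
#' difference is proportional to the diffused pattern plus noise.
#'
#' Each hemisphere is a weighted ring lattice: every region connects to its
#' `neighbor_order` nearest neighbours with weight decaying as
#' `1/distance^decay_power`, log-normal multiplicative noise on every edge,
#' plus sparse weak long-range shortcuts (`shortcut_density`,
#' `shortcut_weight`). Homologous regions are joined by strong
#' (`homotopic_boost`-scaled) callosal edges. This mimics the exponential
#' distance rule of cortical connectivity - strong local, sparse weak
#' long-range, strong homotopic - and, like a real connectome, keeps
#' diffusion slow and localized enough that different seeds remain
#' distinguishable across the model-time grid.
#'
#' Defaults mirror the reference study design where one exists: 82 regions
#' (41 bilateral pairs), baseline group sizes 14 patients vs 12 controls,
#' diffusivity 1, model-time grid 0..50, observation noise 0.05 of the
#' pattern maximum, planted time mid-grid.
#'
#' @param n_regions even node count (default 82)
#' @param neighbor_order lattice neighbours per side within hemisphere
#' @param decay_power weight decay exponent with lattice distance
#' @param shortcut_density density of long-range within-hemisphere
#'   shortcuts, in (0, 1]
#' @param shortcut_weight weight multiplier for shortcut edges
#' @param homotopic_boost weight multiplier for homotopic (callosal) edges
#' @param base_weight streamline-count scale of a nearest-neighbour edge
#' @param weight_sdlog sdlog of the log-normal edge-weight noise
#' @param seed_pair planted bilateral pair index in 1..n_regions/2
#' @param t_star planted model time (must lie on `times`)
#' @param alpha diffusivity constant
#' @param sigma observation noise SD as a fraction of `max f`
#' @param n_patients,n_controls group sizes
#' @param effect maximal fractional volume loss at the most-affected region
#' @param subject_cv subject-level multiplicative volume noise (CV)
#' @param times model-time grid
#' @param rng_seed integer seed for all draws
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_regions = 82, neighbor_order = 2,
                           decay_power = 2, shortcut_density = 0.03,
                           shortcut_weight = 0.05, homotopic_boost = 2,
                           base_weight = 50, weight_sdlog = 0.5,
                           seed_pair = 7, t_star = 15, alpha = 1,
                           sigma = 0.05, n_patients = 14, n_controls = 12,
                           effect = 0.05, subject_cv = 0.02, times = 0:50,
                           rng_seed = 1) {
  if (n_regions %% 2 != 0) stop("n_regions must be even (bilateral atlas)")
  if (sigma < 0) stop("sigma must be nonnegative")
  if (!t_star %in% times) stop("t_star must lie on the model-time grid")
  if (shortcut_density <= 0 || shortcut_density > 1)
    stop("shortcut_density must be in (0, 1]")
  if (seed_pair < 1 || seed_pair > n_regions / 2)
    stop("seed_pair out of range")
  if (neighbor_order < 1 || neighbor_order >= n_regions / 4)
    stop("neighbor_order out of range")
  structure(list(n_regions = as.integer(n_regions),
                 neighbor_order = as.integer(neighbor_order),
                 decay_power = decay_power,
                 shortcut_density = shortcut_density,
                 shortcut_weight = shortcut_weight,
                 homotopic_boost = homotopic_boost,
                 base_weight = base_weight, weight_sdlog = weight_sdlog,
                 seed_pair = as.integer(seed_pair), t_star = t_star,
                 alpha = alpha, sigma = sigma,
                 n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 effect = effect, subject_cv = subject_cv, times = times,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic bilateral connectome
#'
#' See [synthetic_spec()] for the topology. Weights are log-normal
#' (heavy-tailed, strictly positive) around a distance-decaying mean, to
#' mimic streamline counts. The lattice backbone guarantees connectivity in
#' almost every draw; disconnected draws are redrawn (bounded).
#'
#' @param spec `synthetic_spec`
#' @param max_retries redraw budget for disconnected draws
#' @return `ndm_connectome` with labels `lh_region_<k>` / `rh_region_<k>`
#'   and mirrored homologue pairing
#' @export
synth_connectome <- function(spec, max_retries = 50) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_regions
  half <- n %/% 2L
  labels <- c(sprintf("lh_region_%02d", seq_len(half)),
              sprintf("rh_region_%02d", seq_len(half)))
  regions <- data.frame(
    region_id = seq_len(n) - 1L,
    label = labels,
    hemisphere = rep(c("left", "right"), each = half),
    homologue_id = c(seq_len(half) + half, seq_len(half)) - 1L,
    stringsAsFactors = FALSE)

  edge_w <- function() spec$base_weight *
    stats::rlnorm(1, meanlog = 0, sdlog = spec$weight_sdlog)

  for (try in seq_len(max_retries)) {
    w <- matrix(0, n, n)
    for (h in 0:1) {
      off <- h * half
      # ring lattice with distance-decaying weights
      for (i in seq_len(half)) for (d in seq_len(spec$neighbor_order)) {
        j <- ((i - 1L + d) %% half) + 1L
        w[off + i, off + j] <- edge_w() / d^spec$decay_power
      }
      # sparse weak long-range shortcuts
      for (i in seq_len(half - 1L)) for (j in (i + 1L):half) {
        dd <- min(abs(i - j), half - abs(i - j))
        if (dd > spec$neighbor_order &&
            stats::runif(1) < spec$shortcut_density)
          w[off + i, off + j] <- spec$shortcut_weight * edge_w()
      }
    }
    # strong homotopic (callosal) edges anchor the bilateral pairing
    for (k in seq_len(half))
      w[k, k + half] <- spec$homotopic_boost * edge_w()
    w <- w + t(w)
    if (max(graph_components(w > 0)) == 1L)
      return(connectome(w, regions))
  }
  stop("failed to draw a connected synthetic connectome in ", max_retries,
       " attempts")
}

# Diffused pattern from the planted bilateral seed at the planted time,
# rescaled to max 1 so `effect` reads as the maximal fractional loss.
planted_pattern <- function(spec, c, dec = NULL) {
  if (is.null(dec)) dec <- build_laplacian(c)
  pairs <- homologue_pairs(c)
  k <- spec$seed_pair
  f0 <- numeric(nrow(c$regions))
  f0[c(pairs$left[k], pairs$right[k])] <- 1
  traj <- propagate(dec, f0, times = spec$t_star, alpha = spec$alpha)
  f <- drop(traj$values)
  list(f = f / max(f), pair_label = pairs$pair_label[k], pair_index = k)
}

#' Synthetic atrophy map with a planted seed
#'
#' A t-like regional map `a * (f_k(t*) + e)`, `e ~ N(0, (sigma * max f)^2)`,
#' where `f_k(t*)` is the diffusion pattern from the planted bilateral pair
#' at the planted time (normalized to max 1) and `a` a t-statistic-like
#' magnitude. The ground truth (pair, time) is returned in a separate
#' record, never inside the map, so downstream tests cannot leak it.
#'
#' @param spec `synthetic_spec`
#' @param c `ndm_connectome` from [synth_connectome()]
#' @param scale multiplier `a`
#' @return list with `atrophy` (`atrophy_map`) and `truth` (list
#'   `pair_index`, `pair_label`, `t_star`)
#' @export
synth_atrophy <- function(spec, c, scale = 3) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(c, "ndm_connectome"))
  pat <- planted_pattern(spec, c)
  set.seed(spec$rng_seed + 1L)
  noise <- stats::rnorm(length(pat$f), 0, spec$sigma * max(pat$f))
  a <- atrophy_map(scale * (pat$f + noise),
                   labels = c$regions$label, design = "synthetic")
  list(atrophy = a,
       truth = list(pair_index = pat$pair_index,
                    pair_label = pat$pair_label,
                    t_star = spec$t_star))
}

#' Synthetic subject-level volume tables
#'
#' Controls get baseline regional mean volumes; patients get the same means
#' shrunk by `effect * f_k(t*)` (maximal fractional loss `effect` at the
#' most-diffused region). Every subject's volumes scale with their own ICV
#' (drawn around 1.5e6 mm^3 with 7% SD), the head-size confound that ICV
#' normalization is designed to remove, plus multiplicative log-normal
#' subject noise (CV `subject_cv`). A two-sample t-map computed from the
#' output is positively correlated with the planted diffusion pattern.
#'
#' @param spec `synthetic_spec`
#' @param c `ndm_connectome`
#' @return list with `patients`, `controls` (`volume_table`s) and `truth`
#'   (as in [synth_atrophy()])
#' @export
synth_volume_tables <- function(spec, c) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(c, "ndm_connectome"))
  pat <- planted_pattern(spec, c)
  n <- nrow(c$regions)
  set.seed(spec$rng_seed + 2L)
  base_means <- stats::rlnorm(n, meanlog = log(4000), sdlog = 0.5)
  sdlog <- sqrt(log(1 + spec$subject_cv^2))
  icv_ref <- 1.5e6

  draw_group <- function(n_subj, shrink, group, prefix) {
    icv <- stats::rnorm(n_subj, icv_ref, 0.07 * icv_ref)
    vols <- t(vapply(seq_len(n_subj), function(s)
      base_means * shrink * (icv[s] / icv_ref) *
        stats::rlnorm(n, meanlog = 0, sdlog = sdlog),
      numeric(n)))
    colnames(vols) <- c$regions$label
    df <- data.frame(subject_id = sprintf("%s%02d", prefix, seq_len(n_subj)),
                     group = group, ICV = icv, stringsAsFactors = FALSE)
    as_volume_table(cbind(df, as.data.frame(vols, check.names = FALSE)),
                    regions = c)
  }

  patients <- draw_group(spec$n_patients, 1 - spec$effect * pat$f,
                         "patient", "pat")
  controls <- draw_group(spec$n_controls, rep(1, n), "control", "con")
  list(patients = patients, controls = controls,
       truth = list(pair_index = pat$pair_index,
                    pair_label = pat$pair_label,
                    t_star = spec$t_star))
}

#' Write a full synthetic study to a directory
#'
#' Writes `connectome.txt`, `regions.tsv`, `volumes_patients.tsv`,
#' `volumes_controls.tsv`, `atrophy.tsv` and the ground-truth sidecar
#' `truth.tsv` (kept separate so analyses cannot accidentally read it).
#'
#' @param spec `synthetic_spec`
#' @param dir output directory (created if needed)
#' @return invisibly, the list of generated objects
#' @export
write_synthetic_study <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  c <- synth_connectome(spec)
  vt <- synth_volume_tables(spec, c)
  at <- synth_atrophy(spec, c)
  write_connectome(c, file.path(dir, "connectome.txt"),
                   file.path(dir, "regions.tsv"))
  utils::write.table(as.data.frame(vt$patients),
                     file.path(dir, "volumes_patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(vt$controls),
                     file.path(dir, "volumes_controls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_atrophy_map(at$atrophy, file.path(dir, "atrophy.tsv"))
  utils::write.table(
    data.frame(pair_index = at$truth$pair_index,
               pair_label = at$truth$pair_label,
               t_star = at$truth$t_star),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(list(connectome = c, volumes = vt, atrophy = at))
}
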