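#' Read a subject-level regional volume table
#'
#' One row per subject. Required columns: `subject_id`, `group`, `ICV`
#' (total intracranial volume, mm^3) and one column per region label
#' (volumes, mm^3). FreeSurfer `aparcstats2table` / `asegstats2table`
#' exports reshaped to this layout are accepted; column order is free.
#'
#' @param path TSV path
#' @param regions optional region table (or `ndm_connectome`); when given,
#'   region columns are checked and reordered to match it exactly.
#' @return object of class `volume_table`: data.frame with attributes
#'   `region_labels` and `normalized` (FALSE on read)
#' @export
read_volume_table <- function(path, regions = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_volume_table(df, regions)
}

#' Coerce a data.frame to a volume table
#'
#' @param df data.frame with `subject_id`, `group`, `ICV` and region columns
#' @param regions optional region table or `ndm_connectome` to check against
#' @return `volume_table`
#' @export
as_volume_table <- function(df, regions = NULL) {
  meta <- c("subject_id", "group", "ICV")
  missing_meta <- setdiff(meta, names(df))
  if ("ICV" %in% missing_meta)
    stop("missing ICV column")
  if (length(missing_meta))
    stop("missing column(s): ", paste(missing_meta, collapse = ", "))
  region_labels <- setdiff(names(df), meta)
  if (!is.null(regions)) {
    rt <- if (inherits(regions, "ndm_connectome")) regions$regions else regions
    if (!setequal(region_labels, rt$label))
      stop("volume-table regions do not match the connectome region table; ",
           "missing: ", paste(setdiff(rt$label, region_labels), collapse = ", "),
           "; extra: ", paste(setdiff(region_labels, rt$label), collapse = ", "))
    region_labels <- rt$label
    df <- df[, c(meta, region_labels)]
  }
  vols <- as.matrix(df[, region_labels, drop = FALSE])
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("regional volumes must be finite and strictly positive")
  if (any(!is.finite(df$ICV)) || any(df$ICV <= 0))
    stop("ICV must be finite and strictly positive")
  structure(df, class = c("volume_table", "data.frame"),
            region_labels = region_labels, normalized = FALSE)
}

#' Normalize regional volumes by total intracranial volume
#'
#' Divides each subject's regional volumes by that subject's ICV to correct
#' for head size; the result is a dimensionless volume fraction. The t-maps
#' are invariant to this step only when all subjects share the same ICV.
#'
#' @param v `volume_table`
#' @return normalized `volume_table` (attribute `normalized = TRUE`)
#' @export
normalize_icv <- function(v) {
  stopifnot(inherits(v, "volume_table"))
  if (isTRUE(attr(v, "normalized"))) return(v)
  labs <- attr(v, "region_labels")
  v[labs] <- as.data.frame(as.matrix(v[, labs, drop = FALSE]) / v$ICV)
  attr(v, "normalized") <- TRUE
  v
}

volume_matrix <- function(v) {
  as.matrix(as.data.frame(v)[, attr(v, "region_labels"), drop = FALSE])
}

#' Two-sample t-map of regional atrophy
#'
#' Per-region two-sample t-statistic of the patient-vs-control volume
#' difference after ICV normalization, with the pooled-variance test
#' (df = n1 + n2 - 2) by default or Welch's unequal-variance test.
#'
#' Sign convention: positive t means volume loss in the patient group
#' (t is computed as controls minus patients), so larger t = more atrophy.
#'
#' @param patients,controls `volume_table`s on the same regions. Tables not
#'   yet ICV-normalized are normalized internally.
#' @param var_equal pooled (TRUE, default) vs Welch (FALSE) variance
#' @return object of class `atrophy_map`: data.frame `region_label`, `t`,
#'   `p` (two-sided, uncorrected) with design metadata attributes
#' @export
t_map_two_sample <- function(patients, controls, var_equal = TRUE) {
  patients <- normalize_icv(patients)
  controls <- normalize_icv(controls)
  labs <- attr(patients, "region_labels")
  if (!identical(labs, attr(controls, "region_labels")))
    stop("patient and control tables are on different region sets")
  x <- volume_matrix(controls)   # minuend: loss in patients is positive
  y <- volume_matrix(patients)
  n1 <- nrow(x); n2 <- nrow(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  mx <- colMeans(x); my <- colMeans(y)
  vx <- apply(x, 2L, stats::var); vy <- apply(y, 2L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2)
    bad <- sp2 <= 0
    if (any(bad))
      stop("zero pooled variance in region(s): ",
           paste(labs[bad], collapse = ", "), "; t undefined")
    tval <- (mx - my) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(tval))
  } else {
    se2 <- vx / n1 + vy / n2
    bad <- se2 <= 0
    if (any(bad))
      stop("zero variance in region(s): ",
           paste(labs[bad], collapse = ", "), "; t undefined")
    tval <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / n1)^2 / (n1 - 1) + (vy / n2)^2 / (n2 - 1))
  }
  new_atrophy_map(labs, tval, df,
                  design = "two_sample",
                  contrast = "controls - patients (loss-positive)",
                  group_sizes = c(n1 = n1, n2 = n2))
}

#' Paired t-map of longitudinal atrophy
#'
#' Per-region paired t on within-subject differences earlier minus later
#' (so progressive volume loss is positive), df = n - 1. Subjects are
#' matched on `subject_id`; both tables must contain the same subjects.
#'
#' @param earlier,later `volume_table`s for the two timepoints
#' @return `atrophy_map`
#' @export
t_map_paired <- function(earlier, later) {
  earlier <- normalize_icv(earlier)
  later <- normalize_icv(later)
  labs <- attr(earlier, "region_labels")
  if (!identical(labs, attr(later, "region_labels")))
    stop("timepoint tables are on different region sets")
  only_e <- setdiff(earlier$subject_id, later$subject_id)
  only_l <- setdiff(later$subject_id, earlier$subject_id)
  if (length(only_e) || length(only_l))
    stop("unmatched subjects: ",
         paste(c(only_e, only_l), collapse = ", "))
  later <- later[match(earlier$subject_id, later$subject_id), ]
  d <- volume_matrix(earlier) - volume_matrix(later)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 matched subjects")
  sdd <- apply(d, 2L, stats::sd)
  md <- colMeans(d)
  zero <- sdd == 0 & md != 0
  if (any(zero))
    stop("zero variance of nonzero differences in region(s): ",
         paste(labs[zero], collapse = ", "), "; t undefined (infinite)")
  tval <- ifelse(sdd == 0, 0, md / (sdd / sqrt(n)))
  new_atrophy_map(labs, tval, rep(n - 1, length(tval)),
                  design = "paired",
                  contrast = "earlier - later (loss-positive)",
                  group_sizes = c(n = n))
}

new_atrophy_map <- function(labels, t, df, design, contrast, group_sizes) {
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(data.frame(region_label = labels, t = unname(t), p = unname(p),
                       stringsAsFactors = FALSE),
            class = c("atrophy_map", "data.frame"),
            design = design, contrast = contrast,
            group_sizes = group_sizes, df = unname(df))
}

#' Build an atrophy map from a precomputed t-statistic vector
#'
#' For workflows where regional t-statistics were computed elsewhere.
#' p-values, if not supplied, are left as NA.
#'
#' @param t named numeric vector of t-statistics (names = region labels), or
#'   unnamed with `labels` given
#' @param labels region labels (defaults to `names(t)`)
#' @param p optional uncorrected p-values
#' @param design design tag string
#' @return `atrophy_map`
#' @export
atrophy_map <- function(t, labels = names(t), p = NA_real_,
                        design = "precomputed") {
  if (is.null(labels)) stop("region labels required")
  structure(data.frame(region_label = labels, t = unname(t), p = unname(p),
                       stringsAsFactors = FALSE),
            class = c("atrophy_map", "data.frame"),
            design = design, contrast = NA_character_,
            group_sizes = NULL, df = NULL)
}

#' Read / write atrophy maps as TSV (`region_label  t  p`)
#'
#' @param path TSV path
#' @return `atrophy_map`
#' @export
read_atrophy_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  atrophy_map(df$t, labels = df$region_label,
              p = if ("p" %in% names(df)) df$p else NA_real_,
              design = "file")
}

#' @rdname read_atrophy_map
#' @param a `atrophy_map`
#' @export
write_atrophy_map <- function(a, path) {
  stopifnot(inherits(a, "atrophy_map"))
  utils::write.table(as.data.frame(a)[, c("region_label", "t", "p")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(a)
}

#' @export
print.atrophy_map <- function(x, ...) {
  cat("atrophy_map (", attr(x, "design"), "): ", nrow(x), " regions, ",
      sum(x$p < 0.05, na.rm = TRUE), " with p < 0.05 (uncorrected)\n",
      sep = "")
  top <- utils::head(x[order(-x$t), ], 5L)
  print.data.frame(top, row.names = FALSE, digits = 3)
  invisible(x)
}
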