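# Small graph fixtures built in code. Kept independent of the package's
# synthetic-data module so cross-checks do not share a code path with the
# implementation under test.

bilateral_regions <- function(n) {
  stopifnot(n %% 2 == 0)
  half <- n / 2
  data.frame(
    region_id = seq_len(n) - 1L,
    label = c(sprintf("lh_r%02d", seq_len(half)),
              sprintf("rh_r%02d", seq_len(half))),
    hemisphere = rep(c("left", "right"), each = half),
    homologue_id = c(seq_len(half) + half, seq_len(half)) - 1L,
    stringsAsFactors = FALSE)
}

midline_regions <- function(n) {
  data.frame(region_id = seq_len(n) - 1L,
             label = sprintf("m%02d", seq_len(n)),
             hemisphere = "midline",
             homologue_id = NA_integer_,
             stringsAsFactors = FALSE)
}

two_node_connectome <- function(w = 2) {
  connectome(matrix(c(0, w, w, 0), 2), bilateral_regions(2))
}

complete_connectome <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  regs <- if (n %% 2 == 0) bilateral_regions(n) else midline_regions(n)
  connectome(w, regs)
}

# Connected random weighted graph: ring backbone + Bernoulli extras.
random_connectome <- function(n, seed, p = 0.3) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i %% n) + 1
    w[i, j] <- w[j, i] <- runif(1, 0.5, 2)
  }
  extra <- matrix(runif(n * n) < p, n, n) & upper.tri(w) & w == 0
  w[extra] <- runif(sum(extra), 0.1, 5)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  regs <- if (n %% 2 == 0) bilateral_regions(n) else midline_regions(n)
  connectome(w, regs)
}

write_tmp_matrix <- function(w, sep = "\t") {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(apply(w, 1, paste, collapse = sep), path)
  path
}

write_tmp_regions <- function(regions) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Volume table builder: one region column per element of `means`;
# `vols` is subjects x regions.
make_volume_table <- function(vols, icv = 1.5e6, group = "g",
                              prefix = "s", labels = NULL) {
  vols <- as.matrix(vols)
  if (is.null(labels)) labels <- sprintf("r%02d", seq_len(ncol(vols)))
  colnames(vols) <- labels
  df <- data.frame(subject_id = sprintf("%s%02d", prefix, seq_len(nrow(vols))),
                   group = group,
                   ICV = rep_len(icv, nrow(vols)),
                   stringsAsFactors = FALSE)
  as_volume_table(cbind(df, as.data.frame(vols)))
}
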