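# Relative symmetry tolerance: tractography matrices are nominally symmetric
# but float-noisy, so max|W - W'| <= SYM_TOL * max|W| is symmetrized silently
# (with a warning); anything larger is treated as a data error.
SYM_TOL <- 1e-8

#' Construct a validated connectome
#'
#' A connectome is a weighted, undirected, connected graph over a labelled
#' bilateral brain parcellation. Weights are in arbitrary units (typically
#' tractography streamline counts); no thresholding or binarization is
#' applied.
#'
#' @param weights square numeric matrix, nonnegative, symmetric within
#'   tolerance (`max|W - W'| <= 1e-8 max|W|`), zero diagonal. Mildly
#'   asymmetric inputs are symmetrized as `(W + W')/2` with a warning.
#' @param regions region table as returned by [read_region_table()]: a
#'   data.frame with columns `region_id` (0-based, consecutive), `label`,
#'   `hemisphere` (`"left"`, `"right"` or `"midline"`) and `homologue_id`
#'   (0-based index of the contralateral homologue, `NA` for midline).
#'   If `hemisphere`/`homologue_id` are absent they are inferred from
#'   `lh_`/`rh_`/`Left-`/`Right-` label prefixes.
#' @return an object of class `ndm_connectome` with elements `weights`
#'   (dimnamed by region label) and `regions`.
#' @export
connectome <- function(weights, regions) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectome matrix must be square, got ", nrow(weights), " x ",
         ncol(weights))
  n <- nrow(weights)
  if (!is.numeric(weights) || any(!is.finite(weights)))
    stop("connectome matrix contains non-finite or non-numeric entries")
  if (any(weights < 0))
    stop("connectome matrix contains negative entries")

  regions <- validate_region_table(regions, n)

  asym <- max(abs(weights - t(weights)))
  scale <- max(abs(weights))
  if (scale == 0) stop("connectome matrix is all zero")
  if (asym > SYM_TOL * scale)
    stop("connectome matrix is asymmetric beyond tolerance: max|W - W'| = ",
         format(asym), " > ", format(SYM_TOL * scale))
  if (asym > 0) {
    warning("input matrix not exactly symmetric (max|W - W'| = ",
            format(asym), "); symmetrized as (W + W')/2")
    weights <- (weights + t(weights)) / 2
  }
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries (self-connections) set to zero")
    diag(weights) <- 0
  }

  comp <- graph_components(weights > 0)
  if (max(comp) > 1) {
    small <- which(comp != as.integer(names(sort(table(comp),
                                                 decreasing = TRUE))[1]))
    stop("disconnected graph: region(s) ",
         paste(regions$label[small], collapse = ", "),
         " are isolated from the largest component")
  }

  dimnames(weights) <- list(regions$label, regions$label)
  structure(list(weights = weights, regions = regions),
            class = "ndm_connectome")
}

#' Load a connectome from delimited text files
#'
#' @param matrix_path path to a whitespace- or comma-delimited square numeric
#'   table (no header) of connection weights.
#' @param regions_path path to a region table TSV with header
#'   `region_id label hemisphere homologue_id`.
#' @return validated `ndm_connectome`
#' @seealso [write_connectome()] for the inverse operation
#' @export
load_connectome <- function(matrix_path, regions_path) {
  w <- read_square_matrix(matrix_path)
  regions <- read_region_table(regions_path)
  if (nrow(regions) != nrow(w))
    stop("dimension mismatch: matrix is ", nrow(w), " x ", ncol(w),
         " but region table has ", nrow(regions), " rows")
  connectome(w, regions)
}

read_square_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  w <- as.matrix(utils::read.table(path, header = FALSE, sep = sep,
                                   strip.white = TRUE))
  storage.mode(w) <- "double"
  dimnames(w) <- NULL
  w
}

#' Read a region table
#'
#' @param path TSV with header columns `region_id`, `label`, `hemisphere`,
#'   `homologue_id` (the latter two optional; inferred from label prefixes
#'   when absent).
#' @return data.frame region table
#' @export
read_region_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = NA, na.strings = c("NA", ""))
}

#' Write a connectome back to the canonical text format
#'
#' Round-trips bit-identically with [load_connectome()] for finite weights.
#'
#' @param c `ndm_connectome`
#' @param matrix_path,regions_path output file paths
#' @export
write_connectome <- function(c, matrix_path, regions_path) {
  stopifnot(inherits(c, "ndm_connectome"))
  w <- c$weights
  dimnames(w) <- NULL
  lines <- apply(w, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(lines, matrix_path)
  utils::write.table(c$regions, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c)
}

validate_region_table <- function(regions, n) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  if (!"label" %in% names(regions))
    stop("region table must have a 'label' column")
  if (nrow(regions) != n)
    stop("region table has ", nrow(regions), " rows but matrix has ", n)
  if (!"region_id" %in% names(regions))
    regions$region_id <- seq_len(n) - 1L
  if (!identical(as.integer(regions$region_id), seq_len(n) - 1L))
    stop("region_id must be consecutive 0-based integers in file order")
  if (anyDuplicated(regions$label))
    stop("duplicate region labels: ",
         paste(unique(regions$label[duplicated(regions$label)]),
               collapse = ", "))

  if (!all(c("hemisphere", "homologue_id") %in% names(regions)))
    regions <- infer_homologues(regions)
  regions$region_id <- as.integer(regions$region_id)
  regions$homologue_id <- suppressWarnings(as.integer(regions$homologue_id))
  hemi_ok <- regions$hemisphere %in% c("left", "right", "midline")
  if (!all(hemi_ok))
    stop("invalid hemisphere value(s): ",
         paste(unique(regions$hemisphere[!hemi_ok]), collapse = ", "))

  # homologue relation must be symmetric and irreflexive
  h <- regions$homologue_id
  idx <- which(!is.na(h))
  if (any(h[idx] < 0 | h[idx] >= n))
    stop("homologue_id out of range")
  if (any(h[idx] == regions$region_id[idx]))
    stop("homologue relation must be irreflexive")
  back <- h[h[idx] + 1L]
  if (any(is.na(back)) || any(back != regions$region_id[idx]))
    stop("homologue relation must be symmetric")
  if (any(is.na(h) & regions$hemisphere != "midline"))
    stop("non-midline region(s) without homologue: ",
         paste(regions$label[is.na(h) & regions$hemisphere != "midline"],
               collapse = ", "))
  regions
}

# Fallback pairing: strip lh_/rh_/Left-/Right-/ctx-lh-/ctx-rh- style prefixes
# and pair identical stems across hemispheres.
infer_homologues <- function(regions) {
  lab <- regions$label
  left_pat <- "^(ctx[-_])?(lh[-_]|[Ll]eft[-_])"
  right_pat <- "^(ctx[-_])?(rh[-_]|[Rr]ight[-_])"
  hemi <- ifelse(grepl(left_pat, lab), "left",
                 ifelse(grepl(right_pat, lab), "right", "midline"))
  stem <- sub(left_pat, "", lab)
  stem <- sub(right_pat, "", stem)
  hom <- rep(NA_integer_, length(lab))
  for (i in which(hemi == "left")) {
    j <- which(hemi == "right" & stem == stem[i])
    if (length(j) == 1L) {
      hom[i] <- j - 1L
      hom[j] <- i - 1L
    }
  }
  unpaired <- hemi != "midline" & is.na(hom)
  if (any(unpaired))
    stop("could not infer homologue for region(s): ",
         paste(lab[unpaired], collapse = ", "))
  regions$hemisphere <- hemi
  regions$homologue_id <- hom
  regions
}

#' Weighted node degrees (strengths)
#'
#' The degree of a node is the sum of weighted connections emanating from it
#' (the row sum of the weight matrix). Strictly positive for a validated
#' (connected) connectome.
#'
#' @param c `ndm_connectome`
#' @return named numeric vector of per-node degrees
#' @export
node_degrees <- function(c) {
  stopifnot(inherits(c, "ndm_connectome"))
  rowSums(c$weights)
}

#' Bilateral homologue pairs of a connectome
#'
#' @param c `ndm_connectome` (or a region table)
#' @return data.frame with 1-based columns `left`, `right` (matrix indices)
#'   and `pair_label` (the seed label, left-region based), one row per
#'   bilateral pair, in region-table order of the first member. Midline
#'   regions are returned as singleton seeds with `right = NA`.
#' @export
homologue_pairs <- function(c) {
  regions <- if (inherits(c, "ndm_connectome")) c$regions else c
  h <- regions$homologue_id
  seen <- rep(FALSE, nrow(regions))
  left <- integer(0); right <- integer(0); lab <- character(0)
  for (i in seq_len(nrow(regions))) {
    if (seen[i]) next
    seen[i] <- TRUE
    if (is.na(h[i])) {
      left <- c(left, i); right <- c(right, NA_integer_)
      lab <- c(lab, regions$label[i])
    } else {
      j <- h[i] + 1L
      seen[j] <- TRUE
      left <- c(left, i); right <- c(right, j)
      lab <- c(lab, pair_stem(regions$label[i]))
    }
  }
  data.frame(left = left, right = right, pair_label = lab,
             stringsAsFactors = FALSE)
}

pair_stem <- function(label) {
  s <- sub("^(ctx[-_])?(lh[-_]|rh[-_]|[Ll]eft[-_]|[Rr]ight[-_])", "", label)
  if (identical(s, label)) label else s
}

# Connected components of a logical adjacency matrix by breadth-first search.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.ndm_connectome <- function(x, ...) {
  n <- nrow(x$weights)
  np <- sum(!is.na(homologue_pairs(x)$right))
  cat("ndm_connectome: ", n, " regions (", np, " bilateral pairs), ",
      sum(x$weights > 0) / 2, " edges, total weight ",
      format(sum(x$weights) / 2, digits = 6), "\n", sep = "")
  invisible(x)
}
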