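#' Symmetric normalized graph Laplacian and its eigendecomposition
#'
#' Builds `H = I - D^{-1/2} C D^{-1/2}`, where `C` is the connectome weight
#' matrix and `D` the diagonal matrix of weighted node degrees, and
#' diagonalizes it. For a connected graph the spectrum lies in `[0, 2]` with
#' a single zero eigenvalue whose eigenvector is proportional to
#' `sqrt(degree)`.
#'
#' @param c `ndm_connectome`
#' @return object of class `ndm_laplacian`: list with `H` (N x N), `values`
#'   (eigenvalues, ascending), `vectors` (orthonormal eigenmodes as columns,
#'   same order) and the `regions` table.
#' @export
build_laplacian <- function(c) {
  stopifnot(inherits(c, "ndm_connectome"))
  d <- node_degrees(c)
  if (any(d <= 0))
    stop("zero-degree node(s): ",
         paste(c$regions$label[d <= 0], collapse = ", "),
         "; cannot form D^(-1/2)")
  dm <- 1 / sqrt(d)
  H <- -c$weights * outer(dm, dm)
  diag(H) <- diag(H) + 1
  H <- (H + t(H)) / 2           # enforce exact symmetry before eigen()
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  structure(list(H = H,
                 values = e$values[ord],
                 vectors = e$vectors[, ord, drop = FALSE],
                 regions = c$regions),
            class = "ndm_laplacian")
}

#' Propagate a seed pattern over model time (eigenmode solution)
#'
#' Closed-form heat-kernel evolution `f(t) = exp(-alpha H t) f0`, computed
#' through the eigenmode sum
#' `f(t) = sum_i exp(-alpha lambda_i t) (u_i' f0) u_i`
#' rather than repeated matrix exponentiation. Model time is in arbitrary
#' units; `alpha` only rescales the time axis.
#'
#' @param dec `ndm_laplacian`
#' @param f0 initial pattern, length-N numeric (the seed indicator for
#'   epicentre scanning)
#' @param times nonnegative numeric vector of model times (default the unit
#'   grid 0..50)
#' @param alpha positive diffusivity constant (default 1)
#' @return object of class `ndm_trajectory`: list with `times`, `alpha`,
#'   `seed_pattern` and `values`, a `length(times) x N` matrix with one row
#'   per time point. The row at `t = 0` is `f0` exactly.
#' @export
propagate <- function(dec, f0, times = 0:50, alpha = 1) {
  stopifnot(inherits(dec, "ndm_laplacian"))
  n <- length(dec$values)
  if (length(f0) != n)
    stop("f0 has length ", length(f0), " but the graph has ", n, " nodes")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  if (any(times < 0)) stop("times must be nonnegative")

  U <- dec$vectors
  coef <- drop(crossprod(U, f0))                        # u_i' f0
  decay <- exp(-alpha * outer(times, dec$values))       # T x N
  values <- tcrossprod(decay * rep(coef, each = length(times)), U)
  values[times == 0, ] <- rep(f0, each = sum(times == 0))
  colnames(values) <- dec$regions$label
  structure(list(times = times, alpha = alpha, seed_pattern = f0,
                 values = values),
            class = "ndm_trajectory")
}

#' Independent matrix-exponential oracle
#'
#' Computes `exp(-alpha H t) f0` by dense matrix exponentiation (the
#' Ward/Pade scaling-and-squaring algorithm of \pkg{Matrix}), a route fully
#' independent of the eigendecomposition used by [propagate()]. Intended for
#' verification; O(N^3) per time point.
#'
#' @param H Laplacian matrix or an `ndm_laplacian`
#' @param f0 length-N initial pattern
#' @param t single nonnegative model time
#' @param alpha positive diffusivity constant
#' @return length-N numeric vector `f(t)`
#' @export
expm_oracle <- function(H, f0, t, alpha = 1) {
  if (inherits(H, "ndm_laplacian")) H <- H$H
  H <- as.matrix(H)
  if (length(f0) != nrow(H))
    stop("f0 has length ", length(f0), " but H is ", nrow(H), " x ", ncol(H))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  if (length(t) != 1L || t < 0) stop("t must be a single nonnegative time")
  if (t == 0) return(as.numeric(f0))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(-alpha * t * H)))
  unname(drop(E %*% f0))
}

#' Export a trajectory as long-format TSV
#'
#' Columns `time`, `region_label`, `value`, one row per (time, region).
#'
#' @param traj `ndm_trajectory`
#' @param path output file
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ndm_trajectory"))
  long <- data.frame(
    time = rep(traj$times, times = ncol(traj$values)),
    region_label = rep(colnames(traj$values), each = length(traj$times)),
    value = as.vector(traj$values))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(traj)
}

#' @export
print.ndm_laplacian <- function(x, ...) {
  cat("ndm_laplacian: ", length(x$values), " nodes, spectrum [",
      format(min(x$values), digits = 3), ", ",
      format(max(x$values), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' @export
print.ndm_trajectory <- function(x, ...) {
  cat("ndm_trajectory: ", ncol(x$values), " regions x ",
      length(x$times), " time points (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}
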