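#' Vietoris-Rips persistent homology
#'
#' Computes the persistence diagram of the Vietoris-Rips filtration of a
#' distance matrix, up to homology dimension `max_dim` (at most 2), with
#' the filtration capped at `max_edge`. Every initial point contributes
#' an H0 class born at 0; classes still alive at the cap are returned
#' with `death = max_edge` and `capped = TRUE`. Computation is
#' boundary-matrix reduction over Z/2 in compiled code.
#'
#' @param dist A `distance_matrix` (see [distance_matrix()]) or a plain
#'   symmetric numeric matrix with zero diagonal.
#' @param max_dim Highest homology dimension, `<= 2` (default 2).
#' @param max_edge Filtration cap (default 1, the range of
#'   `1 - |connectivity|` distances).
#' @return A `persistence_diagram`: data frame with columns `dimension`,
#'   `birth`, `death`, `capped`, plus a `max_edge` attribute.
#' @export
vr_persistence <- function(dist, max_dim = 2, max_edge = 1) {
  d <- if (inherits(dist, "distance_matrix")) dist$values else dist
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("dist must be a square matrix", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("asymmetric input", call. = FALSE)
  if (max_dim < 0 || max_dim > 2) stop("max_dim must be 0, 1 or 2",
                                       call. = FALSE)
  m <- vr_persistence_cpp(d, as.integer(max_dim), as.numeric(max_edge))
  out <- data.frame(dimension = as.integer(m[, "dimension"]),
                    birth = m[, "birth"], death = m[, "death"],
                    capped = m[, "capped"] > 0)
  out <- out[order(out$dimension, out$birth, out$death), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_edge") <- max_edge
  class(out) <- c("persistence_diagram", "data.frame")
  out
}

diagram_points <- function(diag, dim) {
  diag[diag$dimension == dim, , drop = FALSE]
}

# grid covering the persistence graph of the given points:
# [min birth, max death]; degenerate zero-width range is flagged
vectorization_grid <- function(pts, n, max_edge = 1) {
  if (nrow(pts) == 0) return(list(grid = seq(0, max_edge, length.out = n),
                                  degenerate = TRUE))
  lo <- min(pts$birth); hi <- max(pts$death)
  if (hi <= lo) return(list(grid = rep(lo, n), degenerate = TRUE))
  list(grid = seq(lo, hi, length.out = n), degenerate = FALSE)
}

# tent function of one feature: rises from birth to the lifetime
# midpoint, falls back to zero at death
tent <- function(t, b, d) pmax(0, pmin(t - b, d - t))

#' Persistence landscape
#'
#' The k-th landscape layer evaluates, at each grid point, the k-th
#' largest of the per-feature tent functions (each tent rises linearly
#' from a feature's birth to the midpoint of its lifetime, then falls to
#' zero at its death). Layers are pointwise non-increasing in k.
#'
#' @param diag A `persistence_diagram`.
#' @param dim Homology dimension of the features to use.
#' @param n Grid resolution (default 100).
#' @param k_max Number of layers to return (default 2).
#' @return List with `grid` and a `k_max` x `n` matrix `layers`.
#' @export
persistence_landscape <- function(diag, dim, n = 100, k_max = 2) {
  pts <- diagram_points(diag, dim)
  g <- vectorization_grid(pts, n, attr(diag, "max_edge") %||% 1)
  layers <- matrix(0, k_max, n)
  if (nrow(pts) > 0 && !g$degenerate) {
    tents <- vapply(seq_len(nrow(pts)),
                    function(i) tent(g$grid, pts$birth[i], pts$death[i]),
                    numeric(n))          # n x features
    tents <- matrix(tents, nrow = n)
    srt <- apply(tents, 1, function(row) sort(row, decreasing = TRUE))
    srt <- matrix(srt, ncol = n)         # features x n
    for (k in seq_len(min(k_max, nrow(srt))))
      layers[k, ] <- srt[k, ]
  }
  list(grid = g$grid, layers = layers)
}

#' Betti curve
#'
#' Counts, at each grid point t, the features of the given dimension
#' alive at t under the closed-interval convention `birth <= t <= death`
#' (a feature still counts at its death value).
#'
#' @inheritParams persistence_landscape
#' @return List with `grid` and integer `values`.
#' @export
betti_curve <- function(diag, dim, n = 100) {
  pts <- diagram_points(diag, dim)
  g <- vectorization_grid(pts, n, attr(diag, "max_edge") %||% 1)
  vals <- integer(n)
  if (nrow(pts) > 0) {
    for (i in seq_len(nrow(pts)))
      vals <- vals + as.integer(pts$birth[i] <= g$grid &
                                  g$grid <= pts$death[i])
  }
  list(grid = g$grid, values = vals)
}

#' Persistent entropy
#'
#' Shannon entropy (natural log by default) of the normalized feature
#' lifetimes `p_i = (d_i - b_i) / sum(d_i - b_i)` in one homology
#' dimension. A single feature (or none, or all-zero lifetimes) gives 0.
#'
#' @inheritParams persistence_landscape
#' @param base Logarithm base (default `exp(1)`).
#' @return Non-negative scalar.
#' @export
persistent_entropy <- function(diag, dim, base = exp(1)) {
  pts <- diagram_points(diag, dim)
  life <- pts$death - pts$birth
  life <- life[life > 0]
  if (length(life) == 0) return(0)
  p <- life / sum(life)
  -sum(p * log(p, base = base))
}

#' Persistence-landscape amplitude
#'
#' Grid p-norm of the first `n_layers` landscape layers:
#' `(sum_k sum_j lambda_k(t_j)^p)^(1/p)` over an `n`-point grid covering
#' the diagram.
#'
#' @param diag A `persistence_diagram`.
#' @param dim Homology dimension.
#' @param n_layers Number of layers (1 or 2).
#' @param p Norm order (default 1).
#' @param n Grid resolution (default 100).
#' @return Non-negative scalar.
#' @export
landscape_amplitude <- function(diag, dim, n_layers = 1, p = 1, n = 100) {
  pl <- persistence_landscape(diag, dim, n = n, k_max = n_layers)
  sum(pl$layers[seq_len(n_layers), , drop = FALSE]^p)^(1 / p)
}

#' Betti-curve amplitude
#'
#' Grid p-norm of the Betti curve: `(sum_j beta(t_j)^p)^(1/p)`.
#'
#' @param curve A [betti_curve()] result.
#' @param p Norm order (default 1).
#' @return Non-negative scalar.
#' @export
betti_amplitude <- function(curve, p = 1) {
  sum(curve$values^p)^(1 / p)
}

#' Denoise a persistence diagram
#'
#' Drops features with lifetime below `min_lifetime` and, for feature
#' extraction, all dimensions above 1 (H2 carries no usable signal in
#' these networks).
#'
#' @param diag A `persistence_diagram`.
#' @param min_lifetime Minimum lifetime to keep (default 0: keep all).
#' @param drop_h2 Drop dimensions above 1 (default TRUE).
#' @return Filtered `persistence_diagram`.
#' @export
denoise_diagram <- function(diag, min_lifetime = 0, drop_h2 = TRUE) {
  if (min_lifetime < 0) stop("min_lifetime must be >= 0", call. = FALSE)
  keep <- (diag$death - diag$birth) >= min_lifetime
  if (drop_h2) keep <- keep & diag$dimension <= 1
  out <- diag[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_edge") <- attr(diag, "max_edge")
  class(out) <- c("persistence_diagram", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
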