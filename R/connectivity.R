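#' Pearson correlation connectivity
#'
#' Product-moment correlation between every pair of channels of a
#' segment.
#'
#' @param seg A `band_segment` (see [segment()]).
#' @return A `connectivity_matrix` (symmetric, unit diagonal,
#'   `metric = "pcc"`).
#' @export
pcc_matrix <- function(seg) {
  x <- seg$data
  if (ncol(x) < 2) stop("need at least 2 samples per channel", call. = FALSE)
  v <- apply(x, 1, var)
  if (any(v < .Machine$double.eps)) {
    bad <- seg$channel_labels[which(v < .Machine$double.eps)]
    stop("zero-variance channel(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- cor(t(x))
  diag(m) <- 1
  connectivity_matrix(m, "pcc", seg$channel_labels)
}

# analytic signal via FFT: zero the negative frequencies, double the
# positive ones (Marple construction)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value connectivity
#'
#' PLV between channels i and j is the modulus of the time-averaged unit
#' phasor of their instantaneous phase difference,
#' `|mean(exp(1i * (phi_i - phi_j)))|`, with phases taken from the
#' analytic (Hilbert) signal of each band-filtered channel. Values lie
#' in `[0, 1]`; the diagonal is fixed at 1.
#'
#' @param seg A band-filtered `band_segment`.
#' @return A `connectivity_matrix` with `metric = "plv"`.
#' @export
plv_matrix <- function(seg) {
  x <- seg$data
  if (!is.na(seg$band)) {
    lo <- EEG_BANDS[[seg$band]][1]
    if (ncol(x) < 2 * seg$fs / lo)
      warning("segment shorter than 2 cycles of the ", seg$band,
              " band lower edge; PLV may be unstable")
  }
  z <- t(apply(x, 1, function(ch) {
    a <- analytic_signal(ch)
    a / Mod(a)
  }))
  m <- Mod(z %*% Conj(t(z))) / ncol(x)
  m <- (m + t(m)) / 2
  m[m > 1] <- 1
  diag(m) <- 1
  connectivity_matrix(m, "plv", seg$channel_labels)
}

connectivity_matrix <- function(values, metric, channels = NULL) {
  if (!is.null(channels)) dimnames(values) <- list(channels, channels)
  structure(list(metric = metric, values = values),
            class = "connectivity_matrix")
}

#' Connectivity-to-distance transform
#'
#' Maps a coupling matrix to a dissimilarity suitable for Vietoris-Rips
#' filtration: `d_ij = 1 - |a_ij|` elementwise, with the diagonal forced
#' to zero. Both perfectly correlated and perfectly anti-correlated
#' channel pairs get distance 0.
#'
#' @param conn A `connectivity_matrix`.
#' @return A `distance_matrix` (symmetric, zero diagonal, entries in
#'   `[0, 1]`).
#' @export
distance_matrix <- function(conn) {
  d <- 1 - abs(conn$values)
  d[d < 0] <- 0
  diag(d) <- 0
  structure(list(values = d, metric = conn$metric),
            class = "distance_matrix")
}

#' Build a classifier adjacency from connectivity
#'
#' Either the full weighted coupling matrix, or a sparse graph keeping
#' edges with coupling at or above a threshold (0.3 is the pipeline
#' default; 0.5 and 0.8 are the stricter ablation settings). Self-loops
#' are excluded here — the model's normalization stage adds them.
#'
#' @param conn A `connectivity_matrix` (PLV for thresholded mode).
#' @param mode `"thresholded"` or `"full"`.
#' @param tau Threshold in (0, 1); used in thresholded mode.
#' @param weighted Keep edge weights after thresholding (default binary).
#' @return An `adjacency` object.
#' @export
threshold_adjacency <- function(conn, mode = c("thresholded", "full"),
                                tau = 0.3, weighted = FALSE) {
  mode <- match.arg(mode)
  a <- conn$values
  if (mode == "full") {
    diag(a) <- 0
    return(structure(list(mode = "full", tau = NA_real_, values = a),
                     class = "adjacency"))
  }
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)", call. = FALSE)
  keep <- a >= tau
  out <- if (weighted) a * keep else keep * 1
  diag(out) <- 0
  structure(list(mode = "thresholded", tau = tau, values = out),
            class = "adjacency")
}
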