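#' Time-domain node features
#'
#' Per-channel mean absolute value, standard deviation (n-1
#' denominator), skewness and excess kurtosis (standardized central
#' moments). A constant channel has undefined skewness/kurtosis, which
#' are returned as 0 with a warning.
#'
#' @param seg A `band_segment`.
#' @return Data frame with one row per channel.
#' @export
time_domain_features <- function(seg) {
  x <- seg$data
  if (ncol(x) < 4) stop("need at least 4 samples", call. = FALSE)
  out <- t(apply(x, 1, function(ch) {
    m <- mean(ch)
    c2 <- mean((ch - m)^2)
    if (c2 < .Machine$double.eps) return(c(abs(m), 0, NA, NA))
    c(mean(abs(ch)), sd(ch),
      mean((ch - m)^3) / c2^1.5,
      mean((ch - m)^4) / c2^2 - 3)
  }))
  if (anyNA(out)) {
    warning("constant channel(s): skewness/kurtosis set to 0")
    out[is.na(out)] <- 0
  }
  data.frame(channel = seg$channel_labels, mav = out[, 1], sd = out[, 2],
             skewness = out[, 3], kurtosis = out[, 4])
}

# Welch PSD of one channel: Hann-windowed overlapping sub-segments,
# averaged one-sided periodograms. Returns freq and psd (power / Hz).
welch_psd <- function(x, fs, nperseg = min(256, length(x)), overlap = 0.5) {
  step <- max(1, floor(nperseg * (1 - overlap)))
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)
  u <- sum(w^2)
  acc <- numeric(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)] * w
    acc <- acc + Mod(fft(seg))^2
  }
  psd <- acc / (length(starts) * fs * u)
  half <- floor(nperseg / 2) + 1
  psd <- psd[seq_len(half)]
  scale2 <- rep(2, half); scale2[1] <- 1
  if (nperseg %% 2 == 0) scale2[half] <- 1
  list(freq = (seq_len(half) - 1) * fs / nperseg, psd = psd * scale2)
}

#' Band power node feature
#'
#' Integrated Welch power spectral density of each channel within the
#' segment's frequency band (units: signal-units squared). An in-band
#' sinusoid of amplitude A contributes approximately A^2 / 2.
#'
#' @param seg A `band_segment` with a known `band`.
#' @param band Band name; defaults to the segment's band.
#' @param nperseg Welch sub-window length (default `min(256, n)`).
#' @return Numeric vector, one value per channel.
#' @export
band_power <- function(seg, band = seg$band, nperseg = NULL) {
  if (is.na(band)) stop("segment has no band; supply one", call. = FALSE)
  lims <- EEG_BANDS[[match.arg(band, names(EEG_BANDS))]]
  if (is.null(nperseg)) nperseg <- min(256, ncol(seg$data))
  apply(seg$data, 1, function(ch) {
    p <- welch_psd(ch, seg$fs, nperseg = nperseg)
    sel <- p$freq >= lims[1] & p$freq <= lims[2]
    df <- p$freq[2] - p$freq[1]
    sum(p$psd[sel]) * df
  })
}

#' Local network node features
#'
#' Unweighted local clustering coefficient and normalized shortest-path
#' betweenness centrality of each node of a binary adjacency. Isolated
#' nodes score 0 on both.
#'
#' @param adj An `adjacency` (binary) or 0/1 matrix.
#' @return Data frame with `clustering_coeff` and `betweenness` per node.
#' @export
local_network_features <- function(adj) {
  a <- if (inherits(adj, "adjacency")) adj$values else adj
  g <- igraph::graph_from_adjacency_matrix((a != 0) * 1, mode = "undirected",
                                           diag = FALSE)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  bt <- igraph::betweenness(g, normalized = TRUE)
  bt[!is.finite(bt)] <- 0   # degenerate normalization on < 3 nodes
  data.frame(clustering_coeff = cc, betweenness = unname(bt))
}

HIGHER_ORDER_NAMES <- c("LandAmp_H0_N1", "LandAmp_H0_N2", "LandAmp_H1_N1",
                        "LandAmp_H1_N2", "BettiAmp_H0", "BettiAmp_H1",
                        "PersistenceEntropy_0", "PersistenceEntropy_1")

#' Higher-order (topological) feature vector
#'
#' Runs Vietoris-Rips persistence (max dimension 2, filtration cap 1) on
#' a distance matrix, denoises (drops H2), and summarizes H0 and H1 as
#' eight graph-level descriptors: landscape amplitudes for 1 and 2
#' layers, Betti-curve amplitudes, and persistent entropies (p = 1,
#' 100-point grids).
#'
#' @param dist A `distance_matrix`.
#' @param min_lifetime Denoising threshold (default 0).
#' @param n Grid resolution (default 100).
#' @param max_dim Homology dimension computed. All eight descriptors
#'   draw only on H0/H1 (the denoising rule discards H2), so the
#'   default 1 gives results identical to computing H2 and dropping it;
#'   raise to 2 to pay for (and then discard) the H2 computation.
#' @return Named numeric vector of length 8.
#' @export
higher_order_vector <- function(dist, min_lifetime = 0, n = 100,
                                max_dim = 1) {
  diag <- vr_persistence(dist, max_dim = max_dim, max_edge = 1)
  diag <- denoise_diagram(diag, min_lifetime = min_lifetime)
  vals <- c(
    landscape_amplitude(diag, 0, n_layers = 1, p = 1, n = n),
    landscape_amplitude(diag, 0, n_layers = 2, p = 1, n = n),
    landscape_amplitude(diag, 1, n_layers = 1, p = 1, n = n),
    landscape_amplitude(diag, 1, n_layers = 2, p = 1, n = n),
    betti_amplitude(betti_curve(diag, 0, n = n), p = 1),
    betti_amplitude(betti_curve(diag, 1, n = n), p = 1),
    persistent_entropy(diag, 0),
    persistent_entropy(diag, 1))
  names(vals) <- HIGHER_ORDER_NAMES
  vals
}

CANDIDATE_FEATURES <- c("mav", "sd", "skewness", "kurtosis", "band_power",
                        "clustering_coeff", "betweenness",
                        HIGHER_ORDER_NAMES)

#' Extract the candidate node-feature matrix of one segment
#'
#' Builds the full channels x 15 candidate matrix: four time-domain
#' moments, band power, two local network descriptors (from the
#' thresholded PLV adjacency), and the eight higher-order topological
#' descriptors from the chosen connectivity metric's distance matrix
#' (broadcast to every node, since they are graph-level quantities).
#'
#' @param seg A band-filtered `band_segment`.
#' @param metric `"plv"` or `"pcc"` — connectivity feeding the distance
#'   matrix and higher-order features.
#' @param graph_mode `"thresholded"` or `"full"` classifier adjacency
#'   (always built from PLV).
#' @param tau PLV threshold for the adjacency (default 0.3).
#' @return A `graph_sample`: list with `features` (channels x 15 matrix),
#'   `adjacency`, `label`, `subject_id`, `band`, `origin = "real"`.
#' @export
extract_features <- function(seg, metric = c("plv", "pcc"),
                             graph_mode = "thresholded", tau = 0.3) {
  metric <- match.arg(metric)
  plv <- plv_matrix(seg)
  conn <- if (metric == "plv") plv else pcc_matrix(seg)
  adj <- threshold_adjacency(plv, mode = graph_mode, tau = tau)
  td <- time_domain_features(seg)
  bp <- band_power(seg)
  net <- local_network_features(adj)
  ho <- higher_order_vector(distance_matrix(conn))
  n_ch <- nrow(seg$data)
  feats <- cbind(mav = td$mav, sd = td$sd, skewness = td$skewness,
                 kurtosis = td$kurtosis, band_power = bp,
                 clustering_coeff = net$clustering_coeff,
                 betweenness = net$betweenness,
                 matrix(rep(ho, each = n_ch), n_ch,
                        dimnames = list(NULL, HIGHER_ORDER_NAMES)))
  rownames(feats) <- seg$channel_labels
  structure(list(features = feats, adjacency = adj, label = seg$label,
                 subject_id = seg$subject_id, band = seg$band,
                 origin = "real"),
            class = "graph_sample")
}

#' Feature selection policies
#'
#' `"paper_fixed"` returns the 11 retained features: mean absolute
#' value, standard deviation, band power, betweenness centrality, and
#' all eight higher-order descriptors except `PersistenceEntropy_1`
#' (i.e. 7 of them). `"mi_threshold"` keeps candidates whose mutual
#' information with the label is above `cutoff`.
#'
#' @param candidates Character vector of candidate feature names
#'   (default all 15).
#' @param policy `"paper_fixed"` or `"mi_threshold"`.
#' @param mi Named MI scores (required for `"mi_threshold"`).
#' @param cutoff MI cutoff (default 0).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(candidates = CANDIDATE_FEATURES,
                            policy = c("paper_fixed", "mi_threshold"),
                            mi = NULL, cutoff = 0) {
  policy <- match.arg(policy)
  if (policy == "paper_fixed") {
    keep <- c("mav", "sd", "band_power", "betweenness",
              setdiff(HIGHER_ORDER_NAMES, "PersistenceEntropy_1"))
    return(intersect(candidates, keep))
  }
  if (is.null(mi)) stop("mi_threshold policy needs MI scores", call. = FALSE)
  candidates[mi[candidates] >= cutoff]
}

# Ross (2014) nearest-neighbour MI estimator between a continuous
# variable and a discrete label, in nats; clamped at 0.
mi_mixed_knn <- function(x, labels, k = 3, jitter_seed = 1) {
  n <- length(x)
  x <- x + with_local_seed(jitter_seed,
                           rnorm(n, 0, (sd(x) + 1e-12) * 1e-10))
  classes <- split(seq_len(n), labels)
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  psi_nx <- numeric(n); psi_m <- numeric(n); psi_k <- numeric(n)
  for (idx in classes) {
    nc <- length(idx)
    kk <- min(k, nc - 1)
    if (kk < 1) stop("class with a single member", call. = FALSE)
    for (i in idx) {
      d_same <- sort(abs(x[idx] - x[i]))[kk + 1]   # k-th excluding self
      m <- sum(abs(x - x[i]) <= d_same) - 1
      psi_nx[i] <- digamma(nc)
      psi_m[i] <- digamma(m)
      psi_k[i] <- digamma(kk)
    }
  }
  max(0, digamma(n) - mean(psi_nx) + mean(psi_k) - mean(psi_m))
}

#' Mutual information feature scores
#'
#' Scores every candidate feature by its mutual information with the
#' class label, using a nearest-neighbour estimator for mixed
#' continuous/discrete pairs (k = 3). Node-varying features are averaged
#' over nodes before scoring, giving one value per sample.
#'
#' @param samples List of `graph_sample`s with candidate feature
#'   matrices, or a samples x features numeric matrix.
#' @param labels Class labels (taken from the samples if a list).
#' @param k Neighbour count (default 3).
#' @return Named numeric vector of non-negative MI scores (nats).
#' @export
mutual_information_scores <- function(samples, labels = NULL, k = 3) {
  if (is.list(samples) && !is.data.frame(samples)) {
    labels <- vapply(samples, `[[`, "", "label")
    x <- t(vapply(samples, function(s) colMeans(s$features),
                  numeric(ncol(samples[[1]]$features))))
  } else {
    x <- as.matrix(samples)
  }
  if (length(unique(labels)) < 2)
    stop("need samples from at least 2 classes", call. = FALSE)
  scores <- vapply(seq_len(ncol(x)),
                   function(j) mi_mixed_knn(x[, j], labels, k = k,
                                            jitter_seed = j), 0)
  names(scores) <- colnames(x)
  scores
}

#' Normalize features with training-set statistics
#'
#' Z-scores every feature column using the mean and standard deviation
#' pooled over all nodes of all *training* samples, then applies those
#' frozen statistics to `apply_to`. A zero-variance feature is centered
#' and left at scale 1, with a warning.
#'
#' @param train List of `graph_sample`s defining the statistics.
#' @param apply_to Samples to transform (default `train`).
#' @return `apply_to` with normalized feature matrices; the statistics
#'   are attached as attributes `center` and `scale`.
#' @export
normalize_features <- function(train, apply_to = train) {
  stacked <- do.call(rbind, lapply(train, `[[`, "features"))
  ctr <- colMeans(stacked)
  scl <- apply(stacked, 2, sd)
  zero <- !is.finite(scl) | scl < 1e-12
  if (any(zero)) {
    warning("zero-variance feature(s): ",
            paste(colnames(stacked)[zero], collapse = ", "))
    scl[zero] <- 1
  }
  out <- lapply(apply_to, function(s) {
    s$features <- sweep(sweep(s$features, 2, ctr), 2, scl, "/")
    s
  })
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' SMOTE oversampling of the minority class
#'
#' Balances the two classes by synthesizing minority samples: each
#' synthetic feature matrix is `x + u * (x_nn - x)` with `u ~ U(0, 1)`,
#' where `x_nn` is one of the `k` nearest minority neighbours of a
#' randomly drawn minority sample (Euclidean distance on the flattened
#' feature matrix). Synthetic samples copy their base sample's adjacency,
#' are tagged `origin = "smote"`, and receive fresh subject ids above the
#' real range, grouped into pseudo-subjects of the cohort's typical
#' segments-per-subject count so subject-wise splitting stays meaningful.
#'
#' @param samples List of `graph_sample`s.
#' @param k Neighbour count (default 5; reduced with a warning if the
#'   minority class is too small).
#' @param seed RNG seed (default 42).
#' @return Augmented list of samples (balanced classes).
#' @export
smote_oversample <- function(samples, k = 5, seed = 42) {
  labels <- vapply(samples, `[[`, "", "label")
  tab <- table(labels)
  if (length(tab) < 2) stop("need two classes", call. = FALSE)
  if (tab[1] == tab[2]) return(samples)
  minority <- names(tab)[which.min(tab)]
  min_idx <- which(labels == minority)
  n_syn <- max(tab) - min(tab)
  if (length(min_idx) <= k) {
    warning("minority class has <= k samples; reducing k to ",
            length(min_idx) - 1)
    k <- length(min_idx) - 1
  }
  if (k < 1) stop("minority class too small for SMOTE", call. = FALSE)
  flat <- do.call(rbind, lapply(samples[min_idx],
                                function(s) as.numeric(s$features)))
  dmat <- as.matrix(stats::dist(flat))
  nn <- apply(dmat, 1, function(row) order(row)[2:(k + 1)])
  nn <- matrix(nn, ncol = length(min_idx))     # k x n_min
  ids <- suppressWarnings(as.numeric(vapply(samples, `[[`, "", "subject_id")))
  next_id <- max(c(50, ids), na.rm = TRUE)
  per_subject <- stats::median(table(vapply(samples, `[[`, "", "subject_id")))
  with_local_seed(seed, {
    bases <- sample(seq_along(min_idx), n_syn, replace = TRUE)
    picks <- sample(seq_len(k), n_syn, replace = TRUE)
    gaps <- runif(n_syn)
    syn <- lapply(seq_len(n_syn), function(i) {
      b <- bases[i]
      nb <- nn[picks[i], b]
      s <- samples[[min_idx[b]]]
      f <- flat[b, ] + gaps[i] * (flat[nb, ] - flat[b, ])
      s$features <- matrix(f, nrow(s$features), ncol(s$features),
                           dimnames = dimnames(s$features))
      s$origin <- "smote"
      s$subject_id <- as.character(next_id + ceiling(i / per_subject))
      s
    })
    c(samples, syn)
  })
}
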