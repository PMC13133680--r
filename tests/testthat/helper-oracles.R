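# Independent oracles, deliberately written with different algorithms and
# data structures than the package implementation.

# --- persistent homology: dense GF(2) boundary-matrix reduction ----------

oracle_vr_persistence <- function(d, max_dim = 2, max_edge = 1) {
  n <- nrow(d)
  simp <- list()
  for (size in seq_len(min(n, max_dim + 2))) {
    for (comb in utils::combn(n, size, simplify = FALSE)) {
      val <- if (size == 1) 0 else max(d[t(utils::combn(comb, 2))])
      if (val <= max_edge)
        simp[[length(simp) + 1]] <- list(v = comb, dim = size - 1,
                                         value = val)
    }
  }
  key <- vapply(simp, function(s) paste(s$v, collapse = "-"), "")
  ord <- order(vapply(simp, `[[`, 0, "value"),
               vapply(simp, `[[`, 0, "dim"),
               key)
  simp <- simp[ord]
  key <- key[ord]
  m <- length(simp)
  B <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    s <- simp[[j]]
    if (s$dim == 0) next
    for (drop in seq_along(s$v)) {
      fk <- paste(s$v[-drop], collapse = "-")
      B[match(fk, key), j] <- TRUE
    }
  }
  low <- function(col) { w <- which(col); if (length(w)) max(w) else 0L }
  pivot <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    repeat {
      l <- low(B[, j])
      if (l == 0L) break
      if (is.na(pivot[l])) { pivot[l] <- j; break }
      B[, j] <- xor(B[, j], B[, pivot[l]])
    }
  }
  rows <- list()
  zero_col <- vapply(seq_len(m), function(j) low(B[, j]) == 0L, TRUE)
  for (i in seq_len(m)) {
    if (!zero_col[i]) next
    dm <- simp[[i]]$dim
    if (dm > max_dim) next
    killer <- pivot[i]
    if (!is.na(killer)) {
      de <- simp[[killer]]$value
      if (de > simp[[i]]$value)
        rows[[length(rows) + 1]] <- c(dm, simp[[i]]$value, de, 0)
    } else {
      rows[[length(rows) + 1]] <- c(dm, simp[[i]]$value, max_edge, 1)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
  colnames(out) <- c("dimension", "birth", "death", "capped")
  out
}

diagram_to_matrix <- function(diag) {
  m <- cbind(diag$dimension, diag$birth, diag$death, as.numeric(diag$capped))
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  colnames(m) <- c("dimension", "birth", "death", "capped")
  m
}

random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- round(runif(n * (n - 1) / 2, 0.05, 0.95), 3)
  d + t(d)
}

# --- Mann-Whitney: exhaustive pair counting ------------------------------

oracle_u <- function(a, b) {
  u1 <- 0
  for (x in a) for (y in b) u1 <- u1 + (x > y) + 0.5 * (x == y)
  min(u1, length(a) * length(b) - u1)
}

# --- cycles: brute-force enumeration of all simple cycles ----------------

# all simple cycles of a binary adjacency as sorted node vectors, by
# trying every subset and every cyclic order
oracle_all_cycles <- function(a) {
  n <- nrow(a)
  found <- list()
  if (n < 3) return(found)
  for (size in 3:n) {
    for (sub in utils::combn(n, size, simplify = FALSE)) {
      first <- sub[1]
      rest <- sub[-1]
      perms <- perms_of(rest)
      for (p in perms) {
        cyc <- c(first, p)
        if (cyc[2] > cyc[length(cyc)]) next  # one direction only
        edges_ok <- all(a[cbind(cyc, c(cyc[-1], cyc[1]))] != 0)
        if (edges_ok) found[[length(found) + 1]] <- sort(cyc)
      }
    }
  }
  unique(found)
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

# cycle-count matrix from the per-node minimal cycles of the full
# enumeration
oracle_cycle_counts <- function(a) {
  n <- nrow(a)
  all_cyc <- oracle_all_cycles(a)
  lens <- vapply(all_cyc, length, 0L)
  keep <- rep(FALSE, length(all_cyc))
  for (i in seq_len(n)) {
    through <- vapply(all_cyc, function(cy) i %in% cy, TRUE)
    if (!any(through)) next
    gi <- min(lens[through])
    keep[through & lens == gi] <- TRUE
  }
  cmat <- matrix(0, n, n)
  for (cy in all_cyc[keep]) cmat[cy, cy] <- cmat[cy, cy] + 1
  cmat
}

random_graph <- function(n, p) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# --- shared fixtures -----------------------------------------------------

make_segment <- function(data, fs = 250, band = "gamma",
                         channels = paste0("ch", seq_len(nrow(data))),
                         label = "mild", subject_id = "1") {
  structure(list(subject_id = subject_id, band = band, window_index = 1L,
                 window_seconds = ncol(data) / fs, fs = fs, label = label,
                 channel_labels = channels, data = data),
            class = "band_segment")
}

# distance matrix with a planted low-distance ring among `ring` nodes
ring_distance <- function(n, ring, d_ring = 0.2, d_bg = 0.9) {
  d <- matrix(d_bg, n, n)
  for (i in seq_along(ring)) {
    a <- ring[i]; b <- ring[if (i == length(ring)) 1 else i + 1]
    d[a, b] <- d_ring; d[b, a] <- d_ring
  }
  diag(d) <- 0
  d
}

# small graph samples with controllable features for model/feature tests
toy_samples <- function(n_per_class = 10, n_nodes = 5, n_feat = 3,
                        sep = 2, seed = 1, n_trials = 2) {
  withr::with_seed(seed, {
    out <- list()
    id <- 0
    for (cl in c("mild", "moderate")) {
      for (i in seq_len(n_per_class / n_trials)) {
        id <- id + 1
        for (tr in seq_len(n_trials)) {
          shift <- if (cl == "moderate") sep else 0
          f <- matrix(rnorm(n_nodes * n_feat, shift), n_nodes, n_feat)
          colnames(f) <- paste0("f", seq_len(n_feat))
          a <- matrix(1, n_nodes, n_nodes); diag(a) <- 0
          out[[length(out) + 1]] <- structure(
            list(features = f, adjacency = a, label = cl,
                 subject_id = as.character(id), band = "gamma",
                 origin = "real"),
            class = "graph_sample")
        }
      }
    }
    out
  })
}
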