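#' Lifetime subgraph of the most persistent homology class
#'
#' Runs Vietoris-Rips persistence (max dimension 2, cap 1.0) on a
#' distance matrix, picks the finite (non-capped) cycle class (H1 or H2;
#' H0 components are not cycles) with the longest persistence — ties
#' broken by earliest birth, then lowest dimension — and returns the
#' graph of all edges whose distance enters the filtration within that
#' class's `[birth, death]` interval.
#'
#' @param dist A `distance_matrix` or plain symmetric matrix.
#' @param max_edge Filtration cap (default 1).
#' @return A `lifetime_subgraph`: list with `nodes` (indices), `edges`
#'   (data frame `from`, `to`, `value`), `source_class`, and the binary
#'   `adjacency` over all original nodes. Empty (with a warning) when no
#'   finite class exists.
#' @export
longest_class_subgraph <- function(dist, max_edge = 1) {
  d <- if (inherits(dist, "distance_matrix")) dist$values else dist
  diag <- vr_persistence(d, max_dim = 2, max_edge = max_edge)
  fin <- diag[!diag$capped & diag$dimension >= 1, , drop = FALSE]
  n <- nrow(d)
  empty <- function() {
    warning("no finite-persistence class; empty lifetime subgraph")
    structure(list(nodes = integer(0),
                   edges = data.frame(from = integer(0), to = integer(0),
                                      value = numeric(0)),
                   source_class = NULL,
                   adjacency = matrix(0, n, n)),
              class = "lifetime_subgraph")
  }
  if (nrow(fin) == 0) return(empty())
  life <- fin$death - fin$birth
  ord <- order(-life, fin$birth, fin$dimension)
  cls <- fin[ord[1], ]
  idx <- which(upper.tri(d) & d >= cls$birth & d <= cls$death &
                 d <= max_edge, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty())
  edges <- data.frame(from = idx[, 1], to = idx[, 2],
                      value = d[idx])
  adj <- matrix(0, n, n)
  adj[cbind(edges$from, edges$to)] <- 1
  adj <- adj + t(adj)
  structure(list(nodes = sort(unique(c(edges$from, edges$to))),
                 edges = edges,
                 source_class = list(dimension = cls$dimension,
                                     birth = cls$birth, death = cls$death),
                 adjacency = adj),
            class = "lifetime_subgraph")
}

# all simple cycles of length exactly len through node v, as canonical
# sorted node vectors; depth-limited DFS anchored at v
cycles_through <- function(adjlist, v, len) {
  found <- list()
  path <- integer(len)
  path[1] <- v
  visit <- function(depth) {
    cur <- path[depth]
    for (u in adjlist[[cur]]) {
      if (depth == len) {
        if (u == v) {
          # close the cycle; canonical: second element < last to halve
          # the two traversal directions
          if (path[2] < path[len]) found[[length(found) + 1]] <<- sort(path)
        }
      } else {
        if (u > v && !(u %in% path[seq_len(depth)])) {
          path[depth + 1] <<- u
          visit(depth + 1)
        }
      }
    }
  }
  if (len >= 3) visit(1)
  unique(found)
}

#' Shortest cycles and the cycle-count matrix
#'
#' For every node, enumerates all of its minimum-length simple cycles
#' (the node's girth); the union over nodes is the considered cycle set.
#' Entry `c[i, j]` counts the cycles in that set passing through both
#' `i` and `j`; the diagonal `c[i, i]` counts those through `i`.
#'
#' @param adjacency Binary symmetric matrix, an `adjacency`, or an
#'   igraph graph.
#' @return List with `cycles` (list of node-index vectors) and the
#'   symmetric count matrix `c`.
#' @export
shortest_cycles <- function(adjacency) {
  a <- if (inherits(adjacency, "adjacency")) adjacency$values
  else if (inherits(adjacency, "igraph"))
    as.matrix(igraph::as_adjacency_matrix(adjacency))
  else adjacency
  a <- (a != 0) * 1
  n <- nrow(a)
  adjlist <- lapply(seq_len(n), function(i) which(a[i, ] != 0))
  # node index relabeling so each cycle is found from its smallest node:
  # enumerate cycles anchored at v using only nodes > v, so for node i's
  # minimal cycles we search anchored at every node but keep cycles
  # containing i
  all_min <- list()
  girth_of <- rep(NA_integer_, n)
  # collect cycles by increasing length; a node's minimal cycles are the
  # first length at which any cycle contains it
  max_len <- n
  pending <- seq_len(n)
  found_by_len <- list()
  for (len in 3:max_len) {
    if (!length(pending)) break
    cyc <- list()
    for (v in seq_len(n)) {
      cyc <- c(cyc, cycles_through(adjlist, v, len))
    }
    cyc <- unique(cyc)
    found_by_len[[len]] <- cyc
    if (length(cyc)) {
      members <- unique(unlist(cyc))
      newly <- intersect(pending, members)
      girth_of[newly] <- len
      pending <- setdiff(pending, members)
    }
    # stop early once every node with any cycle is resolved: nodes never
    # on a cycle keep NA; detect via 2-core
    if (len >= 3 && !length(pending)) break
    if (len == 3) {
      core <- two_core(a)
      pending <- intersect(pending, core)
      if (!length(pending)) break
    }
  }
  cycles <- list()
  for (i in seq_len(n)) {
    if (is.na(girth_of[i])) next
    for (cy in found_by_len[[girth_of[i]]])
      if (i %in% cy) cycles[[length(cycles) + 1]] <- cy
  }
  cycles <- unique(cycles)
  cmat <- matrix(0, n, n)
  for (cy in cycles) {
    cmat[cy, cy] <- cmat[cy, cy] + 1
  }
  list(cycles = cycles, c = cmat)
}

# nodes of the 2-core (iteratively strip degree <= 1); only these can
# lie on a cycle
two_core <- function(a) {
  keep <- rep(TRUE, nrow(a))
  repeat {
    deg <- rowSums(a[, keep, drop = FALSE]) * keep
    drop <- keep & deg <= 1
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  which(keep)
}

#' Cycle ratio of every node
#'
#' Node importance from shared shortest cycles: for node i,
#' `r_i = sum over j with c[i, j] > 0 of c[i, j] / c[j, j]`, and
#' `r_i = 0` for nodes on no shortest cycle. On vertex-transitive graphs
#' every node shares one value (e.g. triangle: 3; 4-cycle: 4).
#'
#' @param cmat Cycle-count matrix from [shortest_cycles()] (the `c`
#'   element), or its full result list.
#' @return Numeric vector of non-negative per-node ratios.
#' @export
cycle_ratio <- function(cmat) {
  if (is.list(cmat)) cmat <- cmat$c
  n <- nrow(cmat)
  vapply(seq_len(n), function(i) {
    if (cmat[i, i] == 0) return(0)
    j <- which(cmat[i, ] > 0)
    sum(cmat[i, j] / diag(cmat)[j])
  }, 0)
}

#' Per-channel cycle-ratio map of one subject
#'
#' Averages, over a subject's segments, the cycle ratio computed on each
#' segment's longest-class lifetime subgraph.
#'
#' @param dists List of `distance_matrix` objects (one per segment).
#' @param channels Channel labels.
#' @return Numeric vector (one mean ratio per channel).
#' @export
subject_cycle_ratios <- function(dists, channels) {
  acc <- matrix(0, length(dists), length(channels))
  for (i in seq_along(dists)) {
    sg <- suppressWarnings(longest_class_subgraph(dists[[i]]))
    if (length(sg$nodes))
      acc[i, ] <- cycle_ratio(shortest_cycles(sg$adjacency))
  }
  colMeans(acc)
}

#' Group comparison of regional cycle ratios
#'
#' Per-channel Mann-Whitney comparison of subject-averaged cycle ratios
#' between the two severity groups, with Benjamini-Hochberg adjustment
#' across channels (raw and adjusted p-values both reported).
#'
#' @param maps_mild,maps_moderate Matrices, subjects x channels, of
#'   subject-mean cycle ratios.
#' @param channels Channel labels.
#' @return Data frame: `channel`, `u`, `p`, `p_adj`.
#' @export
group_compare <- function(maps_mild, maps_moderate,
                          channels = colnames(maps_mild)) {
  if (nrow(maps_mild) == 0 || nrow(maps_moderate) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  res <- lapply(seq_len(ncol(maps_mild)), function(j)
    mann_whitney_u(maps_mild[, j], maps_moderate[, j]))
  out <- data.frame(channel = if (is.null(channels))
    as.character(seq_len(ncol(maps_mild))) else channels,
    u = vapply(res, `[[`, 0, "u_statistic"),
    p = vapply(res, `[[`, 0, "p"))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Export a cycle-ratio region map
#'
#' Writes a channel-to-ratio CSV and, optionally (requires ggplot2), a
#' topographic scatter over approximate 10-20 electrode positions.
#'
#' @param ratios Named numeric vector (names = channel labels) or a
#'   vector plus `channels`.
#' @param path Output CSV path.
#' @param channels Channel labels (defaults to `names(ratios)`).
#' @param group,band Optional annotation columns.
#' @param plot_path Optional PNG path for the topographic map.
#' @return `path`, invisibly.
#' @export
export_region_map <- function(ratios, path, channels = names(ratios),
                              group = NA, band = NA, plot_path = NULL) {
  df <- data.frame(channel = channels, cycle_ratio = as.numeric(ratios),
                   group = group, band = band)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(plot_path) && requireNamespace("ggplot2", quietly = TRUE)) {
    xy <- electrode_positions()
    df2 <- merge(df, xy, by = "channel")
    p <- ggplot2::ggplot(df2, ggplot2::aes(x = x, y = y,
                                           size = cycle_ratio,
                                           color = cycle_ratio)) +
      ggplot2::geom_point() +
      ggplot2::geom_text(ggplot2::aes(label = channel), size = 2,
                         vjust = -1.2, color = "black") +
      ggplot2::coord_fixed() + ggplot2::theme_void() +
      ggplot2::scale_color_viridis_c()
    ggplot2::ggsave(plot_path, p, width = 5, height = 5)
  }
  invisible(path)
}

# approximate 2-D projections of 10-20 positions for the default montage
electrode_positions <- function() {
  pos <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7 = c(-0.81, 0.59), F3 = c(-0.45, 0.55), Fz = c(0, 0.5),
    F4 = c(0.45, 0.55), F8 = c(0.81, 0.59),
    FT7 = c(-0.92, 0.31), FC3 = c(-0.55, 0.28), FCz = c(0, 0.25),
    FC4 = c(0.55, 0.28), FT8 = c(0.92, 0.31),
    T3 = c(-1, 0), C3 = c(-0.5, 0), Cz = c(0, 0), C4 = c(0.5, 0),
    T4 = c(1, 0),
    TP7 = c(-0.92, -0.31), CP3 = c(-0.55, -0.28), CPz = c(0, -0.25),
    CP4 = c(0.55, -0.28),
    T5 = c(-0.81, -0.59), P3 = c(-0.45, -0.55), Pz = c(0, -0.5),
    P4 = c(0.45, -0.55), T6 = c(0.81, -0.59),
    O1 = c(-0.31, -0.95), Oz = c(0, -1), O2 = c(0.31, -0.95))
  data.frame(channel = rownames(pos), x = pos[, 1], y = pos[, 2])
}
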