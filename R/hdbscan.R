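#' Hierarchical density-based clustering (HDBSCAN) of 2-D embeddings
#'
#' Density-based population calling on embedding coordinates, with a noise
#' class. The implementation follows the standard HDBSCAN* construction:
#' core distances from the `min_samples`-nearest neighbor, a minimum
#' spanning tree of the mutual-reachability graph (Prim, in C++), the
#' single-linkage hierarchy condensed at `min_cluster_size`, and cluster
#' extraction by excess-of-mass stability.
#'
#' @param x Numeric matrix of coordinates (n x 2).
#' @param min_cluster_size Smallest event count a population may have.
#' @param min_samples Neighborhood size for the core-distance density
#'   estimate; defaults to `min_cluster_size` capped at 25 (large caps only
#'   smooth, they do not change which splits survive condensation).
#' @param allow_single_cluster Permit the hierarchy root as the lone
#'   cluster when no stable split exists.
#' @return Integer vector of cluster labels (`0` = noise, clusters `1..K`
#'   numbered by decreasing size), with attribute `n_clusters`.
#' @export
hdbscan_clusters <- function(x, min_cluster_size = 50,
                             min_samples = min(min_cluster_size, 25L),
                             allow_single_cluster = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(ncol(x) == 2, min_cluster_size >= 2, min_samples >= 1)
  if (n == 0) stop("empty input", call. = FALSE)
  if (n < 2 * min_cluster_size) {
    # Too small to split; one cluster (or noise when forbidden).
    lab <- rep(if (allow_single_cluster) 1L else 0L, n)
    attr(lab, "n_clusters") <- max(lab)
    return(lab)
  }
  k <- min(min_samples, n - 1L)
  core <- FNN::knn.dist(x, k = k)[, k]
  mst <- .mst_mutual_reachability(x, core)
  mst <- mst[order(mst$weight), , drop = FALSE]

  ## Single-linkage hierarchy via union-find; internal nodes n+1 .. 2n-1.
  parent <- integer(2L * n - 1L)          # 0 = root-so-far
  node_size <- c(rep(1L, n), integer(n - 1L))
  node_height <- c(rep(0, n), numeric(n - 1L))
  comp <- seq_len(n)                      # current top node of each component
  uf <- seq_len(n)
  find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  nxt <- n
  for (e in seq_len(nrow(mst))) {
    a <- find(mst$from[e]); b <- find(mst$to[e])
    na <- comp[a]; nb <- comp[b]
    nxt <- nxt + 1L
    parent[na] <- nxt; parent[nb] <- nxt
    node_size[nxt] <- node_size[na] + node_size[nb]
    node_height[nxt] <- mst$weight[e]
    uf[b] <- a
    comp[a] <- nxt
  }
  root <- nxt
  children <- split(seq_len(root - 1L)[parent[seq_len(root - 1L)] > 0],
                    parent[seq_len(root - 1L)][parent[seq_len(root - 1L)] > 0])

  lambda_of <- function(h) 1 / pmax(h, .Machine$double.xmin)

  ## Condense the hierarchy: walk top-down; a child smaller than
  ## min_cluster_size "falls out" of the current condensed cluster, a split
  ## into two large children creates two new condensed clusters.
  n_cond_max <- n
  cond_parent <- integer(n_cond_max); cond_birth <- numeric(n_cond_max)
  cond_stab <- numeric(n_cond_max); cond_children <- vector("list", n_cond_max)
  point_cluster <- integer(n); point_lambda <- numeric(n)
  n_cond <- 1L
  cond_parent[1L] <- 0L
  cond_birth[1L] <- lambda_of(node_height[root])

  # stack entries: (hierarchy node, condensed cluster id)
  stack_node <- root; stack_cl <- 1L
  leaf_points <- function(node) {
    # iterative collection of leaves under a hierarchy node
    out <- integer(0); st <- node
    while (length(st)) {
      v <- st[length(st)]; st <- st[-length(st)]
      if (v <= n) out <- c(out, v) else st <- c(st, children[[as.character(v)]])
    }
    out
  }
  while (length(stack_node)) {
    node <- stack_node[length(stack_node)]
    cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]

    repeat {
      if (node <= n) {  # singleton survived: it exits at its own core level
        point_cluster[node] <- cl
        point_lambda[node] <- cond_birth[cl]
        break
      }
      ch <- children[[as.character(node)]]
      lam <- lambda_of(node_height[node])
      big <- ch[node_size[ch] >= min_cluster_size]
      small <- setdiff(ch, big)
      for (s in small) {
        pts <- leaf_points(s)
        point_cluster[pts] <- cl
        point_lambda[pts] <- lam
        cond_stab[cl] <- cond_stab[cl] +
          sum(pmin(lam, 1e12) - pmin(cond_birth[cl], 1e12)) * length(pts)
      }
      if (length(big) >= 2L) {
        cond_stab[cl] <- cond_stab[cl] +
          (pmin(lam, 1e12) - pmin(cond_birth[cl], 1e12)) *
          sum(node_size[big])
        for (b in big) {
          n_cond <- n_cond + 1L
          cond_parent[n_cond] <- cl
          cond_birth[n_cond] <- lam
          cond_children[[cl]] <- c(cond_children[[cl]], n_cond)
          stack_node <- c(stack_node, b)
          stack_cl <- c(stack_cl, n_cond)
        }
        break
      } else if (length(big) == 1L) {
        node <- big  # cluster continues through the split
      } else break   # everything fell out
    }
  }

  ## Excess-of-mass selection, bottom-up (children have larger ids).
  selected <- logical(n_cond)
  subtree_stab <- cond_stab[seq_len(n_cond)]
  for (cl in n_cond:1) {
    kids <- cond_children[[cl]]
    if (length(kids) == 0L) {
      selected[cl] <- TRUE
    } else if (cond_stab[cl] > sum(subtree_stab[kids]) &&
               (cl > 1L || allow_single_cluster)) {
      selected[cl] <- TRUE
      # deselect entire subtree below
      st <- kids
      while (length(st)) {
        v <- st[length(st)]; st <- st[-length(st)]
        selected[v] <- FALSE
        st <- c(st, cond_children[[v]])
      }
    } else {
      subtree_stab[cl] <- sum(subtree_stab[kids])
    }
  }
  if (n_cond == 1L) selected[1L] <- allow_single_cluster
  else selected[1L] <- selected[1L] && allow_single_cluster

  ## Point labels: nearest selected ancestor-or-self of the condensed
  ## cluster each point fell out of.
  sel_label <- integer(n_cond)
  for (cl in seq_len(n_cond)) {
    sel_label[cl] <- if (selected[cl]) cl
                     else if (cond_parent[cl] > 0L) sel_label[cond_parent[cl]]
                     else 0L
  }
  lab <- ifelse(point_cluster > 0L, sel_label[pmax(point_cluster, 1L)], 0L)
  relabel_by_size(as.integer(lab))
}

#' Relabel clusters by decreasing size
#'
#' Pure permutation of cluster ids (noise `0` unchanged): the largest
#' cluster becomes 1, the next 2, and so on; ties broken by original id.
#'
#' @param labels Integer labels, 0 = noise.
#' @return Relabeled integer vector with attribute `n_clusters`.
#' @export
relabel_by_size <- function(labels) {
  ids <- setdiff(sort(unique(labels)), 0L)
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
    ord <- ids[order(-sizes, ids)]
    remap <- integer(max(ids))
    remap[ord] <- seq_along(ord)
    labels <- ifelse(labels == 0L, 0L, remap[pmax(labels, 1L)])
  }
  labels <- as.integer(labels)
  attr(labels, "n_clusters") <- length(ids)
  labels
}

#' Density-based clustering with a fixed radius (DBSCAN)
#'
#' Classic DBSCAN on embedding coordinates: core points have at least
#' `min_pts` neighbors (self included) within `eps`; clusters are grown from
#' core points, border points join the first reaching cluster, everything
#' else is noise. With `min_pts = 1` every point is core and clusters are
#' exactly the connected components of the eps-neighborhood graph.
#'
#' @param x Numeric matrix of coordinates.
#' @param eps Neighborhood radius, in embedding coordinate units.
#' @param min_pts Minimum neighborhood size for a core point.
#' @return Integer labels (0 = noise), relabeled by decreasing size.
#' @export
dbscan_clusters <- function(x, eps = 1, min_pts = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) return(relabel_by_size(integer(0)))
  if (n == 1) return(relabel_by_size(1L))
  kmax <- n  # hotspot sets are small; exact neighbor lists are affordable
  nn <- RANN::nn2(x, x, k = kmax, searchtype = "radius", radius = eps)
  neigh <- lapply(seq_len(n), function(i) {
    idx <- nn$nn.idx[i, ]
    idx[idx > 0]
  })
  core <- lengths(neigh) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      for (q in neigh[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  relabel_by_size(labels)
}
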