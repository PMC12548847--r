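# Hierarchical density-based clustering on a precomputed distance matrix.
#
# The classic HDBSCAN construction: k-nearest core distances
# (k = min_samples) define a mutual reachability distance
# max(core_i, core_j, d_ij); single linkage on that metric gives the
# density hierarchy; the hierarchy is condensed by discarding splits
# whose smaller side holds fewer than min_cluster_size points; clusters
# are extracted by excess-of-mass stability (lambda = 1/distance), with
# the root never selected when any other cluster exists. Points in no
# selected cluster are outliers.

#' Density-based clusters from a distance matrix
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param min_cluster_size Minimum points for a group to be a cluster
#'   (>= 2).
#' @param min_samples Neighbourhood size for core distances.
#' @return Integer vector of labels: 0 marks outliers, clusters are
#'   numbered 1..k in order of discovery.
#' @export
hdbscan_clusters <- function(d, min_cluster_size = 20, min_samples = 10) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (min_cluster_size < 2) abort_config("`min_cluster_size` must be >= 2.")
  if (n < min_cluster_size) {
    warn("Fewer points than `min_cluster_size`; everything is an outlier.")
    return(integer(n))
  }
  if (max(d) < 1e-12) return(rep(1L, n))  # degenerate: all points coincide
  k <- min(min_samples, n - 1)
  core <- vapply(seq_len(n), function(i) sort(d[i, -i], partial = k)[k], 1)
  mreach <- pmax(d, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(mreach) <- 0
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  condensed_extract(hc, n, min_cluster_size)
}

# Condense the single-linkage tree and extract stable clusters.
condensed_extract <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- pmax(hc$height, 1e-10)
  # subtree sizes and leaf lists per merge node
  size <- integer(n - 1)
  leaves <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    l <- merge[i, 1]; r <- merge[i, 2]
    ll <- if (l < 0) -l else leaves[[l]]
    rl <- if (r < 0) -r else leaves[[r]]
    leaves[[i]] <- c(ll, rl)
    size[i] <- length(leaves[[i]])
  }
  node_size <- function(x) if (x < 0) 1L else size[x]

  # condensed clusters
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_node <- integer(0)
  cl_stab <- numeric(0); cl_children <- list()
  new_cluster <- function(parent, birth, node) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_node[length(cl_node) + 1L] <<- node
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_children) + 1L]] <<- integer(0)
    id <- length(cl_parent)
    if (parent > 0) cl_children[[parent]] <<- c(cl_children[[parent]], id)
    id
  }
  root <- new_cluster(0L, 0, n - 1L)
  stack <- list(list(cid = root, node = n - 1L))
  while (length(stack) > 0) {
    task <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cid <- task$cid
    node <- task$node
    repeat {
      lam <- 1 / height[node]
      l <- merge[node, 1]; r <- merge[node, 2]
      sl <- node_size(l); sr <- node_size(r)
      if (sl >= mcs && sr >= mcs) {
        cl_stab[cid] <- cl_stab[cid] + (sl + sr) * (lam - cl_birth[cid])
        for (ch in c(l, r)) {
          ncid <- new_cluster(cid, lam, ch)
          stack[[length(stack) + 1L]] <- list(cid = ncid, node = ch)
        }
        break
      }
      cont <- NA_integer_
      for (ch in c(l, r)) {
        if (node_size(ch) >= mcs) {
          cont <- ch
        } else {
          cl_stab[cid] <- cl_stab[cid] + node_size(ch) * (lam - cl_birth[cid])
        }
      }
      if (is.na(cont)) break            # cluster dissolves
      if (cont < 0) break               # single leaf left (mcs <= 1 only)
      node <- cont
    }
  }

  n_cl <- length(cl_parent)
  if (n_cl == 1) {
    # no true split anywhere: the whole dataset is one cluster
    return(rep(1L, n))
  }
  # excess-of-mass selection, bottom-up (creation order is top-down)
  sel <- logical(n_cl)
  sel_stab <- numeric(n_cl)
  for (cid in rev(seq_len(n_cl))) {
    kids <- cl_children[[cid]]
    if (length(kids) == 0) {
      sel[cid] <- TRUE
      sel_stab[cid] <- cl_stab[cid]
    } else {
      kid_sum <- sum(sel_stab[kids])
      if (cid != root && cl_stab[cid] >= kid_sum) {
        sel[cid] <- TRUE
        sel_stab[cid] <- cl_stab[cid]
      } else {
        sel_stab[cid] <- kid_sum
      }
    }
  }
  # top-down sweep: a selected cluster claims its whole subtree
  labels <- integer(n)
  next_label <- 0L
  walk <- list(root)
  while (length(walk) > 0) {
    cid <- walk[[length(walk)]]
    walk[[length(walk)]] <- NULL
    if (sel[cid] && cid != root) {
      next_label <- next_label + 1L
      nd <- cl_node[cid]
      pts <- if (nd < 0) -nd else leaves[[nd]]
      labels[pts] <- next_label
    } else {
      for (ch in cl_children[[cid]]) walk[[length(walk) + 1L]] <- ch
    }
  }
  labels
}
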