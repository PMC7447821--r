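#' Cluster mutation frequency vectors into candidate subclones
#'
#' Groups mutations whose first-approximation frequency vectors co-occur
#' across biopsies. The default backend is a density-based hierarchical
#' method in the hdbscan family: single-linkage over the mutual-reachability
#' distance (Euclidean metric with core distances at `min_cluster_size`
#' neighbors), condensed-tree construction, and excess-of-mass cluster
#' extraction. The number of clusters is determined automatically by the
#' minimum number of mutations required to constitute a cluster; points that
#' never join a stable cluster are labeled noise (cluster 0). A trimmed
#' k-means backend is provided as a simple robust alternative.
#'
#' @param x Numeric matrix (rows = mutations, columns = biopsies, entries in
#'   `[0, 1]`) or a data frame in long form with columns `mutation_id`,
#'   `biopsy_id`, `phi_tilde`.
#' @param min_cluster_size Minimum mutations per cluster (default 5).
#' @param method `"density"` (default) or `"trimmed_kmeans"`.
#' @param seed Seed for the trimmed k-means restarts (the density backend is
#'   deterministic).
#' @return Tibble (`mutation_id`, `cluster`) where `cluster` is a positive
#'   integer or `0` for noise. All points noise means no subclones were
#'   detected -- a result, not an error.
#' @export
cluster_frequencies <- function(x, min_cluster_size = 5,
                                method = c("density", "trimmed_kmeans"),
                                seed = NULL) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    x <- phi_long_to_matrix(x)
  }
  check_that(is.matrix(x) && ncol(x) >= 2,
             "at least two biopsies are required for clustering",
             class = "clonefreq_few_biopsies")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  labels <- switch(method,
    density = hdbscan_lite(x, min_cluster_size),
    trimmed_kmeans = with_seed_if(seed, trimmed_kmeans(x, min_cluster_size))
  )
  tibble(mutation_id = ids, cluster = as.integer(labels))
}

phi_long_to_matrix <- function(df) {
  wide <- df %>%
    select("mutation_id", "biopsy_id", "phi_tilde") %>%
    tidyr::pivot_wider(names_from = "biopsy_id", values_from = "phi_tilde")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$mutation_id
  m
}

# ---- density backend ------------------------------------------------------
#
# Condensed-tree clustering over the single-linkage hierarchy of mutual-
# reachability distances. Follows the hdbscan construction: core distance of
# a point = distance to its (min_cluster_size)-th nearest neighbor;
# d_mreach(i, j) = max(core_i, core_j, d(i, j)); the dendrogram is walked
# top-down, branches smaller than min_cluster_size "fall out" of their parent
# cluster at lambda = 1/height, splits into two large-enough branches create
# child clusters; clusters are scored by stability (excess of mass) and the
# most stable antichain is selected. The root is selectable only when the
# hierarchy contains no valid split (single-clone tumors are legitimate).

hdbscan_lite <- function(x, min_cluster_size) {
  n <- nrow(x)
  mcs <- as.integer(min_cluster_size)
  if (n < mcs) return(rep(0L, n))
  d <- as.matrix(dist(x))
  # core distance: distance to the mcs-th nearest neighbor, counting the
  # point itself (the hdbscan convention), i.e. the (mcs-1)-th excluding self
  k <- min(mcs - 1L, n - 1L)
  core <- if (k < 1L) rep(0, n) else
    vapply(seq_len(n), function(i) sort(d[i, -i])[k], numeric(1))
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- hclust(as.dist(mr), method = "single")

  # members of each internal node of the dendrogram
  members <- vector("list", n - 1L)
  node_pts <- function(id) if (id < 0) -id else members[[id]]
  for (i in seq_len(n - 1L)) {
    members[[i]] <- c(node_pts(hc$merge[i, 1]), node_pts(hc$merge[i, 2]))
  }
  lam <- 1 / pmax(hc$height, 1e-12)

  # condensed tree: clusters created by valid splits, points fall out with a
  # lambda value; root cluster id = 1
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_node <- integer(0)
  cl_stab <- numeric(0); cl_children <- list()
  new_cluster <- function(parent, birth, node) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_node[length(cl_node) + 1L] <<- node
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_parent)]] <<- integer(0)
    id <- length(cl_parent)
    if (parent > 0) cl_children[[parent]] <<- c(cl_children[[parent]], id)
    id
  }
  root <- new_cluster(0L, 0, n - 1L)
  # iterative walk: stack of (dendrogram node, owning cluster)
  stack <- list(c(n - 1L, root))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]; cl <- top[2]
    l <- lam[node]
    ch <- hc$merge[node, ]
    sizes <- vapply(ch, function(id) if (id < 0) 1L else length(members[[id]]),
                    integer(1))
    big <- sizes >= mcs
    if (all(big)) {
      # true split: both branches become new clusters
      cl_stab[cl] <- cl_stab[cl] + sum(sizes) * (l - cl_birth[cl])
      for (j in 1:2) {
        kid <- new_cluster(cl, l, ch[j])
        stack[[length(stack) + 1L]] <- c(ch[j], kid)
      }
    } else {
      # small branches fall out of the current cluster at lambda = l
      for (j in 1:2) {
        if (!big[j]) {
          cl_stab[cl] <- cl_stab[cl] + sizes[j] * (l - cl_birth[cl])
        } else {
          stack[[length(stack) + 1L]] <- c(ch[j], cl)
        }
      }
      # both small: the cluster ends here (all its mass accounted above)
    }
  }

  # excess-of-mass selection over non-root clusters
  n_cl <- length(cl_parent)
  selected <- logical(n_cl)
  if (n_cl == 1L) {
    selected[root] <- TRUE     # no valid split anywhere: one cluster
  } else {
    sel_score <- numeric(n_cl)
    # process children before parents (children always have larger ids)
    for (id in rev(seq_len(n_cl))) {
      kids <- cl_children[[id]]
      if (length(kids) == 0) {
        sel_score[id] <- cl_stab[id]
        selected[id] <- TRUE
      } else {
        kid_sum <- sum(sel_score[kids])
        if (id != root && cl_stab[id] >= kid_sum) {
          sel_score[id] <- cl_stab[id]
          selected[id] <- TRUE
          # deselect all descendants
          desc <- kids
          while (length(desc)) {
            selected[desc] <- FALSE
            desc <- unlist(cl_children[desc])
          }
        } else {
          sel_score[id] <- kid_sum
        }
      }
    }
    selected[root] <- FALSE
  }

  labels <- rep(0L, n)
  lab <- 0L
  for (id in seq_len(n_cl)) {
    if (selected[id]) {
      lab <- lab + 1L
      labels[members[[cl_node[id]]]] <- lab
    }
  }
  labels
}

# ---- trimmed k-means backend ----------------------------------------------
#
# Robust alternative: k-means with iterative trimming of the `trim` fraction
# of points farthest from their centers; k is the smallest value explaining
# (1 - elbow_tol) of the reducible trimmed SSE. Clusters smaller than
# min_cluster_size are dissolved into noise.

trimmed_kmeans <- function(x, min_cluster_size, trim = 0.1, k_max = 12L,
                           elbow_tol = 0.05) {
  n <- nrow(x)
  if (n < min_cluster_size) return(rep(0L, n))
  k_max <- min(k_max, floor(n / min_cluster_size))
  if (k_max < 1) return(rep(0L, n))
  fit_k <- function(k) {
    km <- kmeans(x, centers = k, nstart = 5)
    for (it in 1:3) {
      dists <- sqrt(rowSums((x - km$centers[km$cluster, , drop = FALSE])^2))
      keep <- dists <= quantile(dists, 1 - trim)
      if (sum(keep) < k) break
      km2 <- tryCatch(kmeans(x[keep, , drop = FALSE], centers = k, nstart = 2),
                      error = function(e) NULL)
      if (is.null(km2)) break
      full <- apply(x, 1, function(p)
        which.min(colSums((t(km2$centers) - p)^2)))
      km <- list(cluster = full, centers = km2$centers)
    }
    dists <- sqrt(rowSums((x - km$centers[km$cluster, , drop = FALSE])^2))
    keep <- dists <= quantile(dists, 1 - trim)
    list(cluster = km$cluster, keep = keep, sse = sum(dists[keep]^2))
  }
  fits <- lapply(seq_len(k_max), fit_k)
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  reducible <- sse[1] - min(sse)
  k_best <- if (reducible <= 0) 1L else
    min(which(sse - min(sse) <= elbow_tol * reducible))
  f <- fits[[k_best]]
  labels <- ifelse(f$keep, f$cluster, 0L)
  # dissolve undersized clusters
  for (cl in unique(labels[labels > 0])) {
    if (sum(labels == cl) < min_cluster_size) labels[labels == cl] <- 0L
  }
  # relabel compactly
  kept <- sort(unique(labels[labels > 0]))
  match(labels, kept, nomatch = 0L)
}
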