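#' Cluster phage-homologous genes into candidate regions
#'
#' Clusters the genomic midpoints of CDS features that carry phage homology
#' into dense groups, each a candidate prophage region. The production
#' algorithm is HDBSCAN* (mutual-reachability distances with a core distance
#' over `min_pts` neighbours, minimum spanning tree, condensed cluster tree,
#' excess-of-mass cluster selection) with `min_cluster_size = min_samples =
#' min_pts`, matching the reading of MinPts as the minimum number of phage
#' proteins in a region. DBSCAN and OPTICS are provided as alternatives.
#'
#' Clustering is deterministic: points are processed in coordinate order and
#' every tie (equal distances, equal mutual-reachability edges) is broken by
#' (coordinate, feature id). Labels are contiguous integers `0..k-1` assigned
#' in order of the leftmost member of each cluster; noise is `-1`.
#'
#' @param genes Tibble of gene features with at least `feature_id` and
#'   `midpoint` columns (typically the CDS retained by [filter_hits()]).
#' @param method `"hdbscan"` (default), `"dbscan"` or `"optics"`.
#' @param min_pts MinPts: minimum number of phage-homologous genes per region
#'   and density parameter of all three algorithms (default 4).
#' @param eps Neighbourhood radius in bp for DBSCAN, and the extraction
#'   radius for OPTICS (default 10000; ignored by HDBSCAN*).
#' @param allow_single_cluster Permit HDBSCAN*'s excess-of-mass selection to
#'   return the hierarchy root, so a genome whose phage-like genes form one
#'   single dense block still yields a region (default TRUE).
#' @return A `cluster_labeling`: tibble with columns `feature_id`, `midpoint`
#'   and `cluster` (integer, `-1` = noise), sorted by `midpoint`.
#' @export
cluster_phage_genes <- function(genes, method = c("hdbscan", "dbscan", "optics"),
                                min_pts = 4, eps = 10000,
                                allow_single_cluster = TRUE) {
  method <- match.arg(method)
  stopifnot(is.numeric(min_pts), min_pts >= 2, eps > 0)
  min_pts <- as.integer(min_pts)
  genes <- dplyr::arrange(genes, .data$midpoint, .data$feature_id)
  x <- as.numeric(genes$midpoint)
  n <- length(x)
  if (n < min_pts) {
    if (n > 0) {
      warning("fewer input genes (", n, ") than MinPts (", min_pts,
              "): all points labelled noise", call. = FALSE)
    }
    labels <- rep(-1L, n)
  } else {
    labels <- switch(method,
      hdbscan = hdbscan_1d(x, min_pts = min_pts,
                           allow_single_cluster = allow_single_cluster),
      dbscan = dbscan_1d(x, eps = eps, min_pts = min_pts),
      optics = optics_extract_dbscan(x, eps = eps, min_pts = min_pts))
  }
  out <- tibble::tibble(feature_id = genes$feature_id,
                        midpoint = genes$midpoint,
                        cluster = canonical_labels(labels, x))
  class(out) <- c("cluster_labeling", class(out))
  out
}

# Relabel clusters 0..k-1 in order of each cluster's leftmost member.
canonical_labels <- function(labels, x) {
  ids <- unique(labels[labels >= 0])
  if (length(ids) == 0) return(as.integer(labels))
  leftmost <- vapply(ids, function(k) min(x[labels == k]), numeric(1))
  remap <- integer(max(ids) + 1L)
  remap[ids[order(leftmost)] + 1L] <- seq_along(ids) - 1L
  ifelse(labels < 0, -1L, remap[labels + 1L])
}

# ---- DBSCAN (1-D, exact) ----------------------------------------------------

# x must be sorted ascending. Core condition counts the point itself:
# |N_eps(p)| >= min_pts. Border points join the cluster of a core neighbour,
# preferring the one on the left (the cluster that would discover them first
# in a left-to-right seed expansion).
dbscan_1d <- function(x, eps, min_pts) {
  n <- length(x)
  # neighbour counts within [x - eps, x + eps] by binary search on sorted x
  lo <- findInterval(x - eps, x, left.open = TRUE) + 1L
  hi <- findInterval(x + eps, x)
  n_nbr <- hi - lo + 1L
  core <- n_nbr >= min_pts
  labels <- rep(-1L, n)
  cl <- -1L
  prev_core <- -Inf
  prev_core_lab <- -1L
  for (i in seq_len(n)) {
    if (!core[i]) next
    if (x[i] - prev_core <= eps && prev_core_lab >= 0) {
      labels[i] <- prev_core_lab
    } else {
      cl <- cl + 1L
      labels[i] <- cl
    }
    prev_core <- x[i]
    prev_core_lab <- labels[i]
  }
  # border points: nearest core within eps, left core preferred
  core_idx <- which(core)
  if (length(core_idx)) {
    for (i in which(!core)) {
      left <- core_idx[core_idx < i]
      right <- core_idx[core_idx > i]
      l <- if (length(left)) left[length(left)] else NA_integer_
      r <- if (length(right)) right[1] else NA_integer_
      if (!is.na(l) && x[i] - x[l] <= eps) {
        labels[i] <- labels[l]
      } else if (!is.na(r) && x[r] - x[i] <= eps) {
        labels[i] <- labels[r]
      }
    }
  }
  labels
}

#' Brute-force DBSCAN oracle
#'
#' Textbook O(n^2) DBSCAN by direct density-reachability expansion, used as
#' the independent oracle for the production 1-D path. Seeds are tried in
#' coordinate order; the neighbourhood count includes the point itself.
#'
#' @param coords Numeric coordinates (any order).
#' @param eps Neighbourhood radius.
#' @param min_pts Core-point threshold.
#' @return Integer labels aligned with `sort(coords)` order applied to the
#'   input order: labels are returned in the input order of `coords`;
#'   `-1` = noise. Cluster ids are canonical (0..k-1 by leftmost member).
#' @export
dbscan_1d_oracle <- function(coords, eps, min_pts) {
  n <- length(coords)
  if (n == 0) return(integer(0))
  ord <- order(coords)
  x <- coords[ord]
  d <- abs(outer(x, x, "-"))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nbrs) >= min_pts
  labels <- rep(-1L, n)
  visited <- rep(FALSE, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (labels[q] < 0) labels[q] <- cl
        if (!visited[q] && core[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  out <- integer(n)
  out[ord] <- canonical_labels(labels, x)
  out
}

# ---- HDBSCAN* (1-D) ---------------------------------------------------------

# Core distance: distance to the min_pts-th nearest neighbour, the point
# itself counted first (so with min_pts = 4 it is the 3rd other neighbour).
hdbscan_core_distance <- function(x, min_pts) {
  vapply(seq_along(x),
         function(i) sort(abs(x - x[i]), partial = min_pts)[min_pts],
         numeric(1))
}

# Minimum spanning tree of the mutual-reachability graph (Prim, O(n^2)).
# Ties broken by vertex index = coordinate order.
mutual_reachability_mst <- function(x, core) {
  n <- length(x)
  in_tree <- rep(FALSE, n)
  best_w <- rep(Inf, n)
  best_from <- rep(NA_integer_, n)
  in_tree[1] <- TRUE
  mr <- pmax(abs(x - x[1]), core, core[1])
  upd <- mr < best_w
  best_w[upd] <- mr[upd]
  best_from[upd] <- 1L
  edges <- matrix(0, nrow = n - 1, ncol = 3)  # from, to, weight
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]
    edges[k, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    mr <- pmax(abs(x - x[j]), core, core[j])
    upd <- !in_tree & mr < best_w
    best_w[upd] <- mr[upd]
    best_from[upd] <- j
  }
  edges[order(edges[, 3], edges[, 1], edges[, 2]), , drop = FALSE]
}

# Single-linkage dendrogram from sorted MST edges via union-find.
# Internal nodes are n+1 .. 2n-1; arrays give children, height, size.
slink_hierarchy <- function(n, edges) {
  parent <- seq_len(2L * n - 1L)    # union-find with path to current root node
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  left <- right <- integer(2L * n - 1L)
  height <- numeric(2L * n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1])
    b <- find(edges[e, 2])
    nxt <- nxt + 1L
    left[nxt] <- a
    right[nxt] <- b
    height[nxt] <- edges[e, 3]
    size[nxt] <- size[a] + size[b]
    parent[a] <- nxt
    parent[b] <- nxt
  }
  list(left = left, right = right, height = height, size = size,
       root = nxt, n = n)
}

# Condense the hierarchy with min_cluster_size, tracking for every condensed
# cluster its birth lambda, noise departures (point, lambda), death lambda
# and children. Lambda = 1/distance; zero distances are clamped.
condense_hierarchy <- function(h, min_cluster_size) {
  lam <- function(d) if (d > 0) 1 / d else 1e12
  clusters <- list()
  new_cluster <- function(parent, birth) {
    clusters[[length(clusters) + 1L]] <<- list(
      parent = parent, birth = birth, children = integer(0),
      pts = integer(0), pt_lambda = numeric(0), stability = 0)
    length(clusters)
  }
  leaves_under <- function(node) {
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v <= h$n) out <- c(out, v) else stack <- c(stack, h$left[v], h$right[v])
    }
    out
  }
  root_cl <- new_cluster(0L, 0)
  stack_nodes <- h$root
  stack_cl <- root_cl
  while (length(stack_nodes)) {
    node <- stack_nodes[length(stack_nodes)]
    cl <- stack_cl[length(stack_cl)]
    stack_nodes <- stack_nodes[-length(stack_nodes)]
    stack_cl <- stack_cl[-length(stack_cl)]
    repeat {
      l <- h$left[node]; r <- h$right[node]
      lv <- lam(h$height[node])
      sl <- h$size[l]; sr <- h$size[r]
      if (sl >= min_cluster_size && sr >= min_cluster_size) {
        # true split: parent dies here, two children born
        clusters[[cl]]$stability <- clusters[[cl]]$stability +
          (sl + sr) * (lv - clusters[[cl]]$birth)
        cl_l <- new_cluster(cl, lv)
        cl_r <- new_cluster(cl, lv)
        clusters[[cl]]$children <- c(clusters[[cl]]$children, cl_l, cl_r)
        stack_nodes <- c(stack_nodes, l, r)
        stack_cl <- c(stack_cl, cl_l, cl_r)
        break
      } else if (sl < min_cluster_size && sr < min_cluster_size) {
        pts <- c(leaves_under(l), leaves_under(r))
        clusters[[cl]]$pts <- c(clusters[[cl]]$pts, pts)
        clusters[[cl]]$pt_lambda <- c(clusters[[cl]]$pt_lambda,
                                      rep(lv, length(pts)))
        clusters[[cl]]$stability <- clusters[[cl]]$stability +
          length(pts) * (lv - clusters[[cl]]$birth)
        break
      } else {
        small <- if (sl < min_cluster_size) l else r
        big <- if (sl < min_cluster_size) r else l
        pts <- leaves_under(small)
        clusters[[cl]]$pts <- c(clusters[[cl]]$pts, pts)
        clusters[[cl]]$pt_lambda <- c(clusters[[cl]]$pt_lambda,
                                      rep(lv, length(pts)))
        clusters[[cl]]$stability <- clusters[[cl]]$stability +
          length(pts) * (lv - clusters[[cl]]$birth)
        node <- big
      }
    }
  }
  clusters
}

# Excess-of-mass selection over the condensed tree.
eom_select <- function(clusters, allow_single_cluster) {
  k <- length(clusters)
  sigma <- numeric(k)
  wins <- logical(k)
  for (i in rev(seq_len(k))) {   # creation order is top-down, so reverse
    ch <- clusters[[i]]$children
    if (length(ch) == 0) {
      sigma[i] <- clusters[[i]]$stability
      wins[i] <- TRUE
    } else {
      child_sum <- sum(sigma[ch])
      if (clusters[[i]]$stability >= child_sum &&
          (i != 1L || allow_single_cluster)) {
        sigma[i] <- clusters[[i]]$stability
        wins[i] <- TRUE
      } else {
        sigma[i] <- child_sum
        wins[i] <- FALSE
      }
    }
  }
  if (!allow_single_cluster) wins[1L] <- FALSE
  # top-down: select the highest winning cluster on each root-to-leaf path
  selected <- logical(k)
  stack <- 1L
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (wins[i]) selected[i] <- TRUE
    else stack <- c(stack, clusters[[i]]$children)
  }
  selected
}

#' @rdname cluster_phage_genes
#' @param x Sorted numeric coordinates (internal interface; exported for
#'   direct use on raw coordinate vectors).
#' @export
hdbscan_1d <- function(x, min_pts = 4, allow_single_cluster = TRUE) {
  n <- length(x)
  if (is.unsorted(x)) {
    ord <- order(x)
    out <- integer(n)
    out[ord] <- hdbscan_1d(x[ord], min_pts, allow_single_cluster)
    return(out)
  }
  if (n < min_pts || n < 2) return(rep(-1L, n))
  core <- hdbscan_core_distance(x, min_pts)
  edges <- mutual_reachability_mst(x, core)
  h <- slink_hierarchy(n, edges)
  clusters <- condense_hierarchy(h, min_cluster_size = min_pts)
  selected <- eom_select(clusters, allow_single_cluster)
  # a point belongs to the selected cluster it (or an unselected descendant
  # chain it departed from) sits under; otherwise it is noise
  labels <- rep(-1L, n)
  sel_anc <- function(i) {
    while (i != 0L) {
      if (selected[i]) return(i)
      i <- clusters[[i]]$parent
    }
    0L
  }
  lab_of_cluster <- integer(length(clusters))
  for (i in seq_along(clusters)) lab_of_cluster[i] <- sel_anc(i)
  for (i in seq_along(clusters)) {
    if (lab_of_cluster[i] > 0L && length(clusters[[i]]$pts)) {
      labels[clusters[[i]]$pts] <- lab_of_cluster[i]
    }
  }
  labels[labels == 0L] <- -1L
  canonical_labels(ifelse(labels > 0L, labels - 1L, -1L), x)
}

# ---- OPTICS (1-D) -----------------------------------------------------------

# Reachability ordering (Ankerst et al.), then DBSCAN-equivalent extraction
# at radius eps. O(n^2); deterministic seed order (min reachability, then
# coordinate order).
optics_order <- function(x, min_pts, max_eps = Inf) {
  n <- length(x)
  d <- abs(outer(x, x, "-"))
  core_dist <- vapply(seq_len(n), function(i) {
    nb <- sort(d[i, d[i, ] <= max_eps], partial = NULL)
    if (length(nb) >= min_pts) sort(d[i, ])[min_pts] else Inf
  }, numeric(1))
  reach <- rep(Inf, n)
  processed <- rep(FALSE, n)
  ordering <- integer(0)
  while (any(!processed)) {
    cand <- which(!processed)
    i <- cand[order(reach[cand], x[cand])][1]
    processed[i] <- TRUE
    ordering <- c(ordering, i)
    if (is.finite(core_dist[i])) {
      nb <- which(d[i, ] <= max_eps & !processed)
      newr <- pmax(core_dist[i], d[i, nb])
      upd <- newr < reach[nb]
      reach[nb[upd]] <- newr[upd]
    }
  }
  list(order = ordering, reachability = reach[ordering],
       core_dist = core_dist[ordering])
}

optics_extract_dbscan <- function(x, eps, min_pts) {
  n <- length(x)
  o <- optics_order(x, min_pts)
  labels <- rep(-1L, n)
  cl <- -1L
  for (k in seq_len(n)) {
    i <- o$order[k]
    if (o$reachability[k] > eps) {
      if (o$core_dist[k] <= eps) {
        cl <- cl + 1L
        labels[i] <- cl
      }  # else noise
    } else if (cl >= 0L) {
      labels[i] <- cl
    }
  }
  labels
}

# ---- regions ----------------------------------------------------------------

#' Turn a cluster labeling into candidate prophage regions
#'
#' Builds one region per non-noise cluster: the region spans from the
#' smallest member-gene start to the largest member-gene end. Regions are
#' sorted by start and numbered from 1; member genes are attached as a
#' list-column.
#'
#' @param labeling A `cluster_labeling` from [cluster_phage_genes()].
#' @param genes The gene feature tibble the labeling was computed from (must
#'   contain `feature_id`, `start`, `end`, `midpoint`).
#' @param genome The `genome_record` (supplies the sequence id).
#' @return Regions tibble with columns `seqid`, `region_id`, `start`, `end`,
#'   `n_genes` and list-column `genes`.
#' @export
labeling_to_regions <- function(labeling, genes, genome) {
  members <- dplyr::filter(labeling, .data$cluster >= 0)
  if (nrow(members) == 0) return(empty_regions()[, c("seqid", "region_id",
                                                     "start", "end",
                                                     "n_genes", "genes")])
  genes_keyed <- dplyr::select(genes, "feature_id", "start", "end", "midpoint")
  joined <- dplyr::inner_join(dplyr::select(members, "feature_id", "cluster"),
                              genes_keyed, by = "feature_id")
  regions <- joined |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      start = as.integer(min(.data$start)),
      end = as.integer(max(.data$end)),
      n_genes = dplyr::n(),
      genes = list(dplyr::pick("feature_id", "start", "end", "midpoint")),
      .groups = "drop") |>
    dplyr::arrange(.data$start) |>
    dplyr::mutate(seqid = genome$id,
                  region_id = as.integer(dplyr::row_number())) |>
    dplyr::select("seqid", "region_id", "start", "end", "n_genes", "genes")
  regions
}
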