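#' Match predicted regions against reference prophages
#'
#' Matches predicted intervals to reference prophage intervals (both 1-based
#' inclusive, on one genome) and computes sensitivity and positive predictive
#' value: Sn = detected references / total references; PPV = detected
#' references / (detected references + predictions matching no reference).
#' Under the default `any_overlap` rule a reference is detected when some
#' prediction overlaps it by at least 1 bp; under `min_fraction` the overlap
#' must cover at least `min_fraction` of the reference length. Many
#' predictions hitting one reference count it once.
#'
#' @param predicted Tibble/data frame of predicted intervals (`start`, `end`).
#' @param reference Tibble/data frame of reference intervals (`start`, `end`).
#' @param rule `"any_overlap"` (default) or `"min_fraction"`.
#' @param min_fraction Required fraction of the reference covered (used with
#'   `rule = "min_fraction"`).
#' @return A `prophage_eval` object; see [tidy.prophage_eval()] and
#'   [glance.prophage_eval()].
#' @examples
#' ref <- tibble::tibble(start = c(100, 1000), end = c(500, 2000))
#' prd <- tibble::tibble(start = c(90, 5000), end = c(200, 6000))
#' glance(match_regions(prd, ref))
#' @export
match_regions <- function(predicted, reference,
                          rule = c("any_overlap", "min_fraction"),
                          min_fraction = 0.5) {
  rule <- match.arg(rule)
  predicted <- tibble::as_tibble(predicted)
  reference <- tibble::as_tibble(reference)
  for (tab in list(predicted, reference)) {
    if (nrow(tab) && any(tab$end < tab$start)) {
      bad <- which(tab$end < tab$start)[1]
      stop("invalid interval: end (", tab$end[bad], ") < start (",
           tab$start[bad], ")", call. = FALSE)
    }
  }
  np <- nrow(predicted)
  nr <- nrow(reference)
  if (np && nr) {
    ov <- outer(seq_len(np), seq_len(nr), function(i, j) {
      pmax(0, pmin(predicted$end[i], reference$end[j]) -
              pmax(predicted$start[i], reference$start[j]) + 1)
    })
    ref_len <- reference$end - reference$start + 1
    hit <- if (rule == "any_overlap") ov >= 1
           else sweep(ov, 2, min_fraction * ref_len, ">=")
  } else {
    hit <- matrix(FALSE, np, nr)
  }
  ref_detected <- apply(hit, 2, any)
  pred_matched <- apply(hit, 1, any)
  n_detected <- sum(ref_detected)
  n_fp <- sum(!pred_matched)
  structure(list(
    n_reference = nr, n_predicted = np,
    n_detected = n_detected, n_false_positive = n_fp,
    sensitivity = if (nr > 0) n_detected / nr else NA_real_,
    ppv = if (n_detected + n_fp > 0) n_detected / (n_detected + n_fp)
          else NA_real_,
    match_rule = if (rule == "any_overlap") "any_overlap"
                 else sprintf("min_fraction(%g)", min_fraction),
    reference = dplyr::mutate(reference, detected = ref_detected),
    predicted = dplyr::mutate(predicted, matched = pred_matched)),
    class = "prophage_eval")
}

#' @export
print.prophage_eval <- function(x, ...) {
  cat(sprintf(
    "<prophage_eval> %d/%d reference prophages detected, %d false positive(s) [%s]\n  Sn = %.4f  PPV = %.4f\n",
    x$n_detected, x$n_reference, x$n_false_positive, x$match_rule,
    x$sensitivity, x$ppv))
  invisible(x)
}

#' Tidy and summarise an evaluation
#'
#' `tidy()` returns one row per reference prophage with its detection status;
#' `glance()` returns a one-row summary with Sn and PPV.
#'
#' @param x A `prophage_eval` from [match_regions()].
#' @param ... Unused.
#' @method tidy prophage_eval
#' @export
tidy.prophage_eval <- function(x, ...) x$reference

#' @rdname tidy.prophage_eval
#' @method glance prophage_eval
#' @export
glance.prophage_eval <- function(x, ...) {
  tibble::tibble(n_reference = x$n_reference, n_predicted = x$n_predicted,
                 n_detected = x$n_detected,
                 n_false_positive = x$n_false_positive,
                 sensitivity = x$sensitivity, ppv = x$ppv,
                 match_rule = x$match_rule)
}

# ---- cluster validity indices ----------------------------------------------

drop_noise <- function(points, labels, metric) {
  keep <- labels >= 0
  points <- points[keep]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    stop(metric, " undefined: fewer than 2 clusters after removing noise",
         call. = FALSE)
  }
  list(x = as.numeric(points), lab = labels)
}

#' Cluster validity indices for 1-D labelings
#'
#' Silhouette, Dunn, Davies-Bouldin and DBCV over 1-D coordinates with
#' integer cluster labels (noise = -1, always excluded). Definitions:
#' Silhouette is the mean over points of (b-a)/max(a,b) with a the mean
#' intra-cluster distance and b the smallest mean distance to another
#' cluster; Dunn is the minimum single-linkage inter-cluster distance over
#' the maximum intra-cluster diameter (+Inf when the diameter is 0);
#' Davies-Bouldin is the mean over clusters of the worst
#' (sigma_i + sigma_j) / d(c_i, c_j) with sigma the mean distance to the
#' cluster centroid; DBCV follows its published construction (all-points
#' core distances with the dimension term set to 1, per-cluster
#' mutual-reachability minimum spanning trees, density sparseness vs density
#' separation, cluster-size-weighted sum), ranging over \[-1, 1\].
#'
#' @param points Numeric 1-D coordinates.
#' @param labels Integer labels aligned with `points`; -1 = noise.
#' @return `cluster_validity()` returns a one-row tibble with all four
#'   indices plus `n_clusters`; the individual functions return one number.
#' @export
silhouette_score <- function(points, labels) {
  z <- drop_noise(points, labels, "silhouette")
  d <- abs(outer(z$x, z$x, "-"))
  n <- length(z$x)
  s <- vapply(seq_len(n), function(i) {
    own <- z$lab == z$lab[i]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(z$lab), z$lab[i]),
                    function(k) mean(d[i, z$lab == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' @rdname silhouette_score
#' @export
dunn_index <- function(points, labels) {
  z <- drop_noise(points, labels, "Dunn index")
  d <- abs(outer(z$x, z$x, "-"))
  same <- outer(z$lab, z$lab, "==")
  inter <- min(d[!same])
  diam <- max(d[same])
  if (diam == 0) return(Inf)
  inter / diam
}

#' @rdname silhouette_score
#' @export
davies_bouldin <- function(points, labels) {
  z <- drop_noise(points, labels, "Davies-Bouldin index")
  ids <- sort(unique(z$lab))
  cent <- vapply(ids, function(k) mean(z$x[z$lab == k]), numeric(1))
  sigma <- vapply(seq_along(ids), function(k)
    mean(abs(z$x[z$lab == ids[k]] - cent[k])), numeric(1))
  r <- vapply(seq_along(ids), function(i) {
    max(vapply(setdiff(seq_along(ids), i), function(j)
      (sigma[i] + sigma[j]) / abs(cent[i] - cent[j]), numeric(1)))
  }, numeric(1))
  mean(r)
}

# All-points core distance of each member of one cluster (dimension term 1):
# the inverse of the mean inverse distance to the other members.
apts_core_distance <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  vapply(seq_len(n), function(i) {
    inv <- 1 / abs(x[-i] - x[i])
    1 / mean(inv)
  }, numeric(1))
}

# Canonical MST over a full symmetric weight matrix: Kruskal on the strict
# total edge order (weight, i, j), so equal-weight (mutual-reachability)
# ties always resolve the same way and the tree is unique.
mst_edges <- function(w) {
  n <- nrow(w)
  if (n < 2) return(matrix(numeric(0), ncol = 3))
  idx <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(w[idx], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- matrix(0, n - 1, 3)
  k <- 0L
  for (r in seq_len(nrow(idx))) {
    a <- find(idx[r, 1])
    b <- find(idx[r, 2])
    if (a == b) next
    parent[a] <- b
    k <- k + 1L
    edges[k, ] <- c(idx[r, 1], idx[r, 2], w[idx[r, 1], idx[r, 2]])
    if (k == n - 1L) break
  }
  edges
}

#' @rdname silhouette_score
#' @export
dbcv <- function(points, labels) {
  z <- drop_noise(points, labels, "DBCV")
  ids <- sort(unique(z$lab))
  members <- lapply(ids, function(k) z$x[z$lab == k])
  apts <- lapply(members, apts_core_distance)
  # per-cluster MRD minimum spanning tree -> internal nodes, sparseness
  internal <- vector("list", length(ids))
  dsc <- numeric(length(ids))
  for (k in seq_along(ids)) {
    xs <- members[[k]]
    nk <- length(xs)
    if (nk < 2) {
      internal[[k]] <- seq_len(nk)
      dsc[k] <- 0
      next
    }
    w <- pmax(abs(outer(xs, xs, "-")), outer(apts[[k]], apts[[k]], pmax))
    diag(w) <- 0
    ed <- mst_edges(w)
    deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nk)
    int <- which(deg > 1)
    if (length(int) == 0) int <- seq_len(nk)
    internal[[k]] <- int
    both_int <- ed[, 1] %in% int & ed[, 2] %in% int
    dsc[k] <- if (any(both_int)) max(ed[both_int, 3]) else max(ed[, 3])
  }
  # density separation between cluster pairs over internal nodes
  k_n <- length(ids)
  dspc_min <- rep(Inf, k_n)
  for (i in seq_len(k_n - 1)) {
    for (j in seq.int(i + 1, k_n)) {
      xi <- members[[i]][internal[[i]]]
      ai <- apts[[i]][internal[[i]]]
      xj <- members[[j]][internal[[j]]]
      aj <- apts[[j]][internal[[j]]]
      mrd <- pmax(abs(outer(xi, xj, "-")), outer(ai, aj, pmax))
      sep <- min(mrd)
      dspc_min[i] <- min(dspc_min[i], sep)
      dspc_min[j] <- min(dspc_min[j], sep)
    }
  }
  vc <- vapply(seq_len(k_n), function(k) {
    denom <- max(dspc_min[k], dsc[k])
    if (denom == 0) return(0)
    (dspc_min[k] - dsc[k]) / denom
  }, numeric(1))
  sizes <- lengths(members)
  sum(sizes / sum(sizes) * vc)
}

#' @rdname silhouette_score
#' @export
cluster_validity <- function(points, labels) {
  tibble::tibble(
    silhouette = silhouette_score(points, labels),
    dunn = dunn_index(points, labels),
    davies_bouldin = davies_bouldin(points, labels),
    dbcv = dbcv(points, labels),
    n_clusters = length(unique(labels[labels >= 0])))
}
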