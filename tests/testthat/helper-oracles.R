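# Independent brute-force oracles for the cluster validity indices: literal
# double-loop evaluation of the defining formulas, kept free of any code
# shared with the implementations under test.

oracle_silhouette <- function(x, lab) {
  keep <- lab >= 0
  x <- x[keep]; lab <- lab[keep]
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- sum(abs(x[own] - x[i])) / length(own)
    b <- Inf
    for (k in unique(lab)) {
      if (k == lab[i]) next
      other <- which(lab == k)
      b <- min(b, sum(abs(x[other] - x[i])) / length(other))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dunn <- function(x, lab) {
  keep <- lab >= 0
  x <- x[keep]; lab <- lab[keep]
  inter <- Inf; diam <- 0
  n <- length(x)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- abs(x[i] - x[j])
    if (lab[i] == lab[j]) diam <- max(diam, d) else inter <- min(inter, d)
  }
  if (diam == 0) Inf else inter / diam
}

oracle_davies_bouldin <- function(x, lab) {
  keep <- lab >= 0
  x <- x[keep]; lab <- lab[keep]
  ids <- sort(unique(lab))
  total <- 0
  for (i in ids) {
    ci <- mean(x[lab == i])
    si <- mean(abs(x[lab == i] - ci))
    worst <- -Inf
    for (j in ids) {
      if (j == i) next
      cj <- mean(x[lab == j])
      sj <- mean(abs(x[lab == j] - cj))
      worst <- max(worst, (si + sj) / abs(ci - cj))
    }
    total <- total + worst
  }
  total / length(ids)
}

# DBCV by literal construction: all-points core distances (dimension 1),
# per-cluster mutual-reachability MST built with Kruskal + union-find,
# density sparseness (max internal MST edge) vs density separation
# (min internal-node mutual reachability between clusters).
oracle_dbcv <- function(x, lab) {
  keep <- lab >= 0
  x <- x[keep]; lab <- lab[keep]
  ids <- sort(unique(lab))
  apts <- function(xs) {
    nk <- length(xs)
    if (nk < 2) return(rep(0, nk))
    sapply(seq_len(nk), function(i) {
      ((1 / (nk - 1)) * sum((1 / abs(xs[-i] - xs[i]))^1))^(-1 / 1)
    })
  }
  kruskal_mst <- function(w) {
    nk <- nrow(w)
    pairs <- which(upper.tri(w), arr.ind = TRUE)
    # same strict total edge order (weight, i, j) as the definition under test
    pairs <- pairs[order(w[pairs], pairs[, 1], pairs[, 2]), , drop = FALSE]
    parent <- seq_len(nk)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    edges <- NULL
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) {
        parent[a] <- b
        edges <- rbind(edges, c(pairs[r, 1], pairs[r, 2],
                                w[pairs[r, 1], pairs[r, 2]]))
      }
    }
    edges
  }
  core <- list(); internal <- list(); dsc <- numeric(length(ids))
  for (q in seq_along(ids)) {
    xs <- x[lab == ids[q]]
    ap <- apts(xs)
    core[[q]] <- ap
    nk <- length(xs)
    if (nk < 2) { internal[[q]] <- seq_len(nk); dsc[q] <- 0; next }
    w <- matrix(0, nk, nk)
    for (i in seq_len(nk)) for (j in seq_len(nk)) {
      if (i != j) w[i, j] <- max(abs(xs[i] - xs[j]), ap[i], ap[j])
    }
    ed <- kruskal_mst(w)
    deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nk)
    int <- which(deg > 1)
    if (length(int) == 0) int <- seq_len(nk)
    internal[[q]] <- int
    wint <- ed[ed[, 1] %in% int & ed[, 2] %in% int, 3]
    dsc[q] <- if (length(wint)) max(wint) else max(ed[, 3])
  }
  vtot <- 0
  for (q in seq_along(ids)) {
    xs_q <- x[lab == ids[q]][internal[[q]]]
    ap_q <- core[[q]][internal[[q]]]
    sep <- Inf
    for (r in seq_along(ids)) {
      if (r == q) next
      xs_r <- x[lab == ids[r]][internal[[r]]]
      ap_r <- core[[r]][internal[[r]]]
      for (i in seq_along(xs_q)) for (j in seq_along(xs_r)) {
        sep <- min(sep, max(abs(xs_q[i] - xs_r[j]), ap_q[i], ap_r[j]))
      }
    }
    v <- if (max(sep, dsc[q]) == 0) 0 else (sep - dsc[q]) / max(sep, dsc[q])
    vtot <- vtot + sum(lab == ids[q]) / length(x) * v
  }
  vtot
}

# Reference HDBSCAN labels from scikit-learn, via the system python.
# Returns NULL when no usable python is available.
sklearn_hdbscan_labels <- function(x, min_pts, allow_single_cluster = FALSE) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(x = x, min_pts = min_pts,
                            allow_single_cluster = allow_single_cluster),
                       infile, auto_unbox = TRUE, digits = NA)
  script <- paste(
    "import json, sys",
    "from sklearn.cluster import HDBSCAN",
    "import numpy as np",
    sprintf("cfg = json.load(open('%s'))", infile),
    "X = np.array(cfg['x'], dtype=float).reshape(-1, 1)",
    "m = HDBSCAN(min_cluster_size=cfg['min_pts'], min_samples=cfg['min_pts'],",
    "            allow_single_cluster=cfg['allow_single_cluster'])",
    "labels = m.fit_predict(X).tolist()",
    sprintf("json.dump(labels, open('%s', 'w'))", outfile),
    sep = "\n")
  status <- suppressWarnings(system2(py, c("-c", shQuote(script)),
                                     stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(outfile)) return(NULL)
  as.integer(unlist(jsonlite::read_json(outfile)))
}

# Two labelings describe the same partition (same noise set, same grouping).
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a < 0, b < 0)) return(FALSE)
  ka <- a[a >= 0]; kb <- b[b >= 0]
  length(unique(ka)) == length(unique(kb)) &&
    !anyDuplicated(unique(cbind(ka, kb))[, 1]) &&
    !anyDuplicated(unique(cbind(ka, kb))[, 2])
}
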