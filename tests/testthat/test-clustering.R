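genes_from_midpoints <- function(mids, width = 900L) {
  tibble::tibble(feature_id = sprintf("g_%04d", seq_along(mids)),
                 start = as.integer(mids - width %/% 2),
                 end = as.integer(mids + width %/% 2),
                 midpoint = as.integer(mids))
}

test_that("DBSCAN groups three near midpoints and leaves the outlier as noise", {
  genes <- genes_from_midpoints(c(1000, 2000, 3000, 500000), width = 300L)
  lab <- cluster_phage_genes(genes, method = "dbscan", min_pts = 3, eps = 10000)
  expect_equal(lab$cluster, c(0L, 0L, 0L, -1L))
  # and the brute-force oracle agrees
  expect_equal(dbscan_1d_oracle(c(1000, 2000, 3000, 500000), 10000, 3),
               c(0L, 0L, 0L, -1L))
})

test_that("oracle handles singleton core points and all-noise inputs", {
  expect_equal(dbscan_1d_oracle(0, eps = 1, min_pts = 1), 0L)
  expect_equal(dbscan_1d_oracle(c(0, 10), eps = 5, min_pts = 2), c(-1L, -1L))
})

test_that("production DBSCAN matches the brute-force oracle on random instances", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(5:50, 1)
    k <- sample(1:4, 1)
    x <- round(sort(unlist(lapply(seq_len(k), function(i)
      runif(1, 0, 5e5) + rnorm(ceiling(n / k), 0, runif(1, 200, 3000))))))
    x <- x[seq_len(n)]
    eps <- sample(c(1000, 5000, 10000), 1)
    min_pts <- sample(2:6, 1)
    genes <- genes_from_midpoints(x)
    prod <- cluster_phage_genes(genes, method = "dbscan",
                                min_pts = min_pts, eps = eps)
    oracle <- dbscan_1d_oracle(sort(x), eps, min_pts)
    expect_equal(prod$cluster, oracle,
                 info = sprintf("seed %d (eps=%d, min_pts=%d)", seed, eps, min_pts))
  }
})

test_that("fewer input genes than MinPts labels everything noise with a warning", {
  genes <- genes_from_midpoints(c(1000, 2000))
  expect_warning(lab <- cluster_phage_genes(genes, min_pts = 4),
                 "fewer input genes")
  expect_equal(lab$cluster, c(-1L, -1L))
})

test_that("HDBSCAN* recovers two well-separated implanted groups exactly", {
  set.seed(901)
  g1 <- sort(round(10000 + cumsum(runif(10, 200, 1000))))
  g2 <- sort(round(170000 + cumsum(runif(10, 200, 1000))))
  genes <- genes_from_midpoints(c(g1, g2))
  lab <- cluster_phage_genes(genes, method = "hdbscan", min_pts = 4)
  expect_equal(lab$cluster, rep(c(0L, 1L), each = 10))
})

test_that("HDBSCAN* with a single-cluster option recovers one lone dense group", {
  set.seed(902)
  g <- sort(round(50000 + cumsum(runif(12, 200, 1000))))
  genes <- genes_from_midpoints(g)
  lab <- cluster_phage_genes(genes, min_pts = 4, allow_single_cluster = TRUE)
  expect_equal(unique(lab$cluster), 0L)
  # with the root barred, excess-of-mass has nothing to select
  lab2 <- cluster_phage_genes(genes, min_pts = 4,
                              allow_single_cluster = FALSE)
  expect_equal(unique(lab2$cluster), -1L)
})

test_that("HDBSCAN* agrees with the scikit-learn reference on planted groups", {
  checked <- 0
  for (seed in 1:12) {
    set.seed(seed + 700)
    k <- sample(2:4, 1)
    centers <- cumsum(runif(k, 50000, 100000))
    x <- sort(unlist(lapply(centers, function(c0)
      c0 + cumsum(runif(sample(6:15, 1), 100, 1200)))))
    ref <- sklearn_hdbscan_labels(x, min_pts = 4,
                                  allow_single_cluster = FALSE)
    if (is.null(ref)) skip("scikit-learn reference unavailable")
    mine <- hdbscan_1d(x, min_pts = 4, allow_single_cluster = FALSE)
    expect_true(same_partition(mine, ref),
                info = sprintf("seed %d: mine=%s ref=%s", seed,
                               paste(mine, collapse = ","),
                               paste(ref, collapse = ",")))
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("clustering is invariant to translation and label permutation", {
  set.seed(903)
  x <- sort(c(runif(8, 0, 5000), runif(8, 60000, 66000)))
  genes <- genes_from_midpoints(round(x))
  base <- cluster_phage_genes(genes, min_pts = 4)
  shifted <- genes
  shifted$midpoint <- shifted$midpoint + 12345L
  shifted$start <- shifted$start + 12345L
  shifted$end <- shifted$end + 12345L
  moved <- cluster_phage_genes(shifted, min_pts = 4)
  expect_equal(moved$cluster, base$cluster)
  # permuting input row order must not change the assignment per feature
  perm <- sample(nrow(genes))
  relab <- cluster_phage_genes(genes[perm, ], min_pts = 4)
  expect_equal(relab$cluster[match(base$feature_id, relab$feature_id)],
               base$cluster)
})

test_that("OPTICS extraction at the cut radius matches DBSCAN on clean groups", {
  set.seed(904)
  x <- sort(round(c(runif(10, 0, 8000), runif(10, 100000, 108000))))
  genes <- genes_from_midpoints(x)
  opt <- cluster_phage_genes(genes, method = "optics", min_pts = 4, eps = 10000)
  dbs <- cluster_phage_genes(genes, method = "dbscan", min_pts = 4, eps = 10000)
  expect_equal(opt$cluster, dbs$cluster)
})

test_that("regions take the extent of their member genes and sort by start", {
  genes <- tibble::tibble(
    feature_id = c("gA", "gB", "gC", "gD", "gE"),
    start = c(35516L, 39000L, 45000L, 47000L, 49000L),
    end = c(36200L, 40100L, 46100L, 48000L, 49727L),
    midpoint = c(35858L, 39550L, 45550L, 47500L, 49363L))
  labeling <- tibble::tibble(feature_id = genes$feature_id,
                             midpoint = genes$midpoint,
                             cluster = c(0L, 0L, 0L, 0L, 0L))
  genome <- list(id = "NC_TEST")
  regions <- labeling_to_regions(labeling, genes, genome)
  expect_equal(nrow(regions), 1)
  expect_equal(c(regions$start, regions$end), c(35516L, 49727L))
  expect_equal(regions$n_genes, 5L)
  # all-noise labeling gives an empty region set
  labeling$cluster <- -1L
  expect_equal(nrow(labeling_to_regions(labeling, genes, genome)), 0)
})

test_that("every reported region holds at least MinPts phage-homologous genes", {
  for (seed in c(101, 102, 103)) {
    sim <- generate_genome(small_spec(seed = seed, false_hit_rate = 0.05))
    res <- suppressMessages(run_pipeline(sim$genome, sim$hits))
    if (nrow(res$regions)) {
      expect_true(all(res$regions$n_genes >= res$config$min_pts))
    }
  }
})
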