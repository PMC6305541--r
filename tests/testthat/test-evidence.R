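test_that("gc_fraction counts G+C over unambiguous bases only", {
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATAT"), 0.0)
  expect_equal(gc_fraction("ACGTN"), 0.5)    # N excluded: 2/4
  expect_equal(gc_fraction("acgt"), 0.5)     # case-insensitive
  expect_error(gc_fraction("NNNN"), "undefined G\\+C")
  # reverse complement preserves G+C content
  set.seed(61)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(gc_fraction(rc), gc_fraction(s))
})

test_that("window layout and statistics follow the sliding-window contract", {
  uniform <- strrep("ACGT", 1250)   # 5000 bp, G+C exactly 0.5 everywhere
  st <- windowed_gc_stats(uniform, window_size = 1000, step = 100)
  expect_true(all(st$window_values == 0.5))
  expect_equal(st$sd, 0)
  expect_equal(st$starts[1:3], c(1L, 101L, 201L))
  # 1500 bp, window 1000, step 500: exactly two windows, starts 1 and 501
  st2 <- windowed_gc_stats(strrep("ACGT", 375), window_size = 1000, step = 500)
  expect_equal(st2$starts, c(1L, 501L))
  expect_equal(length(st2$window_values), 2)
  # min <= mean <= max always; sd == 0 iff all windows equal
  sim <- generate_genome(small_spec(seed = 71))
  st3 <- windowed_gc_stats(sim$genome)
  expect_lte(st3$mean, max(st3$window_values))
  expect_gte(st3$mean, min(st3$window_values))
  expect_gt(st3$sd, 0)
})

test_that("windowed statistics match a direct single-pass recomputation", {
  sim <- generate_genome(small_spec(seed = 72, prophage_length = c(15000, 20000)))
  st <- windowed_gc_stats(sim$genome, window_size = 1000, step = 100)
  s <- sim$genome$sequence
  direct <- vapply(st$starts, function(p) {
    w <- substr(s, p, p + 999)
    lengths(regmatches(w, gregexpr("[GC]", w))) / 1000
  }, numeric(1))
  expect_equal(st$window_values, direct, tolerance = 1e-12)
  expect_equal(st$mean, mean(direct), tolerance = 1e-12)
  expect_equal(st$sd, sqrt(mean((direct - mean(direct))^2)), tolerance = 1e-12)
  # a genome shorter than the window degrades to one full-length window
  expect_warning(one <- windowed_gc_stats("ACGTACGTAC", window_size = 1000),
                 "shorter than the window")
  expect_equal(length(one$window_values), 1)
})

test_that("the 80%-of-genes rule is boundary-inclusive with strict deviance", {
  # hand-built genome: background at GC 0.5, five genes, four of them shifted
  set.seed(73)
  bg <- sample(c("A", "C", "G", "T"), 30000, TRUE)
  seqv <- paste(bg, collapse = "")
  gene_start <- seq(1000, by = 2000, length.out = 5)
  genes <- tibble::tibble(
    feature_id = sprintf("g%d", 1:5),
    start = as.integer(gene_start), end = as.integer(gene_start + 899),
    midpoint = as.integer(gene_start + 449))
  # overwrite four gene bodies with pure-GC blocks (clearly > mean + sd)
  for (i in 1:4) {
    substr(seqv, genes$start[i], genes$end[i]) <- strrep("GC", 450)
  }
  genome <- structure(list(id = "HAND", sequence = seqv, length = 30000,
                           topology = "linear",
                           features = tibble::tibble(kind = character())),
                      class = "genome_record")
  regions <- tibble::tibble(seqid = "HAND", region_id = 1L,
                            start = min(genes$start), end = max(genes$end),
                            n_genes = 5L, genes = list(genes))
  st <- windowed_gc_stats(genome)
  scored <- gc_evidence(regions, genome, st, gene_fraction_threshold = 0.80)
  expect_equal(scored$deviant_fraction, 0.8)
  expect_true(scored$gc_supported)        # exactly 80% qualifies
  stricter <- gc_evidence(regions, genome, st, gene_fraction_threshold = 0.81)
  expect_false(stricter$gc_supported)
  # raising the threshold can only withdraw support, never grant it
  thresholds <- seq(0, 1, by = 0.1)
  flags <- vapply(thresholds, function(t)
    gc_evidence(regions, genome, st, t)$gc_supported, logical(1))
  expect_false(is.unsorted(rev(flags)))
})

test_that("genes at the genome-mean composition earn no G+C support", {
  sim <- generate_genome(small_spec(seed = 74, prophage_gc_shift = 0))
  res <- suppressMessages(run_pipeline(sim$genome, sim$hits))
  if (nrow(res$regions)) expect_false(any(res$regions$gc_supported))
})

test_that("tRNA flank support uses signed distances to the nearest boundary", {
  feats <- tibble::tibble(
    feature_id = c("t1", "t2", "t3"), kind = "tRNA",
    start = c(49800L, 40000L, 30000L), end = c(49874L, 40074L, 30074L),
    strand = 1L, product = "tRNA-Met", translation = NA_character_,
    midpoint = c(49837L, 40037L, 30037L))
  genome <- structure(list(id = "T", sequence = "ACGT", length = 60000L,
                           topology = "linear", features = feats),
                      class = "genome_record")
  regions <- tibble::tibble(seqid = "T", region_id = 1L, start = 35516L,
                            end = 49727L, n_genes = 5L)
  scored <- trna_evidence(regions, genome, flank_distance = 2000)
  expect_true(scored$trna_supported)
  fl <- scored$flanking_trnas[[1]]
  expect_equal(fl$distance[fl$feature_id == "t1"], 73L)   # downstream flank
  expect_equal(fl$distance[fl$feature_id == "t2"], 0L)    # inside
  expect_false("t3" %in% fl$feature_id)                   # 5.4 kb upstream
  # monotone in flank distance: support at d implies support at d' >= d
  for (d in c(0, 73, 500, 2000, 6000)) {
    sup_d <- trna_evidence(regions, genome, flank_distance = d)$trna_supported
    sup_d2 <- trna_evidence(regions, genome,
                            flank_distance = d + 1000)$trna_supported
    expect_true(!sup_d || sup_d2)
  }
  # genomes without tRNA features are simply unsupported
  genome$features <- feats[0, ]
  expect_false(trna_evidence(regions, genome)$trna_supported)
})

test_that("generator tRNA placement is recovered as flank support", {
  for (seed in 1:10) {
    sim <- generate_genome(small_spec(seed = 200 + seed, n_prophages = 2,
                                      genome_length = 120000))
    regions <- tibble::tibble(seqid = sim$genome$id,
                              region_id = seq_len(nrow(sim$truth)),
                              start = sim$truth$start, end = sim$truth$end,
                              n_genes = sim$truth$n_genes)
    scored <- trna_evidence(regions, sim$genome, flank_distance = 2000)
    # every implant the generator flagged must be supported (controls sit
    # >= 5 kb away, so they can never create support by accident)
    expect_true(all(scored$trna_supported[sim$truth$trna_flank]),
                info = paste("seed", 200 + seed))
  }
})
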