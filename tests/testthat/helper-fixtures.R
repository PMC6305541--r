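# Shared fixtures built in code at test time.

# A minimal hand-written GenBank record: 1 forward CDS, 1 reverse CDS, 1 tRNA.
mini_genbank_text <- function() {
  set.seed(424242)
  seqv <- paste(sample(c("a", "c", "g", "t"), 240, replace = TRUE),
                collapse = "")
  chunks <- substring(seqv, seq(1, 240, 60), seq(60, 240, 60))
  c("LOCUS       TESTREC        240 bp    DNA     linear   BCT 01-JAN-2026",
    "DEFINITION  hand-written test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..240",
    "     CDS             1..30",
    "                     /locus_tag=\"T_0001\"",
    "                     /product=\"hypothetical protein\"",
    "     tRNA            100..175",
    "                     /locus_tag=\"T_0002\"",
    "                     /product=\"tRNA-Met\"",
    "ORIGIN",
    sprintf("%9d %s", seq(1, 240, 60), chunks),
    "//")
}

write_mini_genbank <- function(lines = mini_genbank_text()) {
  path <- withr::local_tempfile(fileext = ".gbk",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Small synthetic spec for fast tests: one genome in ~0.3 s.
small_spec <- function(seed, ...) {
  args <- list(genome_length = 60000, n_prophages = 1,
               prophage_length = c(8000, 12000),
               genes_per_prophage = c(8, 12), n_background_trnas = 1,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

# Random labeled 1-D instances with k planted clusters for metric tests.
random_clustered_points <- function(seed, n_clusters = 3, n_max = 30) {
  set.seed(seed)
  k <- n_clusters
  centers <- sort(runif(k, 0, 1000))
  sizes <- sample(2:max(2, n_max %/% k), k, replace = TRUE)
  x <- unlist(lapply(seq_len(k), function(i) centers[i] + rnorm(sizes[i], 0, 5)))
  list(x = x, labels = rep(seq_len(k) - 1L, sizes))
}

empty_regions_for_test <- function() prophagescan:::empty_regions()

empty_hits_for_test <- function() prophagescan:::empty_hits()
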