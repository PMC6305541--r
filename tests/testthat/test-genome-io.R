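test_that("a minimal GenBank record parses with both feature kinds", {
  path <- write_mini_genbank()
  gen <- read_annotated_genome(path)
  expect_s3_class(gen$features, "tbl_df")
  expect_equal(nrow(gen$features), 2)
  expect_setequal(gen$features$kind, c("CDS", "tRNA"))
  expect_equal(gen$length, 240)
  expect_equal(nchar(gen$sequence), 240)
  cds <- gen$features[gen$features$kind == "CDS", ]
  expect_equal(c(cds$start, cds$end, cds$strand), c(1, 30, 1))
  # translation computed from the sequence with the bacterial code
  expect_match(cds$translation, "^[A-Z*]{10}$")
  trna <- gen$features[gen$features$kind == "tRNA", ]
  expect_equal(c(trna$start, trna$end), c(100, 175))
  expect_true(is.na(trna$translation))
})

test_that("reverse-strand CDS keeps forward coordinates with strand -1", {
  lines <- mini_genbank_text()
  lines <- sub("     CDS             1..30",
               "     CDS             complement(1..30)", lines, fixed = TRUE)
  path <- write_mini_genbank(lines)
  cds <- read_annotated_genome(path)$features |>
    dplyr::filter(kind == "CDS")
  expect_equal(c(cds$start, cds$end, cds$strand), c(1, 30, -1))
})

test_that("compound join locations collapse to their outermost span", {
  lines <- mini_genbank_text()
  lines <- sub("     CDS             1..30",
               "     CDS             join(1..15,19..30)", lines, fixed = TRUE)
  path <- write_mini_genbank(lines)
  cds <- read_annotated_genome(path)$features |>
    dplyr::filter(kind == "CDS")
  expect_equal(c(cds$start, cds$end, cds$strand), c(1, 30, 1))
})

test_that("features come back sorted by start regardless of file order", {
  lines <- mini_genbank_text()
  feat_block <- lines[5:10]
  reordered <- c(lines[1:4], feat_block[c(4:6, 1:3)], lines[11:length(lines)])
  gen <- read_annotated_genome(write_mini_genbank(reordered))
  expect_false(is.unsorted(gen$features$start))
  expect_equal(gen$features$kind, c("CDS", "tRNA"))
})

test_that("EMBL flat files parse to the same record as GenBank", {
  set.seed(77)
  seqv <- paste(sample(c("a", "c", "g", "t"), 240, replace = TRUE),
                collapse = "")
  chunks <- substring(seqv, seq(1, 240, 60), seq(60, 240, 60))
  embl <- c(
    "ID   TESTREC; SV 1; linear; genomic DNA; STD; PRO; 240 BP.",
    "FT   source          1..240",
    "FT   CDS             complement(7..36)",
    "FT                   /locus_tag=\"E_0001\"",
    "FT                   /product=\"phage repressor\"",
    "FT   tRNA            100..175",
    "FT                   /locus_tag=\"E_0002\"",
    "SQ   Sequence 240 BP;",
    paste("    ", chunks, sprintf("%10d", seq(60, 240, 60))),
    "//")
  path <- withr::local_tempfile(fileext = ".embl")
  writeLines(embl, path)
  gen <- read_annotated_genome(path)   # format sniffed from the ID line
  expect_equal(gen$id, "TESTREC")
  expect_equal(toupper(substr(gen$sequence, 1, 240)), toupper(seqv))
  expect_equal(gen$features$kind, c("CDS", "tRNA"))
  expect_equal(gen$features$strand, c(-1, 1))
})

test_that("unparseable input and CDS-free genomes raise the documented errors", {
  bad <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("this is not", "a flat file"), bad)
  expect_error(read_annotated_genome(bad), "format error at line 1")

  lines <- mini_genbank_text()
  no_cds <- lines[!grepl("CDS|locus_tag=\"T_0001\"|hypothetical", lines)]
  path <- write_mini_genbank(no_cds)
  expect_error(read_annotated_genome(path), "no coding features")
})

test_that("a CDS whose length is not a codon multiple warns and truncates", {
  lines <- mini_genbank_text()
  lines <- sub("     CDS             1..30",
               "     CDS             1..31", lines, fixed = TRUE)
  expect_warning(gen <- read_annotated_genome(write_mini_genbank(lines)),
                 "not divisible by 3")
  cds <- gen$features[gen$features$kind == "CDS", ]
  expect_equal(nchar(cds$translation), 10)  # longest in-frame prefix
})

test_that("synthetic genomes round-trip through the GenBank writer/reader", {
  sim <- generate_genome(small_spec(seed = 11), dir = withr::local_tempdir())
  reread <- read_annotated_genome(sim$paths[["genbank"]])
  expect_equal(reread$id, sim$genome$id)
  expect_equal(reread$sequence, sim$genome$sequence)
  expect_equal(as.data.frame(reread$features),
               as.data.frame(sim$genome$features))
})

test_that("region writers honour the coordinate conventions of each format", {
  # one region with the first curated prophage's coordinates
  regions <- tibble::tibble(seqid = "NC_002662", region_id = 1L,
                            start = 35516L, end = 49727L, n_genes = 20L)
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "r.bed")
  write_regions(regions, bed, "bed")
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(35515L, 49727L))  # 0-based half-open
  gff <- file.path(dir, "r.gff3")
  write_regions(regions, gff, "gff3")
  gff_line <- grep("prophage_region", readLines(gff), value = TRUE)[1]
  gcols <- strsplit(gff_line, "\t")[[1]]
  expect_equal(as.integer(gcols[4:5]), c(35516L, 49727L))   # 1-based inclusive
  # BED width equals GFF3 end - start + 1
  expect_equal(as.integer(fields[3]) - as.integer(fields[2]),
               as.integer(gcols[5]) - as.integer(gcols[4]) + 1L)
})

test_that("empty region lists write valid header-only files", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "empty.tsv")
  write_regions(empty_regions_for_test(), tsv, "tsv")
  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(tab), 0)
  expect_true(all(c("region_id", "start", "end", "gc_evidence") %in% names(tab)))
  gff <- file.path(dir, "empty.gff3")
  write_regions(empty_regions_for_test(), gff, "gff3")
  expect_equal(readLines(gff), "##gff-version 3")
})

test_that("the JSON region round-trip is lossless", {
  sim <- generate_genome(small_spec(seed = 21))
  res <- suppressMessages(run_pipeline(sim$genome, sim$hits))
  expect_gt(nrow(res$regions), 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_regions(res$regions, path, "json")
  back <- read_regions_json(path)
  expect_equal(as.data.frame(back[names(res$regions)]),
               as.data.frame(res$regions))
})
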