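#' Read an annotated bacterial genome
#'
#' Parses a GenBank or EMBL flat file into a `genome_record`: the nucleotide
#' sequence plus an ordered table of CDS and tRNA features. Coding sequences
#' that carry no `/translation` qualifier are translated in-package with the
#' bacterial genetic code (translation table 11). Features on the reverse
#' strand keep forward-strand coordinates with `strand == -1`; compound
#' (`join`/`complement(join(...))`) locations are collapsed to their outermost
#' genomic span, which is all downstream clustering and evidence scoring need.
#'
#' @param path Path to a GenBank (`.gb`/`.gbk`) or EMBL (`.embl`/`.dat`) file.
#' @param format `"auto"` (default, sniffed from the first line), `"genbank"`,
#'   or `"embl"`.
#'
#' @return A `genome_record`: a list with `id`, `sequence` (upper-case
#'   character scalar), `length`, `topology` (`"linear"` or `"circular"`) and
#'   `features`, a tibble with columns `feature_id`, `kind` (`"CDS"` or
#'   `"tRNA"`), `start`, `end` (1-based inclusive), `strand` (+1/-1),
#'   `product`, `translation` and `midpoint`, sorted by `start`.
#'
#' @examples
#' gb <- system.file("extdata", "mini_genome.gbk", package = "prophagescan")
#' gen <- read_annotated_genome(gb)
#' gen$features
#' @export
read_annotated_genome <- function(path, format = c("auto", "genbank", "embl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("genome file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    if (is.na(first)) stop("format error at line 1: empty file", call. = FALSE)
    format <- if (startsWith(first, "LOCUS")) "genbank"
    else if (startsWith(first, "ID ")) "embl"
    else stop("format error at line 1: not a GenBank LOCUS or EMBL ID line: ",
              substr(first, 1, 60), call. = FALSE)
  }
  rec <- switch(format,
    genbank = parse_genbank(lines),
    embl    = parse_embl(lines)
  )
  finish_genome_record(rec)
}

#' @rdname read_annotated_genome
#' @param x Object to test or print.
#' @export
is_genome_record <- function(x) inherits(x, "genome_record")

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, %d CDS, %d tRNA\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              sum(x$features$kind == "CDS"), sum(x$features$kind == "tRNA")))
  invisible(x)
}

#' @method tidy genome_record
#' @export
tidy.genome_record <- function(x, ...) x$features

# ---- flat-file parsing ------------------------------------------------------

# Collapse a (possibly multi-line) location string to outermost span + strand.
parse_location <- function(loc, line_no) {
  strand <- if (grepl("complement", loc, fixed = TRUE)) -1L else 1L
  nums <- suppressWarnings(as.numeric(unlist(
    regmatches(loc, gregexpr("[0-9]+", loc)))))
  if (length(nums) == 0 || anyNA(nums)) {
    stop("format error at line ", line_no, ": unparseable location: ", loc,
         call. = FALSE)
  }
  list(start = as.integer(min(nums)), end = as.integer(max(nums)),
       strand = strand)
}

# Extract features of interest from a block of feature-table lines.
# `keys` and `quals` are aligned character vectors: the feature key found on
# each line ("" for continuation lines) and the line remainder.
extract_features <- function(keys, rest, line_nos) {
  starts <- which(keys %in% c("CDS", "tRNA"))
  all_feats <- which(keys != "")
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    nxt <- all_feats[all_feats > s]
    e <- if (length(nxt)) nxt[1] - 1L else length(keys)
    block <- rest[s:e]
    # location: first line plus continuations until a qualifier starts
    qual_at <- which(startsWith(trimws(block), "/"))
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
    loc <- gsub("[[:space:]]", "", paste(block[1:loc_end], collapse = ""))
    pos <- parse_location(loc, line_nos[s])
    qtext <- paste(trimws(block[seq_along(block) > loc_end]), collapse = "\n")
    out[[i]] <- tibble::tibble(
      kind = keys[s],
      start = pos$start, end = pos$end, strand = pos$strand,
      locus_tag = qualifier_value(qtext, "locus_tag"),
      product = qualifier_value(qtext, "product"),
      translation = qualifier_value(qtext, "translation", strip_space = TRUE)
    )
  }
  dplyr::bind_rows(out)
}

# Pull one qualifier's value out of the newline-joined qualifier text.
qualifier_value <- function(qtext, name, strip_space = FALSE) {
  pat <- paste0("/", name, "=\"")
  i <- regexpr(pat, qtext, fixed = TRUE)
  if (i < 0) {
    # unquoted form /name=value
    m <- regmatches(qtext, regexpr(paste0("/", name, "=[^\"\n/]+"), qtext))
    if (length(m) == 0) return(NA_character_)
    return(trimws(sub(paste0("/", name, "="), "", m[1], fixed = TRUE)))
  }
  tail <- substr(qtext, i + attr(i, "match.length"), nchar(qtext))
  j <- regexpr("\"", tail, fixed = TRUE)
  val <- if (j < 0) tail else substr(tail, 1, j - 1)
  val <- gsub("\n", " ", val)
  if (strip_space) gsub("[[:space:]]", "", val) else trimws(val)
}

parse_genbank <- function(lines) {
  locus_i <- which(startsWith(lines, "LOCUS"))[1]
  if (is.na(locus_i)) stop("format error at line 1: no LOCUS line", call. = FALSE)
  locus <- strsplit(trimws(lines[locus_i]), "[[:space:]]+")[[1]]
  id <- if (length(locus) >= 2) locus[2] else "unknown"
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  feat_i <- which(startsWith(lines, "FEATURES"))[1]
  orig_i <- which(startsWith(lines, "ORIGIN"))[1]
  if (is.na(orig_i)) stop("format error: no ORIGIN sequence block", call. = FALSE)
  feats <- tibble::tibble()
  if (!is.na(feat_i) && orig_i > feat_i + 1) {
    block <- lines[(feat_i + 1):(orig_i - 1)]
    line_nos <- (feat_i + 1):(orig_i - 1)
    # a feature key sits at column 6; continuations are indented to column 22
    keys <- ifelse(grepl("^     [^[:space:]]", block),
                   trimws(substr(block, 1, 20)), "")
    rest <- substr(block, 22, nchar(block))
    feats <- extract_features(keys, rest, line_nos)
  }
  end_i <- which(startsWith(lines, "//"))
  end_i <- if (length(end_i)) end_i[end_i > orig_i][1] else length(lines) + 1L
  seq_lines <- lines[(orig_i + 1):(end_i - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  list(id = id, topology = topology, sequence = sequence, features = feats)
}

parse_embl <- function(lines) {
  id_i <- which(startsWith(lines, "ID "))[1]
  if (is.na(id_i)) stop("format error at line 1: no ID line", call. = FALSE)
  id_parts <- strsplit(gsub(";", "", trimws(substr(lines[id_i], 4, 200))),
                       "[[:space:]]+")[[1]]
  id <- id_parts[1]
  topology <- if (any(tolower(id_parts) == "circular")) "circular" else "linear"

  ft <- which(startsWith(lines, "FT"))
  feats <- tibble::tibble()
  if (length(ft)) {
    block <- substr(lines[ft], 6, nchar(lines[ft]))
    keys <- ifelse(grepl("^[^[:space:]]", block),
                   trimws(substr(block, 1, 15)), "")
    rest <- substr(block, 17, nchar(block))
    feats <- extract_features(keys, rest, ft)
  }
  sq_i <- which(startsWith(lines, "SQ"))[1]
  if (is.na(sq_i)) stop("format error: no SQ sequence block", call. = FALSE)
  end_i <- which(startsWith(lines, "//"))
  end_i <- if (length(end_i)) end_i[end_i > sq_i][1] else length(lines) + 1L
  seq_lines <- lines[(sq_i + 1):(end_i - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", gsub("[0-9]", "", paste(seq_lines, collapse = ""))))
  list(id = id, topology = topology, sequence = sequence, features = feats)
}

# Validate, sort, assign ids, fill missing translations.
finish_genome_record <- function(rec) {
  len <- nchar(rec$sequence)
  feats <- rec$features
  if (nrow(feats) == 0 || !any(feats$kind == "CDS")) {
    stop("no coding features: the genome has no CDS annotations; ",
         "the pipeline cannot run", call. = FALSE)
  }
  bad <- feats$start < 1 | feats$end > len | feats$start > feats$end
  if (any(bad)) {
    stop("feature interval outside [1, ", len, "]: ",
         feats$start[bad][1], "..", feats$end[bad][1], call. = FALSE)
  }
  feats <- dplyr::arrange(feats, .data$start, .data$end)
  feats$feature_id <- ifelse(
    is.na(feats$locus_tag) | feats$locus_tag == "",
    sprintf("feat_%04d", seq_len(nrow(feats))), feats$locus_tag)
  feats$midpoint <- (feats$start + feats$end) %/% 2L
  need_tr <- feats$kind == "CDS" & (is.na(feats$translation) | feats$translation == "")
  if (any(need_tr)) {
    feats$translation[need_tr] <- translate_cds_batch(
      rec$sequence, feats$start[need_tr], feats$end[need_tr],
      feats$strand[need_tr], feats$feature_id[need_tr])
  }
  feats$translation[feats$kind != "CDS"] <- NA_character_
  feats <- dplyr::select(feats, "feature_id", "kind", "start", "end",
                         "strand", "product", "translation", "midpoint")
  structure(list(id = rec$id, sequence = rec$sequence, length = len,
                 topology = rec$topology, features = feats),
            class = "genome_record")
}

# Translate CDS spans with the bacterial code (table 11), in one batched
# Biostrings call. A length not divisible by 3 translates the longest
# in-frame prefix, with a warning.
translate_cds_batch <- function(sequence, start, end, strand, ids) {
  nt <- substr(rep(sequence, length(start)), start, end)
  rev <- strand < 0
  if (any(rev)) {
    nt[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(nt[rev])))
  }
  extra <- nchar(nt) %% 3L
  if (any(extra != 0L)) {
    warning("CDS ", paste(ids[extra != 0L], collapse = ", "),
            " length not divisible by 3; translating the longest in-frame ",
            "prefix", call. = FALSE)
    nt <- substr(nt, 1, nchar(nt) - extra)
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve"))
  unname(sub("\\*$", "", aa))
}

translate_cds <- function(sequence, start, end, strand, id = "") {
  translate_cds_batch(sequence, start, end, strand, id)
}

# ---- region output ----------------------------------------------------------

region_tsv_cols <- c("region_id", "start", "end", "n_genes", "gc_evidence",
                     "trna_evidence", "conserved", "best_phage", "phage_fraction")

# Ensure a regions tibble carries every canonical column (NA when a stage
# has not been run), so writers are usable after any pipeline stage.
canonical_regions <- function(regions) {
  defaults <- list(
    seqid = NA_character_, region_id = NA_integer_,
    start = NA_integer_, end = NA_integer_, n_genes = NA_integer_,
    gc_supported = NA, deviant_fraction = NA_real_,
    trna_supported = NA, conserved = NA,
    best_phage = NA_character_, phage_fraction = NA_real_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(regions)) regions[[nm]] <- defaults[[nm]]
  }
  regions
}

#' Write candidate prophage regions
#'
#' Writes a regions table (as produced by [labeling_to_regions()] and
#' augmented by the evidence and conservation stages) to TSV, GFF3, BED or
#' JSON. TSV and GFF3 use 1-based inclusive coordinates; BED converts to
#' 0-based half-open (`chromStart = start - 1`, `chromEnd = end`). JSON keeps
#' the full nested detail (member genes, per-gene G+C values, flanking tRNAs,
#' per-phage gene counts) and round-trips losslessly through
#' [read_regions_json()].
#'
#' @param regions Regions tibble; an empty tibble writes a header-only file.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"gff3"`, `"bed"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "gff3", "bed", "json")) {
  format <- match.arg(format)
  regions <- canonical_regions(regions)
  switch(format,
    tsv = {
      tab <- tibble::tibble(
        region_id = regions$region_id, start = regions$start,
        end = regions$end, n_genes = regions$n_genes,
        gc_evidence = regions$gc_supported,
        trna_evidence = regions$trna_supported,
        conserved = regions$conserved, best_phage = regions$best_phage,
        phage_fraction = regions$phage_fraction)
      readr::write_tsv(tab, path)
    },
    bed = {
      tab <- tibble::tibble(
        chrom = regions$seqid,
        chromStart = regions$start - 1L, chromEnd = regions$end,
        name = paste0("prophage_region_", regions$region_id))
      readr::write_tsv(tab[seq_len(nrow(regions)), ], path, col_names = FALSE)
    },
    gff3 = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("##gff-version 3", con)
      if (nrow(regions)) {
        attrs <- sprintf(
          "ID=prophage_region_%d;n_genes=%d;gc_evidence=%s;trna_evidence=%s;conserved=%s;best_phage=%s;phage_fraction=%s",
          regions$region_id, regions$n_genes,
          tolower(as.character(regions$gc_supported)),
          tolower(as.character(regions$trna_supported)),
          tolower(as.character(regions$conserved)),
          ifelse(is.na(regions$best_phage), "NA", regions$best_phage),
          ifelse(is.na(regions$phage_fraction), "NA",
                 format(regions$phage_fraction, digits = 10)))
        writeLines(sprintf("%s\tprophagescan\tprophage_region\t%d\t%d\t.\t.\t.\t%s",
                           regions$seqid, regions$start, regions$end, attrs), con)
      }
    },
    json = {
      jsonlite::write_json(regions_to_list(regions), path,
                           auto_unbox = TRUE, digits = NA, null = "null",
                           dataframe = "rows", pretty = TRUE)
    }
  )
  invisible(path)
}

regions_to_list <- function(regions) {
  purrr::map(seq_len(nrow(regions)), function(i) {
    row <- as.list(regions[i, setdiff(names(regions),
                                      c("genes", "gene_gc", "flanking_trnas",
                                        "per_phage_counts"))])
    row <- purrr::map(row, function(v) if (is.na(v)) NULL else v)
    row <- row[!purrr::map_lgl(row, is.null)]
    if ("genes" %in% names(regions)) row$genes <- regions$genes[[i]]
    if ("gene_gc" %in% names(regions)) row$gene_gc <- regions$gene_gc[[i]]
    if ("flanking_trnas" %in% names(regions))
      row$flanking_trnas <- regions$flanking_trnas[[i]]
    if ("per_phage_counts" %in% names(regions))
      row$per_phage_counts <- as.list(regions$per_phage_counts[[i]])
    row
  })
}

#' @rdname write_regions
#' @details `read_regions_json()` reconstructs the full regions tibble,
#'   including list-columns, from a JSON file written by `write_regions()`.
#' @export
read_regions_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0) return(empty_regions())
  rows <- purrr::map(raw, function(r) {
    tibble::tibble(
      seqid = r$seqid %||% NA_character_,
      region_id = as.integer(r$region_id %||% NA),
      start = as.integer(r$start), end = as.integer(r$end),
      n_genes = as.integer(r$n_genes %||% NA),
      gc_supported = as.logical(r$gc_supported %||% NA),
      deviant_fraction = as.numeric(r$deviant_fraction %||% NA),
      trna_supported = as.logical(r$trna_supported %||% NA),
      conserved = as.logical(r$conserved %||% NA),
      best_phage = r$best_phage %||% NA_character_,
      phage_fraction = as.numeric(r$phage_fraction %||% NA),
      genes = list(rebind_frame(r$genes, ptype_genes())),
      gene_gc = list(as.numeric(unlist(r$gene_gc))),
      flanking_trnas = list(rebind_frame(r$flanking_trnas, ptype_trnas())),
      per_phage_counts = list(rebind_counts(r$per_phage_counts))
    )
  })
  dplyr::bind_rows(rows)
}

ptype_genes <- function() {
  tibble::tibble(feature_id = character(), start = integer(),
                 end = integer(), midpoint = integer())
}

ptype_trnas <- function() {
  tibble::tibble(feature_id = character(), distance = integer())
}

rebind_frame <- function(x, ptype) {
  if (is.null(x) || length(x) == 0) return(ptype)
  rows <- dplyr::bind_rows(purrr::map(x, tibble::as_tibble))
  for (nm in names(ptype)) {
    rows[[nm]] <- if (is.integer(ptype[[nm]])) as.integer(rows[[nm]])
                  else if (is.character(ptype[[nm]])) as.character(rows[[nm]])
                  else as.numeric(rows[[nm]])
  }
  rows[names(ptype)]
}

rebind_counts <- function(x) {
  out <- unlist(purrr::map(x, as.integer))
  if (is.null(out)) stats::setNames(integer(0), character(0)) else out
}

empty_regions <- function() {
  tibble::tibble(
    seqid = character(), region_id = integer(), start = integer(),
    end = integer(), n_genes = integer(), gc_supported = logical(),
    deviant_fraction = double(), trna_supported = logical(),
    conserved = logical(), best_phage = character(),
    phage_fraction = double(), genes = list(), gene_gc = list(),
    flanking_trnas = list(), per_phage_counts = list())
}

#' Read reference prophage intervals
#'
#' Reads reference (or predicted) prophage intervals from BED (0-based
#' half-open, converted to 1-based inclusive) or from a TSV/CSV with `start`
#' and `end` columns (1-based inclusive as-is).
#'
#' @param path BED or TSV file.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return Tibble with columns `start`, `end` (and `name` when present).
#' @export
read_intervals <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           comment = "#")
    out <- tibble::tibble(start = as.integer(tab[[2]]) + 1L,
                          end = as.integer(tab[[3]]))
    if (ncol(tab) >= 4) out$name <- as.character(tab[[4]])
    out
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    names(tab) <- tolower(names(tab))
    if (!all(c("start", "end") %in% names(tab))) {
      stop("interval TSV must have 'start' and 'end' columns", call. = FALSE)
    }
    tibble::tibble(start = as.integer(tab$start), end = as.integer(tab$end),
                   name = if ("name" %in% names(tab)) as.character(tab$name)
                          else NA_character_)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
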