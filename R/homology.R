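#' Parse a 12-column tabular protein alignment file
#'
#' Reads the de-facto tabular alignment dialect (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore;
#' tab-separated, `#` comment lines skipped) into a tibble of homology hits.
#' The source-phage identifier is extracted from the subject id: the text
#' before the first `|`, or the whole subject id if it has none; a custom
#' regular expression (first capture group) can override this.
#'
#' @param path Path to a hits file, or a character vector of lines via `text`.
#' @param text Optional literal table text (overrides `path`).
#' @param phage_id_regex Optional regex whose first capture group yields the
#'   phage id from the subject id.
#' @return Tibble with columns `query_id`, `subject_id`, `phage_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @export
parse_hits_table <- function(path = NULL, text = NULL, phage_id_regex = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE))
  } else {
    if (!file.exists(path)) stop("hits file not found: ", path, call. = FALSE)
    readLines(path, warn = FALSE)
  }
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  line_nos <- which(keep)
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    bad <- which(nf < 12)[1]
    stop("hits table parse error at line ", line_nos[bad], ": expected >= 12 ",
         "tab-separated fields, found ", nf[bad], call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("hits table parse error at line ", line_nos[bad], ": non-numeric ",
           what, ": ", m[bad, j], call. = FALSE)
    }
    v
  }
  hits <- tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    phage_id = extract_phage_id(m[, 2], phage_id_regex),
    percent_identity = num(3, "percent identity"),
    align_length = as.integer(num(4, "alignment length")),
    mismatches = as.integer(num(5, "mismatch count")),
    gap_opens = as.integer(num(6, "gap open count")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "e-value"), bitscore = num(12, "bitscore"))
  bad <- hits$percent_identity < 0 | hits$percent_identity > 100 | hits$evalue < 0
  if (any(bad)) {
    stop("hits table parse error at line ", line_nos[which(bad)[1]],
         ": identity outside [0,100] or negative e-value", call. = FALSE)
  }
  hits
}

extract_phage_id <- function(subject_id, phage_id_regex = NULL) {
  if (!is.null(phage_id_regex)) {
    m <- regmatches(subject_id, regexec(phage_id_regex, subject_id))
    out <- vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_,
                  character(1))
    if (anyNA(out)) {
      stop("phage_id_regex did not match subject id: ",
           subject_id[is.na(out)][1], call. = FALSE)
    }
    return(out)
  }
  sub("\\|.*$", "", subject_id)
}

empty_hits <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(), phage_id = character(),
    percent_identity = double(), align_length = integer(),
    mismatches = integer(), gap_opens = integer(), qstart = integer(),
    qend = integer(), sstart = integer(), send = integer(),
    evalue = double(), bitscore = double())
}

#' @rdname parse_hits_table
#' @param hits Hits tibble to write back out in the same 12-column dialect.
#' @export
write_hits_table <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   hits$query_id, hits$subject_id,
                   as.character(hits$percent_identity),
                   hits$align_length, hits$mismatches, hits$gap_opens,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   formatC(hits$evalue, format = "e", digits = 2),
                   as.character(hits$bitscore))
  writeLines(lines, path)
  invisible(path)
}

#' Filter homology hits on identity and e-value
#'
#' Retains hits with `percent_identity >= min_identity` (boundary inclusive)
#' and `evalue <= max_evalue`; optionally reduces to the single best hit per
#' query (highest bitscore, ties broken by lower e-value then lexicographically
#' smallest subject id). The identity default follows the 80% alignment
#' identity used for the tool's benchmark runs.
#'
#' @param hits Hits tibble from [parse_hits_table()].
#' @param min_identity Minimum percent identity in \[0, 100\] (default 80).
#' @param max_evalue Maximum e-value (default 1e-5).
#' @param best_hit_per_query Keep only the best hit per query (default TRUE);
#'   the conservation call needs one source phage per gene.
#' @return Filtered hits tibble, sorted by `query_id`.
#' @export
filter_hits <- function(hits, min_identity = 80, max_evalue = 1e-5,
                        best_hit_per_query = TRUE) {
  stopifnot(min_identity >= 0, min_identity <= 100, max_evalue > 0)
  out <- dplyr::filter(hits, .data$percent_identity >= min_identity,
                       .data$evalue <= max_evalue)
  if (best_hit_per_query && nrow(out) > 0) {
    out <- out |>
      dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore),
                     .data$evalue, .data$subject_id) |>
      dplyr::distinct(.data$query_id, .keep_all = TRUE)
  }
  dplyr::arrange(out, .data$query_id)
}

#' Run an external protein aligner to produce a hits table
#'
#' Searches CDS translations against a phage protein FASTA with DIAMOND if
#' available, else NCBI BLAST+ (`makeblastdb` + `blastp`), producing a
#' 12-column tabular file readable by [parse_hits_table()]. The pipeline does
#' not require any aligner: a precomputed hits table is always accepted
#' instead, and a missing executable raises a condition of class
#' `"aligner_missing"`.
#'
#' @param proteins Amino-acid FASTA of query proteins.
#' @param db Phage protein FASTA database.
#' @param out Output path for the tabular hits file.
#' @param max_evalue E-value cutoff passed to the aligner (default 1e-5).
#' @param threads Aligner threads (default 1).
#' @return `out`, invisibly. The command line used is message()d verbatim.
#' @export
run_external_search <- function(proteins, db, out = tempfile(fileext = ".tsv"),
                                max_evalue = 1e-5, threads = 1) {
  if (!file.exists(proteins)) stop("query FASTA not found: ", proteins, call. = FALSE)
  if (!file.exists(db)) stop("database FASTA not found: ", db, call. = FALSE)
  diamond <- Sys.which("diamond")
  blastp <- Sys.which("blastp")
  if (nzchar(diamond)) {
    dbfile <- tempfile(fileext = ".dmnd")
    cmd1 <- c("makedb", "--in", db, "-d", dbfile)
    run_logged(diamond, cmd1)
    cmd2 <- c("blastp", "-q", proteins, "-d", dbfile, "-o", out,
              "--outfmt", "6", "-e", format(max_evalue), "-p", threads)
    run_logged(diamond, cmd2)
  } else if (nzchar(blastp)) {
    makeblastdb <- Sys.which("makeblastdb")
    dbdir <- tempfile("blastdb")
    dir.create(dbdir)
    dbfile <- file.path(dbdir, "phagedb")
    run_logged(makeblastdb, c("-in", db, "-dbtype", "prot", "-out", dbfile))
    run_logged(blastp, c("-query", proteins, "-db", dbfile, "-out", out,
                         "-outfmt", "6", "-evalue", format(max_evalue),
                         "-num_threads", threads))
  } else {
    cond <- structure(
      class = c("aligner_missing", "error", "condition"),
      list(message = paste0(
        "no protein aligner found on PATH (tried diamond, blastp); ",
        "supply a precomputed hits table instead"),
        call = sys.call(-1)))
    stop(cond)
  }
  if (!file.exists(out)) file.create(out)
  invisible(out)
}

run_logged <- function(exe, args) {
  message("running: ", exe, " ", paste(args, collapse = " "))
  status <- system2(exe, args, stdout = FALSE, stderr = FALSE)
  if (status != 0) {
    stop("aligner command failed (exit ", status, "): ", exe, " ",
         paste(args, collapse = " "), call. = FALSE)
  }
  invisible(status)
}

#' Write CDS translations to an amino-acid FASTA
#'
#' @param genome A `genome_record`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(genome, path) {
  cds <- dplyr::filter(genome$features, .data$kind == "CDS",
                       !is.na(.data$translation), nzchar(.data$translation))
  aa <- Biostrings::AAStringSet(gsub("\\*", "", cds$translation))
  names(aa) <- cds$feature_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
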