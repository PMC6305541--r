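#' Specification for a synthetic genome with implanted prophages
#'
#' Defines the study conditions for the seeded generator: a background
#' chromosome of i.i.d. nucleotides at a set G+C level, with non-overlapping
#' prophage cassettes of shifted G+C implanted along it, tRNA genes placed in
#' the flanks of some implants, protein-coding genes tiled inside implants
#' and (at bacterial coding density) across the background, and a matching
#' homology-hits table in which implant genes hit their source phage (with a
#' dropout rate) and background genes occasionally draw a false hit.
#'
#' @param genome_length Chromosome length in bp (default 200000).
#' @param background_gc Background G+C fraction (default 0.45).
#' @param n_prophages Number of implanted cassettes (default 3).
#' @param prophage_length Length range in bp (default c(15000, 45000),
#'   matching curated prophage spans in bacterial chromosomes).
#' @param prophage_gc_shift Additive G+C shift of implants (default +0.10).
#' @param genes_per_prophage Gene-count range per implant (default c(10, 30)).
#' @param background_gene_density Background genes per kb (default 0.8,
#'   typical bacterial coding density).
#' @param trna_flank_probability Probability that an implant receives a tRNA
#'   within 2 kb of one boundary (default 0.5).
#' @param n_background_trnas tRNAs placed far (>= 5 kb) from any implant, as
#'   negative controls (default 2).
#' @param false_hit_rate Probability a background gene draws a spurious
#'   phage hit (default 0.01).
#' @param miss_rate Probability an implant gene's hit is dropped
#'   (default 0.05).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(genome_length = 200000, background_gc = 0.45,
                           n_prophages = 3,
                           prophage_length = c(15000, 45000),
                           prophage_gc_shift = 0.10,
                           genes_per_prophage = c(10, 30),
                           background_gene_density = 0.8,
                           trna_flank_probability = 0.5,
                           n_background_trnas = 2,
                           false_hit_rate = 0.01, miss_rate = 0.05,
                           seed = 1) {
  spec <- list(genome_length = as.integer(genome_length),
               background_gc = background_gc,
               n_prophages = as.integer(n_prophages),
               prophage_length = as.integer(prophage_length),
               genes_per_prophage = as.integer(genes_per_prophage),
               prophage_gc_shift = prophage_gc_shift,
               background_gene_density = background_gene_density,
               trna_flank_probability = trna_flank_probability,
               n_background_trnas = as.integer(n_background_trnas),
               false_hit_rate = false_hit_rate, miss_rate = miss_rate,
               seed = as.integer(seed))
  stopifnot(spec$genome_length >= 10000,
            spec$background_gc > 0, spec$background_gc < 1,
            spec$background_gc + spec$prophage_gc_shift > 0,
            spec$background_gc + spec$prophage_gc_shift < 1,
            spec$n_prophages >= 0,
            length(spec$prophage_length) == 2,
            spec$prophage_length[1] <= spec$prophage_length[2],
            length(spec$genes_per_prophage) == 2,
            spec$genes_per_prophage[1] >= 1,
            spec$trna_flank_probability >= 0, spec$trna_flank_probability <= 1,
            spec$false_hit_rate >= 0, spec$false_hit_rate <= 1,
            spec$miss_rate >= 0, spec$miss_rate <= 1)
  structure(spec, class = "synthetic_spec")
}

# i.i.d. nucleotide vector at the given G+C level
random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Place n non-overlapping implants with margins from the ends and a minimum
# gap, by randomly distributing the free space among the gaps.
place_implants <- function(genome_length, lengths, margin = 5000, gap = 10000) {
  n <- length(lengths)
  if (n == 0) return(integer(0))
  free <- genome_length - 2 * margin - sum(lengths) - (n - 1) * gap
  if (free < 0) {
    stop("cannot place ", n, " implants totalling ", sum(lengths),
         " bp in a ", genome_length, " bp genome; reduce n_prophages or ",
         "prophage_length", call. = FALSE)
  }
  extra <- diff(c(0, sort(stats::runif(n, 0, free))))
  starts <- integer(n)
  pos <- margin
  for (i in seq_len(n)) {
    pos <- pos + extra[i]
    starts[i] <- as.integer(round(pos)) + 1L
    pos <- pos + lengths[i] + gap
  }
  starts
}

# Tile non-overlapping genes across [lo, hi]; lengths are multiples of 3.
tile_genes <- function(lo, hi, n) {
  if (n == 0 || hi - lo + 1 < 200) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = integer()))
  }
  slot <- (hi - lo + 1) %/% n
  n <- if (slot < 200) max(1L, (hi - lo + 1L) %/% 200L) else n
  slot <- (hi - lo + 1) %/% n
  glen <- pmin(slot - 60L, as.integer(round(stats::runif(n, 0.55, 0.85) * slot)))
  glen <- pmax(90L, (glen %/% 3L) * 3L)
  offs <- vapply(slot - glen - 1L, function(m) sample.int(max(m, 1L), 1L),
                 integer(1))
  start <- lo + (seq_len(n) - 1L) * slot + offs
  tibble::tibble(start = as.integer(start),
                 end = as.integer(start + glen - 1L),
                 strand = sample(c(1L, -1L), n, replace = TRUE))
}

#' Generate a synthetic annotated genome with implanted prophages
#'
#' Emits three mutually consistent artifacts: a GenBank file (CDS with
#' translations, tRNA features, full sequence), a ground-truth table of the
#' implanted regions, and a 12-column homology-hits table in which every
#' implant gene hits its source phage (`PHAGE_k|p...` subject ids, identity
#' uniform on \[85, 100\], minus `miss_rate` dropouts) and background genes
#' draw a `DECOY_*` hit at `false_hit_rate`. Byte-identical across runs with
#' the same spec.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory; created if needed. When NULL, nothing is
#'   written and only in-memory objects are returned.
#' @return List with `genome` (a `genome_record`), `truth` (tibble: `start`,
#'   `end`, `phage_id`, `n_genes`, `trna_flank`), `gene_assignments` (tibble:
#'   `feature_id`, `assignment`), `hits` (tibble), and `paths` (named:
#'   `genbank`, `truth_bed`, `hits_tsv`) when `dir` is given.
#' @examples
#' sim <- generate_genome(synthetic_spec(genome_length = 50000,
#'                                       n_prophages = 1, seed = 42))
#' sim$truth
#' @export
generate_genome <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_prophages
  imp_len <- if (n > 0) {
    as.integer(round(stats::runif(n, spec$prophage_length[1],
                                  spec$prophage_length[2])))
  } else integer(0)
  imp_start <- place_implants(spec$genome_length, imp_len)
  imp_end <- imp_start + imp_len - 1L

  # sequence: background segments at background_gc, implants shifted
  bounds <- c(1L, as.vector(rbind(imp_start, imp_end + 1L)),
              spec$genome_length + 1L)
  seq_parts <- character(0)
  for (i in seq_len(length(bounds) - 1)) {
    seg_len <- bounds[i + 1] - bounds[i]
    if (seg_len <= 0) next
    gc <- if (i %% 2 == 0) spec$background_gc + spec$prophage_gc_shift
          else spec$background_gc
    seq_parts <- c(seq_parts, paste(random_bases(seg_len, gc), collapse = ""))
  }
  sequence <- paste(seq_parts, collapse = "")
  stopifnot(nchar(sequence) == spec$genome_length)

  # implant genes
  implant_genes <- purrr::map(seq_len(n), function(k) {
    ng <- sample(seq.int(spec$genes_per_prophage[1],
                         spec$genes_per_prophage[2]), 1)
    g <- tile_genes(imp_start[k], imp_end[k], ng)
    g$origin <- paste0("PHAGE_", k)
    g$product <- paste0("phage protein (PHAGE_", k, ")")
    g
  })
  # background genes across inter-implant segments
  bg_bounds <- matrix(c(1L, imp_end + 1L, imp_start - 1L, spec$genome_length),
                      ncol = 2)
  bg_genes <- purrr::map(seq_len(nrow(bg_bounds)), function(i) {
    lo <- bg_bounds[i, 1]; hi <- bg_bounds[i, 2]
    if (hi - lo < 500) return(NULL)
    ng <- as.integer(round((hi - lo + 1) / 1000 * spec$background_gene_density))
    g <- tile_genes(lo, hi, ng)
    if (nrow(g) == 0) return(NULL)
    g$origin <- "background"
    g$product <- "hypothetical protein"
    g
  })
  cds <- dplyr::bind_rows(c(implant_genes, bg_genes))
  cds$kind <- "CDS"

  # tRNAs: implant flanks with stated probability, plus far-away controls
  trna_flank <- rep(FALSE, n)
  trna_rows <- list()
  amino <- c("Ala", "Arg", "Asn", "Asp", "Gly", "Leu", "Lys", "Met", "Ser", "Thr")
  for (k in seq_len(n)) {
    if (stats::runif(1) > spec$trna_flank_probability) next
    side <- sample(c("left", "right"), 1)
    off <- sample(0:1900, 1)
    if (side == "right") {
      ts <- imp_end[k] + off + 1L
    } else {
      ts <- imp_start[k] - off - 75L
    }
    if (ts < 1 || ts + 74L > spec$genome_length) next
    trna_flank[k] <- TRUE
    trna_rows[[length(trna_rows) + 1]] <- tibble::tibble(
      start = as.integer(ts), end = as.integer(ts + 74L),
      strand = sample(c(1L, -1L), 1), origin = "flank",
      product = paste0("tRNA-", sample(amino, 1)), kind = "tRNA")
  }
  if (spec$n_background_trnas > 0) {
    far <- function(p) n == 0 ||
      all(pmin(abs(p - imp_start), abs(p - imp_end)) >= 5000 &
            (p < imp_start | p > imp_end))
    placed <- 0
    tries <- 0
    while (placed < spec$n_background_trnas && tries < 200) {
      tries <- tries + 1
      p <- sample.int(spec$genome_length - 80L, 1)
      if (!far(p) || !far(p + 74L)) next
      placed <- placed + 1
      trna_rows[[length(trna_rows) + 1]] <- tibble::tibble(
        start = as.integer(p), end = as.integer(p + 74L),
        strand = sample(c(1L, -1L), 1), origin = "background",
        product = paste0("tRNA-", sample(amino, 1)), kind = "tRNA")
    }
  }
  feats <- dplyr::bind_rows(c(list(cds), trna_rows)) |>
    dplyr::arrange(.data$start, .data$end)
  feats$locus_tag <- sprintf("SYN_%04d", seq_len(nrow(feats)))
  origin <- feats$origin

  rec <- finish_genome_record(list(
    id = sprintf("SYNGENOME_%d", spec$seed), topology = "linear",
    sequence = sequence,
    features = dplyr::select(feats, "kind", "start", "end", "strand",
                             "locus_tag", "product") |>
      dplyr::mutate(translation = NA_character_)))

  # hits table, keyed on final locus tags (features are already sorted)
  is_cds <- feats$kind == "CDS"
  hit_rows <- purrr::map(which(is_cds), function(i) {
    org <- origin[i]
    if (org == "background") {
      if (stats::runif(1) >= spec$false_hit_rate) return(NULL)
      sid <- sprintf("DECOY_%02d|p001", sample.int(20, 1))
    } else {
      if (stats::runif(1) < spec$miss_rate) return(NULL)
      sid <- sprintf("%s|p%03d", org, sample.int(500, 1))
    }
    aa_len <- (feats$end[i] - feats$start[i] + 1L) %/% 3L
    pid <- round(stats::runif(1, 85, 100), 1)
    tibble::tibble(
      query_id = feats$locus_tag[i], subject_id = sid,
      phage_id = sub("\\|.*$", "", sid),
      percent_identity = pid, align_length = aa_len,
      mismatches = as.integer(round(aa_len * (100 - pid) / 100)),
      gap_opens = 0L, qstart = 1L, qend = aa_len,
      sstart = 1L, send = aa_len,
      evalue = 10^-sample(20:120, 1),
      bitscore = round(stats::runif(1, 150, 400), 1))
  })
  hits <- dplyr::bind_rows(hit_rows)
  if (nrow(hits) == 0) hits <- empty_hits()

  truth <- tibble::tibble(
    start = imp_start, end = imp_end,
    phage_id = if (n > 0) paste0("PHAGE_", seq_len(n)) else character(0),
    n_genes = purrr::map_int(implant_genes, nrow),
    trna_flank = trna_flank)
  assignments <- tibble::tibble(feature_id = feats$locus_tag,
                                kind = feats$kind, assignment = origin)

  out <- list(genome = rec, truth = truth, gene_assignments = assignments,
              hits = hits, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(genbank = file.path(dir, paste0(rec$id, ".gbk")),
               truth_bed = file.path(dir, paste0(rec$id, ".truth.bed")),
               hits_tsv = file.path(dir, paste0(rec$id, ".hits.tsv")))
    write_genbank(rec, paths[["genbank"]])
    readr::write_tsv(
      tibble::tibble(chrom = rec$id, chromStart = truth$start - 1L,
                     chromEnd = truth$end, name = truth$phage_id),
      paths[["truth_bed"]], col_names = FALSE)
    write_hits_table(hits, paths[["hits_tsv"]])
    out$paths <- paths
  }
  out
}

#' Write a genome record as a GenBank flat file
#'
#' @param genome A `genome_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-17s %d bp    DNA     %-8s BCT 01-JAN-2026",
                     genome$id, genome$length, genome$topology), con)
  writeLines(c(sprintf("DEFINITION  synthetic bacterial chromosome %s.", genome$id),
               sprintf("ACCESSION   %s", genome$id),
               "FEATURES             Location/Qualifiers",
               sprintf("     source          1..%d", genome$length)), con)
  qual <- function(name, value) {
    text <- sprintf("/%s=\"%s\"", name, value)
    out <- character(0)
    while (nchar(text) > 58) {
      out <- c(out, paste0(strrep(" ", 21), substr(text, 1, 58)))
      text <- substr(text, 59, nchar(text))
    }
    c(out, paste0(strrep(" ", 21), text))
  }
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] < 0) loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", f$kind[i], loc), con)
    writeLines(qual("locus_tag", f$feature_id[i]), con)
    if (!is.na(f$product[i])) writeLines(qual("product", f$product[i]), con)
    if (f$kind[i] == "CDS" && !is.na(f$translation[i])) {
      writeLines(qual("translation", f$translation[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- genome$sequence
  starts <- seq.int(1L, nchar(s), by = 60L)
  lines <- vapply(starts, function(p) {
    chunk <- tolower(substr(s, p, min(p + 59L, nchar(s))))
    grp <- substring(chunk, seq(1, nchar(chunk), 10),
                     pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", p, paste(grp, collapse = " "))
  }, character(1))
  writeLines(lines, con)
  writeLines("//", con)
  invisible(path)
}
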