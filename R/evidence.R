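#' G+C fraction of a nucleotide sequence
#'
#' Case-insensitive (G+C)/(A+C+G+T); `N` and other ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param seq Nucleotide character scalar.
#' @return Fraction in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  s <- toupper(seq)
  gc <- nchar(gsub("[^GC]", "", s))
  acgt <- nchar(gsub("[^ACGT]", "", s))
  if (acgt == 0) {
    stop("undefined G+C content: sequence has no unambiguous A/C/G/T bases",
         call. = FALSE)
  }
  gc / acgt
}

# Cumulative base profile over the genome sequence, for O(1) interval
# queries: gc[i] = number of G/C in positions 1..i, acgt[i] likewise.
gc_profile <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  list(gc = cumsum(ch == "G" | ch == "C"),
       acgt = cumsum(ch %in% c("A", "C", "G", "T")))
}

interval_gc <- function(profile, start, end) {
  gc0 <- c(0, profile$gc)
  acgt0 <- c(0, profile$acgt)
  gc <- gc0[end + 1L] - gc0[start]
  acgt <- acgt0[end + 1L] - acgt0[start]
  ifelse(acgt > 0, gc / acgt, NA_real_)
}

#' Sliding-window G+C statistics of a genome
#'
#' Slides a window of `window_size` bp (default 1000) along the genome in
#' steps of `step` bp (default 100); windows start at 1, 1+step, ... while
#' they fit entirely inside the sequence. Returns every window's G+C fraction
#' together with their mean and population standard deviation, the genome-wide
#' baseline against which gene-level deviation is judged.
#'
#' @param genome A `genome_record` (or a plain nucleotide string).
#' @param window_size Window width in bp (default 1000).
#' @param step Step between window starts in bp (default 100).
#' @return A `gc_stats` list: `window_size`, `step`, `starts`,
#'   `window_values`, `mean`, `sd` (population).
#' @export
windowed_gc_stats <- function(genome, window_size = 1000, step = 100) {
  sequence <- if (is_genome_record(genome)) genome$sequence else genome
  len <- nchar(sequence)
  stopifnot(window_size >= 1, step >= 1)
  if (len < window_size) {
    warning("genome (", len, " bp) shorter than the window (", window_size,
            " bp); using one window over the whole sequence", call. = FALSE)
    window_size <- len
  }
  starts <- seq.int(1L, len - window_size + 1L, by = step)
  prof <- gc_profile(sequence)
  vals <- interval_gc(prof, starts, starts + window_size - 1L)
  if (anyNA(vals)) {
    stop("undefined G+C content: a window contains no unambiguous bases",
         call. = FALSE)
  }
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 starts = starts, window_values = vals,
                 mean = mean(vals),
                 sd = sqrt(mean((vals - mean(vals))^2))),
            class = "gc_stats")
}

#' @export
print.gc_stats <- function(x, ...) {
  cat(sprintf("<gc_stats> %d windows of %d bp (step %d): mean %.4f, sd %.4f\n",
              length(x$window_values), x$window_size, x$step, x$mean, x$sd))
  invisible(x)
}

#' Score regions for G+C-content deviation
#'
#' A member gene is deviant when the G+C fraction of its genomic span lies
#' strictly above `mean + sd` or strictly below `mean - sd` of the sliding
#' window statistics; a region is G+C-supported when at least
#' `gene_fraction_threshold` (default 0.80, boundary inclusive) of its genes
#' are deviant. Evidence is annotative: no region is removed, only flagged.
#'
#' @param regions Regions tibble from [labeling_to_regions()].
#' @param genome The `genome_record`.
#' @param stats A `gc_stats` from [windowed_gc_stats()] (computed on demand
#'   when NULL).
#' @param gene_fraction_threshold Fraction of genes that must deviate
#'   (default 0.80).
#' @return `regions` with added columns `gene_gc` (list of per-gene G+C
#'   fractions), `deviant_fraction` and `gc_supported`.
#' @export
gc_evidence <- function(regions, genome, stats = NULL,
                        gene_fraction_threshold = 0.80) {
  stopifnot(gene_fraction_threshold >= 0, gene_fraction_threshold <= 1)
  if (is.null(stats)) stats <- windowed_gc_stats(genome)
  if (nrow(regions) == 0) {
    regions$gene_gc <- list()
    regions$deviant_fraction <- double(0)
    regions$gc_supported <- logical(0)
    return(regions)
  }
  if (any(regions$n_genes == 0)) {
    stop("cannot score G+C evidence for a region with no member genes",
         call. = FALSE)
  }
  prof <- gc_profile(genome$sequence)
  lo <- stats$mean - stats$sd
  hi <- stats$mean + stats$sd
  res <- purrr::map(regions$genes, function(g) {
    vals <- interval_gc(prof, g$start, g$end)
    deviant <- vals > hi | vals < lo
    list(gc = vals, frac = mean(deviant))
  })
  regions$gene_gc <- purrr::map(res, "gc")
  regions$deviant_fraction <- purrr::map_dbl(res, "frac")
  regions$gc_supported <- regions$deviant_fraction >= gene_fraction_threshold
  regions
}

#' Score regions for tRNA genes at the flanks
#'
#' Phages integrate preferentially at tRNA genes, so a tRNA inside a
#' candidate region or within `flank_distance` bp of either boundary is
#' evidence of an insertion event. Each qualifying tRNA is reported with its
#' signed distance to the nearest region boundary: 0 inside the region,
#' negative upstream of the start, positive downstream of the end.
#'
#' @param regions Regions tibble.
#' @param genome The `genome_record` (tRNA features are taken from it).
#' @param flank_distance Flank width in bp (default 2000).
#' @return `regions` with added columns `flanking_trnas` (list of tibbles
#'   `feature_id`, `distance`) and `trna_supported`.
#' @export
trna_evidence <- function(regions, genome, flank_distance = 2000) {
  stopifnot(flank_distance >= 0)
  trnas <- dplyr::filter(genome$features, .data$kind == "tRNA")
  res <- purrr::map2(regions$start, regions$end, function(rs, re) {
    if (nrow(trnas) == 0) {
      return(tibble::tibble(feature_id = character(), distance = integer()))
    }
    inside <- trnas$end >= rs & trnas$start <= re
    dist <- ifelse(inside, 0L,
                   ifelse(trnas$end < rs, -(rs - trnas$end), trnas$start - re))
    keep <- abs(dist) <= flank_distance
    tibble::tibble(feature_id = trnas$feature_id[keep],
                   distance = as.integer(dist[keep]))
  })
  regions$flanking_trnas <- res
  regions$trna_supported <- purrr::map_int(res, nrow) > 0
  regions
}
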