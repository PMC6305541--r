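#' Pipeline configuration
#'
#' Bundles and validates every tunable parameter of the scan pipeline.
#' Precedence when running: argument overrides > config file > these
#' defaults.
#'
#' @param min_identity Minimum percent alignment identity for a hit to count
#'   (default 80, the identity used for benchmarking).
#' @param max_evalue Hit e-value cutoff (default 1e-5).
#' @param best_hit_per_query Keep one best hit per CDS (default TRUE).
#' @param method Clustering algorithm (default `"hdbscan"`).
#' @param min_pts MinPts: minimum phage-homologous genes per region
#'   (default 4).
#' @param eps DBSCAN/OPTICS radius in bp (default 10000).
#' @param allow_single_cluster See [cluster_phage_genes()] (default TRUE).
#' @param gc_window Sliding-window width in bp (default 1000).
#' @param gc_step Sliding-window step in bp (default 100).
#' @param gc_gene_fraction Fraction of genes that must deviate in G+C
#'   (default 0.80).
#' @param flank_distance tRNA flank width in bp (default 2000).
#' @param conservation_threshold Conserved-region threshold (default 0.80).
#' @param match_rule Evaluation overlap rule (default `"any_overlap"`).
#' @param min_overlap_fraction Fraction for `match_rule = "min_fraction"`.
#' @param skip_evidence Skip the optional G+C/tRNA evidence stage
#'   (default FALSE).
#' @param phage_id_regex Optional override for phage-id extraction from
#'   subject ids (first capture group).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(min_identity = 80, max_evalue = 1e-5,
                            best_hit_per_query = TRUE,
                            method = "hdbscan", min_pts = 4, eps = 10000,
                            allow_single_cluster = TRUE,
                            gc_window = 1000, gc_step = 100,
                            gc_gene_fraction = 0.80, flank_distance = 2000,
                            conservation_threshold = 0.80,
                            match_rule = "any_overlap",
                            min_overlap_fraction = 0.5,
                            skip_evidence = FALSE, phage_id_regex = NULL) {
  cfg <- list(min_identity = as.numeric(min_identity),
              max_evalue = as.numeric(max_evalue),
              best_hit_per_query = as.logical(best_hit_per_query),
              method = method, min_pts = as.integer(min_pts),
              eps = as.numeric(eps),
              allow_single_cluster = as.logical(allow_single_cluster),
              gc_window = as.integer(gc_window),
              gc_step = as.integer(gc_step),
              gc_gene_fraction = as.numeric(gc_gene_fraction),
              flank_distance = as.numeric(flank_distance),
              conservation_threshold = as.numeric(conservation_threshold),
              match_rule = match_rule,
              min_overlap_fraction = as.numeric(min_overlap_fraction),
              skip_evidence = as.logical(skip_evidence),
              phage_id_regex = phage_id_regex)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  ok <- cfg$min_identity >= 0 && cfg$min_identity <= 100 &&
    cfg$max_evalue > 0 && cfg$min_pts >= 2 && cfg$eps > 0 &&
    cfg$method %in% c("hdbscan", "dbscan", "optics") &&
    cfg$gc_window >= 1 && cfg$gc_step >= 1 &&
    cfg$gc_gene_fraction >= 0 && cfg$gc_gene_fraction <= 1 &&
    cfg$flank_distance >= 0 &&
    cfg$conservation_threshold >= 0 && cfg$conservation_threshold <= 1 &&
    cfg$match_rule %in% c("any_overlap", "min_fraction") &&
    cfg$min_overlap_fraction > 0 && cfg$min_overlap_fraction <= 1 &&
    !is.na(cfg$best_hit_per_query) && !is.na(cfg$skip_evidence) &&
    !is.na(cfg$allow_single_cluster)
  if (!ok) {
    stop("invalid pipeline configuration: a parameter is outside its ",
         "documented range", call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path A flat `key = value` config file (`#` comments allowed; keys
#'   match the argument names of `pipeline_config()`).
#' @param base Config the file's entries override (default: the built-in
#'   defaults), so the precedence chain composes.
#' @export
read_config <- function(path, base = pipeline_config()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      stop("config parse error: expected key = value, got: ", ln,
           call. = FALSE)
    }
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(base)) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    overrides[[key]] <- val
  }
  update_config(base, overrides)
}

# Apply overrides (possibly character-typed, from a file or CLI) on top of a
# config, re-validating the result.
update_config <- function(cfg, overrides) {
  for (key in names(overrides)) {
    val <- overrides[[key]]
    template <- cfg[[key]]
    cfg[[key]] <- if (key == "phage_id_regex") as.character(val)
      else if (is.logical(template)) as.logical(toupper(as.character(val)))
      else if (is.integer(template)) as.integer(val)
      else if (is.numeric(template)) as.numeric(val)
      else as.character(val)
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Run the full prophage scan pipeline
#'
#' Executes the whole chain on one genome: read the annotation, ingest and
#' filter homology hits, cluster phage-homologous gene midpoints into
#' candidate regions, score G+C and tRNA evidence, call conservation, and
#' (optionally) write region outputs. Deterministic: identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param genome Path to a GenBank/EMBL file, or a `genome_record`.
#' @param hits Path to a 12-column hits table, or a hits tibble.
#' @param config A [pipeline_config()].
#' @param ... Named config overrides (highest precedence).
#' @param output_dir When given, region outputs are written here as
#'   `regions.tsv` and `regions.json`.
#' @return A `prophage_scan` object: `regions` (tibble with all evidence and
#'   conservation columns), `labeling`, `gc_stats`, `config`, stage `counts`
#'   and the run `log` (also emitted via `message()`).
#' @export
run_pipeline <- function(genome, hits, config = pipeline_config(), ...,
                         output_dir = NULL) {
  overrides <- list(...)
  if (length(overrides)) config <- update_config(config, overrides)
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }
  say("prophagescan pipeline (method=%s, min_identity=%g, min_pts=%d)",
      config$method, config$min_identity, config$min_pts)
  if (!is_genome_record(genome)) genome <- read_annotated_genome(genome)
  cds <- dplyr::filter(genome$features, .data$kind == "CDS")
  say("genome %s: %d bp, %d CDS, %d tRNA", genome$id, genome$length,
      nrow(cds), sum(genome$features$kind == "tRNA"))
  if (!is.data.frame(hits)) {
    hits <- parse_hits_table(hits, phage_id_regex = config$phage_id_regex)
  }
  say("hits table: %d raw hits", nrow(hits))
  kept <- filter_hits(hits, min_identity = config$min_identity,
                      max_evalue = config$max_evalue,
                      best_hit_per_query = config$best_hit_per_query)
  say("hits kept after filtering: %d (on %d distinct CDS)",
      nrow(kept), length(unique(kept$query_id)))
  phage_genes <- dplyr::semi_join(cds, kept, by = c(feature_id = "query_id"))
  labeling <- cluster_phage_genes(
    phage_genes, method = config$method, min_pts = config$min_pts,
    eps = config$eps, allow_single_cluster = config$allow_single_cluster)
  n_clusters <- length(unique(labeling$cluster[labeling$cluster >= 0]))
  say("clustering: %d clusters, %d noise genes", n_clusters,
      sum(labeling$cluster < 0))
  regions <- labeling_to_regions(labeling, phage_genes, genome)
  say("%d candidate regions", nrow(regions))
  stats <- NULL
  if (!config$skip_evidence) {
    stats <- windowed_gc_stats(genome, window_size = config$gc_window,
                               step = config$gc_step)
    say("G+C windows: %d, mean %.4f, sd %.4f",
        length(stats$window_values), stats$mean, stats$sd)
    regions <- gc_evidence(regions, genome, stats,
                           gene_fraction_threshold = config$gc_gene_fraction)
    regions <- trna_evidence(regions, genome,
                             flank_distance = config$flank_distance)
    if (nrow(regions)) {
      say("evidence: %d/%d regions G+C-supported, %d/%d tRNA-supported",
          sum(regions$gc_supported), nrow(regions),
          sum(regions$trna_supported), nrow(regions))
    }
  }
  regions <- conservation_call(regions, kept,
                               threshold = config$conservation_threshold)
  if (nrow(regions)) {
    say("conservation: %d/%d regions potentially conserved",
        sum(regions$conserved), nrow(regions))
  }
  result <- structure(list(
    genome_id = genome$id, genome_length = genome$length,
    config = config, regions = regions, labeling = labeling,
    gc_stats = stats,
    counts = c(n_cds = nrow(cds), n_hits_raw = nrow(hits),
               n_hits_kept = nrow(kept), n_phage_genes = nrow(phage_genes),
               n_clusters = n_clusters, n_regions = nrow(regions)),
    log = log), class = "prophage_scan")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_regions(regions, file.path(output_dir, "regions.tsv"), "tsv")
    write_regions(regions, file.path(output_dir, "regions.json"), "json")
  }
  result
}

#' @export
print.prophage_scan <- function(x, ...) {
  cat(sprintf("<prophage_scan> %s: %d candidate prophage region(s)\n",
              x$genome_id, nrow(x$regions)))
  if (nrow(x$regions)) {
    print(dplyr::select(x$regions, "region_id", "start", "end", "n_genes",
                        dplyr::any_of(c("gc_supported", "trna_supported",
                                        "conserved", "best_phage",
                                        "phage_fraction"))))
  }
  invisible(x)
}

#' Tidy and summarise a pipeline run
#'
#' `tidy()` returns the regions tibble; `glance()` a one-row tibble of stage
#' counts.
#'
#' @param x A `prophage_scan` from [run_pipeline()].
#' @param ... Unused.
#' @method tidy prophage_scan
#' @export
tidy.prophage_scan <- function(x, ...) x$regions

#' @rdname tidy.prophage_scan
#' @method glance prophage_scan
#' @export
glance.prophage_scan <- function(x, ...) {
  tibble::as_tibble(as.list(x$counts)) |>
    dplyr::mutate(genome_id = x$genome_id,
                  genome_length = x$genome_length, .before = 1)
}

#' Plot a prophage scan
#'
#' Draws the sliding-window G+C profile with the genome mean +/- 1 SD band
#' and shades the candidate regions (G+C-supported regions darker); tick
#' marks along the base show the clustered phage-homologous genes.
#'
#' @param object A `prophage_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prophage_scan
#' @export
autoplot.prophage_scan <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(object$gc_stats)) {
    wins <- tibble::tibble(pos = object$gc_stats$starts +
                             object$gc_stats$window_size / 2,
                           gc = object$gc_stats$window_values)
    p <- p +
      ggplot2::geom_hline(yintercept = object$gc_stats$mean,
                          linetype = "dashed", colour = "grey40") +
      ggplot2::geom_hline(yintercept = object$gc_stats$mean +
                            c(-1, 1) * object$gc_stats$sd,
                          linetype = "dotted", colour = "grey60") +
      ggplot2::geom_line(data = wins,
                         ggplot2::aes(x = .data$pos, y = .data$gc),
                         linewidth = 0.3)
  }
  if (nrow(object$regions)) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf,
                   alpha = ifelse(isTRUE(.data$gc_supported), 0.35, 0.18)),
      fill = "firebrick", inherit.aes = FALSE) +
      ggplot2::scale_alpha_identity()
  }
  if (nrow(object$labeling)) {
    p <- p + ggplot2::geom_rug(
      data = object$labeling,
      ggplot2::aes(x = .data$midpoint), sides = "b")
  }
  p + ggplot2::labs(x = sprintf("position on %s (bp)", object$genome_id),
                    y = "window G+C fraction",
                    title = "Candidate prophage regions") +
    ggplot2::theme_minimal()
}

#' Plot a cluster labeling
#'
#' Gene midpoints along the genome coloured by cluster (noise in grey).
#'
#' @param object A `cluster_labeling` from [cluster_phage_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_labeling
#' @export
autoplot.cluster_labeling <- function(object, ...) {
  df <- dplyr::mutate(object,
                      cluster_f = factor(ifelse(.data$cluster < 0, "noise",
                                                as.character(.data$cluster))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = 0,
                                   colour = .data$cluster_f)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 1.5) +
    ggplot2::scale_colour_viridis_d(option = "turbo", end = 0.9) +
    ggplot2::labs(x = "gene midpoint (bp)", colour = "cluster", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
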