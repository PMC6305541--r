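#' Call conservation of candidate regions
#'
#' Classifies each region as "potentially conserved" or "not conserved" from
#' the composition of its genes' best-hit source phages: with best-per-query
#' hits, each member gene counts toward the phage its best hit derives from;
#' genes with no surviving hit stay in the denominator. A region is conserved
#' when the largest per-phage fraction reaches `threshold` (default 0.80,
#' boundary inclusive — "80% or more"). Ties for the best phage are broken by
#' the lexicographically smallest phage id; all tied phages remain visible in
#' `per_phage_counts`.
#'
#' @param regions Regions tibble with a `genes` list-column.
#' @param hits Filtered, best-hit-per-query hits tibble (see [filter_hits()]).
#' @param threshold Conservation threshold in \[0, 1\] (default 0.80).
#' @return `regions` with added columns `per_phage_counts` (named integer
#'   list), `best_phage`, `phage_fraction` and `conserved`.
#' @export
conservation_call <- function(regions, hits, threshold = 0.80) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (nrow(regions) > 0 && any(regions$n_genes == 0)) {
    stop("cannot call conservation for a region with no member genes",
         call. = FALSE)
  }
  if (nrow(hits) > 0 && anyDuplicated(hits$query_id)) {
    stop("conservation_call expects one best hit per query; run filter_hits ",
         "with best_hit_per_query = TRUE", call. = FALSE)
  }
  phage_of <- stats::setNames(hits$phage_id, hits$query_id)
  res <- purrr::map(regions$genes, function(g) {
    ph <- unname(phage_of[g$feature_id])
    ph <- ph[!is.na(ph)]
    counts <- if (length(ph)) {
      tab <- table(ph)
      stats::setNames(as.integer(tab), names(tab))[order(names(tab))]
    } else {
      stats::setNames(integer(0), character(0))
    }
    if (length(counts)) {
      best <- names(counts)[counts == max(counts)]
      best <- sort(best)[1]
      frac <- max(counts) / nrow(g)
    } else {
      best <- NA_character_
      frac <- 0
    }
    list(counts = counts, best = best, frac = frac)
  })
  regions$per_phage_counts <- purrr::map(res, "counts")
  regions$best_phage <- purrr::map_chr(res, "best")
  regions$phage_fraction <- purrr::map_dbl(res, "frac")
  regions$conserved <- regions$phage_fraction >= threshold
  regions
}
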