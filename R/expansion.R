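# Expansion/contraction statistics over concordant clones: each C1 clone
# contributes a syntenic region comparing its insert size (the query-side
# extent) with its placement's outer span on the reference. Regions are
# aggregated per chromosome and direction, and the total expansion percent
# is the grand-total ratio.

#' Build syntenic regions from concordant calls
#'
#' One region per C1 (concordant) call: `query_bp` is the clone's insert
#' size, `ref_bp` the placement outer span, `delta_bp` their difference.
#' Regions with `delta_bp > 0` are expanded; ties count as contracted, so
#' "expanded" strictly means larger. Non-C1 calls are ignored.
#'
#' @param calls data.frame from [classify_library()].
#' @param insert_sizes named numeric vector of insert sizes by clone id.
#' @return data.frame clone_id, chrom, query_bp, ref_bp, delta_bp,
#'   direction.
#' @export
build_regions <- function(calls, insert_sizes) {
  c1 <- calls[calls$class_label == "C1", , drop = FALSE]
  if (nrow(c1) == 0L) {
    return(data.frame(clone_id = character(0), chrom = character(0),
                      query_bp = numeric(0), ref_bp = numeric(0),
                      delta_bp = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(c1$clone_id, names(insert_sizes))
  if (length(missing)) {
    stopf("no insert size for concordant clone %s", missing[1])
  }
  query_bp <- as.numeric(insert_sizes[c1$clone_id])
  ref_bp <- as.numeric(c1$span)
  delta <- ref_bp - query_bp
  data.frame(clone_id = c1$clone_id, chrom = c1$chrom,
             query_bp = query_bp, ref_bp = ref_bp, delta_bp = delta,
             direction = ifelse(delta > 0, "expanded", "contracted"),
             stringsAsFactors = FALSE)
}

#' Aggregate syntenic regions by chromosome and direction
#'
#' @param regions data.frame from [build_regions()] (or an equivalent
#'   table with chrom, query_bp, ref_bp, delta_bp, direction).
#' @return list with `by_chromosome` (n_regions and bp sums per chrom x
#'   direction) and `grand_totals` (n_regions, sum_query_bp, sum_ref_bp,
#'   sum_delta_bp over all regions regardless of direction).
#' @export
aggregate_by_chromosome <- function(regions) {
  if (nrow(regions) == 0L) {
    by_chrom <- data.frame(chrom = character(0), direction = character(0),
                           n_regions = integer(0), sum_query_bp = numeric(0),
                           sum_ref_bp = numeric(0), sum_delta_bp = numeric(0),
                           stringsAsFactors = FALSE)
    return(list(by_chromosome = by_chrom,
                grand_totals = c(n_regions = 0, sum_query_bp = 0,
                                 sum_ref_bp = 0, sum_delta_bp = 0)))
  }
  agg <- aggregate(cbind(query_bp, ref_bp, delta_bp) ~ chrom + direction,
                   data = regions, FUN = sum)
  cnt <- aggregate(clone_id ~ chrom + direction, data = regions, FUN = length)
  by_chrom <- merge(cnt, agg, by = c("chrom", "direction"))
  names(by_chrom) <- c("chrom", "direction", "n_regions", "sum_query_bp",
                       "sum_ref_bp", "sum_delta_bp")
  by_chrom <- by_chrom[order(by_chrom$chrom, by_chrom$direction), ]
  rownames(by_chrom) <- NULL
  list(by_chromosome = by_chrom,
       grand_totals = c(n_regions = nrow(regions),
                        sum_query_bp = sum(regions$query_bp),
                        sum_ref_bp = sum(regions$ref_bp),
                        sum_delta_bp = sum(regions$delta_bp)))
}

#' Total expansion percent
#'
#' The reference-over-query grand-total ratio, as a percent difference:
#' 100 * (sum_ref_bp - sum_query_bp) / sum_query_bp, reported to two
#' decimals. Alternative conventions ("per_region_mean": mean of
#' per-region percent differences; "reference_denominator": difference
#' over the reference sum) are available since the choice is a convention,
#' not forced by the data.
#'
#' @param grand_totals named vector from [aggregate_by_chromosome()], or a
#'   regions data.frame when `method = "per_region_mean"`.
#' @param method one of "total_ratio", "per_region_mean",
#'   "reference_denominator".
#' @return expansion percent (positive = reference larger), two decimals.
#' @export
total_expansion_percent <- function(grand_totals, method = "total_ratio") {
  if (method == "per_region_mean") {
    regions <- grand_totals
    if (!is.data.frame(regions)) {
      stopf("per_region_mean needs the regions data.frame")
    }
    if (any(regions$query_bp <= 0)) stopf("region with non-positive query bp")
    return(round(mean(100 * regions$delta_bp / regions$query_bp), 2))
  }
  q <- grand_totals[["sum_query_bp"]]; r <- grand_totals[["sum_ref_bp"]]
  denom <- if (method == "reference_denominator") r else q
  if (denom <= 0) stopf("zero denominator in expansion percent")
  round(100 * (r - q) / denom, 2)
}

#' Library fold-coverage estimate
#'
#' Total cloned bases over the (monoploid) genome size:
#' n_clones * mean_insert_bp / genome_size_bp.
#'
#' @param n_clones number of clones in the library.
#' @param mean_insert_bp mean insert size in bp.
#' @param genome_size_bp genome size in bp.
#' @return fold coverage (real).
#' @export
coverage_estimate <- function(n_clones, mean_insert_bp, genome_size_bp) {
  if (n_clones <= 0 || mean_insert_bp <= 0 || genome_size_bp <= 0) {
    stopf("coverage_estimate needs positive inputs")
  }
  n_clones * mean_insert_bp / genome_size_bp
}

#' Contamination rate as a percent of clones
#'
#' @param n_contaminated number of contaminated clones.
#' @param n_clones total clones (> 0).
#' @return percent, rounded to one decimal.
#' @export
contamination_rate <- function(n_contaminated, n_clones) {
  if (n_clones <= 0) stopf("n_clones must be positive")
  if (n_contaminated < 0 || n_contaminated > n_clones) {
    stopf("n_contaminated must lie in [0, n_clones]")
  }
  round(100 * n_contaminated / n_clones, 1)
}
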