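#' Find all intersecting (query, reference) interval pairs
#'
#' A pair is reported iff the two intervals share at least 1 bp; book-ended
#' intervals (end == next start) do not intersect under the half-open
#' convention. Pairs are ordered by chromosome (layout order), then query
#' start, then reference start. Indices are row numbers into the sorted
#' sets' data frames.
#'
#' @param query,reference [interval_set()]s sharing one layout.
#' @return a data.frame with columns `query` and `reference` (1-based
#'   indices into the respective sorted sets).
#' @export
find_overlap_pairs <- function(query, reference) {
  .check_shared_layout(query, reference)
  qf <- .flatten(query)
  rf <- .flatten(reference)
  nr <- length(rf$start)
  if (length(qf$start) == 0 || nr == 0)
    return(data.frame(query = integer(0), reference = integer(0)))
  o <- order(rf$start, rf$end)
  rs <- rf$start[o]
  re_cummax <- cummax(rf$end[o])
  # candidates for query q: refs (in start order) with index in (lo, hi];
  # lo = last ref whose running-max end is still <= q.start (prefix of
  # non-reachers), hi = last ref starting before q.end.
  lo <- findInterval(qf$start, re_cummax)
  hi <- findInterval(qf$end - 0.5, rs)
  nper <- pmax(0L, hi - lo)
  if (sum(nper) == 0)
    return(data.frame(query = integer(0), reference = integer(0)))
  j <- sequence(nper) + rep(lo, nper)
  qi <- rep(seq_along(qf$start), nper)
  hit <- rf$end[o][j] > qf$start[qi]   # starts already < q.end by hi bound
  qi <- qi[hit]
  ri <- o[j[hit]]
  ord <- order(qi, reference$df$start[ri], ri)
  data.frame(query = qi[ord], reference = ri[ord])
}

#' Common sections of two interval sets
#'
#' The maximal intervals of the base-pair intersection of the two sets'
#' merged coverages. A long region spanning k disjoint regions of the other
#' set yields k sections; conversely several overlapping query regions over
#' one reference region collapse into a single section.
#'
#' @param query,reference [interval_set()]s sharing one layout.
#' @return an [interval_set()] of disjoint sections (symmetric in its
#'   arguments).
#' @export
common_sections <- function(query, reference) {
  .check_shared_layout(query, reference)
  a <- .merged(query)
  b <- .merged(reference)
  sec <- .isect_intervals_flat(a, b)
  loc <- .unflatten(sec$start, sec$end, query$layout)
  interval_set(loc$chrom, loc$start, loc$end, query$layout)
}

#' Venn-style overlap summary of two interval sets
#'
#' @param query,reference [interval_set()]s sharing one layout.
#' @return an object of class `overlap_summary`: `n_query`, `n_reference`,
#'   `n_query_overlapped`, `n_reference_overlapped`, `n_sections`,
#'   `query_overlap_fraction` (rounded to 3 decimals).
#' @export
venn_counts <- function(query, reference) {
  .check_shared_layout(query, reference)
  nq <- n_intervals(query)
  nr <- n_intervals(reference)
  if (nq == 0 || nr == 0) {
    res <- list(n_query = nq, n_reference = nr, n_query_overlapped = 0L,
                n_reference_overlapped = 0L, n_sections = 0L,
                query_overlap_fraction = 0)
    return(structure(res, class = "overlap_summary"))
  }
  pairs <- find_overlap_pairs(query, reference)
  secs <- common_sections(query, reference)
  structure(list(
    n_query = nq, n_reference = nr,
    n_query_overlapped = length(unique(pairs$query)),
    n_reference_overlapped = length(unique(pairs$reference)),
    n_sections = n_intervals(secs),
    query_overlap_fraction =
      round(length(unique(pairs$query)) / nq, 3)),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary>\n",
      "  query regions:           ", x$n_query, "\n",
      "  reference regions:       ", x$n_reference, "\n",
      "  query overlapped:        ", x$n_query_overlapped,
      " (", format(x$query_overlap_fraction * 100), "%)\n",
      "  reference overlapped:    ", x$n_reference_overlapped, "\n",
      "  common sections:         ", x$n_sections, "\n", sep = "")
  invisible(x)
}

#' Gap distance from each query region to its nearest reference region
#'
#' Edge-to-edge bp separation on the same chromosome: 0 when the intervals
#' share a bp (and for the measure-zero book-ended case, where the edge
#' distance is 0 although no bp is shared), `NA` when the query's chromosome
#' carries no reference region.
#'
#' @param query,reference [interval_set()]s sharing one layout.
#' @return a data.frame with one row per query region (in sorted order):
#'   `chrom`, `start`, `end`, `gap`.
#' @export
gap_distances <- function(query, reference) {
  .check_shared_layout(query, reference)
  qd <- query$df
  rd <- reference$df
  gaps <- .nearest_gaps(qd$chrom, qd$start, qd$end,
                        rd$chrom, rd$start, rd$end)
  data.frame(chrom = qd$chrom, start = qd$start, end = qd$end, gap = gaps)
}
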