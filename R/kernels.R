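# Internal vectorized interval kernels on flattened coordinates.
#
# Flattening maps every chromosome onto one numeric axis with a 1-bp guard
# base between chromosomes (see .layout_offsets), so coverage operations
# (merge, intersection, union bp, point-in-coverage) are single-axis sweeps.
# Nearest-neighbour operations are never computed across the guard; callers
# that need per-chromosome semantics (gaps, relative distances, placement
# nulls) group by chromosome explicitly.

.flatten <- function(x) {
  off <- .layout_offsets(x$layout)
  list(start = x$df$start + off[x$df$chrom],
       end = x$df$end + off[x$df$chrom])
}

.unflatten <- function(gstart, gend, layout) {
  off <- .layout_offsets(layout)
  i <- findInterval(gstart, unname(off))
  list(chrom = names(layout)[i],
       start = gstart - unname(off)[i],
       end = gend - unname(off)[i])
}

# Merge possibly-overlapping intervals; book-ended (gap 0) intervals are
# joined. Returns disjoint sorted intervals with pairwise gaps >= 1.
.merge_flat <- function(start, end) {
  n <- length(start)
  if (n == 0) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  s <- start[o]
  e <- cummax(end[o])
  new_grp <- c(TRUE, s[-1] > e[-n])
  list(start = s[new_grp], end = e[c(new_grp[-1], TRUE)])
}

# Covered-bp-up-to-x function for a merged set b: F(x) = bp of b in (-Inf, x].
.cov_bp_upto <- function(b, x) {
  if (length(b$start) == 0) return(numeric(length(x)))
  cl <- cumsum(b$end - b$start)
  i <- findInterval(x, b$start)
  res <- numeric(length(x))
  hit <- i > 0
  ih <- i[hit]
  res[hit] <- cl[ih] - pmax(0, b$end[ih] - x[hit])
  res
}

# Total intersection bp between two merged sets.
.isect_bp_flat <- function(a, b) {
  if (length(a$start) == 0 || length(b$start) == 0) return(0)
  sum(.cov_bp_upto(b, a$end) - .cov_bp_upto(b, a$start))
}

# Explicit intersection intervals between two merged (disjoint, sorted) sets.
.isect_intervals_flat <- function(a, b) {
  if (length(a$start) == 0 || length(b$start) == 0)
    return(list(start = numeric(0), end = numeric(0)))
  lo <- findInterval(a$start, b$end) + 1   # first b with b.end > a.start
  hi <- findInterval(a$end - 0.5, b$start) # last b with b.start < a.end
  nper <- pmax(0L, hi - lo + 1L)
  if (sum(nper) == 0) return(list(start = numeric(0), end = numeric(0)))
  j <- sequence(nper) + rep(lo - 1L, nper)
  ai <- rep(seq_along(a$start), nper)
  list(start = pmax(a$start[ai], b$start[j]),
       end = pmin(a$end[ai], b$end[j]))
}

# Per-query count of reference intervals sharing >= 1 bp, for arbitrary
# (possibly self-overlapping) references. Identity: #{r : r.start < q.end}
# - #{r : r.end <= q.start}; the subtracted set is a subset of the first.
.pair_counts_flat <- function(qs, qe, ref_starts_sorted, ref_ends_sorted) {
  findInterval(qe - 0.5, ref_starts_sorted) -
    findInterval(qs, ref_ends_sorted)
}

# Edge-to-edge gap from each query interval to its nearest reference
# interval, per chromosome. 0 when they share a bp (also for book-ended
# neighbours, where the edge distance is 0); NA when the query's chromosome
# carries no reference interval. Inputs are local (unflattened) coordinates.
.nearest_gaps <- function(q_chrom, q_start, q_end, r_chrom, r_start, r_end) {
  out <- rep(NA_real_, length(q_start))
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    ri <- which(r_chrom == ch)
    if (length(ri) == 0) next
    es <- sort(r_end[ri])       # for nearest left edge
    ss <- sort(r_start[ri])     # for nearest right edge
    li <- findInterval(q_start[qi], es)
    left <- ifelse(li > 0, q_start[qi] - es[pmax(li, 1)], Inf)
    pos <- findInterval(q_end[qi] - 0.5, ss)
    right <- ifelse(pos < length(ss),
                    ss[pmin(pos + 1, length(ss))] - q_end[qi], Inf)
    cnt <- .pair_counts_flat(q_start[qi], q_end[qi], ss, es)
    g <- pmax(0, pmin(left, right))
    g[cnt > 0] <- 0
    out[qi] <- g
  }
  out
}

# Midpoint (floor((start+end)/2)) of intervals.
.midpoints <- function(start, end) floor((start + end) / 2)

# For each point x, TRUE if x lies inside the merged coverage b
# (half-open: b.start <= x < b.end).
.point_in_cov <- function(b, x) {
  if (length(b$start) == 0) return(rep(FALSE, length(x)))
  i <- findInterval(x, b$start)
  i > 0 & x < b$end[pmax(i, 1)]
}

# bp of the pairwise-clipped intersection of one interval list with a
# merged set, summed. a need not be merged; it is merged first.
.merged <- function(x) {
  f <- .flatten(x)
  .merge_flat(f$start, f$end)
}

# Run code with a private RNG state seeded by `seed`, restoring the caller's
# stream afterwards. seed = NULL runs on the ambient stream.
.with_seed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  fun()
}
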