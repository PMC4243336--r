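# Fixtures and independent quadratic / enumeration oracles. Oracles are
# deliberately naive (all-pairs scans, per-base coverage vectors, exhaustive
# placement enumeration) and never share code with the package kernels.

toy_layout <- function(lengths = c(chrA = 1e6, chrB = 1e6)) {
  genome_layout(lengths)
}

random_set <- function(n, layout, min_len = 1, max_len = 200) {
  chrom <- sample(names(layout), n, replace = TRUE)
  cap <- pmin(max_len, unclass(layout)[chrom] - 1)   # fit the chromosome
  len <- min_len + floor(runif(n) * (cap - min_len + 1))
  start <- floor(runif(n) * (unclass(layout)[chrom] - len))
  interval_set(chrom, start, start + len, layout)
}

# all-pairs intersection oracle: >=1 shared bp under half-open coords.
# Quadratic by construction (every pair is tested), vectorized via outer.
oracle_pairs <- function(query, reference) {
  qd <- as.data.frame(query)
  rd <- as.data.frame(reference)
  hit <- outer(qd$chrom, rd$chrom, "==") &
    outer(qd$start, rd$end, "<") & outer(qd$end, rd$start, ">")
  idx <- which(hit, arr.ind = TRUE)
  df <- data.frame(query = idx[, 1], reference = idx[, 2])
  df[order(df$query, rd$start[df$reference], df$reference), , drop = FALSE]
}

# per-base coverage oracle for sections / jaccard on small toy genomes
oracle_coverage <- function(set, layout) {
  cov <- lapply(unclass(layout), function(l) logical(l))
  df <- as.data.frame(set)
  for (i in seq_len(nrow(df)))
    cov[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- TRUE
  cov
}

oracle_sections <- function(query, reference, layout) {
  cq <- oracle_coverage(query, layout)
  cr <- oracle_coverage(reference, layout)
  out <- list()
  k <- 0
  for (ch in names(layout)) {
    both <- cq[[ch]] & cr[[ch]]
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    for (i in which(r$values)) {
      k <- k + 1
      out[[k]] <- data.frame(chrom = ch, start = starts[i], end = ends[i])
    }
  }
  if (k == 0) return(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0)))
  do.call(rbind, out)
}

# nearest edge-to-edge gap oracle: all pairs per query via pmax
oracle_gaps <- function(query, reference) {
  qd <- as.data.frame(query)
  rd <- as.data.frame(reference)
  vapply(seq_len(nrow(qd)), function(i) {
    j <- which(rd$chrom == qd$chrom[i])
    if (length(j) == 0) return(NA_real_)
    min(pmax(0, rd$start[j] - qd$end[i], qd$start[i] - rd$end[j]))
  }, numeric(1))
}

# exhaustive placement-enumeration oracle for the proximity p-value.
# Enumerates every integer start on every domain chromosome.
oracle_region_pvalue <- function(q_chrom, q_start, q_end, reference, domain,
                                 layout) {
  rd <- as.data.frame(reference$set %||% reference)
  dd <- as.data.frame(domain$set)
  # reference restricted to midpoint-in-domain, mirroring the contract
  rmid <- floor((rd$start + rd$end) / 2)
  in_dom <- vapply(seq_len(nrow(rd)), function(i)
    any(dd$chrom == rd$chrom[i] & dd$start <= rmid[i] & rmid[i] < dd$end),
    logical(1))
  rd <- rd[in_dom, , drop = FALSE]
  L <- q_end - q_start
  h <- floor(L / 2)
  gap_to_ref <- function(ch, s, e) {
    # s, e vectors of candidate placements on chromosome ch
    j <- which(rd$chrom == ch)
    if (length(j) == 0) return(rep(Inf, length(s)))
    g <- rep(Inf, length(s))
    for (r in j) g <- pmin(g, pmax(0, rd$start[r] - e, s - rd$end[r]))
    g
  }
  d_obs <- gap_to_ref(q_chrom, q_start, q_end)
  if (!is.finite(d_obs)) return(1)
  num <- 0
  den <- 0
  for (ch in unique(dd$chrom)) {
    clen <- unclass(layout)[[ch]]
    if (clen < L) next
    dch <- dd[dd$chrom == ch, , drop = FALSE]
    s <- 0:(clen - L)                 # every integer placement, exhaustively
    mid <- s + h
    in_dom <- rep(FALSE, length(s))
    for (r in seq_len(nrow(dch)))
      in_dom <- in_dom | (dch$start[r] <= mid & mid < dch$end[r])
    s <- s[in_dom]
    if (length(s) == 0) next
    den <- den + length(s)
    num <- num + sum(gap_to_ref(ch, s, s + L) <= d_obs)
  }
  num / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small null-scenario generator used across calibration tests
null_sim <- function(n = 500, seed = 1) {
  simulate_pair(scenario_config(n_reference = n, n_query = n,
                                scenario = "null", seed = seed))
}
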