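# Whole-cistrome spatial correlation tests. All permutation tests share one
# null model: every query region is independently re-placed uniformly on its
# own chromosome with its length preserved (self-overlap allowed, reference
# fixed), and p-values use the plus-one estimator
# p = (1 + #{null >= observed}) / (1 + n_perm), never reaching 0.

.spatial_result <- function(test_name, observed, p, direction, n_perm = 0L,
                            seed = NA_integer_, null_mean = NA_real_,
                            null_sd = NA_real_, extra = list()) {
  structure(c(list(test_name = test_name, observed_statistic = observed,
                   p_value = p, direction = direction,
                   n_permutations = n_perm, seed = seed,
                   null_mean = null_mean, null_sd = null_sd), extra),
            class = "spatial_test_result")
}

#' @export
print.spatial_test_result <- function(x, ...) {
  cat("<", x$test_name, "> statistic = ", signif(x$observed_statistic, 4),
      ", p = ", signif(x$p_value, 4), " (", x$direction, ")",
      if (x$n_permutations > 0)
        paste0(", ", x$n_permutations, " permutations"),
      "\n", sep = "")
  invisible(x)
}

#' Shuffle an interval set under the placement null
#'
#' Each region is independently re-placed uniformly at random on its own
#' chromosome (start uniform over `[0, chrom_len - L]`); region lengths and
#' chromosome assignments are preserved and shuffled regions may overlap
#' each other. Deterministic given `seed`.
#'
#' @param x an [interval_set()]; every region must be no longer than its
#'   chromosome.
#' @param seed integer seed, or `NULL` to use the ambient RNG stream.
#' @return a shuffled [interval_set()].
#' @export
shuffle_intervals <- function(x, seed = NULL) {
  stopifnot(inherits(x, "interval_set"))
  .with_seed(seed, function() {
    df <- x$df
    L <- df$end - df$start
    clen <- unclass(x$layout)[df$chrom]
    if (any(L > clen)) stop("region longer than its chromosome")
    ns <- floor(stats::runif(nrow(df)) * (clen - L + 1))
    interval_set(df$chrom, ns, ns + L, x$layout, name = df$name,
                 score = df$score, summit_offset = df$summit_offset,
                 strand = df$strand)
  })
}

# Fast internal shuffle on flattened coordinates: returns global starts.
# chrom_lo = chromosome offset per region, room = clen - L + 1.
.shuffle_starts <- function(chrom_lo, room) {
  chrom_lo + floor(stats::runif(length(room)) * room)
}

# Shared precomputation for the permutation loop.
.perm_setup <- function(query, reference) {
  off <- .layout_offsets(query$layout)
  clen <- unclass(query$layout)
  qd <- query$df
  L <- qd$end - qd$start
  list(off = off,
       q_lo = unname(off[qd$chrom]), q_len = L,
       room = unname(clen[qd$chrom]) - L + 1,
       rf = .flatten(reference))
}

#' Monte Carlo interval-count overlap test
#'
#' Observed statistic: the number of intersecting (query, reference) pairs.
#' The null re-places the query set (reference fixed) `n_perm` times and
#' recounts; the attraction-sided p-value is the plus-one fraction of null
#' counts at or above the observed count.
#'
#' @param query,reference non-empty [interval_set()]s sharing one layout.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return a `spatial_test_result`.
#' @export
bits_mc_test <- function(query, reference, n_perm = 10000, seed = NULL) {
  .check_shared_layout(query, reference)
  stopifnot(n_perm >= 1)
  if (n_intervals(query) == 0 || n_intervals(reference) == 0)
    stop("both interval sets must be non-empty")
  su <- .perm_setup(query, reference)
  rs <- sort(su$rf$start)
  re <- sort(su$rf$end)
  qf <- .flatten(query)
  obs <- sum(.pair_counts_flat(qf$start, qf$end, rs, re))
  null <- .with_seed(seed, function() {
    vapply(seq_len(n_perm), function(i) {
      s <- .shuffle_starts(su$q_lo, su$room)
      sum(.pair_counts_flat(s, s + su$q_len, rs, re))
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  .spatial_result("interval_count_mc", obs, p, "attraction", n_perm,
                  if (is.null(seed)) NA_integer_ else seed,
                  mean(null), stats::sd(null))
}

#' Relative distance test (Kolmogorov-Smirnov)
#'
#' For each query midpoint with a reference midpoint on both sides on its
#' chromosome, the relative distance is
#' `r = min(d_left, d_right) / (d_left + d_right)` in `[0, 0.5]`; under
#' independence r is Uniform(0, 0.5). The statistic is the one-sample KS
#' distance of the r sample against that uniform, with the asymptotic KS
#' p-value (two-sided). Direction is attraction when mean(r) < 0.25.
#' Edge midpoints without both flanks are dropped (count reported); a
#' small-sample flag is raised below n = 35 where the asymptotic p is
#' approximate.
#'
#' @param query,reference [interval_set()]s sharing one layout.
#' @param min_eligible minimum eligible query midpoints (default 10).
#' @return a `spatial_test_result` with extras `n_eligible`, `n_dropped`,
#'   `mean_relative_distance`, `small_sample`.
#' @export
relative_distance_test <- function(query, reference, min_eligible = 10) {
  .check_shared_layout(query, reference)
  qd <- query$df
  rd <- reference$df
  qm <- .midpoints(qd$start, qd$end)
  rm_ <- .midpoints(rd$start, rd$end)
  r <- rep(NA_real_, length(qm))
  for (ch in unique(qd$chrom)) {
    qi <- which(qd$chrom == ch)
    refm <- sort(rm_[rd$chrom == ch])
    if (length(refm) < 2) next
    i <- findInterval(qm[qi], refm)
    ok <- i >= 1 & i < length(refm)
    dl <- qm[qi][ok] - refm[i[ok]]
    dr <- refm[i[ok] + 1] - qm[qi][ok]
    rv <- ifelse(dl + dr == 0, 0, pmin(dl, dr) / (dl + dr))
    r[qi[ok]] <- rv
  }
  n_drop <- sum(is.na(r))
  r <- r[!is.na(r)]
  if (length(r) < min_eligible)
    stop("only ", length(r), " eligible query midpoints (need ",
         min_eligible, ")")
  ks <- suppressWarnings(stats::ks.test(r, stats::punif, min = 0, max = 0.5,
                                        exact = FALSE))
  .spatial_result("relative_distance_ks", unname(ks$statistic),
                  max(ks$p.value, .Machine$double.xmin),
                  if (mean(r) < 0.25) "attraction" else "repulsion",
                  extra = list(n_eligible = length(r), n_dropped = n_drop,
                               mean_relative_distance = mean(r),
                               small_sample = length(r) < 35,
                               relative_distances = r))
}

#' Absolute distance permutation test
#'
#' Observed statistic: the mean over query midpoints of the distance to the
#' nearest reference midpoint on the same chromosome. Query regions on
#' chromosomes without a reference region are dropped with a warning. The
#' null re-places the query set; the attraction-sided p-value is the
#' plus-one fraction of null means at or below the observed mean.
#'
#' @param query,reference [interval_set()]s sharing one layout.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return a `spatial_test_result`.
#' @export
absolute_distance_test <- function(query, reference, n_perm = 10000,
                                   seed = NULL) {
  .check_shared_layout(query, reference)
  stopifnot(n_perm >= 1)
  qd <- query$df
  rd <- reference$df
  shared <- intersect(unique(qd$chrom), unique(rd$chrom))
  if (length(shared) == 0)
    stop("no chromosome shared between query and reference")
  drop <- !(qd$chrom %in% shared)
  if (any(drop)) {
    warning("dropping ", sum(drop),
            " query region(s) on chromosomes without reference regions")
    qd <- qd[!drop, , drop = FALSE]
  }
  off <- .layout_offsets(query$layout)
  clen <- unclass(query$layout)
  # reference midpoints flattened; chromosome grouping preserved by offsets,
  # nearest search done per chromosome through sorted local midpoints
  refm_by <- lapply(stats::setNames(shared, shared), function(ch)
    sort(.midpoints(rd$start[rd$chrom == ch], rd$end[rd$chrom == ch])))
  nearest_mean <- function(chrom, mids) {
    tot <- 0
    for (ch in shared) {
      qi <- which(chrom == ch)
      if (length(qi) == 0) next
      refm <- refm_by[[ch]]
      i <- findInterval(mids[qi], refm)
      left <- ifelse(i >= 1, mids[qi] - refm[pmax(i, 1)], Inf)
      right <- ifelse(i < length(refm), refm[pmin(i + 1, length(refm))] -
                        mids[qi], Inf)
      tot <- tot + sum(pmin(left, right))
    }
    tot / length(mids)
  }
  qmid <- .midpoints(qd$start, qd$end)
  obs <- nearest_mean(qd$chrom, qmid)
  L <- qd$end - qd$start
  room <- unname(clen[qd$chrom]) - L + 1
  h <- floor(L / 2)
  null <- .with_seed(seed, function() {
    vapply(seq_len(n_perm), function(i) {
      s <- floor(stats::runif(length(room)) * room)
      nearest_mean(qd$chrom, s + h)
    }, numeric(1))
  })
  p <- (1 + sum(null <= obs)) / (1 + n_perm)
  .spatial_result("absolute_distance_perm", obs, p, "attraction", n_perm,
                  if (is.null(seed)) NA_integer_ else seed,
                  mean(null), stats::sd(null))
}

#' Jaccard statistic of two coverages
#'
#' Intersection bp of the merged coverages divided by their union bp.
#'
#' @param query,reference [interval_set()]s sharing one layout, not both
#'   empty.
#' @return a number in `[0, 1]`, symmetric in its arguments.
#' @export
jaccard_statistic <- function(query, reference) {
  .check_shared_layout(query, reference)
  a <- .merged(query)
  b <- .merged(reference)
  ta <- sum(a$end - a$start)
  tb <- sum(b$end - b$start)
  if (ta + tb == 0) stop("Jaccard statistic of two empty sets is undefined")
  isect <- .isect_bp_flat(a, b)
  isect / (ta + tb - isect)
}

#' Jaccard permutation test
#'
#' Observed statistic: [jaccard_statistic()]. The null re-places the query
#' set (the test is asymmetric even though the statistic is symmetric);
#' attraction-sided plus-one p-value on null Jaccard >= observed.
#'
#' @param query,reference non-empty [interval_set()]s sharing one layout.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return a `spatial_test_result`.
#' @export
jaccard_test <- function(query, reference, n_perm = 10000, seed = NULL) {
  .check_shared_layout(query, reference)
  stopifnot(n_perm >= 1)
  obs <- jaccard_statistic(query, reference)
  su <- .perm_setup(query, reference)
  b <- .merge_flat(su$rf$start, su$rf$end)
  tb <- sum(b$end - b$start)
  null <- .with_seed(seed, function() {
    vapply(seq_len(n_perm), function(i) {
      s <- .shuffle_starts(su$q_lo, su$room)
      a <- .merge_flat(s, s + su$q_len)
      ta <- sum(a$end - a$start)
      isect <- .isect_bp_flat(a, b)
      isect / (ta + tb - isect)
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  .spatial_result("jaccard_perm", obs, p, "attraction", n_perm,
                  if (is.null(seed)) NA_integer_ else seed,
                  mean(null), stats::sd(null))
}

#' Projection binomial test
#'
#' Counts the query midpoints falling inside the merged reference coverage;
#' under independence that count is Binomial(n, c) with c the reference
#' coverage fraction of the genome. Reports the one-sided upper tail
#' P(X >= k) as the primary (attraction) p-value and the doubled two-sided
#' version. The observed statistic is k / n.
#'
#' @param query,reference [interval_set()]s sharing one layout; reference
#'   non-empty, query with at least one midpoint.
#' @return a `spatial_test_result` with extras `k`, `n`,
#'   `coverage_fraction`, `p_two_sided`.
#' @export
projection_test <- function(query, reference) {
  .check_shared_layout(query, reference)
  n <- n_intervals(query)
  if (n < 1 || n_intervals(reference) == 0)
    stop("projection test needs a non-empty query and reference")
  layout <- query$layout
  b <- .merged(reference)
  cvg <- sum(b$end - b$start) / total_bp(layout)
  off <- .layout_offsets(layout)
  mids <- .midpoints(query$df$start, query$df$end) + off[query$df$chrom]
  k <- sum(.point_in_cov(b, mids))
  if (cvg == 0 && k > 0)
    stop("impossible configuration: zero coverage but midpoints inside it")
  p_up <- max(stats::pbinom(k - 1, n, cvg, lower.tail = FALSE),
              .Machine$double.xmin)
  p_dn <- stats::pbinom(k, n, cvg)
  .spatial_result("projection_binomial", k / n, p_up,
                  if (k >= n * cvg) "attraction" else "repulsion",
                  extra = list(k = k, n = n, coverage_fraction = cvg,
                               p_two_sided = min(1, 2 * min(p_up, p_dn))))
}

#' Run the full spatial test battery
#'
#' Runs the Monte Carlo interval-count test and the four pairwise tests
#' (relative distance KS, absolute distance permutation, Jaccard
#' permutation, projection binomial) with per-test sub-seeds derived from
#' one master seed by fixed offsets, so adding a test never perturbs
#' another's stream. Individual test failures are captured per test and do
#' not abort the batch.
#'
#' @param query,reference [interval_set()]s sharing one layout.
#' @param n_perm permutations for the permutation tests (default 10000).
#' @param seed master integer seed.
#' @return a named list of `spatial_test_result` (or `error_result`) in
#'   stable order: interval_count_mc, relative_distance_ks,
#'   absolute_distance_perm, jaccard_perm, projection_binomial.
#' @export
run_all_spatial_tests <- function(query, reference, n_perm = 10000,
                                  seed = NULL) {
  sub <- function(k) if (is.null(seed)) NULL else as.integer(seed) + k
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      structure(list(test_name = name, error = conditionMessage(e)),
                class = "error_result"))
  }
  list(
    interval_count_mc = wrap("interval_count_mc",
      bits_mc_test(query, reference, n_perm, sub(101L))),
    relative_distance_ks = wrap("relative_distance_ks",
      relative_distance_test(query, reference)),
    absolute_distance_perm = wrap("absolute_distance_perm",
      absolute_distance_test(query, reference, n_perm, sub(211L))),
    jaccard_perm = wrap("jaccard_perm",
      jaccard_test(query, reference, n_perm, sub(307L))),
    projection_binomial = wrap("projection_binomial",
      projection_test(query, reference)))
}
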