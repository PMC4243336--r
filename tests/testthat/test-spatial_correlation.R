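test_that("shuffle preserves lengths and chromosomes, is seed-deterministic", {
  gl <- toy_layout(c(a = 1e5, b = 2e5))
  set.seed(5)
  s <- random_set(100, gl, max_len = 500)
  sh1 <- shuffle_intervals(s, seed = 42)
  sh2 <- shuffle_intervals(s, seed = 42)
  expect_equal(as.data.frame(sh1), as.data.frame(sh2))
  expect_equal(sort(interval_lengths(sh1)), sort(interval_lengths(s)))
  expect_equal(table(as.data.frame(sh1)$chrom), table(as.data.frame(s)$chrom))
  df <- as.data.frame(sh1)
  expect_true(all(df$start >= 0 & df$end <= unclass(gl)[df$chrom]))
  expect_error(shuffle_intervals(
    interval_set("a", 0, 1e5, gl)), NA)   # full-length region still fits
})

test_that("shuffled starts are uniform (chi-square at 1%)", {
  gl <- genome_layout(c(c = 1e5))
  s <- interval_set("c", 0, 100, gl)
  starts <- vapply(1:10000, function(i)
    as.data.frame(shuffle_intervals(s, seed = i))$start, numeric(1))
  # 10 equal bins over the 0..99900 start range
  cnt <- tabulate(findInterval(starts, seq(0, 99901, length.out = 11),
                               rightmost.closed = TRUE), nbins = 10)
  pv <- chisq.test(cnt)$p.value
  expect_gt(pv, 0.01)
})

test_that("interval-count MC test behaves at the extremes", {
  gl <- genome_layout(c(c = 1e5))
  # reference covers ~95% of the genome, query misses it: p near 1
  ref <- interval_set("c", 0, 95000, gl)
  q <- interval_set("c", c(96000, 97000, 98000),
                    c(96100, 97100, 98100), gl)
  r1 <- bits_mc_test(q, ref, n_perm = 1000, seed = 1)
  expect_gte(r1$p_value, 0.95)
  # identical stacked sparse sets: no shuffle can reach the observed count
  gl2 <- genome_layout(c(c = 1e6))
  stack <- interval_set("c", rep(100, 5), rep(200, 5), gl2)
  r2 <- bits_mc_test(stack, stack, n_perm = 999, seed = 2)
  expect_equal(r2$p_value, 1 / 1000)
  expect_gte(r2$p_value, 1 / (999 + 1))
  expect_error(bits_mc_test(interval_set(character(0), numeric(0),
                                         numeric(0), gl2), stack, 10, 1),
               "non-empty")
})

test_that("relative distance test: degenerate attraction and repulsion", {
  gl <- genome_layout(c(c = 1e6))
  refs <- interval_set("c", seq(0, 9e5, by = 5e4) + 100,
                       seq(0, 9e5, by = 5e4) + 200, gl)
  # query midpoints coincide with reference midpoints: all r = 0, D = 1
  atop <- relative_distance_test(refs, refs)
  expect_equal(atop$observed_statistic, 1)
  expect_lt(atop$p_value, 1e-4)
  expect_equal(atop$direction, "attraction")
  # midpoints exactly halfway between consecutive reference midpoints
  mids <- seq(0, 9e5, by = 5e4) + 150
  half <- (mids[-1] + mids[-length(mids)]) / 2
  hq <- interval_set("c", half - 50, half + 50, gl)
  rep_ <- relative_distance_test(hq, refs)
  expect_equal(rep_$direction, "repulsion")
  expect_equal(rep_$mean_relative_distance, 0.5)
  expect_error(relative_distance_test(
    interval_set("c", 1, 100, gl), refs), "eligible")
})

test_that("absolute distance test: zero-distance floor and tie handling", {
  gl <- genome_layout(c(c = 1e6))
  refs <- interval_set("c", c(1000, 500000), c(1100, 500100), gl)
  r0 <- absolute_distance_test(refs, refs, n_perm = 499, seed = 3)
  expect_equal(r0$observed_statistic, 0)
  expect_equal(r0$p_value, 1 / 500)
  # single query equidistant from the only two reference midpoints
  q <- interval_set("c", 250500, 250600, gl)
  r1 <- absolute_distance_test(q, refs, n_perm = 99, seed = 4)
  expect_equal(r1$observed_statistic, 250550 - 1050)
  expect_error(absolute_distance_test(
    interval_set("c", 1, 2, genome_layout(c(c = 10, d = 10))),
    interval_set("d", 1, 2, genome_layout(c(c = 10, d = 10)))),
    "shared")
})

test_that("jaccard statistic analytic values and symmetry", {
  gl <- genome_layout(c(c = 1000))
  a <- interval_set("c", 0, 100, gl)
  b <- interval_set("c", 50, 150, gl)
  expect_equal(jaccard_statistic(a, b), 1 / 3)
  expect_equal(jaccard_statistic(b, a), 1 / 3)
  expect_equal(jaccard_statistic(a, a), 1)
  expect_equal(jaccard_statistic(a, interval_set("c", 500, 600, gl)), 0)
  set.seed(6)
  q <- random_set(30, toy_layout(), max_len = 500)
  r <- random_set(30, toy_layout(), max_len = 500)
  expect_equal(jaccard_statistic(q, r), jaccard_statistic(r, q))
})

test_that("jaccard permutation test: identical sparse sets give floor p", {
  gl <- genome_layout(c(c = 1e6))
  s <- interval_set("c", c(100, 5000, 90000), c(300, 5200, 90200), gl)
  r <- jaccard_test(s, s, n_perm = 999, seed = 7)
  expect_equal(r$observed_statistic, 1)
  expect_equal(r$p_value, 1 / 1000)
  expect_equal(r$observed_statistic, jaccard_statistic(s, s))
})

test_that("projection test arithmetic", {
  gl <- genome_layout(c(c = 1000))
  ref_half <- interval_set("c", 0, 500, gl)   # c = 0.5
  q10 <- interval_set("c", seq(0, 450, by = 50), seq(0, 450, by = 50) + 10,
                      gl)  # all 10 midpoints inside coverage
  r <- projection_test(q10, ref_half)
  expect_equal(r$k, 10)
  expect_equal(r$coverage_fraction, 0.5)
  expect_equal(r$p_value, 0.5^10)
  # whole-genome reference: k = n, p = 1
  rall <- projection_test(q10, interval_set("c", 0, 1000, gl))
  expect_equal(rall$k, rall$n)
  expect_equal(rall$p_value, 1)
  # n = 1, k = 0: upper tail P(X >= 0) = 1
  r0 <- projection_test(interval_set("c", 600, 700, gl),
                        interval_set("c", 0, 250, gl))
  expect_equal(r0$k, 0)
  expect_equal(r0$p_value, 1)
})

test_that("permutation p-values respect the plus-one floor and determinism", {
  sim <- simulate_pair(scenario_config(n_reference = 150, n_query = 150,
                                       scenario = "colocated",
                                       coloc_fraction = 0.4, seed = 12))
  res1 <- run_all_spatial_tests(sim$query, sim$reference, n_perm = 99,
                                seed = 31)
  res2 <- run_all_spatial_tests(sim$query, sim$reference, n_perm = 99,
                                seed = 31)
  for (nm in names(res1)) {
    expect_false(inherits(res1[[nm]], "error_result"))
    expect_equal(res1[[nm]]$p_value, res2[[nm]]$p_value)
    expect_gt(res1[[nm]]$p_value, 0)
  }
  perm <- c("interval_count_mc", "absolute_distance_perm", "jaccard_perm")
  for (nm in perm) expect_gte(res1[[nm]]$p_value, 1 / 100)
  # batch failures are captured, not thrown
  gl <- genome_layout(c(c = 1e6))
  lone <- interval_set("c", 1, 100, gl)
  res3 <- run_all_spatial_tests(lone, lone, n_perm = 9, seed = 1)
  expect_s3_class(res3$relative_distance_ks, "error_result")
  expect_s3_class(res3$interval_count_mc, "spatial_test_result")
})

test_that("power ordering on the proximal-not-overlapping scenario", {
  cfg <- scenario_config(n_reference = 600, n_query = 600,
                         scenario = "proximal", coloc_fraction = 0.8,
                         gap_mean = 500, seed = 13)
  sim <- simulate_pair(cfg)
  # near-zero bp intersection but strong proximity
  expect_lt(jaccard_statistic(sim$query, sim$reference), 0.01)
  rel <- relative_distance_test(sim$query, sim$reference)
  abs_ <- absolute_distance_test(sim$query, sim$reference, n_perm = 500,
                                 seed = 14)
  expect_lt(rel$p_value, 0.05)
  expect_equal(rel$direction, "attraction")
  expect_lt(abs_$p_value, 0.05)
  expect_lt(abs_$observed_statistic, abs_$null_mean)
  # the projection test measures different geometry: midpoints sit just
  # outside the reference coverage, so k stays near chance expectation
  proj <- projection_test(sim$query, sim$reference)
  expect_lt(abs(proj$k - proj$n * proj$coverage_fraction),
            4 * sqrt(proj$n * proj$coverage_fraction))
})
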