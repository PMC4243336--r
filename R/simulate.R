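# Synthetic paired cistromes with controlled co-location structure, so every
# analysis stage is testable without sequencing data. Region lengths are
# log-normal, the simplest two-parameter family with mean > median as both
# emulated peak-size summaries show; (meanlog, sdlog) are derived in closed
# form from a target (mean, median): meanlog = log(median),
# sdlog = sqrt(2 * log(mean / median)).

#' Log-normal parameters from a target mean and median
#'
#' @param mean,median target arithmetic mean and median in bp
#'   (`mean >= median > 0`).
#' @return list with `meanlog` and `sdlog` for [stats::rlnorm()].
#' @export
lognormal_from_mean_median <- function(mean, median) {
  stopifnot(mean >= median, median > 0)
  list(meanlog = log(median), sdlog = sqrt(2 * log(mean / median)))
}

#' Scenario configuration for the paired-cistrome simulator
#'
#' @param layout a [genome_layout()]; default 5 toy chromosomes of 2e7 bp.
#' @param n_reference,n_query region counts (> 0).
#' @param ref_length_model,query_length_model lists with `meanlog`, `sdlog`
#'   (bp scale); see [lognormal_from_mean_median()].
#' @param scenario `"null"` (independent uniform placement), `"colocated"`
#'   (a fraction of query regions centred on reference regions with Gaussian
#'   offset) or `"proximal"` (a fraction placed just downstream of reference
#'   regions at an exponential gap - close but non-overlapping).
#' @param coloc_fraction fraction f of query regions tied to reference
#'   regions (ignored for `"null"`).
#' @param offset_sd Gaussian SD in bp of the centre offset in the colocated
#'   scenario.
#' @param gap_mean mean in bp of the exponential gap in the proximal
#'   scenario.
#' @param min_length,max_length truncation bounds for length draws; defaults
#'   50 bp and (shortest chromosome)/100.
#' @param seed integer seed.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(layout = NULL, n_reference = 2000,
                            n_query = 2000,
                            ref_length_model = lognormal_from_mean_median(1508, 1336),
                            query_length_model = lognormal_from_mean_median(601, 529),
                            scenario = c("null", "colocated", "proximal"),
                            coloc_fraction = 0, offset_sd = 150,
                            gap_mean = 500, min_length = 50,
                            max_length = NULL, seed = 1L) {
  if (is.null(layout))
    layout <- genome_layout(stats::setNames(rep(2e7, 5),
                                            paste0("chr", 1:5)))
  scenario <- match.arg(scenario)
  if (is.null(max_length)) max_length <- min(unclass(layout)) / 100
  stopifnot(n_reference > 0, n_query > 0,
            coloc_fraction >= 0, coloc_fraction <= 1,
            offset_sd >= 0, gap_mean > 0,
            min_length >= 1, max_length > min_length)
  if (max_length > min(unclass(layout)))
    stop("max_length exceeds the shortest chromosome: infeasible geometry")
  structure(list(layout = layout, n_reference = n_reference,
                 n_query = n_query, ref_length_model = ref_length_model,
                 query_length_model = query_length_model,
                 scenario = scenario, coloc_fraction = coloc_fraction,
                 offset_sd = offset_sd, gap_mean = gap_mean,
                 min_length = min_length, max_length = max_length,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Named scenario presets
#'
#' `pr_like` and `er_like` are null-scenario single-factor presets whose
#' length models target the emulated peak-size summaries (median 1336 /
#' mean 1508 bp and median 529 / mean 601 bp respectively). `paper_mimic`
#' is a scaled-down two-factor preset: 2,000 reference regions with the
#' long-length model, 1,800 query regions with the short-length model,
#' colocated fraction 0.25, centre-offset SD 150 bp.
#'
#' @param seed integer seed stored in each preset.
#' @return a named list of [scenario_config()]s.
#' @export
default_configs <- function(seed = 1L) {
  list(
    pr_like = scenario_config(
      n_reference = 2000, n_query = 2000,
      ref_length_model = lognormal_from_mean_median(1508, 1336),
      query_length_model = lognormal_from_mean_median(1508, 1336),
      scenario = "null", seed = seed),
    er_like = scenario_config(
      n_reference = 2000, n_query = 2000,
      ref_length_model = lognormal_from_mean_median(601, 529),
      query_length_model = lognormal_from_mean_median(601, 529),
      scenario = "null", seed = seed),
    paper_mimic = scenario_config(
      n_reference = 2000, n_query = 1800,
      ref_length_model = lognormal_from_mean_median(1508, 1336),
      query_length_model = lognormal_from_mean_median(601, 529),
      scenario = "colocated", coloc_fraction = 0.25, offset_sd = 150,
      seed = seed))
}

# truncated log-normal draws
.rlen <- function(n, model, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(n, model$meanlog, model$sdlog))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a paired cistrome
#'
#' Reference regions are placed uniformly, with per-chromosome counts drawn
#' multinomially in proportion to chromosome length. `floor(f * n_query)`
#' query regions are tied to uniformly chosen reference regions by the
#' scenario's offset/gap rule; the remainder (and the whole query set in the
#' null scenario) are placed uniformly. Everything is clamped to chromosome
#' bounds and deterministic given the config seed.
#'
#' @param config a [scenario_config()].
#' @return a list with `reference` and `query` ([interval_set()]s; query
#'   regions carry names `q1..qn`) and `truth`, a data.frame
#'   (`name`, `label` in `tied`/`independent`, aligned to the sorted query
#'   set) so downstream tests never re-infer ground truth.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  layout <- config$layout
  clen <- unclass(layout)
  .with_seed(config$seed, function() {
    place_uniform <- function(n, len) {
      ci <- sample.int(length(clen), n, replace = TRUE,
                       prob = clen / sum(clen))
      chrom <- names(clen)[ci]
      start <- floor(stats::runif(n) * (clen[ci] - len + 1))
      list(chrom = chrom, start = start)
    }
    rlen_ <- .rlen(config$n_reference, config$ref_length_model,
                   config$min_length, config$max_length)
    rp <- place_uniform(config$n_reference, rlen_)
    reference <- interval_set(rp$chrom, rp$start, rp$start + rlen_, layout,
                              name = paste0("r", seq_len(config$n_reference)))
    qlen <- .rlen(config$n_query, config$query_length_model,
                  config$min_length, config$max_length)
    n_tied <- if (config$scenario == "null") 0L
              else floor(config$coloc_fraction * config$n_query)
    qchrom <- character(config$n_query)
    qstart <- numeric(config$n_query)
    if (n_tied > 0) {
      anchor <- sample.int(config$n_reference, n_tied, replace = TRUE)
      # anchors index the *sorted* reference rows
      ac <- reference$df$chrom[anchor]
      as_ <- reference$df$start[anchor]
      ae <- reference$df$end[anchor]
      if (config$scenario == "colocated") {
        centre <- .midpoints(as_, ae) +
          round(stats::rnorm(n_tied, 0, config$offset_sd))
        s <- centre - floor(qlen[seq_len(n_tied)] / 2)
      } else {
        s <- ae + round(stats::rexp(n_tied, 1 / config$gap_mean))
      }
      s <- pmax(0, pmin(s, clen[ac] - qlen[seq_len(n_tied)]))
      qchrom[seq_len(n_tied)] <- ac
      qstart[seq_len(n_tied)] <- s
    }
    if (n_tied < config$n_query) {
      free <- (n_tied + 1):config$n_query
      up <- place_uniform(length(free), qlen[free])
      qchrom[free] <- up$chrom
      qstart[free] <- up$start
    }
    qname <- paste0("q", seq_len(config$n_query))
    query <- interval_set(qchrom, qstart, qstart + qlen, layout,
                          name = qname)
    label <- c(rep("tied", n_tied),
               rep("independent", config$n_query - n_tied))
    truth <- data.frame(name = query$df$name,
                        label = label[match(query$df$name, qname)],
                        stringsAsFactors = FALSE)
    list(reference = reference, query = query, truth = truth)
  })
}
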