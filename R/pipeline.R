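#' Run the full co-localization pipeline on two BED inputs
#'
#' Stage order mirrors a standard post-peak-calling analysis: size
#' summaries, overlap/Venn decomposition, OCV domain sweep (whole genome
#' plus any TSS-window domains derivable from a gene table), the spatial
#' test battery, and region-to-gene association (skipped without genes).
#' Progress is logged to standard error with stage tags; the machine-
#' readable report never mixes with logs.
#'
#' @param query_bed,reference_bed paths to BED peak files.
#' @param chrom_sizes path to a chrom.sizes file.
#' @param gene_table optional path to a 4-column TSS table
#'   (see [read_tss_table()]).
#' @param tss_windows optional two-column matrix of TSS-relative windows to
#'   sweep in addition to the whole genome (requires `gene_table`); default
#'   `cbind(-5000, 5000)` when genes are given.
#' @param n_perm permutations for the spatial tests.
#' @param seed master integer seed.
#' @param alpha OCV significance threshold.
#' @param out_dir optional directory for report files (`report.json`,
#'   `report.txt`, `sections.bed`); created if missing.
#' @return an object of class `run_report` (a list with `inputs`,
#'   `size_summaries`, `overlap`, `ocv_sweep`, `spatial`, `association`,
#'   `seed`, `n_perm`, `version`, `timestamp`), invisibly when `out_dir`
#'   is given.
#' @export
run_pipeline <- function(query_bed, reference_bed, chrom_sizes,
                         gene_table = NULL, tss_windows = NULL,
                         n_perm = 1000, seed = 1L, alpha = 0.05,
                         out_dir = NULL) {
  log_stage <- function(stage, ...)
    message("[", stage, "] ", ...)
  log_stage("parse", "reading inputs")
  layout <- read_chrom_sizes(chrom_sizes)
  query <- read_bed(query_bed, layout)
  reference <- read_bed(reference_bed, layout)
  genes <- if (!is.null(gene_table)) read_tss_table(gene_table, layout)

  log_stage("summarize", "size distributions")
  sizes <- list(query = size_summary(query), reference = size_summary(reference))

  log_stage("overlap", "Venn decomposition and common sections")
  overlap <- venn_counts(query, reference)
  sections <- common_sections(query, reference)

  log_stage("ocv", "domain sweep")
  domains <- list(whole_genome = whole_genome_domain(layout))
  if (!is.null(genes)) {
    w <- if (is.null(tss_windows)) cbind(-5000, 5000) else as.matrix(tss_windows)
    for (i in seq_len(nrow(w)))
      domains[[paste0("tss_", w[i, 1], "_", w[i, 2])]] <-
        build_tss_domain(genes, w[i, , drop = FALSE], layout)
  }
  sweep <- ocv_domain_sweep(query, reference, domains, alpha)

  log_stage("spatial", "test battery (n_perm = ", n_perm, ")")
  spatial <- run_all_spatial_tests(query, reference, n_perm, seed)

  association <- NULL
  if (!is.null(genes)) {
    log_stage("annotate", "region-to-gene association of common sections")
    association <- associate_regions(sections, genes, layout)
  } else log_stage("annotate", "skipped (no gene table)")

  report <- structure(list(
    inputs = list(query_bed = query_bed, reference_bed = reference_bed,
                  chrom_sizes = chrom_sizes, gene_table = gene_table,
                  n_query = n_intervals(query),
                  n_reference = n_intervals(reference)),
    size_summaries = sizes, overlap = overlap, ocv_sweep = sweep,
    spatial = spatial, association = association,
    seed = seed, n_perm = n_perm, alpha = alpha,
    version = as.character(utils::packageVersion("peakcoloc")),
    timestamp = format(Sys.time(), tz = "UTC")), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(sections, file.path(out_dir, "sections.bed"))
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
    return(invisible(report))
  }
  report
}

#' Convert a run report to a plain list for serialization
#'
#' Everything numeric in the report is reproducible from the embedded
#' inputs and seed; the timestamp is the only run-specific field.
#'
#' @param report a `run_report`.
#' @return a nested list of plain vectors.
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "run_report"))
  strip <- function(x) {
    if (inherits(x, "spatial_test_result") || inherits(x, "error_result") ||
        inherits(x, "overlap_summary"))
      return(lapply(unclass(x), strip))
    if (inherits(x, "size_summary"))
      return(list(n = x$n, mean = x$mean, median = x$median,
                  fraction_above = as.list(x$fraction_above)))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  list(inputs = report$inputs,
       size_summaries = strip(report$size_summaries),
       overlap = strip(report$overlap),
       ocv_sweep = report$ocv_sweep,
       spatial = strip(report$spatial),
       association = if (!is.null(report$association))
         list(genes_per_region = as.list(report$association$genes_per_region),
              distance_bins = as.list(report$association$distance_bins),
              orientation = as.list(report$association$orientation)),
       seed = report$seed, n_perm = report$n_perm, alpha = report$alpha,
       version = report$version, timestamp = report$timestamp)
}

#' @export
print.run_report <- function(x, ...) {
  cat("== peakcoloc run report (v", x$version, ") ==\n", sep = "")
  cat("query: ", x$inputs$query_bed, " (", x$inputs$n_query, " regions)\n",
      "reference: ", x$inputs$reference_bed, " (", x$inputs$n_reference,
      " regions)\n", "seed: ", x$seed, "   n_perm: ", x$n_perm, "\n\n",
      sep = "")
  cat("-- size summaries --\n")
  print(x$size_summaries$query)
  print(x$size_summaries$reference)
  cat("\n-- overlap --\n")
  print(x$overlap)
  cat("\n-- OCV domain sweep (alpha = ", x$alpha, ") --\n", sep = "")
  print(x$ocv_sweep)
  cat("\n-- spatial tests --\n")
  for (t in x$spatial) {
    if (inherits(t, "error_result"))
      cat("<", t$test_name, "> ERROR: ", t$error, "\n", sep = "")
    else print(t)
  }
  if (!is.null(x$association)) {
    cat("\n-- region-gene association --\n")
    print(x$association)
  }
  invisible(x)
}
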