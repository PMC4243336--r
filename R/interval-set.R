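#' Interval set: sorted genomic intervals tied to a layout
#'
#' The universal currency of the package. Coordinates are 0-based
#' half-open `[start, end)`: a printed region `chr1:7507615-7508428` is stored
#' as `start = 7507615`, `end = 7508428` and has length `end - start = 813` bp.
#' Intervals are kept sorted by (chromosome in layout order, start, end).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open coordinates.
#' @param layout a [genome_layout()] bounding every interval.
#' @param name optional labels.
#' @param score optional numeric scores.
#' @param summit_offset optional summit position relative to `start`
#'   (`NA` = absent); must satisfy `0 <= summit_offset < end - start`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return an object of class `interval_set`.
#' @examples
#' gl <- genome_layout(c(chr1 = 1e4))
#' s <- interval_set("chr1", c(100, 500), c(200, 900), gl)
#' n_intervals(s)
#' @export
interval_set <- function(chrom, start, end, layout,
                         name = NA_character_, score = NA_real_,
                         summit_offset = NA_real_, strand = NA_character_) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- length(start)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start), end = as.numeric(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   summit_offset = rep_len(as.numeric(summit_offset), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  .validate_intervals(df, layout)
  ci <- match(df$chrom, names(layout))
  df <- df[order(ci, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(df = df, layout = layout), class = "interval_set")
}

.validate_intervals <- function(df, layout) {
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start != floor(df$start) | df$end != floor(df$end))
  if (length(bad))
    stop("non-integer coordinates at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("empty or inverted interval (start >= end) at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(df$start < 0)) stop("negative start coordinate")
  unknown <- setdiff(unique(df$chrom), names(layout))
  if (length(unknown))
    stop("chromosome(s) absent from layout: ",
         paste(unknown, collapse = ", "))
  over <- which(df$end > unclass(layout)[df$chrom])
  if (length(over))
    stop("interval end exceeds chromosome length at record(s) ",
         paste(utils::head(over, 5), collapse = ", "))
  so <- df$summit_offset
  badso <- which(!is.na(so) & (so < 0 | so >= df$end - df$start |
                                 so != floor(so)))
  if (length(badso))
    stop("summit_offset outside [0, length) at record(s) ",
         paste(utils::head(badso, 5), collapse = ", "))
  invisible(TRUE)
}

#' Number of intervals in a set
#' @param x an [interval_set()].
#' @return integer count.
#' @export
n_intervals <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  nrow(x$df)
}

#' Interval lengths (end - start)
#'
#' Under the half-open convention the length of `chr1:7507615-7508428`
#' is 813 bp.
#'
#' @param x an [interval_set()].
#' @return numeric vector of lengths in bp.
#' @export
interval_lengths <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  x$df$end - x$df$start
}

#' Parse a "chrom:start-end" region string
#'
#' The printed form is taken as 0-based half-open, so the parsed length is
#' exactly `end - start`.
#'
#' @param text a string like `"chr1:7507615-7508428"`.
#' @return a list with elements `chrom`, `start`, `end`, `length`.
#' @examples
#' parse_region("chr1:7507615-7508428")$length  # 813
#' @export
parse_region <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)[-–]([0-9,]+)$", text))[[1]]
  if (length(m) != 4) stop("cannot parse region string: ", text)
  start <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
  end <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  if (start >= end) stop("region start must be < end: ", text)
  list(chrom = m[2], start = start, end = end, length = end - start)
}

#' @export
as.data.frame.interval_set <- function(x, ...) x$df

#' @export
print.interval_set <- function(x, ...) {
  cat("<interval_set> ", nrow(x$df), " intervals on ",
      length(unique(x$df$chrom)), " chromosome(s)\n", sep = "")
  if (nrow(x$df)) print(utils::head(x$df, 5))
  invisible(x)
}

.check_shared_layout <- function(a, b) {
  if (!identical(unclass(a$layout), unclass(b$layout)))
    stop("interval sets do not share a genome layout")
  invisible(TRUE)
}

#' Merge overlapping and book-ended intervals
#'
#' Intervals that overlap or touch end-to-start are unioned; total covered
#' bp is unchanged. Per-interval annotation columns are dropped.
#'
#' @param x an [interval_set()].
#' @return a merged [interval_set()].
#' @export
merge_set <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  if (nrow(x$df) == 0)
    return(interval_set(character(0), numeric(0), numeric(0), x$layout))
  off <- .layout_offsets(x$layout)
  m <- .merge_flat(x$df$start + off[x$df$chrom], x$df$end + off[x$df$chrom])
  loc <- .unflatten(m$start, m$end, x$layout)
  interval_set(loc$chrom, loc$start, loc$end, x$layout)
}

#' Resize intervals to a fixed width around their summit
#'
#' Each interval is replaced by `[c - flank, c + flank)` where `c` is
#' `start + summit_offset` when a summit is recorded and the midpoint
#' `floor((start + end) / 2)` otherwise. Results are clamped to chromosome
#' bounds (clamping, not dropping, so paired analyses stay aligned); an
#' interval that would become empty after clamping is dropped with a warning.
#'
#' @param x an [interval_set()].
#' @param flank bp on each side of the summit; the nominal output width is
#'   `2 * flank`.
#' @return an [interval_set()] of fixed-width intervals.
#' @export
resize_fixed_width <- function(x, flank) {
  stopifnot(inherits(x, "interval_set"), flank > 0, flank == floor(flank))
  df <- x$df
  if (nrow(df) == 0) return(x)
  centre <- ifelse(is.na(df$summit_offset),
                   floor((df$start + df$end) / 2),
                   df$start + df$summit_offset)
  clen <- unclass(x$layout)[df$chrom]
  ns <- pmax(0, centre - flank)
  ne <- pmin(clen, centre + flank)
  keep <- ns < ne
  if (any(!keep))
    warning(sum(!keep), " interval(s) empty after clamping were dropped")
  df <- df[keep, , drop = FALSE]
  ns <- ns[keep]; ne <- ne[keep]; centre <- centre[keep]
  interval_set(df$chrom, ns, ne, x$layout, name = df$name, score = df$score,
               summit_offset = pmin(pmax(centre - ns, 0), ne - ns - 1),
               strand = df$strand)
}

#' Summarize the size distribution of an interval set
#'
#' @param x a non-empty [interval_set()].
#' @param bin_width histogram bin width in bp.
#' @param thresholds bp thresholds at which the fraction of intervals with
#'   length strictly greater than the threshold is reported (default 1000,
#'   i.e., the fraction of regions above 1 kb).
#' @return an object of class `size_summary` with fields `n`, `mean`,
#'   `median`, `histogram` (data.frame `bin_start`, `bin_end`, `count`) and
#'   `fraction_above` (named numeric). The median of an even count is the
#'   mean of the two central values.
#' @export
size_summary <- function(x, bin_width = 100, thresholds = 1000) {
  stopifnot(inherits(x, "interval_set"))
  len <- interval_lengths(x)
  if (length(len) == 0) stop("size_summary of an empty interval set")
  stopifnot(bin_width > 0)
  breaks <- seq(0, (max(len) %/% bin_width + 1) * bin_width, by = bin_width)
  cnt <- tabulate(findInterval(len, breaks, left.open = TRUE),
                  nbins = length(breaks) - 1)
  hist <- data.frame(bin_start = breaks[-length(breaks)],
                     bin_end = breaks[-1], count = cnt)
  fa <- vapply(thresholds, function(t) mean(len > t), numeric(1))
  structure(list(n = length(len), mean = mean(len),
                 median = stats::median(len), histogram = hist,
                 fraction_above = stats::setNames(fa, thresholds)),
            class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat("<size_summary> n=", x$n, " mean=", round(x$mean, 1),
      " median=", round(x$median, 1), "\n", sep = "")
  for (t in names(x$fraction_above))
    cat("  fraction > ", t, " bp: ", round(x$fraction_above[[t]], 3), "\n",
        sep = "")
  invisible(x)
}
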