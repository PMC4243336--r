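#' Read a BED file into an interval set
#'
#' Accepts BED3/BED6 and a narrowPeak-like 10-column dialect in which column
#' 10 holds the summit offset from `start` (-1 meaning absent). `track`,
#' `browser` and `#` comment lines are skipped. Coordinates are 0-based
#' half-open as in BED.
#'
#' @param path path to a tab-separated BED file.
#' @param layout a [genome_layout()]; intervals are validated against it.
#' @param on_unknown_chrom policy for records on chromosomes absent from
#'   `layout`: `"reject"` (default; error) or `"drop"` (drop with a warning).
#'   Silent coordinate-space mismatch is the classic interval bug, hence the
#'   strict default.
#' @return an [interval_set()], sorted and validated.
#' @export
read_bed <- function(path, layout, on_unknown_chrom = c("reject", "drop")) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  stopifnot(inherits(layout, "genome_layout"))
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(interval_set(character(0), numeric(0), numeric(0), layout))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", lineno[which(nf < 3)[1]], ": fewer than 3 columns")
  get_col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  chrom <- get_col(1)
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": start >= end (zero-length or inverted)")
  name <- get_col(4)
  score <- suppressWarnings(as.numeric(get_col(5)))
  strand <- get_col(6)
  strand[!strand %in% c("+", "-", ".")] <- NA_character_
  summit <- suppressWarnings(as.numeric(get_col(10)))
  summit[!is.na(summit) & summit < 0] <- NA_real_   # narrowPeak -1 = absent
  unknown <- !(chrom %in% names(layout))
  if (any(unknown)) {
    if (on_unknown_chrom == "reject")
      stop("line ", lineno[which(unknown)[1]],
           ": chromosome not in layout: ", chrom[which(unknown)[1]])
    warning("dropping ", sum(unknown),
            " record(s) on chromosomes absent from layout")
    kp <- !unknown
    chrom <- chrom[kp]; start <- start[kp]; end <- end[kp]
    name <- name[kp]; score <- score[kp]; strand <- strand[kp]
    summit <- summit[kp]; lineno <- lineno[kp]
  }
  over <- which(end > unclass(layout)[chrom])
  if (length(over))
    stop("line ", lineno[over[1]], ": end exceeds chromosome length")
  bad <- which(!is.na(summit) & summit >= end - start)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": summit offset outside interval")
  interval_set(chrom, start, end, layout, name = name, score = score,
               summit_offset = summit, strand = strand)
}

#' Write an interval set as BED
#'
#' Emits BED3 by default, or BED6 when any name/score/strand annotation is
#' present. Tab-separated, newline-terminated, no header; missing name is
#' `.`, missing score `0`, missing strand `.`.
#'
#' @param x an [interval_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  df <- x$df
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  if (all(is.na(df$name)) && all(is.na(df$score)) && all(is.na(df$strand))) {
    out <- paste(df$chrom, fmt(df$start), fmt(df$end), sep = "\t")
  } else {
    out <- paste(df$chrom, fmt(df$start), fmt(df$end),
                 ifelse(is.na(df$name), ".", df$name),
                 ifelse(is.na(df$score), "0", fmt(df$score)),
                 ifelse(is.na(df$strand), ".", df$strand), sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}
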