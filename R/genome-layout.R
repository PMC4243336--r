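#' Genome layout: chromosome names and lengths
#'
#' A `genome_layout` pins every interval operation to one coordinate space.
#' It is a named numeric vector (chromosome name -> length in bp) with
#' uniqueness and positivity enforced at construction.
#'
#' @param lengths named numeric vector of chromosome lengths in bp.
#' @return an object of class `genome_layout`.
#' @examples
#' gl <- genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' total_bp(gl)
#' @export
genome_layout <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("chromosome lengths must be a named vector")
  if (anyDuplicated(nm))
    stop("duplicate chromosome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  len <- as.numeric(lengths)
  if (any(!is.finite(len)) || any(len <= 0) || any(len != floor(len)))
    stop("chromosome lengths must be positive integers")
  structure(stats::setNames(len, nm), class = "genome_layout")
}

#' Read a chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp. No header.
#'
#' @param path path to a chrom.sizes text file.
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"),
                          quote = "", comment.char = "")
  genome_layout(stats::setNames(df$length, df$chrom))
}

#' Write a chrom.sizes file
#'
#' @param layout a [genome_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  writeLines(paste(names(layout), format(unclass(layout), scientific = FALSE,
                                         trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Total genome size of a layout
#' @param layout a [genome_layout()].
#' @return total bp across all chromosomes.
#' @export
total_bp <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(unclass(layout))
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x), " chromosomes, ",
      format(sum(unclass(x)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

# Flattening offsets: concatenated coordinate with a 1-bp guard base between
# chromosomes so book-ended merging can never join intervals across a
# chromosome boundary.
.layout_offsets <- function(layout) {
  len <- unclass(layout)
  stats::setNames(cumsum(c(0, utils::head(len + 1, -1))), names(layout))
}
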