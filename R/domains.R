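#' Domain set: merged allowed genomic space
#'
#' A domain restricts which regions enter the proximity analysis and where
#' the placement null may put an interval. It is a merged (disjoint)
#' interval set plus its total bp.
#'
#' @param x an [interval_set()] (merged internally) or an existing
#'   `domain_set`.
#' @return an object of class `domain_set` with fields `set` (merged
#'   [interval_set()]), `total_bp` and `layout`.
#' @export
domain_set <- function(x) {
  if (inherits(x, "domain_set")) return(x)
  stopifnot(inherits(x, "interval_set"))
  m <- merge_set(x)
  tb <- sum(interval_lengths(m))
  if (tb <= 0) stop("domain has zero total bp")
  structure(list(set = m, total_bp = tb, layout = x$layout),
            class = "domain_set")
}

#' Whole-genome domain for a layout
#' @param layout a [genome_layout()].
#' @return a [domain_set()] covering every chromosome end to end.
#' @export
whole_genome_domain <- function(layout) {
  domain_set(interval_set(names(layout), rep(0, length(layout)),
                          unclass(layout), layout))
}

#' @export
print.domain_set <- function(x, ...) {
  cat("<domain_set> ", n_intervals(x$set), " merged interval(s), ",
      format(x$total_bp, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Gene annotation: id, chromosome, strand, TSS
#'
#' The native gene format is a 4-column table (gene id, chromosome, strand,
#' TSS position in bp); BED6 gene models are deliberately not parsed
#' directly because the TSS convention is ambiguous there — use
#' [tss_from_bed6()].
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss TSS coordinate (bp, 0-based) per gene.
#' @param layout a [genome_layout()].
#' @return an object of class `gene_annotation` (a data.frame sorted by
#'   chromosome, TSS, gene id, with the layout attached).
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand), tss = as.numeric(tss),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("gene ids must be unique")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  unknown <- setdiff(unique(df$chrom), names(layout))
  if (length(unknown))
    stop("gene chromosome(s) absent from layout: ",
         paste(unknown, collapse = ", "))
  if (any(df$tss < 0 | df$tss >= unclass(layout)[df$chrom]))
    stop("TSS outside chromosome bounds")
  ci <- match(df$chrom, names(layout))
  df <- df[order(ci, df$tss, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(df = df, layout = layout), class = "gene_annotation")
}

#' Read a 4-column TSS table
#'
#' Tab-separated, no header: gene id, chromosome, strand, TSS position.
#'
#' @param path path to the table.
#' @param layout a [genome_layout()].
#' @return a [gene_annotation()].
#' @export
read_tss_table <- function(path, layout) {
  if (!file.exists(path)) stop("TSS table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_id", "chrom", "strand", "tss"),
                          colClasses = c("character", "character",
                                         "character", "numeric"),
                          quote = "", comment.char = "#")
  gene_annotation(df$gene_id, df$chrom, df$strand, df$tss, layout)
}

#' Convert BED6 gene models to a TSS annotation
#'
#' Takes the interval start as TSS for `+` strand genes and the interval end
#' coordinate for `-` strand genes.
#'
#' @param path path to a BED6 file of gene bodies.
#' @param layout a [genome_layout()].
#' @return a [gene_annotation()].
#' @export
tss_from_bed6 <- function(path, layout) {
  s <- read_bed(path, layout)
  df <- s$df
  if (any(is.na(df$strand)))
    stop("BED6 gene models must carry a '+' or '-' strand")
  tss <- ifelse(df$strand == "+", df$start, df$end)
  tss <- pmin(tss, unclass(layout)[df$chrom] - 1)
  gene_annotation(df$name, df$chrom, df$strand, tss, layout)
}

#' Build a TSS-window domain
#'
#' Maps each window, given in TSS-relative strand-aware coordinates
#' (negative = upstream), onto every gene and merges the result into a
#' domain. For a `+` strand gene a window `(rel_start, rel_end)` becomes
#' `[tss + rel_start, tss + rel_end)`; for a `-` strand gene
#' `[tss - rel_end, tss - rel_start)`. Windows are clamped to chromosome
#' bounds; a window entirely off-chromosome is dropped with a warning.
#'
#' @param genes a [gene_annotation()].
#' @param windows a two-column matrix or data.frame of
#'   `(rel_start, rel_end)` pairs, `rel_start < rel_end`; e.g.
#'   `cbind(-500, 500)` is "500 bp upstream and downstream of the TSS" and
#'   `cbind(-55000, -45000)` the 45-55 kb upstream annulus.
#' @param layout a [genome_layout()].
#' @return a [domain_set()].
#' @export
build_tss_domain <- function(genes, windows, layout) {
  stopifnot(inherits(genes, "gene_annotation"))
  w <- as.matrix(windows)
  if (ncol(w) != 2 || nrow(w) == 0)
    stop("windows must be a non-empty two-column (rel_start, rel_end) table")
  if (any(w[, 1] >= w[, 2])) stop("each window needs rel_start < rel_end")
  g <- genes$df
  ng <- nrow(g)
  nw <- nrow(w)
  gi <- rep(seq_len(ng), times = nw)
  wi <- rep(seq_len(nw), each = ng)
  plus <- g$strand[gi] == "+"
  abs_start <- ifelse(plus, g$tss[gi] + w[wi, 1], g$tss[gi] - w[wi, 2])
  abs_end <- ifelse(plus, g$tss[gi] + w[wi, 2], g$tss[gi] - w[wi, 1])
  clen <- unclass(layout)[g$chrom[gi]]
  s <- pmax(0, abs_start)
  e <- pmin(clen, abs_end)
  keep <- s < e
  if (any(!keep))
    warning(sum(!keep), " TSS window(s) entirely off-chromosome were dropped")
  domain_set(interval_set(g$chrom[gi][keep], s[keep], e[keep], layout))
}

#' Basal-plus-extension regulatory domains per gene
#'
#' Each gene gets a strand-aware basal interval (`basal_up` bp upstream and
#' `basal_down` bp downstream of its TSS) and an extension on each side up
#' to the nearer of `max_ext` from its own TSS or the adjacent gene's basal
#' boundary, never shrinking below its own basal interval. Ties in TSS are
#' broken by gene id order.
#'
#' @param genes a [gene_annotation()].
#' @param layout a [genome_layout()].
#' @param basal_up,basal_down basal window in bp upstream/downstream of the
#'   TSS (defaults 5000 and 1000).
#' @param max_ext maximum extension from the TSS in bp (default 1e6).
#' @return a data.frame, one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss`, `basal_start`, `basal_end`, `reg_start`, `reg_end` (all 0-based
#'   half-open).
#' @export
great_domains <- function(genes, layout, basal_up = 5000, basal_down = 1000,
                          max_ext = 1e6) {
  stopifnot(inherits(genes, "gene_annotation"))
  g <- genes$df
  plus <- g$strand == "+"
  clen <- unclass(layout)[g$chrom]
  basal_start <- pmax(0, ifelse(plus, g$tss - basal_up, g$tss - basal_down))
  basal_end <- pmin(clen, ifelse(plus, g$tss + basal_down, g$tss + basal_up))
  reg_start <- numeric(nrow(g))
  reg_end <- numeric(nrow(g))
  for (ch in unique(g$chrom)) {
    i <- which(g$chrom == ch)       # already sorted by (tss, gene_id)
    bs <- basal_start[i]
    be <- basal_end[i]
    prev_be <- c(0, cummax(be)[-length(i)])
    next_bs <- rev(cummin(rev(bs)))
    next_bs <- c(next_bs[-1], unclass(layout)[ch])
    reg_start[i] <- pmin(bs, pmax(g$tss[i] - max_ext, prev_be))
    reg_end[i] <- pmax(be, pmin(g$tss[i] + max_ext, next_bs))
  }
  reg_start <- pmax(0, reg_start)
  reg_end <- pmin(clen, reg_end)
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             tss = g$tss, basal_start = basal_start, basal_end = basal_end,
             reg_start = reg_start, reg_end = reg_end,
             stringsAsFactors = FALSE)
}

#' Associate regions with genes through regulatory domains
#'
#' A region associates with every gene whose regulatory interval (see
#' [great_domains()]) contains the region's midpoint. The association is
#' `proximal` when the midpoint lies in the gene's basal interval, `distal`
#' otherwise. Distance is signed and strand-aware: negative upstream of the
#' TSS, positive downstream.
#'
#' @param regions an [interval_set()].
#' @param genes a [gene_annotation()].
#' @param layout a [genome_layout()].
#' @param basal_up,basal_down,max_ext as in [great_domains()].
#' @return an object of class `region_gene_association` with fields
#'   `associations` (data.frame: `region`, `chrom`, `midpoint`, `gene_id`,
#'   `distance`, `class`), `genes_per_region` (named counts for 0, 1, 2,
#'   `>2` genes), `distance_bins` (named counts for |distance| 0-5, 5-50,
#'   50-500, `>500` kb) and `orientation` (upstream/downstream counts).
#' @export
associate_regions <- function(regions, genes, layout, basal_up = 5000,
                              basal_down = 1000, max_ext = 1e6) {
  stopifnot(inherits(regions, "interval_set"),
            inherits(genes, "gene_annotation"))
  gd <- great_domains(genes, layout, basal_up, basal_down, max_ext)
  rd <- regions$df
  mids <- .midpoints(rd$start, rd$end)
  assoc <- vector("list", length(unique(rd$chrom)))
  k <- 0
  for (ch in unique(rd$chrom)) {
    ri <- which(rd$chrom == ch)
    gi <- which(gd$chrom == ch)
    if (length(gi) == 0) next
    # regulatory intervals may overlap; quadratic-free scan via outer on
    # modest per-chromosome gene counts is adequate at annotation scale
    hits <- lapply(ri, function(r) {
      inr <- gi[gd$reg_start[gi] <= mids[r] & mids[r] < gd$reg_end[gi]]
      if (length(inr) == 0) return(NULL)
      data.frame(region = r, stringsAsFactors = FALSE,
                 chrom = ch, midpoint = mids[r],
                 gene_id = gd$gene_id[inr],
                 distance = ifelse(gd$strand[inr] == "+",
                                   mids[r] - gd$tss[inr],
                                   gd$tss[inr] - mids[r]),
                 class = ifelse(gd$basal_start[inr] <= mids[r] &
                                  mids[r] < gd$basal_end[inr],
                                "proximal", "distal"))
    })
    k <- k + 1
    assoc[[k]] <- do.call(rbind, hits)
  }
  assoc <- do.call(rbind, assoc[seq_len(k)])
  if (is.null(assoc))
    assoc <- data.frame(region = integer(0), chrom = character(0),
                        midpoint = numeric(0), gene_id = character(0),
                        distance = numeric(0), class = character(0))
  ngenes <- tabulate(assoc$region, nbins = nrow(rd))
  gpr <- c(`0` = sum(ngenes == 0), `1` = sum(ngenes == 1),
           `2` = sum(ngenes == 2), `>2` = sum(ngenes > 2))
  ad <- abs(assoc$distance)
  dist_bins <- c(`0-5kb` = sum(ad <= 5e3),
                 `5-50kb` = sum(ad > 5e3 & ad <= 5e4),
                 `50-500kb` = sum(ad > 5e4 & ad <= 5e5),
                 `>500kb` = sum(ad > 5e5))
  orientation <- c(upstream = sum(assoc$distance < 0),
                   downstream = sum(assoc$distance >= 0))
  structure(list(associations = assoc, genes_per_region = gpr,
                 distance_bins = dist_bins, orientation = orientation),
            class = "region_gene_association")
}

#' @export
print.region_gene_association <- function(x, ...) {
  cat("<region_gene_association> ", nrow(x$associations),
      " associations\n  genes per region: ", sep = "")
  cat(paste(names(x$genes_per_region), x$genes_per_region, sep = "="),
      sep = ", ")
  cat("\n")
  invisible(x)
}
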