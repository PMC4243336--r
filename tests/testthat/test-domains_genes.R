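make_genes <- function(df, layout) {
  gene_annotation(df$gene_id, df$chrom, df$strand, df$tss, layout)
}

test_that("TSS windows map strand-aware and merge into a domain", {
  gl <- genome_layout(c(c = 2e5))
  g_plus <- make_genes(data.frame(gene_id = "g1", chrom = "c",
                                  strand = "+", tss = 10000), gl)
  d1 <- build_tss_domain(g_plus, cbind(-500, 500), gl)
  expect_equal(as.data.frame(d1$set)[, c("start", "end")],
               data.frame(start = 9500, end = 10500))
  g_minus <- make_genes(data.frame(gene_id = "g2", chrom = "c",
                                   strand = "-", tss = 10000), gl)
  d2 <- build_tss_domain(g_minus, cbind(-5000, 0), gl)
  expect_equal(as.data.frame(d2$set)[, c("start", "end")],
               data.frame(start = 10000, end = 15000))
  g3 <- make_genes(data.frame(gene_id = "g3", chrom = "c",
                              strand = "+", tss = 100000), gl)
  d3 <- build_tss_domain(g3, cbind(-55000, -45000), gl)
  expect_equal(as.data.frame(d3$set)[, c("start", "end")],
               data.frame(start = 45000, end = 55000))
  # off-chromosome windows are clamped / dropped
  g4 <- make_genes(data.frame(gene_id = c("g4", "g5"), chrom = "c",
                              strand = "+", tss = c(100, 100000)), gl)
  expect_warning(d4 <- build_tss_domain(g4, cbind(-55000, -45000), gl),
                 "dropped")
  expect_equal(d4$total_bp, 10000)   # only the in-bounds gene survives
  g6 <- make_genes(data.frame(gene_id = "g6", chrom = "c",
                              strand = "+", tss = 100), gl)
  expect_error(suppressWarnings(
    build_tss_domain(g6, cbind(-55000, -45000), gl)), "zero total bp")
})

test_that("TSS domain output is merged/disjoint and strand-symmetric", {
  gl <- genome_layout(c(c = 1e6))
  set.seed(30)
  tss <- sort(sample(10000:990000, 40))
  strand <- sample(c("+", "-"), 40, replace = TRUE)
  genes <- make_genes(data.frame(gene_id = paste0("g", 1:40), chrom = "c",
                                 strand = strand, tss = tss), gl)
  w <- rbind(c(-5000, 1000), c(-20000, -10000))
  d <- build_tss_domain(genes, w, gl)
  dd <- as.data.frame(d$set)
  expect_true(all(dd$start[-1] > dd$end[-nrow(dd)]))   # disjoint, gaps >= 1
  expect_lte(d$total_bp, 40 * (6000 + 10000))
  # mirroring strands and reflecting coordinates preserves total bp
  flipped <- make_genes(data.frame(
    gene_id = paste0("g", 1:40), chrom = "c",
    strand = ifelse(strand == "+", "-", "+"), tss = 1e6 - tss), gl)
  d_flip <- build_tss_domain(flipped, w, gl)
  expect_equal(d_flip$total_bp, d$total_bp)
})

test_that("basal-plus-extension domains follow the neighbour rule", {
  gl <- genome_layout(c(c = 1e7))
  lone <- make_genes(data.frame(gene_id = "g", chrom = "c", strand = "+",
                                tss = 5e6), gl)
  gd <- great_domains(lone, gl)
  expect_equal(c(gd$reg_start, gd$reg_end), c(4e6, 6e6))
  expect_true(gd$reg_start <= gd$basal_start && gd$basal_end <= gd$reg_end)
  # two + strand genes 20 kb apart: extensions stop at the neighbour's
  # basal boundary (hand-computed: basal g1 [95k,101k), g2 [115k,121k))
  two <- make_genes(data.frame(gene_id = c("g1", "g2"), chrom = "c",
                               strand = "+", tss = c(1e5, 1.2e5)), gl)
  gd2 <- great_domains(two, gl)
  expect_equal(gd2$basal_start, c(95000, 115000))
  expect_equal(gd2$basal_end, c(101000, 121000))
  expect_equal(gd2$reg_end[1], 115000)   # stops at g2's basal start
  expect_equal(gd2$reg_start[2], 101000) # stops at g1's basal end
  expect_equal(gd2$reg_start[1], 0)      # tss - 1 Mb clamped at chromosome 0
  # gene at chromosome start: upstream extension clamped at 0
  edge <- make_genes(data.frame(gene_id = "e", chrom = "c", strand = "+",
                                tss = 2000), gl)
  expect_equal(great_domains(edge, gl)$reg_start, 0)
})

test_that("extensions never shrink below the basal interval", {
  gl <- genome_layout(c(c = 1e6))
  set.seed(31)
  tss <- sort(sample(1000:999000, 60))
  genes <- make_genes(data.frame(gene_id = sprintf("g%02d", 1:60),
                                 chrom = "c",
                                 strand = sample(c("+", "-"), 60, TRUE),
                                 tss = tss), gl)
  gd <- great_domains(genes, gl)
  expect_true(all(gd$reg_start <= gd$basal_start))
  expect_true(all(gd$reg_end >= gd$basal_end))
  # adjacent extensions stop at neighbouring basal boundaries: a gene's
  # extension may not cross the running basal envelope of its neighbours
  o <- order(gd$tss)
  for (i in seq_len(59)) {
    a <- o[i]; b <- o[i + 1]
    expect_gte(gd$reg_start[b], min(gd$basal_start[b],
                                    max(gd$basal_end[a], gd$tss[b] - 1e6)))
  }
})

test_that("region-gene association classes, distances and histograms", {
  gl <- genome_layout(c(c = 1e7))
  genes <- make_genes(data.frame(gene_id = "g", chrom = "c", strand = "+",
                                 tss = 3e6), gl)
  mk <- function(mid) interval_set("c", mid - 50, mid + 50, gl)
  # 2 kb upstream: proximal, negative distance
  a1 <- associate_regions(mk(3e6 - 2000), genes, gl)
  expect_equal(nrow(a1$associations), 1)
  expect_equal(a1$associations$class, "proximal")
  expect_equal(a1$associations$distance, -2000)
  expect_equal(unname(a1$orientation["upstream"]), 1L)
  # 600 kb away: distal (within the 1 Mb extension)
  a2 <- associate_regions(mk(3e6 + 6e5), genes, gl)
  expect_equal(a2$associations$class, "distal")
  expect_equal(unname(a2$distance_bins[">500kb"]), 1L)
  # 1.5 Mb away: no association
  a3 <- associate_regions(mk(3e6 + 15e5), genes, gl)
  expect_equal(nrow(a3$associations), 0)
  expect_equal(unname(a3$genes_per_region["0"]), 1L)
})

test_that("genes-per-region histogram sums to the region count", {
  gl <- genome_layout(c(c = 5e6))
  set.seed(33)
  genes <- make_genes(data.frame(gene_id = sprintf("g%02d", 1:20),
                                 chrom = "c",
                                 strand = sample(c("+", "-"), 20, TRUE),
                                 tss = sort(sample(1e4:49e5, 20))), gl)
  regions <- random_set(200, gl, max_len = 2000)
  a <- associate_regions(regions, genes, gl)
  expect_equal(sum(a$genes_per_region), 200)
  expect_equal(sum(a$distance_bins), nrow(a$associations))
  expect_equal(sum(a$orientation), nrow(a$associations))
  # class consistency with the basal rule
  gd <- great_domains(genes, gl)
  for (i in seq_len(nrow(a$associations))) {
    row <- a$associations[i, ]
    gi <- which(gd$gene_id == row$gene_id)
    inside_basal <- gd$basal_start[gi] <= row$midpoint &&
      row$midpoint < gd$basal_end[gi]
    expect_equal(row$class, if (inside_basal) "proximal" else "distal")
  }
})

test_that("TSS table IO and BED6 conversion", {
  gl <- genome_layout(c(c = 1e6))
  withr::with_tempdir({
    writeLines(c("g1\tc\t+\t1000", "g2\tc\t-\t5000"), "tss.tsv")
    g <- read_tss_table("tss.tsv", gl)
    expect_equal(g$df$gene_id, c("g1", "g2"))
    writeLines(c("c\t1000\t3000\tg1\t0\t+", "c\t2000\t5000\tg2\t0\t-"),
               "genes.bed")
    g2 <- tss_from_bed6("genes.bed", gl)
    expect_equal(g2$df$tss, c(1000, 5000))
    expect_error(gene_annotation(c("a", "a"), "c", "+", c(1, 2), gl),
                 "unique")
    expect_error(gene_annotation("a", "c", ".", 1, gl), "strand")
  })
})
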