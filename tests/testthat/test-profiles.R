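# Relative density, direction percentages, meta-profiles and smoothing.

test_that("relative density counts strictly-above-threshold sites per Mb", {
  regions <- make_region(start = 0L, end = 1000000L, region_class = "TSS")
  sites <- make_sites(seq(100, 1000, by = 100), level = 2)  # 10 sites > 1
  d <- relative_density(sites, regions, level_threshold = 1)
  expect_equal(d$density_per_mb, 10)
  expect_equal(d$n_sites, 10L)
  # boundary: level exactly equal to the threshold is NOT counted
  b <- relative_density(make_sites(100, level = 1), regions, level_threshold = 1)
  expect_equal(b$n_sites, 0L)
  z <- relative_density(make_sites(integer(0)), regions, 1)
  expect_equal(z$n_sites, 0L)
  # overlapping regions are merged before measuring the footprint
  two <- rbind(regions, make_region(start = 500000L, end = 1500000L,
                                    region_class = "TSS"))
  d2 <- relative_density(sites, two, 1)
  expect_equal(d2$bases, 1500000)
})

test_that("direction percentages split hyper/hypo per class and sum to 100", {
  dmrs <- data.frame(chrom = "chr1", start = 1:4 * 100L, end = 1:4 * 100L + 50L,
                     region_class = c("TSS", "TSS", "TSS", "TSS"),
                     gene_name = "G", context = "5mC", n_sites = 3L,
                     p_value = 0.01, p_adjusted = NA_real_,
                     rratio = c(1, 1, 1, -1),
                     direction = c("hyper", "hyper", "hyper", "hypo"),
                     test_name = "exact_ranksum", pair_id = 1:4,
                     is_dmr = TRUE, stringsAsFactors = FALSE)
  ann <- annotate_dmrs(dmrs)
  pct <- direction_percentages(ann)
  expect_equal(pct$pct_hyper, 75)
  expect_equal(pct$pct_hypo, 25)
  expect_equal(pct$pct_hyper + pct$pct_hypo, 100)
  # classes with zero DMRs are absent
  expect_false("TES" %in% pct$region_class)
  empty <- direction_percentages(annotate_dmrs(NULL))
  expect_equal(nrow(empty), 0)
})

make_profile_gene <- function(gene, chrom, offset, level, strand = "+") {
  regions <- rbind(
    make_region(chrom, offset, offset + 2000L, "TSS", gene, strand),
    make_region(chrom, offset + 2000L, offset + 8000L, "gene_body", gene, strand),
    make_region(chrom, offset + 8000L, offset + 10000L, "TES", gene, strand))
  pos <- as.integer(offset + c(500, 1500, 3000, 5000, 7000, 8500, 9500))
  cls <- c("TSS", "TSS", "gene_body", "gene_body", "gene_body", "TES", "TES")
  mrs <- do.call(rbind, lapply(unique(cls), function(rc) {
    pp <- pos[cls == rc]
    make_mr(pp, rep_len(level, length(pp)), chrom = chrom, region_class = rc,
            gene_name = gene)
  }))
  list(regions = regions, mrs = mrs)
}

test_that("meta-profile averages genes on the equalized axis", {
  g1 <- make_profile_gene("A", "chr1", 0L, 0.2)
  g2 <- make_profile_gene("B", "chr1", 50000L, 0.4)
  regions <- rbind(g1$regions, g2$regions)
  mrs <- rbind(g1$mrs, g2$mrs)
  prof <- meta_profile(mrs, regions, n_bins = 50)
  expect_equal(prof$n_genes, 2)
  expect_true(all(abs(prof$value - 0.3) < 1e-12))  # mean of two flat genes
  # a single one-site gene extends by nearest neighbour to a constant
  one <- make_mr(600L, 0.7, region_class = "TSS", gene_name = "C")
  reg1 <- make_region("chr1", 0L, 2000L, "TSS", "C")
  reg1 <- rbind(reg1, make_region("chr1", 2000L, 8000L, "gene_body", "C"),
                make_region("chr1", 8000L, 10000L, "TES", "C"))
  p1 <- meta_profile(one, reg1, n_bins = 20)
  expect_true(all(p1$value == 0.7))
})

test_that("identical site layout and levels across genes pass through unchanged", {
  g1 <- make_profile_gene("A", "chr1", 0L, 0.25)
  g2 <- make_profile_gene("B", "chr2", 0L, 0.25)
  prof <- meta_profile(rbind(g1$mrs, g2$mrs), rbind(g1$regions, g2$regions),
                       n_bins = 30)
  single <- meta_profile(g1$mrs, g1$regions, n_bins = 30)
  expect_equal(prof$value, single$value)
})

test_that("strand flip orients '-' genes in transcription direction", {
  # one site near the transcriptional TSS on each strand -> same axis position
  reg_p <- rbind(make_region("chr1", 0L, 2000L, "TSS", "P", "+"),
                 make_region("chr1", 2000L, 8000L, "gene_body", "P", "+"),
                 make_region("chr1", 8000L, 10000L, "TES", "P", "+"))
  reg_m <- rbind(make_region("chr2", 8000L, 10000L, "TSS", "M", "-"),
                 make_region("chr2", 2000L, 8000L, "gene_body", "M", "-"),
                 make_region("chr2", 0L, 2000L, "TES", "M", "-"))
  # '+' TSS site at fraction 0.1; '-' TSS site at genomic fraction 0.9 of
  # its (high-coordinate) TSS region = transcriptional fraction 0.1
  mr_p <- rbind(make_mr(200L, 0.9, chrom = "chr1", region_class = "TSS", gene_name = "P"),
                make_mr(5000L, 0.1, chrom = "chr1", region_class = "gene_body",
                        gene_name = "P"))
  mr_m <- rbind(make_mr(9800L, 0.9, chrom = "chr2", region_class = "TSS", gene_name = "M"),
                make_mr(5000L, 0.1, chrom = "chr2", region_class = "gene_body",
                        gene_name = "M"))
  p_plus <- meta_profile(mr_p, reg_p, n_bins = 10)
  p_minus <- meta_profile(mr_m, reg_m, n_bins = 10)
  expect_equal(p_plus$value, p_minus$value)
})

test_that("smoothing preserves constants and matches the impulse response", {
  expect_equal(smooth_profile(rep(3.5, 20), window_n = 5, sigma = 2), rep(3.5, 20))
  # hand-computed centred moving average of an impulse, Gaussian off
  expect_equal(smooth_profile(c(0, 0, 1, 0, 0), window_n = 3, sigma = 0),
               c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  # even windows widen to the next odd size
  expect_equal(smooth_profile(c(0, 0, 1, 0, 0), window_n = 2, sigma = 0),
               c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  # normalized kernels keep the mean within edge-effect tolerance
  set.seed(31)
  x <- stats::runif(100)
  expect_equal(mean(smooth_profile(x, 5, 2)), mean(x), tolerance = 0.01)
  expect_message(smooth_profile(c(1, 2, 3), window_n = 9, sigma = 0), "clipped")
})

test_that("smoothing is linear to near machine precision", {
  set.seed(32)
  x <- stats::rnorm(80); y <- stats::rnorm(80)
  a <- 2.5; b <- -1.25
  lhs <- smooth_profile(a * x + b * y, window_n = 5, sigma = 2)
  rhs <- a * smooth_profile(x, 5, 2) + b * smooth_profile(y, 5, 2)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-12)
})

test_that("per-MR site plots export their underlying data", {
  case <- make_mr(c(100L, 300L), c(0.8, 0.9))
  ctrl <- make_mr(100L, 0.1, sample_id = "control1")
  pair <- pair_mrs(case, ctrl)[[1]]
  fig <- tempfile(fileext = ".pdf")
  df <- plot_mr_sites(pair, fig, p_value = 0.04)
  expect_true(file.exists(fig))
  tsv <- sub("\\.pdf$", ".tsv", fig)
  expect_true(file.exists(tsv))
  expect_equal(sum(df$control_imputed), 1)  # exactly one imputed control entry
  expect_equal(sum(df$case_imputed), 0)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$position, df$position)
  expect_equal(back$case_level, df$case_level)
})
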