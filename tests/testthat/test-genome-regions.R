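# Gene-model parsing and genome partition into region classes.

write_refflat <- function(rows) {
  path <- tempfile(fileext = ".refFlat")
  writeLines(rows, path)
  path
}

test_that("refFlat rows map to gene models and bad rows are rejected", {
  p <- write_refflat(c(
    "GENE1\tNM_1\tchr1\t+\t1000\t5000\t1000\t5000\t1\t1000,\t5000,",
    "GENE2\tNM_2\tchr2\t-\t200\t900\t200\t900\t1\t200,\t900,"))
  g <- read_refflat(p)
  expect_equal(nrow(g), 2)
  expect_equal(g$gene_name, c("GENE1", "GENE2"))
  expect_equal(g$tx_start, c(1000L, 200L))
  expect_equal(g$strand, c("+", "-"))

  expect_equal(nrow(read_refflat(write_refflat(character(0)))), 0)
  expect_error(read_refflat(write_refflat("G\tT\tchr1\t+\t5000\t1000\t.\t.\t1\t,\t,")),
               "txStart")
  expect_error(read_refflat(write_refflat("G\tT\tchr1\t*\t10\t20\t.\t.\t1\t,\t,")),
               "strand")
  expect_error(read_refflat(write_refflat("G\tT\tchr1\t+\tabc\t20\t.\t.\t1\t,\t,")),
               "non-integer")
})

test_that("rows on chromosomes missing from the size table are dropped with a warning", {
  p <- write_refflat(c(
    "A\tT1\tchr1\t+\t1000\t9000\t.\t.\t1\t,\t,",
    "B\tT2\tchrUn\t+\t1000\t9000\t.\t.\t1\t,\t,"))
  expect_warning(g <- read_refflat(p, c(chr1 = 100000)), "absent")
  expect_equal(g$gene_name, "A")
})

test_that("region extraction follows the stated interval arithmetic on both strands", {
  sizes <- c(chr1 = 200000)
  g_plus <- data.frame(gene_name = "G", transcript_id = "T", chrom = "chr1",
                       strand = "+", tx_start = 10000L, tx_end = 50000L,
                       stringsAsFactors = FALSE)
  r <- extract_regions(g_plus, sizes)
  get <- function(r, cls) r[r$region_class == cls, c("start", "end")]
  expect_equal(unlist(get(r, "TSS"), use.names = FALSE), c(9000, 11000))
  expect_equal(unlist(get(r, "TES"), use.names = FALSE), c(49000, 51000))
  expect_equal(unlist(get(r, "gene_body"), use.names = FALSE), c(11000, 49000))
  # 5' distance [-90000, 0) clips to empty and is dropped
  expect_equal(nrow(get(r, "five_prime_distance")), 0)

  g_minus <- transform(g_plus, strand = "-")
  r2 <- extract_regions(g_minus, sizes)
  expect_equal(unlist(get(r2, "TSS"), use.names = FALSE), c(49000, 51000))
  expect_equal(unlist(get(r2, "TES"), use.names = FALSE), c(9000, 11000))
  # upstream on '-' extends to higher coordinates, spanning far - near bases
  expect_equal(unlist(get(r2, "five_prime_distance"), use.names = FALSE),
               c(60000, 150000))
  r3 <- extract_regions(g_minus, c(chr1 = 130000))
  expect_equal(unlist(get(r3, "five_prime_distance"), use.names = FALSE),
               c(60000, 130000))
})

test_that("a geneless chromosome becomes one truncated intergenic segment", {
  g <- data.frame(gene_name = "G", transcript_id = "T", chrom = "chr1",
                  strand = "+", tx_start = 10000L, tx_end = 50000L,
                  stringsAsFactors = FALSE)
  r <- extract_regions(g, c(chr1 = 200000, chr2 = 30000))
  ig2 <- r[r$region_class == "intergenic" & r$chrom == "chr2", ]
  expect_equal(nrow(ig2), 1)
  expect_equal(c(ig2$start, ig2$end), c(0, 30000))
  # a long chromosome's segment is truncated to intergenic_max
  r4 <- extract_regions(g, c(chr1 = 200000, chr3 = 500000))
  ig3 <- r4[r4$region_class == "intergenic" & r4$chrom == "chr3", ]
  expect_equal(ig3$end - ig3$start, 100000)
  # split mode tiles the whole segment instead
  r5 <- extract_regions(g, c(chr3 = 250000), intergenic_split = TRUE)
  ig5 <- r5[r5$region_class == "intergenic" & r5$chrom == "chr3", ]
  expect_equal(sum(ig5$end - ig5$start), 250000)
  expect_true(all(ig5$end - ig5$start <= 100000))
})

test_that("a short gene loses its body but keeps its flanks, with a warning", {
  g <- data.frame(gene_name = "S", transcript_id = "T", chrom = "chr1",
                  strand = "+", tx_start = 10000L, tx_end = 11500L,
                  stringsAsFactors = FALSE)
  expect_warning(r <- extract_regions(g, c(chr1 = 100000)), "omitted")
  expect_equal(sum(r$region_class == "gene_body"), 0)
  expect_equal(sum(r$region_class == "TSS"), 1)
  expect_equal(sum(r$region_class == "TES"), 1)
})

test_that("region partition invariants hold over random synthetic genomes", {
  set.seed(42)
  for (rep in 1:20) {
    gen <- simulate_genome(n_chroms = 2, chrom_length = 3e5, genes_per_chrom = 6)
    r <- extract_regions(gen$genes, gen$chrom_sizes)
    # chromosome bounds
    expect_true(all(r$start >= 0))
    expect_true(all(r$end <= gen$chrom_sizes[r$chrom]))
    expect_true(all(r$end > r$start))
    # intergenic length bounds
    ig <- r[r$region_class == "intergenic", ]
    expect_true(all(ig$end - ig$start >= 2000))
    expect_true(all(ig$end - ig$start <= 100000))
    # intergenic never intersects TSS/TES/gene_body
    occ <- r[r$region_class %in% c("TSS", "TES", "gene_body"), ]
    for (chrom in unique(ig$chrom)) {
      a <- ig[ig$chrom == chrom, ]; b <- occ[occ$chrom == chrom, ]
      if (nrow(a) == 0 || nrow(b) == 0) next
      hits <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
        a$start[i] < b$end[j] & b$start[j] < a$end[i]
      })
      expect_false(any(hits))
    }
    # within-gene disjointness of TSS/body/TES for long genes
    long <- gen$genes[gen$genes$tx_end - gen$genes$tx_start > 2000, ]
    for (gn in long$gene_name) {
      rg <- r[r$gene_name == gn & r$region_class %in% c("TSS", "gene_body", "TES"), ]
      rg <- rg[order(rg$start), ]
      if (nrow(rg) > 1) expect_true(all(rg$start[-1] >= rg$end[-nrow(rg)]))
    }
    # order independence
    perm <- gen$genes[sample(nrow(gen$genes)), ]
    expect_equal(extract_regions(perm, gen$chrom_sizes), r)
  }
})

test_that("BED region reading labels, skips headers, keeps overlaps", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("track name=enh", "chr1\t100\t900", "chr1\t100\t900\tE1\t0\t+"), p)
  r <- read_region_bed(p)
  expect_equal(nrow(r), 2)  # overlapping rows kept as-is
  expect_equal(r$region_class, c("enhancer", "enhancer"))
  expect_equal(r$start, c(100L, 100L))
  expect_equal(r$strand, c(".", "+"))
  writeLines("chr1\t900\t100", p)
  expect_error(read_region_bed(p), "start")
})

test_that("per-class BED export round-trips intervals", {
  g <- data.frame(gene_name = "G", transcript_id = "T", chrom = "chr1",
                  strand = "+", tx_start = 10000L, tx_end = 50000L,
                  stringsAsFactors = FALSE)
  r <- extract_regions(g, c(chr1 = 200000))
  d <- tempfile()
  paths <- write_region_beds(r, d)
  back <- read_region_bed(paths[["TSS"]], "TSS")
  expect_equal(back$start, r$start[r$region_class == "TSS"])
  expect_equal(back$end, r$end[r$region_class == "TSS"])
})
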