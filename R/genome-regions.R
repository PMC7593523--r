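# Gene-model parsing and partition of the genome into the region classes
# (TSS, TES, gene body, 5' distance, intergenic, enhancer) that bound all
# downstream methylated-region searches.

#' Read a two-column chromosome-sizes file
#'
#' @param path Tab- or whitespace-separated file with columns chromosome
#'   name and chromosome length (base pairs).
#' @return A named numeric vector mapping chromosome to length.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  if (any(!is.finite(df$size) | df$size <= 0)) {
    stop("chromosome sizes must be positive: ", path, call. = FALSE)
  }
  if (anyDuplicated(df$chrom)) stop("duplicated chromosome in ", path, call. = FALSE)
  stats::setNames(df$size, df$chrom)
}

#' Read gene models from a UCSC refFlat file
#'
#' Parses the 11-column refFlat dialect (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds);
#' exon and CDS columns are read but ignored. Coordinates are 0-based
#' half-open per the UCSC convention.
#'
#' @param path Path to the refFlat file (tab-separated, no header).
#' @param chrom_sizes Optional named vector from [read_chrom_sizes()]; rows
#'   on chromosomes absent from it are dropped with a warning.
#' @return data.frame with columns `gene_name`, `transcript_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end` (one row per transcript).
#' @export
read_refflat <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(gene_name = character(0), transcript_id = character(0),
                      chrom = character(0), strand = character(0),
                      tx_start = integer(0), tx_end = integer(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate whitespace-separated fixtures
  if (any(lengths(fields) < 6L)) fields <- strsplit(lines, "[ \t]+")
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6L) {
      stop(sprintf("%s: line %d: expected >= 6 refFlat columns, found %d",
                   path, i, length(f)), call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[5]))
    e <- suppressWarnings(as.integer(f[6]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("%s: line %d: non-integer txStart/txEnd", path, i), call. = FALSE)
    }
    if (!f[4] %in% c("+", "-")) {
      stop(sprintf("%s: line %d: unknown strand '%s'", path, i, f[4]), call. = FALSE)
    }
    if (s >= e) {
      stop(sprintf("%s: line %d: txStart (%d) must be < txEnd (%d)", path, i, s, e),
           call. = FALSE)
    }
    out[[i]] <- data.frame(gene_name = f[1], transcript_id = f[2], chrom = f[3],
                           strand = f[4], tx_start = s, tx_end = e,
                           stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, out)
  if (!is.null(chrom_sizes)) {
    drop <- !(genes$chrom %in% names(chrom_sizes))
    if (any(drop)) {
      warning(sprintf("dropping %d refFlat row(s) on chromosomes absent from the size table",
                      sum(drop)), call. = FALSE)
      genes <- genes[!drop, , drop = FALSE]
    }
  }
  rownames(genes) <- NULL
  genes
}

.empty_regions <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), region_class = character(0),
             gene_name = character(0), stringsAsFactors = FALSE)
}

.clip_region <- function(start, end, len) {
  c(max(0, min(start, len)), max(0, min(end, len)))
}

#' Partition the genome into methylation-analysis region classes
#'
#' For every transcript, builds a TSS region (`tss_point` +/- `tss_flank`),
#' a TES region likewise, the gene body strictly between the two flank
#' regions, and a strand-aware 5'-distance region `fpd_near`..`fpd_far`
#' upstream of the TSS. Intergenic regions are the per-chromosome complement
#' of the union of all TSS/TES/gene-body regions, with segments shorter than
#' `intergenic_min` discarded and segments longer than `intergenic_max`
#' truncated to their first `intergenic_max` bases (or split into
#' consecutive chunks when `intergenic_split = TRUE`). On the '-' strand
#' the TSS point is `tx_end` and upstream extends to higher coordinates.
#' All coordinates are clipped to `[0, chromosome length)`.
#'
#' @param genes data.frame from [read_refflat()].
#' @param chrom_sizes Named vector from [read_chrom_sizes()].
#' @param tss_flank,tes_flank Half-width (bp) of the TSS/TES regions.
#' @param fpd_near,fpd_far Near/far bounds (bp) of the 5'-distance region
#'   upstream of the TSS.
#' @param intergenic_min,intergenic_max Length bounds (bp) for intergenic
#'   segments.
#' @param intergenic_split Split over-long intergenic segments into
#'   consecutive `intergenic_max` chunks instead of truncating.
#' @return data.frame of regions: `chrom`, `start`, `end`, `strand`
#'   (`.` for intergenic), `region_class`, `gene_name` (`""` for
#'   intergenic), deduplicated and canonically sorted.
#' @export
extract_regions <- function(genes, chrom_sizes,
                            tss_flank = 1000, tes_flank = 1000,
                            fpd_near = 10000, fpd_far = 100000,
                            intergenic_min = 2000, intergenic_max = 100000,
                            intergenic_split = FALSE) {
  stopifnot(tss_flank > 0, tes_flank > 0, fpd_near > 0, fpd_far > fpd_near,
            intergenic_min < intergenic_max)
  rows <- list()
  n_body_dropped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$chrom %in% names(chrom_sizes)) next
    len <- chrom_sizes[[g$chrom]]
    if (g$strand == "+") {
      tss_point <- g$tx_start; tes_point <- g$tx_end
      fpd <- c(tss_point - fpd_far, tss_point - fpd_near)
    } else {
      tss_point <- g$tx_end; tes_point <- g$tx_start
      fpd <- c(tss_point + fpd_near, tss_point + fpd_far)
    }
    tss <- .clip_region(tss_point - tss_flank, tss_point + tss_flank, len)
    tes <- .clip_region(tes_point - tes_flank, tes_point + tes_flank, len)
    body_lo <- min(tss_point, tes_point) + if (g$strand == "+") tss_flank else tes_flank
    body_hi <- max(tss_point, tes_point) - if (g$strand == "+") tes_flank else tss_flank
    body <- .clip_region(body_lo, body_hi, len)
    fpd <- .clip_region(fpd[1], fpd[2], len)
    add <- function(cls, se) {
      if (se[2] > se[1]) {
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = g$chrom, start = se[1], end = se[2], strand = g$strand,
          region_class = cls, gene_name = g$gene_name, stringsAsFactors = FALSE)
      }
    }
    add("TSS", tss)
    add("TES", tes)
    if (body[2] > body[1]) {
      add("gene_body", body)
    } else {
      n_body_dropped <- n_body_dropped + 1L
    }
    add("five_prime_distance", fpd)
  }
  if (n_body_dropped > 0L) {
    warning(sprintf("gene body omitted for %d transcript(s) whose TSS and TES flank regions overlap",
                    n_body_dropped), call. = FALSE)
  }
  reg <- if (length(rows)) do.call(rbind, rows) else .empty_regions()

  # intergenic: complement of TSS/TES/gene_body per chromosome
  inter <- list()
  occ <- reg[reg$region_class %in% c("TSS", "TES", "gene_body"), , drop = FALSE]
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    oc <- occ[occ$chrom == chrom, , drop = FALSE]
    gaps <- complement_intervals(oc$start, oc$end, len)
    if (nrow(gaps) == 0L) next
    gaps <- gaps[gaps$end - gaps$start >= intergenic_min, , drop = FALSE]
    if (nrow(gaps) == 0L) next
    segs <- list()
    for (k in seq_len(nrow(gaps))) {
      s <- gaps$start[k]; e <- gaps$end[k]
      if (e - s <= intergenic_max) {
        segs[[length(segs) + 1L]] <- c(s, e)
      } else if (!intergenic_split) {
        segs[[length(segs) + 1L]] <- c(s, s + intergenic_max)
      } else {
        starts <- seq(s, e - 1, by = intergenic_max)
        for (st in starts) {
          en <- min(st + intergenic_max, e)
          if (en - st >= intergenic_min) segs[[length(segs) + 1L]] <- c(st, en)
        }
      }
    }
    if (length(segs)) {
      m <- do.call(rbind, segs)
      inter[[length(inter) + 1L]] <- data.frame(
        chrom = chrom, start = m[, 1], end = m[, 2], strand = ".",
        region_class = "intergenic", gene_name = "", stringsAsFactors = FALSE)
    }
  }
  out <- rbind(reg, if (length(inter)) do.call(rbind, inter) else .empty_regions())
  out <- unique(out)
  out <- .canonical_order(out)
  rownames(out) <- NULL
  out
}

#' Read a BED file as a set of regions of one class
#'
#' Accepts BED3+ (0-based half-open); `track`, `browser` and `#` header
#' lines are skipped. Overlapping rows are kept as-is.
#'
#' @param path BED file path.
#' @param region_class Class label to assign (default `"enhancer"`).
#' @return Region data.frame as in [extract_regions()].
#' @export
read_region_bed <- function(path, region_class = "enhancer") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(.empty_regions())
  fields <- strsplit(lines, "[ \t]+")
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) stop(sprintf("%s: line %d: BED needs >= 3 columns", path, i), call. = FALSE)
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) stop(sprintf("%s: line %d: non-integer coordinates", path, i), call. = FALSE)
    if (s >= e) stop(sprintf("%s: line %d: start (%d) must be < end (%d)", path, i, s, e), call. = FALSE)
    name <- if (length(f) >= 4L) f[4] else ""
    strand <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "."
    out[[i]] <- data.frame(chrom = f[1], start = s, end = e, strand = strand,
                           region_class = region_class, gene_name = name,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write one BED6 file per region class
#'
#' The annotation products are reusable across runs on the same genome.
#'
#' @param regions Region data.frame.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_region_beds <- function(regions, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cls in unique(regions$region_class)) {
    r <- regions[regions$region_class == cls, , drop = FALSE]
    r <- r[order(r$chrom, r$start, r$end, r$gene_name), , drop = FALSE]
    bed <- data.frame(r$chrom, r$start, r$end,
                      ifelse(r$gene_name == "", ".", r$gene_name),
                      0L, r$strand)
    p <- file.path(out_dir, paste0("regions_", cls, ".bed"))
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[cls] <- p
  }
  invisible(paths)
}
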