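# Clustering of methylated sites into methylated regions (MRs) inside each
# annotated region, by consecutive-site adjacency or fixed-size windows.

#' MR search parameters
#'
#' Minimum site counts follow the CLI convention of the field: `mc1` for
#' TSS/TES, `mc2` for gene body / 5'-distance / intergenic, `mc3` for
#' enhancer (and any custom) regions. `max_gap` is the largest allowed
#' distance between consecutive methylated sites in one MR (gaps exactly
#' equal to it are allowed).
#'
#' @param mc1,mc2,mc3 Minimum number of sites per MR for the three region
#'   groups (defaults 3, 5, 3).
#' @param max_gap Maximum adjacency distance `a` in bp (default 2000).
#' @param use_windows Use fixed-size window tiling instead of adjacency
#'   clustering (suited to dense WGBS data).
#' @param window_size Window width in bp when `use_windows` is on.
#' @param same_trend isST flag: 1 restricts DMR testing to MRs whose
#'   consecutive level changes all share one sign.
#' @return A list of class `mr_params`.
#' @export
mr_params <- function(mc1 = 3, mc2 = 5, mc3 = 3, max_gap = 2000,
                      use_windows = FALSE, window_size = 200, same_trend = 0) {
  stopifnot(mc1 >= 1, mc2 >= 1, mc3 >= 1, max_gap >= 1, window_size >= 1,
            same_trend %in% c(0, 1))
  structure(list(mc1 = mc1, mc2 = mc2, mc3 = mc3, max_gap = max_gap,
                 use_windows = use_windows, window_size = window_size,
                 same_trend = same_trend), class = "mr_params")
}

#' Minimum site count applicable to a region class
#' @param params `mr_params` object.
#' @param region_class One of the region class labels.
#' @return Integer minimum count.
#' @export
min_sites_for_class <- function(params, region_class) {
  switch(region_class,
         TSS = , TES = params$mc1,
         gene_body = , five_prime_distance = , intergenic = params$mc2,
         params$mc3)
}

.empty_mrs <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             region_class = character(0), gene_name = character(0),
             region_id = integer(0), context = character(0),
             sample_id = character(0), n_sites = integer(0),
             sites = I(list()), levels = I(list()), stringsAsFactors = FALSE)
}

.mr_row <- function(region, region_id, pos, lev, context, sample_id) {
  data.frame(chrom = region$chrom, start = pos[1], end = pos[length(pos)] + 1L,
             region_class = region$region_class, gene_name = region$gene_name,
             region_id = region_id, context = context, sample_id = sample_id,
             n_sites = length(pos), sites = I(list(pos)), levels = I(list(lev)),
             stringsAsFactors = FALSE)
}

# site-to-region assignment via interval overlap; membership is half-open
# (start <= pos < end). Returns list: for each region row, the indices of
# sites inside it (coordinate-sorted).
.sites_in_regions <- function(sites, regions) {
  res <- vector("list", nrow(regions))
  for (chrom in unique(regions$chrom)) {
    ri <- which(regions$chrom == chrom)
    si <- which(sites$chrom == chrom)
    if (length(si) == 0L) next
    pos <- sites$pos[si]
    o <- order(pos)
    si <- si[o]; pos <- pos[o]
    q <- IRanges::IRanges(start = pos + 1L, width = 1L)
    s <- IRanges::IRanges(start = regions$start[ri] + 1L, end = regions$end[ri])
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0L) next
    qh <- S4Vectors_queryHits(hits); sh <- S4Vectors_subjectHits(hits)
    sp <- split(si[qh], sh)
    for (nm in names(sp)) res[[ri[as.integer(nm)]]] <- sp[[nm]]
  }
  res
}

S4Vectors_queryHits <- function(h) IRanges::from(h)
S4Vectors_subjectHits <- function(h) IRanges::to(h)

#' Find methylated regions by consecutive-site adjacency
#'
#' Within each annotated region, sites are scanned in coordinate order and a
#' new cluster starts whenever the gap to the previous site exceeds
#' `max_gap`; clusters with fewer than the region-class minimum are
#' discarded. Sites are handled per (sample, context) group.
#'
#' @param sites `SiteTable` data.frame.
#' @param regions Region data.frame from [extract_regions()] (row order
#'   defines `region_id`).
#' @param params [mr_params()] object.
#' @return MR data.frame with list columns `sites` and `levels`.
#' @export
find_mrs_adjacency <- function(sites, regions, params = mr_params()) {
  .find_mrs(sites, regions, params, mode = "adjacency")
}

#' Find methylated regions by fixed-size window tiling
#'
#' Each region is tiled into consecutive non-overlapping windows of
#' `window_size` bp anchored at the region start; sites falling in a window
#' form a candidate MR, subject to the same minimum-count filter.
#'
#' @inheritParams find_mrs_adjacency
#' @return MR data.frame.
#' @export
find_mrs_windows <- function(sites, regions, params = mr_params(use_windows = TRUE)) {
  .find_mrs(sites, regions, params, mode = "windows")
}

.find_mrs <- function(sites, regions, params, mode) {
  if (nrow(sites) == 0L || nrow(regions) == 0L) return(.empty_mrs())
  out <- list()
  groups <- unique(sites[c("sample_id", "context")])
  for (g in seq_len(nrow(groups))) {
    sub <- sites[sites$sample_id == groups$sample_id[g] &
                 sites$context == groups$context[g], , drop = FALSE]
    idx <- .sites_in_regions(sub, regions)
    for (ri in seq_along(idx)) {
      si <- idx[[ri]]
      if (is.null(si) || length(si) == 0L) next
      region <- regions[ri, ]
      nmin <- min_sites_for_class(params, region$region_class)
      pos <- sub$pos[si]; lev <- sub$level[si]
      o <- order(pos); pos <- pos[o]; lev <- lev[o]
      cl <- if (mode == "adjacency") {
        cumsum(c(0L, diff(pos) > params$max_gap))
      } else {
        (pos - region$start) %/% params$window_size
      }
      for (k in unique(cl)) {
        sel <- cl == k
        if (sum(sel) < nmin) next
        out[[length(out) + 1L]] <- .mr_row(region, ri, pos[sel], lev[sel],
                                           groups$context[g], groups$sample_id[g])
      }
    }
  }
  if (length(out) == 0L) return(.empty_mrs())
  res <- do.call(rbind, out)
  res <- res[order(res$context, res$sample_id, res$region_class, res$chrom,
                   res$start, res$end, res$region_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Sign sequence of consecutive level changes in an MR
#'
#' @param levels Numeric level vector in coordinate order.
#' @return Integer vector of signs (+1, -1, 0) of consecutive differences;
#'   empty for a single-site MR.
#' @export
trend_vector <- function(levels) {
  if (length(levels) < 2L) return(integer(0))
  as.integer(sign(diff(levels)))
}

#' Is an MR "same-trend"?
#'
#' TRUE when all nonzero signs of consecutive level changes are identical;
#' zero differences are compatible with any trend, so a flat MR is
#' same-trend vacuously.
#'
#' @param levels Numeric level vector in coordinate order.
#' @return Logical.
#' @export
is_same_trend <- function(levels) {
  s <- trend_vector(levels)
  s <- s[s != 0L]
  length(unique(s)) <= 1L
}

#' Export / import MRs as a BED-like TSV
#'
#' Columns: chrom, start, end, region_class, gene_name, region_id, context,
#' sample_id, n_sites, comma-joined positions, comma-joined levels.
#'
#' @param mrs MR data.frame.
#' @param path TSV path.
#' @return `write_mrs`: path invisibly; `read_mrs`: the MR data.frame.
#' @export
write_mrs <- function(mrs, path) {
  flat <- mrs
  flat$sites <- vapply(mrs$sites, function(p) paste(p, collapse = ","), character(1))
  flat$levels <- vapply(mrs$levels, function(l) paste(sprintf("%.17g", l), collapse = ","),
                        character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mrs
#' @export
read_mrs <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  if (nrow(df) == 0L) return(.empty_mrs())
  out <- data.frame(chrom = df$chrom, start = as.integer(df$start),
                    end = as.integer(df$end), region_class = df$region_class,
                    gene_name = ifelse(is.na(df$gene_name), "", df$gene_name),
                    region_id = as.integer(df$region_id), context = df$context,
                    sample_id = df$sample_id, n_sites = as.integer(df$n_sites),
                    sites = I(lapply(strsplit(df$sites, ","), as.integer)),
                    levels = I(lapply(strsplit(df$levels, ","), as.numeric)),
                    stringsAsFactors = FALSE)
  out
}
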