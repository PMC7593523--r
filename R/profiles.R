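# Genome-wide statistical summaries: relative density of significantly
# modified sites per region class, hyper/hypo DMR percentages, smoothed
# TSS-gene-TES meta-profiles, and per-MR site plots.

#' Relative density of significantly modified sites per region class
#'
#' Counts sites whose level strictly exceeds `level_threshold` (by
#' convention 1 for HMST tag-ratio levels, 0.5 for WGBS/RRBS fractions)
#' inside the merged footprint of each region class, and normalizes per
#' megabase of class footprint. Classes with zero footprint are dropped
#' with a message.
#'
#' @param sites `SiteTable` data.frame (one sample/context).
#' @param regions Region data.frame.
#' @param level_threshold Strict lower threshold on the level.
#' @return data.frame: `region_class`, `n_sites`, `bases`,
#'   `density_per_mb`.
#' @export
relative_density <- function(sites, regions, level_threshold = 1) {
  sig <- sites[sites$level > level_threshold, , drop = FALSE]
  out <- list()
  for (cls in unique(regions$region_class)) {
    r <- regions[regions$region_class == cls, , drop = FALSE]
    bases <- 0
    n <- 0L
    for (chrom in unique(r$chrom)) {
      m <- merge_intervals(r$start[r$chrom == chrom], r$end[r$chrom == chrom])
      bases <- bases + sum(m$end - m$start)
      p <- sig$pos[sig$chrom == chrom]
      if (length(p) && nrow(m)) {
        inside <- vapply(p, function(x) any(x >= m$start & x < m$end), logical(1))
        n <- n + sum(inside)
      }
    }
    if (bases == 0) {
      message("region class ", cls, " has zero footprint; density omitted")
      next
    }
    out[[length(out) + 1L]] <- data.frame(region_class = cls, n_sites = n,
                                          bases = bases,
                                          density_per_mb = n / (bases / 1e6),
                                          stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(region_class = character(0), n_sites = integer(0),
               bases = numeric(0), density_per_mb = numeric(0))
  }
  res <- res[order(res$region_class), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hyper/hypo DMR percentages per region class
#'
#' @param annotated `annotated_dmrs` object.
#' @return data.frame per class x context with `n_hyper`, `n_hypo`,
#'   `pct_hyper`, `pct_hypo` (rows sum to 100); classes with zero DMRs are
#'   absent.
#' @export
direction_percentages <- function(annotated) {
  d <- annotated$dmrs
  d <- d[d$direction %in% c("hyper", "hypo"), , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(context = character(0), region_class = character(0),
                      n_hyper = integer(0), n_hypo = integer(0),
                      pct_hyper = numeric(0), pct_hypo = numeric(0)))
  }
  key <- unique(d[c("context", "region_class")])
  out <- list()
  for (i in seq_len(nrow(key))) {
    sel <- d$context == key$context[i] & d$region_class == key$region_class[i]
    nh <- sum(d$direction[sel] == "hyper")
    nl <- sum(d$direction[sel] == "hypo")
    out[[i]] <- data.frame(context = key$context[i],
                           region_class = key$region_class[i],
                           n_hyper = nh, n_hypo = nl,
                           pct_hyper = 100 * nh / (nh + nl),
                           pct_hypo = 100 * nl / (nh + nl),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$context, res$region_class), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' TSS-gene-TES meta-profile of methylation levels
#'
#' Rescales every gene's TSS, gene-body and TES regions to fixed-length
#' sub-axes of `n_bins` bins each (transcription direction left to right;
#' '-'-strand genes are flipped), places the gene's MR sites on that axis,
#' fills each bin by one-dimensional nearest-neighbour interpolation
#' (exact at observed sites, extending to the ends), and averages over
#' genes. Genes without sites are excluded from the denominator.
#'
#' @param mrs MR data.frame restricted to one sample and context
#'   (TSS/gene_body/TES classes are used).
#' @param regions Region data.frame (provides each gene's segment bounds
#'   and strand).
#' @param n_bins Bins per segment (default 100).
#' @return List of class `profile_grid`: `bin` (1..3*n_bins), `segment`
#'   labels, `value` (per-bin mean), `n_genes`.
#' @export
meta_profile <- function(mrs, regions, n_bins = 100) {
  segs <- c("TSS", "gene_body", "TES")
  mrs <- mrs[mrs$region_class %in% segs, , drop = FALSE]
  total_bins <- 3L * n_bins
  centers <- (seq_len(total_bins) - 0.5) / n_bins  # axis coordinate in [0, 3)
  genes <- unique(mrs$gene_name)
  genes <- genes[genes != ""]
  acc <- numeric(total_bins)
  n_used <- 0L
  for (gene in genes) {
    coords <- numeric(0); levs <- numeric(0)
    gm <- mrs[mrs$gene_name == gene, , drop = FALSE]
    strand <- NA_character_
    for (i in seq_len(nrow(gm))) {
      seg_i <- match(gm$region_class[i], segs) - 1L
      reg <- regions[regions$gene_name == gene &
                     regions$region_class == gm$region_class[i] &
                     regions$chrom == gm$chrom[i], , drop = FALSE]
      if (nrow(reg) == 0L) next
      reg <- reg[1, ]
      strand <- reg$strand
      frac <- (gm$sites[[i]] - reg$start) / (reg$end - reg$start)
      if (reg$strand == "-") frac <- 1 - frac
      coords <- c(coords, seg_i + frac)
      levs <- c(levs, gm$levels[[i]])
    }
    if (length(coords) == 0L) next
    # region_class labels are already transcription-relative (a '-' gene's
    # TSS region sits at its high-coordinate end), so only the
    # within-segment fraction needed flipping above
    nn <- vapply(centers, function(x) levs[which.min(abs(coords - x))], numeric(1))
    acc <- acc + nn
    n_used <- n_used + 1L
  }
  value <- if (n_used > 0L) acc / n_used else rep(NA_real_, total_bins)
  structure(list(bin = seq_len(total_bins),
                 segment = rep(segs, each = n_bins),
                 value = value, n_genes = n_used, n_bins = n_bins),
            class = "profile_grid")
}

#' Smooth a profile: centred moving average, then 1-D Gaussian filter
#'
#' The moving average is `MA_t = (1/n) * sum_{i=-n/2..n/2} A_{t+i}` with
#' reflective edge padding; an even window is widened by one for symmetry.
#' The Gaussian filter uses a normalized kernel truncated at 4 sigma, also
#' with reflective padding; `sigma = 0` skips it. Both steps are linear and
#' preserve constants; output length equals input length.
#'
#' @param values Numeric vector.
#' @param window_n Moving-average window size (default 3).
#' @param sigma Gaussian standard deviation in bins (default 2; 0 = off).
#' @return Smoothed numeric vector.
#' @export
smooth_profile <- function(values, window_n = 3, sigma = 2) {
  stopifnot(window_n >= 1, sigma >= 0)
  n <- length(values)
  if (window_n > n) {
    message("moving-average window clipped from ", window_n, " to vector length ", n)
    window_n <- n
  }
  if (window_n %% 2 == 0) window_n <- window_n + 1
  out <- .reflect_convolve(values, rep(1 / window_n, window_n))
  if (sigma > 0) {
    radius <- ceiling(4 * sigma)
    k <- stats::dnorm(seq(-radius, radius), sd = sigma)
    k <- k / sum(k)
    if (length(k) > 2 * n - 1) {  # degenerate: kernel wider than padded signal
      radius <- n - 1
      k <- stats::dnorm(seq(-radius, radius), sd = sigma)
      k <- k / sum(k)
    }
    out <- .reflect_convolve(out, k)
  }
  out
}

# symmetric convolution with edge-repeating mirror padding
.reflect_convolve <- function(x, kernel) {
  n <- length(x)
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(x * kernel)
  left <- x[pmin(pmax(r:1, 1L), n)]
  right <- x[pmin(pmax(n:(n - r + 1L), 1L), n)]
  padded <- c(left, x, right)
  out <- numeric(n)
  for (t in seq_len(n)) {
    out[t] <- sum(padded[t:(t + 2L * r)] * kernel)
  }
  out
}

#' Plot a paired MR's per-site levels and export the plot data
#'
#' Draws original levels as diamonds and imputed levels as circles for the
#' case and control condition, titled
#' `chrom:start:end:strand:gene p=<p-value>`, and writes a sibling TSV of
#' the plotted values so the figure can be regenerated externally.
#'
#' @param pair Paired-MR record from [pair_mrs()].
#' @param out_path Figure path (`.pdf` or `.png`); the data table goes to
#'   the same path with extension `.tsv`.
#' @param p_value Optional P-value(s) to put in the title.
#' @param strand Strand label for the title (default `"."`).
#' @return Invisibly, the plotted data.frame.
#' @export
plot_mr_sites <- function(pair, out_path, p_value = NULL, strand = ".") {
  k <- length(pair$positions)
  df <- data.frame(position = pair$positions,
                   case_level = pair$case_levels[seq_len(k)],
                   control_level = pair$control_levels[seq_len(k)],
                   case_imputed = pair$case_imputed[seq_len(k)],
                   control_imputed = pair$control_imputed[seq_len(k)],
                   stringsAsFactors = FALSE)
  tsv_path <- sub("\\.[A-Za-z]+$", ".tsv", out_path)
  .write_tsv(df, tsv_path)
  title <- sprintf("%s:%d:%d:%s:%s", pair$chrom, pair$start, pair$end, strand,
                   if (pair$gene_name == "") "NA" else pair$gene_name)
  if (!is.null(p_value)) {
    title <- paste0(title, " p=", paste(signif(p_value, 3), collapse = ","))
  }
  ext <- tolower(sub(".*\\.", "", out_path))
  if (ext == "png") grDevices::png(out_path, width = 800, height = 500) else
    grDevices::pdf(out_path, width = 8, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  ylim <- range(c(df$case_level, df$control_level), finite = TRUE)
  graphics::plot(NA, xlim = range(df$position), ylim = ylim,
                 xlab = "position (bp)", ylab = "methylation level",
                 main = title)
  pch_case <- ifelse(df$case_imputed, 21, 23)      # circle imputed, diamond original
  pch_ctrl <- ifelse(df$control_imputed, 21, 23)
  graphics::points(df$position, df$control_level, pch = pch_ctrl,
                   bg = ifelse(df$control_imputed, "skyblue", "orange"), cex = 1.4)
  graphics::points(df$position, df$case_level, pch = pch_case,
                   bg = ifelse(df$case_imputed, "green3", "red"), cex = 1.4)
  graphics::legend("topright", pch = c(23, 21, 23, 21),
                   pt.bg = c("red", "green3", "orange", "skyblue"),
                   legend = c("case original", "case imputed",
                              "control original", "control imputed"),
                   bty = "n", cex = 0.8)
  invisible(df)
}
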