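# Per-site methylation input: HMST-seq three-library tag counts and
# WGBS/RRBS per-base levels, plus across-sample normalization, tag-ratio
# level computation and coverage QC.

#' Read HMST-seq per-site tag counts for the three libraries
#'
#' The three libraries are MspI (unmodified + 5mC + 5hmC), BGT
#' (beta-GT glucosylation then MspI: unmodified + 5mC) and HpaII
#' (unmodified only); their tag-count ratios yield 5mC and 5hmC levels at
#' CCGG sites. Sites with all three counts zero carry no signal and are
#' dropped. Positions are treated as 0-based.
#'
#' @param path TSV path. A header line is auto-detected.
#' @param sample_id,condition Sample label and `"case"`/`"control"`.
#' @param columns Named integer vector giving the column index of `chrom`,
#'   `pos`, `mspI`, `bgt`, `hpaII` (defaults 1..5).
#' @return data.frame (`TagCountTable`): `chrom`, `pos`, `count_mspI`,
#'   `count_bgt`, `count_hpaII`, `sample_id`, `condition`.
#' @export
read_hmst_tags <- function(path, sample_id, condition = c("case", "control"),
                           columns = c(chrom = 1, pos = 2, mspI = 3, bgt = 4, hpaII = 5)) {
  condition <- match.arg(condition)
  need <- c("chrom", "pos", "mspI", "bgt", "hpaII")
  missing_cols <- setdiff(need, names(columns))
  if (length(missing_cols)) {
    stop("column mapping lacks: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) == 1L) {
    raw <- utils::read.table(path, header = FALSE, quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
  }
  if (ncol(raw) < max(columns)) {
    stop(sprintf("%s: expected >= %d columns, found %d", path, max(columns), ncol(raw)),
         call. = FALSE)
  }
  # header auto-detection: a non-numeric pos field on row 1
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw[1, columns[["pos"]]])))) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      count_mspI = numeric(0), count_bgt = numeric(0),
                      count_hpaII = numeric(0), sample_id = character(0),
                      condition = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    chrom = as.character(raw[[columns[["chrom"]]]]),
    pos = as.integer(as.numeric(raw[[columns[["pos"]]]])),
    count_mspI = as.numeric(raw[[columns[["mspI"]]]]),
    count_bgt = as.numeric(raw[[columns[["bgt"]]]]),
    count_hpaII = as.numeric(raw[[columns[["hpaII"]]]]),
    stringsAsFactors = FALSE)
  cnts <- as.matrix(df[c("count_mspI", "count_bgt", "count_hpaII")])
  if (any(!is.finite(cnts))) stop(path, ": non-numeric tag count", call. = FALSE)
  if (any(cnts < 0)) stop(path, ": negative tag count", call. = FALSE)
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop(path, ": duplicated site(s): ", paste(utils::head(dups, 5), collapse = "; "),
         call. = FALSE)
  }
  df <- df[rowSums(cnts) > 0, , drop = FALSE]
  df$sample_id <- sample_id
  df$condition <- condition
  rownames(df) <- NULL
  df
}

#' Quantile-normalize tag counts across samples
#'
#' Within each library column, each sample's values are replaced by the
#' across-sample mean of the values at the same rank, so every sample ends
#' up with the same sorted multiset per column. Samples of unequal size are
#' interpolated onto a common quantile grid. Ranks (and hence within-sample
#' order) are preserved.
#'
#' @param tables List of `TagCountTable` data.frames (one per sample).
#' @return The list with normalized count columns.
#' @export
quantile_normalize <- function(tables) {
  if (length(tables) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged",
            call. = FALSE)
    return(tables)
  }
  for (col in c("count_mspI", "count_bgt", "count_hpaII")) {
    vals <- lapply(tables, `[[`, col)
    norm <- .qn_vectors(vals)
    for (i in seq_along(tables)) tables[[i]][[col]] <- norm[[i]]
  }
  tables
}

.qn_vectors <- function(vals) {
  L <- max(lengths(vals))
  pp <- (seq_len(L) - 0.5) / L
  qs <- vapply(vals, function(v) {
    n <- length(v); sv <- sort(v)
    if (n == L) sv else stats::approx((seq_len(n) - 0.5) / n, sv, xout = pp, rule = 2)$y
  }, numeric(L))
  ref <- rowMeans(qs)
  lapply(vals, function(v) {
    n <- length(v)
    tgt <- if (n == L) ref else stats::approx(pp, ref, xout = (seq_len(n) - 0.5) / n, rule = 2)$y
    r <- rank(v, ties.method = "average")
    if (n == 1L) return(tgt[1])
    stats::approx(seq_len(n), tgt, xout = r)$y
  })
}

.empty_sites <- function() {
  data.frame(chrom = character(0), pos = integer(0), level = numeric(0),
             context = character(0), sample_id = character(0),
             condition = character(0), stringsAsFactors = FALSE)
}

#' Convert HMST tag counts to 5mC and 5hmC levels
#'
#' The 5mC level at a site is `BGT / HpaII` and the 5hmC level is
#' `MspI / BGT`; a zero denominator is guarded by `max(denominator,
#' epsilon)` so fully methylated sites (HpaII = 0) are retained rather than
#' discarded. A site is emitted for a context only when the respective
#' numerator is positive.
#'
#' @param table `TagCountTable` data.frame.
#' @param epsilon Positive denominator guard, in normalized tag counts.
#' @return `SiteTable` data.frame with a `context` column (`"5mC"` /
#'   `"5hmC"`): `chrom`, `pos`, `level`, `context`, `sample_id`,
#'   `condition`.
#' @export
tags_to_levels <- function(table, epsilon = 1) {
  stopifnot(epsilon > 0)
  if (nrow(table) == 0L) return(.empty_sites())
  mk <- function(num, den, context) {
    keep <- num > 0
    if (!any(keep)) return(.empty_sites())
    data.frame(chrom = table$chrom[keep], pos = table$pos[keep],
               level = num[keep] / pmax(den[keep], epsilon),
               context = context, sample_id = table$sample_id[keep],
               condition = table$condition[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(mk(table$count_bgt, table$count_hpaII, "5mC"),
               mk(table$count_mspI, table$count_bgt, "5hmC"))
  out <- out[order(out$context, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read WGBS/RRBS per-base methylation levels (BED-like)
#'
#' Accepts `chrom, pos, level` (3 columns) or `chrom, start, end, level`
#' (4+ columns; the methylated base is the BED start). Levels are
#' normalized to the 0-1 scale; with `scale = "auto"` the file is treated
#' as percent when any level exceeds 1.
#'
#' @param path File path.
#' @param sample_id,condition Sample label and `"case"`/`"control"`.
#' @param scale `"auto"`, `"fraction"` or `"percent"`.
#' @return `SiteTable` data.frame with `context = "5mC"`.
#' @export
read_bed_levels <- function(path, sample_id, condition = c("case", "control"),
                            scale = c("auto", "fraction", "percent")) {
  condition <- match.arg(condition)
  scale <- match.arg(scale)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(.empty_sites())
  raw <- utils::read.table(text = lines, header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop(path, ": need >= 3 columns (chrom, pos[, end], level)", call. = FALSE)
  level_col <- if (ncol(raw) == 3L) 3L else 4L
  level <- as.numeric(raw[[level_col]])
  if (any(!is.finite(level))) stop(path, ": non-numeric methylation level", call. = FALSE)
  if (scale == "auto") scale <- if (any(level > 1)) "percent" else "fraction"
  hi <- if (scale == "percent") 100 else 1
  if (any(level < 0 | level > hi)) {
    stop(sprintf("%s: methylation level outside [0, %g] for scale '%s'", path, hi, scale),
         call. = FALSE)
  }
  if (scale == "percent") level <- level / 100
  data.frame(chrom = as.character(raw[[1]]), pos = as.integer(raw[[2]]),
             level = level, context = "5mC", sample_id = sample_id,
             condition = condition, stringsAsFactors = FALSE)
}

#' Coverage quality-control summary
#'
#' Reliable DMR prediction wants the bulk of sites at or above ~15X; a
#' warning is emitted for any sample with under half its sites at the
#' threshold.
#'
#' @param counts Named list of per-site read-count vectors, one per sample.
#' @param threshold Coverage threshold (inclusive; default 15).
#' @return data.frame per sample: `sample_id`, `mean_count`,
#'   `median_count`, `frac_ge_threshold`.
#' @export
coverage_summary <- function(counts, threshold = 15) {
  if (length(counts) == 0L) stop("no samples supplied", call. = FALSE)
  if (is.numeric(counts)) counts <- list(sample = counts)
  out <- lapply(names(counts), function(id) {
    v <- counts[[id]]
    if (length(v) == 0L) stop("empty count vector for sample ", id, call. = FALSE)
    if (any(v < 0)) stop("negative read count for sample ", id, call. = FALSE)
    frac <- mean(v >= threshold)
    if (frac < 0.5) {
      warning(sprintf("sample %s: only %.1f%% of sites at >= %gX coverage", id,
                      100 * frac, threshold), call. = FALSE)
    }
    data.frame(sample_id = id, mean_count = mean(v),
               median_count = stats::median(v), frac_ge_threshold = frac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read a site table (exact round trip)
#'
#' Levels are serialized with 17 significant digits so doubles survive the
#' text round trip bit-exactly.
#'
#' @param sites `SiteTable` data.frame.
#' @param path TSV path.
#' @return `write_site_table`: the path, invisibly. `read_site_table`: the
#'   data.frame.
#' @export
write_site_table <- function(sites, path) {
  out <- sites
  out$level <- sprintf("%.17g", sites$level)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  df <- .read_tsv(path, colClasses = c(chrom = "character", pos = "integer",
                                       level = "numeric", context = "character",
                                       sample_id = "character",
                                       condition = "character"))
  df
}
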