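# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All genomic coordinates are 0-based half-open [start, end) internally.
# IRanges is 1-based closed; these two converters are the only place the
# off-by-one lives.
.to_iranges <- function(start, end) {
  keep <- end > start
  IRanges::IRanges(start = as.integer(start[keep]) + 1L, end = as.integer(end[keep]))
}

.from_iranges <- function(ir) {
  data.frame(start = BiocGenerics_start(ir) - 1L, end = BiocGenerics_end(ir))
}

# Avoid importing BiocGenerics just for the accessors.
BiocGenerics_start <- function(x) as.integer(IRanges::start(x))
BiocGenerics_end <- function(x) as.integer(IRanges::end(x))

#' Merge a set of half-open intervals
#'
#' Collapses overlapping or bookended `[start, end)` intervals into their
#' union.
#'
#' @param start,end Integer vectors of 0-based half-open interval bounds.
#' @return A data.frame with columns `start`, `end`, sorted by `start`.
#' @keywords internal
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  .from_iranges(IRanges::reduce(.to_iranges(start, end)))
}

#' Complement of intervals within a chromosome
#'
#' @param start,end 0-based half-open intervals.
#' @param chrom_length Chromosome length in base pairs.
#' @return data.frame of the gap intervals in `[0, chrom_length)`.
#' @keywords internal
complement_intervals <- function(start, end, chrom_length) {
  ir <- IRanges::reduce(.to_iranges(pmax(start, 0L), pmin(end, chrom_length)))
  gaps <- IRanges::gaps(ir, start = 1L, end = as.integer(chrom_length))
  .from_iranges(gaps)
}

# Deterministic fixed-format number printing for byte-stable TSV outputs.
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      sprintf("%.0f", v)
    } else {
      sprintf("%.10g", v)
    }
  }, character(1))
  out
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- .fmt_num(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

.region_classes <- c("TSS", "TES", "gene_body", "five_prime_distance",
                     "intergenic", "enhancer")

# Canonical ordering applied before any table is written, so results are
# independent of the number of workers that produced them.
.canonical_order <- function(df) {
  cols <- intersect(c("context", "region_class", "chrom", "start", "end",
                      "gene_name", "sample_id", "pos"), names(df))
  if (length(cols) == 0L) return(df)
  df[do.call(order, df[cols]), , drop = FALSE]
}
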