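# Mapping called DMRs back onto the region taxonomy, per-site DMC
# extraction, and categorical table/gene-list export.

#' Annotate called DMRs into region-class buckets and a gene index
#'
#' Buckets every record by its parent region class, direction and context,
#' and builds a gene index over the gene-linked classes (TSS, TES,
#' gene body).
#'
#' @param records Tested record data.frame from [call_dmrs()] /
#'   [dmr_test()]; only rows with `is_dmr` are annotated.
#' @return List of class `annotated_dmrs`: `dmrs` (the significant
#'   records), `counts` (per class x direction x context), `gene_index`
#'   (gene name -> row indices into `dmrs`).
#' @export
annotate_dmrs <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    dmrs <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                       region_class = character(0), gene_name = character(0),
                       context = character(0), n_sites = integer(0),
                       p_value = numeric(0), p_adjusted = numeric(0),
                       rratio = numeric(0), direction = character(0),
                       test_name = character(0), pair_id = integer(0),
                       is_dmr = logical(0))
  } else {
    dmrs <- records[records$is_dmr, , drop = FALSE]
  }
  dmrs <- .canonical_order(dmrs)
  rownames(dmrs) <- NULL
  counts <- if (nrow(dmrs)) {
    as.data.frame(table(region_class = dmrs$region_class,
                        direction = dmrs$direction, context = dmrs$context),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(region_class = character(0), direction = character(0),
               context = character(0), Freq = integer(0))
  }
  names(counts)[names(counts) == "Freq"] <- "n"
  gene_rows <- which(dmrs$region_class %in% c("TSS", "TES", "gene_body") &
                     dmrs$gene_name != "")
  gene_index <- split(gene_rows, dmrs$gene_name[gene_rows])
  structure(list(dmrs = dmrs, counts = counts, gene_index = gene_index),
            class = "annotated_dmrs")
}

#' Extract differentially methylated cytosines (DMCs) from called DMRs
#'
#' Every member site of a significant DMR is emitted as a DMC carrying its
#' per-condition levels (first replicate's aligned values) and the parent
#' DMR's P-value. The promoter report lists genes whose TSS-region DMRs
#' contain at least `min_dmcs_per_promoter` DMCs.
#'
#' @param annotated `annotated_dmrs` object.
#' @param pairs Paired-MR list from [dmr_test()] (`pair_id` indexes it).
#' @param min_dmcs_per_promoter Promoter stringency threshold (default 2).
#' @return List: `dmcs` data.frame (chrom, pos, gene_name, region_class,
#'   context, case_level, control_level, case_imputed, control_imputed,
#'   p_value, direction) and `promoter_genes` data.frame (gene_name,
#'   n_dmcs).
#' @export
extract_dmcs <- function(annotated, pairs, min_dmcs_per_promoter = 2) {
  dmrs <- annotated$dmrs
  out <- list()
  for (i in seq_len(nrow(dmrs))) {
    pr <- pairs[[dmrs$pair_id[i]]]
    k <- length(pr$positions)
    out[[length(out) + 1L]] <- data.frame(
      chrom = pr$chrom, pos = pr$positions,
      gene_name = dmrs$gene_name[i], region_class = dmrs$region_class[i],
      context = dmrs$context[i],
      case_level = pr$case_levels[seq_len(k)],
      control_level = pr$control_levels[seq_len(k)],
      case_imputed = pr$case_imputed[seq_len(k)],
      control_imputed = pr$control_imputed[seq_len(k)],
      p_value = dmrs$p_value[i], direction = dmrs$direction[i],
      dmr_id = i, stringsAsFactors = FALSE)
  }
  dmcs <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(0), pos = integer(0), gene_name = character(0),
               region_class = character(0), context = character(0),
               case_level = numeric(0), control_level = numeric(0),
               case_imputed = logical(0), control_imputed = logical(0),
               p_value = numeric(0), direction = character(0),
               dmr_id = integer(0), stringsAsFactors = FALSE)
  }
  dmcs <- .canonical_order(dmcs)
  rownames(dmcs) <- NULL
  prom <- dmcs[dmcs$region_class == "TSS" & dmcs$gene_name != "", , drop = FALSE]
  if (nrow(prom)) {
    tab <- table(prom$gene_name)
    keep <- tab[tab >= min_dmcs_per_promoter]
    promoter_genes <- data.frame(gene_name = names(keep),
                                 n_dmcs = as.integer(keep),
                                 stringsAsFactors = FALSE)
    promoter_genes <- promoter_genes[order(promoter_genes$gene_name), , drop = FALSE]
  } else {
    promoter_genes <- data.frame(gene_name = character(0), n_dmcs = integer(0),
                                 stringsAsFactors = FALSE)
  }
  rownames(promoter_genes) <- NULL
  list(dmcs = dmcs, promoter_genes = promoter_genes)
}

#' Export DMR/DMC tables, BED intervals and gene lists
#'
#' Writes one TSV per region class x direction (empty placeholders
#' included), one BED6 of DMR intervals per direction (score =
#' `-10*log10(p)` capped at 1000), the gene list, the promoter-gene report
#' and the DMC table. File names are deterministic from the comparison
#' label and context, and re-export of the same set is byte-identical.
#'
#' @param annotated `annotated_dmrs` object.
#' @param dmc_set Result of [extract_dmcs()].
#' @param out_dir Output directory.
#' @param label Comparison label used in file names.
#' @return Invisibly, the vector of written paths.
#' @export
export_tables <- function(annotated, dmc_set, out_dir, label = "case_vs_control") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dmrs <- annotated$dmrs
  paths <- character(0)
  contexts <- unique(dmrs$context)
  if (length(contexts) == 0L) contexts <- "5mC"
  drop_cols <- c("pair_id", "is_dmr")
  for (ctx in contexts) {
    ctx_tag <- sub("^5", "", ctx)  # mC / hmC, keeps file names shell-friendly
    for (cls in .region_classes) {
      for (dir_ in c("hyper", "hypo")) {
        sel <- dmrs$context == ctx & dmrs$region_class == cls & dmrs$direction == dir_
        p <- file.path(out_dir, sprintf("%s_%s_%s_%s_dmrs.tsv", label, ctx_tag, cls, dir_))
        .write_tsv(dmrs[sel, setdiff(names(dmrs), drop_cols), drop = FALSE], p)
        paths <- c(paths, p)
      }
    }
    for (dir_ in c("hyper", "hypo")) {
      sel <- dmrs$context == ctx & dmrs$direction == dir_
      d <- dmrs[sel, , drop = FALSE]
      score <- if (nrow(d)) pmin(1000, round(-10 * log10(pmax(d$p_value, 1e-300)))) else integer(0)
      bed <- data.frame(chrom = d$chrom, start = d$start, end = d$end,
                        name = ifelse(d$gene_name == "",
                                      paste0(d$chrom, ":", d$start, "-", d$end),
                                      d$gene_name),
                        score = score, strand = rep(".", nrow(d)))
      p <- file.path(out_dir, sprintf("%s_%s_%s_dmrs.bed", label, ctx_tag, dir_))
      utils::write.table(bed, p, sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      paths <- c(paths, p)
    }
  }
  genes <- sort(unique(names(annotated$gene_index)))
  p <- file.path(out_dir, sprintf("%s_genes_with_dmrs.txt", label))
  writeLines(genes, p); paths <- c(paths, p)
  p <- file.path(out_dir, sprintf("%s_promoter_genes.tsv", label))
  .write_tsv(dmc_set$promoter_genes, p); paths <- c(paths, p)
  p <- file.path(out_dir, sprintf("%s_dmcs.tsv", label))
  .write_tsv(dmc_set$dmcs[, setdiff(names(dmc_set$dmcs), "dmr_id"), drop = FALSE], p)
  paths <- c(paths, p)
  invisible(paths)
}
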