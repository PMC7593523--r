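# Stage orchestration: qc, annotate_genome, preprocess, find_mrs,
# prepare_dmr, dmr_search, annotate_dmrs, summarize — with a run manifest,
# stage skipping, and chromosome-sharded parallelism whose outputs are
# canonicalized so any CPU count yields byte-identical files.

.pipeline_stages <- c("qc", "annotate_genome", "preprocess", "find_mrs",
                      "prepare_dmr", "dmr_search", "annotate_dmrs", "summarize")

#' Build a pipeline configuration
#'
#' Flag names mirror the conventional short options: `a` (adjacency),
#' `mc1`/`mc2`/`mc3` (minimum site counts), `isST` (same trend), `W`
#' (window mode), `p` (CPUs).
#'
#' @param refflat,chrom_sizes,enhancers Input annotation paths
#'   (`enhancers` optional).
#' @param case_files,control_files Methylation input paths (HMST TSV or
#'   WGBS/RRBS BED), one per sample.
#' @param dialect `"hmst"` or `"wgbs"`.
#' @param out_dir Run directory.
#' @param a,mc1,mc2,mc3,isST,W,window_size MR-search parameters
#'   (see [mr_params()]).
#' @param test,alpha,bh_correct,impute,exact_threshold DMR-test parameters
#'   (see [test_config()]).
#' @param tss_flank,tes_flank,fpd_near,fpd_far,intergenic_min,intergenic_max
#'   Region-extraction parameters.
#' @param epsilon Tag-ratio denominator guard (HMST only).
#' @param level_threshold Relative-density threshold; default 1 for HMST
#'   levels and 0.5 for WGBS/RRBS.
#' @param quantile_norm Quantile-normalize HMST tag counts across samples
#'   (only when inputs are not already normalized).
#' @param seed Seed recorded in the manifest (statistical stages are
#'   deterministic; only fixture generation draws random numbers).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(refflat, chrom_sizes, case_files, control_files,
                            out_dir, enhancers = NULL,
                            dialect = c("hmst", "wgbs"),
                            a = 2000, mc1 = 3, mc2 = 5, mc3 = 3, isST = 0,
                            W = FALSE, window_size = 200,
                            test = "ranksum", alpha = 0.05, bh_correct = FALSE,
                            impute = "zeros", exact_threshold = 10,
                            tss_flank = 1000, tes_flank = 1000,
                            fpd_near = 10000, fpd_far = 100000,
                            intergenic_min = 2000, intergenic_max = 100000,
                            epsilon = 1, level_threshold = NULL,
                            quantile_norm = FALSE, seed = 1) {
  dialect <- match.arg(dialect)
  if (is.null(level_threshold)) level_threshold <- if (dialect == "hmst") 1 else 0.5
  cfg <- list(refflat = refflat, chrom_sizes = chrom_sizes,
              enhancers = enhancers, case_files = case_files,
              control_files = control_files, out_dir = out_dir,
              dialect = dialect, a = a, mc1 = mc1, mc2 = mc2, mc3 = mc3,
              isST = isST, W = W, window_size = window_size, test = test,
              alpha = alpha, bh_correct = bh_correct, impute = impute,
              exact_threshold = exact_threshold, tss_flank = tss_flank,
              tes_flank = tes_flank, fpd_near = fpd_near, fpd_far = fpd_far,
              intergenic_min = intergenic_min, intergenic_max = intergenic_max,
              epsilon = epsilon, level_threshold = level_threshold,
              quantile_norm = quantile_norm, seed = seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a key=value configuration file into a pipeline configuration
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Multi-file keys (`case_files`, `control_files`) take comma-separated
#' values. CLI flags override file values.
#'
#' @param path Config file path.
#' @param overrides Named list applied on top of the file values.
#' @return `pipeline_config` object.
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    kv[[key]] <- val
  }
  kv[names(overrides)] <- overrides
  num_keys <- c("a", "mc1", "mc2", "mc3", "isST", "window_size", "alpha",
                "exact_threshold", "tss_flank", "tes_flank", "fpd_near",
                "fpd_far", "intergenic_min", "intergenic_max", "epsilon",
                "level_threshold", "seed")
  lgl_keys <- c("W", "bh_correct", "quantile_norm")
  for (k in intersect(names(kv), num_keys)) kv[[k]] <- as.numeric(kv[[k]])
  for (k in intersect(names(kv), lgl_keys)) {
    kv[[k]] <- tolower(as.character(kv[[k]])) %in% c("true", "yes", "1", "on")
  }
  for (k in c("case_files", "control_files")) {
    if (!is.null(kv[[k]]) && is.character(kv[[k]])) {
      kv[[k]] <- trimws(strsplit(kv[[k]], ",", fixed = TRUE)[[1]])
    }
  }
  do.call(pipeline_config, kv)
}

.manifest_path <- function(cfg) file.path(cfg$out_dir, "manifest.json")

.param_snapshot <- function(cfg) {
  snap <- unclass(cfg)
  snap$out_dir <- NULL
  snap
}

.input_digests <- function(cfg) {
  files <- c(cfg$refflat, cfg$chrom_sizes, cfg$enhancers, cfg$case_files,
             cfg$control_files)
  files <- files[!vapply(files, is.null, logical(1))]
  files <- unlist(files)
  d <- as.list(tools::md5sum(files))
  names(d) <- files
  d
}

.load_manifest <- function(cfg) {
  p <- .manifest_path(cfg)
  if (!file.exists(p)) {
    return(list(run_id = format(cfg$seed), params = .param_snapshot(cfg),
                inputs = .input_digests(cfg), seed = cfg$seed,
                stages = list()))
  }
  jsonlite::read_json(p, simplifyVector = FALSE)
}

.save_manifest <- function(cfg, manifest) {
  jsonlite::write_json(manifest, .manifest_path(cfg), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

.manifest_current <- function(cfg, manifest) {
  identical(jsonlite::toJSON(manifest$params, auto_unbox = TRUE, digits = NA),
            jsonlite::toJSON(.param_snapshot(cfg), auto_unbox = TRUE, digits = NA)) &&
    identical(unlist(manifest$inputs), unlist(.input_digests(cfg)))
}

.stage_done <- function(manifest, stage) isTRUE(manifest$stages[[stage]]$done)

.read_samples <- function(cfg) {
  read_one <- function(path, i, cond) {
    id <- paste0(cond, i)
    if (cfg$dialect == "hmst") {
      read_hmst_tags(path, sample_id = id, condition = cond)
    } else {
      read_bed_levels(path, sample_id = id, condition = cond)
    }
  }
  c(lapply(seq_along(cfg$case_files), function(i) read_one(cfg$case_files[i], i, "case")),
    lapply(seq_along(cfg$control_files), function(i) read_one(cfg$control_files[i], i, "control")))
}

.run_qc <- function(cfg) {
  dir.create(file.path(cfg$out_dir, "qc"), showWarnings = FALSE, recursive = TRUE)
  tabs <- .read_samples(cfg)
  if (cfg$dialect == "hmst") {
    counts <- list()
    for (t in tabs) {
      id <- t$sample_id[1]
      counts[[paste0(id, "_mspI")]] <- t$count_mspI
      counts[[paste0(id, "_bgt")]] <- t$count_bgt
      counts[[paste0(id, "_hpaII")]] <- t$count_hpaII
    }
    summ <- withCallingHandlers(coverage_summary(counts),
                                warning = function(w) {
                                  message("qc: ", conditionMessage(w))
                                  invokeRestart("muffleWarning")
                                })
  } else {
    # WGBS/RRBS level files carry no read counts; report site counts only
    summ <- data.frame(sample_id = vapply(tabs, function(t) t$sample_id[1], character(1)),
                       mean_count = NA_real_, median_count = NA_real_,
                       frac_ge_threshold = NA_real_,
                       n_sites = vapply(tabs, nrow, integer(1)),
                       stringsAsFactors = FALSE)
  }
  .write_tsv(summ, file.path(cfg$out_dir, "qc", "coverage_summary.tsv"))
}

.run_annotate_genome <- function(cfg) {
  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  genes <- read_refflat(cfg$refflat, sizes)
  regions <- extract_regions(genes, sizes, tss_flank = cfg$tss_flank,
                             tes_flank = cfg$tes_flank, fpd_near = cfg$fpd_near,
                             fpd_far = cfg$fpd_far,
                             intergenic_min = cfg$intergenic_min,
                             intergenic_max = cfg$intergenic_max)
  if (!is.null(cfg$enhancers)) {
    regions <- rbind(regions, read_region_bed(cfg$enhancers, "enhancer"))
  }
  write_region_beds(regions, file.path(cfg$out_dir, "regions"))
  .write_tsv(regions, file.path(cfg$out_dir, "regions", "regions_all.tsv"))
}

.load_regions <- function(cfg) {
  df <- .read_tsv(file.path(cfg$out_dir, "regions", "regions_all.tsv"),
                  colClasses = c(chrom = "character", start = "integer",
                                 end = "integer", strand = "character",
                                 region_class = "character",
                                 gene_name = "character"))
  df$gene_name[is.na(df$gene_name)] <- ""
  df
}

.run_preprocess <- function(cfg) {
  dir.create(file.path(cfg$out_dir, "sites"), showWarnings = FALSE, recursive = TRUE)
  tabs <- .read_samples(cfg)
  if (cfg$dialect == "hmst") {
    if (cfg$quantile_norm && length(tabs) >= 2) tabs <- quantile_normalize(tabs)
    sites <- do.call(rbind, lapply(tabs, tags_to_levels, epsilon = cfg$epsilon))
  } else {
    sites <- do.call(rbind, tabs)
  }
  sites <- .canonical_order(sites)
  write_site_table(sites, file.path(cfg$out_dir, "sites", "sites.tsv"))
}

.mr_params_from_cfg <- function(cfg) {
  mr_params(mc1 = cfg$mc1, mc2 = cfg$mc2, mc3 = cfg$mc3, max_gap = cfg$a,
            use_windows = cfg$W, window_size = cfg$window_size,
            same_trend = cfg$isST)
}

.run_find_mrs <- function(cfg, n_cpus) {
  sites <- read_site_table(file.path(cfg$out_dir, "sites", "sites.tsv"))
  regions <- .load_regions(cfg)
  params <- .mr_params_from_cfg(cfg)
  chroms <- sort(unique(regions$chrom))
  find <- if (cfg$W) find_mrs_windows else find_mrs_adjacency
  shards <- parallel::mclapply(chroms, function(chrom) {
    ri <- which(regions$chrom == chrom)
    mrs <- find(sites[sites$chrom == chrom, , drop = FALSE],
                regions[ri, , drop = FALSE], params)
    if (nrow(mrs)) mrs$region_id <- ri[mrs$region_id]  # global region ids
    mrs
  }, mc.cores = n_cpus)
  mrs <- do.call(rbind, shards)
  if (is.null(mrs)) mrs <- .empty_mrs()
  mrs <- mrs[order(mrs$context, mrs$sample_id, mrs$region_class, mrs$chrom,
                   mrs$start, mrs$end, mrs$region_id), , drop = FALSE]
  dir.create(file.path(cfg$out_dir, "mrs"), showWarnings = FALSE, recursive = TRUE)
  write_mrs(mrs, file.path(cfg$out_dir, "mrs", "mrs.tsv"))
}

.pairs_to_df <- function(pairs) {
  if (length(pairs) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      region_class = character(0), region_id = integer(0),
                      gene_name = character(0), context = character(0),
                      positions = character(0), case_levels = character(0),
                      control_levels = character(0), case_imputed = character(0),
                      control_imputed = character(0), case_original = character(0),
                      control_original = character(0), stringsAsFactors = FALSE))
  }
  join_n <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  do.call(rbind, lapply(pairs, function(p) data.frame(
    chrom = p$chrom, start = p$start, end = p$end,
    region_class = p$region_class, region_id = p$region_id,
    gene_name = p$gene_name, context = p$context,
    positions = paste(p$positions, collapse = ","),
    case_levels = join_n(p$case_levels), control_levels = join_n(p$control_levels),
    case_imputed = paste(as.integer(p$case_imputed), collapse = ","),
    control_imputed = paste(as.integer(p$control_imputed), collapse = ","),
    case_original = join_n(p$case_original),
    control_original = join_n(p$control_original),
    stringsAsFactors = FALSE)))
}

.df_to_pairs <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    split_n <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    list(chrom = df$chrom[i], start = df$start[i], end = df$end[i],
         region_class = df$region_class[i], region_id = df$region_id[i],
         gene_name = ifelse(is.na(df$gene_name[i]), "", df$gene_name[i]),
         context = df$context[i],
         positions = as.integer(split_n(df$positions[i])),
         case_levels = split_n(df$case_levels[i]),
         control_levels = split_n(df$control_levels[i]),
         case_imputed = split_n(df$case_imputed[i]) == 1,
         control_imputed = split_n(df$control_imputed[i]) == 1,
         case_original = split_n(df$case_original[i]),
         control_original = split_n(df$control_original[i]),
         n_case_samples = 1L, n_control_samples = 1L)
  })
}

.run_prepare_dmr <- function(cfg, n_cpus) {
  mrs <- read_mrs(file.path(cfg$out_dir, "mrs", "mrs.tsv"))
  dir.create(file.path(cfg$out_dir, "pairs"), showWarnings = FALSE, recursive = TRUE)
  case_ids <- grep("^case", unique(mrs$sample_id), value = TRUE)
  chrom_ctx <- unique(mrs[c("chrom", "context")])
  o <- order(chrom_ctx$context, chrom_ctx$chrom)
  chrom_ctx <- chrom_ctx[o, , drop = FALSE]
  shards <- parallel::mclapply(seq_len(nrow(chrom_ctx)), function(i) {
    sel <- mrs$chrom == chrom_ctx$chrom[i] & mrs$context == chrom_ctx$context[i]
    sub <- mrs[sel, , drop = FALSE]
    pairs <- pair_mrs(sub[sub$sample_id %in% case_ids, , drop = FALSE],
                      sub[!(sub$sample_id %in% case_ids), , drop = FALSE],
                      impute = cfg$impute)
    .pairs_to_df(pairs)
  }, mc.cores = n_cpus)
  df <- do.call(rbind, shards)
  df <- df[order(df$context, df$chrom, df$start, df$end), , drop = FALSE]
  .write_tsv_pairs <- function(d, path) {
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_tsv_pairs(df, file.path(cfg$out_dir, "pairs", "pairs.tsv"))
}

.run_dmr_search <- function(cfg, n_cpus) {
  df <- .read_tsv(file.path(cfg$out_dir, "pairs", "pairs.tsv"),
                  colClasses = "character")
  for (col in c("start", "end", "region_id")) df[[col]] <- as.integer(df[[col]])
  pairs <- .df_to_pairs(df)
  tcfg <- test_config(test = cfg$test, exact_threshold = cfg$exact_threshold,
                      alpha = cfg$alpha, bh_correct = cfg$bh_correct,
                      impute = cfg$impute, isST = cfg$isST)
  recs <- parallel::mclapply(seq_along(pairs), function(i) {
    r <- test_mr(pairs[[i]], tcfg)
    if (!is.null(r)) r$pair_id <- i
    r
  }, mc.cores = n_cpus)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  records <- if (length(recs)) call_dmrs(do.call(rbind, recs), tcfg) else NULL
  dir.create(file.path(cfg$out_dir, "dmrs"), showWarnings = FALSE, recursive = TRUE)
  out <- if (is.null(records)) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               region_class = character(0), gene_name = character(0),
               context = character(0), n_sites = integer(0),
               p_value = numeric(0), p_adjusted = numeric(0), rratio = numeric(0),
               direction = character(0), test_name = character(0),
               pair_id = integer(0), is_dmr = logical(0))
  } else records
  out <- out[order(out$context, out$chrom, out$start, out$end), , drop = FALSE]
  .write_tsv(out, file.path(cfg$out_dir, "dmrs", "records.tsv"))
}

.read_records <- function(cfg) {
  df <- .read_tsv(file.path(cfg$out_dir, "dmrs", "records.tsv"),
                  colClasses = "character")
  if (nrow(df) == 0L) return(NULL)
  for (col in c("start", "end", "n_sites", "pair_id")) df[[col]] <- as.integer(df[[col]])
  for (col in c("p_value", "p_adjusted", "rratio")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$is_dmr <- df$is_dmr == "TRUE"
  df$gene_name[is.na(df$gene_name)] <- ""
  df
}

.run_annotate_dmrs <- function(cfg) {
  records <- .read_records(cfg)
  pairs_df <- .read_tsv(file.path(cfg$out_dir, "pairs", "pairs.tsv"),
                        colClasses = "character")
  for (col in c("start", "end", "region_id")) pairs_df[[col]] <- as.integer(pairs_df[[col]])
  pairs <- .df_to_pairs(pairs_df)
  ann <- annotate_dmrs(records)
  dmcs <- extract_dmcs(ann, pairs)
  export_tables(ann, dmcs, file.path(cfg$out_dir, "export"))
}

.run_summarize <- function(cfg) {
  dir.create(file.path(cfg$out_dir, "summary"), showWarnings = FALSE, recursive = TRUE)
  sites <- read_site_table(file.path(cfg$out_dir, "sites", "sites.tsv"))
  regions <- .load_regions(cfg)
  mrs <- read_mrs(file.path(cfg$out_dir, "mrs", "mrs.tsv"))
  records <- .read_records(cfg)
  ann <- annotate_dmrs(records)
  dens <- list()
  for (sid in sort(unique(sites$sample_id))) {
    for (ctx in sort(unique(sites$context))) {
      sub <- sites[sites$sample_id == sid & sites$context == ctx, , drop = FALSE]
      if (nrow(sub) == 0L) next
      d <- suppressMessages(relative_density(sub, regions, cfg$level_threshold))
      if (nrow(d)) {
        d$sample_id <- sid; d$context <- ctx
        dens[[length(dens) + 1L]] <- d
      }
    }
  }
  dens <- if (length(dens)) do.call(rbind, dens) else
    data.frame(region_class = character(0), n_sites = integer(0),
               bases = numeric(0), density_per_mb = numeric(0),
               sample_id = character(0), context = character(0))
  .write_tsv(.canonical_order(dens), file.path(cfg$out_dir, "summary", "relative_density.tsv"))
  .write_tsv(direction_percentages(ann),
             file.path(cfg$out_dir, "summary", "direction_percentages.tsv"))
  for (sid in sort(unique(mrs$sample_id))) {
    for (ctx in sort(unique(mrs$context))) {
      sub <- mrs[mrs$sample_id == sid & mrs$context == ctx, , drop = FALSE]
      if (nrow(sub) == 0L) next
      prof <- meta_profile(sub, regions)
      smoothed <- if (all(is.na(prof$value))) prof$value else
        smooth_profile(prof$value)
      ctx_tag <- sub("^5", "", ctx)
      .write_tsv(data.frame(bin = prof$bin, segment = prof$segment,
                            mean_level = prof$value, smoothed = smoothed),
                 file.path(cfg$out_dir, "summary",
                           sprintf("profile_%s_%s.tsv", sid, ctx_tag)))
    }
  }
  invisible(NULL)
}

#' Run one pipeline stage
#'
#' Stages must run in order; a missing prerequisite raises an error naming
#' the stage to run first. `find_mrs`, `prepare_dmr` and `dmr_search`
#' shard work across chromosomes over `n_cpus`; outputs are canonically
#' ordered before writing so any CPU count produces identical files.
#'
#' @param stage One of `qc`, `annotate_genome`, `preprocess`, `find_mrs`,
#'   `prepare_dmr`, `dmr_search`, `annotate_dmrs`, `summarize`.
#' @param cfg [pipeline_config()] object.
#' @param n_cpus Worker count for the parallel stages.
#' @return Invisibly, the updated manifest.
#' @export
run_stage <- function(stage, cfg, n_cpus = 1) {
  stage <- match.arg(stage, .pipeline_stages)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- .load_manifest(cfg)
  if (!.manifest_current(cfg, manifest)) {
    # parameters or inputs changed: restart bookkeeping
    manifest <- list(run_id = format(cfg$seed), params = .param_snapshot(cfg),
                     inputs = .input_digests(cfg), seed = cfg$seed,
                     stages = list())
  }
  prereq <- list(qc = NULL, annotate_genome = NULL, preprocess = NULL,
                 find_mrs = c("annotate_genome", "preprocess"),
                 prepare_dmr = "find_mrs", dmr_search = "prepare_dmr",
                 annotate_dmrs = "dmr_search",
                 summarize = c("find_mrs", "dmr_search"))[[stage]]
  for (pre in prereq) {
    if (!.stage_done(manifest, pre)) {
      stop(sprintf("stage '%s' requires stage '%s' to have run first", stage, pre),
           call. = FALSE)
    }
  }
  if (.stage_done(manifest, stage)) {
    message("stage ", stage, " already complete; skipping")
    return(invisible(manifest))
  }
  t0 <- proc.time()[["elapsed"]]
  switch(stage,
         qc = .run_qc(cfg),
         annotate_genome = .run_annotate_genome(cfg),
         preprocess = .run_preprocess(cfg),
         find_mrs = .run_find_mrs(cfg, n_cpus),
         prepare_dmr = .run_prepare_dmr(cfg, n_cpus),
         dmr_search = .run_dmr_search(cfg, n_cpus),
         annotate_dmrs = .run_annotate_dmrs(cfg),
         summarize = .run_summarize(cfg))
  manifest$stages[[stage]] <- list(done = TRUE,
                                   elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  .save_manifest(cfg, manifest)
  invisible(manifest)
}

#' Run the full pipeline
#'
#' Executes all stages in order (skipping any already complete under the
#' current manifest). Both 5mC and 5hmC are processed in the single run on
#' HMST input.
#'
#' @param cfg [pipeline_config()] object.
#' @param n_cpus Worker count for the parallel stages.
#' @return Invisibly, the final manifest.
#' @export
run_pipeline <- function(cfg, n_cpus = 1) {
  for (stage in .pipeline_stages) run_stage(stage, cfg, n_cpus = n_cpus)
  invisible(.load_manifest(cfg))
}
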