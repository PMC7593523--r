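# Synthetic-data generation: a small genome with gene models, HMST-seq
# three-library tag counts (or WGBS-style level files) for a case/control
# pair with planted differential loci, and paired-locus simulations for
# statistical calibration.

#' Simulate paired methylated loci for statistical calibration
#'
#' Generates `n_loci` same-locus MR pairs with shared site positions.
#' Per-site levels are Gaussian around a per-locus baseline with standard
#' deviation `noise_sd`, truncated at zero. A planted fraction of loci gets
#' a mean shift of `delta` in the case condition, with random hyper/hypo
#' sign. Defaults emulate HMST tag-ratio levels: baselines uniform on
#' 0.5-1.5, noise_sd 0.2, 8-15 sites per locus, shift 0.6 (three times the
#' noise scale).
#'
#' @param n_loci Number of paired loci.
#' @param frac_shifted Fraction of loci with a planted shift.
#' @param delta Mean level shift at planted loci.
#' @param noise_sd Per-site level standard deviation.
#' @param sites_range Integer range of sites per locus.
#' @param baseline_range Uniform range of per-locus baseline levels.
#' @param miss_rate Probability a site is unobserved in one condition
#'   (exercises imputation; default 0 = complete data).
#' @param impute Imputation strategy used when building the pairs.
#' @return List: `pairs` (paired-MR records as from [pair_mrs()]) and
#'   `truth` data.frame (`locus_id`, `shifted`, `direction`).
#' @export
simulate_paired_loci <- function(n_loci = 2000, frac_shifted = 0, delta = 0.6,
                                 noise_sd = 0.2, sites_range = c(8, 15),
                                 baseline_range = c(0.5, 1.5), miss_rate = 0,
                                 impute = "zeros") {
  n_shift <- round(n_loci * frac_shifted)
  shifted <- rep(FALSE, n_loci)
  if (n_shift > 0) shifted[sample.int(n_loci, n_shift)] <- TRUE
  dir_sign <- ifelse(stats::runif(n_loci) < 0.5, 1, -1)
  pairs <- vector("list", n_loci)
  truth <- data.frame(locus_id = seq_len(n_loci), shifted = shifted,
                      direction = ifelse(shifted,
                                         ifelse(dir_sign > 0, "hyper", "hypo"),
                                         "none"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_loci)) {
    k <- sample(seq(sites_range[1], sites_range[2]), 1)
    positions <- cumsum(c(1000L, sample(20:500, k - 1, replace = TRUE)))
    base <- stats::runif(1, baseline_range[1], baseline_range[2])
    mu_case <- base + if (shifted[i]) dir_sign[i] * delta else 0
    case_lev <- pmax(0, stats::rnorm(k, mu_case, noise_sd))
    ctrl_lev <- pmax(0, stats::rnorm(k, base, noise_sd))
    case_obs <- stats::runif(k) >= miss_rate
    ctrl_obs <- stats::runif(k) >= miss_rate
    if (!any(case_obs)) case_obs[1] <- TRUE
    if (!any(ctrl_obs)) ctrl_obs[1] <- TRUE
    ic <- .impute_vector(positions, positions[case_obs], case_lev[case_obs], impute)
    it <- .impute_vector(positions, positions[ctrl_obs], ctrl_lev[ctrl_obs], impute)
    pairs[[i]] <- list(chrom = "chrS", start = positions[1],
                       end = positions[k] + 1L, region_class = "gene_body",
                       region_id = i, gene_name = sprintf("LOCUS%04d", i),
                       context = "5mC", positions = positions,
                       case_levels = ic$levels, control_levels = it$levels,
                       case_imputed = ic$imputed, control_imputed = it$imputed,
                       case_original = case_lev[case_obs],
                       control_original = ctrl_lev[ctrl_obs],
                       n_case_samples = 1L, n_control_samples = 1L)
  }
  list(pairs = pairs, truth = truth)
}

#' Simulate a compact annotated genome
#'
#' Non-overlapping genes with alternating strand are laid down per
#' chromosome with intergenic gaps, sized so that TSS/TES flanks and gene
#' bodies are all well formed under the default region parameters.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param genes_per_chrom Genes per chromosome.
#' @return List: `genes` data.frame (refFlat fields) and `chrom_sizes`
#'   named vector.
#' @export
simulate_genome <- function(n_chroms = 3, chrom_length = 1e6, genes_per_chrom = 20) {
  genes <- list()
  for (c_i in seq_len(n_chroms)) {
    chrom <- paste0("chr", c_i)
    slot <- floor(chrom_length / genes_per_chrom)
    for (g_i in seq_len(genes_per_chrom)) {
      slot_start <- (g_i - 1L) * slot
      glen <- sample(5000:min(30000, slot - 10000), 1)
      gstart <- slot_start + sample(2000:(slot - glen - 2000), 1)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_name = sprintf("G%d_%02d", c_i, g_i),
        transcript_id = sprintf("T%d_%02d", c_i, g_i),
        chrom = chrom, strand = if (g_i %% 2 == 0) "-" else "+",
        tx_start = gstart, tx_end = gstart + glen, stringsAsFactors = FALSE)
    }
  }
  list(genes = do.call(rbind, genes),
       chrom_sizes = stats::setNames(rep(chrom_length, n_chroms),
                                     paste0("chr", seq_len(n_chroms))))
}

#' Generate a complete synthetic input file set
#'
#' Writes a refFlat gene-model file, a chromosome-sizes table, an enhancer
#' BED, case and control methylation files, and a truth table of planted
#' differential loci. Sites are placed in every gene's TSS and gene-body
#' regions (plus background intergenic sites); control levels sit around a
#' per-region baseline with Gaussian noise, and a fraction of TSS loci
#' receive a planted case shift of `delta` with random sign, independently
#' for the 5mC and 5hmC contexts. For the HMST dialect, levels are encoded
#' as three-library tag counts by inverse ratio construction
#' (`BGT = 5mC_level * HpaII`, `MspI = 5hmC_level * BGT`), so
#' [tags_to_levels()] recovers them exactly.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed; the file set is a pure function of it.
#' @param dialect `"hmst"` (tag counts) or `"wgbs"` (BED levels, 5mC only).
#' @param n_chroms,chrom_length,genes_per_chrom Genome shape.
#' @param sites_per_tss,sites_per_body Site counts per region.
#' @param frac_dmr Fraction of TSS loci with a planted shift.
#' @param delta Planted mean shift (level units).
#' @param noise_sd Per-site level noise.
#' @param baseline_range Per-region baseline level range.
#' @return Invisibly, a named list of written paths plus the truth table.
#' @export
generate_fixtures <- function(out_dir, seed = 1, dialect = c("hmst", "wgbs"),
                              n_chroms = 3, chrom_length = 1e6,
                              genes_per_chrom = 20, sites_per_tss = 10,
                              sites_per_body = 12, frac_dmr = 0.25,
                              delta = 0.6, noise_sd = 0.2,
                              baseline_range = c(0.5, 1.5)) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  gen <- simulate_genome(n_chroms, chrom_length, genes_per_chrom)
  genes <- gen$genes
  contexts <- if (dialect == "hmst") c("5mC", "5hmC") else "5mC"
  is_wgbs <- dialect == "wgbs"
  lev_scale <- if (is_wgbs) 0.5 else 1  # WGBS levels live on 0-1

  site_rows <- list()   # chrom, pos, and per-context case/control levels
  truth <- list()
  place_sites <- function(chrom, start, end, k) {
    span <- end - start
    if (span <= k + 1) return(integer(0))
    sort(sample(seq(start, end - 1L), min(k, span), replace = FALSE))
  }
  clamp <- function(v) if (is_wgbs) pmin(pmax(v, 0), 1) else pmax(v, 0)

  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tss_point <- if (g$strand == "+") g$tx_start else g$tx_end
    regs <- list(TSS = c(tss_point - 1000L, tss_point + 1000L),
                 gene_body = c(g$tx_start + 1000L, g$tx_end - 1000L))
    planted <- stats::runif(1) < frac_dmr
    plant_sign <- stats::setNames(ifelse(stats::runif(length(contexts)) < 0.5, 1, -1),
                                  contexts)
    for (rc in names(regs)) {
      k <- if (rc == "TSS") sites_per_tss else sites_per_body
      pos <- place_sites(g$chrom, regs[[rc]][1], regs[[rc]][2], k)
      if (length(pos) == 0L) next
      row <- data.frame(chrom = g$chrom, pos = pos, stringsAsFactors = FALSE)
      for (ctx in contexts) {
        base <- stats::runif(1, baseline_range[1], baseline_range[2]) * lev_scale
        shift <- if (planted && rc == "TSS") plant_sign[[ctx]] * delta * lev_scale else 0
        row[[paste0("ctrl_", ctx)]] <- clamp(stats::rnorm(length(pos), base, noise_sd * lev_scale))
        row[[paste0("case_", ctx)]] <- clamp(stats::rnorm(length(pos), base + shift,
                                                          noise_sd * lev_scale))
        if (planted && rc == "TSS") {
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = g$chrom, start = regs[[rc]][1], end = regs[[rc]][2],
            gene_name = g$gene_name, context = ctx,
            direction = if (plant_sign[[ctx]] > 0) "hyper" else "hypo",
            stringsAsFactors = FALSE)
        }
      }
      site_rows[[length(site_rows) + 1L]] <- row
    }
  }
  # low-density intergenic background
  for (c_i in seq_len(n_chroms)) {
    chrom <- paste0("chr", c_i)
    pos <- sort(sample.int(chrom_length, 200) - 1L)
    row <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    for (ctx in contexts) {
      row[[paste0("ctrl_", ctx)]] <- clamp(stats::rnorm(length(pos), 0.8 * lev_scale,
                                                        noise_sd * lev_scale))
      row[[paste0("case_", ctx)]] <- clamp(stats::rnorm(length(pos), 0.8 * lev_scale,
                                                        noise_sd * lev_scale))
    }
    site_rows[[length(site_rows) + 1L]] <- row
  }
  sites <- do.call(rbind, site_rows)
  sites <- sites[!duplicated(sites[c("chrom", "pos")]), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]

  paths <- list()
  # refFlat (11 columns; exon fields are single-exon placeholders)
  rf <- data.frame(genes$gene_name, genes$transcript_id, genes$chrom, genes$strand,
                   genes$tx_start, genes$tx_end, genes$tx_start, genes$tx_end, 1L,
                   paste0(genes$tx_start, ","), paste0(genes$tx_end, ","))
  paths$refflat <- file.path(out_dir, "genes.refFlat")
  utils::write.table(rf, paths$refflat, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$chrom_sizes <- file.path(out_dir, "chrom.sizes")
  utils::write.table(data.frame(names(gen$chrom_sizes), gen$chrom_sizes),
                     paths$chrom_sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # enhancers: one short region per chromosome in intergenic space
  enh <- data.frame(chrom = paste0("chr", seq_len(n_chroms)),
                    start = chrom_length - 5000L, end = chrom_length - 4000L)
  paths$enhancers <- file.path(out_dir, "enhancers.bed")
  utils::write.table(enh, paths$enhancers, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  write_sample <- function(cond) {
    if (dialect == "hmst") {
      hpaII <- stats::runif(nrow(sites), 5, 20)
      bgt <- sites[[paste0(cond, "_5mC")]] * hpaII
      mspI <- sites[[paste0(cond, "_5hmC")]] * bgt
      df <- data.frame(sites$chrom, sites$pos, sprintf("%.17g", mspI),
                       sprintf("%.17g", bgt), sprintf("%.17g", hpaII))
      p <- file.path(out_dir, paste0(cond, "_hmst_tags.tsv"))
    } else {
      df <- data.frame(sites$chrom, sites$pos, sites$pos + 1L,
                       sprintf("%.17g", sites[[paste0(cond, "_5mC")]]))
      p <- file.path(out_dir, paste0(cond, "_levels.bed"))
    }
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    p
  }
  paths$case <- write_sample("case")
  paths$control <- write_sample("ctrl")
  truth_df <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               gene_name = character(0), context = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  }
  truth_df <- truth_df[order(truth_df$context, truth_df$chrom, truth_df$start), ,
                       drop = FALSE]
  paths$truth <- file.path(out_dir, "truth_dmrs.tsv")
  .write_tsv(truth_df, paths$truth)
  invisible(c(paths, list(truth_table = truth_df)))
}
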