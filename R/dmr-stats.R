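# Pairing of same-locus MRs across conditions, missing-value imputation,
# differential testing (exact rank-sum enumeration / Mann-Whitney
# approximation / KS / T-test), BH correction and hyper/hypo direction
# classification by the relative ratio (rratio).

#' DMR test configuration
#'
#' @param test `"ranksum"` (exact enumeration below `exact_threshold` sites,
#'   large-sample Mann-Whitney above), `"ttest"` (two-sample, pooled
#'   variance) or `"ks"` (two-sample Kolmogorov-Smirnov).
#' @param exact_threshold Exact rank-sum enumeration is used when the
#'   number of sites in an MR (`nx`) is strictly below this (default 10).
#' @param alpha Significance threshold on the (adjusted) P-value.
#' @param bh_correct Apply Benjamini-Hochberg FDR correction across the
#'   whole record list before thresholding (off by default).
#' @param impute Missing-site strategy: `"zeros"` (default; a missing level
#'   plausibly records a real unmethylated state), `"median"` (median of
#'   the condition's observed levels in the MR) or `"nearest_neighbour"`.
#' @param isST Same-trend gate: with 1, only pairs whose case and control
#'   level sequences are each same-trend are tested.
#' @param joint_exact_rule Use the alternative small-sample gate
#'   `min(nx, ny) < 10 && nx + ny < 20` instead of `nx < exact_threshold`.
#' @return A list of class `test_config`.
#' @export
test_config <- function(test = c("ranksum", "ttest", "ks"), exact_threshold = 10,
                        alpha = 0.05, bh_correct = FALSE,
                        impute = c("zeros", "median", "nearest_neighbour"),
                        isST = 0, joint_exact_rule = FALSE) {
  test <- match.arg(test)
  impute <- match.arg(impute)
  stopifnot(alpha > 0, alpha < 1, exact_threshold >= 2, isST %in% c(0, 1))
  structure(list(test = test, exact_threshold = exact_threshold, alpha = alpha,
                 bh_correct = bh_correct, impute = impute, isST = isST,
                 joint_exact_rule = joint_exact_rule), class = "test_config")
}

# ---------------------------------------------------------------------------
# MR pairing + imputation

.impute_vector <- function(positions, obs_pos, obs_lev, strategy) {
  lev <- numeric(length(positions))
  mask <- !(positions %in% obs_pos)
  m <- match(positions, obs_pos)
  lev[!mask] <- obs_lev[m[!mask]]
  if (any(mask)) {
    fill <- switch(strategy,
      zeros = 0,
      median = stats::median(obs_lev),
      nearest_neighbour = NA)
    if (strategy == "nearest_neighbour") {
      for (i in which(mask)) {
        d <- abs(obs_pos - positions[i])
        lev[i] <- obs_lev[which.min(d)]  # ties resolved to the lower position
      }
    } else {
      lev[mask] <- fill
    }
  }
  list(levels = lev, imputed = mask)
}

# union-find for transitive merging of overlapping MRs
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Pair same-locus methylated regions across conditions
#'
#' A case MR and a control MR share a locus when their bounding intervals
#' overlap by at least 1 bp within the same parent region; all transitively
#' overlapping MRs (on either side, including replicate samples) are merged
#' into one paired locus. The paired site set is the union of positions;
#' positions a condition did not observe are imputed per the strategy, and
#' replicate samples' aligned vectors are concatenated per condition.
#' MRs without a partner on the other side are dropped (counted in the
#' `n_dropped_case` / `n_dropped_control` attributes).
#'
#' @param case_mrs,control_mrs MR data.frames from the same region class
#'   and context.
#' @param impute Imputation strategy (see [test_config()]).
#' @return List of paired-MR records; each carries the locus, the union
#'   `positions`, per-condition aligned `*_levels` with `*_imputed` masks,
#'   and the per-condition ORIGINAL (non-imputed) level vectors used by
#'   [rratio()].
#' @export
pair_mrs <- function(case_mrs, control_mrs, impute = "zeros") {
  all_mrs <- rbind(case_mrs, control_mrs)
  if (nrow(all_mrs) == 0L) {
    res <- list()
    attr(res, "n_dropped_case") <- nrow(case_mrs)
    attr(res, "n_dropped_control") <- nrow(control_mrs)
    return(res)
  }
  side <- rep(c("case", "control"), c(nrow(case_mrs), nrow(control_mrs)))
  n <- nrow(all_mrs)
  parent <- seq_len(n)
  keys <- paste(all_mrs$context, all_mrs$region_class, all_mrs$region_id)
  for (key in unique(keys)) {
    ii <- which(keys == key)
    if (length(ii) < 2L) next
    ii <- ii[order(all_mrs$start[ii], all_mrs$end[ii])]
    # sweep: link intervals that overlap >= 1 bp (half-open)
    for (a in seq_along(ii)[-1]) {
      for (b in seq_len(a - 1)) {
        i <- ii[a]; j <- ii[b]
        if (all_mrs$start[i] < all_mrs$end[j] && all_mrs$start[j] < all_mrs$end[i]) {
          ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  comps <- split(seq_len(n), roots)
  pairs <- list()
  dropped <- c(case = 0L, control = 0L)
  for (comp in comps) {
    sides <- side[comp]
    if (!("case" %in% sides) || !("control" %in% sides)) {
      for (s in sides) dropped[s] <- dropped[s] + 1L
      next
    }
    positions <- sort(unique(unlist(all_mrs$sites[comp])))
    build <- function(which_side) {
      idx <- comp[side[comp] == which_side]
      levels <- numeric(0); mask <- logical(0); original <- numeric(0)
      for (sid in sort(unique(all_mrs$sample_id[idx]))) {
        sidx <- idx[all_mrs$sample_id[idx] == sid]
        obs_pos <- unlist(all_mrs$sites[sidx])
        obs_lev <- unlist(all_mrs$levels[sidx])
        o <- order(obs_pos)
        obs_pos <- obs_pos[o]; obs_lev <- obs_lev[o]
        keep <- !duplicated(obs_pos)
        obs_pos <- obs_pos[keep]; obs_lev <- obs_lev[keep]
        imp <- .impute_vector(positions, obs_pos, obs_lev, impute)
        levels <- c(levels, imp$levels)
        mask <- c(mask, imp$imputed)
        original <- c(original, obs_lev)
      }
      list(levels = levels, imputed = mask, original = original)
    }
    cs <- build("case"); ct <- build("control")
    first <- comp[1]
    pairs[[length(pairs) + 1L]] <- list(
      chrom = all_mrs$chrom[first],
      start = min(all_mrs$start[comp]), end = max(all_mrs$end[comp]),
      region_class = all_mrs$region_class[first],
      region_id = all_mrs$region_id[first],
      gene_name = all_mrs$gene_name[first],
      context = all_mrs$context[first],
      positions = positions,
      case_levels = cs$levels, control_levels = ct$levels,
      case_imputed = cs$imputed, control_imputed = ct$imputed,
      case_original = cs$original, control_original = ct$original,
      n_case_samples = length(unique(all_mrs$sample_id[comp[side[comp] == "case"]])),
      n_control_samples = length(unique(all_mrs$sample_id[comp[side[comp] == "control"]])))
  }
  o <- order(vapply(pairs, function(p) p$chrom, character(1)),
             vapply(pairs, function(p) p$start, numeric(1)),
             vapply(pairs, function(p) p$end, numeric(1)))
  pairs <- pairs[o]
  attr(pairs, "n_dropped_case") <- dropped[["case"]]
  attr(pairs, "n_dropped_control") <- dropped[["control"]]
  pairs
}

# ---------------------------------------------------------------------------
# exact rank-sum enumeration

#' Exact two-sided Wilcoxon rank-sum P-value by full enumeration
#'
#' Computes the null distribution of the rank-sum statistic of `x` over all
#' `choose(nx+ny, nx)` assignments of the pooled mid-ranks (ties get
#' mid-ranks) using the shift algorithm (a generating-function dynamic
#' programme over integer-doubled ranks), equivalent to literally listing
#' every assignment. Two-sided P = `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#' Recommended for MRs with fewer than 10 sites, where the large-sample
#' approximation is unreliable.
#'
#' @param x,y Numeric vectors (case and control levels), each non-empty.
#' @return The two-sided exact P-value.
#' @export
exact_ranksum_p <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both vectors must be non-empty", call. = FALSE)
  nx <- length(x); n <- nx + length(y)
  r2 <- as.integer(round(2 * rank(c(x, y))))  # doubled mid-ranks: integers
  w_obs <- sum(r2[seq_len(nx)])
  max_sum <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
  # counts[k + 1, s + 1] = number of size-k subsets of processed ranks
  # with doubled-rank sum s
  counts <- matrix(0, nrow = nx + 1L, ncol = max_sum + 1L)
  counts[1L, 1L] <- 1
  for (i in seq_len(n)) {
    r <- r2[i]
    kmax <- min(i, nx)
    for (k in kmax:1) {
      src <- counts[k, 1:(max_sum + 1L - r)]
      counts[k + 1L, (r + 1L):(max_sum + 1L)] <-
        counts[k + 1L, (r + 1L):(max_sum + 1L)] + src
    }
  }
  dist <- counts[nx + 1L, ]
  total <- sum(dist)
  p_le <- sum(dist[seq_len(w_obs + 1L)]) / total
  p_ge <- sum(dist[(w_obs + 1L):(max_sum + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Monte-Carlo estimate of the two-sided rank-sum P-value
#'
#' Random permutations of the pooled mid-ranks; estimates the same
#' two-sided doubled-tail quantity as [exact_ranksum_p()]. Useful as a
#' convergence check against the large-sample approximation.
#'
#' @param x,y Numeric vectors.
#' @param n_perm Number of random assignments.
#' @return Estimated two-sided P-value.
#' @export
mc_ranksum_p <- function(x, y, n_perm = 1e5) {
  nx <- length(x); n <- nx + length(y)
  r2 <- 2 * rank(c(x, y))
  w_obs <- sum(r2[seq_len(nx)])
  w <- vapply(seq_len(n_perm), function(i) sum(r2[sample.int(n, nx)]), numeric(1))
  min(1, 2 * min(mean(w <= w_obs), mean(w >= w_obs)))
}

#' Large-sample two-sided Mann-Whitney P-value
#'
#' Normal approximation with tie and continuity correction, as provided by
#' [stats::wilcox.test()]; all-tied input returns P = 1.
#'
#' @param x,y Numeric vectors.
#' @return Two-sided P-value.
#' @export
approx_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
}

# ---------------------------------------------------------------------------
# per-pair testing, rratio, DMR calling

#' Relative ratio (rratio) of a paired MR
#'
#' `rratio = (mu_case - mu_control) / ((mu_case + mu_control) / 2)` where
#' the mu are medians of the ORIGINAL (non-imputed) levels in each
#' condition. Returns 0 when both medians are zero. Its sign labels a DMR
#' hyper- (`> 0`) or hypomethylated (`< 0`).
#'
#' @param pair Paired-MR record from [pair_mrs()].
#' @return Numeric rratio.
#' @export
rratio <- function(pair) {
  mu_case <- stats::median(pair$case_original)
  mu_ctrl <- stats::median(pair$control_original)
  if (mu_case + mu_ctrl == 0) return(0)
  (mu_case - mu_ctrl) / ((mu_case + mu_ctrl) / 2)
}

.direction_from_rratio <- function(r) {
  if (!is.finite(r) || r == 0) "none" else if (r > 0) "hyper" else "hypo"
}

#' Test one paired MR for differential methylation
#'
#' Dispatches per the configuration: the rank-sum family takes the exact
#' enumeration path when `nx` (the number of sites in the MR) is strictly
#' below `exact_threshold` and the Mann-Whitney approximation otherwise;
#' `"ks"` and `"ttest"` run the two-sided two-sample tests. A zero-variance
#' T-test (identical constant vectors) returns P = 1 by convention. With
#' `isST = 1`, pairs whose case or control original level sequence is not
#' same-trend are skipped (returns `NULL`).
#'
#' @param pair Paired-MR record.
#' @param cfg [test_config()] object.
#' @return One-row data.frame (`DmrRecord`) or `NULL` for an isST-skipped
#'   pair.
#' @export
test_mr <- function(pair, cfg = test_config()) {
  if (cfg$isST == 1 &&
      !(is_same_trend(pair$case_original) && is_same_trend(pair$control_original))) {
    return(NULL)
  }
  x <- pair$case_levels; y <- pair$control_levels
  nx <- length(pair$positions)
  ny <- length(y)
  if (cfg$test == "ranksum") {
    exact <- if (cfg$joint_exact_rule) {
      min(nx, ny) < 10 && nx + ny < 20
    } else {
      nx < cfg$exact_threshold
    }
    if (exact) {
      p <- exact_ranksum_p(x, y); test_name <- "exact_ranksum"
    } else {
      p <- approx_ranksum_p(x, y); test_name <- "mannwhitneyu"
    }
  } else if (cfg$test == "ks") {
    p <- suppressWarnings(stats::ks.test(x, y)$p.value); test_name <- "ks"
  } else {
    if (isTRUE(stats::sd(c(x, y)) == 0)) {
      p <- 1
    } else {
      p <- tryCatch(stats::t.test(x, y, var.equal = TRUE)$p.value,
                    error = function(e) 1)
    }
    test_name <- "ttest"
  }
  r <- rratio(pair)
  data.frame(chrom = pair$chrom, start = pair$start, end = pair$end,
             region_class = pair$region_class, gene_name = pair$gene_name,
             context = pair$context, n_sites = nx, p_value = p,
             p_adjusted = NA_real_, rratio = r,
             direction = .direction_from_rratio(r), test_name = test_name,
             stringsAsFactors = FALSE)
}

#' Call DMRs from tested records
#'
#' With BH correction on, P-values are adjusted over the full record list
#' and the alpha threshold applies to the adjusted values; otherwise to the
#' raw P-values. Direction comes from the rratio sign.
#'
#' @param records data.frame of tested records (rbind of [test_mr()] rows).
#' @param cfg [test_config()] object.
#' @return The records with `p_adjusted` and logical `is_dmr` columns.
#' @export
call_dmrs <- function(records, cfg = test_config()) {
  if (is.null(records) || nrow(records) == 0L) {
    return(cbind(records, is_dmr = logical(0)))
  }
  if (cfg$bh_correct) {
    records$p_adjusted <- stats::p.adjust(records$p_value, method = "BH")
    records$is_dmr <- records$p_adjusted < cfg$alpha
  } else {
    records$p_adjusted <- NA_real_
    records$is_dmr <- records$p_value < cfg$alpha
  }
  records
}

#' Pair, test and call DMRs in one step
#'
#' @param case_mrs,control_mrs MR data.frames (same context).
#' @param cfg [test_config()] object.
#' @return List with `records` (all tested records with `is_dmr`), `pairs`
#'   (the paired MRs, index-aligned via `records$pair_id`) and skip/drop
#'   counts.
#' @export
dmr_test <- function(case_mrs, control_mrs, cfg = test_config()) {
  pairs <- pair_mrs(case_mrs, control_mrs, impute = cfg$impute)
  recs <- list()
  pair_ids <- integer(0)
  n_skipped <- 0L
  for (i in seq_along(pairs)) {
    r <- test_mr(pairs[[i]], cfg)
    if (is.null(r)) { n_skipped <- n_skipped + 1L; next }
    r$pair_id <- i
    recs[[length(recs) + 1L]] <- r
  }
  records <- if (length(recs)) call_dmrs(do.call(rbind, recs), cfg) else NULL
  list(records = records, pairs = pairs, n_skipped_isST = n_skipped,
       n_dropped_case = attr(pairs, "n_dropped_case"),
       n_dropped_control = attr(pairs, "n_dropped_control"))
}
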