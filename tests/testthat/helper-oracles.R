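# Independent oracles and small fixture builders used across test files.

# Literal enumeration of every size-nx assignment of the pooled mid-ranks;
# the reference the shift-algorithm implementation must equal exactly.
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  w <- colSums(matrix(r[combs], nrow = nx))
  min(1, 2 * min(mean(w <= w_obs), mean(w >= w_obs)))
}

# Brute-force gap-graph clustering: connect every pair of sites within
# distance a, take connected components, apply the minimum-count filter.
oracle_cluster_sites <- function(pos, a, nmin) {
  if (length(pos) == 0) return(list())
  pos <- sort(pos)
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= a
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- split(pos, comp)
  Filter(function(cl) length(cl) >= nmin, out)
}

# A one-chromosome region table in the package's layout.
make_region <- function(chrom = "chr1", start = 0L, end = 100000L,
                        region_class = "gene_body", gene_name = "G1",
                        strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             region_class = region_class, gene_name = gene_name,
             stringsAsFactors = FALSE)
}

make_sites <- function(pos, level = 1, chrom = "chr1", context = "5mC",
                       sample_id = "s1", condition = "case") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
             level = rep_len(level, n), context = rep_len(context, n),
             sample_id = rep_len(sample_id, n), condition = rep_len(condition, n),
             stringsAsFactors = FALSE)
}

make_mr <- function(pos, lev, chrom = "chr1", region_class = "gene_body",
                    gene_name = "G1", region_id = 1L, context = "5mC",
                    sample_id = "case1") {
  data.frame(chrom = chrom, start = min(pos), end = max(pos) + 1L,
             region_class = region_class, gene_name = gene_name,
             region_id = region_id, context = context, sample_id = sample_id,
             n_sites = length(pos), sites = I(list(as.integer(pos))),
             levels = I(list(lev)), stringsAsFactors = FALSE)
}

# Random level vectors with a controlled amount of ties.
random_tied_vector <- function(n, tie_prob = 0.5) {
  if (stats::runif(1) < tie_prob) {
    sample(seq_len(max(2, n %/% 2)), n, replace = TRUE) / 2
  } else {
    round(stats::rnorm(n), 3)
  }
}
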