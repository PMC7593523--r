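# MR pairing with imputation, the exact rank-sum enumeration, test
# dispatch, rratio classification and DMR calling.

test_that("pairing aligns union positions and imputes the missing condition", {
  case <- make_mr(c(100, 300), c(0.8, 0.9))
  ctrl <- make_mr(100, 0.1, sample_id = "control1")
  pz <- pair_mrs(case, ctrl, impute = "zeros")
  expect_length(pz, 1)
  p <- pz[[1]]
  expect_equal(p$positions, c(100L, 300L))
  expect_equal(p$control_levels, c(0.1, 0))
  expect_equal(p$control_imputed, c(FALSE, TRUE))
  expect_equal(p$case_imputed, c(FALSE, FALSE))

  pm <- pair_mrs(case, ctrl, impute = "median")[[1]]
  expect_equal(pm$control_levels, c(0.1, 0.1))

  pn <- pair_mrs(case, make_mr(c(100, 600), c(0.1, 0.5), sample_id = "control1"),
                 impute = "nearest_neighbour")[[1]]
  expect_equal(pn$positions, c(100L, 300L, 600L))
  expect_equal(pn$control_levels[2], 0.1)  # nearest observed neighbour

  ident <- pair_mrs(make_mr(c(1, 2, 3), c(.1, .2, .3)),
                    make_mr(c(1, 2, 3), c(.4, .5, .6), sample_id = "control1"))[[1]]
  expect_false(any(ident$case_imputed) || any(ident$control_imputed))
})

test_that("unpaired MRs are dropped and counted", {
  case <- rbind(make_mr(c(100, 300), c(1, 1)),
                make_mr(c(9000, 9100), c(1, 1)))
  ctrl <- make_mr(c(150, 350), c(1, 1), sample_id = "control1")
  pr <- pair_mrs(case, ctrl)
  expect_length(pr, 1)
  expect_equal(attr(pr, "n_dropped_case"), 1L)
  expect_equal(attr(pr, "n_dropped_control"), 0L)
})

test_that("replicate samples concatenate aligned level vectors per condition", {
  case <- rbind(make_mr(c(100, 300), c(0.8, 0.9), sample_id = "case1"),
                make_mr(c(100, 200), c(0.7, 0.6), sample_id = "case2"))
  ctrl <- make_mr(c(150, 250), c(0.2, 0.3), sample_id = "control1")
  p <- pair_mrs(case, ctrl)[[1]]
  expect_equal(p$positions, c(100L, 150L, 200L, 250L, 300L))
  expect_length(p$case_levels, 10)   # 2 replicates x 5 positions
  expect_length(p$control_levels, 5)
  expect_equal(p$n_case_samples, 2L)
})

test_that("exact rank-sum enumeration reproduces hand-derived P-values", {
  expect_equal(exact_ranksum_p(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(exact_ranksum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(exact_ranksum_p(c(5, 5), c(5, 5)), 1)
  # fully tied two-group case, checked against the listing oracle
  x <- c(1, 1, 1, 1); y <- c(0, 0, 0, 0)
  expect_equal(exact_ranksum_p(x, y), oracle_ranksum_p(x, y))
  expect_equal(exact_ranksum_p(x, y), 2 / choose(8, 4) * 1)
  expect_error(exact_ranksum_p(numeric(0), 1), "non-empty")
})

test_that("exact enumeration equals the listing oracle on random tied inputs", {
  set.seed(21)
  for (rep in 1:120) {
    nx <- sample(1:7, 1); ny <- sample(1:7, 1)
    x <- random_tied_vector(nx); y <- random_tied_vector(ny)
    expect_identical(exact_ranksum_p(x, y), oracle_ranksum_p(x, y))
  }
})

test_that("rank-sum dispatch switches from exact to approximation at the threshold", {
  set.seed(22)
  mk_pair <- function(k) {
    pos <- seq_len(k) * 100L
    pair_mrs(make_mr(pos, stats::runif(k)),
             make_mr(pos, stats::runif(k), sample_id = "control1"))[[1]]
  }
  r9 <- test_mr(mk_pair(9), test_config())
  expect_equal(r9$test_name, "exact_ranksum")
  r10 <- test_mr(mk_pair(10), test_config())
  expect_equal(r10$test_name, "mannwhitneyu")
  # the alternative joint small-sample rule
  r10j <- test_mr(mk_pair(9), test_config(joint_exact_rule = TRUE))
  expect_equal(r10j$test_name, "exact_ranksum")  # min(9,9)<10 and 18<20
  r10k <- test_mr(mk_pair(10), test_config(joint_exact_rule = TRUE))
  expect_equal(r10k$test_name, "mannwhitneyu")   # 10+10 >= 20
})

test_that("identical vectors give P = 1 under every test", {
  pos <- c(100L, 200L, 300L, 400L)
  pair <- pair_mrs(make_mr(pos, c(.1, .2, .3, .4)),
                   make_mr(pos, c(.1, .2, .3, .4), sample_id = "control1"))[[1]]
  expect_equal(test_mr(pair, test_config("ranksum"))$p_value, 1)
  expect_equal(test_mr(pair, test_config("ks"))$p_value, 1)
  flat <- pair_mrs(make_mr(pos, rep(.5, 4)),
                   make_mr(pos, rep(.5, 4), sample_id = "control1"))[[1]]
  expect_equal(test_mr(flat, test_config("ttest"))$p_value, 1)  # zero variance
})

test_that("rank-based P-values are invariant under monotone level transforms", {
  set.seed(23)
  pos <- seq_len(8) * 50L
  x <- stats::rlnorm(8); y <- stats::rlnorm(8)
  mk <- function(f) pair_mrs(make_mr(pos, f(x)),
                             make_mr(pos, f(y), sample_id = "control1"))[[1]]
  for (tn in c("ranksum", "ks")) {
    p0 <- test_mr(mk(identity), test_config(tn))$p_value
    expect_equal(test_mr(mk(function(v) v^3), test_config(tn))$p_value, p0)
    expect_equal(test_mr(mk(function(v) log1p(v)), test_config(tn))$p_value, p0)
  }
})

test_that("the same-trend gate skips mixed-trend pairs before testing", {
  pos <- c(100L, 200L, 300L)
  mono <- make_mr(pos, c(.1, .4, .9))
  mixed <- make_mr(pos, c(.1, .9, .4), sample_id = "control1")
  expect_null(test_mr(pair_mrs(mono, mixed)[[1]], test_config(isST = 1)))
  mono_ctrl <- make_mr(pos, c(.9, .5, .2), sample_id = "control1")
  expect_false(is.null(test_mr(pair_mrs(mono, mono_ctrl)[[1]], test_config(isST = 1))))
})

test_that("rratio follows the median formula and its sign rules", {
  mk <- function(cl, kl) {
    pos <- seq_along(cl) * 10L
    pair_mrs(make_mr(pos, cl), make_mr(pos, kl, sample_id = "control1"))[[1]]
  }
  expect_equal(rratio(mk(c(3, 3, 3), c(1, 1, 1))), 1)      # (3-1)/2
  expect_equal(rratio(mk(c(2, 2), c(2, 2))), 0)
  expect_equal(rratio(mk(c(0, 0), c(2, 2))), -2)
  expect_equal(rratio(mk(c(0, 0), c(0, 0))), 0)            # both-zero convention
  r <- test_mr(mk(c(3, 3, 3), c(1, 1, 1)), test_config())
  expect_equal(r$direction, "hyper")
  expect_equal(test_mr(mk(c(0, 0), c(2, 2)), test_config())$direction, "hypo")
})

test_that("rratio is antisymmetric and unaffected by imputation", {
  set.seed(24)
  for (rep in 1:50) {
    k <- sample(3:9, 1)
    pos <- sort(sample.int(5000, k))
    cl <- stats::rlnorm(k); kl <- stats::rlnorm(k)
    fwd <- pair_mrs(make_mr(pos, cl), make_mr(pos, kl, sample_id = "control1"))[[1]]
    rev <- pair_mrs(make_mr(pos, kl), make_mr(pos, cl, sample_id = "control1"))[[1]]
    expect_equal(rratio(fwd), -rratio(rev))
  }
  # a missing site changes the aligned vectors but not the original medians
  case <- make_mr(c(100, 300, 500), c(2, 4, 6))
  ctrl <- make_mr(c(100, 500), c(1, 3), sample_id = "control1")
  for (strat in c("zeros", "median", "nearest_neighbour")) {
    p <- pair_mrs(case, ctrl, impute = strat)[[1]]
    expect_equal(stats::median(p$control_original), 2)
    expect_equal(rratio(p), (4 - 2) / 3)
  }
})

test_that("DMR calling applies the threshold to raw or BH-adjusted P-values", {
  recs <- do.call(rbind, lapply(c(0.01, 0.2), function(p) {
    data.frame(chrom = "chr1", start = 1L, end = 2L, region_class = "TSS",
               gene_name = "G", context = "5mC", n_sites = 3L, p_value = p,
               p_adjusted = NA_real_, rratio = 1, direction = "hyper",
               test_name = "exact_ranksum", stringsAsFactors = FALSE)
  }))
  called <- call_dmrs(recs, test_config())
  expect_equal(called$is_dmr, c(TRUE, FALSE))

  recs4 <- recs[rep(1, 4), ]
  recs4$p_value <- c(0.01, 0.02, 0.03, 0.04)
  bh <- call_dmrs(recs4, test_config(bh_correct = TRUE))
  expect_equal(bh$p_adjusted, rep(0.04, 4))  # hand BH computation
  expect_true(all(bh$is_dmr))

  all1 <- recs; all1$p_value <- c(1, 1)
  expect_false(any(call_dmrs(all1, test_config())$is_dmr))
})

test_that("BH adjustment is monotone and never below the raw P-value", {
  set.seed(25)
  for (rep in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    adj <- stats::p.adjust(p, "BH")
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})
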