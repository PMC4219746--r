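# brute-force Benjamini-Hochberg step-up, the independent reference for
# every adjusted p-value the package reports
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- running
  }
  adj
}

toy_em <- function(values, genes = rownames(values)) {
  expr_matrix(values,
              probes = data.frame(probe_id = rownames(values), gene = genes),
              samples = plain_plan(ncol(values)))
}

test_that("low-signal filtering removes probes below the mean threshold", {
  v <- matrix(rep(c(3, 7, 9), each = 4), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), sprintf("s%03d", 1:4)))
  em <- toy_em(v)
  kept <- suppressMessages(filter_low_signal(em, threshold = 5))
  expect_identical(rownames(kept$values), c("p2", "p3"))
  all_kept <- suppressMessages(filter_low_signal(em, threshold = 0))
  expect_identical(dim(all_kept), dim(em))
  expect_error(suppressMessages(filter_low_signal(em, threshold = 100)),
               "removes all probes")
})

test_that("variance selection keeps top-k, anchors, and boundary ties", {
  # deterministic variances: probe p_i has sd proportional to 11 - i
  v <- outer(10:1, c(-1.5, -0.5, 0.5, 1.5)) + 8
  dimnames(v) <- list(paste0("p", 1:10), sprintf("s%03d", 1:4))
  em <- toy_em(v, genes = paste0("g", 1:10))
  top3 <- select_most_variable(em, k = 3)
  expect_identical(sort(rownames(top3$values)), c("p1", "p2", "p3"))
  # low-variance anchor probe is retained on top of the k best
  with_anchor <- select_most_variable(em, k = 3, anchor_genes = "g10")
  expect_identical(sort(rownames(with_anchor$values)),
                   c("p1", "p10", "p2", "p3"))
  expect_error(select_most_variable(em, k = 11), "exceeds probe count")
  # exact variance tie at the boundary: both probes kept (superset rule)
  v2 <- v
  v2["p4", ] <- v2["p3", ]  # identical profile => identical variance
  em2 <- toy_em(v2, genes = paste0("g", 1:10))
  tied <- select_most_variable(em2, k = 3)
  expect_identical(sort(rownames(tied$values)), c("p1", "p2", "p3", "p4"))
})

test_that("differential expression recovers constructed shifts and nulls", {
  set.seed(42)
  n <- 4
  base <- matrix(rnorm(20 * 2 * n, sd = 0.1), 20, 2 * n,
                 dimnames = list(sprintf("p%02d", 1:20),
                                 sprintf("s%03d", 1:(2 * n))))
  base[1:5, 1:n] <- base[1:5, 1:n] + 2.0   # true shift of 2.0 in 5 probes
  em <- toy_em(base)
  treat <- sprintf("s%03d", 1:n); ctrl <- sprintf("s%03d", (n + 1):(2 * n))
  de <- differential_expression(em, treat, ctrl, label = "shift")
  expect_equal(de$log2_fold_change[1:5], rep(2.0, 5), tolerance = 0.2)
  expect_true(all(de$bh_adjusted_p[1:5] < 0.05))
  expect_true(all(de$bh_adjusted_p >= de$raw_p - 1e-15))
  # null probes: no calls at FDR 0.05
  expect_true(all(de$bh_adjusted_p[6:20] > 0.05))
  expect_error(differential_expression(em, treat[1], ctrl), "treat")
  expect_error(differential_expression(em, treat, ctrl[1]), "control")
})

test_that("BH adjustment equals the hand-applied step-up", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4), tolerance = 1e-15)
  expect_equal(bh_oracle(p), rep(0.04, 4), tolerance = 1e-15)
  set.seed(5)
  for (m in c(7, 100, 1000)) {
    pv <- runif(m)
    expect_lt(max(abs(p.adjust(pv, "BH") - bh_oracle(pv))), 1e-12)
  }
})

test_that("perturbation calls orient signs and apply the cutoff", {
  de <- data.frame(probe = c("t1_a", "t1_b", "t2_a", "t3_a"),
                   gene = c("T1", "T1", "T2", "T3"),
                   log2_fold_change = c(-1.5, 0.2, 0.4, 1.5),
                   raw_p = 0.01, bh_adjusted_p = 0.01, contrast = "c")
  pairs <- data.frame(regulator = "R", target = c("T1", "T2", "T3", "T4"))
  expect_message(
    calls <- classify_perturbation_response(de, pairs, "R", "loss", tau = 1),
    "T4.*skipped")
  # T1: two probes, max |lfc| wins; knockout flips -1.5 to +1
  expect_identical(calls$observed_sign[calls$target == "T1"], 1L)
  expect_identical(calls$observed_sign[calls$target == "T2"], 0L)
  # gain contrast: no flip
  calls_gain <- suppressMessages(
    classify_perturbation_response(de, pairs, "R", "gain", tau = 1))
  expect_identical(calls_gain$observed_sign[calls_gain$target == "T1"], -1L)
  expect_identical(calls_gain$observed_sign[calls_gain$target == "T3"], 1L)
})

test_that("consistency curve matches sign-concordance at the boundaries and
           is monotone in the cutoff", {
  calls <- data.frame(regulator = "R", target = paste0("T", 1:6),
                      oriented_lfc = c(2, 1.2, -0.4, -2, 0.3, 1.4))
  truth <- data.frame(regulator = "R", target = paste0("T", 1:6),
                      mode = c("activating", "activating", "activating",
                               "inhibiting", "none", "none"))
  cc <- perturbation_consistency_curve(calls, truth, tau_grid = c(0, 1, 10))
  # tau=0: every |lfc|>0 fires; only sign-concordant positives count
  expect_equal(cc$tp_rate[1], 3 / 4)
  expect_equal(cc$fp_rate[1], 1)
  expect_equal(cc$tp_rate[2], 3 / 4)   # the -0.4 activating pair misses
  expect_equal(cc$fp_rate[2], 1 / 2)
  expect_equal(cc$tp_rate[3], 0)       # beyond every |lfc|
  expect_equal(cc$fp_rate[3], 0)
  expect_true(all(diff(cc$tp_rate) <= 1e-12))
  expect_true(all(diff(cc$fp_rate) <= 1e-12))
  # no negatives: FP undefined, reported missing
  cc2 <- perturbation_consistency_curve(calls[1:4, ], truth[1:4, ],
                                        tau_grid = 1)
  expect_true(is.na(cc2$fp_rate))
})

test_that("tissue comparison flags single-tissue responders and calibrates
           correlation", {
  de <- data.frame(probe = sprintf("p%04d", 1:1000),
                   gene = sprintf("g%04d", 1:1000),
                   log2_fold_change = rnorm(1000),
                   raw_p = runif(1000), bh_adjusted_p = runif(1000),
                   contrast = "a")
  same <- tissue_response_comparison(de, de, fdr = 0.05)
  expect_identical(same$n_diff_responsive, 0L)
  expect_equal(same$fc_correlation, 1.0)

  # constructed: exactly 50 genes significant only in tissue A
  de_a <- de; de_b <- de
  de_a$bh_adjusted_p <- 1; de_b$bh_adjusted_p <- 1
  de_a$bh_adjusted_p[1:50] <- 0.001
  got <- tissue_response_comparison(de_a, de_b, fdr = 0.05)
  expect_identical(got$n_diff_responsive, 50L)

  # independent fold-change vectors: correlation within 3/sqrt(n) of 0
  set.seed(11)
  de_b$log2_fold_change <- rnorm(1000)
  indep <- tissue_response_comparison(de_a, de_b)
  expect_lt(abs(indep$fc_correlation), 3 / sqrt(1000))

  de_b$probe <- paste0("x", de_b$probe)
  expect_error(tissue_response_comparison(de_a, de_b), "disjoint")
})

test_that("replicate-split control exceeds independent-perturbation control", {
  grn <- sample_grn(n_genes = 30, density = 0.08, seed = 4,
                    n_regulators = 10, n_noeffect = 20)
  hub <- names(sort(table(grn$edges$regulator), decreasing = TRUE))[1:2]
  pa <- simulate_perturbation(grn, hub[1], "loss", replicates = 4, seed = 1,
                              noise_sd = 0.2)
  pb <- simulate_perturbation(grn, hub[2], "loss", replicates = 4, seed = 2,
                              noise_sd = 0.2)
  em <- expr_matrix(cbind(pa$values, pb$values), probes = grn$probes,
                    samples = rbind(pa$samples, pb$samples))
  ids <- function(p, r) p$samples$sample_id[p$samples$role == r]
  ctl <- response_control_correlations(
    em, ids(pa, "case"), ids(pa, "control"),
    ids(pb, "case"), ids(pb, "control"), seed = 3)
  expect_gt(ctl$positive, ctl$negative)
  expect_lt(abs(ctl$negative), 0.5)
})
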