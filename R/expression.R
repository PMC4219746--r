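# Expression preprocessing, two-group differential expression with BH
# correction, fold-change causal classification, and tissue-specific
# response comparison.

#' Remove low-signal probes
#'
#' @param x an `expr_matrix` (log scale).
#' @param threshold probes with mean expression below this are removed.
#'   Default: the matrix-wide 20th percentile of probe means (the filter's
#'   intent is platform-dependent, so the default adapts to the matrix).
#' @return filtered `expr_matrix`.
#' @export
filter_low_signal <- function(x, threshold = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- rowMeans(x$values)
  if (is.null(threshold)) threshold <- unname(quantile(m, 0.2))
  keep <- m >= threshold
  if (!any(keep))
    stop("low-signal threshold ", threshold, " removes all probes")
  message("low-signal filter: removed ", sum(!keep), " of ", length(keep),
          " probes (threshold ", signif(threshold, 4), ")")
  expr_matrix(x$values[keep, , drop = FALSE],
              probes = x$probes[keep, , drop = FALSE], samples = x$samples)
}

#' Keep the k most variable probes plus all anchor-gene probes
#'
#' Ties at the variance boundary are all retained (superset semantics,
#' deterministic), and every probe annotated to an anchor gene (typically
#' the literature regulators and targets) is kept regardless of rank.
#'
#' @param x an `expr_matrix`.
#' @param k number of top-variance probes to keep (`k <= nrow`).
#' @param anchor_genes character vector of gene symbols whose probes are
#'   always retained.
#' @return filtered `expr_matrix`.
#' @export
select_most_variable <- function(x, k, anchor_genes = character()) {
  stopifnot(inherits(x, "expr_matrix"))
  if (k > nrow(x$values)) stop("k exceeds probe count")
  v <- apply(x$values, 1, var)
  keep <- if (k > 0) v >= sort(v, decreasing = TRUE)[k] else rep(FALSE, length(v))
  keep <- keep | x$probes$gene %in% anchor_genes
  expr_matrix(x$values[keep, , drop = FALSE],
              probes = x$probes[keep, , drop = FALSE], samples = x$samples)
}

#' Per-probe fold-change vector between two sample groups
#'
#' @param x an `expr_matrix` (log2 scale, so a mean difference is a log2
#'   fold change).
#' @param treat,control character vectors of sample IDs.
#' @return named numeric vector of log2 fold changes (treat - control).
#' @export
fold_change_vector <- function(x, treat, control) {
  stopifnot(inherits(x, "expr_matrix"))
  absent <- setdiff(c(treat, control), colnames(x$values))
  if (length(absent)) stop("unknown sample(s): ", paste(absent, collapse = ", "))
  rowMeans(x$values[, treat, drop = FALSE]) -
    rowMeans(x$values[, control, drop = FALSE])
}

#' Two-group differential expression (Welch t + Benjamini-Hochberg)
#'
#' Per-probe Welch two-sample t-test with BH adjustment across all probes
#' of the contrast. The log2 fold change is the group mean difference.
#' An optional variance floor pools each probe's variance toward the
#' median probe variance for stability at very small n.
#'
#' @param x an `expr_matrix`.
#' @param treat,control sample-ID vectors; each group needs >= 2 samples.
#' @param label contrast label carried into the result.
#' @param var_shrink weight in \[0, 1\] pulling per-probe group variances
#'   toward the median probe variance (0 = plain Welch, default).
#' @return data.frame: `probe`, `gene`, `log2_fold_change`, `raw_p`,
#'   `bh_adjusted_p`, `contrast`.
#' @export
differential_expression <- function(x, treat, control, label = "contrast",
                                    var_shrink = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(treat) < 2) stop("group 'treat' has fewer than 2 samples")
  if (length(control) < 2) stop("group 'control' has fewer than 2 samples")
  absent <- setdiff(c(treat, control), colnames(x$values))
  if (length(absent)) stop("unknown sample(s): ", paste(absent, collapse = ", "))
  a <- x$values[, treat, drop = FALSE]
  b <- x$values[, control, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
  if (var_shrink > 0) {
    v1 <- (1 - var_shrink) * v1 + var_shrink * stats::median(v1)
    v2 <- (1 - var_shrink) * v2 + var_shrink * stats::median(v2)
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[is.nan(p)] <- 1           # 0/0: no difference, no variance
  p[is.infinite(tstat)] <- 0  # difference with zero variance
  data.frame(probe = rownames(x$values), gene = x$probes$gene,
             log2_fold_change = m1 - m2, raw_p = p,
             bh_adjusted_p = p.adjust(p, method = "BH"),
             contrast = label, stringsAsFactors = FALSE)
}

#' Classify perturbation responses of literature RTP targets
#'
#' For each RTP whose regulator matches the contrast's perturbed entity,
#' the target's log2 fold change (probe with largest \|log2FC\| when a
#' gene has several probes) is turned into an observed sign: `sign(FC)`
#' if `|FC| >= tau`, else 0. For loss-of-function contrasts the sign is
#' flipped so that +1 always means "supports activation", matching the
#' evidence sign convention.
#'
#' @param de a [differential_expression()] result for one perturbation
#'   contrast.
#' @param pairs data.frame of RTPs with columns `regulator`, `target`.
#' @param regulator the perturbed gene of this contrast.
#' @param kind `"loss"` or `"gain"`.
#' @param tau absolute log2 fold-change cutoff.
#' @return data.frame: `regulator`, `target`, `log2_fold_change` (raw),
#'   `oriented_lfc` (flipped for loss contrasts), `observed_sign`, `tau`.
#'   Targets absent from the DE table are skipped with a message.
#' @export
classify_perturbation_response <- function(de, pairs, regulator,
                                           kind = c("loss", "gain"),
                                           tau = 1) {
  kind <- match.arg(kind)
  pairs <- pairs[pairs$regulator == regulator, , drop = FALSE]
  hit <- de[de$gene %in% pairs$target, , drop = FALSE]
  ord <- order(hit$gene, -abs(hit$log2_fold_change))
  hit <- hit[ord[!duplicated(hit$gene[ord])], , drop = FALSE]
  missing <- setdiff(pairs$target, hit$gene)
  if (length(missing))
    message("no expression for target(s) of ", regulator, ": ",
            paste(missing, collapse = ", "), " -- skipped")
  pairs <- pairs[pairs$target %in% hit$gene, , drop = FALSE]
  lfc <- hit$log2_fold_change[match(pairs$target, hit$gene)]
  oriented <- if (kind == "loss") -lfc else lfc
  data.frame(regulator = pairs$regulator, target = pairs$target,
             log2_fold_change = lfc, oriented_lfc = oriented,
             observed_sign = as.integer(ifelse(abs(oriented) >= tau,
                                               sign(oriented), 0)),
             tau = tau, stringsAsFactors = FALSE)
}

#' TP/FP rates of fold-change causal calls over a cutoff grid
#'
#' For each cutoff tau, the true positive rate is the fraction of
#' activating/inhibiting RTPs whose oriented fold change exceeds tau with
#' the matching sign (+ for activating, - for inhibiting); the false
#' positive rate is the fraction of no-effect RTPs firing in either
#' direction.
#'
#' @param calls data.frame with `regulator`, `target`, `oriented_lfc`
#'   (one row per evaluated RTP; see
#'   [classify_perturbation_response()]).
#' @param truth data.frame with `regulator`, `target`, `mode` in
#'   \{activating, none, inhibiting\}.
#' @param tau_grid numeric cutoffs (default 0..3 by 0.1).
#' @return data.frame: `tau`, `tp_rate`, `fp_rate`, `n_pos`, `n_neg`.
#'   With an empty negative set `fp_rate` is `NA`, never 0.
#' @export
perturbation_consistency_curve <- function(calls, truth,
                                           tau_grid = seq(0, 3, by = 0.1)) {
  key <- function(d) paste(d$regulator, d$target, sep = "\r")
  calls$mode <- truth$mode[match(key(calls), key(truth))]
  calls <- calls[!is.na(calls$mode), , drop = FALSE]
  pos <- calls[calls$mode != "none", , drop = FALSE]
  neg <- calls[calls$mode == "none", , drop = FALSE]
  want <- ifelse(pos$mode == "activating", 1, -1)
  out <- lapply(tau_grid, function(tau) {
    tp <- if (nrow(pos)) mean(abs(pos$oriented_lfc) >= tau &
                                sign(pos$oriented_lfc) == want) else NA_real_
    fp <- if (nrow(neg)) mean(abs(neg$oriented_lfc) >= tau) else NA_real_
    data.frame(tau = tau, tp_rate = tp, fp_rate = fp,
               n_pos = nrow(pos), n_neg = nrow(neg))
  })
  do.call(rbind, out)
}

#' Compare responses to the same perturbation in two tissues
#'
#' Genes significant (BH-adjusted p below `fdr`) in exactly one of the
#' two tissues are flagged as differentially responsive; the Pearson
#' correlation of the two log2 fold-change vectors summarises overall
#' agreement. Use [response_control_correlations()] for the
#' replicate-split positive control and independent-perturbation negative
#' control that calibrate this correlation.
#'
#' @param de_a,de_b [differential_expression()] results for the same
#'   perturbation in tissues A and B (probe sets must overlap).
#' @param fdr BH-adjusted significance cutoff (default 0.05).
#' @return list: `table` (per shared probe: lfc and significance in each
#'   tissue, `diff_responsive` flag), `n_diff_responsive`,
#'   `fc_correlation`.
#' @export
tissue_response_comparison <- function(de_a, de_b, fdr = 0.05) {
  shared <- intersect(de_a$probe, de_b$probe)
  if (!length(shared)) stop("disjoint probe sets between the two contrasts")
  a <- de_a[match(shared, de_a$probe), ]
  b <- de_b[match(shared, de_b$probe), ]
  sig_a <- a$bh_adjusted_p < fdr
  sig_b <- b$bh_adjusted_p < fdr
  tab <- data.frame(probe = shared, gene = a$gene,
                    lfc_a = a$log2_fold_change, lfc_b = b$log2_fold_change,
                    sig_a = sig_a, sig_b = sig_b,
                    diff_responsive = xor(sig_a, sig_b),
                    stringsAsFactors = FALSE)
  list(table = tab, n_diff_responsive = sum(tab$diff_responsive),
       fc_correlation = cor(tab$lfc_a, tab$lfc_b))
}

#' Replicate-split and independent-perturbation control correlations
#'
#' Positive control: the perturbed and control replicates of one
#' experiment are each split in half and the two half-sample fold-change
#' vectors are correlated — an upper reference for how reproducible a
#' response can be. Negative control: fold changes of two independent
#' perturbations are correlated — the background for unrelated responses.
#'
#' @param x an `expr_matrix`.
#' @param treat,control sample IDs of the experiment (>= 2 each).
#' @param other_treat,other_control sample IDs of an independent
#'   perturbation.
#' @param seed integer seed for the replicate split.
#' @return list with `positive` and `negative` Pearson correlations.
#' @export
response_control_correlations <- function(x, treat, control, other_treat,
                                          other_control, seed = 1) {
  stopifnot(length(treat) >= 2, length(control) >= 2)
  set.seed(seed)
  half <- function(ids) {
    i <- sample(length(ids), floor(length(ids) / 2))
    list(ids[i], ids[-i])
  }
  ht <- half(treat); hc <- half(control)
  fc1 <- fold_change_vector(x, ht[[1]], hc[[1]])
  fc2 <- fold_change_vector(x, ht[[2]], hc[[2]])
  fc_full <- fold_change_vector(x, treat, control)
  fc_other <- fold_change_vector(x, other_treat, other_control)
  list(positive = cor(fc1, fc2), negative = cor(fc_full, fc_other))
}
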