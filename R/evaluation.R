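# Path-tolerant benchmarking of candidate networks against literature
# RTPs: TP/FP rates per path length, node-label permutation nulls,
# ROC/AUROC, and external-network overlap.

split_pos_neg <- function(pairs) {
  if (!is.null(pairs$mode)) {
    list(pos = pairs[pairs$mode %in% c("activating", "inhibiting"), ,
                     drop = FALSE],
         neg = pairs[pairs$mode == "none", , drop = FALSE])
  } else stop("`pairs` needs a `mode` column (activating/none/inhibiting)")
}

#' Match literature RTPs against a network with path tolerance
#'
#' A pair (u, v) is matched at path length k if the network connects u to
#' v by a path of at most k edges (directed traversal for directed
#' networks, undirected otherwise; for undirected networks either
#' orientation of the directed literature claim counts). Pairs whose
#' regulator or target is absent from the network's node universe are
#' excluded from numerator and denominator, with counts reported.
#'
#' @param network a `grn_network`.
#' @param pairs data.frame with `regulator`, `target`, `mode`
#'   (activating/inhibiting = positives, none = negatives).
#' @param K maximum path length (>= 1).
#' @param nodes optional explicit node universe (adds isolated nodes).
#' @return object of class `grn_evaluation`: `rates` data.frame (`k`,
#'   `tp_rate`, `fp_rate`, `n_pos`, `n_neg`, `network_size`), plus
#'   excluded-pair counts.
#' @export
match_rtp_paths <- function(network, pairs, K = 7, nodes = NULL) {
  if (K < 1) stop("K must be >= 1")
  g <- as_igraph(network, nodes = nodes)
  universe <- igraph::V(g)$name
  pn <- split_pos_neg(pairs)
  eval_side <- function(p) {
    inside <- p$regulator %in% universe & p$target %in% universe
    p <- p[inside, , drop = FALSE]
    d <- if (nrow(p)) {
      D <- igraph::distances(g, v = unique(p$regulator),
                             mode = if (network$directed) "out" else "all")
      D[cbind(match(p$regulator, rownames(D)), match(p$target, colnames(D)))]
    } else numeric()
    list(d = d, n = nrow(p), excluded = sum(!inside))
  }
  pos <- eval_side(pn$pos); neg <- eval_side(pn$neg)
  rates <- data.frame(
    k = seq_len(K),
    tp_rate = vapply(seq_len(K), function(k)
      if (pos$n) mean(pos$d >= 1 & pos$d <= k) else NA_real_, 0),
    fp_rate = vapply(seq_len(K), function(k)
      if (neg$n) mean(neg$d >= 1 & neg$d <= k) else NA_real_, 0),
    n_pos = pos$n, n_neg = neg$n, network_size = nrow(network$edges))
  structure(list(rates = rates, n_pos_excluded = pos$excluded,
                 n_neg_excluded = neg$excluded, K = K,
                 directed = network$directed),
            class = "grn_evaluation")
}

#' @export
print.grn_evaluation <- function(x, ...) {
  cat(sprintf("grn_evaluation (K=%d, %s; %d+%d pairs excluded)\n", x$K,
              if (x$directed) "directed" else "undirected",
              x$n_pos_excluded, x$n_neg_excluded))
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Node-label permutation null for path-tolerant matching
#'
#' Node labels of the candidate network are permuted uniformly at random
#' over its full node universe — topology (degree sequence, component
#' structure) is preserved exactly, gene identity is randomized — and the
#' TP/FP rates of [match_rtp_paths()] are recomputed for each
#' permutation. Since relabelling only permutes the pairwise distance
#' matrix, distances are computed once and re-indexed per permutation.
#'
#' @param network a `grn_network`.
#' @param pairs RTP data.frame as in [match_rtp_paths()].
#' @param K maximum path length.
#' @param n_permutations number of permutations (default 1000).
#' @param seed master seed; permutation streams derive from it.
#' @param nodes optional explicit node universe.
#' @return list: `observed` (`grn_evaluation`), `null` data.frame per k
#'   (mean/sd of null TP and FP rates, observed z-scores and empirical
#'   quantiles), and matrices `null_tp`, `null_fp`
#'   (n_permutations x K).
#' @export
permutation_null <- function(network, pairs, K = 7, n_permutations = 1000,
                             seed = 1, nodes = NULL) {
  stopifnot(n_permutations >= 1)
  observed <- match_rtp_paths(network, pairs, K = K, nodes = nodes)
  g <- as_igraph(network, nodes = nodes)
  universe <- igraph::V(g)$name
  D <- igraph::distances(g, mode = if (network$directed) "out" else "all")
  pn <- split_pos_neg(pairs)
  idx <- function(p) {
    keep <- p$regulator %in% universe & p$target %in% universe
    cbind(match(p$regulator[keep], universe), match(p$target[keep], universe))
  }
  ip <- idx(pn$pos); ineg <- idx(pn$neg)
  n <- length(universe)
  rates_at <- function(d, k) mean(d >= 1 & d <= k)
  null_tp <- matrix(NA_real_, n_permutations, K)
  null_fp <- matrix(NA_real_, n_permutations, K)
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)            # perm[i] = new label index of node i
    inv <- integer(n); inv[perm] <- seq_len(n)
    dp <- if (nrow(ip)) D[cbind(inv[ip[, 1]], inv[ip[, 2]])] else numeric()
    dn <- if (nrow(ineg)) D[cbind(inv[ineg[, 1]], inv[ineg[, 2]])] else numeric()
    for (k in seq_len(K)) {
      null_tp[b, k] <- if (nrow(ip)) rates_at(dp, k) else NA_real_
      null_fp[b, k] <- if (nrow(ineg)) rates_at(dn, k) else NA_real_
    }
  }
  obs <- observed$rates
  null_sum <- data.frame(
    k = seq_len(K),
    null_mean_tp = colMeans(null_tp), null_sd_tp = apply(null_tp, 2, sd),
    null_mean_fp = colMeans(null_fp), null_sd_fp = apply(null_fp, 2, sd))
  null_sum$tp_z <- (obs$tp_rate - null_sum$null_mean_tp) /
    ifelse(null_sum$null_sd_tp > 0, null_sum$null_sd_tp, NA)
  null_sum$tp_quantile <- vapply(seq_len(K), function(k)
    mean(null_tp[, k] <= obs$tp_rate[k]), 0)
  null_sum$fp_quantile <- vapply(seq_len(K), function(k)
    mean(null_fp[, k] <= obs$fp_rate[k]), 0)
  list(observed = observed, null = null_sum,
       null_tp = null_tp, null_fp = null_fp)
}

#' ROC curve and AUROC by threshold sweep
#'
#' The curve sweeps every distinct score as a threshold (predict positive
#' when score >= threshold); the area is the trapezoid rule over the
#' resulting points. Tied scores move the operating point diagonally, so
#' the area equals the Mann-Whitney concordance probability with ties
#' counted 1/2.
#'
#' @param scores numeric statistic, larger = more likely positive.
#' @param labels logical (or coercible) vector, `TRUE` = positive class.
#' @return list: `roc` data.frame (`threshold`, `tpr`, `fpr`) and
#'   `auroc`.
#' @export
roc_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & !is.na(labels)
  if (any(!ok)) message("dropping ", sum(!ok), " pair(s) with missing score")
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(l)[grp_last] / n_pos
  fpr <- cumsum(!l)[grp_last] / n_neg
  roc <- data.frame(threshold = s[grp_last], tpr = tpr, fpr = fpr)
  xs <- c(0, roc$fpr); ys <- c(0, roc$tpr)
  auroc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  list(roc = roc, auroc = auroc)
}

#' Overlap of literature RTPs with an external network
#'
#' The evaluation universe is restricted to genes present in both the
#' external network and the RTP set (after applying an optional alias
#' map; matching is case-exact). The TP rate is the fraction of
#' activating/inhibiting RTPs present as edges in the external set; the
#' FP rate likewise for no-effect RTPs.
#'
#' @param external data.frame with `source`, `target` columns (e.g. from
#'   [read_sif_network()]).
#' @param pairs RTP data.frame with `regulator`, `target`, `mode`.
#' @param directed treat external edges as directed (default FALSE:
#'   either orientation matches).
#' @param alias_map optional named character vector mapping external
#'   symbols to RTP symbols.
#' @return list: `tp_rate`, `fp_rate`, `n_pos`, `n_neg`, `universe_size`,
#'   `n_pos_excluded`, `n_neg_excluded`.
#' @export
external_overlap <- function(external, pairs, directed = FALSE,
                             alias_map = NULL) {
  if (!is.null(alias_map)) {
    rename <- function(v) ifelse(v %in% names(alias_map), alias_map[v], v)
    external$source <- rename(external$source)
    external$target <- rename(external$target)
  }
  ext_nodes <- unique(c(external$source, external$target))
  universe <- intersect(ext_nodes,
                        unique(c(pairs$regulator, pairs$target)))
  if (!length(universe)) stop("empty gene universe between resources")
  edge_keys <- paste(external$source, external$target, sep = "\r")
  if (!directed)
    edge_keys <- c(edge_keys,
                   paste(external$target, external$source, sep = "\r"))
  pn <- split_pos_neg(pairs)
  side <- function(p) {
    inside <- p$regulator %in% universe & p$target %in% universe
    hit <- paste(p$regulator[inside], p$target[inside], sep = "\r") %in%
      edge_keys
    list(rate = if (sum(inside)) mean(hit) else NA_real_,
         n = sum(inside), excluded = sum(!inside))
  }
  pos <- side(pn$pos); neg <- side(pn$neg)
  list(tp_rate = pos$rate, fp_rate = neg$rate, n_pos = pos$n,
       n_neg = neg$n, universe_size = length(universe),
       n_pos_excluded = pos$excluded, n_neg_excluded = neg$excluded)
}
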