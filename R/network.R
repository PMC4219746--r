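# Candidate-network construction from expression data: pairwise
# correlation, binned mutual information, ARACNE-style DPI pruning, and
# tree-ensemble importance with edge-count standardization.

#' Scored inferred network
#'
#' @param edges data.frame with columns `source`, `target`, `score`.
#' @param directed logical; correlation/MI networks are undirected
#'   (canonical node order, each edge stored once), importance networks
#'   are directed.
#' @param method label of the producing method.
#' @param score_type one of `"correlation"`, `"MI"`, `"importance"`.
#' @return a `grn_network`.
#' @export
grn_network <- function(edges, directed, method = "unknown",
                        score_type = "correlation") {
  stopifnot(all(c("source", "target", "score") %in% names(edges)))
  if (any(!is.finite(edges$score))) stop("non-finite edge scores")
  if (!directed) {
    a <- pmin(edges$source, edges$target)
    b <- pmax(edges$source, edges$target)
    edges$source <- a; edges$target <- b
    edges <- edges[!duplicated(paste(a, b, sep = "\r")), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, directed = directed, method = method,
                 score_type = score_type), class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("grn_network [%s, %s]: %d edges, %d nodes, scores %s\n",
              x$method, if (x$directed) "directed" else "undirected",
              nrow(x$edges),
              length(unique(c(x$edges$source, x$edges$target))),
              x$score_type))
  invisible(x)
}

#' Convert an inferred network to an igraph object
#' @param x a `grn_network`.
#' @param nodes optional node universe including isolated nodes.
#' @return igraph graph.
#' @export
as_igraph <- function(x, nodes = NULL) {
  verts <- unique(c(x$edges$source, x$edges$target, nodes))
  igraph::graph_from_data_frame(x$edges[, c("source", "target")],
                                directed = x$directed,
                                vertices = data.frame(name = verts))
}

reduce_to_gene_pairs <- function(stat, probes) {
  # stat: symmetric probe x probe matrix; reduce probe pairs to gene pairs
  # by the maximum absolute statistic
  idx <- which(upper.tri(stat), arr.ind = TRUE)
  g1 <- probes$gene[idx[, 1]]; g2 <- probes$gene[idx[, 2]]
  keep <- g1 != g2 & is.finite(stat[idx])
  if (!all(is.finite(stat[idx]) | g1 == g2)) {
    n_bad <- sum(!is.finite(stat[idx]) & g1 != g2)
    if (n_bad) message("excluding ", n_bad,
                       " probe pair(s) with undefined statistic")
  }
  a <- pmin(g1, g2)[keep]; b <- pmax(g1, g2)[keep]
  s <- stat[idx][keep]
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -abs(s))
  first <- !duplicated(key[ord])
  data.frame(source = a[ord][first], target = b[ord][first],
             score = s[ord][first], stringsAsFactors = FALSE)
}

restrict_pairs <- function(edges, pairs) {
  if (is.null(pairs)) return(edges)
  want <- unique(c(paste(pairs$regulator, pairs$target, sep = "\r"),
                   paste(pairs$target, pairs$regulator, sep = "\r")))
  edges[paste(edges$source, edges$target, sep = "\r") %in% want, ,
        drop = FALSE]
}

#' Pairwise correlation network
#'
#' Pearson or Spearman correlation between all probe pairs (or the probes
#' of a restricted RTP set), reduced to gene pairs by maximum absolute
#' coefficient. Constant probes yield undefined coefficients and are
#' excluded with a message, never scored 0.
#'
#' @param x an `expr_matrix` with >= 3 samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param pairs optional data.frame (`regulator`, `target`) restricting
#'   the scored gene pairs.
#' @return undirected `grn_network` with correlation scores.
#' @export
pairwise_correlation <- function(x, method = c("pearson", "spearman"),
                                 pairs = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 3) stop("need >= 3 samples for correlation")
  cc <- suppressWarnings(cor(t(x$values), method = method))
  edges <- restrict_pairs(reduce_to_gene_pairs(cc, x$probes), pairs)
  grn_network(edges, directed = FALSE, method = method,
              score_type = "correlation")
}

equal_freq_codes <- function(v, bins) {
  ceiling(rank(v, ties.method = "first") * bins / length(v))
}

#' Binned mutual information between two vectors
#'
#' Empirical MI (nats) on an equal-frequency grid: each margin is split
#' into `bins` equally populated bins and MI is computed from the joint
#' histogram. For a deterministic monotone relation this equals
#' `log(bins)`.
#'
#' The plug-in estimate carries an upward bias of roughly
#' `(bins - 1)^2 / (2 n)` nats for independent data; the optional
#' Miller-Madow correction subtracts the count-based estimate of that
#' bias (and can push small MI values slightly below zero).
#'
#' @param v,w numeric vectors of equal length.
#' @param bins number of marginal bins; default `ceiling(sqrt(n))`.
#' @param mm_correction apply the Miller-Madow bias correction.
#' @return MI estimate in nats (nonnegative unless corrected).
#' @export
mi_pair <- function(v, w, bins = ceiling(sqrt(length(v))),
                    mm_correction = FALSE) {
  n <- length(v)
  stopifnot(length(w) == n)
  if (bins < 2) stop("degenerate binning: fewer than 2 bins")
  cx <- equal_freq_codes(v, bins); cy <- equal_freq_codes(w, bins)
  joint <- tabulate(cx + bins * (cy - 1L), nbins = bins * bins) / n
  px <- tabulate(cx, nbins = bins) / n
  py <- tabulate(cy, nbins = bins) / n
  pij <- joint[joint > 0]
  ij <- which(joint > 0)
  i <- (ij - 1L) %% bins + 1L
  j <- (ij - 1L) %/% bins + 1L
  mi <- sum(pij * log(pij / (px[i] * py[j])))
  if (mm_correction)
    mi <- mi - (length(pij) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
  mi
}

#' Mutual-information network
#'
#' MI for all probe pairs (or the probes of a restricted RTP set) from
#' the equal-frequency binned estimator of [mi_pair()], reduced to gene
#' pairs by maximum statistic.
#'
#' @param x an `expr_matrix`; a message warns below 8 samples where the
#'   estimator is badly biased.
#' @param pairs optional RTP restriction as in [pairwise_correlation()].
#' @param bins marginal bin count; default `ceiling(sqrt(n_samples))`.
#' @return undirected `grn_network` with MI scores (nats).
#' @export
mutual_information <- function(x, pairs = NULL, bins = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  n <- ncol(x$values)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  if (bins < 2) stop("degenerate binning: all samples in one bin")
  if (n < 8) message("MI on ", n, " samples: estimates will be biased")
  codes <- t(apply(x$values, 1, equal_freq_codes, bins = bins))
  p <- nrow(codes)
  mi <- matrix(NA_real_, p, p)
  marg <- lapply(seq_len(p), function(i) tabulate(codes[i, ], bins) / n)
  for (i in seq_len(p - 1)) {
    ci <- codes[i, ]
    for (j in (i + 1):p) {
      joint <- tabulate(ci + bins * (codes[j, ] - 1L), bins * bins) / n
      ij <- which(joint > 0)
      pi_ <- marg[[i]][(ij - 1L) %% bins + 1L]
      pj_ <- marg[[j]][(ij - 1L) %/% bins + 1L]
      mi[i, j] <- sum(joint[ij] * log(joint[ij] / (pi_ * pj_)))
    }
  }
  mi[lower.tri(mi)] <- t(mi)[lower.tri(mi)]
  edges <- restrict_pairs(reduce_to_gene_pairs(mi, x$probes), pairs)
  grn_network(edges, directed = FALSE, method = "mi", score_type = "MI")
}

#' Threshold a scored network
#'
#' Retains edges whose (absolute, by default) score reaches the cutoff
#' and removes self-loops — self-loops are only dropped here, at
#' comparison time, never at ingest.
#'
#' @param network a `grn_network`.
#' @param cutoff score cutoff.
#' @param absolute compare `|score|` (default) or the signed score.
#' @return thresholded `grn_network`.
#' @export
threshold_network <- function(network, cutoff, absolute = TRUE) {
  e <- network$edges
  s <- if (absolute) abs(e$score) else e$score
  e <- e[s >= cutoff & e$source != e$target, , drop = FALSE]
  rownames(e) <- NULL
  network$edges <- e
  network
}

#' ARACNE-style data-processing-inequality pruning
#'
#' For every fully connected triple (i, j, k) the weakest edge is flagged
#' as likely indirect and removed when its MI is strictly smaller than
#' `min(other two) - eps`. All removals are decided against the original
#' MI values before any edge is dropped. With `eps = 0` a strict
#' inequality is still required, so fully tied triangles are untouched
#' (non-strict removal would annihilate tied cliques).
#'
#' @param network an undirected MI `grn_network`.
#' @param eps DPI tolerance (default 0, the most aggressive setting that
#'   still respects ties).
#' @return pruned `grn_network`.
#' @export
aracne_prune <- function(network, eps = 0) {
  stopifnot(!network$directed)
  e <- e0 <- network$edges
  e <- e[e$source != e$target, , drop = FALSE]
  nodes <- unique(c(e$source, e$target))
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A <- matrix(FALSE, n, n)
  si <- match(e$source, nodes); ti <- match(e$target, nodes)
  M[cbind(si, ti)] <- M[cbind(ti, si)] <- e$score
  A[cbind(si, ti)] <- A[cbind(ti, si)] <- TRUE
  # best (over k) of min(M[i,k], M[j,k]) among common neighbours k
  best <- matrix(-Inf, n, n)
  for (k in seq_len(n)) {
    ak <- A[, k]
    if (sum(ak) < 2) next
    cand <- pmin(matrix(M[, k], n, n), matrix(M[, k], n, n, byrow = TRUE))
    valid <- outer(ak, ak, `&`)
    cand[!valid] <- -Inf
    best <- pmax(best, cand)
  }
  removed <- A & (M < best - eps)
  keep <- !removed[cbind(si, ti)]
  out <- e[keep, , drop = FALSE]
  # self-loops from the input are carried through untouched
  out <- rbind(out, e0[e0$source == e0$target, , drop = FALSE])
  rownames(out) <- NULL
  network$edges <- out
  network$method <- paste0(network$method, "+aracne")
  network
}

#' Tree-ensemble importance network (GENIE3 recipe)
#'
#' For each target gene a random-forest regression predicts its
#' standardized profile from the standardized profiles of the candidate
#' regulators (excluding the target itself); the per-regulator importance
#' (total decrease in node impurity, i.e. summed variance reduction) is
#' normalized per target to sum to one and becomes the directed
#' regulator-to-target score.
#'
#' @param x an `expr_matrix`; multi-probe genes are collapsed to their
#'   most variable probe ([gene_level_matrix()]).
#' @param regulators candidate regulator gene symbols (>= 2 required;
#'   must be present in the matrix).
#' @param n_trees trees per target ensemble (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param targets optional subset of target genes (default: all genes).
#' @return directed `grn_network` with importance scores.
#' @export
tree_importance_network <- function(x, regulators, n_trees = 1000, seed = 1,
                                    targets = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- gene_level_matrix(x)
  regulators <- intersect(regulators, rownames(m))
  if (length(regulators) < 2) stop("need >= 2 regulators present in matrix")
  if (is.null(targets)) targets <- rownames(m)
  targets <- intersect(targets, rownames(m))
  z <- t(scale(t(m)))            # per-gene standardization
  z[is.na(z)] <- 0               # constant genes carry no signal
  set.seed(seed)
  out <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    tgt <- targets[ti]
    preds <- setdiff(regulators, tgt)
    if (length(preds) < 2) next
    rf <- randomForest::randomForest(
      x = t(z[preds, , drop = FALSE]), y = z[tgt, ],
      ntree = n_trees,
      mtry = max(1, floor(sqrt(length(preds)))))
    imp <- rf$importance[, "IncNodePurity"]
    tot <- sum(imp)
    if (tot <= 0) next
    out[[ti]] <- data.frame(source = preds, target = tgt,
                            score = unname(imp) / tot,
                            stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges)) edges <- data.frame(source = character(),
                                          target = character(),
                                          score = numeric())
  grn_network(edges, directed = TRUE, method = "trees",
              score_type = "importance")
}

#' Standardize a scored network to a reference edge count
#'
#' Keeps the top-N edges by score where N is the size of the reference
#' network (the usual reference is the most unrestricted ARACNE output:
#' eps = 0, no MI threshold). Score ties at the boundary are all retained
#' and reported.
#'
#' @param network a scored `grn_network`.
#' @param reference a `grn_network`, or an integer edge count.
#' @return trimmed `grn_network`.
#' @export
standardize_edge_count <- function(network, reference) {
  n_ref <- if (inherits(reference, "grn_network")) nrow(reference$edges)
           else as.integer(reference)
  e <- network$edges
  if (n_ref >= nrow(e)) {
    if (n_ref > nrow(e))
      warning("reference size ", n_ref, " exceeds available ", nrow(e),
              " edges; keeping all")
    return(network)
  }
  if (n_ref == 0) {
    network$edges <- e[0, , drop = FALSE]
    return(network)
  }
  thr <- sort(e$score, decreasing = TRUE)[n_ref]
  keep <- e$score >= thr
  if (sum(keep) > n_ref)
    message("boundary score tie: retaining ", sum(keep),
            " edges instead of ", n_ref)
  network$edges <- e[keep, , drop = FALSE]
  rownames(network$edges) <- NULL
  network
}
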