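# Shared fixtures. The tooth-like study is expensive (random-forest step),
# so it is built once per test run and cached, together with the pipeline
# products the acceptance checks share.

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

get_benchmark <- function() {
  cached("bench", function() make_benchmark("tooth_like", seed = 1))
}

# literature GRN + candidate networks + evaluations for the benchmark study
get_pipeline <- function() {
  cached("pipeline", function() {
    st <- get_benchmark()
    lit <- suppressMessages(literature_grn(st$evidence))
    pairs <- rbind(lit$edges[, c("regulator", "target", "mode")],
                   lit$negatives[, c("regulator", "target", "mode")])
    em <- st$expression
    anchors <- unique(c(pairs$regulator, pairs$target))
    sub <- select_most_variable(em, k = 0, anchor_genes = anchors)
    corr_net <- suppressMessages(pairwise_correlation(sub, "pearson"))
    corr_thr <- threshold_network(corr_net, 0.5)
    mi_net <- suppressMessages(mutual_information(sub))
    aracne_net <- aracne_prune(mi_net)
    tree_net <- tree_importance_network(
      em, regulators = rownames(gene_level_matrix(em)),
      n_trees = 1000, seed = 1)
    tree_std <- suppressMessages(standardize_edge_count(tree_net, aracne_net))
    fc <- benchmark_fold_changes(st, pairs)
    list(study = st, lit = lit, pairs = pairs, sub = sub,
         corr_net = corr_net, corr_thr = corr_thr, mi_net = mi_net,
         aracne_net = aracne_net, tree_net = tree_net, tree_std = tree_std,
         fold_changes = fc)
  })
}

# per-RTP oriented fold change, max |lfc| across the matching contrasts
benchmark_fold_changes <- function(study, pairs) {
  calls <- lapply(seq_len(nrow(study$perturbations)), function(i) {
    pp <- study$perturbations[i, ]
    cs <- contrast_samples(study, pp$gene, pp$tissue)
    de <- differential_expression(study$expression, cs$case, cs$control,
                                  label = paste(pp$gene, pp$tissue))
    suppressMessages(
      classify_perturbation_response(de, pairs, pp$gene, pp$kind, tau = 1))
  })
  calls <- do.call(rbind, calls)
  key <- paste(calls$regulator, calls$target)
  ord <- order(key, -abs(calls$oriented_lfc))
  calls[ord[!duplicated(key[ord])], , drop = FALSE]
}

# hand-built two-tissue GRN with explicit weights, always-active edges
toy_grn <- function(weights, n_genes = max(3, nrow(weights)),
                    amp = 0, noise_seedable = TRUE) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  W <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  W[seq_len(nrow(weights)), seq_len(ncol(weights))] <- weights
  idx <- which(W != 0, arr.ind = TRUE)
  edges <- data.frame(regulator = genes[idx[, 1]], target = genes[idx[, 2]],
                      weight = W[idx], sign = sign(W[idx]),
                      mode = ifelse(W[idx] > 0, "activating", "inhibiting"),
                      window_start = rep(1L, nrow(idx)),
                      window_end = rep(8L, nrow(idx)),
                      active_epithelium = rep(TRUE, nrow(idx)),
                      active_mesenchyme = rep(TRUE, nrow(idx)),
                      stringsAsFactors = FALSE)
  gene_params <- data.frame(gene = genes, b0 = 0, amp = amp, phase = 0,
                            offset = 8, stringsAsFactors = FALSE)
  tissues <- c("epithelium", "mesenchyme")
  structure(list(genes = genes, regulators = genes, W = W, edges = edges,
                 no_effect = data.frame(regulator = character(),
                                        target = character(),
                                        mode = character()),
                 tissues = tissues, stages = paste0("E", 11:18),
                 gene_params = gene_params,
                 tissue_offsets = matrix(0, n_genes, 2,
                                         dimnames = list(genes, tissues)),
                 probes = data.frame(probe_id = paste0(genes, "_p1"),
                                     gene = genes, stringsAsFactors = FALSE),
                 params = list()),
            class = "ground_truth_grn")
}

plain_plan <- function(n, tissue = "epithelium", stage = "E14") {
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             condition_class = "time_series", tissue = tissue,
             stage = stage, perturbed_entity = "", replicate_group = "g",
             role = "na", stringsAsFactors = FALSE)
}

example_evidence <- function() {
  data.frame(
    regulator = c("Pax9", "Pax9", "Msx1"), target = c("Msx1", "Msx1", "Bmp4"),
    perturbation = c("loss", "loss", "gain"),
    effect = c("down", "none", "up"), species = "mouse",
    stage = "E13", tissue_perturbed = "mesenchyme",
    tissue_measured = "mesenchyme", technique = "ISH", molecule = "mRNA",
    citation = c("PMID:1", "PMID:2", "PMID:3"), stringsAsFactors = FALSE)
}

# all sign multisets of size 1..max_n over {+1, 0, -1}
all_multisets <- function(max_n = 4) {
  out <- list()
  for (n in seq_len(max_n)) {
    for (np in 0:n) for (nz in 0:(n - np)) {
      out[[length(out) + 1]] <- c(rep(1L, np), rep(0L, nz),
                                  rep(-1L, n - np - nz))
    }
  }
  out
}
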