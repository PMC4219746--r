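# Ground-truthed simulator: signed developmental GRNs with tissue/stage
# activity masks, steady-state expression from a (optionally saturating)
# structural equation model, clamp-style perturbations, and noisy
# literature-evidence tables generated by inverting the observation noise
# model.

#' Sample a ground-truth signed GRN
#'
#' Edges run from a designated regulator subset to targets drawn mostly
#' from non-regulator genes (`p_regulator_target` controls how often a
#' target is itself a regulator; keeping this small gives the shallow
#' regulator hierarchy of developmental networks and keeps reachable sets
#' bounded so that genuinely path-free no-effect pairs exist). Edge signs
#' are negative at rate `frac_inhibiting`; |W| is rescaled to spectral
#' radius <= 0.9 so the steady state of the expression model exists. Each
#' edge is active in a random subset of tissues and a contiguous window
#' of developmental stages — the mechanism behind tissue/temporal
#' specificity. No-effect pairs are verified path-free on the full graph
#' (hence path-free in every context).
#'
#' @param n_genes number of genes (>= 5).
#' @param density edge probability over regulator x target ordered pairs,
#'   in (0, 1).
#' @param frac_inhibiting fraction of inhibiting edges.
#' @param seed integer seed.
#' @param n_regulators size of the regulator subset.
#' @param weight_range absolute edge-weight range (uniform).
#' @param p_regulator_target probability an edge targets a regulator.
#' @param tissues tissue labels.
#' @param stages developmental stage labels (ordered).
#' @param edge_tissue_prob per-tissue edge activity probability (each
#'   edge is forced active in at least one tissue).
#' @param n_noeffect number of designated no-effect pairs.
#' @param frac_dup_probes fraction of genes represented by two probes.
#' @param tissue_offset_sd sd of per-gene tissue baseline offsets.
#' @return object of class `ground_truth_grn`.
#' @export
sample_grn <- function(n_genes = 60, density = 0.05, frac_inhibiting = 0.25,
                       seed = 1, n_regulators = max(5, round(n_genes / 3)),
                       weight_range = c(0.4, 0.9),
                       p_regulator_target = 0.1,
                       tissues = c("epithelium", "mesenchyme"),
                       stages = paste0("E", 11:18),
                       edge_tissue_prob = 0.6,
                       n_noeffect = round(n_genes * 2),
                       frac_dup_probes = 0.1,
                       tissue_offset_sd = 0.8) {
  stopifnot(n_genes >= 5, density > 0, density < 1,
            n_regulators < n_genes)
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  regulators <- genes[seq_len(n_regulators)]
  # candidate ordered pairs regulator -> any other gene
  cand <- expand.grid(r = seq_len(n_regulators), t = seq_len(n_genes))
  cand <- cand[cand$r != cand$t, ]
  n_edges <- max(1, round(density * nrow(cand)))
  tgt_is_reg <- cand$t <= n_regulators
  w <- ifelse(tgt_is_reg,
              p_regulator_target / sum(tgt_is_reg),
              (1 - p_regulator_target) / sum(!tgt_is_reg))
  pick <- cand[sample(nrow(cand), n_edges, prob = w), ]
  sign <- ifelse(runif(n_edges) < frac_inhibiting, -1, 1)
  weight <- sign * runif(n_edges, weight_range[1], weight_range[2])
  W <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  W[cbind(pick$r, pick$t)] <- weight
  sr <- max(abs(eigen(abs(W), only.values = TRUE)$values))
  if (sr > 0.9) {
    W <- W * (0.9 / sr)
    weight <- W[cbind(pick$r, pick$t)]
  }
  # tissue masks (>= 1 active tissue per edge) and stage windows
  tm <- matrix(runif(n_edges * length(tissues)) < edge_tissue_prob,
               n_edges, length(tissues), dimnames = list(NULL, tissues))
  dead <- rowSums(tm) == 0
  tm[cbind(which(dead), sample(length(tissues), sum(dead), replace = TRUE))] <- TRUE
  win_len <- ceiling(length(stages) / 2)
  win_start <- sample(length(stages) - win_len + 1L, n_edges, replace = TRUE)
  edges <- data.frame(regulator = genes[pick$r], target = genes[pick$t],
                      weight = weight, sign = sign,
                      mode = ifelse(sign > 0, "activating", "inhibiting"),
                      window_start = win_start,
                      window_end = win_start + win_len - 1L,
                      stringsAsFactors = FALSE)
  for (tt in tissues) edges[[paste0("active_", tt)]] <- tm[, tt]
  # no-effect pairs: no directed path in the full graph
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = TRUE,
                                     vertices = data.frame(name = genes))
  D <- igraph::distances(g, v = regulators, mode = "out")
  free <- which(is.infinite(D), arr.ind = TRUE)
  free <- data.frame(regulator = regulators[free[, 1]],
                     target = colnames(D)[free[, 2]],
                     stringsAsFactors = FALSE)
  free <- free[free$regulator != free$target, ]
  if (nrow(free) < n_noeffect)
    stop("only ", nrow(free), " path-free pairs available for ",
         n_noeffect, " no-effect pairs; lower the density")
  no_effect <- free[sample(nrow(free), n_noeffect), ]
  no_effect$mode <- "none"
  rownames(no_effect) <- NULL
  gene_params <- data.frame(
    gene = genes, b0 = rnorm(n_genes),
    amp = runif(n_genes, 0.5, 1.5), phase = runif(n_genes, 0, 2 * pi),
    offset = runif(n_genes, 6, 10), stringsAsFactors = FALSE)
  toff <- matrix(rnorm(n_genes * length(tissues), sd = tissue_offset_sd),
                 n_genes, length(tissues), dimnames = list(genes, tissues))
  dup <- genes[runif(n_genes) < frac_dup_probes]
  probes <- data.frame(
    probe_id = c(paste0(genes, "_p1"),
                 if (length(dup)) paste0(dup, "_p2")),
    gene = c(genes, dup), stringsAsFactors = FALSE)
  structure(list(genes = genes, regulators = regulators, W = W,
                 edges = edges, no_effect = no_effect, tissues = tissues,
                 stages = stages, gene_params = gene_params,
                 tissue_offsets = toff, probes = probes,
                 params = list(density = density,
                               frac_inhibiting = frac_inhibiting,
                               weight_range = weight_range,
                               edge_tissue_prob = edge_tissue_prob,
                               seed = seed)),
            class = "ground_truth_grn")
}

#' @export
print.ground_truth_grn <- function(x, ...) {
  cat(sprintf(paste0("ground_truth_grn: %d genes (%d regulators), ",
                     "%d signed edges (%d inhibiting), %d no-effect pairs\n"),
              length(x$genes), length(x$regulators), nrow(x$edges),
              sum(x$edges$sign < 0), nrow(x$no_effect)))
  invisible(x)
}

#' All evaluated pairs of a ground-truth GRN (edges + no-effect)
#' @param grn a `ground_truth_grn`.
#' @return data.frame `regulator`, `target`, `mode`.
#' @export
truth_pairs <- function(grn) {
  rbind(grn$edges[, c("regulator", "target", "mode")],
        grn$no_effect[, c("regulator", "target", "mode")])
}

# Active weight matrix for one (tissue, stage) context
active_W <- function(grn, tissue, stage_idx) {
  e <- grn$edges
  on <- e[[paste0("active_", tissue)]] &
    stage_idx >= e$window_start & stage_idx <= e$window_end
  W <- grn$W * 0
  W[cbind(match(e$regulator[on], grn$genes),
          match(e$target[on], grn$genes))] <- e$weight[on]
  W
}

transfer_fun <- function(transfer, sat_scale) {
  switch(transfer,
         linear = identity,
         tanh = function(u) sat_scale * tanh(u / sat_scale),
         clip = function(u) pmin(pmax(u, -sat_scale), sat_scale),
         stop("unknown transfer: ", transfer))
}

# Fixed-point steady state x = b + f(W^T x), optionally with clamped
# coordinates. Converges because the spectral radius of |W| is <= 0.9 and
# every transfer has slope <= 1.
solve_steady <- function(W, b, f, clamp_idx = NULL, clamp_val = NULL,
                         tol = 1e-12, max_iter = 1000) {
  Wt <- t(W)
  x <- b
  if (length(clamp_idx)) x[clamp_idx] <- clamp_val
  for (it in seq_len(max_iter)) {
    xn <- b + f(as.vector(Wt %*% x))
    if (length(clamp_idx)) xn[clamp_idx] <- clamp_val
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  x
}

baseline_for <- function(grn, tissue, stage_idx) {
  gp <- grn$gene_params
  gp$b0 + grn$tissue_offsets[, tissue] +
    gp$amp * sin(2 * pi * stage_idx / length(grn$stages) + gp$phase)
}

probe_expand <- function(grn, gene_values, probe_noise_sd) {
  offs <- grn$gene_params$offset[match(grn$probes$gene, grn$gene_params$gene)]
  pv <- gene_values[match(grn$probes$gene, rownames(gene_values)), ,
                    drop = FALSE] + offs
  pv <- pv + matrix(rnorm(length(pv), sd = probe_noise_sd),
                    nrow(pv), ncol(pv))
  rownames(pv) <- grn$probes$probe_id
  pv
}

#' Simulate steady-state expression for a sample plan
#'
#' Each sample's gene values are the steady state of
#' `x = b + f(W_active' x) + noise`, where `W_active` keeps only the
#' edges active in the sample's tissue and stage, `b` is the gene
#' baseline (gene offset + tissue offset + smooth stage trend), and `f`
#' is the per-gene transfer function (`linear`, saturating `tanh`, or
#' hard `clip`). Output is on a log2-like scale (per-gene array offsets
#' in \[6, 10\]) with additive probe-level measurement noise.
#'
#' @param grn a `ground_truth_grn`.
#' @param plan sample-metadata data.frame (see [expr_matrix()]); `tissue`
#'   must be one of the GRN's tissues and `stage` one of its stage
#'   labels.
#' @param noise_sd sd of the per-gene biological noise entering the
#'   steady state.
#' @param transfer `"linear"`, `"tanh"` or `"clip"`.
#' @param sat_scale saturation scale of the nonlinear transfers.
#' @param probe_noise_sd sd of probe-level measurement noise.
#' @param seed integer seed.
#' @param baseline_shift optional genes x samples matrix added to the
#'   baselines (used e.g. for phenotype-difference groups).
#' @return an `expr_matrix`.
#' @export
simulate_expression <- function(grn, plan, noise_sd = 0.4,
                                transfer = "linear", sat_scale = 1.5,
                                probe_noise_sd = 0.15, seed = 1,
                                baseline_shift = NULL) {
  stopifnot(inherits(grn, "ground_truth_grn"))
  bad_t <- setdiff(unique(plan$tissue), grn$tissues)
  if (length(bad_t)) stop("unknown tissue(s): ", paste(bad_t, collapse = ", "))
  bad_s <- setdiff(unique(plan$stage), grn$stages)
  if (length(bad_s)) stop("unknown stage(s): ", paste(bad_s, collapse = ", "))
  f <- transfer_fun(transfer, sat_scale)
  set.seed(seed)
  n_genes <- length(grn$genes)
  vals <- matrix(NA_real_, n_genes, nrow(plan),
                 dimnames = list(grn$genes, plan$sample_id))
  for (i in seq_len(nrow(plan))) {
    st <- match(plan$stage[i], grn$stages)
    W <- active_W(grn, plan$tissue[i], st)
    b <- baseline_for(grn, plan$tissue[i], st)
    if (!is.null(baseline_shift)) b <- b + baseline_shift[, i]
    eps <- rnorm(n_genes, sd = noise_sd)
    vals[, i] <- solve_steady(W, b + eps, f)
  }
  expr_matrix(probe_expand(grn, vals, probe_noise_sd),
              probes = grn$probes, samples = plan)
}

#' Simulate a clamp-style perturbation experiment with matched controls
#'
#' Loss of function clamps the gene at `baseline - delta` (gain:
#' `+ delta`) and re-solves the steady state for the remaining genes;
#' control replicates come from the unperturbed model in the same tissue
#' and stage. In the linear regime downstream genes shift with sign equal
#' to the product of edge signs along the active paths.
#'
#' @param grn a `ground_truth_grn`.
#' @param gene perturbed gene symbol.
#' @param kind `"loss"` or `"gain"`.
#' @param replicates case and control replicates each.
#' @param noise_sd,transfer,sat_scale,probe_noise_sd as in
#'   [simulate_expression()].
#' @param seed integer seed.
#' @param tissue,stage context of the experiment (defaults: first tissue,
#'   middle stage).
#' @param delta clamp amplitude in expression units (default 2.5).
#' @param condition_class metadata class for the case samples (use
#'   `"signalling_stimulation"` for stimulation-style gains).
#' @return an `expr_matrix` with `replicates` case + `replicates` control
#'   samples (`role` column distinguishes them).
#' @export
simulate_perturbation <- function(grn, gene, kind = c("loss", "gain"),
                                  replicates = 3, noise_sd = 0.4,
                                  transfer = "linear", sat_scale = 1.5,
                                  probe_noise_sd = 0.15, seed = 1,
                                  tissue = grn$tissues[1],
                                  stage = grn$stages[ceiling(length(grn$stages) / 2)],
                                  delta = 2.5,
                                  condition_class = "genetic_perturbation") {
  kind <- match.arg(kind)
  stopifnot(inherits(grn, "ground_truth_grn"))
  if (!gene %in% grn$genes) stop("unknown gene: ", gene)
  f <- transfer_fun(transfer, sat_scale)
  set.seed(seed)
  st <- match(stage, grn$stages)
  W <- active_W(grn, tissue, st)
  b <- baseline_for(grn, tissue, st)
  gi <- match(gene, grn$genes)
  clamp <- b[gi] + if (kind == "loss") -delta else delta
  n_genes <- length(grn$genes)
  ids <- c(sprintf("%s_%s_%s_case_%d", gene, kind, tissue, seq_len(replicates)),
           sprintf("%s_%s_%s_ctrl_%d", gene, kind, tissue, seq_len(replicates)))
  vals <- matrix(NA_real_, n_genes, 2 * replicates,
                 dimnames = list(grn$genes, ids))
  for (r in seq_len(replicates)) {
    eps <- rnorm(n_genes, sd = noise_sd)
    vals[, r] <- solve_steady(W, b + eps, f, clamp_idx = gi,
                              clamp_val = clamp)
  }
  for (r in seq_len(replicates)) {
    eps <- rnorm(n_genes, sd = noise_sd)
    vals[, replicates + r] <- solve_steady(W, b + eps, f)
  }
  plan <- data.frame(
    sample_id = ids, condition_class = condition_class, tissue = tissue,
    stage = stage, perturbed_entity = gene,
    replicate_group = paste(gene, kind, tissue,
                            rep(c("case", "ctrl"), each = replicates),
                            sep = "_"),
    role = rep(c("case", "control"), each = replicates),
    stringsAsFactors = FALSE)
  expr_matrix(probe_expand(grn, vals, probe_noise_sd),
              probes = grn$probes, samples = plan)
}

#' Generate a noisy literature-evidence table from a ground-truth GRN
#'
#' For every true edge and every designated no-effect pair,
#' `n_per_pair` observation signs are drawn from the noise model's
#' conditional matrix `P(obs | mode)` and de-canonicalized into
#' (perturbation, effect) records: the perturbation direction is drawn
#' uniformly and the effect sign is `obs_sign * s(perturbation)`. Edge
#' contexts are drawn from the edge's active (tissue, stage) contexts;
#' no-effect contexts uniformly.
#'
#' @param grn a `ground_truth_grn`.
#' @param noise a [noise_model()].
#' @param n_per_pair observations per pair.
#' @param seed integer seed.
#' @param include_noeffect include the no-effect pairs (default TRUE).
#' @return evidence data.frame with the 11 [evidence_fields] columns plus
#'   `true_mode`.
#' @export
emit_evidence <- function(grn, noise = noise_model(), n_per_pair = 3,
                          seed = 1, include_noeffect = TRUE) {
  stopifnot(inherits(grn, "ground_truth_grn"))
  set.seed(seed)
  pairs <- if (include_noeffect) truth_pairs(grn)
           else grn$edges[, c("regulator", "target", "mode")]
  n_pairs <- nrow(pairs)
  rows <- vector("list", n_pairs)
  obs_signs <- c(1L, 0L, -1L)
  win_len <- ceiling(length(grn$stages) / 2)
  for (i in seq_len(n_pairs)) {
    mode <- pairs$mode[i]
    s <- sample(obs_signs, n_per_pair, replace = TRUE,
                prob = noise$P[, mode])
    if (mode != "none") {
      e <- grn$edges[grn$edges$regulator == pairs$regulator[i] &
                       grn$edges$target == pairs$target[i], ][1, ]
      act_t <- grn$tissues[vapply(grn$tissues, function(tt)
        isTRUE(e[[paste0("active_", tt)]]), TRUE)]
      tis <- sample(act_t, n_per_pair, replace = TRUE)
      stg <- grn$stages[e$window_start +
                          sample.int(win_len, n_per_pair, replace = TRUE) - 1L]
    } else {
      tis <- sample(grn$tissues, n_per_pair, replace = TRUE)
      stg <- sample(grn$stages, n_per_pair, replace = TRUE)
    }
    pert <- sample(c("gain", "loss"), n_per_pair, replace = TRUE)
    eff_sign <- s * ifelse(pert == "gain", 1L, -1L)
    rows[[i]] <- data.frame(
      regulator = pairs$regulator[i], target = pairs$target[i],
      perturbation = pert,
      effect = c("down", "none", "up")[eff_sign + 2L],
      species = "mouse", stage = stg, tissue_perturbed = tis,
      tissue_measured = tis,
      technique = sample(c("ISH", "qRT-PCR"), n_per_pair, replace = TRUE),
      molecule = ifelse(runif(n_per_pair) < 0.9, "mRNA", "protein"),
      citation = sprintf("PMID:SIM%05d", i),
      true_mode = mode, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

benchmark_presets <- list(
  tooth_like = list(n_genes = 160, n_regulators = 50, density = 0.0553,
                    frac_inhibiting = 0.265, n_noeffect = 455,
                    tissues = c("epithelium", "mesenchyme"),
                    ts_replicates = 3, n_genetic = 3, n_stimulation = 3,
                    genetic_reps = 2, stim_reps = 3, n_phenotype = 0),
  heart_like = list(n_genes = 140, n_regulators = 30, density = 0.048,
                    frac_inhibiting = 0.18, n_noeffect = 80,
                    tissues = c("myocardium", "endocardium"),
                    ts_replicates = 2, n_genetic = 5, n_stimulation = 0,
                    genetic_reps = 2, stim_reps = 3, n_phenotype = 12))

#' Build a complete simulated study (GRN + expression + evidence)
#'
#' Bundles [sample_grn()], [simulate_expression()],
#' [simulate_perturbation()] and [emit_evidence()] at preset scales
#' emulating a developmental expression compendium: a wild-type
#' time-series across stages and tissues, clamp perturbations of the
#' highest-out-degree regulators (genetic loss and, in `tooth_like`,
#' stimulation-style gains), and a noisy curated-evidence table. The
#' default expression regime uses the saturating `tanh` transfer and
#' tissue/stage masking — the conditions under which causal regulation
#' need not produce observable co-expression.
#'
#' @param preset `"tooth_like"` (160 genes, 50 regulators, ~440 signed
#'   edges, 455 no-effect pairs, ~108 arrays) or `"heart_like"` (140
#'   genes, 30 regulators, ~200 edges, 80 no-effect pairs, ~74 arrays).
#' @param seed integer master seed; all sub-streams derive from it.
#' @param transfer,sat_scale,noise_sd expression-model regime (defaults:
#'   `tanh`, 1.5, 0.4).
#' @param n_per_pair evidence observations per pair.
#' @return list of class `simulated_study`: `grn`, `expression`
#'   (`expr_matrix` of all arrays), `evidence`, `truth`,
#'   `perturbations` (one row per contrast: gene, kind, tissue, stage).
#' @export
make_benchmark <- function(preset = c("tooth_like", "heart_like"), seed = 1,
                           transfer = "tanh", sat_scale = 1.5,
                           noise_sd = 0.4, n_per_pair = 3) {
  preset <- match.arg(preset)
  p <- benchmark_presets[[preset]]
  set.seed(seed)
  subseed <- sample.int(.Machine$integer.max %/% 2, 40)
  grn <- sample_grn(n_genes = p$n_genes, density = p$density,
                    frac_inhibiting = p$frac_inhibiting,
                    seed = subseed[1], n_regulators = p$n_regulators,
                    tissues = p$tissues, n_noeffect = p$n_noeffect)
  # wild-type time series across stages x tissues
  ts_grid <- expand.grid(stage = grn$stages, tissue = grn$tissues,
                         rep = seq_len(p$ts_replicates),
                         stringsAsFactors = FALSE)
  ts_plan <- data.frame(
    sample_id = sprintf("ts_%s_%s_r%d", ts_grid$tissue, ts_grid$stage,
                        ts_grid$rep),
    condition_class = "time_series", tissue = ts_grid$tissue,
    stage = ts_grid$stage, perturbed_entity = "",
    replicate_group = sprintf("ts_%s_%s", ts_grid$tissue, ts_grid$stage),
    role = "na", stringsAsFactors = FALSE)
  parts <- list(simulate_expression(grn, ts_plan, noise_sd = noise_sd,
                                    transfer = transfer,
                                    sat_scale = sat_scale,
                                    seed = subseed[2]))
  # perturb the top-out-degree regulators (hubs, as real studies do)
  outdeg <- table(factor(grn$edges$regulator, levels = grn$regulators))
  hubs <- names(sort(outdeg, decreasing = TRUE))
  n_pert <- p$n_genetic + p$n_stimulation
  pert_spec <- data.frame(
    gene = hubs[seq_len(n_pert)],
    kind = rep(c("loss", "gain"), c(p$n_genetic, p$n_stimulation)),
    class = rep(c("genetic_perturbation", "signalling_stimulation"),
                c(p$n_genetic, p$n_stimulation)),
    reps = rep(c(p$genetic_reps, p$stim_reps),
               c(p$n_genetic, p$n_stimulation)),
    stringsAsFactors = FALSE)
  mid_stage <- grn$stages[ceiling(length(grn$stages) / 2)]
  perturbations <- list(); si <- 3
  for (i in seq_len(nrow(pert_spec))) {
    for (tt in grn$tissues) {
      parts[[length(parts) + 1]] <- simulate_perturbation(
        grn, pert_spec$gene[i], kind = pert_spec$kind[i],
        replicates = pert_spec$reps[i], noise_sd = noise_sd,
        transfer = transfer, sat_scale = sat_scale, seed = subseed[si],
        tissue = tt, stage = mid_stage,
        condition_class = pert_spec$class[i])
      perturbations[[length(perturbations) + 1]] <- data.frame(
        gene = pert_spec$gene[i], kind = pert_spec$kind[i], tissue = tt,
        stage = mid_stage, stringsAsFactors = FALSE)
      si <- si + 1
    }
  }
  # phenotype-difference arrays: two groups with a baseline shift on a
  # random gene subset (no perturbed entity)
  if (p$n_phenotype > 0) {
    set.seed(subseed[si]); si <- si + 1
    n_half <- p$n_phenotype / 2
    shift_genes <- sample(length(grn$genes), round(length(grn$genes) * 0.1))
    shift <- matrix(0, length(grn$genes), p$n_phenotype)
    shift[shift_genes, seq_len(n_half)] <-
      rnorm(length(shift_genes), sd = 0.8)
    ph_plan <- data.frame(
      sample_id = sprintf("pheno_%s_r%d", rep(c("A", "B"), each = n_half),
                          seq_len(n_half)),
      condition_class = "phenotype_difference", tissue = grn$tissues[1],
      stage = mid_stage, perturbed_entity = "",
      replicate_group = rep(c("pheno_A", "pheno_B"), each = n_half),
      role = "na", stringsAsFactors = FALSE)
    parts[[length(parts) + 1]] <- simulate_expression(
      grn, ph_plan, noise_sd = noise_sd, transfer = transfer,
      sat_scale = sat_scale, seed = subseed[si],
      baseline_shift = shift)
    si <- si + 1
  }
  values <- do.call(cbind, lapply(parts, function(e) e$values))
  samples <- do.call(rbind, lapply(parts, function(e) e$samples))
  expression <- expr_matrix(values, probes = grn$probes, samples = samples)
  evidence <- emit_evidence(grn, n_per_pair = n_per_pair,
                            seed = subseed[30])
  structure(list(grn = grn, expression = expression, evidence = evidence,
                 truth = truth_pairs(grn),
                 perturbations = do.call(rbind, perturbations),
                 preset = preset, seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study '%s' (seed %d)\n", x$preset, x$seed))
  print(x$grn)
  print(x$expression)
  cat(sprintf("%d evidence records over %d pairs; %d perturbation contrasts\n",
              nrow(x$evidence),
              nrow(unique(x$evidence[, c("regulator", "target")])),
              nrow(x$perturbations)))
  invisible(x)
}

#' Case/control sample IDs for a simulated perturbation contrast
#'
#' @param study a `simulated_study`.
#' @param gene,tissue contrast identifiers (one row of
#'   `study$perturbations`).
#' @return list with `case` and `control` sample-ID vectors.
#' @export
contrast_samples <- function(study, gene, tissue) {
  s <- study$expression$samples
  pick <- s$perturbed_entity == gene & s$tissue == tissue
  list(case = s$sample_id[pick & s$role == "case"],
       control = s$sample_id[pick & s$role == "control"])
}
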