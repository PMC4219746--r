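test_that("sampled GRNs satisfy their structural invariants and are
           reproducible", {
  grn <- sample_grn(n_genes = 50, density = 0.02, frac_inhibiting = 0.25,
                    seed = 1)
  grn2 <- sample_grn(n_genes = 50, density = 0.02, frac_inhibiting = 0.25,
                     seed = 1)
  expect_identical(grn$edges, grn2$edges)
  expect_identical(grn$no_effect, grn2$no_effect)
  # steady-state solvability
  expect_lte(max(abs(eigen(abs(grn$W), only.values = TRUE)$values)), 0.9 + 1e-9)
  # no-effect pairs are path-free (independent igraph check)
  g <- igraph::graph_from_data_frame(grn$edges[, 1:2], directed = TRUE,
                                     vertices = data.frame(name = grn$genes))
  d <- igraph::distances(g, v = unique(grn$no_effect$regulator), mode = "out")
  expect_true(all(is.infinite(
    d[cbind(match(grn$no_effect$regulator, rownames(d)),
            match(grn$no_effect$target, colnames(d)))])))
  # every edge is active in at least one tissue and a nonempty stage window
  act <- as.matrix(grn$edges[, grep("^active_", names(grn$edges))])
  expect_true(all(rowSums(act) >= 1))
  expect_true(all(grn$edges$window_end >= grn$edges$window_start))

  all_pos <- sample_grn(n_genes = 30, density = 0.03, frac_inhibiting = 0,
                        seed = 2)
  expect_true(all(all_pos$edges$sign > 0))
  expect_error(sample_grn(n_genes = 20, density = 0.9, seed = 3,
                          n_noeffect = 200), "lower the density")
})

test_that("edge-sign ratio follows the inhibiting fraction binomially", {
  set.seed(5)
  frac <- 0.25
  n_edges <- 0; n_inhib <- 0
  for (s in 1:30) {
    grn <- sample_grn(n_genes = 30, density = 0.05, frac_inhibiting = frac,
                      seed = s, n_noeffect = 5)
    n_edges <- n_edges + nrow(grn$edges)
    n_inhib <- n_inhib + sum(grn$edges$sign < 0)
  }
  se <- sqrt(frac * (1 - frac) / n_edges)
  expect_lt(abs(n_inhib / n_edges - frac), 3 * se)
})

test_that("expression without regulation is uncorrelated noise;
           a strong linear edge gives the closed-form correlation", {
  # W = 0: expected pairwise correlation 0
  null_grn <- toy_grn(matrix(0, 3, 3), n_genes = 12)
  em0 <- simulate_expression(null_grn, plain_plan(60), noise_sd = 0.5,
                             probe_noise_sd = 0, seed = 4)
  cc <- cor(t(em0$values))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.12)

  # two-gene chain, weight w: x_v = w x_u + noise, both driven by equal
  # noise sd => cor = w / sqrt(1 + w^2) = 0.6247 at w = 0.8
  w <- 0.8
  chain <- toy_grn(matrix(c(0, w, 0, 0), 2, 2, byrow = TRUE), n_genes = 2)
  em <- simulate_expression(chain, plain_plan(400), noise_sd = 0.5,
                            probe_noise_sd = 0, seed = 5)
  got <- cor(em$values["G001_p1", ], em$values["G002_p1", ])
  expect_equal(got, w / sqrt(1 + w^2), tolerance = 0.1)

  # hard saturation attenuates the same chain's correlation
  em_sat <- simulate_expression(chain, plain_plan(400), noise_sd = 0.5,
                                probe_noise_sd = 0, seed = 5,
                                transfer = "clip", sat_scale = 0.3)
  got_sat <- cor(em_sat$values["G001_p1", ], em_sat$values["G002_p1", ])
  expect_lt(got_sat, got)
})

test_that("clamp perturbations propagate with the product of edge signs", {
  # chain u -(+0.8)-> v -(-0.8)-> w : loss of u lowers v and raises w
  W <- matrix(0, 3, 3); W[1, 2] <- 0.8; W[2, 3] <- -0.8
  grn <- toy_grn(W, n_genes = 3)
  pert <- simulate_perturbation(grn, "G001", "loss", replicates = 40,
                                noise_sd = 0.1, probe_noise_sd = 0,
                                seed = 6, delta = 2.5)
  fc <- fold_change_vector(
    pert, pert$samples$sample_id[pert$samples$role == "case"],
    pert$samples$sample_id[pert$samples$role == "control"])
  expect_lt(fc["G001_p1"], -2)                    # clamped gene itself
  expect_lt(fc["G002_p1"], -1)                    # downstream, + edge
  expect_gt(fc["G003_p1"], 0.5)                   # two edges, sign product -
  # determinism and metadata contract
  pert2 <- simulate_perturbation(grn, "G001", "loss", replicates = 40,
                                 noise_sd = 0.1, probe_noise_sd = 0,
                                 seed = 6, delta = 2.5)
  expect_identical(pert$values, pert2$values)
  expect_error(simulate_perturbation(grn, "NOPE", "loss"), "unknown gene")

  # a gene with no outgoing edges moves only itself in expectation
  sink <- simulate_perturbation(grn, "G003", "loss", replicates = 40,
                                noise_sd = 0.1, probe_noise_sd = 0, seed = 7)
  fcs <- fold_change_vector(
    sink, sink$samples$sample_id[sink$samples$role == "case"],
    sink$samples$sample_id[sink$samples$role == "control"])
  expect_lt(fcs["G003_p1"], -2)
  expect_lt(max(abs(fcs[c("G001_p1", "G002_p1")])), 0.15)
})

test_that("emitted evidence is noiseless at alpha=1 and conserves counts", {
  grn <- sample_grn(n_genes = 30, density = 0.05, seed = 8, n_noeffect = 20)
  ev <- emit_evidence(grn, noise = noise_model(alpha = 1, beta = 0),
                      n_per_pair = 2, seed = 9)
  expect_identical(nrow(ev), 2L * (nrow(grn$edges) + nrow(grn$no_effect)))
  obs <- canonicalize_evidence(ev)
  want <- c(activating = 1L, none = 0L, inhibiting = -1L)[ev$true_mode]
  expect_identical(obs$sign, unname(want))
  # records are schema-valid as written
  path <- withr::local_tempfile(fileext = ".csv")
  write_evidence_table(ev, path)
  expect_identical(nrow(read_evidence_table(path)), nrow(ev))
})

test_that("emitted observation signs follow the noise-model frequencies", {
  # single-edge GRN sampled many times via n_per_pair draws
  W <- matrix(0, 3, 3); W[1, 2] <- 0.8
  grn <- toy_grn(W, n_genes = 3)
  nm <- noise_model(0.9, 0.05)
  ev <- emit_evidence(grn, noise = nm, n_per_pair = 6000, seed = 10,
                      include_noeffect = FALSE)
  s <- canonicalize_evidence(ev)$sign
  freq <- c(mean(s == 1), mean(s == 0), mean(s == -1))
  se <- sqrt(nm$P[, "activating"] * (1 - nm$P[, "activating"]) / length(s))
  expect_true(all(abs(freq - nm$P[, "activating"]) < 3 * se + 1e-9))
})

test_that("benchmark bundles satisfy the study-composition contract", {
  st <- get_benchmark()
  expect_s3_class(st$grn, "ground_truth_grn")
  expect_s3_class(st$expression, "expr_matrix")
  classes <- unique(st$expression$samples$condition_class)
  expect_true(all(c("time_series", "genetic_perturbation") %in% classes))
  # every evidence record's pair has a defined true mode
  key <- function(d) paste(d$regulator, d$target)
  expect_true(all(key(st$evidence) %in% key(st$truth)))
  expect_identical(nrow(st$evidence), 3L * nrow(st$truth))
  # perturbation contrasts resolve to case and control samples
  cs <- contrast_samples(st, st$perturbations$gene[1],
                         st$perturbations$tissue[1])
  expect_gte(length(cs$case), 2)
  expect_gte(length(cs$control), 2)
  # different seeds give different graphs under identical composition
  st2 <- make_benchmark("tooth_like", seed = 2)
  expect_false(identical(st2$grn$edges, st$grn$edges))
  expect_identical(nrow(st2$grn$no_effect), nrow(st$grn$no_effect))
  expect_identical(length(st2$grn$genes), length(st$grn$genes))
})

test_that("the heart-like preset scales down and includes phenotype arrays", {
  st <- make_benchmark("heart_like", seed = 3)
  expect_identical(length(st$grn$genes), 140L)
  expect_true("phenotype_difference" %in%
                st$expression$samples$condition_class)
  expect_lt(ncol(st$expression$values), 90)
})
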