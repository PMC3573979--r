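test_that("network generation is fully determined by the seed", {
  a <- generate_network(seed = 91)
  b <- generate_network(seed = 91)
  expect_identical(binding_edges(a$binding), binding_edges(b$binding))
  expect_identical(a$w_edges, b$w_edges)
  expect_identical(a$autoreg, b$autoreg)
  expect_identical(a$input_edges, b$input_edges)
  c_ <- generate_network(seed = 92)
  expect_false(identical(a$w_edges, c_$w_edges))
})

test_that("generated networks respect the structural exclusion everywhere", {
  for (s in 93:102) {
    nm <- generate_network(n_genes = 5, n_tfs = 3, seed = s)
    b <- unclass(nm$binding)
    expect_true(all(b[cbind(nm$w_edges$tf, nm$w_edges$source)] == 0))
  }
})

test_that("every generated TF binds a gene and has a regulating gene", {
  for (s in 103:108) {
    nm <- generate_network(n_genes = 5, n_tfs = 3, seed = s)
    b <- unclass(nm$binding)
    expect_true(all(rowSums(b) >= 1))
    expect_true(all(nm$tfs %in% nm$w_edges$tf))
  }
})

test_that("continuous generation enforces spectral stability", {
  for (s in 109:113) {
    nm <- generate_network(n_genes = 5, n_tfs = 3, seed = s,
                           stability_margin = 0.01)
    ev <- eigen(system_matrix(nm)$A, only.values = TRUE)$values
    expect_lt(max(Re(ev)), -0.01)
  }
})

test_that("grid-based generation keeps difference trajectories bounded on the horizon", {
  gaps <- diff(c(0, 3, 6, 12, 24))
  for (s in 114:118) {
    nm <- generate_network(n_genes = 5, n_tfs = 2, seed = s,
                           tf_gene_density = 0.8, gene_tf_density = 0.7,
                           coeff_ranges = list(w = c(0.1, 0.3),
                                               a = c(-0.3, -0.08),
                                               d = c(0.1, 0.3)),
                           discrete_gaps = gaps, discrete_bound = 3)
    A <- system_matrix(nm)$A
    P <- diag(5)
    for (g in gaps) {
      P <- (diag(5) + g * A) %*% P
      expect_lte(norm(P, "2"), 3)
    }
  }
})

test_that("noise-free data gives identical replicates; noisy data does not", {
  nm <- generate_network(seed = 119)
  ds0 <- generate_data(nm, R = 2, sigma = 0, seed = 1)
  expect_identical(ds0$values[, , 1], ds0$values[, , 2])
  ds1 <- generate_data(nm, R = 2, sigma = 0.05, seed = 1)
  expect_false(identical(ds1$values[, , 1], ds1$values[, , 2]))
})

test_that("generated data is rescaled to maximal absolute value one", {
  nm <- generate_network(seed = 120)
  ds <- generate_data(nm, sigma = 0, seed = 2)
  expect_equal(max(abs(ds$values)), 1)
  # the attached truth is coordinate-matched: w and a unchanged, d rescaled
  truth <- attr(ds, "truth")
  expect_identical(truth$w_edges, nm$w_edges)
  expect_identical(truth$autoreg, nm$autoreg)
  s <- attr(ds, "scale")
  expect_equal(truth$input_edges$weight, nm$input_edges$weight / s)
})

test_that("noise-free grid-process data satisfies the difference equation exactly", {
  nm <- generate_network(n_genes = 4, n_tfs = 2, seed = 121,
                         tf_gene_density = 0.8, gene_tf_density = 0.7,
                         coeff_ranges = list(w = c(0.1, 0.3),
                                             a = c(-0.3, -0.08),
                                             d = c(0.1, 0.3)),
                         discrete_gaps = diff(c(0, 3, 6, 12, 24)),
                         discrete_bound = 3)
  ds <- generate_data(nm, sigma = 0, dynamics = "euler", dt = NULL, seed = 3)
  truth <- attr(ds, "truth")
  sm <- system_matrix(truth)
  for (m in 2:length(ds$times)) {
    g <- ds$times[m] - ds$times[m - 1]
    x_prev <- ds$values[, m - 1, 1]
    u <- vapply(truth$inputs, eval_input, 0, t = ds$times[m - 1])
    x_next <- x_prev + g * drop(sm$A %*% x_prev + sm$D %*% u)
    expect_equal(ds$values[, m, 1], x_next, tolerance = 1e-12)
  }
})

test_that("the default scenario has the shape of the motivating study design", {
  scen <- synthetic_scenario(seed = 122)
  expect_equal(scen$data$times, c(0, 3, 6, 12, 24))
  expect_equal(n_replicates(scen$data), 3L)
  expect_equal(length(scen$network$genes), 5L)
  expect_lte(max(abs(scen$data$values)), 1 + 4 * scen$sigma)
  # candidates contain every planted relation plus decoys
  true_rel <- binding_edges(scen$network$binding)
  expect_true(all(paste(true_rel$tf, true_rel$gene) %in%
                    paste(scen$candidates$tf, scen$candidates$gene)))
  expect_gte(nrow(scen$candidates), nrow(true_rel))
  # seed determinism
  scen2 <- synthetic_scenario(seed = 122)
  expect_identical(scen$data$values, scen2$data$values)
  expect_identical(scen$candidates, scen2$candidates)
})

test_that("scoring counts true and false edges as plain set arithmetic", {
  genes <- paste0("g", 1:4)
  mk <- function(edges, sources) {
    bm <- augment_artificial_tfs(
      binding_matrix(data.frame(tf = edges$tf, gene = edges$gene),
                     genes = genes))
    network_model(genes, bm, w_edges = sources)
  }
  truth <- mk(data.frame(tf = "T1", gene = c("g1", "g2")),
              data.frame(tf = "T1", source = c("g3", "g4"),
                         weight = c(0.5, -0.2)))
  # inferred: 3 of 4 gene-to-TF edges correct
  inferred <- mk(data.frame(tf = "T1", gene = c("g1", "g2")),
                 data.frame(tf = c("T1", "T1", "AT_g3", "AT_g4"),
                            source = c("g3", "g4", "g1", "g1"),
                            weight = c(0.6, -0.1, 0.3, 0.2)))
  sc <- score_inference(truth, inferred)
  expect_equal(sc$gene_to_tf$tp, 2L)
  expect_equal(sc$gene_to_tf$precision, 0.5)
  expect_equal(sc$gene_to_tf$recall, 1)
  expect_equal(sc$gene_to_tf$f1, 2 * 0.5 * 1 / 1.5)
  expect_equal(sc$sign_accuracy, 1)
  expect_equal(sc$coef_rmse, sqrt(mean(c(0.1, 0.1)^2)))
  # TF-to-gene relations exclude artificial TFs on both sides
  expect_equal(sc$tf_to_gene$precision, 1)
  expect_equal(sc$tf_to_gene$recall, 1)
})

test_that("an identical network scores perfectly and an empty one by convention", {
  scen <- synthetic_scenario(seed = 123)
  truth <- scen$network
  sc <- score_inference(truth, truth)
  expect_equal(sc$gene_to_tf$precision, 1)
  expect_equal(sc$gene_to_tf$recall, 1)
  expect_equal(sc$gene_to_tf$f1, 1)
  expect_equal(sc$coef_rmse, 0)
  empty <- network_model(truth$genes,
                         augment_artificial_tfs(
                           binding_matrix(NULL, genes = truth$genes)))
  sc0 <- score_inference(truth, empty)
  expect_equal(sc0$gene_to_tf$recall, 0)
  expect_equal(sc0$gene_to_tf$precision, 1)  # empty-set convention
  expect_true(sc0$gene_to_tf$empty_inferred)
  other <- network_model("gX", augment_artificial_tfs(
    binding_matrix(NULL, genes = "gX")))
  expect_error(score_inference(truth, other), "gene sets")
})

test_that("generated datasets satisfy the dataset invariants unchanged", {
  for (s in 124:126) {
    scen <- synthetic_scenario(seed = s, sigma = 0.05)
    ds <- scen$data
    expect_s3_class(ds, "expression_dataset")
    expect_false(anyNA(ds$values))
    expect_true(!is.unsorted(ds$times, strictly = TRUE))
    sc <- scale_profiles(scale_profiles(ds))
    expect_equal(sc$values, scale_profiles(ds)$values)
  }
})
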