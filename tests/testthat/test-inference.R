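test_that("a zero-signal dataset yields an empty coefficient network", {
  genes <- c("g1", "g2")
  ds <- expression_dataset(matrix(0, 2, 5), genes = genes, times = 0:4)
  bm <- augment_artificial_tfs(binding_matrix(NULL, genes = genes))
  fit <- extilar_fit(ds, bm)
  expect_equal(nrow(fit$w_edges), 0L)
  expect_equal(sum(fit$autoreg != 0), 0L)
  expect_equal(fit$diagnostics$rss, 0)
})

test_that("noise-free difference-equation data recovers the planted coefficients", {
  scen <- synthetic_scenario(seed = 71, sigma = 0)
  ctl <- extilar_control(measured_only = TRUE)
  fit <- suppressWarnings(extilar_fit(scen$data, scen$network$binding,
                                      inputs = scen$network$inputs,
                                      control = ctl))
  truth <- scen$network
  # every planted gene-to-TF weight is recovered with matching sign and value
  tk <- paste(truth$w_edges$tf, truth$w_edges$source)
  ik <- paste(fit$w_edges$tf, fit$w_edges$source)
  expect_true(all(tk %in% ik))
  m <- match(tk, ik)
  expect_equal(fit$w_edges$weight[m], truth$w_edges$weight,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$autoreg[truth$genes], truth$autoreg[truth$genes],
               tolerance = 1e-6)
  expect_lt(fit$diagnostics$rss, 1e-12)
})

test_that("stronger prior integration never loses prior-supported edges (fixed data)", {
  scen <- synthetic_scenario(seed = 72, sigma = 0.05)
  truth <- scen$network
  pk <- prior_knowledge(gene_to_tf = data.frame(gene = truth$w_edges$source,
                                                tf = truth$w_edges$tf))
  counts <- vapply(c(1, 0.1), function(d) {
    ctl <- extilar_control(delta = d, measured_only = TRUE)
    fit <- suppressWarnings(extilar_fit(scen$data, truth$binding, pk = pk,
                                        inputs = truth$inputs, control = ctl))
    evaluate_network(fit, pk)$n_prior_supported
  }, 0)
  expect_gte(counts[2], counts[1])
})

test_that("forward selection with no candidates returns the base-structure model", {
  set.seed(73)
  ds <- random_dataset(3, c(0, 3, 6, 12, 24), 2)
  u <- input_signal("exponential-decay", lambda = 0.5)
  fit <- extilar(ds, candidates = NULL, inputs = list(u))
  expect_s3_class(fit, "extilar")
  expect_equal(nrow(fit$trace), 1L)
  expect_equal(fit$final_iteration, 0L)
  # only artificial TFs in the structure
  expect_true(all(binding_edges(fit$binding)$origin == "artificial"))
})

test_that("the forward-selection RSS trace is strictly decreasing", {
  scen <- synthetic_scenario(seed = 74, sigma = 0.01)
  fit <- suppressWarnings(
    extilar(scen$data, scen$candidates, inputs = scen$network$inputs,
            control = extilar_control(measured_only = TRUE), scale = FALSE))
  rssv <- fit$trace$rss[is.finite(fit$trace$rss)]
  expect_true(all(diff(rssv) < 0))
})

test_that("the returned model minimizes Pm over all iteration snapshots", {
  scen <- synthetic_scenario(seed = 75, sigma = 0.01)
  fit <- suppressWarnings(
    extilar(scen$data, scen$candidates, inputs = scen$network$inputs,
            control = extilar_control(measured_only = TRUE), scale = FALSE))
  expect_equal(fit$trace$pm[fit$final_iteration + 1L], min(fit$trace$pm))
  expect_equal(fit$diagnostics$rss,
               fit$trace$rss[fit$final_iteration + 1L])
})

test_that("a single RSS-reducing candidate is added once and the loop stops", {
  scen <- synthetic_scenario(seed = 76, sigma = 0)
  truth <- scen$network
  one <- binding_edges(truth$binding)[1, c("tf", "gene")]
  fit <- suppressWarnings(
    extilar(scen$data, one, inputs = truth$inputs,
            control = extilar_control(measured_only = TRUE,
                                      cp_form = "classical"),
            scale = FALSE))
  expect_lte(nrow(fit$trace), 2L)
  added <- fit$trace[-1, ]
  if (nrow(added)) {
    expect_equal(added$tf, one$tf)
    expect_equal(added$gene, one$gene)
  }
})

test_that("inference is deterministic: same data, same model, byte-identical export", {
  scen <- synthetic_scenario(seed = 77, sigma = 0.05)
  run <- function() {
    fit <- suppressWarnings(
      extilar(scen$data, scen$candidates, inputs = scen$network$inputs,
              control = extilar_control(measured_only = TRUE), scale = FALSE))
    path <- tempfile(fileext = ".json")
    export_network_json(fit, path)
    readLines(path)
  }
  expect_identical(run(), run())
})

test_that("precision arithmetic reproduces worked edge-count ratios", {
  expect_equal(round(precision_from_counts(25, 49), 4), 0.5102)
  expect_equal(round(precision_from_counts(60, 81), 4), 0.7407)
  expect_equal(round(precision_from_counts(77, 119), 4), 0.6471)
  expect_equal(precision_from_counts(0, 10), 0)
})

test_that("network evaluation counts edges and prior support correctly", {
  genes <- c("g1", "g2", "g3")
  bm <- augment_artificial_tfs(
    binding_matrix(data.frame(tf = "T1", gene = c("g1", "g3")), genes = genes))
  nm <- network_model(genes, bm,
                      w_edges = data.frame(tf = "T1", source = "g2",
                                           weight = 0.5),
                      autoreg = c(g1 = -0.2, g2 = -0.1))
  pk <- prior_knowledge(
    gene_to_tf = data.frame(gene = "g2", tf = "T1"),
    validation = data.frame(src_gene = c("g2", "g3"),
                            dst_gene = c("g1", "g1")))
  m <- evaluate_network(nm, pk)
  expect_equal(m$n_gene_to_tf, 1L)
  expect_equal(m$n_autoreg, 2L)
  expect_equal(m$n_prior_supported, 1L)
  expect_equal(m$precision, 1 / 3)  # 1 prior-supported of 1 + 2 non-input edges
  # implied paths g2 -> T1 -> {g1, g3}; validation hits only g2 -> g1
  expect_equal(m$n_validation_hits, 1L)
  m2 <- evaluate_network(nm, pk, include_autoreg = FALSE)
  expect_equal(m2$precision, 1)
})

test_that("a delta sweep returns one row per delta and is reproducible", {
  scen <- synthetic_scenario(seed = 78, sigma = 0.05)
  truth <- scen$network
  pk <- prior_knowledge(gene_to_tf = data.frame(gene = truth$w_edges$source,
                                                tf = truth$w_edges$tf))
  ctl <- extilar_control(measured_only = TRUE, max_iter = 3)
  tab <- suppressWarnings(
    delta_sweep(scen$data, scen$candidates, pk = pk, inputs = truth$inputs,
                deltas = c(1, 0.25), control = ctl, scale = FALSE))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$delta, c(1, 0.25))
  expect_true(all(tab$precision >= 0 & tab$precision <= 1))
  tab2 <- suppressWarnings(
    delta_sweep(scen$data, scen$candidates, pk = pk, inputs = truth$inputs,
                deltas = c(1, 0.25), control = ctl, scale = FALSE))
  expect_equal(tab, tab2, ignore_attr = TRUE)
})

test_that("the weight grid study covers every requested combination", {
  scen <- synthetic_scenario(seed = 79, sigma = 0.05)
  ctl <- extilar_control(measured_only = TRUE, max_iter = 2)
  grid <- suppressWarnings(
    weight_grid_study(scen$data, scen$candidates,
                      inputs = scen$network$inputs,
                      input_weights = c(0.5, 1), autoreg_weights = c(0.75, 1),
                      control = ctl, scale = FALSE))
  expect_equal(nrow(grid), 4L)
  expect_setequal(paste(grid$input_weight, grid$autoreg_weight),
                  c("0.5 0.75", "0.5 1", "1 0.75", "1 1"))
  expect_true(all(is.finite(grid$rss)))
})

test_that("the fitted-model methods expose coefficients, fit and residuals coherently", {
  scen <- synthetic_scenario(seed = 80, sigma = 0.01)
  fit <- suppressWarnings(
    extilar(scen$data, scen$candidates, inputs = scen$network$inputs,
            control = extilar_control(measured_only = TRUE), scale = FALSE))
  beta <- coef(fit, all = TRUE)
  expect_equal(length(beta), ncol(fit$problem$X))
  expect_equal(fitted(fit), as.numeric(fit$problem$X %*% beta))
  expect_equal(residuals(fit), fit$problem$y - fitted(fit))
  expect_equal(sum(residuals(fit)^2), fit$diagnostics$rss)
  expect_equal(unname(predict(fit)), fitted(fit), ignore_attr = TRUE)
  expect_output(print(fit), "gene-to-TF")
  expect_output(print(summary(fit)), "RSS")
  # simulate() is seed-stable and returns a trajectory over the data horizon
  tr <- simulate(fit, x0 = setNames(scen$data$values[, 1, 1], fit$genes),
                 times = scen$data$times)
  expect_s3_class(tr, "network_trajectory")
  expect_equal(nrow(tr$states), length(scen$data$times))
})
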