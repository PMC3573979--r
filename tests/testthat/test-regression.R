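test_that("forward differences divide by the transition length", {
  ds <- expression_dataset(matrix(c(0, 0.5, 1), 1, 3), genes = "g1",
                           times = 0:2)
  resp <- build_response(ds)
  expect_equal(resp$y, c(0.5, 0.5))
  ds2 <- expression_dataset(matrix(c(0, 1), 1, 2), genes = "g1", times = c(0, 2))
  resp2 <- build_response(ds2, measured_only = TRUE)
  expect_equal(resp2$y, 0.5)
  expect_equal(resp2$row_meta$dt, 2)
})

test_that("a constant profile yields an all-zero response", {
  ds <- expression_dataset(matrix(1.3, 2, 4), genes = c("g1", "g2"), times = 0:3)
  expect_equal(build_response(ds)$y, rep(0, (4 - 1) * 2))
})

test_that("response rows are ordered gene-major, then replicate, then time", {
  set.seed(31)
  ds <- random_dataset(2, 0:2, 2)
  resp <- build_response(ds)
  rm_ <- resp$row_meta
  expect_equal(rm_$gene, rep(c("g1", "g2"), each = 4))
  expect_equal(rm_$rep, rep(rep(1:2, each = 2), 2))
  expect_equal(rm_$m, rep(2:3, 4))
})

test_that("design dimensions follow the closed-form row and column counts", {
  # hand case: N=3, F=2, B=3, all genes bound, M=5, R=3, U=2 -> 36 x 8
  genes <- paste0("g", 1:3)
  set.seed(32)
  ds <- random_dataset(3, c(0, 1, 2, 3, 4), 3)
  bm <- binding_matrix(data.frame(tf = c("T1", "T1", "T2"),
                                  gene = c("g1", "g2", "g3")), genes = genes)
  u <- input_signal("exponential-decay", lambda = 0.5)
  pk <- prior_knowledge(input_to_gene = data.frame(input = "input",
                                                   gene = c("g1", "g3")))
  rp <- build_design(ds, bm, pk = pk, inputs = list(u))
  expect_equal(dim(rp$X), c(36L, 8L))
  expect_equal(rp$dims$M_pp, (5 - 1) * 3 * 3)
  expect_equal(rp$dims$N_pp, (2 * 3 - 3) + 2 + 3)
  expect_equal(length(rp$y), nrow(rp$X))
})

test_that("randomized configurations always match the dimension formulas", {
  set.seed(33)
  for (i in 1:25) {
    N <- sample(2:6, 1); F_ <- sample(1:3, 1)
    M <- sample(3:6, 1); R <- sample(1:3, 1)
    genes <- paste0("g", seq_len(N))
    ds <- random_dataset(N, seq_len(M) - 1, R)
    b <- matrix(rbinom(F_ * N, 1, 0.5), F_, N)
    for (k in which(rowSums(b) == 0)) b[k, sample.int(N, 1)] <- 1
    idx <- which(b == 1, arr.ind = TRUE)
    bm <- binding_matrix(data.frame(tf = paste0("T", idx[, 1]),
                                    gene = genes[idx[, 2]]), genes = genes)
    with_input <- runif(1) < 0.7
    inputs <- if (with_input) list(input_signal("constant", value = 1)) else list()
    rp <- build_design(ds, bm, inputs = inputs)
    d <- rp$dims
    B <- sum(unclass(bm))
    N_r_prime <- sum(colSums(unclass(bm)) > 0 | (with_input & rep(TRUE, N)))
    expect_equal(nrow(rp$X), (M - 1) * N_r_prime * R)
    expect_equal(ncol(rp$X), (nrow(bm) * N - B) + d$U + N_r_prime)
    expect_equal(d$M_pp, nrow(rp$X))
    expect_equal(d$N_pp, ncol(rp$X))
  }
})

test_that("no design column pairs a TF with a gene it binds", {
  set.seed(34)
  genes <- paste0("g", 1:4)
  ds <- random_dataset(4, 0:3, 2)
  bm <- binding_matrix(data.frame(tf = c("T1", "T1", "T2"),
                                  gene = c("g1", "g2", "g3")), genes = genes)
  bm <- augment_artificial_tfs(bm)
  rp <- build_design(ds, bm)
  cm <- rp$col_meta
  g2t <- cm[cm$type == "gene_to_tf", ]
  b <- unclass(bm)
  expect_true(all(b[cbind(g2t$tf, g2t$source)] == 0))
})

test_that("a hand-enumerated two-gene design matches entry by entry", {
  # TF A binds gene 1 only; gene 2 is the only legal source for A
  genes <- c("g1", "g2")
  vals <- rbind(c(0.2, 0.5, -0.1), c(1.0, -0.4, 0.3))
  ds <- expression_dataset(vals, genes = genes, times = 0:2)
  bm <- binding_matrix(data.frame(tf = "A", gene = "g1"), genes = genes)
  bm <- augment_artificial_tfs(bm)
  rp <- build_design(ds, bm)
  lbl <- colnames(rp$X)
  # rows of gene 1: column (A, g2) carries x_2 at the previous time point
  r_g1 <- which(rp$row_meta$gene == "g1")
  expect_equal(rp$X[r_g1, "w:g2>A"], vals[2, rp$row_meta$m[r_g1] - 1])
  # ...and zero in every other gene-to-TF column
  other <- setdiff(grep("^w:", lbl, value = TRUE), "w:g2>A")
  for (cc in other) expect_true(all(rp$X[r_g1, cc] == 0))
  # rows of gene 2 never see column (A, g2): A does not bind gene 2
  r_g2 <- which(rp$row_meta$gene == "g2")
  expect_true(all(rp$X[r_g2, "w:g2>A"] == 0))
  # auto-regulation columns are diagonal in the gene blocks
  expect_equal(rp$X[r_g1, "a:g1"], vals[1, rp$row_meta$m[r_g1] - 1])
  expect_true(all(rp$X[r_g2, "a:g1"] == 0))
})

test_that("a gene-to-TF column is shared across all targets of the TF", {
  genes <- c("g1", "g2", "g3")
  set.seed(35)
  ds <- random_dataset(3, 0:3, 1)
  bm <- binding_matrix(data.frame(tf = "T1", gene = c("g1", "g3")),
                       genes = genes)
  bm <- augment_artificial_tfs(bm)
  rp <- build_design(ds, bm)
  col <- rp$X[, "w:g2>T1"]
  rm_ <- rp$row_meta
  for (g in c("g1", "g3")) {
    rows <- which(rm_$gene == g)
    expect_equal(col[rows], unname(ds$values["g2", rm_$m[rows] - 1, 1]))
  }
  expect_true(all(col[rm_$gene == "g2"] == 0))
})

test_that("penalty weights map prior support and column types correctly", {
  genes <- c("g1", "g2")
  set.seed(36)
  ds <- random_dataset(2, 0:2, 1)
  bm <- augment_artificial_tfs(
    binding_matrix(data.frame(tf = "A", gene = "g1"), genes = genes))
  pk <- prior_knowledge(gene_to_tf = data.frame(gene = "g2", tf = "A"))
  ws <- weight_scheme(delta_prior = 0.25, delta_default = 1,
                      input_weight = 0.5, autoreg_weight = 0.75)
  u <- input_signal("constant", value = 1)
  rp <- build_design(ds, bm, pk = pk, inputs = list(u), weights = ws)
  pen <- setNames(rp$penalty, colnames(rp$X))
  expect_equal(unname(pen["w:g2>A"]), 0.25)
  expect_equal(unname(pen["a:g1"]), 0.75)
  expect_equal(unname(pen["d:input>g1"]), 0.5)
  unsupported <- setdiff(grep("^w:", names(pen), value = TRUE), "w:g2>A")
  expect_true(all(pen[unsupported] == 1))
})

test_that("one-step prediction matches a naive double-loop model evaluation", {
  set.seed(37)
  genes <- paste0("g", 1:3)
  ds <- random_dataset(3, 0:3, 2)
  bm <- augment_artificial_tfs(
    binding_matrix(data.frame(tf = c("T1", "T1"), gene = c("g1", "g2")),
                   genes = genes))
  u <- input_signal("exponential-decay", lambda = 0.4)
  rp <- build_design(ds, bm, inputs = list(u))
  beta <- rnorm(ncol(rp$X), sd = 0.3)
  yhat <- one_step_predict(rp, beta)
  # reshape beta into the model's named coefficient blocks
  cm <- rp$col_meta
  b <- unclass(bm)
  w <- matrix(0, nrow(b), ncol(b), dimnames = dimnames(b))
  is_w <- cm$type == "gene_to_tf"
  w[cbind(cm$tf[is_w], cm$source[is_w])] <- beta[is_w]
  a <- setNames(numeric(3), genes)
  is_a <- cm$type == "autoreg"
  a[cm$gene[is_a]] <- beta[is_a]
  dmat <- matrix(0, 1, 3, dimnames = list("input", genes))
  is_d <- cm$type == "input"
  dmat[cbind(cm$input[is_d], cm$gene[is_d])] <- beta[is_d]
  for (row in seq_along(yhat)) {
    rm_ <- rp$row_meta[row, ]
    expect_equal(yhat[row],
                 naive_row_value(ds, b, w, a, dmat, list(u),
                                 rm_$gene, rm_$m, rm_$rep))
  }
  expect_error(one_step_predict(rp, beta[-1]), "length")
})

test_that("measured-only rows skip interpolated grid points", {
  set.seed(38)
  ds <- random_dataset(2, c(0, 3, 6, 12, 24), 2)
  eq <- interpolate_to_grid(ds, 1)
  bm <- augment_artificial_tfs(binding_matrix(NULL, genes = ds$genes))
  rp_full <- build_design(eq, bm)
  rp_meas <- build_design(eq, bm, measured_only = TRUE)
  expect_equal(nrow(rp_full$X), 24 * 2 * 2)
  expect_equal(nrow(rp_meas$X), 4 * 2 * 2)
  expect_setequal(unique(rp_meas$row_meta$dt), c(3, 6, 12))
})
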