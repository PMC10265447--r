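small_dti <- function(seed = 1, n_cells = 400, nd = 40, np = 30) {
  ds <- generate_dti(synthetic_spec(n_drugs = nd, n_proteins = np,
                                    n_cells = n_cells), seed = seed)
  g <- er_graph()
  g <- add_entity(g, "drug", nd, embedding_dim = 8, module_width = 6,
                  module_depth = 2)
  g <- add_entity(g, "protein", np, embedding_dim = 8, module_width = 6,
                  module_depth = 2)
  list(ds = ds,
       graph = add_relation(g, "dti", "drug", "protein", ds$cells,
                            module = list(hidden = 6, head_width = 6)))
}

test_that("training reduces the loss and the history has one row per epoch", {
  sd <- small_dti()
  m <- fit(sd$graph, config = train_config(epochs = 40, batch_size = 256,
                                           seed = 5, patience = Inf))
  expect_equal(nrow(m$history), 40)
  expect_lt(m$history$global[40], m$history$global[1])
})

test_that("fits are bit-identical under the same seed", {
  sd <- small_dti()
  cfg <- train_config(epochs = 8, batch_size = 128, seed = 7)
  m1 <- fit(sd$graph, config = cfg)
  m2 <- fit(sd$graph, config = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params[["e.drug.emb"]], m2$params[["e.drug.emb"]])
  m3 <- fit(sd$graph, config = train_config(epochs = 8, batch_size = 128,
                                            seed = 8))
  expect_false(identical(m1$history$global, m3$history$global))
})

test_that("zero epochs returns the initialized model with empty history", {
  sd <- small_dti()
  m0 <- fit(sd$graph, config = train_config(epochs = 0, seed = 9))
  init <- init_er_model(sd$graph, seed = 9)
  expect_identical(m0$params[["e.drug.emb"]], init$params[["e.drug.emb"]])
  expect_equal(nrow(m0$history), 0)
})

test_that("empty or unfrozen-empty relations are rejected", {
  sd <- small_dti()
  expect_error(fit(sd$graph, train = list(dti = integer(0))),
               "empty main relation")
})

test_that("prediction flags untrained entity instances and is deterministic", {
  sd <- small_dti()
  tr <- which(sd$ds$cells$row != 1)  # hold out every cell of drug 1
  m <- fit(sd$graph, train = list(dti = tr),
           config = train_config(epochs = 5, seed = 3))
  pr <- predict(m, "dti", data.frame(row = c(1, 2), col = c(1, 1)))
  expect_true(pr$untrained[1])
  expect_equal(pr$prob, plogis(pr$score))
  expect_identical(pr, predict(m, "dti", data.frame(row = c(1, 2),
                                                    col = c(1, 1))))
})

test_that("evaluate guards against train/test leakage", {
  sd <- small_dti()
  m <- fit(sd$graph, train = list(dti = 1:300),
           config = train_config(epochs = 3, seed = 2))
  expect_error(evaluate(m, "dti", 300:320), "leakage")
  ev <- evaluate(m, "dti", 301:400)
  expect_true(all(c("auc", "auprc", "precision", "recall") %in% names(ev)))
})

test_that("a perfect predictor scores AUC 1 and a random one ~0.5", {
  labels <- withr_seed(11, rbinom(2000, 1, 0.5))
  scores <- withr_seed(12, runif(2000))
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)
  expect_equal(roc_auc(labels + 0.0, labels), 1)
})

test_that("training-loss plateau triggers early stopping", {
  sd <- small_dti()
  m <- fit(sd$graph, config = train_config(epochs = 500, batch_size = 256,
                                           seed = 4, patience = 5,
                                           min_delta = 0.05))
  expect_lt(nrow(m$history), 500)
})

test_that("auxiliary self-relations train jointly and respect the cap", {
  sd <- small_dti()
  S <- derive_similarity(sd$ds$drug_factors, noise_sd = 0.05, seed = 6)
  g <- sd$graph
  g <- add_relation(g, "dsim", "drug", "drug",
                    data.frame(row = rep(1:40, 40), col = rep(1:40, each = 40),
                               value = as.vector(S)),
                    task = "regression")
  m <- fit(g, config = train_config(epochs = 10, batch_size = 256, seed = 5,
                                    per_relation_cap = 200))
  expect_true(all(c("dti", "dsim") %in% names(m$history)))
  expect_lt(m$history$dsim[10], m$history$dsim[1])
})

test_that("regression relations are evaluated with MSE and CI", {
  spec <- synthetic_spec(n_drugs = 40, n_proteins = 30, n_cells = 500,
                         noise_sd = 0.1)
  ds <- generate_affinity(spec, seed = 3)
  g <- er_graph()
  g <- add_entity(g, "drug", 40, 8, 6, 2)
  g <- add_entity(g, "protein", 30, 8, 6, 2)
  g <- add_relation(g, "aff", "drug", "protein", ds$cells,
                    task = "regression", module = list(hidden = 6))
  m <- fit(g, train = list(aff = 1:400),
           config = train_config(epochs = 150, batch_size = 256, seed = 8,
                                 patience = Inf))
  ev <- evaluate(m, "aff", 401:500)
  expect_true(all(c("mse", "ci") %in% names(ev)))
  expect_gt(ev$ci, 0.6)  # fitted model ranks held-out affinities
})
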