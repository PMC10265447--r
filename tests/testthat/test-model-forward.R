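test_that("entity latents have the configured width and are deterministic", {
  g <- tiny_graph()
  g <- add_entity(g, "wide", 5, embedding_dim = 30, module_width = 20)
  m <- init_er_model(g, seed = 2)
  lat <- entity_latent(m, "wide", 1:5)
  expect_equal(dim(lat), c(5, 20))
  expect_identical(lat, entity_latent(m, "wide", 1:5))
  expect_error(entity_latent(m, "wide", 6), "out of range")
  expect_error(entity_latent(m, "nope", 1), "unknown entity")
})

test_that("models initialized with the same seed are identical", {
  g <- tiny_graph()
  m1 <- init_er_model(g, seed = 11)
  m2 <- init_er_model(g, seed = 11)
  expect_identical(entity_latent(m1, "drug", 1:8),
                   entity_latent(m2, "drug", 1:8))
  m3 <- init_er_model(g, seed = 12)
  expect_false(identical(entity_latent(m1, "drug", 1:8),
                         entity_latent(m3, "drug", 1:8)))
})

test_that("relation scores are finite, order-preserving and validated", {
  g <- tiny_graph()
  m <- init_er_model(g, seed = 4)
  rows <- c(1, 5, 2, 8)
  cols <- c(3, 1, 6, 2)
  sc <- relation_score(m, "dti", rows, cols)
  expect_length(sc, 4)
  expect_true(all(is.finite(sc)))
  # batch scoring preserves input order: singleton calls agree
  one <- vapply(1:4, function(i) relation_score(m, "dti", rows[i], cols[i]),
                numeric(1))
  expect_equal(sc, one)
  expect_error(relation_score(m, "dti", 1:2, 1), "equal length")
  expect_error(relation_score(m, "dti", 9, 1), "out of range")
  expect_error(relation_score(m, "nope", 1, 1), "unknown relation")
})

test_that("a pure bilinear module computes u' W v exactly", {
  g <- er_graph()
  g <- add_entity(g, "a", 4, embedding_dim = 2, module_depth = 0)
  g <- add_entity(g, "b", 3, embedding_dim = 2, module_depth = 0)
  g <- add_relation(g, "r", "a", "b",
                    data.frame(row = 1, col = 1, value = 0),
                    task = "regression",
                    module = list(hidden = 1L, head_depth = 0L,
                                  activation = "identity", norm = FALSE))
  m <- init_er_model(g, seed = 9)
  m$params[["r.r.c"]] <- 0
  U <- m$params[["e.a.emb"]]
  V <- m$params[["e.b.emb"]]
  W <- m$params[["r.r.A"]]  # 2 x 2 (hidden 1)
  for (i in 1:4) for (j in 1:3) {
    manual <- as.numeric(t(U[i, ]) %*% W %*% V[j, ])
    expect_equal(relation_score(m, "r", i, j), manual, tolerance = 1e-12)
  }
})

test_that("sparse and dense side information give identical latents", {
  feat <- withr_seed(8, matrix(rbinom(8 * 12, 1, 0.25), 8, 12))
  g_dense <- add_side_info(tiny_graph(), "drug", feat)
  g_sparse <- add_side_info(tiny_graph(), "drug",
                            Matrix::Matrix(feat, sparse = TRUE))
  m_dense <- init_er_model(g_dense, seed = 21)
  m_sparse <- init_er_model(g_sparse, seed = 21)
  expect_equal(entity_latent(m_dense, "drug", 1:8),
               entity_latent(m_sparse, "drug", 1:8), tolerance = 1e-6)
})

test_that("zeroing the feature matrix removes the side-info contribution", {
  feat <- withr_seed(8, matrix(rbinom(8 * 12, 1, 0.25), 8, 12))
  g_feat <- add_side_info(tiny_graph(), "drug", feat)
  g_zero <- add_side_info(tiny_graph(), "drug", matrix(0, 8, 12))
  m_plain <- init_er_model(tiny_graph(), seed = 33)
  m_zero <- init_er_model(g_zero, seed = 33)
  m_feat <- init_er_model(g_feat, seed = 33)
  # with zero features the latent equals the embedding-only latent
  for (k in grep("^e\\.", m_plain$param_names, value = TRUE))
    m_zero$params[[k]] <- m_plain$params[[k]]
  expect_equal(entity_latent(m_zero, "drug", 1:8),
               entity_latent(m_plain, "drug", 1:8), tolerance = 1e-12)
  # with the same shared parameters, non-zero features change it
  for (k in grep("^e\\.", m_plain$param_names, value = TRUE))
    m_feat$params[[k]] <- m_plain$params[[k]]
  for (k in grep("^s\\.", m_zero$param_names, value = TRUE))
    m_feat$params[[k]] <- m_zero$params[[k]]
  expect_false(isTRUE(all.equal(entity_latent(m_feat, "drug", 1:8),
                                entity_latent(m_plain, "drug", 1:8))))
})

test_that("global_loss is an omega-weighted sum over relation batches", {
  g <- add_entity(er_graph(), "drug", 10, 6, 4, 1)
  g <- add_entity(g, "protein", 8, 6, 4, 1)
  c1 <- data.frame(row = 1:6, col = 1:6, value = c(1, 0, 1, 0, 1, 0))
  c2 <- data.frame(row = 1:4, col = c(2, 3, 4, 5), value = c(0.2, 0.4, 0.1, 0.9))
  g <- add_relation(g, "r1", "drug", "protein", c1, weight = 1)
  g <- add_relation(g, "r2", "drug", "protein", c2, task = "regression",
                    weight = 1)
  m <- init_er_model(g, seed = 6)
  l1 <- global_loss(m, list(r1 = c1))
  l2 <- global_loss(m, list(r2 = c2))
  expect_equal(global_loss(m, list(r1 = c1, r2 = c2)), l1 + l2)
  # scaling omega scales the contribution linearly
  g3 <- g
  g3$relations$r2$weight <- 3
  m3 <- init_er_model(g3, seed = 6)
  expect_equal(global_loss(m3, list(r1 = c1, r2 = c2)), l1 + 3 * l2)
  # permuting the batch leaves the loss unchanged
  perm <- withr_seed(3, sample(nrow(c1)))
  expect_equal(global_loss(m, list(r1 = c1[perm, ])), l1)
  # unobserved cells are rejected
  expect_error(global_loss(m, list(r1 = data.frame(row = 9, col = 8,
                                                   value = 1))),
               "unobserved")
})
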