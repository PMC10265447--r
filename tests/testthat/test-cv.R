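rand_cells <- function(n, nd, np, seed, binary = TRUE) {
  withr_seed(seed, {
    all <- expand.grid(row = seq_len(nd), col = seq_len(np))
    all <- all[sample(nrow(all), n), ]
    all$value <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
    rownames(all) <- NULL
    all
  })
}

test_that("random folds partition cells evenly and disjointly", {
  cells <- rand_cells(1000, 60, 50, seed = 1)
  plan <- make_folds(cells, "random", k = 5, seed = 2)
  sizes <- vapply(1:5, function(f) length(test_cells(plan, f)), integer(1))
  expect_true(all(abs(sizes - 200) <= 1))
  expect_equal(sort(unlist(lapply(1:5, test_cells, plan = plan))), 1:1000)
  for (f in 1:5)
    expect_length(intersect(train_cells(plan, f), test_cells(plan, f)), 0)
})

test_that("entity-stratified schemes keep the stratified entity out of training", {
  cells <- rand_cells(800, 40, 30, seed = 3)
  for (sc in c("protein_strat", "drug_strat")) {
    plan <- make_folds(cells, sc, k = 4, seed = 5)
    side <- if (sc == "drug_strat") "row" else "col"
    for (f in 1:4) {
      tr <- cells[[side]][train_cells(plan, f)]
      te <- cells[[side]][test_cells(plan, f)]
      expect_length(intersect(tr, te), 0)
    }
  }
})

test_that("no_strat guarantees every test entity occurs in training", {
  cells <- rand_cells(600, 30, 25, seed = 7)
  plan <- make_folds(cells, "no_strat", k = 5, seed = 8)
  for (f in 1:5) {
    tr <- train_cells(plan, f)
    te <- test_cells(plan, f)
    expect_true(all(cells$row[te] %in% cells$row[tr]))
    expect_true(all(cells$col[te] %in% cells$col[tr]))
  }
})

test_that("pair stratification discards cells with exactly one held-out endpoint", {
  cells <- rand_cells(1500, 50, 40, seed = 9)
  plan <- make_folds(cells, "pair_strat", k = 5, seed = 10)
  for (f in 1:5) {
    tr <- train_cells(plan, f)
    te <- test_cells(plan, f)
    di <- discarded_cells(plan, f)
    expect_length(intersect(cells$row[tr], cells$row[te]), 0)
    expect_length(intersect(cells$col[tr], cells$col[te]), 0)
    expect_equal(length(tr) + length(te) + length(di), nrow(cells))
    expect_gt(length(di), 0)
    dg <- plan$drug_group[as.character(cells$row[di])]
    pg <- plan$protein_group[as.character(cells$col[di])]
    expect_true(all(xor(dg == f, pg == f)))
  }
})

test_that("pair-strat discard fraction matches the combinatorial expectation", {
  # uniform entities, k = 5: E[discard] = 2(k-1)/k^2 = 32%
  fr <- vapply(1:6, function(s) {
    cells <- rand_cells(2500, 120, 100, seed = 20 + s)
    plan <- make_folds(cells, "pair_strat", k = 5, seed = 30 + s)
    mean(vapply(1:5, function(f) length(discarded_cells(plan, f)) / 2500,
                numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.32), 0.05)
})

test_that("verify_folds passes on all five schemes across seeded instances", {
  for (s in 1:4) {
    cells <- rand_cells(700, 35, 30, seed = 40 + s)
    for (sc in c("random", "no_strat", "protein_strat", "drug_strat",
                 "pair_strat")) {
      plan <- make_folds(cells, sc, k = 5, seed = 50 + s)
      expect_length(verify_folds(plan, cells), 0)
    }
  }
})

test_that("verify_folds pinpoints a corrupted serialized pair plan", {
  cells <- rand_cells(600, 30, 25, seed = 61)
  plan <- make_folds(cells, "pair_strat", k = 5, seed = 62)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fold_plan(plan, path)
  tab <- read_fold_plan(path)
  expect_length(verify_folds(plan, cells, status = tab), 0)
  # leak one held-out drug's discarded cell into fold 1 training
  f1 <- tab[tab$fold == 1, ]
  test_drugs <- unique(cells$row[f1$cell[f1$status == "test"]])
  bad_cell <- with(f1, cell[status == "discarded" &
                            cells$row[cell] %in% test_drugs])[1]
  tab$status[tab$fold == 1 & tab$cell == bad_cell] <- "train"
  v <- verify_folds(plan, cells, status = tab)
  expect_gt(length(v), 0)
  expect_true(any(grepl("drug", v)))
})

test_that("fold plans serialize to TSV and read back", {
  cells <- rand_cells(200, 20, 15, seed = 70)
  plan <- make_folds(cells, "pair_strat", k = 3, seed = 71)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fold_plan(plan, path)
  tab <- read_fold_plan(path)
  expect_equal(nrow(tab), 3 * 200)
  expect_setequal(unique(tab$status), c("train", "test", "discarded"))
  f2 <- tab[tab$fold == 2, ]
  expect_equal(which(f2$status == "test"), test_cells(plan, 2))
})

test_that("polarization_report covers the limiting cases", {
  # every entity sees both labels -> 0
  cells <- data.frame(row = rep(1:3, each = 2), col = rep(1:3, 2),
                      value = rep(c(0, 1), 3))
  expect_equal(polarization_report(cells)$overall, 0)
  # one cell per entity -> 1
  cells1 <- data.frame(row = 1:4, col = 1:4, value = c(1, 0, 1, 0))
  expect_equal(polarization_report(cells1)$overall, 1)
  expect_error(polarization_report(data.frame(row = 1, col = 1, value = 0.3)),
               "binary")
})

test_that("make_folds validates its arguments", {
  cells <- rand_cells(60, 10, 8, seed = 80)
  expect_error(make_folds(cells, "random", k = 1), "k must be")
  expect_error(make_folds(cells[1:6, ], "drug_strat", k = 7), "entities|cells")
})
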