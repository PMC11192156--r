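test_that("separable species give zero OOB error and perfect self-accuracy", {
  ft <- toy_feature_table()
  # mtry = all design columns: every split sees the separating predictor
  m <- train_forest(ft, forest_config(ntree = 50, mtry = 27, seed = 7))
  expect_identical(m$oob_error, 0)
  pr <- predict_species(m, ft)
  expect_identical(pr$species, ft$species)
  votes <- as.matrix(pr[, startsWith(names(pr), "vote_")])
  expect_equal(unname(rowSums(votes)), rep(1, nrow(ft)))
  # predicted label always has the maximal vote fraction
  expect_identical(paste0("vote_", pr$species),
                   colnames(votes)[max.col(votes, ties.method = "first")])
})

test_that("training is deterministic given the seed, and seed-sensitive", {
  ft <- toy_feature_table()
  m1 <- train_forest(ft, forest_config(ntree = 30, seed = 5))
  m2 <- train_forest(ft, forest_config(ntree = 30, seed = 5))
  m3 <- train_forest(ft, forest_config(ntree = 30, seed = 6))
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$importance, m2$importance)
  expect_false(identical(m1$trees, m3$trees))
})

test_that("row order does not matter after a canonical sort", {
  ft <- toy_feature_table()
  probe <- toy_feature_table(n_per = 10, seed = 77)
  canon <- ft[order(ft$species, ft$Area), ]
  with_seed <- get("with_seed", asNamespace("seedmorph"))
  perm <- with_seed(123, ft[sample(nrow(ft)), ])
  perm_canon <- perm[order(perm$species, perm$Area), ]
  p1 <- predict_species(train_forest(canon, forest_config(ntree = 25, seed = 1)), probe)
  p2 <- predict_species(train_forest(perm_canon, forest_config(ntree = 25, seed = 1)), probe)
  expect_identical(p1, p2)
})

test_that("single-tree votes are 0/1; empty tables predict nothing", {
  ft <- toy_feature_table()
  m <- train_forest(ft, forest_config(ntree = 1, seed = 2))
  pr <- predict_species(m, ft)
  expect_true(all(unlist(pr[, startsWith(names(pr), "vote_")]) %in% c(0, 1)))
  pr0 <- predict_species(m, ft[0, ])
  expect_identical(nrow(pr0), 0L)
  expect_identical(names(pr0), names(pr))
})

test_that("schema errors are loud: single class, unseen site, missing column", {
  ft <- toy_feature_table()
  expect_error(train_forest(ft[ft$species == "A", ], forest_config(10)),
               "at least 2 species")
  m <- train_forest(ft, forest_config(ntree = 10, seed = 1))
  bad_site <- ft; bad_site$Site[1] <- "S99"
  expect_error(predict_species(m, bad_site), "S99")
  expect_error(predict_species(m, ft[, setdiff(names(ft), "Circ")]), "Circ")
  expect_error(train_forest(ft, forest_config(ntree = 10, mtry = 100)), "mtry")
})

test_that("importance: constant predictors get exactly 0; signal ranks first", {
  ft <- toy_feature_table()
  ft$Perim <- 1  # constant -> never selectable by any split
  m <- train_forest(ft, forest_config(ntree = 40, seed = 3))
  imp <- forest_importance(m)
  expect_identical(unname(imp["Perim"]), 0)
  expect_true(all(imp >= 0))
  expect_identical(names(imp)[1], "Area")
})

test_that("default mtry and tuning tie-breaks", {
  expect_identical(default_mtry(26), 5L)
  ft <- toy_feature_table()
  tu <- tune_forest(ft, ntree_grid = c(100, 500), mtry_grid = 5, seed = 3)
  expect_identical(nrow(tu$grid), 2L)
  expect_true(all(tu$grid$oob_error == 0))
  expect_identical(tu$best$ntree, 100L)  # tie -> smaller ntree
  expect_identical(tu$best$mtry, 5L)
  expect_error(tune_forest(ft, integer(0), 5), "non-empty")
})

test_that("importance filter refit: no-op at 0, error above max, noise-robust", {
  with_seed <- get("with_seed", asNamespace("seedmorph"))
  ft <- with_seed(8, {
    t <- toy_feature_table(n_per = 40)
    t$Median <- rnorm(nrow(t))  # pure noise column
    t
  })
  sp <- split_train_test(ft, 0.8, seed = 1)
  m <- train_forest(sp$train, forest_config(ntree = 60, seed = 2))
  r0 <- importance_filter_refit(sp$train, sp$test, m, threshold = 0)
  expect_setequal(r0$retained, attr(ft, "predictors"))
  expect_identical(r0$accuracy, r0$baseline_accuracy)
  expect_error(importance_filter_refit(sp$train, sp$test, m,
                                       threshold = max(forest_importance(m)) + 1),
               "lower the threshold")
  # dropping the bottom half (incl. the noise column) barely moves accuracy
  rq <- importance_filter_refit(sp$train, sp$test, m, quantile = 0.5)
  expect_true(length(rq$retained) < 26)
  expect_lt(abs(rq$accuracy - r0$baseline_accuracy), 0.02 + 1e-9)
})

test_that("model archive round-trips through JSON", {
  ft <- toy_feature_table()
  m <- train_forest(ft, forest_config(ntree = 15, seed = 4))
  f <- withr::local_tempfile(fileext = ".json")
  save_forest(m, f)
  m2 <- load_forest(f)
  expect_identical(predict_species(m2, ft), predict_species(m, ft))
  expect_equal(m2$importance, m$importance)
  expect_identical(m2$class_labels, m$class_labels)
})
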