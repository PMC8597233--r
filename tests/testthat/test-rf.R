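test_that("balanced class weights follow w_c = N / (2 N_c)", {
  set.seed(15)
  ds <- data.frame(sequence = random_sequences(110),
                   label = rep(c(1L, 0L), c(10L, 100L)))
  m <- promoter_rf(ds, "hot", trees = 10L, mtry_rule = "log2",
                   tune = FALSE, seed = 1)
  expect_equal(unname(m$class_weights), c(110 / 200, 110 / 20))
  expect_equal(unname(m$class_weights), c(0.55, 5.5))
})

test_that("mtry rules mirror the max_features choices", {
  expect_identical(promforest:::mtry_from_rule("all", 160L), 160L)
  expect_identical(promforest:::mtry_from_rule("sqrt", 160L), 12L)
  expect_identical(promforest:::mtry_from_rule("log2", 160L), 7L)
  expect_identical(promforest:::mtry_from_rule("log2", 256L), 8L)
})

test_that("a separable toy problem is learned perfectly", {
  m <- toy_separable_model()
  probs <- predict(m, c(strrep("A", 40), strrep("T", 40)))
  expect_gt(probs[1], 0.9)
  expect_lt(probs[2], 0.1)
  ev <- pr_roc(c(1, 0), probs)
  expect_equal(ev$auprc, 1)
  expect_equal(ev$auroc, 1)
})

test_that("prediction is stateless, order-preserving and empty-safe", {
  m <- toy_separable_model()
  set.seed(3)
  seqs <- random_sequences(30)
  expect_identical(predict(m, seqs), predict(m, seqs))
  expect_identical(predict(m, rev(seqs)), rev(predict(m, seqs)))
  expect_identical(predict(m, character(0)), numeric(0))
  expect_error(predict(m, "ACGT"), "length 40")
})

test_that("grid-search CV evaluates the full grid and selects by AUPRC", {
  v <- small_sim_model()
  ds <- v$ds
  m <- promoter_rf(ds, "hot", trees = c(20L, 40L),
                   mtry_rule = c("sqrt", "log2"), folds = 3L, seed = 9)
  expect_identical(nrow(m$cv), 4L)
  expect_identical(sum(m$cv$best), 1L)
  best <- m$cv[m$cv$best, ]
  # selection: max AUPRC, ties by AUROC then smaller forest
  ord <- m$cv[order(-m$cv$auprc, -m$cv$auroc, m$cv$trees), ][1, ]
  expect_identical(best$trees, ord$trees)
  expect_identical(best$mtry_rule, ord$mtry_rule)
  expect_identical(m$trees, best$trees)

  m2 <- promoter_rf(ds, "hot", trees = c(20L, 40L),
                    mtry_rule = c("sqrt", "log2"), folds = 3L, seed = 9)
  expect_identical(m$cv, m2$cv)
  expect_identical(predict(m, ds$sequence[1:5]), predict(m2, ds$sequence[1:5]))
})

test_that("degenerate training input is rejected", {
  ds <- data.frame(sequence = random_sequences(20), label = rep(1L, 20))
  expect_error(promoter_rf(ds, "hot", tune = FALSE), "both classes")
  ds2 <- data.frame(sequence = random_sequences(20),
                    label = rep(c(0L, 1L), c(17L, 3L)))
  expect_error(promoter_rf(ds2, "hot", trees = 10L, folds = 10L, seed = 1),
               "minority")
})

test_that("model bundles round-trip with bitwise-identical predictions", {
  m <- toy_separable_model()
  path <- withr::local_tempfile(fileext = ".rds")
  write_promoter_rf(m, path)
  m2 <- read_promoter_rf(path)
  set.seed(12)
  seqs <- random_sequences(100)
  expect_identical(predict(m2, seqs), predict(m, seqs))
  expect_identical(m2$fingerprint, m$fingerprint)

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(oops = 1), bad)
  expect_error(read_promoter_rf(bad), "not a promforest model bundle")
  writeLines("junk", bad)
  expect_error(read_promoter_rf(bad), "failed to read")
})

test_that("label-shuffled training is no better than chance on held-out data", {
  set.seed(42)
  n <- 2000L
  ds <- data.frame(sequence = random_sequences(2 * n),
                   label = sample(rep(c(0L, 1L), n)))
  sp <- split_train_test(ds, 0.25, seed = 42)
  m <- promoter_rf(sp$train, "hot", trees = 100L, mtry_rule = "log2",
                   tune = FALSE, seed = 42)
  ev <- pr_roc(sp$test$label, predict(m, sp$test))
  expect_gt(ev$auroc, 0.45)
  expect_lt(ev$auroc, 0.55)
})
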