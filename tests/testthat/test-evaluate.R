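test_that("overlap labelling applies the >=10% same-strand rule", {
  truth <- genomic_intervals("c1", 100, 140, "+")
  w <- genomic_intervals("c1", c(96, 63, 96), c(136, 103, 136),
                         c("+", "+", "-"))
  lab <- label_by_overlap(w, truth)
  expect_identical(lab, c(TRUE, FALSE, FALSE))  # 36 bp, 3 bp, wrong strand
})

test_that("overlap labelling agrees with the all-pairs oracle", {
  set.seed(77)
  for (i in 1:40) {
    w <- random_interval_set(sample(50:300, 1))
    truth <- random_interval_set(sample(5:40, 1))
    expect_identical(label_by_overlap(w, truth), oracle_overlap(w, truth))
  }
})

test_that("cluster labelling applies the k-nearest-within-100-nt rule", {
  truth <- genomic_intervals("c1", 1000, 1040, "+")
  pred <- genomic_intervals("c1", c(1090, 1190), c(1130, 1230), "+",
                            score = 1)
  expect_identical(label_by_cluster(pred, truth),
                   c(TRUE, FALSE))  # gaps 51 and 151

  # 7 predictions within 20 nt of one truth: only the 5 nearest are TP
  pred7 <- genomic_intervals("c1", 1041 + (0:6) * 2, 1081 + (0:6) * 2, "+",
                             score = 1)
  lab7 <- label_by_cluster(pred7, truth)
  expect_identical(sum(lab7), 5L)
  expect_identical(lab7, oracle_cluster(pred7, truth))
})

test_that("cluster labelling agrees with the brute-force k-nearest oracle", {
  set.seed(78)
  for (i in 1:40) {
    pred <- random_interval_set(sample(50:300, 1), span = 3000)
    truth <- random_interval_set(sample(3:25, 1), span = 3000)
    expect_identical(label_by_cluster(pred, truth),
                     oracle_cluster(pred, truth))
  }
})

test_that("PR/ROC handles perfect and inverted rankings", {
  perfect <- pr_roc(c(1, 0), c(0.9, 0.1))
  expect_equal(perfect$auprc, 1)
  expect_equal(perfect$auroc, 1)
  inverted <- pr_roc(c(1, 0), c(0.1, 0.9))
  expect_equal(inverted$auroc, 0)
  expect_error(pr_roc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("PR/ROC matches exhaustive threshold enumeration on small inputs", {
  set.seed(81)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    mine <- pr_roc(labels, scores)
    ref <- oracle_pr_roc(labels, scores)
    expect_equal(mine$auprc, ref$auprc, tolerance = 1e-12)
    expect_equal(mine$auroc, ref$auroc, tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(82)
  labels <- sample(0:1, 500, replace = TRUE)
  scores <- runif(500) + 0.3 * labels
  mine <- pr_roc(labels, scores)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine$auroc, ref, tolerance = 1e-10)
})

test_that("random scores give AUPRC near prevalence and AUROC near 0.5", {
  set.seed(83)
  n <- 1e5
  prevalence <- 0.05
  labels <- as.integer(runif(n) < prevalence)
  scores <- runif(n)
  ev <- pr_roc(labels, scores)
  expect_lt(abs(ev$auprc - prevalence), 0.02)
  expect_lt(abs(ev$auroc - 0.5), 0.02)
  expect_equal(baseline_auprc(sum(labels), n), mean(labels))
})

test_that("balanced evaluation reports MCC and accuracy at p >= 0.5", {
  m <- toy_separable_model()
  ds <- data.frame(sequence = rep(c(strrep("A", 40), strrep("T", 40)),
                                  each = 10),
                   label = rep(c(1L, 0L), each = 10))
  ev <- evaluate_balanced(m, ds)
  expect_equal(ev$mcc, 1)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auprc, 1)

  # degenerate all-same predictions: MCC defined as 0
  ds_same <- data.frame(sequence = rep(strrep("A", 40), 10),
                        label = rep(c(1L, 0L), 5))
  ev2 <- evaluate_balanced(m, ds_same)
  expect_identical(ev2$mcc, 0)
})

test_that("genome-wide overlap evaluation scores a perfect track as 1", {
  truth <- genomic_intervals("c", seq(500, 4500, 1000),
                             seq(540, 4540, 1000), "+")
  hits <- truth
  hits$score <- 1
  noise <- genomic_intervals("c", seq(0, 4900, 250), seq(40, 4940, 250),
                             "-", score = 0)
  pred <- rbind(hits, noise)
  ev_o <- evaluate_genome_wide(pred, truth, "overlap")
  ev_c <- evaluate_genome_wide(pred, truth, "cluster")
  expect_equal(ev_o$auprc, 1)
  expect_equal(ev_c$auprc, 1)
  expect_error(evaluate_genome_wide(pred, truth[0, ], "overlap"), "empty")
})
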