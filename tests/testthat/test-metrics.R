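# Metric identities and aggregation rules.

test_that("one-vs-rest confusion counts satisfy their invariants", {
  # perfect prediction, 4 classes x 10
  y <- rep(0:3, each = 10)
  cc <- confusion(y, y, 4)
  expect_true(all(cc$per_class$FP == 0) && all(cc$per_class$FN == 0))
  expect_identical(cc$Nc, 40L)
  # all predictions class 0 on a balanced set: direct counting oracle
  cc <- confusion(y, rep(0L, 40), 4)
  expect_identical(cc$per_class$TP, c(10L, 0L, 0L, 0L))
  expect_identical(cc$per_class$FP[1L], 30L)
  expect_identical(cc$per_class$FN, c(0L, 10L, 10L, 10L))
  expect_true(all(with(cc$per_class, TP + FP + TN + FN) == cc$N))
  expect_identical(sum(cc$per_class$TP), cc$Nc)
  # single agreeing sample
  cc1 <- confusion(0L, 0L, 2)
  expect_identical(c(cc1$N, cc1$Nc), c(1L, 1L))
  expect_error(confusion(c(0, 1), 0, 2), "equal length")
  expect_error(confusion(0L, 5L, 2), "out of range")
})

test_that("accuracy is correct-over-total and matches the confusion trace", {
  y <- rep(0:3, each = 10)
  set.seed(2)
  p <- y; p[sample(40, 13)] <- (y[sample(40, 13)] + 1) %% 4
  cc <- confusion(y, p, 4)
  expect_equal(accuracy(cc), sum(diag(cc$table)) / sum(cc$table))
  # 27 correct out of 40
  p <- y; p[1:13] <- (y[1:13] + 1L) %% 4L
  expect_equal(accuracy(confusion(y, p, 4)), 0.675)
  expect_equal(accuracy(confusion(y, y, 4)), 1)
  expect_equal(accuracy(confusion(y, (y + 1L) %% 4L, 4)), 0)
})

test_that("precision, sensitivity and specificity match a counting oracle", {
  y <- c(0, 0, 0, 1, 1, 2, 2, 2, 2, 2)
  p <- c(0, 1, 0, 1, 2, 2, 2, 0, 2, 2)
  cc <- confusion(y, p, 3)
  expect_equal(sensitivity(cc, class = 0), 2 / 3)
  expect_equal(sensitivity(cc, class = 2), 4 / 5)
  expect_equal(precision(cc, class = 0), 2 / 3)
  expect_equal(specificity(cc, class = 1), 7 / 8)
  # macro = unweighted mean of the per-class values
  se_hand <- mean(c(2 / 3, 1 / 2, 4 / 5))
  expect_equal(sensitivity(cc), se_hand)
  # simple ratio checks
  expect_equal(9 / (9 + 1), 0.9)
  cc2 <- confusion(c(0, 0, 0, 0, 0, 1), c(1, 1, 1, 1, 1, 1), 2)
  expect_equal(specificity(cc2, class = 1), 0)
})

test_that("undefined per-class metrics are excluded from macro means", {
  # class 2 never occurs in truth: sensitivity undefined for it
  y <- c(0, 0, 1, 1)
  p <- c(0, 1, 1, 1)
  cc <- confusion(y, p, 3)
  expect_equal(sensitivity(cc), mean(c(1 / 2, 1)))
  expect_error(sensitivity(cc, class = 2), "undefined")
})

test_that("the Youden index is se + sp - 1 with its bounds and chance line", {
  expect_equal(youden_index(0.8731, 0.9014), 0.7745, tolerance = 1e-12)
  expect_equal(youden_index(0.35, 0.65), 0)
  expect_equal(youden_index(1, 1), 1)
  set.seed(4)
  se <- runif(50); sp <- runif(50)
  yi <- youden_index(se, sp)
  expect_true(all(yi >= -1 & yi <= 1))
  expect_equal(youden_index(se, 1 - se), rep(0, 50))
  expect_error(youden_index(1.2, 0.5))
})

test_that("metrics are invariant under consistent class relabeling", {
  set.seed(6)
  y <- sample(0:3, 60, replace = TRUE)
  p <- sample(0:3, 60, replace = TRUE)
  perm <- c(2L, 0L, 3L, 1L)
  cc <- confusion(y, p, 4)
  cc2 <- confusion(perm[y + 1L], perm[p + 1L], 4)
  expect_equal(accuracy(cc), accuracy(cc2))
  expect_equal(sensitivity(cc), sensitivity(cc2))
  expect_equal(specificity(cc), specificity(cc2))
  expect_equal(precision(cc), precision(cc2))
})

test_that("the evaluation report assembles per-class and macro metrics", {
  y <- rep(0:3, each = 5)
  set.seed(7)
  p <- y; p[sample(20, 6)] <- sample(0:3, 6, replace = TRUE)
  rep_ <- evaluate_predictions(y, p, 4)
  expect_named(rep_$macro,
               c("accuracy", "precision", "sensitivity", "specificity",
                 "youden"))
  expect_equal(rep_$macro$youden,
               rep_$macro$sensitivity + rep_$macro$specificity - 1)
  expect_identical(nrow(rep_$per_class), 4L)
})
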