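test_that("SMOTE balances minority classes by convex interpolation", {
  set.seed(61)
  bal <- blob_data(10)
  out <- smote_oversample(bal$features, bal$labels)
  expect_equal(nrow(out$features), 20)  # already balanced: unchanged
  x <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(8) + 5, 4, 2))
  y <- factor(rep(c("a", "b"), c(10, 4)))
  out2 <- smote_oversample(x, y)
  expect_equal(as.vector(table(out2$labels)), c(10, 10))
  expect_equal(out2$features[1:14, ], x)  # originals retained
  # class members on a line segment: synthetic points stay on it
  xs <- cbind(seq(0, 1, length.out = 5), 2 * seq(0, 1, length.out = 5))
  xl <- rbind(matrix(rnorm(40), 20, 2), xs)
  yl <- factor(rep(c("big", "line"), c(20, 5)))
  out3 <- smote_oversample(xl, yl, k = 2)
  synth <- out3$features[out3$labels == "line", , drop = FALSE][-(1:5), ]
  expect_equal(synth[, 2], 2 * synth[, 1])
  expect_error(smote_oversample(rbind(x, c(9, 9)), factor(c(as.character(y), "c"))),
               "singleton.*c")
})

test_that("train/test split is stratified, seeded, and validated", {
  y <- factor(rep(0:3, each = 25))
  set.seed(62)
  sp <- train_test_split(y, 0.2)
  expect_equal(length(sp$test), 20)
  expect_equal(as.vector(table(y[sp$test])), rep(5, 4))
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  set.seed(62)
  sp2 <- train_test_split(y, 0.2)
  expect_identical(sp, sp2)
  expect_error(train_test_split(y, 0), "strictly between")
  expect_error(train_test_split(factor(rep(0:1, c(3, 50)))), "at least 5")
})

test_that("RBF kernel evaluates the Gaussian similarity", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2)), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), sigma = 1), exp(-1))
  expect_equal(rbf_kernel(c(0, 3), c(4, 0)), rbf_kernel(c(4, 0), c(0, 3)))
  expect_error(rbf_kernel(1, 1, sigma = 0), "positive")
})

test_that("categorical cross-entropy is the negative true-class log-probability", {
  expect_equal(categorical_cross_entropy(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(categorical_cross_entropy(c(1, 0, 0, 0), rep(0.25, 4)), log(4))
  expect_equal(categorical_cross_entropy(c(0, 1), c(1 - exp(-2), exp(-2))), 2)
  expect_warning(categorical_cross_entropy(c(1, 0), c(0, 1)), "clipped")
})

test_that("degenerate single-class training yields a constant predictor", {
  x <- matrix(rnorm(20), 10, 2)
  y <- factor(rep("a", 10), levels = c("a", "b"))
  for (kind in c("tree", "nn2")) {
    fp <- fit_predict(kind, list(features = x, labels = y),
                      list(features = x))
    expect_true(all(fp$pred == "a"))
    expect_equal(unname(fp$prob[, "a"]), rep(1, 10))
  }
})

test_that("the RBF SVM separates a linearly separable two-feature toy set", {
  set.seed(63)
  d <- blob_data(20, centers = rbind(c(0, 0), c(6, 6)), sd = 0.4)
  sp <- train_test_split(d$labels, 0.25)
  fp <- fit_predict("svm_rbf",
                    list(features = d$features[sp$train, ], labels = d$labels[sp$train]),
                    list(features = d$features[sp$test, ]))
  expect_equal(mean(fp$pred == d$labels[sp$test]), 1.0)
})

test_that("neural-net training is reproducible under a fixed seed", {
  set.seed(64)
  d <- blob_data(15, centers = rbind(c(0, 0), c(3, 3), c(0, 3)), sd = 0.7)
  tr <- list(features = d$features, labels = d$labels)
  te <- list(features = d$features, labels = d$labels)
  set.seed(7); a <- fit_predict("nn4", tr, te, hyper = list(epochs = 20))
  set.seed(7); b <- fit_predict("nn4", tr, te, hyper = list(epochs = 20))
  expect_identical(a$val_loss, b$val_loss)
  expect_identical(a$prob, b$prob)
  expect_equal(length(a$val_loss), 20)
})

test_that("evaluation metrics match hand-computed values", {
  truth <- factor(c(0, 0, 1, 1))
  pred <- factor(c(0, 1, 1, 1), levels = levels(truth))
  ev <- evaluate(pred, NULL, truth)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(as.vector(ev$confusion), c(1, 0, 1, 2))
  perfect <- evaluate(truth, one_hot(truth), truth)
  expect_equal(unname(unlist(perfect[c("accuracy", "precision", "recall", "f1", "auc")])),
               rep(1, 5))
  # uniform probabilities carry no ranking information: chance AUC
  unif <- matrix(0.5, 4, 2, dimnames = list(NULL, levels(truth)))
  ev_u <- evaluate(pred, unif, truth)
  expect_equal(ev_u$auc, 0.5)
})

test_that("evaluation is invariant to joint permutation of the records", {
  set.seed(65)
  truth <- factor(sample(0:3, 40, replace = TRUE))
  pred <- factor(sample(0:3, 40, replace = TRUE), levels = levels(truth))
  prob <- matrix(runif(160), 40, 4, dimnames = list(NULL, levels(truth)))
  prob <- prob / rowSums(prob)
  ev1 <- evaluate(pred, prob, truth)
  perm <- sample(40)
  ev2 <- evaluate(pred[perm], prob[perm, ], truth[perm])
  expect_equal(ev1[c("accuracy", "precision", "recall", "f1", "auc")],
               ev2[c("accuracy", "precision", "recall", "f1", "auc")])
})

test_that("cross-validation stratifies folds and is seed-reproducible", {
  set.seed(66)
  d <- blob_data(25, centers = rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0)),
                 sd = 0.6)
  cv <- cross_validate(d$features, d$labels, model_kind = "tree", folds = 5,
                       seed = 8)
  expect_s3_class(cv, "eval_report")
  expect_equal(length(cv$folds), 5)
  expect_equal(sum(cv$confusion), 100)           # every record held out once
  expect_equal(unname(rowSums(cv$confusion)), rep(25, 4))
  cv2 <- cross_validate(d$features, d$labels, model_kind = "tree", folds = 5,
                        seed = 8)
  expect_identical(cv$mean, cv2$mean)
  expect_error(cross_validate(d$features[1:8, ], d$labels[1:8], folds = 5),
               "at least")
})
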