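test_that("metric identities hold on constructed confusion tables", {
  # TP=9, FN=1, TN=8, FP=2
  y_true <- c(rep("pos", 10), rep("neg", 10))
  y_pred <- c(rep("pos", 9), "neg", rep("neg", 8), rep("pos", 2))
  m <- compute_metrics(y_true, y_pred, positive = "pos")
  expect_equal(m$acc, 85)
  expect_equal(m$dr, 90)
  expect_equal(m$fpr, 0.2)
  expect_equal(unname(m$confusion), c(9, 2, 8, 1))

  perfect <- compute_metrics(y_true, y_true, scores = c(rep(1, 10), rep(0, 10)),
                             positive = "pos")
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$dr, 100)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$auc, 1)

  allpos <- compute_metrics(y_true, rep("pos", 20), positive = "pos")
  expect_equal(allpos$dr, 100)
  expect_equal(allpos$fpr, 1)
  expect_equal(allpos$acc, 50)

  expect_error(compute_metrics(character(0), character(0)), "non-empty")
})

test_that("rank-statistic AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  y <- sample(c("a", "b"), 40, replace = TRUE)
  s <- rnorm(40) + (y == "b")
  ours <- ssdmix:::auc_rank(s, y, positive = "b")
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("a", "b"), direction = "<",
                                        quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("precomputed-kernel SVM separates a block-structured Gram matrix", {
  # two classes, within-class similarity 1, cross-class 0
  K <- kronecker(diag(2), matrix(1, 4, 4)) + 1e-6 * diag(8)
  ids <- paste0("i", 1:8)
  dimnames(K) <- list(ids, ids)
  labels <- setNames(rep(c("a", "b"), each = 4), ids)
  svm <- train_svm(K, labels, C = 1)
  pred <- predict(svm, K)
  expect_equal(pred$class, unname(labels))

  # held-out image similar only to class "a"
  row <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 1)
  expect_equal(predict(svm, row)$class, "a")

  expect_error(train_svm(K, setNames(rep("a", 8), ids)), "single class")
})

test_that("prediction is invariant to training order", {
  set.seed(52)
  X <- matrix(rnorm(40), 10, 4)
  K <- tcrossprod(X); ids <- paste0("i", 1:10)
  dimnames(K) <- list(ids, ids)
  labels <- setNames(rep(c("a", "b"), 5), ids)
  svm1 <- train_svm(K, labels)
  perm <- sample(ids)
  svm2 <- train_svm(K[perm, perm], labels[perm])
  Ktest <- K[1:3, , drop = FALSE]
  p1 <- predict(svm1, Ktest[, svm1$train_ids, drop = FALSE])
  p2 <- predict(svm2, Ktest[, svm2$train_ids, drop = FALSE])
  expect_equal(p1$class, p2$class)
})

test_that("cross-validation partitions ids, is seeded, and does not leak", {
  gt <- default_ground_truth(n_images = 6, vectors_per_image = 25, seed = 53)
  dat <- sample_mixture_bags(gt)
  cv <- cross_validate(dat$bags, dat$labels, kernel_type = "skk",
                       folds = 3, seed = 54, L = 300)
  info <- attr(cv, "fold_info")
  test_ids <- unlist(lapply(info, `[[`, "test"))
  expect_setequal(test_ids, names(dat$bags))
  expect_equal(anyDuplicated(test_ids), 0L)

  cv2 <- cross_validate(dat$bags, dat$labels, kernel_type = "skk",
                        folds = 3, seed = 54, L = 300)
  expect_equal(cv$acc, cv2$acc)
  expect_equal(cv$per_fold, cv2$per_fold)

  cvf <- cross_validate(dat$bags, dat$labels, kernel_type = "fisher",
                        folds = 3, seed = 55)
  for (fi in attr(cvf, "fold_info")) {
    expect_length(intersect(fi$background_ids, fi$test), 0)
    expect_setequal(union(fi$train, fi$test), names(dat$bags))
  }
  expect_true(cvf$acc >= 0 && cvf$acc <= 100)
})

test_that("indistinguishable classes classify at chance level", {
  m <- test_mixture_k2()
  gt <- default_ground_truth(n_images = 10, vectors_per_image = 25, seed = 56)
  gt$class_models <- list(classA = m, classB = m)
  dat <- sample_mixture_bags(gt)
  cv <- cross_validate(dat$bags, dat$labels, kernel_type = "skk",
                       folds = 5, seed = 57, L = 300)
  # 20 test decisions; 3 binomial SE around 50%
  se <- 100 * sqrt(0.25 / 20)
  expect_lt(abs(cv$acc - 50), 3 * se)
})

test_that("holdout split evaluates a single stratified train/test division", {
  gt <- default_ground_truth(n_images = 10, vectors_per_image = 25, seed = 58)
  dat <- sample_mixture_bags(gt)
  cv <- cross_validate(dat$bags, dat$labels, kernel_type = "skk",
                       seed = 59, L = 300, holdout = 0.3)
  info <- attr(cv, "fold_info")
  expect_length(info, 1)
  expect_length(info[[1]]$test, 6)
  expect_length(info[[1]]$train, 14)
})
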