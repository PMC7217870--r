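test_that("feature assembly lays maps out as samples x in-mask voxels", {
  f <- null_features(n_subjects = 30, dims = c(10, 5, 4), seed = 1)
  expect_equal(dim(f$X), c(60, 200))
  expect_equal(levels(f$labels), c("gratitude", "joy"))
  expect_equal(sum(f$labels == "gratitude"), 30)

  mask <- array(FALSE, c(3, 3, 3)); mask[1:10] <- TRUE
  g <- lapply(1:4, function(i) as_voxel_map(array(seq_len(27) + i, c(3, 3, 3))))
  f2 <- assemble_features(g, g, mask)
  expect_equal(ncol(f2$X), 10)
  # identical gratitude and joy maps: identical rows, different labels
  expect_equal(f2$X[1, ], f2$X[5, ])
  expect_false(f2$labels[1] == f2$labels[5])
  expect_error(assemble_features(g[1:3], g, mask), "one map per subject")
})

test_that("min-max scaling uses training parameters on the test set", {
  train <- cbind(c(2, 4, 3), c(0, 10, 5))
  test <- cbind(c(3, 5), c(20, -10))
  sc <- scale_features(train, test)
  expect_equal(sc$test[1, 1], 0.5)
  expect_equal(sc$test[2, 1], 1.5)     # outside [0,1], no clipping
  expect_equal(sc$test[1, 2], 2)
  expect_equal(sc$test[2, 2], -1)
  # brute-force per-column oracle
  set.seed(2)
  tr <- matrix(rnorm(50), 10); te <- matrix(rnorm(15), 3)
  sc2 <- scale_features(tr, te)
  for (j in 1:5) {
    expect_equal(sc2$train[, j], (tr[, j] - min(tr[, j])) /
                   (max(tr[, j]) - min(tr[, j])))
    expect_equal(sc2$test[, j], (te[, j] - min(tr[, j])) /
                   (max(tr[, j]) - min(tr[, j])))
  }
  # zero-range features map to 0 and are flagged
  sc3 <- scale_features(cbind(rep(7, 4), 1:4), cbind(9, 2))
  expect_true(sc3$zero_range[1])
  expect_equal(unname(sc3$train[, 1]), rep(0, 4))
  expect_equal(unname(sc3$test[1, 1]), 0)
})

test_that("paired-t selection matches a per-feature t.test oracle", {
  set.seed(3)
  d <- matrix(rnorm(5 * 40), 5, 40)
  d[, 1] <- d[, 1] + 5                   # strongly shifted feature
  d[, 2] <- 0                            # identical across labels
  d[, 3] <- 2                            # constant nonzero difference
  sel <- select_features_paired(d, alpha = 0.05)
  expect_true(sel[1])
  expect_false(sel[2])
  expect_true(sel[3])
  for (j in 4:40) {
    p <- t.test(d[, j])$p.value
    expect_equal(sel[j], p < 0.05, info = paste("feature", j))
  }
  expect_error(select_features_paired(d[1, , drop = FALSE]), "2 training pairs")
})

# brute-force primal SVM oracle: subgradient descent on
# ||w||^2/2 + C sum hinge(y (w'x + b)); deterministic, slow, independent
svm_oracle <- function(X, y, C = 1, iters = 200000) {
  w <- numeric(ncol(X)); b <- 0
  for (i in seq_len(iters)) {
    eta <- 1 / (i * 0.05 + 100)
    marg <- y * (X %*% w + b)
    viol <- marg < 1
    gw <- w - C * colSums(X[viol, , drop = FALSE] * y[viol])
    gb <- -C * sum(y[viol])
    w <- w - eta * gw
    b <- b - eta * gb
  }
  list(w = w, b = b)
}

test_that("the linear classifier solves the maximum-margin problem", {
  # two separable points: weight proportional to the difference vector
  X <- rbind(c(1, 0), c(-1, 0))
  lab <- factor(c("gratitude", "joy"), levels = c("gratitude", "joy"))
  cls <- train_linear_classifier(X, lab, C = 1)
  expect_equal(as.character(emofmri:::predict_emotion(cls$decision(X))),
               as.character(lab))
  expect_gt(cls$weights[1], 0)
  expect_lt(abs(cls$weights[2]), 1e-8)

  # label swap flips the signed weights after reorientation is undone:
  # the oriented decision must stay identical (positive = gratitude)
  cls_sw <- train_linear_classifier(X[2:1, ], lab, C = 1)
  expect_equal(cls_sw$decision(X), cls$decision(X) * -1, tolerance = 1e-6)
  expect_equal(abs(cls_sw$weights), abs(cls$weights), tolerance = 1e-6)

  # 4-point 2D toy set vs the brute-force QP oracle
  X4 <- rbind(c(2, 1), c(1, 2), c(-1, -1.5), c(-2, -0.5))
  y4 <- c(1, 1, -1, -1)
  lab4 <- factor(ifelse(y4 > 0, "gratitude", "joy"),
                 levels = c("gratitude", "joy"))
  cls4 <- train_linear_classifier(X4, lab4, C = 1)
  or <- svm_oracle(X4, y4, C = 1)
  expect_equal(cls4$decision(X4), drop(X4 %*% or$w + or$b), tolerance = 0.02)

  expect_error(train_linear_classifier(X, factor(c("joy", "joy"),
                                                 levels = c("gratitude", "joy"))),
               "both classes")
})

test_that("LOPO cross-validation counts folds and scores per class", {
  f <- signal_features(n_subjects = 10, effect = 50, noise = 0.01, seed = 4)
  cv <- run_lopo_cv(f)
  expect_length(cv$folds, 10)
  expect_length(cv$predictions, 20)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(cv$sensitivity, 1)

  f0 <- null_features(n_subjects = 8, dims = c(4, 3, 2), seed = 5)
  cv0 <- run_lopo_cv(f0)
  expect_equal(cv0$accuracy, (cv0$specificity + cv0$sensitivity) / 2)
})

test_that("a fold with no selected features predicts by bias sign and is flagged", {
  f <- null_features(n_subjects = 6, dims = c(2, 2, 2), seed = 6)
  cv <- run_lopo_cv(f, alpha = 1e-12)
  expect_true(all(vapply(cv$folds, function(x) x$flagged, TRUE)))
  expect_true(all(cv$predictions == "gratitude"))   # tie-break contract
})

test_that("permutation p follows the counting rules on recorded accuracies", {
  f <- signal_features(n_subjects = 8, effect = 1, noise = 1, seed = 7)
  cv <- run_lopo_cv(f)
  pt1 <- permutation_test(f, n_perm = 20, seed = 8, observed = cv$accuracy)
  expect_equal(pt1$p, mean(pt1$perm_accuracies > cv$accuracy))
  pt2 <- permutation_test(f, n_perm = 20, seed = 8, observed = cv$accuracy,
                          rule = "conservative")
  expect_equal(pt2$p,
               (sum(pt2$perm_accuracies >= cv$accuracy) + 1) / 21)
  # an observed accuracy above every permutation gives p = 0 under the strict
  # rule and 1/(n+1) under the safeguard
  ptop <- permutation_test(f, n_perm = 20, seed = 8, observed = 2)
  expect_equal(ptop$p, 0)
  ptop2 <- permutation_test(f, n_perm = 20, seed = 8, observed = 2,
                            rule = "conservative")
  expect_equal(ptop2$p, 1 / 21)
  # an observed value at the permutation median gives p near 0.5
  med <- median(pt1$perm_accuracies)
  pmid <- permutation_test(f, n_perm = 20, seed = 8, observed = med)
  expect_lt(abs(pmid$p - 0.5), 0.3)
  # the full-shuffle scheme runs and returns a valid p
  ptf <- permutation_test(f, n_perm = 10, seed = 9, observed = cv$accuracy,
                          scheme = "full")
  expect_true(ptf$p >= 0 && ptf$p <= 1)
})

test_that("consensus weight maps respect every-fold selection and min cluster size", {
  # hand-built CV result: 3 folds over a 3x3x1 grid (9 features)
  dims <- c(3, 3, 1)
  f <- list(X = matrix(0, 6, 9), labels = factor(rep(c("gratitude", "joy"), 3)),
            subject = rep(1:3, each = 2), voxel_index = 1:9, dims = dims)
  class(f) <- "feature_matrix"
  folds <- list(
    list(selected = c(1, 2, 5), weights = c(0.2, 0.1, 0.3), flagged = FALSE),
    list(selected = c(1, 2), weights = c(-0.2, 0.3), flagged = FALSE),
    list(selected = c(1, 2, 7), weights = c(0.2, -0.1, 0.4), flagged = FALSE))
  cv <- structure(list(folds = folds), class = "cv_result")
  wm <- consensus_weight_map(cv, f, min_cluster_size = 2, connectivity = 6)
  expect_equal(which(wm$consensus), c(1, 2))      # feature 5 missing from fold 2
  arr <- unclass(wm$map)
  expect_equal(arr[1, 1, 1], 0.2)                 # mean(|0.2|, |-0.2|, |0.2|)
  expect_equal(arr[2, 1, 1], mean(c(0.1, 0.3, 0.1)))
  expect_equal(arr[3, 1, 1], 0)
  expect_equal(nrow(wm$clusters), 1)
  expect_equal(wm$clusters$size, 2)

  # a consensus blob below the minimum size is absent from the table
  wm5 <- consensus_weight_map(cv, f, min_cluster_size = 5)
  expect_equal(nrow(wm5$clusters), 0)

  # empty consensus warns
  folds2 <- list(list(selected = 1, weights = 0.5, flagged = FALSE),
                 list(selected = 2, weights = 0.5, flagged = FALSE))
  cv2 <- structure(list(folds = folds2), class = "cv_result")
  expect_warning(consensus_weight_map(cv2, f), "every fold")
})

test_that("no information leaks from the held-out subject into fold training", {
  f <- null_features(n_subjects = 8, dims = c(4, 3, 2), seed = 10)
  cv <- run_lopo_cv(f)
  # corrupt the held-out subject's data; its fold must be bit-identical
  for (held in c(1, 5)) {
    f2 <- f
    f2$X[f2$subject == held, ] <- 1e6
    cv2 <- run_lopo_cv(f2)
    expect_identical(cv$folds[[held]]$selected, cv2$folds[[held]]$selected)
    expect_identical(cv$folds[[held]]$scaler, cv2$folds[[held]]$scaler)
    expect_identical(cv$folds[[held]]$weights, cv2$folds[[held]]$weights)
    expect_identical(cv$folds[[held]]$bias, cv2$folds[[held]]$bias)
  }
})
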