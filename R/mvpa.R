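#' Assemble per-subject beta maps into a feature matrix
#'
#' One row per beta map (each subject contributes one gratitude and one joy
#' map), one column per in-mask voxel, in a fixed deterministic voxel order.
#'
#' @param beta_maps_g,beta_maps_j lists of per-subject \code{voxel_map}s on a
#'   common grid (same subject order).
#' @param mask logical 3D array (e.g. gray-matter probability binarized at
#'   0.2).
#' @return object of class \code{feature_matrix}: \code{X} (2n x V),
#'   \code{labels} (factor gratitude/joy), \code{subject}, \code{voxel_index}
#'   (column -> linear grid index), \code{dims}.
#' @export
assemble_features <- function(beta_maps_g, beta_maps_j, mask) {
  n <- length(beta_maps_g)
  stop_if_not(length(beta_maps_j) == n, "one map per subject per emotion required")
  dims <- dim(mask)
  for (m in c(beta_maps_g, beta_maps_j))
    stop_if_not(identical(dim(m), dims), "grid mismatch between map and mask")
  vox <- which(mask)
  row_of <- function(m) unclass(m)[vox]
  X <- rbind(t(vapply(beta_maps_g, row_of, numeric(length(vox)))),
             t(vapply(beta_maps_j, row_of, numeric(length(vox)))))
  stop_if_not(!anyNA(X), "NA feature values inside the mask")
  structure(list(X = X,
                 labels = factor(rep(EMOTIONS, each = n), levels = EMOTIONS),
                 subject = rep(seq_len(n), 2),
                 voxel_index = vox, dims = dims),
            class = "feature_matrix")
}

#' Min-max scale features on the training set
#'
#' Each feature is affinely mapped so its training minimum and maximum become
#' 0 and 1; the identical parameters are applied to the test rows, whose
#' values may therefore fall outside [0, 1]. Zero-range features map to 0 and
#' are flagged.
#'
#' @param train,test numeric matrices (samples x features).
#' @return list with \code{train}, \code{test}, \code{min}, \code{range},
#'   \code{zero_range} (logical).
#' @export
scale_features <- function(train, test = NULL) {
  mn <- apply(train, 2, min)
  mx <- apply(train, 2, max)
  rg <- mx - mn
  zr <- rg == 0
  rg[zr] <- 1
  sc <- function(M) {
    M <- sweep(sweep(M, 2, mn), 2, rg, "/")
    M[, zr] <- 0
    M
  }
  list(train = sc(train), test = if (!is.null(test)) sc(test),
       min = mn, range = ifelse(zr, 0, rg), zero_range = zr)
}

#' Paired-t feature selection on the training set
#'
#' For every feature, a paired two-tailed t-test across training subjects'
#' gratitude-minus-joy differences; features with p below alpha are retained.
#' Features whose paired differences are constant are excluded when the
#' constant is zero (no information) and retained when nonzero (infinite t).
#'
#' @param d matrix of paired differences (training subjects x features).
#' @param alpha uncorrected selection threshold (default 0.05).
#' @return logical vector of selected features.
#' @export
select_features_paired <- function(d, alpha = 0.05) {
  n <- nrow(d)
  stop_if_not(n >= 2, "need at least 2 training pairs")
  m <- colMeans(d)
  s2 <- (colSums(d * d) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  zero_sd <- s2 == 0
  t <- m / sqrt(s2 / n)
  p <- 2 * pt(abs(t), n - 1, lower.tail = FALSE)
  sel <- !is.na(p) & p < alpha
  sel[zero_sd] <- m[zero_sd] != 0
  sel
}

# unpaired two-sample t selection (used by the full-shuffle permutation scheme)
select_features_unpaired <- function(X, labels, alpha = 0.05) {
  g <- X[labels == "gratitude", , drop = FALSE]
  j <- X[labels == "joy", , drop = FALSE]
  n1 <- nrow(g); n2 <- nrow(j)
  v1 <- apply(g, 2, var); v2 <- apply(j, 2, var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (colMeans(g) - colMeans(j)) / sqrt(sp * (1 / n1 + 1 / n2))
  p <- 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE)
  sel <- !is.na(p) & p < alpha
  sel[!is.na(t) & is.infinite(t)] <- TRUE
  sel
}

#' Train a linear maximum-margin classifier
#'
#' Linear support-vector machine (hinge loss, penalty C) via LIBSVM
#' (\code{e1071::svm}). The returned weight vector and bias are oriented so a
#' positive decision value predicts gratitude; a decision value of exactly 0
#' also predicts gratitude (deterministic tie-break).
#'
#' @param X training matrix (samples x features).
#' @param labels factor with levels gratitude/joy.
#' @param C soft-margin penalty (default 1).
#' @return list with \code{weights}, \code{bias}, and \code{decision}
#'   (function mapping a matrix to decision values).
#' @export
train_linear_classifier <- function(X, labels, C = 1) {
  stop_if_not(nlevels(droplevels(labels)) == 2, "both classes must be present")
  fit <- e1071::svm(x = X, y = labels, kernel = "linear", cost = C,
                    scale = FALSE, type = "C-classification")
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  dec <- drop(X %*% w) + b
  if (mean(dec[labels == "gratitude"]) < mean(dec[labels == "joy"])) {
    w <- -w; b <- -b
  }
  list(weights = w, bias = b,
       decision = function(M) drop(M %*% w) + b)
}

predict_emotion <- function(decision_values) {
  factor(ifelse(decision_values >= 0, "gratitude", "joy"), levels = EMOTIONS)
}

# label-independent per-fold precomputation: training/test split and min-max
# scaling (neither depends on the sample labels)
precompute_folds <- function(features) {
  n <- max(features$subject)
  lapply(seq_len(n), function(s) {
    test_rows <- which(features$subject == s)
    train_rows <- which(features$subject != s)
    sc <- scale_features(features$X[train_rows, , drop = FALSE],
                         features$X[test_rows, , drop = FALSE])
    train_subj <- features$subject[train_rows]
    g_rows <- features$labels[train_rows] == "gratitude"
    subj_levels <- sort(unique(train_subj))
    d <- sc$train[g_rows, , drop = FALSE][order(train_subj[g_rows]), , drop = FALSE] -
      sc$train[!g_rows, , drop = FALSE][order(train_subj[!g_rows]), , drop = FALSE]
    list(held = s, test_rows = test_rows, train_rows = train_rows,
         scaled_train = sc$train, scaled_test = sc$test,
         scaler = sc[c("min", "range", "zero_range")],
         train_labels = features$labels[train_rows],
         train_subject = train_subj, pair_subjects = subj_levels, d = d)
  })
}

run_fold <- function(fold, features, C, alpha, flips = NULL, full_labels = NULL) {
  if (is.null(full_labels)) {
    d <- fold$d
    if (!is.null(flips)) d <- d * flips[fold$pair_subjects]
    sel <- select_features_paired(d, alpha)
    tr_labels <- fold$train_labels
    if (!is.null(flips)) {
      fl <- flips[fold$train_subject] < 0
      tr_labels[fl] <- ifelse(tr_labels[fl] == "gratitude", "joy", "gratitude")
      tr_labels <- factor(tr_labels, levels = EMOTIONS)
    }
  } else {
    tr_labels <- full_labels[fold$train_rows]
    sel <- select_features_unpaired(fold$scaled_train, tr_labels, alpha)
  }
  if (!any(sel)) {
    return(list(held = fold$held, selected = integer(0),
                scaler = fold$scaler, weights = numeric(0), bias = 0,
                decision = c(0, 0), predictions = predict_emotion(c(0, 0)),
                flagged = TRUE))
  }
  cls <- train_linear_classifier(fold$scaled_train[, sel, drop = FALSE],
                                 tr_labels, C)
  dec <- cls$decision(fold$scaled_test[, sel, drop = FALSE])
  list(held = fold$held, selected = which(sel), scaler = fold$scaler,
       weights = cls$weights, bias = cls$bias, decision = dec,
       predictions = predict_emotion(dec), flagged = FALSE)
}

#' Leave-one-participant-out cross-validated classification
#'
#' For each fold, both samples of one subject are held out; features are
#' min-max scaled and selected (paired t, p < alpha) on the training set
#' only; a linear SVM (cost C) is trained and the two held-out samples
#' predicted. Accuracy is the proportion of all 2n predictions correct;
#' specificity and sensitivity are the proportions of gratitude and joy
#' samples correctly classified. A fold whose selected-feature set is empty
#' predicts via the bias sign and is flagged.
#'
#' @param features a \code{feature_matrix}.
#' @param C SVM penalty (default 1).
#' @param alpha feature-selection threshold (default 0.05).
#' @param folds optional precomputed folds (internal reuse).
#' @return object of class \code{cv_result}: \code{folds} (per-fold
#'   artifacts), \code{predictions}, \code{accuracy}, \code{specificity},
#'   \code{sensitivity}, \code{n_subjects}.
#' @export
run_lopo_cv <- function(features, C = 1, alpha = 0.05, folds = NULL) {
  n <- max(features$subject)
  stop_if_not(n >= 3, "need at least 3 subjects")
  folds <- folds %||% precompute_folds(features)
  res <- lapply(folds, run_fold, features = features, C = C, alpha = alpha)
  pred <- factor(rep(NA_character_, nrow(features$X)), levels = EMOTIONS)
  for (i in seq_along(res)) pred[folds[[i]]$test_rows] <- res[[i]]$predictions
  correct <- pred == features$labels
  g <- features$labels == "gratitude"
  structure(list(folds = res, predictions = pred,
                 accuracy = mean(correct),
                 specificity = mean(correct[g]),
                 sensitivity = mean(correct[!g]),
                 n_subjects = n, C = C, alpha = alpha),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOPO-CV over %d subjects: accuracy %.1f%% (specificity %.1f%%, sensitivity %.1f%%)\n",
              x$n_subjects, 100 * x$accuracy, 100 * x$specificity,
              100 * x$sensitivity))
  invisible(x)
}

#' Permutation test of the cross-validated accuracy
#'
#' Re-runs the complete cross-validation (including per-fold scaling and
#' feature selection) under permuted labels. The default scheme swaps the two
#' labels within randomly chosen subjects, respecting the
#' two-samples-per-subject pairing that the paired-t selection requires; the
#' \code{"full"} scheme shuffles all labels (selection then falls back to an
#' unpaired t-test). The p value is the proportion of permutation accuracies
#' strictly above the observed one; \code{rule = "conservative"} uses
#' (count of >= observed + 1) / (n_perm + 1).
#'
#' @param features a \code{feature_matrix}.
#' @param n_perm number of permutations (1,000 for production runs).
#' @param seed integer seed.
#' @param scheme "within_subject" or "full".
#' @param rule "strict" or "conservative".
#' @param observed observed accuracy; computed when NULL.
#' @param C,alpha classifier settings.
#' @return list with \code{p}, \code{observed}, \code{perm_accuracies},
#'   \code{scheme}, \code{rule}.
#' @export
permutation_test <- function(features, n_perm = 1000L, seed,
                             scheme = c("within_subject", "full"),
                             rule = c("strict", "conservative"),
                             observed = NULL, C = 1, alpha = 0.05) {
  scheme <- match.arg(scheme)
  rule <- match.arg(rule)
  stop_if_not(n_perm >= 1, "n_perm must be >= 1")
  folds <- precompute_folds(features)
  if (is.null(observed))
    observed <- run_lopo_cv(features, C, alpha, folds = folds)$accuracy
  n <- max(features$subject)
  set.seed(seed)
  acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    if (scheme == "within_subject") {
      flips <- sample(c(1, -1), n, replace = TRUE)
      labs <- features$labels
      fl <- flips[features$subject] < 0
      labs[fl] <- ifelse(labs[fl] == "gratitude", "joy", "gratitude")
      labs <- factor(labs, levels = EMOTIONS)
      res <- lapply(folds, run_fold, features = features, C = C, alpha = alpha,
                    flips = flips)
    } else {
      labs <- sample(features$labels)
      res <- lapply(folds, run_fold, features = features, C = C, alpha = alpha,
                    full_labels = labs)
    }
    pred <- factor(rep(NA_character_, nrow(features$X)), levels = EMOTIONS)
    for (i in seq_along(res)) pred[folds[[i]]$test_rows] <- res[[i]]$predictions
    acc[b] <- mean(pred == labs)
  }
  p <- if (rule == "strict") mean(acc > observed) else
    (sum(acc >= observed) + 1) / (n_perm + 1)
  list(p = p, observed = observed, perm_accuracies = acc,
       scheme = scheme, rule = rule, n_perm = n_perm)
}

#' Consensus absolute-weight map with cluster localization
#'
#' Restricts features to those selected in every cross-validation fold, maps
#' the mean absolute SVM weight of each onto the voxel grid, and reports
#' connected clusters of at least \code{min_cluster_size} voxels.
#'
#' @param cv a \code{cv_result}.
#' @param features the \code{feature_matrix} the CV was run on.
#' @param min_cluster_size minimum reported cluster extent (default 5).
#' @param connectivity cluster connectivity.
#' @return list (class \code{weight_map}) with \code{map} (voxel map of mean
#'   absolute weights, 0 off-consensus), \code{consensus} (logical feature
#'   vector), and \code{clusters} (data.frame: size, peak coordinates, peak
#'   mean absolute weight \code{w}).
#' @export
consensus_weight_map <- function(cv, features, min_cluster_size = 5L,
                                 connectivity = 26L) {
  V <- ncol(features$X)
  sel_mat <- vapply(cv$folds, function(f) {
    v <- logical(V); v[f$selected] <- TRUE; v
  }, logical(V))
  consensus <- rowSums(sel_mat) == length(cv$folds)
  if (!any(consensus)) warning("no feature was selected in every fold")
  wsum <- numeric(V)
  for (f in cv$folds) wsum[f$selected] <- wsum[f$selected] + abs(f$weights)
  wmean <- ifelse(consensus, wsum / length(cv$folds), 0)

  arr <- array(0, features$dims)
  arr[features$voxel_index] <- wmean
  lab <- cluster_label(arr > 0, connectivity)
  sizes <- attr(lab, "sizes")
  rows <- list()
  for (k in seq_along(sizes)) {
    if (sizes[k] < min_cluster_size) next
    vox <- which(lab == k)
    peak <- vox[which.max(arr[vox])]
    pc <- arrayInd(peak, features$dims)
    rows[[length(rows) + 1L]] <- data.frame(
      size = sizes[k], peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
      w = arr[peak])
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size = integer(0), peak_x = integer(0), peak_y = integer(0),
               peak_z = integer(0), w = numeric(0))
  structure(list(map = as_voxel_map(arr), consensus = consensus,
                 clusters = clusters),
            class = "weight_map")
}
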