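# symbolic expansion oracle for the printed contrast formulas: build each
# formula term by term over collapsed cell sets, independent of the
# implementation's vectorized construction
expand_contrast_oracle <- function(kind) {
  w <- setNames(numeric(18),
                paste(rep(EMOTIONS, each = 9),
                      rep(rep(INTENTION_LEVELS, each = 3), 2),
                      rep(VALUE_LEVELS, 6), sep = "_"))
  add <- function(emotion, intent, value, coef) {
    # a term over a cell set spreads its coefficient evenly over the cells
    cells <- as.vector(outer(intent, value, function(i, v)
      paste(emotion, i, v, sep = "_")))
    w[cells] <<- w[cells] + coef / length(cells)
  }
  for (emo in EMOTIONS) {
    s <- if (emo == "gratitude") 1 else -1
    if (kind == "gratitude_vs_joy") {
      add(emo, INTENTION_LEVELS, VALUE_LEVELS, s)
    } else if (kind == "emotion_by_intention") {
      add(emo, "strong", VALUE_LEVELS, s)
      add(emo, "weak", VALUE_LEVELS, -s / 2)
      add(emo, "no", VALUE_LEVELS, -s / 2)
    } else if (kind == "emotion_by_value") {
      add(emo, INTENTION_LEVELS, "low", s / 2)
      add(emo, INTENTION_LEVELS, "zero", s / 2)
      add(emo, INTENTION_LEVELS, "high", -s)
    } else if (kind == "three_way") {
      # (LowZero,Strong - High,Strong) - (LowZero,WeakNo - High,WeakNo)
      add(emo, "strong", c("low", "zero"), s)
      add(emo, "strong", "high", -s)
      add(emo, c("weak", "no"), c("low", "zero"), -s)
      add(emo, c("weak", "no"), "high", s)
    }
  }
  w
}

test_that("contrast weights match the symbolic expansion of the printed formulas", {
  for (kind in c("gratitude_vs_joy", "emotion_by_intention",
                 "emotion_by_value", "three_way")) {
    w <- build_interaction_contrast(kind)
    oracle <- expand_contrast_oracle(kind)
    expect_equal(unclass(w)[names(oracle)], oracle, tolerance = 1e-12,
                 info = kind)
    expect_equal(sum(w), 0, tolerance = 1e-12)
    # gratitude block mirrors the joy block with opposite sign
    g <- unclass(w)[grep("^gratitude_", names(w))]
    j <- unclass(w)[grep("^joy_", names(w))]
    expect_equal(unname(g), -unname(j))
  }
  expect_equal(as.numeric(build_interaction_contrast("gratitude_vs_joy")),
               rep(c(1 / 9, -1 / 9), each = 9))
  expect_error(build_interaction_contrast("nope"))
})

test_that("the three interaction contrasts are mutually non-collinear", {
  M <- cbind(unclass(build_interaction_contrast("emotion_by_intention")),
             unclass(build_interaction_contrast("emotion_by_value")),
             unclass(build_interaction_contrast("three_way")))
  expect_equal(qr(M)$rank, 3)
})

test_that("one-sample t maps match the hand formula and its symmetries", {
  set.seed(21)
  dims <- c(3, 3, 2)
  maps <- lapply(1:5, function(i) as_voxel_map(array(rnorm(prod(dims)), dims)))
  res <- one_sample_t_map(maps)
  arr <- simplify2array(lapply(maps, unclass))
  v <- arr[2, 3, 1, ]
  t_hand <- mean(v) / (sd(v) / sqrt(5))
  expect_equal(unclass(res$t)[2, 3, 1], t_hand, tolerance = 1e-10)
  expect_equal(res$df, 4)
  # Z is the probability transform of t
  expect_equal(unclass(res$z)[2, 3, 1],
               qnorm(pt(t_hand, 4)), tolerance = 1e-8)

  flipped <- one_sample_t_map(lapply(maps, function(m) as_voxel_map(-unclass(m))))
  expect_equal(unclass(flipped$t), -unclass(res$t), tolerance = 1e-10)
})

test_that("degenerate voxels are capped and flagged", {
  dims <- c(2, 2, 2)
  base <- array(1, dims); base[1, 1, 1] <- 0
  maps <- lapply(1:4, function(i) as_voxel_map(base))
  res <- one_sample_t_map(maps)
  expect_true(all(res$zero_variance))
  expect_equal(unclass(res$z)[2, 2, 2], 10)      # constant nonzero: capped
  expect_equal(unclass(res$t)[1, 1, 1], 0)       # constant zero: t = 0
})

test_that("paired t maps equal the one-sample map of differences", {
  set.seed(22)
  dims <- c(3, 2, 2)
  a <- lapply(1:6, function(i) as_voxel_map(array(rnorm(prod(dims)), dims)))
  b <- lapply(1:6, function(i) as_voxel_map(array(rnorm(prod(dims)), dims)))
  pr <- paired_t_map(a, b)
  diffs <- lapply(1:6, function(i) as_voxel_map(unclass(a[[i]]) - unclass(b[[i]])))
  os <- one_sample_t_map(diffs)
  expect_equal(unclass(pr$t), unclass(os$t), tolerance = 1e-12)
  # a vs a: all-zero t
  same <- paired_t_map(a, a)
  expect_true(all(unclass(same$t) == 0))
  # arithmetic oracle at one voxel
  dv <- unclass(a[[1]])[1, 1, 1] - unclass(b[[1]])[1, 1, 1]
  dvs <- vapply(1:6, function(i)
    unclass(a[[i]])[1, 1, 1] - unclass(b[[i]])[1, 1, 1], 0)
  expect_equal(unclass(pr$t)[1, 1, 1],
               mean(dvs) / (sd(dvs) / sqrt(6)), tolerance = 1e-10)
})

test_that("connectivity conventions split or join diagonal voxels", {
  b <- array(FALSE, c(4, 4, 4))
  b[2, 2, 2] <- TRUE; b[3, 3, 3] <- TRUE    # corner-touching pair
  lab26 <- cluster_label(b, 26)
  expect_equal(length(attr(lab26, "sizes")), 1)
  expect_equal(attr(lab26, "sizes"), 2L)
  lab6 <- cluster_label(b, 6)
  expect_equal(length(attr(lab6, "sizes")), 2)
  b[2, 2, 3] <- TRUE                         # edge-sharing with both
  lab18 <- cluster_label(b, 18)
  expect_equal(length(attr(lab18, "sizes")), 1)
})

test_that("extract_clusters applies extent thresholds and tiers", {
  dims <- c(6, 6, 6)
  z <- array(0, dims)
  blob <- as.matrix(expand.grid(x = 2:3, y = 2:3, z = 2:3))[1:7, ]
  z[blob] <- 4                                # 7-voxel significant blob
  z[6, 6, 6] <- 4                             # isolated singleton
  z[5, 1, 1] <- 2.9                           # trend-tier voxel (p<.005 only)
  zm <- as_voxel_map(z)
  tab <- extract_clusters(zm, voxel_p = 0.001, critical_size = 5,
                          trend_voxel_p = 0.005, trend_critical_size = 1)
  sig <- tab[tab$tier == "significant", ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$size, 7)
  trend <- tab[tab$tier == "trend", ]
  # the singleton fails the primary extent but reappears at the trend tier;
  # the 2.9 voxel exists only at the trend tier
  expect_true(any(trend$size == 1 & trend$peak_Z == 4))
  expect_true(any(abs(trend$peak_Z - 2.9) < 1e-9))
  # the significant blob is not re-reported as a trend
  expect_false(any(trend$size == 7))
  # empty suprathreshold set
  empty <- extract_clusters(as_voxel_map(array(0, dims)), 0.001, 5)
  expect_equal(nrow(empty), 0)
})

test_that("the null max-cluster distribution matches an igraph oracle at fwhm 0", {
  skip_if_not_installed("igraph")
  dims <- c(4, 4, 4)
  mask <- array(TRUE, dims)
  voxel_p <- 0.05
  n_sim <- 4000
  nd <- monte_carlo_cluster_threshold(mask, fwhm = 0, voxel_p = voxel_p,
                                      n_sim = n_sim, connectivity = 26, seed = 5)

  # independent oracle: white-noise thresholding + igraph connected components
  coords <- as.matrix(expand.grid(x = 1:4, y = 1:4, z = 1:4))
  adj <- which(as.matrix(dist(coords, method = "maximum")) == 1, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  zt <- qnorm(1 - voxel_p)
  set.seed(99)
  oracle_sizes <- replicate(n_sim, {
    supra <- rnorm(64) > zt
    if (!any(supra)) return(0L)
    keep <- adj[supra[adj[, 1]] & supra[adj[, 2]], , drop = FALSE]
    if (nrow(keep) == 0) return(1L)
    g <- igraph::graph_from_edgelist(matrix(as.character(keep), ncol = 2),
                                     directed = FALSE)
    max(c(1L, igraph::components(g)$csize))
  })
  # the two empirical 95% quantiles agree
  q_pkg <- quantile(nd$sizes, 0.95, type = 7)
  q_orc <- quantile(oracle_sizes, 0.95, type = 7)
  expect_lte(abs(q_pkg - q_orc), 1)
  # tail probabilities agree within Monte-Carlo error at the critical size
  p_pkg <- mean(nd$sizes >= nd$critical_size)
  p_orc <- mean(oracle_sizes >= nd$critical_size)
  expect_lt(abs(p_pkg - p_orc), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.005)
})

test_that("the critical size grows with smoothing and with a laxer voxel threshold", {
  mask <- array(TRUE, c(6, 6, 6))
  nd_white <- monte_carlo_cluster_threshold(mask, fwhm = 0, voxel_p = 0.005,
                                            n_sim = 600, seed = 3)
  nd_smooth <- monte_carlo_cluster_threshold(mask, fwhm = 2.5, voxel_p = 0.005,
                                             n_sim = 600, seed = 3)
  expect_gte(nd_smooth$critical_size, nd_white$critical_size)
  nd_strict <- monte_carlo_cluster_threshold(mask, fwhm = 1.5, voxel_p = 0.001,
                                             n_sim = 600, seed = 4)
  nd_lax <- monte_carlo_cluster_threshold(mask, fwhm = 1.5, voxel_p = 0.005,
                                          n_sim = 600, seed = 4)
  expect_gte(nd_lax$critical_size, nd_strict$critical_size)
  expect_error(monte_carlo_cluster_threshold(array(FALSE, c(2, 2, 2)),
                                             1, n_sim = 10, seed = 1), "empty")
})

test_that("a planted high-amplitude blob is detected as a significant cluster", {
  mask <- array(TRUE, c(6, 6, 6))
  nd <- monte_carlo_cluster_threshold(mask, fwhm = 1.5, voxel_p = 0.005,
                                      n_sim = 1000, seed = 6)
  set.seed(7)
  hits <- replicate(20, {
    maps <- lapply(1:15, function(i) {
      x <- array(rnorm(216), c(6, 6, 6))
      x[2:3, 2:3, 2:4] <- x[2:3, 2:3, 2:4] + 2      # strong 12-voxel effect
      as_voxel_map(gaussian_smooth_3d(x, 1.5))
    })
    tm <- one_sample_t_map(maps, mask = mask)
    tab <- extract_clusters(tm$z, voxel_p = 0.005,
                            critical_size = nd$critical_size,
                            trend_voxel_p = NULL)
    nrow(tab[tab$tier == "significant", ]) > 0
  })
  expect_gte(mean(hits), 0.9)
})
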