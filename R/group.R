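#' Interaction contrast weights over the 18 condition regressors
#'
#' Builds the weight vector for one of the study's group contrasts, spreading
#' each formula term evenly over the levels of any collapsed factor:
#' \itemize{
#' \item \code{gratitude_vs_joy}: +1/9 on every gratitude cell, -1/9 on every
#'   joy cell.
#' \item \code{emotion_by_intention}: Gratitude (Strong - 1/2 Weak - 1/2 No)
#'   minus the same for Joy, each intention term averaged over its three
#'   value cells.
#' \item \code{emotion_by_value}: Gratitude (1/2 Low + 1/2 Zero - High) minus
#'   the same for Joy, averaged over intention cells.
#' \item \code{three_way}: Gratitude [(Low/Zero,Strong - High,Strong) -
#'   (Low/Zero,Weak/No - High,Weak/No)] minus the same for Joy, where
#'   Low/Zero and Weak/No average the two collapsed levels.
#' }
#'
#' @param kind contrast name.
#' @return named numeric vector of length 18 summing to zero (class
#'   \code{contrast_spec}).
#' @export
build_interaction_contrast <- function(kind = c("emotion_by_intention",
                                                "emotion_by_value",
                                                "three_way",
                                                "gratitude_vs_joy")) {
  kind <- match.arg(kind)
  cells <- expand.grid(value = VALUE_LEVELS, intention = INTENTION_LEVELS,
                       emotion = EMOTIONS, stringsAsFactors = FALSE)[, 3:1]
  nm <- paste(cells$emotion, cells$intention, cells$value, sep = "_")
  emo_sign <- ifelse(cells$emotion == "gratitude", 1, -1)

  w <- switch(kind,
    gratitude_vs_joy = emo_sign / 9,
    emotion_by_intention = {
      ic <- c(strong = 1, weak = -1 / 2, no = -1 / 2)
      emo_sign * ic[cells$intention] / 3
    },
    emotion_by_value = {
      vc <- c(high = -1, low = 1 / 2, zero = 1 / 2)
      emo_sign * vc[cells$value] / 3
    },
    three_way = {
      vc <- c(high = -1, low = 1 / 2, zero = 1 / 2)
      ic <- c(strong = 1, weak = -1 / 2, no = -1 / 2)
      emo_sign * vc[cells$value] * ic[cells$intention]
    })
  structure(setNames(as.numeric(w), nm), kind = kind, class = "contrast_spec")
}

t_to_z <- function(t, df, cap = 10) {
  lp <- pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  z <- -sign(t) * qnorm(lp, log.p = TRUE)
  pmin(pmax(z, -cap), cap)
}

stack_maps <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 4L) return(maps)
  arr <- array(NA_real_, c(dim(maps[[1]]), length(maps)))
  for (i in seq_along(maps)) arr[, , , i] <- unclass(maps[[i]])
  arr
}

#' Group-level one-sample t and Z maps
#'
#' Per voxel, t = mean / (sd / sqrt(n)) against zero with df = n - 1; Z is
#' the probability-transformed t, capped at |Z| = 10 for numerically
#' degenerate values. Zero-variance voxels are flagged; a constant nonzero
#' voxel maps to the Z cap, a constant zero voxel to t = 0.
#'
#' @param maps list of per-subject \code{voxel_map}s (or a 4D array,
#'   subjects last).
#' @param mask optional logical array (e.g. a binarized gray-matter map)
#'   restricting the analysis.
#' @return list with \code{t}, \code{z} (voxel maps), \code{df}, \code{n},
#'   and \code{zero_variance} (logical array).
#' @export
one_sample_t_map <- function(maps, mask = NULL) {
  arr <- stack_maps(maps)
  n <- dim(arr)[4]
  stop_if_not(n >= 3, "need at least 3 subject maps")
  m <- apply(arr, 1:3, mean)
  s <- apply(arr, 1:3, sd)
  if (!is.null(mask)) { m[!mask] <- NA; s[!mask] <- NA }
  zv <- !is.na(s) & s == 0
  t <- m / (s / sqrt(n))
  # zero-variance voxels: identically zero -> t = 0; constant nonzero -> +/-Inf
  # (Z then hits the cap); both flagged in zero_variance
  t[zv] <- ifelse(m[zv] == 0, 0, Inf * sign(m[zv]))
  z <- t_to_z(t, n - 1)
  list(t = as_voxel_map(t), z = as_voxel_map(z), df = n - 1, n = n,
       zero_variance = zv)
}

#' Group-level paired t map
#'
#' One-sample t map of the per-subject difference maps a - b.
#'
#' @param maps_a,maps_b lists of per-subject voxel maps, same subject order.
#' @param mask optional analysis mask.
#' @return as \code{\link{one_sample_t_map}}.
#' @export
paired_t_map <- function(maps_a, maps_b, mask = NULL) {
  a <- stack_maps(maps_a); b <- stack_maps(maps_b)
  stop_if_not(identical(dim(a), dim(b)), "map stacks differ in shape")
  one_sample_t_map(a - b, mask = mask)
}

neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  d <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d <= 2, "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, ])
}

#' Label connected components of a 3D binary image
#'
#' Breadth-first flood fill under 6-, 18- or 26-connectivity.
#'
#' @param binary logical 3D array.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners).
#' @return integer array of component labels (0 = background); attribute
#'   \code{"sizes"} gives voxels per component.
#' @export
cluster_label <- function(binary, connectivity = 26L) {
  dims <- dim(binary)
  labels <- array(0L, dims)
  idx <- which(binary)
  if (!length(idx)) { attr(labels, "sizes") <- integer(0); return(labels) }
  off <- neighbor_offsets(connectivity)
  coords <- arrayInd(idx, dims)
  inset <- array(FALSE, dims); inset[idx] <- TRUE
  lab <- 0L
  sizes <- integer(0)
  for (s in seq_along(idx)) {
    if (labels[idx[s]] != 0L) next
    lab <- lab + 1L
    queue <- matrix(coords[s, ], 1)
    labels[idx[s]] <- lab
    count <- 1L
    while (nrow(queue)) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(off, 2, v, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
      new <- lin[inset[lin] & labels[lin] == 0L]
      if (length(new)) {
        labels[new] <- lab
        count <- count + length(new)
        queue <- rbind(queue, arrayInd(new, dims))
      }
    }
    sizes <- c(sizes, count)
  }
  attr(labels, "sizes") <- sizes
  labels
}

#' Monte-Carlo null distribution of the maximum cluster size
#'
#' Simulates smooth Gaussian null fields on the mask grid (white noise,
#' separable Gaussian smoothing at the given FWHM, exact per-voxel
#' renormalization to unit variance), thresholds them one-sidedly at the
#' voxel-level p, and records the largest suprathreshold cluster per field.
#' The critical size is the ceiling of the empirical (1 - alpha) quantile of
#' the max-cluster-size distribution; clusters at least that large are called
#' significant.
#'
#' @param mask logical 3D array.
#' @param fwhm smoothness FWHM in voxel units (scalar or length 3; 0 = white
#'   noise).
#' @param voxel_p one-sided voxel-level threshold (0.001 primary tier, 0.005
#'   trend tier).
#' @param n_sim number of simulated fields (10,000 for production runs).
#' @param connectivity cluster connectivity (default 26).
#' @param seed integer seed.
#' @param alpha family-wise error target (default 0.05).
#' @return object of class \code{null_cluster_dist} with \code{sizes},
#'   \code{critical_size}, and the simulation settings.
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm, voxel_p = 0.001,
                                          n_sim = 10000L, connectivity = 26L,
                                          seed, alpha = 0.05) {
  stop_if_not(any(mask), "empty mask")
  stop_if_not(all(fwhm >= 0), "fwhm must be nonnegative")
  dims <- dim(mask)
  zt <- qnorm(1 - voxel_p)
  smooth <- any(fwhm > 0)
  if (smooth) sd_map <- smoothed_noise_sd(dims, fwhm)
  set.seed(seed)
  sizes <- integer(n_sim)
  for (i in seq_len(n_sim)) {
    z <- array(rnorm(prod(dims)), dims)
    if (smooth) z <- gaussian_smooth_3d(z, fwhm) / sd_map
    supra <- z > zt & mask
    if (!any(supra)) next
    sizes[i] <- max(attr(cluster_label(supra, connectivity), "sizes"))
  }
  crit <- critical_cluster_size(sizes, alpha)
  structure(list(sizes = sizes, n_sim = n_sim, voxel_p = voxel_p,
                 fwhm = fwhm, connectivity = connectivity, alpha = alpha,
                 critical_size = crit),
            class = "null_cluster_dist")
}

critical_cluster_size <- function(sizes, alpha = 0.05) {
  max(1L, as.integer(ceiling(quantile(sizes, 1 - alpha, type = 7, names = FALSE))))
}

#' @export
print.null_cluster_dist <- function(x, ...) {
  cat("Monte-Carlo cluster null:", x$n_sim, "fields, voxel p =", x$voxel_p,
      "; critical size =", x$critical_size, "voxels at FWE", x$alpha, "\n")
  invisible(x)
}

#' Extract suprathreshold clusters from a Z map
#'
#' Connected components of the one-sided suprathreshold set at the primary
#' voxel threshold, labeled significant if their extent reaches the primary
#' critical size; components at the (laxer) trend threshold reaching the
#' trend critical size, and not already significant, are labeled trends.
#'
#' @param z_map a \code{voxel_map} of Z values.
#' @param voxel_p primary voxel threshold (default 0.001).
#' @param critical_size primary cluster-extent threshold.
#' @param connectivity cluster connectivity.
#' @param trend_voxel_p trend-tier voxel threshold (default 0.005; NULL
#'   disables the tier).
#' @param trend_critical_size extent threshold for the trend tier (required
#'   when the tier is enabled).
#' @return data.frame (class \code{cluster_table}) with \code{label, tier,
#'   size, peak_x, peak_y, peak_z, peak_Z}.
#' @export
extract_clusters <- function(z_map, voxel_p = 0.001, critical_size,
                             connectivity = 26L, trend_voxel_p = 0.005,
                             trend_critical_size = NULL) {
  z <- unclass(z_map)
  z[is.na(z)] <- -Inf
  rows <- list()
  # harvests clusters at one tier; returns the mask of voxels in kept clusters
  harvest <- function(p_thr, min_size, tier, exclude = NULL) {
    supra <- z > qnorm(1 - p_thr)
    lab <- cluster_label(supra, connectivity)
    sizes <- attr(lab, "sizes")
    kept <- array(FALSE, dim(z))
    for (k in seq_along(sizes)) {
      if (sizes[k] < min_size) next
      vox <- which(lab == k)
      if (!is.null(exclude) && any(exclude[vox])) next
      peak <- vox[which.max(z[vox])]
      pc <- arrayInd(peak, dim(z))
      kept[vox] <- TRUE
      rows[[length(rows) + 1L]] <<- data.frame(
        label = length(rows) + 1L, tier = tier, size = sizes[k],
        peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
        peak_Z = z[peak])
    }
    kept
  }
  sig_vox <- harvest(voxel_p, critical_size, "significant")
  if (!is.null(trend_voxel_p)) {
    if (is.null(trend_critical_size)) trend_critical_size <- critical_size
    # trend clusters that contain an already-significant voxel are not re-reported
    harvest(trend_voxel_p, trend_critical_size, "trend", exclude = sig_vox)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), tier = character(0), size = integer(0),
               peak_x = integer(0), peak_y = integer(0), peak_z = integer(0),
               peak_Z = numeric(0))
  out$label <- seq_len(nrow(out))
  class(out) <- c("cluster_table", "data.frame")
  out
}
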