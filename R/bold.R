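#' Ground truth for the BOLD simulator
#'
#' Defines, on a fixed voxel grid, the per-voxel response amplitude of each
#' of the 18 condition regressors and the per-voxel slope of each Model-2
#' parametric modulator for each emotion, together with the noise model.
#' Defaults mimic the study's effect structure: equal baseline amplitudes for
#' all cells (no average activation difference between emotions) and
#' modulation-slope differences between emotions confined to two disjoint
#' regions of interest — one whose intention-linear slopes differ and one
#' whose value-linear slopes differ. Outside the ROIs all slopes are equal
#' (zero) between emotions.
#'
#' @param grid_dim grid shape (default 6 x 6 x 6).
#' @param voxel_size voxel edge length in mm (default 3).
#' @param mask logical array; default all-TRUE.
#' @param baseline_amplitude common amplitude of all 18 condition regressors.
#' @param roi_slope_diff gratitude-minus-joy slope difference inside each ROI
#'   (split +/- between the emotions).
#' @param rois named list of integer matrices (one row per voxel, columns
#'   x,y,z) or NULL for the built-in pair of 12-voxel blocks. Names must be a
#'   subset of the modulator names; each ROI carries the slope difference of
#'   its modulator.
#' @param ar1 lag-1 autoregressive coefficient of the noise.
#' @param noise_sd innovation SD of the noise.
#' @param fwhm_mm spatial smoothing FWHM in mm applied to the simulated data
#'   (0 = none; multivariate analyses use unsmoothed maps).
#' @return object of class \code{ground_truth} with fields
#'   \code{amplitudes} (x,y,z,18), \code{slopes} (x,y,z,4,2),
#'   \code{roi_labels}, \code{mask}, \code{gray_matter}, \code{ar1},
#'   \code{noise_sd}, \code{fwhm_mm}, \code{voxel_size},
#'   \code{condition_names}.
#' @export
ground_truth <- function(grid_dim = c(6L, 6L, 6L), voxel_size = 3,
                         mask = NULL, baseline_amplitude = 1,
                         roi_slope_diff = 0.5, rois = NULL,
                         ar1 = 0.3, noise_sd = 1, fwhm_mm = 0) {
  mask <- mask %||% array(TRUE, grid_dim)
  stop_if_not(identical(dim(mask), as.integer(grid_dim)) ||
                identical(dim(mask), grid_dim), "mask grid mismatch")

  cells <- expand.grid(value = VALUE_LEVELS, intention = INTENTION_LEVELS,
                       emotion = EMOTIONS, stringsAsFactors = FALSE)[, 3:1]
  condition_names <- paste(cells$emotion, cells$intention, cells$value, sep = "_")

  amp <- array(0, c(grid_dim, 18L))
  for (k in 1:18) {
    a <- array(0, grid_dim); a[mask] <- baseline_amplitude
    amp[, , , k] <- a
  }

  if (is.null(rois)) {
    lim <- pmin(grid_dim, c(6L, 6L, 6L))
    block <- function(xr, yr, zr) as.matrix(expand.grid(x = xr, y = yr, z = zr))
    rois <- list(
      intention_linear = block(1:min(2, lim[1]), 1:min(2, lim[2]), 1:min(3, lim[3])),
      value_linear = block(max(1, lim[1] - 1):lim[1], max(1, lim[2] - 1):lim[2],
                           max(1, lim[3] - 2):lim[3])
    )
  }
  stop_if_not(all(names(rois) %in% MODULATOR_ORDER),
              "ROI names must be modulator names")

  slopes <- array(0, c(grid_dim, 4L, 2L),
                  dimnames = list(NULL, NULL, NULL, MODULATOR_ORDER, EMOTIONS))
  roi_labels <- array(0L, grid_dim)
  for (i in seq_along(rois)) {
    vox <- as.matrix(rois[[i]])
    stop_if_not(all(roi_labels[vox] == 0L), "ROIs must be disjoint")
    j <- match(names(rois)[i], MODULATOR_ORDER)
    slopes[cbind(vox, j, 1L)] <- roi_slope_diff / 2
    slopes[cbind(vox, j, 2L)] <- -roi_slope_diff / 2
    roi_labels[vox] <- i
  }
  attr(roi_labels, "roi_names") <- names(rois)

  gm <- array(0, grid_dim); gm[mask] <- 1
  structure(list(amplitudes = amp, slopes = slopes, roi_labels = roi_labels,
                 mask = mask, gray_matter = gm, ar1 = ar1, noise_sd = noise_sd,
                 fwhm_mm = fwhm_mm, voxel_size = voxel_size,
                 grid_dim = grid_dim, condition_names = condition_names,
                 rois = rois),
            class = "ground_truth")
}

#' Simulate 4D BOLD data for one subject
#'
#' Per run, the voxel signal is the Model-1 condition regressor matrix times
#' the ground-truth amplitudes plus the Model-2 (serially orthogonalized)
#' modulator columns times the ground-truth slopes; noise is stationary AR(1)
#' Gaussian, independent across voxels, optionally followed by spatial
#' Gaussian smoothing. Voxels outside the brain mask are zero.
#'
#' @param design a \code{subject_design}.
#' @param ratings the subject's rating records.
#' @param truth a \code{ground_truth} (grids must match).
#' @param seed integer seed.
#' @param oversampling HRF convolution oversampling.
#' @return object of class \code{simulated_bold}: \code{runs} (list of 4D
#'   arrays), \code{tr}, \code{mask}, \code{gray_matter} (voxel maps).
#' @export
simulate_bold <- function(design, ratings, truth, seed, oversampling = 16L) {
  tr <- attr(design$runs[[1]], "tr")
  n_volumes <- attr(design$runs[[1]], "n_volumes")
  dims <- truth$grid_dim
  vox <- which(truth$mask)
  V <- length(vox)

  A <- matrix(truth$amplitudes, ncol = 18L)[vox, , drop = FALSE]      # V x 18
  S <- matrix(truth$slopes, ncol = 8L)[vox, , drop = FALSE]           # V x 8
  mods <- model2_modulators(design, ratings)
  sratings <- ratings[ratings$subject_id == design$subject_id, ]

  runs <- lapply(seq_along(design$runs), function(ri) {
    run <- design$runs[[ri]]
    tri <- usable_trials(run, sratings)
    cells <- expand.grid(value = VALUE_LEVELS, intention = INTENTION_LEVELS,
                         emotion = EMOTIONS, stringsAsFactors = FALSE)[, 3:1]
    sets <- lapply(1:18, function(k) {
      sel <- tri$intention_level == cells$intention[k] &
        tri$value_level == cells$value[k]
      ev <- rating_event_times(tri[sel, , drop = FALSE], cells$emotion[k])
      list(onsets = ev$onset, durations = ev$duration, amplitudes = 1)
    })
    for (emo in EMOTIONS) {
      m <- mods[[ri]][[emo]]
      ev <- rating_event_times(m$trials, emo)
      for (j in 1:4) {
        sets[[length(sets) + 1L]] <- if (attr(m$orth, "dropped")[j])
          list(onsets = numeric(0), durations = numeric(0))
        else list(onsets = ev$onset, durations = ev$duration,
                  amplitudes = m$orth[, j])
      }
    }
    Xall <- convolve_event_columns(sets, n_volumes, tr, oversampling)
    signal <- Xall[, 1:18] %*% t(A) + Xall[, 19:26] %*% t(S)           # T x V

    set.seed(derive_seed(seed, design$subject_id, ri, 31L))
    e <- matrix(rnorm(n_volumes * V, 0, truth$noise_sd), n_volumes, V)
    if (truth$ar1 != 0) {
      e[1, ] <- e[1, ] / sqrt(1 - truth$ar1^2)   # stationary start
      e <- unclass(stats::filter(e, truth$ar1, method = "recursive"))
    }
    y <- signal + e

    arr <- array(0, c(dims, n_volumes))
    flat <- matrix(arr, ncol = n_volumes)
    flat[vox, ] <- t(y)
    arr <- array(flat, c(dims, n_volumes))
    if (truth$fwhm_mm > 0) {
      fw <- truth$fwhm_mm / truth$voxel_size
      for (t in seq_len(n_volumes)) {
        arr[, , , t] <- gaussian_smooth_3d(arr[, , , t], fw)
      }
      flat <- matrix(arr, ncol = n_volumes)
      flat[-vox, ] <- 0
      arr <- array(flat, c(dims, n_volumes))
    }
    arr
  })

  structure(list(runs = runs, tr = tr,
                 mask = as_voxel_map(array(as.numeric(truth$mask), dims),
                                     voxel_size = truth$voxel_size),
                 gray_matter = as_voxel_map(truth$gray_matter,
                                            voxel_size = truth$voxel_size)),
            class = "simulated_bold")
}

#' @export
print.simulated_bold <- function(x, ...) {
  cat("simulated BOLD:", length(x$runs), "runs of",
      dim(x$runs[[1]])[4], "volumes,",
      paste(dim(x$runs[[1]])[1:3], collapse = " x "), "grid (tr =", x$tr, "s)\n")
  invisible(x)
}
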