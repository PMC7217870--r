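#' Fit an ordinary-least-squares GLM to every in-mask voxel
#'
#' Solves Y = X beta + e per voxel by pivoted QR; a rank-deficient design
#' triggers a warning and a minimum-norm (pseudo-inverse) solution, leaving
#' coefficients of full-rank columns identified. Residual degrees of freedom
#' are n_timepoints - rank(X).
#'
#' @param bold 4D array (x, y, z, t), list of per-run 4D arrays, or a
#'   \code{simulated_bold}.
#' @param X a \code{design_matrix} or plain numeric matrix.
#' @param mask logical 3D array of voxels to fit.
#' @param keep_residuals retain the residual time series (needed for
#'   smoothness estimation).
#' @return object of class \code{glm_fit}: \code{betas} (regressors x
#'   voxels), \code{names}, \code{sigma2}, \code{df}, \code{mask},
#'   \code{dims}, optional \code{residuals}.
#' @export
fit_glm <- function(bold, X, mask, keep_residuals = TRUE) {
  if (inherits(bold, "simulated_bold")) bold <- bold$runs
  if (is.list(bold)) {
    tdim <- length(dim(bold[[1]]))
    Y4 <- array(0, c(dim(bold[[1]])[1:3], sum(vapply(bold, function(b) dim(b)[4], 0))))
    t0 <- 0L
    for (b in bold) {
      Y4[, , , t0 + seq_len(dim(b)[4])] <- b
      t0 <- t0 + dim(b)[4]
    }
    bold <- Y4
  }
  dims <- dim(bold)[1:3]
  stop_if_not(identical(dim(mask), dims), "mask grid mismatch")
  Xm <- if (inherits(X, "design_matrix")) X$X else as.matrix(X)
  if (is.null(colnames(Xm))) colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
  n <- dim(bold)[4]
  stop_if_not(nrow(Xm) == n, "time dimension of data and design differ")

  vox <- which(mask)
  Y <- matrix(aperm(bold, c(4, 1, 2, 3)), nrow = n)[, vox, drop = FALSE]

  qx <- qr(Xm)
  p <- ncol(Xm)
  if (qx$rank < p) {
    warning("design matrix is rank deficient (rank ", qx$rank, " of ", p,
            "); using minimum-norm solution")
    sv <- svd(Xm)
    pos <- sv$d > max(sv$d) * 1e-10
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    betas <- pinv %*% Y
  } else {
    betas <- qr.coef(qx, Y)
  }
  rownames(betas) <- colnames(Xm)
  fitted <- Xm %*% betas
  resid <- Y - fitted
  df <- n - qx$rank
  sigma2 <- colSums(resid^2) / df

  structure(list(betas = betas, names = colnames(Xm), sigma2 = sigma2,
                 df = df, rank = qx$rank, mask = mask, dims = dims,
                 voxels = vox,
                 residuals = if (keep_residuals) resid else NULL),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("GLM fit:", length(x$names), "regressors,", length(x$voxels),
      "voxels, df =", x$df, "\n")
  invisible(x)
}

vector_to_map <- function(values, fit) {
  arr <- array(NA_real_, fit$dims)
  arr[fit$voxels] <- values
  as_voxel_map(arr, mask = fit$mask)
}

#' Extract one regressor's beta image
#'
#' @param fit a \code{glm_fit}.
#' @param name regressor name.
#' @return a \code{voxel_map}.
#' @export
beta_map <- function(fit, name) {
  i <- match(name, fit$names)
  stop_if_not(!is.na(i), paste("no regressor named", name))
  vector_to_map(fit$betas[i, ], fit)
}

#' Linear contrast of beta images
#'
#' Per-voxel weighted sum of fitted coefficients. Weights may be a full
#' vector over all regressors or a named vector over a subset (others 0).
#'
#' @param fit a \code{glm_fit}.
#' @param weights numeric vector, full-length or named.
#' @return a \code{voxel_map}.
#' @export
contrast_image <- function(fit, weights) {
  p <- length(fit$names)
  if (!is.null(names(weights))) {
    w <- setNames(numeric(p), fit$names)
    miss <- setdiff(names(weights), fit$names)
    stop_if_not(length(miss) == 0,
                paste("unknown regressor(s):", paste(miss, collapse = ", ")))
    w[names(weights)] <- weights
  } else {
    stop_if_not(length(weights) == p, "weight length must match regressor count")
    w <- weights
  }
  vector_to_map(drop(crossprod(fit$betas, w)), fit)
}

#' Estimate residual field smoothness (gradient method)
#'
#' Standardizes each voxel's residual series to unit variance and estimates,
#' per axis, the FWHM (in voxels) of the equivalent Gaussian smoothing kernel
#' from the variance of spatial first differences. A field produced by
#' smoothing white noise with a Gaussian kernel of SD sigma has neighbor
#' correlation rho = exp(-d^2 / (4 sigma^2)), so
#' FWHM = sqrt(8 log 2) * sqrt(-1 / (4 log rho)) for unit voxel spacing —
#' the same convention \code{\link{monte_carlo_cluster_threshold}} uses for
#' its null fields.
#'
#' @param fit a \code{glm_fit} with residuals retained.
#' @return list with per-axis \code{fwhm} (voxels) and their geometric
#'   \code{mean}.
#' @export
estimate_smoothness <- function(fit) {
  stop_if_not(!is.null(fit$residuals), "fit was made with keep_residuals = FALSE")
  n <- nrow(fit$residuals)
  sdv <- sqrt(fit$sigma2 * fit$df / n)
  Z <- sweep(fit$residuals, 2, pmax(sdv, 1e-12), "/")
  arr <- array(NA_real_, c(fit$dims, n))
  flat <- matrix(arr, ncol = n)
  flat[fit$voxels, ] <- t(Z)
  arr <- array(flat, c(fit$dims, n))

  fwhm <- numeric(3)
  for (ax in 1:3) {
    d <- apply(arr, setdiff(1:4, ax), diff)
    vd <- mean(d^2, na.rm = TRUE)
    rho <- max(min(1 - vd / 2, 0.999), 1e-6)
    fwhm[ax] <- sqrt(8 * log(2)) * sqrt(-1 / (4 * log(rho)))
  }
  list(fwhm = fwhm, mean = exp(mean(log(fwhm))))
}
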