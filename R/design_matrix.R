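#' Serially orthogonalize parametric-modulator values
#'
#' Each column is mean-centered (residualized against the unmodulated onset
#' column, which over events is a column of ones) and then residualized
#' against all earlier orthogonalized columns, in the given order. Later
#' modulators therefore carry only variance not explained by earlier ones.
#' Columns whose residual is numerically zero (constant or fully explained)
#' are zeroed and flagged.
#'
#' @param M numeric matrix, one row per event, one column per modulator in
#'   serial order.
#' @param tol numeric tolerance for a degenerate column.
#' @return matrix of the same shape; attribute \code{"dropped"} flags zeroed
#'   columns.
#' @export
serial_orthogonalize <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  dropped <- logical(ncol(M))
  basis <- matrix(1 / sqrt(nrow(M)), nrow(M), 1)  # unit-norm onset column
  for (j in seq_len(ncol(M))) {
    r <- M[, j] - basis %*% crossprod(basis, M[, j])
    nr <- sqrt(sum(r^2))
    if (nr < tol * max(1, sqrt(sum(M[, j]^2)))) {
      dropped[j] <- TRUE
    } else {
      out[, j] <- r
      basis <- cbind(basis, r / nr)
    }
  }
  attr(out, "dropped") <- dropped
  out
}

#' The four Model-2 parametric modulators for one emotion's rating events
#'
#' In fixed serial order: the trial's ordinal rating of that emotion, the
#' benefactor-intention level in linear coding (strong/weak/no = 1/0/-1), its
#' square (quadratic coding, computed before centering), and the
#' benefit-value level in linear coding (high/low/zero = 1/0/-1).
#'
#' @param trials data.frame of non-null trials (run-schedule rows).
#' @param rating integer vector, the subject's rating of this emotion on each
#'   trial.
#' @return matrix with columns \code{emotion_rating, intention_linear,
#'   intention_quadratic, value_linear}.
#' @export
modulator_codes <- function(trials, rating) {
  il <- level_code(trials$intention_level, "intention")
  cbind(emotion_rating = as.numeric(rating),
        intention_linear = il,
        intention_quadratic = il^2,
        value_linear = level_code(trials$value_level, "value"))
}

#' Fixed serial order of the Model-2 parametric modulators
#' @export
MODULATOR_ORDER <- c("emotion_rating", "intention_linear",
                     "intention_quadratic", "value_linear")

# shared scaffolding: frame times, run intercepts, nuisance columns
nuisance_columns <- function(design, n_volumes, motion = NULL,
                             rating_order_nuisance = "per_run") {
  n_runs <- length(design$runs)
  total <- n_volumes * n_runs
  run_of_row <- rep(seq_len(n_runs), each = n_volumes)
  cols <- NULL
  if (rating_order_nuisance == "per_run") {
    ind <- vapply(design$runs, function(r) r$rating_order[1] == "gratitude_first",
                  logical(1))
    cols <- cbind(rating_order = as.numeric(ind[run_of_row]))
  }
  if (!is.null(motion)) {
    mo <- do.call(rbind, motion)
    stop_if_not(nrow(mo) == total && ncol(mo) == 6, "motion must be n_volumes x 6 per run")
    colnames(mo) <- paste0("motion", 1:6)
    cols <- cbind(cols, mo)
  }
  ri <- matrix(0, total, n_runs,
               dimnames = list(NULL, paste0("run", seq_len(n_runs))))
  ri[cbind(seq_len(total), run_of_row)] <- 1
  list(cols = cbind(cols, ri), run_of_row = run_of_row)
}

new_design_matrix <- function(X, tr, condition_cols, run_of_row,
                              modulator_order = NULL, orthogonalized = FALSE) {
  structure(list(X = X, names = colnames(X), tr = tr,
                 condition_cols = condition_cols,
                 run_of_row = run_of_row,
                 modulator_order = modulator_order,
                 orthogonalized = orthogonalized),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design matrix:", nrow(x$X), "volumes x", ncol(x$X), "regressors (tr =",
      x$tr, "s)\n")
  invisible(x)
}

# trials usable for event modelling: non-null and, when ratings are supplied,
# with both ratings present (missing-rating trials are excluded everywhere)
usable_trials <- function(run, ratings) {
  tr <- run[!run$is_null, ]
  if (is.null(ratings)) return(tr)
  r <- ratings[ratings$run_index == run$run_index[1], ]
  ok <- r$trial_index[!is.na(r$gratitude) & !is.na(r$joy)]
  tr[tr$trial_index %in% ok, ]
}

#' Build the Model-1 (condition) design matrix
#'
#' One HRF-convolved regressor per emotion x intention x value cell (18
#' columns), with events at the corresponding emotion's rating-screen onsets
#' and durations; plus the rating-order indicator, optional motion columns,
#' and per-run intercepts. Runs are concatenated.
#'
#' @param design a \code{subject_design}.
#' @param ratings optional rating records; when supplied, trials with either
#'   rating missing are excluded from all condition regressors.
#' @param motion optional list (per run) of n_volumes x 6 nuisance series.
#' @param rating_order_nuisance "per_run" (indicator constant within run;
#'   note it is then collinear with the run intercepts and absorbed at fit
#'   time) or "none".
#' @param n_volumes,tr acquisition geometry (defaults from the run
#'   schedules).
#' @param oversampling HRF convolution oversampling.
#' @return a \code{design_matrix}.
#' @export
build_model1 <- function(design, ratings = NULL, motion = NULL,
                         rating_order_nuisance = c("per_run", "none"),
                         n_volumes = NULL, tr = NULL, oversampling = 16L) {
  rating_order_nuisance <- match.arg(rating_order_nuisance)
  tr <- tr %||% attr(design$runs[[1]], "tr")
  n_volumes <- n_volumes %||% attr(design$runs[[1]], "n_volumes")
  n_runs <- length(design$runs)

  cells <- expand.grid(value = VALUE_LEVELS, intention = INTENTION_LEVELS,
                       emotion = EMOTIONS, stringsAsFactors = FALSE)[, 3:1]
  cond_names <- paste(cells$emotion, cells$intention, cells$value, sep = "_")

  blocks <- lapply(design$runs, function(run) {
    tri <- usable_trials(run, if (is.null(ratings)) NULL else
      ratings[ratings$subject_id == design$subject_id, ])
    sets <- lapply(seq_len(nrow(cells)), function(k) {
      sel <- tri$intention_level == cells$intention[k] &
        tri$value_level == cells$value[k]
      ev <- rating_event_times(tri[sel, , drop = FALSE], cells$emotion[k])
      list(onsets = ev$onset, durations = ev$duration, amplitudes = 1)
    })
    Xc <- convolve_event_columns(sets, n_volumes, tr, oversampling)
    colnames(Xc) <- cond_names
    Xc
  })
  Xc <- do.call(rbind, blocks)
  if (any(colSums(abs(Xc)) == 0))
    warning("condition regressor(s) with no events: ",
            paste(cond_names[colSums(abs(Xc)) == 0], collapse = ", "))

  nu <- nuisance_columns(design, n_volumes, motion, rating_order_nuisance)
  X <- cbind(Xc, nu$cols)
  new_design_matrix(X, tr, condition_cols = cond_names, run_of_row = nu$run_of_row)
}

#' Per-run raw and orthogonalized Model-2 modulators
#'
#' Exposes the modulator construction used by \code{\link{build_model2}}:
#' for every run and emotion, the usable events (non-null, both ratings
#' present), the raw modulator codes, and their serially orthogonalized
#' counterparts. Centering and orthogonalization are performed within run.
#'
#' @param design a \code{subject_design}.
#' @param ratings the subject's rating records.
#' @return nested list \code{[[run]][[emotion]]} with elements
#'   \code{trials}, \code{raw}, \code{orth}.
#' @export
model2_modulators <- function(design, ratings) {
  ratings <- ratings[ratings$subject_id == design$subject_id, ]
  lapply(design$runs, function(run) {
    tri <- usable_trials(run, ratings)
    r <- ratings[ratings$run_index == run$run_index[1], ]
    r <- r[match(tri$trial_index, r$trial_index), ]
    out <- list()
    for (emo in EMOTIONS) {
      raw <- modulator_codes(tri, r[[emo]])
      out[[emo]] <- list(trials = tri, raw = raw, orth = serial_orthogonalize(raw))
    }
    out
  })
}

#' Build the Model-2 (parametric modulation) design matrix
#'
#' Per emotion: one unmodulated regressor at that emotion's rating-screen
#' events, followed by four parametrically modulated regressors in fixed
#' serial order (emotion rating, intention linear, intention quadratic, value
#' linear). Modulator values are mean-centered and serially orthogonalized
#' within run before being laid onto the event boxcars and convolved.
#' Nuisance columns as in Model 1. Trials with either rating missing are
#' dropped.
#'
#' @inheritParams build_model1
#' @param ratings the subject's rating records (required).
#' @return a \code{design_matrix} with \code{orthogonalized = TRUE}.
#' @export
build_model2 <- function(design, ratings, motion = NULL,
                         rating_order_nuisance = c("per_run", "none"),
                         n_volumes = NULL, tr = NULL, oversampling = 16L) {
  rating_order_nuisance <- match.arg(rating_order_nuisance)
  tr <- tr %||% attr(design$runs[[1]], "tr")
  n_volumes <- n_volumes %||% attr(design$runs[[1]], "n_volumes")

  mods <- model2_modulators(design, ratings)
  names_out <- unlist(lapply(EMOTIONS, function(e)
    c(paste0(e, "_onset"), paste0(e, "_x_", MODULATOR_ORDER))))
  dropped_any <- character(0)

  blocks <- lapply(seq_along(design$runs), function(ri) {
    sets <- list()
    for (emo in EMOTIONS) {
      m <- mods[[ri]][[emo]]
      ev <- rating_event_times(m$trials, emo)
      sets[[paste0(emo, "_onset")]] <-
        list(onsets = ev$onset, durations = ev$duration, amplitudes = 1)
      drop <- attr(m$orth, "dropped")
      for (j in seq_along(MODULATOR_ORDER)) {
        nm <- paste0(emo, "_x_", MODULATOR_ORDER[j])
        if (drop[j]) {
          dropped_any <<- c(dropped_any, paste0("run", ri, ":", nm))
          sets[[nm]] <- list(onsets = numeric(0), durations = numeric(0))
        } else {
          sets[[nm]] <- list(onsets = ev$onset, durations = ev$duration,
                             amplitudes = m$orth[, j])
        }
      }
    }
    Xr <- convolve_event_columns(sets[names_out], n_volumes, tr, oversampling)
    colnames(Xr) <- names_out
    Xr
  })
  Xm <- do.call(rbind, blocks)
  if (length(dropped_any))
    warning("degenerate modulator column(s) dropped: ",
            paste(dropped_any, collapse = ", "))
  zero <- colSums(abs(Xm)) == 0
  if (any(zero)) {
    warning("all-zero regressor(s) removed: ",
            paste(names_out[zero], collapse = ", "))
    Xm <- Xm[, !zero, drop = FALSE]
  }

  nu <- nuisance_columns(design, n_volumes, motion, rating_order_nuisance)
  X <- cbind(Xm, nu$cols)
  new_design_matrix(X, tr, condition_cols = colnames(Xm),
                    run_of_row = nu$run_of_row,
                    modulator_order = MODULATOR_ORDER, orthogonalized = TRUE)
}

#' Synthesize slow-drift motion nuisance series
#'
#' Six per-run random-walk series standing in for realignment parameters;
#' keeps the nuisance block of the design matrix at its real-data shape.
#'
#' @param n_volumes volumes per run.
#' @param seed integer seed.
#' @param step innovation SD of the walk.
#' @return n_volumes x 6 matrix.
#' @export
simulate_motion <- function(n_volumes, seed, step = 0.02) {
  set.seed(seed)
  apply(matrix(rnorm(n_volumes * 6, 0, step), n_volumes, 6), 2, cumsum)
}
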