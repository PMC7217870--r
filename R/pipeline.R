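#' Simulate a complete study (designs and ratings)
#'
#' Generates the cohort's counterbalanced designs and ordinal ratings under
#' one master seed. BOLD volumes are simulated separately per subject with
#' \code{\link{simulate_bold}} (they are large); this function returns
#' everything the behavioral analysis needs and the inputs the imaging
#' simulator consumes.
#'
#' @param n_subjects cohort size (default 30).
#' @param seed master seed.
#' @param params rating-generator parameters.
#' @param ... passed to \code{\link{generate_experiment}}.
#' @return list with \code{designs}, \code{ratings}, \code{params},
#'   \code{seed}.
#' @export
simulate_study <- function(n_subjects = 30L, seed, params = rating_params(), ...) {
  designs <- generate_experiment(n_subjects, seed, ...)
  ratings <- generate_cohort_ratings(designs, params, seed)
  list(designs = designs, ratings = ratings, params = params, seed = seed)
}

#' Fit Model 2 and extract one modulator's beta maps for both emotions
#'
#' Simulates (or accepts) the subject's BOLD data, fits the
#' parametric-modulation GLM, and returns the beta images of the requested
#' modulator for the gratitude and the joy event stream — the inputs of the
#' multivariate analysis.
#'
#' @param design a \code{subject_design}.
#' @param ratings the cohort rating records.
#' @param bold a \code{simulated_bold} (or list of 4D run arrays).
#' @param mask logical analysis mask.
#' @param modulator one of emotion_rating, intention_linear,
#'   intention_quadratic, value_linear.
#' @return list with \code{gratitude} and \code{joy} \code{voxel_map}s and
#'   the underlying \code{fit}.
#' @export
subject_modulator_betas <- function(design, ratings, bold, mask,
                                    modulator = "intention_linear") {
  X <- build_model2(design, ratings)
  fit <- fit_glm(bold, X, mask, keep_residuals = FALSE)
  list(gratitude = beta_map(fit, paste0("gratitude_x_", modulator)),
       joy = beta_map(fit, paste0("joy_x_", modulator)),
       fit = fit)
}

#' End-to-end multivariate decoding of gratitude vs joy from one modulator
#'
#' For every subject: simulate BOLD from the ground truth, fit Model 2, and
#' collect the unsmoothed beta maps of the chosen modulator; then run
#' leave-one-participant-out SVM classification and, optionally, the
#' permutation test and consensus weight map.
#'
#' @param study output of \code{\link{simulate_study}}.
#' @param truth a \code{ground_truth}.
#' @param modulator modulator whose slope patterns are decoded.
#' @param n_perm permutations (0 disables the test).
#' @param seed seed for BOLD noise and permutations.
#' @param C,alpha classifier settings.
#' @return list with \code{features}, \code{cv}, \code{perm} (or NULL),
#'   \code{weight_map}.
#' @export
mvpa_pipeline <- function(study, truth, modulator = "intention_linear",
                          n_perm = 1000L, seed, C = 1, alpha = 0.05) {
  mask <- truth$gray_matter >= 0.2
  maps_g <- list(); maps_j <- list()
  for (i in seq_along(study$designs)) {
    d <- study$designs[[i]]
    bold <- simulate_bold(d, study$ratings, truth, seed = derive_seed(seed, i))
    mb <- subject_modulator_betas(d, study$ratings, bold, mask, modulator)
    maps_g[[i]] <- mb$gratitude
    maps_j[[i]] <- mb$joy
  }
  features <- assemble_features(maps_g, maps_j, mask)
  cv <- run_lopo_cv(features, C = C, alpha = alpha)
  perm <- if (n_perm > 0)
    permutation_test(features, n_perm = n_perm,
                     seed = derive_seed(seed, 9090L),
                     observed = cv$accuracy, C = C, alpha = alpha)
  wm <- consensus_weight_map(cv, features)
  list(features = features, cv = cv, perm = perm, weight_map = wm)
}
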