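# small fixtures shared across tests; everything is generated in code

tiny_design <- function(subject_id = 1, seed = 11, n_runs = 2) {
  generate_subject_design(subject_id, "ABBAAB", seed = seed, n_runs = n_runs)
}

tiny_ratings <- function(design, seed = 11, nonresponse_rate = 0) {
  generate_ratings(design, rating_params(nonresponse_rate = nonresponse_rate),
                   seed = seed)
}

noiseless_truth <- function(...) {
  ground_truth(ar1 = 0, noise_sd = 0, ...)
}

# feature matrix with iid standard-normal features (exchangeable null)
null_features <- function(n_subjects = 30, dims = c(10, 5, 4), seed = 1) {
  set.seed(seed)
  mask <- array(TRUE, dims)
  g <- lapply(seq_len(n_subjects), function(i)
    as_voxel_map(array(rnorm(prod(dims)), dims)))
  j <- lapply(seq_len(n_subjects), function(i)
    as_voxel_map(array(rnorm(prod(dims)), dims)))
  assemble_features(g, j, mask)
}

# feature matrix with a planted gratitude-minus-joy difference on some voxels
signal_features <- function(n_subjects = 20, dims = c(5, 4, 3), effect = 2,
                            n_signal = 10, noise = 1, seed = 1) {
  set.seed(seed)
  mask <- array(TRUE, dims)
  V <- prod(dims)
  g <- lapply(seq_len(n_subjects), function(i) {
    x <- rnorm(V, 0, noise); x[seq_len(n_signal)] <- x[seq_len(n_signal)] + effect / 2
    as_voxel_map(array(x, dims))
  })
  j <- lapply(seq_len(n_subjects), function(i) {
    x <- rnorm(V, 0, noise); x[seq_len(n_signal)] <- x[seq_len(n_signal)] - effect / 2
    as_voxel_map(array(x, dims))
  })
  assemble_features(g, j, mask)
}
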