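# Shared test fixtures.

# A volume whose intensity rises linearly along the x axis.
coordgrid_volume <- function(dims) {
  arr <- array(rep(seq_len(dims[1]) * 10, times = dims[2] * dims[3]),
               dim = dims)
  image_volume(arr)
}

# A small synthetic feature table with iid Gaussian features, two batches.
gaussian_table <- function(n_per_batch = 50, p = 10, seed = 1,
                           batches = c("arterial", "venous")) {
  set.seed(seed)
  n <- n_per_batch * length(batches)
  mat <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  dplyr::bind_cols(
    tibble::tibble(
      meta_patient_id = sprintf("P%04d", seq_len(n)),
      meta_lesion_id = sprintf("L%04d", seq_len(n)),
      meta_batch = rep(batches, each = n_per_batch)),
    tibble::as_tibble(mat))
}
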