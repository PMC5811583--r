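# Shared in-code fixtures. Everything is generated programmatically; no
# binary files ship with the tests.

# Independent brute-force oracle for mask_sum: explicit position-wise loop.
brute_force_mask_sum <- function(values, selected) {
  total <- 0
  for (i in seq_along(values)) {
    if (selected[i]) total <- total + values[i]
  }
  total
}

random_image <- function(seed, dims = c(8, 8, 8), spacing = c(4.8, 4.8, 4.8)) {
  set.seed(seed)
  voxel_image(array(runif(prod(dims)) * 1000, dims), spacing = spacing)
}

random_mask <- function(seed, dims = c(8, 8, 8), p = 0.5) {
  set.seed(seed)
  roi_mask(array(runif(prod(dims)) < p, dims), label = "random")
}

# The six tabulated extrahepatic depositions (threshold volume ml,
# margin-sum activity MBq) used across dosimetry and acceptance tests.
cohort_pairs <- function() extrahepatic_cohort()

# One default noiseless phantom + calibration, generated once per test run
# (a few seconds) and reused by calibration and acceptance tests.
default_calibration <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_threshold()
    cache
  }
})

# One default noiseless patient scene, shared likewise.
default_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_patient_scene(patient_scene_spec())
    cache
  }
})
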