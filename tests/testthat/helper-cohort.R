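# fixtures are built in code: small synthetic cohorts and hand-made aligned
# subjects used across the test files

# aligned subject directly from a 6 x 101 matrix
aligned_from_matrix <- function(values, subject_id = "A1", motion = "squat") {
  structure(list(subject_id = subject_id, motion = motion, grid = 0:100,
                 values = values),
            class = "aligned_subject")
}

# prepped training matrix from the synthetic generator
tiny_training <- function(p = 10, K = 3, noise_sd = 0.02, seed = 1,
                          motion = "squat", spectrum = NULL, ...) {
  gt <- make_ground_truth(motion, K = K, spectrum = spectrum,
                          noise_sd = noise_sd, seed = seed, ...)
  prep_cohort(simulate_cohort(gt, p = p, seed = seed + 1000))
}

# unstructured gaussian training matrix (pure-noise null)
noise_training <- function(p = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(606 * p), 606, p)
  colnames(X) <- sprintf("N%02d", seq_len(p))
  structure(X, subject_ids = colnames(X), motion = "squat",
            class = "kinetic_training")
}

# raw trial with a clean flexion bump; forces supplied per channel on the
# frame grid (n frames), flexion peak strictly interior
bump_trial <- function(n = 101, peak = 51, forces = NULL, subject_id = "B1",
                       motion = "squat", flex_base = 20, flex_peak = 110) {
  stopifnot(peak > 1, peak < n)
  g <- c(seq(0, 50, length.out = peak),
         seq(50, 100, length.out = n - peak + 1)[-1])
  flex <- flex_base + (flex_peak - flex_base) * sin(pi * g / 100)^2
  if (is.null(forces)) forces <- matrix(rnorm(n * 6), n, 6)
  kinetic_trial(subject_id, motion, 100, flex, forces)
}
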