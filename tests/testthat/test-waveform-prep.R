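test_that("peak flexion detection finds the global maximum, earliest on ties", {
  tri <- c(seq(0, 30, by = 1), seq(29, 0, by = -1))
  expect_identical(detect_peak_flexion(tri), 31L)  # unique maximum

  two <- c(0, rep(c(seq(1, 10), seq(9, 1)), 2), 0)
  peaks <- which(two == max(two))
  expect_length(peaks, 2L)
  expect_identical(detect_peak_flexion(two), peaks[1])  # first occurrence
})

test_that("degenerate and boundary-peak flexion sequences error", {
  expect_error(detect_peak_flexion(rep(5, 50)), "degenerate")
  expect_error(detect_peak_flexion(seq(0, 10, length.out = 20)), "boundary")
  expect_error(detect_peak_flexion(seq(10, 0, length.out = 20)), "boundary")
  expect_error(detect_peak_flexion(c(1, 2)), "at least 3")
  expect_error(detect_peak_flexion(c(1, NA, 2, 1)), "non-finite")
})

test_that("closed-chain filter drops flagged lunges only", {
  mk <- function(motion, cc, id) {
    tr <- bump_trial(subject_id = id, motion = motion)
    tr$closed_chain <- cc
    tr
  }
  lunges <- lapply(1:5, function(i) mk("lunge", i > 2, paste0("L", i)))
  expect_length(filter_closed_chain(lunges), 3L)

  squats <- lapply(1:5, function(i) mk("squat", FALSE, paste0("S", i)))
  expect_length(filter_closed_chain(squats), 5L)  # flag ignored for squats

  open <- lapply(1:3, function(i) mk("lunge", FALSE, paste0("O", i)))
  expect_error(filter_closed_chain(open), "no usable trials")
})

test_that("aligning an already-aligned 101-frame trial is the identity", {
  set.seed(11)
  tr <- bump_trial(n = 101, peak = 51)
  al <- align_resample(tr, trim_frac = 0)
  expect_equal(al$values, t(tr$forces), ignore_attr = TRUE, tolerance = 1e-12)

  # idempotence: re-aligning the aligned output changes nothing
  tr2 <- kinetic_trial("B1", "squat", 100, tr$knee_flexion, t(al$values))
  al2 <- align_resample(tr2, trim_frac = 0)
  expect_lt(max(abs(al2$values - al$values)), 1e-9)
})

test_that("the peak frame is pinned exactly at instant 51", {
  set.seed(12)
  # peak at ~30% of the recording
  tr <- bump_trial(n = 200, peak = 60)
  al <- align_resample(tr, trim_frac = 0)
  expect_identical(unname(al$values[, 51]), unname(tr$forces[60, ]))
})

test_that("resampling a sinusoidal channel matches the closed-form warp", {
  n <- 500; peak <- 150
  t_frames <- seq_len(n)
  forces <- matrix(rep(sin(t_frames / 40), 6), n, 6)
  tr <- bump_trial(n = n, peak = peak, forces = forces)
  al <- align_resample(tr, trim_frac = 0)
  # closed form: the warp maps instants 1..51 linearly onto frames 1..peak
  # and instants 52..101 onto (peak, n]
  pos <- c(seq(1, peak, length.out = 51), peak + seq_len(50) * (n - peak) / 50)
  expected <- sin(pos / 40)
  for (c in 1:6)
    expect_lt(max(abs(al$values[c, ] - expected)), 1e-3)
})

test_that("trimming drops standing plateaus and keeps the motion window", {
  gt <- make_ground_truth("squat", K = 2, seed = 3)
  tr <- simulate_cohort(gt, p = 4, seed = 4)[[1]]
  win <- trim_flexion_window(tr$knee_flexion)
  thr <- min(tr$knee_flexion) + 0.05 * diff(range(tr$knee_flexion))
  expect_true(all(tr$knee_flexion[win[1]:win[2]] >= thr))
  if (win[1] > 1) expect_lt(tr$knee_flexion[win[1] - 1], thr)
  if (win[2] < length(tr$knee_flexion))
    expect_lt(tr$knee_flexion[win[2] + 1], thr)
  # the generator's plateaus sit near 5 degrees, far below threshold
  expect_gt(win[1], 1)
  expect_lt(win[2], length(tr$knee_flexion))
})

test_that("feature vectors stack channels in the contracted order", {
  ones <- aligned_from_matrix(matrix(1, 6, 101))
  expect_identical(unname(assemble_feature_vector(ones)), rep(1, 606))

  ramp <- matrix(0, 6, 101)
  ramp[1, ] <- (0:100) / 100  # HJRFx = progress/100
  v <- assemble_feature_vector(aligned_from_matrix(ramp))
  expect_equal(unname(v[1:101]), (0:100) / 100)
  expect_identical(unname(v[102:606]), rep(0, 505))
  expect_identical(names(v)[304], "kjrf_x_000")  # KJRFx at 0% progress
  expect_length(v, 606L)
})

test_that("feature stacking and channel reshaping are inverse bijections", {
  set.seed(13)
  vals <- matrix(rnorm(606), 6, 101)
  v <- assemble_feature_vector(aligned_from_matrix(vals))
  expect_equal(feature_to_channels(v), vals, ignore_attr = TRUE)
})

test_that("training matrix assembly enforces its invariants", {
  set.seed(14)
  subs <- lapply(1:50, function(i)
    aligned_from_matrix(matrix(rnorm(606), 6, 101), sprintf("S%02d", i)))
  X <- build_training_matrix(subs)
  expect_identical(dim(X), c(606L, 50L))
  expect_identical(attr(X, "subject_ids"), sprintf("S%02d", 1:50))
  # columns preserve input order
  expect_identical(unname(X[, 7]),
                   unname(assemble_feature_vector(subs[[7]])))

  expect_error(build_training_matrix(subs[1]), "too few subjects")
  mixed <- subs[1:4]
  mixed[[2]]$motion <- "lunge"
  expect_error(build_training_matrix(mixed), "mixed motions")
  dup <- subs[1:4]
  dup[[3]]$subject_id <- "S01"
  expect_error(build_training_matrix(dup), "duplicate subject_id")
})

test_that("repeated trials are averaged into one aligned subject", {
  a <- aligned_from_matrix(matrix(1, 6, 101), "S1")
  b <- aligned_from_matrix(matrix(3, 6, 101), "S1")
  expect_identical(average_aligned(list(a, b))$values, matrix(2, 6, 101))
  other <- aligned_from_matrix(matrix(0, 6, 101), "S2")
  expect_error(average_aligned(list(a, other)), "one subject")
})

test_that("prep_cohort averages retained trials per subject", {
  gt <- make_ground_truth("lunge", K = 2, seed = 5)
  trials <- simulate_cohort(gt, p = 5, seed = 6, n_trials = 3)
  X <- prep_cohort(trials)
  expect_identical(dim(X), c(606L, 5L))
  expect_identical(attr(X, "motion"), "lunge")
  # averaging by hand for subject 1
  al <- lapply(trials[1:3], align_resample)
  byhand <- Reduce(`+`, lapply(al, `[[`, "values")) / 3
  expect_equal(unname(X[, 1]),
               unname(assemble_feature_vector(aligned_from_matrix(byhand))))
})
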