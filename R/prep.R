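#' Locate the peak knee flexion frame
#'
#' The frame with peak knee flexion defines 50% motion progress. Ties are
#' broken toward the earliest frame so alignment is deterministic and
#' order-stable.
#'
#' @param flexion Numeric vector of knee flexion angles (degrees), length >= 3.
#' @return 1-based index of the peak frame.
#' @details Errors on a constant sequence (no extremum to align on) and on a
#'   peak at the first or last frame (no descent/ascent on both sides).
#' @export
detect_peak_flexion <- function(flexion) {
  flexion <- as.numeric(flexion)
  n <- length(flexion)
  if (n < 3L) stop("flexion sequence must have at least 3 frames")
  if (!all(is.finite(flexion))) stop("flexion sequence has non-finite values")
  if (diff(range(flexion)) == 0)
    stop("degenerate trial: constant knee flexion, no peak to align on")
  peak <- which.max(flexion)  # which.max takes the first of tied maxima
  if (peak == 1L || peak == n)
    stop("unusable trial: peak knee flexion at recording boundary (frame ",
         peak, " of ", n, ")")
  peak
}

#' Trim a recording to the motion window around peak flexion
#'
#' Leading and trailing frames near standing posture are irrelevant
#' transients. The motion window is the maximal contiguous run of frames
#' around the peak in which knee flexion exceeds
#' `min(flexion) + trim_frac * range(flexion)`.
#'
#' @param flexion Knee flexion angles (degrees).
#' @param trim_frac Fraction of the flexion range above the minimum that
#'   counts as "in motion" (default 0.05).
#' @return Integer vector `c(first, last)` of retained frame indices.
#' @export
trim_flexion_window <- function(flexion, trim_frac = 0.05) {
  peak <- detect_peak_flexion(flexion)
  thr <- min(flexion) + trim_frac * diff(range(flexion))
  # inclusive comparison so trim_frac = 0 keeps the whole recording
  lo <- peak
  while (lo > 1L && flexion[lo - 1L] >= thr) lo <- lo - 1L
  hi <- peak
  n <- length(flexion)
  while (hi < n && flexion[hi + 1L] >= thr) hi <- hi + 1L
  c(lo, hi)
}

#' Drop open-chain lunge trials
#'
#' Only the closed-chain part of the lunge (forward foot on its force plate)
#' is modeled; recordings where the foot left the plate are left aside. Squat
#' trials pass through unchanged regardless of their flag.
#'
#' @param trials List of [kinetic_trial()] objects.
#' @return The retained trials; errors if none remain.
#' @export
filter_closed_chain <- function(trials) {
  keep <- vapply(trials, function(tr)
    tr$motion != "lunge" || isTRUE(tr$closed_chain), logical(1))
  out <- trials[keep]
  if (!length(out))
    stop("no usable trials: every lunge recording is flagged open-chain")
  out
}

#' Align and resample a trial onto the 101-instant progress grid
#'
#' Trims the recording to the motion window, pins the peak-flexion frame at
#' 50% progress, and linearly resamples each force channel so that 51 evenly
#' spaced samples span window start to peak (0--50%) and 50 further evenly
#' spaced samples span peak to window end (51--100%). The value at instant 51
#' equals the raw channel value at the peak frame exactly.
#'
#' @param trial A [kinetic_trial()].
#' @param trim_frac Passed to [trim_flexion_window()].
#' @return An `aligned_subject`: list with `subject_id`, `motion`, `grid`
#'   (progress 0..100) and `values` (6 x 101 matrix, BW, rows in channel
#'   order).
#' @export
align_resample <- function(trial, trim_frac = 0.05) {
  stopifnot(inherits(trial, "kinetic_trial"))
  win <- trim_flexion_window(trial$knee_flexion, trim_frac)
  lo <- win[1]; hi <- win[2]
  flex <- trial$knee_flexion[lo:hi]
  peak <- detect_peak_flexion(flex)  # re-detect inside the window
  n <- length(flex)
  # resampling positions in (trimmed) frame coordinates
  down <- seq(1, peak, length.out = 51L)
  up <- peak + seq_len(50L) * (n - peak) / 50
  pos <- c(down, up)
  frames <- seq_len(n)
  vals <- matrix(NA_real_, 6L, .kin_n_instants,
                 dimnames = list(.kin_channels, NULL))
  raw <- trial$forces[lo:hi, , drop = FALSE]
  for (c in seq_len(6L))
    vals[c, ] <- approx(frames, raw[, c], xout = pos, rule = 2)$y
  vals[, 51L] <- raw[peak, ]  # exact pinning, no interpolation round-off
  structure(list(subject_id = trial$subject_id, motion = trial$motion,
                 grid = 0:100, values = vals),
            class = "aligned_subject")
}

#' @export
print.aligned_subject <- function(x, ...) {
  cat(sprintf("<aligned_subject> %s (%s): 6 x 101 BW matrix, peak at 50%%\n",
              x$subject_id, x$motion))
  invisible(x)
}

#' Average repeated aligned trials of one subject
#'
#' When a subject performed the motion several times, the retained aligned
#' trials are averaged element-wise into one 6 x 101 matrix, giving one
#' training column per subject.
#'
#' @param aligned List of `aligned_subject` objects from one subject and
#'   motion.
#' @return A single `aligned_subject`.
#' @export
average_aligned <- function(aligned) {
  stopifnot(length(aligned) >= 1L)
  ids <- unique(vapply(aligned, `[[`, character(1), "subject_id"))
  mots <- unique(vapply(aligned, `[[`, character(1), "motion"))
  if (length(ids) != 1L || length(mots) != 1L)
    stop("average_aligned() expects trials from one subject and one motion")
  out <- aligned[[1L]]
  out$values <- Reduce(`+`, lapply(aligned, `[[`, "values")) / length(aligned)
  out
}

#' Stack an aligned subject into a 606-element feature vector
#'
#' Channels are concatenated in the order HJRFx, HJRFy, HJRFz, KJRFx, KJRFy,
#' KJRFz, each contributing its 101 instants in progress order: element 1 is
#' HJRFx at 0%, element 304 is KJRFx at 0%, element 606 is KJRFz at 100%.
#'
#' @param subject An `aligned_subject`.
#' @return Named numeric vector of length 606.
#' @export
assemble_feature_vector <- function(subject) {
  stopifnot(inherits(subject, "aligned_subject"))
  v <- as.vector(t(subject$values))
  names(v) <- .kin_feature_names()
  v
}

#' Reshape a 606-element feature vector back to a 6 x 101 channel matrix
#'
#' Inverse of [assemble_feature_vector()].
#'
#' @param x Numeric vector of length 606 (or a 606 x m matrix, reshaped
#'   column by column into a list).
#' @return 6 x 101 matrix with channel rownames (or a list of them).
#' @export
feature_to_channels <- function(x) {
  if (is.matrix(x)) return(lapply(seq_len(ncol(x)),
                                  function(j) feature_to_channels(x[, j])))
  stopifnot(length(x) == .kin_n_features)
  matrix(x, nrow = 6L, ncol = .kin_n_instants, byrow = TRUE,
         dimnames = list(.kin_channels, NULL))
}

#' Assemble the training matrix from aligned subjects
#'
#' Columns are subject feature vectors in input order; rows are the 606
#' observations (6 channels x 101 instants).
#'
#' @param subjects List of `aligned_subject` objects, one per subject, all of
#'   the same motion, at least 4.
#' @return A `kinetic_training` object: the 606 x p matrix with attributes
#'   `subject_ids` and `motion`.
#' @export
build_training_matrix <- function(subjects) {
  p <- length(subjects)
  if (p < 4L)
    stop("too few subjects: need at least 4 training columns, got ", p)
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  mots <- unique(vapply(subjects, `[[`, character(1), "motion"))
  if (length(mots) != 1L)
    stop("mixed motions in training set: ", paste(mots, collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate subject_id in training set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  X <- vapply(subjects, assemble_feature_vector, numeric(.kin_n_features))
  dimnames(X) <- list(.kin_feature_names(), ids)
  structure(X, subject_ids = ids, motion = mots, class = "kinetic_training")
}

#' @export
print.kinetic_training <- function(x, ...) {
  cat(sprintf("<kinetic_training> %s: 606 observations x %d subjects (BW)\n",
              attr(x, "motion"), ncol(x)))
  invisible(x)
}

#' Prepare a cohort of raw trials into a training matrix
#'
#' Full preprocessing pipeline: drop open-chain lunge trials, align and
#' resample every retained trial, average repeated trials per subject, and
#' assemble the 606 x p training matrix.
#'
#' @param trials List of [kinetic_trial()] objects (one motion).
#' @param trim_frac Passed to [align_resample()].
#' @return A `kinetic_training` matrix.
#' @export
prep_cohort <- function(trials, trim_frac = 0.05) {
  trials <- filter_closed_chain(trials)
  ids <- vapply(trials, `[[`, character(1), "subject_id")
  per_subject <- lapply(split(trials, factor(ids, levels = unique(ids))),
                        function(trs) {
    average_aligned(lapply(trs, align_resample, trim_frac = trim_frac))
  })
  build_training_matrix(unname(per_subject))
}
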