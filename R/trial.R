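#' Construct a kinetic trial
#'
#' A kinetic trial holds one raw recording of a squat or lunge: the knee
#' flexion angle used for alignment and trimming, and the six hip/knee
#' joint-reaction-force channels in body-weight units, sampled at a fixed rate.
#'
#' @param subject_id Subject identifier (character scalar).
#' @param motion `"squat"` or `"lunge"`.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param knee_flexion Knee flexion angle in degrees, one value per frame.
#' @param forces Numeric matrix, frames x 6, columns in the order
#'   `hjrf_x, hjrf_y, hjrf_z, kjrf_x, kjrf_y, kjrf_z`, in BW.
#' @param closed_chain Logical; for lunges, whether the forward foot stayed on
#'   its force plate for the whole recording. Squat trials are always treated
#'   as closed-chain.
#' @param grf_z Optional vertical ground-reaction-force channel (BW), used by
#'   [derive_closed_chain()] when no explicit flag is available.
#' @param trial Trial number within the subject (integer, default 1).
#' @return An object of class `kinetic_trial`.
#' @export
kinetic_trial <- function(subject_id, motion, sample_rate, knee_flexion,
                          forces, closed_chain = TRUE, grf_z = NULL,
                          trial = 1L) {
  motion <- .kin_check_motion(motion)
  knee_flexion <- as.numeric(knee_flexion)
  forces <- as.matrix(forces)
  n <- length(knee_flexion)
  if (n < 3L)
    stop("a kinetic trial needs at least 3 frames, got ", n)
  if (nrow(forces) != n || ncol(forces) != 6L)
    stop("'forces' must be a ", n, " x 6 matrix (one row per frame)")
  if (!all(is.finite(forces)))
    stop("force channels contain non-finite values")
  if (!all(is.finite(knee_flexion)))
    stop("knee flexion contains non-finite values")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("'sample_rate' must be a positive scalar (Hz)")
  if (!is.null(grf_z)) {
    grf_z <- as.numeric(grf_z)
    if (length(grf_z) != n)
      stop("'grf_z' must have one value per frame")
  }
  colnames(forces) <- .kin_channels
  structure(
    list(subject_id = as.character(subject_id), motion = motion,
         sample_rate = sample_rate, knee_flexion = knee_flexion,
         forces = forces, closed_chain = isTRUE(closed_chain),
         grf_z = grf_z, trial = as.integer(trial)),
    class = "kinetic_trial")
}

#' @export
print.kinetic_trial <- function(x, ...) {
  cat(sprintf("<kinetic_trial> subject %s, %s, trial %d: %d frames @ %g Hz%s\n",
              x$subject_id, x$motion, x$trial, length(x$knee_flexion),
              x$sample_rate,
              if (x$motion == "lunge")
                sprintf(", closed_chain=%s", x$closed_chain) else ""))
  cat(sprintf("  peak knee flexion %.1f deg; force range [%.2f, %.2f] BW\n",
              max(x$knee_flexion), min(x$forces), max(x$forces)))
  invisible(x)
}

#' Read one trial file
#'
#' Trial files are comma-separated text with a header row and columns
#' `time_s, knee_flexion_deg, hjrf_x, hjrf_y, hjrf_z, kjrf_x, kjrf_y, kjrf_z`
#' and optionally `grf_z`; forces are already body-weight normalized.
#'
#' @param path Path to the trial file.
#' @param subject_id,motion,trial Trial metadata (usually from the cohort
#'   manifest).
#' @param closed_chain Explicit closed-chain flag; if `NA` and a `grf_z`
#'   column is present, the flag is derived with [derive_closed_chain()].
#' @return A [kinetic_trial()].
#' @export
read_trial <- function(path, subject_id, motion, trial = 1L,
                       closed_chain = NA) {
  dat <- read.csv(path, check.names = TRUE)
  need <- c("time_s", "knee_flexion_deg", .kin_channels)
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("trial file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(dat) >= 2L) {
    dt <- diff(dat$time_s)
    rate <- 1 / median(dt)
  } else rate <- 1
  tr <- kinetic_trial(subject_id, motion, rate, dat$knee_flexion_deg,
                      as.matrix(dat[.kin_channels]),
                      closed_chain = if (is.na(closed_chain)) TRUE
                                     else closed_chain,
                      grf_z = if ("grf_z" %in% names(dat)) dat$grf_z else NULL,
                      trial = trial)
  if (is.na(closed_chain) && !is.null(tr$grf_z))
    tr$closed_chain <- derive_closed_chain(tr)
  tr
}

#' Write one trial file
#'
#' Inverse of [read_trial()]; emits the comma-separated dialect with a header
#' row. Numeric values are written at full double precision so that a
#' write/read round trip is exact to ~1e-15 relative.
#'
#' @param trial A [kinetic_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "kinetic_trial"))
  n <- length(trial$knee_flexion)
  dat <- data.frame(
    time_s = (seq_len(n) - 1L) / trial$sample_rate,
    knee_flexion_deg = trial$knee_flexion)
  dat <- cbind(dat, as.data.frame(trial$forces))
  if (!is.null(trial$grf_z)) dat$grf_z <- trial$grf_z
  # fixed significant-digit formatting keeps files byte-stable across runs
  txt <- vapply(dat, function(col) sprintf("%.15g", col), character(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(dat), collapse = ","), con)
  writeLines(apply(txt, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Derive the closed-chain flag from a vertical ground-reaction channel
#'
#' A lunge recording counts as closed-chain when the forward foot's vertical
#' ground reaction force stays above a small threshold for the whole trimmed
#' motion window, i.e. the foot never leaves its plate.
#'
#' @param trial A [kinetic_trial()] with a non-`NULL` `grf_z` channel.
#' @param threshold Contact threshold in BW (default 0.05).
#' @param trim_frac Flexion trimming fraction passed to
#'   [trim_flexion_window()].
#' @return Logical flag.
#' @export
derive_closed_chain <- function(trial, threshold = 0.05, trim_frac = 0.05) {
  stopifnot(inherits(trial, "kinetic_trial"))
  if (is.null(trial$grf_z))
    stop("trial has no grf_z channel; supply an explicit closed_chain flag")
  win <- trim_flexion_window(trial$knee_flexion, trim_frac)
  all(trial$grf_z[win[1]:win[2]] > threshold)
}

#' Read a cohort of trials from a manifest
#'
#' The manifest is a comma-separated file with columns
#' `subject_id, motion, trial, file` and optionally `closed_chain`
#' (`TRUE`/`FALSE`); `file` paths are resolved relative to the manifest's
#' directory.
#'
#' @param manifest Path to the manifest file.
#' @return List of [kinetic_trial()] objects.
#' @export
read_cohort <- function(manifest) {
  man <- read.csv(manifest, check.names = TRUE)
  need <- c("subject_id", "motion", "trial", "file")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  base <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    cc <- if ("closed_chain" %in% names(man)) as.logical(man$closed_chain[i])
          else NA
    read_trial(file.path(base, man$file[i]), man$subject_id[i],
               man$motion[i], trial = man$trial[i], closed_chain = cc)
  })
}

#' Write a cohort of trials plus manifest
#'
#' Writes one trial file per trial (named `<subject_id>_t<trial>.csv`) and a
#' `manifest.csv` in `dir`. Existing files are overwritten.
#'
#' @param trials List of [kinetic_trial()] objects.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(trials, function(tr) {
    fn <- sprintf("%s_t%d.csv", tr$subject_id, tr$trial)
    write_trial(tr, file.path(dir, fn))
    data.frame(subject_id = tr$subject_id, motion = tr$motion,
               trial = tr$trial, file = fn, closed_chain = tr$closed_chain)
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
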