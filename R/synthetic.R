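# smooth curve basis on the progress grid: cos(j*pi*g/100), j = 0..n_harm-1
.kin_cos_basis <- function(n_harm = 12L) {
  g <- 0:100
  vapply(0:(n_harm - 1L), function(j) cos(j * pi * g / 100),
         numeric(.kin_n_instants))
}

# raised-cosine bump: 0 at progress 0/100, 1 at progress 50 (unique maximum
# on the integer grid)
.kin_bump <- function(g = 0:100) sin(pi * g / 100)^2

# motion defaults: peak resultant joint reaction forces (BW) and peak knee
# flexion (degrees) typical of maximal-depth squatting and forward lunging
.kin_motion_defaults <- function(motion) {
  if (motion == "squat")
    list(hjrf_peak = 3.08, kjrf_peak = 4.52, flex_peak = 112)
  else
    list(hjrf_peak = 4.76, kjrf_peak = 7.16, flex_peak = 104)
}

#' Construct a ground-truth generative model for synthetic cohorts
#'
#' Defines the population a synthetic cohort is drawn from: smooth mean force
#' templates whose resultant hip and knee joint reaction forces peak at
#' motion-typical magnitudes at 50% progress, `K` orthonormal smooth mode
#' waveforms with a prescribed variance spectrum, white measurement noise,
#' and a knee-flexion template with a unique interior peak. Mode waveforms
#' are envelope-modulated toward mid-motion: inter-subject variability is
#' largest around peak loading and small near standing posture, as in real
#' squat and lunge kinetics.
#'
#' @param motion `"squat"` or `"lunge"`. Default peak force resultants are
#'   3.08 BW (hip) / 4.52 BW (knee) for the squat and 4.76 / 7.16 BW for the
#'   lunge; flexion peaks at 112 (squat) / 104 (lunge) degrees.
#' @param K Number of planted modes (1..20).
#' @param spectrum Positive non-increasing length-`K` vector of planted mode
#'   variances in BW^2. Default: the reference squat spectral shape scaled to
#'   a total planted variance of 24 BW^2, giving an element-wise
#'   inter-subject spread of roughly 0.2 BW.
#' @param noise_sd White-noise standard deviation per instant per channel
#'   (BW), default 0.01.
#' @param n_harm Number of cosine harmonics in the smoothness basis
#'   (default 12; `K <= 6 * n_harm` is required).
#' @param seed Integer seed; the model is deterministic given the seed.
#' @return An object of class `kin_ground_truth` with elements `motion`,
#'   `mean` (6 x 101, BW), `modes` (606 x K orthonormal), `mode_sd`
#'   (`sqrt(spectrum)`), `noise_sd`, `flexion` (101-vector, degrees).
#' @export
#' @examples
#' gt <- make_ground_truth("squat", seed = 1)
#' max(sqrt(colSums(gt$mean[4:6, ]^2)))  # knee resultant peaks at 4.52 BW
make_ground_truth <- function(motion = c("squat", "lunge"), K = 15L,
                              spectrum = NULL, noise_sd = 0.01,
                              n_harm = 12L, seed = 1L) {
  motion <- .kin_check_motion(motion)
  if (K < 1L || K > 20L) stop("'K' must be in 1..20")
  if (K > 6L * n_harm) stop("'K' exceeds the smoothness basis size")
  if (is.null(spectrum)) {
    shape <- reference_spectrum()[seq_len(min(K, 15L))]
    if (K > 15L) shape <- c(shape, rep(shape[15L], K - 15L))
    spectrum <- 24 * shape / sum(shape)
  }
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != K || any(spectrum <= 0) ||
      is.unsorted(rev(spectrum)))
    stop("'spectrum' must be positive, non-increasing, length K")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  def <- .kin_motion_defaults(motion)
  s <- .kin_bump()
  # fixed unit direction per joint; resultant at peak equals the target
  hip_dir <- c(0.20, 0.93, 0.30); hip_dir <- hip_dir / sqrt(sum(hip_dir^2))
  knee_dir <- c(0.15, 0.95, 0.27); knee_dir <- knee_dir / sqrt(sum(knee_dir^2))
  base_res <- 0.5  # standing baseline resultant (BW)
  mean6 <- matrix(NA_real_, 6L, .kin_n_instants,
                  dimnames = list(.kin_channels, NULL))
  for (c in 1:3) {
    b <- base_res * hip_dir[c]; a <- def$hjrf_peak * hip_dir[c]
    mean6[c, ] <- b + (a - b) * s
  }
  for (c in 1:3) {
    b <- base_res * knee_dir[c]; a <- def$kjrf_peak * knee_dir[c]
    mean6[c + 3L, ] <- b + (a - b) * s
  }
  flexion <- 20 + (def$flex_peak - 20) * s
  modes <- .kin_with_seed(seed, 101L, {
    basis <- .kin_cos_basis(n_harm)
    decay <- 1 / (1 + 0:(n_harm - 1L))
    # inter-subject variability concentrates around peak loading: near
    # standing posture all subjects look alike, so mode amplitude is
    # envelope-modulated toward mid-motion
    envelope <- 0.15 + 0.85 * s
    raw <- vapply(seq_len(K), function(k) {
      as.vector(vapply(seq_len(6L), function(c)
        envelope * drop(basis %*% (rnorm(n_harm) * decay)),
        numeric(.kin_n_instants)))
    }, numeric(.kin_n_features))
    Q <- qr.Q(qr(raw))[, seq_len(K), drop = FALSE]
    for (k in seq_len(K)) {
      j <- which.max(abs(Q[, k]))
      if (Q[j, k] < 0) Q[, k] <- -Q[, k]
    }
    Q
  })
  structure(list(motion = motion, mean = mean6, modes = modes,
                 mode_sd = sqrt(spectrum), noise_sd = noise_sd,
                 flexion = flexion, seed = as.integer(seed)),
            class = "kin_ground_truth")
}

#' @export
print.kin_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<kin_ground_truth> %s: %d planted modes, mode SDs %.3f..%.3f BW, noise %.3f BW\n",
    x$motion, length(x$mode_sd), max(x$mode_sd), min(x$mode_sd), x$noise_sd))
  invisible(x)
}

#' Simulate a cohort of raw kinetic trials
#'
#' Each subject draws independent standard-normal scores for the planted
#' modes; the subject's aligned 6 x 101 curve is the ground-truth mean plus
#' the score-weighted modes plus white noise. The curve is then embedded in a
#' longer raw recording: a standing plateau (flexion about 5 degrees) of
#' random length on both sides, and random per-half frame densities so that
#' trimming and resampling are genuinely exercised. The flexion channel's
#' unique peak coincides with the force-peak frame, and the raw frame grid
#' contains every integer-progress point, so preprocessing recovers the
#' planted curve exactly.
#'
#' @param gt A [make_ground_truth()] model.
#' @param p Number of subjects (>= 4).
#' @param seed Integer seed. Mode scores are drawn before any embedding
#'   jitter or noise, so cohorts generated with the same seed but different
#'   `noise_sd` in `gt` share their planted scores.
#' @param n_trials Trials per subject (default 1); repeated trials share the
#'   subject's scores but have independent noise and embedding jitter.
#' @param sample_rate Nominal sampling rate in Hz (metadata only).
#' @return List of [kinetic_trial()] objects with attribute `scores`
#'   (K x p matrix of the planted standard-normal mode scores).
#' @export
simulate_cohort <- function(gt, p, seed = 1L, n_trials = 1L,
                            sample_rate = 100) {
  stopifnot(inherits(gt, "kin_ground_truth"))
  if (p < 4L) stop("'p' must be >= 4")
  K <- length(gt$mode_sd)
  .kin_with_seed(seed, 211L, {
    scores <- matrix(rnorm(K * p), K, p)
    signal <- as.vector(t(gt$mean)) +
      gt$modes %*% (scores * gt$mode_sd)  # 606 x p, noise-free
    trials <- vector("list", p * n_trials)
    idx <- 0L
    for (i in seq_len(p)) {
      sid <- sprintf("S%03d", i)
      for (tr in seq_len(n_trials)) {
        idx <- idx + 1L
        curve <- matrix(signal[, i] + gt$noise_sd * rnorm(.kin_n_features),
                        nrow = .kin_n_instants, ncol = 6L)
        # per-trial embedding jitter
        m1 <- sample(2:5, 1L); m2 <- sample(2:5, 1L)
        lead <- sample(20:60, 1L); trail <- sample(20:60, 1L)
        g_down <- seq(0, 50, length.out = 50L * m1 + 1L)
        g_up <- seq(50, 100, length.out = 50L * m2 + 1L)[-1L]
        g_raw <- c(g_down, g_up)
        flex_motion <- 20 + (max(gt$flexion) - 20) * .kin_bump(g_raw)
        forces_motion <- vapply(seq_len(6L), function(c)
          approx(0:100, curve[, c], xout = g_raw)$y, numeric(length(g_raw)))
        plateau_flex <- function(n) 4.9 + runif(n, -0.05, 0.05)
        flex <- c(plateau_flex(lead), flex_motion, plateau_flex(trail))
        forces <- rbind(
          matrix(rep(curve[1L, ], each = lead), lead, 6L),
          forces_motion,
          matrix(rep(curve[.kin_n_instants, ], each = trail), trail, 6L))
        n <- length(flex)
        grf <- 1.02 + 0.03 * sin(2 * pi * seq_len(n) / n)
        trials[[idx]] <- kinetic_trial(
          sid, gt$motion, sample_rate, flex, forces,
          closed_chain = TRUE, grf_z = grf, trial = tr)
      }
    }
    colnames(scores) <- sprintf("S%03d", seq_len(p))
    attr(trials, "scores") <- scores
    trials
  })
}

#' Flag a fraction of trials as open-chain
#'
#' Marks `ceiling(fraction * length(trials))` randomly chosen trials as
#' open-chain (forward foot off its plate), so the lunge closed-chain filter
#' can be exercised on synthetic data.
#'
#' @param trials List of [kinetic_trial()] objects.
#' @param fraction Fraction in `[0, 1]` of trials to flag.
#' @param seed Integer seed.
#' @return The trial list with updated `closed_chain` flags.
#' @export
perturb_open_chain <- function(trials, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  n_flag <- ceiling(fraction * length(trials))
  if (n_flag == 0) return(trials)
  att <- attributes(trials)
  flagged <- .kin_with_seed(seed, 389L,
                            sample(length(trials), n_flag))
  for (i in flagged) trials[[i]]$closed_chain <- FALSE
  attributes(trials) <- att
  trials
}

#' Serialize a ground-truth model
#'
#' Writes the generative model (and optionally the realized cohort scores) as
#' a JSON sidecar so tests can assert against the planted truth.
#'
#' @param gt A [make_ground_truth()] model.
#' @param path Output path.
#' @param scores Optional realized K x p score matrix from
#'   [simulate_cohort()].
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path, scores = NULL) {
  obj <- list(format = "kineticsm-ground-truth", motion = gt$motion,
              mean = unname(gt$mean), modes = unname(gt$modes),
              mode_sd = gt$mode_sd, noise_sd = gt$noise_sd,
              flexion = gt$flexion, seed = gt$seed)
  if (!is.null(scores)) obj$scores <- unname(scores)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
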