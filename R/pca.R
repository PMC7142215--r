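#' Standardize a training matrix
#'
#' Each of the 606 observation rows is mean-centered and divided by its
#' standard deviation (denominator p - 1), giving the residual matrix R whose
#' rows all have mean 0 and variance 1. The row means and SDs are returned in
#' BW units for later un-standardization.
#'
#' @param X A `kinetic_training` matrix (606 x p) or plain numeric matrix.
#' @return List with `R` (606 x p), `mean` (606-vector, BW), `row_sd`
#'   (606-vector, BW).
#' @export
standardize_training <- function(X) {
  X <- unclass(X)
  if (!is.matrix(X) || !all(is.finite(X)))
    stop("training matrix must be a finite numeric matrix")
  m <- rowMeans(X)
  ctr <- X - m
  s <- sqrt(rowSums(ctr^2) / (ncol(X) - 1L))
  bad <- which(s == 0)
  if (length(bad))
    stop("degenerate observation row(s) with zero variance: ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "")
  list(R = ctr / s, mean = m, row_sd = s)
}

#' Fit a principal-mode model of kinetic waveform variability
#'
#' Standardizes the 606 x p training matrix (correlation-matrix convention)
#' and decomposes it by thin singular value decomposition
#' \eqn{R = U L A^T}. Eigenvalues are \eqn{\lambda_k = s_k^2/(p-1)}, the
#' per-mode variances of the standardized data; their sum equals 606 (the
#' number of unit-variance observation rows) up to the dropped numerical-zero
#' tail. Mode signs are fixed so each mode's largest-magnitude element is
#' positive.
#'
#' @param X A `kinetic_training` matrix from [build_training_matrix()], or any
#'   606 x p numeric matrix (p >= 4).
#' @param tol Relative eigenvalue threshold: components with
#'   `lambda < tol * lambda[1]` are dropped (default 1e-10).
#' @return An object of class `kinetic_pca` with elements `mean`, `row_sd`
#'   (BW), `modes` (606 x r orthonormal U), `loadings` (p x r orthonormal A),
#'   `eigenvalues` (length r, non-increasing), `singular_values`, `p`,
#'   `motion`, `subject_ids`, `n_features`.
#' @seealso [compactness()], [subject_scores()], [project_subjects()],
#'   [reconstruct_subjects()], [mode_curves()], [simulate.kinetic_pca()]
#' @export
#' @examples
#' gt <- make_ground_truth("squat", K = 4, seed = 1)
#' X <- prep_cohort(simulate_cohort(gt, p = 12, seed = 2))
#' fit <- kinetic_pca(X)
#' summary(fit)
kinetic_pca <- function(X, tol = 1e-10) {
  motion <- attr(X, "motion")
  ids <- attr(X, "subject_ids")
  if (is.null(ids)) ids <- colnames(X)
  std <- standardize_training(X)
  p <- ncol(std$R)
  if (p < 4L) stop("too few subjects: need p >= 4, got ", p)
  sv <- svd(std$R)
  lambda <- sv$d^2 / (p - 1L)
  keep <- which(lambda > tol * lambda[1])
  U <- sv$u[, keep, drop = FALSE]
  A <- sv$v[, keep, drop = FALSE]
  # reproducible sign convention: largest-|u| element positive
  for (k in seq_along(keep)) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) { U[, k] <- -U[, k]; A[, k] <- -A[, k] }
  }
  rownames(U) <- rownames(std$R)
  rownames(A) <- ids
  structure(
    list(mean = std$mean, row_sd = std$row_sd, modes = U, loadings = A,
         eigenvalues = lambda[keep], singular_values = sv$d[keep],
         p = p, motion = if (is.null(motion)) NA_character_ else motion,
         subject_ids = ids, n_features = nrow(std$R)),
    class = "kinetic_pca")
}

#' @export
print.kinetic_pca <- function(x, ...) {
  r <- length(x$eigenvalues)
  cat(sprintf("Kinetic principal-mode model (%s): %d subjects, %d modes\n",
              x$motion, x$p, r))
  cat(sprintf("  total variance %.2f; leading modes %s%% of variance\n",
              sum(x$eigenvalues),
              paste(sprintf("%.1f", 100 * head(x$eigenvalues, 3L) /
                              sum(x$eigenvalues)), collapse = ", ")))
  cat(sprintf("  95%% of variance in the first %d modes\n",
              n_components_for_variance(x, 0.95)))
  invisible(x)
}

#' Summarize a kinetic principal-mode model
#'
#' @param object A `kinetic_pca` fit.
#' @param ... Unused.
#' @return A `summary.kinetic_pca`: data frame with one row per mode
#'   (eigenvalue, percent of variance, cumulative percent).
#' @export
summary.kinetic_pca <- function(object, ...) {
  lam <- object$eigenvalues
  tab <- data.frame(
    pc = seq_along(lam),
    eigenvalue = lam,
    pct_variance = 100 * lam / sum(lam),
    cum_pct = 100 * cumsum(lam) / sum(lam))
  structure(list(table = tab, motion = object$motion, p = object$p),
            class = "summary.kinetic_pca")
}

#' @export
print.summary.kinetic_pca <- function(x, digits = 2, ...) {
  cat(sprintf("Kinetic principal-mode model (%s), p = %d subjects\n",
              x$motion, x$p))
  tab <- x$table
  tab$eigenvalue <- round(tab$eigenvalue, digits)
  tab$pct_variance <- round(tab$pct_variance, digits)
  tab$cum_pct <- round(tab$cum_pct, digits)
  print(head(tab, 20L), row.names = FALSE)
  if (nrow(tab) > 20L) cat("  ... (", nrow(tab) - 20L, " more modes)\n")
  invisible(x)
}

#' Cumulative variance fraction of the first k modes
#'
#' Model compactness: the fraction of total variance carried by the first
#' `k` modes. Also works on a bare eigenvalue spectrum, optionally against an
#' explicit total (e.g. 606 for a fully standardized 606-row model whose
#' printed spectrum is truncated).
#'
#' @param x A `kinetic_pca` fit or a numeric eigenvalue spectrum.
#' @param k Number of leading modes, `0 <= k <= length(spectrum)`.
#' @param total Total variance to divide by (default: sum of the spectrum).
#' @return Fraction in `[0, 1]`.
#' @export
compactness <- function(x, k, total = NULL) {
  lam <- if (inherits(x, "kinetic_pca")) x$eigenvalues else as.numeric(x)
  if (length(k) != 1L || k < 0 || k > length(lam) || k != round(k))
    stop("'k' must be an integer in 0..", length(lam))
  if (is.null(total)) total <- sum(lam)
  if (k == 0) 0 else sum(lam[seq_len(k)]) / total
}

#' Number of modes needed to reach a variance fraction
#'
#' Smallest `k` with `compactness(x, k) >= fraction` — the model
#' dimensionality at a given variance level.
#'
#' @inheritParams compactness
#' @param fraction Target variance fraction in `(0, 1]`.
#' @return Integer `k`.
#' @export
n_components_for_variance <- function(x, fraction, total = NULL) {
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  lam <- if (inherits(x, "kinetic_pca")) x$eigenvalues else as.numeric(x)
  if (is.null(total)) total <- sum(lam)
  cum <- cumsum(lam) / total
  k <- which(cum >= fraction - 1e-12)[1]
  if (is.na(k)) length(lam) else k
}

#' Per-subject mode scores of the training data
#'
#' Score of subject i on mode k is \eqn{s_k A_{ik}}; across subjects the
#' mode-k scores have variance \eqn{\lambda_k} (denominator p - 1).
#'
#' @param model A `kinetic_pca` fit.
#' @return p x r numeric matrix of scores (rows = subjects).
#' @export
subject_scores <- function(model) {
  stopifnot(inherits(model, "kinetic_pca"))
  z <- model$loadings * rep(model$singular_values, each = model$p)
  dimnames(z) <- list(model$subject_ids,
                      paste0("pc", seq_along(model$eigenvalues)))
  z
}

#' @export
coef.kinetic_pca <- function(object, ...) subject_scores(object)

#' Project new feature vectors onto the mode basis
#'
#' Standardizes `newdata` with the model's row means and SDs and returns the
#' scores on the first `ncomp` modes.
#'
#' @param model A `kinetic_pca` fit.
#' @param newdata 606-vector or 606 x m matrix (BW).
#' @param ncomp Number of leading modes (default: model rank).
#' @return `ncomp` x m score matrix (a vector input gives a length-`ncomp`
#'   vector).
#' @export
project_subjects <- function(model, newdata, ncomp = NULL) {
  stopifnot(inherits(model, "kinetic_pca"))
  r <- length(model$eigenvalues)
  if (is.null(ncomp)) ncomp <- r
  if (ncomp < 0 || ncomp > r)
    stop("'ncomp' must be in 0..", r)
  vec <- !is.matrix(newdata)
  nd <- as.matrix(newdata)
  if (nrow(nd) != model$n_features)
    stop("newdata must have ", model$n_features, " rows (observations)")
  rstd <- (nd - model$mean) / model$row_sd
  z <- crossprod(model$modes[, seq_len(ncomp), drop = FALSE], rstd)
  if (vec) drop(z) else z
}

#' Reconstruct feature vectors from mode scores
#'
#' Truncated reconstruction \eqn{\hat x = \bar x + D \sum_{m \le t} z_m u_m},
#' un-standardized back to BW units. With `ncomp = 0` the mean vector is
#' returned.
#'
#' @param model A `kinetic_pca` fit.
#' @param scores Score vector (length >= `ncomp`) or `ncomp` x m matrix as
#'   returned by [project_subjects()].
#' @param ncomp Number of leading modes to use (default: all rows of
#'   `scores`).
#' @return 606-vector or 606 x m matrix in BW.
#' @export
reconstruct_subjects <- function(model, scores, ncomp = NULL) {
  stopifnot(inherits(model, "kinetic_pca"))
  vec <- !is.matrix(scores)
  z <- as.matrix(scores)
  if (is.null(ncomp)) ncomp <- nrow(z)
  r <- length(model$eigenvalues)
  if (ncomp < 0 || ncomp > r) stop("'ncomp' must be in 0..", r)
  if (ncomp == 0) {
    out <- matrix(model$mean, model$n_features, ncol(z))
  } else {
    zt <- z[seq_len(ncomp), , drop = FALSE]
    out <- model$mean +
      model$row_sd * (model$modes[, seq_len(ncomp), drop = FALSE] %*% zt)
  }
  rownames(out) <- names(model$mean)
  if (vec) drop(out) else out
}

#' @export
fitted.kinetic_pca <- function(object, ncomp = NULL, ...) {
  z <- t(subject_scores(object))
  if (is.null(ncomp)) ncomp <- nrow(z)
  out <- reconstruct_subjects(object, z, ncomp = ncomp)
  colnames(out) <- object$subject_ids
  out
}

#' @export
residuals.kinetic_pca <- function(object, X, ncomp = NULL, ...) {
  unclass(X) - fitted(object, ncomp = ncomp)
}

#' @export
predict.kinetic_pca <- function(object, newdata, ncomp = NULL,
                                type = c("scores", "reconstruction"), ...) {
  type <- match.arg(type)
  z <- project_subjects(object, newdata, ncomp = ncomp)
  if (type == "scores") return(z)
  out <- reconstruct_subjects(object, as.matrix(z))
  if (!is.matrix(newdata)) drop(out) else out
}

#' Sample virtual subjects from the fitted model
#'
#' New waveform sets are generated by drawing independent standard-normal
#' scores \eqn{n_m} for each retained mode:
#' \eqn{\hat x' = \bar x + D \sum_{m \le t} n_m \sqrt{\lambda_m} u_m}.
#'
#' @param object A `kinetic_pca` fit.
#' @param nsim Number of virtual subjects.
#' @param seed Optional integer seed (an isolated stream; the caller's RNG
#'   state is untouched).
#' @param ncomp Number of leading modes `t` (default: model rank).
#' @param ... Unused.
#' @return 606 x `nsim` matrix in BW.
#' @export
simulate.kinetic_pca <- function(object, nsim = 1, seed = NULL,
                                 ncomp = NULL, ...) {
  r <- length(object$eigenvalues)
  if (is.null(ncomp)) ncomp <- r
  if (ncomp < 0 || ncomp > r) stop("'ncomp' must be in 0..", r)
  draw <- function() matrix(rnorm(ncomp * nsim), ncomp, nsim)
  n <- if (is.null(seed)) draw() else .kin_with_seed(seed, 977L, draw())
  z <- n * sqrt(object$eigenvalues[seq_len(ncomp)])
  reconstruct_subjects(object, z, ncomp = ncomp)
}

#' Sample one virtual subject
#'
#' Convenience wrapper around [simulate.kinetic_pca()] that also accepts
#' explicit mode scores (in units of standard deviations per mode), e.g. all
#' zeros to recover the mean subject.
#'
#' @param model A `kinetic_pca` fit.
#' @param ncomp Number of leading modes (default: model rank).
#' @param scores Optional length-`ncomp` vector of standard-normal mode
#'   scores; drawn from N(0,1) when `NULL`.
#' @param seed Optional seed used when drawing.
#' @return 606-vector in BW.
#' @export
sample_virtual_subject <- function(model, ncomp = NULL, scores = NULL,
                                   seed = NULL) {
  r <- length(model$eigenvalues)
  if (is.null(ncomp)) ncomp <- r
  if (is.null(scores))
    return(drop(simulate(model, nsim = 1, seed = seed, ncomp = ncomp)))
  stopifnot(length(scores) == ncomp)
  z <- scores * sqrt(model$eigenvalues[seq_len(ncomp)])
  reconstruct_subjects(model, z, ncomp = ncomp)
}

#' Mean and mode-perturbed waveform curves
#'
#' For mode `k`, returns the mean curves and the mean plus/minus two standard
#' deviations of that mode (\eqn{\bar x \pm 2\sqrt{\lambda_k} D u_k}),
#' reshaped to 6 x 101 channel matrices — the data behind the classic
#' mode-band figures.
#'
#' @param model A `kinetic_pca` fit.
#' @param k Mode number (1..r).
#' @param n_sd Band half-width in mode standard deviations (default 2).
#' @return List with `mean`, `plus`, `minus` (6 x 101 matrices, BW) and
#'   `pct_variance` of the mode.
#' @export
mode_curves <- function(model, k, n_sd = 2) {
  r <- length(model$eigenvalues)
  if (k < 1 || k > r) stop("'k' must be in 1..", r)
  dev <- n_sd * sqrt(model$eigenvalues[k]) * model$row_sd * model$modes[, k]
  list(mean = feature_to_channels(model$mean),
       plus = feature_to_channels(model$mean + dev),
       minus = feature_to_channels(model$mean - dev),
       pct_variance = 100 * model$eigenvalues[k] / sum(model$eigenvalues))
}

#' Plot mode bands of a kinetic model
#'
#' One panel per force channel: mean curve with the plus/minus `n_sd`
#' standard-deviation band of mode `k` against motion progress.
#'
#' @param x A `kinetic_pca` fit.
#' @param k Mode to display (default 1).
#' @param n_sd Band half-width in mode SDs (default 2).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.kinetic_pca <- function(x, k = 1, n_sd = 2, ...) {
  mc <- mode_curves(x, k, n_sd)
  old <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  g <- 0:100
  for (c in seq_len(6L)) {
    matplot(g, cbind(mc$mean[c, ], mc$plus[c, ], mc$minus[c, ]),
            type = "l", lty = c(1, 2, 2), col = c("darkgreen", "red", "blue"),
            xlab = "motion progress (%)", ylab = "force (BW)",
            main = toupper(.kin_channels[c]), ...)
  }
  invisible(x)
}

#' @export
screeplot.kinetic_pca <- function(x, npcs = min(20L, length(x$eigenvalues)),
                                  ...) {
  lam <- x$eigenvalues
  cum <- 100 * cumsum(lam) / sum(lam)
  plot(seq_len(npcs), cum[seq_len(npcs)], type = "b",
       xlab = "mode", ylab = "cumulative variance (%)",
       main = sprintf("Scree (%s)", x$motion), ylim = c(0, 100), ...)
  abline(h = 95, lty = 3)
  invisible(x)
}

#' Serialize a kinetic model to a structured text file
#'
#' Writes the full model (mean, row SDs, modes, loadings, eigenvalues,
#' metadata) as JSON at full double precision; [read_kinetic_pca()] restores
#' it with numerics equal to ~1e-15 relative and metadata bit-stable.
#'
#' @param model A `kinetic_pca` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_pca <- function(model, path) {
  stopifnot(inherits(model, "kinetic_pca"))
  obj <- list(
    format = "kineticsm-model", version = 1L,
    motion = model$motion, p = model$p,
    subject_ids = model$subject_ids,
    channels = .kin_channels, n_instants = .kin_n_instants,
    mean = unname(model$mean), row_sd = unname(model$row_sd),
    eigenvalues = model$eigenvalues,
    singular_values = model$singular_values,
    modes = unname(model$modes), loadings = unname(model$loadings))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Read a serialized kinetic model
#'
#' @param path Path written by [write_kinetic_pca()].
#' @return A `kinetic_pca` fit.
#' @export
read_kinetic_pca <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "kineticsm-model"))
    stop("'", path, "' is not a kineticsm model file")
  U <- as.matrix(obj$modes)
  A <- as.matrix(obj$loadings)
  m <- as.numeric(obj$mean)
  names(m) <- .kin_feature_names()
  rownames(U) <- names(m)
  rownames(A) <- obj$subject_ids
  structure(
    list(mean = m, row_sd = as.numeric(obj$row_sd), modes = U, loadings = A,
         eigenvalues = as.numeric(obj$eigenvalues),
         singular_values = as.numeric(obj$singular_values),
         p = as.integer(obj$p), motion = obj$motion,
         subject_ids = as.character(obj$subject_ids),
         n_features = nrow(U)),
    class = "kinetic_pca")
}
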