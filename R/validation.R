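# per-subject-per-channel RMSE of a 606 x m residual matrix -> m x 6 matrix
.kin_rmse_by_channel <- function(res) {
  res <- as.matrix(res)
  out <- vapply(seq_len(6L), function(c) {
    rows <- ((c - 1L) * .kin_n_instants + 1L):(c * .kin_n_instants)
    sqrt(colMeans(res[rows, , drop = FALSE]^2))
  }, numeric(ncol(res)))
  if (ncol(res) == 1L) out <- matrix(out, 1L, 6L)
  colnames(out) <- .kin_channels
  out
}

# overall per-subject RMSE over all 606 observations
.kin_rmse_overall <- function(res) sqrt(colMeans(as.matrix(res)^2))

#' In-sample model accuracy
#'
#' Reconstruction error of the training subjects from a model truncated to
#' `ncomp` modes: for every subject and every force channel, the RMSE over
#' the 101 instants between original and reconstructed waveform, in BW.
#'
#' @param model A `kinetic_pca` fit of `X`.
#' @param X The training matrix the model was fitted on (BW).
#' @param ncomp Number of retained modes `t` (0..r).
#' @return List with `rmse` (p x 6 matrix, BW), `median`, `iqr` (pooled over
#'   subjects and channels), and `grand_mean` (mean over subjects of the
#'   full-vector RMSE).
#' @export
model_accuracy <- function(model, X, ncomp) {
  res <- unclass(X) - fitted(model, ncomp = ncomp)
  rmse <- .kin_rmse_by_channel(res)
  rownames(rmse) <- model$subject_ids
  list(rmse = rmse, median = median(rmse), iqr = IQR(rmse),
       grand_mean = mean(.kin_rmse_overall(res)), ncomp = ncomp)
}

#' Out-of-sample generalization curve
#'
#' Leave-one-out style evaluation of how many training subjects are needed:
#' for each training-set size `n`, repeat `T_g` times drawing one held-out
#' subject uniformly and `n` training subjects uniformly from the rest, fit
#' the model, keep the number of modes reaching `variance_fraction`, project
#' and reconstruct the held-out subject, and record the per-channel RMSE in
#' BW.
#'
#' @param X A `kinetic_training` matrix (606 x p).
#' @param n_values Training-set sizes, each in `4..p-1` (default `4:(p-1)`).
#' @param T_g Replicates per size (default 200).
#' @param variance_fraction Variance level defining model dimensionality per
#'   replicate (default 0.95).
#' @param seed Integer master seed.
#' @return Object of class `kin_generalization`: list with `draws`
#'   (`T_g` x 6 x length(n_values) array of RMSE) and `summary` (data frame
#'   of median and quartiles per channel per n).
#' @export
generalization_curve <- function(X, n_values = NULL, T_g = 200,
                                 variance_fraction = 0.95, seed = 1L) {
  X <- unclass(X)
  p <- ncol(X)
  if (is.null(n_values)) n_values <- 4:(p - 1L)
  if (any(n_values < 4L) || any(n_values > p - 1L))
    stop("every n must be in 4..p-1 (p = ", p, ")")
  if (T_g < 1L) stop("'T_g' must be >= 1")
  draws <- array(NA_real_, c(T_g, 6L, length(n_values)),
                 dimnames = list(NULL, .kin_channels, n_values))
  .kin_with_seed(seed, 547L, {
    for (j in seq_along(n_values)) {
      n <- n_values[j]
      for (b in seq_len(T_g)) {
        held <- sample.int(p, 1L)
        train <- sample((seq_len(p))[-held], n)
        fit <- kinetic_pca(X[, train, drop = FALSE])
        k <- n_components_for_variance(fit, variance_fraction)
        z <- project_subjects(fit, X[, held], ncomp = k)
        xhat <- reconstruct_subjects(fit, z, ncomp = k)
        draws[b, , j] <- .kin_rmse_by_channel(xhat - X[, held])
      }
    }
  })
  qs <- apply(draws, c(2L, 3L), quantile, probs = c(0.25, 0.5, 0.75))
  summ <- do.call(rbind, lapply(seq_along(n_values), function(j)
    data.frame(n = n_values[j], channel = .kin_channels,
               q1 = qs[1L, , j], median = qs[2L, , j], q3 = qs[3L, , j],
               row.names = NULL)))
  structure(list(draws = draws, summary = summ, n_values = n_values,
                 T_g = T_g, variance_fraction = variance_fraction),
            class = "kin_generalization")
}

#' @export
print.kin_generalization <- function(x, ...) {
  cat(sprintf(
    "<kin_generalization> %d sizes (n = %d..%d), T_g = %d, %.0f%% variance models\n",
    length(x$n_values), min(x$n_values), max(x$n_values), x$T_g,
    100 * x$variance_fraction))
  med <- with(x$summary, tapply(median, n, stats::median))
  cat("  pooled median RMSE (BW) by n:\n")
  print(round(med, 4))
  invisible(x)
}

#' Model specificity
#'
#' Soundness of model-generated data: `T_s` virtual subjects are sampled per
#' variance level and each is compared (full-vector RMSE, BW) against its
#' most similar training sample; the median of those nearest-sample errors
#' is the specificity.
#'
#' With the default `sampling = "full"` the virtual subjects draw
#' standard-normal scores on every retained mode, so the levels differ only
#' by their independent Monte-Carlo draws and the specificity is nearly
#' level-independent; `sampling = "truncated"` restricts the draw to the
#' level's dimensionality, which makes the error grow with the cumulative
#' variance retained.
#'
#' @param model A `kinetic_pca` fit of `X`.
#' @param X Training matrix in BW.
#' @param variance_levels Variance fractions labelling (and under
#'   `"truncated"`, limiting) each tested model (default
#'   0.80/0.90/0.95/0.98).
#' @param T_s Virtual subjects per level (default 2000).
#' @param seed Integer master seed.
#' @param sampling `"full"` (all retained modes) or `"truncated"` (the
#'   level's dimensionality).
#' @return Data frame with one row per level: `level`, `ncomp`, `median`,
#'   `iqr` (BW).
#' @export
model_specificity <- function(model, X, variance_levels = c(0.8, 0.9, 0.95, 0.98),
                              T_s = 2000, seed = 1L,
                              sampling = c("full", "truncated")) {
  if (T_s < 1L) stop("'T_s' must be >= 1")
  sampling <- match.arg(sampling)
  X <- unclass(X)
  xs2 <- colSums(X^2)
  rows <- lapply(seq_along(variance_levels), function(li) {
    lev <- variance_levels[li]
    t <- n_components_for_variance(model, lev)
    V <- simulate(model, nsim = T_s, seed = .kin_substream(seed, 700L + li),
                  ncomp = if (sampling == "full")
                    length(model$eigenvalues) else t)
    # nearest training column by RMSE == nearest by squared distance
    d2 <- outer(colSums(V^2), xs2, `+`) - 2 * crossprod(V, X)
    nn <- pmax(apply(d2, 1L, min), 0)
    rmse <- sqrt(nn / nrow(X))
    data.frame(level = lev, ncomp = t, median = median(rmse),
               iqr = IQR(rmse))
  })
  do.call(rbind, rows)
}

# permute the entries of each row of M independently (destroys inter-row
# correlation, preserves every row's marginal distribution)
.kin_permute_rows <- function(M) {
  r <- nrow(M); p <- ncol(M)
  Mt <- t(M)
  o <- order(rep.int(seq_len(r), rep.int(p, r)), runif(r * p))
  t(matrix(Mt[o], p, r))
}

#' Monte-Carlo permutation test for the number of signal components
#'
#' Tests each leading principal component against a permutation null in
#' which the entries of every observation row are permuted independently
#' (destroying inter-row correlation while preserving row means and SDs).
#' Each permuted matrix is refitted and its spectrum compared with the
#' observed one position by position:
#' \itemize{
#'   \item rank of roots: statistic \eqn{\lambda_k}, compared with the k-th
#'     permuted eigenvalue; p-value `(# permuted >= observed + 1) / (B + 1)`.
#'     For a component carrying real inter-row correlation the permuted
#'     eigenvalue almost never reaches the observed one (p at the floor);
#'     for a noise component the permuted spectrum at position k is
#'     typically far larger, driving the p-value to 1.
#'   \item equality of roots: statistic
#'     \eqn{\lambda_k / \mathrm{mean}(\lambda_k \ldots \lambda_r)} — the
#'     k-th root against the mean of the remaining roots — with the same
#'     null and correction.
#' }
#' The smallest attainable p-value is `1/(B + 1)`.
#'
#' @param X A `kinetic_training` matrix (606 x p).
#' @param n_pc Number of leading components to test (default
#'   `min(15, rank)`).
#' @param B Number of permutations (>= 99; default 999).
#' @param seed Integer master seed.
#' @return Data frame with one row per tested component: `pc`, `eigenvalue`,
#'   `pct_variance`, `cum_pct`, `rank_of_roots_p`, `equality_of_roots_p`.
#' @export
permutation_component_test <- function(X, n_pc = NULL, B = 999, seed = 1L) {
  if (B < 99L) stop("'B' must be at least 99 permutations")
  std <- standardize_training(X)
  p <- ncol(std$R)
  sv <- svd(std$R)
  lambda <- sv$d^2 / (p - 1L)
  r <- sum(lambda > 1e-10 * lambda[1])
  lambda <- lambda[seq_len(r)]
  if (is.null(n_pc)) n_pc <- min(15L, r)
  n_pc <- min(n_pc, r)
  total <- sum(lambda)
  ks <- seq_len(n_pc)
  obs_rank <- lambda[ks]
  obs_eq <- vapply(ks, function(k) lambda[k] / mean(lambda[k:r]), numeric(1))
  ge_rank <- ge_eq <- integer(n_pc)
  .kin_with_seed(seed, 811L, {
    for (b in seq_len(B)) {
      P <- .kin_permute_rows(std$R)
      ev <- eigen(crossprod(P), symmetric = TRUE,
                  only.values = TRUE)$values / (p - 1L)
      ev <- pmax(ev[seq_len(r)], 0)
      perm_eq <- vapply(ks, function(k) ev[k] / mean(ev[k:r]), numeric(1))
      ge_rank <- ge_rank + (ev[ks] >= obs_rank)
      ge_eq <- ge_eq + (perm_eq >= obs_eq)
    }
  })
  p_rank <- (ge_rank + 1L) / (B + 1L)
  p_eq <- (ge_eq + 1L) / (B + 1L)
  data.frame(pc = seq_len(n_pc),
             eigenvalue = lambda[seq_len(n_pc)],
             pct_variance = 100 * lambda[seq_len(n_pc)] / total,
             cum_pct = 100 * cumsum(lambda[seq_len(n_pc)]) / total,
             rank_of_roots_p = p_rank,
             equality_of_roots_p = p_eq)
}

#' Run the full validation suite on a cohort
#'
#' Fits the model and computes the four goodness measures plus the
#' permutation component-selection table at the configured scale.
#'
#' @param X A `kinetic_training` matrix.
#' @param variance_levels Variance levels for accuracy/specificity
#'   dimensionality (default 0.80/0.90/0.95/0.98).
#' @param T_g Generalization replicates per training-set size.
#' @param T_s Virtual subjects per specificity level.
#' @param B Permutations for the component test.
#' @param n_values Generalization training-set sizes (default a short grid
#'   from 4 to p-1).
#' @param n_pc Components to test by permutation (default `min(15, rank)`).
#' @param seed Master seed; each estimator draws from an independently keyed
#'   substream, so results do not depend on call order.
#' @return Object of class `kin_validation`: list with `model`, `accuracy`
#'   (data frame per level), `specificity`, `generalization`, `permutation`,
#'   `compactness` (cumulative variance curve), and the configuration.
#' @export
validate_model <- function(X, variance_levels = c(0.8, 0.9, 0.95, 0.98),
                           T_g = 200, T_s = 2000, B = 199,
                           n_values = NULL, n_pc = NULL, seed = 1L) {
  model <- kinetic_pca(X)
  p <- model$p
  acc <- do.call(rbind, lapply(variance_levels, function(lev) {
    t <- n_components_for_variance(model, lev)
    a <- model_accuracy(model, X, t)
    data.frame(level = lev, ncomp = t, median = a$median, iqr = a$iqr,
               grand_mean = a$grand_mean)
  }))
  spec <- model_specificity(model, X, variance_levels, T_s = T_s,
                            seed = .kin_substream(seed, 2L))
  if (is.null(n_values))
    n_values <- unique(pmin(pmax(round(seq(4, p - 1L, length.out = 6L)), 4L),
                            p - 1L))
  gen <- generalization_curve(X, n_values = n_values, T_g = T_g,
                              seed = .kin_substream(seed, 3L))
  perm <- permutation_component_test(X, n_pc = n_pc, B = B,
                                     seed = .kin_substream(seed, 4L))
  structure(list(model = model, accuracy = acc, specificity = spec,
                 generalization = gen, permutation = perm,
                 compactness = cumsum(model$eigenvalues) /
                   sum(model$eigenvalues),
                 config = list(variance_levels = variance_levels, T_g = T_g,
                               T_s = T_s, B = B, n_values = n_values,
                               seed = seed)),
            class = "kin_validation")
}

#' @export
print.kin_validation <- function(x, ...) {
  cat(sprintf("Validation of %s kinetic model (p = %d)\n",
              x$model$motion, x$model$p))
  cat("\nAccuracy / specificity by variance level:\n")
  tab <- merge(x$accuracy, x$specificity, by = c("level", "ncomp"),
               suffixes = c("_accuracy", "_specificity"))
  print(format(tab, digits = 4), row.names = FALSE)
  cat("\nPermutation component selection:\n")
  perm <- x$permutation
  perm$eigenvalue <- round(perm$eigenvalue, 2)
  perm$pct_variance <- round(perm$pct_variance, 2)
  perm$cum_pct <- round(perm$cum_pct, 2)
  print(perm, row.names = FALSE)
  gm <- with(x$generalization$summary, tapply(median, n, stats::median))
  cat("\nGeneralization pooled median RMSE (BW) by training size:\n")
  print(round(gm, 4))
  invisible(x)
}

#' Write validation report files
#'
#' Emits machine-readable report tables: a component-selection table
#' (`component_selection.tsv`), a per-level summary
#' (`validation_summary.tsv`), the generalization summaries
#' (`generalization.tsv`) and a structured JSON summary
#' (`validation.json`).
#'
#' @param report A [validate_model()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "kin_validation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$permutation,
              file.path(dir, "component_selection.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  summ <- merge(report$accuracy, report$specificity,
                by = c("level", "ncomp"),
                suffixes = c("_accuracy", "_specificity"))
  write.table(summ, file.path(dir, "validation_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(report$generalization$summary,
              file.path(dir, "generalization.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(motion = report$model$motion, p = report$model$p,
         accuracy = report$accuracy, specificity = report$specificity,
         generalization = report$generalization$summary,
         permutation = report$permutation,
         compactness = report$compactness, config = report$config),
    file.path(dir, "validation.json"),
    digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(dir)
}
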