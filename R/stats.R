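#' Bootstrap mean accuracy with a percentile confidence interval
#'
#' Resamples the per-item correctness vector with replacement `n_boot`
#' times; reports the mean of the resampled accuracies and the 2.5/97.5
#' percentile interval.
#'
#' @param correct logical (or 0/1) vector of per-item correctness on the
#'   test set.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with `mean`, `ci` (`c(lo, hi)`) and `boot_means`.
#' @export
bootstrap_accuracy <- function(correct, n_boot = 1000L, seed = 1L) {
  correct <- as.numeric(correct)
  n <- length(correct)
  if (n < 1L) stop("bootstrap_accuracy: empty vector")
  boot_means <- with_local_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(correct[idx], nrow = n, ncol = n_boot))
  })
  ci <- unname(stats::quantile(boot_means, c(0.025, 0.975)))
  list(mean = mean(boot_means), ci = ci, boot_means = boot_means)
}

#' Paired permutation test on the accuracy difference of two classifiers
#'
#' Both models are scored on the same test items, so the null
#' distribution of the observed statistic `t = acc_b - acc_a` is built by
#' independently swapping each item's pair of correctness indicators with
#' probability 1/2 (a paired sign-flip scheme).  The two-sided p-value
#' uses the add-one correction, so it is never exactly zero.  Bootstrap
#' means and 95% intervals for each model's accuracy and for the
#' difference are computed alongside.
#'
#' @param correct_a,correct_b logical (or 0/1) vectors of per-item
#'   correctness of models A and B on the same items.
#' @param n_perm number of permutations (default 10000).
#' @param n_boot bootstrap resamples for the accuracy intervals.
#' @param seed integer seed.
#' @return an object of class `comparison_result`: `mean_acc_a`,
#'   `mean_acc_b`, `ci_a`, `ci_b`, `mean_diff`, `ci_diff`, `t_obs`,
#'   `p_value`, `perm_stats` (the permuted statistics, for
#'   histogramming), `n_boot`, `n_perm`, `n`, `seed`.
#' @export
permutation_test <- function(correct_a, correct_b, n_perm = 10000L,
                             n_boot = 1000L, seed = 1L) {
  if (length(correct_a) != length(correct_b))
    stop("permutation_test: length mismatch")
  n <- length(correct_a)
  if (n < 2L) stop("permutation_test: need at least 2 items")
  a <- as.numeric(correct_a); b <- as.numeric(correct_b)
  d <- b - a
  t_obs <- mean(d)
  disc <- which(d != 0)
  perm_stats <- with_local_seed(derive_seed(seed, 1L), {
    if (length(disc) == 0L) rep(0, n_perm)
    else {
      signs <- matrix(sample(c(-1, 1), length(disc) * n_perm, replace = TRUE),
                      nrow = length(disc))
      colSums(signs * d[disc]) / n
    }
  })
  p <- (1 + sum(abs(perm_stats) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
  ba <- bootstrap_accuracy(a, n_boot, derive_seed(seed, 2L))
  bb <- bootstrap_accuracy(b, n_boot, derive_seed(seed, 3L))
  bd <- with_local_seed(derive_seed(seed, 4L), {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(d[idx], nrow = n, ncol = n_boot))
  })
  structure(
    list(mean_acc_a = ba$mean, mean_acc_b = bb$mean,
         ci_a = ba$ci, ci_b = bb$ci,
         mean_diff = mean(bd),
         ci_diff = unname(stats::quantile(bd, c(0.025, 0.975))),
         t_obs = t_obs, p_value = p, perm_stats = perm_stats,
         n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
         n = n, seed = as.integer(seed)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Model A accuracy: %.4f (95%% CI %.4f, %.4f)\n",
              x$mean_acc_a, x$ci_a[1L], x$ci_a[2L]))
  cat(sprintf("Model B accuracy: %.4f (95%% CI %.4f, %.4f)\n",
              x$mean_acc_b, x$ci_b[1L], x$ci_b[2L]))
  cat(sprintf("Difference (B - A): %.4f (95%% CI %.4f, %.4f)\n",
              x$mean_diff, x$ci_diff[1L], x$ci_diff[2L]))
  cat(sprintf("Permutation test: t = %.4f, p = %.4g (%d permutations)\n",
              x$t_obs, x$p_value, x$n_perm))
  invisible(x)
}

#' Export a comparison result
#'
#' Writes the result as JSON and the permuted statistics as a one-column
#' CSV (for histogramming) next to it.
#'
#' @param result a `comparison_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison_result <- function(result, path) {
  x <- unclass(result)
  perm <- x$perm_stats
  x$perm_stats <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(data.frame(t_perm = perm),
                   sub("\\.json$", "_perm.csv", path), row.names = FALSE)
  invisible(path)
}
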