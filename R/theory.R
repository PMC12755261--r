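#' Small-noise mean first-passage time, single gene
#'
#' Deterministic-trajectory approximation of the mean time for an
#' activated gene's level to reach relative threshold `alpha`:
#' `<T> = (1/gamma) log(1 / (1 - alpha))`, i.e. the time at which the mean
#' saturation curve `xbar (1 - exp(-gamma t))` hits `alpha * xbar`. The
#' approximation overestimates the true mean as `alpha -> 0` and
#' underestimates it as `alpha -> 1`.
#'
#' @param alpha Relative threshold(s) in (0, 1); vectorized.
#' @param gamma Dilution rate (1/min). With `gamma = 1` the result is the
#'   dimensionless relative time `gamma <T>`.
#' @return Mean first-passage time(s), minutes.
#' @export
mean_fpt_single <- function(alpha, gamma = 1) {
  check_alpha(alpha)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  log(1 / (1 - alpha)) / gamma
}

#' Small-noise first-passage-time noise, single gene
#'
#' Squared coefficient of variation of the single-gene first-passage time
#' under the small-noise approximation (protein variance at the threshold
#' mapped through the slope of the mean trajectory):
#' \deqn{CV_T^2 = CV_1^2 \frac{\alpha (2 - \alpha)}
#'       {(1 - \alpha)^2 \ln^2(1 - \alpha)}.}
#' Convex in `alpha` with an interior minimum near 0.55, independent of
#' `CV_1^2` (the intrinsic noise only scales the curve).
#'
#' @param alpha Relative threshold(s) in (0, 1); vectorized.
#' @param cv2_gene Stationary intrinsic noise CV^2 of the gene product
#'   (> 0); see [intrinsic_noise()].
#' @return Dimensionless CV_T^2, same length as `alpha`.
#' @export
fpt_noise_single <- function(alpha, cv2_gene) {
  check_alpha(alpha)
  if (any(cv2_gene <= 0)) stop("cv2_gene must be positive", call. = FALSE)
  cv2_gene * alpha * (2 - alpha) / ((1 - alpha)^2 * log(1 - alpha)^2)
}

#' Small-noise FPT noise of a two-gene cascade at fixed mean
#'
#' CV_T^2 of the total first-passage time T = T1 + T2, written as a
#' function of the second gene's relative threshold `alpha2` after the
#' fixed-mean constraint eliminates `alpha1` (via
#' `alpha1 = 1 - exp(-gammaT) / (1 - alpha2)`):
#' \deqn{CV_T^2 = \frac{1}{(\gamma <T>)^2}\left[
#'   CV_1^2 \{(1-\alpha_2)^2 e^{2\gamma <T>} - 1\}
#'   + CV_2^2 \frac{\alpha_2 (2-\alpha_2)}{(1-\alpha_2)^2}\right].}
#' Feasibility requires `0 <= alpha2 < 1 - exp(-gammaT)`; at `alpha2 = 0`
#' the value equals the single-gene formula for gene 1 at
#' `alpha = 1 - exp(-gammaT)`.
#'
#' @param alpha2 Second gene's relative threshold(s); vectorized.
#' @param cv2_1,cv2_2 Intrinsic noises CV^2 of genes 1 and 2.
#' @param gammaT Dimensionless mean first-passage time `gamma * <T>` (> 0).
#' @return Dimensionless CV_T^2.
#' @export
fpt_noise_two_gene <- function(alpha2, cv2_1, cv2_2, gammaT) {
  if (gammaT <= 0) stop("gammaT must be positive", call. = FALSE)
  amax <- 1 - exp(-gammaT)
  if (any(alpha2 < 0 | alpha2 >= amax))
    stop(sprintf("alpha2 must lie in [0, %.6g) = [0, 1 - exp(-gammaT)) for the mean constraint to be satisfiable",
                 amax), call. = FALSE)
  (cv2_1 * ((1 - alpha2)^2 * exp(2 * gammaT) - 1) +
     cv2_2 * alpha2 * (2 - alpha2) / (1 - alpha2)^2) / gammaT^2
}

#' Mean and noise of the FPT of an N-gene cascade
#'
#' Treats the cascade as N independent stages (exact under step activation
#' with zero initial levels): the mean first-passage time adds over
#' stages, `<T> = (1/gamma) sum_i log(1/(1 - alpha_i))`, and so do the
#' stage variances, giving
#' \deqn{CV_T^2 = \frac{1}{(\gamma <T>)^2}
#'   \sum_i CV_i^2 \frac{\alpha_i (2 - \alpha_i)}{(1 - \alpha_i)^2}.}
#' A stage with `alpha_i = 0` is unused and contributes nothing to either
#' sum.
#'
#' @param alphas Per-gene relative thresholds, each in [0, 1).
#' @param cv2_list Per-gene intrinsic noises CV^2 (> 0), same length.
#' @param gamma Dilution rate (1/min); `gamma = 1` for dimensionless
#'   output.
#' @return An object of class `theory_prediction`: list with `mean_T`,
#'   `cv2_T`, `per_stage_alphas`, and `regime_valid` (are all alphas
#'   strictly inside the feasible interval `(0, 1 - exp(-gamma mean_T))`,
#'   i.e. no degenerate unused or boundary stage).
#' @export
fpt_stats_cascade <- function(alphas, cv2_list, gamma = 1) {
  if (length(alphas) != length(cv2_list))
    stop("alphas and cv2_list must have equal length", call. = FALSE)
  if (any(alphas < 0 | alphas >= 1))
    stop("each alpha must lie in [0, 1)", call. = FALSE)
  if (any(cv2_list <= 0)) stop("intrinsic noises must be positive", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (all(alphas == 0))
    stop("at least one alpha must be positive (zero mean FPT otherwise)",
         call. = FALSE)
  mean_T <- sum(log(1 / (1 - alphas))) / gamma
  gT <- gamma * mean_T
  cv2 <- sum(cv2_list * alphas * (2 - alphas) / (1 - alphas)^2) / gT^2
  # every stage strictly interior: no unused gene (alpha = 0) and, for
  # N >= 2, no stage carrying the whole mean (alpha at 1 - exp(-gamma T),
  # which can only happen together with a zero-threshold stage)
  valid <- all(alphas > 0) &&
    (length(alphas) == 1L || all(alphas < 1 - exp(-gT)))
  structure(list(mean_T = mean_T, cv2_T = cv2, per_stage_alphas = alphas,
                 regime_valid = valid),
            class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf("<theory_prediction: <T> = %.6g min, CV_T^2 = %.6g%s>\n",
              x$mean_T, x$cv2_T,
              if (x$regime_valid) "" else " [outside small-noise regime]"))
  cat("  alphas:", paste(signif(x$per_stage_alphas, 6), collapse = ", "), "\n")
  invisible(x)
}

#' FPT noise of N identical genes at the optimal equal thresholds
#'
#' For N identical genes at fixed dimensionless mean time `gammaT`, the
#' optimal thresholds are equal, `alpha = 1 - exp(-gammaT / N)`, and the
#' resulting noise is
#' \deqn{CV_T^2 = CV_1^2 \, N \, \frac{e^{2\gamma <T>/N} - 1}
#'       {(\gamma <T>)^2},}
#' strictly decreasing in N at fixed `gammaT` (roughly 1/N for large N)
#' and convex in `gammaT` at fixed N, with the minimum located by
#' [optimal_mean_time_identical()].
#'
#' @param n Number of genes (>= 1); vectorized.
#' @param cv2_1 Per-gene intrinsic noise CV^2.
#' @param gammaT Dimensionless mean FPT `gamma * <T>` (> 0); vectorized.
#' @return Dimensionless CV_T^2.
#' @export
fpt_noise_identical <- function(n, cv2_1, gammaT) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(gammaT <= 0)) stop("gammaT must be positive", call. = FALSE)
  cv2_1 * n * (exp(2 * gammaT / n) - 1) / gammaT^2
}

check_alpha <- function(alpha) {
  if (any(!is.finite(alpha) | alpha <= 0 | alpha >= 1))
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  invisible(alpha)
}
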