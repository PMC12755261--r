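#' Classify the optimization regime of a two-gene cascade
#'
#' At a fixed dimensionless mean FPT `gammaT`, whether coupling both genes
#' lowers timing noise depends only on the intrinsic-noise ratio
#' `CV2/CV1`:
#' \itemize{
#'   \item `CV2/CV1 > exp(gammaT)` — gene 2 is too noisy; timing on gene 1
#'     alone is optimal (`gene1_only`).
#'   \item `exp(-gammaT) < CV2/CV1 < exp(gammaT)` — splitting the mean
#'     time across both genes strictly lowers the noise (`coupled`).
#'   \item `CV2/CV1 < exp(-gammaT)` — gene 1 is too noisy; gene 2 alone is
#'     optimal (`gene2_only`).
#' }
#' The interval widens symmetrically on a log scale as `gammaT` grows and
#' collapses to the point \{1\} as `gammaT -> 0` (without dilution,
#' coupling can never help). Ratios exactly at a boundary classify as the
#' adjacent single-gene regime; the coupled formulas return a zero
#' threshold there, so the optimum is continuous across the boundary.
#'
#' @param cv_ratio `CV2 / CV1` (> 0), the ratio of intrinsic noise
#'   standard deviations (not squared).
#' @param gammaT Dimensionless mean FPT (> 0).
#' @return One of `"gene1_only"`, `"coupled"`, `"gene2_only"`.
#' @export
classify_two_gene <- function(cv_ratio, gammaT) {
  stopifnot(cv_ratio > 0, gammaT > 0)
  if (cv_ratio >= exp(gammaT)) "gene1_only"
  else if (cv_ratio <= exp(-gammaT)) "gene2_only"
  else "coupled"
}

#' Optimal thresholds of a two-gene cascade at fixed mean FPT
#'
#' Minimizes the cascade FPT noise [fpt_noise_two_gene()] over the
#' feasible thresholds at fixed `gammaT`. Closed forms by regime
#' (see [classify_two_gene()]):
#' in the coupled regime
#' `alpha1* = 1 - sqrt((CV1/CV2) exp(-gammaT))`,
#' `alpha2* = 1 - sqrt((CV2/CV1) exp(-gammaT))`
#' (the noisier gene gets the lower threshold); in the single-gene regimes
#' the optimum sits on the boundary, `(1 - exp(-gammaT), 0)` or
#' `(0, 1 - exp(-gammaT))`. The returned pair always satisfies the mean
#' constraint `(1 - alpha1)(1 - alpha2) = exp(-gammaT)`.
#'
#' @param cv2_1,cv2_2 Intrinsic noises CV^2 of genes 1 and 2 (> 0).
#' @param gammaT Dimensionless mean FPT (> 0).
#' @return An `optimization_result`: list with `regime`, `alphas_opt`
#'   (length 2), `cv2_T_opt`, `excluded_genes`, `gammaT`.
#' @export
optimize_two_gene <- function(cv2_1, cv2_2, gammaT) {
  stopifnot(cv2_1 > 0, cv2_2 > 0, gammaT > 0)
  ratio <- sqrt(cv2_2 / cv2_1)
  regime <- classify_two_gene(ratio, gammaT)
  amax <- 1 - exp(-gammaT)
  alphas <- switch(regime,
    gene1_only = c(amax, 0),
    gene2_only = c(0, amax),
    coupled = c(1 - sqrt(exp(-gammaT) / ratio),
                1 - sqrt(exp(-gammaT) * ratio))
  )
  structure(list(regime = regime, alphas_opt = alphas,
                 cv2_T_opt = fpt_stats_cascade(alphas, c(cv2_1, cv2_2))$cv2_T,
                 excluded_genes = which(alphas == 0), gammaT = gammaT),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result: regime %s, gammaT = %g>\n",
              x$regime, x$gammaT))
  cat("  alpha*:", paste(signif(x$alphas_opt, 6), collapse = ", "), "\n")
  cat(sprintf("  CV_T^2 at optimum: %.6g\n", x$cv2_T_opt))
  if (length(x$excluded_genes))
    cat("  excluded genes:", paste(x$excluded_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Optimal thresholds for an N-gene cascade at fixed mean FPT
#'
#' Stationary solution of the constrained minimization of the cascade FPT
#' noise at fixed `gammaT`: for the genes kept in the cascade,
#' \deqn{\alpha_n^* = 1 - e^{-\gamma <T> / N}
#'       \prod_{i=1}^{N} (CV_n / CV_i)^{1/N},}
#' so that `CV_i / (1 - alpha_i*)` is the same for every included gene
#' (noisier genes get lower thresholds). A gene whose intrinsic noise is
#' too large relative to the geometric mean of the others (see
#' [inclusion_criterion()]) would receive a negative threshold; such genes
#' are excluded — the worst violator is dropped and the closed form
#' re-solved on the remaining set, iterating until all surviving
#' thresholds are feasible. The least-noisy gene always survives.
#'
#' @param cv2_list Per-gene intrinsic noises CV^2 (> 0), length N >= 1.
#' @param gammaT Dimensionless mean FPT (> 0).
#' @return An `optimization_result` with `regime` `"all_included"` or
#'   `"some_excluded"`, full-length `alphas_opt` (zeros for excluded
#'   genes), `cv2_T_opt`, and `excluded_genes`.
#' @export
optimal_thresholds_general <- function(cv2_list, gammaT) {
  stopifnot(length(cv2_list) >= 1, all(cv2_list > 0), gammaT > 0)
  cv <- sqrt(cv2_list)
  keep <- seq_along(cv)
  repeat {
    n <- length(keep)
    gm <- exp(mean(log(cv[keep])))
    a <- 1 - exp(-gammaT / n) * cv[keep] / gm
    if (all(a >= 0)) break
    # drop the worst violator (largest noise => most negative threshold)
    keep <- keep[-which.min(a)]
    if (length(keep) == 0)
      stop("internal error: all genes excluded", call. = FALSE) # unreachable
  }
  alphas <- numeric(length(cv))
  alphas[keep] <- a
  zero_kept <- keep[a == 0]           # degenerate boundary: unused gene
  excluded <- sort(c(setdiff(seq_along(cv), keep), zero_kept))
  structure(list(
    regime = if (length(excluded)) "some_excluded" else "all_included",
    alphas_opt = alphas,
    cv2_T_opt = fpt_stats_cascade(alphas, cv2_list)$cv2_T,
    excluded_genes = excluded, gammaT = gammaT),
    class = "optimization_result")
}

#' Does a gene improve the cascade's timekeeping?
#'
#' A gene can contribute to an N-gene cascade (receive a feasible positive
#' optimal threshold) if and only if its intrinsic noise, relative to the
#' geometric mean of all N genes' noises (itself included), lies strictly
#' inside
#' \deqn{e^{-\frac{N-1}{N}\gamma <T>} <
#'   \frac{CV_n}{(\prod_i CV_i)^{1/N}} < e^{\gamma <T> / N}.}
#' For N = 2 this is exactly the coupled-regime interval
#' `exp(-gammaT) < CV2/CV1 < exp(gammaT)`; as `gammaT -> 0` the interval
#' collapses to the single point \{1\} and only exactly-identical noises
#' pass.
#'
#' @param cv_n Intrinsic noise CV (not squared) of the gene under
#'   evaluation; must be one of the entries of `cv_list`.
#' @param cv_list CVs of all N genes in the candidate cascade (including
#'   `cv_n`).
#' @param gammaT Dimensionless mean FPT (> 0).
#' @return `TRUE` if including the gene can reduce timing noise.
#' @export
inclusion_criterion <- function(cv_n, cv_list, gammaT) {
  stopifnot(cv_n > 0, all(cv_list > 0), gammaT > 0)
  n <- length(cv_list)
  rel <- cv_n / exp(mean(log(cv_list)))
  rel > exp(-(n - 1) * gammaT / n) && rel < exp(gammaT / n)
}

#' Optimal dimensionless mean FPT for N identical genes
#'
#' Relaxing the fixed-mean constraint, the identical-cascade noise
#' [fpt_noise_identical()] is convex in `gammaT` with a unique minimum at
#' `gammaT* = N x*`, where `x*` is the unique root in (0, 1) of the
#' per-stage stationarity condition
#' \deqn{(1 - x) e^{2x} = 1.}
#' Solved by bracketed root-finding (`stats::uniroot`) to a residual below
#' 1e-12; `x* = 0.79681...`.
#'
#' @param n Number of genes (>= 1).
#' @return `gammaT* = n * x*` (dimensionless).
#' @examples
#' optimal_mean_time_identical(1)  # ~0.797
#' @export
optimal_mean_time_identical <- function(n = 1) {
  stopifnot(n >= 1)
  n * stage_time_root()
}

# unique root of (1 - x) e^{2x} = 1 on (0, 1); x = 0 is the trivial root,
# f > 0 just above it and f(1) = -1, so the bracket (eps, 1 - eps) is safe
stage_time_root <- function() {
  f <- function(x) (1 - x) * exp(2 * x) - 1
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-15)$root
}

#' Minimum achievable FPT noise of an identical-gene cascade
#'
#' The identical-cascade noise evaluated at the optimal mean time of
#' [optimal_mean_time_identical()], which simplifies to
#' \deqn{CV_{T,\min}^2 = \frac{CV_1^2}{N\, x^* (1 - x^*)} \approx
#'       6.18 \frac{CV_1^2}{N},}
#' with `x*` the per-stage root of `(1 - x) exp(2x) = 1`. Exact 1/N
#' scaling: lengthening an identical cascade divides the best attainable
#' timing noise by the number of genes.
#'
#' @param n Number of genes (>= 1).
#' @param cv2_1 Per-gene intrinsic noise CV^2.
#' @return Dimensionless minimum CV_T^2 (full-precision root; about
#'   `6.176 cv2_1 / n`).
#' @export
min_noise_identical <- function(n = 1, cv2_1 = 1) {
  stopifnot(n >= 1, cv2_1 > 0)
  x <- stage_time_root()
  cv2_1 / (n * x * (1 - x))
}
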