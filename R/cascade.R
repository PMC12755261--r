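#' Specify one gene of an activation cascade
#'
#' A gene is described by its burst production kinetics and its activation
#' threshold. Production can be given either as the burst rate `burst_rate`
#' (bursts per minute) or as the target steady-state level `steady_state`
#' (from which the burst rate is derived as `k = gamma * steady_state / <b>`
#' once the shared dilution rate is known). The threshold can be given
#' either absolutely (`threshold`, same concentration units as the protein
#' level) or relative to the steady state (`relative_threshold`, in (0, 1)).
#'
#' @param burst A [burst_model()].
#' @param burst_rate Burst frequency k in bursts/minute (>= 0; zero means
#'   a silent gene, useful only for degenerate checks), or `NULL`.
#' @param steady_state Steady-state level `k <b> / gamma`, or `NULL`.
#'   Exactly one of `burst_rate`, `steady_state` must be given.
#' @param threshold Absolute activation threshold X (> 0), or `NULL`.
#' @param relative_threshold Relative threshold alpha = X / steady state,
#'   or `NULL`. Exactly one of `threshold`, `relative_threshold` must be
#'   given.
#' @return An object of class `gene_spec`.
#' @examples
#' g <- gene_spec(burst_model("geometric", 4), steady_state = 800,
#'                relative_threshold = 0.55)
#' steady_state_level(g, gamma = 0.05)
#' @export
gene_spec <- function(burst, burst_rate = NULL, steady_state = NULL,
                      threshold = NULL, relative_threshold = NULL) {
  stopifnot(inherits(burst, "burst_model"))
  if (is.null(burst_rate) == is.null(steady_state))
    stop("give exactly one of burst_rate or steady_state", call. = FALSE)
  if (!is.null(burst_rate) && (!is.finite(burst_rate) || burst_rate < 0))
    stop("burst_rate must be non-negative", call. = FALSE)
  if (!is.null(steady_state) && (!is.finite(steady_state) || steady_state <= 0))
    stop("steady_state must be positive", call. = FALSE)
  if (is.null(threshold) == is.null(relative_threshold))
    stop("give exactly one of threshold or relative_threshold", call. = FALSE)
  if (!is.null(threshold) && (!is.finite(threshold) || threshold <= 0))
    stop("threshold must be positive", call. = FALSE)
  if (!is.null(relative_threshold)) {
    a <- relative_threshold
    if (!is.finite(a) || a <= 0 || a >= 1)
      warning("relative_threshold outside (0,1): outside the feasible regime ",
              "of the small-noise theory", call. = FALSE)
  }
  structure(list(burst = burst, burst_rate = burst_rate,
                 steady_state = steady_state, threshold = threshold,
                 relative_threshold = relative_threshold),
            class = "gene_spec")
}

#' @export
print.gene_spec <- function(x, ...) {
  kin <- if (!is.null(x$burst_rate)) sprintf("k = %g /min", x$burst_rate)
         else sprintf("xbar = %g", x$steady_state)
  thr <- if (!is.null(x$threshold)) sprintf("X = %g", x$threshold)
         else sprintf("alpha = %g", x$relative_threshold)
  cat(sprintf("<gene_spec: %s, %s, burst %s <b>=%g>\n",
              kin, thr, x$burst$family, x$burst$mean))
  invisible(x)
}

#' Specify a gene-activation cascade
#'
#' An ordered list of genes sharing one dilution rate. Gene 1 is
#' constitutively active from time 0; gene i is switched on (step-function
#' activation) the instant the product of gene i-1 first reaches its
#' threshold; the cascade's first-passage time is the instant the last
#' gene's product reaches its own threshold.
#'
#' @param genes List of [gene_spec()] objects (length N >= 1).
#' @param dilution_rate Shared dilution rate gamma in 1/minute (> 0); the
#'   cell growth rate, diluting every protein as `dx/dt = -gamma x`
#'   between bursts.
#' @return An object of class `cascade_spec`.
#' @seealso [identical_cascade()] for the common all-genes-equal case.
#' @export
cascade_spec <- function(genes, dilution_rate) {
  if (inherits(genes, "gene_spec")) genes <- list(genes)
  stopifnot(length(genes) >= 1L, all(vapply(genes, inherits, TRUE, "gene_spec")))
  if (!is.numeric(dilution_rate) || length(dilution_rate) != 1L ||
      !is.finite(dilution_rate) || dilution_rate <= 0)
    stop("dilution_rate must be a single positive rate", call. = FALSE)
  structure(list(genes = genes, dilution_rate = dilution_rate),
            class = "cascade_spec")
}

#' @export
print.cascade_spec <- function(x, ...) {
  cat(sprintf("<cascade_spec: N = %d genes, gamma = %g /min>\n",
              length(x$genes), x$dilution_rate))
  for (g in x$genes) print(g)
  invisible(x)
}

#' @export
length.cascade_spec <- function(x) length(x$genes)

#' Cascade of N identical genes
#'
#' Convenience constructor for the identical-gene case: every stage has the
#' same burst statistics and steady state, and per-stage relative thresholds
#' are set so the cascade's mean first-passage time equals `mean_fpt`
#' (equal split: alpha = 1 - exp(-gamma * mean_fpt / N) per stage).
#'
#' @param n Number of genes.
#' @param gamma Dilution rate (1/min).
#' @param steady_state Per-gene steady-state level.
#' @param burst A [burst_model()].
#' @param mean_fpt Target mean first-passage time (minutes); used to place
#'   the equal per-stage thresholds. Alternatively give `alpha` directly.
#' @param alpha Per-stage relative threshold (overrides `mean_fpt`).
#' @return A [cascade_spec()].
#' @export
identical_cascade <- function(n, gamma, steady_state, burst,
                              mean_fpt = NULL, alpha = NULL) {
  stopifnot(n >= 1)
  if (is.null(alpha)) {
    if (is.null(mean_fpt)) stop("give mean_fpt or alpha", call. = FALSE)
    alpha <- 1 - exp(-gamma * mean_fpt / n)
  }
  genes <- replicate(n, gene_spec(burst, steady_state = steady_state,
                                  relative_threshold = alpha),
                     simplify = FALSE)
  cascade_spec(genes, dilution_rate = gamma)
}

#' Steady-state protein level
#'
#' The stationary mean of the burst-dilution process for an always-active
#' gene: `xbar = k <b> / gamma` (burst influx over dilution).
#'
#' @param gene A [gene_spec()].
#' @param gamma Dilution rate (> 0, 1/min).
#' @return Steady-state concentration (scalar, > 0).
#' @export
steady_state_level <- function(gene, gamma) {
  stopifnot(inherits(gene, "gene_spec"))
  if (!is.finite(gamma) || gamma <= 0)
    stop("gamma must be a positive rate", call. = FALSE)
  if (!is.null(gene$steady_state)) gene$steady_state
  else gene$burst_rate * gene$burst$mean / gamma
}

#' Burst rate of a gene
#'
#' Returns k directly if declared, otherwise derives it from the declared
#' steady state as `k = gamma * xbar / <b>`.
#'
#' @inheritParams steady_state_level
#' @return Burst rate (bursts/min).
#' @export
burst_rate <- function(gene, gamma) {
  stopifnot(inherits(gene, "gene_spec"))
  if (!is.finite(gamma) || gamma <= 0)
    stop("gamma must be a positive rate", call. = FALSE)
  if (!is.null(gene$burst_rate)) gene$burst_rate
  else gamma * gene$steady_state / gene$burst$mean
}

#' Relative activation threshold
#'
#' alpha = X / xbar: the threshold as a fraction of the steady-state level.
#' Values outside (0, 1) are returned with a warning (the small-noise
#' theory requires 0 < alpha < 1; the optimizer legitimately emits
#' alpha = 0 boundary cases).
#'
#' @inheritParams steady_state_level
#' @return Dimensionless relative threshold.
#' @export
relative_threshold <- function(gene, gamma) {
  stopifnot(inherits(gene, "gene_spec"))
  if (!is.null(gene$relative_threshold)) return(gene$relative_threshold)
  a <- gene$threshold / steady_state_level(gene, gamma)
  if (a <= 0 || a >= 1)
    warning(sprintf("relative threshold %g outside (0,1)", a), call. = FALSE)
  a
}

#' Absolute activation threshold
#'
#' X = alpha * xbar, the inverse conversion of [relative_threshold()];
#' the two round-trip to better than 1e-12 relative error.
#'
#' @inheritParams steady_state_level
#' @return Threshold concentration.
#' @export
threshold_level <- function(gene, gamma) {
  stopifnot(inherits(gene, "gene_spec"))
  if (!is.null(gene$threshold)) return(gene$threshold)
  gene$relative_threshold * steady_state_level(gene, gamma)
}

#' Intrinsic gene-expression noise
#'
#' Stationary squared coefficient of variation of the protein level under
#' bursty production and dilution: `CV^2 = <b^2> / (2 <b> xbar)`. At fixed
#' steady state it depends only on the burst-size statistics, not on k or
#' gamma separately.
#'
#' @inheritParams steady_state_level
#' @return Dimensionless squared coefficient of variation.
#' @export
intrinsic_noise <- function(gene, gamma) {
  stopifnot(inherits(gene, "gene_spec"))
  if (gene$burst$mean <= 0)
    stop("mean burst size must be positive", call. = FALSE)
  xbar <- steady_state_level(gene, gamma)
  if (xbar <= 0)
    stop("intrinsic noise undefined for a silent gene (steady state 0)",
         call. = FALSE)
  gene$burst$second_moment / (2 * gene$burst$mean * xbar)
}

#' Read a cascade configuration file
#'
#' Reads a YAML cascade description with fields
#' `gamma` and `genes`, where each gene has `burst_rate` or `steady_state`,
#' `burst: {family, mean}` (optional `second_moment`), and `threshold` or
#' `relative_threshold`.
#'
#' @param path Path to a YAML file.
#' @return A [cascade_spec()].
#' @export
read_cascade_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$gamma) || is.null(cfg$genes))
    stop("config must contain 'gamma' and 'genes'", call. = FALSE)
  genes <- lapply(cfg$genes, function(g) {
    if (is.null(g$burst) || is.null(g$burst$family) || is.null(g$burst$mean))
      stop("each gene needs burst: {family, mean}", call. = FALSE)
    bm <- burst_model(g$burst$family, g$burst$mean,
                      second_moment = g$burst$second_moment)
    gene_spec(bm,
              burst_rate = g$burst_rate,
              steady_state = g$steady_state,
              threshold = g$threshold,
              relative_threshold = g$relative_threshold)
  })
  cascade_spec(genes, dilution_rate = cfg$gamma)
}

#' Write a cascade configuration file
#'
#' Inverse of [read_cascade_config()].
#'
#' @param spec A [cascade_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_config <- function(spec, path) {
  stopifnot(inherits(spec, "cascade_spec"))
  genes <- lapply(spec$genes, function(g) {
    out <- list(burst = list(family = g$burst$family, mean = g$burst$mean,
                             second_moment = g$burst$second_moment))
    if (!is.null(g$burst_rate)) out$burst_rate <- g$burst_rate
    if (!is.null(g$steady_state)) out$steady_state <- g$steady_state
    if (!is.null(g$threshold)) out$threshold <- g$threshold
    if (!is.null(g$relative_threshold))
      out$relative_threshold <- g$relative_threshold
    out
  })
  yaml::write_yaml(list(gamma = spec$dilution_rate, genes = genes), path)
  invisible(path)
}
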