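#' Burst-size model for one gene
#'
#' Describes the distribution of the random protein amount added per
#' transcriptional burst. Only the first two moments enter the timing
#' theory; a sampler for each family backs the stochastic simulator.
#'
#' Supported families:
#' \describe{
#'   \item{`geometric`}{Geometric on support \{0, 1, 2, ...\} with mean
#'     `m`, so the variance is `m(m+1)` and the second moment `m(2m+1)`.
#'     Zero-size bursts are legal no-op events; this support admits burst
#'     means below 1.}
#'   \item{`geometric1`}{Geometric on the shifted support \{1, 2, ...\}
#'     (number-of-trials convention) with mean `m >= 1`; second moment
#'     `2m^2 - m`. Provided for comparison with the zero-inclusive
#'     convention.}
#'   \item{`fixed`}{Deterministic burst of size `mean`.}
#'   \item{`exponential`}{Exponential with mean `m`; second moment `2m^2`.}
#' }
#'
#' @param family One of `"geometric"`, `"geometric1"`, `"fixed"`,
#'   `"exponential"`.
#' @param mean Mean burst size (concentration per burst), > 0.
#' @param second_moment Optional second moment; defaults to the family's
#'   closed form. Must satisfy `second_moment >= mean^2`.
#' @return An object of class `burst_model` with fields `family`, `mean`,
#'   `second_moment`.
#' @examples
#' b <- burst_model("geometric", mean = 4)
#' b$second_moment  # 4 * (2*4 + 1) = 36
#' @export
burst_model <- function(family = c("geometric", "geometric1", "fixed", "exponential"),
                        mean, second_moment = NULL) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("burst mean must be a single positive number", call. = FALSE)
  if (family == "geometric1" && mean < 1)
    stop("geometric1 (support {1,2,...}) requires mean >= 1; use family 'geometric'",
         call. = FALSE)
  m2_default <- switch(family,
    geometric   = mean * (2 * mean + 1),
    geometric1  = 2 * mean^2 - mean,
    fixed       = mean^2,
    exponential = 2 * mean^2
  )
  if (is.null(second_moment)) second_moment <- m2_default
  if (second_moment < mean^2)
    stop("second_moment must be >= mean^2 (non-negative variance)", call. = FALSE)
  structure(list(family = family, mean = mean, second_moment = second_moment),
            class = "burst_model")
}

#' @export
print.burst_model <- function(x, ...) {
  cat(sprintf("<burst_model: %s, <b> = %g, <b^2> = %g>\n",
              x$family, x$mean, x$second_moment))
  invisible(x)
}

#' Draw burst sizes
#'
#' Samples from a burst-size model using R's global random-number stream.
#'
#' @param model A [burst_model()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_bursts <- function(model, n) {
  stopifnot(inherits(model, "burst_model"))
  m <- model$mean
  switch(model$family,
    geometric   = as.numeric(stats::rgeom(n, prob = 1 / (1 + m))),
    geometric1  = as.numeric(stats::rgeom(n, prob = 1 / m)) + 1,
    fixed       = rep(m, n),
    exponential = stats::rexp(n, rate = 1 / m)
  )
}

# integer code used by the compiled simulator
burst_family_code <- function(model) {
  match(model$family, c("geometric", "fixed", "exponential", "geometric1")) - 1L
}
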