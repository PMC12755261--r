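#' Simulate single-stage first-passage times
#'
#' Draws first-passage times of one always-active gene started at level 0:
#' bursts arrive as a Poisson process at rate k, each adds a random amount
#' from the gene's burst model, and the level decays as
#' `exp(-gamma * dt)` between bursts (computed analytically — there is no
#' internal time step). Since the level is non-increasing between bursts,
#' the threshold can only be crossed at a burst instant; the crossing
#' condition is `level >= X` (inclusive).
#'
#' Uses R's global RNG stream; call `set.seed()` (or use
#' [sample_fpt_ensemble()]) for reproducibility.
#'
#' @param gene A [gene_spec()].
#' @param gamma Dilution rate (1/min).
#' @param n Number of independent replicates.
#' @param event_cap Maximum bursts per replicate before the replicate is
#'   declared non-crossing (guards thresholds at or above what the process
#'   can reach); exceeding it is an error, never a silent truncation.
#' @return Numeric vector of `n` first-passage times (minutes).
#' @export
simulate_stage_fpt <- function(gene, gamma, n = 1L, event_cap = 1e7) {
  stopifnot(inherits(gene, "gene_spec"), n >= 1)
  k <- burst_rate(gene, gamma)
  if (k <= 0)
    stop("a silent gene (burst rate 0) never crosses its threshold",
         call. = FALSE)
  X <- threshold_level(gene, gamma)
  fpt <- cpp_stage_fpt(as.integer(n), k, gamma, X,
                       burst_family_code(gene$burst), gene$burst$mean,
                       event_cap)
  if (anyNA(fpt))
    stop(sprintf(paste0("%d of %d replicates did not cross the threshold ",
                        "within %g burst events (threshold X = %g, steady ",
                        "state = %g)"),
                 sum(is.na(fpt)), n, event_cap, X,
                 steady_state_level(gene, gamma)), call. = FALSE)
  fpt
}

#' Simulate cascade first-passage times
#'
#' Simulates the N-gene step-activation cascade and returns per-stage and
#' total first-passage times. The default `"decomposed"` mode simulates
#' each stage independently in stage-local time (each gene starts at level
#' 0 the instant its activator crosses — exact under step activation with
#' zero initial conditions, since the stages are independent). The
#' `"coupled"` mode runs the full multi-gene process on one clock and is
#' kept as a cross-validation oracle for that independence argument.
#'
#' @param spec A [cascade_spec()].
#' @param n Number of replicates.
#' @param mode `"decomposed"` (default) or `"coupled"`.
#' @param event_cap Maximum burst events per replicate (total across
#'   stages in coupled mode).
#' @return A data frame of class `fpt_samples` with columns `replicate`,
#'   `stage_1` ... `stage_N`, `total`; `total` is exactly the row sum of
#'   the stage times.
#' @export
simulate_cascade_fpt <- function(spec, n = 1L,
                                 mode = c("decomposed", "coupled"),
                                 event_cap = 1e7) {
  stopifnot(inherits(spec, "cascade_spec"), n >= 1)
  mode <- match.arg(mode)
  gamma <- spec$dilution_rate
  N <- length(spec$genes)
  if (mode == "decomposed") {
    stage <- vapply(spec$genes, simulate_stage_fpt, numeric(n),
                    gamma = gamma, n = n, event_cap = event_cap)
    stage <- matrix(stage, nrow = n, ncol = N)
  } else {
    k <- vapply(spec$genes, burst_rate, 0, gamma = gamma)
    X <- vapply(spec$genes, threshold_level, 0, gamma = gamma)
    fam <- vapply(spec$genes, function(g) burst_family_code(g$burst), 0L)
    mb <- vapply(spec$genes, function(g) g$burst$mean, 0)
    cross <- cpp_cascade_fpt_coupled(as.integer(n), k, gamma, X, fam, mb,
                                     event_cap)
    if (anyNA(cross))
      stop(sprintf("%d of %d replicates did not complete within %g events",
                   sum(is.na(cross[, N])), n, event_cap), call. = FALSE)
    stage <- cross - cbind(0, cross[, -N, drop = FALSE]) # global -> stage
  }
  out <- data.frame(replicate = seq_len(n), stage)
  names(out) <- c("replicate", paste0("stage_", seq_len(N)))
  out$total <- rowSums(stage)
  class(out) <- c("fpt_samples", class(out))
  out
}

#' Seeded first-passage-time ensemble with summary statistics
#'
#' Reproducible Monte-Carlo ensemble of cascade first-passage times. The
#' summary reports the plug-in estimators `mean_T`, `var_T`,
#' `cv2_T = var_T / mean_T^2`, plus a delta-method standard error for
#' `cv2_T` (propagating the sampling covariance of the mean and variance
#' through the ratio, using sample central moments up to order 4).
#'
#' @param spec A [cascade_spec()].
#' @param n_replicates Number of replicates (>= 2).
#' @param seed Integer seed; same (spec, n, seed) gives a bit-identical
#'   ensemble.
#' @param mode Passed to [simulate_cascade_fpt()].
#' @param event_cap Passed to [simulate_cascade_fpt()].
#' @return An object of class `fpt_ensemble`: list with `samples` (the
#'   `fpt_samples` data frame), `seed`, `spec`, and `summary` (list with
#'   `n`, `mean_T`, `var_T`, `cv2_T`, `sem_cv2`).
#' @examples
#' spec <- identical_cascade(1, gamma = 0.05, steady_state = 800,
#'                           burst = burst_model("geometric", 4),
#'                           alpha = 0.55)
#' ens <- sample_fpt_ensemble(spec, 2000, seed = 1)
#' ens$summary$cv2_T
#' @export
sample_fpt_ensemble <- function(spec, n_replicates, seed,
                                mode = c("decomposed", "coupled"),
                                event_cap = 1e7) {
  stopifnot(n_replicates >= 2)
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  samples <- simulate_cascade_fpt(spec, n = n_replicates, mode = mode,
                                  event_cap = event_cap)
  T <- samples$total
  m <- mean(T)
  v <- stats::var(T)
  structure(list(samples = samples, seed = as.integer(seed), spec = spec,
                 summary = list(n = n_replicates, mean_T = m, var_T = v,
                                cv2_T = v / m^2,
                                sem_cv2 = cv2_delta_se(T))),
            class = "fpt_ensemble")
}

# delta-method standard error of the plug-in CV^2 estimator
cv2_delta_se <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  mu2 <- mean(d^2)
  mu3 <- mean(d^3)
  mu4 <- mean(d^4)
  v <- 4 * mu2^3 / m^6 - 4 * mu2 * mu3 / m^5 + (mu4 - mu2^2) / m^4
  sqrt(max(v, 0) / n)
}

#' @export
print.fpt_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<fpt_ensemble: n = %d, seed = %d, N = %d genes>\n",
                     "  mean T = %.4g min, var T = %.4g, CV_T^2 = %.4g ",
                     "(se %.2g)\n"),
              s$n, x$seed, length(x$spec$genes), s$mean_T, s$var_T,
              s$cv2_T, s$sem_cv2))
  invisible(x)
}

#' Simulate a full cascade trajectory
#'
#' Event log of one realization of the coupled cascade up to `t_max`:
#' burst instants, post-burst levels, and the activation/crossing instants
#' of each gene. Decay between events is analytic. Intended for plotting
#' and for validating the transient moment formulas.
#'
#' @param spec A [cascade_spec()].
#' @param t_max End time (minutes, > 0).
#' @return An object of class `cascade_trajectory`: list with `events`
#'   (data frame: `time`, `gene`, `level`, `event` in
#'   \{"burst", "crossing"\}) and `activation_times` (per-gene activation
#'   instants; gene 1 at 0, `NA` if not reached before `t_max`).
#' @export
simulate_trajectory <- function(spec, t_max) {
  stopifnot(inherits(spec, "cascade_spec"), t_max > 0)
  gamma <- spec$dilution_rate
  N <- length(spec$genes)
  activation <- c(0, rep(NA_real_, N - 1))
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    t0 <- activation[i]
    if (is.na(t0)) break
    g <- spec$genes[[i]]
    k <- burst_rate(g, gamma)
    X <- threshold_level(g, gamma)
    span <- t_max - t0
    if (k <= 0 || span <= 0) next
    # Poisson burst instants on (t0, t_max]
    nb <- stats::rpois(1, k * span)
    if (nb == 0) next
    tb <- t0 + sort(stats::runif(nb, 0, span))
    b <- sample_bursts(g$burst, nb)
    lev <- numeric(nb)
    x <- 0
    tprev <- t0
    crossed_at <- NA_real_
    for (j in seq_len(nb)) {
      x <- x * exp(-gamma * (tb[j] - tprev)) + b[j]
      lev[j] <- x
      tprev <- tb[j]
      if (is.na(crossed_at) && x >= X) crossed_at <- tb[j]
    }
    ev <- data.frame(time = tb, gene = i, level = lev, event = "burst")
    if (!is.na(crossed_at)) {
      ev <- rbind(ev, data.frame(time = crossed_at, gene = i,
                                 level = lev[match(crossed_at, tb)],
                                 event = "crossing"))
      if (i < N) activation[i + 1] <- crossed_at
    }
    rows[[i]] <- ev
  }
  events <- do.call(rbind, rows)
  if (is.null(events))
    events <- data.frame(time = numeric(0), gene = integer(0),
                         level = numeric(0), event = character(0))
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, activation_times = activation,
                 t_max = t_max, spec = spec),
            class = "cascade_trajectory")
}

#' Evaluate a trajectory's protein level on a time grid
#'
#' Reconstructs gene `gene`'s level at arbitrary times from the event log
#' (exact exponential decay from the last burst before each query time).
#'
#' @param traj A `cascade_trajectory`.
#' @param gene Gene index.
#' @param times Query times (minutes).
#' @return Numeric vector of levels.
#' @export
trajectory_levels <- function(traj, gene, times) {
  stopifnot(inherits(traj, "cascade_trajectory"))
  gamma <- traj$spec$dilution_rate
  ev <- traj$events
  ev <- ev[ev$gene == gene & ev$event == "burst", , drop = FALSE]
  vapply(times, function(tt) {
    prior <- ev$time <= tt
    if (!any(prior)) return(0)
    j <- max(which(prior))
    ev$level[j] * exp(-gamma * (tt - ev$time[j]))
  }, numeric(1))
}

#' Write an FPT ensemble to disk
#'
#' Writes the replicate table as CSV (columns `replicate`, `stage`,
#' `stage_time`, `total_time`, long format over stages) and the summary as
#' JSON (`n`, `seed`, `mean_T`, `var_T`, `cv2_T`, `sem`).
#'
#' @param ensemble An `fpt_ensemble`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_fpt_ensemble <- function(ensemble, dir, prefix = "fpt") {
  stopifnot(inherits(ensemble, "fpt_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- ensemble$samples
  N <- sum(startsWith(names(s), "stage_"))
  long <- do.call(rbind, lapply(seq_len(N), function(i)
    data.frame(replicate = s$replicate, stage = i,
               stage_time = s[[paste0("stage_", i)]],
               total_time = s$total)))
  long <- long[order(long$replicate, long$stage), ]
  csv <- file.path(dir, paste0(prefix, "_samples.csv"))
  utils::write.csv(long, csv, row.names = FALSE)
  su <- ensemble$summary
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(n = su$n, seed = ensemble$seed,
                            mean_T = su$mean_T, var_T = su$var_T,
                            cv2_T = su$cv2_T, sem = su$sem_cv2),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
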