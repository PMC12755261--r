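#' Built-in study parameterizations
#'
#' Returns the parameter sets used by the package's reproduction
#' experiments, each a fully specified cascade plus the sweep that the
#' corresponding experiment runs. Available fixtures:
#' \describe{
#'   \item{`single_gene_threshold_sweep`}{One gene, gamma = 0.05/min,
#'     geometric bursts of mean 4, steady state 800; sweeps the relative
#'     threshold to expose the U-shaped FPT-noise curve with its minimum
#'     near alpha = 0.55.}
#'   \item{`two_gene_fixed_mean`}{Two identical genes (steady state 800,
#'     geometric mean-4 bursts), mean FPT fixed at 40 min (gammaT = 2);
#'     sweeps the second threshold under the mean constraint.}
#'   \item{`two_gene_noise_ratio`}{Two genes with steady state 1000 and
#'     mean FPT 10 min (gammaT = 0.5); gene 1 has burst mean 4, gene 2's
#'     burst mean takes 0.625 / 4 / 17.5, giving intrinsic-noise ratios
#'     CV2/CV1 of 0.5 / 1.0 / 2.0 — one case per optimization regime.}
#'   \item{`identical_cascade_lengths`}{Identical-gene cascades of length
#'     1 and 5 (gamma = 0.05/min, steady state 1000, geometric mean-4
#'     bursts) with equal stage thresholds holding the total mean FPT at
#'     40 min: the length-5 timer is far more precise.}
#'   \item{`relative_time_sweep`}{Identical cascades of length 1..5 over a
#'     grid of dimensionless mean times gammaT, equal stage thresholds
#'     `1 - exp(-gammaT/N)` per point; each noise curve is convex with its
#'     minimum near `N * 0.797`.}
#' }
#'
#' @param experiment Fixture name (see above).
#' @return A list with elements depending on the fixture: always `gamma`,
#'   `burst`, `steady_state`, `caption_replicates`, `description`, plus
#'   sweep definitions (`alpha_grid`, `burst2_means`, `gammaT`, `lengths`,
#'   `mean_fpt`, ... as applicable).
#' @export
cascade_fixture <- function(experiment = c("single_gene_threshold_sweep",
                                           "two_gene_fixed_mean",
                                           "two_gene_noise_ratio",
                                           "identical_cascade_lengths",
                                           "relative_time_sweep")) {
  experiment <- match.arg(experiment)
  geo4 <- burst_model("geometric", 4)
  switch(experiment,
    single_gene_threshold_sweep = list(
      experiment = experiment, gamma = 0.05, burst = geo4,
      steady_state = 800,
      alpha_grid = seq(0.1, 0.9, by = 0.05),
      caption_replicates = 1e5,
      description = "FPT noise vs relative threshold, single gene"),
    two_gene_fixed_mean = list(
      experiment = experiment, gamma = 0.05, burst = geo4,
      steady_state = 800, mean_fpt = 40,
      alpha2_grid = seq(0, 0.8, by = 0.05),
      caption_replicates = 1e5,
      description = "two-gene threshold trade-off at fixed mean FPT"),
    two_gene_noise_ratio = list(
      experiment = experiment, gamma = 0.05, burst = geo4,
      steady_state = 1000, mean_fpt = 10,
      burst2_means = c(0.625, 4, 17.5),   # CV2/CV1 = 0.5, 1.0, 2.0
      alpha2_grid = seq(0, 0.36, by = 0.03),
      caption_replicates = 2e5,
      description = "optimization regimes vs intrinsic-noise ratio"),
    identical_cascade_lengths = list(
      experiment = experiment, gamma = 0.05, burst = geo4,
      steady_state = 1000, mean_fpt = 40, lengths = c(1, 5),
      caption_replicates = 1e5,
      description = "noise suppression by cascade length at fixed mean"),
    relative_time_sweep = list(
      experiment = experiment, gamma = 0.05, burst = geo4,
      steady_state = 1000, lengths = 1:5,
      gammaT_grid = seq(0.4, 4, by = 0.4),
      caption_replicates = 2e5,
      description = "identical-cascade noise vs dimensionless mean time")
  )
}

#' Run a reproduction experiment
#'
#' Runs one of the built-in experiments of [cascade_fixture()]: evaluates
#' the small-noise theory curve and a Monte-Carlo ensemble side by side
#' over the fixture's sweep and returns (optionally writes) a tidy results
#' table plus a run manifest. Deterministic given `seed`: per-point
#' sub-seeds are derived from the root seed so the output is bit-identical
#' across runs.
#'
#' @param experiment Fixture name (see [cascade_fixture()]).
#' @param seed Integer root seed.
#' @param replicates Replicates per sweep point; default 1e4 (desk scale).
#'   Set `full = TRUE` to use the fixture's full replicate count instead.
#' @param full Use the fixture's full (publication-scale) replicate count.
#' @param out_dir If non-NULL, write `<experiment>.csv` and
#'   `<experiment>_manifest.json` there.
#' @return List with `table` (data frame), `manifest` (list), and
#'   `fixture`.
#' @export
run_experiment <- function(experiment, seed = 1L, replicates = NULL,
                           full = FALSE, out_dir = NULL) {
  fx <- cascade_fixture(experiment)
  reps <- if (!is.null(replicates)) replicates
          else if (full) fx$caption_replicates else 1e4
  point_seed <- function(i)
    as.integer((as.numeric(seed) * 10007 + 31 * i) %% 2147483647)
  cv2_of <- function(bm, xbar) bm$second_moment / (2 * bm$mean * xbar)
  gamma <- fx$gamma

  table <- switch(experiment,
    single_gene_threshold_sweep = {
      cv2 <- cv2_of(fx$burst, fx$steady_state)
      do.call(rbind, lapply(seq_along(fx$alpha_grid), function(i) {
        a <- fx$alpha_grid[i]
        spec <- cascade_spec(gene_spec(fx$burst,
                                       steady_state = fx$steady_state,
                                       relative_threshold = a), gamma)
        ens <- sample_fpt_ensemble(spec, reps, point_seed(i))
        data.frame(alpha = a,
                   mean_T_theory = mean_fpt_single(a, gamma),
                   cv2_T_theory = fpt_noise_single(a, cv2),
                   mean_T_sim = ens$summary$mean_T,
                   cv2_T_sim = ens$summary$cv2_T,
                   sem_cv2 = ens$summary$sem_cv2)
      }))
    },
    two_gene_fixed_mean = ,
    two_gene_noise_ratio = {
      b2_means <- if (is.null(fx$burst2_means)) fx$burst$mean else fx$burst2_means
      gT <- gamma * fx$mean_fpt
      cv2_1 <- cv2_of(fx$burst, fx$steady_state)
      grid <- expand.grid(burst2_mean = b2_means, alpha2 = fx$alpha2_grid)
      grid <- grid[grid$alpha2 < 1 - exp(-gT), , drop = FALSE]
      do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        b2 <- burst_model("geometric", grid$burst2_mean[i])
        cv2_2 <- cv2_of(b2, fx$steady_state)
        a2 <- grid$alpha2[i]
        a1 <- 1 - exp(-gT) / (1 - a2)
        alphas <- c(a1, a2)
        bursts <- list(fx$burst, b2)
        # an unused gene (alpha = 0) contributes zero time: simulate the rest
        used <- which(alphas > 0)
        genes <- lapply(used, function(j)
          gene_spec(bursts[[j]], steady_state = fx$steady_state,
                    relative_threshold = alphas[j]))
        spec <- cascade_spec(genes, gamma)
        ens <- sample_fpt_ensemble(spec, reps, point_seed(i))
        data.frame(burst2_mean = grid$burst2_mean[i],
                   cv_ratio = sqrt(cv2_2 / cv2_1),
                   alpha1 = a1, alpha2 = a2,
                   cv2_T_theory = fpt_noise_two_gene(a2, cv2_1, cv2_2, gT),
                   mean_T_sim = ens$summary$mean_T,
                   cv2_T_sim = ens$summary$cv2_T,
                   sem_cv2 = ens$summary$sem_cv2)
      }))
    },
    identical_cascade_lengths = {
      cv2_1 <- cv2_of(fx$burst, fx$steady_state)
      gT <- gamma * fx$mean_fpt
      do.call(rbind, lapply(seq_along(fx$lengths), function(i) {
        n <- fx$lengths[i]
        spec <- identical_cascade(n, gamma, fx$steady_state, fx$burst,
                                  mean_fpt = fx$mean_fpt)
        ens <- sample_fpt_ensemble(spec, reps, point_seed(i))
        data.frame(n_genes = n, mean_T_target = fx$mean_fpt,
                   cv2_T_theory = fpt_noise_identical(n, cv2_1, gT),
                   mean_T_sim = ens$summary$mean_T,
                   cv2_T_sim = ens$summary$cv2_T,
                   sem_cv2 = ens$summary$sem_cv2)
      }))
    },
    relative_time_sweep = {
      cv2_1 <- cv2_of(fx$burst, fx$steady_state)
      grid <- expand.grid(n_genes = fx$lengths, gammaT = fx$gammaT_grid)
      do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        n <- grid$n_genes[i]
        gT <- grid$gammaT[i]
        spec <- identical_cascade(n, gamma, fx$steady_state, fx$burst,
                                  mean_fpt = gT / gamma)
        ens <- sample_fpt_ensemble(spec, reps, point_seed(i))
        data.frame(n_genes = n, gammaT = gT,
                   cv2_T_theory = fpt_noise_identical(n, cv2_1, gT),
                   mean_T_sim = ens$summary$mean_T,
                   cv2_T_sim = ens$summary$cv2_T,
                   sem_cv2 = ens$summary$sem_cv2)
      }))
    }
  )
  rownames(table) <- NULL
  manifest <- list(experiment = experiment, seed = as.integer(seed),
                   replicates = reps,
                   package_version = as.character(utils::packageVersion("cascadeclock")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table, file.path(out_dir, paste0(experiment, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(experiment, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = table, manifest = manifest, fixture = fx)
}
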