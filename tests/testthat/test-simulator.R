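test_that("a burst of exactly threshold size crosses on the first burst", {
  g <- gene_spec(burst_model("fixed", 50), burst_rate = 2, threshold = 50)
  set.seed(101)
  fpt <- simulate_stage_fpt(g, 0.1, n = 2e4)
  # first-burst times are exponential with mean 1/k
  expect_lt(abs(mean(fpt) - 0.5), 3 * sd(fpt) / sqrt(length(fpt)))
  # in fact identically the first inter-burst waits: same RNG stream
  set.seed(101)
  expect_identical(fpt, rexp(2e4, rate = 2))
})

test_that("stage mean FPT tracks the saturation-time approximation", {
  g <- gene_spec(geo4(), steady_state = 800, relative_threshold = 0.55)
  set.seed(102)
  fpt <- simulate_stage_fpt(g, 0.05, n = 2e4)
  th <- mean_fpt_single(0.55, 0.05)
  expect_lt(abs(mean(fpt) - th) / th, 0.005)
})

test_that("simulated FPT noise is within 25% of the small-noise formula", {
  set.seed(103)
  for (a in c(0.4, 0.55, 0.7)) {
    g <- gene_spec(geo4(), steady_state = 800, relative_threshold = a)
    fpt <- simulate_stage_fpt(g, 0.05, n = 2e4)
    cv2_sim <- var(fpt) / mean(fpt)^2
    cv2_th <- fpt_noise_single(a, intrinsic_noise(g, 0.05))
    expect_lt(abs(cv2_sim - cv2_th) / cv2_th, 0.25)
  }
})

test_that("deterministic production limit: frequent tiny bursts", {
  # fixed bursts, k -> infinity at fixed burst influx k<b>: the mean FPT
  # approaches the deterministic saturation time and the noise vanishes
  gamma <- 0.05
  alpha <- 0.55
  th <- mean_fpt_single(alpha, gamma)
  set.seed(104)
  cv2s <- means <- numeric(0)
  for (k in c(1, 10, 100)) {
    b <- 0.05 * 800 / k   # keeps steady state at 800
    g <- gene_spec(burst_model("fixed", b), burst_rate = k,
                   relative_threshold = alpha)
    fpt <- simulate_stage_fpt(g, gamma, n = 5e3)
    means <- c(means, mean(fpt))
    cv2s <- c(cv2s, var(fpt) / mean(fpt)^2)
  }
  expect_true(all(diff(cv2s) < 0))
  # noise scales as 1/k (CV_1^2 = b / (2 xbar) halves per tenfold k)
  expect_lt(cv2s[3], 0.003)
  expect_equal(cv2s[1] / cv2s[2], 10, tolerance = 0.5)
  expect_lt(abs(means[3] - th) / th, 0.01)
})

test_that("replicates that cannot cross raise an explicit error", {
  g <- gene_spec(burst_model("fixed", 1), burst_rate = 1, threshold = 1e6)
  expect_error(simulate_stage_fpt(g, 1, n = 2, event_cap = 1e4),
               "did not cross")
  silent <- gene_spec(geo4(), burst_rate = 0, threshold = 10)
  expect_error(simulate_stage_fpt(silent, 1), "silent")
})

test_that("cascade samples: totals are exact stage sums; N = 1 reduces", {
  spec <- identical_cascade(3, 0.05, 500, geo4(), mean_fpt = 30)
  set.seed(105)
  s <- simulate_cascade_fpt(spec, n = 500)
  expect_identical(s$total, rowSums(as.matrix(s[, paste0("stage_", 1:3)])))
  expect_true(all(s$total > 0))
  # single-gene cascade equals the stage simulator in distribution
  g <- single_gene(800, 0.55)
  set.seed(106); a <- simulate_cascade_fpt(cascade_spec(g, 0.05), n = 5e3)$total
  set.seed(106); b <- simulate_stage_fpt(g, 0.05, n = 5e3)
  expect_identical(a, b)
})

test_that("two identical stages: i.i.d. stage times, additive mean", {
  spec <- identical_cascade(2, 0.05, 800, geo4(), alpha = 0.5)
  set.seed(107)
  s <- simulate_cascade_fpt(spec, n = 2e4)
  m1 <- mean(s$stage_1); m2 <- mean(s$stage_2)
  sem <- sd(s$stage_1) / sqrt(nrow(s))
  expect_lt(abs(m1 - m2), 4 * sem)
  expect_lt(abs(cor(s$stage_1, s$stage_2)), 0.03)
  expect_equal(mean(s$total), m1 + m2)
})

test_that("ensembles are seed-reproducible with a consistent summary", {
  spec <- identical_cascade(2, 0.05, 500, geo4(), mean_fpt = 20)
  e1 <- sample_fpt_ensemble(spec, 2000, seed = 42)
  e2 <- sample_fpt_ensemble(spec, 2000, seed = 42)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$summary, e2$summary)
  e3 <- sample_fpt_ensemble(spec, 2000, seed = 43)
  expect_false(identical(e3$samples, e1$samples))
  # summary is recomputable from the samples
  T <- e1$samples$total
  expect_equal(e1$summary$cv2_T, var(T) / mean(T)^2, tolerance = 1e-12)
  expect_equal(e1$summary$mean_T, mean(T), tolerance = 1e-12)
})

test_that("ensemble summaries are statistically consistent across sizes", {
  spec <- identical_cascade(1, 0.05, 1000, geo4(), mean_fpt = 40)
  small <- sample_fpt_ensemble(spec, 2e3, seed = 7)
  large <- sample_fpt_ensemble(spec, 2e4, seed = 8)
  tol <- 4 * sqrt(small$summary$sem_cv2^2 + large$summary$sem_cv2^2)
  expect_lt(abs(small$summary$cv2_T - large$summary$cv2_T), tol)
})

test_that("stage decomposition agrees with the fully coupled process", {
  spec <- identical_cascade(3, 0.05, 300, geo4(), mean_fpt = 24)
  dec <- sample_fpt_ensemble(spec, 1e4, seed = 9, mode = "decomposed")
  cou <- sample_fpt_ensemble(spec, 1e4, seed = 10, mode = "coupled")
  ks <- suppressWarnings(ks.test(dec$samples$total, cou$samples$total))
  expect_gt(ks$p.value, 0.01)
  # and per-stage marginals agree too
  ks1 <- suppressWarnings(ks.test(dec$samples$stage_2, cou$samples$stage_2))
  expect_gt(ks1$p.value, 0.01)
})

test_that("trajectory event log obeys exact decay and activation order", {
  spec <- cascade_spec(list(
    gene_spec(geo4(), steady_state = 400, relative_threshold = 0.4),
    gene_spec(geo4(), steady_state = 400, relative_threshold = 0.4)),
    dilution_rate = 0.05)
  set.seed(108)
  traj <- simulate_trajectory(spec, t_max = 120)
  ev <- traj$events
  expect_true(all(diff(ev$time) >= 0))
  expect_true(all(ev$level >= 0))
  # gene 2 bursts only after gene 1's crossing
  act2 <- traj$activation_times[2]
  expect_false(is.na(act2))
  expect_true(all(ev$time[ev$gene == 2] >= act2))
  cross1 <- ev[ev$gene == 1 & ev$event == "crossing", ]
  expect_equal(cross1$time, act2)
  expect_gte(cross1$level, 0.4 * 400)
  # between two bursts of gene 1 the level decays exactly exponentially
  b1 <- ev[ev$gene == 1 & ev$event == "burst", ]
  tt <- (b1$time[5] + b1$time[6]) / 2
  expect_equal(trajectory_levels(traj, 1, tt),
               b1$level[5] * exp(-0.05 * (tt - b1$time[5])), tolerance = 1e-12)
})

test_that("trajectory ensembles reproduce the transient moments", {
  g <- gene_spec(geo4(), steady_state = 200, relative_threshold = 0.99)
  spec <- cascade_spec(g, 0.05)
  set.seed(109)
  grid <- c(5, 10, 20, 40)
  nrep <- 800
  lev <- matrix(0, nrep, length(grid))
  for (r in seq_len(nrep)) {
    traj <- simulate_trajectory(spec, t_max = 41)
    lev[r, ] <- trajectory_levels(traj, 1, grid)
  }
  ref <- transient_moments(g, 0.05, grid)
  for (j in seq_along(grid)) {
    sem <- sd(lev[, j]) / sqrt(nrep)
    expect_lt(abs(mean(lev[, j]) - ref$mean[j]), 3 * sem)
    # variance of the sample variance via normal-ish approximation
    sev <- sd((lev[, j] - mean(lev[, j]))^2) / sqrt(nrep)
    expect_lt(abs(var(lev[, j]) - ref$variance[j]), 4 * sev)
  }
})

test_that("ensemble files round-trip through CSV and JSON", {
  spec <- identical_cascade(2, 0.05, 300, geo4(), mean_fpt = 20)
  ens <- sample_fpt_ensemble(spec, 200, seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_fpt_ensemble(ens, dir)
  long <- read.csv(file.path(dir, "fpt_samples.csv"))
  expect_equal(nrow(long), 400)  # replicates x stages
  expect_equal(sort(unique(long$stage)), 1:2)
  back <- long[long$stage == 1, "stage_time"]
  expect_equal(back, ens$samples$stage_1)
  summ <- jsonlite::read_json(file.path(dir, "fpt_summary.json"))
  expect_equal(summ$cv2_T, ens$summary$cv2_T, tolerance = 1e-12)
  expect_equal(summ$n, 200)
})
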