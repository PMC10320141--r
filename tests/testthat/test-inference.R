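test_that("expected marker frequency is the clamped product g * F", {
  expect_equal(expected_marker_freq(0.6, 0.5, eps = 0.001), 0.30)
  expect_equal(expected_marker_freq(0, 1, eps = 0.001), 0.001)
  expect_equal(expected_marker_freq(1, 1, eps = 0.001), 0.999)
  expect_equal(
    expected_marker_freq(c(0.2, 0.9), c(1 / 3, 1), eps = 0.002),
    c(0.2 / 3, 0.9)
  )
  expect_error(expected_marker_freq(1.2, 1), "\\[0, 1\\]")
})

test_that("log-likelihood matches an independent binomial computation", {
  model <- make_toy_model(
    tibble::tibble(lineage = "A", parent = NA_character_),
    tibble::tibble(lineage = "A", site = "s1", g_m = 1)
  )
  counts <- make_counts("s1", 30L, 100L)
  # independently: log C(100,30) + 30 log 0.3 + 70 log 0.7 = -2.4443349
  want <- lchoose(100, 30) + 30 * log(0.3) + 70 * log(0.7)
  got <- lineage_loglik(c(A = 0.3), model, counts, eps = 1e-12)
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(got, -2.4443349, tolerance = 1e-6)

  # the eps floor keeps boundary evaluations finite
  expect_true(is.finite(lineage_loglik(c(A = 0), model, counts, eps = 0.002)))
  expect_error(
    lineage_loglik(c(A = 0.3), model, make_counts("s1", 1L, 5L)),
    "no usable markers"
  )
})

test_that("scaling all counts leaves the maximizing frequency unchanged", {
  set.seed(5)
  model <- make_toy_model(
    tibble::tibble(lineage = "A", parent = NA_character_),
    tibble::tibble(lineage = "A", site = paste0("s", 1:5), g_m = c(1, 1, 0.5, 0.5, 1))
  )
  d <- rep(80L, 5)
  x <- as.integer(rbinom(5, d, 0.35 * model$markers$g_m))
  est1 <- infer_frequencies(model, make_counts(model$markers$site, x, d), seed = 2)
  est2 <- infer_frequencies(model, make_counts(model$markers$site, 2L * x, 2L * d), seed = 2)
  expect_equal(est1$frequency, est2$frequency, tolerance = 1e-4)
})

test_that("closed-form single-lineage maxima are recovered", {
  # all markers g = 1, pooled x/d = 0.3 -> F = 0.3
  m1 <- make_toy_model(
    tibble::tibble(lineage = "A", parent = NA_character_),
    tibble::tibble(lineage = "A", site = paste0("s", 1:3), g_m = 1)
  )
  est1 <- infer_frequencies(
    m1, make_counts(paste0("s", 1:3), c(30L, 28L, 32L), rep(100L, 3)),
    eps = 1e-6
  )
  expect_equal(est1$frequency, 0.300, tolerance = 1e-3)

  # all markers g = 1/2, pooled x/d = 0.2 -> F = 0.4
  m2 <- make_toy_model(
    tibble::tibble(lineage = "A", parent = NA_character_),
    tibble::tibble(lineage = "A", site = paste0("s", 1:2), g_m = 0.5)
  )
  est2 <- infer_frequencies(
    m2, make_counts(paste0("s", 1:2), c(20L, 20L), c(100L, 100L)),
    eps = 1e-6
  )
  expect_equal(est2$frequency, 0.400, tolerance = 1e-3)
})

test_that("parent-child tension resolves to the constrained optimum", {
  # parent markers pooled at 0.20, child at 0.30, equal evidence: the
  # constrained maximum ties the two at ~0.25
  model <- make_toy_model(
    tibble::tibble(lineage = c("P", "C"), parent = c(NA, "P")),
    tibble::tibble(
      lineage = rep(c("P", "C"), each = 4),
      site = paste0("s", 1:8), g_m = 1
    )
  )
  counts <- make_counts(
    paste0("s", 1:8),
    c(rep(20L, 4), rep(30L, 4)), rep(100L, 8)
  )
  est <- infer_frequencies(model, counts, eps = 1e-6, seed = 4)
  f <- setNames(est$frequency, est$lineage)
  expect_equal(unname(f["C"]), unname(f["P"]), tolerance = 1e-3)
  expect_equal(unname(f["P"]), 0.25, tolerance = 5e-3)
  # grid oracle at 0.005 resolution agrees on the achieved likelihood
  oracle <- grid_search_loglik(model, counts, eps = 1e-6, step = 0.005)
  expect_gte(attr(est, "loglik") + 1e-3, oracle)
})

test_that("optimizer matches exhaustive grid search on random small instances", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    est <- infer_frequencies(inst$model, inst$counts, eps = 0.002, seed = seed)
    oracle <- grid_search_loglik(inst$model, inst$counts, eps = 0.002)
    expect_gte(attr(est, "loglik") + 1e-3, oracle)
  }
})

test_that("estimates satisfy the nested-sum invariants", {
  for (seed in c(3, 9, 21)) {
    inst <- random_instance(seed)
    est <- infer_frequencies(inst$model, inst$counts, seed = seed)
    f <- setNames(est$frequency, est$lineage)
    expect_true(all(f >= 0 & f <= 1))
    for (i in seq_along(est$lineage)) {
      kids <- est$lineage[!is.na(est$parent) & est$parent == est$lineage[i]]
      expect_lte(sum(f[kids]), f[[est$lineage[i]]] + 1e-6)
    }
    expect_lte(sum(f[is.na(est$parent)]), 1 + 1e-6)
    expect_true(all(est$exclusive >= -1e-6))
    expect_gte(est$residual[1], -1e-6)
  }
})

test_that("exclusive frequencies and residual partition the population", {
  est <- tibble::tibble(
    timepoint = 0,
    lineage = c("root", "mid", "leaf"),
    parent = c(NA, "root", "mid"),
    frequency = c(0.9, 0.5, 0.2)
  )
  out <- exclusive_frequencies(est)
  expect_equal(out$exclusive, c(0.4, 0.3, 0.2))
  expect_equal(out$residual, rep(0.1, 3))
  expect_equal(sum(out$exclusive) + out$residual[1], 1)

  two <- tibble::tibble(
    timepoint = 0, lineage = c("r", "c"), parent = c(NA, "r"),
    frequency = c(1, 0.4)
  )
  out2 <- exclusive_frequencies(two)
  expect_equal(out2$exclusive, c(0.6, 0.4))
  expect_equal(out2$residual[1], 0)

  none <- tibble::tibble(
    timepoint = 0, lineage = "a", parent = NA_character_, frequency = 0
  )
  expect_equal(exclusive_frequencies(none)$residual, 1)

  broken <- tibble::tibble(
    timepoint = 0, lineage = c("r", "c"), parent = c(NA, "r"),
    frequency = c(0.2, 0.5)
  )
  expect_error(exclusive_frequencies(broken), "constraints violated")
})

test_that("trajectories are inferred independently per timepoint", {
  truth <- make_fixed_truth()
  model <- make_toy_model(
    dplyr::select(truth$lineages, "lineage", "parent"),
    truth$markers
  )
  vm <- purrr::map_dfr(seq_along(truth$timepoints), function(k) {
    sample_metagenome(truth, truth$timepoints[k],
      depth = 100, seed = 100 + k,
      sample_name = sprintf("m%02d", k)
    )
  })
  sheet <- tibble::tibble(
    sample = sprintf("m%02d", seq_along(truth$timepoints)),
    role = "metagenome", site_year = "sim", timepoint_days = truth$timepoints
  )
  est <- infer_trajectories(model, vm, sheet, seed = 5)
  sheet_perm <- sheet[rev(seq_len(nrow(sheet))), ]
  est_perm <- infer_trajectories(model, vm, sheet_perm, seed = 5)
  expect_equal(
    tibble::as_tibble(est)[, c("timepoint", "lineage", "frequency")],
    tibble::as_tibble(est_perm)[, c("timepoint", "lineage", "frequency")]
  )
  expect_equal(sort(unique(est$timepoint)), sort(truth$timepoints))

  # constant truth: per-timepoint scatter consistent with binomial noise.
  # With M markers of copy fraction g at depth d, the pooled estimator has
  # sd ~ sqrt(p(1-p) / (M d g^2)); allow a generous factor for clamping.
  f_hat <- est$frequency[est$lineage == "L1"]
  expect_equal(mean(f_hat), 0.45, tolerance = 0.03)
  g_bar <- mean(truth$markers$g_m[truth$markers$lineage == "L1"])
  sd_bound <- sqrt(0.45 * 0.55 / (12 * 100 * g_bar^2))
  expect_lt(sd(f_hat), 4 * sd_bound)
})

test_that("an invading lineage's inferred sweep crosses 0.5 on time", {
  # invader absent for the first half of the season, then sweeping along a
  # logistic curve that crosses 0.5 between timepoints 8 and 9
  truth <- make_fixed_truth(n_timepoints = 12)
  n_t <- 12
  sweep <- c(rep(0, 6), 0.02, 0.15, 0.45, 0.70, 0.85, 0.92)
  scale <- (1 - sweep) / 1 # remaining mass shared as at baseline
  traj <- truth$trajectories
  for (id in c("L1", "L2", "L3")) {
    rows <- traj$lineage == id
    traj$frequency[rows] <- traj$frequency[rows] * scale
    traj$exclusive[rows] <- traj$exclusive[rows] * scale
  }
  inv_rows <- tibble::tibble(
    timepoint = truth$timepoints, lineage = "INV",
    frequency = sweep, exclusive = sweep,
    residual = traj$residual[traj$lineage == "L1"] * scale
  )
  traj$residual <- rep(inv_rows$residual, 3)
  truth$trajectories <- dplyr::bind_rows(traj, inv_rows)
  truth$lineages <- dplyr::bind_rows(
    truth$lineages,
    tibble::tibble(
      lineage = "INV", parent = NA_character_, founder = "INV",
      ploidy = 2L, fitness = 0.8, origin_step = 6L
    )
  )
  inv_markers <- tibble::tibble(
    lineage = "INV", g_m = rep(c(1 / 2, 1), 6),
    site = sprintf("chrI:%d", 90000 + 1:12)
  )
  truth$markers <- dplyr::bind_rows(truth$markers, inv_markers)
  truth$sites <- dplyr::bind_rows(
    truth$sites,
    tibble::tibble(
      chrom = "chrI", pos = 90000L + 1:12, ref = "A", alt = "T",
      site = inv_markers$site
    )
  )

  model <- make_toy_model(
    dplyr::select(truth$lineages, "lineage", "parent"), truth$markers
  )
  vm <- purrr::map_dfr(seq_len(n_t), function(k) {
    sample_metagenome(truth, truth$timepoints[k],
      depth = 90, seed = 300 + k, sample_name = sprintf("m%02d", k)
    )
  })
  sheet <- tibble::tibble(
    sample = sprintf("m%02d", seq_len(n_t)), role = "metagenome",
    site_year = "sim", timepoint_days = truth$timepoints
  )
  est <- infer_trajectories(model, vm, sheet, seed = 6)
  inv_est <- tibble::as_tibble(est)[est$lineage == "INV", ]
  inv_est <- inv_est[order(inv_est$timepoint), ]
  expect_true(all(inv_est$frequency[1:6] < 0.05))
  cross_true <- which(sweep > 0.5)[1]
  cross_est <- which(inv_est$frequency > 0.5)[1]
  expect_lte(abs(cross_est - cross_true), 1)
})

test_that("cell-fraction conversion reweights by ploidy and renormalizes", {
  est <- tibble::tibble(
    timepoint = 0, lineage = c("a", "b"), parent = c(NA, NA),
    frequency = c(0.6, 0.4), exclusive = c(0.6, 0.4), residual = 0
  )
  out <- as_cell_fractions(est, c(a = 2, b = 3))
  w <- c(0.6 / 2, 0.4 / 3)
  expect_equal(out$cell_fraction, w / sum(w))
  expect_equal(sum(out$cell_fraction), 1)
  expect_error(as_cell_fractions(est, c(a = 2)), "no ploidy")
})
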