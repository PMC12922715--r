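# Synthetic data: feasible kappa range, correlated binary pairs, the trial
# table generator and its latent-difficulty structure, synthetic images.

test_that("feasible kappa range matches the Frechet bounds", {
  expect_equal(unname(feasible_kappa_range(0.5, 0.5)), c(-1, 1))
  expect_equal(feasible_kappa_range(0.7, 0.7)[["kappa_max"]], 1)
  expect_equal(feasible_kappa_range(0.3, 0.3)[["kappa_max"]], 1)
  # exhaustive check over all 2x2 tables with these marginals at n = 1000
  p1 <- 0.9; p2 <- 0.5; n <- 1000
  r <- p1 * n; c <- p2 * n
  n11 <- seq(max(0, r + c - n), min(r, c))
  kap <- vapply(n11, function(x) {
    cohens_kappa(contingency_counts(x, r - x, c - x, n - r - c + x))
  }, numeric(1))
  rng <- feasible_kappa_range(p1, p2)
  expect_equal(min(kap), rng[["kappa_min"]], tolerance = 1e-12)
  expect_equal(max(kap), rng[["kappa_max"]], tolerance = 1e-12)
})

test_that("binary pair simulation hits the degenerate corners exactly", {
  p <- simulate_binary_pair(0.7, 0.7, kappa_target = 1, n = 500, seed = 1)
  expect_identical(p$a, p$b)
  expect_equal(mean(p$a), 0.7, tolerance = 3 * sqrt(0.21 / 500))
  # independence: joint both-correct cell is p1 * p2
  p0 <- simulate_binary_pair(0.5, 0.5, kappa_target = 0, n = 2e4, seed = 2)
  cc <- count_contingency(p0)
  expect_lt(abs(cc$n11 / cc$n - 0.25), 3 * sqrt(0.25 * 0.75 / 2e4))
})

test_that("simulated pairs recover the target kappa within 3 SE", {
  p <- simulate_binary_pair(0.8, 0.7, kappa_target = 0.4, n = 1e5, seed = 3)
  bt <- bootstrap_kappa(p, n_resamples = 300, seed = 4)
  se <- (bt$upper - bt$lower) / 2
  expect_lt(abs(bt$point - 0.4), 3 * se)
})

test_that("infeasible targets raise a feasibility error naming the range", {
  expect_error(simulate_binary_pair(0.9, 0.5, kappa_target = 0.9, n = 10),
               class = "errcon_infeasible_kappa")
  expect_error(simulate_binary_pair(0.9, 0.5, kappa_target = 0.9, n = 10),
               "valid range")
})

test_that("the full default design yields the closed-form trial count", {
  des <- design_spec(observers = list(observer_skill("s1", "human")))
  tt <- simulate_trial_table(des, seed = 2)
  expect_equal(nrow(tt), 2 * 2 * (2 * 3 * 48 + 4 * 3 * 96))  # 5760
  expect_equal(sum(tt$is_practice), 2 * 2 * 6 * 3)  # 3 per block
  expect_gt(sum(tt$is_repeat), 0)
  expect_no_error(validate_trials(tt, design_frames = des$frames))
  # determinism under the root seed
  tt2 <- simulate_trial_table(des, seed = 2)
  expect_identical(tt, tt2)
  expect_false(identical(tt, simulate_trial_table(des, seed = 3)))
})

test_that("zero difficulty variance makes observers independent (kappa ~ 0)", {
  frames <- c(4L)
  des <- design_spec(
    frames = frames, corruptions = "noise", sessions = 1L,
    rounds_per_session = 1L, set_size = setNames(400L, frames),
    images_per_class = setNames(50L, frames),
    shared_per_class = setNames(50L, frames), practice_per_block = 0L,
    difficulty_sd = 0,
    observers = list(observer_skill("h1", "human", location = 3.2),
                     observer_skill("h2", "human", location = 3.4)))
  tt <- simulate_trial_table(des, seed = 31)
  ec <- ec_by_condition(tt, n_resamples = 300, seed = 1)
  se <- (ec$ci_high - ec$ci_low) / 2
  expect_lt(abs(ec$kappa), 3 * se)
})

test_that("error consistency grows with shared difficulty variance", {
  frames <- c(4L)
  kap <- vapply(c(0.3, 0.8, 1.5), function(sd_d) {
    des <- design_spec(
      frames = frames, corruptions = "noise", sessions = 1L,
      rounds_per_session = 1L, set_size = setNames(400L, frames),
      images_per_class = setNames(50L, frames),
      shared_per_class = setNames(50L, frames), practice_per_block = 0L,
      difficulty_sd = sd_d,
      observers = list(observer_skill("h1", "human", location = 3.2),
                       observer_skill("h2", "human", location = 3.4)))
    tt <- simulate_trial_table(des, seed = 17)
    ec_by_condition(tt)$kappa
  }, numeric(1))
  expect_true(all(diff(kap) > 0))
  expect_gt(kap[3], 0.2)
})

test_that("generator accuracies track the analytic psychometric values", {
  frames <- c(16L, 2L)
  des <- design_spec(
    frames = frames, corruptions = c("none", "lowpass"), sessions = 1L,
    rounds_per_session = 1L, set_size = setNames(c(320L, 320L), frames),
    images_per_class = setNames(c(40L, 40L), frames),
    shared_per_class = setNames(c(20L, 20L), frames),
    practice_per_block = 0L,
    observers = list(observer_skill("h1", "human")))
  tt <- simulate_trial_table(des, seed = 23)
  for (f in frames) {
    for (co in des$corruptions) {
      s <- correctness_series(tt, "h1", f, co)
      p <- analytic_accuracy(des$observers[[1]], f, co, des)
      expect_lt(abs(mean(s) - p), 3 * sqrt(p * (1 - p) / length(s)))
    }
  }
  # longer presentation time helps, corruption hurts
  expect_gt(analytic_accuracy(des$observers[[1]], 16, "none", des),
            analytic_accuracy(des$observers[[1]], 2, "none", des))
  expect_gt(analytic_accuracy(des$observers[[1]], 16, "none", des),
            analytic_accuracy(des$observers[[1]], 16, "lowpass", des))
})

test_that("a simulated model observer is consistent with models, not humans", {
  frames <- c(4L)
  des <- design_spec(
    frames = frames, corruptions = "noise", sessions = 1L,
    rounds_per_session = 1L, set_size = setNames(400L, frames),
    images_per_class = setNames(50L, frames),
    shared_per_class = setNames(50L, frames), practice_per_block = 0L,
    observers = list(observer_skill("h1", "human", location = 3.2),
                     observer_skill("h2", "human", location = 3.4),
                     observer_skill("m1", "model"),
                     observer_skill("m2", "model")))
  tt <- simulate_trial_table(des, seed = 29)
  ec <- ec_by_condition(tt, n_resamples = 300, seed = 6)
  pick <- function(a, b) ec[ec$observer_a == a & ec$observer_b == b, ]
  hh <- pick("h1", "h2"); mm <- pick("m1", "m2")
  expect_gt(hh$kappa, 0.1)
  expect_gt(mm$kappa, 0.1)
  for (r in list(pick("h1", "m1"), pick("h2", "m2"))) {
    expect_lt(abs(r$kappa), 3 * (r$ci_high - r$ci_low) / 2)
  }
})

test_that("synthetic images are seeded, in range, and spectrally ordered", {
  sm <- synth_image(32, 32, "smooth_field", seed = 5)
  rd <- synth_image(32, 32, "random", seed = 5)
  ed <- synth_image(32, 32, "edges", seed = 5)
  for (img in list(sm, rd, ed)) {
    expect_equal(dim(img), c(32, 32, 3))
    expect_gte(min(img), 0)
    expect_lte(max(img), 1)
  }
  expect_lt(laplacian_energy(sm[, , 1]), laplacian_energy(rd[, , 1]))
  expect_identical(synth_image(16, 16, "edges", seed = 2),
                   synth_image(16, 16, "edges", seed = 2))
})
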