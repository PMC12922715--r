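# Core agreement statistics: contingency tabulation, expected agreement
# from independent binomial marginals, Cohen's kappa, kappa_max, the
# accuracy-maintaining flip distance and the stability flag.

test_that("contingency counting tabulates the four joint outcomes", {
  cc <- count_contingency(binary_pair(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(c(cc$n11, cc$n10, cc$n01, cc$n00), c(1, 1, 1, 1))
  expect_equal(cc$n, 4L)

  cc2 <- count_contingency(binary_pair(c(1, 0, 1, 0), c(1, 0, 1, 0)))
  expect_equal(c(cc2$n11, cc2$n10, cc2$n01, cc2$n00), c(2, 0, 0, 2))

  # random length-50 pair against an exhaustive per-trial tally
  set.seed(42)
  a <- rbinom(50, 1, 0.6)
  b <- rbinom(50, 1, 0.45)
  cc3 <- count_contingency(binary_pair(a, b))
  tally <- c(0, 0, 0, 0)
  for (i in 1:50) {
    cell <- if (a[i] == 1 && b[i] == 1) 1 else if (a[i] == 1) 2 else
      if (b[i] == 1) 3 else 4
    tally[cell] <- tally[cell] + 1
  }
  expect_equal(c(cc3$n11, cc3$n10, cc3$n01, cc3$n00), tally)
})

test_that("misaligned or non-binary sequences are rejected", {
  expect_error(binary_pair(c(1, 0), c(1, 0, 1)), "aligned")
  expect_error(binary_pair(c(1, 2), c(1, 0)), "binary")
  expect_error(binary_pair(c(1, 0), c(1, 0), item_ids = c("a", "a")),
               "unique")
  expect_error(contingency_counts(-1, 0, 0, 2), "nonnegative")
})

test_that("expected agreement follows the independent-binomial model", {
  # symmetric half-half marginals give exactly chance level 0.5
  expect_equal(expected_agreement(contingency_counts(25, 25, 25, 25)), 0.5)
  expect_equal(marginal_expected_agreement(0.8, 0.6), 0.56)
  # near-ceiling marginals: p_e = 0.95125 at p1 = p2 = 0.975, and the
  # kappa denominator amplifies a changed answer by 1 / (1 - p_e)
  expect_equal(marginal_expected_agreement(0.975, 0.975), 0.95125)
  expect_equal(1 / (1 - 0.95), 20)
  expect_equal(1 / (1 - 0.95125), 20.5, tolerance = 0.002)
})

test_that("kappa reproduces the worked near-ceiling examples", {
  # balanced mid-accuracy pair: insensitive to one extra joint error
  expect_equal(round(cohens_kappa(contingency_counts(49, 1, 1, 49)), 2), 0.96)
  expect_equal(round(cohens_kappa(contingency_counts(49, 1, 1, 50)), 4), 0.9604)
  # near-ceiling pair: the same single trial moves kappa drastically
  expect_equal(round(cohens_kappa(contingency_counts(96, 1, 1, 1)), 2), 0.49)
  expect_equal(round(cohens_kappa(contingency_counts(96, 1, 1, 2)), 2), 0.66)
})

test_that("kappa is 1 iff sequences are identical and 0 at chance", {
  expect_equal(cohens_kappa(contingency_counts(2, 0, 0, 2)), 1.0)
  expect_equal(cohens_kappa(contingency_counts(25, 25, 25, 25)), 0)
  p <- binary_pair(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0))
  expect_equal(cohens_kappa(count_contingency(p)), 1.0)
  # any disagreement forces kappa < 1
  expect_lt(cohens_kappa(contingency_counts(3, 1, 0, 2)), 1.0)
})

test_that("independent observers yield kappa near zero (Monte-Carlo null)", {
  set.seed(7)
  a <- rbinom(1e5, 1, 0.7)
  b <- rbinom(1e5, 1, 0.7)
  expect_lt(abs(cohens_kappa(count_contingency(binary_pair(a, b)))), 0.02)
  # mean kappa over replicates at unequal marginals is 0 within 3 SE
  ks <- vapply(1:20, function(i) {
    set.seed(100 + i)
    cohens_kappa(count_contingency(
      binary_pair(rbinom(2000, 1, 0.6), rbinom(2000, 1, 0.8))))
  }, numeric(1))
  expect_lt(abs(mean(ks)), 3 * sd(ks) / sqrt(20))
})

test_that("degenerate marginals signal undefined kappa, never a silent 0", {
  expect_error(cohens_kappa(contingency_counts(5, 0, 0, 0)),
               class = "errcon_undefined_kappa")
  expect_error(cohens_kappa(contingency_counts(0, 0, 0, 5)),
               class = "errcon_undefined_kappa")
  expect_error(kappa_max(contingency_counts(5, 0, 0, 0)),
               class = "errcon_undefined_kappa")
  # one observer at ceiling but the other not: kappa is still defined
  expect_no_error(cohens_kappa(contingency_counts(3, 2, 0, 0)))
})

test_that("kappa_max is 1 iff marginals are equal, else the closed form", {
  expect_equal(kappa_max(contingency_counts(49, 1, 1, 49)), 1.0)
  # p1 = 0.8, p2 = 0.6: kappa_max = (0.8 - 0.56) / 0.44
  expect_equal(kappa_max(contingency_counts(50, 30, 10, 10)),
               (0.8 - 0.56) / 0.44)
  cnt <- contingency_counts(5, 3, 1, 1)
  expect_gte(kappa_max(cnt), cohens_kappa(cnt))
})

test_that("flip distance counts two flipped trials per accuracy-maintaining pair", {
  expect_equal(as.integer(flips_to_kappa_max(contingency_counts(2, 0, 0, 2))), 0L)
  expect_equal(as.integer(flips_to_kappa_max(contingency_counts(96, 1, 1, 1))), 2L)
  f <- flips_to_kappa_max(contingency_counts(5, 3, 1, 1))
  expect_equal(as.integer(f), 2L)
  expect_equal(attr(f, "pairs"), 1L)
  # applying the flip pair reaches kappa_max with marginals unchanged
  after <- contingency_counts(6, 2, 0, 2)
  expect_equal(marginal_accuracies(after),
               marginal_accuracies(contingency_counts(5, 3, 1, 1)))
  expect_equal(cohens_kappa(after), kappa_max(contingency_counts(5, 3, 1, 1)))
})

test_that("stability flag applies the flip threshold", {
  expect_false(stability_flag(contingency_counts(96, 1, 1, 1)))       # 2 < 10
  expect_true(stability_flag(contingency_counts(40, 10, 10, 40)))     # 20 >= 10
  expect_true(stability_flag(contingency_counts(96, 1, 1, 1), threshold = 0))
})

test_that("ceiling sensitivity: one extra joint error is drastic near ceiling only", {
  near <- cohens_kappa(contingency_counts(96, 1, 1, 1))
  near2 <- cohens_kappa(contingency_counts(96, 1, 1, 2))
  expect_gte(abs(near2 - near), 0.15)
  mid <- cohens_kappa(contingency_counts(49, 1, 1, 49))
  mid2 <- cohens_kappa(contingency_counts(49, 1, 1, 50))
  expect_lte(abs(mid2 - mid), 0.001)
})

test_that("agreement bundles all diagnostics consistently", {
  ag <- agreement(pair_from_counts(5, 3, 1, 1))
  expect_s3_class(ag, "ec_agreement")
  expect_equal(ag$n, 10L)
  expect_equal(ag$p_o, 0.6)
  expect_equal(ag$p_e, 0.56)
  expect_equal(ag$kappa, cohens_kappa(contingency_counts(5, 3, 1, 1)))
  expect_equal(ag$kappa_max, kappa_max(contingency_counts(5, 3, 1, 1)))
  expect_equal(ag$flip_distance, 2L)
  expect_false(ag$stable)
  expect_true(ag$defined)
  expect_output(print(ag), "kappa")
})
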