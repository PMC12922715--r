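# Trial table I/O, validation, and the filtering/grouping rules.

test_that("frames convert to ms at 120 Hz as in the design", {
  expect_equal(frames_to_ms(1), 8.33, tolerance = 0.005)
  expect_equal(frames_to_ms(2), 16.67, tolerance = 0.005)
  expect_equal(frames_to_ms(32), 266.67, tolerance = 0.005)
  expect_equal(frames_to_ms(12, refresh_hz = 60), 200)
})

test_that("trial tables round-trip through the delimited format", {
  tt <- miniature_study(5)
  path <- tempfile(fileext = ".tsv")
  write_trials(tt, path)
  back <- suppressMessages(read_trials(path, design_frames = c(2L, 16L)))
  attr(tt, "difficulty") <- NULL
  attr(tt, "difficulty2") <- NULL
  expect_equal(back, tt, tolerance = 1e-9)
  unlink(path)
})

test_that("a minimal hand-written file parses, NO_RESPONSE preserved", {
  path <- tempfile(fileext = ".tsv")
  hdr <- c("observer_id", "session", "round", "block", "set_index",
           "trial_index", "image_id", "true_class", "response_class",
           "presentation_frames", "presentation_ms", "corruption", "rt_ms",
           "is_practice", "is_repeat")
  rows <- c(
    paste(c("s1", 1, 1, 1, 1, 1, "im1", "dog", "dog", 4, 1000 * 4 / 120,
            "none", 512.3, FALSE, FALSE), collapse = "\t"),
    paste(c("s1", 1, 1, 1, 1, 2, "im2", "car", "boat", 4, 1000 * 4 / 120,
            "none", 633.1, FALSE, FALSE), collapse = "\t"),
    paste(c("s1", 1, 1, 1, 1, 3, "im3", "bird", "NO_RESPONSE", 4,
            1000 * 4 / 120, "none", NA, FALSE, FALSE), collapse = "\t"))
  writeLines(c(paste(hdr, collapse = "\t"), rows), path)
  tt <- suppressMessages(read_trials(path))
  expect_equal(nrow(tt), 3L)
  expect_equal(tt$response_class[3], NO_RESPONSE)
  expect_true(is.na(tt$rt_ms[3]))
  unlink(path)
})

test_that("schema violations are reported with offending rows", {
  tt <- miniature_study(6)
  bad <- tt
  bad$true_class[2] <- "cat"
  expect_error(validate_trials(bad, design_frames = c(2L, 16L)),
               "unknown true_class.*row")
  bad2 <- tt
  bad2$presentation_frames[5] <- 7L
  expect_error(validate_trials(bad2, design_frames = c(2L, 16L)),
               "design set")
  bad3 <- tt
  bad3$presentation_ms[1] <- bad3$presentation_ms[1] + 1
  expect_error(validate_trials(bad3, design_frames = c(2L, 16L)),
               "inconsistent")
  expect_error(validate_trials(tt[, -3], design_frames = c(2L, 16L)),
               "missing required column")
})

test_that("practice filtering removes exactly the flagged rows", {
  tt <- miniature_study(7)
  n_prac <- sum(tt$is_practice)
  expect_gt(n_prac, 0)
  out <- suppressMessages(filter_practice(tt))
  expect_equal(nrow(out), nrow(tt) - n_prac)
  expect_false(any(out$is_practice))
  # idempotent
  expect_equal(suppressMessages(filter_practice(out)), out)
})

test_that("median split keeps the faster half with ties going fast", {
  base <- data.frame(
    observer_id = "s1", presentation_frames = 4L, corruption = "none",
    rt_ms = c(100, 200, 300, 400), stringsAsFactors = FALSE)
  fast <- median_split_by_rt(base, keep = "faster")
  expect_equal(sort(fast$rt_ms), c(100, 200))
  slow <- median_split_by_rt(base, keep = "slower")
  expect_equal(sort(slow$rt_ms), c(300, 400))
  odd <- base[1:3, ]
  fast_odd <- median_split_by_rt(odd, keep = "faster")
  expect_equal(sort(fast_odd$rt_ms), c(100, 200))  # median row goes fast
})

test_that("median split is computed within observer-condition cells", {
  tt <- rbind(
    data.frame(observer_id = "s1", presentation_frames = 4L,
               corruption = "none", rt_ms = c(100, 200, 300, 400)),
    data.frame(observer_id = "s1", presentation_frames = 16L,
               corruption = "none", rt_ms = c(1000, 2000, 3000, 4000)))
  fast <- median_split_by_rt(tt, keep = "faster")
  # each cell keeps its own faster half, not a global split
  expect_equal(sort(fast$rt_ms), c(100, 200, 1000, 2000))
  # faster-half median below the full median on skewed RTs
  set.seed(4)
  big <- data.frame(observer_id = "s1", presentation_frames = 4L,
                    corruption = "noise",
                    rt_ms = 150 + rlnorm(500, log(400), 0.4))
  f <- median_split_by_rt(big, keep = "faster")
  expect_lt(median(f$rt_ms), median(big$rt_ms))
  # all-missing cell is skipped with a warning
  miss <- data.frame(observer_id = "s2", presentation_frames = 4L,
                     corruption = "none", rt_ms = NA_real_)
  expect_warning(median_split_by_rt(miss, keep = "faster"), "skipped")
})

test_that("correctness series aligns by image and honours the miss rule", {
  tt <- data.frame(
    observer_id = "s1", session = 1L, round = 1L, block = 1L, set_index = 1L,
    trial_index = 1:4, image_id = c("i3", "i1", "i4", "i2"),
    true_class = c("dog", "car", "bird", "bear"),
    response_class = c("dog", "car", "boat", "bear"),
    presentation_frames = 4L, presentation_ms = frames_to_ms(4),
    corruption = "none", rt_ms = 500, is_practice = FALSE, is_repeat = FALSE,
    stringsAsFactors = FALSE)
  s <- correctness_series(tt, "s1", 4, "none")
  expect_equal(names(s), c("i1", "i2", "i3", "i4"))
  expect_equal(unname(s), c(1L, 1L, 1L, 0L))
  # a missed deadline counts as incorrect by default, excluded on request
  tt$response_class[1] <- NO_RESPONSE
  expect_equal(unname(correctness_series(tt, "s1", 4, "none")["i3"]), 0L)
  expect_false("i3" %in% names(
    correctness_series(tt, "s1", 4, "none", no_response = "exclude")))
  # unflagged duplicates are malformed
  dup <- rbind(tt, tt[1, ])
  dup$trial_index[5] <- 5L
  expect_error(correctness_series(dup, "s1", 4, "none"), "duplicate")
})

test_that("series from the generator reproduce its per-condition accuracy", {
  frames <- c(4L)
  des <- design_spec(
    frames = frames, corruptions = "noise", sessions = 1L,
    rounds_per_session = 1L, set_size = setNames(400L, frames),
    images_per_class = setNames(50L, frames),
    shared_per_class = setNames(50L, frames), practice_per_block = 0L,
    observers = list(observer_skill("s1", "human")))
  tt <- simulate_trial_table(des, seed = 8)
  s <- correctness_series(tt, "s1", 4, "noise")
  p <- analytic_accuracy(des$observers[[1]], 4, "noise", des)
  expect_lt(abs(mean(s) - p), 3 * sqrt(p * (1 - p) / length(s)))
})

test_that("repeat presentations feed the self-consistency pair", {
  tt <- miniature_study(9)
  expect_gt(sum(tt$is_repeat), 0)
  rp <- repeat_pair(tt, "s1", 16, "none")
  expect_s3_class(rp, "ec_pair")
  expect_equal(length(rp$a), length(rp$b))
  # self-consistency kappa is computable with the usual machinery
  expect_no_error(agreement(rp))
})
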