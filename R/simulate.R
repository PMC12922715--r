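# Synthetic inputs for the whole pipeline: correlated binary observer pairs
# with a target kappa, full trial tables driven by a latent image-difficulty
# model, and seeded test images.  Everything is reproducible from one root
# seed with a fixed draw order (image allocation and difficulties first,
# then each observer's trials in observer order).

#' Feasible kappa range at given marginal accuracies
#'
#' The joint probability of both observers being correct is constrained by
#' the Frechet bounds, `p11` in `[max(0, p1 + p2 - 1), min(p1, p2)]`.
#' Mapping the two extremes through the kappa formula (with
#' `p_o = 1 - p1 - p2 + 2 p11`) gives the attainable kappa interval.
#'
#' @param p1,p2 marginal accuracies, strictly inside (0, 1).
#' @return Named vector `c(kappa_min, kappa_max)`.  `kappa_max = 1` iff
#'   `p1 == p2`.
#' @export
feasible_kappa_range <- function(p1, p2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  p_e <- marginal_expected_agreement(p1, p2)
  p11 <- c(max(0, p1 + p2 - 1), min(p1, p2))
  p_o <- 1 - p1 - p2 + 2 * p11
  k <- (p_o - p_e) / (1 - p_e)
  c(kappa_min = k[1L], kappa_max = k[2L])
}

#' Simulate a correlated binary observer pair with target kappa
#'
#' Inverts the kappa formula: the observed agreement implied by the target
#' is `p_o = kappa (1 - p_e) + p_e`, the both-correct cell is
#' `p11 = (p_o + p1 + p2 - 1) / 2`, and each trial is drawn independently
#' from the resulting 2x2 joint distribution.  The expected sample kappa
#' equals `kappa_target`.
#'
#' @param p1,p2 marginal accuracies in (0, 1).
#' @param kappa_target target kappa, inside [feasible_kappa_range()].
#' @param n number of trials.
#' @param seed integer seed.
#' @return A [binary_pair()] of length `n`.
#' @export
simulate_binary_pair <- function(p1, p2, kappa_target, n, seed = NULL) {
  stopifnot(n >= 1)
  rng <- feasible_kappa_range(p1, p2)
  tol <- 1e-12
  if (kappa_target < rng[1L] - tol || kappa_target > rng[2L] + tol) {
    stop(structure(class = c("errcon_infeasible_kappa", "error", "condition"),
                   list(message = sprintf(
                          "kappa_target %.4f infeasible at p1 = %.3f, p2 = %.3f; valid range [%.4f, %.4f]",
                          kappa_target, p1, p2, rng[1L], rng[2L]),
                        call = NULL)))
  }
  p_e <- marginal_expected_agreement(p1, p2)
  p_o <- kappa_target * (1 - p_e) + p_e
  p11 <- (p_o + p1 + p2 - 1) / 2
  cell <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
  cell <- pmax(cell, 0)  # guard tiny negative rounding at the boundary
  cell <- cell / sum(cell)
  draw <- with_seed(seed, sample.int(4L, n, replace = TRUE, prob = cell))
  a <- as.integer(draw %in% c(1L, 2L))
  b <- as.integer(draw %in% c(1L, 3L))
  binary_pair(a, b)
}

#' Observer skill specification for the trial-table generator
#'
#' Each simulated observer responds according to a reverse-Gumbel
#' psychometric function of log presentation time whose location is shifted
#' by the corruption condition and by a per-image latent difficulty.
#' Human-like observers load fully on the shared difficulty axis
#' (`difficulty_loading = 1`), which is what produces above-chance
#' between-observer error consistency; "model"-like observers can load on
#' an independent second axis instead (`difficulty_loading = 0`), making
#' them consistent with each other but not with the humans.  Intermediate
#' loadings interpolate.
#'
#' @param name observer id.
#' @param type `"human"` or `"model"` (grouping label only).
#' @param location psychometric location in log-ms.
#' @param scale psychometric scale (> 0).
#' @param lapse lapse rate.
#' @param corruption_shift named vector of location shifts per corruption.
#' @param difficulty_loading loading in \[0, 1\] on the shared difficulty
#'   axis; the residual loading `sqrt(1 - loading^2)` goes on the
#'   independent axis.
#' @param rt_shift,rt_median,rt_sd shifted-lognormal reaction-time model:
#'   `rt = rt_shift + Lognormal(meanlog = log(rt_median(frames) - rt_shift),
#'   sdlog = rt_sd)`.
#' @return Object of class `"ec_observer"`.
#' @export
observer_skill <- function(name, type = c("human", "model"),
                           location = 3.3, scale = 0.6, lapse = 0.02,
                           corruption_shift = c(none = 0, noise = 0.35,
                                                lowpass = 0.55,
                                                grayscale = 0.15),
                           difficulty_loading = if (type[1L] == "human") 1 else 0,
                           rt_shift = 150, rt_median = 400, rt_sd = 0.25) {
  type <- match.arg(type)
  stopifnot(scale > 0, lapse >= 0, lapse < 0.5,
            difficulty_loading >= 0, difficulty_loading <= 1,
            rt_shift >= 0, rt_median > rt_shift)
  structure(list(name = name, type = type, location = location,
                 scale = scale, lapse = lapse,
                 corruption_shift = corruption_shift,
                 difficulty_loading = difficulty_loading,
                 rt_shift = rt_shift, rt_median = rt_median, rt_sd = rt_sd),
            class = "ec_observer")
}

#' Design specification for a synthetic study
#'
#' Defaults reproduce the experiment structure of the speeded 8-way
#' identification study: 8 classes, six presentation times
#' (1 to 32 frames at 120 Hz), three corruption sets per block in fixed
#' order (none, noise, lowpass), two sessions of two rounds, 48 images per
#' set at the extreme times and 96 otherwise (so each observer completes
#' `2 * 2 * (2 * 3 * 48 + 4 * 3 * 96) = 5760` trials), 88 images allocated
#' per class and time (44 at the extremes) of which 22 (11) are shared
#' across corruptions, and three practice trials at the start of each
#' block's uncorrupted set.
#'
#' @param classes category labels.
#' @param frames presentation-time design set, in block order (longest
#'   first by default).
#' @param corruptions corruption sets per block, in presentation order.
#' @param sessions,rounds_per_session experiment structure.
#' @param set_size named vector: images presented per set, keyed by frames.
#' @param images_per_class named vector: images allocated per class and
#'   time, keyed by frames.
#' @param shared_per_class named vector: images per class shared across all
#'   corruptions, keyed by frames.
#' @param practice_per_block practice trials at the start of each block.
#' @param difficulty_sd standard deviation of the latent per-image
#'   difficulty (log-time location-shift units).
#' @param p_no_response probability of missing the response deadline.
#' @param refresh_hz display refresh rate.
#' @param observers list of [observer_skill()] objects.
#' @return Object of class `"ec_design"`.
#' @export
design_spec <- function(classes = SUPERCLASSES,
                        frames = c(32L, 16L, 8L, 4L, 2L, 1L),
                        corruptions = c("none", "noise", "lowpass"),
                        sessions = 2L, rounds_per_session = 2L,
                        set_size = NULL, images_per_class = NULL,
                        shared_per_class = NULL,
                        practice_per_block = 3L,
                        difficulty_sd = 0.8,
                        p_no_response = 0.01,
                        refresh_hz = 120,
                        observers = default_observers()) {
  extremes <- frames %in% range(frames) & length(frames) > 1L
  if (is.null(set_size)) {
    set_size <- stats::setNames(ifelse(extremes, 48L, 96L), frames)
  }
  if (is.null(images_per_class)) {
    images_per_class <- stats::setNames(ifelse(extremes, 44L, 88L), frames)
  }
  if (is.null(shared_per_class)) {
    shared_per_class <- stats::setNames(ifelse(extremes, 11L, 22L), frames)
  }
  for (v in list(set_size, images_per_class, shared_per_class)) {
    stopifnot(!is.null(names(v)), all(as.character(frames) %in% names(v)),
              all(v >= 1))
  }
  stopifnot(all(shared_per_class[as.character(frames)] <=
                  images_per_class[as.character(frames)]),
            all(corruptions %in% CORRUPTION_LEVELS),
            sessions >= 1L, rounds_per_session >= 1L,
            practice_per_block >= 0L, difficulty_sd >= 0,
            p_no_response >= 0, p_no_response < 1,
            length(observers) >= 1L)
  structure(list(classes = classes, frames = frames,
                 corruptions = corruptions, sessions = sessions,
                 rounds_per_session = rounds_per_session,
                 set_size = set_size, images_per_class = images_per_class,
                 shared_per_class = shared_per_class,
                 practice_per_block = practice_per_block,
                 difficulty_sd = difficulty_sd,
                 p_no_response = p_no_response,
                 refresh_hz = refresh_hz, observers = observers),
            class = "ec_design")
}

default_observers <- function() {
  list(observer_skill("s1", "human", location = 3.15, scale = 0.55),
       observer_skill("s2", "human", location = 3.30, scale = 0.60),
       observer_skill("s3", "human", location = 3.45, scale = 0.65))
}

# Probability of a correct response for one observer on one trial.
observer_p_correct <- function(obs, time_ms, corruption, difficulty,
                               guess_rate = 1 / 8) {
  shift <- obs$corruption_shift[[corruption]]
  if (is.null(shift)) shift <- 0
  loc <- obs$location + shift + difficulty
  guess_rate + (1 - guess_rate - obs$lapse) *
    reverse_gumbel_cdf(log(time_ms), loc, obs$scale)
}

# Median RT in ms as a function of frames: faster at longer presentation
# times, except a fast guessing bump at the single-frame condition.
rt_median_ms <- function(obs, frames, max_frames) {
  if (frames <= 1L) return(obs$rt_median - 20)
  obs$rt_median + 30 * (log2(max_frames) - log2(frames))
}

#' Simulate a full synthetic trial table
#'
#' Builds the complete study: image pools per time and corruption (with the
#' shared-image structure), one latent difficulty per image drawn once and
#' shared across observers, and per-trial responses where the probability
#' of a correct answer follows each observer's psychometric function of
#' presentation time, corruption, and image difficulty.  Wrong responses
#' are uniform over the other 7 classes; reaction times follow a shifted
#' lognormal; a small fraction of trials misses the response deadline
#' (`NO_RESPONSE`).  Sets that present more trials than the pool holds
#' re-show images, flagged `is_repeat`; the first `practice_per_block`
#' trials of each block's first uncorrupted set are flagged `is_practice`.
#'
#' @param design an [design_spec()] object.
#' @param seed root seed; the whole table is reproducible from it.
#' @return A validated trial table (see [validate_trials()]) with the
#'   per-image difficulties attached as attribute `"difficulty"` (and the
#'   independent model-axis difficulties as `"difficulty2"`).
#' @export
simulate_trial_table <- function(design, seed = 1L) {
  stopifnot(inherits(design, "ec_design"))
  with_seed(seed, simulate_trial_table_impl(design))
}

simulate_trial_table_impl <- function(design) {
  frames_chr <- as.character(design$frames)
  n_corr <- length(design$corruptions)
  # --- image allocation: per (time, corruption) pools with shared images
  pools <- list()
  all_images <- character()
  for (f in frames_chr) {
    n_img <- design$images_per_class[[f]]
    n_shared <- design$shared_per_class[[f]]
    nonshared_per_corr <- (n_img - n_shared) %/% n_corr
    for (cls in design$classes) {
      ids <- sprintf("f%02d_%s_%03d", as.integer(f), cls, seq_len(n_img))
      all_images <- c(all_images, ids)
      shared <- ids[seq_len(n_shared)]
      for (ci in seq_len(n_corr)) {
        co <- design$corruptions[ci]
        extra <- if (nonshared_per_corr > 0) {
          ids[n_shared + ((ci - 1L) * nonshared_per_corr + 1L):
                (ci * nonshared_per_corr)]
        } else character()
        key <- paste(f, co, sep = "|")
        pools[[key]] <- c(pools[[key]], shared, extra)
      }
    }
  }
  # --- latent difficulties: shared axis and independent model axis
  difficulty <- stats::setNames(
    stats::rnorm(length(all_images), 0, design$difficulty_sd), all_images)
  difficulty2 <- stats::setNames(
    stats::rnorm(length(all_images), 0, design$difficulty_sd), all_images)
  max_frames <- max(design$frames)
  rows <- list()
  for (obs in design$observers) {
    # per-condition presentation queues: shuffled pool, recycled when a
    # set needs more images than the pool holds (those re-shows are the
    # repeat presentations)
    queues <- lapply(pools, sample)
    cursor <- stats::setNames(rep(1L, length(queues)), names(queues))
    seen <- lapply(pools, function(p) character())
    trial_i <- 0L
    for (sess in seq_len(design$sessions)) {
      for (rnd in seq_len(design$rounds_per_session)) {
        for (bi in seq_along(design$frames)) {
          f <- design$frames[bi]
          f_chr <- as.character(f)
          t_ms <- frames_to_ms(f, design$refresh_hz)
          n_set <- design$set_size[[f_chr]]
          for (si in seq_len(n_corr)) {
            co <- design$corruptions[si]
            key <- paste(f_chr, co, sep = "|")
            pool_len <- length(queues[[key]])
            imgs <- character(0)
            pos <- cursor[[key]]
            while (length(imgs) < n_set) {
              if (pos > pool_len) {
                queues[[key]] <- sample(queues[[key]])
                pos <- 1L
              }
              imgs <- c(imgs, queues[[key]][pos])
              pos <- pos + 1L
            }
            cursor[[key]] <- pos
            is_rep <- imgs %in% seen[[key]] | duplicated(imgs)
            seen[[key]] <- unique(c(seen[[key]], imgs))
            true_cls <- sub("^f[0-9]+_([a-z]+)_[0-9]+$", "\\1", imgs)
            load <- obs$difficulty_loading
            d_eff <- load * difficulty[imgs] +
              sqrt(1 - load^2) * difficulty2[imgs]
            p_corr <- observer_p_correct(obs, t_ms, co, d_eff,
                                         guess_rate = 1 / length(design$classes))
            correct <- stats::runif(n_set) < p_corr
            resp <- true_cls
            wrong_idx <- which(!correct)
            if (length(wrong_idx)) {
              resp[wrong_idx] <- vapply(true_cls[wrong_idx], function(tc) {
                sample(setdiff(design$classes, tc), 1L)
              }, character(1))
            }
            rt_med <- rt_median_ms(obs, f, max_frames)
            rt <- obs$rt_shift + stats::rlnorm(n_set,
                                               log(rt_med - obs$rt_shift),
                                               obs$rt_sd)
            missed <- stats::runif(n_set) < design$p_no_response
            resp[missed] <- NO_RESPONSE
            rt[missed] <- NA_real_
            practice <- rep(FALSE, n_set)
            if (si == 1L && design$practice_per_block > 0L) {
              practice[seq_len(min(design$practice_per_block, n_set))] <- TRUE
            }
            rows[[length(rows) + 1L]] <- data.frame(
              observer_id = obs$name, session = sess, round = rnd,
              block = bi, set_index = si,
              trial_index = trial_i + seq_len(n_set),
              image_id = imgs, true_class = true_cls, response_class = resp,
              presentation_frames = f, presentation_ms = t_ms,
              corruption = co, rt_ms = rt, is_practice = practice,
              is_repeat = is_rep, stringsAsFactors = FALSE)
            trial_i <- trial_i + n_set
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_trials(out, design_frames = design$frames,
                  refresh_hz = design$refresh_hz)
  attr(out, "difficulty") <- difficulty
  attr(out, "difficulty2") <- difficulty2
  out
}

#' Analytic error consistency implied by the generator
#'
#' For two simulated observers in one condition, the per-image correctness
#' probabilities are conditionally independent given the latent
#' difficulties, so the joint both-correct probability is the expectation
#' of the product of the two psychometric functions over the difficulty
#' distribution.  The expectation is computed by Gauss-Hermite quadrature
#' over the shared axis (and the independent axis when either observer
#' loads on it), and mapped through the kappa formula.  Trials lost to the
#' response deadline are folded in as incorrect with probability
#' `p_no_response`, matching the pipeline's default handling.
#'
#' @param obs_a,obs_b [observer_skill()] objects.
#' @param frames presentation frames.
#' @param corruption corruption label.
#' @param design the [design_spec()] (for difficulty_sd, class count,
#'   deadline probability, refresh rate).
#' @param n_nodes quadrature nodes per axis.
#' @return List with `kappa`, `p1`, `p2`, `p11`, `p_o`, `p_e`.
#' @export
analytic_condition_kappa <- function(obs_a, obs_b, frames, corruption,
                                     design, n_nodes = 41L) {
  t_ms <- frames_to_ms(frames, design$refresh_hz)
  guess <- 1 / length(design$classes)
  sd <- design$difficulty_sd
  gh <- gauss_hermite(n_nodes)
  q_miss <- design$p_no_response  # deadline misses are independent, scored wrong
  psi <- function(obs, d1, d2) {
    load <- obs$difficulty_loading
    d <- load * d1 + sqrt(1 - load^2) * d2
    (1 - q_miss) * observer_p_correct(obs, t_ms, corruption, d, guess)
  }
  needs_d2 <- obs_a$difficulty_loading < 1 || obs_b$difficulty_loading < 1
  if (sd == 0) {
    p1 <- psi(obs_a, 0, 0); p2 <- psi(obs_b, 0, 0); p11 <- p1 * p2
  } else if (!needs_d2) {
    d <- gh$nodes * sd
    pa <- psi(obs_a, d, 0)
    pb <- psi(obs_b, d, 0)
    p1 <- sum(gh$weights * pa)
    p2 <- sum(gh$weights * pb)
    p11 <- sum(gh$weights * pa * pb)
  } else {
    d1 <- gh$nodes * sd
    d2 <- gh$nodes * sd
    w2 <- outer(gh$weights, gh$weights)
    pa <- outer(d1, d2, function(x, y) psi(obs_a, x, y))
    pb <- outer(d1, d2, function(x, y) psi(obs_b, x, y))
    p1 <- sum(w2 * pa)
    p2 <- sum(w2 * pb)
    p11 <- sum(w2 * pa * pb)
  }
  p_o <- 1 - p1 - p2 + 2 * p11
  p_e <- marginal_expected_agreement(p1, p2)
  list(kappa = (p_o - p_e) / (1 - p_e), p1 = p1, p2 = p2, p11 = p11,
       p_o = p_o, p_e = p_e)
}

# Gauss-Hermite nodes/weights for E[f(Z)], Z ~ N(0, 1) (probabilists'
# normalisation), via the Golub-Welsch eigendecomposition.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  jac <- matrix(0, n, n)
  jac[cbind(i, i + 1L)] <- sqrt(i)
  jac[cbind(i + 1L, i)] <- sqrt(i)
  eig <- eigen(jac, symmetric = TRUE)
  list(nodes = eig$values, weights = eig$vectors[1L, ]^2)
}

#' Analytic accuracy of a simulated observer in one condition
#'
#' @inheritParams analytic_condition_kappa
#' @param obs an [observer_skill()] object.
#' @return Expected proportion correct (deadline misses counted wrong).
#' @export
analytic_accuracy <- function(obs, frames, corruption, design,
                              n_nodes = 41L) {
  t_ms <- frames_to_ms(frames, design$refresh_hz)
  guess <- 1 / length(design$classes)
  sd <- design$difficulty_sd
  if (sd == 0) {
    p <- observer_p_correct(obs, t_ms, corruption, 0, guess)
  } else {
    gh <- gauss_hermite(n_nodes)
    p <- sum(gh$weights *
               observer_p_correct(obs, t_ms, corruption, gh$nodes * sd, guess))
  }
  (1 - design$p_no_response) * p
}

#' A complete miniature synthetic study
#'
#' Two human-like observers, two presentation times, two corruptions, and a
#' 40-image pool per time; runs in well under a second and exercises every
#' downstream stage.
#'
#' @param seed root seed.
#' @return A trial table.
#' @export
miniature_study <- function(seed = 1L) {
  frames <- c(16L, 2L)
  design <- design_spec(
    frames = frames, corruptions = c("none", "noise"),
    sessions = 1L, rounds_per_session = 1L,
    set_size = stats::setNames(c(40L, 40L), frames),
    images_per_class = stats::setNames(c(5L, 5L), frames),
    shared_per_class = stats::setNames(c(3L, 3L), frames),
    practice_per_block = 3L,
    observers = list(observer_skill("s1", "human", location = 3.1),
                     observer_skill("s2", "human", location = 3.3)))
  simulate_trial_table(design, seed = seed)
}

#' Seeded synthetic test images
#'
#' `"smooth_field"` superimposes a few low-frequency sinusoidal gratings
#' (low Laplacian energy), `"edges"` draws random axis-aligned intensity
#' steps, and `"random"` is i.i.d. uniform pixel noise.
#'
#' @param height,width dimensions (>= 8).
#' @param kind `"smooth_field"`, `"edges"` or `"random"`.
#' @param seed integer seed.
#' @return `height x width x 3` array with values in \[0, 1\].
#' @export
synth_image <- function(height, width,
                        kind = c("smooth_field", "edges", "random"),
                        seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(height >= 8L, width >= 8L)
  with_seed(seed, {
    ch <- function() {
      switch(kind,
        random = matrix(stats::runif(height * width), height, width),
        smooth_field = {
          y <- seq_len(height) / height
          x <- seq_len(width) / width
          field <- matrix(0, height, width)
          for (i in 1:3) {
            fy <- stats::runif(1, 0.5, 3)
            fx <- stats::runif(1, 0.5, 3)
            ph <- stats::runif(2, 0, 2 * pi)
            field <- field + outer(sin(2 * pi * fy * y + ph[1L]),
                                   sin(2 * pi * fx * x + ph[2L]))
          }
          (field - min(field)) / (max(field) - min(field))
        },
        edges = {
          field <- matrix(stats::runif(1), height, width)
          for (i in 1:4) {
            v <- stats::runif(1)
            if (stats::runif(1) < 0.5) {
              r <- sample.int(height - 1L, 1L)
              field[seq_len(r), ] <- v
            } else {
              cidx <- sample.int(width - 1L, 1L)
              field[, seq_len(cidx)] <- v
            }
          }
          field
        })
    }
    if (kind == "random") {
      array(stats::runif(height * width * 3L), dim = c(height, width, 3L))
    } else {
      array(rep(ch(), 3L), dim = c(height, width, 3L))
    }
  })
}
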