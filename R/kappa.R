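# Error consistency: Cohen's kappa on trial-level correctness, with the
# expected agreement derived from independent binomial observers, plus the
# stability diagnostics (kappa_max, accuracy-maintaining flip distance).

#' Aligned binary outcome pair
#'
#' Bundle two observers' correctness sequences recorded on the same items,
#' aligned by position.  Outcomes may be logical or 0/1 numeric.
#'
#' @param outcomes_a,outcomes_b correctness flags (logical or 0/1), equal
#'   length, aligned by item.
#' @param item_ids optional unique item identifiers; defaults to positions.
#' @return An object of class `"ec_pair"`: a list with `items`, `a`, `b`.
#' @examples
#' binary_pair(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
binary_pair <- function(outcomes_a, outcomes_b, item_ids = NULL) {
  a <- as_binary(outcomes_a, "outcomes_a")
  b <- as_binary(outcomes_b, "outcomes_b")
  if (length(a) != length(b)) {
    stop("outcomes_a and outcomes_b differ in length (", length(a), " vs ",
         length(b), "); sequences must be aligned by item", call. = FALSE)
  }
  if (length(a) < 1L) stop("need at least one trial", call. = FALSE)
  if (is.null(item_ids)) item_ids <- seq_along(a)
  if (length(item_ids) != length(a)) {
    stop("item_ids length does not match the outcome sequences", call. = FALSE)
  }
  if (anyDuplicated(item_ids)) {
    stop("item_ids must be unique", call. = FALSE)
  }
  structure(list(items = item_ids, a = a, b = b), class = "ec_pair")
}

as_binary <- function(x, what) {
  if (is.logical(x)) x <- as.integer(x)
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop(what, " must be binary (0/1 or logical) with no missing values",
         call. = FALSE)
  }
  x
}

#' Construct a 2x2 correctness contingency table
#'
#' @param n11 trials both observers answered correctly.
#' @param n10 trials only observer A answered correctly.
#' @param n01 trials only observer B answered correctly.
#' @param n00 trials both observers answered incorrectly.
#' @return An object of class `"ec_counts"`.
#' @export
contingency_counts <- function(n11, n10, n01, n00) {
  v <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  v <- stats::setNames(as.integer(round(v)), names(v))
  n <- sum(v)
  if (n < 1L) stop("contingency table must contain at least one trial",
                   call. = FALSE)
  structure(list(n11 = v[["n11"]], n10 = v[["n10"]], n01 = v[["n01"]],
                 n00 = v[["n00"]], n = n),
            class = "ec_counts")
}

#' Tabulate joint correctness of an aligned pair
#'
#' @param pair an [binary_pair()] object.
#' @return [contingency_counts()] of the four joint outcomes.
#' @examples
#' count_contingency(binary_pair(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' @export
count_contingency <- function(pair) {
  stopifnot(inherits(pair, "ec_pair"))
  a <- pair$a
  b <- pair$b
  contingency_counts(n11 = sum(a == 1L & b == 1L),
                     n10 = sum(a == 1L & b == 0L),
                     n01 = sum(a == 0L & b == 1L),
                     n00 = sum(a == 0L & b == 0L))
}

as_counts <- function(x) {
  if (inherits(x, "ec_counts")) return(x)
  if (inherits(x, "ec_pair")) return(count_contingency(x))
  stop("expected an ec_pair or ec_counts object", call. = FALSE)
}

#' Marginal accuracies of a contingency table
#'
#' @param counts an `"ec_counts"` object.
#' @return Named vector `c(acc_a, acc_b)`.
#' @export
marginal_accuracies <- function(counts) {
  counts <- as_counts(counts)
  c(acc_a = (counts$n11 + counts$n10) / counts$n,
    acc_b = (counts$n11 + counts$n01) / counts$n)
}

#' Expected agreement of two independent binomial observers
#'
#' The agreement expected by chance when each observer is modelled as an
#' independent Bernoulli responder with its marginal accuracy:
#' `p_e = p1 * p2 + (1 - p1) * (1 - p2)`.
#'
#' @param counts an `"ec_counts"` (or `"ec_pair"`) object.
#' @return Expected agreement in \[0, 1\].
#' @seealso [marginal_expected_agreement()] for the version on raw marginals.
#' @export
expected_agreement <- function(counts) {
  m <- marginal_accuracies(counts)
  marginal_expected_agreement(m[["acc_a"]], m[["acc_b"]])
}

#' @rdname expected_agreement
#' @param p1,p2 marginal accuracies in \[0, 1\].
#' @export
marginal_expected_agreement <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  p1 * p2 + (1 - p1) * (1 - p2)
}

#' Observed agreement
#'
#' Proportion of trials on which both observers were jointly correct or
#' jointly incorrect.
#'
#' @inheritParams expected_agreement
#' @export
observed_agreement <- function(counts) {
  counts <- as_counts(counts)
  (counts$n11 + counts$n00) / counts$n
}

undefined_kappa <- function(counts) {
  stop(structure(class = c("errcon_undefined_kappa", "error", "condition"),
                 list(message = paste0(
                        "kappa is undefined: expected agreement is 1 ",
                        "(both observers at 0% or both at 100% accuracy; ",
                        "counts n11=", counts$n11, " n10=", counts$n10,
                        " n01=", counts$n01, " n00=", counts$n00, ")"),
                      call = NULL)))
}

kappa_from_parts <- function(p_o, p_e) (p_o - p_e) / (1 - p_e)

#' Cohen's kappa (error consistency)
#'
#' Chance-corrected trial-level agreement,
#' `kappa = (p_o - p_e) / (1 - p_e)`, with `p_e` the expected agreement of
#' independent binomial observers at the empirical marginals.  `kappa = 1`
#' iff the two correctness sequences are identical; `kappa = 0` under exact
#' chance agreement.
#'
#' @inheritParams expected_agreement
#' @return Scalar kappa.  When `p_e = 1` (both observers all-correct or both
#'   all-incorrect) kappa has no value and a classed error
#'   (`errcon_undefined_kappa`) is signalled rather than silently returning 0.
#' @examples
#' cohens_kappa(contingency_counts(49, 1, 1, 49))   # 0.96
#' cohens_kappa(contingency_counts(96, 1, 1, 1))    # ~0.49
#' @export
cohens_kappa <- function(counts) {
  counts <- as_counts(counts)
  p_e <- expected_agreement(counts)
  if (p_e >= 1) undefined_kappa(counts)
  kappa_from_parts(observed_agreement(counts), p_e)
}

#' Maximum kappa attainable at fixed marginal accuracies
#'
#' Holding both observers' accuracies fixed, observed agreement is maximised
#' at `p_o_max = 1 - |p1 - p2|` (the off-diagonal cells cannot both vanish
#' unless the marginals are equal), giving
#' `kappa_max = (p_o_max - p_e) / (1 - p_e)`.  The closed form is validated
#' against exhaustive enumeration of accuracy-preserving flip sets in the
#' test suite.
#'
#' @inheritParams expected_agreement
#' @return Scalar `kappa_max >= cohens_kappa(counts)`; equals 1 iff the
#'   marginals are equal.
#' @export
kappa_max <- function(counts) {
  counts <- as_counts(counts)
  m <- marginal_accuracies(counts)
  p_e <- marginal_expected_agreement(m[["acc_a"]], m[["acc_b"]])
  if (p_e >= 1) undefined_kappa(counts)
  kappa_from_parts(1 - abs(m[["acc_a"]] - m[["acc_b"]]), p_e)
}

#' Flip distance to kappa_max
#'
#' Number of trials that would have to be flipped in one observer (correct to
#' incorrect or vice versa, always flipping a pair of responses so that the
#' observer's accuracy is maintained) to reach `kappa_max`.  Each
#' accuracy-maintaining modification moves one A-only-correct trial to
#' both-incorrect and one B-only-correct trial to both-correct (or the
#' mirror image in observer B), i.e. two flipped trials per pair, so the
#' distance is `2 * min(n10, n01)`.
#'
#' @inheritParams expected_agreement
#' @return Integer count of flipped trials; the number of flip *pairs* is
#'   attached as attribute `"pairs"`.
#' @export
flips_to_kappa_max <- function(counts) {
  counts <- as_counts(counts)
  pairs <- min(counts$n10, counts$n01)
  structure(2L * pairs, pairs = pairs)
}

#' Stability flag for a kappa estimate
#'
#' A condition is flagged unstable when fewer than `threshold` flipped trials
#' would suffice to reach `kappa_max`: a few unlucky trials could then have
#' produced a drastically different kappa.  The conservative default
#' threshold is 10 flipped trials.
#'
#' @inheritParams expected_agreement
#' @param threshold minimum flip distance regarded as stable.
#' @return `TRUE` if stable (`flips >= threshold`), `FALSE` if unstable.
#' @export
stability_flag <- function(counts, threshold = 10L) {
  as.integer(flips_to_kappa_max(counts)) >= threshold
}

#' Full agreement summary for one observer pair
#'
#' @param x an `"ec_pair"` or `"ec_counts"` object.
#' @param threshold flip-distance stability threshold (trials).
#' @return An object of class `"ec_agreement"`: list with `n`, `p_o`, `p_e`,
#'   `kappa`, `kappa_max`, `flip_distance`, `flip_pairs`, `stable`, `acc_a`,
#'   `acc_b`.  Undefined kappa (p_e = 1) is propagated as `NA` entries with
#'   `defined = FALSE`.
#' @export
agreement <- function(x, threshold = 10L) {
  counts <- as_counts(x)
  m <- marginal_accuracies(counts)
  p_e <- marginal_expected_agreement(m[["acc_a"]], m[["acc_b"]])
  p_o <- observed_agreement(counts)
  flips <- flips_to_kappa_max(counts)
  defined <- p_e < 1
  structure(list(
    n = counts$n,
    p_o = p_o,
    p_e = p_e,
    kappa = if (defined) kappa_from_parts(p_o, p_e) else NA_real_,
    kappa_max = if (defined) {
      kappa_from_parts(1 - abs(m[["acc_a"]] - m[["acc_b"]]), p_e)
    } else NA_real_,
    flip_distance = as.integer(flips),
    flip_pairs = attr(flips, "pairs"),
    stable = as.integer(flips) >= threshold,
    acc_a = m[["acc_a"]],
    acc_b = m[["acc_b"]],
    defined = defined
  ), class = "ec_agreement")
}

#' @export
print.ec_agreement <- function(x, ...) {
  cat("Error consistency (n =", x$n, "trials)\n")
  if (!x$defined) {
    cat("  kappa undefined: expected agreement is 1\n")
  } else {
    cat(sprintf("  p_o = %.4f, p_e = %.4f\n", x$p_o, x$p_e))
    cat(sprintf("  kappa = %.4f (kappa_max = %.4f)\n", x$kappa, x$kappa_max))
    cat(sprintf("  flips to kappa_max = %d (%s)\n", x$flip_distance,
                if (x$stable) "stable" else "UNSTABLE"))
  }
  cat(sprintf("  accuracies: A = %.4f, B = %.4f\n", x$acc_a, x$acc_b))
  invisible(x)
}

# kappa for many 2x2 tables at once; rows of `cnt` are (n11, n10, n01, n00).
# Returns NA where p_e = 1.
kappa_vec <- function(cnt) {
  n <- rowSums(cnt)
  p1 <- (cnt[, 1L] + cnt[, 2L]) / n
  p2 <- (cnt[, 1L] + cnt[, 3L]) / n
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  p_o <- (cnt[, 1L] + cnt[, 4L]) / n
  out <- (p_o - p_e) / (1 - p_e)
  out[p_e >= 1] <- NA_real_
  out
}

#' Percentile bootstrap interval for kappa
#'
#' Trials are resampled with replacement in a paired fashion (the same item
#' index is drawn for both observers), and the percentile interval of the
#' resampled kappa distribution is reported.  Because kappa depends on the
#' trials only through their 2x2 cell membership, paired trial resampling is
#' realised as a multinomial resample of the observed cell counts, which is
#' distributionally identical and fast.  Resamples with `p_e = 1` carry no
#' kappa and are dropped; the effective resample count is reported.
#'
#' @param pair an `"ec_pair"` or `"ec_counts"` object (length >= 2 trials).
#' @param n_resamples number of bootstrap resamples (>= 1).
#' @param coverage central coverage of the percentile interval, default 0.68.
#' @param seed integer seed for reproducibility.
#' @return Object of class `"ec_boot"`: list with `point`, `lower`, `upper`,
#'   `coverage`, `n_resamples`, `n_effective`, `seed`.
#' @export
bootstrap_kappa <- function(pair, n_resamples = 2000L, coverage = 0.68,
                            seed = NULL) {
  counts <- as_counts(pair)
  if (counts$n < 2L) stop("need at least 2 trials to bootstrap", call. = FALSE)
  stopifnot(n_resamples >= 1L, coverage > 0, coverage < 1)
  if (expected_agreement(counts) >= 1) {
    # every multinomial resample of these cells is degenerate too
    stop(structure(class = c("errcon_undefined_interval", "error", "condition"),
                   list(message = paste("kappa is undefined for this pair",
                                        "(expected agreement 1) and every",
                                        "resample is degenerate; interval",
                                        "undefined"),
                        call = NULL)))
  }
  point <- cohens_kappa(counts)
  prob <- c(counts$n11, counts$n10, counts$n01, counts$n00) / counts$n
  draws <- with_seed(seed, {
    t(stats::rmultinom(n_resamples, size = counts$n, prob = prob))
  })
  k <- kappa_vec(draws)
  k <- k[!is.na(k)]
  if (length(k) == 0L) {
    stop(structure(class = c("errcon_undefined_interval", "error", "condition"),
                   list(message = paste("all bootstrap resamples were",
                                        "degenerate (p_e = 1); interval",
                                        "undefined"),
                        call = NULL)))
  }
  alpha <- (1 - coverage) / 2
  qs <- stats::quantile(k, probs = c(alpha, 1 - alpha), names = FALSE)
  structure(list(point = point, lower = qs[1L], upper = qs[2L],
                 coverage = coverage, n_resamples = as.integer(n_resamples),
                 n_effective = length(k), seed = seed),
            class = "ec_boot")
}

#' @export
print.ec_boot <- function(x, ...) {
  cat(sprintf("kappa = %.4f, %d%% percentile interval [%.4f, %.4f] (%d/%d resamples)\n",
              x$point, round(100 * x$coverage), x$lower, x$upper,
              x$n_effective, x$n_resamples))
  invisible(x)
}

#' Pairwise error-consistency matrix
#'
#' Compute kappa (and the full agreement diagnostics) for every pair among a
#' set of observers recorded on a shared item set.
#'
#' @param observers named list of correctness sequences.  If the vectors are
#'   named, names are item identifiers; otherwise alignment is positional.
#' @param align `"strict"` requires every observer to carry the identical
#'   item set (same ids, or same length when unnamed); `"intersect"`
#'   restricts explicitly to the common items.
#' @param threshold stability flip threshold passed to [agreement()].
#' @return List with `kappa` (symmetric matrix; diagonal 1 where defined and
#'   `NA` for degenerate observers) and `pairs` (data frame with one row per
#'   unordered pair: `observer_a`, `observer_b`, `n`, `p_o`, `p_e`, `kappa`,
#'   `kappa_max`, `flip_distance`, `stable`).  Undefined pairs carry `NA`
#'   kappa.
#' @export
pairwise_kappa_matrix <- function(observers, align = c("strict", "intersect"),
                                  threshold = 10L) {
  align <- match.arg(align)
  if (!is.list(observers) || length(observers) < 2L) {
    stop("need a list of at least two observers", call. = FALSE)
  }
  if (is.null(names(observers)) || anyDuplicated(names(observers))) {
    stop("observers must be uniquely named", call. = FALSE)
  }
  named <- vapply(observers, function(x) !is.null(names(x)), logical(1))
  if (any(named) && !all(named)) {
    stop("either all or none of the observers may carry item names",
         call. = FALSE)
  }
  if (all(named)) {
    if (align == "strict") {
      ref <- sort(names(observers[[1L]]))
      for (nm in names(observers)) {
        if (!identical(sort(names(observers[[nm]])), ref)) {
          stop("observer '", nm, "' is recorded on a different item set; ",
               "use align = \"intersect\" to restrict to common items",
               call. = FALSE)
        }
      }
      items <- ref
    } else {
      items <- Reduce(intersect, lapply(observers, names))
      if (length(items) < 1L) stop("no common items", call. = FALSE)
      items <- sort(items)
    }
    observers <- lapply(observers, function(x) x[items])
  } else {
    len <- unique(vapply(observers, length, integer(1)))
    if (length(len) != 1L) {
      stop("unnamed observer sequences must have equal length", call. = FALSE)
    }
  }
  obs_names <- names(observers)
  k <- length(observers)
  mat <- matrix(NA_real_, k, k, dimnames = list(obs_names, obs_names))
  rows <- list()
  for (i in seq_len(k)) {
    self <- agreement(binary_pair(observers[[i]], observers[[i]]), threshold)
    mat[i, i] <- if (self$defined) 1 else NA_real_
    if (i == k) break
    for (j in seq((i + 1L), k)) {
      ag <- agreement(binary_pair(observers[[i]], observers[[j]]), threshold)
      mat[i, j] <- mat[j, i] <- ag$kappa
      rows[[length(rows) + 1L]] <- data.frame(
        observer_a = obs_names[i], observer_b = obs_names[j],
        n = ag$n, p_o = ag$p_o, p_e = ag$p_e, kappa = ag$kappa,
        kappa_max = ag$kappa_max, flip_distance = ag$flip_distance,
        stable = ag$stable, stringsAsFactors = FALSE)
    }
  }
  list(kappa = mat, pairs = do.call(rbind, rows))
}

#' Group-mean error consistencies
#'
#' Unweighted mean kappa within and between observer groups, excluding the
#' diagonal and undefined (NA) pairs.
#'
#' @param kappa_matrix symmetric kappa matrix from [pairwise_kappa_matrix()].
#' @param groups named character vector mapping observer name to group label.
#' @return Symmetric matrix of group-pair mean kappas.
#' @export
group_mean_kappa <- function(kappa_matrix, groups) {
  stopifnot(all(rownames(kappa_matrix) %in% names(groups)))
  g <- groups[rownames(kappa_matrix)]
  lev <- unique(g)
  out <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (gi in lev) {
    for (gj in lev) {
      vals <- kappa_matrix[g == gi, g == gj, drop = FALSE]
      if (gi == gj) {
        vals <- vals[lower.tri(vals)]
      }
      vals <- vals[!is.na(vals)]
      out[gi, gj] <- if (length(vals)) mean(vals) else NA_real_
    }
  }
  out
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
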