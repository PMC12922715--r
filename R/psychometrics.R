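# Psychometric analysis: proportion correct over presentation time, the
# reverse-Gumbel psychometric function on log time, MAP fitting with a beta
# prior on the lapse rate, and criterion thresholds (60/75/90% correct).

#' Reverse-Gumbel psychometric function
#'
#' `psi(x) = gamma + (1 - gamma - lambda) * F(log x; m, s)` with
#' `F(z) = 1 - exp(-exp((z - m) / s))`, the reverse Gumbel (log-Weibull,
#' minimum-type Gumbel) CDF, oriented so that psi increases with
#' presentation time `x`.  `gamma` is the guess rate (lower asymptote),
#' `lambda` the lapse rate (`psi -> 1 - lambda` as `x -> Inf`), `m` the
#' location in log-ms (`F(m) = 1 - exp(-1)`) and `s > 0` the scale.
#'
#' @param x presentation time in ms (> 0).
#' @param m location on the log-ms axis.
#' @param s scale (> 0).
#' @param gamma guess rate.
#' @param lambda lapse rate.
#' @return Proportion correct predicted at `x`.
#' @export
psych_fun <- function(x, m, s, gamma, lambda) {
  stopifnot(all(x > 0), s > 0)
  gamma + (1 - gamma - lambda) * reverse_gumbel_cdf(log(x), m, s)
}

reverse_gumbel_cdf <- function(z, m, s) 1 - exp(-exp((z - m) / s))

# Inverse of the reverse-Gumbel CDF.
reverse_gumbel_quantile <- function(p, m, s) m + s * log(-log(1 - p))

#' Collapse the 8-way task to binary animal detection
#'
#' Maps both the true and the response class to `animal` (bear, bird, dog,
#' elephant) or `nonanimal` (airplane, bicycle, boat, car).  A response that
#' is wrong at the 8-way level but lands in the correct group counts as
#' correct in the binary task; `NO_RESPONSE` is preserved.
#'
#' @param trials a trial table (see [read_trials()]).
#' @return The table with `true_class` and `response_class` replaced by
#'   binary labels.
#' @export
collapse_to_animal_task <- function(trials) {
  to_binary <- function(x) {
    out <- ifelse(x %in% ANIMAL_CLASSES, "animal",
                  ifelse(x %in% SUPERCLASSES, "nonanimal", NA_character_))
    out[x == NO_RESPONSE] <- NO_RESPONSE
    if (anyNA(out)) {
      bad <- unique(x[is.na(out)])
      stop("unknown class label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out
  }
  trials$true_class <- to_binary(trials$true_class)
  trials$response_class <- to_binary(trials$response_class)
  trials
}

#' Aggregate trials into performance-curve points
#'
#' @param trials trial table with responses.
#' @param by extra grouping columns (e.g. `"corruption"`, `"observer_id"`).
#' @param no_response `"incorrect"` counts missed-deadline trials as errors;
#'   `"exclude"` drops them.
#' @return Data frame with the grouping columns plus `presentation_ms`,
#'   `n_correct`, `n_total`.
#' @export
performance_points <- function(trials, by = character(),
                               no_response = c("incorrect", "exclude")) {
  no_response <- match.arg(no_response)
  if (no_response == "exclude") {
    trials <- trials[trials$response_class != NO_RESPONSE, , drop = FALSE]
  }
  correct <- as.integer(trials$response_class == trials$true_class &
                          trials$response_class != NO_RESPONSE)
  keys <- trials[, c(by, "presentation_ms"), drop = FALSE]
  agg <- stats::aggregate(correct, by = keys, FUN = function(v) {
    c(n_correct = sum(v), n_total = length(v))
  })
  out <- cbind(agg[, c(by, "presentation_ms"), drop = FALSE],
               n_correct = agg$x[, "n_correct"],
               n_total = agg$x[, "n_total"])
  out[order(out$presentation_ms), , drop = FALSE]
}

#' Fit the reverse-Gumbel psychometric function (MAP)
#'
#' Maximises the binomial likelihood of the observed correct counts under
#' [psych_fun()] penalised by a Beta prior on the lapse rate (a MAP fit).
#' The guess rate is fixed by the task design (1/8 for 8-way
#' identification, 1/2 for the binary animal task).  Optimisation uses
#' `stats::optim` (L-BFGS-B) from five fixed deterministic starts; the fit
#' is reproducible given the data.
#'
#' @param time_ms presentation times in ms (>= 3 distinct values).
#' @param n_correct,n_total correct and total counts per time.
#' @param guess_rate fixed lower asymptote `gamma`.
#' @param lambda_max upper bound for the lapse rate (default 0.1).
#' @param lambda_prior `c(shape1, shape2)` of the Beta prior on lambda.
#' @return Object of class `"ec_psychfit"`: list with `m`, `s`, `gamma`,
#'   `lambda`, `log_posterior`, `log_likelihood`, `converged`, and the data.
#'   All-ceiling or all-floor data raise a classed error
#'   (`errcon_degenerate_fit`) with diagnostics instead of returning a
#'   silent estimate.
#' @export
fit_psychometric <- function(time_ms, n_correct, n_total, guess_rate,
                             lambda_max = 0.1, lambda_prior = c(1.5, 20)) {
  stopifnot(length(time_ms) == length(n_correct),
            length(time_ms) == length(n_total),
            all(time_ms > 0), all(n_total >= 1),
            all(n_correct >= 0), all(n_correct <= n_total),
            guess_rate >= 0, guess_rate < 1)
  if (length(unique(time_ms)) < 3L) {
    stop("need at least 3 distinct presentation times", call. = FALSE)
  }
  phat <- n_correct / n_total
  if (all(phat >= 1 - lambda_max - 0.02)) {
    degenerate_fit("all points at ceiling", phat)
  }
  if (all(phat <= guess_rate + 0.02)) {
    degenerate_fit("all points at floor (guess rate)", phat)
  }
  lt <- log(time_ms)
  neglp <- function(par) {
    m <- par[1L]; s <- exp(par[2L]); lambda <- par[3L]
    p <- guess_rate + (1 - guess_rate - lambda) * reverse_gumbel_cdf(lt, m, s)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- sum(n_correct * log(p) + (n_total - n_correct) * log(1 - p))
    lprior <- stats::dbeta(min(max(lambda, 1e-12), 1 - 1e-12),
                           lambda_prior[1L], lambda_prior[2L], log = TRUE)
    -(ll + lprior)
  }
  starts <- expand.grid(
    m = stats::quantile(lt, c(0.25, 0.5, 0.75), names = FALSE),
    log_s = log(c(0.3, 0.8)))
  starts <- starts[seq_len(min(5L, nrow(starts))), , drop = FALSE]
  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(
      c(starts$m[i], starts$log_s[i], 0.02), neglp, method = "L-BFGS-B",
      lower = c(min(lt) - 5, log(1e-3), 0),
      upper = c(max(lt) + 5, log(20), lambda_max)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0L
    }
  }
  if (is.null(best)) stop("optimisation failed from all starts", call. = FALSE)
  m <- best$par[1L]; s <- exp(best$par[2L]); lambda <- best$par[3L]
  p <- guess_rate + (1 - guess_rate - lambda) * reverse_gumbel_cdf(lt, m, s)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(n_correct * log(p) + (n_total - n_correct) * log(1 - p))
  structure(list(m = m, s = s, gamma = guess_rate, lambda = lambda,
                 log_posterior = -best$value, log_likelihood = ll,
                 converged = converged,
                 data = data.frame(time_ms = time_ms, n_correct = n_correct,
                                   n_total = n_total)),
            class = "ec_psychfit")
}

degenerate_fit <- function(why, phat) {
  stop(structure(class = c("errcon_degenerate_fit", "error", "condition"),
                 list(message = paste0(
                        "degenerate psychometric data: ", why,
                        " (observed proportions ",
                        paste(sprintf("%.3f", phat), collapse = ", "), ")"),
                      call = NULL)))
}

#' @export
print.ec_psychfit <- function(x, ...) {
  cat("Reverse-Gumbel psychometric fit (MAP)\n")
  cat(sprintf("  m = %.3f log-ms (%.1f ms), s = %.3f, gamma = %.3f, lambda = %.4f\n",
              x$m, exp(x$m), x$s, x$gamma, x$lambda))
  cat(sprintf("  log posterior = %.2f, converged: %s\n",
              x$log_posterior, x$converged))
  invisible(x)
}

#' Presentation time needed to reach a criterion performance
#'
#' Inverts the fitted psychometric function at the requested proportion
#' correct.
#'
#' @param fit an `"ec_psychfit"` object.
#' @param criterion target proportion correct, strictly inside
#'   `(gamma, 1 - lambda)`.
#' @return Presentation time in ms.
#' @export
threshold_at <- function(fit, criterion) {
  stopifnot(inherits(fit, "ec_psychfit"))
  if (criterion <= fit$gamma || criterion >= 1 - fit$lambda) {
    stop(structure(class = c("errcon_unattainable_criterion", "error",
                             "condition"),
                   list(message = sprintf(
                          "criterion %.3f is unattainable: must lie in (%.3f, %.3f)",
                          criterion, fit$gamma, 1 - fit$lambda),
                        call = NULL)))
  }
  p <- (criterion - fit$gamma) / (1 - fit$gamma - fit$lambda)
  exp(reverse_gumbel_quantile(p, fit$m, fit$s))
}

#' Summarise a fit as a one-row table with criterion thresholds
#'
#' @param fit an `"ec_psychfit"` object.
#' @param criteria proportions correct at which to report thresholds.
#' @return One-row data frame with parameters and `threshold_*` columns (ms);
#'   unattainable criteria yield `NA`.
#' @export
psychfit_summary <- function(fit, criteria = c(0.6, 0.75, 0.9)) {
  th <- vapply(criteria, function(cr) {
    tryCatch(threshold_at(fit, cr), error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(m = fit$m, s = fit$s, gamma = fit$gamma,
                    lambda = fit$lambda, log_likelihood = fit$log_likelihood,
                    converged = fit$converged)
  for (i in seq_along(criteria)) {
    out[[sprintf("threshold_%d", round(100 * criteria[i]))]] <- th[i]
  }
  out
}
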