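# Brute-force oracle for kappa_max and the accuracy-maintaining flip
# distance: breadth-first search over elementary flip moves.  An elementary
# accuracy-maintaining modification flips one correct and one incorrect
# trial in the same observer (two flipped trials), which moves the 2x2
# table by +/-(1, -1, -1, 1) subject to cell nonnegativity.  The oracle
# never uses the closed forms it is checking.

flip_oracle <- function(n11, n10, n01, n00) {
  start <- c(n11, n10, n01, n00)
  key <- function(s) paste(s, collapse = ",")
  dist <- new.env(parent = emptyenv())
  assign(key(start), 0L, envir = dist)
  frontier <- list(start)
  while (length(frontier)) {
    nxt <- list()
    for (s in frontier) {
      d <- get(key(s), envir = dist)
      cand <- list()
      if (s[2] >= 1 && s[3] >= 1) cand <- c(cand, list(s + c(1, -1, -1, 1)))
      if (s[1] >= 1 && s[4] >= 1) cand <- c(cand, list(s + c(-1, 1, 1, -1)))
      for (s2 in cand) {
        k2 <- key(s2)
        if (!exists(k2, envir = dist)) {
          assign(k2, d + 2L, envir = dist)  # two trials flipped per move
          nxt[[length(nxt) + 1L]] <- s2
        }
      }
    }
    frontier <- nxt
  }
  states <- ls(envir = dist)
  tabs <- do.call(rbind, lapply(strsplit(states, ","), as.integer))
  costs <- vapply(states, get, integer(1), envir = dist)
  n <- sum(start)
  p1 <- (tabs[, 1] + tabs[, 2]) / n
  p2 <- (tabs[, 1] + tabs[, 3]) / n
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  p_o <- (tabs[, 1] + tabs[, 4]) / n
  kap <- ifelse(p_e >= 1, NA_real_, (p_o - p_e) / (1 - p_e))
  if (all(is.na(kap))) return(list(kappa_max = NA_real_, flips = NA_integer_))
  kmax <- max(kap, na.rm = TRUE)
  at_max <- which(!is.na(kap) & abs(kap - kmax) < 1e-12)
  list(kappa_max = kmax, flips = min(costs[at_max]))
}

# Aligned correctness pair realising the given 2x2 table.
pair_from_counts <- function(n11, n10, n01, n00) {
  binary_pair(c(rep(1, n11), rep(1, n10), rep(0, n01), rep(0, n00)),
              c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00)))
}

# All 2x2 tables with total count n (including zero cells).
all_tables <- function(n) {
  g <- expand.grid(n11 = 0:n, n10 = 0:n, n01 = 0:n)
  g <- g[g$n11 + g$n10 + g$n01 <= n, ]
  g$n00 <- n - g$n11 - g$n10 - g$n01
  g
}

# Discrete Laplacian energy of one image channel (high-frequency content).
laplacian_energy <- function(ch) {
  h <- nrow(ch); w <- ncol(ch)
  lap <- 4 * ch[2:(h - 1), 2:(w - 1)] -
    ch[1:(h - 2), 2:(w - 1)] - ch[3:h, 2:(w - 1)] -
    ch[2:(h - 1), 1:(w - 2)] - ch[2:(h - 1), 3:w]
  mean(lap^2)
}
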