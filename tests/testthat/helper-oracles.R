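# Independent brute-force oracles used to cross-check the scan
# implementations. These apply the criterion definitions literally and
# share no code with the package internals.

oracle_sd <- function(x, denom = "n-1") {
  n <- length(x)
  m <- sum(x) / n
  ss <- sum((x - m)^2)
  sqrt(ss / if (denom == "n") n else n - 1)
}

# Quadratic fit by explicit normal equations on the centred session index.
oracle_quad_fit <- function(v, rmse_df = "n-3") {
  n <- length(v)
  x <- seq_len(n) - (n + 1) / 2
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% v)
  # same 1e-9 cleaning convention as the package: ratings carry ~0.1
  # precision, so ties at machine epsilon are rounding artefacts
  beta <- round(as.numeric(beta), 9)
  fitted <- round(as.numeric(X %*% beta), 9)
  res <- round(v - fitted, 9)
  df <- if (rmse_df == "n") n else n - 3
  list(coef = beta, fitted = fitted, rmse = round(sqrt(sum(res^2) / df), 9))
}

# Session-by-session check of all four conditions of the residual-outlier
# rule. Returns integer rupture sessions or the string "excluded".
oracle_stiles <- function(v, mult = 2, floor_val = NULL,
                          excl_first_last = TRUE, excl_neg = TRUE,
                          below_prev = TRUE) {
  fit <- oracle_quad_fit(v)
  if (excl_neg && fit$coef[2] < 0) return("excluded")
  n <- length(v)
  hits <- integer(0)
  for (t in seq_len(n)) {
    if (v[t] > fit$fitted[t] - mult * fit$rmse) next
    if (excl_first_last && (t == 1 || t == n)) next
    if (below_prev && (t == 1 || v[t] >= v[t - 1])) next
    if (!is.null(floor_val) && v[t] >= floor_val) next
    hits <- c(hits, t)
  }
  hits
}

# Literal step-level reading of the decrease/increase rule. Returns a
# matrix with one row per rupture (start, trough, repair, magnitude,
# repair_magnitude) plus an "excluded" attribute for the original
# end-unrepaired exclusion.
oracle_strauss <- function(v, thr, base_sd = thr,
                           aggregate = FALSE, match_repair = FALSE,
                           drop_exclusion = TRUE) {
  n <- length(v)
  rs <- re <- integer(0)
  i <- 1
  while (i < n) {
    if (v[i + 1] - v[i] <= -thr) {
      j <- i
      if (aggregate)
        while (j + 1 < n && v[j + 2] - v[j + 1] <= -thr) j <- j + 1
      rs <- c(rs, i); re <- c(re, j + 1)
      i <- j + 1
    } else i <- i + 1
  }
  m <- length(rs)
  out <- matrix(NA_real_, m, 5)
  for (k in seq_len(m)) {
    st <- rs[k]; tr <- re[k]
    mag <- v[st] - v[tr]
    lim <- if (k < m) rs[k + 1] else n
    rp <- NA; rmag <- NA
    if (match_repair && mag >= 2 * base_sd) {
      t <- tr + 1
      while (t <= lim) {
        if (v[t] - v[tr] >= mag) { rp <- t; rmag <- v[t] - v[tr]; break }
        t <- t + 1
      }
    } else {
      t <- tr
      while (t < lim) {
        if (v[t + 1] - v[t] >= thr) { rp <- t + 1; rmag <- v[t + 1] - v[t]; break }
        t <- t + 1
      }
    }
    out[k, ] <- c(st, tr, rp, mag, rmag)
  }
  excluded <- !drop_exclusion && m > 0 && is.na(out[m, 3])
  if (excluded) out <- out[0, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

# Literal walk for the cumulative-decline criterion: find the earliest
# qualifying decline, track the running minimum (last session attaining
# it), repair at the first session back within the threshold band after an
# upward step, count qualifying declines inside the episode. Returns a
# matrix with columns start, trough, repair, magnitude, n_declines.
oracle_crisis <- function(v, thr) {
  n <- length(v)
  out <- NULL
  cursor <- 1
  while (cursor <= n - 1) {
    a <- NA
    for (s in cursor:(n - 1)) {
      if (v[s + 1] >= v[s]) next             # a start needs a strictly-down step
      b <- s + 1
      while (b < n && v[b + 1] <= v[b]) b <- b + 1
      if (v[s] - v[b] >= thr) { a <- s; break }
    }
    if (is.na(a)) break
    vs <- v[a]
    trough <- a + 1
    rp <- NA
    for (t in (a + 1):n) {
      if (v[t] <= v[trough]) trough <- t
      if (v[t] >= vs - thr && v[t] > v[trough]) { rp <- t; break }
    }
    # count threshold-reaching declines inside the episode span
    span_end <- if (is.na(rp)) n else rp
    ndec <- 0
    s <- a
    while (s < span_end) {
      if (v[s + 1] < v[s]) {
        b <- s + 1
        while (b < n && v[b + 1] <= v[b]) b <- b + 1
        if (v[s] - v[b] >= thr) ndec <- ndec + 1
        s <- b
      } else s <- s + 1
    }
    out <- rbind(out, c(a, trough, rp, vs - v[trough], ndec))
    if (is.na(rp)) break
    cursor <- rp
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 5)
  out
}

# Random course generator for property tests (plain, not the package's).
rand_course_values <- function(n, lo = 0, hi = 100) {
  round(stats::runif(n, lo, hi), 1)
}

# Enumerate all value vectors of length n over a grid, as a matrix with one
# course per row.
grid_courses <- function(n, grid) {
  m <- as.matrix(expand.grid(rep(list(grid), n)))
  dimnames(m) <- NULL
  m
}

make_profile <- function(intra, inter = NA_real_,
                         mode = "intra_only", denom = "n-1") {
  structure(list(intra = intra, inter = inter, mode = mode, denom = denom),
            class = "rre_profile")
}
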