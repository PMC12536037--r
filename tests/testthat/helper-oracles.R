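# Independent oracles used to cross-check the package's computation paths.
# They re-derive each quantity from its mathematical definition with code
# that shares nothing with the implementation.

# Benjamini-Hochberg by the step-up definition: sort p ascending, compute
# m*p_(i)/i, enforce monotonicity from the largest rank down, cap at 1.
bh_stepup_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- m * p[o] / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Kruskal-Wallis H from its rank definition with midranks and the tie
# correction.
kw_statistic_direct <- function(x, g) {
  g <- as.factor(g)
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation p-value of the KW statistic by full enumeration of the
# distinct assignments of observations to groups (multinomial coefficient;
# feasible for total n <= 10).
kw_exact_p <- function(x, g) {
  g <- as.factor(g)
  n <- length(x)
  stopifnot(n <= 10)
  sizes <- as.integer(table(g))
  h_obs <- kw_statistic_direct(x, g)
  assignments <- enumerate_assignments(seq_len(n), sizes)
  labels <- rep(levels(g), sizes)
  hs <- vapply(assignments, function(idx) {
    kw_statistic_direct(x[idx], labels)
  }, numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# All ways to split `pool` into ordered groups of the given sizes; returns
# a list of index vectors (concatenated group members in group order).
enumerate_assignments <- function(pool, sizes) {
  if (length(sizes) == 1) return(list(pool))
  first <- utils::combn(pool, sizes[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- enumerate_assignments(setdiff(pool, f), sizes[-1])
    out <- c(out, lapply(rest, function(r) c(f, r)))
  }
  out
}

# Exhaustive stay enumeration oracle: for each anchor i, find the longest
# prefix-valid window [i, j] (every window [i, k], k <= j, has all members
# within eps of its own centroid), recomputing each window from scratch.
# Anchors advance exactly as the segmentation contract prescribes.
stays_bruteforce <- function(x, y, tmin, eps, min_duration, max_time_gap) {
  n <- length(x)
  chunk <- cumsum(c(1, diff(tmin) > max_time_gap))
  kind <- character(n)
  for (ch in unique(chunk)) {
    idx <- which(chunk == ch)
    m <- length(idx)
    i <- 1L
    while (i <= m) {
      j_valid <- i
      for (j in i:m) {
        sel <- idx[i:j]
        cx <- sum(x[sel]) / length(sel)
        cy <- sum(y[sel]) / length(sel)
        ok <- all(sqrt((x[sel] - cx)^2 + (y[sel] - cy)^2) <= eps)
        if (!ok) break
        j_valid <- j
      }
      if (j_valid > i &&
          (tmin[idx[j_valid]] - tmin[idx[i]] + 1) >= min_duration) {
        kind[idx[i:j_valid]] <- "stay"
        i <- j_valid + 1L
      } else {
        kind[idx[i]] <- "trip"
        i <- i + 1L
      }
    }
  }
  kind
}

# A small raw-stream constructor for preprocessing tests.
make_stream <- function(n, participant = "P001",
                        start = as.POSIXct("2019-01-07 08:00:00", tz = "UTC")) {
  tibble::tibble(
    participant_id = participant,
    timestamp_utc = start + (seq_len(n) - 1) * 60,
    pnc_gt0p3 = 100L, pnc_gt0p5 = 40L, pnc_gt1 = 10L,
    pnc_gt2p5 = 3L, pnc_gt5 = 1L, pnc_gt10 = 0L,
    pm1 = 3, pm25 = 5, pm10 = 6,
    temp_c = 20, rh_pct = 50, lat = 47.6, lon = -122.3)
}

# Random wander tracks with planted stays, for segmentation oracle tests.
random_track <- function(n, seed) {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  i <- 1
  cx <- 0; cy <- 0
  while (i <= n) {
    if (runif(1) < 0.5) { # a stay of 5-40 fixes with small jitter
      len <- min(n - i + 1, sample(5:40, 1))
      x[i:(i + len - 1)] <- cx + rnorm(len, 0, 5)
      y[i:(i + len - 1)] <- cy + rnorm(len, 0, 5)
      i <- i + len
    } else { # a movement burst
      len <- min(n - i + 1, sample(2:10, 1))
      for (k in seq_len(len)) {
        cx <- cx + runif(1, 40, 120); cy <- cy + runif(1, -60, 60)
        x[i] <- cx; y[i] <- cy
        i <- i + 1
        if (i > n) break
      }
    }
  }
  tibble::tibble(
    participant_id = "P001",
    timestamp_utc = as.POSIXct("2019-01-07", tz = "UTC") + (seq_len(n) - 1) * 60,
    x = x, y = y)
}
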