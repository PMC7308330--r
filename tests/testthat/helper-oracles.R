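# Independent oracles used across the suite. These deliberately use brute
# force / closed forms, not the package's own code paths.

# Exhaustive one-to-one assignment of events to slots of ONE instrument:
# maximize matches within tolerance, then minimize total |deviation|.
# Returns list(count, cost, assign) with assign[j] = event index or NA.
oracle_assign <- function(ev, sl, tol) {
  q <- length(sl)
  rec <- function(j, used) {
    if (j > q) return(list(count = 0L, cost = 0, assign = integer(0)))
    best <- rec(j + 1L, used)
    best$assign <- c(NA_integer_, best$assign)
    for (i in seq_along(ev)) {
      if (!used[i] && abs(ev[i] - sl[j]) <= tol) {
        used2 <- used; used2[i] <- TRUE
        sub <- rec(j + 1L, used2)
        cand <- list(count = sub$count + 1L,
                     cost = sub$cost + abs(ev[i] - sl[j]),
                     assign = c(i, sub$assign))
        if (cand$count > best$count ||
            (cand$count == best$count && cand$cost < best$cost - 1e-12))
          best <- cand
      }
    }
    best
  }
  rec(1L, rep(FALSE, length(ev)))
}

# Oracle scoring of a whole small stream against a grid: per-bar completion
# flags plus global matched count and total deviation, via oracle_assign
# per instrument.
oracle_score <- function(events, grid, tol) {
  matched <- rep(FALSE, nrow(grid))
  total_count <- 0L
  total_cost <- 0
  for (inst in unique(grid$instrument)) {
    si <- which(grid$instrument == inst)
    si <- si[order(grid$nominal_ms[si])]
    ei <- which(events$instrument == inst)
    if (!length(ei)) next
    o <- oracle_assign(events$onset_ms[ei], grid$nominal_ms[si], tol)
    matched[si] <- !is.na(o$assign)
    total_count <- total_count + o$count
    total_cost <- total_cost + o$cost
  }
  completed <- tapply(matched, grid$bar_index, all)
  list(completed = as.logical(completed[order(as.integer(names(completed)))]),
       count = total_count, cost = total_cost)
}

# Exact two-sided Mann-Whitney p by enumeration of all C(n, n_x) labelings.
oracle_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# Kendall tau-b by direct pairwise concordant/discordant counting.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# E[max - min] of independent Gaussians with means mu and common sd, by
# numerical integration of the max (and min via negation symmetry).
oracle_expected_range <- function(mu, sd) {
  e_max <- function(means) {
    Fx <- function(x) Reduce(`*`, lapply(means, function(m) pnorm(x, m, sd)))
    up <- stats::integrate(function(x) 1 - Fx(x), 0, Inf,
                           rel.tol = 1e-10)$value
    lo <- stats::integrate(Fx, -Inf, 0, rel.tol = 1e-10)$value
    up - lo
  }
  e_max(mu) + e_max(-mu)
}

# Power of the ANCOVA group F test from the noncentral F distribution, for a
# given design matrix of covariates (incl. intercept), group indicator g,
# effect delta and noise sd.
oracle_ancova_power <- function(g, X, delta, sigma, alpha = 0.05) {
  M <- diag(length(g)) - X %*% solve(crossprod(X)) %*% t(X)
  lambda <- delta^2 * drop(t(g) %*% M %*% g) / sigma^2
  df2 <- length(g) - ncol(X) - 1
  crit <- qf(1 - alpha, 1, df2)
  pf(crit, 1, df2, ncp = lambda, lower.tail = FALSE)
}

# Hand-rolled SMF assembler (independent of write_smf): one track, constant
# tempo, list of (tick, note) note-ons at velocity 100.
raw_smf <- function(ticks, notes, tempo_us = 500000L, ppq = 480L, format = 0L) {
  varlen <- function(v) {
    out <- as.raw(v %% 128); v <- v %/% 128
    while (v > 0) { out <- c(as.raw(128 + v %% 128), out); v <- v %/% 128 }
    out
  }
  be <- function(v, n) {
    out <- raw(n)
    for (k in n:1) { out[k] <- as.raw(v %% 256); v <- v %/% 256 }
    out
  }
  ord <- order(ticks)
  ticks <- ticks[ord]; notes <- notes[ord]
  body <- c(varlen(0), as.raw(c(0xFF, 0x51, 0x03)), be(tempo_us, 3))
  last <- 0
  for (i in seq_along(ticks)) {
    body <- c(body, varlen(ticks[i] - last),
              as.raw(c(0x99, notes[i], 100)))
    last <- ticks[i]
  }
  body <- c(body, varlen(0), as.raw(c(0xFF, 0x2F, 0x00)))
  c(charToRaw("MThd"), be(6, 4), be(format, 2), be(1, 2), be(ppq, 2),
    charToRaw("MTrk"), be(length(body), 4), body)
}

# Random small event stream over a 4-bar quarter grid for oracle comparisons.
random_small_stream <- function(grid, tol, n_extra = 2, keep_prob = 0.8) {
  keep <- runif(nrow(grid)) < keep_prob
  g <- grid[keep, ]
  onset <- g$nominal_ms + rnorm(nrow(g), 0, tol)  # many beyond tolerance
  kit <- c("ride", "kick", "snare", "hihat_pedal")
  nx <- rpois(1, n_extra)
  i2l <- drumscore::default_limb_map()$instrument_to_limb
  extra_inst <- sample(kit, nx, replace = TRUE)
  drumscore::drum_events(
    pmax(0, c(onset, runif(nx, min(grid$nominal_ms), max(grid$nominal_ms)))),
    c(g$instrument, extra_inst),
    c(g$limb, unname(i2l[extra_inst])),
    rep(100L, nrow(g) + nx))
}
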