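# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities by different means (grids,
# exhaustive enumeration, textbook definitions) than the package code.

# Build a deterministic track from a location sequence and its breakpoints.
make_track <- function(locations, breaks) {
  stopifnot(length(breaks) == length(locations) + 1)
  data.frame(location = locations,
             start_s = breaks[-length(breaks)],
             end_s = breaks[-1],
             stringsAsFactors = FALSE)
}

# Round a track's interval boundaries to whole seconds, preserving the
# tiling (each boundary is rounded once and shared by its two intervals).
# On integer-boundary tracks a 1-s grid tally is an exact integral, so the
# grid oracle and interval arithmetic must agree to rounding error only.
round_track <- function(track) {
  b <- round(c(track$start_s, track$end_s[nrow(track)]))
  keep <- b[-1] > b[-length(b)]
  make_track(track$location[keep],
             c(b[-length(b)][keep], b[length(b)]))
}

# 1-s grid tally of per-compartment time for one mouse in a window.
grid_fractions <- function(track, window, topology, step = 1) {
  mids <- seq(window[1] + step / 2, window[2], by = step)
  loc <- locate_track(track, mids)
  per <- vapply(topology$compartments,
                function(cc) step * sum(loc == cc), 0)
  tot <- sum(per)
  list(fractions = per / tot, t_analyzable_s = tot)
}

# 1-s grid tally of pair co-occupancy: O, T, E and s.
grid_pair <- function(track_i, track_j, window, topology, step = 1) {
  mids <- seq(window[1] + step / 2, window[2], by = step)
  li <- locate_track(track_i, mids)
  lj <- locate_track(track_j, mids)
  comp <- topology$compartments
  both <- li %in% comp & lj %in% comp
  t_pair <- step * sum(both)
  o <- step * sum(both & li == lj)
  p_i <- vapply(comp, function(cc) sum(both & li == cc), 0) / sum(both)
  p_j <- vapply(comp, function(cc) sum(both & lj == cc), 0) / sum(both)
  e <- t_pair * sum(p_i * p_j)
  list(together_s = o, analyzable_s = t_pair, expected_s = e,
       s = (o - e) / t_pair)
}

# Textbook Benjamini-Hochberg step-up: sort ascending, running minimum of
# p_(j) * m / j from the largest rank down, back in input order.
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run <- Inf
  for (j in m:1) {
    run <- min(run, ps[j] * m / j)
    adj[j] <- min(run, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive subset-enumeration upper-tail hypergeometric probability:
# fix A = {1..n_a}; over all C(N, n_b) subsets B, the fraction with
# |A intersect B| >= k.  Returns the whole tail table for one (N, n_a, n_b).
enum_hyper_tails <- function(n_a, n_b, N) {
  masks <- 0:(2^N - 1)
  bits <- vapply(0:(N - 1),
                 function(b) bitwAnd(masks, bitwShiftL(1L, b)) > 0L,
                 logical(length(masks)))
  size <- rowSums(bits)
  sel <- size == n_b
  inter <- if (n_a == 0) rep(0, sum(sel)) else
    rowSums(bits[sel, seq_len(n_a), drop = FALSE])
  vapply(0:min(n_a, n_b), function(k) mean(inter >= k), 0)
}

# A short dark-only schedule for fast simulations.
dark_only_schedule <- function(dark_s = 86400) {
  as_phase_schedule(data.frame(label = "dark1", kind = "dark",
                               start_s = 0, end_s = dark_s,
                               stringsAsFactors = FALSE))
}

# Two-group block affinity matrix.
block_affinity <- function(groups, a_within = 1.5) {
  n <- length(groups)
  aff <- matrix(0, n, n)
  for (g in unique(groups)) {
    ix <- which(groups == g)
    aff[ix, ix] <- a_within
  }
  diag(aff) <- 0
  aff
}
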