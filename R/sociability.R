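# Pairwise in-cohort sociability and approach to a social odor.
#
# The pair statistic is s_ij = (O_ij - E_ij) / T_ij where, within a phase
# window, O_ij is the time both mice spend in the same compartment, T_ij the
# pair-analyzable time (both compartment-located), and E_ij = T_ij *
# sum_c p_i(c) p_j(c) the co-occupancy expected if the two mice moved
# independently with their observed compartment preferences.  Occupancy
# fractions for E are estimated on the same pair-analyzable base as O, so
# numerator and denominator see the same missing data.

# shared sweep over the common refinement of two clipped tracks
pair_sweep <- function(track_i, track_j, window, comp_labels) {
  ti <- clip_track(track_i, window)
  tj <- clip_track(track_j, window)
  bp <- sort(unique(c(ti$start_s, ti$end_s, tj$start_s, tj$end_s)))
  len <- diff(bp)
  mid <- bp[-length(bp)] + len / 2
  li <- ti$location[findInterval(mid, ti$start_s)]
  lj <- tj$location[findInterval(mid, tj$start_s)]
  both <- (li %in% comp_labels) & (lj %in% comp_labels)
  t_pair <- sum(len[both])
  together <- sum(len[both & li == lj])
  p_i <- p_j <- stats::setNames(rep(NA_real_, length(comp_labels)), comp_labels)
  if (t_pair > 0) {
    for (cc in comp_labels) {
      p_i[cc] <- sum(len[both & li == cc]) / t_pair
      p_j[cc] <- sum(len[both & lj == cc]) / t_pair
    }
  }
  list(together_s = together, analyzable_s = t_pair, p_i = p_i, p_j = p_j)
}

#' Time a pair of mice spends together in a phase window
#'
#' Seconds during which both animals are in the same compartment; corridor
#' and unknown time never counts.  Also returns the pair-analyzable time
#' (both animals compartment-located), the denominator of the sociability
#' statistic.
#'
#' @param track_i,track_j Per-animal track data frames covering the window.
#' @param window Numeric `c(start_s, end_s)` half-open window.
#' @param topology An `eh_topology`.
#' @return List with `together_s`, `analyzable_s` and `defined` (`FALSE`
#'   when the pair has no common compartment-located time, in which case
#'   the pair must be excluded for this phase).
#' @export
time_together <- function(track_i, track_j, window, topology) {
  sw <- pair_sweep(track_i, track_j, window, topology$compartments)
  list(together_s = sw$together_s, analyzable_s = sw$analyzable_s,
       defined = sw$analyzable_s > 0)
}

#' Expected time together under independent compartment preferences
#'
#' `T_ij * sum_c p_i(c) * p_j(c)`: the co-occupancy time expected if the two
#' animals located themselves independently with the given preferences.
#'
#' @param p_i,p_j Named occupancy-fraction vectors over the same
#'   compartments, each summing to 1.
#' @param t_analyzable_s Pair-analyzable time in seconds.
#' @return Expected seconds together; `NA` if either fraction vector is
#'   undefined.
#' @export
expected_time_together <- function(p_i, p_j, t_analyzable_s) {
  if (anyNA(p_i) || anyNA(p_j)) return(NA_real_)
  stopifnot(identical(names(p_i), names(p_j)))
  if (abs(sum(p_i) - 1) > 1e-6 || abs(sum(p_j) - 1) > 1e-6) {
    stop("occupancy fractions must sum to 1")
  }
  t_analyzable_s * sum(p_i * p_j)
}

#' Pairwise in-cohort sociability matrix for one phase
#'
#' For every pair, `s_ij = (O_ij - E_ij) / T_ij` (observed minus expected
#' co-occupancy as a fraction of pair-analyzable time, making the statistic
#' invariant to phase length); values fall in `[-1, 1]`, positive values
#' meaning the pair spends more time together than its members' individual
#' compartment preferences explain.  Pairs with no analyzable time are
#' `NA`, never 0.
#'
#' @param tracks Named list of per-animal tracks (at least 2).
#' @param window Numeric `c(start_s, end_s)` phase window.
#' @param topology An `eh_topology`.
#' @param phase Optional phase label stored in the result.
#' @return Object of class `sociability_matrix`: list with `phase`, `s`
#'   (symmetric matrix, zero diagonal, `NA` for undefined pairs) and
#'   `t_base` (matrix of pair-analyzable seconds).
#' @export
incohort_sociability <- function(tracks, window, topology, phase = NA_character_) {
  tags <- names(tracks)
  n <- length(tags)
  if (n < 2) stop("need at least 2 tracks")
  s <- matrix(NA_real_, n, n, dimnames = list(tags, tags))
  t_base <- matrix(0, n, n, dimnames = list(tags, tags))
  diag(s) <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sw <- pair_sweep(tracks[[i]], tracks[[j]], window, topology$compartments)
      t_base[i, j] <- t_base[j, i] <- sw$analyzable_s
      if (sw$analyzable_s > 0) {
        e <- expected_time_together(sw$p_i, sw$p_j, sw$analyzable_s)
        s[i, j] <- s[j, i] <- (sw$together_s - e) / sw$analyzable_s
      }
    }
  }
  structure(list(phase = phase, s = s, t_base = t_base),
            class = "sociability_matrix")
}

#' @export
print.sociability_matrix <- function(x, ...) {
  off <- x$s[upper.tri(x$s)]
  cat(sprintf("<sociability_matrix> phase %s: %d mice, mean s = %.4f (%d undefined pairs)\n",
              x$phase, nrow(x$s), mean(off, na.rm = TRUE), sum(is.na(off))))
  invisible(x)
}

#' Per-mouse sociability summarized over assessment phases
#'
#' Two-stage mean: within each phase, each mouse's sociability is the mean
#' of `s_ij` over its defined partners; the per-mouse value is then the mean
#' over phases in which the mouse is defined (a mouse missing from one phase
#' is averaged over the remaining phases only).
#'
#' @param matrices List of `sociability_matrix` objects (typically the
#'   three assessment dark phases), all over the same tags.
#' @return Named numeric vector, `NA` for mice undefined in every phase.
#' @export
per_mouse_sociability <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  tags <- rownames(matrices[[1]]$s)
  per_phase <- vapply(matrices, function(m) {
    stopifnot(identical(rownames(m$s), tags))
    s <- m$s
    diag(s) <- NA
    v <- rowMeans(s, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }, numeric(length(tags)))
  per_phase <- matrix(per_phase, nrow = length(tags),
                      dimnames = list(tags, NULL))
  out <- rowMeans(per_phase, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Approach to a social odor relative to a baseline dark phase
#'
#' Ratio of smoothed stimulus/neutral occupancy ratios:
#' `[(t_social + eps) / (t_neutral + eps)]_test / [(t_social + eps) /
#' (t_neutral + eps)]_baseline`, where times are compartment-located seconds
#' in the named compartments.  A value of 1 means no change from baseline;
#' the additive `epsilon_s` regularizes phases in which a compartment was
#' never visited.
#'
#' @param tracks Named list of per-animal tracks.
#' @param stimulus_compartment,neutral_compartment Distinct compartment
#'   labels.
#' @param test_window,baseline_window Numeric `c(start_s, end_s)` windows
#'   (typically the dark phases of day 6 and day 5).
#' @param topology An `eh_topology`.
#' @param epsilon_s Additive smoothing in seconds (default 1).
#' @return Data frame `tag`, `ratio`, `t_social_test`, `t_neutral_test`,
#'   `t_social_base`, `t_neutral_base`; animals with zero analyzable time
#'   in either phase get `NA` ratios.
#' @export
approach_to_social_odor <- function(tracks, stimulus_compartment,
                                    neutral_compartment, test_window,
                                    baseline_window, topology,
                                    epsilon_s = 1.0) {
  if (identical(stimulus_compartment, neutral_compartment)) {
    stop("stimulus and neutral compartments must differ")
  }
  stopifnot(all(c(stimulus_compartment, neutral_compartment) %in%
                  topology$compartments))
  comp_time <- function(track, window, cc) {
    cl <- clip_track(track, window)
    sum((cl$end_s - cl$start_s)[cl$location == cc])
  }
  analyzable <- function(track, window) {
    cl <- clip_track(track, window)
    sum((cl$end_s - cl$start_s)[cl$location %in% topology$compartments])
  }
  rows <- lapply(names(tracks), function(tg) {
    tr <- tracks[[tg]]
    st <- comp_time(tr, test_window, stimulus_compartment)
    nt <- comp_time(tr, test_window, neutral_compartment)
    sb <- comp_time(tr, baseline_window, stimulus_compartment)
    nb <- comp_time(tr, baseline_window, neutral_compartment)
    ratio <- if (analyzable(tr, test_window) <= 0 ||
                 analyzable(tr, baseline_window) <= 0) {
      eh_log("warn", "mouse %s has no analyzable time in test or baseline phase", tg)
      NA_real_
    } else {
      ((st + epsilon_s) / (nt + epsilon_s)) /
        ((sb + epsilon_s) / (nb + epsilon_s))
    }
    data.frame(tag = tg, ratio = ratio, t_social_test = st, t_neutral_test = nt,
               t_social_base = sb, t_neutral_base = nb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-form export of sociability matrices
#'
#' @param matrices List of `sociability_matrix` objects.
#' @return Data frame `phase`, `tag_i`, `tag_j`, `s`, `t_base_s` with one
#'   row per unordered pair and phase.
#' @export
sociability_long <- function(matrices) {
  rows <- lapply(matrices, function(m) {
    tags <- rownames(m$s)
    idx <- which(upper.tri(m$s), arr.ind = TRUE)
    data.frame(phase = m$phase, tag_i = tags[idx[, 1]], tag_j = tags[idx[, 2]],
               s = m$s[idx], t_base_s = m$t_base[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
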