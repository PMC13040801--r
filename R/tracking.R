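#' Reconstruct per-mouse occupancy from antenna events
#'
#' Deterministic state machine assigning a location to every gap between an
#' animal's consecutive reads `x@t1`, `y@t2`:
#' \enumerate{
#'   \item same antenna (`x == y`): the antenna's home compartment (a mouse
#'     lingering at a compartment entrance re-triggers one antenna);
#'   \item different antennas of the same corridor with `t2 - t1 <=
#'     max_transit_s`: `CORRIDOR`;
#'   \item different corridors whose antennas flank one compartment (equal
#'     antenna homes): that compartment;
#'   \item anything else — including rule 2 with a gap longer than
#'     `max_transit_s` (a missed read, not a plausible crossing): `UNKNOWN`.
#' }
#' Time before an animal's first and after its last read is `UNKNOWN`; an
#' animal with no events at all gets a single `UNKNOWN` interval.  Every
#' returned track tiles `[0, session_end_s)` exactly with half-open
#' intervals (adjacent intervals with equal locations are merged).
#'
#' @param events Event data frame from [read_events()] or
#'   [simulate_cohort()], sorted by `(time_s, antenna, tag)`.
#' @param topology An `eh_topology`; all event antennas must be known to it.
#' @param session_end_s Session length in seconds; events beyond it are an
#'   error.
#' @param max_transit_s Longest same-corridor gap still interpreted as a
#'   crossing (default 30 s; far above real transit times, far below
#'   typical compartment dwell).
#' @param tags Optional character vector of animals to reconstruct; defaults
#'   to the tags present in `events`.  Tags without events yield an
#'   all-`UNKNOWN` track rather than an error.
#' @return Named list (one element per tag) of data frames with columns
#'   `location` (compartment label, `"CORRIDOR"` or `"UNKNOWN"`), `start_s`,
#'   `end_s`.
#' @export
reconstruct_occupancy <- function(events, topology, session_end_s,
                                  max_transit_s = 30, tags = NULL) {
  stopifnot(inherits(topology, "eh_topology"), session_end_s > 0)
  if (any(events$time_s > session_end_s)) {
    stop("event time exceeds session_end_s")
  }
  known <- as.integer(names(topology$antenna_home))
  if (!all(events$antenna %in% known)) stop("event antenna unknown to topology")
  home <- topology$antenna_home
  corr <- antenna_corridor(topology)
  if (is.null(tags)) tags <- sort(unique(events$tag))

  one_track <- function(tg) {
    sel <- events$tag == tg
    tt <- events$time_s[sel]
    aa <- as.character(events$antenna[sel])
    m <- length(tt)
    if (m == 0) {
      return(data.frame(location = "UNKNOWN", start_s = 0,
                        end_s = session_end_s, stringsAsFactors = FALSE))
    }
    loc <- character(m + 1L)
    start <- c(0, tt)
    end <- c(tt, session_end_s)
    loc[1] <- "UNKNOWN"
    loc[m + 1L] <- "UNKNOWN"
    if (m > 1) {
      x <- aa[-m]; y <- aa[-1]
      dt <- tt[-1] - tt[-m]
      same_ant <- x == y
      same_cor <- corr[x] == corr[y]
      same_home <- home[x] == home[y]
      loc[2:m] <- ifelse(same_ant, home[x],
                  ifelse(same_cor & dt <= max_transit_s, "CORRIDOR",
                  ifelse(!same_cor & same_home, home[x], "UNKNOWN")))
    }
    keep <- end > start
    d <- data.frame(location = loc[keep], start_s = start[keep],
                    end_s = end[keep], stringsAsFactors = FALSE)
    merge_track(d)
  }
  stats::setNames(lapply(tags, one_track), tags)
}

# merge adjacent intervals with identical locations
merge_track <- function(track) {
  n <- nrow(track)
  if (n <= 1) return(track)
  new_run <- c(TRUE, track$location[-1] != track$location[-n])
  grp <- cumsum(new_run)
  d <- data.frame(
    location = track$location[new_run],
    start_s = track$start_s[new_run],
    end_s = as.numeric(tapply(track$end_s, grp, function(e) e[length(e)])),
    stringsAsFactors = FALSE
  )
  rownames(d) <- NULL
  d
}

# clip a tiling track to a half-open window
clip_track <- function(track, window) {
  keep <- track$end_s > window[1] & track$start_s < window[2]
  d <- track[keep, , drop = FALSE]
  d$start_s <- pmax(d$start_s, window[1])
  d$end_s <- pmin(d$end_s, window[2])
  rownames(d) <- NULL
  d
}

#' Locate an animal at given times
#'
#' Evaluates a track (a tiling list of half-open intervals) as a step
#' function of time.
#'
#' @param track A per-animal track data frame (`location`, `start_s`,
#'   `end_s`).
#' @param times Numeric vector of times in `[0, session_end)`.
#' @return Character vector of locations, one per time.
#' @export
locate_track <- function(track, times) {
  idx <- findInterval(times, track$start_s)
  if (any(idx == 0) || any(times >= track$end_s[nrow(track)])) {
    stop("times outside the track's span")
  }
  track$location[idx]
}

#' Per-compartment occupancy fractions in a phase window
#'
#' Fraction of an animal's *compartment-located* time spent in each
#' compartment within the window; corridor and unknown time is excluded
#' from both numerator and denominator (never imputed).
#'
#' @param track A per-animal track data frame.
#' @param window Numeric `c(start_s, end_s)` half-open phase window.
#' @param topology An `eh_topology` supplying the compartment labels.
#' @return List with `fractions` (named numeric vector over compartments,
#'   summing to 1, or all `NA` when undefined), `t_analyzable_s` (the
#'   compartment-located denominator in seconds) and `defined` (logical;
#'   `FALSE` when the animal has no compartment-located time in the window,
#'   in which case the caller must exclude this animal/phase).
#' @export
occupancy_fractions <- function(track, window, topology) {
  stopifnot(window[2] > window[1])
  comp <- topology$compartments
  cl <- clip_track(track, window)
  len <- cl$end_s - cl$start_s
  per <- vapply(comp, function(cc) sum(len[cl$location == cc]), 0)
  tot <- sum(per)
  if (tot <= 0) {
    return(list(fractions = stats::setNames(rep(NA_real_, length(comp)), comp),
                t_analyzable_s = 0, defined = FALSE))
  }
  list(fractions = per / tot, t_analyzable_s = tot, defined = TRUE)
}

#' Time-weighted agreement between two sets of tracks
#'
#' Fraction of total mouse-time on which two reconstructions (for example,
#' reconstructed vs ground-truth tracks) assign the same location.
#'
#' @param tracks_a,tracks_b Named lists of track data frames with matching
#'   names.
#' @param window Numeric `c(start_s, end_s)`; defaults to the full common
#'   span.
#' @return A single fraction in `[0, 1]`.
#' @export
track_agreement <- function(tracks_a, tracks_b, window = NULL) {
  tags <- intersect(names(tracks_a), names(tracks_b))
  stopifnot(length(tags) > 0)
  tot <- 0
  agree <- 0
  for (tg in tags) {
    ta <- tracks_a[[tg]]; tb <- tracks_b[[tg]]
    w <- if (is.null(window)) {
      c(max(ta$start_s[1], tb$start_s[1]),
        min(ta$end_s[nrow(ta)], tb$end_s[nrow(tb)]))
    } else window
    ta <- clip_track(ta, w); tb <- clip_track(tb, w)
    bp <- sort(unique(c(ta$start_s, ta$end_s, tb$start_s, tb$end_s)))
    len <- diff(bp)
    mid <- bp[-length(bp)] + len / 2
    la <- ta$location[findInterval(mid, ta$start_s)]
    lb <- tb$location[findInterval(mid, tb$start_s)]
    tot <- tot + sum(len)
    agree <- agree + sum(len[la == lb])
  }
  agree / tot
}

#' Check that a track tiles a session exactly
#'
#' @param track A per-animal track data frame.
#' @param session_end_s Session length in seconds.
#' @param tol Numeric tolerance on boundary equality.
#' @return `TRUE` if intervals are ordered, disjoint, gap-free and cover
#'   `[0, session_end_s)`; otherwise `FALSE`.
#' @export
is_tiling <- function(track, session_end_s, tol = 1e-9) {
  n <- nrow(track)
  if (n == 0) return(FALSE)
  all(track$end_s > track$start_s) &&
    abs(track$start_s[1]) <= tol &&
    abs(track$end_s[n] - session_end_s) <= tol &&
    (n == 1 || all(abs(track$start_s[-1] - track$end_s[-n]) <= tol))
}
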