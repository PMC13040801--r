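#' Habitat topology: compartments joined in a ring by antenna-flanked corridors
#'
#' The habitat is a ring of `n_compartments` boxes joined by tubular
#' corridors; an RFID antenna sits at each end of each corridor, so a
#' completed crossing produces two reads.  `ring_topology()` builds the
#' default numbering: corridor *k* joins compartment *Ck* to *C(k mod n + 1)*
#' and carries antennas *2k - 1* (on the *Ck* side) and *2k* (on the far
#' side).  A custom corridor table can be supplied instead via `topology()`.
#'
#' @param n_compartments Number of compartments on the ring (default 4).
#' @return An object of class `eh_topology`: a list with `compartments`
#'   (character vector), `corridors` (data frame with columns `corridor`,
#'   `antenna_a`, `antenna_b`, `compartment_a`, `compartment_b`) and
#'   `antenna_home` (named character vector mapping each antenna id to its
#'   adjacent compartment).
#' @examples
#' topo <- ring_topology()
#' topo$antenna_home[["3"]]  # antenna 3 sits at the C2 end of corridor 2
#' @export
ring_topology <- function(n_compartments = 4) {
  stopifnot(is.numeric(n_compartments), n_compartments >= 3)
  n <- as.integer(n_compartments)
  comp <- paste0("C", seq_len(n))
  nxt <- c(seq_len(n)[-1], 1L)
  corridors <- data.frame(
    corridor = seq_len(n),
    antenna_a = 2L * seq_len(n) - 1L,
    antenna_b = 2L * seq_len(n),
    compartment_a = comp,
    compartment_b = comp[nxt],
    stringsAsFactors = FALSE
  )
  topology(corridors, compartments = comp)
}

#' Build and validate a habitat topology from an explicit corridor table
#'
#' @param corridors Data frame with columns `corridor`, `antenna_a`,
#'   `antenna_b`, `compartment_a`, `compartment_b`; antenna ids are the two
#'   ends of the corridor, `antenna_a` adjacent to `compartment_a`.
#' @param compartments Optional ordered character vector of compartment
#'   labels; defaults to the sorted labels appearing in `corridors`.
#' @return An `eh_topology` object; see [ring_topology()].
#' @export
topology <- function(corridors, compartments = NULL) {
  need <- c("corridor", "antenna_a", "antenna_b", "compartment_a", "compartment_b")
  if (!all(need %in% names(corridors))) {
    stop("corridor table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(compartments)) {
    compartments <- sort(unique(c(corridors$compartment_a, corridors$compartment_b)))
  }
  antennas <- c(corridors$antenna_a, corridors$antenna_b)
  if (anyDuplicated(antennas)) {
    stop("each antenna must belong to exactly one corridor; duplicated antenna id ",
         antennas[duplicated(antennas)][1])
  }
  touches <- table(c(corridors$compartment_a, corridors$compartment_b))
  bad <- setdiff(compartments, names(touches)[touches == 2])
  if (length(bad)) {
    stop("ring topology requires every compartment to touch exactly two corridors; ",
         "violated by: ", paste(bad, collapse = ", "))
  }
  antenna_home <- c(
    stats::setNames(corridors$compartment_a, corridors$antenna_a),
    stats::setNames(corridors$compartment_b, corridors$antenna_b)
  )
  antenna_home <- antenna_home[order(as.integer(names(antenna_home)))]
  structure(
    list(compartments = compartments, corridors = corridors,
         antenna_home = antenna_home),
    class = "eh_topology"
  )
}

#' @export
print.eh_topology <- function(x, ...) {
  cat(sprintf("<eh_topology> %d compartments (%s), %d corridors, %d antennas\n",
              length(x$compartments), paste(x$compartments, collapse = ", "),
              nrow(x$corridors), length(x$antenna_home)))
  invisible(x)
}

# corridor id for each antenna, as a named integer vector
antenna_corridor <- function(topology) {
  with(topology$corridors, {
    v <- c(stats::setNames(corridor, antenna_a), stats::setNames(corridor, antenna_b))
    v[order(as.integer(names(v)))]
  })
}

#' Light/dark phase schedule
#'
#' Builds the experiment timeline as alternating 12 h light and dark phases
#' (durations configurable), labeled `light1, dark1, ..., lightN, darkN`.
#' Time is in seconds since session start; phases are half-open
#' `[start_s, end_s)` and tile the session.
#'
#' @param n_days Number of experiment days (one light + one dark phase each).
#' @param light_s,dark_s Phase durations in seconds (default 43200 = 12 h).
#' @param lights_on_first If `TRUE` (default) each day starts with the light
#'   phase.
#' @return A data frame of class `eh_phase_schedule` with columns `label`,
#'   `kind` (`"light"` or `"dark"`), `start_s`, `end_s`.
#' @examples
#' sch <- phase_schedule(6)
#' phase_window(sch, "dark3")
#' @export
phase_schedule <- function(n_days = 6, light_s = 43200, dark_s = 43200,
                           lights_on_first = TRUE) {
  stopifnot(n_days >= 1, light_s > 0, dark_s > 0)
  kinds <- if (lights_on_first) c("light", "dark") else c("dark", "light")
  durs <- if (lights_on_first) c(light_s, dark_s) else c(dark_s, light_s)
  kind <- rep(kinds, n_days)
  dur <- rep(durs, n_days)
  end_s <- cumsum(dur)
  start_s <- c(0, end_s[-length(end_s)])
  label <- paste0(kind, rep(seq_len(n_days), each = 2))
  as_phase_schedule(data.frame(label = label, kind = kind,
                               start_s = start_s, end_s = end_s,
                               stringsAsFactors = FALSE))
}

#' Validate an explicit phase table as a schedule
#'
#' @param phases Data frame with columns `label`, `kind`, `start_s`, `end_s`.
#' @return The validated `eh_phase_schedule`.
#' @export
as_phase_schedule <- function(phases) {
  need <- c("label", "kind", "start_s", "end_s")
  if (!all(need %in% names(phases))) {
    stop("phase table must have columns: ", paste(need, collapse = ", "))
  }
  phases <- phases[order(phases$start_s), need, drop = FALSE]
  if (anyDuplicated(phases$label)) {
    stop("phase labels must be unique; duplicated: ",
         phases$label[duplicated(phases$label)][1])
  }
  if (!all(phases$kind %in% c("light", "dark"))) {
    stop("phase kind must be 'light' or 'dark'")
  }
  if (any(phases$end_s <= phases$start_s)) stop("phases must have positive duration")
  if (nrow(phases) > 1 &&
      any(phases$start_s[-1] < phases$end_s[-nrow(phases)] - 1e-9)) {
    stop("phases must be non-overlapping and ascending")
  }
  rownames(phases) <- NULL
  class(phases) <- c("eh_phase_schedule", "data.frame")
  phases
}

#' Half-open time window of a named phase
#'
#' @param schedule An `eh_phase_schedule`.
#' @param label A phase label present in the schedule.
#' @return Numeric length-2 vector `c(start_s, end_s)`.
#' @export
phase_window <- function(schedule, label) {
  i <- match(label, schedule$label)
  if (is.na(i)) stop("unknown phase label: ", label)
  c(schedule$start_s[i], schedule$end_s[i])
}

#' Session end time of a schedule (seconds)
#' @param schedule An `eh_phase_schedule`.
#' @return The end of the last phase, in seconds since session start.
#' @export
session_end <- function(schedule) max(schedule$end_s)
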