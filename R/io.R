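#' Read an antenna-crossing event stream
#'
#' Events CSV dialect: header `time_ms,antenna,tag`; `time_ms` is integer
#' milliseconds since session start, `antenna` an integer id known to the
#' topology, `tag` an opaque animal identifier.  Times are converted to
#' seconds on read.  Rows are returned sorted by `(time_s, antenna, tag)`;
#' out-of-order input is accepted and sorted with a logged warning count.
#'
#' @param path Path to the events CSV file.
#' @param topology An `eh_topology`; rows with antenna ids unknown to it are
#'   rejected with an error naming the offending line.
#' @return A data frame with columns `time_s` (numeric seconds, millisecond
#'   resolution), `antenna` (integer), `tag` (character), sorted by
#'   `(time_s, antenna, tag)`.
#' @export
read_events <- function(path, topology) {
  stopifnot(inherits(topology, "eh_topology"))
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!identical(names(raw), c("time_ms", "antenna", "tag"))) {
    stop("events file must have header 'time_ms,antenna,tag', got: ",
         paste(names(raw), collapse = ","))
  }
  time_ms <- suppressWarnings(as.numeric(raw$time_ms))
  antenna <- suppressWarnings(as.integer(raw$antenna))
  bad <- which(is.na(time_ms) | is.na(antenna) | !nzchar(raw$tag) |
                 time_ms < 0)
  if (length(bad)) {
    stop(sprintf("malformed event row at line %d of %s", bad[1] + 1L, path))
  }
  known <- as.integer(names(topology$antenna_home))
  alien <- which(!(antenna %in% known))
  if (length(alien)) {
    stop(sprintf("unknown antenna id %d at line %d of %s (topology has antennas %s)",
                 antenna[alien[1]], alien[1] + 1L, path,
                 paste(range(known), collapse = "-")))
  }
  ev <- data.frame(time_s = time_ms / 1000, antenna = antenna, tag = raw$tag,
                   stringsAsFactors = FALSE)
  n_disorder <- sum(diff(ev$time_s) < 0)
  if (n_disorder > 0) {
    eh_log("warn", "%d out-of-order timestamps in %s; sorting", n_disorder, path)
  }
  ev <- ev[order(ev$time_s, ev$antenna, ev$tag), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write an antenna-crossing event stream
#'
#' Inverse of [read_events()]: times are written as integer milliseconds.
#'
#' @param events Data frame with columns `time_s`, `antenna`, `tag`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("time_s", "antenna", "tag") %in% names(events)))
  out <- data.frame(
    time_ms = sprintf("%.0f", round(events$time_s * 1000)),
    antenna = events$antenna,
    tag = events$tag
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' TSV dialect: header `gene_id`, `log2fc`, `pvalue`, `padj` (tab-separated);
#' missing p-values are encoded as empty fields or `"NA"` and preserved as
#' `NA` (never coerced to 0 or 1, so the significance filter sees true
#' missingness).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `gene_id` (character, unique), `log2fc`,
#'   `pvalue`, `padj` (numeric, possibly `NA`).
#' @export
read_deg_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", strip.white = TRUE,
                           na.strings = NULL)
  need <- c("gene_id", "log2fc", "pvalue", "padj")
  if (!identical(names(raw), need)) {
    stop("DEG table must have header gene_id<TAB>log2fc<TAB>pvalue<TAB>padj, got: ",
         paste(names(raw), collapse = ", "))
  }
  if (anyDuplicated(raw$gene_id)) {
    stop("duplicate gene_id in ", path, ": ",
         raw$gene_id[duplicated(raw$gene_id)][1])
  }
  parse_num <- function(x, col, missing_ok = TRUE) {
    miss <- x == "" | x == "NA"
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !miss)
    if (length(bad)) {
      stop(sprintf("unparseable %s value '%s' at line %d of %s",
                   col, x[bad[1]], bad[1] + 1L, path))
    }
    if (!missing_ok && any(miss)) {
      stop(sprintf("missing %s at line %d of %s", col, which(miss)[1] + 1L, path))
    }
    v
  }
  data.frame(
    gene_id = raw$gene_id,
    log2fc = parse_num(raw$log2fc, "log2fc", missing_ok = FALSE),
    pvalue = parse_num(raw$pvalue, "pvalue"),
    padj = parse_num(raw$padj, "padj"),
    stringsAsFactors = FALSE
  )
}

#' Write a differential-expression result table
#'
#' Inverse of [read_deg_table()]; missing values are written as `NA`.
#'
#' @param table Data frame with columns `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path) {
  stopifnot(all(c("gene_id", "log2fc", "pvalue", "padj") %in% names(table)))
  utils::write.table(table[, c("gene_id", "log2fc", "pvalue", "padj")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read/write reconstructed or ground-truth occupancy tracks
#'
#' Long-form CSV dialect `tag,location,start_ms,end_ms`; in memory, tracks
#' are a named list (one element per animal) of data frames with columns
#' `location`, `start_s`, `end_s` (half-open intervals tiling the session).
#'
#' @param tracks Named list of per-animal track data frames.
#' @param path CSV path.
#' @return `write_tracks()`: `path` invisibly; `read_tracks()`: the named
#'   list of tracks.
#' @export
write_tracks <- function(tracks, path) {
  long <- do.call(rbind, lapply(names(tracks), function(tg) {
    tr <- tracks[[tg]]
    data.frame(tag = tg, location = tr$location,
               start_ms = sprintf("%.0f", round(tr$start_s * 1000)),
               end_ms = sprintf("%.0f", round(tr$end_s * 1000)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  long <- utils::read.csv(path, colClasses = "character")
  need <- c("tag", "location", "start_ms", "end_ms")
  if (!identical(names(long), need)) {
    stop("tracks file must have header tag,location,start_ms,end_ms")
  }
  start_s <- as.numeric(long$start_ms) / 1000
  end_s <- as.numeric(long$end_ms) / 1000
  if (anyNA(start_s) || anyNA(end_s)) stop("unparseable interval bounds in ", path)
  split_idx <- split(seq_len(nrow(long)), long$tag)
  lapply(split_idx, function(ix) {
    tr <- data.frame(location = long$location[ix],
                     start_s = start_s[ix], end_s = end_s[ix],
                     stringsAsFactors = FALSE)
    tr <- tr[order(tr$start_s), , drop = FALSE]
    rownames(tr) <- NULL
    tr
  })
}

#' Load a YAML analysis configuration
#'
#' The configuration is a single declarative YAML file with sections
#' `topology`, `phases`, `analysis` and `simulation`.  All omitted keys are
#' materialized from documented defaults and the result is logged together
#' with the file's MD5 hash.  See `system.file("extdata",
#' "default_config.yaml", package = "ecosoc")` for the packaged default:
#' a 4-compartment ring with 8 antennas and a 6-day, 12 h/12 h protocol.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `topology` (`eh_topology`), `schedule`
#'   (`eh_phase_schedule`), `analysis` (list of analysis parameters),
#'   `simulation` (list of simulator parameters) and `config_hash`
#'   (MD5 of the file).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)

  topo_cfg <- cfg$topology
  if (!is.null(topo_cfg$corridors)) {
    cor <- do.call(rbind, lapply(topo_cfg$corridors, function(r) {
      need <- c("corridor", "antenna_a", "antenna_b", "compartment_a", "compartment_b")
      if (!all(need %in% names(r))) {
        stop("corridor record missing antenna/compartment mapping: needs ",
             paste(need, collapse = ", "))
      }
      data.frame(corridor = as.integer(r$corridor),
                 antenna_a = as.integer(r$antenna_a),
                 antenna_b = as.integer(r$antenna_b),
                 compartment_a = r$compartment_a,
                 compartment_b = r$compartment_b,
                 stringsAsFactors = FALSE)
    }))
    topo <- topology(cor, compartments = topo_cfg$compartments)
  } else {
    topo <- ring_topology(topo_cfg$n_compartments %||% 4)
  }

  ph_cfg <- cfg$phases
  if (!is.null(ph_cfg$phases)) {
    ph <- do.call(rbind, lapply(ph_cfg$phases, function(p) {
      data.frame(label = p$label, kind = p$kind,
                 start_s = as.numeric(p$start_s), end_s = as.numeric(p$end_s),
                 stringsAsFactors = FALSE)
    }))
    sch <- as_phase_schedule(ph)
  } else {
    sch <- phase_schedule(
      n_days = ph_cfg$n_days %||% 6,
      light_s = ph_cfg$light_s %||% 43200,
      dark_s = ph_cfg$dark_s %||% 43200,
      lights_on_first = ph_cfg$lights_on_first %||% TRUE
    )
  }

  an <- cfg$analysis
  analysis <- list(
    max_transit_s = an$max_transit_s %||% 30,
    assessment_phases = unlist(an$assessment_phases) %||% c("dark3", "dark4", "dark5"),
    odor_test_phase = an$odor_test_phase %||% "dark6",
    odor_baseline_phase = an$odor_baseline_phase %||% "dark5",
    stimulus_compartment = an$stimulus_compartment %||% "C3",
    neutral_compartment = an$neutral_compartment %||% "C1",
    epsilon_s = an$epsilon_s %||% 1.0,
    lfc_threshold = an$lfc_threshold %||% 1.0,
    fdr_threshold = an$fdr_threshold %||% 0.05
  )
  for (lbl in c(analysis$assessment_phases, analysis$odor_test_phase,
                analysis$odor_baseline_phase)) {
    if (!(lbl %in% sch$label)) {
      stop("analysis refers to phase '", lbl, "' absent from the schedule")
    }
  }

  si <- cfg$simulation
  simulation <- list(
    n_mice = si$n_mice %||% 12L,
    leave_rate_dark = si$leave_rate_dark %||% (1 / 300),
    leave_rate_light = si$leave_rate_light %||% (1 / 900),
    kappa_stay = si$kappa_stay %||% 1.0,
    kappa_dest = si$kappa_dest %||% 1.0,
    transit_s = si$transit_s %||% 2.0,
    p_miss = si$p_miss %||% 0.0,
    seed = si$seed %||% 1L
  )

  hash <- unname(tools::md5sum(path))
  eh_log("info", "config %s (md5 %s): %d compartments, %d antennas, %d phases, seed %d",
         basename(path), hash, length(topo$compartments),
         length(topo$antenna_home), nrow(sch), as.integer(simulation$seed))
  list(topology = topo, schedule = sch, analysis = analysis,
       simulation = simulation, config_hash = hash)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
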