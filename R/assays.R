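# Closed-form per-animal assay measures.

#' Three-chamber social preference index
#'
#' `SI = (TS - TNS) / (TS + TNS)` where `TS` is the time interacting with
#' the social-stimulus cup and `TNS` the time with the control cup; the
#' index lies in `[-1, 1]`, positive when the social stimulus is preferred.
#' Vectorized over animals.
#'
#' @param TS,TNS Non-negative interaction times in seconds.
#' @return Numeric vector in `[-1, 1]`; `NA` (with a logged warning) where
#'   `TS + TNS == 0`.
#' @export
social_preference_index <- function(TS, TNS) {
  stopifnot(length(TS) == length(TNS))
  if (any(TS < 0 | TNS < 0, na.rm = TRUE)) stop("interaction times must be >= 0")
  tot <- TS + TNS
  undef <- !is.na(tot) & tot == 0
  if (any(undef)) {
    eh_log("warn", "%d animal(s) with TS + TNS = 0: SI undefined", sum(undef))
  }
  out <- (TS - TNS) / tot
  out[undef] <- NA_real_
  out
}

#' Percent correct responses in an operant session
#'
#' Percentage of visits to the rewarded corner in which the first nosepoke
#' was directed at the reward side, out of all visits to that corner in the
#' session.
#'
#' @param visits Data frame with columns `tag`, `session`, `corner`,
#'   `first_nosepoke_side` (`"reward"` or `"other"`), `licks_reward`,
#'   `licks_other` (one row per visit).
#' @param session Session label to score.
#' @param corner Optional corner label; defaults to all corners present
#'   (use when `visits` is already restricted to the rewarded corner).
#' @param by_animal If `TRUE` (default) return a named vector per animal;
#'   otherwise a single pooled percentage.
#' @return Percentage(s) in `[0, 100]`; `NA` where an animal has no
#'   qualifying visits.
#' @export
percent_correct <- function(visits, session, corner = NULL, by_animal = TRUE) {
  v <- visits[visits$session == session, , drop = FALSE]
  if (!is.null(corner)) v <- v[v$corner == corner, , drop = FALSE]
  if (!all(v$first_nosepoke_side %in% c("reward", "other"))) {
    stop("first_nosepoke_side must be 'reward' or 'other'")
  }
  if (!by_animal) {
    if (nrow(v) == 0) return(NA_real_)
    return(100 * mean(v$first_nosepoke_side == "reward"))
  }
  if (nrow(v) == 0) {
    eh_log("warn", "no qualifying visits in session %s", session)
    return(stats::setNames(numeric(0), character(0)))
  }
  vapply(split(v$first_nosepoke_side, v$tag),
         function(x) 100 * mean(x == "reward"), 0)
}

#' Sucrose preference from lick counts
#'
#' Percentage of licks at the sucrose (reward) bottle relative to total
#' licks in the session.
#'
#' @inheritParams percent_correct
#' @return Percentage(s) in `[0, 100]`; `NA` where total licks are zero.
#' @export
sucrose_preference <- function(visits, session, corner = NULL, by_animal = TRUE) {
  v <- visits[visits$session == session, , drop = FALSE]
  if (!is.null(corner)) v <- v[v$corner == corner, , drop = FALSE]
  if (any(v$licks_reward < 0 | v$licks_other < 0)) stop("lick counts must be >= 0")
  pref <- function(r, o) {
    tot <- sum(r) + sum(o)
    if (tot == 0) NA_real_ else 100 * sum(r) / tot
  }
  if (!by_animal) return(pref(v$licks_reward, v$licks_other))
  rs <- split(v$licks_reward, v$tag)
  os <- split(v$licks_other, v$tag)
  out <- mapply(pref, rs, os)
  if (anyNA(out)) eh_log("warn", "%d animal(s) with zero total licks", sum(is.na(out)))
  out
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' `2^-((Ct_target_sample - Ct_ref_sample) - (Ct_target_control -
#' Ct_ref_control))`.  Each argument may contain technical replicates, which
#' are averaged on the Ct scale before the difference is taken.
#'
#' @param ct_target_sample,ct_ref_sample Ct values of the target and
#'   reference gene in the sample condition.
#' @param ct_target_control,ct_ref_control Ct values in the control
#'   (calibrator) condition.
#' @return A single fold change (1 = no change relative to control after
#'   normalization to the reference gene).
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (mean(ct_target_sample) - mean(ct_ref_sample)) -
    (mean(ct_target_control) - mean(ct_ref_control))
  2^(-ddct)
}
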