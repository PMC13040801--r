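# Composite autistic-like score on [0, 3].

#' Min-max standardization across a cohort
#'
#' Maps each value by `(x - min) / (max - min)` using the cohort minimum and
#' maximum, so the cohort minimum maps to 0 and the maximum to 1.  A
#' degenerate cohort (all values equal) maps every animal to 0.5 with a
#' logged warning: the score stays defined while that domain carries no
#' information.
#'
#' @param values Numeric vector of at least 2 finite values.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @export
minmax_standardize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to standardize")
  if (!all(is.finite(values))) stop("values must be finite")
  rng <- max(values) - min(values)
  if (rng == 0) {
    eh_log("warn", "degenerate cohort: all %d values equal (%.4g); standardizing to 0.5",
           length(values), values[1])
    return(rep(0.5, length(values)))
  }
  (values - min(values)) / rng
}

#' Composite autistic-like score
#'
#' Builds the composite index from four per-animal behavioral parameters:
#' sociability (group home-cage test), approach to social odor, three-chamber
#' social preference index, and marbles buried.  Each parameter is min-max
#' standardized across the supplied cohort; the two social-interest measures
#' (odor approach and preference index) are averaged so each of the three
#' domains — social interaction, social interest, repetitive behavior —
#' contributes equally; the prosocial domains are inverted (`1 -`
#' standardized value) so that higher always means more autistic-like; and
#' the three domain scores are summed:
#' `score = (1 - std_sociability) + (1 - std_social_interest) +
#' std_repetitive`, giving a score in `[0, 3]`.
#'
#' The standardization cohort is exactly the set of profiles passed in;
#' whether that is one sex, one genotype or the whole experiment is the
#' caller's choice.
#'
#' @param profiles Data frame with columns `tag`, `sociability`,
#'   `odor_ratio`, `si`, `marbles` (at least 2 complete rows).  Animals with
#'   any missing parameter are excluded from standardization and output,
#'   with a logged warning.
#' @return Data frame `tag`, `std_sociability`, `std_odor`, `std_si`,
#'   `std_social_interest`, `std_repetitive`, `score`.
#' @export
autistic_score <- function(profiles) {
  need <- c("tag", "sociability", "odor_ratio", "si", "marbles")
  if (!all(need %in% names(profiles))) {
    stop("profiles must have columns: ", paste(need, collapse = ", "))
  }
  num <- profiles[, c("sociability", "odor_ratio", "si", "marbles")]
  complete <- stats::complete.cases(num) &
    apply(num, 1, function(r) all(is.finite(as.numeric(r))))
  if (any(!complete)) {
    eh_log("warn", "excluding %d animal(s) with missing parameters: %s",
           sum(!complete), paste(profiles$tag[!complete], collapse = ", "))
  }
  p <- profiles[complete, , drop = FALSE]
  if (nrow(p) < 2) stop("need at least 2 complete profiles")
  std_soc <- minmax_standardize(p$sociability)
  std_odor <- minmax_standardize(p$odor_ratio)
  std_si <- minmax_standardize(p$si)
  std_rep <- minmax_standardize(p$marbles)
  std_interest <- (std_odor + std_si) / 2
  data.frame(
    tag = p$tag,
    std_sociability = std_soc,
    std_odor = std_odor,
    std_si = std_si,
    std_social_interest = std_interest,
    std_repetitive = std_rep,
    score = (1 - std_soc) + (1 - std_interest) + std_rep,
    stringsAsFactors = FALSE
  )
}
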