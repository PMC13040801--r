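#' Simulator configuration for a group-housed cohort on the ring habitat
#'
#' Parameters of the continuous-time Markov movement model used by
#' [simulate_cohort()].  Each mouse occupies one compartment of the ring (or
#' a corridor while in transit).  A mouse in compartment *c* leaves with
#' hazard `leave_rate_<phase> * exp(-kappa_stay * sum_j a_ij * [j in c])`,
#' i.e. co-location with affine partners lowers the leaving hazard; on
#' leaving it picks one of the two ring neighbours *c'* with weight
#' `exp(pref[i, c'] + kappa_dest * sum_j a_ij * [j in c'])`.  Hazards are
#' piecewise constant between state changes, so the joint process is sampled
#' exactly (Gillespie-style: total rate, exponential waiting time,
#' categorical mover/destination).
#'
#' @param n_mice Number of animals (> 0).
#' @param tags Animal identifiers; default `m01, m02, ...`.
#' @param pref `n_mice x 4` matrix of per-compartment log preference
#'   weights; default all 0 (uniform).
#' @param affinity Symmetric non-negative `n_mice x n_mice` matrix `a_ij`
#'   with zero diagonal; 0 means independent movement.  Default all 0.
#' @param leave_rate_dark,leave_rate_light Leaving hazards in 1/s.  Defaults
#'   1/300 and 1/900: dark-phase activity dominates, as in the protocol this
#'   simulator emulates; the values themselves are simulator conventions.
#' @param kappa_stay,kappa_dest Dimensionless affinity coupling strengths.
#' @param transit_s Fixed corridor crossing time in seconds.
#' @param p_miss Probability that any single antenna read is dropped,
#'   independently per read; in `[0, 1)`.
#' @param schedule An `eh_phase_schedule`; default [phase_schedule()] with
#'   six 12 h/12 h days.
#' @param odor Optional list `list(phase =, compartment =, delta =)` adding
#'   a per-mouse preference increment `delta` (length `n_mice` or 1) for the
#'   stimulus compartment during the named phase, emulating an olfactory cue.
#' @param seed Integer RNG seed; identical configurations and seeds give
#'   identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_mice = 12, tags = sprintf("m%02d", seq_len(n_mice)),
                       pref = NULL, affinity = NULL,
                       leave_rate_dark = 1 / 300, leave_rate_light = 1 / 900,
                       kappa_stay = 1, kappa_dest = 1, transit_s = 2,
                       p_miss = 0, schedule = phase_schedule(6),
                       odor = NULL, seed = 1L) {
  n_mice <- as.integer(n_mice)
  if (n_mice < 1) stop("n_mice must be >= 1")
  stopifnot(length(tags) == n_mice, !anyDuplicated(tags))
  if (is.null(pref)) pref <- matrix(0, n_mice, 4)
  pref <- as.matrix(pref)
  stopifnot(nrow(pref) == n_mice, ncol(pref) >= 3)
  if (is.null(affinity)) affinity <- matrix(0, n_mice, n_mice)
  affinity <- as.matrix(affinity)
  if (!isTRUE(all.equal(affinity, t(affinity))) || any(affinity < 0) ||
      any(diag(affinity) != 0)) {
    stop("affinity must be symmetric and non-negative with zero diagonal")
  }
  if (leave_rate_dark <= 0 || leave_rate_light <= 0) stop("leave rates must be > 0")
  if (transit_s <= 0) stop("transit_s must be > 0")
  if (p_miss < 0 || p_miss >= 1) stop("p_miss must be in [0, 1)")
  stopifnot(inherits(schedule, "eh_phase_schedule"), nrow(schedule) >= 1)
  if (!is.null(odor)) {
    stopifnot(all(c("phase", "compartment", "delta") %in% names(odor)))
    if (!(odor$phase %in% schedule$label)) stop("odor phase not in schedule")
    if (length(odor$delta) == 1) odor$delta <- rep(odor$delta, n_mice)
    stopifnot(length(odor$delta) == n_mice)
  }
  structure(
    list(n_mice = n_mice, tags = tags, pref = pref, affinity = affinity,
         leave_rate_dark = leave_rate_dark, leave_rate_light = leave_rate_light,
         kappa_stay = kappa_stay, kappa_dest = kappa_dest,
         transit_s = transit_s, p_miss = p_miss, schedule = schedule,
         odor = odor, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# growable record buffer (amortized O(1) append)
new_buffer <- function(ncol, init = 1024L) {
  env <- new.env(parent = emptyenv())
  env$m <- matrix(NA_real_, init, ncol)
  env$n <- 0L
  env
}
buf_push <- function(env, row) {
  if (env$n == nrow(env$m)) {
    env$m <- rbind(env$m, matrix(NA_real_, nrow(env$m), ncol(env$m)))
  }
  env$n <- env$n + 1L
  env$m[env$n, ] <- row
}
buf_get <- function(env) env$m[seq_len(env$n), , drop = FALSE]

#' Simulate antenna events and ground truth for a housed cohort
#'
#' Event-driven exact simulation of the joint movement process described in
#' [sim_config()].  Every completed move emits two antenna reads — the
#' origin-side antenna of the traversed corridor at departure and the
#' destination-side antenna `transit_s` later — each independently dropped
#' with probability `p_miss`.  Ground-truth occupancy intervals (compartment
#' and corridor) tile `[0, session_end)` exactly for every mouse.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#' \describe{
#'   \item{events}{data frame `time_s`, `antenna`, `tag`, sorted by
#'     `(time_s, antenna, tag)`, times rounded to milliseconds (the file
#'     dialect's resolution);}
#'   \item{truth}{list with `tracks` (named list of per-mouse data frames
#'     `location`, `start_s`, `end_s` tiling the session), `affinity` (the
#'     generating matrix) and `config`;}
#'   \item{topology}{the `eh_topology` of the simulated habitat.}
#' }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_mice
  nc <- ncol(config$pref)
  topo <- ring_topology(nc)
  comp_labels <- topo$compartments
  sch <- config$schedule
  end_s <- session_end(sch)
  aff <- config$affinity
  has_aff <- any(aff > 0)
  ks <- config$kappa_stay
  kd <- config$kappa_dest
  transit <- config$transit_s
  p_miss <- config$p_miss

  # ring neighbour and antenna lookup (default numbering: corridor k joins
  # Ck to C(k mod nc + 1) with antennas 2k-1 on the Ck side, 2k opposite)
  nxt <- c(seq_len(nc)[-1], 1L)
  prv <- c(nc, seq_len(nc)[-nc])
  ant_dep_fwd <- 2L * seq_len(nc) - 1L   # leaving c towards nxt[c]
  ant_arr_fwd <- 2L * seq_len(nc)
  ant_dep_bwd <- 2L * prv                # leaving c towards prv[c]
  ant_arr_bwd <- 2L * prv - 1L

  lam <- ifelse(sch$kind == "dark", config$leave_rate_dark, config$leave_rate_light)

  pref_phase <- function(ph) {
    p <- config$pref
    if (!is.null(config$odor) && sch$label[ph] == config$odor$phase) {
      ci <- match(config$odor$compartment, comp_labels)
      p[, ci] <- p[, ci] + config$odor$delta
    }
    p
  }

  ph <- 1L
  pref_eff <- pref_phase(ph)

  # initial compartments ~ softmax of phase-1 preferences
  loc <- integer(n)
  for (i in seq_len(n)) {
    w <- exp(pref_eff[i, ] - max(pref_eff[i, ]))
    loc[i] <- sample.int(nc, 1L, prob = w)
  }
  arr_t <- rep(Inf, n)       # pending arrival times (Inf = not in transit)
  arr_dest <- integer(n)
  arr_ant <- integer(n)
  cur_start <- numeric(n)    # start of the current ground-truth interval

  ev <- new_buffer(3L)       # time, antenna, mouse index
  tr <- new_buffer(4L)       # mouse, location code (comp idx or 0=corridor), start, end
  emit <- function(time, ant, i) {
    if (stats::runif(1) >= p_miss) buf_push(ev, c(time, ant, i))
  }

  t <- 0
  repeat {
    t_arr <- min(arr_t)
    t_next <- min(t_arr, sch$end_s[ph])
    act <- which(loc > 0L)
    if (length(act)) {
      if (has_aff) {
        co <- vapply(act, function(i) sum(aff[i, act[loc[act] == loc[i]]]), 0)
        h <- lam[ph] * exp(-ks * co)
      } else {
        h <- rep(lam[ph], length(act))
      }
      rtot <- sum(h)
    } else rtot <- 0

    dt <- if (rtot > 0) stats::rexp(1L, rtot) else Inf

    if (t + dt < t_next) {
      # a mouse leaves its compartment
      t <- t + dt
      i <- if (length(act) == 1L) act else act[sample.int(length(act), 1L, prob = h)]
      c0 <- loc[i]
      wf <- exp(pref_eff[i, nxt[c0]] + kd * sum(aff[i, loc == nxt[c0]]))
      wb <- exp(pref_eff[i, prv[c0]] + kd * sum(aff[i, loc == prv[c0]]))
      fwd <- stats::runif(1) < wf / (wf + wb)
      buf_push(tr, c(i, c0, cur_start[i], t))
      cur_start[i] <- t
      loc[i] <- 0L
      arr_t[i] <- t + transit
      if (fwd) {
        arr_dest[i] <- nxt[c0]; arr_ant[i] <- ant_arr_fwd[c0]
        emit(t, ant_dep_fwd[c0], i)
      } else {
        arr_dest[i] <- prv[c0]; arr_ant[i] <- ant_arr_bwd[c0]
        emit(t, ant_dep_bwd[c0], i)
      }
    } else {
      t <- t_next
      if (t >= end_s) break
      if (t_arr <= sch$end_s[ph]) {
        # corridor transit completes (ties broken by mouse index)
        i <- which.min(arr_t)
        buf_push(tr, c(i, 0, cur_start[i], t))
        cur_start[i] <- t
        loc[i] <- arr_dest[i]
        arr_t[i] <- Inf
        emit(t, arr_ant[i], i)
      } else {
        ph <- ph + 1L
        pref_eff <- pref_phase(ph)
      }
    }
  }
  # close open intervals at session end
  for (i in seq_len(n)) {
    if (cur_start[i] < end_s) {
      buf_push(tr, c(i, if (loc[i] > 0L) loc[i] else 0, cur_start[i], end_s))
    }
  }

  evm <- buf_get(ev)
  events <- data.frame(
    time_s = round(evm[, 1] * 1000) / 1000,
    antenna = as.integer(evm[, 2]),
    tag = config$tags[as.integer(evm[, 3])],
    stringsAsFactors = FALSE
  )
  events <- events[order(events$time_s, events$antenna, events$tag), , drop = FALSE]
  rownames(events) <- NULL

  trm <- buf_get(tr)
  loc_label <- c("CORRIDOR", comp_labels)[trm[, 2] + 1]
  tracks <- stats::setNames(lapply(seq_len(n), function(i) {
    sel <- trm[, 1] == i
    d <- data.frame(location = loc_label[sel],
                    start_s = trm[sel, 3], end_s = trm[sel, 4],
                    stringsAsFactors = FALSE)
    d <- d[order(d$start_s), , drop = FALSE]
    rownames(d) <- NULL
    d
  }), config$tags)

  list(events = events,
       truth = list(tracks = tracks, affinity = aff, config = config),
       topology = topo)
}

#' Simulate three-chamber interaction times
#'
#' Interaction bouts with the social and non-social stimulus cups are drawn
#' from gamma distributions: `TS_i ~ Gamma(shape, scale * theta_i)` and
#' `TNS_i ~ Gamma(shape, scale)`, so the expected social preference index is
#' increasing in the per-animal preference multiplier `theta_i` and is 0 in
#' distribution when `theta_i = 1`.
#'
#' @param n_animals Number of animals.
#' @param theta Per-animal preference multipliers (> 0); length 1 or
#'   `n_animals`.
#' @param shape,scale Gamma parameters of the baseline interaction time
#'   (seconds); defaults shape 2, scale 30 (mean 60 s of cup interaction in
#'   a 10-minute phase).
#' @param seed Integer RNG seed.
#' @return Data frame `tag`, `TS_s`, `TNS_s`, `theta`.
#' @export
simulate_three_chamber <- function(n_animals, theta = 1, shape = 2, scale = 30,
                                   seed = 1L) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0")
  if (any(theta <= 0)) stop("theta must be > 0")
  if (length(theta) == 1) theta <- rep(theta, n_animals)
  stopifnot(length(theta) == n_animals)
  set.seed(seed)
  data.frame(
    tag = sprintf("m%02d", seq_len(n_animals)),
    TS_s = stats::rgamma(n_animals, shape = shape, scale = scale * theta),
    TNS_s = stats::rgamma(n_animals, shape = shape, scale = scale),
    theta = theta,
    stringsAsFactors = FALSE
  )
}

#' Simulate marble-burying counts
#'
#' `count_i ~ Binomial(n_marbles, q_i)` with per-animal burying propensity
#' `q_i`.
#'
#' @param n_animals Number of animals.
#' @param q Per-animal burying propensities in `[0, 1]`; length 1 or
#'   `n_animals`.
#' @param n_marbles Marbles presented (default 12).
#' @param seed Integer RNG seed.
#' @return Data frame `tag`, `marbles_buried`.
#' @export
simulate_marbles <- function(n_animals, q = 0.5, n_marbles = 12, seed = 1L) {
  if (any(q < 0 | q > 1)) stop("q must be in [0, 1]")
  if (length(q) == 1) q <- rep(q, n_animals)
  stopifnot(length(q) == n_animals)
  set.seed(seed)
  data.frame(
    tag = sprintf("m%02d", seq_len(n_animals)),
    marbles_buried = stats::rbinom(n_animals, n_marbles, q),
    stringsAsFactors = FALSE
  )
}

#' Simulate IntelliCage-style visit records
#'
#' Per animal and session, `n_visits ~ Poisson(visits_per_session)` visits to
#' the rewarded corner; each visit's first nosepoke is on the reward side
#' with probability `p_correct_i`, and lick counts at the two bottles are
#' Poisson with the reward bottle favoured by `lick_bias_i`.
#'
#' @param n_animals Number of animals.
#' @param sessions Character vector of session labels.
#' @param p_correct Probability the first nosepoke is on the reward side;
#'   length 1, `n_animals`, or an `n_animals x length(sessions)` matrix.
#' @param visits_per_session Mean visits per animal and session.
#' @param mean_licks Mean licks per visit at the non-reward bottle.
#' @param lick_bias Multiplier on reward-bottle lick rate (>= 0).
#' @param corner Corner label for the rewarded corner.
#' @param seed Integer RNG seed.
#' @return Data frame `tag`, `session`, `corner`, `first_nosepoke_side`
#'   (`"reward"`/`"other"`), `licks_reward`, `licks_other`: one row per visit.
#' @export
simulate_visits <- function(n_animals, sessions = paste0("T", 1:5),
                            p_correct = 0.5, visits_per_session = 30,
                            mean_licks = 10, lick_bias = 2, corner = "corner1",
                            seed = 1L) {
  if (any(p_correct < 0 | p_correct > 1)) stop("p_correct must be in [0, 1]")
  ns <- length(sessions)
  pc <- if (is.matrix(p_correct)) p_correct else
    matrix(rep(p_correct, length.out = n_animals), n_animals, ns)
  stopifnot(nrow(pc) == n_animals, ncol(pc) == ns)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_animals)) {
    for (s in seq_len(ns)) {
      nv <- stats::rpois(1, visits_per_session)
      if (nv == 0) next
      side <- ifelse(stats::runif(nv) < pc[i, s], "reward", "other")
      rows[[length(rows) + 1]] <- data.frame(
        tag = sprintf("m%02d", i), session = sessions[s], corner = corner,
        first_nosepoke_side = side,
        licks_reward = stats::rpois(nv, mean_licks * lick_bias),
        licks_other = stats::rpois(nv, mean_licks),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a pair of differential-expression tables with a shared true-DE module
#'
#' Null genes receive `pvalue ~ Uniform(0, 1)` and `log2fc ~ Normal(0,
#' 0.25)`.  True-DE genes receive `pvalue ~ Beta(alpha, 1)` with
#' `alpha = 1 / (1 + effect_size^2)` (drawn by inverse CDF, so a saturating
#' effect size drives p-values to 0) and `|log2fc| ~ Normal(effect_size,
#' 0.25)` with random sign; genes in the shared module get the same sign in
#' both tables.  `padj` is the Benjamini-Hochberg adjustment of `pvalue`
#' within each table (via [bh_adjust()]).
#'
#' @param n_genes Universe size (rows per table).
#' @param n_shared_de True-DE genes common to both tables.
#' @param n_a_only,n_b_only True-DE genes private to table A / table B.
#' @param effect_size Dimensionless effect strength (both the mean |log2fc|
#'   and, through `alpha`, the p-value concentration near 0).
#' @param seed Integer RNG seed.
#' @return List with `table_a`, `table_b` (DEG data frames: `gene_id`,
#'   `log2fc`, `pvalue`, `padj`) and `truth` (list of gene-id vectors
#'   `shared`, `a_only`, `b_only`).
#' @export
simulate_deg_tables <- function(n_genes, n_shared_de, n_a_only, n_b_only,
                                effect_size = 5, seed = 1L) {
  if (n_shared_de + n_a_only > n_genes || n_shared_de + n_b_only > n_genes) {
    stop("true-DE counts exceed n_genes")
  }
  if (n_shared_de < 0 || n_a_only < 0 || n_b_only < 0) stop("counts must be >= 0")
  set.seed(seed)
  ids <- sprintf("g%05d", seq_len(n_genes))
  shared <- ids[seq_len(n_shared_de)]
  a_only <- ids[n_shared_de + seq_len(n_a_only)]
  b_only <- ids[n_shared_de + n_a_only + seq_len(n_b_only)]
  alpha <- 1 / (1 + effect_size^2)
  shared_sign <- sample(c(-1, 1), n_shared_de, replace = TRUE)

  one_table <- function(true_ids, shared_ids, shared_sign) {
    is_true <- ids %in% true_ids
    p <- stats::runif(n_genes)
    p[is_true] <- exp(log(stats::runif(sum(is_true))) / alpha)
    lfc <- stats::rnorm(n_genes, 0, 0.25)
    sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
    sgn[match(shared_ids, ids)] <- shared_sign
    lfc[is_true] <- (sgn * abs(stats::rnorm(n_genes, effect_size, 0.25)))[is_true]
    data.frame(gene_id = ids, log2fc = lfc, pvalue = p, padj = bh_adjust(p),
               stringsAsFactors = FALSE)
  }
  table_a <- one_table(c(shared, a_only), shared, shared_sign)
  table_b <- one_table(c(shared, b_only), shared, shared_sign)
  list(table_a = table_a, table_b = table_b,
       truth = list(shared = shared, a_only = a_only, b_only = b_only))
}
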