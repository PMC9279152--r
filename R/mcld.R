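#' Parameters of the stochastic fluctuation-assay model
#'
#' Combines the birth-death rates of untreated/resistant cells, the
#' mutation rates of sensitive and persister cells, and the treatment-
#' phase population dynamics (a [tp_parameters()] object plus the applied
#' dose).  The simulator advances all cells in fixed steps `dt`, drawing
#' at most one event (division, death, state switch, mutation) per cell
#' per step with probability `rate * dt`; validity requires
#' `dt * (sum of per-cell rates) <= 0.1`.
#'
#' @param b division rate of untreated and resistant cells (per day).
#' @param d death rate of untreated and resistant cells (per day),
#'   `d < b`.
#' @param mu_s mutation rate of sensitive cells (per cell per day).
#' @param mu_p mutation rate of persister cells (per cell per day).
#' @param tp a [tp_parameters()] object governing the treatment phase.
#' @param dose drug concentration applied during treatment (units of
#'   `1/tp$a`).
#' @param dt simulation step (days).
#' @param nu_pre rate at which expanding untreated cells are pre-assigned
#'   a persister fate (per cell per day).  Zero (default) is the
#'   drug-induced scenario; a positive value generates Luria-Delbruck
#'   distributed pre-existing persisters for scenario comparisons.
#' @param mutate_sensitive_during_treatment keep the (negligible)
#'   sensitive-cell mutation channel open under drug.
#' @return An object of class `"mcld_parameters"`.
#' @export
mcld_parameters <- function(b, d, mu_s, mu_p, tp, dose, dt = 0.05,
                            nu_pre = 0,
                            mutate_sensitive_during_treatment = TRUE) {
  stopifnot(inherits(tp, "tp_parameters"))
  if (d < 0 || b <= d)
    stop("need b > d >= 0 (expanding untreated population)", call. = FALSE)
  if (mu_s < 0 || mu_p < 0 || nu_pre < 0)
    stop("mutation/assignment rates must be nonnegative", call. = FALSE)
  if (dose < 0) stop("'dose' must be nonnegative", call. = FALSE)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  p <- structure(list(b = b, d = d, mu_s = mu_s, mu_p = mu_p, tp = tp,
                      dose = dose, dt = dt, nu_pre = nu_pre,
                      mutate_sensitive_during_treatment =
                        mutate_sensitive_during_treatment),
                 class = "mcld_parameters")
  chk <- max(dt * (b + d + mu_s + nu_pre),
             dt * (tp$B + death_rate(tp, dose) + transition_rate(tp, dose) +
                     mu_s),
             dt * (tp$Dp + mu_p))
  if (chk > 0.1)
    stop(sprintf(paste0("step-size invariant violated: dt * (total per-cell",
                        " rate) = %.3f > 0.1; reduce dt"), chk),
         call. = FALSE)
  p
}

#' Design of the two-step fluctuation experiment
#'
#' Wells are seeded with a small clonal inoculum, expanded drug-free
#' until a per-well target size (or a maximal duration) is reached, then
#' placed under constant treatment and observed for resistant colonies.
#' Colonies first visible by the early cutoff are scored "early", those
#' first visible at or after the late cutoff "late"; colonies appearing
#' in between are scored "intermediate" and ignored by the estimators.
#'
#' @param n_plates number of plates.
#' @param wells_per_plate wells per plate.
#' @param seed_cells_per_well initial cells per well.
#' @param expansion_target_cells per-well size at which expansion stops
#'   and treatment begins.
#' @param T_treat maximal drug-free expansion time (days).
#' @param T_obs treatment observation horizon (days).
#' @param early_cutoff_days early-colony cutoff (days of treatment).
#' @param late_cutoff_days late-colony cutoff (days of treatment).
#' @param colony_detection_threshold resistant-lineage size at which a
#'   colony is counted as visible (cells).
#' @param persister_read_day treatment day at which residual persister
#'   positivity is read out.
#' @return An object of class `"experiment_design"`.
#' @examples
#' d <- experiment_design()
#' d$n_plates * d$wells_per_plate  # 1920 wells
#' @export
experiment_design <- function(n_plates = 20, wells_per_plate = 96,
                              seed_cells_per_well = 500,
                              expansion_target_cells = 20000,
                              T_treat = 14, T_obs = 84,
                              early_cutoff_days = 28,
                              late_cutoff_days = 70,
                              colony_detection_threshold = 50,
                              persister_read_day = 21) {
  cnt <- c(n_plates, wells_per_plate, seed_cells_per_well,
           expansion_target_cells, colony_detection_threshold)
  if (any(cnt < 1) || any(cnt != round(cnt)))
    stop("counts must be positive integers", call. = FALSE)
  if (!(early_cutoff_days < late_cutoff_days && late_cutoff_days <= T_obs))
    stop("need early_cutoff_days < late_cutoff_days <= T_obs", call. = FALSE)
  if (T_treat <= 0 || T_obs <= 0)
    stop("durations must be positive", call. = FALSE)
  structure(list(n_plates = n_plates, wells_per_plate = wells_per_plate,
                 seed_cells_per_well = seed_cells_per_well,
                 expansion_target_cells = expansion_target_cells,
                 T_treat = T_treat, T_obs = T_obs,
                 early_cutoff_days = early_cutoff_days,
                 late_cutoff_days = late_cutoff_days,
                 colony_detection_threshold = colony_detection_threshold,
                 persister_read_day = persister_read_day),
            class = "experiment_design")
}

#' Per-well population state
#'
#' Tracks, for a batch of wells advanced in lockstep, the sensitive and
#' persister counts plus every resistant (or pre-assigned persister)
#' lineage individually: its well, origin, founding time, current size,
#' and the time it first crossed the colony-visibility threshold.
#'
#' @param sensitive integer vector of sensitive-cell counts (one entry
#'   per well).
#' @param persisters integer vector of persister counts.
#' @param t current time (days).
#' @return An object of class `"well_state"`.
#' @export
well_state <- function(sensitive, persisters = rep(0L, length(sensitive)),
                       t = 0) {
  if (any(sensitive < 0) || any(persisters < 0))
    stop("counts must be nonnegative integers", call. = FALSE)
  structure(list(S = as.integer(sensitive), P = as.integer(persisters),
                 t = t,
                 lin = list(well = integer(0), origin = character(0),
                            t_found = numeric(0), size = integer(0),
                            first_cross = numeric(0))),
            class = "well_state")
}

## sequential binomial thinning of a multinomial split: each of `n` cells
## experiences at most one event, category i with probability p[i]
split_events <- function(n, p) {
  ptot <- sum(p)
  if (ptot > 1) stop("per-cell event probability exceeds 1: reduce dt",
                     call. = FALSE)
  out <- matrix(0L, nrow = length(n), ncol = length(p))
  rem_n <- stats::rbinom(length(n), n, ptot)
  rem_p <- ptot
  for (i in seq_along(p)) {
    if (rem_p <= 0) break
    ni <- stats::rbinom(length(n), rem_n, min(1, p[i] / rem_p))
    out[, i] <- ni
    rem_n <- rem_n - ni
    rem_p <- rem_p - p[i]
  }
  out
}

## append newly founded lineages (n_new[w] founders in well w at time t)
add_lineages <- function(lin, n_new, origin, t, mask_idx = NULL) {
  tot <- sum(n_new)
  if (tot == 0L) return(lin)
  wells <- rep(if (is.null(mask_idx)) seq_along(n_new) else mask_idx, n_new)
  lin$well <- c(lin$well, wells)
  lin$origin <- c(lin$origin, rep(origin, tot))
  lin$t_found <- c(lin$t_found, rep(t, tot))
  lin$size <- c(lin$size, rep(1L, tot))
  lin$first_cross <- c(lin$first_cross, rep(NA_real_, tot))
  lin
}

## advance lineage sizes one step (birth b, death d), recording threshold
## crossings; rows with active == FALSE are frozen.  Resistant lineages
## are also frozen once they reach the visibility threshold: a colony of
## `threshold` cells has extinction probability (d/b)^threshold ~ 0, so
## freezing preserves both its established status and its crossing time
## while keeping sizes bounded.  Pre-assigned persister clones are exempt
## (their full size distribution carries the fluctuation signal).
step_lineages <- function(lin, b, d, dt, t_next, threshold,
                          active = NULL) {
  if (!length(lin$size)) return(lin)
  grow <- lin$size > 0L &
    (lin$size < threshold | lin$origin == "pre_persister")
  idx <- which(if (is.null(active)) grow else grow & active)
  if (!length(idx)) return(lin)
  sz <- lin$size[idx]
  ev <- split_events(sz, c(b, d) * dt)
  sz <- sz + ev[, 1] - ev[, 2]
  lin$size[idx] <- sz
  crossed <- is.na(lin$first_cross[idx]) & sz >= threshold
  if (any(crossed)) lin$first_cross[idx][crossed] <- t_next
  lin
}

#' Advance a batch of wells by one simulation step
#'
#' One fixed-duration step of the coarse-grained stochastic branching
#' process: every cell independently experiences at most one event, drawn
#' with probability `rate * dt`.  During `"expansion"` sensitive cells
#' divide (`b`), die (`d`), mutate to resistance (`mu_s`) and may be
#' pre-assigned a persister fate (`nu_pre`); during `"treatment"`
#' sensitive cells use the TP rates (B, D(M), lambda(M)) and mutate at
#' `mu_s`, persisters die at `Dp` and mutate at `mu_p`, and resistant
#' lineages always divide/die at (`b`, `d`).  New mutants found lineages
#' tagged with their origin.
#'
#' @param state a [well_state()].
#' @param phase `"expansion"` or `"treatment"`.
#' @param params an [mcld_parameters()].
#' @param dt step size (days); defaults to `params$dt`.
#' @param threshold colony-visibility threshold for crossing times.
#' @param active optional logical mask of wells still being advanced.
#' @param rates optional override list (`b`, `d`, `mu_s`, `nu_pre`) for
#'   the expansion phase, used for analytic cross-checks.
#' @return The updated `well_state`.
#' @export
step_wells <- function(state, phase = c("expansion", "treatment"), params,
                       dt = params$dt, threshold = 50, active = NULL,
                       rates = NULL) {
  stopifnot(inherits(state, "well_state"), inherits(params, "mcld_parameters"))
  phase <- match.arg(phase)
  n <- length(state$S)
  idx <- if (is.null(active)) seq_len(n) else which(active)
  t_next <- state$t + dt
  if (phase == "expansion") {
    b <- if (is.null(rates)) params$b else rates$b
    d <- if (is.null(rates)) params$d else rates$d
    mu <- if (is.null(rates)) params$mu_s else rates$mu_s
    nu <- if (is.null(rates)) params$nu_pre else rates$nu_pre
    ev <- split_events(state$S[idx], c(b, d, mu, nu) * dt)
    state$S[idx] <- state$S[idx] + ev[, 1] - ev[, 2] - ev[, 3] - ev[, 4]
    state$lin <- add_lineages(state$lin, ev[, 3], "sensitive", t_next, idx)
    state$lin <- add_lineages(state$lin, ev[, 4], "pre_persister", t_next,
                              idx)
    lin_active <- if (is.null(active)) NULL else active[state$lin$well]
    state$lin <- step_lineages(state$lin, b, d, dt, t_next, threshold,
                               lin_active)
  } else {
    tp <- params$tp
    Dm <- death_rate(tp, params$dose)
    lam <- transition_rate(tp, params$dose)
    mu_s <- if (params$mutate_sensitive_during_treatment) params$mu_s else 0
    ev <- split_events(state$S[idx], c(tp$B, Dm, lam, mu_s) * dt)
    state$S[idx] <- state$S[idx] + ev[, 1] - ev[, 2] - ev[, 3] - ev[, 4]
    state$P[idx] <- state$P[idx] + ev[, 3]
    state$lin <- add_lineages(state$lin, ev[, 4], "sensitive", t_next, idx)
    evp <- split_events(state$P[idx], c(tp$Dp, params$mu_p) * dt)
    state$P[idx] <- state$P[idx] - evp[, 1] - evp[, 2]
    state$lin <- add_lineages(state$lin, evp[, 2], "persister", t_next, idx)
    lin_active <- if (is.null(active)) NULL else active[state$lin$well]
    state$lin <- step_lineages(state$lin, params$b, params$d, dt, t_next,
                               threshold, lin_active)
  }
  state$t <- t_next
  state
}

## full two-phase simulation of a batch of wells; optionally records
## population sizes on a grid of treatment times
sim_wells <- function(n_wells, design, params, record_times = NULL,
                      treatment_horizon = design$T_obs) {
  thr <- design$colony_detection_threshold
  state <- well_state(rep(design$seed_cells_per_well, n_wells))
  ## --- expansion, per-well clocks; wells freeze once the target is hit
  t_hit <- rep(NA_real_, n_wells)
  active <- rep(TRUE, n_wells)
  pre_done <- state$S >= design$expansion_target_cells
  t_hit[pre_done] <- 0
  active[pre_done] <- FALSE
  while (any(active)) {
    state <- step_wells(state, "expansion", params, threshold = thr,
                        active = active)
    done <- active & (state$S >= design$expansion_target_cells |
                        state$t >= design$T_treat)
    t_hit[done] <- state$t
    active[done] <- FALSE
  }
  ## expansion founding times -> treatment-relative (nonpositive)
  if (length(state$lin$t_found))
    state$lin$t_found <- state$lin$t_found - t_hit[state$lin$well]
  state$lin$first_cross[] <- 0  # visible pre-treatment colonies score at 0
  state$lin$first_cross[state$lin$size < thr] <- NA_real_
  ## pre-assigned persister lineages join the persister pool
  pre <- state$lin$origin == "pre_persister"
  if (any(pre)) {
    add <- tapply(state$lin$size[pre], state$lin$well[pre], sum)
    w <- as.integer(names(add))
    state$P[w] <- state$P[w] + as.integer(add)
    keep <- !pre
    state$lin <- lapply(state$lin, `[`, keep)
  }
  S_at_treatment <- state$S
  ## --- treatment, common clock
  state$t <- 0
  n_steps <- ceiling(treatment_horizon / params$dt)
  rec <- NULL
  if (!is.null(record_times)) {
    rec <- matrix(NA_real_, nrow = length(record_times), ncol = 3,
                  dimnames = list(NULL, c("S_mean", "P_mean", "N_mean")))
    rec_full <- vector("list", length(record_times))
    rec_idx <- pmin(pmax(round(record_times / params$dt), 0L), n_steps)
  }
  P_at_read <- rep(NA_integer_, n_wells)
  read_step <- round(design$persister_read_day / params$dt)
  record_now <- function(k) {
    if (!is.null(record_times) && any(rec_idx == k)) {
      for (j in which(rec_idx == k)) {
        rec[j, ] <<- c(mean(state$S), mean(state$P),
                       mean(state$S + state$P + res_per_well(state, n_wells)))
        rec_full[[j]] <<- state$S + state$P + res_per_well(state, n_wells)
      }
    }
  }
  record_now(0L)
  for (k in seq_len(n_steps)) {
    state <- step_wells(state, "treatment", params, threshold = thr)
    if (k == read_step) P_at_read <- state$P
    record_now(k)
  }
  if (read_step > n_steps) P_at_read <- state$P
  outcomes <- build_outcomes(state, n_wells, design, P_at_read,
                             S_at_treatment)
  list(outcomes = outcomes, state = state, t_hit = t_hit,
       record = if (is.null(record_times)) NULL else
         list(times = record_times, means = rec, N_wells = rec_full))
}

res_per_well <- function(state, n_wells) {
  out <- rep(0L, n_wells)
  if (length(state$lin$size)) {
    s <- tapply(state$lin$size, state$lin$well, sum)
    out[as.integer(names(s))] <- as.integer(s)
  }
  out
}

build_outcomes <- function(state, n_wells, design, P_at_read,
                           S_at_treatment) {
  lin <- state$lin
  first_time <- rep(NA_real_, n_wells)
  first_origin <- rep(NA_character_, n_wells)
  vis <- which(!is.na(lin$first_cross))
  if (length(vis)) {
    ord <- vis[order(lin$first_cross[vis])]
    firsts <- ord[!duplicated(lin$well[ord])]
    first_time[lin$well[firsts]] <- lin$first_cross[firsts]
    first_origin[lin$well[firsts]] <- lin$origin[firsts]
  }
  cls <- ifelse(is.na(first_time), "none",
                ifelse(first_time <= design$early_cutoff_days, "early",
                       ifelse(first_time >= design$late_cutoff_days, "late",
                              "intermediate")))
  est_s <- est_p <- rep(0L, n_wells)
  alive <- lin$size > 0L
  if (any(alive)) {
    for (orig in c("sensitive", "persister")) {
      sel <- alive & lin$origin == orig
      if (any(sel)) {
        cnt <- tapply(rep(1L, sum(sel)), lin$well[sel], sum)
        if (orig == "sensitive")
          est_s[as.integer(names(cnt))] <- as.integer(cnt)
        else est_p[as.integer(names(cnt))] <- as.integer(cnt)
      }
    }
  }
  data.frame(
    well = seq_len(n_wells),
    persister_positive = P_at_read > 0L,
    colony_time_d = first_time,
    colony_class = cls,
    colony_origin = ifelse(is.na(first_origin), "none",
                           ifelse(first_origin == "sensitive",
                                  "sensitive-derived", "persister-derived")),
    final_sensitive = state$S,
    final_persisters = state$P,
    final_resistant = res_per_well(state, n_wells),
    established_sensitive_derived = est_s,
    established_persister_derived = est_p,
    sensitive_at_treatment = S_at_treatment
  )
}

#' Simulate a single fluctuation-assay well
#'
#' Runs the drug-free expansion (until the target size or the expansion
#' deadline) followed by the treatment phase, and summarises the outcome:
#' persister positivity at the read-out day, the first colony time and
#' class, and final counts.
#'
#' @param design an [experiment_design()].
#' @param params an [mcld_parameters()].
#' @param seed optional integer seed.
#' @return A one-row well-outcome data frame (see
#'   [simulate_experiment()] for columns).
#' @export
run_well <- function(design, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim_wells(1L, design, params)$outcomes
}

#' Simulate the full multiwell fluctuation experiment
#'
#' Simulates every well of every plate, plate by plate with independent
#' reproducible RNG streams derived from `master_seed`, and returns the
#' per-well outcome table together with a per-plate summary.
#'
#' @param design an [experiment_design()].
#' @param params an [mcld_parameters()].
#' @param master_seed integer seed; identical seeds give identical
#'   outcome tables.
#' @return A list of class `"mcld_experiment"`: `outcomes` (one row per
#'   well: `well`, `plate`, `persister_positive`, `colony_time_d`,
#'   `colony_class`, `colony_origin`, final counts, established-lineage
#'   counts by origin) and `summary` (per-plate early/late colony counts
#'   and positive-well fractions).
#' @examples
#' \donttest{
#' p <- preset_parameters("widr")$assay
#' x <- simulate_experiment(experiment_design(n_plates = 2,
#'                                            wells_per_plate = 24),
#'                          p, master_seed = 1)
#' table(x$outcomes$colony_class)
#' }
#' @export
simulate_experiment <- function(design, params, master_seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "mcld_parameters"))
  set.seed(as.integer(master_seed))
  plate_seeds <- sample.int(.Machine$integer.max, design$n_plates)
  out <- vector("list", design$n_plates)
  for (pl in seq_len(design$n_plates)) {
    set.seed(plate_seeds[pl])
    o <- sim_wells(design$wells_per_plate, design, params)$outcomes
    o$plate <- pl
    o$well <- o$well + (pl - 1L) * design$wells_per_plate
    out[[pl]] <- o
  }
  outcomes <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(split(outcomes, outcomes$plate),
                                function(o) data.frame(
    plate = o$plate[1],
    wells = nrow(o),
    early_colonies = sum(o$colony_class == "early"),
    late_colonies = sum(o$colony_class == "late"),
    intermediate_colonies = sum(o$colony_class == "intermediate"),
    persister_positive_fraction = mean(o$persister_positive))))
  rownames(summ) <- NULL
  structure(list(outcomes = outcomes, summary = summ, design = design,
                 master_seed = master_seed),
            class = "mcld_experiment")
}

#' @export
print.mcld_experiment <- function(x, ...) {
  o <- x$outcomes
  cat(sprintf("Fluctuation experiment: %d wells (%d plates)\n",
              nrow(o), x$design$n_plates))
  cat(sprintf("  early colonies %d | intermediate %d | late %d\n",
              sum(o$colony_class == "early"),
              sum(o$colony_class == "intermediate"),
              sum(o$colony_class == "late")))
  cat(sprintf("  persister-positive wells: %.1f%%\n",
              100 * mean(o$persister_positive)))
  invisible(x)
}

#' Simulate per-well persister abundance under competing scenarios
#'
#' Generates the persister count per well at the read-out day under the
#' drug-induced scenario (persister fate assigned only under treatment,
#' at rate lambda(M); counts are Poisson across wells) or the
#' pre-existing scenario (persister fate assigned at a constant per-cell
#' rate during the drug-free expansion so that persister clones expand
#' with the population; counts follow a heavy-tailed Luria-Delbruck-type
#' distribution with variance far exceeding the mean).  The two
#' scenarios differ only in *when* persister fate is assigned and their
#' means can be matched, so the variance-to-mean ratio is the
#' discriminating statistic.
#'
#' @param scenario `"drug_induced"` or `"pre_existing"`.
#' @param n_wells number of wells.
#' @param params an [mcld_parameters()]; for `"pre_existing"` its
#'   `nu_pre` must be positive (see [matched_preexisting_rate()]).
#' @param design an [experiment_design()]; the read-out day is
#'   `design$persister_read_day`.
#' @param seed integer seed.
#' @return Integer vector of per-well persister counts.
#' @export
simulate_persister_counts <- function(scenario = c("drug_induced",
                                                   "pre_existing"),
                                      n_wells, params, design,
                                      seed = 1L) {
  scenario <- match.arg(scenario)
  set.seed(as.integer(seed))
  params$mu_s <- 0
  params$mu_p <- 0
  if (scenario == "drug_induced") {
    params$nu_pre <- 0
  } else if (params$nu_pre <= 0) {
    stop("pre_existing scenario needs params$nu_pre > 0", call. = FALSE)
  }
  if (scenario == "pre_existing") {
    p2 <- params
    p2$tp$k <- 0
    p2$tp$lambda0 <- 0
    params <- p2
  }
  sim <- sim_wells(n_wells, design, params,
                   treatment_horizon = design$persister_read_day)
  sim$state$P
}

#' Pre-assignment rate matching the drug-induced persister mean
#'
#' Computes the per-cell fate-assignment rate `nu_pre` for the
#' pre-existing scenario such that the expected persister count per well
#' at the read-out day matches a target mean: founders arising at rate
#' `nu` from the expanding population carry an expected
#' `X_final * t_hit * nu` descendants to treatment start, which then
#' decay at `Dp` until the read-out.
#'
#' @param target_mean desired mean persisters per well at read-out.
#' @param design an [experiment_design()].
#' @param params an [mcld_parameters()].
#' @return Rate per cell per day.
#' @export
matched_preexisting_rate <- function(target_mean, design, params) {
  g <- params$b - params$d
  t_hit <- log(design$expansion_target_cells /
                 design$seed_cells_per_well) / g
  surv <- exp(-params$tp$Dp * design$persister_read_day)
  target_mean / (design$expansion_target_cells * t_hit * surv)
}
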