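#' Three-compartment pharmacokinetic parameters with an effect site
#'
#' Rate-constant parameterization of the standard mammillary three-compartment
#' model plus a first-order effect compartment: central volume `v1` (L),
#' elimination `k10` and inter-compartmental constants `k12, k21, k13, k31`
#' (all 1/min), and the plasma-effect-site equilibration constant `ke0`
#' (1/min). Amounts are in mg and rates in mg/min, so plasma concentration
#' `Cp = a1 / v1` is in mg/L = ug/mL.
#'
#' @param v1 Central volume of distribution (L).
#' @param k10,k12,k21,k13,k31 First-order rate constants (1/min).
#' @param ke0 Effect-site equilibration rate constant (1/min).
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(v1, k10, k12, k21, k13, k31, ke0) {
  vals <- c(v1 = v1, k10 = k10, k12 = k12, k21 = k21,
            k13 = k13, k31 = k31, ke0 = ke0)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0)) {
    stop("all PK parameters must be positive numbers", call. = FALSE)
  }
  structure(as.list(vals), class = "pk_params")
}

#' Synthetic pediatric-scale PK parameter set for examples and fixtures
#'
#' Plausible propofol-like constants for a ~19 kg child (clearance about
#' 0.76 L/min, V1 about 9.5 L, fast effect-site equilibration). These are
#' *synthetic* values for self-contained simulation; they are not the
#' parameters of any published pump model, which must be supplied by the user
#' for a real concentration comparison.
#'
#' @return A [pk_params] object.
#' @export
synthetic_pediatric_pk <- function() {
  pk_params(v1 = 9.5, k10 = 0.08, k12 = 0.11, k21 = 0.055,
            k13 = 0.042, k31 = 0.0035, ke0 = 0.8)
}

# System matrix (per minute) for state x = (a1, a2, a3, Ce):
# amounts in compartments 1-3 (mg) and effect-site concentration (ug/mL).
pk_matrix <- function(pk) {
  with(pk, matrix(c(
    -(k10 + k12 + k13), k21,  k31,  0,
    k12,               -k21,  0,    0,
    k13,                0,   -k31,  0,
    ke0 / v1,           0,    0,   -ke0
  ), nrow = 4L, byrow = TRUE))
}

# Exact one-step transition operators for a constant infusion rate u (mg/min)
# over dt seconds: x(t+dt) = E %*% x(t) + G * u.
step_operators <- function(pk, dt_sec) {
  A <- pk_matrix(pk)
  dtm <- dt_sec / 60
  E <- as.matrix(Matrix::expm(A * dtm))
  G <- as.numeric(solve(A, (E - diag(4L)) %*% c(1, 0, 0, 0)))
  list(E = E, G = G)
}

#' Replay an infusion log through a PK model
#'
#' Solves the three-compartment + effect-site system for a piecewise-constant
#' infusion by per-interval matrix exponentials (exact for constant rates;
#' the rate applied over each `dt` step is the logged rate in force at the
#' step's start, so the solution is exact whenever events fall on the `dt`
#' grid).
#'
#' @param pk A [pk_params] object.
#' @param infusion An [infusion_log] for a single subject (columns `time`
#'   seconds, `rate` mg/min) or a data.frame with those columns.
#' @param dt Output/integration step in seconds; must not exceed the
#'   shortest interval between infusion events.
#' @param t_end End of simulation in seconds (default: last event time).
#' @param x0 Optional initial state `(a1, a2, a3, ce)`; default drug-free.
#' @return A data.frame of class `concentration_trajectory` with columns
#'   `time` (s), `rate` (mg/min, in force over `[time, time + dt)`),
#'   `cp` and `ce` (ug/mL).
#' @export
simulate_concentrations <- function(pk, infusion, dt = 1, t_end = NULL, x0 = NULL) {
  stopifnot(inherits(pk, "pk_params"))
  infusion <- as.data.frame(infusion)
  stopifnot(all(c("time", "rate") %in% names(infusion)))
  if (any(infusion$rate < 0)) stop("negative infusion rate", call. = FALSE)
  if (is.unsorted(infusion$time, strictly = TRUE)) {
    stop("infusion event times must be strictly increasing", call. = FALSE)
  }
  if (nrow(infusion) > 1L && dt > min(diff(infusion$time))) {
    stop("`dt` exceeds the shortest infusion interval", call. = FALSE)
  }
  if (is.null(t_end)) t_end <- max(infusion$time)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  times <- seq(0, t_end, by = dt)
  # rate in force over [t, t+dt): last event at or before t (0 before first)
  idx <- findInterval(times, infusion$time)
  rates <- c(0, infusion$rate)[idx + 1L]
  op <- step_operators(pk, dt)
  n <- length(times)
  x <- if (is.null(x0)) numeric(4L) else as.numeric(x0)
  cp <- ce <- numeric(n)
  cp[1L] <- x[1L] / pk$v1; ce[1L] <- x[4L]
  for (i in seq_len(n - 1L)) {
    x <- op$E %*% x + op$G * rates[i]
    cp[i + 1L] <- x[1L] / pk$v1
    ce[i + 1L] <- x[4L]
  }
  structure(data.frame(time = times, rate = rates, cp = cp, ce = ce),
            class = c("concentration_trajectory", "data.frame"))
}

#' Step-up effect-site TCI protocol for a study design
#'
#' Describes the observation protocol of the sedation study: effect-site
#' targets stepped up 1 to 6 ug/mL in 1 ug/mL increments, each held for
#' 2 min after it is reached, with the UMSS assessed every 20 s.
#'
#' @param targets Increasing positive effect-site targets (ug/mL).
#' @param hold_after_reach Seconds each target is held once reached
#'   (default 120); must be a multiple of `eval_step`.
#' @param eval_step Observation grid spacing in seconds (default 20).
#' @return An object of class `study_design`.
#' @export
study_design <- function(targets = 1:6, hold_after_reach = 120, eval_step = 20) {
  targets <- as.numeric(targets)
  if (any(targets <= 0) || is.unsorted(targets, strictly = TRUE)) {
    stop("`targets` must be positive and strictly increasing", call. = FALSE)
  }
  if (hold_after_reach %% eval_step != 0) {
    stop("`eval_step` must divide `hold_after_reach`", call. = FALSE)
  }
  structure(list(targets = targets, hold_after_reach = hold_after_reach,
                 eval_step = eval_step), class = "study_design")
}

#' Idealized effect-site target-controlled infusion
#'
#' Generates an infusion schedule whose simulated effect-site concentration
#' climbs through the design's target staircase: for each target the
#' controller infuses at the maximum rate that keeps the predicted plasma
#' concentration at or below 4x the target (plasma overshoot cap), throttles
#' the final approach tick so the predicted zero-input Ce peak lands on the
#' target, coasts to the peak, and then retargets Ce every control tick
#' (1 s) to hold the target. A target counts as reached when
#' `|Ce - target| <= 0.02` ug/mL on two consecutive ticks; it is then held
#' `hold_after_reach` seconds before the next step. Any controller achieving
#' the Ce staircase is equivalent for the pharmacodynamic analysis; this one
#' is deliberately simple and swappable.
#'
#' @param pk A [pk_params] object.
#' @param design A [study_design].
#' @param x0 Optional initial state (default drug-free).
#' @param tick Control interval in seconds (default 1).
#' @param max_minutes Abort with an error naming the target if a target is
#'   not reached and held within this budget (default 120).
#' @return A list with `infusion` (an [infusion_log], tick-wise rates
#'   compressed to change events plus a terminal rate-0 event), `trajectory`
#'   (tick-resolution `concentration_trajectory`) and `reach_times` (seconds
#'   at which each target was first reached).
#' @export
effect_site_step_protocol <- function(pk, design, x0 = NULL, tick = 1,
                                      max_minutes = 120) {
  stopifnot(inherits(pk, "pk_params"), inherits(design, "study_design"))
  op <- step_operators(pk, tick)
  look <- step_operators(pk, 5)      # coarse zero-input lookahead operator
  E <- op$E; G <- op$G
  peak_ce <- function(x) {
    m <- x[4L]
    for (i in seq_len(120L)) {
      x <- look$E %*% x
      if (x[4L] > m) m <- x[4L] else if (i > 2L) break
    }
    m
  }
  x <- if (is.null(x0)) numeric(4L) else as.numeric(x0)
  max_ticks <- ceiling(max_minutes * 60 / tick)
  rates <- numeric(0); cp <- x[1L] / pk$v1; ce <- x[4L]
  reach_times <- rep(NA_real_, length(design$targets))
  ki <- 1L; phase <- "approach"; in_band <- 0L; reached_at <- NA_real_
  t <- 0
  for (step_i in seq_len(max_ticks)) {
    target <- design$targets[ki]
    cap_a1 <- 4 * target * pk$v1
    xe <- E %*% x                         # zero-input state after this tick
    u_cap <- max(0, (cap_a1 - xe[1L]) / G[1L])
    u <- 0
    if (phase == "approach" && x[4L] >= target - 0.02) phase <- "track"
    if (phase == "approach") {
      # infuse so the predicted zero-input Ce peak lands on the target,
      # then coast into the band (lookahead peak is a lower bound on the
      # true peak, so the band is always entered)
      p0 <- peak_ce(xe)
      if (p0 < target) {
        pc <- peak_ce(xe + G * u_cap)
        if (pc <= target) {
          u <- u_cap
        } else {
          # land the zero-input Ce peak on the target: Newton-type updates
          # with the secant slope (the peak is nearly linear in the rate)
          slope <- max((pc - p0) / u_cap, 1e-12)
          u <- (target - p0) / slope
          for (it in 1:4) {
            p <- peak_ce(xe + G * u)
            if (abs(p - target) < 0.004) break
            u <- min(max(u + (target - p) / slope, 0), u_cap)
          }
        }
      }
    } else {
      u <- min(max(0, (target - xe[4L]) / G[4L]), u_cap)
    }
    x <- xe + G * u
    t <- t + tick
    rates <- c(rates, u); cp <- c(cp, x[1L] / pk$v1); ce <- c(ce, x[4L])
    if (phase == "track") {
      in_band <- if (abs(x[4L] - target) <= 0.02) in_band + 1L else 0L
      if (is.na(reached_at) && in_band >= 2L) {
        reached_at <- t
        reach_times[ki] <- t
      }
      if (!is.na(reached_at) && t - reached_at >= design$hold_after_reach) {
        if (ki == length(design$targets)) break
        ki <- ki + 1L; phase <- "approach"; in_band <- 0L; reached_at <- NA_real_
      }
    }
    if (step_i == max_ticks) {
      stop(sprintf("target %.3g ug/mL not reached within %g minutes",
                   target, max_minutes), call. = FALSE)
    }
  }
  times <- seq(0, by = tick, length.out = length(ce))
  traj <- structure(data.frame(time = times, rate = c(rates, 0),
                               cp = cp, ce = ce),
                    class = c("concentration_trajectory", "data.frame"))
  chg <- c(TRUE, diff(rates) != 0)
  inf <- infusion_log(data.frame(id = "protocol",
                                 time = c(times[-length(times)][chg], max(times)),
                                 rate = c(rates[chg], 0)))
  list(infusion = inf, trajectory = traj, reach_times = reach_times)
}
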