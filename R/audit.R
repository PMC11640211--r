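# Audit engine: recompute the required ventilation rate from an operation
# log, classify the ventilation/temperature discrepancies into quadrants,
# and account fan/pad runtimes and electrical energy.

#' Ventilation and temperature discrepancies of an operation log
#'
#' For every record the required ventilation rate is recomputed from the
#' logged indoor/outdoor temperatures, set temperature, humidity and bird
#' age via the heat-balance equations; the ventilation-rate discrepancy is
#' `VRR - actual` (positive = under-ventilated) and the temperature
#' discrepancy is `Td - Ti` (negative = too hot). Records with the pads
#' running are flagged so they can be excluded from the quadrant analysis.
#' A near-degenerate denominator is capped at the air-exchange rate.
#'
#' @param log A `bv_log` / data.frame with the standard log columns.
#' @param cfg A [house_config()].
#' @param bird_count Number of birds housed during the logged period.
#' @return data.frame: `timestamp_s`, `vr_disc_m3h`, `t_disc_C`, `pad_on`.
#' @export
compute_discrepancies <- function(log, cfg, bird_count) {
  need <- c("timestamp_s", "Ti_C", "To_C", "RHo_pct", "Td_C", "age_days",
            "actual_vent_m3h", "pad_on")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("compute_discrepancies: missing channels: ",
                         paste(miss, collapse = ", "))
  if (nrow(log) == 0) stop("compute_discrepancies: empty log")
  n <- nrow(log)
  vrr_m3h <- numeric(n)
  vrr2 <- air_exchange_rate(cfg)
  for (i in seq_len(n)) {
    age <- log$age_days[i]
    flock <- flock_state(age, bird_count, mass_floor_kg = cfg$mass_floor_kg)
    hr <- (log$timestamp_s[i] / 3600) %% 24
    heat <- flock_heat(flock, log$Ti_C[i], hr, clamp_negative = TRUE)
    Qd <- envelope_heat(log$Ti_C[i], log$To_C[i], cfg$envelope)
    Qv <- ventilation_heat_requirement(log$Ti_C[i], log$Td_C[i],
                                       heat$Qa, heat$Ql, Qd, cfg)
    Tc <- 0
    if (log$pad_on[i] > 0) {
      Tow <- wet_bulb(log$To_C[i], log$RHo_pct[i])
      Tc <- pad_temperature_drop(log$To_C[i], Tow, cfg$pad_efficiency, TRUE)
    }
    if (Qv < 0) {
      vrr <- 0
    } else {
      rv <- required_ventilation_rate(Qv, log$Ti_C[i], log$To_C[i], Tc, cfg)
      vrr <- if (rv$degenerate) vrr2 else rv$vrr
    }
    vrr_m3h[i] <- vrr * 3600
  }
  data.frame(
    timestamp_s = log$timestamp_s,
    vr_disc_m3h = vrr_m3h - log$actual_vent_m3h,
    t_disc_C = log$Td_C - log$Ti_C,
    pad_on = log$pad_on > 0
  )
}

#' Quadrant classification of discrepancy records
#'
#' Records within `band` degC of the set temperature count as "proper".
#' The remainder are classified by the signs of the two discrepancies:
#' \describe{
#'   \item{high_undervent}{under-ventilated and too hot
#'     (`vr_disc > 0, t_disc < 0`) --- fixable by ventilating at the
#'     required rate}
#'   \item{low_overvent}{over-ventilated and too cold
#'     (`vr_disc < 0, t_disc > 0`) --- likewise fixable}
#'   \item{anomalous}{over-ventilated yet too hot
#'     (`vr_disc <= 0, t_disc <= 0`) --- against the model, usually a
#'     time-lag effect}
#'   \item{rare}{under-ventilated yet too cold
#'     (`vr_disc >= 0, t_disc >= 0`)}
#' }
#' Sign-boundary records outside the proper band fall on the non-negative
#' side. Percentages are computed from exact counts and sum to 100.
#'
#' @param discs Output of [compute_discrepancies()].
#' @param band Proper-temperature half-width, degC (default 1.5).
#' @param exclude_pad_on Drop records with the pads running (default TRUE;
#'   the pads confound the ventilation/temperature relation).
#' @return List: `proper_pct`, `high_undervent_pct`, `low_overvent_pct`,
#'   `anomalous_pct`, `rare_pct`, `potential_proper_pct` (proper plus the
#'   two fixable quadrants), `record_count`.
#' @export
quadrant_summary <- function(discs, band = 1.5, exclude_pad_on = TRUE) {
  d <- if (exclude_pad_on) discs[!discs$pad_on, , drop = FALSE] else discs
  if (nrow(d) == 0) stop("quadrant_summary: no records after pad exclusion")
  n <- nrow(d)
  proper <- abs(d$t_disc_C) <= band
  rest <- d[!proper, , drop = FALSE]
  hi_uv <- sum(rest$vr_disc_m3h > 0 & rest$t_disc_C < 0)
  lo_ov <- sum(rest$vr_disc_m3h < 0 & rest$t_disc_C > 0)
  anom  <- sum(rest$vr_disc_m3h <= 0 & rest$t_disc_C <= 0)
  rare  <- sum(rest$vr_disc_m3h >= 0 & rest$t_disc_C >= 0)
  list(
    proper_pct = 100 * sum(proper) / n,
    high_undervent_pct = 100 * hi_uv / n,
    low_overvent_pct = 100 * lo_ov / n,
    anomalous_pct = 100 * anom / n,
    rare_pct = 100 * rare / n,
    potential_proper_pct = 100 * (sum(proper) + hi_uv + lo_ov) / n,
    record_count = n
  )
}

#' Total fan runtime of a log, in fan-hours
#'
#' One fan-hour is one fan running for one hour: `sum(n_fans * dt) / 3600`
#' over a uniformly sampled log. Stage-0 records count the intermittent
#' pair for the whole interval (the log does not carry the duty phase).
#'
#' @param log A log data.frame with `timestamp_s` and `n_fans`.
#' @return Fan-hours.
#' @export
fan_hours <- function(log) {
  if (nrow(log) == 0) return(0)
  dt <- diff(log$timestamp_s)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-6) {
    stop("fan_hours: log timestep is not uniform")
  }
  step <- if (length(dt)) dt[1] else 1
  sum(log$n_fans) * step / 3600
}

#' Fan electrical energy from fan-hours
#'
#' @param fan_hours Fan runtime, fan-hours (>= 0).
#' @param fan_power_w Power draw per fan, W (default 836).
#' @return List: `kwh` (raw) and `kwh_reported` (rounded to the nearest
#'   kWh, the reporting convention).
#' @export
fan_energy_kwh <- function(fan_hours, fan_power_w = 836) {
  stopifnot(fan_hours >= 0, fan_power_w >= 0)
  kwh <- fan_hours * fan_power_w / 1000
  list(kwh = kwh, kwh_reported = round(kwh))
}

#' Usage comparison between a control and an experimental period
#'
#' @param control List with `fan_hours`, `pad_hours` and optionally
#'   `fan_energy_kwh` for the control (reference) building/period.
#' @param experimental Same for the experimental building/period. Both must
#'   cover periods of equal duration.
#' @param fan_power_w Power draw per fan, W, used when energies are absent.
#' @return List: `fan_usage_pct` (100 * experimental / control fan-hours),
#'   `pad_fold_change` (experimental / control pad-hours),
#'   `energy_saved_kwh` (control minus experimental fan energy, raw and
#'   rounded), `control_kwh`, `experimental_kwh`.
#' @export
usage_comparison <- function(control, experimental, fan_power_w = 836) {
  if (control$fan_hours <= 0) stop("usage_comparison: zero control fan-hours")
  e_c <- control$fan_energy_kwh %||% fan_energy_kwh(control$fan_hours, fan_power_w)$kwh
  e_e <- experimental$fan_energy_kwh %||%
    fan_energy_kwh(experimental$fan_hours, fan_power_w)$kwh
  pad_fold <- if (!is.null(control$pad_hours) && control$pad_hours > 0) {
    experimental$pad_hours / control$pad_hours
  } else NA_real_
  list(
    fan_usage_pct = 100 * experimental$fan_hours / control$fan_hours,
    pad_fold_change = pad_fold,
    control_kwh = e_c,
    experimental_kwh = e_e,
    energy_saved_kwh = e_c - e_e,
    energy_saved_kwh_reported = round(e_c) - round(e_e)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
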