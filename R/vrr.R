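# Heat-balance ventilation-rate-requirement (VRR) controller: energy balance,
# required airflow, stage mapping, pad hysteresis, and the exception clauses.

#' Heat to be removed by ventilation over the control horizon
#'
#' Energy balance of the single zone:
#' `Qv = rho*cp*Vb*(Ti - Td)/delta_t + Qa + Ql + Qd` --- the rate needed to
#' bring the indoor air mass from Ti to the set temperature Td within
#' `delta_t`, plus the flock's sensible and latent heat and the envelope
#' exchange.
#'
#' @param Ti Indoor temperature, degC.
#' @param Td Set temperature, degC.
#' @param Qa,Ql Flock sensible and latent heat, W.
#' @param Qd Envelope heat, W (negative when the house loses heat outdoors).
#' @param cfg A [house_config()].
#' @return Qv, W. Negative values mean no ventilation cooling is required.
#' @export
ventilation_heat_requirement <- function(Ti, Td, Qa, Ql, Qd, cfg) {
  cfg$rho * cfg$cp * cfg$Vb * (Ti - Td) / cfg$delta_t + Qa + Ql + Qd
}

#' Required ventilation rate
#'
#' Airflow that removes `Qv` given the indoor-to-inlet temperature
#' difference: `VRR = Qv / (rho * cp * dT_eff)` with
#' `dT_eff = Ti - (To - Tc)` in `inlet_corrected` mode (the default; pad
#' cooling widens the usable difference) or `Ti - To - Tc` in `as_printed`
#' mode. Clamped at zero.
#'
#' @param Qv Heat to remove, W.
#' @param Ti,To Indoor and outdoor temperatures, degC.
#' @param Tc Pad temperature drop, degC (0 when pads are off).
#' @param cfg A [house_config()].
#' @param denominator_mode Override of `cfg$denominator_mode`.
#' @return List with `vrr` (m3/s) and `degenerate` (TRUE when `|dT_eff|` is
#'   below `cfg$degenerate_tol`, in which case the caller must fall back to
#'   the air-exchange rate `Vb / delta_t`; `vrr` is then NA).
#' @export
required_ventilation_rate <- function(Qv, Ti, To, Tc = 0, cfg,
                                      denominator_mode = cfg$denominator_mode) {
  dT <- if (denominator_mode == "as_printed") Ti - To - Tc else Ti - (To - Tc)
  if (abs(dT) < cfg$degenerate_tol) {
    return(list(vrr = NA_real_, degenerate = TRUE))
  }
  list(vrr = max(0, Qv / (cfg$rho * cfg$cp * dT)), degenerate = FALSE)
}

#' Air-exchange ventilation rate
#'
#' The rate that exchanges the house air volume once per control horizon,
#' `VRR2 = Vb / delta_t`; the fallback cap used when the indoor/outdoor
#' temperature difference is small.
#'
#' @param cfg A [house_config()].
#' @return m3/s.
#' @export
air_exchange_rate <- function(cfg) cfg$Vb / cfg$delta_t

#' Map a required ventilation rate onto the fan-stage ladder
#'
#' The required rate is divided by the per-fan capacity and rounded up to a
#' whole number of fans (rounding up guarantees the delivered capacity
#' covers the requirement); the smallest continuous stage with at least that
#' many fans is chosen, capped at the top stage. Requirements at or below
#' the age-dependent minimum ventilation map to stage 0, where the
#' intermittent fan pair runs at the duty fraction that delivers exactly the
#' minimum rate.
#'
#' @param vrr Required ventilation, m3/s (>= 0).
#' @param age_days Bird age (selects the minimum-ventilation rate).
#' @param cfg A [house_config()].
#' @return List: `stage` (0-5), `n_fans`, `stage0_duty` (in \[0,1\]; 1 for
#'   stages >= 1), `q_m3s` (delivered airflow, m3/s).
#' @export
stage_from_vrr <- function(vrr, age_days, cfg) {
  stopifnot(vrr >= 0)
  minv_m3s <- min_vent_at(cfg$min_vent, age_days) / 3600
  cap_m3s <- cfg$fan_capacity / 3600
  n_req <- ceiling(vrr / cap_m3s - 1e-9)
  if (n_req <= 0 || vrr <= minv_m3s + 1e-12) {
    duty <- min(1, minv_m3s / (cfg$stage_fans[1] * cap_m3s))
    return(list(stage = 0L, n_fans = cfg$stage_fans[1], stage0_duty = duty,
                q_m3s = cfg$stage_fans[1] * cap_m3s * duty))
  }
  ladder <- cfg$stage_fans[-1]                      # continuous stages 1..top
  stage <- which(ladder >= n_req)[1]
  if (is.na(stage)) stage <- length(ladder)
  n_fans <- ladder[stage]
  list(stage = as.integer(stage), n_fans = as.integer(n_fans),
       stage0_duty = 1, q_m3s = n_fans * cap_m3s)
}

#' Cooling-pad hysteresis
#'
#' Pads switch ON only in genuinely hot conditions --- outdoor temperature
#' at least `Td + 3*Tda` AND indoor above `Td + 2*Tda + 0.5` --- and switch
#' OFF once the indoor temperature has come down to `Td + 2*Tda`. Between
#' the two thresholds the previous state is held, which prevents rapid
#' cycling (chatter) near the boundary.
#'
#' @param Ti,To Indoor and outdoor temperatures, degC.
#' @param Td Set temperature, degC.
#' @param cfg A [house_config()] (supplies `Tda`).
#' @param prev_pad_state Logical; pad state at the previous tick.
#' @return Logical pad state.
#' @export
pad_hysteresis <- function(Ti, To, Td, cfg, prev_pad_state = FALSE) {
  off_at <- Td + 2 * cfg$Tda
  if (Ti <= off_at) return(FALSE)
  if (To >= Td + 3 * cfg$Tda && Ti > off_at + 0.5) return(TRUE)
  isTRUE(prev_pad_state)
}

#' One control decision of the heat-balance (VRR) controller
#'
#' Computes the flock and envelope heat loads, the ventilation heat
#' requirement Qv and the required ventilation rate, then applies the three
#' exception clauses in numerical order (the first that fires short-circuits
#' the rest):
#' \enumerate{
#'   \item If `Qv < 0` or `Ti < Td + Tda`: stage 0 (minimum ventilation);
#'     the house is at or below target and needs no cooling.
#'   \item Pad logic: when hot outside (`To >= Td + 3*Tda`) the pads run
#'     under hysteresis ([pad_hysteresis()]); the required rate is then
#'     recomputed with the pad-cooled inlet temperature within the same
#'     tick and staged.
#'   \item If `To >= Td + Tda` (warm outside, pads not running): the stage
#'     is computed from `min(VRR, Vb/delta_t)` so a small indoor/outdoor
#'     difference cannot demand an unbounded rate.
#' }
#' When no clause fires the stage follows the required rate directly. A
#' near-zero denominator anywhere falls back to the air-exchange rate.
#'
#' @param Ti,To Indoor and outdoor temperatures, degC.
#' @param RHo Outdoor relative humidity, percent (for the pad wet-bulb).
#' @param flock A [flock_state()].
#' @param Td Set temperature, degC.
#' @param hour_of_day Hour in `[0, 24)`.
#' @param cfg A [house_config()].
#' @param prev_pad_state Logical; pad state at the previous tick.
#' @return A `bv_decision` list: `stage`, `n_fans`, `stage0_duty`,
#'   `pad_on`, `pad_duty`, `vrr` (m3/s, the staged requirement), `q_m3s`
#'   (delivered airflow), `qv` (W), `Tc` (degC), `exception_fired`
#'   (`"none"`, `"1"`, `"2"`, `"3"`).
#' @export
decide_vrr <- function(Ti, To, RHo, flock, Td, hour_of_day, cfg,
                       prev_pad_state = FALSE) {
  heat <- flock_heat(flock, Ti, hour_of_day, clamp_negative = TRUE)
  Qd <- envelope_heat(Ti, To, cfg$envelope)
  Qv <- ventilation_heat_requirement(Ti, Td, heat$Qa, heat$Ql, Qd, cfg)
  vrr2 <- air_exchange_rate(cfg)
  age <- flock$age_days

  finish <- function(stage_sel, pad_on, vrr, Tc, exception) {
    structure(list(
      stage = stage_sel$stage, n_fans = stage_sel$n_fans,
      stage0_duty = stage_sel$stage0_duty, pad_on = pad_on,
      pad_duty = if (pad_on) 1 else 0, vrr = vrr, q_m3s = stage_sel$q_m3s,
      qv = Qv, Tc = Tc, exception_fired = exception
    ), class = "bv_decision")
  }

  # Exception 1: no cooling needed
  if (Qv < 0 || Ti < Td + cfg$Tda) {
    sel <- stage_from_vrr(0, age, cfg)
    return(finish(sel, pad_on = FALSE, vrr = 0, Tc = 0, exception = "1"))
  }

  # Exception 2: evaporative-pad operation with hysteresis
  pad_on <- pad_hysteresis(Ti, To, Td, cfg, prev_pad_state)
  if (pad_on) {
    Tow <- wet_bulb(To, RHo)
    Tc <- pad_temperature_drop(To, Tow, cfg$pad_efficiency, TRUE)
    rv <- required_ventilation_rate(Qv, Ti, To, Tc, cfg)
    vrr <- if (rv$degenerate) vrr2 else rv$vrr
    sel <- stage_from_vrr(vrr, age, cfg)
    return(finish(sel, pad_on = TRUE, vrr = vrr, Tc = Tc, exception = "2"))
  }

  rv <- required_ventilation_rate(Qv, Ti, To, 0, cfg)
  vrr <- if (rv$degenerate) vrr2 else rv$vrr

  # Exception 3: warm outside, cap by one air exchange per control horizon
  if (To >= Td + cfg$Tda) {
    vrr <- min(vrr, vrr2)
    sel <- stage_from_vrr(vrr, age, cfg)
    return(finish(sel, pad_on = FALSE, vrr = vrr, Tc = 0, exception = "3"))
  }

  sel <- stage_from_vrr(vrr, age, cfg)
  finish(sel, pad_on = FALSE, vrr = vrr, Tc = 0, exception = "none")
}
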