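# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Iterative psychrometric wet-bulb solver: find Tw such that the
# saturation-balance (psychrometer) equation holds at standard pressure.
# Magnus saturation vapour pressure, psychrometer constant ~6.6e-4 / degC.
oracle_wet_bulb <- function(T, RH, P_kpa = 101.325) {
  es <- function(t) 0.6112 * exp(17.62 * t / (243.12 + t))  # kPa
  e_air <- es(T) * RH / 100
  f <- function(Tw) es(Tw) - 6.6e-4 * P_kpa * (T - Tw) - e_air
  stats::uniroot(f, lower = -40, upper = T + 1e-6, tol = 1e-8)$root
}

# Brute-force interpreter of the exception-clause precedence, written
# straight from the rules: first satisfied clause wins.
oracle_exception <- function(Qv, Ti, To, Td, Tda, pad_would_run) {
  if (Qv < 0 || Ti < Td + Tda) return("1")
  if (pad_would_run) return("2")
  if (To >= Td + Tda) return("3")
  "none"
}

# Closed-form single-zone temperature (duplicated here so the test does not
# lean on the package's zone_closed_form for its own verification).
oracle_zone_T <- function(Ti0, q, Ta, L, rho, cp, Vb, t) {
  Tss <- Ta + L / (rho * cp * q)
  Tss + (Ti0 - Tss) * exp(-q * t / Vb)
}

# Shared small fixtures -------------------------------------------------------

tiny_cfg <- function(...) house_config(...)

# A hand-built log data.frame with the canonical columns.
make_log <- function(n = 3, dt = 600, Ti = 25, To = 20, RHo = 60, Td = 24,
                     age = 30, stage = 1, n_fans = 4, pad_on = 0,
                     vent = 148000) {
  data.frame(
    timestamp_s = (seq_len(n) - 1) * dt,
    Ti_C = rep_len(Ti, n), To_C = rep_len(To, n),
    RHo_pct = rep_len(RHo, n), Td_C = rep_len(Td, n),
    age_days = rep_len(age, n), stage = rep_len(stage, n),
    n_fans = rep_len(n_fans, n), pad_on = rep_len(pad_on, n),
    actual_vent_m3h = rep_len(vent, n)
  )
}
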