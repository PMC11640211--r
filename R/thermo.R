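# Psychrometrics, evaporative-pad cooling, and envelope heat transfer.

#' Wet-bulb temperature (Stull approximation)
#'
#' Single-expression empirical fit for wet-bulb temperature from dry-bulb
#' temperature and relative humidity at standard pressure. Valid for
#' RH in \[5, 99\]% and T in \[-20, 50\] degC; accurate to a few tenths of a
#' degree over most of that box.
#'
#' @param T Dry-bulb temperature, degC.
#' @param RH Relative humidity, percent.
#' @return Wet-bulb temperature, degC (always <= T).
#' @references Stull, R. (2011) J. Appl. Meteor. Climatol. 50, 2267-2269.
#' @export
wet_bulb <- function(T, RH) {
  if (any(RH < 5 | RH > 99)) stop("wet_bulb: RH outside validity range [5, 99]%")
  if (any(T < -20 | T > 50)) stop("wet_bulb: T outside validity range [-20, 50] degC")
  Tw <- T * atan(0.151977 * sqrt(RH + 8.313659)) +
    atan(T + RH) - atan(RH - 1.676331) +
    0.00391838 * RH^1.5 * atan(0.023101 * RH) - 4.686035
  pmin(Tw, T)
}

#' Temperature drop across the evaporative cooling pad
#'
#' The pad cools incoming air by a fraction (the pad efficiency) of the
#' wet-bulb depression of outdoor air: `Tc = (To - Tow) * eff` when the pad
#' runs, 0 when it does not.
#'
#' @param To Outdoor dry-bulb temperature, degC.
#' @param Tow Outdoor wet-bulb temperature, degC (<= To).
#' @param efficiency Pad saturation efficiency in \[0, 1\].
#' @param pad_on Logical; pad operating state.
#' @return Temperature drop Tc, degC (>= 0).
#' @export
pad_temperature_drop <- function(To, Tow, efficiency, pad_on = TRUE) {
  stopifnot(efficiency >= 0, efficiency <= 1)
  if (any(Tow > To + 1e-9)) stop("pad_temperature_drop: Tow must be <= To")
  ifelse(pad_on, (To - Tow) * efficiency, 0)
}

#' Envelope specification
#'
#' Thermal transmittances (U-values) and areas for the building shell. The
#' default wall area is computed from the reference house geometry
#' (87 x 14 m floor, 3.5 m eaves, 5 m ridge): two side walls, two gable
#' ends, and the roof planes.
#'
#' @param Uw Wall/roof U-value, W m-2 K-1.
#' @param Uf Floor U-value, W m-2 K-1.
#' @param Aw Wall + roof area, m2.
#' @param Af Floor area, m2.
#' @return A `bv_envelope` list.
#' @export
envelope_spec <- function(Uw = 0.247, Uf = 2.75,
                          Aw = default_wall_area(), Af = 87 * 14) {
  vals <- c(Uw = Uw, Uf = Uf, Aw = Aw, Af = Af)
  if (any(vals <= 0)) {
    stop("envelope_spec: ", names(vals)[vals <= 0][1], " must be > 0")
  }
  structure(list(Uw = Uw, Uf = Uf, Aw = Aw, Af = Af), class = "bv_envelope")
}

#' Wall + roof area of the reference house
#'
#' Side walls `2 * L * eave`, gable ends `2 * cross-section`, and roof planes
#' `2 * L * slope length` for a gabled house.
#'
#' @param length_m,width_m,eave_m,ridge_m House dimensions, m.
#' @return Area, m2.
#' @export
default_wall_area <- function(length_m = 87, width_m = 14,
                              eave_m = 3.5, ridge_m = 5) {
  rise <- ridge_m - eave_m
  cross_section <- width_m * eave_m + 0.5 * width_m * rise
  slope <- sqrt((width_m / 2)^2 + rise^2)
  2 * length_m * eave_m + 2 * cross_section + 2 * length_m * slope
}

#' Envelope heat exchange
#'
#' Conductive heat flow through walls, roof and floor:
#' `Qd = -(Uw*Aw + Uf*Af) * (Ti - To)`. Negative when the house is warmer
#' than outdoors (the envelope then sheds heat, reducing the ventilation
#' load).
#'
#' @param Ti Indoor temperature, degC.
#' @param To Outdoor temperature, degC.
#' @param spec An [envelope_spec()].
#' @return Envelope heat flow, W (sign convention: heat added to the room).
#' @export
envelope_heat <- function(Ti, To, spec) {
  -(spec$Uw * spec$Aw + spec$Uf * spec$Af) * (Ti - To)
}
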