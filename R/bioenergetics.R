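# Flock bioenergetics: body-mass growth curve, circadian activity modulation,
# and per-bird / flock sensible and latent heat production.

# kcal day^-1 -> W
KCAL_PER_DAY_TO_W <- 4184 / (24 * 3600)

#' Broiler body mass from age
#'
#' Quadratic growth curve fitted to weekly reference weights for commercial
#' broilers. The polynomial is evaluated in grams and converted to kilograms.
#' It is negative for ages 0--1 day, where real chicks weigh about 42 g; by
#' default this raises an error, but a hatch-weight floor can be supplied for
#' simulations that start at stocking.
#'
#' @param age_days Age in days since stocking (non-negative integer-ish).
#' @param floor_kg Optional minimum mass in kg returned where the polynomial
#'   is non-positive (e.g. 0.042 for hatch weight). `NULL` (default) raises.
#' @return Mass per bird in kg.
#' @examples
#' broiler_mass(35) # ~1.37 kg
#' @export
broiler_mass <- function(age_days, floor_kg = NULL) {
  if (any(age_days < 0)) stop("age_days must be >= 0")
  grams <- -35.783 + 19.098 * age_days + 0.6008 * age_days^2
  kg <- grams / 1000
  bad <- kg <= 0
  if (any(bad)) {
    if (is.null(floor_kg)) {
      stop("broiler_mass: growth polynomial is non-positive at age ",
           paste(age_days[bad], collapse = ", "),
           " days; supply floor_kg to clamp (e.g. hatch weight 0.042)")
    }
    kg[bad] <- floor_kg
  }
  kg
}

#' Circadian activity modulation factor
#'
#' Sinusoidal modulation of heat production over the day,
#' `Sc = 1 - a * sin(2*pi*(h + 6 - hmin)/24)`, bounded in `[1-a, 1+a]` with
#' mean 1 over 24 h. Sensible and latent heat use different constants.
#'
#' @param hour_of_day Hour in `[0, 24)` (recycled/vectorised).
#' @param amplitude Dimensionless amplitude `a` in `[0, 1)`; 0.21 for
#'   sensible heat, 0.46 for latent heat.
#' @param phase_const Phase constant `hmin` in hours; 0.38 for sensible,
#'   0.67 for latent heat.
#' @return Dimensionless factor.
#' @export
activity_modulation <- function(hour_of_day, amplitude, phase_const) {
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must be in [0, 1)")
  1 - amplitude * sin(2 * pi * (hour_of_day + 6 - phase_const) / 24)
}

#' Sensible heat production per bird
#'
#' Metabolic-mass scaled sensible heat output as a function of indoor
#' temperature, with circadian modulation. The temperature polynomial is in
#' kcal per kg^0.75 per day and is converted to watts.
#'
#' @param Ti Indoor dry-bulb temperature, degC.
#' @param mass_per_bird Bird mass, kg (> 0).
#' @param hour_of_day Hour in `[0, 24)` used for the activity modulation.
#' @param Sc Optional override of the modulation factor (e.g. `1` to disable).
#' @return Sensible heat per bird, W.
#' @export
sensible_heat_per_bird <- function(Ti, mass_per_bird, hour_of_day = 12, Sc = NULL) {
  if (any(mass_per_bird <= 0)) stop("mass_per_bird must be > 0")
  if (is.null(Sc)) Sc <- activity_modulation(hour_of_day, 0.21, 0.38)
  poly <- 307.87 - 15.63 * Ti + 0.3105 * Ti^2
  mass_per_bird^0.75 * poly * KCAL_PER_DAY_TO_W * Sc
}

#' Latent heat production per bird
#'
#' Latent heat released by evaporation of drinking water (about 40% of the
#' daily water intake evaporates indoors), as a function of indoor
#' temperature and bird mass, with circadian modulation. Positive values are
#' heat added to the indoor air.
#'
#' @inheritParams sensible_heat_per_bird
#' @param clamp_negative The water-intake polynomial goes negative above
#'   roughly 36.6 degC indoor (outside the formula's fitted envelope). By
#'   default that raises an error; with `clamp_negative = TRUE` the latent
#'   heat is clamped at 0 W instead, which is how the controller, simulator
#'   and audit use it so that extreme heat episodes remain computable.
#' @return Latent heat per bird, W.
#' @export
latent_heat_per_bird <- function(Ti, mass_per_bird, hour_of_day = 12, Sc = NULL,
                                 clamp_negative = FALSE) {
  if (any(mass_per_bird <= 0)) stop("mass_per_bird must be > 0")
  if (is.null(Sc)) Sc <- activity_modulation(hour_of_day, 0.46, 0.67)
  poly <- 583.5 - 17.1 * Ti + 25.25 * mass_per_bird
  if (any(poly < 0)) {
    if (!clamp_negative) stop("latent_heat_per_bird: negative evaporation polynomial")
    poly <- pmax(poly, 0)
  }
  0.4 * poly * KCAL_PER_DAY_TO_W * Sc
}

#' Flock state
#'
#' @param age_days Days since stocking (>= 0).
#' @param bird_count Number of birds (>= 0).
#' @param mass_per_bird Mass per bird in kg; derived from [broiler_mass()]
#'   when omitted.
#' @param mass_floor_kg Passed to [broiler_mass()] when mass is derived.
#' @return A `bv_flock` list.
#' @export
flock_state <- function(age_days, bird_count, mass_per_bird = NULL,
                        mass_floor_kg = NULL) {
  stopifnot(age_days >= 0, bird_count >= 0)
  if (is.null(mass_per_bird)) {
    mass_per_bird <- broiler_mass(age_days, floor_kg = mass_floor_kg)
  }
  if (mass_per_bird <= 0) stop("mass_per_bird must be > 0")
  structure(list(age_days = age_days, bird_count = bird_count,
                 mass_per_bird = mass_per_bird), class = "bv_flock")
}

#' Flock-level sensible and latent heat
#'
#' Per-bird heat production scaled by the bird count.
#'
#' @param flock A [flock_state()].
#' @param Ti Indoor temperature, degC.
#' @param hour_of_day Hour in `[0, 24)`.
#' @param clamp_negative Passed to [latent_heat_per_bird()].
#' @return List with `Qa` (sensible, W) and `Ql` (latent, W).
#' @export
flock_heat <- function(flock, Ti, hour_of_day, clamp_negative = FALSE) {
  if (flock$bird_count == 0) return(list(Qa = 0, Ql = 0))
  list(
    Qa = flock$bird_count * sensible_heat_per_bird(Ti, flock$mass_per_bird, hour_of_day),
    Ql = flock$bird_count * latent_heat_per_bird(Ti, flock$mass_per_bird, hour_of_day,
                                                 clamp_negative = clamp_negative)
  )
}
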