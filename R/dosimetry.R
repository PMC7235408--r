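#' Ultrasound stimulation protocol
#'
#' Parameters of a pulsed-ultrasound stimulation carried by every trigger
#' event. Two canned protocols match the published experiments:
#' [protocol_neuromodulation()] (500 kHz, 1 kHz PRF, 400 ms, 40% duty) for
#' theta phase-locked stimulation and [protocol_antiepileptic()] (500 kHz,
#' 500 Hz PRF, 30 s, 5% duty) for seizure inhibition, both at 0.23 MPa.
#'
#' @param fundamental_hz Carrier frequency (Hz), default 500 kHz.
#' @param prf_hz Pulse repetition frequency (Hz).
#' @param duration_s Stimulation duration (s).
#' @param duty_frac Duty cycle as a fraction in (0, 1].
#' @param pressure_mpa Peak acoustic pressure (MPa), default 0.23.
#' @return A list of class `stim_protocol`.
#' @export
stim_protocol <- function(fundamental_hz = 5e5, prf_hz, duration_s, duty_frac,
                          pressure_mpa = 0.23) {
  if (!(duty_frac > 0 && duty_frac <= 1)) {
    stop("duty_frac must be in (0, 1]", call. = FALSE)
  }
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (prf_hz <= 0) stop("prf_hz must be > 0", call. = FALSE)
  if (pressure_mpa <= 0) stop("pressure_mpa must be > 0", call. = FALSE)
  structure(list(
    fundamental_hz = fundamental_hz, prf_hz = prf_hz, duration_s = duration_s,
    duty_frac = duty_frac, pressure_mpa = pressure_mpa
  ), class = "stim_protocol")
}

#' @rdname stim_protocol
#' @export
protocol_neuromodulation <- function() {
  stim_protocol(5e5, prf_hz = 1000, duration_s = 0.4, duty_frac = 0.40)
}

#' @rdname stim_protocol
#' @export
protocol_antiepileptic <- function() {
  stim_protocol(5e5, prf_hz = 500, duration_s = 30, duty_frac = 0.05)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %g kHz carrier, PRF %g Hz, %g s, duty %.0f%%, %.2f MPa\n",
    x$fundamental_hz / 1e3, x$prf_hz, x$duration_s, 100 * x$duty_frac,
    x$pressure_mpa
  ))
  invisible(x)
}

#' Spatial-peak pulse-average intensity from pressure
#'
#' Plane-wave relation `I = p^2 / (2 rho c)`, converted to W/cm^2. Default
#' medium constants are water (rho = 1000 kg/m^3, c = 1500 m/s); no derating
#' is applied.
#'
#' @param p_mpa Peak pressure in MPa (> 0).
#' @param rho_kg_m3 Medium density (kg/m^3).
#' @param c_m_s Speed of sound (m/s).
#' @return I_sppa in W/cm^2.
#' @export
isppa_from_pressure <- function(p_mpa, rho_kg_m3 = 1000, c_m_s = 1500) {
  if (any(p_mpa <= 0) || rho_kg_m3 <= 0 || c_m_s <= 0) {
    stop("pressure and medium constants must be > 0", call. = FALSE)
  }
  (p_mpa * 1e6)^2 / (2 * rho_kg_m3 * c_m_s) / 1e4
}

#' Spatial-peak temporal-average intensity
#'
#' `I_spta = I_sppa x duty cycle`, reported in mW/cm^2 (the unit of the
#' 720 mW/cm^2 regulatory limit).
#'
#' @param i_sppa_w_cm2 I_sppa in W/cm^2.
#' @param duty_frac Duty cycle in (0, 1].
#' @return I_spta in mW/cm^2.
#' @export
ispta <- function(i_sppa_w_cm2, duty_frac) {
  if (any(duty_frac <= 0) || any(duty_frac > 1)) {
    stop("duty_frac must be in (0, 1]", call. = FALSE)
  }
  if (any(i_sppa_w_cm2 < 0)) stop("i_sppa must be >= 0", call. = FALSE)
  i_sppa_w_cm2 * duty_frac * 1000
}

#' Mechanical index
#'
#' `MI = p / sqrt(f)` with the peak-rarefactional pressure in MPa and the
#' frequency in MHz; compared against the 1.9 safety limit.
#'
#' @param p_mpa Peak-rarefactional pressure (MPa).
#' @param f_mhz Carrier frequency (MHz), > 0.
#' @return The dimensionless mechanical index.
#' @export
mechanical_index <- function(p_mpa, f_mhz) {
  if (any(f_mhz <= 0)) stop("frequency must be > 0", call. = FALSE)
  if (any(p_mpa <= 0)) stop("pressure must be > 0", call. = FALSE)
  p_mpa / sqrt(f_mhz)
}

#' Acoustic exposure summary for a protocol
#'
#' Deterministic dosimetry bookkeeping: I_sppa from the protocol pressure by
#' the plane-wave relation, I_spta = I_sppa x duty, mechanical index, and
#' flags against the non-obstetric imaging limits (I_spta <= 720 mW/cm^2,
#' MI <= 1.9).
#'
#' @param protocol A [stim_protocol()].
#' @param rho_kg_m3,c_m_s Medium constants (defaults: water).
#' @param ispta_limit_mw_cm2,mi_limit Safety limits.
#' @return One-row tibble: `i_sppa_w_cm2`, `i_spta_mw_cm2`, `mechanical_index`,
#'   `within_ispta_limit`, `within_mi_limit`.
#' @export
exposure_summary <- function(protocol, rho_kg_m3 = 1000, c_m_s = 1500,
                             ispta_limit_mw_cm2 = 720, mi_limit = 1.9) {
  stopifnot(inherits(protocol, "stim_protocol"))
  i_sppa <- isppa_from_pressure(protocol$pressure_mpa, rho_kg_m3, c_m_s)
  i_spta <- ispta(i_sppa, protocol$duty_frac)
  mi <- mechanical_index(protocol$pressure_mpa, protocol$fundamental_hz / 1e6)
  tibble::tibble(
    i_sppa_w_cm2 = i_sppa,
    i_spta_mw_cm2 = i_spta,
    mechanical_index = mi,
    within_ispta_limit = i_spta <= ispta_limit_mw_cm2,
    within_mi_limit = mi <= mi_limit
  )
}
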