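#' Equivalent-circuit model of the SiNW-FET sensing interface
#'
#' The electrode/electrolyte interface of an impedimetric SiNW-FET sensor is
#' reduced to four lumped elements: a series access resistance `Rs`, a series
#' interface capacitance `Cs`, and a parallel RC pair (`Rp`, `Cp`) describing
#' the charge-transfer branch. The default wiring is
#' \deqn{Z(\omega) = R_s + \frac{1}{j\omega C_s} + \frac{R_p}{1 + j\omega R_p C_p},}
#' a standard reduction for impedimetric biosensors. The topology is kept as a
#' field so alternative wirings can be swapped in.
#'
#' @param Rs Series resistance (Ohm).
#' @param Cs Series interface capacitance (F).
#' @param Rp Parallel (charge-transfer) resistance (Ohm).
#' @param Cp Parallel (double-layer) capacitance (F).
#' @param topology Circuit wiring; currently `"series_rc_parallel_rc"`.
#'
#' @return An object of class `impedance_model`.
#' @examples
#' zm <- impedance_model()
#' impedance(zm, 1e6)
#' @export
impedance_model <- function(Rs = 1e3, Cs = 1e-9, Rp = 1e4, Cp = 1e-10,
                            topology = "series_rc_parallel_rc") {
  vals <- c(Rs = Rs, Cs = Cs, Rp = Rp, Cp = Cp)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("all circuit elements (Rs, Cs, Rp, Cp) must be strictly positive and finite")
  }
  topology <- match.arg(topology)
  structure(list(Rs = Rs, Cs = Cs, Rp = Rp, Cp = Cp, topology = topology),
            class = "impedance_model")
}

#' @export
print.impedance_model <- function(x, ...) {
  cat("<impedance_model> ", x$topology, "\n", sep = "")
  cat(sprintf("  Rs = %.3g Ohm, Cs = %.3g F, Rp = %.3g Ohm, Cp = %.3g F\n",
              x$Rs, x$Cs, x$Rp, x$Cp))
  invisible(x)
}

#' Complex impedance of the sensing interface
#'
#' Evaluates the equivalent-circuit impedance at one or more frequencies.
#'
#' @param model An [impedance_model()].
#' @param freq Frequency or vector of frequencies (Hz), all strictly positive.
#'
#' @return Complex impedance(s) in Ohm, same length as `freq`.
#' @examples
#' impedance(impedance_model(), c(6e3, 6e6))
#' @export
impedance <- function(model, freq) {
  stopifnot(inherits(model, "impedance_model"))
  if (!is.numeric(freq) || length(freq) == 0 || any(!is.finite(freq)) || any(freq <= 0)) {
    abort("`freq` must be strictly positive and finite")
  }
  w <- 2 * pi * freq
  model$Rs + 1 / (1i * w * model$Cs) + model$Rp / (1 + 1i * w * model$Rp * model$Cp)
}

#' Table of simulated analyte classes
#'
#' Five analyte categories drive the synthetic binding response: high- and
#' low-affinity target antigens (virus present), non-specific and
#' cross-reactive antigens, and a receptor-only blank. Each class carries a
#' Langmuir equilibrium occupancy, a response coefficient mapping occupancy to
#' fractional impedance change, and an association time constant. The products
#' `equilibrium_occupancy * response_coefficient` are calibrated so the
#' asymptotic impedance changes are 0.92, 0.78, 0.05 and 0.07 for the four
#' non-blank classes.
#'
#' @return A tibble with columns `name`, `equilibrium_occupancy`,
#'   `response_coefficient`, `association_time_constant` (s) and `virus_present`.
#' @examples
#' analyte_classes()
#' @export
analyte_classes <- function() {
  tibble::tibble(
    name = c("target_high_affinity", "target_low_affinity",
             "non_specific", "cross_reactive", "blank"),
    equilibrium_occupancy = c(0.92, 0.78, 0.25, 0.35, 0),
    response_coefficient = c(1, 1, 0.2, 0.2, 0),
    association_time_constant = c(120, 300, 60, 90, 60),
    virus_present = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Look up one analyte class
#'
#' @param name One of `"target_high_affinity"`, `"target_low_affinity"`,
#'   `"non_specific"`, `"cross_reactive"`, `"blank"`.
#' @param classes Class table, defaults to [analyte_classes()].
#' @return A one-row tibble.
#' @export
analyte_class <- function(name, classes = analyte_classes()) {
  name <- match.arg(name, classes$name)
  cls <- classes[classes$name == name, ]
  if (cls$name == "blank" && cls$response_coefficient != 0) {
    abort("blank class must have response_coefficient = 0")
  }
  cls
}

#' Drive (readout) parameters of the transistor channel
#'
#' The source-drain current is modelled as
#' `Isd = Vds * G0 * (1 + transduction_gain * impedance_change)`.
#' Defaults give a 10 uA baseline and place the high-affinity equilibrium at
#' 12.5 uA, comfortably above the 11 uA detection threshold, while
#' non-specific binding stays below 10.2 uA.
#'
#' @param Vds Source-drain bias voltage (V).
#' @param G0 Baseline channel conductance (S), must be positive.
#' @param transduction_gain Dimensionless gain from fractional impedance
#'   change to fractional current change.
#' @return An object of class `drive_params`.
#' @export
drive_params <- function(Vds = 0.1, G0 = 1e-4, transduction_gain = 0.25 / 0.92) {
  if (G0 <= 0) abort("baseline conductance `G0` must be positive")
  structure(list(Vds = Vds, G0 = G0, transduction_gain = transduction_gain),
            class = "drive_params")
}

#' Source-drain current from a binding state
#'
#' @param impedance_change Fractional impedance change(s) in `[0, 1]`.
#' @param drive A [drive_params()] object.
#' @return Current(s) in A, strictly increasing in `impedance_change`.
#' @examples
#' isd_from_state(0.92) # high-affinity equilibrium, ~12.5 uA
#' @export
isd_from_state <- function(impedance_change, drive = drive_params()) {
  stopifnot(inherits(drive, "drive_params"))
  drive$Vds * drive$G0 * (1 + drive$transduction_gain * impedance_change)
}

#' Langmuir binding time course for one analyte class
#'
#' Receptor occupancy follows a single-exponential approach to equilibrium,
#' \eqn{\theta(t) = \theta_{eq} (1 - e^{-t/\tau})}; the fractional impedance
#' change is `response_coefficient * theta`, clipped to `[0, 1]`, and the
#' source-drain current follows from [isd_from_state()].
#'
#' @param cls A one-row analyte class tibble (see [analyte_class()]) or a
#'   class name.
#' @param duration Total exposure time (s), positive.
#' @param n_points Number of time points (>= 2).
#' @param drive A [drive_params()] object.
#' @return A tibble with columns `time`, `occupancy`, `impedance_change`, `isd`.
#' @examples
#' binding_time_course("target_high_affinity", duration = 600, n_points = 50)
#' @export
binding_time_course <- function(cls, duration, n_points,
                                drive = drive_params()) {
  if (is.character(cls)) cls <- analyte_class(cls)
  if (!is.finite(duration) || duration <= 0) abort("`duration` must be positive")
  if (n_points < 2) abort("`n_points` must be at least 2")
  time <- seq(0, duration, length.out = n_points)
  occupancy <- cls$equilibrium_occupancy * (1 - exp(-time / cls$association_time_constant))
  impedance_change <- pmin(pmax(cls$response_coefficient * occupancy, 0), 1)
  tibble::tibble(
    time = time,
    occupancy = occupancy,
    impedance_change = impedance_change,
    isd = isd_from_state(impedance_change, drive)
  )
}
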