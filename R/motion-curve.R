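#' Respiratory motion-time curve
#'
#' Amplitude fraction m(t) of the respiratory cycle, normalised to the
#' maximum displacement between end of exhalation (EOE, t = 0 s) and end
#' of inhalation (EOI, t = 2 s), periodic with the 5 s cycle. The curve is
#' an asymmetric squared sinusoid (2 s inhale, 3 s exhale):
#' \deqn{m(t) = \sin^2(\pi t / 4), \quad 0 \le t < 2}
#' \deqn{m(t) = \cos^2(\pi (t - 2) / 6), \quad 2 \le t < 5}
#' Both pieces meet at 1 for t = 2 and at 0 at the period boundary, so m is
#' continuous; m(t) in [0, 1] with its maximum attained only at EOI.
#'
#' @param t time in seconds (vectorised); taken modulo the cycle.
#' @param cycle cycle length in seconds (default 5).
#' @return amplitude fraction(s) in [0, 1].
#' @examples
#' evalMotionCurve(c(0, 1, 2, 3.5, 5))  # 0, 0.5, 1, 0.5, 0
#' @export
evalMotionCurve <- function(t, cycle = 5) {
  stopifnot(all(is.finite(t)))
  tm <- t %% cycle
  # inhale/exhale split scales with the cycle (2:3 at 5 s)
  t_eoi <- cycle * 0.4
  ifelse(tm < t_eoi,
         sin(pi * tm / (2 * t_eoi))^2,
         cos(pi * (tm - t_eoi) / (2 * (cycle - t_eoi)))^2)
}

#' Uniformly spaced phase times
#'
#' @param n_phases number of phases (default 10).
#' @param cycle respiratory cycle length in seconds (default 5).
#' @return numeric vector of phase start times: 0, cycle/n, ...
#' @examples
#' phaseTimes()        # 0.0, 0.5, ..., 4.5
#' phaseTimes(4, 2.0)  # 0.0, 0.5, 1.0, 1.5
#' @export
phaseTimes <- function(n_phases = 10, cycle = 5) {
  if (length(n_phases) != 1L || !is.finite(n_phases) || n_phases < 1 ||
      n_phases != round(n_phases))
    phantomStop("invalid_argument", "n_phases must be a positive integer")
  if (length(cycle) != 1L || !is.finite(cycle) || cycle <= 0)
    phantomStop("invalid_argument", "cycle must be positive")
  seq(0, by = cycle / n_phases, length.out = n_phases)
}

#' Breathing presets
#'
#' Three amplitude presets: \code{large} (maximum diaphragm SI motion
#' 3.0 cm, maximum chest AP motion 2.0 cm), \code{normal} (2.0 / 1.2 cm)
#' and \code{limited} (2.0 / 0.5 cm).
#'
#' @return \code{motionPresets()} returns a data.frame of the three
#'   presets; \code{motionPreset(name)} a list with \code{name},
#'   \code{A_d_cm} and \code{A_ap_cm}.
#' @export
motionPresets <- function() {
  data.frame(name = c("large", "normal", "limited"),
             A_d_cm = c(3.0, 2.0, 2.0),
             A_ap_cm = c(2.0, 1.2, 0.5),
             stringsAsFactors = FALSE)
}

#' @rdname motionPresets
#' @param name preset name, one of \code{"large"}, \code{"normal"},
#'   \code{"limited"}.
#' @export
motionPreset <- function(name) {
  p <- motionPresets()
  i <- match(name, p$name)
  if (is.na(i))
    phantomStop("invalid_config", "unknown breathing preset '%s'", name)
  list(name = p$name[i], A_d_cm = p$A_d_cm[i], A_ap_cm = p$A_ap_cm[i])
}
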