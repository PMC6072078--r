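#' Exponential-relaxation forcing
#'
#' Several rates in the model decline from a vigorous early-planet value
#' towards their modern value as radiogenic heating and the impactor flux
#' decay.  All of them share the same two-level exponential form
#' \deqn{F(t) = F_0 + (F_1 - F_0)\,e^{-t/\tau},}
#' where \eqn{F_1} is the value at planet formation (\eqn{t = 0}),
#' \eqn{F_0} the late-time asymptote, and \eqn{\tau} the e-folding time.
#' Model time runs from 0 at planet formation to 4.5 Gyr at the present.
#'
#' @param F1 initial value at `t = 0` (units of the forced quantity, e.g.
#'   kg N/yr for a delivery flux or 1/yr for a circulation rate).
#' @param F0 asymptotic late-time value, same units; `F1 >= F0 >= 0`.
#' @param tau e-folding time in years, `> 0`.
#' @return An object of class `"decay_forcing"`.
#' @examples
#' comet <- decay_forcing(F1 = 2.4e8, F0 = 2.4e5, tau = 1.5e8)
#' evaluate_forcing(comet, c(0, 1.5e8, 4.5e9))
#' @seealso [evaluate_forcing()]
#' @export
decay_forcing <- function(F1, F0, tau) {
  stopifnot(is.numeric(F1), is.numeric(F0), is.numeric(tau),
            length(F1) == 1L, length(F0) == 1L, length(tau) == 1L)
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be a positive, finite number of years")
  if (F0 < 0) stop("'F0' must be non-negative")
  if (F1 < F0) stop("'F1' must be >= 'F0' (forcings decay downward)")
  structure(list(F1 = F1, F0 = F0, tau = tau), class = "decay_forcing")
}

#' Evaluate a decay forcing at model time t
#'
#' @param f a [decay_forcing()].
#' @param t model time in years (vectorized); `t = 0` is planet formation.
#' @return `F0 + (F1 - F0) * exp(-t / tau)`, same units as `F1`.
#' @export
evaluate_forcing <- function(f, t) {
  stopifnot(inherits(f, "decay_forcing"), is.numeric(t))
  if (any(t < 0)) stop("model time 't' must be non-negative")
  f$F0 + (f$F1 - f$F0) * exp(-t / f$tau)
}

#' @export
print.decay_forcing <- function(x, ...) {
  cat(sprintf("decay forcing: F(t) = %g + (%g - %g) exp(-t / %g yr)\n",
              x$F0, x$F1, x$F0, x$tau))
  invisible(x)
}

#' Continental crust growth model
#'
#' Volume of continental crust as a function of model time.  The default
#' two-phase history grows rapidly at `early_rate` until `breakpoint`
#' (onset of modern-style subduction), then more slowly at `late_rate`
#' to the present.  The `"constant"` alternative is a single linear ramp
#' reaching `present_volume` at 4.5 Gyr, so both modes are volume-matched
#' at the present day.
#'
#' The mean crustal thickness converts volume to the surface area that
#' the erosion flux scales with; crustal geometry is otherwise
#' unresolved.
#'
#' @param mode `"two_phase"` or `"constant"`.
#' @param early_rate,late_rate growth rates in km^3/yr (two-phase mode).
#' @param breakpoint model time of the rate transition, yr.
#' @param present_volume crustal volume at 4.5 Gyr, km^3 (constant mode;
#'   the two-phase default reaches the same 6.9e9 km^3).
#' @param mean_thickness mean crustal thickness in m, for the
#'   volume-to-area conversion.
#' @return An object of class `"continental_growth"`.
#' @examples
#' g <- continental_growth()
#' continental_volume(g, c(0, 1.5e9, 4.5e9))   # km^3
#' continental_area(g, 4.5e9)                  # m^2
#' @export
continental_growth <- function(mode = c("two_phase", "constant"),
                               early_rate = 3, late_rate = 0.8,
                               breakpoint = 1.5e9,
                               present_volume = 6.9e9,
                               mean_thickness = 4e4) {
  mode <- match.arg(mode)
  if (early_rate < 0 || late_rate < 0) stop("growth rates must be non-negative")
  if (breakpoint <= 0 || breakpoint >= 4.5e9)
    stop("'breakpoint' must lie strictly between 0 and 4.5e9 yr")
  if (present_volume < 0) stop("'present_volume' must be non-negative")
  if (mean_thickness <= 0) stop("'mean_thickness' must be positive")
  structure(list(mode = mode, early_rate = early_rate, late_rate = late_rate,
                 breakpoint = breakpoint, present_volume = present_volume,
                 mean_thickness = mean_thickness),
            class = "continental_growth")
}

#' Continental crust volume at model time t
#'
#' @param g a [continental_growth()] model.
#' @param t model time in years (vectorized).
#' @return Crustal volume in km^3; non-decreasing in `t`.
#' @export
continental_volume <- function(g, t) {
  stopifnot(inherits(g, "continental_growth"), is.numeric(t))
  if (any(t < 0)) stop("model time 't' must be non-negative")
  if (g$mode == "two_phase") {
    g$early_rate * pmin(t, g$breakpoint) + g$late_rate * pmax(0, t - g$breakpoint)
  } else {
    g$present_volume * t / 4.5e9
  }
}

#' Continental surface area at model time t
#'
#' Volume divided by the mean crustal thickness; used by the erosion flux,
#' which is proportional to exposed continental area.
#'
#' @inheritParams continental_volume
#' @return Area in m^2.
#' @export
continental_area <- function(g, t) {
  continental_volume(g, t) * 1e9 / g$mean_thickness  # km^3 -> m^3, / m
}
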