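#' Temporal pH drivers
#'
#' A pH driver maps time (hours) to environmental pH.  Three kinds are
#' supported:
#' \describe{
#'   \item{constant}{`p(t) = p0`.}
#'   \item{sinusoid}{`p(t) = p0 + dph * sin(2 * pi * f_ph * t)`, the
#'     controlled fluctuation used in the amplitude/frequency sweeps.}
#'   \item{telegraph}{random switching between the two discrete levels
#'     `p0 - dph` and `p0 + dph`, with independent exponentially
#'     distributed holding times of mean `1/f_ph` so the characteristic
#'     switching frequency is comparable to a sinusoid of frequency
#'     `f_ph`.  Fully reproducible from `seed`.}
#' }
#' Emitted pH is always clamped to `range`, the pH interval over which the
#' strain responses were characterized.
#'
#' @param p0 center pH.  The default 6.3 is the midpoint of the 5.1-7.5
#'   characterization range.
#' @param dph fluctuation amplitude (pH units), >= 0.
#' @param f_ph fluctuation frequency (1/h), > 0.
#' @param seed integer seed for the telegraph switching schedule.
#' @param range length-2 clamp interval.
#' @return An object of class `"ph_driver"`.
#' @name ph_driver
NULL

new_driver <- function(kind, p0, dph, f_ph, seed, range) {
  if (!is_number(p0)) stopf("p0 must be a finite pH value")
  if (!is_number(dph) || dph < 0) stopf("dph must be >= 0")
  if (kind != "constant" && (!is_number(f_ph) || f_ph <= 0))
    stopf("f_ph must be > 0 for a %s driver", kind)
  structure(list(kind = kind, p0 = p0, dph = dph, f_ph = f_ph, seed = seed,
                 range = as.numeric(range)),
            class = "ph_driver")
}

#' @rdname ph_driver
#' @export
ph_constant <- function(p0 = 6.3, range = c(5.1, 7.5)) {
  new_driver("constant", p0, 0, NA_real_, NULL, range)
}

#' @rdname ph_driver
#' @export
ph_sinusoid <- function(p0 = 6.3, dph = 0.5, f_ph = 1, range = c(5.1, 7.5)) {
  new_driver("sinusoid", p0, dph, f_ph, NULL, range)
}

#' @rdname ph_driver
#' @export
ph_telegraph <- function(p0 = 6.3, dph = 0.5, f_ph = 1, seed = 1,
                         range = c(5.1, 7.5)) {
  new_driver("telegraph", p0, dph, f_ph, as.integer(seed), range)
}

#' @export
print.ph_driver <- function(x, ...) {
  cat("<ph_driver>", x$kind, sprintf("p0=%g dpH=%g", x$p0, x$dph),
      if (x$kind != "constant") sprintf("f_pH=%g/h", x$f_ph) else "", "\n")
  invisible(x)
}

# Telegraph switching schedule on [0, t_max]: alternating levels
# p0 +/- dph with iid Exp(f_ph) holding times; starting level is a fair
# coin.  Regenerating with a larger t_max extends the same sequence
# because draws are consumed in order from the same seed.
telegraph_schedule <- function(driver, t_max) {
  stopifnot(driver$kind == "telegraph")
  with_seed(driver$seed, {
    up_first <- runif(1) < 0.5
    times <- 0
    repeat {
      holds <- rexp(64, rate = driver$f_ph)
      times <- c(times, times[length(times)] + cumsum(holds))
      if (times[length(times)] > t_max) break
    }
    times <- times[times <= t_max]
    lv <- rep(c(driver$p0 + driver$dph, driver$p0 - driver$dph),
              length.out = length(times))
    if (!up_first) lv <- rep(c(driver$p0 - driver$dph, driver$p0 + driver$dph),
                             length.out = length(times))
    list(times = times, levels = pmin(pmax(lv, driver$range[1]),
                                      driver$range[2]))
  })
}

#' Evaluate a pH driver
#'
#' @param driver a [ph_driver].
#' @param t time(s) in hours, >= 0.
#' @return pH value(s), clamped to the driver's range.
#' @export
#' @examples
#' ph_at(ph_sinusoid(p0 = 6.3, dph = 0.5, f_ph = 1), 0.25)  # 6.8
ph_at <- function(driver, t) {
  stopifnot(inherits(driver, "ph_driver"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stopf("t must be finite and >= 0")
  p <- switch(driver$kind,
    constant = rep(driver$p0, length(t)),
    sinusoid = driver$p0 + driver$dph * sin(2 * pi * driver$f_ph * t),
    telegraph = {
      sch <- telegraph_schedule(driver, max(t) + 1)
      sch$levels[findInterval(t, sch$times)]
    })
  pmin(pmax(p, driver$range[1]), driver$range[2])
}
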