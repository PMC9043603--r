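#' Dosing schedule
#'
#' Describes a repeated-bolus administration: route, per-administration dose
#' (mg per kg body weight), dosing interval, and number of doses. For the
#' oral route, `fabs` is the fraction of each dose absorbed from the gut
#' lumen (default 1, the conservative 100%-absorption screening assumption)
#' and `ka` the first-order gut absorption rate.
#'
#' @param route `"oral"` or `"iv"`.
#' @param dose_per_admin Dose per administration, mg/kg body weight.
#' @param interval Time between administrations, h. Must be positive.
#' @param n_doses Number of administrations (>= 1). Doses occur at
#'   `0, interval, ..., (n_doses - 1) * interval` hours.
#' @param fabs Oral fraction absorbed, in (0, 1].
#' @param ka Gut absorption rate constant, 1/h (default 2.18).
#' @return An object of class `dosing_schedule`.
#' @examples
#' dosing_schedule("oral", 1, interval = 1, n_doses = 24)  # hourly for 24 h
#' @export
dosing_schedule <- function(route = c("oral", "iv"), dose_per_admin,
                            interval, n_doses, fabs = 1, ka = 2.18) {
  route <- match.arg(route)
  if (!is.numeric(dose_per_admin) || dose_per_admin < 0)
    stop("dosing_schedule: 'dose_per_admin' must be >= 0")
  if (!is.numeric(interval) || interval <= 0)
    stop("dosing_schedule: 'interval' must be > 0")
  if (!is.numeric(n_doses) || n_doses < 1 || n_doses != round(n_doses))
    stop("dosing_schedule: 'n_doses' must be an integer >= 1")
  if (!is.numeric(fabs) || fabs <= 0 || fabs > 1)
    stop("dosing_schedule: 'fabs' must lie in (0, 1]")
  if (!is.numeric(ka) || ka <= 0)
    stop("dosing_schedule: 'ka' must be > 0")
  structure(list(route = route, dose_per_admin = dose_per_admin,
                 interval = interval, n_doses = as.integer(n_doses),
                 fabs = fabs, ka = ka),
            class = "dosing_schedule")
}

#' @export
print.dosing_schedule <- function(x, ...) {
  cat(sprintf("<dosing_schedule> %s %.4g mg/kg every %.4g h x %d (fabs %.3g, ka %.3g /h)\n",
              x$route, x$dose_per_admin, x$interval, x$n_doses, x$fabs, x$ka))
  invisible(x)
}

# Administration times in hours.
dose_times <- function(schedule) {
  (seq_len(schedule$n_doses) - 1L) * schedule$interval
}

#' Parse a dosing-schedule expression
#'
#' Mini-grammar `route:<dose>mg/kg@<interval>h x<N>`, for example
#' `"oral:1mg/kg@1h x24"` (an hourly 1 mg/kg oral bolus, 24 doses) or
#' `"iv:0.5mg/kg@24h x1"`. Whitespace around tokens is ignored.
#'
#' @param spec The schedule string.
#' @param fabs,ka Optional absorption settings forwarded to
#'   [dosing_schedule()].
#' @return A [dosing_schedule()].
#' @examples
#' parse_schedule("oral:1mg/kg@1h x24")
#' @export
parse_schedule <- function(spec, fabs = 1, ka = 2.18) {
  stopifnot(is.character(spec), length(spec) == 1L)
  pat <- paste0("^\\s*(oral|iv)\\s*:\\s*([0-9.eE+-]+)\\s*mg/kg\\s*@\\s*",
                "([0-9.eE+-]+)\\s*h\\s*x\\s*([0-9]+)\\s*$")
  m <- regmatches(spec, regexec(pat, spec))[[1L]]
  if (!length(m))
    stop("parse_schedule: cannot parse \"", spec,
         "\"; expected e.g. \"oral:1mg/kg@1h x24\"")
  dosing_schedule(route = m[[2L]],
                  dose_per_admin = as.numeric(m[[3L]]),
                  interval = as.numeric(m[[4L]]),
                  n_doses = as.integer(m[[5L]]),
                  fabs = fabs, ka = ka)
}
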