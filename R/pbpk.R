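#' Build a flow-limited PBPK model for one chemical
#'
#' Assembles the state equations, rate parameters, and dosing-event list
#' for a flow-limited (perfusion-limited) compartmental model with six
#' reported compartments: venous plasma, arterial plasma, gut, liver,
#' kidney, and a lumped rest-of-body tissue. States are amounts in umol;
#' reported concentrations are amount/volume in uM. With
#' `C_x = A_x / V_x` and tissue venous outflow at `C_t / Kp_t`:
#'
#' \itemize{
#'   \item gut lumen: `dA_lumen/dt = -ka * A_lumen`; the absorbed flux
#'     `fabs * ka * A_lumen` enters gut tissue, the remainder passes to
#'     feces;
#'   \item gut: `dA/dt = fabs * ka * A_lumen + Q_gut (C_art - C_gut/Kp_gut)`;
#'   \item liver: inflow from hepatic artery and portal (gut) vein, outflow
#'     at `C_liv/Kp_liv`, plus hepatic metabolism
#'     `CLint_whole * fub * C_liv/Kp_liv` (well-stirred, on unbound venous-
#'     equivalent concentration);
#'   \item kidney: perfusion exchange plus renal filtration
#'     `GFR * fub * C_kid/Kp_kid`;
#'   \item rest: perfusion exchange only;
#'   \item venous/arterial plasma: collect tissue outflows and recirculate
#'     at the cardiac plasma flow (the lung is lumped into the arterial
#'     leg).
#' }
#'
#' Oral administrations add `dose_per_admin * bw / mw * 1000` umol to the
#' gut lumen at each administration time; IV administrations add the same
#' amount to venous plasma. All processes are first order, so the model is
#' dose-linear.
#'
#' @param profile A resolved [chemical_profile()].
#' @param physiology A [physiology()] object.
#' @param schedule A [dosing_schedule()].
#' @return An object of class `pbpk_model`: parameters, partition
#'   coefficients, initial state, event table, and the derivative function.
#' @export
build_model <- function(profile, physiology, schedule) {
  if (!inherits(profile, "chemical_profile"))
    stop("build_model: 'profile' must be a resolved chemical_profile")
  stopifnot(inherits(physiology, "physiology"),
            inherits(schedule, "dosing_schedule"))

  comps <- physiology_compositions(physiology)
  kp <- calc_partition_coefficients(profile, comps,
                                    plasma = physiology$plasma_composition)
  for (tn in c("gut", "liver", "kidney", "rest"))
    if (!is.finite(kp[[tn]]) || kp[[tn]] <= 0)
      stop("build_model: invalid partition coefficient for tissue '", tn,
           "' of ", profile$casrn)

  clint_whole <- scale_intrinsic_clearance(
    profile$clint, physiology$hepatocellularity, physiology$liver_mass)

  p <- list(
    ka = schedule$ka, fabs = schedule$fabs,
    V_gut = physiology$tissues$gut$volume,
    V_liv = physiology$tissues$liver$volume,
    V_kid = physiology$tissues$kidney$volume,
    V_rest = physiology$tissues$rest$volume,
    V_ven = physiology$v_ven, V_art = physiology$v_art,
    Q_gut = physiology$tissues$gut$flow,
    Q_kid = physiology$tissues$kidney$flow,
    Q_rest = physiology$tissues$rest$flow,
    Q_ha = physiology$q_hepatic_artery,
    Q_card = physiology$q_cardiac,
    Kp_gut = kp[["gut"]], Kp_liv = kp[["liver"]],
    Kp_kid = kp[["kidney"]], Kp_rest = kp[["rest"]],
    CLint_whole = clint_whole, fub = profile$fub,
    GFR = physiology$gfr)

  dose_umol <- schedule$dose_per_admin * physiology$bw / profile$mw * 1000
  target <- if (schedule$route == "oral") "A_gutlumen" else "A_ven"
  events <- data.frame(var = target, time = dose_times(schedule),
                       value = dose_umol, method = "add",
                       stringsAsFactors = FALSE)

  states <- c("A_gutlumen", "A_gut", "A_liver", "A_kidney", "A_rest",
              "A_ven", "A_art", "A_metabolized", "A_urine", "A_feces")
  y0 <- stats::setNames(numeric(length(states)), states)

  derivs <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      C_gut  <- A_gut / V_gut
      C_liv  <- A_liver / V_liv
      C_kid  <- A_kidney / V_kid
      C_rest <- A_rest / V_rest
      C_ven  <- A_ven / V_ven
      C_art  <- A_art / V_art
      absorbed <- fabs * ka * A_gutlumen
      unabsorbed <- (1 - fabs) * ka * A_gutlumen
      met <- CLint_whole * fub * C_liv / Kp_liv
      ur  <- GFR * fub * C_kid / Kp_kid
      dGl   <- -ka * A_gutlumen
      dGut  <- absorbed + Q_gut * (C_art - C_gut / Kp_gut)
      dLiv  <- Q_ha * C_art + Q_gut * C_gut / Kp_gut -
        (Q_ha + Q_gut) * C_liv / Kp_liv - met
      dKid  <- Q_kid * (C_art - C_kid / Kp_kid) - ur
      dRest <- Q_rest * (C_art - C_rest / Kp_rest)
      dVen  <- (Q_ha + Q_gut) * C_liv / Kp_liv + Q_kid * C_kid / Kp_kid +
        Q_rest * C_rest / Kp_rest - Q_card * C_ven
      dArt  <- Q_card * C_ven - Q_card * C_art
      list(c(dGl, dGut, dLiv, dKid, dRest, dVen, dArt, met, ur, unabsorbed))
    })
  }

  structure(
    list(profile = profile, physiology = physiology, schedule = schedule,
         kp = kp, clint_whole = clint_whole, parms = p, y0 = y0,
         events = events, dose_umol = dose_umol, derivs = derivs),
    class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s: %s, %.4g umol/administration, CLint(whole) %.4g L/h\n",
              x$profile$casrn, x$schedule$route, x$dose_umol, x$clint_whole))
  cat("  Kp:", paste(sprintf("%s=%.3g", names(x$kp), x$kp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate a PBPK model
#'
#' Integrates the model with an adaptive stiff-capable solver
#' (`deSolve::lsoda`), applying each administration as an exact state jump
#' at its event time. The output grid carries at least 20 points per dosing
#' interval (configurable) plus all event times. Tolerances default to
#' rtol 1e-8 and atol 1e-10 umol so that mass-balance and dose-linearity
#' checks are meaningful.
#'
#' @param model A [build_model()] result.
#' @param duration Simulated time, h; must cover the last administration.
#' @param output_points Number of output grid points; defaults to 20 per
#'   dosing interval over the duration (minimum 100).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `pk_sim_result` with fields `time` (h),
#'   `conc` (matrix, uM, columns `plasma_ven`, `plasma_art`, `gut`,
#'   `liver`, `kidney`, `rest`), cumulative elimination ledgers
#'   `a_metabolized`, `a_urine`, `a_feces` (umol), `total_administered`
#'   (umol), and the schedule used.
#' @export
simulate_pk <- function(model, duration, output_points = NULL,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "pbpk_model"))
  sched <- model$schedule
  last_dose <- max(dose_times(sched))
  if (duration < last_dose)
    stop("simulate_pk: 'duration' (", duration,
         " h) must cover the last administration at ", last_dose, " h")
  if (is.null(output_points))
    output_points <- max(100L, ceiling(20 * duration / sched$interval))
  grid <- seq(0, duration, length.out = output_points + 1L)

  # First dose goes into the initial state; later doses are solver events.
  y0 <- model$y0
  ev <- model$events
  first <- ev$time == 0
  if (any(first))
    y0[ev$var[first]] <- y0[ev$var[first]] + ev$value[first]
  ev <- ev[!first & ev$time <= duration, , drop = FALSE]
  # The solver reports the pre-event state at an event time; add a point
  # just after each event so the post-jump state is also on the grid.
  eps <- sched$interval * 1e-6
  times <- sort(unique(c(grid, ev$time,
                         ev$time[ev$time + eps <= duration] + eps)))

  out <- try(deSolve::ode(
    y = y0, times = times, func = model$derivs, parms = model$parms,
    method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000,
    events = if (nrow(ev)) list(data = ev) else NULL), silent = TRUE)
  if (inherits(out, "try-error") || any(!is.finite(out[, -1])))
    stop("simulate_pk: solver failure for chemical ", model$profile$casrn,
         if (!inherits(out, "try-error"))
           paste0(" near t = ", signif(max(out[is.finite(rowSums(out)), 1]), 4),
                  " h"))

  out <- as.data.frame(out)
  p <- model$parms
  conc <- cbind(
    plasma_ven = out$A_ven / p$V_ven,
    plasma_art = out$A_art / p$V_art,
    gut = out$A_gut / p$V_gut,
    liver = out$A_liver / p$V_liv,
    kidney = out$A_kidney / p$V_kid,
    rest = out$A_rest / p$V_rest)

  n_given <- sum(dose_times(sched) <= duration)
  total_admin <- model$dose_umol * n_given

  res <- structure(
    list(time = out$time, conc = conc,
         a_gutlumen = out$A_gutlumen,
         amounts = out[, c("A_gutlumen", "A_gut", "A_liver", "A_kidney",
                           "A_rest", "A_ven", "A_art")],
         a_metabolized = out$A_metabolized, a_urine = out$A_urine,
         a_feces = out$A_feces, total_administered = total_admin,
         dose_umol = model$dose_umol,
         schedule = sched, casrn = model$profile$casrn,
         solver = list(rtol = rtol, atol = atol)),
    class = "pk_sim_result")

  if (min(res$conc) < -1e-6 * max(abs(res$conc)))
    stop("simulate_pk: negative concentrations for ", model$profile$casrn)
  res$conc[res$conc < 0] <- 0
  res
}

#' @export
print.pk_sim_result <- function(x, ...) {
  cat(sprintf("<pk_sim_result> %s: %d time points over %.4g h, %.5g umol administered\n",
              x$casrn, length(x$time), max(x$time), x$total_administered))
  cm <- apply(x$conc, 2, max)
  cat("  Cmax (uM):", paste(sprintf("%s=%.4g", names(cm), cm),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Mass-balance error of a simulation
#'
#' Relative deviation of (amount in all compartments + eliminated amounts)
#' from the cumulative administered amount at each output time, as a
#' fraction of the total administered dose. A correct integration keeps
#' this below 1e-3 everywhere.
#'
#' At an administration time the reported state is the pre-dose state (the
#' dose is applied as an instantaneous jump), so a dose counts as delivered
#' only at strictly later output times; the first dose (t = 0) is part of
#' the initial state.
#'
#' @param result A [simulate_pk()] result.
#' @return Numeric vector of signed relative errors, one per output time.
#' @export
mass_balance_error <- function(result) {
  stopifnot(inherits(result, "pk_sim_result"))
  sched <- result$schedule
  later <- dose_times(sched)[dose_times(sched) > 0]
  given <- result$dose_umol * (1 + vapply(result$time, function(t)
    sum(later < t - 1e-12), numeric(1)))
  in_system <- rowSums(result$amounts) + result$a_metabolized +
    result$a_urine + result$a_feces
  if (result$total_administered == 0) return(in_system * 0)
  (in_system - given) / result$total_administered
}

# Resolve a window specification to index range into result$time.
window_idx <- function(result, window) {
  if (identical(window, "full")) {
    idx <- seq_along(result$time)
  } else if (identical(window, "last_interval")) {
    t0 <- max(dose_times(result$schedule))
    idx <- which(result$time >= t0 - 1e-12)
  } else stop("window must be \"full\" or \"last_interval\"")
  if (!length(idx)) stop("empty window")
  idx
}

#' Maximum concentration and its time
#'
#' Returns the maximum simulated concentration of a compartment over the
#' requested window and the time at which it occurs. Ties are broken by the
#' earliest time.
#'
#' @param result A [simulate_pk()] result.
#' @param compartment One of the reported compartments (default
#'   `"plasma_ven"`, the venous plasma pool used for IVIVE).
#' @param window `"full"` (whole simulation) or `"last_interval"` (from the
#'   last administration to the end).
#' @return Named numeric vector `c(cmax = , tmax = )`, uM and h.
#' @export
cmax <- function(result, compartment = "plasma_ven", window = "full") {
  stopifnot(inherits(result, "pk_sim_result"))
  if (!compartment %in% colnames(result$conc))
    stop("cmax: unknown compartment '", compartment, "'")
  idx <- window_idx(result, window)
  y <- result$conc[idx, compartment]
  i <- which.max(y)  # which.max returns the first (earliest) maximum
  c(cmax = y[[i]], tmax = result$time[idx][[i]])
}

#' Trapezoidal area under the concentration curve
#'
#' @param result A [simulate_pk()] result.
#' @param compartment Reported compartment name.
#' @param t0,t1 Integration window, h; must lie within the simulated range
#'   with `t0 < t1`.
#' @return AUC in uM*h on the output grid (trapezoidal rule).
#' @export
pk_auc <- function(result, compartment = "plasma_ven", t0 = 0,
                   t1 = max(result$time)) {
  stopifnot(inherits(result, "pk_sim_result"))
  if (!compartment %in% colnames(result$conc))
    stop("pk_auc: unknown compartment '", compartment, "'")
  if (t0 >= t1 || t0 < min(result$time) - 1e-12 ||
      t1 > max(result$time) + 1e-12)
    stop("pk_auc: window [", t0, ", ", t1, "] outside the simulated range")
  keep <- result$time >= t0 - 1e-12 & result$time <= t1 + 1e-12
  tt <- result$time[keep]
  yy <- result$conc[keep, compartment]
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Time-series data frame of a simulation
#'
#' @param x A [simulate_pk()] result.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return data.frame with columns `time_h`, per-compartment concentrations
#'   in uM, and cumulative eliminated amounts in umol.
#' @export
as.data.frame.pk_sim_result <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(time_h = x$time,
             plasma_ven_uM = x$conc[, "plasma_ven"],
             plasma_art_uM = x$conc[, "plasma_art"],
             gut_uM = x$conc[, "gut"],
             liver_uM = x$conc[, "liver"],
             kidney_uM = x$conc[, "kidney"],
             rest_uM = x$conc[, "rest"],
             a_metabolized_umol = x$a_metabolized,
             a_urine_umol = x$a_urine,
             a_feces_umol = x$a_feces)
}

#' Write a simulation time-series CSV
#'
#' Writes the standard time-series layout with 6 significant digits, the
#' package's fixed output precision (so a re-read reproduces the printed
#' values exactly).
#'
#' @param result A [simulate_pk()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  df <- as.data.frame(result)
  out <- as.data.frame(lapply(df, function(col) signif(col, 6)))
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
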