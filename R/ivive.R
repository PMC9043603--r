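#' Venous plasma Cmax at a unit (1 mg/kg) administered dose
#'
#' Runs the forward PBPK simulation under the user's dosing schedule with
#' the per-administration dose set to 1 mg/kg and returns the venous plasma
#' Cmax over the full simulation window. This is the normalizing internal
#' concentration for Cmax-based reverse dosimetry; because the model is
#' first order, the EAD for any bioactive concentration follows by simple
#' scaling. The dosing schedule matters: repeat dosing of a slowly cleared
#' chemical accumulates, so EADs depend on dosing frequency.
#'
#' @param profile A resolved [chemical_profile()].
#' @param physiology A [physiology()] object.
#' @param schedule A [dosing_schedule()] used as a template; its
#'   `dose_per_admin` is replaced by 1 mg/kg.
#' @param duration Simulated time, h; defaults to `n_doses * interval`.
#' @return Venous plasma Cmax in uM at 1 mg/kg per administration.
#' @export
unit_dose_cmax <- function(profile, physiology, schedule,
                           duration = schedule$n_doses * schedule$interval) {
  unit_sched <- schedule
  unit_sched$dose_per_admin <- 1
  model <- build_model(profile, physiology, unit_sched)
  res <- simulate_pk(model, duration = duration)
  unname(cmax(res, "plasma_ven", "full")[["cmax"]])
}

#' Equivalent administered dose from an AC50
#'
#' Reverse dosimetry by Cmax scaling: the administered dose (mg/kg per
#' administration, reported as mg/kg/day under the schedule used) whose
#' predicted plasma Cmax equals the in vitro bioactive concentration is
#'
#' \deqn{EAD = \frac{AC50}{Cmax_{unit}} \times 1\ mg/kg/day}
#'
#' where `cmax_unit` is the plasma Cmax predicted at 1 mg/kg per
#' administration under the same schedule ([unit_dose_cmax()]).
#'
#' @param ac50 Bioactive concentration, uM. Must be positive.
#' @param cmax_unit Unit-dose plasma Cmax, uM. Must be positive.
#' @return EAD in mg/kg/day.
#' @examples
#' compute_ead(20.04, 1.4815)  # ~13.53 mg/kg/day
#' @export
compute_ead <- function(ac50, cmax_unit) {
  if (any(!is.finite(ac50)) || any(ac50 <= 0))
    stop("compute_ead: 'ac50' must be positive")
  if (!is.finite(cmax_unit) || cmax_unit <= 0)
    stop("compute_ead: 'cmax_unit' must be positive")
  ac50 / cmax_unit
}

#' Summarize per-assay EADs for one chemical
#'
#' Filters to active assay records, converts each AC50 to an EAD via
#' [compute_ead()], and reports distribution summaries. The median uses the
#' midpoint-of-two convention for even counts (the default of
#' [stats::median()]).
#'
#' @param records data.frame of assay records for one chemical (and
#'   typically one annotation group) with columns `casrn`, `assay_id`,
#'   `ac50` (uM), `active` (logical), and optionally `group`.
#' @param cmax_unit Unit-dose plasma Cmax, uM.
#' @param schedule Optional [dosing_schedule()] recorded in the result so
#'   every EAD is traceable to the dosing frequency that produced its
#'   normalizing Cmax.
#' @return An object of class `ead_result` with `per_assay` (data.frame:
#'   `assay_id`, `ac50`, `ead`), `summary` (named vector: `median`, `q1`,
#'   `q3`, `min`, `max`, mg/kg/day), `n_active`, `cmax_unit`, `casrn`, and
#'   the schedule. When no record is active the result is an empty signal:
#'   `n_active == 0`, zero-row `per_assay`, all-`NA` summary — not an
#'   error.
#' @export
summarize_eads <- function(records, cmax_unit, schedule = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("casrn", "assay_id", "ac50", "active")
  if (!all(need %in% names(records)))
    stop("summarize_eads: records need columns ", paste(need, collapse = ", "))
  casrn <- if (nrow(records)) as.character(records$casrn[[1L]]) else NA_character_
  act <- records[as.logical(records$active), , drop = FALSE]
  if (nrow(act) && (any(!is.finite(act$ac50)) || any(act$ac50 <= 0)))
    stop("summarize_eads: active records must have positive AC50 (", casrn, ")")
  if (!nrow(act)) {
    return(structure(list(
      casrn = casrn, cmax_unit = cmax_unit, schedule = schedule,
      n_active = 0L,
      per_assay = data.frame(assay_id = character(), ac50 = numeric(),
                             ead = numeric()),
      summary = c(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                  min = NA_real_, max = NA_real_)),
      class = "ead_result"))
  }
  ead <- compute_ead(act$ac50, cmax_unit)
  per_assay <- data.frame(assay_id = as.character(act$assay_id),
                          ac50 = act$ac50, ead = ead,
                          stringsAsFactors = FALSE)
  qs <- stats::quantile(ead, c(0.25, 0.75), names = FALSE)
  structure(list(
    casrn = casrn, cmax_unit = cmax_unit, schedule = schedule,
    n_active = nrow(act), per_assay = per_assay,
    summary = c(median = stats::median(ead), q1 = qs[[1L]], q3 = qs[[2L]],
                min = min(ead), max = max(ead))),
    class = "ead_result")
}

#' @export
print.ead_result <- function(x, ...) {
  if (x$n_active == 0L) {
    cat(sprintf("<ead_result> %s: no active assay records\n", x$casrn))
    return(invisible(x))
  }
  cat(sprintf("<ead_result> %s: %d active assays, unit-dose Cmax %.4g uM\n",
              x$casrn, x$n_active, x$cmax_unit))
  cat(sprintf("  EAD mg/kg/day: median %.4g [IQR %.4g-%.4g, range %.4g-%.4g]\n",
              x$summary[["median"]], x$summary[["q1"]], x$summary[["q3"]],
              x$summary[["min"]], x$summary[["max"]]))
  invisible(x)
}

#' Margin of exposure
#'
#' The ratio of an equivalent administered dose to an expected daily
#' exposure. Values near or below the uncertainty factors used in risk
#' assessment flag chemicals for priority follow-up; large values indicate
#' a wide margin between predicted bioactive doses and anticipated intake.
#'
#' @param ead EAD, mg/kg/day.
#' @param exposure Expected daily exposure, mg/kg/day. Must be positive.
#' @return Dimensionless margin of exposure, `ead / exposure`.
#' @examples
#' margin_of_exposure(271.26, 7.19e-4)  # ~377274
#' @export
margin_of_exposure <- function(ead, exposure) {
  if (!is.finite(ead) || ead <= 0)
    stop("margin_of_exposure: 'ead' must be positive")
  if (!is.finite(exposure) || exposure <= 0)
    stop("margin_of_exposure: 'exposure' must be positive")
  ead / exposure
}

#' Rank chemicals by margin of exposure
#'
#' Ascending, stable sort: the smallest margins (highest screening
#' priority) come first and ties preserve the input order.
#'
#' @param moe_results data.frame with at least columns `casrn` and `moe`,
#'   or a list of such rows.
#' @return The data.frame reordered ascending by `moe`.
#' @export
rank_chemicals <- function(moe_results) {
  if (is.list(moe_results) && !is.data.frame(moe_results))
    moe_results <- do.call(rbind, lapply(moe_results, as.data.frame))
  stopifnot(is.data.frame(moe_results), nrow(moe_results) >= 1L,
            all(c("casrn", "moe") %in% names(moe_results)))
  out <- moe_results[order(moe_results$moe), , drop = FALSE]  # stable sort
  rownames(out) <- NULL
  out
}

#' Read an assay table CSV, normalizing AC50 units to uM
#'
#' Columns: `casrn,assay_id,group,ac50,ac50_units,active` with
#' `ac50_units` one of `uM`, `nM`, `M`. AC50s are converted to uM on
#' ingest so all downstream arithmetic is unit-consistent.
#'
#' @param path Path to the CSV.
#' @return data.frame with `ac50` in uM and logical `active`.
#' @export
read_assays <- function(path) {
  if (!file.exists(path)) stop("read_assays: file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("casrn", "assay_id", "ac50", "active")
  if (!all(need %in% names(tab)))
    stop("read_assays: CSV must have columns ", paste(need, collapse = ", "))
  if (is.null(tab$ac50_units)) tab$ac50_units <- "uM"
  fac <- c(uM = 1, nM = 1e-3, M = 1e6)[tab$ac50_units]
  if (any(is.na(fac)))
    stop("read_assays: unknown ac50_units in row(s) ",
         paste(utils::head(which(is.na(fac)), 5L), collapse = ", "),
         " (allowed: uM, nM, M)")
  tab$ac50 <- as.numeric(tab$ac50) * unname(fac)
  tab$ac50_units <- "uM"
  tab$active <- as.logical(tab$active)
  tab
}

#' Read an exposure table CSV
#'
#' Columns: `casrn,exposure_mg_per_kg_day` and optionally
#' `percentile_label` (e.g. `"95th"`).
#'
#' @param path Path to the CSV.
#' @return data.frame of exposure estimates in mg/kg/day.
#' @export
read_exposures <- function(path) {
  if (!file.exists(path)) stop("read_exposures: file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("casrn", "exposure_mg_per_kg_day")
  if (!all(need %in% names(tab)))
    stop("read_exposures: CSV must have columns ",
         paste(need, collapse = ", "))
  tab$exposure_mg_per_kg_day <- as.numeric(tab$exposure_mg_per_kg_day)
  if (any(!is.finite(tab$exposure_mg_per_kg_day) |
            tab$exposure_mg_per_kg_day <= 0))
    stop("read_exposures: exposures must be positive")
  tab
}
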