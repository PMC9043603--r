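#' Chemical profile: physicochemical and ADME parameters with provenance
#'
#' Container for the chemical-specific quantities the PBPK model needs:
#' molecular weight, lipophilicity, ionization constants, plasma protein
#' binding, intrinsic hepatic clearance, the blood:plasma ratio, and any
#' directly supplied tissue:plasma partition coefficients. Every numeric
#' parameter carries a provenance tag (`"measured"`, `"predicted"`, or
#' `"default"`) so each model output is traceable to its input sources.
#'
#' @param name Chemical name (free text).
#' @param casrn Chemical identifier (CASRN or any stable id).
#' @param mw Molecular weight, g/mol. Must be positive.
#' @param logp log10 octanol:water partition coefficient (dimensionless).
#' @param pka Optional list of ionizable groups; each element is a list with
#'   `value` (the pKa) and `kind` (`"acid"` or `"base"`). `NULL` for
#'   neutral chemicals.
#' @param fub Fraction unbound in plasma, in (0, 1].
#' @param clint Intrinsic clearance, uL/min per 10^6 hepatocytes. Must be
#'   non-negative.
#' @param rb2p Blood:plasma concentration ratio (dimensionless, default 1).
#' @param kp_overrides Optional named numeric vector of tissue:plasma
#'   partition coefficients that take precedence over composition-derived
#'   values (names are model tissues, e.g. `liver`). All must be positive.
#' @param provenance Named character vector mapping parameter names to
#'   `"measured"`, `"predicted"`, or `"default"`. Parameters without an
#'   entry are tagged `"default"`.
#' @param extras Named numeric vector of additional stored parameters that
#'   do not enter the oral-route model (e.g. a Henry's law constant);
#'   retained for schema parity with upstream parameter providers.
#'
#' @return An object of class `chemical_profile`.
#' @examples
#' chemical_profile(
#'   name = "examplol", casrn = "0-00-0", mw = 250, logp = 2.5,
#'   fub = 0.2, clint = 10
#' )
#' @export
chemical_profile <- function(name, casrn, mw, logp, pka = NULL, fub, clint,
                             rb2p = 1, kp_overrides = NULL,
                             provenance = character(), extras = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(casrn), length(casrn) == 1L)
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0)
    stop("chemical_profile: 'mw' must be a positive number for ", casrn)
  if (!is.numeric(logp) || length(logp) != 1L || !is.finite(logp))
    stop("chemical_profile: 'logp' must be a finite number for ", casrn)
  if (!is.numeric(fub) || length(fub) != 1L || !is.finite(fub) ||
      fub <= 0 || fub > 1)
    stop("chemical_profile: 'fub' must lie in (0, 1] for ", casrn)
  if (!is.numeric(clint) || length(clint) != 1L || !is.finite(clint) ||
      clint < 0)
    stop("chemical_profile: 'clint' must be >= 0 for ", casrn)
  if (!is.numeric(rb2p) || length(rb2p) != 1L || !is.finite(rb2p) ||
      rb2p <= 0)
    stop("chemical_profile: 'rb2p' must be > 0 for ", casrn)
  if (!is.null(pka)) {
    stopifnot(is.list(pka))
    for (grp in pka) {
      if (!is.list(grp) || is.null(grp$value) || is.null(grp$kind) ||
          !grp$kind %in% c("acid", "base"))
        stop("chemical_profile: each pKa entry needs a 'value' and a 'kind' ",
             "of \"acid\" or \"base\" (", casrn, ")")
    }
  }
  if (!is.null(kp_overrides)) {
    if (is.null(names(kp_overrides)) || any(!nzchar(names(kp_overrides))))
      stop("chemical_profile: 'kp_overrides' must be a named vector")
    if (any(!is.finite(kp_overrides)) || any(kp_overrides <= 0))
      stop("chemical_profile: all kp_overrides must be positive (", casrn, ")")
  }
  numeric_params <- c("mw", "logp", "fub", "clint", "rb2p",
                      if (!is.null(pka)) vapply(seq_along(pka), function(i)
                        paste0("pka_", pka[[i]]$kind, i), character(1)),
                      if (!is.null(kp_overrides))
                        paste0("kp_", names(kp_overrides)),
                      names(extras))
  prov <- rep("default", length(numeric_params))
  names(prov) <- numeric_params
  if (length(provenance)) {
    bad <- setdiff(unique(provenance), c("measured", "predicted", "default"))
    if (length(bad))
      stop("chemical_profile: unknown provenance value(s): ",
           paste(bad, collapse = ", "))
    keep <- intersect(names(provenance), numeric_params)
    prov[keep] <- provenance[keep]
  }
  structure(
    list(name = name, casrn = casrn, mw = mw, logp = logp, pka = pka,
         fub = fub, clint = clint, rb2p = rb2p,
         kp_overrides = kp_overrides, provenance = prov, extras = extras),
    class = "chemical_profile")
}

#' @export
print.chemical_profile <- function(x, ...) {
  cat(sprintf("<chemical_profile> %s (%s)\n", x$name, x$casrn))
  cat(sprintf("  mw %.4g g/mol | logP %.3g | fub %.3g | CLint %.4g uL/min/1e6 cells | Rb:p %.3g\n",
              x$mw, x$logp, x$fub, x$clint, x$rb2p))
  if (!is.null(x$pka))
    cat("  pKa:", paste(vapply(x$pka, function(g)
      sprintf("%.2f (%s)", g$value, g$kind), character(1)), collapse = ", "),
      "\n")
  if (!is.null(x$kp_overrides))
    cat("  Kp overrides:", paste(sprintf("%s=%.3g", names(x$kp_overrides),
                                         x$kp_overrides), collapse = ", "), "\n")
  invisible(x)
}

# Parameters that must have at least one candidate value; everything else
# either has a documented default (rb2p) or is optional.
.required_params <- c("mw", "fub", "clint")

#' Resolve per-parameter candidate values into a chemical profile
#'
#' Applies the source-preference policy to a long-format table of candidate
#' parameter values: for each parameter the measured value is used where
#' available and the predicted (in silico) value otherwise; `rb2p` falls
#' back to a documented default of 1 when no candidate exists. The chosen
#' source is recorded per parameter in the profile's provenance map.
#'
#' Passing an already resolved `chemical_profile` returns it unchanged, so
#' resolution is idempotent.
#'
#' @param raw_records A data.frame with columns `parameter`, `value`,
#'   `source` (one of `measured`, `predicted`, `default`) and optionally
#'   `casrn` and `name`, holding all candidate rows for one chemical.
#'   Recognised parameter names: `mw`, `logp`, `pka_acid`, `pka_base`,
#'   `fub`, `clint`, `rb2p`, `kp_<tissue>`; any other parameter is stored
#'   in the profile's `extras` without entering the model.
#' @param policy Character vector giving the source-preference order.
#' @return A [chemical_profile()].
#' @examples
#' recs <- data.frame(
#'   parameter = c("mw", "logp", "fub", "fub", "clint"),
#'   value = c(250, 2.1, 0.1, 0.3, 5),
#'   source = c("measured", "predicted", "measured", "predicted", "predicted")
#' )
#' p <- resolve_parameters(recs)
#' p$fub                 # 0.1 -- measured wins
#' p$provenance[["fub"]] # "measured"
#' @export
resolve_parameters <- function(raw_records,
                               policy = c("measured", "predicted", "default")) {
  if (inherits(raw_records, "chemical_profile")) return(raw_records)
  stopifnot(is.data.frame(raw_records))
  need <- c("parameter", "value", "source")
  if (!all(need %in% names(raw_records)))
    stop("resolve_parameters: records need columns ",
         paste(need, collapse = ", "))
  casrn <- if ("casrn" %in% names(raw_records) && nrow(raw_records))
    as.character(raw_records$casrn[[1L]]) else "unknown"
  name <- if ("name" %in% names(raw_records) && nrow(raw_records))
    as.character(raw_records$name[[1L]]) else casrn

  pick <- function(param) {
    rows <- raw_records[raw_records$parameter == param, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    for (src in policy) {
      hit <- rows[rows$source == src, , drop = FALSE]
      if (nrow(hit))
        return(list(value = as.numeric(hit$value[[1L]]), source = src))
    }
    NULL
  }

  missing <- .required_params[vapply(.required_params,
                                     function(p) is.null(pick(p)), logical(1))]
  if (length(missing))
    stop("resolve_parameters: no candidate value of any source for ",
         "parameter(s) [", paste(missing, collapse = ", "), "] of chemical ",
         casrn)

  prov <- character()
  take <- function(param, default = NULL) {
    cand <- pick(param)
    if (is.null(cand)) {
      if (is.null(default)) return(NULL)
      prov[[param]] <<- "default"
      return(default)
    }
    prov[[param]] <<- cand$source
    cand$value
  }

  mw    <- take("mw")
  fub   <- take("fub")
  clint <- take("clint")
  logp  <- take("logp", default = 0)
  rb2p  <- take("rb2p", default = 1)

  pka <- list()
  i <- 0L
  for (kind in c("acid", "base")) {
    cand <- pick(paste0("pka_", kind))
    if (!is.null(cand)) {
      i <- i + 1L
      pka[[i]] <- list(value = cand$value, kind = kind)
      prov[[paste0("pka_", kind, i)]] <- cand$source
    }
  }
  if (!length(pka)) pka <- NULL

  all_params <- unique(as.character(raw_records$parameter))
  kp_params <- grep("^kp_", all_params, value = TRUE)
  kp_overrides <- NULL
  if (length(kp_params)) {
    kp_overrides <- vapply(kp_params, function(p) {
      cand <- pick(p)
      prov[[p]] <<- cand$source
      cand$value
    }, numeric(1))
    names(kp_overrides) <- sub("^kp_", "", kp_params)
  }

  known <- c("mw", "logp", "pka_acid", "pka_base", "fub", "clint", "rb2p",
             kp_params)
  extra_params <- setdiff(all_params, known)
  extras <- NULL
  if (length(extra_params)) {
    extras <- vapply(extra_params, function(p) {
      cand <- pick(p)
      prov[[p]] <<- cand$source
      cand$value
    }, numeric(1))
    names(extras) <- extra_params
  }

  chemical_profile(name = name, casrn = casrn, mw = mw, logp = logp,
                   pka = pka, fub = fub, clint = clint, rb2p = rb2p,
                   kp_overrides = kp_overrides, provenance = prov,
                   extras = extras)
}

#' Read a chemical parameter CSV and resolve all chemicals
#'
#' Expects one row per (chemical, parameter, source) with columns
#' `casrn,name,parameter,value,units,source`, `source` in
#' \{measured, predicted, default\}.
#'
#' @param path Path to the CSV file.
#' @param policy Source-preference order passed to [resolve_parameters()].
#' @return A named list of [chemical_profile()] objects keyed by CASRN.
#' @export
read_chemical_params <- function(path,
                                 policy = c("measured", "predicted", "default")) {
  if (!file.exists(path))
    stop("read_chemical_params: file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("casrn", "parameter", "value", "source")
  if (!all(need %in% names(tab)))
    stop("read_chemical_params: CSV must have columns ",
         paste(need, collapse = ", "))
  bad <- which(!tab$source %in% c("measured", "predicted", "default") |
                 !is.finite(suppressWarnings(as.numeric(tab$value))))
  if (length(bad))
    stop("read_chemical_params: malformed row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " in ", path, " (bad source tag or non-numeric value)")
  tab$value <- as.numeric(tab$value)
  split_tab <- split(tab, tab$casrn)
  profiles <- lapply(split_tab, resolve_parameters, policy = policy)
  names(profiles) <- names(split_tab)
  profiles
}

#' Whole-liver intrinsic clearance from a per-cell rate
#'
#' Scales an intrinsic clearance measured per million hepatocytes up to the
#' whole organ: `clint * hepatocellularity * liver_mass * 60e-6` converts
#' uL/min/10^6 cells to L/h for the whole liver.
#'
#' @param clint Intrinsic clearance, uL/min per 10^6 hepatocytes.
#' @param hepatocellularity 10^6 cells per gram of liver (default 110).
#' @param liver_mass Liver mass, g (default 1800, reference adult human).
#' @return Whole-liver intrinsic clearance, L/h.
#' @examples
#' scale_intrinsic_clearance(1, 110, 1800)  # 11.88 L/h
#' @export
scale_intrinsic_clearance <- function(clint, hepatocellularity = 110,
                                      liver_mass = 1800) {
  vals <- c(clint = clint, hepatocellularity = hepatocellularity,
            liver_mass = liver_mass)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("scale_intrinsic_clearance: all inputs must be finite and >= 0")
  clint * hepatocellularity * liver_mass * 60 * 1e-6
}

#' Henderson-Hasselbalch neutral fraction
#'
#' Fraction of an ionizable group in its neutral form at a given pH:
#' `1 / (1 + 10^(ph - pka))` for acids and `1 / (1 + 10^(pka - ph))` for
#' bases. Chemicals without a pKa are fully neutral (fraction 1).
#'
#' @param pka The group's pKa.
#' @param kind `"acid"` or `"base"`.
#' @param ph The pH at which to evaluate (physiological plasma pH is 7.4).
#' @return The neutral fraction, in \[0, 1\].
#' @examples
#' neutral_fraction(7.4, "acid", 7.4)  # 0.5
#' neutral_fraction(4.0, "acid", 7.4)  # ~3.98e-4
#' @export
neutral_fraction <- function(pka, kind, ph = 7.4) {
  stopifnot(is.numeric(pka), is.numeric(ph))
  if (!kind %in% c("acid", "base"))
    stop("neutral_fraction: 'kind' must be \"acid\" or \"base\", got \"",
         kind, "\"")
  if (kind == "acid") 1 / (1 + 10^(ph - pka)) else 1 / (1 + 10^(pka - ph))
}

# Product of per-group neutral fractions; 1 for neutral chemicals.
profile_neutral_fraction <- function(profile, ph = 7.4) {
  if (is.null(profile$pka)) return(1)
  prod(vapply(profile$pka,
              function(g) neutral_fraction(g$value, g$kind, ph), numeric(1)))
}

#' Tissue composition for partition-coefficient prediction
#'
#' Volume fractions of water, neutral lipid, and phospholipid used in the
#' composition-based tissue:plasma partition model.
#'
#' @param f_water,f_neutral_lipid,f_phospholipid Volume fractions, each in
#'   \[0, 1\] and summing to at most 1.
#' @return An object of class `tissue_composition`.
#' @export
tissue_composition <- function(f_water, f_neutral_lipid, f_phospholipid) {
  fr <- c(f_water = f_water, f_neutral_lipid = f_neutral_lipid,
          f_phospholipid = f_phospholipid)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("tissue_composition: each fraction must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-9)
    stop("tissue_composition: fractions must sum to at most 1")
  structure(as.list(fr), class = "tissue_composition")
}

#' Composition-based tissue:plasma partition coefficients
#'
#' Predicts Kp for each model tissue from tissue composition using a
#' Poulin-Theil-style volume-fraction formula. With
#' `P = 10^logP * f_neutral(pH)` (the effective neutral-species partition
#' coefficient at the given pH, the product over ionizable groups for
#' multiprotic chemicals),
#'
#' \deqn{Kp_t = \frac{P (f_{nl,t} + 0.3 f_{pl,t}) + (f_{w,t} + 0.7 f_{pl,t})}
#'                   {P (f_{nl,p} + 0.3 f_{pl,p}) + (f_{w,p} + 0.7 f_{pl,p})}}
#'
#' where subscripts t and p denote tissue and plasma. The unbound-fraction
#' tissue/plasma ratio is taken as 1 (documented simplification). Any
#' tissue named in the profile's `kp_overrides` uses the override verbatim,
#' so values from any external prediction method can be injected.
#'
#' @param profile A [chemical_profile()].
#' @param compositions Named list of [tissue_composition()] objects, one per
#'   model tissue.
#' @param plasma The plasma [tissue_composition()].
#' @param ph pH at which ionization is evaluated (default 7.4).
#' @return Named numeric vector of Kp values (tissue:plasma), all positive.
#' @export
calc_partition_coefficients <- function(profile, compositions, plasma,
                                        ph = 7.4) {
  stopifnot(inherits(profile, "chemical_profile"), is.list(compositions))
  if (is.null(names(compositions)) || any(!nzchar(names(compositions))))
    stop("calc_partition_coefficients: 'compositions' must be a named list")
  P <- 10^profile$logp * profile_neutral_fraction(profile, ph)
  lip <- function(comp) P * (comp$f_neutral_lipid + 0.3 * comp$f_phospholipid) +
    (comp$f_water + 0.7 * comp$f_phospholipid)
  denom <- lip(plasma)
  kp <- vapply(names(compositions), function(tn) {
    comp <- compositions[[tn]]
    if (is.null(comp))
      stop("calc_partition_coefficients: composition missing for tissue '",
           tn, "'")
    lip(comp) / denom
  }, numeric(1))
  if (!is.null(profile$kp_overrides)) {
    ov <- intersect(names(profile$kp_overrides), names(kp))
    kp[ov] <- profile$kp_overrides[ov]
  }
  kp
}
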