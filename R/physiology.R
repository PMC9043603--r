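#' Species physiology for the flow-limited PBPK model
#'
#' Body weight, compartment volumes and plasma flows, renal filtration, and
#' liver scaling factors. The model distributes chemical through four
#' perfused tissues (gut, liver, kidney, and a lumped rest-of-body
#' compartment) connected by venous and arterial plasma pools. The liver
#' receives the hepatic artery plus the gut (portal) outflow, so total
#' cardiac plasma flow must satisfy
#' `q_cardiac = q_hepatic_artery + Q_gut + Q_kidney + Q_rest`; this balance
#' is validated at construction and violation is an error.
#'
#' All flows are plasma flows in L/h, all volumes in L. Tissue
#' compositions (for composition-based Kp prediction) ride along with the
#' physiology so that a single configuration file describes the species.
#'
#' @param species Species label (default `"human"`).
#' @param bw Body weight, kg.
#' @param tissues Named list over `gut`, `liver`, `kidney`, `rest`; each
#'   element a list with `volume` (L), `flow` (plasma L/h) and optionally
#'   `composition` (a [tissue_composition()]).
#' @param v_ven,v_art Venous and arterial plasma volumes, L.
#' @param q_hepatic_artery Hepatic artery plasma flow, L/h.
#' @param gfr Glomerular filtration rate, L/h (plasma).
#' @param hepatocellularity 10^6 hepatocytes per gram of liver.
#' @param liver_mass Liver mass, g.
#' @param plasma_composition Plasma [tissue_composition()] used as the Kp
#'   reference phase.
#' @return An object of class `physiology`. `q_cardiac` (total plasma flow)
#'   is derived from the flow balance. The liver's `flow` field, if given,
#'   must equal `q_hepatic_artery + Q_gut`; it is filled in otherwise.
#' @export
physiology <- function(species = "human", bw, tissues, v_ven, v_art,
                       q_hepatic_artery, gfr, hepatocellularity = 110,
                       liver_mass = 1800, plasma_composition = NULL) {
  need <- c("gut", "liver", "kidney", "rest")
  if (!all(need %in% names(tissues)))
    stop("physiology: 'tissues' must contain ",
         paste(need, collapse = ", "))
  bw <- as.numeric(bw); v_ven <- as.numeric(v_ven)
  v_art <- as.numeric(v_art)
  q_hepatic_artery <- as.numeric(q_hepatic_artery)
  gfr <- as.numeric(gfr)
  hepatocellularity <- as.numeric(hepatocellularity)
  liver_mass <- as.numeric(liver_mass)
  tissues <- lapply(tissues, function(t) {
    t$volume <- as.numeric(t$volume)
    if (!is.null(t$flow)) t$flow <- as.numeric(t$flow)
    t
  })
  scalars <- c(bw = bw, v_ven = v_ven, v_art = v_art,
               q_hepatic_artery = q_hepatic_artery, gfr = gfr,
               hepatocellularity = hepatocellularity, liver_mass = liver_mass)
  if (any(!is.finite(scalars)) || any(scalars <= 0))
    stop("physiology: all scalar quantities must be finite and > 0")
  for (tn in need) {
    t <- tissues[[tn]]
    if (is.null(t$volume) || !is.finite(t$volume) || t$volume <= 0)
      stop("physiology: tissue '", tn, "' needs a positive volume")
    if (tn != "liver" &&
        (is.null(t$flow) || !is.finite(t$flow) || t$flow <= 0))
      stop("physiology: tissue '", tn, "' needs a positive plasma flow")
  }
  q_liver <- q_hepatic_artery + tissues$gut$flow
  if (!is.null(tissues$liver$flow) &&
      abs(tissues$liver$flow - q_liver) > 1e-6 * q_liver)
    stop("physiology: liver flow must equal hepatic artery + gut outflow (",
         signif(q_liver, 6), " L/h), got ", tissues$liver$flow)
  tissues$liver$flow <- q_liver
  q_cardiac <- q_hepatic_artery + tissues$gut$flow + tissues$kidney$flow +
    tissues$rest$flow
  structure(
    list(species = species, bw = bw, tissues = tissues, v_ven = v_ven,
         v_art = v_art, q_cardiac = q_cardiac,
         q_hepatic_artery = q_hepatic_artery, gfr = gfr,
         hepatocellularity = hepatocellularity, liver_mass = liver_mass,
         plasma_composition = plasma_composition),
    class = "physiology")
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s, bw %.4g kg, cardiac plasma flow %.4g L/h, GFR %.3g L/h\n",
              x$species, x$bw, x$q_cardiac, x$gfr))
  for (tn in names(x$tissues))
    cat(sprintf("  %-7s V = %6.3g L  Q = %6.4g L/h\n", tn,
                x$tissues[[tn]]$volume, x$tissues[[tn]]$flow))
  invisible(x)
}

#' Reference adult human physiology (70 kg)
#'
#' The shipped default parameterization: a 70 kg adult with reference-human
#' plasma flows and volumes and standard tissue lipid/water compositions.
#' These values are configuration, not ground truth; the same structure can
#' be loaded from an edited YAML file via [read_physiology()]. The packaged
#' copy lives at `system.file("extdata", "human_70kg.yaml", package =
#' "revdose")`.
#'
#' @return A [physiology()] object.
#' @export
default_human_physiology <- function() {
  read_physiology(system.file("extdata", "human_70kg.yaml",
                              package = "revdose"))
}

#' Read a physiology configuration from YAML
#'
#' The file uses unit-suffixed keys (`volume_L`, `flow_L_per_h`, ...) and
#' nested tissue blocks; see the shipped `human_70kg.yaml` for the format.
#'
#' @param path Path to the YAML file.
#' @return A [physiology()] object.
#' @export
read_physiology <- function(path) {
  if (!file.exists(path))
    stop("read_physiology: file not found: ", path)
  y <- yaml::read_yaml(path)
  comp <- function(block) {
    if (is.null(block)) return(NULL)
    tissue_composition(f_water = block$f_water,
                       f_neutral_lipid = block$f_neutral_lipid,
                       f_phospholipid = block$f_phospholipid)
  }
  tissues <- lapply(y$tissues, function(t)
    list(volume = t$volume_L, flow = t$flow_L_per_h,
         composition = comp(t$composition)))
  physiology(
    species = y$species, bw = y$bw_kg, tissues = tissues,
    v_ven = y$venous_plasma_volume_L, v_art = y$arterial_plasma_volume_L,
    q_hepatic_artery = y$hepatic_artery_flow_L_per_h, gfr = y$gfr_L_per_h,
    hepatocellularity = y$hepatocellularity_1e6_per_g,
    liver_mass = y$liver_mass_g,
    plasma_composition = comp(y$plasma_composition))
}

#' Write a physiology configuration to YAML
#'
#' Inverse of [read_physiology()]; useful for exporting the default and
#' editing it.
#'
#' @param phys A [physiology()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_physiology <- function(phys, path) {
  stopifnot(inherits(phys, "physiology"))
  comp <- function(cc) if (is.null(cc)) NULL else
    list(f_water = cc$f_water, f_neutral_lipid = cc$f_neutral_lipid,
         f_phospholipid = cc$f_phospholipid)
  y <- list(
    species = phys$species, bw_kg = phys$bw,
    venous_plasma_volume_L = phys$v_ven,
    arterial_plasma_volume_L = phys$v_art,
    hepatic_artery_flow_L_per_h = phys$q_hepatic_artery,
    gfr_L_per_h = phys$gfr,
    hepatocellularity_1e6_per_g = phys$hepatocellularity,
    liver_mass_g = phys$liver_mass,
    plasma_composition = comp(phys$plasma_composition),
    tissues = lapply(phys$tissues, function(t)
      list(volume_L = t$volume, flow_L_per_h = t$flow,
           composition = comp(t$composition))))
  yaml::write_yaml(y, path)
  invisible(path)
}

# Compositions for the physiology's tissues, as a named list suitable for
# calc_partition_coefficients(). Errors if any model tissue lacks one.
physiology_compositions <- function(phys) {
  comps <- lapply(phys$tissues, `[[`, "composition")
  missing <- names(comps)[vapply(comps, is.null, logical(1))]
  if (length(missing))
    stop("physiology: no tissue composition for ",
         paste(missing, collapse = ", "))
  comps
}
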