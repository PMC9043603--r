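# Shared fixtures for the suite. Simulations of the two archetypes under
# the reference hourly schedule are cached here because several files
# assert against them.

ref_phys <- default_human_physiology()
hourly24 <- parse_schedule("oral:1mg/kg@1h x24")
archetypes <- make_archetypes()

sim_archetype <- local({
  cache <- list()
  function(which) {
    if (is.null(cache[[which]])) {
      model <- build_model(archetypes$profiles[[which]], ref_phys, hourly24)
      cache[[which]] <<- simulate_pk(model, duration = 24)
    }
    cache[[which]]
  }
})

# Peak venous plasma concentration within the k-th dosing interval
# ((k-1) h, k h] of an hourly-dosed simulation.
interval_peak <- function(result, k, compartment = "plasma_ven") {
  sel <- result$time >= (k - 1) & result$time <= k
  max(result$conc[sel, compartment])
}

# A physiology in the perfusion-non-limiting regime: every plasma flow
# scaled by 1e6 so that all compartments equilibrate instantly and the
# system collapses to one well-mixed volume (for closed-form oracles).
highflow_physiology <- function(scale = 1e6) {
  p <- ref_phys
  for (tn in c("gut", "kidney", "rest"))
    p$tissues[[tn]]$flow <- p$tissues[[tn]]$flow * scale
  p$q_hepatic_artery <- p$q_hepatic_artery * scale
  p$tissues$liver$flow <- p$tissues$liver$flow * scale
  p$q_cardiac <- p$q_cardiac * scale
  p
}

total_volume <- function(phys) {
  sum(vapply(phys$tissues, `[[`, numeric(1), "volume")) +
    phys$v_ven + phys$v_art
}

# Simple neutral test chemical used across files.
basic_profile <- function(clint = 5, logp = 1.5, fub = 0.5, mw = 250,
                          kp_overrides = NULL) {
  chemical_profile(name = "testchem", casrn = "TST-0001", mw = mw,
                   logp = logp, fub = fub, clint = clint,
                   kp_overrides = kp_overrides)
}
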