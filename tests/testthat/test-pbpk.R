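test_that("dose events convert mg/kg to umol and target the route's compartment", {
  p <- chemical_profile(name = "d", casrn = "D", mw = 263.89, logp = 2,
                        fub = 0.5, clint = 1)
  m_oral <- build_model(p, ref_phys, hourly24)
  expect_equal(m_oral$dose_umol, 1 * 70 / 263.89 * 1000)
  expect_equal(m_oral$dose_umol, 265.26, tolerance = 1e-4)
  expect_true(all(m_oral$events$var == "A_gutlumen"))
  expect_equal(m_oral$events$time, 0:23)

  m_iv <- build_model(p, ref_phys,
                      dosing_schedule("iv", 1, interval = 1, n_doses = 3))
  expect_true(all(m_iv$events$var == "A_ven"))
})

test_that("zero dosing yields identically zero concentrations", {
  p <- basic_profile()
  sched <- dosing_schedule("oral", 0, interval = 1, n_doses = 4)
  r <- simulate_pk(build_model(p, ref_phys, sched), 6)
  expect_true(all(r$conc == 0))
  expect_identical(r$total_administered, 0)
})

test_that("mass balance holds within 0.1% across randomized parameter sets", {
  profiles <- random_profiles(4, seed = 42)
  scheds <- list(hourly24,
                 dosing_schedule("oral", 2, interval = 6, n_doses = 4,
                                 fabs = 0.6),
                 dosing_schedule("iv", 0.5, interval = 8, n_doses = 3))
  for (p in profiles[1:2]) {
    for (s in scheds) {
      r <- simulate_pk(build_model(p, ref_phys, s), 24)
      expect_lt(max(abs(mass_balance_error(r))), 1e-3)
    }
  }
  # archetypes under the reference schedule
  expect_lt(max(abs(mass_balance_error(sim_archetype("dtac_like")))), 1e-3)
  expect_lt(max(abs(mass_balance_error(sim_archetype("cnpa_like")))), 1e-3)
})

test_that("all processes are first order: concentrations scale with dose", {
  p <- archetypes$profiles$dtac_like
  r1 <- sim_archetype("dtac_like")
  s3 <- dosing_schedule("oral", 3, interval = 1, n_doses = 24)
  r3 <- simulate_pk(build_model(p, ref_phys, s3), 24)
  expect_lt(max(abs(r3$conc - 3 * r1$conc)) / max(r3$conc), 1e-6)
  expect_equal(cmax(r3)[["cmax"]], 3 * cmax(r1)[["cmax"]],
               tolerance = 1e-6)
})

test_that("with no elimination an IV bolus conserves mass and equilibrates to D / sum(Vj Kpj)", {
  p <- chemical_profile(name = "inert", casrn = "INRT", mw = 300, logp = 2,
                        fub = 0.5, clint = 0)
  phys <- ref_phys
  phys$gfr <- 1e-12  # renal filtration effectively off
  m <- build_model(p, phys,
                   dosing_schedule("iv", 1, interval = 1, n_doses = 1))
  r <- simulate_pk(m, 2000)
  # total amount in compartments stays equal to the dose
  totals <- rowSums(r$amounts)
  expect_lt(max(abs(totals - r$total_administered)) / r$total_administered,
            1e-6)
  # every Ct/Kpt converges to the common equilibrium value
  vols <- vapply(phys$tissues, `[[`, numeric(1), "volume")
  pred <- r$total_administered /
    (sum(vols * m$kp[names(vols)]) + phys$v_ven + phys$v_art)
  n <- length(r$time)
  eq <- c(r$conc[n, "plasma_ven"], r$conc[n, "plasma_art"],
          r$conc[n, "gut"] / m$kp[["gut"]],
          r$conc[n, "liver"] / m$kp[["liver"]],
          r$conc[n, "kidney"] / m$kp[["kidney"]],
          r$conc[n, "rest"] / m$kp[["rest"]])
  expect_equal(unname(eq), rep(pred, 6), tolerance = 1e-6)
})

test_that("the perfusion-non-limiting unit-Kp model matches the Bateman closed form within 1%", {
  p <- chemical_profile(name = "b", casrn = "BAT", mw = 250, logp = 0,
                        fub = 1, clint = 2,
                        kp_overrides = c(gut = 1, liver = 1, kidney = 1,
                                         rest = 1))
  phys <- highflow_physiology()
  fabs <- 0.8
  ka <- 2.18
  sched <- dosing_schedule("oral", 1, interval = 6, n_doses = 1,
                           fabs = fabs, ka = ka)
  m <- build_model(p, phys, sched)
  r <- simulate_pk(m, 24)
  v_tot <- total_volume(phys)
  ke <- (scale_intrinsic_clearance(2, phys$hepatocellularity,
                                   phys$liver_mass) + phys$gfr) / v_tot
  D <- m$dose_umol
  bateman <- fabs * D * ka / (v_tot * (ka - ke)) *
    (exp(-ke * r$time) - exp(-ka * r$time))
  sel <- r$time > 0
  rel <- abs(r$conc[sel, "plasma_ven"] - bateman[sel]) /
    pmax(bateman[sel], 1e-9 * max(bateman))
  expect_lt(max(rel), 0.01)
  # closed-form AUC to infinity: F D / (V ke); 24 h covers >> 5 half-lives
  expect_equal(pk_auc(r, "plasma_ven", 0, 24), fabs * D / (v_tot * ke),
               tolerance = 0.01)
  # unabsorbed fraction reaches the feces ledger
  expect_equal(max(r$a_feces), (1 - fabs) * D, tolerance = 1e-6)
})

test_that("cmax reports the earliest maximum over the requested window", {
  p <- basic_profile()
  r_iv <- simulate_pk(
    build_model(p, ref_phys,
                dosing_schedule("iv", 1, interval = 1, n_doses = 1)), 12)
  cm <- cmax(r_iv, "plasma_ven", "full")
  expect_identical(cm[["tmax"]], 0)  # monotone decay from the bolus

  # constant (all-zero) series: tie broken at the window start
  r0 <- simulate_pk(
    build_model(p, ref_phys,
                dosing_schedule("oral", 0, interval = 1, n_doses = 4)), 8)
  expect_identical(cmax(r0, "liver", "full")[["tmax"]], 0)
  expect_equal(cmax(r0, "liver", "last_interval")[["tmax"]], 3)

  expect_error(cmax(r0, "bone"), "compartment")
})

test_that("a slowly cleared accumulating chemical peaks in the final dosing interval", {
  r <- sim_archetype("dtac_like")
  cm <- cmax(r, "plasma_ven", "full")
  expect_gte(cm[["tmax"]], 23)
  expect_equal(cm[["cmax"]],
               cmax(r, "plasma_ven", "last_interval")[["cmax"]])
})

test_that("trapezoidal AUC handles degenerate and windowed cases", {
  p <- basic_profile()
  r0 <- simulate_pk(
    build_model(p, ref_phys,
                dosing_schedule("oral", 0, interval = 1, n_doses = 2)), 4)
  expect_identical(pk_auc(r0, "plasma_ven"), 0)
  r <- sim_archetype("dtac_like")
  expect_equal(pk_auc(r, "plasma_ven", 0, 10) + pk_auc(r, "plasma_ven", 10, 24),
               pk_auc(r, "plasma_ven", 0, 24))
  expect_error(pk_auc(r, "plasma_ven", 10, 5), "window")
  expect_error(pk_auc(r, "plasma_ven", 0, 48), "window")
})

test_that("plasma AUC decreases with intrinsic clearance; less frequent dosing does not raise Cmax", {
  r_lo <- simulate_pk(build_model(basic_profile(clint = 5), ref_phys,
                                  hourly24), 24)
  r_hi <- simulate_pk(build_model(basic_profile(clint = 50), ref_phys,
                                  hourly24), 24)
  expect_lt(pk_auc(r_hi), pk_auc(r_lo))

  every2h <- dosing_schedule("oral", 1, interval = 2, n_doses = 12)
  r_2h <- simulate_pk(build_model(basic_profile(clint = 5), ref_phys,
                                  every2h), 24)
  expect_lte(cmax(r_2h)[["cmax"]], cmax(r_lo)[["cmax"]])
})

test_that("simulation requires the window to cover the dosing schedule", {
  p <- basic_profile()
  m <- build_model(p, ref_phys, hourly24)
  expect_error(simulate_pk(m, 10), "last administration")
})

test_that("an unresolved profile or missing tissue composition is rejected", {
  expect_error(build_model(data.frame(mw = 1), ref_phys, hourly24),
               "chemical_profile")
  phys <- ref_phys
  phys$tissues$rest$composition <- NULL
  expect_error(build_model(basic_profile(), phys, hourly24), "rest")
})
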