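test_that("parameter resolution prefers measured over predicted and records provenance", {
  recs <- data.frame(
    casrn = "C-1", name = "chem1",
    parameter = c("mw", "logp", "fub", "fub", "clint", "kp_liver", "logh"),
    value = c(250, 2.1, 0.1, 0.3, 5, 0.5, -3),
    source = c("measured", "predicted", "measured", "predicted",
               "predicted", "predicted", "predicted"),
    stringsAsFactors = FALSE)
  p <- resolve_parameters(recs)
  expect_s3_class(p, "chemical_profile")
  expect_identical(p$fub, 0.1)
  expect_identical(unname(p$provenance[["fub"]]), "measured")
  expect_identical(p$clint, 5)
  expect_identical(unname(p$provenance[["clint"]]), "predicted")
  # rb2p has a documented default of 1 when no candidate exists
  expect_identical(p$rb2p, 1)
  expect_identical(unname(p$provenance[["rb2p"]]), "default")
  # direct Kp candidates become overrides; unknown parameters are stored
  expect_identical(unname(p$kp_overrides[["liver"]]), 0.5)
  expect_identical(unname(p$extras[["logh"]]), -3)
})

test_that("resolution rejects chemicals missing a required parameter, naming it", {
  recs <- data.frame(casrn = "C-2", name = "chem2",
                     parameter = c("logp", "fub", "clint"),
                     value = c(2, 0.5, 1),
                     source = rep("predicted", 3), stringsAsFactors = FALSE)
  expect_error(resolve_parameters(recs), "mw")
  expect_error(resolve_parameters(recs), "C-2")
})

test_that("resolution is idempotent on an already-resolved profile", {
  p <- basic_profile()
  expect_identical(resolve_parameters(p), p)
})

test_that("pKa candidates become ionization groups with provenance", {
  recs <- data.frame(casrn = "C-3", name = "chem3",
                     parameter = c("mw", "fub", "clint", "pka_base"),
                     value = c(300, 0.2, 2, 9.0),
                     source = c("measured", "measured", "predicted",
                                "predicted"), stringsAsFactors = FALSE)
  p <- resolve_parameters(recs)
  expect_length(p$pka, 1L)
  expect_identical(p$pka[[1L]]$kind, "base")
  expect_identical(p$pka[[1L]]$value, 9.0)
})

test_that("profile invariants are enforced at construction", {
  expect_error(chemical_profile(name = "x", casrn = "X", mw = -1, logp = 0,
                                fub = 0.5, clint = 1), "mw")
  expect_error(chemical_profile(name = "x", casrn = "X", mw = 100, logp = 0,
                                fub = 1.5, clint = 1), "fub")
  expect_error(chemical_profile(name = "x", casrn = "X", mw = 100, logp = 0,
                                fub = 0.5, clint = -1), "clint")
  expect_error(chemical_profile(name = "x", casrn = "X", mw = 100, logp = 0,
                                fub = 0.5, clint = 1,
                                kp_overrides = c(liver = -2)), "kp_overrides")
})

test_that("intrinsic-clearance scaling converts units and is linear in each argument", {
  expect_identical(scale_intrinsic_clearance(0, 110, 1800), 0)
  expect_equal(scale_intrinsic_clearance(1, 110, 1800), 11.88)
  expect_equal(scale_intrinsic_clearance(10, 110, 1800), 118.8)
  base <- scale_intrinsic_clearance(3.7, 95, 1500)
  expect_equal(scale_intrinsic_clearance(2 * 3.7, 95, 1500), 2 * base)
  expect_equal(scale_intrinsic_clearance(3.7, 3 * 95, 1500), 3 * base)
  expect_equal(scale_intrinsic_clearance(3.7, 95, 5 * 1500), 5 * base)
  expect_error(scale_intrinsic_clearance(-1, 110, 1800), ">= 0")
})

test_that("neutral fraction follows Henderson-Hasselbalch for acids and bases", {
  expect_equal(neutral_fraction(7.4, "acid", 7.4), 0.5)
  expect_equal(neutral_fraction(4.0, "acid", 7.4), 1 / (1 + 10^3.4))
  expect_equal(neutral_fraction(4.0, "acid", 7.4), 3.98e-4, tolerance = 1e-3)
  expect_equal(neutral_fraction(9.0, "base", 7.4), 1 / (1 + 10^1.6))
  expect_equal(neutral_fraction(9.0, "base", 7.4), 0.0245, tolerance = 1e-2)
  expect_error(neutral_fraction(7, "zwitterion", 7.4), "kind")
})

test_that("neutral plus ionized fractions sum to one across pKa/pH grids", {
  for (pka in seq(2, 12, by = 2.5)) {
    for (ph in c(1, 5.5, 7.4, 9)) {
      ionized_acid <- 1 - 1 / (1 + 10^(ph - pka))
      expect_equal(neutral_fraction(pka, "acid", ph) + ionized_acid, 1)
    }
  }
})

test_that("partition coefficients follow the composition formula", {
  plasma <- tissue_composition(0.945, 0.0023, 0.0013)
  # identical composition to plasma gives Kp = 1 for any chemical
  p <- basic_profile(logp = 3.1)
  expect_equal(
    unname(calc_partition_coefficients(p, list(t = plasma), plasma)), 1)

  tis <- tissue_composition(0.75, 0.05, 0.01)
  # hydrophilic limit: lipid terms vanish, water/phospholipid ratio remains
  p_lo <- basic_profile(logp = -30)
  kp_lo <- calc_partition_coefficients(p_lo, list(t = tis), plasma)
  expect_equal(unname(kp_lo),
               (0.75 + 0.7 * 0.01) / (0.945 + 0.7 * 0.0013),
               tolerance = 1e-9)

  # hand-computed value at P = 1000
  p_hi <- basic_profile(logp = 3)  # 10^3 = 1000, neutral chemical
  kp_hi <- calc_partition_coefficients(p_hi, list(t = tis), plasma)
  expect_equal(unname(kp_hi), 53.757 / 3.63591, tolerance = 1e-6)
  expect_equal(unname(kp_hi), 14.79, tolerance = 1e-3)
})

test_that("Kp is monotonically non-decreasing in logP for lipid-rich tissues", {
  plasma <- tissue_composition(0.945, 0.0023, 0.0013)
  tis <- list(liver = tissue_composition(0.751, 0.0348, 0.0252))
  kps <- vapply(seq(-2, 6, by = 0.5), function(lp)
    calc_partition_coefficients(basic_profile(logp = lp), tis, plasma)[["liver"]],
    numeric(1))
  expect_true(all(diff(kps) >= -1e-12))
})

test_that("ionization lowers the effective partition coefficient", {
  plasma <- tissue_composition(0.945, 0.0023, 0.0013)
  tis <- list(liver = tissue_composition(0.751, 0.0348, 0.0252))
  neutral <- basic_profile(logp = 3)
  acid <- chemical_profile(name = "a", casrn = "A", mw = 250, logp = 3,
                           pka = list(list(value = 4, kind = "acid")),
                           fub = 0.5, clint = 5)
  kp_n <- calc_partition_coefficients(neutral, tis, plasma)[["liver"]]
  kp_a <- calc_partition_coefficients(acid, tis, plasma)[["liver"]]
  expect_lt(kp_a, kp_n)
  # multiprotic: product of group neutral fractions
  diacid <- chemical_profile(name = "d", casrn = "D", mw = 250, logp = 3,
                             pka = list(list(value = 4, kind = "acid"),
                                        list(value = 9, kind = "base")),
                             fub = 0.5, clint = 5)
  kp_d <- calc_partition_coefficients(diacid, tis, plasma)[["liver"]]
  expect_lt(kp_d, kp_a)
})

test_that("direct Kp overrides take precedence over the formula", {
  plasma <- tissue_composition(0.945, 0.0023, 0.0013)
  tis <- list(liver = tissue_composition(0.751, 0.0348, 0.0252),
              rest = tissue_composition(0.63, 0.10, 0.02))
  p <- basic_profile(logp = 3, kp_overrides = c(liver = 0.42))
  kp <- calc_partition_coefficients(p, tis, plasma)
  expect_identical(unname(kp[["liver"]]), 0.42)
  expect_gt(kp[["rest"]], 1)  # non-overridden tissue still formula-based
})
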