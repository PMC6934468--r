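test_that("TIAC of a decay-only system matches the analytic integral", {
  p <- inert_patient()
  nuc <- lu177()
  sys <- build_system(p, ligand_kinetics(0, 0, 0),
                      injection_protocol(20, 7.3e9, nuc))
  res <- simulate_pbpk(sys, 30000)
  # plasma holds the whole body here: a_i(T) = (1 - 2^(-T/T1/2)) / lambda
  lam <- nuc$lambda_phys
  expected <- (1 - 2^(-30000 / nuc$half_life)) / lam
  expect_equal(tiac(res, "plasma", 30000), expected, tolerance = 1e-5)
  # and is bounded by the T -> Inf limit 1/lambda = T1/2 / ln 2
  expect_lt(tiac(res, "plasma", 30000), 1 / lam)
  expect_error(tiac(res, "plasma", 40000), "horizon")
})

test_that("every tissue TIAC respects the 1/lambda bound", {
  p <- patient5_exemplar()
  sys <- build_system(p, ligand_kinetics(0.1, 0.001, 0.001),
                      injection_protocol(100, 7.3e9, lu177()))
  res <- simulate_pbpk(sys, 30000)
  for (tn in c("tumour_lesion_1", "tumour_rest", "kidneys", "red_marrow",
               "plasma", "urine")) {
    expect_lte(tiac(res, tn, 30000), 1 / lu177()$lambda_phys)
  }
})

test_that("sphere S-values decrease with mass and respect energy conservation", {
  nuc <- lu177()
  tab <- sphere_s_table(nuc)
  expect_true(all(diff(tab$s_gy_per_bq_min) < 0))
  # absorbed energy per decay never exceeds the emitted energy
  expect_true(all(tab$s_gy_per_bq_min * tab$mass_kg / 60 <=
                    nuc$delta_electron + nuc$delta_photon + 1e-20))
  # for small spheres the photon term is tiny: S ~ 60 * Delta_e / m
  expect_equal(sphere_s_value(0.001, nuc), 60 * nuc$delta_electron / 0.001,
               tolerance = 0.02)
  # interpolation is exact at the nodes and monotone between them
  expect_equal(sphere_s_value(tab$mass_kg[10], nuc), tab$s_gy_per_bq_min[10],
               tolerance = 1e-12)
  expect_lt(sphere_s_value(0.4, nuc), sphere_s_value(0.2, nuc))
  expect_error(sphere_s_value(10, nuc), "span")
  expect_error(sphere_s_value(1e-5, nuc), "span")
})

test_that("the MIRD dose is the exact product of its three factors", {
  expect_identical(absorbed_dose(1, 1, 1), 1)
  expect_identical(absorbed_dose(0, 5, 2), 0)
  expect_identical(absorbed_dose(2e9, 100, 5e-12), 2e9 * 100 * 5e-12)
  expect_equal(absorbed_dose(2, 3, 4), 2 * absorbed_dose(1, 3, 4))
  expect_error(absorbed_dose(-1, 1, 1), ">= 0")
})

test_that("therapy report: no binding leaves only free-ligand residence doses", {
  p <- p5_receptor_only()
  rep0 <- therapy_report(p, ligand_kinetics(0, 0.01, 0.001), 100)
  rep1 <- therapy_report(p, ligand_kinetics(0.1, 0.01, 0.001), 100)
  d0 <- rep0$targets$dose_Gy[rep0$targets$target == "tumour_lesion_1"]
  d1 <- rep1$targets$dose_Gy[rep1$targets$target == "tumour_lesion_1"]
  expect_gt(d0, 0)        # perfusion still delivers free ligand
  expect_gt(d1, 10 * d0)  # receptor binding dominates the dose
  # ratio fields equal the dose quotients to machine precision
  kid <- rep1$targets$dose_Gy[rep1$targets$target == "kidneys"]
  expect_identical(rep1$ratios[["tumour_lesion_1"]], d1 / kid)
})

test_that("higher affinity increases the tumour-lesion dose", {
  p <- patient5_exemplar()
  lo <- therapy_report(p, ligand_kinetics(0.1, 0.1, 0.001), 100)
  hi <- therapy_report(p, ligand_kinetics(0.1, 0.01, 0.001), 100)
  expect_gt(hi$targets$dose_Gy[hi$targets$target == "tumour_lesion_1"],
            lo$targets$dose_Gy[lo$targets$target == "tumour_lesion_1"])
})

test_that("doses are linear in the injected activity at fixed ligand amount", {
  p <- patient5_exemplar()
  p2 <- p
  p2$injected_activity <- p$injected_activity / 2
  kin <- ligand_kinetics(0.1, 0.01, 0.001)
  full <- therapy_report(p, kin, 100)
  half <- therapy_report(p2, kin, 100)
  expect_equal(full$targets$dose_Gy, 2 * half$targets$dose_Gy,
               tolerance = 1e-6)
  expect_equal(full$ratios, half$ratios, tolerance = 1e-6)
})

test_that("total absorbed energy never exceeds the emitted decay energy", {
  p <- patient5_exemplar()
  nuc <- lu177()
  rep <- therapy_report(p, ligand_kinetics(0.1, 0.001, 0.001), 100)
  energy_absorbed <- sum(rep$targets$dose_Gy * rep$targets$mass_kg)
  n_decays <- rep$A0_bq / nuc$lambda_phys * 60  # upper bound on decays
  expect_lt(energy_absorbed,
            n_decays * (nuc$delta_electron + nuc$delta_photon))
})
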