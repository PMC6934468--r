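test_that("pure decay halves the plasma hot amount every half-life", {
  p <- inert_patient()
  kin <- ligand_kinetics(0, 0, 0)
  nuc <- lu177()
  prot <- injection_protocol(20, 7.3e9, nuc)
  sys <- build_system(p, kin, prot)
  res <- simulate_pbpk(sys, 2.5 * nuc$half_life,
                       c(0, nuc$half_life, 2 * nuc$half_life))
  hot_p <- res$y[, "hot.plasma"]
  expect_equal(hot_p[2], prot$hot_amount / 2, tolerance = 1e-7)
  expect_equal(hot_p[3], prot$hot_amount / 4, tolerance = 1e-7)
  # whole-body activity follows A0 * 2^(-t/T1/2)
  wb <- activity_in(res, "plasma", nuc$half_life)
  expect_equal(wb, prot$activity_A0 / 2, tolerance = 1e-6)
})

test_that("total ligand (hot + cold + urine) is conserved through a full solve", {
  p <- patient5_exemplar()
  sys <- build_system(p, ligand_kinetics(0.1, 0.01, 0.001),
                      injection_protocol(100, 7.3e9, lu177()))
  res <- simulate_pbpk(sys, 30000)
  tl <- total_ligand(res)
  expect_lt(max(abs(tl - tl[1])) / tl[1], 1e-6)
})

test_that("with excretion disabled the total hot amount decays exactly", {
  p <- p5_receptor_only()
  p$gfr <- 0
  nuc <- lu177()
  sys <- build_system(p, ligand_kinetics(0.1, 0.01, 0.001),
                      injection_protocol(50, 7.3e9, nuc))
  res <- simulate_pbpk(sys, 5000, c(0, 100, 1000, 5000))
  hot_tot <- rowSums(res$y[, grepl("^hot", colnames(res$y))])
  expect_equal(hot_tot,
               hot_tot[1] * exp(-nuc$lambda_phys * res$times),
               tolerance = 1e-7)
})

test_that("kon = 0 leaves all receptor-bound and internalized pools empty", {
  p <- p5_receptor_only()
  sys <- build_system(p, ligand_kinetics(0, 0.01, 0.001),
                      injection_protocol(50, 7.3e9, lu177()))
  res <- simulate_pbpk(sys, 5000)
  bn <- res$y[, grepl("\\.(B|N)\\.", colnames(res$y))]
  expect_true(all(bn == 0))
})

test_that("closed single-tissue system relaxes to the mass-action equilibrium", {
  p <- inert_patient()
  tn <- "tumour_lesion_1"
  ti <- p$tissues[[tn]]
  Veff <- ti$volume * ti$accessible_fraction
  Rtot <- ti$receptor_density * ti$volume
  for (L0 in c(0.1, 0.66, 5)) {
    kin <- ligand_kinetics(0.05, 0.02, 0)  # lambda_int 0, lambda_rel unused
    sys <- build_system(p, kin, injection_protocol(L0, 0, stable_nuclide()))
    y0 <- sys$y0 * 0
    y0[state_index(sys, "hot", "F", tn)] <- L0
    res <- simulate_pbpk(sys, 50000, c(0, 50000), y0 = y0)
    B <- unname(res$y[2, state_index(sys, "hot", "B", tn)])
    B_exp <- equilibrium_bound(L0, Rtot, Veff, kin$kon, kin$koff)
    expect_equal(B, B_exp, tolerance = 1e-6)
    # occupancy obeys the binding isotherm: occ = c_free / (KD + c_free)
    c_free <- (L0 - B) / Veff
    expect_equal(B / Rtot, c_free / (kin$kd + c_free), tolerance = 1e-5)
  }
  # occupancy is one half when the free concentration equals K_D:
  # pick L0 so that the equilibrium free concentration is exactly KD
  kin <- ligand_kinetics(0.05, 0.02, 0)
  L0 <- kin$kd * Veff + Rtot / 2
  sys <- build_system(p, kin, injection_protocol(L0, 0, stable_nuclide()))
  y0 <- sys$y0 * 0
  y0[state_index(sys, "hot", "F", tn)] <- L0
  res <- simulate_pbpk(sys, 80000, c(0, 80000), y0 = y0)
  B <- unname(res$y[2, state_index(sys, "hot", "B", tn)])
  expect_equal(B / Rtot, 0.5, tolerance = 1e-5)
})

test_that("with binding off the solution matches the matrix exponential", {
  skip_if_not_installed("Matrix")
  p <- p5_receptor_only()
  nuc <- lu177()
  sys <- build_system(p, ligand_kinetics(0, 0, 0),
                      injection_protocol(20, 7.3e9, nuc))
  # hot subsystem: plasma, one free pool per tissue, urine (linear)
  tn <- sys$tissues
  nt <- length(tn)
  A <- matrix(0, nt + 2, nt + 2)
  Vp <- p$plasma_volume; fu <- p$unbound_fraction
  for (j in seq_len(nt)) {
    ti <- p$tissues[[tn[j]]]
    Veff <- ti$volume * ti$accessible_fraction
    A[1 + j, 1] <- ti$flow * fu / Vp        # plasma -> tissue
    A[1, 1 + j] <- ti$flow / Veff           # tissue -> plasma
    A[1 + j, 1 + j] <- -ti$flow / Veff
    A[1, 1] <- A[1, 1] - ti$flow * fu / Vp
  }
  A[nt + 2, 1] <- p$gfr * fu / Vp           # plasma -> urine
  A[1, 1] <- A[1, 1] - p$gfr * fu / Vp
  diag(A) <- diag(A) - nuc$lambda_phys
  y0 <- c(sys$y0[1], numeric(nt + 1))
  for (t in c(30, 300, 3000)) {
    expected <- as.numeric(Matrix::expm(A * t) %*% y0)
    res <- simulate_pbpk(sys, t, c(0, t))
    got <- c(res$y[2, "hot.plasma"],
             vapply(tn, function(x)
               res$y[2, state_index(sys, "hot", "F", x)], 0),
             res$y[2, "hot.urine"])
    expect_equal(got, expected, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("activities are exactly proportional to A0 at fixed total amount", {
  p <- patient5_exemplar()
  kin <- ligand_kinetics(0.1, 0.01, 0.001)
  nuc <- lu177()
  r1 <- simulate_pbpk(build_system(p, kin, injection_protocol(100, 3.65e9, nuc)),
                      3000, c(0, 60, 3000))
  r2 <- simulate_pbpk(build_system(p, kin, injection_protocol(100, 7.3e9, nuc)),
                      3000, c(0, 60, 3000))
  for (tn in c("tumour_lesion_1", "kidneys", "plasma")) {
    a1 <- activity_in(r1, tn, c(60, 3000))
    a2 <- activity_in(r2, tn, c(60, 3000))
    expect_equal(a2, 2 * a1, tolerance = 1e-6)
  }
})

test_that("bound amounts never exceed the receptor capacity", {
  p <- patient5_exemplar()
  sys <- build_system(p, ligand_kinetics(0.1, 0.001, 0.001),
                      injection_protocol(1000, 7.3e9, lu177()))
  res <- simulate_pbpk(sys, 30000)
  for (tn in c("tumour_lesion_1", "tumour_rest", "kidneys")) {
    ti <- p$tissues[[tn]]
    b_tot <- res$y[, state_index(sys, "hot", "B", tn)] +
      res$y[, state_index(sys, "cold", "B", tn)]
    expect_true(all(b_tot <= ti$receptor_density * ti$volume * (1 + 1e-6)))
  }
})

test_that("constructors and solver reject invalid inputs by name", {
  p <- patient5_exemplar()
  expect_error(injection_protocol(5, 7.3e9, lu177()), "exceeds total")
  expect_error(injection_protocol(-1, 0, lu177()), "total_amount")
  tis <- p$tissues
  tis$kidneys <- NULL
  expect_error(virtual_patient("x", tis), "kidneys")
  expect_error(tissue_params("t", volume = -1, perfusion = 0.1), "volume")
  sys <- build_system(p, ligand_kinetics(0.1, 0.01, 0.001),
                      injection_protocol(100, 7.3e9, lu177()))
  expect_error(simulate_pbpk(sys, 100, c(0, 200)), "output_times")
  res <- simulate_pbpk(sys, 100)
  expect_error(activity_in(res, "spleen", 10), "unknown tissue")
  expect_error(activity_in(res, "kidneys", 200), "time span")
})

test_that("identical inputs reproduce bit-identical trajectories", {
  p <- patient5_exemplar()
  sys <- build_system(p, ligand_kinetics(0.1, 0.01, 0.001),
                      injection_protocol(100, 7.3e9, lu177()))
  r1 <- simulate_pbpk(sys, 1000)
  r2 <- simulate_pbpk(sys, 1000)
  expect_identical(r1$y, r2$y)
})
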