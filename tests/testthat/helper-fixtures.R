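# Shared fixtures, built in code.

N_AVOGADRO <- 6.02214076e23

# exemplar patient with all unspecific uptake switched off: the pure
# receptor-only model used by the analytic oracles
p5_receptor_only <- function() {
  p <- patient5_exemplar()
  for (tn in names(p$tissues)) p$tissues[[tn]]$lambda_unspecific <- 0
  p
}

# patient with no perfusion and no renal filtration: every compartment is
# isolated, so only decay (and any pre-seeded tissue content) evolves
inert_patient <- function() {
  p <- p5_receptor_only()
  for (tn in names(p$tissues)) {
    p$tissues[[tn]]$perfusion <- 0
    p$tissues[[tn]]$flow <- 0
  }
  p$gfr <- 0
  p
}

# practically stable nuclide for decay-free closed-system experiments
stable_nuclide <- function() nuclide("pseudo-stable", 1e12, 0, 0)

# analytic equilibrium of the closed single-tissue mass-action system:
# kon * (L0 - B)/Veff * (Rtot - B) = koff * B, smaller root
equilibrium_bound <- function(L0, Rtot, Veff, kon, koff) {
  a <- kon / Veff
  b <- -(kon / Veff * (L0 + Rtot) + koff)
  cc <- kon / Veff * L0 * Rtot
  (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
}
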