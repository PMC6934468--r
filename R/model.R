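#' Injection protocol
#'
#' A bolus intravenous injection of `total_amount` nmol of ligand, of which
#' the radiolabelled (hot) part is the molar amount implied by `activity_bq`
#' for the given nuclide; the remainder is unlabelled (cold) carrier.
#'
#' @param total_amount Total ligand amount, hot + cold (nmol), > 0.
#' @param activity_bq Injected activity (Bq), >= 0.
#' @param nuclide A [nuclide()].
#' @return An object of class `injection_protocol` with fields
#'   `total_amount`, `activity_A0`, `nuclide` and the derived `hot_amount`.
#' @export
injection_protocol <- function(total_amount, activity_bq, nuclide) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (!is.numeric(total_amount) || total_amount <= 0) {
    stop("total_amount must be > 0")
  }
  hot <- hot_amount_from_activity(activity_bq, nuclide)
  if (hot > total_amount * (1 + 1e-12)) {
    stop(sprintf(
      "infeasible protocol: hot amount %.3g nmol implied by %.3g Bq exceeds total amount %.3g nmol",
      hot, activity_bq, total_amount))
  }
  structure(
    list(total_amount = total_amount, activity_A0 = activity_bq,
         nuclide = nuclide, hot_amount = min(hot, total_amount)),
    class = "injection_protocol"
  )
}

# state names for one species block
.block_names <- function(tissues) {
  # per tissue the three pools are consecutive: F, B, N
  c("plasma",
    as.vector(outer(c("F", "B", "N"), tissues,
                    function(a, b) paste(a, b, sep = "."))),
    "urine")
}

#' Assemble the PBPK ODE system
#'
#' Builds the parameter vector, initial state and bookkeeping for one
#' (patient, kinetics, protocol) triple. Mechanisms per tissue and species:
#' flow-limited plasma/tissue exchange of unbound ligand, second-order
#' association to the shared free-receptor pool, dissociation,
#' internalization, first-order release of internalized ligand back to the
#' tissue free pool, optional unspecific uptake; systemically, glomerular
#' filtration of unbound plasma ligand to urine and physical decay converting
#' hot into cold in every compartment. The bolus places the full hot and cold
#' amounts in plasma at t = 0.
#'
#' @param patient A [virtual_patient()].
#' @param kinetics A [ligand_kinetics()].
#' @param protocol An [injection_protocol()].
#' @return An object of class `pbpk_system`.
#' @export
build_system <- function(patient, kinetics, protocol) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(kinetics, "ligand_kinetics"),
            inherits(protocol, "injection_protocol"))
  tn <- TISSUE_NAMES
  nt <- length(tn)
  per_tissue <- unlist(lapply(patient$tissues[tn], function(ti) {
    c(ti$volume * ti$accessible_fraction,  # Veff
      ti$flow,
      ti$receptor_density * ti$volume,     # Rtot, nmol
      ti$lambda_release,
      ti$lambda_unspecific)
  }), use.names = FALSE)
  parms <- c(nt, patient$plasma_volume, patient$unbound_fraction,
             patient$gfr, protocol$nuclide$lambda_phys,
             kinetics$kon, kinetics$koff, kinetics$lambda_int,
             per_tissue)
  # the DLL's parameter block is a fixed 128 doubles; pad the tail
  parms <- c(parms, numeric(128 - length(parms)))
  m <- 2 + 3 * nt
  y0 <- numeric(2 * m)
  y0[1] <- protocol$hot_amount
  y0[m + 1] <- protocol$total_amount - protocol$hot_amount
  nm <- c(paste0("hot.", .block_names(tn)), paste0("cold.", .block_names(tn)))
  names(y0) <- nm
  structure(
    list(parms = parms, y0 = y0, state_names = nm, tissues = tn,
         n_tissues = nt, block_size = m,
         patient = patient, kinetics = kinetics, protocol = protocol),
    class = "pbpk_system"
  )
}

#' Index of a state in the state vector
#'
#' @param system A `pbpk_system`.
#' @param species `"hot"` or `"cold"`.
#' @param compartment `"plasma"`, `"urine"`, or one of `"F"`, `"B"`, `"N"`.
#' @param tissue Tissue name, required for `"F"`, `"B"`, `"N"`.
#' @return Integer index into the state vector.
#' @export
state_index <- function(system, species, compartment, tissue = NULL) {
  o <- if (species == "hot") 0L else system$block_size
  if (compartment == "plasma") return(o + 1L)
  if (compartment == "urine") return(o + 1L + 3L * system$n_tissues + 1L)
  j <- match(tissue, system$tissues)
  if (is.na(j)) stop("unknown tissue: ", tissue)
  k <- match(compartment, c("F", "B", "N"))
  if (is.na(k)) stop("unknown compartment: ", compartment)
  o + 1L + 3L * (j - 1L) + k
}

#' Integrate the PBPK system
#'
#' Stiff integration (LSODA, compiled right-hand side) at tight tolerances.
#' Small negative excursions, bounded by ten times the solver tolerance, are
#' clipped to zero after the solve; anything larger is an error. Results are
#' reproducible bit-identically for identical inputs and solver settings.
#'
#' @param system A `pbpk_system` from [build_system()].
#' @param horizon End of integration (min), > 0.
#' @param output_times Times at which to report the state, within
#'   `[0, horizon]`. Default: 0 plus 250 log-spaced points up to `horizon`.
#' @param y0 Optional replacement initial state (advanced use, e.g. closed
#'   sub-system experiments); must match the system's state length.
#' @param rtol,atol Solver tolerances (default 1e-8 relative, 1e-12 nmol).
#' @return An object of class `psma_sim` with `times`, state matrix `y`
#'   (rows = times), the `system` and solver `diagnostics`.
#' @export
simulate_pbpk <- function(system, horizon, output_times = NULL, y0 = NULL,
                          rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(system, "pbpk_system"))
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (is.null(output_times)) {
    output_times <- c(0, 10^seq(-2, log10(horizon), length.out = 250))
  }
  output_times <- sort(unique(c(0, output_times)))
  if (min(output_times) < 0 || max(output_times) > horizon * (1 + 1e-12)) {
    stop("output_times must lie within [0, horizon]")
  }
  if (is.null(y0)) y0 <- system$y0
  if (length(y0) != length(system$y0)) stop("y0 has wrong length")

  out <- deSolve::ode(
    y = unname(y0), times = output_times, func = "derivs",
    parms = system$parms, dllname = "psmapbpk", initfunc = "initmod",
    method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000
  )
  istate <- attributes(out)$istate[1]
  if (is.null(istate) || istate < 0) {
    stop(sprintf(
      "ODE integration failed (istate = %s) for patient %s, kon = %g, koff = %g, lambda_int = %g, amount = %g",
      istate, system$patient$id, system$kinetics$kon,
      system$kinetics$koff, system$kinetics$lambda_int,
      system$protocol$total_amount))
  }
  y <- unclass(out)[, -1, drop = FALSE]
  colnames(y) <- system$state_names
  # clip numerically negative amounts; refuse to hide real negativity
  scale <- sum(y0)
  thr <- 10 * (atol + rtol * scale)
  worst <- min(y)
  if (worst < -thr) {
    stop(sprintf("negative state excursion %.3g nmol exceeds 10x solver tolerance %.3g", worst, thr))
  }
  y[y < 0] <- 0

  structure(
    list(times = output_times, y = y, system = system,
         diagnostics = list(istate = istate, rtol = rtol, atol = atol,
                            n_steps = attributes(out)$istate[3])),
    class = "psma_sim"
  )
}

#' @export
print.psma_sim <- function(x, ...) {
  cat(sprintf(
    "<psma_sim> patient %s, %s, %d states, %d times in [0, %g] min\n",
    x$system$patient$id, x$system$protocol$nuclide$name,
    ncol(x$y), length(x$times), max(x$times)))
  invisible(x)
}

# hot (or cold) amount time course in a region; tissues sum F + B + N
.region_amount <- function(result, tissue, species = "hot") {
  sys <- result$system
  if (tissue %in% c("plasma", "urine")) {
    return(result$y[, state_index(sys, species, tissue)])
  }
  if (!tissue %in% sys$tissues) stop("unknown tissue: ", tissue)
  idx <- vapply(c("F", "B", "N"), function(cp)
    state_index(sys, species, cp, tissue), integer(1))
  rowSums(result$y[, idx, drop = FALSE])
}

#' Activity in a region at time t
#'
#' \eqn{A_i(t) = \lambda_{phys} n_{hot,i}(t) N_A} with \eqn{\lambda} in 1/s
#' and the hot amount in mol. The hot trajectory already contains physical
#' decay; no decay correction is applied. Off-grid times are evaluated by
#' cubic-spline interpolation of the stored trajectory.
#'
#' @param result A `psma_sim`.
#' @param tissue Tissue name, `"plasma"` or `"urine"`.
#' @param t Time (min) within the simulated span (vectorized).
#' @return Activity in Bq.
#' @export
activity_in <- function(result, tissue, t) {
  stopifnot(inherits(result, "psma_sim"))
  if (any(t < 0) || any(t > max(result$times) * (1 + 1e-12))) {
    stop("t outside the simulated time span")
  }
  amt <- .region_amount(result, tissue, "hot")
  amt_t <- if (all(t %in% result$times)) {
    amt[match(t, result$times)]
  } else {
    stats::splinefun(result$times, amt, method = "natural")(t)
  }
  pmax(0, activity_from_amount(amt_t, result$system$protocol$nuclide))
}

#' Total ligand amount over time (conservation check)
#'
#' @param result A `psma_sim`.
#' @return Vector over output times of the summed hot + cold amount in all
#'   compartments including urine (nmol); constant for a correct solve.
#' @export
total_ligand <- function(result) {
  rowSums(result$y)
}

#' Tidy long-format trajectory
#'
#' @param x A `psma_sim`.
#' @param ... Unused.
#' @return A data.frame with columns `time_min`, `tissue`, `species`,
#'   `compartment`, `amount_nmol` and `activity_Bq` (NA for cold species).
#' @export
as.data.frame.psma_sim <- function(x, ...) {
  nm <- x$system$state_names
  parts <- strsplit(nm, ".", fixed = TRUE)
  species <- vapply(parts, `[[`, "", 1L)
  comp <- vapply(parts, `[[`, "", 2L)
  tissue <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else p[[2]], "")
  n_t <- length(x$times)
  d <- data.frame(
    time_min = rep(x$times, times = length(nm)),
    tissue = rep(tissue, each = n_t),
    species = rep(species, each = n_t),
    compartment = rep(comp, each = n_t),
    amount_nmol = as.vector(x$y),
    stringsAsFactors = FALSE
  )
  d$activity_Bq <- ifelse(
    d$species == "hot",
    activity_from_amount(d$amount_nmol, x$system$protocol$nuclide),
    NA_real_)
  d
}
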