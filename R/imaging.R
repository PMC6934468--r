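#' The nine-region imaging readout panel
#'
#' Tumour lesions, tumour REST, background (muscle + fat lumped), organs at
#' risk (kidneys, liver, red marrow), gastrointestinal tract and lung.
#' @format Character vector of nine tissue names.
#' @export
IMAGING_PANEL <- c(
  "tumour_lesion_1", "tumour_lesion_2", "tumour_rest", "background",
  "kidneys", "liver", "red_marrow", "gi_tract", "lung"
)

#' Normalized activity concentration
#'
#' The imaging readout \eqn{c_i(t) = A_i(t) / (A_0 V_i)}: organ activity
#' divided by injected activity and organ volume, in 1/L, without decay
#' correction (the simulated hot trajectory already decays physically).
#' Because the species-sum kinetics are independent of the hot/cold split,
#' \eqn{c_i} is invariant to the injected activity at fixed total ligand
#' amount.
#'
#' @param result A `psma_sim`.
#' @param tissue Tissue name (must have a defined volume).
#' @param t Time post injection (min), within the simulated span.
#' @param A0 Injected activity (Bq), > 0; defaults to the simulated
#'   protocol's activity.
#' @return Normalized concentration (1/L).
#' @export
normalized_concentration <- function(result, tissue, t,
                                     A0 = result$system$protocol$activity_A0) {
  stopifnot(inherits(result, "psma_sim"))
  if (A0 <= 0) stop("A0 must be > 0")
  ti <- result$system$patient$tissues[[tissue]]
  if (is.null(ti)) stop("unknown tissue: ", tissue)
  activity_in(result, tissue, t) / (A0 * ti$volume)
}

#' Imaging panel at 1 h after a Ga-68 injection
#'
#' Runs the Ga-68 PBPK simulation for one patient and kinetics and evaluates
#' the normalized activity concentration of the nine-region panel at
#' `t_eval` (default 60 min), the evaluation time being an explicit solver
#' output point rather than a nearest-grid neighbour.
#'
#' @param patient A [virtual_patient()].
#' @param kinetics A [ligand_kinetics()].
#' @param amount Total ligand amount (nmol), in (0, 1000].
#' @param activity_bq Injected imaging activity (Bq), default 150e6 (the
#'   metric is invariant to it at fixed amount).
#' @param t_eval Evaluation time (min), default 60.
#' @return An object of class `imaging_result`: data.frame with columns
#'   `tissue`, `volume_L`, `c_per_L`, plus attributes `t_eval` and protocol.
#' @export
imaging_panel <- function(patient, kinetics, amount,
                          activity_bq = 150e6, t_eval = 60) {
  if (!is.numeric(amount) || amount <= 0 || amount > 1000) {
    stop("amount must be in (0, 1000] nmol")
  }
  prot <- injection_protocol(amount, activity_bq, ga68())
  sys <- build_system(patient, kinetics, prot)
  horizon <- max(90, t_eval * 1.5)
  times <- sort(unique(c(0, 10^seq(-2, log10(horizon), length.out = 200),
                         t_eval)))
  res <- simulate_pbpk(sys, horizon, times)
  d <- data.frame(
    tissue = IMAGING_PANEL,
    volume_L = vapply(IMAGING_PANEL,
                      function(tn) patient$tissues[[tn]]$volume, 0),
    c_per_L = vapply(IMAGING_PANEL, function(tn)
      normalized_concentration(res, tn, t_eval), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(d, class = c("imaging_result", "data.frame"),
            t_eval = t_eval, protocol = prot, patient_id = patient$id)
}
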