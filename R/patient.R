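#' Canonical tissue set of the whole-body model
#'
#' PSMA-positive tissues are those with nonzero receptor density: the tumour
#' regions, kidneys, liver and the gastrointestinal tract.
#' @format Character vector of the ten modelled tissues.
#' @export
TISSUE_NAMES <- c(
  "tumour_lesion_1", "tumour_lesion_2", "tumour_rest", "kidneys", "liver",
  "gi_tract", "lung", "red_marrow", "background", "rest_of_body"
)

#' Per-tissue model parameters
#'
#' @param name Tissue identifier (one of [TISSUE_NAMES] for patients).
#' @param volume Tissue volume (L), > 0.
#' @param mass Tissue mass (kg), > 0. Defaults to `volume` at unit density.
#' @param perfusion Blood flow per tissue mass (ml g^-1 min^-1). Converted
#'   once at construction to a plasma flow `flow` in L/min (= perfusion x
#'   mass in kg, the ml/g and g/kg factors cancel).
#' @param receptor_density PSMA receptor concentration (nmol/L); 0 for
#'   PSMA-negative tissue.
#' @param accessible_fraction Fraction of the tissue volume reachable by free
#'   ligand, in (0, 1]. Default 0.6, reflecting the assumption that ligand
#'   crossing the capillary wall is instantaneously diffused with access to
#'   binding sites (vascular plus an effectively well-mixed interstitium).
#' @param lambda_release First-order release rate of internalized ligand back
#'   to the tissue free pool (min^-1).
#' @param lambda_unspecific Optional first-order non-receptor uptake rate
#'   from the tissue free pool into the internalized pool (min^-1), default 0
#'   for the bare constructor; [default_physiology()] sets a small nonzero
#'   value for kidneys (residual uptake not blocked by amino-acid
#'   co-infusion) and for the deep background tissues.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(name, volume, mass = volume, perfusion,
                          receptor_density = 0,
                          accessible_fraction = 0.6,
                          lambda_release = 2.5e-4,
                          lambda_unspecific = 0) {
  chk <- function(x, what, lo = 0, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (strict && x <= lo) || (!strict && x < lo)) {
      stop(sprintf("tissue '%s': %s must be %s %g", name, what,
                   if (strict) ">" else ">=", lo))
    }
  }
  chk(volume, "volume"); chk(mass, "mass")
  chk(perfusion, "perfusion", strict = FALSE)
  chk(receptor_density, "receptor_density", strict = FALSE)
  chk(lambda_release, "lambda_release", strict = FALSE)
  chk(lambda_unspecific, "lambda_unspecific", strict = FALSE)
  if (accessible_fraction <= 0 || accessible_fraction > 1) {
    stop(sprintf("tissue '%s': accessible_fraction must be in (0, 1]", name))
  }
  structure(
    list(name = name, volume = volume, mass = mass, perfusion = perfusion,
         flow = perfusion * mass,  # L/min
         receptor_density = receptor_density,
         accessible_fraction = accessible_fraction,
         lambda_release = lambda_release,
         lambda_unspecific = lambda_unspecific),
    class = "tissue_params"
  )
}

#' Default adult physiology table
#'
#' ICRP-style reference-adult organ volumes, masses and perfusions used for
#' all non-tumour tissues unless overridden per patient. Kidney receptor
#' density and (age-adjusted) perfusion follow the exemplar patient; liver
#' and gastrointestinal receptor densities are moderate effective values that
#' together with the kidneys form a normal-tissue receptor sink of roughly
#' 19 nmol. The kidney release rate is twice the tumour release rate. The
#' kidneys carry a small affinity-independent (unspecific) first-order uptake
#' of 0.005 min^-1 of the kidney free pool; background and rest-of-body carry
#' the same rate as a slow deep-tissue distribution pool, emulating
#' non-receptor cellular uptake in muscle and fat.
#'
#' @param lambda_release_tumour Tumour release rate (min^-1), default 2.5e-4,
#'   the geometric mean of the Lu-177 decay constant and the reference
#'   internalization rate 1e-3 min^-1.
#' @return Named list of [tissue_params()] for the seven non-tumour tissues,
#'   plus entries `plasma_volume` (L), `unbound_fraction`, `gfr` (L/min),
#'   `body_weight` (kg) and `age` (years).
#' @export
default_physiology <- function(lambda_release_tumour = 2.5e-4) {
  lr <- lambda_release_tumour
  list(
    kidneys      = tissue_params("kidneys", 0.31, 0.31, 1.7,
                                 receptor_density = 19,
                                 lambda_release = 2 * lr,
                                 lambda_unspecific = 0.005),
    liver        = tissue_params("liver", 1.8, 1.8, 0.9,
                                 receptor_density = 3, lambda_release = lr),
    gi_tract     = tissue_params("gi_tract", 1.2, 1.2, 0.7,
                                 receptor_density = 6, lambda_release = lr),
    lung         = tissue_params("lung", 1.0, 0.5, 0.4, lambda_release = lr),
    red_marrow   = tissue_params("red_marrow", 1.17, 1.17, 0.15,
                                 lambda_release = lr),
    background   = tissue_params("background", 39, 39, 0.04,
                                 lambda_release = lr,
                                 lambda_unspecific = 0.005),
    rest_of_body = tissue_params("rest_of_body", 20, 20, 0.1,
                                 lambda_release = lr,
                                 lambda_unspecific = 0.005),
    plasma_volume = 3.0,
    unbound_fraction = 0.3,
    gfr = 0.1,
    body_weight = 73,
    age = 67
  )
}

#' Virtual patient
#'
#' A fully specified whole-body parameterization: systemic covariates, plasma
#' and renal parameters, and the ten-tissue set (two explicit tumour lesions,
#' the merged remaining tumour burden "tumour REST", the kidneys and other
#' organs). Serum protein binding is modelled as an instantaneous equilibrium
#' through the unbound fraction.
#'
#' @param id Patient identifier.
#' @param tissues Named list of [tissue_params()] covering exactly
#'   [TISSUE_NAMES].
#' @param injected_activity Therapy activity (GBq), default 7.3.
#' @param body_weight Body weight (kg).
#' @param age Age (years).
#' @param plasma_volume Plasma volume (L).
#' @param unbound_fraction Fraction of plasma ligand not bound to serum
#'   proteins, in (0, 1].
#' @param gfr Glomerular filtration rate (L/min); only unbound plasma ligand
#'   is filtered to urine.
#' @return An object of class `virtual_patient`.
#' @export
virtual_patient <- function(id, tissues, injected_activity = 7.3,
                            body_weight = 73, age = 67,
                            plasma_volume = 3.0, unbound_fraction = 0.3,
                            gfr = 0.1) {
  missing_t <- setdiff(TISSUE_NAMES, names(tissues))
  if (length(missing_t)) {
    stop("missing tissue(s): ", paste(missing_t, collapse = ", "))
  }
  extra <- setdiff(names(tissues), TISSUE_NAMES)
  if (length(extra)) {
    stop("unknown tissue(s): ", paste(extra, collapse = ", "))
  }
  if (anyDuplicated(names(tissues))) stop("duplicated tissue names")
  for (nm in TISSUE_NAMES) {
    if (!inherits(tissues[[nm]], "tissue_params")) {
      stop(sprintf("tissues$%s is not a tissue_params object", nm))
    }
  }
  if (unbound_fraction <= 0 || unbound_fraction > 1) {
    stop("unbound_fraction must be in (0, 1]")
  }
  stopifnot(plasma_volume > 0, gfr >= 0, injected_activity >= 0)
  structure(
    list(id = id, body_weight = body_weight, age = age,
         plasma_volume = plasma_volume, unbound_fraction = unbound_fraction,
         gfr = gfr, tissues = tissues[TISSUE_NAMES],
         injected_activity = injected_activity),
    class = "virtual_patient"
  )
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf("<virtual_patient %s> %g kg, A_inj = %g GBq\n",
              x$id, x$body_weight, x$injected_activity))
  tt <- do.call(rbind, lapply(x$tissues, function(ti) {
    data.frame(volume_L = ti$volume, perfusion = ti$perfusion,
               receptor_nmol_L = ti$receptor_density)
  }))
  print(tt)
  invisible(x)
}

#' The exemplar patient ("patient 5")
#'
#' The one patient whose tumour and kidney parameters are printed: a tumour
#' lesion with receptor density 33 nmol/L and perfusion 0.08 ml/g/min,
#' tumour REST with 66 nmol/L and 0.04 ml/g/min, and kidneys with
#' 19 nmol/L and age-adjusted perfusion 1.7 ml/g/min. The second lesion
#' mirrors the first; lesion volumes (0.02 L each) and the REST volume
#' (0.3 L) are documented defaults near the cohort median total volume.
#'
#' @return A [virtual_patient()].
#' @export
patient5_exemplar <- function() {
  phys <- default_physiology()
  lr <- 2.5e-4
  tissues <- c(
    list(
      tumour_lesion_1 = tissue_params("tumour_lesion_1", 0.02, 0.02, 0.08,
                                      receptor_density = 33,
                                      lambda_release = lr),
      tumour_lesion_2 = tissue_params("tumour_lesion_2", 0.02, 0.02, 0.08,
                                      receptor_density = 33,
                                      lambda_release = lr),
      tumour_rest = tissue_params("tumour_rest", 0.3, 0.3, 0.04,
                                  receptor_density = 66,
                                  lambda_release = lr)
    ),
    phys[c("kidneys", "liver", "gi_tract", "lung", "red_marrow",
           "background", "rest_of_body")]
  )
  virtual_patient("patient5", tissues,
                  injected_activity = 7.3,
                  body_weight = phys$body_weight, age = phys$age,
                  plasma_volume = phys$plasma_volume,
                  unbound_fraction = phys$unbound_fraction,
                  gfr = phys$gfr)
}
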