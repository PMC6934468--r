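PATIENT_SCHEMA_VERSION <- 1L

#' Serialize a virtual patient to YAML or JSON
#'
#' @param patient A [virtual_patient()].
#' @param path Output file; format inferred from the extension (`.yaml`,
#'   `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_patient <- function(patient, path) {
  stopifnot(inherits(patient, "virtual_patient"))
  doc <- list(
    schema_version = PATIENT_SCHEMA_VERSION,
    id = patient$id,
    body_weight = patient$body_weight,
    age = patient$age,
    plasma_volume = patient$plasma_volume,
    unbound_fraction = patient$unbound_fraction,
    gfr = patient$gfr,
    injected_activity = patient$injected_activity,
    tissues = lapply(patient$tissues, function(ti) {
      ti[c("volume", "mass", "perfusion", "receptor_density",
           "accessible_fraction", "lambda_release", "lambda_unspecific")]
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(doc, path, precision = 15)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported patient file extension: ", path)
  }
  invisible(path)
}

#' Read a virtual patient from YAML or JSON
#'
#' @param path Patient file written by [write_patient()].
#' @return A [virtual_patient()].
#' @export
read_patient <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported patient file extension: ", path)
  }
  if (is.null(doc$schema_version) ||
      doc$schema_version != PATIENT_SCHEMA_VERSION) {
    stop("unsupported or missing patient schema_version in ", path)
  }
  tissues <- lapply(names(doc$tissues), function(nm) {
    ti <- doc$tissues[[nm]]
    tissue_params(nm, volume = ti$volume, mass = ti$mass,
                  perfusion = ti$perfusion,
                  receptor_density = ti$receptor_density,
                  accessible_fraction = ti$accessible_fraction,
                  lambda_release = ti$lambda_release,
                  lambda_unspecific = ti$lambda_unspecific)
  })
  names(tissues) <- names(doc$tissues)
  virtual_patient(doc$id, tissues,
                  injected_activity = doc$injected_activity,
                  body_weight = doc$body_weight, age = doc$age,
                  plasma_volume = doc$plasma_volume,
                  unbound_fraction = doc$unbound_fraction,
                  gfr = doc$gfr)
}

#' Run configuration
#'
#' Validated configuration tying cohort generation, the sweep grid and
#' output settings together. Unknown keys are rejected.
#'
#' @param seed Integer seed for cohort generation.
#' @param n_patients Cohort size, default 13.
#' @param amounts,lambda_ints Grid axes (defaults as in [sweep_grid()]).
#' @param mode `"both"`, `"imaging"` or `"therapy"`.
#' @param out_dir Output directory.
#' @param imaging_activity_bq Imaging activity (Bq).
#' @param extra Named list of overrides for [cohort_spec()] fields.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_patients = 13L,
                       amounts = 10^seq(0, 3, by = 0.5),
                       lambda_ints = c(0.01, 0.001, 0.0001),
                       mode = c("both", "imaging", "therapy"),
                       out_dir = ".", imaging_activity_bq = 150e6,
                       extra = list()) {
  mode <- match.arg(mode)
  known <- names(formals(cohort_spec))
  bad <- setdiff(names(extra), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  structure(
    list(schema_version = 1L, seed = as.integer(seed),
         n_patients = as.integer(n_patients), amounts = amounts,
         lambda_ints = lambda_ints, mode = mode, out_dir = out_dir,
         imaging_activity_bq = imaging_activity_bq, extra = extra),
    class = "run_config"
  )
}

.config_cohort <- function(config) {
  do.call(cohort_spec, c(list(n_patients = config$n_patients,
                              seed = config$seed), config$extra))
}

#' Write a cohort of patient files plus manifest
#'
#' Generates the seeded cohort and writes one YAML file per patient plus a
#' JSON manifest recording the seed, schema version and every file written.
#' Reruns with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @return Character vector of the patient file paths, invisibly.
#' @export
cmd_generate_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(.config_cohort(config))
  files <- vapply(cohort, function(p) {
    f <- file.path(config$out_dir, paste0(p$id, ".yaml"))
    write_patient(p, f)
    f
  }, "")
  manifest <- list(schema_version = PATIENT_SCHEMA_VERSION,
                   seed = config$seed, n_patients = config$n_patients,
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' Run the full simulation study from a configuration
#'
#' Generates the seeded cohort, runs the requested sweep mode(s), and writes
#' tidy CSV results, the tumour-to-kidney summary table (therapy), and
#' per-tissue heatmap matrices (amount x combo of cohort means). Every file
#' carries the seed in a sidecar provenance JSON.
#'
#' @param config A [run_config()].
#' @return Named list of `sweep_result` objects, invisibly.
#' @export
cmd_run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(.config_cohort(config))
  modes <- if (config$mode == "both") c("imaging", "therapy") else config$mode
  results <- list()
  for (m in modes) {
    grid <- sweep_grid(amounts = config$amounts,
                       lambda_ints = config$lambda_ints, mode = m)
    sw <- run_sweep(cohort, grid,
                    imaging_activity_bq = config$imaging_activity_bq)
    utils::write.csv(sw, file.path(config$out_dir,
                                   paste0("sweep_", m, ".csv")),
                     row.names = FALSE)
    if (m == "therapy") {
      utils::write.csv(tumour_to_kidney_table(sw),
                       file.path(config$out_dir, "tumour_to_kidney.csv"),
                       row.names = FALSE)
    }
    results[[m]] <- sw
  }
  jsonlite::write_json(
    list(schema_version = 1L, seed = config$seed,
         n_patients = config$n_patients, mode = config$mode,
         n_failed = vapply(results, function(r) attr(r, "n_failed"), 0L),
         package_version = as.character(utils::packageVersion("psmapbpk"))),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' One-cell convenience run
#'
#' Runs a single (patient, kinetics, amount) cell in one mode and returns
#' the panel or report; useful for interactive exploration.
#'
#' @param patient A [virtual_patient()] (e.g. [patient5_exemplar()]).
#' @param kon,koff,lambda_int Kinetic rates.
#' @param amount Total ligand amount (nmol).
#' @param mode `"imaging"` or `"therapy"`.
#' @return An `imaging_result` or `dose_report`.
#' @export
cmd_single <- function(patient, kon, koff, lambda_int, amount,
                       mode = c("imaging", "therapy")) {
  mode <- match.arg(mode)
  kin <- ligand_kinetics(kon, koff, lambda_int)
  if (mode == "imaging") {
    imaging_panel(patient, kin, amount)
  } else {
    therapy_report(patient, kin, amount)
  }
}
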