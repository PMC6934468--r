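#' Simulation sweep grid
#'
#' The parameter grid of the simulation study: (kon, koff) combinations,
#' total ligand amounts in half-decade steps of sqrt(10) from 1 to 1000 nmol,
#' and internalization rates, for one mode (imaging or therapy). The default
#' grid has 6 x 7 x 3 = 126 cells.
#'
#' @param combos data.frame with columns `kon`, `koff` (default
#'   [kinetics_combos()]).
#' @param amounts Strictly increasing ligand amounts (nmol) within
#'   `[1, 1000]`; default `10^seq(0, 3, by = 0.5)`.
#' @param lambda_ints Internalization rates (min^-1), default
#'   `c(0.01, 0.001, 0.0001)`.
#' @param mode `"imaging"` or `"therapy"`.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(combos = kinetics_combos(),
                       amounts = 10^seq(0, 3, by = 0.5),
                       lambda_ints = c(0.01, 0.001, 0.0001),
                       mode = c("therapy", "imaging")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(combos), all(c("kon", "koff") %in% names(combos)),
            nrow(combos) >= 1)
  if (any(diff(amounts) <= 0) || min(amounts) < 1 - 1e-9 ||
      max(amounts) > 1000 + 1e-9) {
    stop("amounts must be strictly increasing within [1, 1000] nmol")
  }
  structure(
    list(combos = combos[, c("kon", "koff")], amounts = amounts,
         lambda_ints = lambda_ints, mode = mode),
    class = "sweep_grid"
  )
}

#' Cells of a sweep grid
#' @param grid A [sweep_grid()].
#' @return data.frame of all (kon, koff, lambda_int, amount) cells.
#' @export
grid_cells <- function(grid) {
  cells <- expand.grid(combo = seq_len(nrow(grid$combos)),
                       lambda_int = grid$lambda_ints,
                       amount = grid$amounts,
                       KEEP.OUT.ATTRS = FALSE)
  data.frame(kon = grid$combos$kon[cells$combo],
             koff = grid$combos$koff[cells$combo],
             lambda_int = cells$lambda_int,
             amount = cells$amount)
}

.cell_records <- function(patient, kon, koff, lambda_int, amount, mode,
                          s_table, imaging_activity_bq) {
  kin <- ligand_kinetics(kon, koff, lambda_int)
  base <- data.frame(patient = patient$id, kon = kon, koff = koff,
                     kd = koff / kon, lambda_int = lambda_int,
                     amount = amount, stringsAsFactors = FALSE)
  if (mode == "imaging") {
    pan <- imaging_panel(patient, kin, amount,
                         activity_bq = imaging_activity_bq)
    cbind(base[rep(1, nrow(pan)), ], tissue = pan$tissue,
          metric = "conc_1h", value = pan$c_per_L,
          status = "ok", row.names = NULL)
  } else {
    rep_ <- therapy_report(patient, kin, amount, s_table = s_table)
    d1 <- cbind(base[rep(1, nrow(rep_$targets)), ],
                tissue = rep_$targets$target, metric = "dose_Gy",
                value = rep_$targets$dose_Gy, status = "ok",
                row.names = NULL)
    d2 <- cbind(base[rep(1, length(rep_$ratios)), ],
                tissue = names(rep_$ratios), metric = "t2k_ratio",
                value = unname(rep_$ratios), status = "ok",
                row.names = NULL)
    rbind(d1, d2)
  }
}

#' Run a parameter sweep over a cohort
#'
#' Executes every grid cell for every patient: imaging mode evaluates the 1 h
#' Ga-68 panel, therapy mode the Lu-177 dose report with the patient's
#' sampled activity. Cells are independent and the result is deterministic
#' for a fixed cohort; a failed cell (including therapy cells whose ligand
#' amount cannot accommodate the hot molar amount of ~7.3 GBq Lu-177) is
#' recorded with a failure marker and the sweep continues.
#'
#' @param cohort List of [virtual_patient()].
#' @param grid A [sweep_grid()].
#' @param imaging_activity_bq Imaging activity (Bq), default 150e6.
#' @return An object of class `sweep_result`: long data.frame with columns
#'   `patient`, `kon`, `koff`, `kd`, `lambda_int`, `amount`, `tissue`,
#'   `metric`, `value`, `status`; attribute `n_failed`.
#' @export
run_sweep <- function(cohort, grid, imaging_activity_bq = 150e6) {
  stopifnot(inherits(grid, "sweep_grid"), length(cohort) >= 1)
  cells <- grid_cells(grid)
  s_table <- if (grid$mode == "therapy") sphere_s_table(lu177()) else NULL
  out <- vector("list", nrow(cells) * length(cohort))
  k <- 0L
  for (p in cohort) {
    for (i in seq_len(nrow(cells))) {
      k <- k + 1L
      out[[k]] <- tryCatch(
        .cell_records(p, cells$kon[i], cells$koff[i], cells$lambda_int[i],
                      cells$amount[i], grid$mode, s_table,
                      imaging_activity_bq),
        error = function(e) {
          data.frame(patient = p$id, kon = cells$kon[i],
                     koff = cells$koff[i],
                     kd = cells$koff[i] / cells$kon[i],
                     lambda_int = cells$lambda_int[i],
                     amount = cells$amount[i], tissue = NA_character_,
                     metric = "error", value = NA_real_,
                     status = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$patient, res$kon, res$koff, res$lambda_int,
                   res$amount, res$metric, res$tissue), ]
  rownames(res) <- NULL
  structure(res, class = c("sweep_result", "data.frame"),
            mode = grid$mode,
            n_failed = sum(res$metric == "error"))
}

# rows of a sweep for one tissue/metric; "tumour_lesions" averages the two
# explicit lesions per (patient, cell)
.sweep_values <- function(sweep, tissue, metric) {
  if (tissue == "tumour_lesions" && metric != "t2k_ratio" &&
      !any(sweep$tissue == "tumour_lesions" & sweep$metric == metric)) {
    d <- sweep[sweep$tissue %in% c("tumour_lesion_1", "tumour_lesion_2") &
                 sweep$metric == metric, ]
    agg <- stats::aggregate(
      value ~ patient + kon + koff + kd + lambda_int + amount,
      data = d, FUN = mean)
    return(agg)
  }
  sweep[sweep$tissue == tissue & sweep$metric == metric,
        c("patient", "kon", "koff", "kd", "lambda_int", "amount", "value")]
}

.match_cell <- function(d, cell) {
  ok <- rep(TRUE, nrow(d))
  for (f in names(cell)) {
    ok <- ok & abs(d[[f]] - cell[[f]]) <= 1e-9 * pmax(1, abs(cell[[f]]))
  }
  d[ok, ]
}

#' Cohort fold-change between two grid cells
#'
#' Per-patient ratio value(cell_b) / value(cell_a) of one tissue metric, then
#' the cohort mean and sd (n-1 denominator), matching the "factor of X +- Y"
#' summaries. Patients with a zero denominator are excluded with a warning.
#'
#' @param sweep A `sweep_result`.
#' @param tissue Tissue name; `"tumour_lesions"` averages the two explicit
#'   lesions per patient first.
#' @param metric Metric name (`"conc_1h"`, `"dose_Gy"`, `"t2k_ratio"`).
#' @param cell_a,cell_b Named lists identifying the cells, e.g.
#'   `list(kon = 0.01, koff = 0.01, lambda_int = 0.001, amount = 10)`.
#' @return List with `mean`, `sd`, `n` and the per-patient `ratios`.
#' @export
fold_change <- function(sweep, tissue, metric, cell_a, cell_b) {
  d <- .sweep_values(sweep, tissue, metric)
  a <- .match_cell(d, cell_a)
  b <- .match_cell(d, cell_b)
  if (!nrow(a) || !nrow(b)) stop("cell not present in sweep result")
  m <- merge(a[, c("patient", "value")], b[, c("patient", "value")],
             by = "patient", suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no patients present in both cells")
  zero <- m$value_a == 0
  if (any(zero)) {
    warning(sprintf("excluding %d patient(s) with zero denominator",
                    sum(zero)))
    m <- m[!zero, ]
  }
  r <- m$value_b / m$value_a
  list(mean = mean(r), sd = stats::sd(r), n = length(r), ratios = r)
}

#' Tumour-to-kidney dose-ratio summary table
#'
#' Cohort mean +- sd of the per-patient tumour-to-kidney absorbed dose
#' ratios for the therapy-relevant amounts (grid points 10^1.5, 10^2 and
#' 10^2.5 nmol, labelled 32, 100 and 316), every (kon, koff) combination and
#' internalization rate, for the lesion mean and for tumour REST. The
#' maximum of each (lambda_int, group) column is flagged.
#'
#' @param sweep A therapy `sweep_result`.
#' @return data.frame with columns `kd`, `koff`, `kon`, `amount_label`,
#'   `amount`, `lambda_int`, `group`, `mean`, `sd`, `n`, `is_max`.
#' @export
tumour_to_kidney_table <- function(sweep) {
  if (!identical(attr(sweep, "mode"), "therapy")) {
    stop("tumour_to_kidney_table requires a therapy sweep")
  }
  amounts <- c(`32` = 10^1.5, `100` = 100, `316` = 10^2.5)
  groups <- c(tumour_lesions = "tumour_lesions", tumour_rest = "tumour_rest")
  rows <- list()
  for (g in names(groups)) {
    d <- .sweep_values(sweep, groups[[g]], "t2k_ratio")
    for (ai in seq_along(amounts)) {
      sub <- d[abs(d$amount - amounts[ai]) < 1e-9 * amounts[ai], ]
      if (!nrow(sub)) next
      agg_m <- stats::aggregate(value ~ kon + koff + kd + lambda_int,
                                data = sub, FUN = mean)
      agg_s <- stats::aggregate(value ~ kon + koff + kd + lambda_int,
                                data = sub, FUN = stats::sd)
      agg_n <- stats::aggregate(value ~ kon + koff + kd + lambda_int,
                                data = sub, FUN = length)
      agg <- agg_m
      names(agg)[names(agg) == "value"] <- "mean"
      agg$sd <- agg_s$value
      agg$n <- agg_n$value
      agg$amount_label <- names(amounts)[ai]
      agg$amount <- amounts[[ai]]
      agg$group <- g
      rows[[length(rows) + 1L]] <- agg
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$group, tab$kd, tab$koff, tab$amount, tab$lambda_int),
             c("kd", "koff", "kon", "amount_label", "amount", "lambda_int",
               "group", "mean", "sd", "n")]
  tab$is_max <- FALSE
  for (g in unique(tab$group)) {
    for (li in unique(tab$lambda_int)) {
      sel <- tab$group == g & tab$lambda_int == li
      tab$is_max[sel] <- seq_len(sum(sel)) == which.max(tab$mean[sel])
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Optimal grid cell per group
#'
#' Argmax of the cohort-mean metric over grid cells within each group
#' (default: per internalization rate). Ties are broken toward the smaller
#' ligand amount, then the smaller kon.
#'
#' @param sweep A `sweep_result`.
#' @param metric Metric name, default `"t2k_ratio"`.
#' @param tissue Tissue, default `"tumour_lesions"`.
#' @param group_by Grouping column, default `"lambda_int"`.
#' @return data.frame with one row per group: the optimal `kon`, `koff`,
#'   `amount` and the achieved cohort `mean`.
#' @export
find_optimum <- function(sweep, metric = "t2k_ratio",
                         tissue = "tumour_lesions",
                         group_by = "lambda_int") {
  d <- .sweep_values(sweep, tissue, metric)
  if (!nrow(d)) stop("metric not present in sweep result")
  agg <- stats::aggregate(value ~ kon + koff + kd + lambda_int + amount,
                          data = d, FUN = mean)
  out <- lapply(split(agg, agg[[group_by]]), function(g) {
    g <- g[order(-g$value, g$amount, g$kon), ]
    g[1, ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
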