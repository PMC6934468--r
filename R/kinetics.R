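#' Ligand-receptor binding kinetics
#'
#' Second-order association to free PSMA receptors (rate constant `kon`),
#' first-order dissociation (`koff`) and effective first-order
#' internalization of the surface-bound complex (`lambda_int`). The affinity
#' is summarized by the dissociation constant K_D = koff/kon: lower K_D means
#' higher affinity.
#'
#' @param kon Association rate constant (L nmol^-1 min^-1), >= 0.
#' @param koff Dissociation rate constant (min^-1), >= 0.
#' @param lambda_int Internalization rate of the bound complex (min^-1), >= 0.
#' @return An object of class `ligand_kinetics` with the three rates and the
#'   derived `kd` (nmol/L, i.e. nM).
#' @examples
#' ligand_kinetics(kon = 0.1, koff = 0.01, lambda_int = 0.001)$kd  # 0.1 nM
#' @export
ligand_kinetics <- function(kon, koff, lambda_int = 0.001) {
  for (v in c("kon", "koff", "lambda_int")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
      stop(sprintf("%s must be a single non-negative number", v))
    }
  }
  structure(
    list(kon = kon, koff = koff, lambda_int = lambda_int,
         kd = if (kon > 0) koff / kon else Inf),
    class = "ligand_kinetics"
  )
}

#' @export
print.ligand_kinetics <- function(x, ...) {
  cat(sprintf(
    "<ligand_kinetics> kon = %g L/nmol/min, koff = %g /min, KD = %g nM, lambda_int = %g /min\n",
    x$kon, x$koff, x$kd, x$lambda_int
  ))
  invisible(x)
}

#' The six investigated (kon, koff) combinations
#'
#' Two combinations for each dissociation constant K_D in {0.01, 0.1, 1} nM,
#' spanning kon 0.01-0.1 L/nmol/min and koff 0.0001-0.1 min^-1.
#'
#' @return A data.frame with columns `kon` (L/nmol/min), `koff` (min^-1) and
#'   the derived `kd` (nM), six rows.
#' @export
kinetics_combos <- function() {
  d <- data.frame(
    koff = c(0.0001, 0.001, 0.001, 0.01, 0.01, 0.1),
    kon  = c(0.01,   0.1,   0.01,  0.1,  0.01, 0.1)
  )
  d$kd <- d$koff / d$kon
  d[, c("kd", "koff", "kon")]
}
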