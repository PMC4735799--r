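#' Ligand specification
#'
#' Describes an EGFR ligand by name, dose and equilibrium dissociation
#' constant. The receptor model makes no distinction between ligands other
#' than their affinity: both share the association rate `kon` of the
#' parameter set, and the dissociation rate is `koff = kon * kd`.
#'
#' @param name Ligand label, e.g. `"EGF"` or `"AREG"`.
#' @param concentration Ligand concentration in nM (>= 0). The default
#'   1.8 nM corresponds to the routine culture dose (EGF 10 ng/mL,
#'   AREG 20 ng/mL).
#' @param kd Equilibrium dissociation constant in nM (> 0). If `NULL`, a
#'   packaged default is used for the names `"EGF"` (20 nM) and `"AREG"`
#'   (200 nM); the 10-fold ratio encodes AREG's 10-fold lower affinity
#'   for EGFR.
#'
#' @return An object of class `ligand_spec`: a list with fields `name`,
#'   `concentration` and `kd`.
#' @examples
#' ligand_spec("EGF")
#' ligand_spec("AREG", concentration = 1.8)
#' @export
ligand_spec <- function(name, concentration = 1.8, kd = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(kd)) {
    kd <- switch(name, EGF = 20, AREG = 200,
                 stop("no default kd for ligand '", name,
                      "'; supply `kd` explicitly", call. = FALSE))
  }
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0) {
    stop("ligand concentration must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(kd) || length(kd) != 1L || is.na(kd) || kd <= 0) {
    stop("ligand kd must be a single number > 0", call. = FALSE)
  }
  structure(list(name = name, concentration = concentration, kd = kd),
            class = "ligand_spec")
}

#' @export
print.ligand_spec <- function(x, ...) {
  cat(sprintf("<ligand_spec> %s: %g nM, Kd = %g nM\n",
              x$name, x$concentration, x$kd))
  invisible(x)
}
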