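#' Receptor trafficking model parameters
#'
#' Rate constants and pool scaling of the mass-action EGFR trafficking
#' model. The model tracks five receptor species: free surface receptor
#' (`Rs`), unphosphorylated surface ligand-receptor complex (`Cs`),
#' phosphorylated surface complex (`Ps`), internalized phosphorylated
#' receptor (`Pi`) and internalized non-phosphorylated receptor (`Ri`).
#' Receptor amounts are dimensionless, normalized so that the ligand-free
#' steady-state surface pool of the epithelial reference cell (`r_scale = 1`)
#' equals 1; western-blot readouts are relative, so the absolute receptor
#' count is not identifiable.
#'
#' The packaged defaults are a calibration: they place 1.8 nM stimulation in
#' the subsaturating, binding-pre-equilibrated regime so that (i) the
#' EGF:AREG ratio of 0-60 min integrated phospho-EGFR is close to the
#' observed 10-fold difference and (ii) a 10-fold larger surface pool under
#' AREG compensates for its 10-fold lower affinity (see the package
#' vignette for the calibration rationale).
#'
#' @param kon Association rate, per nM per min, shared by all ligands.
#' @param kp Phosphorylation rate of the surface complex, per min.
#' @param kdp Dephosphorylation rate at the surface, per min.
#' @param ke0 Constitutive internalization rate of free surface receptor,
#'   per min.
#' @param ke1 Induced internalization rate of the phosphorylated complex,
#'   per min; must be >= `ke0`.
#' @param kdpi Dephosphorylation rate of internalized receptor, per min.
#' @param kr Recycling rate of internal non-phospho receptor to the
#'   surface, per min.
#' @param kdeg Degradation rate of internal non-phospho receptor, per min.
#' @param kdegP Degradation rate of internal phospho receptor, per min.
#' @param vs Synthesis rate of surface receptor, receptor units per min.
#'   `NULL` (the default) sets `vs` so that the ligand-free steady state has
#'   `Rs = 1` at `r_scale = 1`, i.e. `vs = ke0 * kdeg / (kr + kdeg)` (0 when
#'   `kdeg = 0`).
#' @param r_scale Dimensionless multiplier on the pre-stimulation receptor
#'   pools: 1 for the E-cell scenario, 10 for the A-cell surface scenario
#'   (cell-surface EGFR is about 10-fold higher in A-cells).
#'
#' @return An object of class `receptor_params` (named list of rates).
#' @seealso [initial_steady_state()], [simulate_receptor()]
#' @examples
#' receptor_params()                 # packaged defaults, E-cell pool
#' receptor_params(r_scale = 10)     # A-cell surface pool
#' @export
receptor_params <- function(kon = 0.1, kp = 0.05, kdp = 0.3,
                            ke0 = 0.02, ke1 = 0.2, kdpi = 0.1,
                            kr = 0.05, kdeg = 0.02, kdegP = 0.1,
                            vs = NULL, r_scale = 1) {
  if (is.null(vs)) {
    vs <- if (kdeg > 0) ke0 * kdeg / (kr + kdeg) else 0
  }
  p <- list(kon = kon, kp = kp, kdp = kdp, ke0 = ke0, ke1 = ke1,
            kdpi = kdpi, kr = kr, kdeg = kdeg, kdegP = kdegP,
            vs = vs, r_scale = r_scale)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("parameter '", nm, "' must be a single number >= 0", call. = FALSE)
    }
  }
  if (p$ke1 < p$ke0) {
    stop("ke1 must be >= ke0 (induced internalization at least constitutive)",
         call. = FALSE)
  }
  structure(p, class = "receptor_params")
}

#' @export
print.receptor_params <- function(x, ...) {
  cat("<receptor_params>\n")
  cat(paste0("  ", names(x), " = ", signif(unlist(x), 5), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Model state vector
#'
#' @param Rs,Cs,Ps,Pi,Ri Non-negative amounts of the five receptor species
#'   (free surface, surface complex, phospho surface complex, internal
#'   phospho, internal non-phospho).
#' @return Named numeric vector of class `model_state`.
#' @export
model_state <- function(Rs = 0, Cs = 0, Ps = 0, Pi = 0, Ri = 0) {
  s <- c(Rs = Rs, Cs = Cs, Ps = Ps, Pi = Pi, Ri = Ri)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("all state components must be finite and >= 0", call. = FALSE)
  }
  structure(s, class = "model_state")
}

.species <- c("Rs", "Cs", "Ps", "Pi", "Ri")

#' Ligand-free steady state
#'
#' Solves for the resting state of the model after prolonged growth-factor
#' deprivation (no ligand): all complex and phospho pools are zero, and
#' `Rs`, `Ri` balance synthesis, constitutive internalization, recycling
#' and degradation: `vs - ke0*Rs + kr*Ri = 0` and
#' `ke0*Rs - (kr + kdeg)*Ri = 0`. The solved pools are then multiplied by
#' `r_scale`.
#'
#' When the surface pool is closed (`vs = 0` and `ke0 = 0`, or `vs = 0`
#' with `kdeg = 0`), the balance fixes only ratios, and the free pool is
#' set by the unit convention `Rs = 1` (before `r_scale`). With synthesis
#' but no route to degradation (`vs > 0` and `ke0 = 0` or `kdeg = 0`) the
#' receptor pool grows without bound and an error of class
#' `non_convergent_equilibrium` is signalled.
#'
#' @param params A [receptor_params()] object.
#' @return A [model_state()] with `Cs = Ps = Pi = 0`.
#' @examples
#' initial_steady_state(receptor_params())
#' @export
initial_steady_state <- function(params) {
  stopifnot(inherits(params, "receptor_params"))
  p <- params
  if (p$vs > 0) {
    if (p$ke0 == 0 || p$kdeg == 0) {
      stop(errorCondition(
        "no finite ligand-free steady state: synthesis without degradation route",
        class = c("non_convergent_equilibrium", "error")))
    }
    Rs <- p$vs * (p$kr + p$kdeg) / (p$ke0 * p$kdeg)
    Ri <- p$vs / p$kdeg
  } else if (p$ke0 == 0) {
    # closed surface pool: unit convention
    Rs <- 1
    Ri <- 0
  } else if (p$kdeg == 0) {
    if (p$kr > 0) {
      # closed recirculating pool: convention Rs = 1
      Rs <- 1
      Ri <- p$ke0 / p$kr
    } else {
      # everything drains into the internal pool
      Rs <- 0
      Ri <- 1
    }
  } else {
    Rs <- 0
    Ri <- 0
  }
  model_state(Rs = p$r_scale * Rs, Ri = p$r_scale * Ri)
}

.receptor_rhs <- function(t, y, parms) {
  kon <- parms[1L]; koff <- parms[2L]; kp <- parms[3L]; kdp <- parms[4L]
  ke0 <- parms[5L]; ke1 <- parms[6L]; kdpi <- parms[7L]; kr <- parms[8L]
  kdeg <- parms[9L]; kdegP <- parms[10L]; vs <- parms[11L]; L <- parms[12L]
  Rs <- y[1L]; Cs <- y[2L]; Ps <- y[3L]; Pi <- y[4L]; Ri <- y[5L]
  list(c(
    vs - kon * L * Rs + koff * Cs - ke0 * Rs + kr * Ri,
    kon * L * Rs - koff * Cs - kp * Cs + kdp * Ps,
    kp * Cs - kdp * Ps - ke1 * Ps,
    ke1 * Ps - kdpi * Pi - kdegP * Pi,
    ke0 * Rs + kdpi * Pi - kr * Ri - kdeg * Ri
  ))
}

#' Simulate the receptor trafficking model
#'
#' Integrates the five-species mass-action system under constant ligand
#' concentration (the bulk medium is not depleted at nM doses):
#' \deqn{dRs/dt = vs - kon L Rs + koff Cs - ke0 Rs + kr Ri}
#' \deqn{dCs/dt = kon L Rs - koff Cs - kp Cs + kdp Ps}
#' \deqn{dPs/dt = kp Cs - kdp Ps - ke1 Ps}
#' \deqn{dPi/dt = ke1 Ps - kdpi Pi - kdegP Pi}
#' \deqn{dRi/dt = ke0 Rs + kdpi Pi - kr Ri - kdeg Ri}
#' with `koff = kon * ligand$kd`. Integration uses the stiff-capable
#' `lsoda` solver (relative tolerance 1e-8, absolute 1e-10); fast binding
#' and slow trafficking can differ by orders of magnitude in time scale.
#'
#' @param params A [receptor_params()] object.
#' @param ligand A [ligand_spec()].
#' @param times Strictly increasing time grid in minutes, starting at 0.
#' @param init Initial [model_state()]; defaults to the ligand-free steady
#'   state of `params` (stimulation after growth-factor deprivation).
#' @return An object of class `egfr_trajectory`: list with `times`,
#'   `states` (matrix, one row per time, columns `Rs,Cs,Ps,Pi,Ri`),
#'   `ligand` and `params`.
#' @examples
#' traj <- simulate_receptor(receptor_params(), ligand_spec("EGF"),
#'                           times = seq(0, 60, 1))
#' head(as.data.frame(traj))
#' @export
simulate_receptor <- function(params, ligand, times,
                              init = initial_steady_state(params)) {
  stopifnot(inherits(params, "receptor_params"),
            inherits(ligand, "ligand_spec"))
  if (length(times) < 2L || times[1L] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing and start at 0", call. = FALSE)
  }
  init <- do.call(model_state, as.list(unclass(init)[.species]))
  parms <- c(params$kon, params$kon * ligand$kd, params$kp, params$kdp,
             params$ke0, params$ke1, params$kdpi, params$kr,
             params$kdeg, params$kdegP, params$vs, ligand$concentration)
  out <- deSolve::ode(y = unclass(init), times = times,
                      func = .receptor_rhs, parms = parms,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  attrs <- attributes(out)
  if (!is.null(attrs$istate) && attrs$istate[1L] < 0) {
    stop(errorCondition(
      sprintf("ODE integration failed near t = %g min", max(out[, 1L])),
      class = c("integration_error", "error")))
  }
  states <- unname(out[, -1L, drop = FALSE])
  colnames(states) <- .species
  neg <- states < 0
  if (any(states[neg] < -1e-9)) {
    bad <- which(apply(states < -1e-9, 1L, any))[1L]
    stop(errorCondition(
      sprintf("negative species beyond tolerance at t = %g min",
              times[bad]),
      class = c("integration_error", "error")))
  }
  states[neg] <- 0
  structure(list(times = as.numeric(times), states = states,
                 ligand = ligand, params = params),
            class = "egfr_trajectory")
}

#' @export
print.egfr_trajectory <- function(x, ...) {
  cat(sprintf("<egfr_trajectory> %s %g nM, %d time points over %g min\n",
              x$ligand$name, x$ligand$concentration,
              length(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.egfr_trajectory <- function(x, ...) {
  data.frame(time_min = x$times, as.data.frame(x$states))
}

#' Scalar readouts of a trajectory
#'
#' Maps simulated species onto the quantities measured experimentally:
#' `"pEGFR_total"` (`Ps + Pi`) matches whole-lysate phospho-EGFR blots
#' (RIPA lysates capture all compartments), `"surface_EGFR"`
#' (`Rs + Cs + Ps`) matches cell-surface receptor measurements, and
#' `"total_EGFR"` sums all five species as in total-EGFR blots.
#'
#' @param traj An `egfr_trajectory` from [simulate_receptor()].
#' @param kind One of `"pEGFR_total"`, `"surface_EGFR"`, `"total_EGFR"`.
#' @return Numeric vector, one value per time point of `traj`.
#' @examples
#' traj <- simulate_receptor(receptor_params(), ligand_spec("EGF"),
#'                           times = seq(0, 60, 10))
#' readout(traj, "pEGFR_total")
#' @export
readout <- function(traj, kind = c("pEGFR_total", "surface_EGFR",
                                   "total_EGFR")) {
  stopifnot(inherits(traj, "egfr_trajectory"))
  if (!is.character(kind) || length(kind) < 1L ||
      !(kind[1L] %in% c("pEGFR_total", "surface_EGFR", "total_EGFR"))) {
    stop(errorCondition(paste0("unknown readout kind: ", kind[1L]),
                        class = c("invalid_readout", "error")))
  }
  kind <- kind[1L]
  s <- traj$states
  switch(kind,
         pEGFR_total  = s[, "Ps"] + s[, "Pi"],
         surface_EGFR = s[, "Rs"] + s[, "Cs"] + s[, "Ps"],
         total_EGFR   = rowSums(s))
}

#' Trapezoidal area under a sampled curve
#'
#' @param times Strictly increasing sample times (minutes).
#' @param values Values at `times`.
#' @return The trapezoidal integral, in value-units times minutes.
#' @export
auc_trapezoid <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2L,
            all(diff(times) > 0))
  pracma::trapz(times, values)
}

#' Integrated phospho-EGFR signal of a simulation
#'
#' Convenience wrapper: simulates from the ligand-free steady state on a
#' 1-min grid and returns the trapezoidal integral of whole-lysate
#' phospho-EGFR (`Ps + Pi`) over `[0, tmax]` minutes. This is the
#' model-side "integrated signal strength" used to compare EGF and AREG
#' stimulation.
#'
#' @param params A [receptor_params()] object.
#' @param ligand A [ligand_spec()].
#' @param tmax Window end in minutes (default 60, the 1-h window).
#' @param grid_step Grid resolution in minutes.
#' @return Integrated phospho-EGFR (receptor-units x minutes).
#' @examples
#' integrated_pEGFR(receptor_params(), ligand_spec("EGF")) /
#'   integrated_pEGFR(receptor_params(), ligand_spec("AREG"))
#' @export
integrated_pEGFR <- function(params, ligand, tmax = 60, grid_step = 1) {
  times <- seq(0, tmax, by = grid_step)
  traj <- simulate_receptor(params, ligand, times)
  auc_trapezoid(traj$times, readout(traj, "pEGFR_total"))
}
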