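#' Penalty objective value for failed model evaluations
#'
#' Returned by [fit_objective()] when the ODE integration fails for a
#' candidate parameter set, so that the evolutionary search stays totally
#' ordered without raising exceptions.
#' @export
FIT_PENALTY <- 1e12

#' One observed series of a fitting dataset
#'
#' @param condition Condition label (e.g. `"EGF-lo"`).
#' @param ligand A [ligand_spec()] describing the stimulation.
#' @param r_scale Receptor pool scaling of the condition (1 for E-cells,
#'   10 for the A-cell surface pool).
#' @param readout Readout kind, see [readout()].
#' @param times Observation times in minutes (non-negative, increasing).
#' @param observed Observed normalized band intensities at `times` (>= 0).
#' @return An object of class `fit_series`.
#' @export
fit_series <- function(condition, ligand, r_scale = 1,
                       readout = "pEGFR_total", times, observed) {
  stopifnot(inherits(ligand, "ligand_spec"),
            length(times) == length(observed))
  if (length(times) < 3L) {
    stop("each series needs at least 3 time points", call. = FALSE)
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("series times must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (any(observed < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(condition = condition, ligand = ligand,
                 r_scale = r_scale, readout = readout,
                 times = as.numeric(times), observed = as.numeric(observed)),
            class = "fit_series")
}

#' Dataset for parameter estimation
#'
#' Bundles one or more observed time-course series with the reference
#' point used to normalize model predictions. Band intensities on blots
#' are relative, so both data and model outputs are expressed relative to
#' the model prediction of `reference$condition` at `reference$time`
#' minutes; the data are assumed normalized by the same convention.
#'
#' @param series List of [fit_series()] objects.
#' @param reference List with `condition` and `time`: the normalization
#'   point (it must belong to one of the series).
#' @return An object of class `fit_dataset`.
#' @export
fit_dataset <- function(series, reference) {
  if (inherits(series, "fit_series")) series <- list(series)
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, logical(1L), "fit_series")),
            is.list(reference),
            all(c("condition", "time") %in% names(reference)))
  conds <- vapply(series, `[[`, character(1L), "condition")
  if (!(reference$condition %in% conds)) {
    stop("reference condition '", reference$condition,
         "' not present in the series", call. = FALSE)
  }
  structure(list(series = series, reference = reference),
            class = "fit_dataset")
}

# Simulate every series of `data` under `params` (with per-series ligand
# kd overrides from `kd_override`, a named vector by ligand name) and
# return the list of predicted, reference-normalized curves.
.predict_dataset <- function(params, data, kd_override = NULL) {
  ref <- data$reference
  preds <- vector("list", length(data$series))
  ref_value <- NA_real_
  for (i in seq_along(data$series)) {
    s <- data$series[[i]]
    lig <- s$ligand
    if (!is.null(kd_override) && lig$name %in% names(kd_override)) {
      lig <- ligand_spec(lig$name, lig$concentration,
                         kd = unname(kd_override[lig$name]))
    }
    p <- params
    p$r_scale <- s$r_scale
    p <- do.call(receptor_params, unclass(p))
    times <- s$times
    need_ref <- s$condition == ref$condition && !(ref$time %in% times)
    sim_times <- if (need_ref) sort(unique(c(times, ref$time))) else times
    if (sim_times[1L] != 0) sim_times <- c(0, sim_times)
    traj <- simulate_receptor(p, lig, sim_times)
    vals <- readout(traj, s$readout)
    if (s$condition == ref$condition) {
      ref_value <- vals[match(ref$time, traj$times)]
    }
    preds[[i]] <- vals[match(times, traj$times)]
  }
  if (!is.finite(ref_value) || ref_value <= 0) {
    stop(errorCondition("reference prediction is zero or undefined",
                        class = c("invalid_reference", "error")))
  }
  lapply(preds, function(v) v / ref_value)
}

#' Sum-of-squared-residuals objective
#'
#' The estimation objective: the sum over all series and time points of
#' the squared difference between observed normalized intensities and the
#' reference-normalized model prediction. Deterministic for fixed inputs.
#' If the ODE integration fails for a candidate parameter set, the large
#' finite penalty [FIT_PENALTY] is returned instead of an error.
#'
#' @param params A [receptor_params()] object (its `r_scale` is overridden
#'   per series).
#' @param data A [fit_dataset()].
#' @param kd_override Optional named numeric vector of ligand kd values by
#'   ligand name, overriding the kd stored in each series' ligand (used
#'   when kd is itself being estimated).
#' @return Non-negative scalar.
#' @export
fit_objective <- function(params, data, kd_override = NULL) {
  stopifnot(inherits(data, "fit_dataset"))
  preds <- tryCatch(.predict_dataset(params, data, kd_override),
                    error = function(e) NULL)
  if (is.null(preds)) return(FIT_PENALTY)
  ssr <- 0
  for (i in seq_along(data$series)) {
    r <- data$series[[i]]$observed - preds[[i]]
    ssr <- ssr + sum(r * r)
  }
  ssr
}

#' Estimation settings
#'
#' Controls for the hybrid meta-evolutionary-programming / Nelder-Mead
#' search. The search runs in log10 parameter space; rates span orders of
#' magnitude and log coordinates equalize the mutation scale.
#'
#' @param bounds Named list of `c(low, high)` bounds in log10 space, one
#'   entry per free parameter. Names are fields of [receptor_params()] or
#'   `"kd_<NAME>"` for a ligand dissociation constant (e.g. `"kd_EGF"`).
#'   The default box `[-4, 2]` spans six orders of magnitude per rate.
#' @param pop_size Population size of the evolutionary search.
#' @param generations Number of generations.
#' @param tournament_size Opponents per individual in the q-tournament
#'   survivor selection.
#' @param nm_max_iter Maximum Nelder-Mead iterations.
#' @param nm_xtol,nm_ftol Nelder-Mead convergence tolerances.
#' @param n_restarts Number of independent restarts of the full chain; the
#'   reference protocol uses 200 independent estimations and keeps the
#'   minimum-objective fit.
#' @param seed Base random seed; restart `i` uses `seed + i - 1`.
#' @return An object of class `estimation_settings`.
#' @export
estimation_settings <- function(bounds, pop_size = 50, generations = 100,
                                tournament_size = 10, nm_max_iter = 1000,
                                nm_xtol = 1e-8, nm_ftol = 1e-8,
                                n_restarts = 200, seed = 1L) {
  stopifnot(is.list(bounds), length(bounds) >= 1L,
            !is.null(names(bounds)), all(nzchar(names(bounds))))
  for (b in bounds) {
    if (length(b) != 2L || !(b[1L] < b[2L])) {
      stop("each bound must be c(low, high) with low < high", call. = FALSE)
    }
  }
  counts <- c(pop_size = pop_size, generations = generations,
              tournament_size = tournament_size, nm_max_iter = nm_max_iter,
              n_restarts = n_restarts)
  if (any(counts < 1)) stop("all counts must be positive", call. = FALSE)
  structure(list(bounds = bounds, pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 nm_max_iter = as.integer(nm_max_iter),
                 nm_xtol = nm_xtol, nm_ftol = nm_ftol,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "estimation_settings")
}

.bounds_matrix <- function(settings) {
  lo <- vapply(settings$bounds, `[`, numeric(1L), 1L)
  hi <- vapply(settings$bounds, `[`, numeric(1L), 2L)
  rbind(low = lo, high = hi)
}

.new_estimation_result <- function(par, objective, settings, seed,
                                   n_evaluations, restart_index = NA_integer_,
                                   converged = TRUE) {
  structure(list(par = par, objective = objective,
                 restart_index = restart_index, seed = seed,
                 n_evaluations = n_evaluations, converged = converged,
                 settings = settings),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> objective = %.6g (%d evaluations%s)\n",
              x$objective, x$n_evaluations,
              if (!is.na(x$restart_index))
                sprintf(", restart %d", x$restart_index) else ""))
  if (!is.null(names(x$par))) {
    cat(paste0("  ", names(x$par), " = ", signif(x$par, 5),
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Self-adaptive (meta) evolutionary programming
#'
#' Classic meta-EP: each individual carries per-coordinate mutation step
#' sizes. An offspring of \eqn{(x, \sigma)} is
#' \eqn{x_i' = x_i + \sigma_i N(0,1)} and
#' \eqn{\sigma_i' = \sigma_i \exp(\tau' N(0,1) + \tau N_i(0,1))} with
#' \eqn{\tau = 1/\sqrt{2\sqrt{n}}} and \eqn{\tau' = 1/\sqrt{2n}}.
#' Survivor selection over the union of parents and offspring is by
#' q-tournament (each candidate scores wins against `tournament_size`
#' random opponents; the top `pop_size` by wins survive, ties broken by
#' objective value). Coordinates are clipped to the bounds box.
#'
#' @param fn Objective callable mapping a numeric vector (in the bounded
#'   search space) to a scalar.
#' @param settings An [estimation_settings()]; its `bounds` define the box
#'   and the search dimension.
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @return An `estimation_result` whose `par` is the best point found (in
#'   search-space coordinates) and `objective` its value.
#' @examples
#' s <- estimation_settings(list(x = c(-5, 5), y = c(-5, 5)),
#'                          pop_size = 30, generations = 60, n_restarts = 1)
#' meta_ep(function(z) sum(z^2), s, seed = 1)$objective
#' @export
meta_ep <- function(fn, settings, seed = settings$seed) {
  stopifnot(inherits(settings, "estimation_settings"))
  bm <- .bounds_matrix(settings)
  n <- ncol(bm)
  mu <- settings$pop_size
  q <- settings$tournament_size
  tau <- 1 / sqrt(2 * sqrt(n))
  tau_prime <- 1 / sqrt(2 * n)
  span <- bm["high", ] - bm["low", ]
  sigma_min <- 1e-8 * span

  set.seed(seed)
  X <- matrix(stats::runif(mu * n, bm["low", ], bm["high", ]),
              nrow = mu, ncol = n, byrow = TRUE)
  S <- matrix(span / 10, nrow = mu, ncol = n, byrow = TRUE)
  f <- apply(X, 1L, fn)
  n_eval <- mu

  clip <- function(M) {
    M <- pmax(M, matrix(bm["low", ], nrow(M), n, byrow = TRUE))
    pmin(M, matrix(bm["high", ], nrow(M), n, byrow = TRUE))
  }

  for (g in seq_len(settings$generations)) {
    Xo <- clip(X + S * matrix(stats::rnorm(mu * n), mu, n))
    So <- S * exp(tau_prime * stats::rnorm(mu) +
                  tau * matrix(stats::rnorm(mu * n), mu, n))
    So <- pmax(So, matrix(sigma_min, mu, n, byrow = TRUE))
    fo <- apply(Xo, 1L, fn)
    n_eval <- n_eval + mu

    Xa <- rbind(X, Xo); Sa <- rbind(S, So); fa <- c(f, fo)
    wins <- vapply(seq_len(2L * mu), function(i) {
      opp <- sample.int(2L * mu, q, replace = TRUE)
      sum(fa[i] <= fa[opp])
    }, integer(1L))
    keep <- order(-wins, fa)[seq_len(mu)]
    X <- Xa[keep, , drop = FALSE]
    S <- Sa[keep, , drop = FALSE]
    f <- fa[keep]
  }
  best <- which.min(f)
  par <- X[best, ]
  names(par) <- colnames(bm)
  .new_estimation_result(par, f[best], settings, seed, n_eval)
}

#' Nelder-Mead refinement
#'
#' Local simplex search (reflection 1, expansion 2, contraction 0.5,
#' shrink 0.5) from a starting point, via [stats::optim()]'s Nelder-Mead
#' with `reltol = nm_ftol`, wrapped in a bound penalty so the simplex
#' stays inside the box. After convergence one polish restart is made from
#' the found point; if it improves by less than `nm_xtol` (relative) the
#' first result stands. The returned objective never exceeds `fn(start)`.
#'
#' @param fn Objective callable.
#' @param start Numeric starting point, inside the bounds of `settings`.
#' @param settings An [estimation_settings()].
#' @return An `estimation_result`; `converged` is `FALSE` when the
#'   iteration budget was exhausted.
#' @export
nelder_mead <- function(fn, start, settings) {
  stopifnot(inherits(settings, "estimation_settings"))
  bm <- .bounds_matrix(settings)
  if (any(start < bm["low", ]) || any(start > bm["high", ])) {
    stop("start must lie inside the bounds", call. = FALSE)
  }
  n_eval <- 0L
  fn_box <- function(x) {
    n_eval <<- n_eval + 1L
    out <- pmax(0, bm["low", ] - x) + pmax(0, x - bm["high", ])
    if (any(out > 0)) return(FIT_PENALTY * (1 + sum(out)))
    fn(x)
  }
  ctrl <- list(maxit = settings$nm_max_iter, reltol = settings$nm_ftol)
  # optim warns that 1-D Nelder-Mead can be unreliable; the polish restart
  # below covers that case, so the warning is muffled
  nm_optim <- function(par) {
    withCallingHandlers(
      stats::optim(par, fn_box, method = "Nelder-Mead", control = ctrl),
      warning = function(w) {
        if (grepl("Nelder-Mead", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  r1 <- nm_optim(start)
  r2 <- nm_optim(r1$par)
  best <- if (r2$value < r1$value * (1 - settings$nm_xtol)) r2 else
          if (r2$value < r1$value) r2 else r1
  f0 <- fn_box(start)
  if (f0 < best$value) best <- list(par = start, value = f0, convergence = 0L)
  par <- best$par
  names(par) <- colnames(bm)
  .new_estimation_result(par, best$value, settings, NA_integer_, n_eval,
                         converged = identical(best$convergence, 0L))
}

#' Multistart hybrid fit of the receptor model
#'
#' Runs `n_restarts` independent estimation chains, each a global meta-EP
#' search followed by Nelder-Mead refinement of its best point, seeded
#' `seed + i - 1` for restart `i`, and returns the chain with the minimum
#' objective. The free parameters and their log10 boxes come from
#' `settings$bounds`; all other rates stay at `base_params`.
#'
#' @param data A [fit_dataset()].
#' @param settings An [estimation_settings()].
#' @param base_params Fixed values of the parameters not being estimated.
#' @return An `estimation_result` with `par` (free parameters on the
#'   natural scale), `params` (the full fitted [receptor_params()]),
#'   `kd_override` (fitted ligand kds, if any were free), `objective`,
#'   `restart_index`, `seed` and `n_evaluations`.
#' @examples
#' \donttest{
#' sc <- scenario_presets()[["E-EGF"]]
#' gen <- gen_timecourse(sc, receptor_params(), seed = 1, noise_cv = 0)
#' st <- estimation_settings(list(kd_EGF = c(0, 3), kp = c(-4, 1)),
#'                           pop_size = 10, generations = 15,
#'                           n_restarts = 2, seed = 1)
#' multistart_fit(gen$fit_data, st)
#' }
#' @export
multistart_fit <- function(data, settings, base_params = receptor_params()) {
  stopifnot(inherits(data, "fit_dataset"),
            inherits(settings, "estimation_settings"))
  free <- names(settings$bounds)
  kd_names <- grepl("^kd_", free)
  fn <- function(z) {
    v <- 10^z
    names(v) <- free
    p <- unclass(base_params)
    for (nm in free[!kd_names]) p[[nm]] <- unname(v[[nm]])
    p <- tryCatch(do.call(receptor_params, p), error = function(e) NULL)
    if (is.null(p)) return(FIT_PENALTY)
    kd_ov <- if (any(kd_names)) {
      stats::setNames(unname(v[kd_names]), sub("^kd_", "", free[kd_names]))
    } else NULL
    fit_objective(p, data, kd_override = kd_ov)
  }

  best <- NULL
  total_eval <- 0L
  any_ok <- FALSE
  for (i in seq_len(settings$n_restarts)) {
    seed_i <- settings$seed + i - 1L
    ep <- meta_ep(fn, settings, seed = seed_i)
    nm <- nelder_mead(fn, ep$par, settings)
    total_eval <- total_eval + ep$n_evaluations + nm$n_evaluations
    if (nm$objective < FIT_PENALTY) any_ok <- TRUE
    if (is.null(best) || nm$objective < best$objective) {
      best <- nm
      best$restart_index <- i
      best$seed <- seed_i
    }
  }
  if (!any_ok) {
    stop(errorCondition("all restarts failed to evaluate the model",
                        class = c("estimation_failure", "error")))
  }
  v <- 10^best$par
  names(v) <- free
  p <- unclass(base_params)
  for (nm in free[!kd_names]) p[[nm]] <- unname(v[[nm]])
  best$params <- do.call(receptor_params, p)
  best$kd_override <- if (any(kd_names)) {
    stats::setNames(unname(v[kd_names]), sub("^kd_", "", free[kd_names]))
  } else NULL
  best$par <- v
  best$n_evaluations <- total_eval
  best
}
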