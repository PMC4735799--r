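#' Specification of a synthetic nuclei image
#'
#' Parameters of the generator that emulates Hoechst-stained nuclei
#' micrographs with controllable spatial clustering and known ground
#' truth.
#'
#' @param width,height Image size in pixels.
#' @param n_nuclei Total number of nuclei.
#' @param n_clusters Number of spatial clusters (`<= n_nuclei`).
#' @param cluster_sd Gaussian spread of nucleus centers around their
#'   cluster center, in pixels.
#' @param nucleus_radius Disk radius of a drawn nucleus in pixels
#'   (default 5, about half a cell diameter).
#' @param min_gap Minimum edge-to-edge Chebyshev gap in pixels between
#'   any two nucleus rasters, or `NULL` for no constraint. A gap of `g`
#'   means `g` background pixels separate the two disks along the closest
#'   approach.
#' @param peak_intensity,background_intensity Disk and background
#'   intensity, 8-bit scale.
#' @param noise_sd Gaussian pixel noise standard deviation (0 for
#'   noise-free images).
#' @param seed Integer seed; the generated image is reproducible per seed.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(width = 512L, height = 512L, n_nuclei = 20L,
                       n_clusters = n_nuclei, cluster_sd = 30,
                       nucleus_radius = 5L, min_gap = NULL,
                       peak_intensity = 200, background_intensity = 10,
                       noise_sd = 5, seed = 1L) {
  stopifnot(width >= 1L, height >= 1L, n_nuclei >= 1L,
            n_clusters >= 1L, n_clusters <= n_nuclei,
            nucleus_radius >= 1, peak_intensity > background_intensity,
            background_intensity >= 0, noise_sd >= 0, cluster_sd >= 0)
  if (!is.null(min_gap)) stopifnot(min_gap >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_nuclei = as.integer(n_nuclei),
                 n_clusters = as.integer(n_clusters),
                 cluster_sd = cluster_sd, nucleus_radius = nucleus_radius,
                 min_gap = min_gap, peak_intensity = peak_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "image_spec")
}

# pixel offsets of a rasterized disk (Euclidean) of radius r around (0,0)
.disk_offsets <- function(r) {
  d <- expand.grid(dr = -floor(r):floor(r), dc = -floor(r):floor(r))
  d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
}

# minimal Chebyshev distance between rasters of two disks with centers
# `c1`, `c2` (row, col): min over pixel pairs, computed via the
# difference set of disk offsets
.disk_cheb_dist <- function(c1, c2, deltas) {
  dd <- c(c1[1L] - c2[1L], c1[2L] - c2[2L])
  min(pmax(abs(dd[1L] + deltas$dr), abs(dd[2L] + deltas$dc)))
}

.disk_delta_set <- function(r) {
  off <- .disk_offsets(r)
  g <- expand.grid(i = seq_len(nrow(off)), j = seq_len(nrow(off)))
  d <- unique(data.frame(dr = off$dr[g$i] - off$dr[g$j],
                         dc = off$dc[g$i] - off$dc[g$j]))
  d
}

#' Generate a synthetic nuclei image with known ground truth
#'
#' Cluster centers are placed uniformly in the frame; nucleus centers are
#' drawn from isotropic Gaussians (`cluster_sd`) around their cluster
#' center and, when `min_gap` is set, rejection-sampled until every pair
#' of nucleus rasters keeps at least that edge-to-edge Chebyshev gap.
#' Nuclei are drawn as solid disks at `peak_intensity` on the background,
#' Gaussian noise is added, and intensities are clipped to the 8-bit
#' range.
#'
#' @param spec An [image_spec()].
#' @param max_tries Rejection-sampling budget per nucleus before a
#'   `layout_infeasible` error is signalled.
#' @return List with `image` (a [nuclei_image()]), `centers` (matrix of
#'   ground-truth nucleus centers, columns `row`, `col`),
#'   `cluster_id` (cluster membership of each nucleus) and `spec`.
#' @examples
#' g <- gen_nuclei_image(image_spec(n_nuclei = 5, noise_sd = 0, seed = 2))
#' nn_distance_index(g$image)
#' @export
gen_nuclei_image <- function(spec, max_tries = 500L) {
  stopifnot(inherits(spec, "image_spec"))
  r <- spec$nucleus_radius
  margin <- floor(r) + 1L
  if (spec$width < 2L * margin || spec$height < 2L * margin) {
    stop("frame too small for the nucleus radius", call. = FALSE)
  }
  set.seed(spec$seed)
  deltas <- if (!is.null(spec$min_gap)) .disk_delta_set(r) else NULL

  ccenters <- cbind(row = stats::runif(spec$n_clusters, margin,
                                       spec$height - margin + 1),
                    col = stats::runif(spec$n_clusters, margin,
                                       spec$width - margin + 1))
  cluster_id <- rep_len(seq_len(spec$n_clusters), spec$n_nuclei)
  centers <- matrix(NA_real_, spec$n_nuclei, 2L,
                    dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(spec$n_nuclei)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- round(c(
        stats::rnorm(1L, ccenters[cluster_id[i], "row"], spec$cluster_sd),
        stats::rnorm(1L, ccenters[cluster_id[i], "col"], spec$cluster_sd)))
      if (cand[1L] < margin || cand[1L] > spec$height - margin + 1 ||
          cand[2L] < margin || cand[2L] > spec$width - margin + 1) next
      if (!is.null(spec$min_gap) && i > 1L) {
        gaps_ok <- TRUE
        for (j in seq_len(i - 1L)) {
          dmin <- .disk_cheb_dist(cand, centers[j, ], deltas)
          if (dmin - 1 < spec$min_gap) { gaps_ok <- FALSE; break }
        }
        if (!gaps_ok) next
      }
      centers[i, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(errorCondition(
        sprintf("could not place nucleus %d within %d tries", i, max_tries),
        class = c("layout_infeasible", "error")))
    }
  }

  img <- matrix(spec$background_intensity, spec$height, spec$width)
  off <- .disk_offsets(r)
  for (i in seq_len(spec$n_nuclei)) {
    rr <- centers[i, "row"] + off$dr
    cc <- centers[i, "col"] + off$dc
    keep <- rr >= 1 & rr <= spec$height & cc >= 1 & cc <= spec$width
    img[cbind(rr[keep], cc[keep])] <- spec$peak_intensity
  }
  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  }
  img <- pmin(pmax(round(img), 0), 255)
  list(image = nuclei_image(img, bit_depth = 8L),
       centers = centers, cluster_id = cluster_id, spec = spec)
}

#' Write a nuclei image to PNG
#'
#' @param img A [nuclei_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nuclei_png <- function(img, path) {
  stopifnot(inherits(img, "nuclei_image"))
  maxv <- 2^attr(img, "bit_depth") - 1
  png::writePNG(unclass(img) / maxv, path)
  invisible(path)
}

#' Scenario configuration for synthetic time courses
#'
#' @param name Condition label.
#' @param ligand A [ligand_spec()].
#' @param r_scale Receptor pool scaling (1 = E-cell, 10 = A-cell surface).
#' @param sampling_times Observation grid in minutes.
#' @param noise_cv Lognormal coefficient of variation of multiplicative
#'   replicate noise (default 0.1, typical of densitometry).
#' @param n_replicates Number of replicates (default 3 independent
#'   experiments).
#' @param pERK_shape Parameters of the phenomenological ERK curve: list
#'   with `peak_time` (min), `peak_width` (log-time SD), `second_onset`
#'   (min, `NA` for none), `second_amp` (relative amplitude),
#'   `second_rise` (min to the second-pulse maximum after onset) and
#'   `second_width` (log-time SD).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name, ligand, r_scale = 1,
                            sampling_times = seq(0, 60, by = 10),
                            noise_cv = 0.1, n_replicates = 3L,
                            pERK_shape = list(peak_time = 10,
                                              peak_width = 0.9,
                                              second_onset = NA_real_,
                                              second_amp = 0,
                                              second_rise = 20,
                                              second_width = 0.8)) {
  stopifnot(inherits(ligand, "ligand_spec"),
            all(diff(sampling_times) > 0), noise_cv >= 0,
            n_replicates >= 1L, r_scale > 0)
  structure(list(name = name, ligand = ligand, r_scale = r_scale,
                 sampling_times = as.numeric(sampling_times),
                 noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
                 pERK_shape = pERK_shape),
            class = "scenario_config")
}

#' Packaged stimulation scenarios
#'
#' The four conditions of the ligand-switching experiments, with the
#' constants of the study design: both ligands dosed at 1.8 nM; the
#' A-cell surface receptor pool 10-fold larger than the E-cell pool; and,
#' in the A-to-E switch condition, a second ERK pulse whose rise is
#' programmed at 160 min after stimulation. Short (0-60 min) conditions
#' are sampled every 10 min, long (0-310 min) conditions every 10 min.
#'
#' @return Named list of [scenario_config()] objects: `"E-EGF"`,
#'   `"E-AREG"`, `"A-AREG"`, `"A-EGF-switch"`.
#' @export
scenario_presets <- function() {
  short <- seq(0, 60, by = 10)
  long <- seq(0, 310, by = 10)
  single <- list(peak_time = 10, peak_width = 0.9,
                 second_onset = NA_real_, second_amp = 0,
                 second_rise = 20, second_width = 0.8)
  reactiv <- list(peak_time = 10, peak_width = 0.9,
                  second_onset = 160, second_amp = 0.8,
                  second_rise = 20, second_width = 0.8)
  list(
    "E-EGF" = scenario_config("E-EGF", ligand_spec("EGF", 1.8),
                              r_scale = 1, sampling_times = short,
                              pERK_shape = single),
    "E-AREG" = scenario_config("E-AREG", ligand_spec("AREG", 1.8),
                               r_scale = 1, sampling_times = short,
                               pERK_shape = single),
    "A-AREG" = scenario_config("A-AREG", ligand_spec("AREG", 1.8),
                               r_scale = 10, sampling_times = long,
                               pERK_shape = single),
    "A-EGF-switch" = scenario_config("A-EGF-switch", ligand_spec("EGF", 1.8),
                                     r_scale = 10, sampling_times = long,
                                     pERK_shape = reactiv)
  )
}

#' Phenomenological ERK activation curve
#'
#' Two log-normal pulses: an immediate transient peaking at
#' `peak_time` with unit amplitude, plus an optional re-activation pulse
#' that starts at `second_onset` and peaks `second_rise` minutes later
#' with amplitude `second_amp`. ERK is not part of the mechanistic
#' receptor model, so its curve is generated phenomenologically with
#' analytic ground truth.
#'
#' @param t Times in minutes.
#' @param shape `pERK_shape` list, see [scenario_config()].
#' @return Numeric vector of latent pERK values (0 at `t = 0`).
#' @export
perk_curve <- function(t, shape) {
  lnpulse <- function(t, tp, sig) {
    y <- numeric(length(t))
    pos <- t > 0
    y[pos] <- exp(-(log(t[pos] / tp))^2 / (2 * sig^2))
    y
  }
  y <- lnpulse(t, shape$peak_time, shape$peak_width)
  if (!is.na(shape$second_onset) && shape$second_amp > 0) {
    y <- y + shape$second_amp *
      lnpulse(t - shape$second_onset, shape$second_rise, shape$second_width)
  }
  y
}

#' Generate a synthetic signaling time course for a scenario
#'
#' Produces the noise-free latent curves (pEGFR from the mechanistic
#' receptor model, pERK from the phenomenological two-pulse curve) and
#' `n_replicates` noisy realizations at the scenario's sampling times.
#' Noise is multiplicative lognormal per observation with coefficient of
#' variation `noise_cv` (mean ratio to the latent curve is 1). Ground
#' truth is returned alongside for recovery tests.
#'
#' @param scenario A [scenario_config()].
#' @param params [receptor_params()] used for the mechanistic pEGFR
#'   curve (`r_scale` is taken from the scenario).
#' @param seed Integer seed.
#' @param noise_cv Override of the scenario's noise level (optional).
#' @return List with `timecourse` (a [timecourse_data()] with targets
#'   `pEGFR` and `pERK`), `latent` (data frame of noise-free curves),
#'   `fit_data` (a [fit_dataset()] of the replicate-mean pEGFR series,
#'   normalized to the 10-min point of this scenario), `params`,
#'   `scenario` and `seed`.
#' @export
gen_timecourse <- function(scenario, params = receptor_params(),
                           seed = 1L, noise_cv = scenario$noise_cv) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(params, "receptor_params"))
  tt <- scenario$sampling_times
  p <- params
  p$r_scale <- scenario$r_scale
  p <- do.call(receptor_params, unclass(p))
  sim_times <- if (tt[1L] == 0) tt else c(0, tt)
  traj <- simulate_receptor(p, scenario$ligand, sim_times)
  pegfr <- readout(traj, "pEGFR_total")[match(tt, traj$times)]
  perk <- perk_curve(tt, scenario$pERK_shape)

  set.seed(seed)
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  rows <- list()
  for (rep_i in seq_len(scenario$n_replicates)) {
    for (target in c("pEGFR", "pERK")) {
      latent <- if (target == "pEGFR") pegfr else perk
      noisy <- if (sdlog > 0) {
        latent * stats::rlnorm(length(latent), -sdlog^2 / 2, sdlog)
      } else latent
      rows[[length(rows) + 1L]] <- data.frame(
        condition = scenario$name, target = target, replicate = rep_i,
        time_min = tt, intensity = noisy)
    }
  }
  tc <- timecourse_data(do.call(rbind, rows))

  # replicate-mean pEGFR, normalized to this scenario's 10-min value
  ref_time <- if (10 %in% tt) 10 else tt[which.max(pegfr)]
  pe <- tc[tc$target == "pEGFR", , drop = FALSE]
  mean_pe <- as.numeric(tapply(pe$intensity, pe$time_min, mean))
  ref_val <- mean_pe[match(ref_time, sort(unique(pe$time_min)))]
  fit_data <- fit_dataset(
    fit_series(scenario$name, scenario$ligand, r_scale = scenario$r_scale,
               readout = "pEGFR_total", times = tt,
               observed = mean_pe / ref_val),
    reference = list(condition = scenario$name, time = ref_time))

  list(timecourse = tc,
       latent = data.frame(time_min = tt, pEGFR = pegfr, pERK = perk),
       fit_data = fit_data, params = p, scenario = scenario, seed = seed)
}
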