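#' Densitometry time-course container
#'
#' Validates and classes a long-format table of band intensities, the
#' quantified output of western-blot densitometry: one row per condition,
#' target, replicate and time point.
#'
#' @param df Data frame with columns `condition`, `target`, `replicate`,
#'   `time_min`, `intensity`. Within each (condition, target, replicate)
#'   the times must be strictly increasing and intensities non-negative.
#' @param normalized Logical flag: has the table already been normalized
#'   to a reference band?
#' @param reference The normalization reference (list with `condition`,
#'   `target`, `time`) when `normalized` is `TRUE`.
#' @return A data frame of class `timecourse_data`.
#' @seealso [normalize_timecourse()], [integrated_signal()]
#' @export
timecourse_data <- function(df, normalized = FALSE, reference = NULL) {
  need <- c("condition", "target", "replicate", "time_min", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  if (!is.numeric(df$time_min) || !is.numeric(df$intensity)) {
    stop("time_min and intensity must be numeric", call. = FALSE)
  }
  if (any(df$intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  key <- interaction(df$condition, df$target, df$replicate, drop = TRUE)
  for (k in levels(key)) {
    t <- df$time_min[key == k]
    if (any(diff(t) <= 0)) {
      stop("times not strictly increasing within replicate group ", k,
           call. = FALSE)
    }
  }
  structure(df, class = c("timecourse_data", "data.frame"),
            normalized = isTRUE(normalized), reference = reference)
}

.tc_is_normalized <- function(tc) isTRUE(attr(tc, "normalized"))

#' Normalize a time course to a reference band
#'
#' Divides every intensity by the intensity of the reference band
#' (a given condition, target and time). The reference is matched per
#' replicate when the same replicate id carries a reference measurement;
#' otherwise the mean reference intensity across replicates is used.
#' After normalization the reference point maps to 1.0 (exactly, for
#' replicate-matched references). Normalizing an already-normalized table
#' is a no-op.
#'
#' @param tc A [timecourse_data()] table.
#' @param reference List with `condition`, `target`, `time` naming the
#'   reference band, e.g. pERK in EGF-treated E-cells at 10 min.
#' @return A normalized `timecourse_data`.
#' @export
normalize_timecourse <- function(tc, reference) {
  stopifnot(inherits(tc, "timecourse_data"))
  if (.tc_is_normalized(tc)) return(tc)
  stopifnot(all(c("condition", "target", "time") %in% names(reference)))
  ref_rows <- tc$condition == reference$condition &
    tc$target == reference$target & tc$time_min == reference$time
  if (!any(ref_rows)) {
    stop(errorCondition("reference point not present in the dataset",
                        class = c("invalid_reference", "error")))
  }
  ref_by_rep <- tapply(tc$intensity[ref_rows], tc$replicate[ref_rows], mean)
  ref_mean <- mean(tc$intensity[ref_rows])
  if (ref_mean <= 0 || any(ref_by_rep <= 0)) {
    stop(errorCondition("reference intensity is zero",
                        class = c("invalid_reference", "error")))
  }
  denom <- ref_by_rep[as.character(tc$replicate)]
  denom[is.na(denom)] <- ref_mean
  out <- tc
  out$intensity <- tc$intensity / as.numeric(denom)
  attr(out, "normalized") <- TRUE
  attr(out, "reference") <- reference
  out
}

.single_group <- function(tc, condition, target) {
  if (!is.null(condition)) tc <- tc[tc$condition == condition, , drop = FALSE]
  if (!is.null(target)) tc <- tc[tc$target == target, , drop = FALSE]
  if (nrow(tc) == 0L) stop("no rows match the requested group", call. = FALSE)
  if (length(unique(tc$condition)) > 1L || length(unique(tc$target)) > 1L) {
    stop("multiple condition/target groups present; specify `condition` ",
         "and `target`", call. = FALSE)
  }
  tc
}

#' Integrated signal strength (area under the curve)
#'
#' Computes, per replicate, the trapezoidal area under the normalized
#' intensity curve over a stated window, then summarizes across
#' replicates. When a replicate is sampled beyond the window edges the
#' curve is linearly interpolated to the edges, so the trapezoid rule is
#' exact for piecewise-linear signals. This is the "integrated signal
#' strength" summary of pathway activation, e.g. over 0-60 min (1 h) or
#' 0-310 min (5 h) windows.
#'
#' @param tc A normalized [timecourse_data()].
#' @param window Numeric `c(start, end)` in minutes, `start < end`.
#' @param condition,target Select one condition/target group when the
#'   table holds several.
#' @return An object of class `signal_summary`: list with `auc` (mean
#'   across replicates), `auc_sd`, `auc_replicates`, `window`,
#'   `n_replicates`, `condition`, `target`.
#' @export
integrated_signal <- function(tc, window, condition = NULL, target = NULL) {
  stopifnot(inherits(tc, "timecourse_data"))
  if (!.tc_is_normalized(tc)) {
    stop("time course must be normalized first; see normalize_timecourse()",
         call. = FALSE)
  }
  if (length(window) != 2L || !(window[1L] < window[2L])) {
    stop("window must be c(start, end) with start < end", call. = FALSE)
  }
  tc <- .single_group(tc, condition, target)
  reps <- unique(tc$replicate)
  aucs <- vapply(reps, function(r) {
    d <- tc[tc$replicate == r, , drop = FALSE]
    t <- d$time_min; y <- d$intensity
    if (length(t) < 2L || min(t) > window[1L] || max(t) < window[2L]) {
      stop(errorCondition(
        sprintf("replicate %s does not cover the window [%g, %g]",
                r, window[1L], window[2L]),
        class = c("insufficient_coverage", "error")))
    }
    grid <- sort(unique(c(window, t[t > window[1L] & t < window[2L]])))
    yi <- stats::approx(t, y, xout = grid)$y
    pracma::trapz(grid, yi)
  }, numeric(1L))
  structure(list(auc = mean(aucs),
                 auc_sd = if (length(aucs) > 1L) stats::sd(aucs) else NA_real_,
                 auc_replicates = as.numeric(aucs),
                 window = as.numeric(window),
                 n_replicates = length(aucs),
                 condition = unique(tc$condition),
                 target = unique(tc$target)),
            class = "signal_summary")
}

#' @export
print.signal_summary <- function(x, ...) {
  cat(sprintf(
    "<signal_summary> %s/%s: AUC = %.4g +/- %.3g over [%g, %g] min (n = %d)\n",
    x$condition, x$target, x$auc,
    ifelse(is.na(x$auc_sd), 0, x$auc_sd),
    x$window[1L], x$window[2L], x$n_replicates))
  invisible(x)
}

#' Fold change between two integrated signals
#'
#' @param a,b [integrated_signal()] summaries over matching windows.
#' @return `a$auc / b$auc`, a positive scalar (e.g. the 10-fold lower
#'   1-h integrated EGFR signal under AREG vs EGF is
#'   `fold_change(egf, areg) = 10`).
#' @export
fold_change <- function(a, b) {
  stopifnot(inherits(a, "signal_summary"), inherits(b, "signal_summary"))
  if (!isTRUE(all.equal(a$window, b$window))) {
    stop(errorCondition("windows of the two summaries differ",
                        class = c("window_mismatch", "error")))
  }
  if (b$auc <= 0) {
    stop(errorCondition("denominator AUC is zero",
                        class = c("undefined_ratio", "error")))
  }
  a$auc / b$auc
}

#' Detect the onset of ERK re-activation
#'
#' Operationalizes "re-activation after the initial transient": on the
#' replicate-mean signal, find the global early peak, then the subsequent
#' trough (minimum after the peak); the onset is the earliest time after
#' the trough at which the signal exceeds
#' `trough + rise_fraction * (peak - trough)` and does not fall back below
#' that level at the next sample. Returns `NA` (with a `reason`
#' attribute) when no re-activation exists, e.g. for monotonically
#' decaying signals.
#'
#' @param tc A normalized [timecourse_data()] with at least 5 time points
#'   spanning an initial peak.
#' @param rise_fraction Fraction of the peak-trough amplitude that must be
#'   regained (default 0.2).
#' @param condition,target Group selection as in [integrated_signal()].
#' @return Onset time in minutes, or `NA_real_` with attribute `reason`.
#' @export
reactivation_onset <- function(tc, rise_fraction = 0.2,
                               condition = NULL, target = NULL) {
  stopifnot(inherits(tc, "timecourse_data"), rise_fraction >= 0)
  if (!.tc_is_normalized(tc)) {
    stop("time course must be normalized first", call. = FALSE)
  }
  tc <- .single_group(tc, condition, target)
  mean_y <- tapply(tc$intensity, tc$time_min, mean)
  t <- as.numeric(names(mean_y))
  o <- order(t)
  t <- t[o]; y <- as.numeric(mean_y)[o]
  if (length(t) < 5L) {
    stop("need at least 5 time points", call. = FALSE)
  }
  i_peak <- which.max(y)
  if (i_peak >= length(y)) {
    return(structure(NA_real_, reason = "no-peak"))
  }
  after <- seq(i_peak + 1L, length(y))
  i_trough <- after[which.min(y[after])]
  if (i_trough >= length(y)) {
    return(structure(NA_real_, reason = "no-reactivation"))
  }
  thr <- y[i_trough] + rise_fraction * (y[i_peak] - y[i_trough])
  for (k in seq(i_trough + 1L, length(y))) {
    if (y[k] > thr && (k == length(y) || y[k + 1L] >= thr)) {
      return(t[k])
    }
  }
  structure(NA_real_, reason = "no-reactivation")
}
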