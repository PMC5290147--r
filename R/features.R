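# ---- per-curve feature extraction -----------------------------------------
#
# The vendor software used in the original assay is proprietary; every rule
# here is explicit and configurable: baseline tail = final 30% of retract
# travel, one pass of 3 x MAD outlier rejection in the linear tail fit,
# robust noise scale = MAD/0.6745 of the tail residuals, rupture steps called
# at k_sigma = 5 with a 5-sample window.

retract_tail_idx <- function(height, tail_fraction) {
  rng <- range(height)
  which(height >= rng[1] + (1 - tail_fraction) * (rng[2] - rng[1]))
}

#' Baseline-correct the retract segment of a force curve
#'
#' Fits a straight line (force versus height) to the far-from-surface tail of
#' the retract segment — by default the final 30% of the travel — using least
#' squares with one pass of 3 x MAD outlier rejection, and subtracts the
#' fitted baseline from the whole retract segment. The robust noise scale
#' (scaled MAD of the tail residuals, consistent for a Gaussian s.d.) is
#' stored on the returned curve and reused by the event detector. The
#' operation is idempotent: correcting twice returns (numerically) the same
#' curve.
#'
#' @param curve a [force_curve()].
#' @param tail_fraction fraction of retract travel treated as baseline tail
#'   (default 0.30); must contain at least 10 samples.
#' @return List with `curve` (corrected; attributes `baseline_corrected`,
#'   `noise_sd_robust`), `intercept` (N), `slope` (N/m) and `noise_sd` (N).
#' @export
correct_baseline <- function(curve, tail_fraction = 0.30) {
  validate_force_curve(curve)
  h <- curve$segments$retract$height
  f <- curve$segments$retract$force
  idx <- retract_tail_idx(h, tail_fraction)
  if (length(idx) < 10L) stop("baseline tail has fewer than 10 samples")
  x <- h[idx]; y <- f[idx]
  if (all(is.na(y))) stop("baseline tail is all NA")
  fit <- simple_lm(x, y)
  res <- y - fit["intercept"] - fit["slope"] * x
  s <- stats::mad(res)
  if (s > 0) {
    keep <- abs(res - stats::median(res)) <= 3 * s
    if (sum(keep) >= 10L) {
      fit <- simple_lm(x[keep], y[keep])
      res <- y - fit["intercept"] - fit["slope"] * x
    }
  }
  curve$segments$retract$force <- f - fit["intercept"] - fit["slope"] * h
  attr(curve, "baseline_corrected") <- TRUE
  attr(curve, "noise_sd_robust") <- stats::mad(res)
  list(curve = curve, intercept = unname(fit["intercept"]),
       slope = unname(fit["slope"]),
       noise_sd = unname(stats::mad(res)))
}

ensure_corrected <- function(curve, tail_fraction = 0.30) {
  if (isTRUE(attr(curve, "baseline_corrected"))) curve
  else correct_baseline(curve, tail_fraction)$curve
}

#' Adhesion force at maximum cantilever deflection
#'
#' The adhesion force of a curve is the magnitude of the largest downward
#' (adhesive) deflection of the baseline-corrected retract segment:
#' `-min(force)`, clipped at zero for pure-noise curves. Baseline correction
#' is applied automatically when the curve has not been corrected yet.
#'
#' @param curve a [force_curve()].
#' @param tail_fraction passed to [correct_baseline()] when needed.
#' @return Adhesion force in newtons (>= 0).
#' @export
extract_adhesion_force <- function(curve, tail_fraction = 0.30) {
  validate_force_curve(curve)
  curve <- ensure_corrected(curve, tail_fraction)
  max(0, -min(curve$segments$retract$force))
}

#' Detect rupture events on the retract segment
#'
#' A rupture is an abrupt upward force step after a loading (negative)
#' excursion: unbinding of a molecular link releases the cantilever towards
#' the baseline. The detector compares the mean force over the `window`
#' samples after each point with the mean over the `window` samples before
#' it; a candidate requires (i) a windowed step larger than
#' `k_sigma * noise_sd_robust`, (ii) a preceding negative excursion (the
#' pre-window mean below `-k_sigma * noise_sd_robust`), and (iii) sharpness —
#' the largest single-sample jump in the neighbourhood carrying at least half
#' of the windowed step, which separates genuine discontinuities from smooth
#' unloading ramps. Runs of neighbouring candidates are merged into one event
#' located at the largest single-sample jump.
#'
#' @param curve a [force_curve()] (baseline-corrected automatically).
#' @param k_sigma detection threshold in units of the robust noise s.d.
#'   (> 0, default 5).
#' @param window step window in samples (default 5).
#' @param tail_fraction passed to [correct_baseline()] when needed.
#' @return Data frame with columns `height_m` and `step_N`, sorted by height
#'   (zero rows when no event is found).
#' @export
detect_rupture_events <- function(curve, k_sigma = 5, window = 5L,
                                  tail_fraction = 0.30) {
  if (k_sigma <= 0) stop("'k_sigma' must be > 0")
  validate_force_curve(curve)
  curve <- ensure_corrected(curve, tail_fraction)
  f <- curve$segments$retract$force
  h <- curve$segments$retract$height
  n <- length(f)
  w <- as.integer(window)
  if (n < 2L * w + 2L) return(data.frame(height_m = numeric(), step_N = numeric()))
  sigma <- max(attr(curve, "noise_sd_robust"), 1e-16)

  cs <- c(0, cumsum(f))
  i <- (w + 1L):(n - w)                      # candidate jump indices (f[i-1] -> f[i])
  pre <- (cs[i] - cs[i - w]) / w             # mean f[(i-w) .. (i-1)]
  post <- (cs[i + w] - cs[i]) / w            # mean f[i .. (i+w-1)]
  stat <- post - pre
  cand <- which(stat > k_sigma * sigma & pre < -k_sigma * sigma)
  if (!length(cand)) return(data.frame(height_m = numeric(), step_N = numeric()))

  jump <- f[i] - f[i - 1L]                   # single-sample differences
  grp <- cumsum(c(1L, diff(cand) > w))
  out <- lapply(split(cand, grp), function(g) {
    j <- g[which.max(jump[g])]
    if (jump[j] < 0.5 * stat[j]) return(NULL)   # smooth ramp, not a step
    data.frame(height_m = h[i[j]], step_N = stat[j])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(height_m = numeric(), step_N = numeric()))
  out[order(out$height_m), , drop = FALSE]
}

#' Call specific binding on a single-molecule curve
#'
#' A curve counts as a specific binding event when at least one rupture event
#' is detected and the corrected force minimum lies below
#' `-k_sigma * noise_sd_robust`.
#'
#' @inheritParams detect_rupture_events
#' @return Logical scalar.
#' @export
call_specific_binding <- function(curve, k_sigma = 5, window = 5L,
                                  tail_fraction = 0.30) {
  curve <- ensure_corrected(curve, tail_fraction)
  ev <- detect_rupture_events(curve, k_sigma = k_sigma, window = window)
  sigma <- max(attr(curve, "noise_sd_robust"), 1e-16)
  nrow(ev) >= 1L && min(curve$segments$retract$force) < -k_sigma * sigma
}

#' Batch feature extraction over a list of curves
#'
#' @param curves list of [force_curve()]s.
#' @param k_sigma,window,tail_fraction processing parameters, see
#'   [detect_rupture_events()] and [correct_baseline()].
#' @return Data frame with one row per curve: `curve_id`, `cell_id`,
#'   `condition`, `contact_time_s`, `adhesion_force_N`, `n_events`,
#'   `specific_binding`, `noise_sd_N`, `baseline_intercept_N`,
#'   `baseline_slope_N_per_m`.
#' @export
extract_features <- function(curves, k_sigma = 5, window = 5L,
                             tail_fraction = 0.30) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  rows <- lapply(curves, function(cu) {
    cb <- correct_baseline(cu, tail_fraction)
    ev <- detect_rupture_events(cb$curve, k_sigma = k_sigma, window = window)
    sigma <- max(attr(cb$curve, "noise_sd_robust"), 1e-16)
    data.frame(
      curve_id = cu$curve_id, cell_id = cu$cell_id, condition = cu$condition,
      contact_time_s = cu$meta$contact_time %||% NA_real_,
      adhesion_force_N = max(0, -min(cb$curve$segments$retract$force)),
      n_events = nrow(ev),
      specific_binding = nrow(ev) >= 1L &&
        min(cb$curve$segments$retract$force) < -k_sigma * sigma,
      noise_sd_N = cb$noise_sd,
      baseline_intercept_N = cb$intercept,
      baseline_slope_N_per_m = cb$slope)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cell binding probability from specific-binding calls
#'
#' The binding probability of a condition is estimated per cell as the
#' fraction of that cell's curves called bound (the per-cell binomial MLE);
#' the reported statistic is the mean and s.d. over cells, with the pooled
#' curve count as the published `n`. With a single cell the s.d. is
#' undefined; it is reported as 0 with `sd_defined = FALSE` rather than
#' propagating `NA`.
#'
#' @param calls data frame with columns `cell_id` and `bound` (logical),
#'   e.g. the `specific_binding` column of [extract_features()] or the
#'   `bound` column of a simulation truth table.
#' @return List with `per_cell` (named vector of per-cell fractions),
#'   `mean`, `sd`, `sd_defined`, `n_cells`, `n_curves`.
#' @export
estimate_binding_probability <- function(calls) {
  stopifnot(is.data.frame(calls))
  if (!all(c("cell_id", "bound") %in% names(calls)))
    stop("'calls' needs columns 'cell_id' and 'bound'")
  if (!nrow(calls)) stop("empty group: no curves to estimate from")
  p_i <- tapply(as.logical(calls$bound), calls$cell_id, mean)
  p_i <- p_i[!is.na(p_i)]
  if (!length(p_i)) stop("empty group: no curves to estimate from")
  sd_def <- length(p_i) > 1L
  list(per_cell = c(p_i), mean = mean(p_i),
       sd = if (sd_def) stats::sd(p_i) else 0,
       sd_defined = sd_def, n_cells = length(p_i), n_curves = nrow(calls))
}

#' Spring-constant calibration by the thermal-noise (equipartition) method
#'
#' Removes a linear trend from the deflection trace and applies the
#' equipartition theorem, `k = k_B T / var(deflection)`. This is the simple
#' equipartition form (no power-spectral-density fit); it is exact for the
#' white-noise traces produced by [simulate_thermal_noise()] and is
#' scale-equivariant: scaling the trace by `c` divides the estimate by `c^2`.
#'
#' @param trace deflection trace in metres (>= 1000 samples).
#' @param temperature bath temperature, K (> 0).
#' @return Spring constant estimate, N/m.
#' @export
#' @examples
#' tr <- simulate_thermal_noise(0.06, 310, 1e5, seed = 1)
#' calibrate_spring_constant(tr, 310)
calibrate_spring_constant <- function(trace, temperature = 310) {
  if (!is.numeric(trace) || length(trace) < 1000L)
    stop("'trace' must be numeric with at least 1000 samples")
  stop_if_not_scalar_number(temperature, "temperature")
  if (temperature <= 0) stop("'temperature' must be > 0")
  x <- seq_along(trace)
  fit <- simple_lm(x, trace)
  res <- trace - fit["intercept"] - fit["slope"] * x
  v <- sum(res^2) / (length(res) - 2L)
  if (v <= 0) stop("zero-variance trace: cannot calibrate")
  .kB * temperature / v
}
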