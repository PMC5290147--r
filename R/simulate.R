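#' Construct a force-distance curve object
#'
#' A force curve is the raw SCFS measurement unit: ordered approach, dwell
#' and retract segments of piezo height (m) versus vertical force (N), plus
#' acquisition metadata. The retract segment is mandatory; heights must be
#' monotone within each segment and all values finite.
#'
#' @param curve_id,cell_id identifiers (strings).
#' @param segments named list with elements `approach`, `dwell`, `retract`,
#'   each a list with numeric vectors `height` and `force` of equal length.
#' @param meta list of acquisition metadata (`spring_constant`,
#'   `retract_speed`, `setpoint_force`, `contact_time`, `sampling_rate`).
#' @param condition condition label.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(curve_id, segments, meta = list(),
                        condition = NA_character_, cell_id = NA_character_) {
  x <- structure(list(curve_id = curve_id, segments = segments, meta = meta,
                      condition = condition, cell_id = cell_id),
                 class = "force_curve")
  validate_force_curve(x)
  x
}

validate_force_curve <- function(x) {
  if (!inherits(x, "force_curve")) stop("not a force_curve")
  if (is.null(x$segments$retract)) stop("retract segment is mandatory")
  for (nm in names(x$segments)) {
    seg <- x$segments[[nm]]
    h <- seg$height; f <- seg$force
    if (length(h) != length(f) || length(h) < 2L)
      stop(sprintf("segment '%s': height/force must have equal length >= 2", nm))
    if (any(!is.finite(h)) || any(!is.finite(f)))
      stop(sprintf("segment '%s': non-finite values", nm))
    d <- diff(h)
    if (!(all(d >= 0) || all(d <= 0)))
      stop(sprintf("segment '%s': heights must be monotone", nm))
  }
  invisible(x)
}

#' @export
print.force_curve <- function(x, ...) {
  n <- vapply(x$segments, function(s) length(s$height), 0L)
  cat(sprintf("<force_curve> %s (%s, cell %s)\n  segments: %s\n",
              x$curve_id, x$condition, x$cell_id,
              paste(sprintf("%s[%d]", names(n), n), collapse = " ")))
  if (isTRUE(attr(x, "baseline_corrected"))) cat("  baseline-corrected\n")
  invisible(x)
}

#' Simulate a retract force-distance curve with known adhesion and ruptures
#'
#' Builds a retract segment whose baseline-corrected global minimum equals
#' exactly `-true_adhesion_force` before noise. The clean curve consists of a
#' detachment well (force ramps linearly from 0 at contact down to
#' `-true_adhesion_force` at 8% of the travel, then recovers to baseline by
#' 35%), optional discrete rupture events — short loading ramps ending in an
#' upward force step at the given positions — and an event-free baseline tail
#' over at least the final 30% of the travel. Linear baseline drift
#' (`acq$drift_slope` per metre of height) and additive Gaussian noise
#' (`acq$noise_sd`) are applied last. Small approach and dwell segments are
#' attached so the object is a complete curve.
#'
#' @param true_adhesion_force adhesion force magnitude, N (>= 0). Must be >=
#'   every event step so the global minimum is exactly its negative.
#' @param events list of `c(position_m, step_N)` pairs (or a 2-column
#'   matrix): rupture positions along the retract travel, in
#'   `(0.35, 0.70] * retract_distance`, and positive step sizes.
#' @param acq an [acquisition_params()] object.
#' @param seed optional integer; when given the curve is reproducible and the
#'   global RNG state is left untouched.
#' @param curve_id,cell_id,condition,contact_time metadata.
#' @return A [force_curve()] object.
#' @export
#' @examples
#' acq <- acquisition_params(noise_sd = 0)
#' cu <- simulate_retract_curve(1.5e-9, acq = acq)
#' -min(cu$segments$retract$force)  # exactly 1.5e-9
simulate_retract_curve <- function(true_adhesion_force, events = list(),
                                   acq = acquisition_params(), seed = NULL,
                                   curve_id = "curve", cell_id = NA_character_,
                                   condition = NA_character_,
                                   contact_time = NA_real_) {
  stop_if_not_scalar_number(true_adhesion_force, "true_adhesion_force")
  if (true_adhesion_force < 0) stop("'true_adhesion_force' must be >= 0")
  stopifnot(inherits(acq, "acquisition_params"))
  n <- max(60L, as.integer(round(
    acq$retract_distance / acq$retract_speed * acq$sampling_rate)))
  h <- seq(0, acq$retract_distance, length.out = n)
  f <- numeric(n)

  ip <- max(3L, as.integer(round(0.08 * n)))   # well apex index
  irec <- as.integer(round(0.35 * n))          # back at baseline
  if (true_adhesion_force > 0) {
    f[1:ip] <- seq(0, -true_adhesion_force, length.out = ip)
    f[ip:irec] <- seq(-true_adhesion_force, 0, length.out = irec - ip + 1L)
  }

  ev <- normalize_events(events)
  if (nrow(ev)) {
    if (any(ev$step > true_adhesion_force + 1e-18))
      stop("event steps must not exceed 'true_adhesion_force'")
    if (any(ev$position <= h[irec] | ev$position > 0.7 * acq$retract_distance))
      stop("event positions must lie in (0.35, 0.70] of the retract travel")
    ev <- ev[order(ev$position), , drop = FALSE]
    prev <- irec
    for (j in seq_len(nrow(ev))) {
      ie <- which.min(abs(h - ev$position[j]))
      is <- max(prev + 1L, ie - as.integer(round(0.08 * n)))
      if (ie - is < 2L) stop("rupture events too close together to resolve")
      ramp <- seq_len(ie - is)
      f[is:(ie - 1L)] <- f[is:(ie - 1L)] - ev$step[j] * ramp / (ie - is)
      prev <- ie
    }
  }

  true_min <- -max(true_adhesion_force, if (nrow(ev)) max(ev$step) else 0)
  f <- f + acq$drift_slope * h
  if (acq$noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(n, 0, acq$noise_sd))

  # minimal approach (height decreasing towards contact) and dwell segments
  n_app <- 50L
  h_app <- seq(acq$retract_distance, 0, length.out = n_app)
  f_app <- c(numeric(n_app - 5L),
             seq(0, acq$setpoint_force, length.out = 5L))
  seg <- list(approach = list(height = h_app, force = f_app),
              dwell = list(height = c(0, 0),
                           force = rep(acq$setpoint_force, 2L)),
              retract = list(height = h, force = f))
  cu <- force_curve(curve_id, seg,
                    meta = list(spring_constant = acq$spring_constant,
                                retract_speed = acq$retract_speed,
                                setpoint_force = acq$setpoint_force,
                                sampling_rate = acq$sampling_rate,
                                contact_time = contact_time),
                    condition = condition, cell_id = cell_id)
  attr(cu, "true_min") <- true_min
  cu
}

normalize_events <- function(events) {
  if (is.null(events) || (is.list(events) && !length(events)))
    return(data.frame(position = numeric(), step = numeric()))
  if (is.matrix(events)) events <- asplit(events, 1)
  pos <- vapply(events, function(e) e[[1]], 0)
  step <- vapply(events, function(e) e[[2]], 0)
  if (any(step <= 0)) stop("event steps must be > 0")
  data.frame(position = pos, step = step)
}

#' Simulate one single-molecule force curve with latent binding state
#'
#' With probability `cond$p_bind` the curve carries one specific rupture
#' event whose force is drawn from a truncated normal (default mean 60 pN,
#' s.d. 15 pN, floor 20 pN) at a uniform position in the mid-retract;
#' otherwise the curve is bare noisy baseline. The latent bound state and
#' rupture force are recorded in the accompanying truth record.
#'
#' @param cond a [condition_spec()]; only `p_bind` is used.
#' @param acq acquisition preset, default [sm_acquisition_params()].
#' @param seed optional integer seed.
#' @param rupture_mean,rupture_sd,rupture_floor truncated-normal parameters
#'   of the rupture-force distribution, N.
#' @param curve_id,cell_id,contact_time metadata.
#' @return List with elements `curve` (a [force_curve()]) and `truth`
#'   (one-row data frame: curve_id, cell_id, condition, contact_time_s,
#'   true_adhesion_force_N, bound, true_rupture_force_N).
#' @export
simulate_single_molecule_curve <- function(cond, acq = sm_acquisition_params(),
                                           seed = NULL,
                                           rupture_mean = 6e-11,
                                           rupture_sd = 1.5e-11,
                                           rupture_floor = 2e-11,
                                           curve_id = "sm", cell_id = "cell",
                                           contact_time = 0.1) {
  stopifnot(inherits(cond, "condition_spec"), inherits(acq, "acquisition_params"))
  with_seed(seed, {
    bound <- stats::runif(1) < cond$p_bind
    if (bound) {
      repeat {
        f_rup <- stats::rnorm(1, rupture_mean, rupture_sd)
        if (f_rup >= rupture_floor) break
      }
      pos <- stats::runif(1, 0.40, 0.65) * acq$retract_distance
      cu <- simulate_retract_curve(f_rup, list(c(pos, f_rup)), acq = acq,
                                   curve_id = curve_id, cell_id = cell_id,
                                   condition = cond$name,
                                   contact_time = contact_time)
    } else {
      f_rup <- NA_real_
      cu <- simulate_retract_curve(0, acq = acq, curve_id = curve_id,
                                   cell_id = cell_id, condition = cond$name,
                                   contact_time = contact_time)
    }
    list(curve = cu,
         truth = data.frame(curve_id = curve_id, cell_id = cell_id,
                            condition = cond$name,
                            contact_time_s = contact_time,
                            true_adhesion_force_N = ifelse(bound, f_rup, 0),
                            bound = bound,
                            true_rupture_force_N = f_rup))
  })
}

#' Simulate a batch of single-molecule curves grouped by cell
#'
#' @param cond a [condition_spec()].
#' @param n_cells number of cells.
#' @param curves_per_cell curves recorded per cell.
#' @param acq acquisition preset.
#' @param seed master seed; per-cell substreams are derived with
#'   [substream_seed()] so the batch is reproducible cell by cell.
#' @param ... passed to [simulate_single_molecule_curve()].
#' @return List with `curves` (list of [force_curve()]) and `truth`
#'   (data frame, one row per curve).
#' @export
simulate_single_molecule_batch <- function(cond, n_cells, curves_per_cell,
                                           acq = sm_acquisition_params(),
                                           seed = 1L, ...) {
  curves <- vector("list", n_cells * curves_per_cell)
  truth <- vector("list", n_cells * curves_per_cell)
  k <- 0L
  for (i in seq_len(n_cells)) {
    cell <- sprintf("%s_c%02d", cond$name, i)
    cell_seed <- substream_seed(seed, cond$name, i, "sm")
    with_seed(cell_seed, {
      for (j in seq_len(curves_per_cell)) {
        k <- k + 1L
        out <- simulate_single_molecule_curve(
          cond, acq = acq, seed = NULL,
          curve_id = sprintf("%s_k%04d", cell, j), cell_id = cell, ...)
        curves[[k]] <- out$curve
        truth[[k]] <- out$truth
      }
    })
  }
  list(curves = curves, truth = do.call(rbind, truth))
}

#' Simulate a cantilever thermal-noise deflection trace
#'
#' I.i.d. Gaussian deflections with the equipartition variance
#' `k_B * T / k`, optionally with an added linear drift (ramping from 0 to
#' `drift` metres across the trace). The `T -> 0` limit is a zero-variance
#' trace.
#'
#' @param k spring constant, N/m (> 0).
#' @param temperature bath temperature, K (> 0; `0` allowed as the
#'   deterministic zero-noise limit).
#' @param n number of samples (>= 2).
#' @param drift total linear drift over the trace, m.
#' @param seed optional integer seed.
#' @return Numeric vector of deflections in metres.
#' @export
#' @examples
#' var(simulate_thermal_noise(0.06, 310, 1e5, seed = 1))  # ~ 7.13e-20 m^2
simulate_thermal_noise <- function(k, temperature = 310, n, drift = 0,
                                   seed = NULL) {
  stop_if_not_scalar_number(k, "k")
  stop_if_not_scalar_number(temperature, "temperature")
  if (k <= 0) stop("'k' must be > 0")
  if (temperature < 0) stop("'temperature' must be >= 0")
  if (n < 2) stop("'n' must be >= 2")
  sd <- sqrt(.kB * temperature / k)
  x <- if (sd > 0) with_seed(seed, stats::rnorm(n, 0, sd)) else numeric(n)
  x + seq(0, drift, length.out = n)
}

#' Draw one adhesion-force measurement for a cell
#'
#' The two-level variability model: a fixed multiplicative per-cell effect
#' scales the condition's mean force, additive Gaussian measurement noise is
#' applied, and the result is truncated at zero (a force cannot be negative).
#'
#' @param cond a [condition_spec()].
#' @param t contact time, s.
#' @param cell_effect positive multiplicative cell effect (drawn once per
#'   cell, lognormal with mean 1 and relative s.d. `cond$cell_sd_rel`).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return Nonnegative force draw(s), N.
#' @export
sample_cell_adhesion <- function(cond, t, cell_effect, n = 1L, seed = NULL) {
  stopifnot(inherits(cond, "condition_spec"))
  stop_if_not_scalar_number(cell_effect, "cell_effect")
  if (cell_effect <= 0) stop("'cell_effect' must be > 0")
  mu <- cell_effect * mean_adhesion_force(cond, t)
  noise <- if (cond$meas_sd > 0)
    with_seed(seed, stats::rnorm(n, 0, cond$meas_sd)) else numeric(n)
  pmax(0, mu + noise)
}

# lognormal(mean 1, relative sd cv) parameters
lognormal_pars <- function(cv) {
  sdlog <- sqrt(log(1 + cv^2))
  c(meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Full generative specification of a simulated SCFS experiment
#'
#' Defaults follow the reference protocol: contact times 5, 20, 50 and 120 s,
#' at least 10 cells per condition, one curve per cell and contact time (each
#' fibroblast probed once at every contact time).
#'
#' @param conditions list of [condition_spec()]s with unique names.
#' @param contact_times strictly increasing positive contact times, s.
#' @param n_cells cells per condition (>= 1).
#' @param curves_per_cell_per_time repeated curves per cell and time (>= 1).
#' @param acquisition an [acquisition_params()] object.
#' @param seed integer master seed; every random draw in the simulated
#'   experiment is derived from it, so a fixed configuration reproduces
#'   byte-identical output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(conditions = study_conditions(),
                              contact_times = c(5, 20, 50, 120),
                              n_cells = 10L, curves_per_cell_per_time = 1L,
                              acquisition = acquisition_params(),
                              seed = 1L) {
  stopifnot(is.list(conditions), length(conditions) >= 1L)
  if (!all(vapply(conditions, inherits, TRUE, "condition_spec")))
    stop("'conditions' must be a list of condition_spec objects")
  nms <- vapply(conditions, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate condition names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(conditions) <- nms
  if (any(contact_times <= 0) || any(diff(contact_times) <= 0))
    stop("'contact_times' must be strictly increasing and positive")
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (curves_per_cell_per_time < 1) stop("'curves_per_cell_per_time' must be >= 1")
  stopifnot(inherits(acquisition, "acquisition_params"))
  structure(list(conditions = conditions, contact_times = contact_times,
                 n_cells = as.integer(n_cells),
                 curves_per_cell_per_time = as.integer(curves_per_cell_per_time),
                 acquisition = acquisition, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a tidy adhesion-force dataset (force level, no curve synthesis)
#'
#' The fast generator for the statistics layer: draws the per-cell effects
#' and per-time adhesion forces of every condition without synthesising
#' force-distance curve arrays. Forces are identical in distribution to the
#' ones underlying [simulate_dataset()]. Ground truth (per-cell effects and
#' noise-free mean forces) is attached as attribute `"ground_truth"`.
#'
#' @param config a [simulation_config()].
#' @return An `adhesion_dataset`: data frame with columns `cell_id`,
#'   `condition`, `contact_time_s`, `adhesion_force_N` (class
#'   `c("adhesion_dataset", "data.frame")`).
#' @export
#' @examples
#' ds <- simulate_adhesion_dataset(simulation_config(seed = 7))
#' head(ds)
simulate_adhesion_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tt <- config$contact_times
  rows <- list(); truths <- list(); k <- 0L
  for (cond in config$conditions) {
    lp <- lognormal_pars(cond$cell_sd_rel)
    for (i in seq_len(config$n_cells)) {
      cell <- sprintf("%s_c%02d", cond$name, i)
      with_seed(substream_seed(config$seed, cond$name, i, "forces"), {
        eff <- stats::rlnorm(1, lp["meanlog"], lp["sdlog"])
        for (r in seq_len(config$curves_per_cell_per_time)) {
          mu <- eff * mean_adhesion_force(cond, tt)
          fr <- pmax(0, mu + stats::rnorm(length(tt), 0, cond$meas_sd))
          k <- k + 1L
          rows[[k]] <- data.frame(cell_id = cell, condition = cond$name,
                                  contact_time_s = tt, adhesion_force_N = fr)
          truths[[k]] <- data.frame(cell_id = cell, condition = cond$name,
                                    contact_time_s = tt, cell_effect = eff,
                                    true_mean_force_N = mu)
        }
      })
    }
  }
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  class(ds) <- c("adhesion_dataset", "data.frame")
  attr(ds, "ground_truth") <- do.call(rbind, truths)
  ds
}

as_adhesion_dataset <- function(df) {
  need <- c("cell_id", "condition", "contact_time_s", "adhesion_force_N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$adhesion_force_N < 0)) stop("adhesion forces must be >= 0")
  df <- as.data.frame(df)[need]
  class(df) <- c("adhesion_dataset", "data.frame")
  df
}

#' Simulate a complete curve-level SCFS experiment
#'
#' For each condition, `n_cells` cells each contribute
#' `curves_per_cell_per_time` force-distance curves at every contact time.
#' Per-(condition, cell) random substreams are derived from the master seed
#' by a counter scheme, so extending a configuration with a new condition
#' never perturbs the curves of existing ones; a fixed configuration yields
#' byte-identical output.
#'
#' @param config a [simulation_config()].
#' @return List with `curves` (list of [force_curve()]s) and `truth`
#'   (data frame: curve_id, cell_id, condition, contact_time_s,
#'   true_adhesion_force_N, bound, true_rupture_force_N).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tt <- config$contact_times
  curves <- list(); truth <- list(); k <- 0L
  for (cond in config$conditions) {
    lp <- lognormal_pars(cond$cell_sd_rel)
    for (i in seq_len(config$n_cells)) {
      cell <- sprintf("%s_c%02d", cond$name, i)
      with_seed(substream_seed(config$seed, cond$name, i, "curves"), {
        eff <- stats::rlnorm(1, lp["meanlog"], lp["sdlog"])
        for (t in tt) for (r in seq_len(config$curves_per_cell_per_time)) {
          fr <- pmax(0, eff * mean_adhesion_force(cond, t) +
                       stats::rnorm(1, 0, cond$meas_sd))
          k <- k + 1L
          id <- sprintf("%s_t%03ds_r%d", cell, as.integer(round(t)), r)
          curves[[k]] <- simulate_retract_curve(
            fr, acq = config$acquisition, seed = NULL, curve_id = id,
            cell_id = cell, condition = cond$name, contact_time = t)
          truth[[k]] <- data.frame(curve_id = id, cell_id = cell,
                                   condition = cond$name, contact_time_s = t,
                                   true_adhesion_force_N = fr, bound = NA,
                                   true_rupture_force_N = NA_real_)
        }
      })
    }
  }
  list(curves = curves, truth = do.call(rbind, truth))
}
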