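#' Define an experimental condition for the adhesion-force generator
#'
#' A condition describes one cell line / cantilever-coating combination as a
#' generative model of its adhesion kinetics. Mean adhesion force follows a
#' saturating exponential in contact time,
#' \deqn{F(t) = F_{floor} + F_{max} (1 - e^{-t/\tau}),}
#' the simplest monotone three-parameter shape consistent with adhesion that
#' strengthens with contact time towards a plateau. Per-cell variability is a
#' multiplicative lognormal effect (mean 1, relative s.d. `cell_sd_rel`) drawn
#' once per cell; within-cell scatter is additive Gaussian with s.d.
#' `meas_sd`, truncated at zero force. `p_bind` is the probability that a
#' short-contact, low-force (single-molecule) curve contains one specific
#' rupture event.
#'
#' @param name condition label, e.g. `"pKO-aV/b1"`. Must be non-empty.
#' @param f_max saturating plateau of the mean adhesion force above the
#'   floor, in newtons (>= 0).
#' @param tau saturation timescale in seconds (> 0).
#' @param f_floor nonspecific adhesion level in newtons (>= 0).
#' @param cell_sd_rel relative s.d. of the per-cell multiplicative effect
#'   (dimensionless, >= 0).
#' @param meas_sd within-cell measurement s.d. in newtons (>= 0).
#' @param p_bind single-molecule specific-binding probability in `[0, 1]`.
#' @return An object of class `condition_spec`.
#' @seealso [mean_adhesion_force()], [study_conditions()],
#'   [simulation_config()]
#' @export
#' @examples
#' cond <- condition_spec("pKO-b1", f_max = 3.6e-9, tau = 50,
#'                        f_floor = 2e-10, p_bind = 0.12)
#' mean_adhesion_force(cond, c(5, 20, 50, 120))
condition_spec <- function(name, f_max, tau, f_floor = 0,
                           cell_sd_rel = 0.25, meas_sd = 1.5e-10,
                           p_bind = 0.25) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  for (nm in c("f_max", "tau", "f_floor", "cell_sd_rel", "meas_sd", "p_bind"))
    stop_if_not_scalar_number(get(nm), nm)
  if (f_max < 0) stop("'f_max' must be >= 0")
  if (f_floor < 0) stop("'f_floor' must be >= 0")
  if (tau <= 0) stop("'tau' must be > 0")
  if (cell_sd_rel < 0) stop("'cell_sd_rel' must be >= 0")
  if (meas_sd < 0) stop("'meas_sd' must be >= 0")
  if (p_bind < 0 || p_bind > 1) stop("'p_bind' must be in [0, 1]")
  structure(list(name = name, f_max = f_max, tau = tau, f_floor = f_floor,
                 cell_sd_rel = cell_sd_rel, meas_sd = meas_sd,
                 p_bind = p_bind),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf(
    "<condition_spec> %s\n  F(t) = %.3g + %.3g*(1 - exp(-t/%g)) N; cell CV %.2f, meas sd %.3g N, p_bind %.2f\n",
    x$name, x$f_floor, x$f_max, x$tau, x$cell_sd_rel, x$meas_sd, x$p_bind))
  invisible(x)
}

#' Mean adhesion force of a condition at given contact times
#'
#' Evaluates the saturating-exponential mean model
#' `f_floor + f_max * (1 - exp(-t/tau))`. Non-decreasing in `t`; tends to
#' `f_floor` as `t -> 0` and to `f_floor + f_max` as `t -> Inf`.
#'
#' @param cond a [condition_spec()].
#' @param t contact time(s) in seconds, all >= 0.
#' @return Mean adhesion force(s) in newtons, same length as `t`.
#' @export
mean_adhesion_force <- function(cond, t) {
  stopifnot(inherits(cond, "condition_spec"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric")
  if (any(t < 0)) stop("contact time 't' must be >= 0")
  cond$f_floor + cond$f_max * (1 - exp(-t / cond$tau))
}

#' The four fibroblast conditions of the reference adhesion study
#'
#' Generative presets emulating the adhesion phenotypes of pan-integrin
#' knockout (pKO) mouse kidney fibroblasts and their integrin-reconstituted
#' lines probed on an RGD-containing fibronectin fragment: the bare pKO line
#' shows a constant, negligible adhesion floor; lines expressing aV-class
#' and/or a5b1 integrins strengthen adhesion with contact time; the
#' a5b1-only line reaches roughly twice the 120-s adhesion of the
#' double-expressing line (competition pattern). Single-molecule binding
#' probabilities follow the four measured regimes: 0.25 (both classes),
#' 0.40 (aV only active), 0.12 (a5b1 only active), 0.10 (no FN-binding
#' integrins, nonspecific).
#'
#' @return Named list of four [condition_spec()] objects:
#'   `pKO`, `pKO-aV`, `pKO-b1`, `pKO-aV/b1`.
#' @export
#' @examples
#' sapply(study_conditions(), function(k) mean_adhesion_force(k, 120))
study_conditions <- function() {
  list(
    "pKO"       = condition_spec("pKO",       f_max = 0,      tau = 50,
                                 f_floor = 2e-10, p_bind = 0.10),
    "pKO-aV"    = condition_spec("pKO-aV",    f_max = 1.5e-9, tau = 40,
                                 f_floor = 2e-10, p_bind = 0.40),
    "pKO-b1"    = condition_spec("pKO-b1",    f_max = 3.6e-9, tau = 50,
                                 f_floor = 2e-10, p_bind = 0.12),
    "pKO-aV/b1" = condition_spec("pKO-aV/b1", f_max = 1.6e-9, tau = 40,
                                 f_floor = 2e-10, p_bind = 0.25)
  )
}

#' Build a four-condition configuration that is exactly additive
#'
#' Constructs conditions `{0, A, B, AB}` sharing one saturation timescale so
#' that the additive null holds exactly in expectation at every contact time:
#' `mean(AB) + mean(0) = mean(A) + mean(B)`. Used to calibrate the
#' interaction test under its generative null.
#'
#' @param f_a,f_b plateau forces (N) of the two single-class conditions.
#' @param f_floor shared nonspecific floor (N).
#' @param tau shared saturation timescale (s).
#' @param ... further arguments passed to every [condition_spec()]
#'   (`cell_sd_rel`, `meas_sd`, `p_bind`).
#' @return Named list of four `condition_spec`s: `ctrl`, `A`, `B`, `AB`.
#' @export
additive_conditions <- function(f_a = 1.5e-9, f_b = 1.6e-9,
                                f_floor = 2e-10, tau = 40, ...) {
  list(
    ctrl = condition_spec("ctrl", f_max = 0,         tau = tau,
                          f_floor = f_floor, ...),
    A    = condition_spec("A",    f_max = f_a,       tau = tau,
                          f_floor = f_floor, ...),
    B    = condition_spec("B",    f_max = f_b,       tau = tau,
                          f_floor = f_floor, ...),
    AB   = condition_spec("AB",   f_max = f_a + f_b, tau = tau,
                          f_floor = f_floor, ...)
  )
}
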