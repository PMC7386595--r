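#' Novelty schedule
#'
#' The novelty signal is a scalar that jumps to 1 when the animal enters
#' the environment and decays exponentially with time constant `tau_n`.
#' It drives the interneuron-activity schedules (see [inhibition_at()]).
#' Optional reset times model protocols that artificially restore the
#' novel-environment inhibition levels mid-session.
#'
#' @param enabled If `FALSE` the environment is treated as permanently
#'   novel: the signal stays at 1 and inhibition is constant at its
#'   initial (novel-environment) values.
#' @param tau_n Decay time constant (ms).
#' @param t0 Session time of environment entry (ms).
#' @param reset_times Session times (ms) at which the signal is reset
#'   to 1.
#' @return An object of class `ca1_novelty`.
#' @export
novelty_schedule <- function(enabled = TRUE, tau_n = 1e5, t0 = 0,
                             reset_times = numeric(0)) {
  stopifnot(tau_n > 0, t0 >= 0, all(reset_times >= t0))
  structure(list(enabled = enabled, tau_n = tau_n, t0 = t0,
                 reset_times = sort(reset_times)),
            class = "ca1_novelty")
}

#' Novelty signal value
#'
#' `exp(-(t - t') / tau_n)` where `t'` is the most recent entry or reset
#' time not later than `t`. With the schedule disabled the signal is
#' held at 1 (permanently novel environment).
#'
#' @param t Session times (ms), `>= t0`.
#' @param sched A [novelty_schedule()].
#' @return Values in `(0, 1]`.
#' @export
novelty_value <- function(t, sched) {
  stopifnot(all(t >= sched$t0))
  if (!sched$enabled) return(rep(1, length(t)))
  ref <- vapply(t, function(ti) {
    marks <- c(sched$t0, sched$reset_times)
    max(marks[marks <= ti])
  }, numeric(1))
  exp(-(t - ref) / sched$tau_n)
}

#' Scheduled interneuron inhibition
#'
#' Dendritic and somatic inhibition interpolate between their
#' novel-environment values (novelty = 1) and familiar-environment
#' values (novelty = 0):
#' `I(t) = I_inf - (I_inf - I_0) n(t)`.
#' With the orderings `I_dend_0 < I_dend_inf` and
#' `I_soma_0 > I_soma_inf`, dendritic inhibition rises and somatic
#' inhibition falls as the environment becomes familiar.
#'
#' @param t Session times (ms).
#' @param sched A [novelty_schedule()].
#' @param params A [model_params()] object.
#' @return List with vectors `I_dend` and `I_soma`.
#' @export
inhibition_at <- function(t, sched, params) {
  n <- novelty_value(t, sched)
  list(
    I_dend = params$I_dend_inf - (params$I_dend_inf - params$I_dend_0) * n,
    I_soma = params$I_soma_inf - (params$I_soma_inf - params$I_soma_0) * n
  )
}

#' Induction / injection protocol
#'
#' A declarative description of an externally imposed perturbation: a
#' constant current injected into the dendrite or soma, or a
#' multiplicative suppression of dendritic inhibition, active while the
#' animal is inside a region of the track during a window of laps.
#'
#' @param kind One of `"dendritic_current"`, `"somatic_current"`,
#'   `"dendritic_disinhibition"`.
#' @param region Numeric length-2, start and end of the active arc as
#'   fractions of the track length, half-open `[start, end)`. `start >
#'   end` denotes an arc wrapping through the 0/L seam; `c(0, 1)` covers
#'   the whole track.
#' @param first_lap First active lap (1-based).
#' @param n_laps Number of consecutive active laps.
#' @param amplitude Current amplitude (a.u.) for the current kinds, or
#'   suppression fraction in `[0, 1]` for disinhibition (1 removes
#'   dendritic inhibition entirely inside the region).
#' @return An object of class `ca1_induction`.
#' @examples
#' # dendritic induction over 15% of the track, laps 100-102
#' induction_protocol("dendritic_current", region = c(0.875, 0.025),
#'                    first_lap = 100, n_laps = 3, amplitude = 10)
#' @export
induction_protocol <- function(kind = c("dendritic_current",
                                        "somatic_current",
                                        "dendritic_disinhibition"),
                               region = c(0, 1), first_lap = 1,
                               n_laps = 1, amplitude = 0) {
  kind <- match.arg(kind)
  stopifnot(length(region) == 2, all(region >= 0), all(region <= 1),
            first_lap >= 1, n_laps >= 1, amplitude >= 0)
  if (kind == "dendritic_disinhibition" && amplitude > 1) {
    stop("disinhibition suppression level must be in [0, 1]")
  }
  structure(list(kind = kind, region = as.numeric(region),
                 first_lap = as.integer(first_lap),
                 n_laps = as.integer(n_laps),
                 amplitude = amplitude),
            class = "ca1_induction")
}

in_region <- function(p_frac, region) {
  if (region[1] <= region[2]) {
    p_frac >= region[1] & p_frac < region[2]
  } else {
    p_frac >= region[1] | p_frac < region[2]
  }
}

#' External currents from a set of protocols
#'
#' Sums the contributions of all protocols active at lap `lap` and
#' position `p`. Current protocols add their amplitudes to the external
#' dendritic/somatic currents; disinhibition protocols combine into a
#' single multiplicative suppression applied to the scheduled dendritic
#' inhibition. Overlapping disinhibition protocols are rejected.
#'
#' @param p Position (track units).
#' @param lap Lap index (1-based).
#' @param protocols List of [induction_protocol()] objects.
#' @param L Track length.
#' @return List with `I_dend_ext`, `I_soma_ext`, `suppression` (the
#'   fraction of dendritic inhibition removed, 0 if none).
#' @export
protocol_currents <- function(p, lap, protocols, L) {
  out <- list(I_dend_ext = 0, I_soma_ext = 0, suppression = 0)
  if (!length(protocols)) return(out)
  n_dis <- 0
  for (pr in protocols) {
    active <- lap >= pr$first_lap && lap < pr$first_lap + pr$n_laps &&
      in_region(p / L, pr$region)
    if (!active) next
    if (pr$kind == "dendritic_current") {
      out$I_dend_ext <- out$I_dend_ext + pr$amplitude
    } else if (pr$kind == "somatic_current") {
      out$I_soma_ext <- out$I_soma_ext + pr$amplitude
    } else {
      n_dis <- n_dis + 1
      out$suppression <- pr$amplitude
    }
  }
  if (n_dis > 1) stop("overlapping disinhibition protocols")
  out
}
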