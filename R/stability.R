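#' Noise specification for the stability protocol
#'
#' Three noise models perturb a frozen network state:
#' \describe{
#'   \item{`presyn_field`}{Each input's place-field amplitude is
#'     multiplied by an independent draw from `Normal(1, N^2)`.}
#'   \item{`presyn_rate`}{Each input receives an additive, spatially
#'     untuned rate offset drawn from `Normal(0, N^2)` rectified at
#'     zero.}
#'   \item{`weights`}{Each synaptic weight receives an additive
#'     `Normal(0, N^2)` draw.}
#' }
#' All draws are made once per probe lap (one value per neuron per
#' sample), and are reproducible from `(seed, draw index)`.
#'
#' @param kind One of `"presyn_field"`, `"presyn_rate"`, `"weights"`.
#' @param amplitude Noise amplitude `N >= 0` (the standard deviation of
#'   the perturbing distribution).
#' @param n_samples Number of Monte-Carlo samples `N_noise`.
#' @param seed Integer base seed.
#' @return An object of class `ca1_noise`.
#' @export
noise_spec <- function(kind = c("presyn_field", "presyn_rate", "weights"),
                       amplitude = 0.1, n_samples = 100, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0, n_samples >= 1)
  structure(list(kind = kind, amplitude = amplitude,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "ca1_noise")
}

draw_seed <- function(spec, draw) {
  (spec$seed %% 1000003L) * 2039L + draw * 7L
}

#' Apply one noise draw to a frozen network state
#'
#' Returns a copy of the state with the perturbation of the given noise
#' kind applied; the input state is untouched. With `amplitude = 0` the
#' perturbed state is identical to the input.
#'
#' @param state A [session_state()] snapshot.
#' @param spec A [noise_spec()].
#' @param draw Sample index (1-based); together with `spec$seed` it
#'   fixes the random draw.
#' @return A perturbed `ca1_state`.
#' @export
perturb_network <- function(state, spec, draw = 1) {
  stopifnot(inherits(state, "ca1_state"), inherits(spec, "ca1_noise"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(draw_seed(spec, draw))
  # discard warm-up draws: the first variates after seeding correlate
  # with the seed value itself
  invisible(stats::runif(20))
  n <- length(state$pop$centers)
  N <- spec$amplitude
  out <- state
  if (spec$kind == "presyn_field") {
    out$pop$gains <- state$pop$gains * stats::rnorm(n, 1, N)
  } else if (spec$kind == "presyn_rate") {
    out$pop$offsets <- state$pop$offsets + pmax(stats::rnorm(n, 0, N), 0)
  } else {
    out$w <- state$w + stats::rnorm(length(state$w), 0, N)
  }
  out
}

probe_protocol <- function(state, n_bins) {
  ca1_protocol(params = state$params, n_laps = 1, novelty = FALSE,
               weights = state$w, plasticity = FALSE, n_bins = n_bins,
               name = "stability_probe")
}

#' Plasticity-free probe lap from a frozen state
#'
#' Re-runs one lap of exploration from a network snapshot with
#' plasticity disabled and the inhibition frozen at the snapshot
#' levels, and returns the somatic rate map of that lap.
#'
#' @param state A `ca1_state` (possibly perturbed).
#' @param n_bins Spatial bins for the map.
#' @return Numeric rate map of the probe lap.
#' @export
probe_lap <- function(state, n_bins = 50) {
  sess <- run_session(
    probe_protocol(state, n_bins), pop = state$pop,
    init = list(w = state$w, r_dend = state$r_dend,
                r_soma = state$r_soma, t0 = state$t0,
                const_inhibition = c(state$I_dend, state$I_soma)))
  sess$map_soma[1, ]
}

#' Place-field stability under noise
#'
#' The perturbation-based stability measurement: (1) take the frozen
#' network state; (2) simulate one plasticity-free lap; (3) bin the
#' somatic place field; (4) rescale it to unit peak; (5) perturb the
#' state with one noise draw; (6) re-run the plasticity-free lap and
#' rescale its field; (7) compute the mean absolute distance between
#' the two rescaled fields; (8) repeat (5)-(7) `n_samples` times and
#' average.
#'
#' @param state A [session_state()] snapshot.
#' @param spec A [noise_spec()].
#' @param n_bins Spatial bins for the rate maps.
#' @return An object of class `ca1_stability`: list with
#'   `per_sample_distances`, `mean_distance`, `state_label` (the
#'   snapshotted lap), `baseline_map`, and `silent` (`TRUE` when the
#'   baseline map had zero peak, in which case distances use the
#'   unscaled maps).
#' @examples
#' s <- run_session(preset_protocol("novel_active", n_laps = 2))
#' st <- session_state(s, 1)
#' stability_protocol(st, noise_spec("weights", 0.05, n_samples = 3))
#' @export
stability_protocol <- function(state, spec, n_bins = 50) {
  base_map <- probe_lap(state, n_bins)
  silent <- max(base_map) <= 0
  d <- vapply(seq_len(spec$n_samples), function(i) {
    pert <- perturb_network(state, spec, draw = i)
    field_change(base_map, probe_lap(pert, n_bins))
  }, numeric(1))
  structure(list(per_sample_distances = d, mean_distance = mean(d),
                 state_label = state$lap, baseline_map = base_map,
                 silent = silent, spec = spec),
            class = "ca1_stability")
}

#' @export
print.ca1_stability <- function(x, ...) {
  cat(sprintf("Place-field stability probe (lap-%s state): %s noise, N = %g\n",
              x$state_label, x$spec$kind, x$spec$amplitude))
  cat(sprintf("  mean field change over %d samples: %.4f%s\n",
              length(x$per_sample_distances), x$mean_distance,
              if (x$silent) " [silent baseline]" else ""))
  invisible(x)
}

#' Sweep noise amplitudes for several frozen states
#'
#' Convenience wrapper running [stability_protocol()] over a grid of
#' noise kinds and amplitudes for each supplied state.
#'
#' @param states Named list of `ca1_state` snapshots.
#' @param kinds Noise kinds to sweep.
#' @param amplitudes Noise amplitudes to sweep.
#' @param n_samples Samples per cell.
#' @param seed Base seed (shared across states so that matched
#'   comparisons use common random numbers).
#' @param n_bins Spatial bins.
#' @return A data frame with one row per (state, kind, amplitude).
#' @export
stability_sweep <- function(states, kinds = c("presyn_field", "presyn_rate",
                                              "weights"),
                            amplitudes = c(0.05, 0.1, 0.2),
                            n_samples = 100, seed = 1, n_bins = 50) {
  grid <- expand.grid(state = names(states), kind = kinds,
                      amplitude = amplitudes, stringsAsFactors = FALSE)
  grid$mean_distance <- mapply(function(st, kd, am) {
    stability_protocol(states[[st]],
                       noise_spec(kd, am, n_samples, seed), n_bins
                       )$mean_distance
  }, grid$state, grid$kind, grid$amplitude)
  grid
}

#' Compensated state manipulations preserving the place field
#'
#' Artificially modifies a frozen familiar-environment state while
#' keeping its baseline place field (peak amplitude) unchanged, by
#' solving for the compensating inhibition level:
#' \describe{
#'   \item{`"weights_down"`}{Scales all synaptic weights by
#'     `scale < 1` and lowers dendritic inhibition to restore the
#'     original field amplitude.}
#'   \item{`"dend_inhibition_down"`}{Scales dendritic inhibition by
#'     `scale < 1` and raises somatic inhibition to restore the
#'     original field amplitude.}
#' }
#' The compensation is found by a scalar root solve on the probe-lap
#' field amplitude (tolerance 1e-3).
#'
#' @param state A `ca1_state`.
#' @param manipulation Which manipulation to apply.
#' @param scale Scaling factor in (0, 1].
#' @param n_bins Spatial bins for the probe maps.
#' @return The modified `ca1_state`.
#' @export
compensated_state <- function(state,
                              manipulation = c("weights_down",
                                               "dend_inhibition_down"),
                              scale = 0.5, n_bins = 50) {
  manipulation <- match.arg(manipulation)
  target <- field_metrics(probe_lap(state, n_bins))$amplitude
  if (target <= 0) stop("state has no place field to preserve")
  amp_at <- function(st) field_metrics(probe_lap(st, n_bins))$amplitude
  out <- state
  bracket_root <- function(f, grid) {
    vals <- vapply(grid, f, numeric(1))
    sgn <- sign(vals)
    for (flip in which(sgn[-1] * sgn[-length(sgn)] <= 0)) {
      root <- stats::uniroot(f, grid[c(flip, flip + 1)], tol = 1e-3)$root
      # a sign change across the propagation gate is a discontinuity,
      # not a root: accept only genuine amplitude matches
      if (abs(f(root)) < 5e-3) return(root)
    }
    stop("no compensating level preserves the field (the required ",
         "inhibition would cross the propagation-gate threshold)")
  }
  if (manipulation == "weights_down") {
    out$w <- state$w * scale
    f <- function(Id) { st <- out; st$I_dend <- Id; amp_at(st) - target }
    out$I_dend <- bracket_root(f, seq(state$I_dend, -10, length.out = 41))
  } else {
    out$I_dend <- state$I_dend * scale
    f <- function(Is) { st <- out; st$I_soma <- Is; amp_at(st) - target }
    out$I_soma <- bracket_root(f, seq(state$I_soma, state$I_soma + 10,
                                      length.out = 41))
  }
  out
}
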