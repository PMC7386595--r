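#' Declare a simulation protocol
#'
#' A protocol bundles everything one session needs: model parameters,
#' session length in laps, the novelty schedule, the initial synaptic
#' weights, induction/injection protocols, and recording settings.
#' [preset_protocol()] builds the packaged experiment protocols.
#'
#' @param params A [model_params()] object.
#' @param n_laps Number of laps to simulate.
#' @param novelty `TRUE`/`FALSE`, or a [novelty_schedule()] for resets.
#' @param weights Either a numeric weight vector of length `N_pre` or a
#'   list spec passed to [initial_weights()]
#'   (e.g. `list(generator = "single_bump", delta = 1.2)`).
#' @param inductions List of [induction_protocol()] objects.
#' @param plasticity If `FALSE`, weights are frozen for the whole
#'   session (used by the injection experiment and stability probes).
#' @param n_bins Number of spatial bins for the per-lap rate maps.
#' @param seed Integer seed for any randomized component (currently the
#'   `random_perturbed_uniform` weight generator).
#' @param input_novelty_coef Coefficient of an extra novelty-gated
#'   additive drive to every input neuron (0 disables; the
#'   novelty-on-inputs control uses a positive value).
#' @param input_gain_noise Standard deviation of per-lap multiplicative
#'   noise on the input place-field amplitudes (one `Normal(1, sd^2)`
#'   draw per neuron per lap; 0 disables).
#' @param input_rate_noise Standard deviation of per-lap additive,
#'   rectified rate noise on the inputs (0 disables).
#' @param name Optional label.
#' @return An object of class `ca1_protocol`.
#' @export
ca1_protocol <- function(params = model_params(), n_laps = 100,
                         novelty = TRUE, weights = list(),
                         inductions = list(), plasticity = TRUE,
                         n_bins = 50, seed = NULL,
                         input_novelty_coef = 0,
                         input_gain_noise = 0, input_rate_noise = 0,
                         name = "custom") {
  validate_params(params)
  if (isTRUE(novelty) || isFALSE(novelty)) {
    novelty <- novelty_schedule(enabled = novelty, tau_n = params$tau_n)
  }
  stopifnot(inherits(novelty, "ca1_novelty"), n_laps >= 1, n_bins >= 1)
  spl <- params$L / (params$v * params$dt)
  if (abs(spl - round(spl)) > 1e-9) {
    stop("dt, v and L must give an integer number of steps per lap")
  }
  if (round(spl) %% n_bins != 0) {
    stop("steps per lap must be a multiple of n_bins")
  }
  if (inherits(inductions, "ca1_induction")) inductions <- list(inductions)
  structure(list(params = params, n_laps = as.integer(n_laps),
                 novelty = novelty, weights = weights,
                 inductions = inductions, plasticity = plasticity,
                 n_bins = as.integer(n_bins), seed = seed,
                 input_novelty_coef = input_novelty_coef,
                 input_gain_noise = input_gain_noise,
                 input_rate_noise = input_rate_noise, name = name),
            class = "ca1_protocol")
}

#' Packaged experiment protocols
#'
#' The five scenarios the package ships:
#' \describe{
#'   \item{`"familiar_injection"`}{A silent cell in a familiar
#'     environment (constant inhibition, frozen weights): the substrate
#'     of the somatic current-injection experiment
#'     ([current_injection_sweep()]). Two laps by default.}
#'   \item{`"novel_silent"`}{An initially silent cell exploring a novel
#'     environment for 100 laps; dendritic disinhibition plus
#'     plasticity gradually turn it into a place cell.}
#'   \item{`"novel_active"`}{An initially active cell in a novel
#'     environment; its mean activity overshoots during early laps and
#'     returns toward the first-lap level as the environment becomes
#'     familiar.}
#'   \item{`"novel_induction"`}{A cell with one strong input synapse in
#'     a novel environment; the substrate of the dendritic induction
#'     experiments ([min_induction_laps()]).}
#'   \item{`"nonlinearity_control"`}{Near-uniform random initial
#'     weights, permanently novel environment (novelty schedule
#'     disabled); used to compare place-field development between
#'     nonlinear and linear dendrites.}
#' }
#'
#' @param preset Scenario name (see Details).
#' @param n_laps Number of laps (defaults per scenario).
#' @param seed Seed for randomized initial weights.
#' @param ... Overrides forwarded to [ca1_protocol()] (e.g.
#'   `inductions = `, `novelty = `) or to [model_params()] via a
#'   `params` argument.
#' @return A `ca1_protocol`.
#' @examples
#' pr <- preset_protocol("novel_active", n_laps = 5)
#' sess <- run_session(pr)
#' summary(sess)
#' @export
preset_protocol <- function(preset = c("familiar_injection", "novel_silent",
                                       "novel_active", "novel_induction",
                                       "nonlinearity_control"),
                            n_laps = NULL, seed = NULL, ...) {
  preset <- match.arg(preset)
  dots <- list(...)
  par_preset <- if (preset == "nonlinearity_control") "novel_active" else preset
  params <- if ("params" %in% names(dots)) dots$params else
    model_params(par_preset)
  dots$params <- NULL
  defaults <- switch(preset,
    familiar_injection = list(
      n_laps = 2, novelty = FALSE, plasticity = FALSE,
      weights = list(generator = "single_bump", total = 6.81,
                     delta = 0.64, bump_index = 5)),
    novel_silent = list(
      n_laps = 100, novelty = TRUE,
      weights = list(generator = "single_bump", total = 3,
                     delta = 0.3, bump_index = 5)),
    novel_active = list(
      n_laps = 100, novelty = TRUE,
      weights = list(generator = "single_bump", total = 3,
                     delta = 1.2, bump_index = 5)),
    novel_induction = list(
      n_laps = 100, novelty = TRUE,
      weights = list(generator = "single_bump", total = 2,
                     delta = 0.5, bump_index = 5)),
    nonlinearity_control = list(
      n_laps = 100, novelty = FALSE, input_gain_noise = 0.5,
      weights = list(generator = "random_perturbed_uniform",
                     jitter = 0.05))
  )
  if (!is.null(n_laps)) defaults$n_laps <- n_laps
  args <- utils::modifyList(defaults, dots)
  args$params <- params
  args$seed <- seed
  args$name <- preset
  do.call(ca1_protocol, args)
}

resolve_weights <- function(protocol) {
  w <- protocol$weights
  if (is.numeric(w)) {
    if (length(w) != protocol$params$N_pre) {
      stop("weight vector must have length N_pre")
    }
    return(w)
  }
  spec <- w
  spec$params <- protocol$params
  if (is.null(spec$seed)) spec$seed <- protocol$seed
  if (is.null(spec$generator)) spec$generator <- "uniform"
  do.call(initial_weights, spec)
}

inductions_matrix <- function(inductions) {
  if (!length(inductions)) {
    return(matrix(numeric(0), ncol = 6))
  }
  t(vapply(inductions, function(pr) {
    kind <- match(pr$kind, c("dendritic_current", "somatic_current",
                             "dendritic_disinhibition"))
    c(kind, pr$region[1], pr$region[2], pr$first_lap,
      pr$first_lap + pr$n_laps - 1, pr$amplitude)
  }, numeric(6)))
}

#' Run a simulation session
#'
#' Advances the full model lap by lap: trajectory, input rates, novelty
#' and inhibition schedules, protocol currents, the two-compartment
#' rate dynamics, and (unless disabled) the plasticity rule, using
#' explicit Euler steps of size `dt`. Deterministic given the protocol
#' and seed.
#'
#' @param protocol A [ca1_protocol()] or [preset_protocol()].
#' @param engine `"cpp"` (compiled inner loop, default) or `"r"` (pure-R
#'   reference implementation built from the exported single-step
#'   primitives; identical results, much slower).
#' @param pop Optional [input_population()] overriding the default
#'   (used by the stability module to run perturbed populations).
#' @param init Optional list with `w`, `r_dend`, `r_soma`, `t0` to
#'   resume from a frozen network state (see [session_state()]);
#'   `const_inhibition = c(I_dend, I_soma)` freezes the inhibition.
#' @return An object of class `ca1_session` with per-lap rate maps of
#'   both compartments (`map_dend`, `map_soma`), the subthreshold
#'   somatic map (`map_sub`), the dendritic-potential map
#'   (`map_pdend`), per-lap mean activities, per-lap novelty and
#'   inhibition levels, weight and rate snapshots at every lap start,
#'   and per-lap dendritic-spike counts.
#' @examples
#' s <- run_session(preset_protocol("novel_active", n_laps = 3))
#' s$mean_soma
#' @export
run_session <- function(protocol, engine = c("cpp", "r"), pop = NULL,
                        init = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(protocol, "ca1_protocol"))
  params <- protocol$params
  if (is.null(pop)) pop <- input_population(params)
  w0 <- if (!is.null(init$w)) init$w else resolve_weights(protocol)
  r_d0 <- if (!is.null(init$r_dend)) init$r_dend else 0
  r_s0 <- if (!is.null(init$r_soma)) init$r_soma else 0
  t0 <- if (!is.null(init$t0)) init$t0 else 0
  const_inh <- init$const_inhibition
  if (!is.null(protocol$seed) &&
      (protocol$input_gain_noise > 0 || protocol$input_rate_noise > 0)) {
    set.seed(protocol$seed)
  }
  eng <- if (engine == "cpp") .session_engine_cpp else .session_engine_r
  res <- eng(
    par = unclass(params), centers = pop$centers, gains = pop$gains,
    offsets = pop$offsets, w0 = as.numeric(w0),
    r_dend0 = r_d0, r_soma0 = r_s0,
    n_laps = protocol$n_laps, n_bins = protocol$n_bins,
    plasticity = protocol$plasticity,
    novelty_enabled = protocol$novelty$enabled,
    reset_times = protocol$novelty$reset_times,
    input_novelty_coef = protocol$input_novelty_coef,
    I_dend_const = if (is.null(const_inh)) 0 else const_inh[1],
    I_soma_const = if (is.null(const_inh)) 0 else const_inh[2],
    const_inhib = !is.null(const_inh),
    inductions = inductions_matrix(protocol$inductions),
    t0 = t0,
    gain_noise_sd = protocol$input_gain_noise,
    rate_noise_sd = protocol$input_rate_noise
  )
  res$protocol <- protocol
  res$params <- params
  res$pop <- pop
  res$engine <- engine
  res$bin_centers <- (seq_len(protocol$n_bins) - 0.5) *
    params$L / protocol$n_bins
  class(res) <- "ca1_session"
  res
}

# Pure-R reference engine; mirrors src/session_engine.cpp step for step
# but is assembled from the exported single-step primitives.
.session_engine_r <- function(par, centers, gains, offsets, w0, r_dend0,
                              r_soma0, n_laps, n_bins, plasticity,
                              novelty_enabled, reset_times,
                              input_novelty_coef, I_dend_const,
                              I_soma_const, const_inhib, inductions, t0,
                              gain_noise_sd = 0, rate_noise_sd = 0) {
  params <- par
  class(params) <- "ca1_params"
  pop <- structure(list(centers = centers, amplitude = par$A_pre,
                        sigma = par$sigma_pre, L = par$L, gains = gains,
                        offsets = offsets), class = "ca1_inputs")
  steps <- round(par$L / (par$v * par$dt))
  binw <- par$L / n_bins
  lap_offset <- round(par$v * t0 / par$L)
  n_pre <- length(w0)

  w <- as.numeric(w0)
  state <- list(r_dend = r_dend0, r_soma = r_soma0, t = t0)
  map_d <- map_s <- map_u <- map_p <- matrix(0, n_laps, n_bins)
  cnt <- matrix(0L, n_laps, n_bins)
  mean_d <- mean_s <- nov_lap <- Id_lap <- Is_lap <- numeric(n_laps)
  w_snap <- matrix(0, n_laps + 1, n_pre)
  r_snap <- matrix(0, n_laps + 1, 2)
  spikes <- integer(n_laps)
  first_spike_lap <- 0L
  prev_pdend <- -Inf

  sched <- novelty_schedule(enabled = TRUE, tau_n = par$tau_n,
                            reset_times = reset_times)
  ind_list <- apply(inductions, 1, function(row) {
    structure(list(kind = c("dendritic_current", "somatic_current",
                            "dendritic_disinhibition")[row[1]],
                   region = row[2:3], first_lap = row[4],
                   n_laps = row[5] - row[4] + 1, amplitude = row[6]),
              class = "ca1_induction")
  })

  for (lap in seq_len(n_laps)) {
    w_snap[lap, ] <- w
    r_snap[lap, ] <- c(state$r_dend, state$r_soma)
    abs_lap <- lap_offset + lap
    lap_gains <- gains
    lap_offsets <- offsets
    if (gain_noise_sd > 0 || rate_noise_sd > 0) {
      lap_gains <- gains * (if (gain_noise_sd > 0)
        stats::rnorm(n_pre, 1, gain_noise_sd) else 1)
      off <- if (rate_noise_sd > 0)
        pmax(stats::rnorm(n_pre, 0, rate_noise_sd), 0) else 0
      lap_offsets <- offsets + off
    }
    acc_d <- acc_s <- 0
    for (s in seq_len(steps) - 1L) {
      t <- t0 + ((lap - 1) * steps + s) * par$dt
      p <- position_at(t, par$L, par$v)$position
      n <- if (novelty_enabled) novelty_value(t, sched) else 1
      if (const_inhib) {
        I_dend <- I_dend_const; I_soma <- I_soma_const
      } else {
        inh <- list(
          I_dend = par$I_dend_inf - (par$I_dend_inf - par$I_dend_0) * n,
          I_soma = par$I_soma_inf - (par$I_soma_inf - par$I_soma_0) * n)
        I_dend <- inh$I_dend; I_soma <- inh$I_soma
      }
      pc <- protocol_currents(p, abs_lap, ind_list, par$L)
      I_dend <- I_dend * (1 - pc$suppression)
      if (s == 0) {
        nov_lap[lap] <- n; Id_lap[lap] <- I_dend; Is_lap[lap] <- I_soma
      }
      pop$gains <- lap_gains
      pop$offsets <- lap_offsets + input_novelty_coef * n
      R <- input_rates(p, pop)
      p_dend <- dendritic_drive(w, R, I_dend, pc$I_dend_ext)
      sd <- somatic_drive(par$E_soma_int, pc$I_soma_ext, I_soma)
      gate <- g_prop(sd$V_soma, params)

      b <- min(floor(p / binw) + 1, n_bins)
      map_d[lap, b] <- map_d[lap, b] + state$r_dend
      map_s[lap, b] <- map_s[lap, b] + state$r_soma
      map_u[lap, b] <- map_u[lap, b] + gate * state$r_dend + sd$V_soma
      map_p[lap, b] <- map_p[lap, b] + p_dend
      cnt[lap, b] <- cnt[lap, b] + 1L
      acc_d <- acc_d + state$r_dend
      acc_s <- acc_s + state$r_soma

      if (is.infinite(prev_pdend)) prev_pdend <- p_dend
      if (p_dend > par$I0 && prev_pdend <= par$I0) {
        spikes[lap] <- spikes[lap] + 1L
        if (first_spike_lap == 0) first_spike_lap <- abs_lap
      }
      prev_pdend <- p_dend

      w_new <- if (plasticity) {
        weight_update(w, state$r_dend, R, params, par$dt)
      } else w
      state <- step_dynamics(
        state, list(p_dend = p_dend, E_soma = sd$E_soma, I_soma = I_soma),
        params)
      w <- w_new
    }
    if (any(cnt[lap, ] == 0)) stop("empty spatial bin")
    map_d[lap, ] <- map_d[lap, ] / cnt[lap, ]
    map_s[lap, ] <- map_s[lap, ] / cnt[lap, ]
    map_u[lap, ] <- map_u[lap, ] / cnt[lap, ]
    map_p[lap, ] <- map_p[lap, ] / cnt[lap, ]
    mean_d[lap] <- acc_d / steps
    mean_s[lap] <- acc_s / steps
  }
  w_snap[n_laps + 1, ] <- w
  r_snap[n_laps + 1, ] <- c(state$r_dend, state$r_soma)
  list(map_dend = map_d, map_soma = map_s, map_sub = map_u,
       map_pdend = map_p, mean_dend = mean_d, mean_soma = mean_s,
       novelty = nov_lap, I_dend = Id_lap, I_soma = Is_lap,
       w_snapshots = w_snap, r_snapshots = r_snap,
       dend_spikes = spikes, first_spike_lap = first_spike_lap,
       t_end = t0 + n_laps * steps * par$dt)
}

#' Frozen network state at the start of a lap
#'
#' Extracts everything the stability protocol needs to re-run a lap
#' from a snapshot: the weights, the compartment rates, the scheduled
#' inhibition levels, and the session time at the start of the given
#' lap.
#'
#' @param session A [run_session()] result.
#' @param lap Lap whose start is snapshotted (1-based).
#' @return A list of class `ca1_state` with `w`, `r_dend`, `r_soma`,
#'   `I_dend`, `I_soma`, `t0`, `lap`, `params`, `pop`.
#' @export
session_state <- function(session, lap) {
  stopifnot(inherits(session, "ca1_session"),
            lap >= 1, lap <= session$protocol$n_laps)
  structure(list(
    w = session$w_snapshots[lap, ],
    r_dend = session$r_snapshots[lap, 1],
    r_soma = session$r_snapshots[lap, 2],
    I_dend = session$I_dend[lap],
    I_soma = session$I_soma[lap],
    t0 = (lap - 1) * session$params$L / session$params$v,
    lap = lap,
    params = session$params,
    pop = session$pop
  ), class = "ca1_state")
}

#' @export
print.ca1_protocol <- function(x, ...) {
  cat(sprintf("CA1 session protocol '%s': %d laps, novelty %s, plasticity %s\n",
              x$name, x$n_laps,
              if (x$novelty$enabled) "on" else "off",
              if (x$plasticity) "on" else "off"))
  if (length(x$inductions)) {
    cat(sprintf("  %d induction protocol(s)\n", length(x$inductions)))
  }
  invisible(x)
}

#' @export
print.ca1_session <- function(x, ...) {
  cat(sprintf("CA1 session ('%s'): %d laps of %g s, %d bins\n",
              x$protocol$name, x$protocol$n_laps,
              x$params$L / x$params$v / 1000, x$protocol$n_bins))
  cat(sprintf("  final mean rates: dendrite %.3f, soma %.3f\n",
              tail(x$mean_dend, 1), tail(x$mean_soma, 1)))
  cat(sprintf("  dendritic spikes: %d (first on lap %s)\n",
              sum(x$dend_spikes),
              if (x$first_spike_lap > 0) x$first_spike_lap else "none"))
  invisible(x)
}

#' @export
summary.ca1_session <- function(object, threshold = 0.1, ...) {
  fm <- apply(object$map_soma, 1, function(m) {
    f <- field_metrics(m, threshold = threshold)
    c(amplitude = f$amplitude, peak = f$peak_location_bin,
      field = as.numeric(f$is_place_field))
  })
  first_field <- which(fm["field", ] > 0)[1]
  out <- list(
    n_laps = object$protocol$n_laps,
    first_somatic_field_lap = if (is.na(first_field)) NA_integer_
                              else as.integer(first_field),
    final_amplitude = fm["amplitude", ncol(fm)],
    mean_soma = object$mean_soma,
    mean_dend = object$mean_dend,
    weight_sum = rowSums(object$w_snapshots)
  )
  class(out) <- "summary.ca1_session"
  out
}

#' @export
print.summary.ca1_session <- function(x, ...) {
  cat(sprintf("CA1 session summary: %d laps\n", x$n_laps))
  cat(sprintf("  first somatic place field on lap: %s\n",
              if (is.na(x$first_somatic_field_lap)) "never"
              else x$first_somatic_field_lap))
  cat(sprintf("  final place-field amplitude: %.3f\n", x$final_amplitude))
  cat(sprintf("  mean somatic rate: lap 1 = %.4f, max = %.4f (lap %d), final = %.4f\n",
              x$mean_soma[1], max(x$mean_soma), which.max(x$mean_soma),
              tail(x$mean_soma, 1)))
  cat(sprintf("  weight sum: initial %.3f, final %.3f\n",
              x$weight_sum[1], tail(x$weight_sum, 1)))
  invisible(x)
}

#' Plot a simulated session
#'
#' Four panels: somatic and dendritic rate maps across laps (position
#' by lap images), per-lap mean activities, and the inhibition /
#' novelty schedules.
#'
#' @param x A `ca1_session`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.ca1_session <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  laps <- seq_len(x$protocol$n_laps)
  graphics::image(x$bin_centers, laps, t(x$map_soma),
                  xlab = "position", ylab = "lap", main = "somatic rate",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  graphics::image(x$bin_centers, laps, t(x$map_dend),
                  xlab = "position", ylab = "lap", main = "dendritic rate",
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE))
  graphics::matplot(laps, cbind(x$mean_soma, x$mean_dend), type = "l",
                    lty = c(1, 2), col = c("black", "grey40"),
                    xlab = "lap", ylab = "mean activity",
                    main = "lap-averaged activity")
  graphics::legend("topright", c("soma", "dendrite"), lty = c(1, 2),
                   col = c("black", "grey40"), bty = "n")
  graphics::matplot(laps, cbind(x$I_dend, x$I_soma, x$novelty), type = "l",
                    lty = 1, col = c("darkgreen", "purple", "red"),
                    xlab = "lap", ylab = "level",
                    main = "inhibition and novelty")
  graphics::legend("right", c("I_dend", "I_soma", "novelty"), lty = 1,
                   col = c("darkgreen", "purple", "red"), bty = "n")
  invisible(x)
}
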