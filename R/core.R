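#' Dendritic input-output nonlinearity
#'
#' Static transfer function of the dendritic compartment. In the default
#' nonlinear mode it is the sum of a rectified saturating gain and a
#' sigmoidal dendritic-spike term,
#' \deqn{g(I) = \alpha_1 [\tanh(I/I_0)]_+ +
#'   \alpha_2 \tfrac{1}{2}(\tanh(2(I - I_0)) + 1),}
#' so that inputs above `I0` recruit an extra, step-like activity
#' increment (the rate-model analogue of a dendritic spike). In
#' `dendrite_mode = "linear"` the spike term is removed and replaced by
#' a single rectified saturating curve with the same maximal activity
#' `alpha1 + alpha2` and the same small-signal slope `alpha1 / I0`
#' (attained with a widened half-saturation current
#' `I0 (alpha1 + alpha2) / alpha1`).
#'
#' @param I Dendritic drive (a.u.); vectorized.
#' @param params A [model_params()] object.
#' @return Activity values in `[0, alpha1 + alpha2]`.
#' @examples
#' p <- model_params()
#' g_dend(p$I0, p)  # ~ 4/3 tanh(1) + 1/3
#' @export
g_dend <- function(I, params) {
  if (any(!is.finite(I))) stop("non-finite dendritic drive")
  if (identical(params$dendrite_mode, "linear")) {
    I0lin <- params$I0 * (params$alpha1 + params$alpha2) / params$alpha1
    return((params$alpha1 + params$alpha2) * pmax(tanh(I / I0lin), 0))
  }
  params$alpha1 * pmax(tanh(I / params$I0), 0) +
    params$alpha2 * 0.5 * (tanh(2 * (I - params$I0)) + 1)
}

#' Dendrite-to-soma propagation gate
#'
#' All-or-nothing gate on the propagation of dendritic activity to the
#' soma, controlled by the somatic potential: closed (0) below
#' `theta_prop` and open (1) above. By default the gate opens at
#' equality (`gate_strict = FALSE`); when the gate is disabled entirely
#' (`gate_enabled = FALSE`) it returns 1 for any potential.
#'
#' @param V_soma Somatic potential (a.u.); vectorized.
#' @param params A [model_params()] object.
#' @return 0/1 vector.
#' @export
g_prop <- function(V_soma, params) {
  if (any(!is.finite(V_soma))) stop("non-finite somatic potential")
  if (!params$gate_enabled) return(rep(1, length(V_soma)))
  if (params$gate_strict) {
    as.numeric(V_soma > params$theta_prop)
  } else {
    as.numeric(V_soma >= params$theta_prop)
  }
}

#' Dendritic drive
#'
#' Total current to the dendritic compartment: synaptic input minus
#' dendritic inhibition plus any external dendritic current,
#' `sum(w * R) - I_dend + I_dend_ext`.
#'
#' @param w Synaptic weights.
#' @param R Input firing rates (same length as `w`).
#' @param I_dend Dendritic inhibition (a.u.).
#' @param I_dend_ext External dendritic current (a.u.), default 0.
#' @return The dendritic potential (a.u., scalar).
#' @export
dendritic_drive <- function(w, R, I_dend, I_dend_ext = 0) {
  if (length(w) != length(R)) stop("w and R must have the same length")
  sum(w * R) - I_dend + I_dend_ext
}

#' Somatic drive and potential
#'
#' The excitatory somatic drive is the constant internal drive plus any
#' external injected current, `E_soma = E_soma_int + I_soma_ext`; the
#' somatic potential subtracts somatic inhibition,
#' `V_soma = E_soma - I_soma`.
#'
#' @param E_soma_int Constant excitatory somatic drive (a.u.).
#' @param I_soma_ext External somatic current (a.u.).
#' @param I_soma Somatic inhibition (a.u.).
#' @return List with `E_soma` and `V_soma`.
#' @export
somatic_drive <- function(E_soma_int, I_soma_ext, I_soma) {
  stopifnot(is.finite(E_soma_int), is.finite(I_soma_ext), is.finite(I_soma))
  E <- E_soma_int + I_soma_ext
  list(E_soma = E, V_soma = E - I_soma)
}

#' One Euler step of the two-compartment rate dynamics
#'
#' Advances both compartments by one explicit Euler step of
#' \deqn{\tau_0 \dot r_{dend} = -r_{dend} + g_{dend}(p_{dend})}
#' \deqn{\tau_0 \dot r_{soma} = -r_{soma} +
#'   [g_{prop}(V_{soma}) r_{dend} + E_{soma} - I_{soma} - N_{th}]_+}
#' All drives are evaluated from the state at the start of the step
#' (synchronous update); rates are clamped at zero afterwards.
#'
#' @param state List with `r_dend`, `r_soma`, `t` (ms).
#' @param drive List with `p_dend`, `E_soma`, `I_soma` (and optionally
#'   `V_soma`; if absent it is computed as `E_soma - I_soma`).
#' @param params A [model_params()] object.
#' @return Updated state list.
#' @export
step_dynamics <- function(state, drive, params) {
  if (!all(is.finite(c(state$r_dend, state$r_soma)))) {
    stop("non-finite neuron state")
  }
  V <- if (is.null(drive$V_soma)) drive$E_soma - drive$I_soma else drive$V_soma
  a <- params$dt / params$tau0
  target_d <- g_dend(drive$p_dend, params)
  target_s <- max(g_prop(V, params) * state$r_dend +
                    drive$E_soma - drive$I_soma - params$N_th, 0)
  state$r_dend <- max(state$r_dend + a * (target_d - state$r_dend), 0)
  state$r_soma <- max(state$r_soma + a * (target_s - state$r_soma), 0)
  state$t <- state$t + params$dt
  state
}
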