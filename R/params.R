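#' Model parameters for the two-compartment CA1 neuron
#'
#' Builds the full parameter set of the model: the rate dynamics of the
#' dendritic and somatic compartments, the dendritic nonlinearity, the
#' dendrite-to-soma propagation gate, the Hebbian/homeostatic plasticity
#' rule, the Gaussian place-tuned input layer, the novelty-driven
#' inhibition schedules, and the track/integration settings.
#'
#' Four presets bundle the parameter combinations used by the packaged
#' experiment protocols; individual values can be overridden through
#' `...`.
#'
#' \describe{
#'   \item{`"familiar_injection"`}{Somatic current-injection experiment in a
#'     familiar environment: no intrinsic somatic drive
#'     (`E_soma_int = 0`), inhibition held constant.}
#'   \item{`"novel_silent"`}{Initially silent cell exploring a novel
#'     environment (`E_soma_int = 0.5`, asymptotic dendritic inhibition
#'     7.5).}
#'   \item{`"novel_active"`}{Initially active cell exploring a novel
#'     environment (`E_soma_int = 1`, asymptotic dendritic inhibition
#'     8.5).}
#'   \item{`"novel_induction"`}{Single strong input synapse in a novel
#'     environment, used by the induction protocols
#'     (`theta_homeo = 2`, otherwise as `"novel_active"`).}
#' }
#'
#' @param preset One of `"familiar_injection"`, `"novel_silent"`,
#'   `"novel_active"`, `"novel_induction"`, or `NULL` for the base set
#'   (identical to `"novel_active"` apart from scenario-specific fields).
#' @param ... Named overrides for any parameter listed below.
#'
#' @return An object of class `ca1_params`: a named list with fields
#' \describe{
#'   \item{tau0}{Time constant of both rate equations (ms).}
#'   \item{alpha1}{Linear dendritic gain (dimensionless).}
#'   \item{alpha2}{Amplitude of the dendritic-spike term (dimensionless).}
#'   \item{I0}{Minimum dendritic current for a dendritic spike (a.u.).}
#'   \item{N_th}{Somatic activation threshold (a.u.).}
#'   \item{theta_prop}{Propagation-gate threshold on the somatic potential
#'     (a.u.).}
#'   \item{eta_ex, eta_homeo}{Hebbian and homeostatic learning rates
#'     (1/ms).}
#'   \item{theta_homeo}{Homeostatic target for the summed weights (a.u.).}
#'   \item{A_pre, sigma_pre}{Amplitude (a.u.) and width (track units) of
#'     the presynaptic place fields.}
#'   \item{tau_n}{Novelty decay time constant (ms).}
#'   \item{I_dend_0, I_dend_inf}{Dendritic inhibition in novel (initial)
#'     and familiar (asymptotic) environments (a.u.).}
#'   \item{I_soma_0, I_soma_inf}{Somatic inhibition in novel and familiar
#'     environments (a.u.).}
#'   \item{N_pre}{Number of place-tuned input neurons.}
#'   \item{E_soma_int}{Constant excitatory somatic drive (a.u.).}
#'   \item{L, v}{Track length (track units) and running speed
#'     (track units/ms).}
#'   \item{dt}{Euler integration step (ms).}
#'   \item{dendrite_mode}{`"nonlinear"` (default) or `"linear"` (control
#'     without the spike term but with the same maximal activity).}
#'   \item{gate_enabled}{If `FALSE`, dendritic activity propagates to the
#'     soma unconditionally (gate-removal control).}
#'   \item{gate_strict}{If `TRUE` the gate opens only for
#'     `V_soma > theta_prop`; the default (`FALSE`) opens at equality, so
#'     that the silent-to-place transition in the injection experiment
#'     occurs exactly at `I_ext = I_soma + theta_prop`.}
#'   \item{`w_max`}{Upper bound on each synaptic weight (a.u.).
#'     Potentiation saturates individual synapses at `w_max`, which
#'     bounds the Hebbian positive feedback so that a tuned weight
#'     profile persists once the environment is familiar. `Inf`
#'     disables the bound.}
#'   \item{`clip_weights`}{If `TRUE`, synaptic weights are clipped at zero
#'     after every update. Default `FALSE`: the subtractive homeostatic
#'     term is allowed to drive out-of-field weights negative, which is
#'     what lets a single strongly tuned input keep the dendrite above
#'     threshold under strong familiar-environment dendritic inhibition.}
#' }
#'
#' @examples
#' p <- model_params("novel_active")
#' p$theta_homeo
#' model_params("novel_induction", dt = 0.5)$dt
#' @export
model_params <- function(preset = NULL, ...) {
  p <- list(
    tau0       = 5,
    alpha1     = 4 / 3,
    alpha2     = 2 / 3,
    I0         = 2.5,
    N_th       = 1,
    theta_prop = -0.2,
    eta_ex     = 2e-4,
    eta_homeo  = 2e-4,
    theta_homeo = 3,
    A_pre      = 2.2,
    sigma_pre  = 5,
    tau_n      = 1e5,   # 100 s
    I_dend_0   = 0.8,
    I_dend_inf = 8.5,
    I_soma_0   = 1.2,
    I_soma_inf = 0,
    N_pre      = 10L,
    E_soma_int = 1,
    L          = 50,
    v          = 1e-2,
    dt         = 1,
    w_max      = 1.7,
    dendrite_mode = "nonlinear",
    gate_enabled  = TRUE,
    gate_strict   = FALSE,
    clip_weights  = FALSE
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("familiar_injection", "novel_silent",
                                  "novel_active", "novel_induction"))
    p <- switch(preset,
      familiar_injection = utils::modifyList(p, list(E_soma_int = 0)),
      novel_silent       = utils::modifyList(p, list(E_soma_int = 0.5,
                                                     I_dend_inf = 7.5)),
      novel_active       = p,
      novel_induction    = utils::modifyList(p, list(theta_homeo = 2,
                                                     w_max = 1.8))
    )
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    p <- utils::modifyList(p, dots)
  }
  p$N_pre <- as.integer(p$N_pre)
  class(p) <- "ca1_params"
  validate_params(p)
  p
}

#' Validate a `ca1_params` object
#'
#' Checks positivity of the time constants, track geometry and input
#' width, the Euler stability condition `dt <= tau0`, and the dendrite
#' mode. Called by [model_params()]; exported so that hand-edited
#' parameter lists can be re-checked.
#'
#' @param p A `ca1_params` object (or plain named list with the same
#'   fields).
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  num <- vapply(p[setdiff(names(p), c("dendrite_mode", "gate_enabled",
                                      "gate_strict", "clip_weights",
                                      "w_max"))],
                function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(num)[!num], collapse = ", "))
  }
  stopifnot(
    p$tau0 > 0, p$dt > 0, p$L > 0, p$v > 0, p$N_pre > 0,
    p$sigma_pre > 0, p$A_pre >= 0, p$tau_n > 0, p$w_max > 0
  )
  if (p$dt > p$tau0) {
    stop("dt must not exceed tau0 (explicit Euler stability)")
  }
  if (!p$dendrite_mode %in% c("nonlinear", "linear")) {
    stop("dendrite_mode must be 'nonlinear' or 'linear'")
  }
  invisible(p)
}

#' @export
print.ca1_params <- function(x, ...) {
  cat("CA1 two-compartment model parameters\n")
  cat(sprintf("  dynamics : tau0 = %g ms, dt = %g ms, dendrite = %s, gate %s\n",
              x$tau0, x$dt, x$dendrite_mode,
              if (x$gate_enabled) "enabled" else "disabled"))
  cat(sprintf("  dendrite : alpha1 = %.4g, alpha2 = %.4g, I0 = %g\n",
              x$alpha1, x$alpha2, x$I0))
  cat(sprintf("  soma     : N_th = %g, theta_prop = %g, E_soma_int = %g\n",
              x$N_th, x$theta_prop, x$E_soma_int))
  cat(sprintf("  plasticity: eta_ex = %g, eta_homeo = %g, theta_homeo = %g, w_max = %g\n",
              x$eta_ex, x$eta_homeo, x$theta_homeo, x$w_max))
  cat(sprintf("  inputs   : N_pre = %d, A_pre = %g, sigma_pre = %g\n",
              x$N_pre, x$A_pre, x$sigma_pre))
  cat(sprintf("  inhibition: I_dend %g -> %g, I_soma %g -> %g, tau_n = %g s\n",
              x$I_dend_0, x$I_dend_inf, x$I_soma_0, x$I_soma_inf,
              x$tau_n / 1000))
  cat(sprintf("  track    : L = %g, v = %g /ms (lap = %g s)\n",
              x$L, x$v, x$L / x$v / 1000))
  invisible(x)
}
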