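#' Hebbian + homeostatic weight update
#'
#' One Euler step of the plasticity rule
#' \deqn{\dot w_j = \eta_{ex}\, r_{dend} R_j -
#'   \eta_{homeo} (\textstyle\sum_k w_k - \theta_{homeo}),}
#' i.e. a Hebbian term gated by dendritic activity and a subtractive
#' homeostatic term, identical for all synapses, that pulls the summed
#' weight toward `theta_homeo`. The homeostatic term uses the
#' pre-update weight sum (synchronous update). With
#' `clip_weights = TRUE` the updated weights are rectified at zero.
#'
#' @param w Weight vector.
#' @param r_dend Dendritic activity (a.u., scalar).
#' @param R Input rates (same length as `w`).
#' @param params A [model_params()] object.
#' @param dt Step size (ms); defaults to `params$dt`.
#' @return Updated weight vector.
#' @export
weight_update <- function(w, r_dend, R, params, dt = params$dt) {
  if (length(w) != length(R)) stop("w and R must have the same length")
  dw <- params$eta_ex * r_dend * R -
    params$eta_homeo * (sum(w) - params$theta_homeo)
  w <- pmin(w + dt * dw, params$w_max)
  if (!all(is.finite(w))) stop("non-finite weights after update")
  if (params$clip_weights) w <- pmax(w, 0)
  w
}

#' Initial synaptic-weight profiles
#'
#' Generators for the initial weight vector of a session:
#' \describe{
#'   \item{`uniform`}{All weights equal to `total / N_pre`.}
#'   \item{`single_bump`}{Uniform background plus an increment `delta`
#'     on one synapse (`bump_index`); the profile sums to `total`.}
#'   \item{`random_perturbed_uniform`}{Uniform profile multiplied by
#'     `1 + e` with i.i.d. `e ~ Normal(0, jitter^2)`, then rescaled to
#'     sum to `total`; seed-reproducible.}
#' }
#'
#' @param params A [model_params()] object.
#' @param generator One of `"uniform"`, `"single_bump"`,
#'   `"random_perturbed_uniform"`.
#' @param total Target weight sum; defaults to `theta_homeo`.
#' @param bump_index Index of the strengthened synapse (single_bump).
#' @param delta Increment on the strengthened synapse (single_bump).
#' @param jitter Relative jitter standard deviation
#'   (random_perturbed_uniform).
#' @param seed Optional integer seed (random_perturbed_uniform).
#' @return Numeric weight vector of length `N_pre`, with attributes
#'   `generator` and (where used) `seed`.
#' @examples
#' w <- initial_weights(model_params(), "single_bump", delta = 1.2)
#' which.max(w)
#' @export
initial_weights <- function(params,
                            generator = c("uniform", "single_bump",
                                          "random_perturbed_uniform"),
                            total = params$theta_homeo,
                            bump_index = 5, delta = 1,
                            jitter = 0.05, seed = NULL) {
  generator <- match.arg(generator)
  n <- params$N_pre
  w <- switch(generator,
    uniform = rep(total / n, n),
    single_bump = {
      stopifnot(bump_index >= 1, bump_index <= n, delta >= 0,
                total > delta)
      base <- (total - delta) / n
      out <- rep(base, n)
      out[bump_index] <- out[bump_index] + delta
      out
    },
    random_perturbed_uniform = {
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
          get(".Random.seed", envir = globalenv()) else NULL
        on.exit(if (!is.null(old))
          assign(".Random.seed", old, envir = globalenv()))
        set.seed(seed)
      }
      out <- (total / n) * (1 + stats::rnorm(n, 0, jitter))
      out <- pmax(out, 0)
      out * total / sum(out)
    }
  )
  attr(w, "generator") <- generator
  if (!is.null(seed)) attr(w, "seed") <- seed
  w
}

#' Write / read a weight profile as delimited text
#'
#' Serializes a weight vector (one weight per line, with the generator
#' recorded in a header comment) so that initial conditions can be
#' shared across runs.
#'
#' @param w Weight vector (as from [initial_weights()]).
#' @param path File path.
#' @return `write_weights` returns `path` invisibly; `read_weights`
#'   returns the weight vector.
#' @export
write_weights <- function(w, path) {
  gen <- attr(w, "generator")
  hdr <- sprintf("# ca1place weights%s",
                 if (is.null(gen)) "" else paste0(" generator=", gen))
  writeLines(c(hdr, format(as.numeric(w), digits = 17)), path)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  as.numeric(lines[!startsWith(lines, "#")])
}
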