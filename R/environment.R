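#' Circular distance along an annular track
#'
#' Shortest distance between two positions on a ring of circumference
#' `L`, i.e. `min(|p - p0|, L - |p - p0|)`.
#'
#' @param p,p0 Positions in `[0, L)` (recycled against each other).
#' @param L Track length; must be positive.
#' @return Distances in `[0, L/2]`.
#' @examples
#' circular_distance(49, 0, 50)  # wraps: 1
#' @export
circular_distance <- function(p, p0, L) {
  if (!is.numeric(L) || L <= 0) stop("L must be positive")
  d <- abs(p - p0) %% L
  pmin(d, L - d)
}

#' Position and lap index at a given session time
#'
#' Constant-speed unidirectional traversal of the annular track:
#' position `(v t) mod L`, lap index `floor(v t / L)` (0-based).
#'
#' @param t Session time (ms), non-negative.
#' @param L Track length (track units).
#' @param v Speed (track units per ms).
#' @return A list with components `position` and `lap`.
#' @export
position_at <- function(t, L, v) {
  stopifnot(all(t >= 0), L > 0, v > 0)
  x <- v * t
  list(position = x %% L, lap = floor(x / L))
}

#' Place-tuned input population
#'
#' The presynaptic layer: `N_pre` neurons with Gaussian spatial tuning
#' curves of common amplitude `A_pre` and width `sigma_pre`, with
#' centers uniformly spaced at track midpoints
#' `L (i + 0.5) / N_pre`, `i = 0..N_pre-1` (no center on the 0/L seam).
#' Per-neuron multiplicative gains and additive rate offsets default to
#' 1 and 0; they are the handles used by the stability module's noise
#' models.
#'
#' @param params A [model_params()] object.
#' @param centers Optional custom centers in `[0, L)`.
#' @param gains Optional per-neuron multiplicative gain factors.
#' @param offsets Optional per-neuron additive rate offsets (a.u.).
#' @return An object of class `ca1_inputs` with fields `centers`,
#'   `amplitude`, `sigma`, `L`, `gains`, `offsets`.
#' @examples
#' pop <- input_population(model_params())
#' range(input_rates(22.5, pop))
#' @export
input_population <- function(params, centers = NULL, gains = NULL,
                             offsets = NULL) {
  n <- params$N_pre
  if (is.null(centers)) {
    centers <- params$L * (seq_len(n) - 0.5) / n
  }
  if (length(centers) != n) stop("need exactly N_pre centers")
  if (any(centers < 0 | centers >= params$L)) {
    stop("centers must lie in [0, L)")
  }
  if (is.null(gains)) gains <- rep(1, n)
  if (is.null(offsets)) offsets <- rep(0, n)
  stopifnot(length(gains) == n, length(offsets) == n,
            all(is.finite(gains)), all(is.finite(offsets)))
  structure(list(centers = centers, amplitude = params$A_pre,
                 sigma = params$sigma_pre, L = params$L,
                 gains = gains, offsets = offsets),
            class = "ca1_inputs")
}

#' Firing rates of the input population at a position
#'
#' Each input fires at
#' `[gain * A_pre * exp(-d^2 / (2 sigma_pre^2)) + offset]_+`
#' where `d` is the circular distance from the animal's position to the
#' neuron's place-field center; rates are rectified at zero.
#'
#' @param p A single position in `[0, L)`.
#' @param pop A [input_population()] object.
#' @return Numeric vector of length `N_pre`, all entries `>= 0`.
#' @export
input_rates <- function(p, pop) {
  d <- circular_distance(p, pop$centers, pop$L)
  r <- pop$gains * pop$amplitude * exp(-d^2 / (2 * pop$sigma^2)) +
    pop$offsets
  pmax(r, 0)
}

#' @export
print.ca1_inputs <- function(x, ...) {
  cat(sprintf("Place-tuned input population: %d neurons on [0, %g)\n",
              length(x$centers), x$L))
  cat(sprintf("  amplitude %g, width %g; centers %s\n", x$amplitude,
              x$sigma, paste(signif(x$centers, 4), collapse = ", ")))
  if (any(x$gains != 1) || any(x$offsets != 0)) {
    cat("  perturbed gains/offsets present\n")
  }
  invisible(x)
}
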