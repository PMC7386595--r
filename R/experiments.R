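#' First lap with a place field
#'
#' The first lap whose rate map of the given compartment classifies as
#' a place field under [field_metrics()].
#'
#' @param session A `ca1_session`.
#' @param compartment `"soma"` or `"dendrite"`.
#' @param threshold Amplitude threshold for the classification.
#' @return Lap index, or `NA` if no lap qualifies.
#' @export
first_field_lap <- function(session, compartment = c("soma", "dendrite"),
                            threshold = 0.1) {
  m <- switch(match.arg(compartment), soma = session$map_soma,
              dendrite = session$map_dend)
  hit <- which(apply(m, 1, function(x)
    field_metrics(x, threshold, session$params$L)$is_place_field))
  if (length(hit)) hit[1] else NA_integer_
}

#' Somatic current-injection sweep
#'
#' The silent-to-place conversion experiment: for each injected-current
#' amplitude, the frozen familiar-environment network runs one
#' no-injection lap followed by one lap with a constant, spatially
#' uniform somatic current, each sweep point starting from the same
#' frozen initial state (no carry-over between amplitudes). Because of
#' the gated dendrite-to-soma propagation the transition is
#' all-or-nothing: below the gate threshold the somatic map stays
#' flat, above it a place field appears whose amplitude does not grow
#' with the current.
#'
#' @param amplitudes Injected-current amplitudes (a.u.).
#' @param protocol Base protocol; defaults to
#'   `preset_protocol("familiar_injection")`.
#' @param threshold Place-field amplitude criterion.
#' @return A data frame with one row per amplitude: `amplitude`,
#'   `field_amplitude`, `peak`, `baseline`, `is_place_field`; the lap-2
#'   somatic maps are attached as attribute `maps`.
#' @examples
#' sweep <- current_injection_sweep(c(0, 1, 1.5))
#' sweep$is_place_field
#' @export
current_injection_sweep <- function(amplitudes = c(0, 1, 1.5),
                                    protocol = preset_protocol("familiar_injection"),
                                    threshold = 0.1) {
  maps <- list()
  rows <- lapply(amplitudes, function(a) {
    pr <- protocol
    pr$inductions <- list(induction_protocol(
      "somatic_current", region = c(0, 1), first_lap = 2, n_laps = 1,
      amplitude = a))
    pr$n_laps <- 2L
    sess <- run_session(pr)
    m <- sess$map_soma[2, ]
    maps[[length(maps) + 1]] <<- m
    fm <- field_metrics(m, threshold, pr$params$L)
    data.frame(amplitude = a, field_amplitude = fm$amplitude,
               peak = fm$peak, baseline = fm$baseline,
               is_place_field = fm$is_place_field)
  })
  out <- do.call(rbind, rows)
  attr(out, "maps") <- maps
  out
}

#' Induction region on the far side of the track
#'
#' A contiguous arc covering `frac` of the track, centered at the
#' antipode of a reference position (the pre-induction place-field
#' peak), expressed as half-open fractions of `L` as used by
#' [induction_protocol()].
#'
#' @param peak_location Reference position (track units).
#' @param frac Fraction of the track covered by the region.
#' @param L Track length.
#' @return Numeric length-2 fractions `(start, end)`, possibly wrapped.
#' @export
induction_region <- function(peak_location, frac, L = 50) {
  stopifnot(frac > 0, frac < 1)
  center <- (peak_location + L / 2) %% L
  start <- (center - frac * L / 2) %% L
  end <- (center + frac * L / 2) %% L
  c(start, end) / L
}

classify_outcome <- function(maps, region, L, threshold, consec) {
  n <- nrow(maps)
  stopifnot(n >= consec)
  rows <- (n - consec + 1):n
  fms <- lapply(rows, function(i) field_metrics(maps[i, ], threshold, L))
  fields <- vapply(fms, `[[`, logical(1), "is_place_field")
  peaks <- vapply(fms, `[[`, numeric(1), "peak_location")
  list(removed = !any(fields),
       shifted = all(fields) && all(in_region(peaks / L, region)))
}

#' Minimal number of induction laps for a place-field outcome
#'
#' Sweeps the number of consecutive dendritic-induction laps and
#' returns the smallest count that removes the original place field or
#' shifts it into the induction region. For each candidate count the
#' full session is re-run from the protocol's initial state: the
#' pre-induction laps, the induction laps (a constant dendritic current
#' inside the region), and a post-induction observation window. The
#' outcome is classified on the final `consec` laps of the window, so
#' transient removals that re-emerge are not classified as removed.
#'
#' @param protocol Base session protocol; defaults to
#'   `preset_protocol("novel_induction")`.
#' @param outcome `"removed"` (no place field on the final window) or
#'   `"shifted"` (place field with peak inside the region throughout
#'   the final window).
#' @param sweep Candidate induction-lap counts, in increasing order.
#' @param first_lap First induction lap.
#' @param region_frac Induction-region size as a fraction of the track.
#' @param amplitude Dendritic induction current (a.u.). The default 25
#'   drives the dendritic potential above the dendritic-spike threshold
#'   everywhere in the region even against familiar-environment
#'   dendritic inhibition and negative out-of-field weights.
#' @param post_window Number of observation laps after induction ends.
#' @param consec Number of final observation laps the classifier must
#'   agree on.
#' @param threshold Place-field amplitude criterion.
#' @return List with `min_laps` (smallest qualifying count or `NA`),
#'   `outcomes` (logical per sweep entry), `region` (fractions), and
#'   `peak0` (the pre-induction peak position).
#' @examples
#' \donttest{
#' res <- min_induction_laps(outcome = "shifted", sweep = c(1, 3, 5),
#'                           first_lap = 5, region_frac = 0.45)
#' res$min_laps
#' }
#' @export
min_induction_laps <- function(protocol = preset_protocol("novel_induction"),
                               outcome = c("removed", "shifted"),
                               sweep = c(1, 2, 3, 5, 10, 15),
                               first_lap = 100, region_frac = 0.15,
                               amplitude = 25, post_window = 30,
                               consec = 20, threshold = 0.1) {
  outcome <- match.arg(outcome)
  L <- protocol$params$L
  peak0 <- pre_induction_peak(protocol, first_lap, threshold)
  region <- induction_region(peak0, region_frac, L)
  hits <- logical(length(sweep))
  for (i in seq_along(sweep)) {
    k <- sweep[i]
    pr <- protocol
    pr$n_laps <- as.integer(first_lap - 1 + k + post_window)
    pr$inductions <- c(protocol$inductions, list(induction_protocol(
      "dendritic_current", region = region, first_lap = first_lap,
      n_laps = k, amplitude = amplitude)))
    sess <- run_session(pr)
    post <- sess$map_soma[(first_lap + k):pr$n_laps, , drop = FALSE]
    cls <- classify_outcome(post, region, L, threshold, consec)
    hits[i] <- cls[[outcome]]
  }
  min_laps <- if (any(hits)) sweep[which(hits)[1]] else NA_integer_
  list(min_laps = min_laps, outcomes = hits, sweep = sweep,
       region = region, peak0 = peak0)
}

pre_induction_peak <- function(protocol, first_lap, threshold = 0.1) {
  pr <- protocol
  pr$n_laps <- as.integer(max(first_lap - 1, 1))
  base <- run_session(pr)
  last <- pr$n_laps
  fm <- field_metrics(base$map_soma[last, ], threshold, pr$params$L)
  if (fm$is_place_field) return(fm$peak_location)
  # no somatic field yet (early-novel induction): fall back to the
  # dendritic tuning peak, which marks the field that would develop
  field_metrics(base$map_dend[last, ], threshold, pr$params$L)$peak_location
}
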