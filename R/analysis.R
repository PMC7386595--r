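#' Bin a one-lap trace into a spatial rate map
#'
#' Mean activity of all samples falling into each of `n_bins` half-open
#' bins covering `[0, L)`. The constant-speed trajectory guarantees
#' every bin is visited when `dt * v` does not exceed the bin width;
#' an empty bin is an error (wrong `dt`/`n_bins` combination).
#'
#' @param position Positions of the samples (track units, one lap).
#' @param activity Activity values at those samples.
#' @param n_bins Number of bins.
#' @param L Track length.
#' @return Numeric vector of per-bin mean activity, with attribute
#'   `bin_centers`.
#' @export
bin_rate_map <- function(position, activity, n_bins, L) {
  stopifnot(length(position) == length(activity), n_bins >= 1, L > 0)
  b <- pmin(floor(position / (L / n_bins)) + 1, n_bins)
  counts <- tabulate(b, n_bins)
  if (any(counts == 0)) stop("empty spatial bin")
  sums <- vapply(seq_len(n_bins), function(k) sum(activity[b == k]),
                 numeric(1))
  out <- sums / counts
  attr(out, "bin_centers") <- (seq_len(n_bins) - 0.5) * L / n_bins
  out
}

#' Place-field metrics of a rate map
#'
#' Peak, baseline, amplitude, and a place-field classification for one
#' spatially binned map. The baseline is the mean of the lowest decile
#' of bins (robust to single-bin noise); the amplitude is
#' `peak - baseline`; the map is classified as a place field when the
#' amplitude exceeds `threshold`.
#'
#' @param map Numeric vector of per-bin activity.
#' @param threshold Amplitude threshold for the place-field
#'   classification (a.u.), default 0.1.
#' @param L Track length used to convert the peak bin to a position;
#'   default 50.
#' @return A list with `peak`, `baseline`, `amplitude`,
#'   `peak_location` (track units, bin center), `peak_location_bin`,
#'   and `is_place_field`.
#' @export
field_metrics <- function(map, threshold = 0.1, L = 50) {
  map <- as.numeric(map)
  n <- length(map)
  stopifnot(n >= 10)
  k <- max(1, floor(n / 10))
  baseline <- mean(sort(map)[seq_len(k)])
  peak <- max(map)
  ib <- which.max(map)
  list(peak = peak, baseline = baseline, amplitude = peak - baseline,
       peak_location = (ib - 0.5) * L / n, peak_location_bin = ib,
       is_place_field = (peak - baseline) > threshold)
}

#' Field-change distance between two rate maps
#'
#' Each map is rescaled to unit peak and the distance is the mean
#' absolute difference across bins. The measure is symmetric,
#' non-negative, zero only for maps equal after rescaling, and
#' invariant to positive rescaling of either map. A map with zero peak
#' cannot be rescaled; it is treated as all-zero and the result is
#' flagged with attribute `zero_peak = TRUE`.
#'
#' @param map_a,map_b Rate maps on the same binning.
#' @return Mean absolute difference of the unit-peak maps (with
#'   attribute `zero_peak` when a degenerate map was encountered).
#' @export
field_change <- function(map_a, map_b) {
  map_a <- as.numeric(map_a); map_b <- as.numeric(map_b)
  if (length(map_a) != length(map_b)) stop("maps must share a binning")
  zero <- FALSE
  resc <- function(m) {
    pk <- max(m)
    if (pk <= 0) { zero <<- TRUE; rep(0, length(m)) } else m / pk
  }
  d <- mean(abs(resc(map_a) - resc(map_b)))
  if (zero) attr(d, "zero_peak") <- TRUE
  d
}

#' Block-wise spatial correlation across laps
#'
#' For each block of `block_size` consecutive laps, the mean Pearson
#' correlation over all within-block lap pairs. Laps whose maps have
#' zero variance cannot be correlated; they are excluded from the pair
#' list and reported via the `n_excluded` attribute (a block with fewer
#' than two usable laps yields `NA`).
#'
#' @param maps Matrix of per-lap rate maps (laps in rows).
#' @param block_size Laps per block (default 10).
#' @return Numeric vector of per-block mean correlations.
#' @export
spatial_correlation_blocks <- function(maps, block_size = 10) {
  maps <- as.matrix(maps)
  n_laps <- nrow(maps)
  stopifnot(block_size >= 2)
  n_blocks <- floor(n_laps / block_size)
  excluded <- 0L
  out <- vapply(seq_len(n_blocks), function(bk) {
    rows <- ((bk - 1) * block_size + 1):(bk * block_size)
    ok <- rows[apply(maps[rows, , drop = FALSE], 1, stats::sd) > 0]
    excluded <<- excluded + length(rows) - length(ok)
    if (length(ok) < 2) return(NA_real_)
    cm <- stats::cor(t(maps[ok, , drop = FALSE]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  attr(out, "n_excluded") <- excluded
  out
}

#' Detect dendritic events in a dendritic-potential trace
#'
#' Upward crossings of the dendritic potential through the
#' dendritic-spike threshold `I0`; consecutive supra-threshold samples
#' form a single event.
#'
#' @param p_dend Dendritic-potential time series.
#' @param params A [model_params()] object (supplies `I0`).
#' @return Integer indices of the samples at which events start.
#' @export
detect_dendritic_events <- function(p_dend, params) {
  if (any(!is.finite(p_dend))) stop("non-finite dendritic potential")
  above <- p_dend > params$I0
  which(above & !c(FALSE, above[-length(above)]))
}

#' Export per-lap rate maps as delimited text
#'
#' One row per (lap, bin) with the compartment name, lap index, bin
#' center and value; readable with any delimited-text tool.
#'
#' @param session A `ca1_session`.
#' @param path Output file path (tab-separated).
#' @param compartment `"soma"`, `"dendrite"`, or `"subthreshold"`.
#' @return `path`, invisibly.
#' @export
write_rate_maps <- function(session, path, compartment = "soma") {
  m <- switch(match.arg(compartment, c("soma", "dendrite", "subthreshold")),
              soma = session$map_soma, dendrite = session$map_dend,
              subthreshold = session$map_sub)
  df <- data.frame(
    compartment = compartment,
    lap = rep(seq_len(nrow(m)), each = ncol(m)),
    bin_center = rep(session$bin_centers, nrow(m)),
    activity = as.vector(t(m))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
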