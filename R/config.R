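#' Read a session protocol from a YAML file
#'
#' The config file mirrors the arguments of [ca1_protocol()]:
#'
#' ```yaml
#' preset: novel_induction        # optional parameter preset
#' params: {dt: 1, theta_homeo: 2}  # optional overrides
#' n_laps: 120
#' novelty: true
#' seed: 42
#' weights: {generator: single_bump, total: 2, delta: 0.8, bump_index: 5}
#' inductions:
#'   - {kind: dendritic_current, region: [0.875, 0.025],
#'      first_lap: 100, n_laps: 3, amplitude: 10}
#' ```
#'
#' @param path Path to the YAML protocol file.
#' @return A [ca1_protocol()].
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  par_args <- if (is.null(cfg$params)) list() else cfg$params
  params <- do.call(model_params, c(list(preset = cfg$preset), par_args))
  inds <- lapply(cfg$inductions, function(x) do.call(induction_protocol, x))
  args <- cfg[intersect(names(cfg),
                        c("n_laps", "novelty", "weights", "plasticity",
                          "n_bins", "seed", "input_novelty_coef", "name"))]
  args$params <- params
  args$inductions <- inds
  do.call(ca1_protocol, args)
}

#' Write the per-lap summaries of a session as delimited text
#'
#' One row per lap: mean activities, novelty, inhibition levels,
#' weight sum and dendritic-spike count.
#'
#' @param session A `ca1_session`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_lap_summary <- function(session, path) {
  n <- session$protocol$n_laps
  df <- data.frame(
    lap = seq_len(n),
    mean_dend = session$mean_dend,
    mean_soma = session$mean_soma,
    novelty = session$novelty,
    I_dend = session$I_dend,
    I_soma = session$I_soma,
    weight_sum = rowSums(session$w_snapshots)[seq_len(n)],
    dend_spikes = session$dend_spikes
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
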