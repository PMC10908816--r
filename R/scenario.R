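#' Generate a complete synthetic scenario
#'
#' Runs the synthetic generators end to end: site network and velocity
#' field, drifter cohorts advected from every representative (fjord-mouth)
#' site, age-binned concentration fields, the windowed connectivity matrix
#' and hydrodynamic-distance table, and finally the two ASV tables whose
#' compositional structure is planted on the measured hydrodynamic
#' distances. The result is a pure function of the configuration
#' (including its seed).
#'
#' @param config a [scenario_config()].
#' @param schedule a [seeding_schedule()].
#' @param bins list of age bins, see [default_age_bins()].
#' @param window_size connectivity averaging window (odd cell count).
#' @param dt advection time step, days.
#' @param keep_trajectories retain the per-site trajectory sets (memory
#'   permitting).
#' @return An object of class `synthetic_scenario`: `config`, `schedule`,
#'   `field`, `metadata`, `representative` (site ids),
#'   `connectivity` (long connectivity matrix), `hydro`
#'   (hydrodynamic-distance table), `asv_pro`, `asv_euk`, `trophic`,
#'   `truth`, and optionally `trajectories`.
#' @export
generate_scenario <- function(config = scenario_config(),
                              schedule = seeding_schedule(),
                              bins = default_age_bins(),
                              window_size = 15L,
                              dt = 0.25,
                              keep_trajectories = FALSE) {
  validate_scenario_config(config)
  meta <- generate_site_network(config)
  field <- generate_velocity_field(config)
  reps <- select_representative_sites(meta)

  fields <- list()
  trajs <- if (keep_trajectories) list() else NULL
  for (s in seq_len(nrow(reps))) {
    site <- reps[s, ]
    init <- seed_cohorts(site, field, schedule,
                         seed = derive_seed(config$seed,
                                            paste0("seed_", site$site_id)))
    tr <- advect(init, field, dt = dt, lifetime = schedule$lifetime,
                 release_site = site$site_id)
    if (keep_trajectories) trajs[[site$site_id]] <- tr
    for (b in bins) {
      fields[[length(fields) + 1L]] <- concentration_field(tr, b, field)
    }
  }
  cm <- connectivity_matrix(fields, reps, field, window_size = window_size)
  hd <- hydrodynamic_distance(cm)
  asv <- generate_asv_tables(meta, hd, config)

  structure(list(
    config = config, schedule = schedule, field = field,
    metadata = meta, representative = reps$site_id,
    connectivity = cm, hydro = hd,
    asv_pro = asv$asv_pro, asv_euk = asv$asv_euk,
    trophic = asv$trophic, truth = asv$truth,
    trajectories = trajs
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: %d fjords / %d sites, %d representative\n",
    x$config$n_fjords, nrow(x$metadata), length(x$representative)))
  cat(sprintf("  ASV tables: 16S %d x %d, 18S %d x %d (depth %d)\n",
              nrow(x$asv_pro$counts), ncol(x$asv_pro$counts),
              nrow(x$asv_euk$counts), ncol(x$asv_euk$counts),
              x$config$seq_depth))
  conn <- x$hydro[x$hydro$bin_hi == max(x$hydro$bin_hi), ]
  cat(sprintf("  connected pairs (longest bin): %d / %d\n",
              sum(conn$connected), nrow(conn)))
  invisible(x)
}
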