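#' Configuration of a synthetic fjord scenario
#'
#' Bundles every knob of the synthetic-data generator: the gridded coastal
#' domain, the boundary current, the along-path temperature gradient with its
#' inter-subzone step ("temperature barrier"), and the planted community
#' structure of the two marker-gene ASV tables (16S prokaryotes, 18S
#' picoeukaryotes).
#'
#' The defaults describe the study system the generator emulates: a chain of
#' 21 fjords strung along a coastal boundary current on a 4-km grid, a
#' temperature gradient from temperate (12 degC) to high-Arctic (0 degC)
#' water with a 3 degC step halfway along the path, compositional
#' distance-decay with hydrodynamic distance in both domains, roughly twice
#' the temperature sensitivity for prokaryotes as for picoeukaryotes, and a
#' prokaryotic richness penalty at the cold end.
#'
#' @param grid_nx,grid_ny grid cell counts (x = along-coast, y = cross-shore);
#'   both at least 16.
#' @param cell_size cell edge length in km.
#' @param n_fjords number of fjords strung along the current path (>= 3).
#' @param current_speed along-coast boundary-current speed, km/day.
#' @param meander_amplitude cross-stream meander amplitude as a fraction of
#'   `current_speed` (0 = straight channel flow; must be <= 2 so that all
#'   speeds stay below `2 * current_speed`).
#' @param temp_range numeric length-2, (cold end, warm end) surface
#'   temperature in degC; the span must be at least `barrier_step`.
#' @param barrier_position along-path fraction in \[0, 1\] at which the sharp
#'   inter-subzone temperature step sits.
#' @param barrier_step size of the temperature step in degC.
#' @param n_asv_pro,n_asv_euk ASV counts of the prokaryotic (16S) and
#'   picoeukaryotic (18S) tables.
#' @param decay_rate_pro,decay_rate_euk planted compositional divergence
#'   (Aitchison/CLR units) per unit hydrodynamic distance.
#' @param temp_sensitivity_pro,temp_sensitivity_euk planted divergence per
#'   degC of between-site temperature difference; both >= 0.
#' @param seq_depth reads per sample (>= 100); row sums of the generated
#'   count tables equal this exactly.
#' @param richness_cold_penalty_pro fraction of prokaryotic ASVs excluded at
#'   the coldest site, tapering linearly to 0 at the warmest site.
#' @param trophic_cold_shift CLR-unit abundance shift planting cold-site
#'   eukaryote dominance within each trophic functional group.
#' @param overdispersion Dirichlet-multinomial overdispersion of the count
#'   draw (0 = plain multinomial, the default; larger values add
#'   between-sample compositional noise beyond sampling).
#' @param local_sd within-fjord compositional jitter (Aitchison units)
#'   separating head/middle sites from the fjord-mouth site.
#' @param n_days number of daily velocity snapshots generated.
#' @param seed RNG seed; the whole scenario is a pure function of the config.
#'
#' @return An object of class `scenario_config` (a validated list).
#' @examples
#' cfg <- scenario_config(n_fjords = 5, grid_nx = 48, grid_ny = 16)
#' cfg$n_fjords
#' @export
scenario_config <- function(grid_nx = 96L,
                            grid_ny = 24L,
                            cell_size = 4,
                            n_fjords = 21L,
                            current_speed = 15,
                            meander_amplitude = 0.5,
                            temp_range = c(0, 12),
                            barrier_position = 0.5,
                            barrier_step = 3,
                            n_asv_pro = 400L,
                            n_asv_euk = 400L,
                            decay_rate_pro = 50,
                            decay_rate_euk = 50,
                            temp_sensitivity_pro = 2.4,
                            temp_sensitivity_euk = 1.2,
                            seq_depth = 10000L,
                            richness_cold_penalty_pro = 0.4,
                            trophic_cold_shift = 6,
                            overdispersion = 0,
                            local_sd = 0.5,
                            n_days = 420L,
                            seed = 1L) {
  cfg <- list(
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    cell_size = cell_size, n_fjords = as.integer(n_fjords),
    current_speed = current_speed, meander_amplitude = meander_amplitude,
    temp_range = as.numeric(temp_range),
    barrier_position = barrier_position, barrier_step = barrier_step,
    n_asv_pro = as.integer(n_asv_pro), n_asv_euk = as.integer(n_asv_euk),
    decay_rate_pro = decay_rate_pro, decay_rate_euk = decay_rate_euk,
    temp_sensitivity_pro = temp_sensitivity_pro,
    temp_sensitivity_euk = temp_sensitivity_euk,
    seq_depth = as.integer(seq_depth),
    richness_cold_penalty_pro = richness_cold_penalty_pro,
    trophic_cold_shift = trophic_cold_shift,
    overdispersion = overdispersion,
    local_sd = local_sd,
    n_days = as.integer(n_days),
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  fc_assert(is_count(cfg$grid_nx, 16) && is_count(cfg$grid_ny, 16),
            "grid dimensions must be at least 16 x 16")
  fc_assert(is_number(cfg$cell_size) && cfg$cell_size > 0,
            "cell_size must be a positive number (km)")
  fc_assert(is_count(cfg$n_fjords, 3), "n_fjords must be an integer >= 3")
  fc_assert(is_number(cfg$current_speed) && cfg$current_speed > 0,
            "current_speed must be positive (km/day)")
  fc_assert(is_number(cfg$meander_amplitude) &&
              cfg$meander_amplitude >= 0 && cfg$meander_amplitude <= 2,
            "meander_amplitude must lie in [0, 2]")
  fc_assert(length(cfg$temp_range) == 2 && all(is.finite(cfg$temp_range)) &&
              diff(cfg$temp_range) >= cfg$barrier_step,
            "temp_range must be (cold, warm) spanning at least barrier_step")
  fc_assert(is_number(cfg$barrier_position) &&
              cfg$barrier_position >= 0 && cfg$barrier_position <= 1,
            "barrier_position must lie in [0, 1]")
  fc_assert(is_number(cfg$barrier_step) && cfg$barrier_step >= 0,
            "barrier_step must be >= 0 (degC)")
  fc_assert(is_count(cfg$n_asv_pro) && is_count(cfg$n_asv_euk),
            "ASV counts must be integers >= 1")
  for (f in c("decay_rate_pro", "decay_rate_euk",
              "temp_sensitivity_pro", "temp_sensitivity_euk")) {
    fc_assert(is_number(cfg[[f]]) && cfg[[f]] >= 0,
              paste(f, "must be >= 0"))
  }
  fc_assert(is_count(cfg$seq_depth, 100), "seq_depth must be an integer >= 100")
  fc_assert(is_number(cfg$richness_cold_penalty_pro) &&
              cfg$richness_cold_penalty_pro >= 0 &&
              cfg$richness_cold_penalty_pro < 1,
            "richness_cold_penalty_pro must lie in [0, 1)")
  fc_assert(is_number(cfg$trophic_cold_shift) && cfg$trophic_cold_shift >= 0,
            "trophic_cold_shift must be >= 0")
  fc_assert(is_number(cfg$overdispersion) && cfg$overdispersion >= 0,
            "overdispersion must be >= 0")
  fc_assert(is_number(cfg$local_sd) && cfg$local_sd >= 0,
            "local_sd must be >= 0")
  fc_assert(is_count(cfg$n_days, 2), "n_days must be an integer >= 2")
  fc_assert(is_count(cfg$seed, 0), "seed must be a non-negative integer")
  # Each fjord needs a 1-cell-wide indentation plus spacing; 3 cells of
  # coastline per fjord plus a 4-cell margin each side is the minimum.
  fc_assert(cfg$grid_nx >= cfg$n_fjords * 3 + 8,
            sprintf("grid_nx = %d too small to host %d fjords (need >= %d)",
                    cfg$grid_nx, cfg$n_fjords, cfg$n_fjords * 3 + 8),
            class = "fc_sizing_error")
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic fjord scenario: %d fjords on a %dx%d grid (%g km cells)\n",
    x$n_fjords, x$grid_nx, x$grid_ny, x$cell_size))
  cat(sprintf("  current %g km/day, meander %g; T %g..%g degC, step %g at %.2f\n",
              x$current_speed, x$meander_amplitude, x$temp_range[1],
              x$temp_range[2], x$barrier_step, x$barrier_position))
  cat(sprintf("  ASVs pro/euk %d/%d, depth %d, decay %g/%g, temp-sens %g/%g\n",
              x$n_asv_pro, x$n_asv_euk, x$seq_depth,
              x$decay_rate_pro, x$decay_rate_euk,
              x$temp_sensitivity_pro, x$temp_sensitivity_euk))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Drifter cohort seeding schedule
#'
#' Describes how synthetic drifters are released at a site: cohorts of
#' `floats_per_cohort` drifters every `cohort_interval` days, spread evenly
#' over the ocean part of a `seeding_window` x `seeding_window` cell square
#' centred on the site, each cohort tracked for `lifetime` days.
#'
#' The source study released cohorts of ~1000 floats every 10 days per site,
#' in 3 x 3 grid-cell windows, tracked for five years; the defaults keep the
#' 10-day cadence and 3-cell window at desk scale (smaller cohorts, one-year
#' lifetime).
#'
#' @param cohort_interval days between cohort releases (>= 1).
#' @param floats_per_cohort drifters per cohort (>= 1).
#' @param seeding_window side length, in grid cells, of the square seeding
#'   area centred on the site (odd integer).
#' @param lifetime tracking duration per cohort in days
#'   (>= `cohort_interval`).
#' @param n_cohorts number of cohorts released per site.
#' @return An object of class `seeding_schedule`.
#' @examples
#' seeding_schedule(floats_per_cohort = 100, n_cohorts = 10)
#' @export
seeding_schedule <- function(cohort_interval = 10,
                             floats_per_cohort = 50L,
                             seeding_window = 3L,
                             lifetime = 365,
                             n_cohorts = 6L) {
  s <- list(cohort_interval = cohort_interval,
            floats_per_cohort = as.integer(floats_per_cohort),
            seeding_window = as.integer(seeding_window),
            lifetime = lifetime,
            n_cohorts = as.integer(n_cohorts))
  fc_assert(is_number(s$cohort_interval) && s$cohort_interval >= 1,
            "cohort_interval must be >= 1 day")
  fc_assert(is_count(s$floats_per_cohort), "floats_per_cohort must be >= 1")
  fc_assert(is_count(s$seeding_window) && s$seeding_window %% 2L == 1L,
            "seeding_window must be an odd cell count")
  fc_assert(is_number(s$lifetime) && s$lifetime >= s$cohort_interval,
            "lifetime must be >= cohort_interval")
  fc_assert(is_count(s$n_cohorts), "n_cohorts must be >= 1")
  class(s) <- "seeding_schedule"
  s
}
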