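#' Pipeline configuration
#'
#' Exactly one input mode must be configured: `synthetic` (a
#' [scenario_config()]; the generator supplies everything) or `paths` (a
#' named list of files for a real dataset: `metadata`, `asv_16s`,
#' `asv_18s`, optional `annotations_16s`, `annotations_18s`,
#' `velocity_field`). All randomness downstream derives from `seed`.
#'
#' @param synthetic a [scenario_config()] or `NULL`.
#' @param paths named list of input paths or `NULL`.
#' @param schedule a [seeding_schedule()].
#' @param bins age bins, see [default_age_bins()].
#' @param window_size connectivity window (odd cells).
#' @param n_perm permutations for PERMANOVA/RDA.
#' @param alpha forward-selection entry threshold.
#' @param perm_max forward-selection permutation cap.
#' @param n_boot alpha-diversity bootstrap resamples.
#' @param exclude_sites representative-site exclusion list.
#' @param seed global RNG seed, recorded in all outputs.
#' @param output_dir directory the result bundle is written to.
#' @param write_field also write the (large) gridded velocity field.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = scenario_config(),
                            paths = NULL,
                            schedule = seeding_schedule(),
                            bins = default_age_bins(),
                            window_size = 15L,
                            n_perm = 999,
                            alpha = 0.05,
                            perm_max = 200,
                            n_boot = 100,
                            exclude_sites = character(),
                            seed = 1L,
                            output_dir = tempfile("fjordconnect_run_"),
                            write_field = FALSE) {
  fc_assert(xor(is.null(synthetic), is.null(paths)),
            "exactly one of 'synthetic' and 'paths' must be set")
  if (!is.null(synthetic)) {
    fc_assert(inherits(synthetic, "scenario_config"),
              "synthetic must be a scenario_config")
    synthetic$seed <- as.integer(seed)
  } else {
    fc_assert(all(c("metadata", "asv_16s", "asv_18s", "velocity_field") %in%
                    names(paths)),
              "paths must name metadata, asv_16s, asv_18s, velocity_field")
  }
  structure(list(synthetic = synthetic, paths = paths, schedule = schedule,
                 bins = bins, window_size = as.integer(window_size),
                 n_perm = n_perm, alpha = alpha, perm_max = perm_max,
                 n_boot = n_boot, exclude_sites = exclude_sites,
                 seed = as.integer(seed), output_dir = output_dir,
                 write_field = write_field),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The file mirrors [pipeline_config()]: an optional `synthetic` mapping
#' (arguments of [scenario_config()]), an optional `paths` mapping, an
#' optional `schedule` mapping (arguments of [seeding_schedule()]), an
#' optional `bins` list of `[lo, hi]` pairs, and any scalar fields of
#' [pipeline_config()] (`window_size`, `n_perm`, `alpha`, `perm_max`,
#' `n_boot`, `seed`, `output_dir`, `exclude_sites`).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  args$synthetic <- if (!is.null(y$synthetic)) {
    do.call(scenario_config, y$synthetic)
  }
  args$paths <- y$paths
  if (!is.null(y$schedule)) {
    args$schedule <- do.call(seeding_schedule, y$schedule)
  }
  if (!is.null(y$bins)) args$bins <- lapply(y$bins, as.numeric)
  for (f in c("window_size", "n_perm", "alpha", "perm_max", "n_boot",
              "seed", "output_dir", "exclude_sites", "write_field")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(pipeline_config, args)
}

#' Run the full inference chain and write a result bundle
#'
#' Executes synthetic generation (or input loading), drifter advection and
#' connectivity, the compositional stack, alpha diversity, PERMANOVA of
#' bioclimatic subzone, RDA with forward permutation selection,
#' representative-site distance-decay correlations, Aitchison-vs-dT
#' regressions, and trophic-profile tests; writes every table (TSV/CSV), a
#' machine-readable `summary.json` and a `run_log.txt` recording versions,
#' the seed and every design flag in effect. Identical configuration and
#' seed reproduce an identical `summary.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`scenario` or
#'   inputs, `composition`, `alpha`, `permanova`, `rda`, `selection`,
#'   `pair_table`, `correlations`, `regressions`, `profiles`,
#'   `trophic_tests`, `summary`, `output_dir`).
#' @export
run_pipeline <- function(cfg) {
  fc_assert(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      fc_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "fc_stage_error")
    })
  }

  if (!is.null(cfg$synthetic)) {
    sc <- stage("synthetic", generate_scenario(
      cfg$synthetic, cfg$schedule, cfg$bins, cfg$window_size))
    meta <- sc$metadata; asv16 <- sc$asv_pro; asv18 <- sc$asv_euk
    field <- sc$field; hd <- sc$hydro; cm <- sc$connectivity
    annot <- sc$trophic
    reps <- select_representative_sites(meta, cfg$exclude_sites)
  } else {
    meta <- stage("io", read_sample_metadata(cfg$paths$metadata))
    asv16 <- stage("io", read_asv_table(
      cfg$paths$asv_16s, "16S",
      annotations_path = cfg$paths$annotations_16s))
    asv18 <- stage("io", read_asv_table(
      cfg$paths$asv_18s, "18S",
      annotations_path = cfg$paths$annotations_18s))
    field <- stage("io", read_velocity_field(cfg$paths$velocity_field))
    annot <- rbind(
      cbind(asv16$annotations[, c("asv_id", "flag", "trophic_group")],
            domain = "prokaryote"),
      cbind(asv18$annotations[, c("asv_id", "flag", "trophic_group")],
            domain = "eukaryote"))
    reps <- select_representative_sites(meta, cfg$exclude_sites)
    fields <- list()
    for (s in seq_len(nrow(reps))) {
      site <- reps[s, ]
      init <- stage("advection", seed_cohorts(
        site, field, cfg$schedule,
        seed = derive_seed(cfg$seed, paste0("seed_", site$site_id))))
      tr <- stage("advection", advect(init, field,
                                      lifetime = cfg$schedule$lifetime,
                                      release_site = site$site_id))
      for (b in cfg$bins) {
        fields[[length(fields) + 1L]] <-
          stage("connectivity", concentration_field(tr, b, field))
      }
    }
    cm <- stage("connectivity",
                connectivity_matrix(fields, reps, field, cfg$window_size))
    hd <- stage("connectivity", hydrodynamic_distance(cm))
    sc <- NULL
  }

  comp16 <- stage("composition", aitchison_from_counts(asv16))
  comp18 <- stage("composition", aitchison_from_counts(asv18))

  common <- intersect(rownames(comp16$clr), rownames(comp18$clr))
  meta_c <- meta[match(common, meta$site_id), ]

  alpha16 <- stage("diversity", alpha_diversity(
    comp16$table, n_boot = cfg$n_boot, seed = derive_seed(cfg$seed, "a16")))
  alpha18 <- stage("diversity", alpha_diversity(
    comp18$table, n_boot = cfg$n_boot, seed = derive_seed(cfg$seed, "a18")))

  env_cols <- intersect(c("temperature", "salinity", "no3", "po4", "si",
                          "fluorescence", "bottom_depth", "sun_elevation"),
                        names(meta_c))
  env <- meta_c[, env_cols, drop = FALSE]

  perm16 <- stage("diversity", permanova(
    comp16$dist[common, common], meta_c$subzone, cfg$n_perm,
    derive_seed(cfg$seed, "perm16")))
  perm18 <- stage("diversity", permanova(
    comp18$dist[common, common], meta_c$subzone, cfg$n_perm,
    derive_seed(cfg$seed, "perm18")))

  rda16 <- stage("diversity", rda_constrained(
    comp16$clr[common, , drop = FALSE], env, cfg$n_perm,
    derive_seed(cfg$seed, "rda16")))
  rda18 <- stage("diversity", rda_constrained(
    comp18$clr[common, , drop = FALSE], env, cfg$n_perm,
    derive_seed(cfg$seed, "rda18")))
  sel16 <- stage("diversity", forward_select(
    comp16$clr[common, , drop = FALSE], env, cfg$alpha, cfg$perm_max,
    derive_seed(cfg$seed, "sel16")))
  sel18 <- stage("diversity", forward_select(
    comp18$clr[common, , drop = FALSE], env, cfg$alpha, cfg$perm_max,
    derive_seed(cfg$seed, "sel18")))

  reps_c <- reps[reps$site_id %in% common, ]
  pt <- stage("coupling", build_pair_table(
    reps_c, comp16$dist, comp18$dist, hd))
  cor16 <- stage("coupling", correlate_hd_beta(pt, "16S"))
  cor18 <- stage("coupling", correlate_hd_beta(pt, "18S"))
  reg16 <- stage("coupling", suppressWarnings(beta_vs_deltaT(pt, "16S")))
  reg18 <- stage("coupling", suppressWarnings(beta_vs_deltaT(pt, "18S")))

  profiles <- stage("trophic", trophic_profiles(
    comp16$clr[common, , drop = FALSE], comp18$clr[common, , drop = FALSE],
    annot))
  ttests <- stage("trophic", trophic_group_tests(
    profiles, meta_c$subzone))

  out <- cfg$output_dir
  write_sample_metadata(meta, file.path(out, "metadata.tsv"))
  write_asv_table(asv16, file.path(out, "asv_16s.tsv"))
  write_asv_table(asv18, file.path(out, "asv_18s.tsv"))
  utils::write.csv(cm, file.path(out, "connectivity.csv"), row.names = FALSE)
  utils::write.csv(hd, file.path(out, "hydro_distance.csv"),
                   row.names = FALSE)
  utils::write.csv(alpha16, file.path(out, "alpha_16s.csv"),
                   row.names = FALSE)
  utils::write.csv(alpha18, file.path(out, "alpha_18s.csv"),
                   row.names = FALSE)
  utils::write.csv(pt, file.path(out, "pair_table.csv"), row.names = FALSE)
  utils::write.csv(rbind(cbind(marker = "16S", cor16),
                         cbind(marker = "18S", cor18)),
                   file.path(out, "hd_beta_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(cbind(marker = "16S", reg16),
                         cbind(marker = "18S", reg18)),
                   file.path(out, "deltaT_regressions.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(profiles)),
                   file.path(out, "trophic_profiles.csv"))
  utils::write.csv(ttests, file.path(out, "trophic_tests.csv"),
                   row.names = FALSE)
  if (cfg$write_field) {
    write_velocity_field(field, file.path(out, "velocity_field.csv"))
  }

  summary <- list(
    seed = cfg$seed,
    n_samples = length(common),
    n_representative = nrow(reps_c),
    n_pairs = nrow(pt),
    permanova = list(
      subzone_16S = list(r2 = perm16$r2, p = perm16$p),
      subzone_18S = list(r2 = perm18$r2, p = perm18$p)),
    rda = list(
      constrained_fraction_16S = rda16$constrained_fraction,
      constrained_fraction_18S = rda18$constrained_fraction,
      p_16S = rda16$p, p_18S = rda18$p),
    forward_selection = list(predictors_16S = sel16$predictor,
                             predictors_18S = sel18$predictor),
    hd_beta_correlations = list(
      r_16S = cor16$r, p_16S = cor16$p,
      r_18S = cor18$r, p_18S = cor18$p),
    deltaT_slope_all = list(
      slope_16S = reg16$slope[reg16$scope == "all"],
      slope_18S = reg18$slope[reg18$scope == "all"]),
    flags = list(zero_replacement = "GBM", symmetrize = "max",
                 hd_transform = "neglog10", evenness_default = "paper",
                 merge_arctic = TRUE)
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("fjordconnect %s | R %s | vegan %s",
            as.character(utils::packageVersion("fjordconnect")),
            paste(R.version$major, R.version$minor, sep = "."),
            as.character(utils::packageVersion("vegan"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("mode: %s", if (is.null(cfg$synthetic)) "real-input" else
      "synthetic"),
    sprintf("flags: zero_replacement=GBM symmetrize=max %s",
            "hd_transform=neglog10 evenness=paper merge_arctic=TRUE"),
    sprintf("bins: %s", paste(vapply(cfg$bins, function(b)
      sprintf("(%g,%g]", b[1], b[2]), character(1)), collapse = " ")),
    sprintf("window_size: %d  n_perm: %d  alpha: %g  perm_max: %d",
            cfg$window_size, cfg$n_perm, cfg$alpha, cfg$perm_max),
    sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), file.path(out, "run_log.txt"))

  invisible(list(
    scenario = sc, metadata = meta, connectivity = cm, hydro = hd,
    composition = list(`16S` = comp16, `18S` = comp18),
    alpha = list(`16S` = alpha16, `18S` = alpha18),
    permanova = list(`16S` = perm16, `18S` = perm18),
    rda = list(`16S` = rda16, `18S` = rda18),
    selection = list(`16S` = sel16, `18S` = sel18),
    pair_table = pt,
    correlations = list(`16S` = cor16, `18S` = cor18),
    regressions = list(`16S` = reg16, `18S` = reg18),
    profiles = profiles, trophic_tests = ttests,
    summary = summary, output_dir = out
  ))
}
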