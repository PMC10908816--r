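test_that("scenario configuration rejects invalid parameter combinations", {
  expect_error(scenario_config(grid_nx = 8), "16 x 16")
  expect_error(scenario_config(n_fjords = 2), "n_fjords")
  expect_error(scenario_config(n_fjords = 21, grid_nx = 40),
               class = "fc_sizing_error")
  expect_error(scenario_config(barrier_position = 1.5), "barrier_position")
  expect_error(scenario_config(seq_depth = 50), "seq_depth")
  expect_error(scenario_config(temp_range = c(0, 2), barrier_step = 3),
               "temp_range")
})

test_that("zero meander gives straight channel flow with v identically 0", {
  f <- generate_velocity_field(small_config(meander_amplitude = 0))
  expect_true(all(f$v == 0))
  off_land <- !f$mask
  u1 <- f$u[, , 1][off_land]
  expect_true(all(u1 %in% c(0, small_config()$current_speed)))
})

test_that("speeds are bounded by twice the current speed for any config", {
  for (ma in c(0, 0.5, 2)) {
    cfg <- small_config(meander_amplitude = ma, current_speed = 12)
    f <- generate_velocity_field(cfg)
    expect_lte(max(abs(f$u)), 2 * cfg$current_speed + 1e-12)
    expect_lte(max(abs(f$v)), 2 * cfg$current_speed + 1e-12)
  }
})

test_that("velocity field regeneration from one config is byte-identical", {
  f1 <- generate_velocity_field(small_config(seed = 42))
  f2 <- generate_velocity_field(small_config(seed = 42))
  expect_identical(f1, f2)
})

test_that("site network places sites on ocean cells with one representative per fjord", {
  cfg <- small_config()
  meta <- generate_site_network(cfg)
  f <- generate_velocity_field(cfg)
  expect_equal(nrow(meta), cfg$n_fjords * 3)
  expect_false(any(f$mask[cbind(meta$cell_y, meta$cell_x)]))
  per_fjord <- tapply(meta$representative, meta$fjord, sum)
  expect_true(all(per_fjord == 1))
  rep_rows <- meta[meta$representative, ]
  min_d <- tapply(meta$distance_to_mouth_km, meta$fjord, min)
  expect_equal(as.vector(min_d[rep_rows$fjord]),
               rep_rows$distance_to_mouth_km)
})

test_that("temperature decreases monotonically with one barrier step", {
  cfg <- small_config(barrier_step = 3)
  meta <- generate_site_network(cfg)
  reps <- meta[meta$representative, ]
  reps <- reps[order(reps$path_frac), ]
  dT <- diff(reps$temperature)
  expect_true(all(dT < 0))
  smooth_inc <- (diff(cfg$temp_range) - cfg$barrier_step) / cfg$n_fjords
  # exactly one adjacent gap carries the extra barrier step
  expect_equal(sum(abs(-dT - smooth_inc) > 1e-9), 1)
  expect_equal(max(-dT), smooth_inc + cfg$barrier_step, tolerance = 1e-9)

  flat <- generate_site_network(small_config(barrier_step = 0))
  fr <- flat[flat$representative, ]
  fr <- fr[order(fr$path_frac), ]
  expect_equal(max(abs(diff(fr$temperature))),
               diff(small_config()$temp_range) / cfg$n_fjords,
               tolerance = 1e-9)
})

test_that("21 fjords yield 210 unordered representative-site pairs", {
  meta <- generate_site_network(scenario_config(n_fjords = 21))
  reps <- select_representative_sites(meta)
  expect_equal(nrow(reps), 21)
  expect_equal(choose(nrow(reps), 2), 210)
})

test_that("ASV tables have exact row sums and are reproducible from config", {
  cfg <- small_config(seed = 9)
  meta <- generate_site_network(cfg)
  out1 <- generate_asv_tables(meta, NULL, cfg)
  out2 <- generate_asv_tables(meta, NULL, cfg)
  expect_identical(out1, out2)
  expect_true(all(rowSums(out1$asv_pro$counts) == cfg$seq_depth))
  expect_true(all(rowSums(out1$asv_euk$counts) == cfg$seq_depth))
})

test_that("null planting (all rates 0) leaves only multinomial noise between sites", {
  cfg <- small_config(decay_rate_pro = 0, decay_rate_euk = 0,
                      temp_sensitivity_pro = 0, temp_sensitivity_euk = 0,
                      richness_cold_penalty_pro = 0, trophic_cold_shift = 0,
                      local_sd = 0, seq_depth = 5000)
  meta <- generate_site_network(cfg)
  out <- generate_asv_tables(meta, NULL, cfg)
  # all latent compositions identical
  expect_equal(max(truth_aitchison(out$truth, "prokaryote")), 0,
               tolerance = 1e-12)
  # observed distances then carry no between-site structure: distance
  # uncorrelated with temperature difference
  d <- aitchison_from_counts(out$asv_pro)$dist
  ids <- rownames(d)
  tmp <- meta$temperature[match(ids, meta$site_id)]
  pr <- utils::combn(seq_along(ids), 2)
  ct <- stats::cor.test(d[t(pr)], abs(tmp[pr[1, ]] - tmp[pr[2, ]]))
  expect_gt(ct$p.value, 0.01)
})

test_that("cold-site richness penalty halves latent occupancy at the coldest site", {
  cfg <- small_config(richness_cold_penalty_pro = 0.5, seq_depth = 200000,
                      n_asv_pro = 200, decay_rate_pro = 0,
                      temp_sensitivity_pro = 0, trophic_cold_shift = 0,
                      local_sd = 0)
  meta <- generate_site_network(cfg)
  out <- generate_asv_tables(meta, NULL, cfg)
  occ <- out$truth$occupancy_pro
  coldest <- names(which.max(out$truth$coldness))
  warmest <- names(which.min(out$truth$coldness))
  # oracle: direct count of nonzero latent occupancies
  expect_equal(sum(occ[coldest, ]) / sum(occ[warmest, ]), 0.5,
               tolerance = 0.01)
  # at large depth the observed richness tracks the latent occupancy
  rich <- hill_diversity(out$asv_pro, q = 0)
  r_cold <- rich$diversity[rich$sample == coldest]
  r_warm <- rich$diversity[rich$sample == warmest]
  expect_equal(r_cold / r_warm, 0.5, tolerance = 0.1)
})

test_that("planted temperature sensitivity shows in 16S but not 18S latent slopes", {
  cfg <- small_config(temp_sensitivity_pro = 3, temp_sensitivity_euk = 0,
                      decay_rate_pro = 0, decay_rate_euk = 0, local_sd = 0,
                      richness_cold_penalty_pro = 0, trophic_cold_shift = 0)
  meta <- generate_site_network(cfg)
  out <- generate_asv_tables(meta, NULL, cfg)
  # oracle: regression on the noise-free latent distances
  slope_of <- function(domain) {
    d <- truth_aitchison(out$truth, domain)
    ids <- rownames(d)
    tmp <- meta$temperature[match(ids, meta$site_id)]
    pr <- utils::combn(seq_along(ids), 2)
    stats::coef(stats::lm(d[t(pr)] ~ abs(tmp[pr[1, ]] - tmp[pr[2, ]])))[2]
  }
  expect_gt(slope_of("prokaryote"), 1)
  expect_lt(abs(slope_of("eukaryote")), 1e-9)
})

test_that("generated scenario is deterministic and internally consistent", {
  cfg <- small_config(seed = 21)
  sched <- fast_schedule()
  sc1 <- generate_scenario(cfg, sched)
  sc2 <- generate_scenario(cfg, sched)
  expect_identical(sc1$hydro, sc2$hydro)
  expect_identical(sc1$asv_pro$counts, sc2$asv_pro$counts)
  expect_setequal(sc1$representative,
                  sc1$metadata$site_id[sc1$metadata$representative])
  # planted-truth record recomputes expected divergences without rerunning
  td <- truth_aitchison(sc1$truth, "prokaryote")
  expect_true(all(td >= 0) && isSymmetric(td))
})

test_that("overdispersed counts add compositional noise beyond multinomial", {
  base <- small_config(decay_rate_pro = 0, decay_rate_euk = 0,
                       temp_sensitivity_pro = 0, temp_sensitivity_euk = 0,
                       richness_cold_penalty_pro = 0, trophic_cold_shift = 0,
                       local_sd = 0, seq_depth = 5000, seed = 3)
  over <- small_config(decay_rate_pro = 0, decay_rate_euk = 0,
                       temp_sensitivity_pro = 0, temp_sensitivity_euk = 0,
                       richness_cold_penalty_pro = 0, trophic_cold_shift = 0,
                       local_sd = 0, seq_depth = 5000, seed = 3,
                       overdispersion = 0.05)
  meta <- generate_site_network(base)
  d0 <- aitchison_from_counts(
    generate_asv_tables(meta, NULL, base)$asv_pro)$dist
  d1 <- aitchison_from_counts(
    generate_asv_tables(meta, NULL, over)$asv_pro)$dist
  expect_gt(mean(d1[upper.tri(d1)]), mean(d0[upper.tri(d0)]))
  expect_true(all(rowSums(generate_asv_tables(meta, NULL,
                                              over)$asv_pro$counts) == 5000))
})
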