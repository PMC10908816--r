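make_rep_meta <- function(k, temps = NULL, subzones = NULL) {
  data.frame(
    site_id = sprintf("S%02d", seq_len(k)),
    fjord = sprintf("F%02d", seq_len(k)),
    distance_to_mouth_km = 0.5,
    temperature = if (is.null(temps)) seq(10, 1, length.out = k) else temps,
    subzone = if (is.null(subzones)) rep(c("temperate", "subarctic"),
                                         length.out = k) else subzones,
    representative = TRUE,
    stringsAsFactors = FALSE
  )
}

test_that("representative-site selection takes the fjord-mouth minimum", {
  meta <- data.frame(
    site_id = c("f1-a", "f1-b", "f1-c", "f2-a"),
    fjord = c("f1", "f1", "f1", "f2"),
    distance_to_mouth_km = c(3, 0.5, 8, 2),
    stringsAsFactors = FALSE
  )
  sel <- select_representative_sites(meta)
  expect_setequal(sel$site_id, c("f1-b", "f2-a"))

  # single-site fjord selects that site; ties break by site id with a note
  tie <- data.frame(site_id = c("z-site", "a-site"), fjord = "f",
                    distance_to_mouth_km = c(1, 1), stringsAsFactors = FALSE)
  expect_message(st <- select_representative_sites(tie), "tie")
  expect_equal(st$site_id, "a-site")
})

test_that("23 candidate stations minus 2 exclusions give 21 sites and 210 pairs", {
  meta <- generate_site_network(scenario_config(n_fjords = 23))
  all23 <- select_representative_sites(meta)
  expect_equal(nrow(all23), 23)
  expect_message(
    sel <- select_representative_sites(meta, exclude = all23$site_id[c(2, 17)]),
    "excluding")
  expect_equal(nrow(sel), 21)
  expect_equal(choose(nrow(sel), 2), 210)
})

test_that("pair table carries distances, delta-T and subzone relations", {
  k <- 5
  sites <- make_rep_meta(k, temps = c(8, 8, 5, 3, 1),
                         subzones = c("temperate", "temperate", "subarctic",
                                      "low Arctic", "low Arctic"))
  cm <- matrix(stats::runif(k * k), k, k,
               dimnames = list(sites$site_id, sites$site_id))
  d <- (cm + t(cm)) / 2; diag(d) <- 0
  hd <- data.frame(site_a = "S01", site_b = "S02", bin_lo = 0, bin_hi = 30,
                   concentration = 1e-3, connected = TRUE, distance = 0.2)
  pt <- build_pair_table(sites, d, d, hd)
  expect_equal(nrow(pt), choose(k, 2))
  expect_equal(pt$delta_T[pt$site_a == "S01" & pt$site_b == "S02"], 0)
  expect_equal(pt$relation[pt$site_a == "S01" & pt$site_b == "S02"], "within")
  expect_equal(pt$relation[pt$site_a == "S01" & pt$site_b == "S03"],
               "subarctic x temperate")
  expect_equal(pt$aitchison_16S, d[cbind(pt$site_a, pt$site_b)])
  # unconnected pairs stay as rows with NA hydrodynamic distance
  expect_equal(sum(is.na(pt$hd_0_30)), choose(k, 2) - 1)

  bad <- d[-1, -1]
  expect_error(build_pair_table(sites, bad, d, hd), class = "fc_key_error")
})

test_that("hd-beta correlation is exact on linear data and guards degeneracies", {
  k <- 8
  sites <- make_rep_meta(k)
  hdv <- seq(0, 1, length.out = choose(k, 2))
  pr <- t(utils::combn(sites$site_id, 2))
  hd <- data.frame(site_a = pr[, 1], site_b = pr[, 2], bin_lo = 0,
                   bin_hi = 30, concentration = 1e-2,
                   connected = TRUE, distance = hdv)
  d <- matrix(0, k, k, dimnames = list(sites$site_id, sites$site_id))
  d[cbind(pr[, 1], pr[, 2])] <- 2 + 3 * hdv
  d <- pmax(d, t(d))
  pt <- build_pair_table(sites, d, d, hd)
  cr <- correlate_hd_beta(pt, "16S")
  expect_equal(cr$r, 1, tolerance = 1e-12)
  expect_equal(cr$n_pairs, choose(k, 2))

  # constant hydrodynamic distances: correlation undefined, flagged
  hd$distance <- 0.4
  ptc <- build_pair_table(sites, d, d, hd)
  expect_warning(crc <- correlate_hd_beta(ptc, "16S"), "constant")
  expect_true(is.na(crc$r))

  # fewer than 3 connected pairs: bin skipped with warning
  hd$distance <- hdv
  hd$distance[-(1:2)] <- NA
  pt2 <- build_pair_table(sites, d, d, hd)
  expect_warning(cr2 <- correlate_hd_beta(pt2, "16S"), "fewer than 3")
  expect_equal(nrow(cr2), 0)
})

test_that("delta-T regression recovers exact linear structure per scope", {
  k <- 8
  sites <- make_rep_meta(k, temps = seq(12, 1, length.out = k),
                         subzones = rep(c("temperate", "subarctic"), each = 4))
  pr <- t(utils::combn(sites$site_id, 2))
  tmp <- stats::setNames(sites$temperature, sites$site_id)
  dT <- abs(tmp[pr[, 1]] - tmp[pr[, 2]])
  d <- matrix(0, k, k, dimnames = list(sites$site_id, sites$site_id))
  d[cbind(pr[, 1], pr[, 2])] <- 2 + 0.3 * dT
  d <- pmax(d, t(d))
  hd <- data.frame(site_a = pr[1, 1], site_b = pr[1, 2], bin_lo = 0,
                   bin_hi = 30, concentration = 1, connected = TRUE,
                   distance = 0)
  pt <- build_pair_table(sites, d, d, hd)
  # by-class scopes with < 3 pairs warn and are skipped; not under test here
  reg <- suppressWarnings(beta_vs_deltaT(pt, "16S"))
  expect_equal(reg$slope[reg$scope == "all"], 0.3, tolerance = 1e-10)
  expect_equal(reg$r[reg$scope == "all"], 1, tolerance = 1e-10)
  expect_true("subarctic x temperate" %in% reg$scope)

  # all-equal temperatures: flagged undefined
  sites0 <- make_rep_meta(4, temps = rep(5, 4))
  pr0 <- t(utils::combn(sites0$site_id, 2))
  d0 <- matrix(1, 4, 4, dimnames = list(sites0$site_id, sites0$site_id))
  diag(d0) <- 0
  pt0 <- build_pair_table(sites0, d0, d0, hd)
  expect_warning(r0 <- beta_vs_deltaT(pt0, "16S", scopes = "all"),
                 "zero-variance")
  expect_true(is.na(r0$slope))
})

test_that("trophic profiles normalise to 1 and honour annotations", {
  clr16 <- matrix(stats::rnorm(12), 3, 4,
                  dimnames = list(paste0("s", 1:3), paste0("p", 1:4)))
  clr16 <- clr16 - rowMeans(clr16)
  clr18 <- matrix(stats::rnorm(15), 3, 5,
                  dimnames = list(paste0("s", 1:3), paste0("e", 1:5)))
  clr18 <- clr18 - rowMeans(clr18)
  annot <- data.frame(
    asv_id = c(paste0("p", 1:4), paste0("e", 1:5)),
    domain = rep(c("prokaryote", "eukaryote"), c(4, 5)),
    trophic_group = c("autotroph", "heterotroph", "heterotroph", "unknown",
                      "autotroph", "autotroph", "mixotroph", "heterotroph",
                      "unknown"),
    stringsAsFactors = FALSE
  )
  pr <- trophic_profiles(clr16, clr18, annot)
  expect_equal(unname(rowSums(pr)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(pr >= 0))

  # column order and zero-information duplicates do not change profiles
  perm <- sample(ncol(clr18))
  pr2 <- trophic_profiles(clr16, clr18[, perm], annot)
  expect_equal(pr, pr2, tolerance = 1e-12)

  # a sample whose entire signal is autotroph-eukaryote fills that cell
  one <- matrix(c(2, 1, 0.5), 1, 3,
                dimnames = list("s1", paste0("e", 1:3)))
  empty16 <- matrix(numeric(0), 1, 0, dimnames = list("s1", NULL))
  ann1 <- data.frame(asv_id = paste0("e", 1:3), domain = "eukaryote",
                     trophic_group = "autotroph", stringsAsFactors = FALSE)
  p1 <- trophic_profiles(empty16, one, ann1)
  expect_equal(unname(p1[1, "autotroph_eukaryote"]), 1)

  # sample mismatch is a keying error
  expect_error(trophic_profiles(clr16[1:2, ], clr18, annot),
               class = "fc_key_error")
})

test_that("trophic group tests merge Arctic labels and run per cell", {
  set.seed(9)
  n <- 18
  profiles <- matrix(stats::runif(n * 7), n, 7)
  profiles <- profiles / rowSums(profiles)
  colnames(profiles) <- c("autotroph_prokaryote", "autotroph_eukaryote",
                          "mixotroph_prokaryote", "mixotroph_eukaryote",
                          "heterotroph_prokaryote", "heterotroph_eukaryote",
                          "unknown")
  rownames(profiles) <- paste0("s", 1:n)
  sz <- rep(c("high Arctic", "low Arctic", "subarctic", "temperate"),
            length.out = n)
  tt <- trophic_group_tests(profiles, sz)
  expect_setequal(unique(tt$cell), colnames(profiles))
  # merged Arctic: 3 groups -> 3 pairwise tests per cell
  expect_equal(nrow(tt), 7 * 3)
  expect_true(all(c("Arctic") %in% c(tt$group_a, tt$group_b)))
  # merge off: 4 labels -> 6 pairwise tests per cell
  tt4 <- trophic_group_tests(profiles, sz, merge_arctic = FALSE)
  expect_equal(nrow(tt4), 7 * 6)
  # identical profiles across groups: raw p = 1
  flat <- profiles; flat[] <- rep(profiles[1, ], each = n)
  ttf <- suppressWarnings(trophic_group_tests(flat, sz))
  expect_true(all(ttf$p_raw == 1))
})

test_that("correlations and regressions are invariant to site relabelling", {
  k <- 7
  sites <- make_rep_meta(k)
  pr <- t(utils::combn(sites$site_id, 2))
  set.seed(17)
  hdv <- runif(nrow(pr))
  hd <- data.frame(site_a = pr[, 1], site_b = pr[, 2], bin_lo = 0,
                   bin_hi = 30, concentration = 1e-2, connected = TRUE,
                   distance = hdv)
  d <- matrix(0, k, k, dimnames = list(sites$site_id, sites$site_id))
  d[cbind(pr[, 1], pr[, 2])] <- 1 + 2 * hdv + rnorm(nrow(pr), 0, 0.1)
  d <- pmax(d, t(d))
  base_r <- correlate_hd_beta(build_pair_table(sites, d, d, hd), "16S")$r
  base_s <- beta_vs_deltaT(build_pair_table(sites, d, d, hd), "16S",
                           scopes = "all")$slope
  perm <- sample(k)
  sites2 <- sites[perm, ]
  d2 <- d[perm, perm]
  r2 <- correlate_hd_beta(build_pair_table(sites2, d2, d2, hd), "16S")$r
  s2 <- beta_vs_deltaT(build_pair_table(sites2, d2, d2, hd), "16S",
                       scopes = "all")$slope
  expect_equal(base_r, r2, tolerance = 1e-12)
  expect_equal(base_s, s2, tolerance = 1e-12)
})
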