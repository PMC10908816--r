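#' Generate the synthetic fjord site network and sample metadata
#'
#' Places `n_fjords` fjords downstream along the boundary-current path, each
#' with three sites (head / middle / mouth) inside the fjord indentation.
#' Surface temperature decreases monotonically with along-path position from
#' the warm to the cold end of `temp_range`, with one sharp step of
#' `barrier_step` degC where the path crosses `barrier_position` (the
#' inter-subzone temperature barrier). Bioclimatic subzones (temperate,
#' subarctic, low Arctic, high Arctic) are assigned by path-position
#' quartile; geographic regions group three consecutive fjords. Nutrient
#' covariates are drawn with fjord-head enrichment (terrestrial/glacial
#' input concentrates at the head).
#'
#' @param config a [scenario_config()].
#' @return A data frame of sample metadata, one row per site: `site_id`,
#'   `fjord`, `region`, `subzone`, `path_frac`, grid cell (`cell_x`,
#'   `cell_y`) and km coordinates, `distance_to_mouth_km`, `temperature`
#'   (degC), `salinity`, `no3`, `po4`, `si` (umol/L), `fluorescence`,
#'   `bottom_depth` (m), `sun_elevation` (deg) and a logical
#'   `representative` flag marking the fjord-mouth site.
#' @export
generate_site_network <- function(config) {
  validate_scenario_config(config)
  geo <- fjord_geometry(config)
  K <- config$n_fjords
  frac <- (seq_len(K) - 0.5) / K

  warm <- config$temp_range[2]; cold <- config$temp_range[1]
  smooth_span <- warm - cold - config$barrier_step
  temp_f <- warm - smooth_span * frac -
    config$barrier_step * (frac > config$barrier_position)

  subzone_f <- cut(frac, breaks = c(0, 0.25, 0.5, 0.75, 1),
                   labels = c("temperate", "subarctic",
                              "low Arctic", "high Arctic"),
                   include.lowest = TRUE)
  fjord_id <- sprintf("F%02d", seq_len(K))
  region_f <- sprintf("region_%02d", ceiling(seq_len(K) / 3))

  roles <- c("mouth", "mid", "head")
  rows <- geo$fjord_rows                  # mouth row first
  cs <- config$cell_size

  out <- with_seed(derive_seed(config$seed, "site_network"), {
    recs <- lapply(seq_len(K), function(k) {
      head_enrich <- c(0, 1, 2)           # mouth, mid, head
      data.frame(
        site_id = paste0(fjord_id[k], "-", roles),
        fjord = fjord_id[k],
        region = region_f[k],
        subzone = as.character(subzone_f[k]),
        path_frac = frac[k],
        cell_x = geo$fjord_x[k],
        cell_y = rows[seq_along(roles)],
        x_km = (geo$fjord_x[k] - 0.5) * cs,
        y_km = (rows[seq_along(roles)] - 0.5) * cs,
        distance_to_mouth_km = (seq_along(roles) - 0.5) * cs,
        temperature = temp_f[k],
        salinity = 35 - 0.4 * head_enrich + stats::rnorm(3, 0, 0.1),
        no3 = pmax(0.1, 2 + 6 * frac[k] + 1.5 * head_enrich +
                     stats::rnorm(3, 0, 0.3)),
        po4 = pmax(0.02, 0.2 + 0.5 * frac[k] + 0.1 * head_enrich +
                     stats::rnorm(3, 0, 0.03)),
        si = pmax(0.1, 1 + 4 * frac[k] + 0.8 * head_enrich +
                    stats::rnorm(3, 0, 0.2)),
        fluorescence = pmax(0.05, 1.5 - frac[k] + 0.3 * head_enrich +
                              stats::rnorm(3, 0, 0.1)),
        bottom_depth = round(120 + 180 * stats::runif(3)),
        sun_elevation = 35 - 25 * frac[k] + stats::rnorm(3, 0, 1),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, recs)
  })
  out$representative <- stats::ave(out$distance_to_mouth_km, out$fjord,
                                   FUN = min) == out$distance_to_mouth_km
  rownames(out) <- out$site_id
  out
}

default_trophic_probs <- function(domain) {
  if (domain == "prokaryote") {
    c(autotroph = 0.15, mixotroph = 0.10, heterotroph = 0.55, unknown = 0.20)
  } else {
    c(autotroph = 0.35, mixotroph = 0.20, heterotroph = 0.25, unknown = 0.20)
  }
}

softmax <- function(v) {
  keep <- is.finite(v)
  p <- numeric(length(v))
  if (any(keep)) {
    e <- exp(v[keep] - max(v[keep]))
    p[keep] <- e / sum(e)
  }
  p
}

# Latent CLR-space model for one marker domain: base abundances + a Gaussian
# random walk along the representative-site chain (step variance proportional
# to decay_rate^2 * hydrodynamic distance, so expected Aitchison divergence
# grows with planted hydrodynamic separation) + a temperature loading with
# expected contribution temp_sensitivity * |dT|, + within-fjord jitter.
build_latent <- function(meta, hd_ref, n_asv, decay, temp_sens, local_sd,
                         seed) {
  with_seed(seed, {
    D <- n_asv
    alpha <- stats::rnorm(D, 0, 1.5)
    reps <- meta[meta$representative, ]
    reps <- reps[order(reps$path_frac, reps$site_id), ]
    K <- nrow(reps)

    walk <- matrix(0, K, D, dimnames = list(reps$site_id, NULL))
    if (K > 1) {
      for (k in seq_len(K - 1)) {
        key <- pair_key(reps$site_id[k], reps$site_id[k + 1])
        dhd <- hd_ref[key]
        if (is.null(dhd) || is.na(dhd)) {
          dhd <- abs(reps$path_frac[k + 1] - reps$path_frac[k])
        }
        step <- stats::rnorm(D, 0, decay * sqrt(max(dhd, 0)) / sqrt(D))
        walk[k + 1, ] <- walk[k, ] + step
      }
    }

    beta <- stats::rnorm(D, 0, 1 / sqrt(D))
    t_ctr <- meta$temperature - mean(meta$temperature)

    rep_of <- stats::setNames(reps$site_id[match(meta$fjord, reps$fjord)],
                              meta$site_id)
    latent <- matrix(0, nrow(meta), D, dimnames = list(meta$site_id, NULL))
    for (s in seq_len(nrow(meta))) {
      w <- walk[rep_of[meta$site_id[s]], ]
      if (!meta$representative[s]) {
        w <- w + stats::rnorm(D, 0, local_sd / sqrt(D))
      }
      latent[s, ] <- alpha + w + temp_sens * t_ctr[s] * beta
    }
    latent
  })
}

#' Generate the two synthetic ASV count tables with planted structure
#'
#' Builds, for each marker domain (16S prokaryotes, 18S picoeukaryotes),
#' latent per-site log-relative-abundance vectors whose expected pairwise
#' Aitchison distance grows with `decay_rate * hydrodynamic distance +
#' temp_sensitivity * |dT|`, then draws counts multinomially at `seq_depth`
#' reads per sample (row sums are exact). At cold sites a temperature-scaled
#' fraction (up to `richness_cold_penalty_pro` at the coldest site) of
#' prokaryotic ASVs has occupancy forced to zero, planting the lower
#' cold-site prokaryotic richness. Every ASV is labelled
#' autotroph / mixotroph / heterotroph / unknown with domain-dependent
#' probabilities, and a temperature-dependent abundance shift
#' (`trophic_cold_shift`) makes cold sites eukaryote-heavy within each named
#' trophic group. A few ASVs carry organelle (16S) or metazoan (18S) flags
#' so downstream filtering has work to do.
#'
#' @param metadata site metadata from [generate_site_network()].
#' @param connectivity a hydrodynamic-distance table from
#'   [hydrodynamic_distance()] covering all representative sites (its
#'   largest age bin anchors the planted walk), or `NULL` to fall back to
#'   along-path separation.
#' @param config a [scenario_config()].
#' @return A list with elements `asv_pro`, `asv_euk` (each an
#'   [asv_table()]), `trophic` (the pooled annotation data frame) and
#'   `truth` (planted latent matrices, occupancy masks and parameters,
#'   sufficient to recompute every expected pairwise divergence).
#' @export
generate_asv_tables <- function(metadata, connectivity, config) {
  validate_scenario_config(config)
  reps <- metadata[metadata$representative, ]
  hd_ref <- extract_reference_hd(connectivity, reps$site_id)

  tmax <- max(metadata$temperature); tmin <- min(metadata$temperature)
  coldness <- if (tmax > tmin) {
    (tmax - metadata$temperature) / (tmax - tmin)
  } else {
    rep(0, nrow(metadata))
  }
  names(coldness) <- metadata$site_id

  build_domain <- function(domain, n_asv, decay, tsens, marker) {
    latent <- build_latent(metadata, hd_ref, n_asv, decay, tsens,
                           config$local_sd,
                           derive_seed(config$seed, paste0("latent_", domain)))
    ann <- with_seed(derive_seed(config$seed, paste0("annot_", domain)), {
      probs <- default_trophic_probs(domain)
      troph <- sample(names(probs), n_asv, replace = TRUE, prob = probs)
      flag <- rep("none", n_asv)
      nflag <- max(1L, round(0.02 * n_asv))
      flagged <- sample.int(n_asv, nflag)
      flag[flagged] <- if (domain == "prokaryote") {
        sample(c("chloroplast", "mitochondria"), nflag, replace = TRUE)
      } else {
        "metazoa"
      }
      list(trophic = troph, flag = flag)
    })

    # cold-site trophic shift: named-group eukaryotes gain and named-group
    # prokaryotes lose abundance with site coldness (CLR recentring spreads
    # the balance onto the unknown cell), planting eukaryote dominance
    # within each named trophic group at cold sites
    named <- ann$trophic != "unknown"
    sgn <- if (domain == "eukaryote") 1 else -1
    latent <- latent + sgn * config$trophic_cold_shift *
      outer(coldness, as.numeric(named))

    occupancy <- matrix(TRUE, nrow(metadata), n_asv,
                        dimnames = list(metadata$site_id, NULL))
    if (domain == "prokaryote" && config$richness_cold_penalty_pro > 0) {
      n_excl <- floor(config$richness_cold_penalty_pro * coldness * n_asv)
      for (s in seq_len(nrow(metadata))) {
        if (n_excl[s] > 0) {
          occupancy[s, (n_asv - n_excl[s] + 1L):n_asv] <- FALSE
        }
      }
    }
    latent[!occupancy] <- -Inf

    counts <- with_seed(derive_seed(config$seed, paste0("counts_", domain)), {
      t(vapply(seq_len(nrow(metadata)), function(s) {
        p <- softmax(latent[s, ])
        if (config$overdispersion > 0) {
          # Dirichlet-multinomial: perturb the composition before drawing
          nz <- p > 0
          g <- stats::rgamma(sum(nz), shape = p[nz] / config$overdispersion)
          p[nz] <- if (sum(g) > 0) g / sum(g) else p[nz]
        }
        as.integer(stats::rmultinom(1, config$seq_depth, p))
      }, integer(n_asv)))
    })
    asv_ids <- sprintf("%s_ASV%04d",
                       if (domain == "prokaryote") "pro" else "euk",
                       seq_len(n_asv))
    dimnames(counts) <- list(metadata$site_id, asv_ids)
    annotations <- data.frame(
      asv_id = asv_ids,
      domain = domain,
      trophic_group = ann$trophic,
      flag = ann$flag,
      stringsAsFactors = FALSE
    )
    taxonomy <- data.frame(
      asv_id = asv_ids,
      lineage = paste0(if (domain == "prokaryote") "Bacteria" else "Eukaryota",
                       ";", ann$trophic),
      stringsAsFactors = FALSE
    )
    list(table = asv_table(counts, marker = marker, taxonomy = taxonomy,
                           annotations = annotations),
         latent = latent, occupancy = occupancy)
  }

  pro <- build_domain("prokaryote", config$n_asv_pro,
                      config$decay_rate_pro, config$temp_sensitivity_pro,
                      "16S")
  euk <- build_domain("eukaryote", config$n_asv_euk,
                      config$decay_rate_euk, config$temp_sensitivity_euk,
                      "18S")

  truth <- list(
    latent_pro = pro$latent, latent_euk = euk$latent,
    occupancy_pro = pro$occupancy, occupancy_euk = euk$occupancy,
    coldness = coldness, hd_reference = hd_ref,
    params = config
  )
  list(asv_pro = pro$table, asv_euk = euk$table,
       trophic = rbind(pro$table$annotations, euk$table$annotations),
       truth = truth)
}

# Reference hydrodynamic distances (largest age bin) keyed by unordered pair.
extract_reference_hd <- function(connectivity, rep_sites) {
  if (is.null(connectivity)) return(stats::setNames(numeric(0), character(0)))
  hd <- connectivity
  fc_assert(all(c("site_a", "site_b", "bin_hi", "distance") %in% names(hd)),
            "connectivity must be a hydrodynamic-distance table",
            "fc_key_error")
  missing <- setdiff(rep_sites, unique(c(hd$site_a, hd$site_b)))
  fc_assert(length(missing) == 0,
            paste("connectivity table missing site(s):",
                  paste(missing, collapse = ", ")),
            "fc_key_error")
  hd <- hd[hd$bin_hi == max(hd$bin_hi), ]
  stats::setNames(hd$distance, pair_key(hd$site_a, hd$site_b))
}

#' Expected (noise-free) Aitchison distances from a planted-truth record
#'
#' Recomputes the expected pairwise divergence between sites directly from
#' the latent matrices stored by [generate_asv_tables()], without rerunning
#' generation: latent vectors are restricted to the pair's shared occupied
#' support, row-centred (the CLR of the corresponding softmax composition)
#' and compared in Euclidean distance.
#'
#' @param truth the `truth` element of [generate_asv_tables()] output.
#' @param domain `"prokaryote"` or `"eukaryote"`.
#' @return A symmetric matrix of expected Aitchison distances between sites.
#' @export
truth_aitchison <- function(truth, domain = c("prokaryote", "eukaryote")) {
  domain <- match.arg(domain)
  lat <- if (domain == "prokaryote") truth$latent_pro else truth$latent_euk
  occ <- if (domain == "prokaryote") truth$occupancy_pro else truth$occupancy_euk
  S <- nrow(lat)
  d <- matrix(0, S, S, dimnames = list(rownames(lat), rownames(lat)))
  for (a in seq_len(S - 1)) {
    for (b in (a + 1):S) {
      keep <- occ[a, ] & occ[b, ]
      va <- lat[a, keep]; vb <- lat[b, keep]
      d[a, b] <- d[b, a] <- sqrt(sum(((va - mean(va)) - (vb - mean(vb)))^2))
    }
  }
  d
}
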