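#' Default cumulative drifter-age bins
#'
#' One-, three-, six- and twelve-month cumulative age windows `(0, hi]`
#' (days). Cumulative bins make connectivity monotone: widening the window
#' can only add connected pairs.
#'
#' @return A list of numeric length-2 vectors `(lo, hi]`.
#' @export
default_age_bins <- function() {
  list(c(0, 30), c(0, 90), c(0, 180), c(0, 365))
}

#' Age-binned ensemble drifter concentration field
#'
#' Pools every stored daily snapshot of every drifter (all cohorts) whose
#' age falls in `(age_bin[1], age_bin[2]]`, bins in-domain drifters to their
#' current grid cell (beached drifters count at their beaching cell), and
#' divides by the total number of pooled drifter-observations of those ages
#' — including drifters that have left the domain, which enter the
#' denominator only. The resulting per-cell fractions sum to at most 1, and
#' to exactly 1 when no drifter of the bin has left the domain.
#'
#' @param traj a `trajectory_set` from [advect()] (all cohorts of one
#'   release site), or a list of them to pool.
#' @param age_bin numeric `(lo, hi]` in days.
#' @param field the [velocity_field()] defining the grid.
#' @param snapshots `"pooled"` (default: every stored daily snapshot whose
#'   age falls in the bin) or `"bin_end"` (only the snapshot at the bin's
#'   upper bound).
#' @return An object of class `concentration_field`: `conc` (ny x nx
#'   matrix of fractions), `release_site`, `age_bin`, `n_obs` (pooled
#'   observations incl. out-of-domain), `n_in_domain`. An empty bin (no
#'   drifter reaches it) yields a zero field with `n_obs = 0`.
#' @export
concentration_field <- function(traj, age_bin, field,
                                snapshots = c("pooled", "bin_end")) {
  snapshots <- match.arg(snapshots)
  trajs <- if (inherits(traj, "trajectory_set")) list(traj) else traj
  fc_assert(length(trajs) > 0 && all(vapply(trajs, inherits, TRUE,
                                            "trajectory_set")),
            "traj must be a trajectory_set or list of them")
  lo <- age_bin[1]; hi <- age_bin[2]
  conc_counts <- matrix(0, field$ny, field$nx)
  n_obs <- 0; n_in <- 0
  for (tr in trajs) {
    ages <- tr$ages[tr$ages > lo & tr$ages <= hi]
    if (snapshots == "bin_end") ages <- ages[ages == min(hi, tr$lifetime)]
    for (a in ages) {
      col <- a + 1L
      is_out <- !is.na(tr$out_age) & tr$out_age <= a
      n_obs <- n_obs + length(is_out)
      keep <- !is_out
      if (any(keep)) {
        cl <- cell_index(field, tr$x[keep, col], tr$y[keep, col])
        idx <- (cl$i - 1L) * field$ny + cl$j
        tab <- tabulate(idx, nbins = field$ny * field$nx)
        conc_counts <- conc_counts + tab
        n_in <- n_in + sum(keep)
      }
    }
  }
  if (n_obs == 0) {
    warning(sprintf("no drifter observation in age bin (%g, %g]", lo, hi))
    conc <- conc_counts
  } else {
    conc <- conc_counts / n_obs
  }
  structure(list(
    release_site = trajs[[1]]$release_site,
    age_bin = c(lo, hi),
    conc = conc, n_obs = n_obs, n_in_domain = n_in
  ), class = "concentration_field")
}

#' Windowed release-to-receive connectivity matrix
#'
#' For each release site's concentration field and each receiving site, the
#' connectivity entry is the mean drifter concentration over a
#' `window_size x window_size` cell square centred on the receiving site's
#' cell. Land cells count in the averaging denominator; at domain edges the
#' window is clipped, shrinking the averaging area.
#'
#' @param fields a list of [concentration_field()] objects (any mix of
#'   release sites and age bins).
#' @param sites receiving-site metadata: a data frame with `site_id`,
#'   `cell_x`, `cell_y`.
#' @param field the [velocity_field()] (grid geometry).
#' @param window_size odd cell count (the study used 15 x 15); windows
#'   larger than the grid are simply clipped.
#' @return A long-format data frame of class `connectivity_matrix`:
#'   `release`, `receive`, `bin_lo`, `bin_hi`, `value`.
#' @export
connectivity_matrix <- function(fields, sites, field, window_size = 15L) {
  fc_assert(is_count(window_size) && window_size %% 2L == 1L,
            "window_size must be an odd integer")
  fc_assert(all(c("site_id", "cell_x", "cell_y") %in% names(sites)),
            "sites must provide site_id, cell_x, cell_y", "fc_key_error")
  half <- (window_size - 1L) %/% 2L
  rows <- lapply(fields, function(cf) {
    vals <- vapply(seq_len(nrow(sites)), function(s) {
      cx <- sites$cell_x[s]; cy <- sites$cell_y[s]
      ix <- max(1L, cx - half):min(field$nx, cx + half)
      iy <- max(1L, cy - half):min(field$ny, cy + half)
      mean(cf$conc[iy, ix])
    }, numeric(1))
    data.frame(release = cf$release_site, receive = sites$site_id,
               bin_lo = cf$age_bin[1], bin_hi = cf$age_bin[2],
               value = vals, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("connectivity_matrix", "data.frame")
  out
}

#' Hydrodynamic distance between site pairs
#'
#' Turns windowed connectivity into the between-site dispersal statistic:
#' directed entries of each unordered pair are symmetrised (default: the
#' larger of the two directions — transport either way can homogenise
#' communities), pairs with zero concentration in both directions are
#' marked unconnected (and excluded from normalisation, never assigned
#' distance 1), the raw distance is `-log10(concentration)`, and raw
#' distances are min-max normalised to \[0, 1\] within each age bin over
#' the connected pairs. Distance is therefore strictly decreasing in
#' symmetrised concentration within a bin: 0 for the best-connected pair,
#' 1 for the weakest connected pair.
#'
#' @param cm a [connectivity_matrix()].
#' @param symmetrize `"max"` (default) or `"mean"`.
#' @param transform `"neglog10"` (default; bounded and monotone on (0, 1])
#'   or `"reciprocal"` (`1 / log10 C`).
#' @return A data frame of class `hydro_distance_table`: `site_a`,
#'   `site_b` (unordered, a < b), `bin_lo`, `bin_hi`, `concentration`
#'   (symmetrised), `connected`, `distance` (NA when unconnected).
#' @export
hydrodynamic_distance <- function(cm, symmetrize = c("max", "mean"),
                                  transform = c("neglog10", "reciprocal")) {
  symmetrize <- match.arg(symmetrize)
  transform <- match.arg(transform)
  fc_assert(inherits(cm, "data.frame") &&
              all(c("release", "receive", "bin_lo", "bin_hi", "value") %in%
                    names(cm)),
            "cm must be a connectivity_matrix", "fc_key_error")
  cm <- cm[cm$release != cm$receive, ]
  key <- pair_key(cm$release, cm$receive)
  bins <- unique(cm[, c("bin_lo", "bin_hi")])
  out <- lapply(seq_len(nrow(bins)), function(b) {
    sl <- cm[cm$bin_lo == bins$bin_lo[b] & cm$bin_hi == bins$bin_hi[b], ]
    k <- pair_key(sl$release, sl$receive)
    agg <- if (symmetrize == "max") {
      tapply(sl$value, k, max)
    } else {
      tapply(sl$value, k, mean)
    }
    ab <- do.call(rbind, strsplit(names(agg), "|", fixed = TRUE))
    conc <- as.numeric(agg)
    connected <- conc > 0
    raw <- rep(NA_real_, length(conc))
    raw[connected] <- if (transform == "neglog10") {
      -log10(conc[connected])
    } else {
      1 / log10(conc[connected])
    }
    dist <- rep(NA_real_, length(conc))
    if (any(connected)) {
      rng <- range(raw[connected])
      dist[connected] <- if (diff(rng) > 0) {
        (raw[connected] - rng[1]) / diff(rng)
      } else {
        0
      }
    } else {
      warning(sprintf("all pairs unconnected in age bin (%g, %g]",
                      bins$bin_lo[b], bins$bin_hi[b]))
    }
    data.frame(site_a = ab[, 1], site_b = ab[, 2],
               bin_lo = bins$bin_lo[b], bin_hi = bins$bin_hi[b],
               concentration = conc, connected = connected,
               distance = dist, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("hydro_distance_table", "data.frame")
  out
}
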