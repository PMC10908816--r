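#' Select one representative (fjord-mouth) site per fjord
#'
#' Between-fjord community structure dominates within-fjord structure, so
#' fjords enter the connectivity analyses through a single representative
#' site: the one closest to the fjord mouth. Ties are broken
#' deterministically by site id (logged). An exclusion list removes
#' mouth stations that the flow model's coastline cannot resolve; since a
#' fjord is represented only by its mouth station, excluding that station
#' removes the fjord from the representative set.
#'
#' @param meta metadata frame from [generate_site_network()] (needs
#'   `site_id`, `fjord`, `distance_to_mouth_km`).
#' @param exclude character vector of representative site ids to drop
#'   after selection (their fjords leave the analysis).
#' @return The metadata rows of the selected sites, at most one per fjord,
#'   ordered by fjord.
#' @export
select_representative_sites <- function(meta, exclude = character()) {
  fc_assert(all(c("site_id", "fjord", "distance_to_mouth_km") %in%
                  names(meta)),
            "meta must have site_id, fjord, distance_to_mouth_km",
            "fc_key_error")
  picked <- lapply(split(meta, meta$fjord), function(f) {
    best <- f[f$distance_to_mouth_km == min(f$distance_to_mouth_km), ,
              drop = FALSE]
    if (nrow(best) > 1) {
      best <- best[order(best$site_id), , drop = FALSE]
      message(sprintf(
        "select_representative_sites: tie in fjord %s broken by site id (%s)",
        best$fjord[1], best$site_id[1]))
    }
    best[1, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  if (length(exclude) > 0) {
    dropped <- intersect(out$site_id, exclude)
    if (length(dropped) > 0) {
      message("select_representative_sites: excluding station(s) ",
              paste(dropped, collapse = ", "),
              " (their fjords leave the analysis)")
    }
    out <- out[!(out$site_id %in% exclude), , drop = FALSE]
  }
  fc_assert(nrow(out) > 0, "all representative sites excluded")
  rownames(out) <- out$site_id
  out[order(out$fjord), , drop = FALSE]
}

#' Build the representative-site pair table
#'
#' One row per unordered pair of representative sites, carrying both
#' markers' Aitchison distances, the hydrodynamic distance in every age
#' bin (NA where the pair is oceanographically unconnected; such pairs
#' stay in the table and are excluded only inside correlations), the
#' absolute temperature difference, both sites' temperatures and the
#' subzone relation (`"within"` or the sorted crossing class, e.g.
#' `"subarctic x temperate"`).
#'
#' @param sites representative-site metadata from
#'   [select_representative_sites()].
#' @param d16,d18 Aitchison distance matrices (sample ids as dimnames)
#'   for the 16S and 18S tables.
#' @param hd a [hydrodynamic_distance()] table.
#' @return A data frame of class `pair_table` with columns `site_a`,
#'   `site_b`, `aitchison_16S`, `aitchison_18S`, `delta_T`, `temp_a`,
#'   `temp_b`, `relation`, `within_subzone` and one `hd_<lo>_<hi>` column
#'   per age bin; the bin bounds are attached as attribute `"bins"`.
#' @export
build_pair_table <- function(sites, d16, d18, hd) {
  ids <- sort(sites$site_id)
  for (nm in c("d16", "d18")) {
    d <- get(nm)
    missing <- setdiff(ids, rownames(d))
    fc_assert(length(missing) == 0,
              paste0("site(s) missing from ", nm, ": ",
                     paste(missing, collapse = ", ")),
              "fc_key_error")
  }
  pr <- utils::combn(ids, 2)
  a <- pr[1, ]; b <- pr[2, ]
  tmp <- stats::setNames(sites$temperature, sites$site_id)
  sz <- stats::setNames(sites$subzone, sites$site_id)
  relation <- ifelse(
    sz[a] == sz[b], "within",
    paste(pmin(sz[a], sz[b]), pmax(sz[a], sz[b]), sep = " x "))
  out <- data.frame(
    site_a = a, site_b = b,
    aitchison_16S = d16[cbind(a, b)],
    aitchison_18S = d18[cbind(a, b)],
    delta_T = abs(tmp[a] - tmp[b]),
    temp_a = unname(tmp[a]), temp_b = unname(tmp[b]),
    relation = unname(relation),
    within_subzone = unname(sz[a] == sz[b]),
    stringsAsFactors = FALSE
  )
  bins <- unique(hd[, c("bin_lo", "bin_hi")])
  key <- pair_key(out$site_a, out$site_b)
  for (k in seq_len(nrow(bins))) {
    sl <- hd[hd$bin_lo == bins$bin_lo[k] & hd$bin_hi == bins$bin_hi[k], ]
    v <- stats::setNames(sl$distance, pair_key(sl$site_a, sl$site_b))
    out[[sprintf("hd_%g_%g", bins$bin_lo[k], bins$bin_hi[k])]] <-
      unname(v[key])
  }
  rownames(out) <- NULL
  attr(out, "bins") <- bins
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Correlate hydrodynamic distance with Aitchison distance per age bin
#'
#' Pearson correlation between the normalised hydrodynamic distances and
#' the chosen marker's Aitchison distances, one correlation per age bin,
#' restricted to oceanographically connected pairs. Bins with fewer than 3
#' connected pairs are skipped with a warning; bins whose hydrodynamic
#' distances are constant are flagged (r undefined).
#'
#' @param pt a [build_pair_table()] result.
#' @param marker `"16S"` or `"18S"`.
#' @return A data frame with one row per usable bin: `bin_lo`, `bin_hi`,
#'   `r`, `p`, `n_pairs`.
#' @export
correlate_hd_beta <- function(pt, marker = c("16S", "18S")) {
  marker <- match.arg(marker)
  beta <- pt[[paste0("aitchison_", marker)]]
  bins <- attr(pt, "bins")
  rows <- lapply(seq_len(nrow(bins)), function(k) {
    col <- sprintf("hd_%g_%g", bins$bin_lo[k], bins$bin_hi[k])
    hdv <- pt[[col]]
    ok <- !is.na(hdv)
    if (sum(ok) < 3) {
      warning(sprintf("bin (%g, %g]: fewer than 3 connected pairs; skipped",
                      bins$bin_lo[k], bins$bin_hi[k]))
      return(NULL)
    }
    if (stats::sd(hdv[ok]) == 0) {
      warning(sprintf("bin (%g, %g]: constant hydrodynamic distances; ",
                      bins$bin_lo[k], bins$bin_hi[k]),
              "correlation undefined")
      return(data.frame(bin_lo = bins$bin_lo[k], bin_hi = bins$bin_hi[k],
                        r = NA_real_, p = NA_real_, n_pairs = sum(ok)))
    }
    ct <- stats::cor.test(hdv[ok], beta[ok], method = "pearson")
    data.frame(bin_lo = bins$bin_lo[k], bin_hi = bins$bin_hi[k],
               r = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ok))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      r = numeric(0), p = numeric(0), n_pairs = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Regress Aitchison distance on between-site temperature difference
#'
#' Ordinary least squares of a marker's Aitchison distance on `delta_T`,
#' fitted separately per scope: all pairs, within-subzone pairs, and each
#' subzone-crossing class. Scopes with fewer than 3 pairs are skipped;
#' zero-variance `delta_T` is flagged (slope undefined).
#'
#' @param pt a [build_pair_table()] result.
#' @param marker `"16S"` or `"18S"`.
#' @param scopes which scopes to fit: any of `"all"`, `"within"` and
#'   crossing-class labels appearing in `pt$relation`; the default fits
#'   all of them.
#' @return A data frame with one row per fitted scope: `scope`, `slope`,
#'   `intercept`, `r`, `ci_lo`, `ci_hi` (95% slope CI), `n`.
#' @export
beta_vs_deltaT <- function(pt, marker = c("16S", "18S"), scopes = NULL) {
  marker <- match.arg(marker)
  beta <- pt[[paste0("aitchison_", marker)]]
  if (is.null(scopes)) {
    scopes <- c("all", "within", sort(unique(pt$relation[!pt$within_subzone])))
  }
  rows <- lapply(scopes, function(sc) {
    sel <- switch(sc,
                  all = rep(TRUE, nrow(pt)),
                  within = pt$within_subzone,
                  pt$relation == sc)
    if (sum(sel) < 3) {
      warning(sprintf("scope '%s': fewer than 3 pairs; skipped", sc))
      return(NULL)
    }
    dT <- pt$delta_T[sel]; y <- beta[sel]
    if (stats::sd(dT) == 0) {
      warning(sprintf("scope '%s': zero-variance delta_T; slope undefined",
                      sc))
      return(data.frame(scope = sc, slope = NA_real_, intercept = NA_real_,
                        r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        n = sum(sel), stringsAsFactors = FALSE))
    }
    fit <- stats::lm(y ~ dT)
    ci <- stats::confint(fit, "dT", level = 0.95)
    data.frame(scope = sc, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r = stats::cor(dT, y), ci_lo = ci[1], ci_hi = ci[2],
               n = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(scope = character(0), slope = numeric(0),
                      intercept = numeric(0), r = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0), n = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Trophic functional-group profiles from concatenated CLR tables
#'
#' Per sample, the two independently CLR-transformed marker tables are
#' concatenated, shifted by subtracting the sample-wise minimum (making
#' every contribution non-negative) and divided by the sample total, so
#' contributions sum to 1. Shifted-normalised contributions are then summed
#' within each trophic-group x domain cell; unannotated signal is kept as
#' an explicit `unknown` cell rather than dropped, preserving the
#' normalisation.
#'
#' @param clr16,clr18 CLR matrices (from [clr()]) of the 16S and 18S
#'   tables over the same samples.
#' @param annot annotation data frame with `asv_id`, `domain`
#'   (`"prokaryote"`/`"eukaryote"`) and `trophic_group`.
#' @return A samples x 7 matrix of class `trophic_profile` with columns
#'   `autotroph_prokaryote`, `autotroph_eukaryote`, `mixotroph_prokaryote`,
#'   `mixotroph_eukaryote`, `heterotroph_prokaryote`,
#'   `heterotroph_eukaryote`, `unknown`; each row sums to 1.
#' @export
trophic_profiles <- function(clr16, clr18, annot) {
  fc_assert(setequal(rownames(clr16), rownames(clr18)) &&
              nrow(clr16) == nrow(clr18),
            "clr16 and clr18 must cover the same samples", "fc_key_error")
  clr18 <- clr18[rownames(clr16), , drop = FALSE]
  both <- cbind(clr16, clr18)
  ids <- colnames(both)
  fc_assert(all(ids %in% annot$asv_id),
            "every ASV must appear in the annotation table", "fc_key_error")
  ann <- annot[match(ids, annot$asv_id), ]
  cell <- ifelse(ann$trophic_group == "unknown", "unknown",
                 paste(ann$trophic_group, ann$domain, sep = "_"))
  cells <- c("autotroph_prokaryote", "autotroph_eukaryote",
             "mixotroph_prokaryote", "mixotroph_eukaryote",
             "heterotroph_prokaryote", "heterotroph_eukaryote", "unknown")
  out <- matrix(0, nrow(both), length(cells),
                dimnames = list(rownames(both), cells))
  for (s in seq_len(nrow(both))) {
    w <- both[s, ] - min(both[s, ])
    tot <- sum(w)
    w <- if (tot > 0) w / tot else rep(1 / length(w), length(w))
    agg <- tapply(w, factor(cell, levels = cells), sum, default = 0)
    out[s, ] <- agg
  }
  attr(out, "normalization") <- "min-shift-sum"
  class(out) <- c("trophic_profile", class(out))
  out
}

#' Eukaryote share of each named trophic group
#'
#' For every sample and each of autotroph / mixotroph / heterotroph, the
#' fraction of the group's signal carried by eukaryotes:
#' `euk / (euk + pro)`.
#'
#' @param profiles a [trophic_profiles()] matrix.
#' @return A samples x 3 matrix of shares in \[0, 1\].
#' @export
trophic_euk_share <- function(profiles) {
  groups <- c("autotroph", "mixotroph", "heterotroph")
  out <- sapply(groups, function(g) {
    e <- profiles[, paste0(g, "_eukaryote")]
    p <- profiles[, paste0(g, "_prokaryote")]
    ifelse(e + p > 0, e / (e + p), NA_real_)
  })
  rownames(out) <- rownames(profiles)
  out
}

#' Test trophic-cell differences between bioclimatic subzones
#'
#' Runs the [group_tests()] scheme (default: ANOVA + pairwise Welch
#' t-tests, Bonferroni within each cell's pairwise family) on every
#' trophic x domain cell of the profile matrix across subzones. By default
#' the high and low Arctic are merged into one `"Arctic"` group (the
#' Arctic subzones are individually small).
#'
#' @param profiles a [trophic_profiles()] matrix.
#' @param subzones character/factor of bioclimatic subzone per sample
#'   (same order as profile rows).
#' @param merge_arctic merge `"low Arctic"` and `"high Arctic"` into
#'   `"Arctic"`.
#' @param scheme passed to [group_tests()].
#' @return A data frame stacking each cell's pairwise results with a
#'   leading `cell` column; each cell's overall test is kept in attribute
#'   `"overall"` (named list).
#' @export
trophic_group_tests <- function(profiles, subzones, merge_arctic = TRUE,
                                scheme = "anova_welch") {
  subzones <- as.character(subzones)
  fc_assert(length(subzones) == nrow(profiles),
            "one subzone label per profile row", "fc_key_error")
  if (merge_arctic) {
    subzones[subzones %in% c("low Arctic", "high Arctic")] <- "Arctic"
  }
  tab <- table(subzones)
  fc_assert(sum(tab >= 2) >= 2,
            "need >= 2 subzones with >= 2 samples each",
            "fc_degenerate_design")
  cells <- colnames(profiles)
  overall <- list()
  rows <- lapply(cells, function(cl) {
    gt <- group_tests(profiles[, cl], subzones, scheme = scheme)
    overall[[cl]] <<- attr(gt, "overall")
    cbind(cell = cl, as.data.frame(gt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "overall") <- overall
  out
}
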