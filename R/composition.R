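#' Construct an ASV count table
#'
#' @param counts samples x ASVs matrix of non-negative integers with unique
#'   row (sample) and column (ASV) names.
#' @param marker `"16S"` (prokaryotes) or `"18S"` (picoeukaryotes).
#' @param taxonomy optional data frame with `asv_id` and lineage columns.
#' @param annotations optional data frame with `asv_id`, `flag`
#'   (`"none"`, `"mitochondria"`, `"chloroplast"`, `"metazoa"`) and
#'   `trophic_group` (`"autotroph"`, `"mixotroph"`, `"heterotroph"`,
#'   `"unknown"`); missing columns are filled with defaults.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, marker = c("16S", "18S"), taxonomy = NULL,
                      annotations = NULL) {
  marker <- match.arg(marker)
  counts <- as.matrix(counts)
  fc_assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
            "counts must carry sample (row) and ASV (column) names")
  fc_assert(!anyDuplicated(rownames(counts)) &&
              !anyDuplicated(colnames(counts)),
            "sample and ASV ids must be unique")
  fc_assert(all(counts >= 0), "counts must be non-negative")
  fc_assert(all(counts == round(counts)), "counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(annotations)) {
    annotations <- data.frame(asv_id = colnames(counts),
                              flag = "none", trophic_group = "unknown",
                              stringsAsFactors = FALSE)
  }
  fc_assert(all(colnames(counts) %in% annotations$asv_id),
            "annotations must cover every ASV", "fc_key_error")
  annotations <- annotations[match(colnames(counts), annotations$asv_id), ,
                             drop = FALSE]
  structure(list(counts = counts, marker = marker,
                 taxonomy = taxonomy, annotations = annotations),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table (%s): %d samples x %d ASVs, %d total reads\n",
              x$marker, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Filter an ASV table
#'
#' Applies the table-hygiene rules used before any compositional analysis:
#' drops ASVs with a total count of <= 1 across all samples (singletons and
#' absentees), drops organelle reads (ASVs flagged mitochondria or
#' chloroplast) from 16S tables and metazoan ASVs from 18S tables, then
#' drops — with a message naming them — any samples left with zero reads.
#'
#' @param t an [asv_table()].
#' @return The filtered [asv_table()]; ids of dropped samples are attached
#'   as attribute `"dropped_samples"`.
#' @export
filter_asvs <- function(t) {
  fc_assert(inherits(t, "asv_table"), "t must be an asv_table")
  flags <- t$annotations$flag
  bad_flag <- if (t$marker == "16S") {
    flags %in% c("mitochondria", "chloroplast")
  } else {
    flags %in% "metazoa"
  }
  keep_asv <- colSums(t$counts) > 1 & !bad_flag
  counts <- t$counts[, keep_asv, drop = FALSE]
  dropped <- rownames(counts)[rowSums(counts) == 0]
  if (length(dropped) > 0) {
    message("filter_asvs: dropping sample(s) with zero reads after ",
            "filtering: ", paste(dropped, collapse = ", "))
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  }
  out <- asv_table(counts, marker = t$marker,
                   taxonomy = if (!is.null(t$taxonomy)) {
                     t$taxonomy[t$taxonomy$asv_id %in% colnames(counts), ,
                                drop = FALSE]
                   },
                   annotations = t$annotations[keep_asv, , drop = FALSE])
  attr(out, "dropped_samples") <- dropped
  out
}

#' Bayesian-multiplicative zero replacement
#'
#' Replaces zero counts by small positive proportions before log-ratio
#' analysis, using the Bayesian-multiplicative treatment: the posterior
#' expectation of a zero part under a Dirichlet prior with strength
#' `s_i = sqrt(n_i)` (square-root prior) and prior proportions `t_j`, with
#' the non-zero parts adjusted multiplicatively so each row still sums
#' to 1. The default `"GBM"` (geometric Bayesian-multiplicative) takes
#' `t_j` proportional to the geometric mean of part `j`'s observed non-zero
#' proportions across samples, `"SQ"` uses the uniform prior `t_j = 1/D`,
#' and `"multiplicative"` is the closed-form simple multiplicative
#' replacement with a fixed imputed proportion `delta` (the classical
#' fallback, handy as an oracle). Imputed values are capped below each
#' sample's smallest observed proportion (at 65%, re-adjusting the closure
#' iteratively), so replacement never overtakes observed parts.
#'
#' @param t an [asv_table()] or a samples x parts count matrix.
#' @param method `"GBM"`, `"SQ"` or `"multiplicative"`.
#' @param delta imputed proportion for `method = "multiplicative"`.
#' @return A samples x parts matrix of strictly positive proportions, rows
#'   summing to 1.
#' @export
replace_zeros <- function(t, method = c("GBM", "SQ", "multiplicative"),
                          delta = NULL) {
  method <- match.arg(method)
  x <- if (inherits(t, "asv_table")) t$counts else as.matrix(t)
  fc_assert(all(x >= 0), "counts must be non-negative")
  nz <- rowSums(x > 0)
  fc_assert(all(nz >= 2),
            paste("degenerate sample(s) with < 2 nonzero parts:",
                  paste(rownames(x)[nz < 2], collapse = ", ")),
            "fc_degenerate_sample")
  n_i <- rowSums(x)
  p <- x / n_i
  D <- ncol(x)

  if (method == "multiplicative") {
    fc_assert(is_number(delta) && delta > 0 && delta < 1 / D * D,
              "delta must be a positive proportion")
    out <- p
    for (i in seq_len(nrow(x))) {
      z <- x[i, ] == 0
      if (any(z)) {
        out[i, z] <- delta
        out[i, !z] <- p[i, !z] * (1 - sum(z) * delta)
      }
    }
    return(out)
  }

  t_j <- if (method == "GBM") {
    g <- vapply(seq_len(D), function(j) {
      obs <- p[x[, j] > 0, j]
      if (length(obs) == 0) NA_real_ else exp(mean(log(obs)))
    }, numeric(1))
    # parts never observed fall back to the smallest observed prior mass
    g[is.na(g)] <- min(g, na.rm = TRUE)
    g / sum(g)
  } else {
    rep(1 / D, D)
  }

  out <- p
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (!any(z)) next
    s_i <- sqrt(n_i[i])
    r <- t_j[z] * s_i / (n_i[i] + s_i)
    minp <- min(p[i, !z])
    # cap imputations below the smallest observed (adjusted) proportion,
    # re-closing until stable
    for (it in 1:10) {
      fac <- 1 - sum(r)
      cap <- 0.65 * minp * fac
      if (all(r <= cap + 1e-15)) break
      r <- pmin(r, cap)
    }
    out[i, z] <- r
    out[i, !z] <- p[i, !z] * (1 - sum(r))
  }
  fc_assert(all(out > 0), "zero replacement failed to produce positive parts")
  out
}

#' Centred log-ratio transform
#'
#' Maps each row of a strictly positive composition to
#' `ln(part / geometric mean of the row)`. Rows of the result sum to zero;
#' the transform is invariant to row rescaling.
#'
#' @param p samples x parts matrix of strictly positive values.
#' @return A samples x parts matrix of CLR values; the per-sample geometric
#'   mean reference is attached as attribute `"geometric_mean"`.
#' @export
clr <- function(p) {
  p <- as.matrix(p)
  fc_assert(all(is.finite(p)) && all(p > 0),
            "clr requires strictly positive entries", "fc_domain_error")
  lp <- log(p)
  gm <- rowMeans(lp)
  out <- lp - gm
  attr(out, "geometric_mean") <- exp(gm)
  out
}

#' Aitchison distance matrix
#'
#' Pairwise Euclidean distance between the CLR-transformed samples — the
#' compositional beta-diversity metric used throughout the package.
#'
#' @param c a CLR matrix from [clr()] (samples x parts).
#' @return A symmetric samples x samples distance matrix with zero
#'   diagonal and the sample names as dimnames.
#' @export
aitchison <- function(c) {
  d <- as.matrix(stats::dist(c, method = "euclidean"))
  dimnames(d) <- list(rownames(c), rownames(c))
  d
}

#' One-call Aitchison distances from counts
#'
#' Convenience wrapper chaining [filter_asvs()], [replace_zeros()], [clr()]
#' and [aitchison()].
#'
#' @param t an [asv_table()].
#' @param method zero-replacement method, see [replace_zeros()].
#' @return A list with `clr` (the CLR matrix) and `dist` (the Aitchison
#'   distance matrix).
#' @export
aitchison_from_counts <- function(t, method = "GBM") {
  ft <- filter_asvs(t)
  cm <- clr(replace_zeros(ft, method = method))
  list(clr = cm, dist = aitchison(cm), table = ft)
}
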