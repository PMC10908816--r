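#' Hill diversity of one order
#'
#' Hill number of order `q` per sample: `q = 0` is observed richness (count
#' of non-zero ASVs), `q = 1` the exponential of Shannon entropy (effective
#' number of equally-abundant ASVs). An optional bootstrap standard error
#' resamples each sample multinomially at its observed depth.
#'
#' @param t an [asv_table()] or samples x ASVs count matrix.
#' @param q Hill order, 0 or 1.
#' @param n_boot bootstrap resamples for the s.e. (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return A data frame with `sample`, `q`, `diversity` and (if
#'   `n_boot > 0`) `se`.
#' @export
hill_diversity <- function(t, q = 0, n_boot = 0, seed = 1L) {
  fc_assert(q %in% c(0, 1), "q must be 0 or 1")
  x <- if (inherits(t, "asv_table")) t$counts else as.matrix(t)
  fc_assert(all(rowSums(x) > 0), "empty sample(s): all totals must be > 0")
  div1 <- function(counts) {
    if (q == 0) return(sum(counts > 0))
    p <- counts[counts > 0] / sum(counts)
    exp(-sum(p * log(p)))
  }
  d <- apply(x, 1, div1)
  out <- data.frame(sample = rownames(x), q = q, diversity = unname(d),
                    stringsAsFactors = FALSE)
  if (n_boot > 0) {
    out$se <- with_seed(seed, {
      vapply(seq_len(nrow(x)), function(i) {
        depth <- sum(x[i, ])
        reps <- vapply(seq_len(n_boot), function(b) {
          div1(stats::rmultinom(1, depth, x[i, ] / depth)[, 1])
        }, numeric(1))
        stats::sd(reps)
      }, numeric(1))
    })
  }
  out
}

#' Alpha diversity summary per sample
#'
#' Richness (Hill q = 0), Shannon entropy (nats), Hill-Shannon diversity
#' (Hill q = 1) and both evenness variants (see [evenness()]) for every
#' sample, with optional bootstrap standard errors.
#'
#' @inheritParams hill_diversity
#' @return A data frame of class `alpha_diversity` with one row per sample:
#'   `sample`, `richness`, `shannon_entropy`, `hill_shannon`,
#'   `evenness_paper`, `evenness_pielou`, and `richness_se`/`hill_shannon_se`
#'   when `n_boot > 0`.
#' @export
alpha_diversity <- function(t, n_boot = 0, seed = 1L) {
  x <- if (inherits(t, "asv_table")) t$counts else as.matrix(t)
  fc_assert(all(rowSums(x) > 0), "empty sample(s): all totals must be > 0")
  shannon <- apply(x, 1, function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  })
  out <- data.frame(
    sample = rownames(x),
    richness = apply(x, 1, function(z) sum(z > 0)),
    shannon_entropy = unname(shannon),
    stringsAsFactors = FALSE
  )
  out$hill_shannon <- exp(out$shannon_entropy)
  out$evenness_paper <- evenness(out, "paper")
  out$evenness_pielou <- evenness(out, "pielou")
  if (n_boot > 0) {
    out$richness_se <- hill_diversity(x, 0, n_boot,
                                      derive_seed(seed, "rich"))$se
    out$hill_shannon_se <- hill_diversity(x, 1, n_boot,
                                          derive_seed(seed, "hill"))$se
  }
  class(out) <- c("alpha_diversity", "data.frame")
  out
}

#' Evenness of per-sample diversity
#'
#' Two readings of Shannon-based evenness: `"paper"` divides Shannon
#' entropy by sample richness `S` (the literal formula of the source
#' protocol), `"pielou"` is the classical Pielou index `H / ln(S)`. Both
#' are reported by [alpha_diversity()]; `"paper"` is the default here.
#' Pielou evenness is undefined for single-ASV samples (flagged `NaN` with
#' a warning).
#'
#' @param a an [alpha_diversity()] frame (or any frame with
#'   `shannon_entropy` and `richness` columns).
#' @param variant `"paper"` or `"pielou"`.
#' @return Numeric vector, one value per sample.
#' @export
evenness <- function(a, variant = c("paper", "pielou")) {
  variant <- match.arg(variant)
  fc_assert(all(a$richness >= 1), "richness must be >= 1")
  if (variant == "paper") {
    a$shannon_entropy / a$richness
  } else {
    if (any(a$richness == 1)) {
      warning("Pielou evenness undefined for single-ASV sample(s); ",
              "returning NaN")
    }
    a$shannon_entropy / log(a$richness)
  }
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' One-factor PERMANOVA: partitions the (squared) pairwise distances by a
#' grouping factor via the Gower-centred inner-product decomposition and
#' tests the pseudo-F statistic by free (unrestricted) permutation of the
#' rows, with the add-one convention `p = (1 + #permuted F >= observed) /
#' (1 + n_perm)`. Computed through `vegan::adonis2`.
#'
#' @param d a distance matrix (`dist` or symmetric matrix) over samples.
#' @param groups factor (or coercible) of group labels, one per sample.
#' @param n_perm number of permutations (>= 99; the protocol default
#'   is 999).
#' @param seed RNG seed for the permutations.
#' @return An object of class `permanova_result`: `r2`, `pseudo_F`, `p`,
#'   `n_perm`, `df_between`, `df_resid`, `n`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  fc_assert(is_count(n_perm, 99), "n_perm must be an integer >= 99")
  dd <- stats::as.dist(d)
  groups <- factor(groups)
  n <- attr(dd, "Size")
  fc_assert(length(groups) == n, "groups must have one label per sample")
  fc_assert(nlevels(groups) >= 2, "need at least 2 groups",
            "fc_degenerate_design")
  fc_assert(max(table(groups)) < n,
            "a group equal to all samples is a degenerate design",
            "fc_degenerate_design")
  df <- data.frame(g = groups)
  fit <- with_seed(seed,
                   vegan::adonis2(dd ~ g, data = df, permutations = n_perm))
  structure(list(
    r2 = fit$R2[1], pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1],
    n_perm = n_perm, df_between = fit$Df[1], df_resid = fit$Df[2], n = n
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: R2 = %.3f, pseudo-F(%d, %d) = %.3f, p = %.4g (%d perms)\n",
    x$r2, x$df_between, x$df_resid, x$pseudo_F, x$p, x$n_perm))
  invisible(x)
}

# Formula-free scoping shim: vegan's rda/ordiR2step re-evaluate formulas in
# their environment, so build them in a dedicated environment holding the
# response and predictors.
rda_workspace <- function(y, env) {
  fc_assert(is.data.frame(env) || is.matrix(env),
            "env must be a data frame or matrix of predictors")
  env <- as.data.frame(env)
  fc_assert(nrow(env) == nrow(y), "y and env must have matching samples")
  e <- new.env(parent = getNamespace("vegan"))
  assign("..y", as.matrix(y), envir = e)
  assign("..env", env, envir = e)
  e
}

#' Redundancy analysis of a CLR matrix on environmental predictors
#'
#' Constrained ordination: column-centres the response, projects it onto
#' the span of the (z-scored) predictors, and decomposes the fitted values
#' into constrained axes. The constrained fraction is the share of total
#' variance captured by the predictor span; the model p-value permutes the
#' predictor rows. Computed through `vegan::rda`.
#'
#' @param y samples x ASVs CLR matrix (response).
#' @param env data frame of numeric predictors; z-scored internally unless
#'   `scale_env = FALSE` (columns with zero variance are rejected).
#' @param n_perm permutations for the model test.
#' @param seed RNG seed.
#' @param scale_env z-score predictors before fitting.
#' @return An object of class `rda_result`: `constrained_fraction`,
#'   `axis_fractions` (summing to the constrained fraction),
#'   `site_scores`, `biplot_scores`, `p`, `n_perm` and the underlying
#'   vegan model as `fit`.
#' @export
rda_constrained <- function(y, env, n_perm = 999, seed = 1L,
                            scale_env = TRUE) {
  env <- as.data.frame(env)
  fc_assert(nrow(y) > ncol(env) + 1,
            "need n_samples > n_predictors + 1")
  if (scale_env) {
    sds <- vapply(env, stats::sd, numeric(1))
    fc_assert(all(sds > 0), "constant predictor column(s) cannot be z-scored")
    env <- as.data.frame(scale(env))
  }
  e <- rda_workspace(y, env)
  fml <- stats::as.formula("..y ~ .", env = e)
  fit <- eval(bquote(vegan::rda(.(fml), data = ..env)), envir = e)
  aliased <- tryCatch(vegan::alias(fit, names = TRUE),
                      error = function(err) NULL)
  if (length(aliased) > 0) {
    warning("collinear predictor(s) aliased: ",
            paste(unlist(aliased), collapse = ", "))
  }
  pv <- with_seed(seed, stats::anova(fit, permutations = n_perm))
  structure(list(
    constrained_fraction = fit$CCA$tot.chi / fit$tot.chi,
    axis_fractions = fit$CCA$eig / fit$tot.chi,
    site_scores = vegan::scores(fit, display = "sites",
                                choices = seq_len(min(2, fit$CCA$rank))),
    biplot_scores = fit$CCA$biplot,
    p = pv$`Pr(>F)`[1], n_perm = n_perm, fit = fit
  ), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: %.1f%% of variance constrained, p = %.4g (%d perms)\n",
              100 * x$constrained_fraction, x$p, x$n_perm))
  invisible(x)
}

#' Forward selection of predictors for redundancy analysis
#'
#' Greedy forward selection maximising adjusted R2: a candidate enters only
#' if its marginal permutation p-value is below `alpha` and the running
#' adjusted R2 stays within the full-model adjusted-R2 scope. The scope
#' bound carries a finite-sample allowance of
#' `(1 - R2adj_full) * p / (n - p - 1)` — the share of residual variance
#' that `p` uninformative predictors absorb in expectation — so a genuine
#' predictor is not rejected merely because noise covariates depress the
#' full model's adjusted R2 below its own. Model fits and marginal
#' permutation tests run through vegan (`rda`, `anova.cca`); an empty
#' selection is a valid result.
#'
#' @param y samples x ASVs CLR matrix.
#' @param env data frame of candidate predictors (>= 2 columns); z-scored
#'   internally.
#' @param alpha entry threshold on the marginal permutation p-value.
#' @param perm_max maximum permutations per step test.
#' @param seed RNG seed (selection is reproducible for a fixed seed).
#' @return A data frame of selected predictors in entry order with
#'   `predictor`, `adj_r2` (running), `p`; zero rows when nothing enters.
#' @export
forward_select <- function(y, env, alpha = 0.05, perm_max = 200, seed = 1L) {
  env <- as.data.frame(env)
  fc_assert(ncol(env) >= 2, "need at least 2 candidate predictors")
  sds <- vapply(env, stats::sd, numeric(1))
  fc_assert(all(sds > 0), "constant predictor column(s) cannot be z-scored")
  env <- as.data.frame(scale(env))
  e <- rda_workspace(y, env)
  dat <- get("..env", e)
  assign("..dat", dat, envir = e)
  fit_terms <- function(terms) {
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    fml <- stats::as.formula(paste("..y ~", rhs), env = e)
    eval(bquote(vegan::rda(.(fml), data = ..dat)), envir = e)
  }
  adj_r2 <- function(m) {
    r <- vegan::RsquareAdj(m)$adj.r.squared
    if (!length(r) || is.na(r)) 0 else r
  }
  m_full <- fit_terms(names(dat))
  r2_full <- adj_r2(m_full)
  n <- nrow(dat); p <- ncol(dat)
  scope_limit <- min(1, r2_full + (1 - r2_full) * p / (n - p - 1))

  with_seed(seed, {
    selected <- character(0)
    remaining <- names(dat)
    r2_prev <- 0
    m_cur <- fit_terms(selected)
    rows <- list()
    while (length(remaining) > 0) {
      cand <- vapply(remaining,
                     function(v) adj_r2(fit_terms(c(selected, v))),
                     numeric(1))
      best <- names(cand)[which.max(cand)]
      if (cand[best] <= r2_prev || cand[best] > scope_limit) break
      m_best <- fit_terms(c(selected, best))
      pv <- stats::anova(m_cur, m_best,
                         permutations = perm_max - 1)$`Pr(>F)`[2]
      if (is.na(pv) || pv >= alpha) break
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = best, adj_r2 = unname(cand[best]), p = pv,
        stringsAsFactors = FALSE)
      r2_prev <- cand[best]
      m_cur <- m_best
    }
    if (length(rows) == 0) {
      data.frame(predictor = character(0), adj_r2 = numeric(0),
                 p = numeric(0), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, rows)
    }
  })
}

#' Univariate group tests with Bonferroni-adjusted pairwise comparisons
#'
#' Either an ANOVA across groups followed by pairwise Welch two-sample
#' t-tests (`var.equal = FALSE`), or a Kruskal-Wallis test followed by
#' pairwise Wilcoxon rank-sum tests. Pairwise p-values are
#' Bonferroni-adjusted across the pairwise family. Pairs involving a group
#' with fewer than 2 samples are flagged and skipped for variance-based
#' tests.
#'
#' @param values numeric vector, one value per sample.
#' @param groups factor (or coercible) of group labels.
#' @param scheme `"anova_welch"` or `"kruskal"`.
#' @return A data frame of class `group_test_result`, one row per pairwise
#'   comparison: `group_a`, `group_b`, `statistic`, `p_raw`, `p_adjusted`,
#'   `method`, `n_a`, `n_b`; the overall test is attached as attribute
#'   `"overall"` (a list with `statistic`, `p`, `method`).
#' @export
group_tests <- function(values, groups, scheme = c("anova_welch", "kruskal")) {
  scheme <- match.arg(scheme)
  groups <- factor(groups)
  fc_assert(nlevels(groups) >= 2, "need at least 2 groups",
            "fc_degenerate_design")
  overall <- if (scheme == "anova_welch") {
    fit <- stats::anova(stats::aov(values ~ groups))
    list(statistic = fit$`F value`[1], p = fit$`Pr(>F)`[1], method = "ANOVA")
  } else {
    kt <- stats::kruskal.test(values, groups)
    list(statistic = unname(kt$statistic), p = kt$p.value,
         method = "Kruskal-Wallis")
  }
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    va <- values[groups == a]; vb <- values[groups == b]
    if (scheme == "anova_welch" && (length(va) < 2 || length(vb) < 2)) {
      warning(sprintf("pair %s-%s skipped: group with < 2 samples", a, b))
      return(data.frame(group_a = a, group_b = b, statistic = NA_real_,
                        p_raw = NA_real_, method = "skipped",
                        n_a = length(va), n_b = length(vb),
                        stringsAsFactors = FALSE))
    }
    tst <- if (scheme == "anova_welch") {
      tt <- tryCatch(stats::t.test(va, vb, var.equal = FALSE),
                     error = function(err) NULL)
      if (is.null(tt)) {
        # both groups constant: identical means are a null result
        list(stat = if (mean(va) == mean(vb)) 0 else Inf,
             p = as.numeric(mean(va) == mean(vb)), method = "Welch t")
      } else {
        list(stat = unname(tt$statistic), p = tt$p.value, method = "Welch t")
      }
    } else {
      wt <- suppressWarnings(stats::wilcox.test(va, vb))
      list(stat = unname(wt$statistic), p = wt$p.value, method = "Wilcoxon")
    }
    data.frame(group_a = a, group_b = b, statistic = tst$stat,
               p_raw = tst$p, method = tst$method,
               n_a = length(va), n_b = length(vb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "bonferroni")
  out <- out[, c("group_a", "group_b", "statistic", "p_raw", "p_adjusted",
                 "method", "n_a", "n_b")]
  attr(out, "overall") <- overall
  class(out) <- c("group_test_result", "data.frame")
  out
}
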