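test_that("Hill numbers match hand computations", {
  x <- rbind(s1 = c(5L, 0L, 3L, 1L))
  colnames(x) <- paste0("a", 1:4)
  expect_equal(hill_diversity(x, q = 0)$diversity, 3)

  eq <- rbind(s1 = rep(10L, 4)); colnames(eq) <- paste0("a", 1:4)
  expect_equal(hill_diversity(eq, q = 1)$diversity, 4, tolerance = 1e-12)

  y <- rbind(s1 = c(2L, 1L, 1L)); colnames(y) <- paste0("a", 1:3)
  a <- alpha_diversity(y)
  expect_equal(a$shannon_entropy, 1.5 * log(2), tolerance = 1e-12)
  expect_equal(a$hill_shannon, 2^1.5, tolerance = 1e-12)

  expect_error(hill_diversity(rbind(s1 = c(0L, 0L)), q = 0), "empty")
  # bootstrap s.e. present, finite, and reproducible under one seed
  b1 <- hill_diversity(x, q = 1, n_boot = 50, seed = 3)
  b2 <- hill_diversity(x, q = 1, n_boot = 50, seed = 3)
  expect_identical(b1, b2)
  expect_true(is.finite(b1$se))
})

test_that("replication invariance: merging identical samples keeps Hill q=1", {
  x <- rbind(s1 = c(4L, 8L, 2L, 6L))
  colnames(x) <- paste0("a", 1:4)
  merged <- rbind(s12 = 2L * x[1, ])
  expect_equal(hill_diversity(x, 1)$diversity,
               hill_diversity(merged, 1)$diversity, tolerance = 1e-12)
})

test_that("evenness variants follow their formulas and flag degeneracies", {
  eq <- rbind(s1 = rep(5L, 4)); colnames(eq) <- paste0("a", 1:4)
  a <- alpha_diversity(eq)
  expect_equal(a$evenness_paper, log(4) / 4, tolerance = 1e-12)
  expect_equal(a$evenness_pielou, 1, tolerance = 1e-12)

  one <- rbind(s1 = c(9L, 0L)); colnames(one) <- c("a", "b")
  a1 <- suppressWarnings(alpha_diversity(one))
  expect_equal(a1$evenness_paper, 0)
  expect_warning(evenness(a1, "pielou"), "undefined")
})

test_that("PERMANOVA matches the sums-of-squares oracle on random instances", {
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    y <- matrix(stats::rnorm(n * 4), n)
    rownames(y) <- paste0("s", 1:n)
    d <- aitchison(y)
    g <- sample(rep(c("a", "b", "c"), length.out = n))
    while (length(unique(g)) < 2) g <- sample(c("a", "b"), n, replace = TRUE)
    res <- permanova(d, g, n_perm = 99, seed = rep)
    orc <- permanova_ss_oracle(d, g)
    expect_equal(res$r2, orc$r2, tolerance = 1e-10)
    expect_equal(res$pseudo_F, orc$pseudo_F, tolerance = 1e-10)
  }
})

test_that("PERMANOVA detects perfect separation and rejects degenerate designs", {
  y <- rbind(matrix(0, 4, 3), matrix(5, 4, 3)) +
    matrix(0, 8, 3)
  rownames(y) <- paste0("s", 1:8)
  d <- aitchison(y)  # zero within, positive between
  g <- rep(c("a", "b"), each = 4)
  res <- permanova(d, g, n_perm = 199, seed = 1)
  expect_equal(res$r2, 1, tolerance = 1e-10)
  expect_equal(res$p, 1 / 200, tolerance = 1e-12)
  expect_error(permanova(d, rep("a", 8), n_perm = 99),
               class = "fc_degenerate_design")
})

test_that("PERMANOVA p-values are calibrated under an exchangeable null", {
  set.seed(77)
  rej <- 0; nsim <- 120
  for (i in seq_len(nsim)) {
    n <- 16
    y <- matrix(stats::rnorm(n * 4), n); rownames(y) <- paste0("s", 1:n)
    p <- permanova(aitchison(y), rep(c("a", "b"), each = n / 2),
                   n_perm = 99, seed = i)$p
    rej <- rej + (p <= 0.05)
  }
  expect_gt(rej / nsim, 0.01)
  expect_lt(rej / nsim, 0.11)
})

test_that("RDA recovers a perfect predictor and respects invariances", {
  set.seed(12)
  n <- 30
  env <- data.frame(temperature = stats::rnorm(n), no3 = stats::rnorm(n))
  y <- outer(env$temperature, stats::rnorm(10))
  rownames(y) <- paste0("s", 1:n)
  r <- rda_constrained(y, env["temperature"], n_perm = 99, seed = 2)
  expect_equal(r$constrained_fraction, 1, tolerance = 1e-10)
  expect_equal(sum(r$axis_fractions), r$constrained_fraction,
               tolerance = 1e-10)

  # invariance to invertible linear reparameterisation of predictors
  yn <- y + matrix(stats::rnorm(n * 10, 0, 0.4), n)
  rownames(yn) <- paste0("s", 1:n)
  r1 <- rda_constrained(yn, env, n_perm = 99, seed = 3, scale_env = FALSE)
  env2 <- data.frame(p1 = env$temperature + 2 * env$no3,
                     p2 = env$temperature - env$no3)
  r2 <- rda_constrained(yn, env2, n_perm = 99, seed = 3, scale_env = FALSE)
  expect_equal(r1$constrained_fraction, r2$constrained_fraction,
               tolerance = 1e-10)

  # joint relabelling of samples leaves the fit unchanged
  perm <- sample(n)
  r3 <- rda_constrained(yn[perm, ], env[perm, , drop = FALSE],
                        n_perm = 99, seed = 3, scale_env = FALSE)
  expect_equal(r1$constrained_fraction, r3$constrained_fraction,
               tolerance = 1e-10)
  expect_equal(sort(abs(r1$site_scores[, 1])), sort(abs(r3$site_scores[, 1])),
               tolerance = 1e-8)
})

test_that("random orthogonal predictors constrain about p/(n-1) of the variance", {
  set.seed(40)
  fr <- replicate(30, {
    n <- 25; p <- 3
    y <- matrix(stats::rnorm(n * 8), n); rownames(y) <- paste0("s", 1:n)
    env <- as.data.frame(matrix(stats::rnorm(n * p), n))
    rda_constrained(y, env, n_perm = 99, seed = 1)$constrained_fraction
  })
  expect_equal(mean(fr), 3 / 24, tolerance = 0.25)
})

test_that("forward selection finds planted predictors and respects the null", {
  set.seed(55)
  n <- 40
  env <- data.frame(signal = stats::rnorm(n), noise1 = stats::rnorm(n),
                    noise2 = stats::rnorm(n))
  y <- outer(env$signal, stats::rnorm(12)) +
    matrix(stats::rnorm(n * 12, 0, 0.5), n)
  rownames(y) <- paste0("s", 1:n)
  sel <- forward_select(y, env, seed = 6)
  expect_equal(sel$predictor[1], "signal")
  sel2 <- forward_select(y, env, seed = 6)
  expect_identical(sel, sel2)

  # pure-noise predictors are mostly never selected
  empties <- sum(replicate(20, {
    yn <- matrix(stats::rnorm(n * 12), n); rownames(yn) <- paste0("s", 1:n)
    nrow(forward_select(yn, env, seed = sample.int(1e6, 1))) == 0
  }))
  expect_gte(empties, 15)
})

test_that("group tests combine ANOVA/Welch and Kruskal schemes with Bonferroni", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  gt <- group_tests(v, g)
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p_raw, 1)
  expect_equal(gt$p_adjusted, pmin(1, gt$p_raw * nrow(gt)))

  set.seed(3)
  v3 <- stats::rnorm(30)
  g3 <- rep(c("a", "b", "c"), 10)
  gt3 <- group_tests(v3, g3)
  expect_equal(nrow(gt3), 3)
  expect_equal(gt3$p_adjusted, pmin(1, gt3$p_raw * 3), tolerance = 1e-12)
  kw <- group_tests(v3, g3, scheme = "kruskal")
  expect_equal(attr(kw, "overall")$method, "Kruskal-Wallis")

  # Kruskal-Wallis calibration under a shared null distribution
  set.seed(11)
  rej <- mean(replicate(150, {
    vv <- stats::rnorm(24); gg <- rep(c("a", "b", "c"), each = 8)
    attr(group_tests(vv, gg, scheme = "kruskal"), "overall")$p <= 0.05
  }))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)

  # tiny group flagged and skipped for the variance-based scheme
  expect_warning(gs <- group_tests(c(1, 2, 3, 4), c("a", "a", "a", "b")),
                 "skipped")
  expect_equal(gs$method, "skipped")
})
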