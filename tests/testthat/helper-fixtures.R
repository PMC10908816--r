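# Shared fixtures and independent oracles, all built in code.

# Uniform open-water field (no land) with constant (u0, v0).
uniform_field <- function(u0, v0, nx = 32, ny = 32, n_days = 40,
                          cell_size = 1) {
  u <- array(u0, c(ny, nx, n_days))
  v <- array(v0, c(ny, nx, n_days))
  velocity_field(u, v, matrix(FALSE, ny, nx), cell_size)
}

# Steady solid-body rotation about the domain centre: u = -w*(y-yc),
# v = w*(x-xc). Linear in space, so bilinear interpolation is exact.
rotation_field <- function(omega, nx = 64, ny = 64, n_days = 70,
                           cell_size = 1) {
  xc <- nx * cell_size / 2; yc <- ny * cell_size / 2
  x <- (seq_len(nx) - 0.5) * cell_size
  y <- (seq_len(ny) - 0.5) * cell_size
  u1 <- matrix(rep(-omega * (y - yc), nx), ny, nx)
  v1 <- matrix(rep(omega * (x - xc), each = ny), ny, nx)
  u <- array(u1, c(ny, nx, n_days))
  v <- array(v1, c(ny, nx, n_days))
  velocity_field(u, v, matrix(FALSE, ny, nx), cell_size)
}

# Random small count table with guaranteed >= 2 nonzero parts per sample.
random_count_table <- function(n_samples, n_asvs, depth = 500) {
  p <- exp(stats::rnorm(n_asvs, 0, 1))
  x <- t(stats::rmultinom(n_samples, depth, p / sum(p)))
  while (any(rowSums(x > 0) < 2)) {
    x <- t(stats::rmultinom(n_samples, depth, p / sum(p)))
  }
  dimnames(x) <- list(paste0("s", seq_len(n_samples)),
                      paste0("a", seq_len(n_asvs)))
  x
}

# Brute-force Aitchison distance straight from the log-ratio definition:
# d^2(x, y) = (1/(2D)) * sum_{i,j} (ln(x_i/x_j) - ln(y_i/y_j))^2.
aitchison_logratio_oracle <- function(p) {
  n <- nrow(p); D <- ncol(p)
  d <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a >= b) next
      acc <- 0
      for (i in seq_len(D)) {
        for (j in seq_len(D)) {
          acc <- acc + (log(p[a, i] / p[a, j]) - log(p[b, i] / p[b, j]))^2
        }
      }
      d[a, b] <- d[b, a] <- sqrt(acc / (2 * D))
    }
  }
  dimnames(d) <- list(rownames(p), rownames(p))
  d
}

# Brute-force one-factor PERMANOVA from sums of squared pairwise distances
# (SS_total = sum_{i<j} d_ij^2 / n; within-group analogue per group).
permanova_ss_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- sum(vapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) return(0)
    sub <- d[idx, idx]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  k <- nlevels(groups)
  list(r2 = ss_between / ss_total,
       pseudo_F = (ss_between / (k - 1)) / (ss_within / (n - k)))
}

# Tiny deterministic ASV table for filter tests: 5 ASVs with totals
# 0, 1, 2, 2, 9; one of the 2-count ASVs flagged chloroplast.
toy_filter_table <- function() {
  counts <- rbind(
    s1 = c(0L, 1L, 2L, 0L, 4L),
    s2 = c(0L, 0L, 0L, 2L, 5L)
  )
  colnames(counts) <- paste0("a", 1:5)
  ann <- data.frame(asv_id = paste0("a", 1:5),
                    flag = c("none", "none", "none", "chloroplast", "none"),
                    trophic_group = "unknown", stringsAsFactors = FALSE)
  asv_table(counts, marker = "16S", annotations = ann)
}

# Hand-built connectivity matrix covering one age bin with symmetrised
# pair concentrations conc_ab, conc_ac, conc_bc (reverse direction zero).
toy_connectivity <- function(conc_ab, conc_ac, conc_bc,
                             bin = c(0, 30)) {
  df <- data.frame(
    release = c("A", "A", "B", "B", "C", "C"),
    receive = c("B", "C", "A", "C", "A", "B"),
    bin_lo = bin[1], bin_hi = bin[2],
    value = c(conc_ab, conc_ac, 0, conc_bc, 0, 0),
    stringsAsFactors = FALSE
  )
  class(df) <- c("connectivity_matrix", "data.frame")
  df
}

fast_schedule <- function() {
  seeding_schedule(floats_per_cohort = 25L, n_cohorts = 2L, lifetime = 60)
}

small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(grid_nx = 32L, grid_ny = 16L, n_fjords = 6L,
         n_asv_pro = 120L, n_asv_euk = 120L, seq_depth = 2000L,
         n_days = 80L, seed = seed),
    list(...))
  do.call(scenario_config, args)
}
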