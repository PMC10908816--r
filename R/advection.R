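#' Seed drifter cohorts around a site
#'
#' Generates initial drifter positions for every cohort release: positions
#' are drawn uniformly over the ocean portion of a
#' `seeding_window x seeding_window` cell square centred on the site's grid
#' cell, one set per cohort release time (releases every `cohort_interval`
#' days starting at day 0).
#'
#' @param site one row of the metadata frame from [generate_site_network()]
#'   (needs `site_id`, `cell_x`, `cell_y`), or any list with those fields.
#' @param field a [velocity_field()].
#' @param schedule a [seeding_schedule()].
#' @param seed RNG seed (positions are the only stochastic part of
#'   advection).
#' @return A data frame with one row per drifter: `cohort`, `release_day`,
#'   `x`, `y` (km).
#' @export
seed_cohorts <- function(site, field, schedule, seed = 1L) {
  cx <- site$cell_x; cy <- site$cell_y
  fc_assert(!field$mask[cy, cx],
            sprintf("site %s lies on a land cell", site$site_id),
            "fc_seeding_error")
  half <- (schedule$seeding_window - 1L) %/% 2L
  ix <- max(1L, cx - half):min(field$nx, cx + half)
  iy <- max(1L, cy - half):min(field$ny, cy + half)
  cells <- expand.grid(i = ix, j = iy)
  cells <- cells[!field$mask[cbind(cells$j, cells$i)], , drop = FALSE]
  fc_assert(nrow(cells) > 0, "seeding window entirely on land",
            "fc_seeding_error")
  cs <- field$cell_size
  with_seed(seed, {
    out <- lapply(seq_len(schedule$n_cohorts), function(k) {
      pick <- cells[sample.int(nrow(cells), schedule$floats_per_cohort,
                               replace = TRUE), , drop = FALSE]
      data.frame(
        cohort = k,
        release_day = (k - 1) * schedule$cohort_interval,
        x = (pick$i - 1 + stats::runif(schedule$floats_per_cohort)) * cs,
        y = (pick$j - 1 + stats::runif(schedule$floats_per_cohort)) * cs
      )
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

# Day slice index for continuous time t (days): piecewise constant over
# (d-1, d], recycled periodically if t exceeds the stored span.
day_slice <- function(field, t) {
  d <- ceiling(pmax(t, .Machine$double.eps))
  ((as.integer(d) - 1L) %% field$n_days) + 1L
}

# Vectorised bilinear interpolation of (u, v) at positions (px, py), day
# slice d (per-position). Positions are clamped to the outermost cell
# centres; land cells contribute zero velocity (enforced at construction).
interp_uv <- function(field, px, py, d) {
  cs <- field$cell_size
  ci <- px / cs + 0.5
  cj <- py / cs + 0.5
  i0 <- pmin(pmax(floor(ci), 1), field$nx - 1)
  j0 <- pmin(pmax(floor(cj), 1), field$ny - 1)
  fx <- pmin(pmax(ci - i0, 0), 1)
  fy <- pmin(pmax(cj - j0, 0), 1)
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  base <- (d - 1L) * (field$ny * field$nx)
  k00 <- base + (i0 - 1L) * field$ny + j0
  k10 <- k00 + field$ny            # (i0+1, j0)
  k01 <- k00 + 1L                  # (i0, j0+1)
  k11 <- k10 + 1L
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  list(u = w00 * field$u[k00] + w10 * field$u[k10] +
         w01 * field$u[k01] + w11 * field$u[k11],
       v = w00 * field$v[k00] + w10 * field$v[k10] +
         w01 * field$v[k01] + w11 * field$v[k11])
}

#' Interpolate the velocity field at one position and time
#'
#' Bilinear interpolation in space between the four surrounding cell
#' centres, piecewise-constant (daily) in time. Velocities at land cells are
#' treated as zero, so flow decays smoothly to rest at the coast.
#'
#' @param field a [velocity_field()].
#' @param position numeric length-2, `(x, y)` in km.
#' @param t time in days.
#' @return Named numeric `(u, v)` in km/day.
#' @export
interpolate_velocity <- function(field, position, t) {
  px <- position[1]; py <- position[2]
  if (!in_domain(field, px, py)) {
    fc_stop(sprintf("position (%.2f, %.2f) outside the model domain", px, py),
            "fc_out_of_domain")
  }
  uv <- interp_uv(field, px, py, day_slice(field, t))
  c(u = uv$u, v = uv$v)
}

#' Advect drifters through the velocity field
#'
#' Steps every drifter with classical 4th-order Runge-Kutta at time step
#' `dt`, sampling the daily-mean flow at each substage. A drifter whose
#' updated position falls on a land cell is flagged beached and frozen
#' there (coastal retention); one leaving the domain is flagged
#' out-of-domain and frozen. Positions are stored at daily resolution,
#' indexed by drifter age 0..`lifetime`, so cohorts released at different
#' times align by age; the flow is sampled at each drifter's absolute time
#' `release_day + age`.
#'
#' @param init initial positions, a data frame from [seed_cohorts()] (or any
#'   frame with `x`, `y` and optionally `release_day`, default 0).
#' @param field a [velocity_field()].
#' @param dt integration step in days; must be <= 1 and divide 1 exactly.
#' @param lifetime tracking duration in days (integer).
#' @param release_site site id recorded on the result.
#' @param beaching `"freeze"` (default: a drifter reaching land stays at
#'   its beaching cell and keeps counting toward concentrations — coastal
#'   retention) or `"reflect"` (the offending step is cancelled and the
#'   drifter stays active at its previous position).
#' @return An object of class `trajectory_set`: matrices `x`, `y` of dim
#'   `n_drifters x (lifetime + 1)` (columns = ages 0..lifetime, km),
#'   `release_day`, `beach_age`, `out_age` (NA while never
#'   beached/exited), and `ages`.
#' @export
advect <- function(init, field, dt = 0.25, lifetime = 365,
                   release_site = NA_character_,
                   beaching = c("freeze", "reflect")) {
  beaching <- match.arg(beaching)
  fc_assert(is_number(dt) && dt > 0 && dt <= 1 &&
              abs(1 / dt - round(1 / dt)) < 1e-9,
            "dt must be <= 1 day and divide 1 day exactly")
  fc_assert(is_count(lifetime), "lifetime must be a positive integer")
  n <- nrow(init)
  release_day <- if ("release_day" %in% names(init)) init$release_day else
    rep(0, n)

  n_ages <- lifetime + 1L
  X <- matrix(NA_real_, n, n_ages)
  Y <- matrix(NA_real_, n, n_ages)
  X[, 1] <- init$x; Y[, 1] <- init$y
  beach_age <- rep(NA_real_, n)
  out_age <- rep(NA_real_, n)

  # drifters seeded outside or on land are flagged immediately
  cl <- cell_index(field, init$x, init$y)
  beach0 <- field$mask[cbind(cl$j, cl$i)] & in_domain(field, init$x, init$y)
  out0 <- !in_domain(field, init$x, init$y)
  beach_age[beach0] <- 0; out_age[out0] <- 0

  px <- init$x; py <- init$y
  steps_per_day <- round(1 / dt)
  for (a in seq_len(lifetime)) {
    active <- is.na(beach_age) & is.na(out_age)
    if (any(active)) {
      ax <- px[active]; ay <- py[active]
      t0 <- release_day[active] + (a - 1)
      for (s in seq_len(steps_per_day)) {
        ts <- t0 + (s - 1) * dt
        d1 <- day_slice(field, ts + 1e-9)
        d2 <- day_slice(field, ts + dt / 2)
        d4 <- day_slice(field, ts + dt)
        k1 <- interp_uv(field, ax, ay, d1)
        k2 <- interp_uv(field, ax + dt / 2 * k1$u, ay + dt / 2 * k1$v, d2)
        k3 <- interp_uv(field, ax + dt / 2 * k2$u, ay + dt / 2 * k2$v, d2)
        k4 <- interp_uv(field, ax + dt * k3$u, ay + dt * k3$v, d4)
        if (anyNA(k1$u) || anyNA(k4$u)) {
          fc_stop(sprintf("NaN velocity encountered near day %.2f", ts),
                  "fc_data_error")
        }
        ax <- ax + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
        ay <- ay + dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
      }
      px[active] <- ax; py[active] <- ay

      inside <- in_domain(field, px, py)
      cl <- cell_index(field, px, py)
      on_land <- field$mask[cbind(cl$j, cl$i)] & inside
      newly_out <- active & !inside
      newly_beached <- active & inside & on_land
      out_age[newly_out] <- a
      if (beaching == "freeze") {
        beach_age[newly_beached] <- a
      } else if (any(newly_beached)) {
        # reflect: cancel the day's displacement, stay active offshore
        px[newly_beached] <- X[newly_beached, a]
        py[newly_beached] <- Y[newly_beached, a]
      }
    }
    frozen_out <- !is.na(out_age) & out_age <= a
    X[, a + 1L] <- ifelse(frozen_out, NA_real_, px)
    Y[, a + 1L] <- ifelse(frozen_out, NA_real_, py)
    # beached drifters keep their beaching position (already frozen in px/py)
    if (all(!is.na(beach_age) | !is.na(out_age))) {
      # nothing active: remaining ages repeat the frozen state
      if (a < lifetime) {
        for (b in (a + 1L):lifetime) {
          X[, b + 1L] <- X[, a + 1L]
          Y[, b + 1L] <- Y[, a + 1L]
        }
      }
      break
    }
  }
  structure(list(
    release_site = release_site,
    release_day = release_day,
    x = X, y = Y,
    beach_age = beach_age, out_age = out_age,
    ages = 0:lifetime,
    lifetime = lifetime, dt = dt
  ), class = "trajectory_set")
}

#' Drifter status by age
#'
#' @param traj a `trajectory_set` from [advect()].
#' @param age drifter age in days.
#' @return Character vector per drifter: `"active"`, `"beached"` or
#'   `"out"`. Once beached or out, a drifter never becomes active again.
#' @export
drifter_status <- function(traj, age) {
  st <- rep("active", length(traj$beach_age))
  st[!is.na(traj$beach_age) & traj$beach_age <= age] <- "beached"
  st[!is.na(traj$out_age) & traj$out_age <= age] <- "out"
  st
}

#' @export
print.trajectory_set <- function(x, ...) {
  st <- drifter_status(x, x$lifetime)
  cat(sprintf(
    "Trajectory set (%s): %d drifters over %d days (dt = %g)\n",
    if (is.na(x$release_site)) "unnamed" else x$release_site,
    nrow(x$x), x$lifetime, x$dt))
  cat(sprintf("  final status: %d active, %d beached, %d out-of-domain\n",
              sum(st == "active"), sum(st == "beached"), sum(st == "out")))
  invisible(x)
}
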