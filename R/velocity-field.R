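#' Construct a gridded velocity field
#'
#' Container for a 2-D, time-varying flow on a regular grid with a land mask:
#' the physical substrate drifters are advected through. Velocities are daily
#' means; within day `d` (times in `(d-1, d]`) the flow is the `d`-th slice.
#'
#' @param u,v arrays of dim `(ny, nx, n_days)`, km/day. Entries on land cells
#'   are forced to zero (land exerts no advection during interpolation).
#' @param mask logical `ny x nx` matrix, `TRUE` = land.
#' @param cell_size cell edge length, km.
#' @param time integer vector of day indices `1:n_days` (strictly increasing).
#' @return An object of class `velocity_field` with cell-centre coordinate
#'   vectors `x` (length nx) and `y` (length ny) in km.
#' @export
velocity_field <- function(u, v, mask, cell_size, time = seq_len(dim(u)[3])) {
  fc_assert(length(dim(u)) == 3 && identical(dim(u), dim(v)),
            "u and v must be (ny, nx, n_days) arrays of equal shape")
  fc_assert(is.matrix(mask) && identical(dim(mask), dim(u)[1:2]),
            "mask must be an ny x nx logical matrix")
  fc_assert(all(diff(time) > 0), "time must be strictly increasing")
  fc_assert(length(time) == dim(u)[3], "time length must match u/v")
  ny <- dim(u)[1]; nx <- dim(u)[2]
  land <- which(mask)
  for (d in seq_len(dim(u)[3])) {
    u[, , d][land] <- 0
    v[, , d][land] <- 0
  }
  fc_assert(all(is.finite(u)) && all(is.finite(v)),
            "u and v must be finite on ocean cells")
  structure(list(
    u = u, v = v, mask = mask, cell_size = cell_size,
    time = as.integer(time),
    x = (seq_len(nx) - 0.5) * cell_size,
    y = (seq_len(ny) - 0.5) * cell_size,
    nx = nx, ny = ny, n_days = dim(u)[3]
  ), class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("Velocity field: %d x %d cells (%g km), %d daily snapshots\n",
              x$nx, x$ny, x$cell_size, x$n_days))
  cat(sprintf("  land fraction %.2f; max speed %.2f km/day\n",
              mean(x$mask), max(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

# Grid cell index (i = x-column, j = y-row) of a position, clamped to grid.
cell_index <- function(field, px, py) {
  i <- pmin(pmax(ceiling(px / field$cell_size), 1L), field$nx)
  j <- pmin(pmax(ceiling(py / field$cell_size), 1L), field$ny)
  list(i = as.integer(i), j = as.integer(j))
}

in_domain <- function(field, px, py) {
  px >= 0 & px <= field$nx * field$cell_size &
    py >= 0 & py <= field$ny * field$cell_size
}

# Along-coast fjord geometry shared by the field and site-network
# generators: a land band of `band` rows along the top ("coast") edge with
# one-cell-wide, (band-1)-cell-deep fjord indentations at evenly spaced
# x-columns. Row ny stays land (the fjord head wall).
fjord_geometry <- function(cfg) {
  band <- 4L
  fc_assert(cfg$grid_ny > band + 4L, "grid_ny too small for the coastal band")
  fx <- round(cfg$grid_nx * (seq_len(cfg$n_fjords) - 0.5) / cfg$n_fjords)
  fx <- as.integer(pmin(pmax(fx, 2L), cfg$grid_nx - 1L))
  fc_assert(!anyDuplicated(fx), "fjords collide on the grid; enlarge grid_nx",
            class = "fc_sizing_error")
  list(band = band,
       fjord_x = fx,
       # rows of the indentation, mouth first (adjacent to the open channel)
       fjord_rows = (cfg$grid_ny - band + 1L):(cfg$grid_ny - 1L),
       channel_rows = 1L:(cfg$grid_ny - band))
}

#' Generate the synthetic coastal velocity field
#'
#' Builds a boundary-current flow along a coastline that connects the fjords
#' in sequence: a land band occupies the top grid edge with one-cell-wide
#' fjord indentations; the open channel below it carries a uniform
#' along-coast current `u = current_speed`, plus (for
#' `meander_amplitude > 0`) a travelling cross-stream meander
#' `v = A sin(2 pi (x / lambda - t / tau))` with `A = meander_amplitude *
#' current_speed`. Because `u` varies only across the channel and `v` has no
#' cross-stream gradient, the flow is non-divergent in the channel interior.
#' Fjord cells are quiescent (u = v = 0), modelling fjord retention. All
#' speeds are bounded by `2 * current_speed` by construction.
#'
#' @param config a [scenario_config()].
#' @return A [velocity_field()] with `config$n_days` daily snapshots.
#' @export
generate_velocity_field <- function(config) {
  validate_scenario_config(config)
  geo <- fjord_geometry(config)
  nx <- config$grid_nx; ny <- config$grid_ny; nd <- config$n_days

  mask <- matrix(FALSE, ny, nx)
  mask[(ny - geo$band + 1L):ny, ] <- TRUE          # coastal land band
  for (k in seq_along(geo$fjord_x)) {
    mask[geo$fjord_rows, geo$fjord_x[k]] <- FALSE  # carve the fjord
  }

  u0 <- matrix(0, ny, nx)
  u0[geo$channel_rows, ] <- config$current_speed
  # u stays within bounds: |u| = current_speed <= 2 * current_speed

  xkm <- (seq_len(nx) - 0.5) * config$cell_size
  lambda <- nx * config$cell_size / 4   # meander wavelength: quarter domain
  tau <- 30                             # meander period, days
  amp <- config$meander_amplitude * config$current_speed

  u <- array(0, dim = c(ny, nx, nd))
  v <- array(0, dim = c(ny, nx, nd))
  for (d in seq_len(nd)) {
    u[, , d] <- u0
    if (amp > 0) {
      vrow <- amp * sin(2 * pi * (xkm / lambda - (d - 0.5) / tau))
      vd <- matrix(0, ny, nx)
      vd[geo$channel_rows, ] <- rep(vrow, each = length(geo$channel_rows))
      v[, , d] <- vd
    }
  }
  velocity_field(u, v, mask, config$cell_size)
}

#' Write / read a velocity field as long-format text
#'
#' Gridded fields are serialised as a long-format CSV with one row per
#' `(time, y, x)` cell holding `u`, `v` and the land mask, plus a `#`-prefixed
#' header line carrying the cell size, so fields round-trip exactly.
#'
#' @param field a [velocity_field()].
#' @param path file path.
#' @param days optional subset of day indices to write (default: all).
#' @return `write_velocity_field` returns `path` invisibly;
#'   `read_velocity_field` returns a [velocity_field()].
#' @export
write_velocity_field <- function(field, path, days = NULL) {
  if (is.null(days)) days <- seq_len(field$n_days)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# velocity_field cell_size=%.17g ny=%d nx=%d",
                     field$cell_size, field$ny, field$nx), con)
  grid <- expand.grid(y = seq_len(field$ny), x = seq_len(field$nx))
  rows <- do.call(rbind, lapply(days, function(d) {
    data.frame(time = d, y = grid$y, x = grid$x,
               u = as.vector(field$u[, , d]), v = as.vector(field$v[, , d]),
               mask = as.integer(field$mask[cbind(grid$y, grid$x)]))
  }))
  utils::write.table(rows, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  hdr <- readLines(path, n = 1L)
  fc_assert(grepl("^# velocity_field", hdr),
            "not a velocity_field file (missing header)", "fc_parse_error")
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.eE+-]+", hdr))[[1]]
  kv <- do.call(rbind, strsplit(meta, "="))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  df <- utils::read.csv(path, comment.char = "#")
  ny <- as.integer(vals["ny"]); nx <- as.integer(vals["nx"])
  days <- sort(unique(df$time))
  u <- array(0, c(ny, nx, length(days)))
  v <- array(0, c(ny, nx, length(days)))
  mask <- matrix(FALSE, ny, nx)
  for (k in seq_along(days)) {
    sl <- df[df$time == days[k], ]
    u[cbind(sl$y, sl$x, k)] <- sl$u
    v[cbind(sl$y, sl$x, k)] <- sl$v
    if (k == 1L) mask[cbind(sl$y, sl$x)] <- sl$mask == 1L
  }
  velocity_field(u, v, mask, vals[["cell_size"]], time = days)
}
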