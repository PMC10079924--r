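#' Mechanical shove relaxation
#'
#' Resolves overlaps between cells' zones of influence (radius times the
#' shove factor `k_shov`) by symmetric pairwise displacement along the line
#' of centres, sweeping in randomised order until the largest overlap falls
#' below `tol_shove` or `max_sweeps` is exhausted. The lateral direction is
#' periodic; the substratum reflects, so cells end with `z >= radius`.
#'
#' @param state a `biofilm_state`.
#' @param cfg a [bf_config()].
#' @param max_sweeps optional override of `cfg$max_sweeps` (e.g. 1 to test a
#'   single sweep).
#' @return The relaxed `biofilm_state`.
#' @export
shove <- function(state, cfg, max_sweeps = cfg$max_sweeps) {
  n <- nrow(state$cells)
  if (n < 2L) {
    if (n == 1L) state$cells$z <- pmax(state$cells$z, state$cells$radius)
    return(state)
  }
  seed <- sample.int(.Machine$integer.max, 1L)
  res <- shove_cpp(state$cells$x, state$cells$z, state$cells$radius,
                   cfg$k_shov, cfg$L_y, cfg$tol_shove,
                   as.integer(max_sweeps), seed)
  ## the residual is zone-of-influence overlap; warn only when it
  ## approaches the hard-contact scale (~1 um on 1.5-2 um radii)
  if (res$residual >= max(10 * cfg$tol_shove, 1.0))
    warning(sprintf("shove: residual overlap %.3g um after %d sweeps",
                    res$residual, res$sweeps), call. = FALSE)
  state$cells$x <- res$x
  state$cells$z <- res$z
  state
}

## Largest zone-of-influence overlap, brute force over all pairs (test oracle
## and small-n reference).
max_overlap <- function(state, cfg) {
  n <- nrow(state$cells)
  if (n < 2L) return(0)
  x <- state$cells$x; z <- state$cells$z; r <- state$cells$radius
  dx <- abs(outer(x, x, "-"))
  dx <- pmin(dx, cfg$L_y - dx)
  d <- sqrt(dx^2 + outer(z, z, "-")^2)
  ov <- cfg$k_shov * outer(r, r, "+") - d
  diag(ov) <- -Inf
  max(0, max(ov))
}

#' Grow all cells for one time step under a frozen nutrient field
#'
#' Sets each cell's specific growth rate from the Monod law at the nutrient
#' concentration of the voxel containing its centre, then integrates biomass
#' exactly under that frozen rate: `m <- m * exp(mu * dt)`. Radii are updated
#' through the disc closure. Returns the amount of nutrient consumed,
#' `sum(dm) / Y`, as attribute `"consumed"`.
#'
#' @param state a `biofilm_state`.
#' @param grid a solved [nutrient_grid].
#' @param cfg a [bf_config()].
#' @param dt time step, h.
#' @return Updated `biofilm_state` (time is advanced by the caller).
#' @export
grow <- function(state, grid, cfg, dt = cfg$dt) {
  if (dt <= 0) stop("grow: dt must be positive", call. = FALSE)
  if (!nrow(state$cells)) return(state)
  S <- sample_concentration(grid, state$cells$x, state$cells$z)
  mu <- monod_rate(S, cfg$mu_max, cfg$k_S)
  m0 <- state$cells$biomass
  m1 <- m0 * exp(mu * dt)
  state$cells$mu <- mu
  state$cells$biomass <- m1
  state$cells$radius <- biomass_to_radius(m1, cfg$rho_B, cfg$d_cell)
  attr(state, "consumed") <- sum(m1 - m0) / cfg$Y
  state
}

#' Stochastic cell division
#'
#' Every cell whose radius has reached its own drawn division radius is
#' replaced by two daughters with biomass fractions `1/2 + eps` and
#' `1/2 - eps`, `eps ~ U(0, split_spread)`; the daughters are placed tangent
#' to one another along a uniformly random direction with the parent's centre
#' of mass preserved, and each draws a fresh division radius
#' `U(r_div (1 - delta), r_div (1 + delta))`. Total biomass is conserved
#' exactly.
#'
#' @param state a `biofilm_state`.
#' @param cfg a [bf_config()].
#' @return Updated `biofilm_state` (call [shove()] afterwards to resolve the
#'   overlaps division creates).
#' @export
divide_cells <- function(state, cfg) {
  cells <- state$cells
  idx <- which(cells$radius >= cells$division_radius)
  k <- length(idx)
  if (!k) return(state)
  eps <- stats::runif(k, 0, cfg$split_spread)
  f1 <- 0.5 + eps
  m <- cells$biomass[idx]
  m1 <- m * f1
  m2 <- m - m1
  r1 <- biomass_to_radius(m1, cfg$rho_B, cfg$d_cell)
  r2 <- biomass_to_radius(m2, cfg$rho_B, cfg$d_cell)
  ang <- stats::runif(k, 0, 2 * pi)
  ux <- cos(ang); uz <- sin(ang)
  sep <- r1 + r2
  ## centre of mass preserved: offsets inversely proportional to mass
  o1 <- sep * m2 / m
  o2 <- sep * m1 / m
  d1 <- data.frame(id = seq.int(state$next_id, length.out = k),
                   x = (cells$x[idx] + o1 * ux) %% cfg$L_y,
                   z = cells$z[idx] + o1 * uz,
                   radius = r1, biomass = m1, mu = cells$mu[idx],
                   division_radius = draw_division_radius(k, cfg))
  d2 <- data.frame(id = seq.int(state$next_id + k, length.out = k),
                   x = (cells$x[idx] - o2 * ux) %% cfg$L_y,
                   z = cells$z[idx] - o2 * uz,
                   radius = r2, biomass = m2, mu = cells$mu[idx],
                   division_radius = draw_division_radius(k, cfg))
  d1$z <- pmax(d1$z, d1$radius)
  d2$z <- pmax(d2$z, d2$radius)
  state$cells <- rbind(cells[-idx, , drop = FALSE], d1, d2)
  rownames(state$cells) <- NULL
  state$next_id <- state$next_id + 2L * k
  state
}

#' Advance the simulation by one growth step
#'
#' One cycle of: rasterise biomass onto the nutrient lattice, solve the
#' steady-state reaction-diffusion equation, grow all cells under the frozen
#' field, divide, shove, advance time.
#'
#' @param state a `biofilm_state`.
#' @param cfg a [bf_config()].
#' @param field optional pre-solved [nutrient_grid] to reuse as the Picard
#'   warm start.
#' @return Updated `biofilm_state`; the solved field is kept in attribute
#'   `"field"` and the step's nutrient consumption in attribute `"consumed"`.
#' @export
step_biofilm <- function(state, cfg, field = NULL) {
  if (!nrow(state$cells)) {
    state$time <- state$time + cfg$dt
    return(state)
  }
  grid <- rasterize(state, cfg)
  grid <- solve_steady_state(grid, cfg, warm = field)
  state <- grow(state, grid, cfg, cfg$dt)
  consumed <- attr(state, "consumed")
  state <- divide_cells(state, cfg)
  state <- shove(state, cfg)
  state$time <- state$time + cfg$dt
  attr(state, "field") <- grid
  attr(state, "consumed") <- consumed
  state
}

#' Run a complete biofilm simulation
#'
#' Initialises a biofilm from `cfg`, then repeats growth steps, taking an
#' analysis snapshot every `snapshot_interval` hours and clipping inactive
#' deep biomass every `clip_interval` hours, until the cumulative cell count
#' reaches `target_cell_count` or simulated time reaches `max_time`.
#'
#' @param cfg a [bf_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @param snapshot_dir optional directory: snapshots are also written there
#'   in the text format of [write_snapshot()].
#' @param quiet suppress progress messages.
#' @param stop_on_steady also stop once the roughness series over the
#'   snapshots taken so far passes the [steady_state_window()] criterion
#'   with at least 20 steady points (checked from `min_snapshots` snapshots
#'   onwards).
#' @param min_snapshots earliest snapshot count at which the steady-state
#'   stop is evaluated.
#' @return A list with `snapshots` (list of `biofilm_state`, one per
#'   snapshot time, cells carried in the clipped frame), `state` (final),
#'   `clip_log` (data frame of clip events) and `config`.
#' @export
run_simulation <- function(cfg, seed = cfg$seed, snapshot_dir = NULL,
                           quiet = TRUE, stop_on_steady = FALSE,
                           min_snapshots = 30L) {
  set.seed(seed)
  state <- initialize_biofilm(cfg)
  snaps <- list()
  W_series <- numeric()
  clip_log <- data.frame(time = numeric(), removed = integer(),
                         baseline_offset = numeric())
  next_snap <- 0
  next_clip <- cfg$clip_interval
  field <- NULL
  repeat {
    if (state$time >= next_snap - 1e-9) {
      snaps[[length(snaps) + 1L]] <- state
      if (!is.null(snapshot_dir))
        write_snapshot(state, file.path(snapshot_dir,
                       sprintf("snapshot_%05.0fh.txt", state$time)), cfg)
      next_snap <- next_snap + cfg$snapshot_interval
      if (stop_on_steady) {
        g <- build_grid(state, cfg)
        iface <- extract_interface(g)
        W_series <- c(W_series, if (nrow(iface)) roughness(iface) else NA_real_)
      }
      if (!quiet)
        message(sprintf("t = %6.1f h  alive %6d  total %6d", state$time,
                        nrow(state$cells), total_cells(state)))
    }
    if (total_cells(state) >= cfg$target_cell_count ||
        state$time >= cfg$max_time) break
    if (stop_on_steady && length(W_series) >= min_snapshots) {
      Wok <- W_series[!is.na(W_series)]
      ss <- steady_state_window(Wok)
      if (!is.na(ss) && (length(Wok) - ss + 1L) >= 20L) break
    }
    if (state$time >= next_clip - 1e-9) {
      clipped <- clip(state, cfg)
      state <- clipped$state
      clip_log <- rbind(clip_log,
                        data.frame(time = state$time,
                                   removed = clipped$removed_count,
                                   baseline_offset = state$baseline_offset))
      next_clip <- next_clip + cfg$clip_interval
    }
    state <- step_biofilm(state, cfg, field)
    field <- attr(state, "field")
  }
  list(snapshots = snaps, state = state, clip_log = clip_log, config = cfg)
}
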