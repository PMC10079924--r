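#' Monod specific growth rate
#'
#' Saturating growth kinetics `mu = mu_max * S / (k_S + S)`.
#'
#' @param S local nutrient concentration, g/L (vectorised).
#' @param mu_max maximum specific growth rate, 1/h.
#' @param k_S half-saturation concentration, g/L.
#' @return Specific growth rate(s), 1/h; monotone in `S`, bounded by `mu_max`.
#' @export
#' @examples
#' monod_rate(8.12e-4, 0.29, 8.12e-4)  # half saturation -> mu_max / 2
monod_rate <- function(S, mu_max, k_S) {
  if (any(S < 0)) stop("monod_rate: negative concentration", call. = FALSE)
  stopifnot(mu_max > 0, k_S > 0)
  mu_max * S / (k_S + S)
}

#' Disc biomass-radius closure
#'
#' Cells are discs of a fictitious depth `d_cell`, so mass and radius are
#' linked by `m = rho_B * pi * r^2 * d_cell` with `rho_B` in g/L converted to
#' g/um^3 (1 g/L = 1e-15 g/um^3).
#'
#' @param m biomass, g (vectorised).
#' @param r radius, um (vectorised).
#' @param rho_B biomass density, g/L.
#' @param d_cell disc depth, um.
#' @return radius in um, or biomass in g.
#' @export
biomass_to_radius <- function(m, rho_B, d_cell = 1) {
  if (any(m <= 0)) stop("biomass_to_radius: biomass must be positive", call. = FALSE)
  sqrt(m / (rho_B * 1e-15 * pi * d_cell))
}

#' @rdname biomass_to_radius
#' @export
radius_to_biomass <- function(r, rho_B, d_cell = 1) {
  if (any(r <= 0)) stop("radius_to_biomass: radius must be positive", call. = FALSE)
  rho_B * 1e-15 * pi * r^2 * d_cell
}

## Construct a biofilm state from parallel cell vectors.
## `z` is the height in the clipped frame; absolute height is
## z + baseline_offset.  `total_produced` counts alive + clipped cells so the
## biofilm "size" axis survives clipping.
new_biofilm_state <- function(cells, time = 0, baseline_offset = 0,
                              removed = 0L, next_id = NULL) {
  stopifnot(is.data.frame(cells),
            all(c("id", "x", "z", "radius", "biomass", "mu",
                  "division_radius") %in% names(cells)))
  if (is.null(next_id)) next_id <- if (nrow(cells)) max(cells$id) + 1L else 1L
  structure(list(cells = cells, time = time,
                 baseline_offset = baseline_offset,
                 removed = as.integer(removed),
                 next_id = as.integer(next_id)),
            class = "biofilm_state")
}

#' @export
print.biofilm_state <- function(x, ...) {
  cat(sprintf("<biofilm_state> t = %.2f h, %d cells alive, %d clipped, baseline %.1f um\n",
              x$time, nrow(x$cells), x$removed, x$baseline_offset))
  invisible(x)
}

#' Total number of cells produced by a simulation (alive + clipped)
#' @param state a `biofilm_state`.
#' @return integer count.
#' @export
total_cells <- function(state) nrow(state$cells) + state$removed

## Uniform division-radius draw, U(r_div (1 - delta), r_div (1 + delta)).
draw_division_radius <- function(n, cfg) {
  cfg$r_div * stats::runif(n, 1 - cfg$div_radius_spread, 1 + cfg$div_radius_spread)
}

#' Seed an initial biofilm state
#'
#' Places `N_0` cells on the substratum: each draws a division radius and a
#' current radius corresponding to a biomass uniform between 40% and 60% of
#' its division mass (a freshly divided population).  Lateral positions are
#' stratified along the width in proportion to cell diameter, with uniform
#' jitter inside each stratum, so the seed monolayer is space-filling without
#' large overlaps; residual overlaps are resolved by shoving.
#'
#' @param cfg a [bf_config()].
#' @return A `biofilm_state` at `time = 0` with `baseline_offset = 0`.
#' @export
initialize_biofilm <- function(cfg) {
  n <- as.integer(cfg$N_0)
  div_r <- draw_division_radius(n, cfg)
  m_div <- radius_to_biomass(div_r, cfg$rho_B, cfg$d_cell)
  m <- m_div * stats::runif(n, 0.4, 0.6)
  r <- biomass_to_radius(m, cfg$rho_B, cfg$d_cell)
  if (sum(2 * r) > 2 * cfg$L_y)
    stop("initialize_biofilm: N_0 cells cannot pack into a monolayer of width L_y",
         call. = FALSE)
  ## stratified placement: cell i occupies a stratum proportional to its
  ## diameter, shuffled so sizes are not ordered along x
  ord <- sample.int(n)
  w <- 2 * r[ord]
  edges <- c(0, cumsum(w)) / sum(w) * cfg$L_y
  x <- numeric(n)
  x[ord] <- edges[-(n + 1L)] + stats::runif(n) * diff(edges)
  cells <- data.frame(id = seq_len(n), x = x, z = r, radius = r,
                      biomass = m, mu = 0, division_radius = div_r)
  st <- new_biofilm_state(cells)
  shove(st, cfg)
}
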