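#' Simulation configuration
#'
#' Build a validated configuration for the individual-based biofilm model.
#' Defaults reproduce the standard oxygen-limited *Pseudomonas aeruginosa*
#' flow-cell parameterisation used throughout the package; any field can be
#' overridden.  Internally all lengths are micrometres, times hours and masses
#' grams; concentrations and biomass densities stay in g/L (the
#' reaction-diffusion equation is homogeneous in the concentration unit).
#'
#' @param S_bulk bulk concentration of the limiting nutrient (oxygen), g/L.
#' @param Y yield: grams of biomass produced per gram of nutrient consumed.
#' @param mu_max maximum specific growth rate, 1/h.
#' @param k_S half-saturation nutrient concentration, g/L.
#' @param D_S nutrient diffusion coefficient in the liquid, m^2/day (the
#'   conventional unit; converted internally to um^2/h, see `D_S_um2h`).
#' @param biofilm_diffusivity_factor dimensionless multiplier on `D_S` inside
#'   biofilm voxels.
#' @param h_bl diffusion boundary layer height, um.
#' @param rho_B biomass density of a cell, g/L.
#' @param r_div mean maximum (division) radius, um.
#' @param k_shov shove factor: multiplies a cell radius to give its zone of
#'   influence. Must be >= 1.
#' @param L_y lateral domain width, um (periodic direction). Must be an
#'   integer multiple of `bin_width` and `grid_spacing_pde`.
#' @param N_0 number of cells seeded on the substratum.
#' @param dt growth time step, h. Default `0.05 / mu_max` so biomass changes
#'   by at most ~5\% per step and the frozen-field approximation holds.
#' @param snapshot_interval cadence of analysis snapshots, h.
#' @param clip_interval time between clipping events, h.
#' @param clip_margin extra depth retained below the clip line, um.
#' @param grid_spacing_pde lattice spacing of the nutrient solver, um.
#' @param bin_width analysis bin width, um (8 um grid).
#' @param active_threshold_fraction fraction of the maximal attainable Monod
#'   rate defining the active layer (default 1/1000).
#' @param pin_lag lag used by the pinning test, h. Must be an integer
#'   multiple of `snapshot_interval`.
#' @param seed RNG seed for a simulation run.
#' @param target_cell_count stop condition: cumulative number of cells
#'   produced (alive plus clipped).
#' @param max_time stop condition on simulated time, h.
#' @param d_cell fictitious disc depth closing the 2D mass-geometry relation
#'   `m = rho_B * pi * r^2 * d_cell`, um.
#' @param div_radius_spread relative half-width of the uniform distribution of
#'   per-cell division radii about `r_div`.
#' @param split_spread maximum biomass asymmetry of a division
#'   (daughter fractions 1/2 +- eps, eps ~ U(0, split_spread)).
#' @param tol_shove residual overlap tolerance of the shoving relaxation, um.
#' @param max_sweeps maximum shoving sweeps per relaxation.
#' @param tol_pde_frac nutrient solver residual tolerance as a fraction of
#'   `S_bulk`.
#' @param max_outer maximum Picard iterations of the nutrient solver.
#' @param picard_relax Picard damping factor in (0, 1].
#'
#' @return An object of class `bf_config`: a named list with the fields above
#'   plus `D_S_um2h`, the diffusion coefficient converted to um^2/h.
#' @export
#' @examples
#' cfg <- bf_config()
#' cfg$S_bulk
#' cfg$D_S_um2h  # 2.3e-4 m^2/day in um^2/h
bf_config <- function(S_bulk = 6.6e-3,
                      Y = 0.64,
                      mu_max = 0.29,
                      k_S = 8.12e-4,
                      D_S = 2.3e-4,
                      biofilm_diffusivity_factor = 0.8,
                      h_bl = 80,
                      rho_B = 200,
                      r_div = 2,
                      k_shov = 1.15,
                      L_y = 1032,
                      N_0 = 300,
                      dt = NULL,
                      snapshot_interval = 6,
                      clip_interval = 24,
                      clip_margin = 16,
                      grid_spacing_pde = 8,
                      bin_width = 8,
                      active_threshold_fraction = 1e-3,
                      pin_lag = 6,
                      seed = 1L,
                      target_cell_count = 15000,
                      max_time = Inf,
                      d_cell = 1,
                      div_radius_spread = 0.1,
                      split_spread = 0.05,
                      tol_shove = 0.01,
                      max_sweeps = 30L,
                      max_outer = 200L,
                      tol_pde_frac = 1e-6,
                      picard_relax = 0.7) {
  if (is.null(dt)) dt <- 0.05 / mu_max
  cfg <- list(
    S_bulk = S_bulk, Y = Y, mu_max = mu_max, k_S = k_S, D_S = D_S,
    biofilm_diffusivity_factor = biofilm_diffusivity_factor,
    h_bl = h_bl, rho_B = rho_B, r_div = r_div, k_shov = k_shov,
    L_y = L_y, N_0 = N_0, dt = dt,
    snapshot_interval = snapshot_interval,
    clip_interval = clip_interval, clip_margin = clip_margin,
    grid_spacing_pde = grid_spacing_pde, bin_width = bin_width,
    active_threshold_fraction = active_threshold_fraction,
    pin_lag = pin_lag, seed = as.integer(seed),
    target_cell_count = target_cell_count, max_time = max_time,
    d_cell = d_cell,
    div_radius_spread = div_radius_spread, split_spread = split_spread,
    tol_shove = tol_shove, max_sweeps = as.integer(max_sweeps),
    max_outer = as.integer(max_outer), tol_pde_frac = tol_pde_frac,
    picard_relax = picard_relax
  )
  cfg$D_S_um2h <- convert_D_to_um2h(D_S)
  class(cfg) <- "bf_config"
  validate_config(cfg)
}

# m^2/day -> um^2/h  (1 m^2 = 1e12 um^2, 1 day = 24 h)
convert_D_to_um2h <- function(D_m2day) D_m2day * 1e12 / 24

#' @export
print.bf_config <- function(x, ...) {
  cat("<bf_config>\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "bf_config"))
  pos_fields <- c("S_bulk", "Y", "mu_max", "k_S", "D_S",
                  "biofilm_diffusivity_factor", "h_bl", "rho_B", "r_div",
                  "k_shov", "L_y", "N_0", "dt", "snapshot_interval",
                  "clip_interval", "grid_spacing_pde", "bin_width",
                  "pin_lag", "target_cell_count", "d_cell", "tol_shove",
                  "max_sweeps", "max_outer", "tol_pde_frac", "picard_relax")
  for (f in pos_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("config validation: field '%s' must be a single positive number", f),
           call. = FALSE)
  }
  nonneg_fields <- c("clip_margin", "div_radius_spread", "split_spread")
  for (f in nonneg_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("config validation: field '%s' must be a single non-negative number", f),
           call. = FALSE)
  }
  if (cfg$k_shov < 1)
    stop("config validation: field 'k_shov' must be >= 1", call. = FALSE)
  if (cfg$active_threshold_fraction <= 0 || cfg$active_threshold_fraction >= 1)
    stop("config validation: field 'active_threshold_fraction' must lie in (0,1)",
         call. = FALSE)
  if (abs(cfg$pin_lag / cfg$snapshot_interval -
          round(cfg$pin_lag / cfg$snapshot_interval)) > 1e-9)
    stop("config validation: 'pin_lag' must be an integer multiple of 'snapshot_interval'",
         call. = FALSE)
  for (f in c("bin_width", "grid_spacing_pde")) {
    if (abs(cfg$L_y / cfg[[f]] - round(cfg$L_y / cfg[[f]])) > 1e-9)
      stop(sprintf("config validation: 'L_y' must be an integer multiple of '%s'", f),
           call. = FALSE)
  }
  cfg
}

## Keys that must be present in a parameter file; everything else falls back
## to the bf_config() defaults.
.required_keys <- c("S_bulk", "Y", "mu_max", "k_S", "D_S",
                    "biofilm_diffusivity_factor", "h_bl", "rho_B",
                    "r_div", "k_shov", "L_y", "N_0")

#' Load a simulation configuration from a flat parameter file
#'
#' The file format is one `key: value` pair per line; `#` starts a comment.
#' Keys are the field names of [bf_config()]; `D_S` is given in m^2/day and
#' converted to um^2/h internally. The core physical parameters
#' (`S_bulk`, `Y`, `mu_max`, `k_S`, `D_S`, `biofilm_diffusivity_factor`,
#' `h_bl`, `rho_B`, `r_div`, `k_shov`, `L_y`, `N_0`) are required; all other
#' keys are optional and take the documented defaults.
#'
#' @param source path to a parameter file, or a character vector of lines.
#' @param overrides named list of values overriding the file (used by the
#'   command line interface).
#' @return A validated [bf_config()] object.
#' @export
load_config <- function(source, overrides = list()) {
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source) else source
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.+)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("parameter file parse error at line: ", lines[bad][1L], call. = FALSE)
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  if (anyDuplicated(keys))
    stop("duplicate parameter key: ", keys[duplicated(keys)][1L], call. = FALSE)
  known <- names(formals(bf_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  parsed <- as.list(suppressWarnings(as.numeric(trimws(vals))))
  names(parsed) <- keys
  if (anyNA(unlist(parsed)))
    stop("non-numeric parameter value for key: ",
         keys[is.na(unlist(parsed))][1L], call. = FALSE)
  parsed[names(overrides)] <- overrides
  missing <- setdiff(.required_keys, names(parsed))
  if (length(missing))
    stop("missing required parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(bf_config, parsed)
}

#' Write a configuration to a flat parameter file
#'
#' @param cfg a [bf_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "bf_config"))
  keep <- intersect(names(formals(bf_config)), names(cfg))
  lines <- sprintf("%s: %.17g", keep, vapply(cfg[keep], as.numeric, 0))
  writeLines(c("# biofilmpin parameter file", lines), path)
  invisible(path)
}

## Polynomial rolling hash (mod 2^31 - 1) for config fingerprints in
## snapshot headers.  Exact in double arithmetic: intermediate values < 2^53.
## The seed is run metadata, not part of the physical configuration, so it
## is excluded: snapshots stay compatible with an analysis config that
## differs only in seed.
config_fingerprint <- function(cfg) {
  keep <- setdiff(intersect(names(formals(bf_config)), names(cfg)), "seed")
  txt <- paste(keep, vapply(cfg[keep], function(v) sprintf("%.17g", as.numeric(v)), ""),
               collapse = ";")
  bytes <- utf8ToInt(txt)
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% m
  sprintf("%08x", as.integer(h))
}
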