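## Shared test configurations. Small domains keep the suite fast; physical
## parameters stay at the package defaults unless a test says otherwise.

test_config <- function(...) {
  args <- utils::modifyList(list(L_y = 64, N_0 = 18, target_cell_count = 600),
                            list(...))
  do.call(bf_config, args)
}

## random loose-packed state for property tests (no overlaps guaranteed)
random_state <- function(n, cfg, zmax = 40) {
  r <- runif(n, 0.8, 2)
  cells <- data.frame(id = seq_len(n),
                      x = runif(n, 0, cfg$L_y),
                      z = runif(n, r, zmax),
                      radius = r,
                      biomass = radius_to_biomass(r, cfg$rho_B, cfg$d_cell),
                      mu = runif(n, 0, cfg$mu_max),
                      division_radius = rep(cfg$r_div, n))
  new_biofilm_state(cells, time = runif(1, 0, 100),
                    baseline_offset = sample(c(0, 512), 1))
}

## random small occupancy grid (H x D) for interface property tests
random_grid <- function(H, D, p = 0.5, bin = 8, row0 = 0L) {
  occ <- matrix(runif(H * D) < p, H, D)
  structure(list(biomass = occ * 1e-12, rate = matrix(0, H, D), occ = occ,
                 row0 = as.integer(row0), bin = bin, D = D, H = H),
            class = "analysis_grid")
}
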