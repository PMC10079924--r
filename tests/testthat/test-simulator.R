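test_that("Monod kinetics: half-saturation, limits, and reference value", {
  expect_equal(monod_rate(8.12e-4, 0.29, 8.12e-4), 0.29 / 2)
  expect_equal(monod_rate(0, 0.29, 8.12e-4), 0)
  ## default parameter set at bulk concentration: 0.29 * 6.6e-3 / 7.412e-3
  expect_equal(monod_rate(6.6e-3, 0.29, 8.12e-4), 0.25823, tolerance = 1e-4)
  ## monotone, bounded
  S <- seq(0, 1, length.out = 50)
  mu <- monod_rate(S, 0.29, 8.12e-4)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu <= 0.29))
  expect_error(monod_rate(-1e-9, 0.29, 8.12e-4), "negative")
})

test_that("biomass-radius closure inverts and scales", {
  cfg <- test_config()
  m <- radius_to_biomass(2, cfg$rho_B, cfg$d_cell)
  expect_equal(biomass_to_radius(m, cfg$rho_B, cfg$d_cell), 2)
  expect_equal(biomass_to_radius(2 * m, cfg$rho_B, cfg$d_cell), 2 * sqrt(2))
  ## unit case: m = rho_B * pi * d_cell * (1 um)^2  (rho_B in g/um^3)
  expect_equal(biomass_to_radius(cfg$rho_B * 1e-15 * pi * cfg$d_cell,
                                 cfg$rho_B, cfg$d_cell), 1)
  expect_error(biomass_to_radius(0, cfg$rho_B), "positive")
})

test_that("initialization seeds a relaxed monolayer", {
  cfg <- bf_config(L_y = 1032, N_0 = 300, target_cell_count = 1e5)
  set.seed(7)
  st <- initialize_biofilm(cfg)
  expect_equal(nrow(st$cells), 300)
  expect_true(all(st$cells$z <= 2 * cfg$r_div))
  expect_true(all(st$cells$z >= st$cells$radius - 1e-9))
  expect_true(all(st$cells$x >= 0 & st$cells$x < cfg$L_y))
  expect_equal(st$time, 0)
  expect_equal(st$baseline_offset, 0)
  ## determinism under a fixed seed
  set.seed(11); a <- initialize_biofilm(cfg)
  set.seed(11); b <- initialize_biofilm(cfg)
  expect_identical(a, b)
  ## degenerate single cell sits on the substratum
  set.seed(1)
  one <- initialize_biofilm(bf_config(L_y = 64, N_0 = 1))
  expect_equal(one$cells$z, one$cells$radius)
  ## overfull seed errors
  expect_error(initialize_biofilm(bf_config(L_y = 64, N_0 = 300)),
               "monolayer")
})

test_that("growth is an exact exponential integrator under a frozen field", {
  cfg <- test_config()
  set.seed(3)
  st <- initialize_biofilm(cfg)
  grid <- solve_steady_state(rasterize(st, cfg), cfg)
  ## uniform S = S_bulk when consumption is negligible at a monolayer:
  ## impose it exactly by overwriting the field
  grid$S[] <- cfg$S_bulk
  g1 <- grow(st, grid, cfg, dt = 0.3)
  fac <- exp(monod_rate(cfg$S_bulk, cfg$mu_max, cfg$k_S) * 0.3)
  expect_equal(g1$cells$biomass, st$cells$biomass * fac, tolerance = 1e-12)
  ## zero nutrient: no growth
  grid0 <- grid; grid0$S[] <- 0
  expect_equal(grow(st, grid0, cfg, dt = 0.3)$cells$biomass,
               st$cells$biomass)
  ## composition: n steps of dt equal one step of n*dt
  g3 <- st
  for (i in 1:3) g3 <- grow(g3, grid, cfg, dt = 0.1)
  expect_equal(g3$cells$biomass, g1$cells$biomass, tolerance = 1e-12)
  expect_error(grow(st, grid, cfg, dt = 0), "dt")
})

test_that("division conserves biomass and respects thresholds", {
  cfg <- test_config()
  set.seed(5)
  st <- initialize_biofilm(cfg)
  ## no cell at threshold: no-op
  expect_identical(divide_cells(st, cfg)$cells, st$cells)
  ## push one cell over its division radius (away from the substratum so
  ## daughter placement is not clipped by the floor)
  st2 <- st
  st2$cells$z[4] <- 20
  st2$cells$radius[4] <- st2$cells$division_radius[4]
  st2$cells$biomass[4] <- radius_to_biomass(st2$cells$radius[4], cfg$rho_B)
  div <- divide_cells(st2, cfg)
  expect_equal(nrow(div$cells), nrow(st2$cells) + 1L)
  expect_equal(sum(div$cells$biomass), sum(st2$cells$biomass))
  ## daughters tangent: separation equals sum of radii
  kids <- div$cells[div$cells$id >= st2$next_id, ]
  dx <- abs(kids$x[1] - kids$x[2]); dx <- min(dx, cfg$L_y - dx)
  d <- sqrt(dx^2 + (kids$z[1] - kids$z[2])^2)
  expect_equal(d, sum(kids$radius), tolerance = 1e-9)
  ## symmetric split when split_spread = 0
  cfg0 <- test_config(split_spread = 0)
  div0 <- divide_cells(st2, cfg0)
  kids0 <- div0$cells[div0$cells$id >= st2$next_id, ]
  expect_equal(kids0$biomass[1], kids0$biomass[2])
  ## biomass-radius consistency after the operation
  expect_equal(div$cells$biomass,
               radius_to_biomass(div$cells$radius, cfg$rho_B, cfg$d_cell),
               tolerance = 1e-12)
})

test_that("shove resolves a single overlapping pair to the closed form", {
  cfg <- test_config(L_y = 200)
  r <- 1.5
  m <- radius_to_biomass(r, cfg$rho_B)
  cells <- data.frame(id = 1:2, x = c(100, 101.8), z = c(50, 51),
                      radius = r, biomass = m, mu = 0,
                      division_radius = cfg$r_div)
  st <- new_biofilm_state(cells)
  d0 <- sqrt(1.8^2 + 1)
  u0 <- c(1.8, 1) / d0
  set.seed(9)
  out <- shove(st, cfg)
  dx <- out$cells$x[2] - out$cells$x[1]
  dz <- out$cells$z[2] - out$cells$z[1]
  d1 <- sqrt(dx^2 + dz^2)
  target <- cfg$k_shov * 2 * r
  expect_equal(d1, target, tolerance = cfg$tol_shove)
  ## along the original line of centres, symmetric displacement
  expect_equal(c(dx, dz) / d1, u0, tolerance = 1e-6)
  expect_equal(mean(out$cells$x), mean(cells$x), tolerance = 1e-9)
  ## non-overlapping pair untouched
  cells2 <- cells; cells2$x <- c(100, 110)
  expect_equal(shove(new_biofilm_state(cells2), cfg)$cells$x, cells2$x)
  ## substratum reflection
  cells3 <- cells[1, ]; cells3$z <- 0.2
  expect_gte(shove(new_biofilm_state(cells3), cfg)$cells$z, r)
})

test_that("a shove sweep does not increase the maximum overlap (vs brute force)", {
  cfg <- test_config(L_y = 120)
  set.seed(21)
  for (rep in 1:8) {
    st <- random_state(12, cfg, zmax = 30)
    ## compress a little to create overlaps
    st$cells$radius <- st$cells$radius * 1.4
    st$cells$biomass <- radius_to_biomass(st$cells$radius, cfg$rho_B)
    ov0 <- max_overlap(st, cfg)
    st1 <- suppressWarnings(shove(st, cfg, max_sweeps = 1))
    ov1 <- max_overlap(st1, cfg)
    expect_lte(ov1, ov0 + 1e-9)
  }
})

test_that("a growth step keeps the yield bookkeeping and mass balance", {
  cfg <- test_config(N_0 = 12)
  set.seed(13)
  st <- initialize_biofilm(cfg)
  b0 <- sum(st$cells$biomass)
  st1 <- step_biofilm(st, cfg)
  expect_equal(st1$time, cfg$dt)
  expect_gte(nrow(st1$cells), nrow(st$cells))
  consumed <- attr(st1, "consumed")
  expect_equal(sum(st1$cells$biomass) - b0, cfg$Y * consumed,
               tolerance = 1e-9)
  ## instantaneous PDE consumption matches the biomass production rate to
  ## within the frozen-field integration error (~mu*dt/2)
  fb <- flux_balance(attr(st1, "field"), cfg)
  expect_equal(cfg$Y * fb[["consumption"]] * cfg$dt,
               sum(st1$cells$biomass) - b0,
               tolerance = cfg$mu_max * cfg$dt)
  ## empty system: only time advances
  empty <- new_biofilm_state(st$cells[0, ])
  e1 <- step_biofilm(empty, cfg)
  expect_equal(nrow(e1$cells), 0L)
  expect_equal(e1$time, cfg$dt)
})

test_that("with abundant nutrient the colony doubles at ln2/mu_max", {
  ## S_bulk >> k_S everywhere keeps every cell at mu ~ mu_max
  cfg <- bf_config(L_y = 64, N_0 = 10, S_bulk = 5, target_cell_count = 1e6)
  set.seed(17)
  st <- initialize_biofilm(cfg)
  b0 <- sum(st$cells$biomass)
  n_steps <- 20L
  for (i in seq_len(n_steps)) st <- step_biofilm(st, cfg, attr(st, "field"))
  growth <- log(sum(st$cells$biomass) / b0) / (n_steps * cfg$dt)
  expect_equal(growth, cfg$mu_max, tolerance = 0.05)
})

test_that("identical config and seed give identical trajectories", {
  cfg <- test_config(target_cell_count = 120)
  r1 <- run_simulation(cfg, seed = 4)
  r2 <- run_simulation(cfg, seed = 4)
  expect_identical(lapply(r1$snapshots, `[[`, "cells"),
                   lapply(r2$snapshots, `[[`, "cells"))
})
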