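test_that("analysis grid bins cells by centre and conserves biomass", {
  cfg <- test_config()
  m <- radius_to_biomass(1, cfg$rho_B)
  cells <- data.frame(id = 1:3,
                      x = c(3, 4, 60), z = c(3, 5, 10),
                      radius = 1, biomass = m, mu = c(0.1, 0.3, 0.2),
                      division_radius = cfg$r_div)
  st <- new_biofilm_state(cells)
  g <- build_grid(st, cfg)
  ## cells 1 and 2 share the square (row 1, col 1): equal biomass -> mean rate
  expect_equal(g$rate[1, 1], 0.2)
  expect_equal(g$biomass[1, 1], 2 * m)
  ## cell 3 alone in (row 2, col 8)
  expect_equal(g$biomass[2, 8], m)
  expect_equal(g$rate[2, 8], 0.2)
  expect_equal(sum(g$biomass), sum(cells$biomass))
  expect_equal(sum(g$occ), 2L)
})

test_that("active mask applies the strict threshold", {
  cfg <- test_config()
  thr <- active_threshold(cfg)
  m <- radius_to_biomass(1, cfg$rho_B)
  mk <- function(mu) {
    cells <- data.frame(id = 1L, x = 3, z = 3, radius = 1, biomass = m,
                        mu = mu, division_radius = cfg$r_div)
    active_mask(build_grid(new_biofilm_state(cells), cfg), cfg)[1, 1]
  }
  ## maximal attainable rate is active; zero is not; the threshold itself
  ## is excluded (strict inequality)
  expect_true(mk(cfg$mu_max * cfg$S_bulk / (cfg$k_S + cfg$S_bulk)))
  expect_false(mk(0))
  expect_false(mk(thr))
  expect_true(mk(thr * (1 + 1e-12)))
})

test_that("active-layer profile counts non-adjacent squares and gaps", {
  cfg <- test_config()
  D <- 8L; H <- 5L
  occ <- matrix(TRUE, H, D)
  rate <- matrix(0, H, D)
  thr <- active_threshold(cfg)
  ## column 1: 3 active squares; column 2: split active layer around an
  ## inactive trough; column 3: none (gap)
  rate[3:5, 1] <- 2 * thr
  rate[c(1, 5), 2] <- 2 * thr
  grid <- structure(list(biomass = occ * 1e-12, rate = rate, occ = occ,
                         row0 = 0L, bin = 8, D = D, H = H),
                    class = "analysis_grid")
  prof <- active_layer_profile(grid, active_mask(grid, cfg))
  expect_equal(prof$thickness[1], 24)
  expect_equal(prof$thickness[2], 16)  # both strata counted
  expect_equal(prof$thickness[3], 0)
  expect_true(prof$gap[3])
  expect_equal(prof$n_gaps, sum(prof$thickness == 0))
  ## uniform profile: zero spread
  uni <- active_layer_profile(grid, matrix(TRUE, H, D))
  expect_equal(uni$sd, 0)
  expect_equal(uni$cv, 0)
})

test_that("interface extraction matches geometry on canonical shapes", {
  mk_grid <- function(occ, bin = 8, row0 = 0L) {
    structure(list(biomass = occ * 1e-12, rate = occ * 0, occ = occ,
                   row0 = as.integer(row0), bin = bin, D = ncol(occ),
                   H = nrow(occ)), class = "analysis_grid")
  }
  ## filled monolayer: every occupied square has an empty top neighbour
  mono <- mk_grid(matrix(TRUE, 1, 6))
  expect_equal(nrow(extract_interface(mono)), 6L)
  ## a filled rectangle (width 4 of 8 columns, height 3): top row + sides
  occ <- matrix(FALSE, 3, 8)
  occ[, 3:6] <- TRUE
  rect <- extract_interface(mk_grid(occ))
  expect_equal(nrow(rect), 4L + 2L * 2L)
  bf <- interface_bruteforce(mk_grid(occ))
  expect_equal(rect[order(rect$col, rect$row), c("col", "row")],
               bf[order(bf$col, bf$row), c("col", "row")],
               ignore_attr = TRUE)
  ## empty grid: empty interface, roughness is an error
  none <- extract_interface(mk_grid(matrix(FALSE, 2, 4)))
  expect_equal(nrow(none), 0L)
  expect_error(roughness(none), "empty")
})

test_that("interface extraction equals the brute-force scan on random grids", {
  set.seed(31)
  for (rep in 1:20) {
    g <- random_grid(sample(2:7, 1), sample(3:9, 1), p = runif(1, 0.2, 0.8),
                     row0 = sample(c(0L, 64L), 1))
    a <- extract_interface(g)
    b <- interface_bruteforce(g)
    expect_equal(a[order(a$col, a$row), c("col", "row", "h")],
                 b[order(b$col, b$row), c("col", "row", "h")],
                 ignore_attr = TRUE)
  }
})

test_that("roughness implements the rms height deviation", {
  iface <- structure(data.frame(col = 1:10, row = rep(c(1L, 2L), 5),
                                h = rep(c(10, 20), 5)),
                     N_int = 10L, bin = 8,
                     class = c("interface_set", "data.frame"))
  expect_equal(roughness(iface), 5)
  ## flat interface
  flat <- iface; flat$h <- rep(12, 10)
  expect_equal(roughness(flat), 0)
  ## translation invariance in height (clip-frame shifts)
  shifted <- iface; shifted$h <- iface$h + 512
  expect_equal(roughness(shifted), roughness(iface))
})

test_that("pinned fraction counts stationary inactive interface squares", {
  cfg <- bf_config(L_y = 1200, N_0 = 300)  # D = 150 columns
  frames <- make_pinning_sequence(3, base_height = 40, cfg,
                                  pinned_cols = 11:22)  # 12 columns
  grids <- lapply(frames, build_grid, cfg = cfg)
  masks <- lapply(grids, active_mask, cfg = cfg)
  ifaces <- lapply(grids, extract_interface)
  pr <- pinned_set(ifaces[[2]], ifaces[[1]], masks[[2]], grids[[2]],
                   lag = cfg$pin_lag)
  expect_equal(pr$N_int, 150L)
  expect_equal(pr$N_P, 12L)
  expect_equal(pr$f_P, 0.08)
  expect_equal(pr$pinned_cols, 11:22)
  ## fully active advancing front: no pinning
  frames0 <- make_pinning_sequence(2, base_height = 40, cfg)
  g0 <- lapply(frames0, build_grid, cfg = cfg)
  pr0 <- pinned_set(extract_interface(g0[[2]]), extract_interface(g0[[1]]),
                    active_mask(g0[[2]], cfg), g0[[2]], lag = cfg$pin_lag)
  expect_equal(pr0$f_P, 0)
  ## identical frames, everything inactive: total pinning
  st <- frames[[1]]
  g <- build_grid(st, cfg)
  i1 <- extract_interface(g)
  all_inactive <- active_mask(g, cfg) & FALSE
  pr1 <- pinned_set(i1, i1, all_inactive, g, lag = cfg$pin_lag)
  expect_equal(pr1$f_P, 1)
})

test_that("W and f_P are invariant under clipping-frame shifts", {
  cfg <- test_config()
  set.seed(41)
  st <- random_state(60, cfg, zmax = 48)
  st$cells$mu <- ifelse(st$cells$z > 24, cfg$mu_max / 2, 0)
  ## same absolute configuration in two clipping frames (bin-aligned)
  st$baseline_offset <- 16
  st2 <- st
  st2$cells$z <- st$cells$z + 16
  st2$baseline_offset <- 0
  g1 <- build_grid(st, cfg); g2 <- build_grid(st2, cfg)
  expect_equal(roughness(extract_interface(g1)),
               roughness(extract_interface(g2)))
  p1 <- active_layer_profile(g1, active_mask(g1, cfg))
  p2 <- active_layer_profile(g2, active_mask(g2, cfg))
  expect_equal(p1$thickness, p2$thickness)
})
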