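## Synthetic biofilm fixtures with closed-form ground truth.
##
## All fixtures are built from an analytically constructed occupancy matrix
## (one entry per analysis square): each occupied square is filled with a
## dense lattice of radius-1 um cells (spacing 2 um) whose specific growth
## rate is the square's prescribed rate. Ground-truth morphometrics are
## computed from that occupancy by an exhaustive neighbour scan at
## generation time, independently of the vectorised analysis path under
## test, and stored in attribute "truth".

## cells filling the occupied squares of occ (H x D), with per-square rates.
## row0 gives the absolute row of occ row 1 (usually 0).
state_from_occupancy <- function(occ, rate, cfg, row0 = 0L) {
  bin <- cfg$bin_width
  stopifnot(bin %% 2 == 0, ncol(occ) * bin == cfg$L_y)
  w <- which(occ, arr.ind = TRUE)
  per_side <- bin / 2
  off <- seq(1, bin - 1, by = 2)
  nsq <- nrow(w)
  xs <- rep((w[, 2L] - 1L) * bin, each = per_side^2) +
    rep(rep(off, each = per_side), nsq)
  zs <- rep((row0 + w[, 1L] - 1L) * bin, each = per_side^2) +
    rep(rep(off, times = per_side), nsq)
  mus <- rep(rate[w], each = per_side^2)
  r <- 1
  m <- radius_to_biomass(r, cfg$rho_B, cfg$d_cell)
  cells <- data.frame(id = seq_along(xs), x = xs, z = zs,
                      radius = r, biomass = m, mu = mus,
                      division_radius = cfg$r_div)
  new_biofilm_state(cells)
}

## ground truth from an occupancy/rate matrix: interface squares (exhaustive
## scan), W, per-column thickness, gaps.
occupancy_truth <- function(occ, rate, cfg, row0 = 0L) {
  thr <- active_threshold(cfg)
  g <- list(occ = occ, row0 = as.integer(row0), bin = cfg$bin_width,
            D = ncol(occ), H = nrow(occ))
  iface <- interface_bruteforce(g)
  active <- occ & rate > thr
  thickness <- cfg$bin_width * colSums(active)
  list(interface = iface, N_int = nrow(iface),
       W = if (nrow(iface)) sqrt(mean((iface$h - mean(iface$h))^2)) else NA_real_,
       thickness = thickness, gap = thickness == 0, active = active)
}

max_rate <- function(cfg) cfg$mu_max * cfg$S_bulk / (cfg$k_S + cfg$S_bulk)

#' Flat biofilm fixture
#'
#' A laterally uniform slab of cells: every square up to `height` is
#' occupied; squares within `active_depth` of the top carry the maximal
#' attainable rate, deeper squares rate 0. Ground truth (attribute
#' `"truth"`): every column thickness equals `active_depth`, W = 0, no gaps.
#'
#' @param height,active_depth slab height and active depth, um; multiples of
#'   `cfg$bin_width`, with `active_depth <= height`.
#' @param cfg a [bf_config()] whose `L_y` is the fixture width.
#' @return A `biofilm_state` with attribute `"truth"`.
#' @export
make_flat_biofilm <- function(height, active_depth, cfg) {
  stopifnot(active_depth <= height)
  bin <- cfg$bin_width
  H <- as.integer(round(height / bin))
  D <- as.integer(round(cfg$L_y / bin))
  occ <- matrix(TRUE, H, D)
  rate <- matrix(0, H, D)
  n_act <- as.integer(round(active_depth / bin))
  if (n_act > 0) rate[seq.int(H - n_act + 1L, H), ] <- max_rate(cfg)
  st <- state_from_occupancy(occ, rate, cfg)
  attr(st, "truth") <- occupancy_truth(occ, rate, cfg)
  st
}

#' Fingered biofilm fixture
#'
#' Alternating fingers and troughs, optionally with mushroom overhangs
#' (caps wider than their stalk, leaving empty squares beneath the cap
#' edges, so the interface is genuinely multi-valued and `N_int > D`).
#' Squares within `active_depth` of the local top are active; troughs can be
#' forced inactive to create active-layer gaps.
#'
#' @param finger_height,trough_height heights in um (bin multiples);
#'   `finger_height > trough_height`.
#' @param n_fingers number of fingers across the width.
#' @param finger_fraction fraction of each period occupied by the finger
#'   stalk.
#' @param overhang lateral cap extension beyond the stalk on each side, um
#'   (bin multiple); the cap occupies the top bin row of the finger.
#' @param active_depth depth of the active stratum below the local top, um.
#' @param trough_active logical: are trough tops active?
#' @param cfg a [bf_config()].
#' @return A `biofilm_state` with attribute `"truth"`.
#' @export
make_fingered_biofilm <- function(finger_height, trough_height, cfg,
                                  n_fingers = 2L, finger_fraction = 0.5,
                                  overhang = 0, active_depth = cfg$bin_width,
                                  trough_active = TRUE) {
  stopifnot(finger_height > trough_height)
  bin <- cfg$bin_width
  D <- as.integer(round(cfg$L_y / bin))
  period <- D / n_fingers
  stopifnot(period == round(period))
  n_stalk <- max(1L, as.integer(round(period * finger_fraction)))
  n_over <- as.integer(round(overhang / bin))
  if (n_stalk + 2L * n_over > period)
    stop("make_fingered_biofilm: overhang wider than the finger pitch",
         call. = FALSE)
  Hf <- as.integer(round(finger_height / bin))
  Ht <- as.integer(round(trough_height / bin))
  occ <- matrix(FALSE, Hf, D)
  finger_col <- rep(FALSE, D)
  for (k in seq_len(n_fingers)) {
    j0 <- (k - 1L) * period
    finger_col[j0 + seq_len(n_stalk)] <- TRUE
  }
  occ[seq_len(Ht), ] <- TRUE
  occ[seq_len(Hf), finger_col] <- TRUE
  if (n_over > 0) {
    cap_cols <- finger_col
    for (d in seq_len(n_over)) {
      cap_cols <- cap_cols |
        finger_col[c(D - d + seq_len(d), seq_len(D - d))] |
        finger_col[c(seq_len(D - d) + d, seq_len(d))]
    }
    occ[Hf, cap_cols] <- TRUE
  }
  ## activity: within active_depth of the local column top, tracking
  ## the (possibly multi-valued) occupancy from the top down
  n_act <- as.integer(round(active_depth / bin))
  rate <- matrix(0, Hf, D)
  for (j in seq_len(D)) {
    top <- max(which(occ[, j]))
    act_rows <- seq.int(max(1L, top - n_act + 1L), top)
    rate[act_rows, j] <- ifelse(occ[act_rows, j], max_rate(cfg), 0)
  }
  if (!trough_active) rate[, !finger_col] <- 0
  st <- state_from_occupancy(occ, rate, cfg)
  attr(st, "truth") <- occupancy_truth(occ, rate, cfg)
  st
}

#' Frame sequence with prescribed pinning and gap motion
#'
#' Generates `n_frames` states `snapshot_interval` hours apart in which most
#' columns advance by `advance_rows` analysis rows per frame while
#' `pinned_cols` keep their initial top height with zero growth rate
#' (stationary, inactive interface squares), and `gap_cols` (optionally
#' drifting laterally by `gap_drift` columns per frame) are made inactive to
#' create active-layer gaps. Ground truth per frame (attribute `"truth"` of
#' each state) carries the occupancy-derived interface and thickness; the
#' expected pinned fraction for a frame pair is the brute-force count of
#' stationary inactive interface squares over `N_int`.
#'
#' @param n_frames number of frames.
#' @param base_height initial uniform top height, um (bin multiple).
#' @param advance_rows rows advanced per frame by unpinned columns.
#' @param pinned_cols integer column indices that stay put (inactive).
#' @param gap_cols integer column indices with no active squares.
#' @param gap_drift lateral drift of `gap_cols`, columns per frame.
#' @param active_depth active stratum depth below the local top, um.
#' @param cfg a [bf_config()].
#' @return List of `biofilm_state` frames.
#' @export
make_pinning_sequence <- function(n_frames, base_height, cfg,
                                  advance_rows = 1L,
                                  pinned_cols = integer(),
                                  gap_cols = integer(), gap_drift = 0L,
                                  active_depth = 2 * cfg$bin_width) {
  bin <- cfg$bin_width
  D <- as.integer(round(cfg$L_y / bin))
  Hb <- as.integer(round(base_height / bin))
  n_act <- as.integer(round(active_depth / bin))
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    adv <- (k - 1L) * advance_rows
    tops <- rep(Hb + adv, D)
    tops[pinned_cols] <- Hb
    H <- max(tops)
    occ <- matrix(FALSE, H, D)
    for (j in seq_len(D)) occ[seq_len(tops[j]), j] <- TRUE
    rate <- matrix(0, H, D)
    for (j in seq_len(D)) {
      act_rows <- seq.int(max(1L, tops[j] - n_act + 1L), tops[j])
      rate[act_rows, j] <- max_rate(cfg)
    }
    rate[, pinned_cols] <- 0
    gcols <- if (length(gap_cols))
      ((gap_cols - 1L + (k - 1L) * gap_drift) %% D) + 1L else integer()
    rate[, gcols] <- 0
    st <- state_from_occupancy(occ, rate, cfg)
    st$time <- (k - 1L) * cfg$snapshot_interval
    attr(st, "truth") <- c(occupancy_truth(occ, rate, cfg),
                           list(gap_cols = gcols, pinned_cols = pinned_cols))
    frames[[k]] <- st
  }
  frames
}
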