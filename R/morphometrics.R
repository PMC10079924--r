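#' Build the 8 um analysis grid
#'
#' Bins cells (by centre position, in the absolute height frame
#' `z_abs = z + baseline_offset`, so results are comparable across clipping
#' events) into squares of `bin_width`, accumulating biomass and the
#' biomass-weighted mean specific growth rate per square.
#'
#' @param state a `biofilm_state`.
#' @param cfg a [bf_config()].
#' @param bin bin width, um; defaults to `cfg$bin_width`. Must divide `L_y`.
#' @return An `analysis_grid`: list with matrices `biomass`, `rate`, `occ`
#'   (rows = vertical bins, row 1 being the substratum row of the clipped
#'   frame; columns = lateral bins), `row0` (0-based absolute row index of
#'   matrix row 1), `bin`, `D` columns and `H` rows.
#' @export
build_grid <- function(state, cfg, bin = cfg$bin_width) {
  if (abs(cfg$L_y / bin - round(cfg$L_y / bin)) > 1e-9)
    stop("build_grid: bin width must divide L_y", call. = FALSE)
  D <- as.integer(round(cfg$L_y / bin))
  cells <- state$cells
  row0 <- as.integer(floor(state$baseline_offset / bin + 1e-9))
  if (nrow(cells)) {
    z_abs <- cells$z + state$baseline_offset
    rmax <- as.integer(max(floor(z_abs / bin)))
    H <- rmax - row0 + 1L
    col <- pmin(D, floor((cells$x %% cfg$L_y) / bin) + 1L)
    row <- as.integer(floor(z_abs / bin)) - row0 + 1L
    lin <- (col - 1L) * H + row
    biomass <- matrix(0, H, D)
    ratesum <- matrix(0, H, D)
    msum <- rowsum(cells$biomass, lin)
    wsum <- rowsum(cells$biomass * cells$mu, lin)
    at <- as.integer(rownames(msum))
    biomass[at] <- msum
    ratesum[at] <- wsum
    rate <- matrix(0, H, D)
    occ <- biomass > 0
    rate[occ] <- ratesum[occ] / biomass[occ]
  } else {
    H <- 1L
    biomass <- matrix(0, 1L, D)
    rate <- matrix(0, 1L, D)
    occ <- biomass > 0
  }
  structure(list(biomass = biomass, rate = rate, occ = occ,
                 row0 = row0, bin = bin, D = D, H = H),
            class = "analysis_grid")
}

#' Active-layer mask
#'
#' A square is active when it is occupied and its biomass-weighted mean
#' specific growth rate strictly exceeds the threshold
#' `active_threshold_fraction * mu_max * S_bulk / (k_S + S_bulk)` --
#' a small fraction (default 1/1000) of the maximal rate attainable under
#' the simulation's bulk conditions.
#'
#' @param grid an [build_grid()] `analysis_grid`.
#' @param cfg a [bf_config()].
#' @return Logical matrix of the grid's dimensions.
#' @export
active_mask <- function(grid, cfg) {
  thr <- active_threshold(cfg)
  grid$occ & grid$rate > thr
}

#' @rdname active_mask
#' @export
active_threshold <- function(cfg) {
  cfg$active_threshold_fraction * cfg$mu_max * cfg$S_bulk / (cfg$k_S + cfg$S_bulk)
}

#' Per-column active-layer thickness profile
#'
#' Local thickness in a column is `bin` times the number of active squares
#' in it; the squares need not be contiguous (a growing trough and a growing
#' crest both count). A gap is a column with no active squares. The summary
#' statistics use the population (divide-by-D) convention.
#'
#' @param grid an `analysis_grid`.
#' @param mask the matching [active_mask()].
#' @return An `active_profile`: list with `thickness` (um, length D),
#'   `gap` (logical), `mean`, `sd`, `cv` (NA when the mean is 0) and
#'   `n_gaps`.
#' @export
active_layer_profile <- function(grid, mask) {
  thickness <- grid$bin * colSums(mask)
  m <- mean(thickness)
  s <- sqrt(mean((thickness - m)^2))
  structure(list(thickness = thickness, gap = thickness == 0,
                 mean = m, sd = s, cv = if (m > 0) s / m else NA_real_,
                 n_gaps = sum(thickness == 0)),
            class = "active_profile")
}

#' Extract the multi-valued biofilm interface
#'
#' Interface squares are occupied squares with at least one empty
#' 4-connected neighbour (periodic laterally). The virtual row below the
#' substratum counts as occupied, so substratum contact is not interface;
#' anything above the top row is empty. Because a lateral position can
#' contribute several interface squares at different heights, overhangs are
#' represented faithfully and `N_int >= D` whenever every column is
#' occupied.
#'
#' @param grid an `analysis_grid`.
#' @return An `interface_set`: data frame with `col`, `row` (0-based
#'   absolute row index) and `h` (absolute height of the square centre, um),
#'   with attributes `N_int` and `bin`.
#' @export
extract_interface <- function(grid) {
  occ <- grid$occ
  H <- nrow(occ); D <- ncol(occ)
  up    <- rbind(occ[-1L, , drop = FALSE], matrix(FALSE, 1L, D))
  down  <- rbind(matrix(TRUE, 1L, D), occ[-H, , drop = FALSE])
  left  <- occ[, c(D, seq_len(D - 1L)), drop = FALSE]
  right <- occ[, c(seq_len(D - 1L) + 1L, 1L), drop = FALSE]
  iface <- occ & (!up | !down | !left | !right)
  w <- which(iface, arr.ind = TRUE)
  out <- data.frame(col = unname(w[, 2L]),
                    row = grid$row0 + unname(w[, 1L]) - 1L)
  out$h <- (out$row + 0.5) * grid$bin
  structure(out, N_int = nrow(out), bin = grid$bin, class = c("interface_set", "data.frame"))
}

#' Interface roughness
#'
#' Root-mean-square deviation of the interface square heights about their
#' mean, over the multi-valued interface set (population convention).
#' Invariant under any uniform height shift, hence under clipping-frame
#' changes.
#'
#' @param interface an [extract_interface()] result.
#' @return Roughness W in um.
#' @export
roughness <- function(interface) {
  if (!nrow(interface))
    stop("roughness: empty interface", call. = FALSE)
  h <- interface$h
  sqrt(mean((h - mean(h))^2))
}

#' Pinned interface squares between two configurations
#'
#' A square is pinned when it belongs to the interface both now and `lag`
#' hours earlier (identical absolute position) and is inactive now (its
#' square fails the active-layer threshold). The pinned fraction is
#' `f_P = N_P / N_int(now)`.
#'
#' @param interface_now,interface_prev [extract_interface()] results taken
#'   `lag` hours apart, both in the absolute frame.
#' @param mask_now the [active_mask()] of the current configuration.
#' @param grid_now the current `analysis_grid` (to map absolute rows onto
#'   `mask_now`).
#' @param lag the lag in hours (recorded, not used in the computation).
#' @return A `pinning_record`: list with `pinned` (data frame of pinned
#'   squares), `N_P`, `N_int`, `f_P`, `pinned_cols` (unique columns) and
#'   `lag`.
#' @export
pinned_set <- function(interface_now, interface_prev, mask_now, grid_now,
                       lag) {
  if (!identical(attr(interface_now, "bin"), attr(interface_prev, "bin")))
    stop("pinned_set: interfaces from inconsistent frames", call. = FALSE)
  N_int <- nrow(interface_now)
  key_now <- interface_now$col * 1e9 + interface_now$row
  key_prev <- interface_prev$col * 1e9 + interface_prev$row
  common <- key_now %in% key_prev
  ## activity of the square now (absolute row -> matrix row)
  mrow <- interface_now$row - grid_now$row0 + 1L
  ok <- mrow >= 1L & mrow <= grid_now$H
  act <- rep(FALSE, N_int)
  act[ok] <- mask_now[cbind(mrow[ok], interface_now$col[ok])]
  pin <- common & !act
  pinned <- interface_now[pin, , drop = FALSE]
  structure(list(pinned = pinned, N_P = sum(pin), N_int = N_int,
                 f_P = if (N_int > 0) sum(pin) / N_int else NA_real_,
                 pinned_cols = sort(unique(pinned$col)), lag = lag),
            class = "pinning_record")
}

## Brute-force interface scan (test oracle): per-square loop over the four
## neighbours with the same boundary conventions as extract_interface().
interface_bruteforce <- function(grid) {
  occ <- grid$occ
  H <- nrow(occ); D <- ncol(occ)
  res <- list()
  for (i in seq_len(H)) for (j in seq_len(D)) {
    if (!occ[i, j]) next
    below <- if (i == 1L) TRUE else occ[i - 1L, j]
    above <- if (i == H) FALSE else occ[i + 1L, j]
    lft <- occ[i, if (j == 1L) D else j - 1L]
    rgt <- occ[i, if (j == D) 1L else j + 1L]
    if (!below || !above || !lft || !rgt)
      res[[length(res) + 1L]] <- c(j, grid$row0 + i - 1L)
  }
  m <- do.call(rbind, res)
  out <- if (is.null(m)) data.frame(col = integer(), row = integer())
         else data.frame(col = m[, 1L], row = m[, 2L])
  out$h <- (out$row + 0.5) * grid$bin
  structure(out, N_int = nrow(out), bin = grid$bin,
            class = c("interface_set", "data.frame"))
}
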