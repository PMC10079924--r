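#' Rasterise a biofilm state onto the nutrient lattice
#'
#' Deposits each cell's biomass into the voxel containing its centre and
#' labels every voxel as `biofilm` (contains biomass), `boundary` (within a
#' Euclidean distance `h_bl` of a biofilm voxel: the stationary fluid layer
#' through which nutrient diffuses), or `bulk` (everything beyond, held at
#' `S_bulk`). Diffusivity is `D_S` outside the biofilm and
#' `biofilm_diffusivity_factor * D_S` inside.
#'
#' The lattice lives in the clipped frame: row 1 sits on the (possibly
#' clipped) substratum, where a zero-flux condition applies; the lateral
#' direction is periodic. The lattice extends `h_bl` plus a two-voxel margin
#' above the highest biomass, so the top rows are always bulk.
#'
#' @param state a `biofilm_state`.
#' @param cfg a [bf_config()].
#' @param spacing voxel edge, um; defaults to `cfg$grid_spacing_pde`.
#' @return A `nutrient_grid`: list with `spacing`, matrices `S`, `rho`
#'   (g/L), `Dloc` (um^2/h) and `region` (H rows x D columns, row 1 at the
#'   substratum), and scalars `S_bulk`, `H`, `D`.
#' @export
rasterize <- function(state, cfg, spacing = cfg$grid_spacing_pde) {
  if (abs(cfg$L_y / spacing - round(cfg$L_y / spacing)) > 1e-9)
    stop("rasterize: spacing must divide L_y", call. = FALSE)
  D <- as.integer(round(cfg$L_y / spacing))
  cells <- state$cells
  if (nrow(cells)) {
    if (any(cells$x < 0 | cells$x >= cfg$L_y) || any(cells$z < 0))
      stop("rasterize: cell outside domain", call. = FALSE)
    ztop <- max(cells$z)
  } else ztop <- 0
  H <- as.integer(ceiling((ztop + cfg$h_bl) / spacing)) + 2L
  rho <- matrix(0, H, D)
  if (nrow(cells)) {
    col <- pmin(D, floor(cells$x / spacing) + 1L)
    row <- pmin(H, floor(cells$z / spacing) + 1L)
    vox <- (col - 1L) * H + row
    mass <- rowsum(cells$biomass, vox)
    rho[as.integer(rownames(mass))] <- mass / (spacing^2 * cfg$d_cell * 1e-15)
  }
  biofilm <- rho > 0
  region <- matrix("bulk", H, D)
  if (any(biofilm)) {
    region[dilate_mask(biofilm, cfg$h_bl / spacing)] <- "boundary"
    region[biofilm] <- "biofilm"
  }
  Dloc <- matrix(cfg$D_S_um2h, H, D)
  Dloc[biofilm] <- cfg$biofilm_diffusivity_factor * cfg$D_S_um2h
  S <- matrix(cfg$S_bulk, H, D)
  structure(list(spacing = spacing, S = S, rho = rho, Dloc = Dloc,
                 region = region, S_bulk = cfg$S_bulk, H = H, D = D),
            class = "nutrient_grid")
}

## Binary dilation of a logical H x D mask by a disc of the given radius
## (in voxel units), periodic in columns, clipped in rows.
dilate_mask <- function(mask, radius_vox) {
  H <- nrow(mask); D <- ncol(mask)
  r <- floor(radius_vox)
  out <- mask
  for (di in -r:r) {
    dj_max <- floor(sqrt(radius_vox^2 - di^2))
    rows_src <- seq_len(H)
    rows_dst <- rows_src + di
    ok <- rows_dst >= 1L & rows_dst <= H
    if (!any(ok)) next
    band <- matrix(FALSE, H, D)
    band[rows_dst[ok], ] <- mask[rows_src[ok], , drop = FALSE]
    if (dj_max > 0) {
      acc <- band
      for (dj in seq_len(min(dj_max, D - 1L))) {
        idx_l <- ((seq_len(D) - 1L - dj) %% D) + 1L
        idx_r <- ((seq_len(D) - 1L + dj) %% D) + 1L
        acc <- acc | band[, idx_l, drop = FALSE] | band[, idx_r, drop = FALSE]
      }
      band <- acc
    }
    out <- out | band
  }
  out
}

#' Solve the nutrient field to steady state
#'
#' Solves the nonlinear steady-state reaction-diffusion equation
#' `div(D grad S) = mu_max S / (k_S + S) * rho / Y` over the biofilm and
#' boundary-layer voxels with Dirichlet `S = S_bulk` on faces adjacent to
#' bulk voxels, zero flux at the substratum and lateral periodicity. The
#' Monod nonlinearity is handled by damped Picard iteration: the saturation
#' factor is frozen at the current iterate, the resulting linear system is an
#' M-matrix (solved sparsely), and the update is relaxed by
#' `picard_relax`. Convergence requires the nonlinear residual, scaled to
#' concentration units by `spacing^2 / D_S`, to fall below
#' `tol_pde_frac * S_bulk` in max norm. The converged field is non-negative
#' without any clamping.
#'
#' @param grid a `nutrient_grid` from [rasterize()].
#' @param cfg a [bf_config()].
#' @param warm optional previous `nutrient_grid` used as the initial iterate
#'   (must have identical dimensions to be used).
#' @return The grid with `S` replaced by the steady-state field; attribute
#'   `"iterations"` records the Picard count.
#' @export
solve_steady_state <- function(grid, cfg, warm = NULL) {
  solve_mask <- grid$region != "bulk"
  if (!any(solve_mask)) {
    grid$S[] <- grid$S_bulk
    return(structure(grid, iterations = 0L))
  }
  H <- grid$H; D <- grid$D; a <- grid$spacing
  idx <- matrix(0L, H, D)
  M <- sum(solve_mask)
  idx[solve_mask] <- seq_len(M)
  vi <- which(solve_mask)                 # linear indices, column-major
  ri <- (vi - 1L) %% H + 1L
  ci <- (vi - 1L) %/% H + 1L
  Dv <- grid$Dloc[vi]
  rho_v <- grid$rho[vi]

  ## assemble face lists for the 4-neighbour stencil
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  diag_acc <- numeric(M)
  b <- numeric(M)
  neighbour <- function(dr, dc) {
    r2 <- ri + dr
    c2 <- (ci - 1L + dc) %% D + 1L
    inside <- r2 >= 1L & r2 <= H
    list(r2 = r2, c2 = c2, inside = inside)
  }
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- neighbour(d[1L], d[2L])
    inside <- nb$inside
    ## faces below row 1 are the substratum: zero flux, skip entirely;
    ## faces above row H cannot occur (top rows are bulk)
    if (!any(inside)) next
    vj <- (nb$c2[inside] - 1L) * H + nb$r2[inside]
    Df <- 2 * Dv[inside] * grid$Dloc[vj] / (Dv[inside] + grid$Dloc[vj]) / a^2
    jsolved <- idx[vj]
    is_bulk <- jsolved == 0L
    ii <- which(inside)
    ## solved-solved faces: off-diagonal entries
    if (any(!is_bulk)) {
      trip_i <- c(trip_i, ii[!is_bulk])
      trip_j <- c(trip_j, jsolved[!is_bulk])
      trip_x <- c(trip_x, Df[!is_bulk])
    }
    ## Dirichlet faces: diagonal + RHS
    if (any(is_bulk)) b[ii[is_bulk]] <- b[ii[is_bulk]] + Df[is_bulk] * grid$S_bulk
    diag_acc[ii] <- diag_acc[ii] + Df
  }
  Lmat <- Matrix::sparseMatrix(i = c(trip_i, seq_len(M)),
                               j = c(trip_j, seq_len(M)),
                               x = c(trip_x, -diag_acc),
                               dims = c(M, M))
  ## -L as a symmetric matrix built once (lower triangle), with the
  ## positions of its diagonal entries cached so the Picard loop can update
  ## the reaction term in place instead of re-allocating sparse matrices
  low <- trip_i >= trip_j
  Lneg <- Matrix::sparseMatrix(i = c(trip_i[low], seq_len(M)),
                               j = c(trip_j[low], seq_len(M)),
                               x = c(-trip_x[low], diag_acc),
                               dims = c(M, M), symmetric = TRUE)
  entry_col <- rep(seq_len(M), diff(Lneg@p))
  dpos <- which(Lneg@i + 1L == entry_col)
  stopifnot(length(dpos) == M)
  base_diag <- Lneg@x[dpos]
  ## warm start: previous field mapped by overlapping bottom rows (an
  ## initial guess only; a stale guess just costs extra Picard iterations)
  S_old <- rep(grid$S_bulk, M)
  if (!is.null(warm) && warm$D == D) {
    Hc <- min(warm$H, H)
    S_init <- matrix(grid$S_bulk, H, D)
    S_init[seq_len(Hc), ] <- warm$S[seq_len(Hc), ]
    S_old <- pmin(pmax(S_init[vi], 0), grid$S_bulk)
  }
  kcoef <- cfg$mu_max * rho_v / cfg$Y     # g/(L h) at full saturation
  tol <- cfg$tol_pde_frac * grid$S_bulk
  scale <- a^2 / cfg$D_S_um2h            # residual -> concentration units
  converged <- FALSE
  it <- 0L
  chol_cache <- NULL
  relax <- cfg$picard_relax
  prev_resid <- Inf
  P <- Lneg
  repeat {
    g <- kcoef / (cfg$k_S + S_old)
    P@x[dpos] <- base_diag + g            # symmetric positive definite
    ## reuse the symbolic Cholesky analysis across Picard iterations
    if (is.null(chol_cache)) {
      chol_cache <- Matrix::Cholesky(P, LDL = FALSE, super = TRUE)
    } else {
      chol_cache <- Matrix::update(chol_cache, P)
    }
    S_new <- as.numeric(Matrix::solve(chol_cache, b, system = "A"))
    S_relax <- relax * S_new + (1 - relax) * S_old
    resid_v <- as.numeric(Lmat %*% S_relax) + b -
      kcoef * S_relax / (cfg$k_S + S_relax)
    resid <- max(abs(resid_v))
    it <- it + 1L
    S_old <- S_relax
    if (resid * scale < tol) { converged <- TRUE; break }
    if (it >= cfg$max_outer) break
    ## once the damped iteration is contracting steadily, drop the damping
    ## (the undamped Monod-Picard map is itself a contraction; damping is
    ## only needed while the iterate is far from the fixed point)
    if (it >= 3L && resid < 0.8 * prev_resid) relax <- 1
    prev_resid <- resid
  }
  if (!converged)
    stop(sprintf("solve_steady_state: no convergence after %d iterations (residual %.3g)",
                 it, resid * scale), call. = FALSE)
  grid$S[] <- grid$S_bulk
  grid$S[vi] <- S_old
  structure(grid, iterations = it)
}

#' Sample the nutrient field at a point
#'
#' Returns the concentration of the voxel containing `(x, z)` (clipped
#' frame); positions above the lattice return `S_bulk`.
#'
#' @param grid a solved `nutrient_grid`.
#' @param x,z coordinates in um (vectorised).
#' @return concentration(s), g/L.
#' @export
sample_concentration <- function(grid, x, z) {
  if (any(z < 0)) stop("sample_concentration: position below substratum",
                       call. = FALSE)
  a <- grid$spacing
  col <- floor((x %% (grid$D * a)) / a) + 1L
  row <- floor(z / a) + 1L
  out <- rep(grid$S_bulk, length(x))
  ok <- row <= grid$H
  out[ok] <- grid$S[(col[ok] - 1L) * grid$H + row[ok]]
  out
}

## Steady-state flux balance diagnostics (used by tests): net diffusive
## influx through Dirichlet faces and total consumption, both in g/h.
flux_balance <- function(grid, cfg) {
  solve_mask <- grid$region != "bulk"
  H <- grid$H; D <- grid$D; a <- grid$spacing
  vol_L <- a^2 * cfg$d_cell * 1e-15
  vi <- which(solve_mask)
  ri <- (vi - 1L) %% H + 1L
  ci <- (vi - 1L) %/% H + 1L
  influx <- 0
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r2 <- ri + d[1L]
    c2 <- (ci - 1L + d[2L]) %% D + 1L
    inside <- r2 >= 1L & r2 <= H
    vj <- (c2[inside] - 1L) * H + r2[inside]
    is_bulk <- !solve_mask[vj]
    src <- vi[inside][is_bulk]
    dst <- vj[is_bulk]
    Df <- 2 * grid$Dloc[src] * grid$Dloc[dst] / (grid$Dloc[src] + grid$Dloc[dst])
    influx <- influx + sum(Df * (grid$S_bulk - grid$S[src]) / a^2)
  }
  consumption <- sum(cfg$mu_max * grid$S[vi] / (cfg$k_S + grid$S[vi]) *
                     grid$rho[vi] / cfg$Y)
  c(influx = influx * vol_L, consumption = consumption * vol_L)
}
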