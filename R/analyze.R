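#' Compute morphometrics for a snapshot sequence
#'
#' Runs the full spatial-structure pipeline on each snapshot: analysis grid,
#' active mask, per-column active-layer profile, multi-valued interface,
#' roughness, and (once `pin_lag` of history is available) the pinned
#' interface fraction against the snapshot `pin_lag` hours earlier.
#'
#' @param snapshots list of `biofilm_state`, `snapshot_interval` hours
#'   apart.
#' @param cfg a [bf_config()].
#' @return A metrics data frame with one row per snapshot: `time`, `cells`
#'   (cumulative), `alive`, `N_int`, `W`, `f_P` (NA before the lag is
#'   available), `mean_thickness`, `sd_thickness`, `cv_thickness`,
#'   `gaps`. Attributes: `"pinned_cols"` (list of pinned column sets),
#'   `"profiles"` (list of [active_layer_profile()]s, for kymographs).
#' @export
analyze_snapshots <- function(snapshots, cfg) {
  n <- length(snapshots)
  lag_steps <- as.integer(round(cfg$pin_lag / cfg$snapshot_interval))
  rows <- vector("list", n)
  ifaces <- vector("list", n)
  profiles <- vector("list", n)
  pinned_cols <- vector("list", n)
  for (i in seq_len(n)) {
    st <- snapshots[[i]]
    grid <- build_grid(st, cfg)
    mask <- active_mask(grid, cfg)
    prof <- active_layer_profile(grid, mask)
    iface <- extract_interface(grid)
    ifaces[[i]] <- iface
    profiles[[i]] <- prof
    W <- if (nrow(iface)) roughness(iface) else NA_real_
    f_P <- NA_real_
    if (i > lag_steps) {
      pr <- pinned_set(iface, ifaces[[i - lag_steps]], mask, grid,
                       lag = cfg$pin_lag)
      f_P <- pr$f_P
      pinned_cols[[i]] <- pr$pinned_cols
    }
    rows[[i]] <- data.frame(
      time = st$time, cells = total_cells(st), alive = nrow(st$cells),
      N_int = nrow(iface), W = W, f_P = f_P,
      mean_thickness = prof$mean, sd_thickness = prof$sd,
      cv_thickness = prof$cv, gaps = prof$n_gaps)
  }
  out <- do.call(rbind, rows)
  attr(out, "pinned_cols") <- pinned_cols
  attr(out, "profiles") <- profiles
  out
}

#' Write a metrics table as CSV
#'
#' Fixed, documented header: `time,cells,alive,N_int,W,f_P,mean_thickness,`
#' `sd_thickness,cv_thickness,gaps`.
#'
#' @param metrics a metrics data frame from [analyze_snapshots()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
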