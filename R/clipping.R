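#' Clip inactive deep biomass
#'
#' Removes cells that sit below the lowest actively growing cell *and* below
#' the minimum point of the multi-valued interface (these can be different
#' places), minus a safety margin. The clip line is additionally kept below
#' the lowest empty analysis square, and snapped down to a `bin_width`
#' multiple, which makes every morphometric computed in the absolute frame
#' exactly invariant under clipping. The removed slab height is added to
#' `baseline_offset` so absolute heights of the retained cells are
#' unchanged; the substratum zero-flux boundary subsequently applies at the
#' new domain bottom.
#'
#' @param state a `biofilm_state` with at least one cell.
#' @param cfg a [bf_config()]; uses `clip_margin` and the active-layer
#'   threshold.
#' @return A list with `state` (clipped) and `removed_count`.
#' @export
clip <- function(state, cfg) {
  if (!nrow(state$cells))
    stop("clip: no cells, interface not extractable", call. = FALSE)
  thr <- active_threshold(cfg)
  z_abs <- state$cells$z + state$baseline_offset
  active <- state$cells$mu > thr
  grid <- build_grid(state, cfg)
  iface <- extract_interface(grid)
  z_A <- if (any(active)) min(z_abs[active]) else Inf
  z_I <- min(iface$h) - grid$bin / 2   # lower edge of lowest interface square
  ## guard: never clip above the lowest empty square (buried voids)
  empty_rows <- which(!grid$occ, arr.ind = TRUE)
  z_E <- if (nrow(empty_rows)) (grid$row0 + min(empty_rows[, 1L]) - 1L) * grid$bin else Inf
  line <- min(z_A, z_I, z_E) - cfg$clip_margin
  line <- floor(line / cfg$bin_width) * cfg$bin_width
  if (!is.finite(line) || line <= state$baseline_offset)
    return(list(state = state, removed_count = 0L))
  drop <- z_abs < line
  if (!any(drop))          # nothing to remove: leave the frame untouched
    return(list(state = state, removed_count = 0L))
  if (any(drop & active))
    stop("clip: internal error, clip line above an active cell", call. = FALSE)
  ## keep the new substratum below every retained cell body so the frame
  ## shift cannot push anyone into the floor
  line <- min(line,
              floor(min(z_abs[!drop] - state$cells$radius[!drop]) /
                    cfg$bin_width) * cfg$bin_width)
  if (line <= state$baseline_offset)
    return(list(state = state, removed_count = 0L))
  drop <- z_abs < line
  removed <- sum(drop)
  if (removed) {
    state$cells <- state$cells[!drop, , drop = FALSE]
    rownames(state$cells) <- NULL
    state$removed <- state$removed + removed
  }
  state$cells$z <- state$cells$z - (line - state$baseline_offset)
  state$baseline_offset <- line
  list(state = state, removed_count = as.integer(removed))
}
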