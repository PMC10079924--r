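#' Dimensionless transport-growth control parameter
#'
#' Computes the inverse-square-root combined parameter describing the
#' balance between nutrient transport into the biofilm and microbial
#' growth,
#' `sqrt(D_B * Y * (k_S + S_bulk) / (L_y^2 * rho_B * mu_max))` with
#' `D_B = biofilm_diffusivity_factor * D_S` (the `G1` variant); the `G2`
#' variant replaces `(k_S + S_bulk)` by `S_bulk`. The value is unit-free:
#' `D_B / (L_y^2 mu_max)` and the concentration ratio each cancel
#' dimensions.
#'
#' @param cfg a [bf_config()].
#' @param which `"G1"` or `"G2"`.
#' @return The dimensionless value (of the inverse-square-root form).
#' @export
#' @examples
#' control_parameter(bf_config())  # ~0.0243 for the default parameter set
control_parameter <- function(cfg, which = c("G1", "G2")) {
  which <- match.arg(which)
  D_B <- cfg$biofilm_diffusivity_factor * cfg$D_S_um2h   # um^2/h
  conc <- if (which == "G1") cfg$k_S + cfg$S_bulk else cfg$S_bulk
  sqrt(D_B * cfg$Y * conc / (cfg$L_y^2 * cfg$rho_B * cfg$mu_max))
}

#' Active-layer kymograph
#'
#' Stacks per-column active-layer thickness profiles into a matrix indexed
#' by biofilm size (cell count) and lateral bin. Zero entries mark
#' active-layer gaps; their drift and mergers trace the creation and
#' annihilation of pinning sites.
#'
#' @param profiles list of [active_layer_profile()] results, time-ordered.
#' @param index numeric vector of cell counts (one per profile), used as row
#'   names (the biofilm-size axis).
#' @param pinned optional list of `pinning_record`s aligned with
#'   `profiles`; pinned columns are returned in attribute `"pinned"` as a
#'   two-column (frame, col) matrix for overlay.
#' @return Matrix `length(profiles) x D` of thicknesses (um).
#' @export
kymograph <- function(profiles, index = seq_along(profiles), pinned = NULL) {
  Ds <- vapply(profiles, function(p) length(p$thickness), 0L)
  if (length(unique(Ds)) > 1L)
    stop("kymograph: profiles have inconsistent column counts", call. = FALSE)
  m <- do.call(rbind, lapply(profiles, `[[`, "thickness"))
  rownames(m) <- as.character(index)
  if (!is.null(pinned)) {
    ov <- do.call(rbind, lapply(seq_along(pinned), function(i) {
      pc <- pinned[[i]]$pinned_cols
      if (length(pc)) cbind(frame = i, col = pc) else NULL
    }))
    attr(m, "pinned") <- ov
  }
  m
}

#' Detect the steady-state window of a time series
#'
#' Returns the earliest index after which the rolling mean (window
#' `window` points) of the remainder of the series drifts by less than
#' 1.5 rolling standard deviations (the mean of the rolling SDs over the
#' same stretch); `NA` if no such index exists (e.g. perpetual drift).
#' The 1.5 factor calibrates the rule so that a white-noise series is
#' accepted near its start: the range of overlapping rolling means of an
#' iid stretch is itself close to one rolling SD, so an uncalibrated
#' comparison rejects even stationary noise.
#'
#' @param series numeric vector, length >= 20.
#' @param window rolling window, points.
#' @param min_tail minimum number of points that must remain after the
#'   detected start.
#' @return Integer start index, or `NA_integer_` if a steady state is not
#'   reached.
#' @export
steady_state_window <- function(series, window = 10L, min_tail = 2L * window) {
  n <- length(series)
  if (n < 20L) stop("steady_state_window: series too short (need >= 20 points)",
                    call. = FALSE)
  for (s in seq_len(n - min_tail + 1L)) {
    tail_s <- series[s:n]
    k <- length(tail_s) - window + 1L
    idx <- seq_len(k)
    csum <- cumsum(c(0, tail_s))
    csum2 <- cumsum(c(0, tail_s^2))
    rm_ <- (csum[idx + window] - csum[idx]) / window
    rv <- (csum2[idx + window] - csum2[idx]) / window - rm_^2
    rsd <- sqrt(pmax(rv, 0))
    if ((max(rm_) - min(rm_)) < 1.5 * mean(rsd)) return(s)
  }
  NA_integer_
}

#' Integrated autocorrelation time
#'
#' Windowed (Sokal-style) estimator: `tau = 1 + 2 * sum(rho_t, t <= M)`
#' with the smallest cutoff `M >= c * tau(M)`. Returns at least 1 sampling
#' interval.
#'
#' @param series numeric vector from a stationary window, length >= 50.
#' @param c window factor (default 5).
#' @return tau in sampling intervals; attribute `"cutoff"` records M.
#' @export
autocorrelation_time <- function(series, c = 5) {
  n <- length(series)
  if (n < 50L)
    stop("autocorrelation_time: series too short for a reliable estimate",
         call. = FALSE)
  if (stats::var(series) == 0)
    stop("autocorrelation_time: zero-variance series, autocorrelation undefined",
         call. = FALSE)
  lag_max <- min(n - 1L, max(50L, floor(n / 2)))
  rho <- as.numeric(stats::acf(series, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  csum <- 1 + 2 * cumsum(rho)
  M <- which(seq_along(csum) >= c * csum)
  M <- if (length(M)) M[1L] else lag_max
  structure(max(1, csum[M]), cutoff = M)
}

#' Standard error of the mean for correlated data
#'
#' `sigma` is the SD of the points, the effective sample size is
#' `n_eff = n / tau`, and `SEM = sigma / sqrt(n_eff)`. A zero-variance
#' series yields SEM = 0 directly.
#'
#' @param series numeric vector (a steady-state window).
#' @param tau optional externally supplied autocorrelation time; by default
#'   estimated with [autocorrelation_time()] (1 for short series).
#' @return List with `sigma`, `tau`, `n_eff`, `sem`.
#' @export
sem_correlated <- function(series, tau = NULL) {
  n <- length(series)
  sigma <- stats::sd(series)
  if (!is.finite(sigma) || sigma == 0)
    return(list(sigma = 0, tau = 1, n_eff = n, sem = 0))
  if (is.null(tau))
    tau <- if (n >= 50L) as.numeric(autocorrelation_time(series)) else 1
  tau <- min(max(tau, 1), n)
  n_eff <- n / tau
  list(sigma = sigma, tau = tau, n_eff = n_eff, sem = sigma / sqrt(n_eff))
}

## Theil-Sen slope with a percentile bootstrap CI.
theil_sen <- function(y, x = seq_along(y), B = 200L, conf = 0.95) {
  slope_of <- function(y, x) {
    cmb <- utils::combn(length(x), 2L)
    stats::median((y[cmb[2L, ]] - y[cmb[1L, ]]) / (x[cmb[2L, ]] - x[cmb[1L, ]]),
                  na.rm = TRUE)
  }
  n <- length(y)
  est <- slope_of(y, x)
  bs <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    while (length(unique(x[i])) < 2L) i <- sample.int(n, n, replace = TRUE)
    slope_of(y[i], x[i])
  }, 0)
  ci <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(slope = est, ci = ci)
}

#' Summarise a simulation trajectory
#'
#' Computes, from a metrics table (one row per snapshot, see
#' [analyze_snapshots()]), the steady-state window of the roughness series,
#' autocorrelation-corrected steady-state statistics for roughness, pinned
#' fraction and the active-layer thickness statistics, and the phase label.
#'
#' @param metrics a metrics data frame with columns `time`, `cells`, `W`,
#'   `f_P`, `mean_thickness`, `sd_thickness`, `cv_thickness`, and attribute
#'   `"pinned_cols"` (list of pinned column sets per snapshot) when
#'   available.
#' @param cfg the [bf_config()] used for the run.
#' @return A `trajectory_summary`: list with the steady-state start index,
#'   per-series statistics (`stats`, each a [sem_correlated()] list plus the
#'   steady-state mean), the phase label and the input metrics.
#' @export
summarize_trajectory <- function(metrics, cfg) {
  W <- metrics$W
  ss <- tryCatch(steady_state_window(W), error = function(e) NA_integer_)
  series_names <- c("W", "f_P", "mean_thickness", "sd_thickness", "cv_thickness")
  stats_out <- list()
  if (!is.na(ss)) {
    for (s in series_names) {
      v <- metrics[[s]][ss:nrow(metrics)]
      v <- v[!is.na(v)]
      st <- sem_correlated(v)
      st$mean <- mean(v)
      stats_out[[s]] <- st
    }
  }
  out <- structure(list(steady_start = ss, stats = stats_out,
                        metrics = metrics, config = cfg),
                   class = "trajectory_summary")
  out$phase <- classify_phase(out)
  out
}

#' Classify the pinning phase of a trajectory
#'
#' Implements the three-phase taxonomy of biofilm interface dynamics:
#' `unpinned` (roughness steady state, pinned fraction identically zero
#' there), `pinned` (a pinned column persists from its formation to the end
#' of the run and roughness rises robustly over the final half: Theil-Sen
#' slope > 0 with a bootstrap 95% CI excluding zero), `transiently_pinned`
#' (pinning occurs but every episode terminates and roughness reaches a
#' steady state), and `transitional` for everything else.
#'
#' @param summary a [summarize_trajectory()] result (phase field ignored).
#' @return Character phase label.
#' @export
classify_phase <- function(summary) {
  metrics <- summary$metrics
  n <- nrow(metrics)
  ss <- summary$steady_start
  fp <- metrics$f_P
  half <- seq.int(floor(n / 2) + 1L, n)
  W_half <- metrics$W[half]
  rising <- FALSE
  if (length(half) >= 5L && stats::var(W_half) > 0) {
    ts <- theil_sen(W_half)
    rising <- ts$slope > 0 && ts$ci[1L] > 0
  }
  pc <- attr(metrics, "pinned_cols")
  persistent <- FALSE
  if (!is.null(pc) && length(pc)) {
    avail <- which(!vapply(pc, is.null, TRUE))
    if (length(avail) >= 3L) {
      last <- pc[[max(avail)]]
      for (col in last) {
        present <- vapply(avail, function(i) col %in% pc[[i]], TRUE)
        started <- which(present)[1L]
        ## pinned continuously from formation to the end, formed at least
        ## 3 snapshots before the end
        if (!is.na(started) && all(present[started:length(avail)]) &&
            (length(avail) - started) >= 2L) {
          persistent <- TRUE
          break
        }
      }
    }
  }
  if (persistent && rising) return("pinned")
  if (!is.na(ss)) {
    fp_ss <- fp[ss:n]
    fp_ss <- fp_ss[!is.na(fp_ss)]
    if (length(fp_ss) && all(fp_ss == 0)) return("unpinned")
    if (any(fp > 0, na.rm = TRUE) && !persistent) return("transiently_pinned")
  }
  "transitional"
}

#' Assemble a phase diagram table
#'
#' One row per simulation: the chosen steady-state active-layer statistic
#' (control parameter) and the steady-state mean pinned interface fraction
#' (order parameter), both with correlated-data SEMs, plus the phase label.
#' Runs without a steady state, and transitional runs, are excluded; the
#' excluded run indices and reasons are kept in attribute `"excluded"`.
#'
#' @param summaries list of [summarize_trajectory()] results.
#' @param control `"cv"`, `"mean"` or `"sd"` of the active-layer thickness.
#' @return Data frame with columns `run`, `control`, `control_sem`, `f_P`,
#'   `f_P_sem`, `phase`.
#' @export
phase_diagram <- function(summaries, control = c("cv", "mean", "sd")) {
  control <- match.arg(control)
  key <- paste0(control, "_thickness")
  rows <- list(); excl <- list()
  for (i in seq_along(summaries)) {
    s <- summaries[[i]]
    if (is.na(s$steady_start)) {
      excl[[length(excl) + 1L]] <- data.frame(run = i, reason = "no steady state")
      next
    }
    if (s$phase == "transitional") {
      excl[[length(excl) + 1L]] <- data.frame(run = i, reason = "transitional")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      run = i,
      control = s$stats[[key]]$mean, control_sem = s$stats[[key]]$sem,
      f_P = s$stats$f_P$mean, f_P_sem = s$stats$f_P$sem,
      phase = s$phase)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = integer(), control = numeric(), control_sem = numeric(),
               f_P = numeric(), f_P_sem = numeric(), phase = character())
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}
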