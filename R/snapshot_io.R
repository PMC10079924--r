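## Snapshot persistence: a self-describing plain-text archive.
##
## Layout: header lines "#& key value" (time, baseline_offset, removed,
## next_id, config fingerprint, RNG state as comma-separated integers),
## followed by a CSV table of per-cell records. Numeric fields are written
## with 17 significant digits so write -> read round-trips bit-exactly.

#' Write / read a biofilm snapshot
#'
#' @param state a `biofilm_state`.
#' @param path file path.
#' @param cfg optional [bf_config()]; when given, its fingerprint is stored
#'   and checked on read (mismatches warn).
#' @return `write_snapshot`: `path` invisibly. `read_snapshot`: the
#'   restored `biofilm_state` (including the RNG state in attribute
#'   `"rng_state"`, which [restore_rng()] can reinstall).
#' @export
write_snapshot <- function(state, path, cfg = NULL) {
  stopifnot(inherits(state, "biofilm_state"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("#& format biofilmpin-snapshot-1"),
    sprintf("#& time %.17g", state$time),
    sprintf("#& baseline_offset %.17g", state$baseline_offset),
    sprintf("#& removed %d", state$removed),
    sprintf("#& next_id %d", state$next_id),
    sprintf("#& n_cells %d", nrow(state$cells)))
  if (!is.null(cfg))
    hdr <- c(hdr, sprintf("#& config %s", config_fingerprint(cfg)))
  if (exists(".Random.seed", envir = globalenv()))
    hdr <- c(hdr, paste("#& rng", paste(get(".Random.seed", envir = globalenv()),
                                        collapse = ",")))
  writeLines(hdr, con)
  writeLines("id,x,z,radius,biomass,mu,division_radius", con)
  if (nrow(state$cells)) {
    c_ <- state$cells
    writeLines(sprintf("%d,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g",
                       c_$id, c_$x, c_$z, c_$radius, c_$biomass, c_$mu,
                       c_$division_radius), con)
  }
  invisible(path)
}

#' @rdname write_snapshot
#' @param path file path of a stored snapshot.
#' @export
read_snapshot <- function(path, cfg = NULL) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#& ")
  hdr <- strsplit(sub("^#& ", "", lines[is_hdr]), " ", fixed = TRUE)
  keys <- vapply(hdr, `[`, "", 1L)
  vals <- vapply(hdr, function(p) paste(p[-1L], collapse = " "), "")
  names(vals) <- keys
  if (!identical(unname(vals["format"]), "biofilmpin-snapshot-1"))
    stop("read_snapshot: not a biofilmpin snapshot: ", path, call. = FALSE)
  body <- lines[!is_hdr]
  if (!length(body) || body[1L] != "id,x,z,radius,biomass,mu,division_radius")
    stop("read_snapshot: corrupt snapshot (missing cell table header) at line ",
         sum(is_hdr) + 1L, call. = FALSE)
  n <- as.integer(vals["n_cells"])
  recs <- body[-1L]
  if (length(recs) != n)
    stop(sprintf("read_snapshot: truncated snapshot: expected %d cell records, found %d (at record %d)",
                 n, length(recs), length(recs) + 1L), call. = FALSE)
  if (n > 0L) {
    parts <- strsplit(recs, ",", fixed = TRUE)
    if (any(vapply(parts, length, 0L) != 7L))
      stop("read_snapshot: malformed cell record at record ",
           which(vapply(parts, length, 0L) != 7L)[1L], call. = FALSE)
    m <- matrix(as.numeric(unlist(parts)), ncol = 7L, byrow = TRUE)
    cells <- data.frame(id = as.integer(m[, 1L]), x = m[, 2L], z = m[, 3L],
                        radius = m[, 4L], biomass = m[, 5L], mu = m[, 6L],
                        division_radius = m[, 7L])
  } else {
    cells <- data.frame(id = integer(), x = numeric(), z = numeric(),
                        radius = numeric(), biomass = numeric(),
                        mu = numeric(), division_radius = numeric())
  }
  st <- new_biofilm_state(cells,
                          time = as.numeric(vals["time"]),
                          baseline_offset = as.numeric(vals["baseline_offset"]),
                          removed = as.integer(vals["removed"]),
                          next_id = as.integer(vals["next_id"]))
  if (!is.null(cfg) && "config" %in% names(vals) &&
      !identical(unname(vals["config"]), config_fingerprint(cfg)))
    warning("read_snapshot: config fingerprint mismatch", call. = FALSE)
  if ("rng" %in% names(vals))
    attr(st, "rng_state") <- as.integer(strsplit(vals[["rng"]], ",")[[1L]])
  st
}

#' Reinstall the RNG state stored in a snapshot
#' @param state a `biofilm_state` from [read_snapshot()].
#' @return `TRUE` invisibly if a state was restored.
#' @export
restore_rng <- function(state) {
  rs <- attr(state, "rng_state")
  if (is.null(rs)) return(invisible(FALSE))
  assign(".Random.seed", rs, envir = globalenv())
  invisible(TRUE)
}
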