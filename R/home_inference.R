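#' Infer the home location from a trace
#'
#' Home is established mathematically as the statistical mode of the
#' recorded coordinates: the location where the most fixes (hence, at a
#' near-constant sampling rate, the most time) were recorded. A mode of
#' continuous coordinates is undefined without discretization, so fixes are
#' binned on a fixed latitude/longitude grid; the default pitch of 1e-4
#' degrees (~11 m) matches the ~10 m outdoor GPS accuracy of smartphone
#' receivers. The returned home coordinate is the arithmetic mean of the
#' fixes inside the modal cell. Ties between cells are broken by the
#' lexicographically smallest `(cell_lat, cell_lon)` index pair, a fixed
#' convention so results are order-invariant.
#'
#' @param trace An [ls_trace()]; must be non-empty.
#' @param cell_size_deg Grid pitch in degrees (> 0).
#' @return A list of class `home_estimate`: `home` ([geo_point()]),
#'   `modal_cell` (integer pair), `cell_size_deg`, `support` (fixes in the
#'   modal cell), `support_fraction`.
#' @export
infer_home <- function(trace, cell_size_deg = 1e-4) {
  stopifnot(cell_size_deg > 0)
  n <- nrow(trace)
  if (n == 0L) {
    rlang::abort("Cannot infer home from an empty trace.")
  }
  ci <- floor(trace$lat / cell_size_deg)
  cj <- floor(trace$lon / cell_size_deg)
  # one count per occupied cell; modal cell, ties to smallest (ci, cj)
  key <- paste(ci, cj)
  counts <- table(key)
  top <- counts[counts == max(counts)]
  idx <- do.call(rbind, lapply(strsplit(names(top), " ", fixed = TRUE),
                               as.numeric))
  ord <- order(idx[, 1L], idx[, 2L])
  modal <- idx[ord[1L], ]
  in_cell <- ci == modal[1L] & cj == modal[2L]
  support <- sum(in_cell)
  structure(list(
    home = geo_point(mean(trace$lat[in_cell]), mean(trace$lon[in_cell])),
    modal_cell = c(cell_lat = modal[1L], cell_lon = modal[2L]),
    cell_size_deg = cell_size_deg,
    support = support,
    support_fraction = support / n
  ), class = "home_estimate")
}

#' @export
print.home_estimate <- function(x, ...) {
  cat(sprintf(
    "<home_estimate> lat %.6f, lon %.6f (cell %.0g deg, support %d = %.1f%% of fixes)\n",
    x$home[["lat"]], x$home[["lon"]], x$cell_size_deg,
    x$support, 100 * x$support_fraction))
  invisible(x)
}

#' Per-fix at-home indicator
#'
#' Being at home is operationalized as being within `radius_km` of the
#' established home; the default 500 m is a deliberately cautious threshold
#' against GPS inaccuracy. A fix at exactly the radius counts as at home
#' (the boundary uses `<=`).
#'
#' @param trace An [ls_trace()].
#' @param home A [geo_point()] or `c(lat, lon)`.
#' @param radius_km Home radius in kilometers (default 0.5).
#' @return A logical vector, one element per fix.
#' @export
at_home_mask <- function(trace, home, radius_km = 0.5) {
  stopifnot(radius_km > 0)
  home <- as_geo_point(home)
  haversine_km(trace$lat, trace$lon, home[["lat"]], home[["lon"]]) <= radius_km
}

#' Mean-subtracted coordinates (privacy transform)
#'
#' Subtracts the trace centroid from every coordinate, preserving the shape
#' of the Lifespace while removing absolute location: the output alone does
#' not reveal where the participant lives. This is the only coordinate frame
#' the reporting/plotting layer emits.
#'
#' @param trace An [ls_trace()].
#' @return A tibble with columns `dlat`, `dlon` (degrees, centroid at the
#'   origin to numerical tolerance); empty for an empty trace.
#' @export
mean_subtract <- function(trace) {
  if (nrow(trace) == 0L) {
    return(tibble::tibble(dlat = numeric(), dlon = numeric()))
  }
  tibble::tibble(dlat = trace$lat - mean(trace$lat),
                 dlon = trace$lon - mean(trace$lon))
}
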