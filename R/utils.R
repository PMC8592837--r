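#' @keywords internal
#' @import stats
#' @importFrom utils read.csv write.csv
#' @importFrom rlang .data
#' @importFrom mclust Mclust mclustBIC
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert pixel distances to micrometres
#'
#' Histology coordinates are stored in pixels; physical distances depend on
#' the scanner resolution. The default scale corresponds to a 20x objective
#' whole-slide scan at 0.22 um/pixel.
#'
#' @param px Distance(s) in pixels.
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @return Distance(s) in micrometres.
#' @examples
#' px_to_um(100)  # 22 um, the default cell-interaction radius
#' @export
px_to_um <- function(px, pixel_size_um = 0.22) {
  stopifnot(is.numeric(px), is.numeric(pixel_size_um), pixel_size_um > 0)
  px * pixel_size_um
}

## Stop with a field-naming configuration error.
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

## Deterministic per-patient seed derived from the cohort seed, so that
## adding patients to a cohort never perturbs earlier patients.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483399) + 1L
}

## Count, for each point in (ax, ay), the number of points in (bx, by)
## within `threshold` (inclusive), using a grid partition with bin width
## equal to the threshold so only 3x3 neighbourhoods need scanning.
## Returns an integer vector of length(ax). Self-pairs are NOT excluded
## here; callers subtract shared cell ids.
radius_neighbour_counts <- function(ax, ay, bx, by, threshold) {
  na <- length(ax); nb <- length(bx)
  out <- integer(na)
  if (na == 0L || nb == 0L) return(out)
  h <- threshold
  thr2 <- threshold^2
  x0 <- min(ax, bx); y0 <- min(ay, by)
  abin_x <- floor((ax - x0) / h); abin_y <- floor((ay - y0) / h)
  bbin_x <- floor((bx - x0) / h); bbin_y <- floor((by - y0) / h)
  bkey <- paste(bbin_x, bbin_y)
  bidx <- split(seq_len(nb), bkey)
  akey <- paste(abin_x, abin_y)
  agroups <- split(seq_len(na), akey)
  for (key in names(agroups)) {
    ia <- agroups[[key]]
    cx <- abin_x[ia[1L]]; cy <- abin_y[ia[1L]]
    neigh <- as.vector(outer(
      paste(cx + (-1:1)), cy + (-1:1),
      function(px, py) paste(px, py)
    ))
    ib <- unlist(bidx[intersect(neigh, names(bidx))], use.names = FALSE)
    if (length(ib) == 0L) next
    d2 <- outer(ax[ia], bx[ib], "-")^2 + outer(ay[ia], by[ib], "-")^2
    out[ia] <- as.integer(rowSums(d2 <= thr2))
  }
  out
}

## Write a provenance sidecar describing how an output was produced.
write_provenance <- function(path, info) {
  info$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  info$r_version <- as.character(getRversion())
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
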