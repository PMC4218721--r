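#' Build the regional layout of a fundus field
#'
#' Combines manually traced vessel masks with the optic nerve head (ONH)
#' mask into disjoint class masks (precedence on overlap: ONH > artery >
#' vein, overlaps reported), labels the four retinal quadrants (superior,
#' nasal, inferior, temporal) as 90-degree sectors centred on the ONH, and
#' assigns eccentricity zones from micrometre distance to the ONH centre.
#' With the default radii the inner zone is d <= 640 um and the outer zone
#' 640 < d <= 1280 um (boundaries closed on the inner side); an arbitrary
#' vector of radii supports finer annuli (e.g. 200 um bins). The
#' capillary/choroid class is everything that is neither vessel nor ONH.
#'
#' @param artery_mask,vein_mask,onh_mask Logical H x W matrices (same
#'   shape). Manual tracings; no automatic segmentation is shipped.
#' @param meta An \code{\link{acquisition_meta}} carrying
#'   \code{um_per_px}.
#' @param onh_center_px \code{c(row, col)} of the ONH centre; defaults to
#'   the metadata's.
#' @param orientation_deg Angle (degrees, clockwise) of the superior axis
#'   relative to image-up; quadrant boundaries sit at
#'   \code{orientation_deg +- 45} and the perpendicular.
#' @param zone_radii_um Increasing annulus boundaries in micrometres,
#'   default \code{c(640, 1280)}.
#' @return An object of class \code{"region_layout"}: the class masks,
#'   \code{quadrant_map} (factor levels superior/nasal/inferior/temporal),
#'   \code{zone_map} (levels inner/outer/beyond for the default radii),
#'   \code{distance_um}, \code{onh_center_px}, \code{zone_radii_um}.
#' @export
build_layout <- function(artery_mask, vein_mask, onh_mask, meta,
                         onh_center_px = meta$onh_center_px,
                         orientation_deg = 0,
                         zone_radii_um = c(640, 1280)) {
  stopifnot(is.logical(artery_mask), is.logical(vein_mask),
            is.logical(onh_mask),
            identical(dim(artery_mask), dim(vein_mask)),
            identical(dim(artery_mask), dim(onh_mask)),
            inherits(meta, "acquisition_meta"),
            !is.null(onh_center_px),
            !is.unsorted(zone_radii_um), all(zone_radii_um > 0))
  h <- nrow(artery_mask); w <- ncol(artery_mask)
  if (onh_center_px[1] < 1 || onh_center_px[1] > h ||
      onh_center_px[2] < 1 || onh_center_px[2] > w)
    stop(sprintf("ONH centre (%g, %g) outside the %dx%d image",
                 onh_center_px[1], onh_center_px[2], h, w))
  n_ov <- sum(onh_mask & (artery_mask | vein_mask)) +
    sum(artery_mask & vein_mask & !onh_mask)
  if (n_ov > 0)
    message(n_ov, " overlapping mask pixels resolved (ONH > artery > vein)")
  artery <- artery_mask & !onh_mask
  vein <- vein_mask & !onh_mask & !artery
  capillary <- !artery & !vein & !onh_mask

  dy <- matrix(seq_len(h) - onh_center_px[1], h, w)
  dx <- matrix(seq_len(w) - onh_center_px[2], h, w, byrow = TRUE)
  dist_um <- sqrt(dy^2 + dx^2) * meta$um_per_px
  # angle 0 = image-up, increasing clockwise; quadrants are 90-degree
  # sectors centred on the (rotated) cardinal axes
  ang <- (atan2(dx, -dy) * 180 / pi - orientation_deg) %% 360
  sector <- floor(((ang + 45) %% 360) / 90)
  qlev <- c("superior", "nasal", "inferior", "temporal")
  quadrant <- factor(qlev[sector + 1L], levels = qlev)
  dim(quadrant) <- c(h, w)

  zi <- findInterval(dist_um, zone_radii_um, left.open = TRUE) + 1L
  zlev <- if (length(zone_radii_um) == 2L) c("inner", "outer", "beyond")
          else c(paste0("z", seq_along(zone_radii_um)), "beyond")
  zone <- factor(zlev[zi], levels = zlev)
  dim(zone) <- c(h, w)

  structure(list(artery_mask = artery, vein_mask = vein,
                 onh_mask = onh_mask, capillary_mask = capillary,
                 quadrant_map = quadrant, zone_map = zone,
                 distance_um = dist_um,
                 onh_center_px = as.numeric(onh_center_px),
                 orientation_deg = orientation_deg,
                 zone_radii_um = zone_radii_um),
            class = "region_layout")
}

#' @export
print.region_layout <- function(x, ...) {
  cat(sprintf(
    "Region layout: %d artery, %d vein, %d ONH, %d capillary px\n",
    sum(x$artery_mask), sum(x$vein_mask), sum(x$onh_mask),
    sum(x$capillary_mask)))
  cat(sprintf("  zones at %s um, superior axis %g deg\n",
              paste(x$zone_radii_um, collapse = "/"), x$orientation_deg))
  invisible(x)
}

#' Regional summary of kinetic parameter maps
#'
#' Mean and SEM of every kinetic parameter in each vessel-class x quadrant
#' x eccentricity-zone cell, the ONH excluded. Half-fall rows additionally
#' report the fraction of capped pixels in the cell (capped pixels are
#' included in the offset and half-fall averages and flagged here).
#' Empty cells are reported with n = 0, never dropped; single-pixel cells
#' get SEM 0 by convention (one warning summarises how many).
#'
#' @param maps A \code{\link{extract_maps}} result.
#' @param layout A \code{\link{build_layout}} result of the same shape.
#' @return A data frame with columns \code{vessel_class},
#'   \code{quadrant}, \code{zone}, \code{parameter}, \code{n},
#'   \code{mean}, \code{sem}, \code{capped_fraction} (NA except for
#'   half-fall rows).
#' @export
summarize_regions <- function(maps, layout) {
  stopifnot(inherits(maps, "kinetics_maps"),
            inherits(layout, "region_layout"),
            identical(dim(maps$valid_mask), dim(layout$artery_mask)))
  params <- c("half_rise_s", "half_fall_s", "offset_pct", "peak_time_s",
              "peak_value")
  classes <- list(artery = layout$artery_mask, vein = layout$vein_mask,
                  capillary = layout$capillary_mask)
  qlev <- levels(layout$quadrant_map[1, 1])
  zlev <- levels(layout$zone_map[1, 1])
  rows <- list(); n_single <- 0L
  for (cl in names(classes)) {
    base <- classes[[cl]] & maps$valid_mask
    for (q in qlev) for (z in zlev) {
      cell <- base & layout$quadrant_map == q & layout$zone_map == z
      n <- sum(cell)
      if (n == 1L) n_single <- n_single + 1L
      for (p in params) {
        v <- maps[[p]][cell]
        if (n == 0L) { m <- NA_real_; s <- NA_real_ }
        else if (n == 1L) { m <- v; s <- 0 }
        else { m <- mean(v); s <- stats::sd(v) / sqrt(n) }
        rows[[length(rows) + 1L]] <- data.frame(
          vessel_class = cl, quadrant = q, zone = z, parameter = p,
          n = n, mean = m, sem = s,
          capped_fraction = if (p == "half_fall_s" && n > 0)
            mean(maps$capped[cell]) else NA_real_)
      }
    }
  }
  if (n_single > 0L)
    warning(n_single, " single-pixel cell(s): SEM set to 0 by convention")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
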