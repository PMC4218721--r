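#' Standard-deviation (probability) map of a kinetic parameter
#'
#' Expresses a parameter at each pixel as the number of standard
#' deviations from the eye-wide mean, \eqn{z = (x - \mu)/\sigma}, with
#' \eqn{\mu} and \eqn{\sigma} estimated over \code{included_mask} only
#' (typically the capillary/choroid field with large vessels, the ONH and
#' capped pixels excluded). The thresholded level map records, per pixel,
#' the largest threshold k with \eqn{z \ge k} (positive tail: injury
#' prolongs half-fall and elevates offset); \code{two_tailed = TRUE} uses
#' \eqn{|z|} instead. Levels correspond to the probability that a normal
#' pixel strays that far by chance.
#'
#' @param map Numeric H x W parameter map (NA = not analysed).
#' @param included_mask Logical H x W mask of pixels entering mu and
#'   sigma; must select at least 2 finite pixels with nonzero spread.
#' @param thresholds Increasing positive thresholds, default \code{1:4}.
#' @param two_tailed Logical, default FALSE (signed, positive tail).
#' @param parameter Optional name of the mapped parameter (metadata).
#' @return An object of class \code{"anomaly_map"}: \code{z_map},
#'   integer \code{level_map} (0 where below the first threshold, NA where
#'   the input is NA), \code{mu}, \code{sigma}, \code{included_mask},
#'   \code{thresholds}, \code{two_tailed}, \code{parameter}.
#' @export
zscore_map <- function(map, included_mask, thresholds = 1:4,
                       two_tailed = FALSE, parameter = NULL) {
  stopifnot(is.matrix(map), is.logical(included_mask),
            identical(dim(map), dim(included_mask)),
            all(thresholds > 0), !is.unsorted(thresholds))
  inc <- included_mask & is.finite(map)
  vals <- map[inc]
  if (length(vals) < 2L)
    stop("included_mask selects ", length(vals),
         " finite pixels; need at least 2")
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  if (sigma == 0)
    stop("degenerate (constant) parameter field: sigma = 0")
  z <- (map - mu) / sigma
  score <- if (two_tailed) abs(z) else z
  lev <- matrix(NA_integer_, nrow(map), ncol(map))
  ok <- is.finite(score)
  lev[ok] <- findInterval(score[ok], thresholds)
  structure(list(z_map = z, level_map = lev, mu = mu, sigma = sigma,
                 included_mask = inc, thresholds = thresholds,
                 two_tailed = two_tailed, parameter = parameter),
            class = "anomaly_map")
}

#' @export
print.anomaly_map <- function(x, ...) {
  cat(sprintf("Anomaly map%s: mu = %.4g, sigma = %.4g (%d included px, %s)\n",
              if (!is.null(x$parameter)) paste0(" of ", x$parameter) else "",
              x$mu, x$sigma, sum(x$included_mask),
              if (x$two_tailed) "two-tailed" else "positive tail"))
  for (k in x$thresholds)
    cat(sprintf("  >= %g SD: %d px\n", k,
                sum(x$level_map >= k, na.rm = TRUE)))
  invisible(x)
}

#' Global abnormality indices from an anomaly map
#'
#' For each threshold k: the abnormal pixel count, abnormal area in
#' square micrometres (count x um_per_px^2), the number of 8-connected
#' abnormal components, and the largest component's area. These global
#' indices support monitoring lesion extent across longitudinal trials.
#'
#' @param am An \code{\link{zscore_map}} result.
#' @param meta An \code{\link{acquisition_meta}} providing the pixel
#'   scale.
#' @return Data frame with one row per threshold: \code{threshold_sd},
#'   \code{n_pixels}, \code{area_um2}, \code{n_components},
#'   \code{largest_component_um2}.
#' @export
abnormality_indices <- function(am, meta) {
  stopifnot(inherits(am, "anomaly_map"), inherits(meta, "acquisition_meta"))
  px_um2 <- meta$um_per_px^2
  rows <- lapply(am$thresholds, function(k) {
    mask <- !is.na(am$level_map) & am$level_map >= k
    n <- sum(mask)
    if (n == 0L)
      return(data.frame(threshold_sd = k, n_pixels = 0L, area_um2 = 0,
                        n_components = 0L, largest_component_um2 = 0))
    lab <- connected_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    data.frame(threshold_sd = k, n_pixels = n, area_um2 = n * px_um2,
               n_components = length(sizes),
               largest_component_um2 = max(sizes) * px_um2)
  })
  do.call(rbind, rows)
}

#' Label 8-connected components of a binary mask
#'
#' Two-pass union-find labelling; pixels touching by edge or corner join
#' the same component. Labels are positive integers in first-encounter
#' (column-major) order; background is 0.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape.
#' @export
connected_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(matrix(0L, h, w))
  parent <- seq_along(idx)
  pos <- integer(h * w)          # 0 = background, else index into idx
  pos[idx] <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_along(idx)) {
    p <- idx[k]
    i <- (p - 1L) %% h + 1L
    j <- (p - 1L) %/% h + 1L
    # neighbours already visited in column-major order:
    # same column above; previous column (j-1) rows i-1, i, i+1
    nb <- integer(0)
    if (i > 1L) nb <- c(nb, p - 1L)
    if (j > 1L) {
      q <- p - h
      if (i > 1L) nb <- c(nb, q - 1L)
      nb <- c(nb, q)
      if (i < h) nb <- c(nb, q + 1L)
    }
    for (q in nb) {
      if (pos[q] > 0L) {
        ra <- find(k); rb <- find(pos[q])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  lab_of_root <- integer(length(idx))
  nxt <- 0L
  labs <- integer(length(idx))
  for (k in seq_along(idx)) {
    r <- roots[k]
    if (lab_of_root[r] == 0L) { nxt <- nxt + 1L; lab_of_root[r] <- nxt }
    labs[k] <- lab_of_root[r]
  }
  out <- matrix(0L, h, w)
  out[idx] <- labs
  out
}
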