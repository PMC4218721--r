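#' @export
plot.image_sequence <- function(x, pixel = NULL, ...) {
  t <- frame_times(x)
  if (is.null(pixel)) {
    y <- apply(x$frames, 3, function(f) mean(f[x$valid_mask]))
    lab <- "mean intensity over valid pixels (a.u.)"
  } else {
    y <- x$frames[pixel[1], pixel[2], ]
    lab <- sprintf("intensity at (%d, %d) (a.u.)", pixel[1], pixel[2])
  }
  plot(t, y, type = "l", xlab = "time since infusion (s)", ylab = lab, ...)
  invisible(x)
}

#' @export
plot.pca_model <- function(x, n = 6, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  n <- min(n, length(x$explained))
  graphics::plot(seq_len(n), 100 * x$explained[seq_len(n)], type = "b",
                 xlab = "components", ylab = "cumulative variance (%)",
                 ylim = c(0, 100), ...)
  graphics::abline(h = 95, lty = 2)
  graphics::matplot(x$component_curves[, 1:2], type = "l", lty = 1,
                    xlab = "frame", ylab = "component weight")
  invisible(x)
}

#' @export
plot.kinetics_maps <- function(x, parameter = "half_fall_s", ...) {
  m <- x[[parameter]]
  image(t(m[nrow(m):1, ]), useRaster = TRUE, axes = FALSE,
        col = grDevices::hcl.colors(64, "viridis"), main = parameter, ...)
  invisible(x)
}

#' @export
plot.anomaly_map <- function(x, ...) {
  m <- x$level_map
  image(t(m[nrow(m):1, ]), useRaster = TRUE, axes = FALSE,
        zlim = c(0, length(x$thresholds)),
        col = grDevices::hcl.colors(length(x$thresholds) + 1, "inferno"),
        main = sprintf("abnormality level (SD), mu=%.3g sigma=%.3g",
                       x$mu, x$sigma), ...)
  invisible(x)
}
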