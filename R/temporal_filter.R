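#' Fit a temporal principal component model to a registered sequence
#'
#' Treats every valid pixel as an observation described by T dependent
#' variables (the frames). Variables are centred by the mean intensity per
#' frame over pixels (no per-pixel standardization, so amplitude
#' information stays in the scores) and decomposed exactly via the
#' eigendecomposition of the T x T covariance matrix. Components are
#' ordered by decreasing explained variance; each component's sign is fixed
#' so that its largest-magnitude element is positive, making the model
#' deterministic.
#'
#' @param seq A registered \code{\link{image_sequence}}.
#' @param mask Logical H x W matrix of pixels to enter the model; defaults
#'   to the sequence's valid mask.
#' @return An object of class \code{"pca_model"} with elements
#'   \code{values} (eigenvalues), \code{explained} (cumulative variance
#'   fractions), \code{component_curves} (T x T temporal basis),
#'   \code{scores} (n_pixels x T loadings), \code{temporal_mean},
#'   \code{mask}, \code{n_pixels}.
#' @export
fit_pca <- function(seq, mask = seq$valid_mask) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$frames)
  stopifnot(identical(dim(mask), d[1:2]))
  idx <- which(mask)
  if (length(idx) < 2L)
    stop("PCA needs at least 2 valid pixels, got ", length(idx))
  X <- matrix(seq$frames, d[1] * d[2], d[3])[idx, , drop = FALSE]
  tm <- colMeans(X)
  Xc <- sweep(X, 2L, tm)
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  ee <- eigen(C, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  V <- ee$vectors
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  tot <- sum(vals)
  explained <- if (tot > 0) cumsum(vals) / tot else rep(1, length(vals))
  structure(list(values = vals, explained = explained,
                 component_curves = V, scores = Xc %*% V,
                 temporal_mean = tm, mask = mask,
                 n_pixels = length(idx)),
            class = "pca_model")
}

#' Cumulative explained-variance fraction at k components
#'
#' @param model A \code{"pca_model"}.
#' @param k Component count.
#' @return Fraction in [0, 1], nondecreasing in \code{k}, 1 at \code{k = T}.
#' @export
explained_fraction <- function(model, k) {
  stopifnot(inherits(model, "pca_model"), k >= 1,
            k <= length(model$explained))
  model$explained[k]
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("Temporal PCA model: %d pixels x %d frames\n", x$n_pixels,
              length(x$temporal_mean)))
  kk <- seq_len(min(4L, length(x$explained)))
  cat("  cumulative variance: ",
      paste(sprintf("PC%d %.1f%%", kk, 100 * x$explained[kk]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reconstruct a smoothed sequence from k principal components
#'
#' Replaces each modelled pixel's series by the temporal mean plus its k
#' leading score-weighted components, i.e. the PCA-filtered profile.
#' Pixels outside the model mask are left untouched. The default k = 2
#' reflects that two components usually explain >= 95\% of the variance in
#' control sequences; \code{k = "auto95"} picks the smallest k reaching
#' that fraction.
#'
#' @param seq The \code{\link{image_sequence}} the model was fitted to.
#' @param model A \code{"pca_model"}.
#' @param k Component count, or \code{"auto95"}.
#' @return A smoothed \code{\link{image_sequence}} (negative
#'   reconstructions are not clipped; reconstruction with all components
#'   reproduces the input to float tolerance).
#' @export
reconstruct <- function(seq, model, k = 2) {
  stopifnot(inherits(seq, "image_sequence"), inherits(model, "pca_model"))
  nt <- length(model$temporal_mean)
  if (identical(k, "auto95")) k <- which(model$explained >= 0.95)[1L]
  if (!is.numeric(k) || k < 1 || k > nt)
    stop("k must be in 1..", nt, " or \"auto95\"")
  k <- as.integer(k)
  d <- dim(seq$frames)
  stopifnot(d[3] == nt)
  idx <- which(model$mask)
  rec <- model$scores[, seq_len(k), drop = FALSE] %*%
    t(model$component_curves[, seq_len(k), drop = FALSE])
  rec <- sweep(rec, 2L, model$temporal_mean, "+")
  out <- matrix(seq$frames, d[1] * d[2], d[3])
  out[idx, ] <- rec
  image_sequence(array(pmax(out, 0), dim = d), seq$meta, seq$valid_mask)
}

#' Three-point moving median filter along time
#'
#' Replaces every pixel's series by the centred 3-point median; the first
#' and last samples are kept (the edge sample is conceptually replicated
#' once so the window is always three long, and the median of \{x1, x1,
#' x2\} is x1). Suited to high-variance fields such as focal laser injury,
#' where a global PCA basis is a poor fit; single-frame spikes are
#' rejected and output values never leave the local 3-point range.
#'
#' @param x An \code{\link{image_sequence}} (filtered along the third
#'   axis) or a numeric vector.
#' @return Object of the same type as \code{x}.
#' @export
moving_median3 <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) < 3L) stop("need at least 3 samples")
    return(med3_matrix(matrix(x, 1L)) [1L, ])
  }
  stopifnot(inherits(x, "image_sequence"))
  d <- dim(x$frames)
  if (d[3] < 3L) stop("need at least 3 frames")
  M <- med3_matrix(matrix(x$frames, d[1] * d[2], d[3]))
  image_sequence(array(M, dim = d), x$meta, x$valid_mask)
}

# rowwise centred 3-point median with kept endpoints, fully vectorised:
# median(a,b,c) = max(min(a,b), min(max(a,b), c))
med3_matrix <- function(X) {
  nt <- ncol(X)
  a <- X[, 1:(nt - 2), drop = FALSE]
  b <- X[, 2:(nt - 1), drop = FALSE]
  c_ <- X[, 3:nt, drop = FALSE]
  med <- pmax(pmin(a, b), pmin(pmax(a, b), c_))
  cbind(X[, 1L], med, X[, nt])
}
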