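#' Z-score normalization
#'
#' Standardizes a numeric vector to zero mean and unit *population*
#' standard deviation: `x# = (x - mean(x)) / sigma`.  The returned
#' parameters allow the exact inverse transform.
#'
#' @param values numeric vector (>= 2 values, not all identical).
#' @return list with `normalized` and `params` (list `mean`, `std`).
#' @export
zscore_normalize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    stop("`values` must be a numeric vector of length >= 2 without NA",
         call. = FALSE)
  }
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))  # population sigma
  if (s == 0) stop("zero variance: all input values identical", call. = FALSE)
  list(normalized = (values - m) / s, params = list(mean = m, std = s))
}

#' Invert a z-score normalization
#' @param normalized z-scored values.
#' @param params the `params` returned by [zscore_normalize()].
#' @return the original-scale values.
#' @export
zscore_denormalize <- function(normalized, params) {
  stopifnot(is.list(params), params$std > 0)
  normalized * params$std + params$mean
}

# separable convolution with reflected borders (used by gaussian denoise)
.conv_sep <- function(img, kernel) {
  k <- length(kernel); half <- (k - 1L) %/% 2L
  pad_idx <- function(n) pmin(pmax(seq(1 - half, n + half), 1L), n)
  ri <- pad_idx(nrow(img)); ci <- pad_idx(ncol(img))
  p <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nrow(p), ncol(img))
  for (o in seq_len(k)) {
    out <- out + kernel[o] * p[, seq(o, o + ncol(img) - 1L), drop = FALSE]
  }
  res <- matrix(0, nrow(img), ncol(img))
  for (o in seq_len(k)) {
    res <- res + kernel[o] * out[seq(o, o + nrow(img) - 1L), , drop = FALSE]
  }
  res
}

.median3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  ri <- pmin(pmax(0:(h + 1L), 1L), h); ci <- pmin(pmax(0:(w + 1L), 1L), w)
  p <- img[ri, ci, drop = FALSE]
  stack <- array(0, c(h, w, 9L))
  s <- 1L
  for (dr in 0:2) for (dc in 0:2) {
    stack[, , s] <- p[seq(1L + dr, dr + h), seq(1L + dc, dc + w)]
    s <- s + 1L
  }
  apply(stack, c(1, 2), stats::median)
}

#' Preprocess an image: denoising and contrast augmentation
#'
#' @param image numeric matrix in \[0, 1\].
#' @param denoise `"none"`, `"median"` (3x3) or `"gaussian"` (sigma 1).
#' @param contrast `"none"`, `"stretch"` (min-max; constant images are
#'   returned unchanged) or `"clahe"` (clip-limited histogram
#'   equalization).
#' @return processed image in \[0, 1\], same shape.
#' @export
preprocess_image <- function(image,
                             denoise = c("none", "median", "gaussian"),
                             contrast = c("none", "stretch", "clahe")) {
  .check_image(image)
  denoise <- match.arg(denoise); contrast <- match.arg(contrast)
  out <- switch(denoise,
    none = image,
    median = .median3(image),
    gaussian = {
      x <- seq(-3, 3); k <- exp(-x^2 / 2); k <- k / sum(k)
      .conv_sep(image, k)
    })
  out <- switch(contrast,
    none = out,
    stretch = {
      rng <- range(out)
      if (diff(rng) == 0) out else (out - rng[1]) / diff(rng)
    },
    clahe = .clip_limited_equalize(out))
  pmin(pmax(out, 0), 1)
}

# clip-limited histogram equalization over 256 levels; the clip limit
# bounds any single bin's mass, redistributing the excess uniformly, so
# flat regions are not over-amplified (the property CLAHE targets)
.clip_limited_equalize <- function(img, clip = 0.02, levels = 256L) {
  q <- pmin(floor(img * levels), levels - 1L)
  h <- tabulate(q + 1L, nbins = levels) / length(q)
  excess <- sum(pmax(h - clip, 0))
  h <- pmin(h, clip) + excess / levels
  cdf <- cumsum(h)
  lo <- cdf[1L]
  map <- if (cdf[levels] - lo > 0) (cdf - lo) / (cdf[levels] - lo) else cdf
  matrix(map[q + 1L], nrow(img), ncol(img))
}

#' Otsu's threshold of an image quantized to 256 gray levels
#'
#' Returns the gray level (in \[0, 1\]) maximizing between-class
#' variance; pixels strictly above the threshold are foreground.
#'
#' @param image numeric matrix in \[0, 1\].
#' @return threshold on the \[0, 1\] scale.
#' @export
otsu_threshold <- function(image) {
  .check_image(image)
  levels <- 256L
  q <- pmin(floor(as.vector(image) * levels), levels - 1L)
  h <- tabulate(q + 1L, nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:(levels - 1L)))
  mu_t <- mu[levels]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  t_level <- which.max(sigma_b) - 1L  # threshold level; foreground > level
  (t_level + 0.5) / levels
}

#' Segment an image into a binary mask
#'
#' @param image numeric matrix in \[0, 1\].
#' @param method `"otsu"`, `"fixed"` (threshold `t`), or `"region_grow"`.
#' @param t threshold for `method = "fixed"`; pixels strictly greater
#'   than `t` are marked.
#' @param seeds for `region_grow`: a matrix or list of `(row, col)` seed
#'   pixels (1-based), at least one, inside the image.
#' @param tol for `region_grow`: maximum absolute intensity difference to
#'   the seed pixel for inclusion (4-connectivity).
#' @return logical mask of the same shape.
#' @export
segment <- function(image, method = c("otsu", "fixed", "region_grow"),
                    t = 0.5, seeds = NULL, tol = 0.1) {
  .check_image(image)
  method <- match.arg(method)
  switch(method,
    otsu = image > otsu_threshold(image),
    fixed = image > t,
    region_grow = {
      if (is.null(seeds)) stop("region_grow requires at least one seed", call. = FALSE)
      if (is.list(seeds)) seeds <- do.call(rbind, seeds)
      seeds <- matrix(as.integer(seeds), ncol = 2L)
      h <- nrow(image); w <- ncol(image)
      if (any(seeds[, 1] < 1 | seeds[, 1] > h | seeds[, 2] < 1 | seeds[, 2] > w)) {
        stop("seed outside image bounds", call. = FALSE)
      }
      mask <- matrix(FALSE, h, w)
      for (s in seq_len(nrow(seeds))) {
        mask <- mask | .flood_grow(image, seeds[s, 1], seeds[s, 2], tol)
      }
      mask
    })
}

# BFS flood fill: include 4-connected pixels within tol of the seed value
.flood_grow <- function(image, r0, c0, tol) {
  h <- nrow(image); w <- ncol(image)
  ref <- image[r0, c0]
  inside <- abs(image - ref) <= tol
  mask <- matrix(FALSE, h, w)
  if (!inside[r0, c0]) return(mask)
  queue <- integer(h * w); queue[1L] <- (c0 - 1L) * h + r0
  head <- 1L; tail <- 1L
  mask[r0, c0] <- TRUE
  while (head <= tail) {
    idx <- queue[head]; head <- head + 1L
    r <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
    for (d in 1:4) {
      nr <- r + c(-1L, 1L, 0L, 0L)[d]; nc <- cc + c(0L, 0L, -1L, 1L)[d]
      if (nr >= 1L && nr <= h && nc >= 1L && nc <= w &&
          !mask[nr, nc] && inside[nr, nc]) {
        mask[nr, nc] <- TRUE
        tail <- tail + 1L
        queue[tail] <- (nc - 1L) * h + nr
      }
    }
  }
  mask
}

#' Connected components of a binary mask (4-connectivity)
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    idx <- todo[1L]
    cur <- cur + 1L
    r <- ((idx - 1L) %% nrow(mask)) + 1L; cc <- ((idx - 1L) %/% nrow(mask)) + 1L
    comp <- .flood_grow(mask * 1.0, r, cc, 0.5)
    lab[comp] <- cur
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Extract intensity, shape and texture features from a masked region
#'
#' Intensity: histogram over the masked pixels (`hist_bins` equal-width
#' bins on \[0, 1\]), mean and variance.  Shape: pixel-count area,
#' boundary-pixel perimeter, and eccentricity from the second central
#' moments of the mask.  Texture: gray-level co-occurrence matrix at
#' offset (0, 1), symmetric, quantized to `hist_bins` levels, from which
#' contrast, homogeneity, energy and entropy are computed.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param mask logical matrix, nonempty.
#' @param hist_bins number of histogram / quantization bins (default 32).
#' @return object of class `feature_vector`.
#' @export
extract_features <- function(image, mask, hist_bins = 32L) {
  .check_image(image)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  px <- image[mask]
  q <- pmin(floor(px * hist_bins), hist_bins - 1L)
  hist <- tabulate(q + 1L, nbins = hist_bins)

  # shape block
  area <- sum(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L); pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[2:(h + 1L), 2:(w + 1L)]
  nbr_all <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  perimeter <- sum(inner & !nbr_all)
  rc <- which(mask, arr.ind = TRUE)
  mu <- colMeans(rc)
  d <- sweep(rc, 2L, mu)
  cov <- crossprod(d) / nrow(rc)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- if (ev[1] <= 1e-12) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))

  # texture block: symmetric GLCM, offset (0, 1), masked pairs only
  qm <- matrix(NA_integer_, h, w)
  qm[mask] <- pmin(floor(image[mask] * hist_bins), hist_bins - 1L) + 1L
  a <- qm[, -w, drop = FALSE]; b <- qm[, -1L, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  glcm <- matrix(0, hist_bins, hist_bins)
  if (any(keep)) {
    tab <- table(factor(a[keep], levels = seq_len(hist_bins)),
                 factor(b[keep], levels = seq_len(hist_bins)))
    glcm <- unclass(tab) + t(unclass(tab))
    glcm <- glcm / sum(glcm)
  } else {
    glcm[1L, 1L] <- 1  # single-column masks: degenerate flat texture
  }
  ii <- matrix(seq_len(hist_bins), hist_bins, hist_bins)
  jj <- t(ii)
  contrast <- sum(glcm * (ii - jj)^2)
  homogeneity <- sum(glcm / (1 + (ii - jj)^2))
  energy <- sum(glcm^2)
  pos <- glcm[glcm > 0]
  entropy <- -sum(pos * log(pos))

  structure(list(
    intensity = list(hist = hist, mean = mean(px),
                     var = if (length(px) > 1) mean((px - mean(px))^2) else 0),
    shape = list(area = area, perimeter = perimeter, eccentricity = ecc),
    texture = list(contrast = contrast, homogeneity = homogeneity,
                   energy = energy, entropy = entropy)
  ), class = "feature_vector")
}

#' Flatten a feature vector to a named numeric vector
#' @param v a `feature_vector`.
#' @return named numeric vector (histogram bins then scalar features).
#' @export
as_numeric_features <- function(v) {
  stopifnot(inherits(v, "feature_vector"))
  out <- c(v$intensity$hist, v$intensity$mean, v$intensity$var,
           v$shape$area, v$shape$perimeter, v$shape$eccentricity,
           v$texture$contrast, v$texture$homogeneity, v$texture$energy,
           v$texture$entropy)
  names(out) <- c(paste0("hist", seq_along(v$intensity$hist)),
                  "int_mean", "int_var", "area", "perimeter", "eccentricity",
                  "contrast", "homogeneity", "energy", "entropy")
  out
}

#' Map a feature vector onto the probability simplex
#'
#' Shift-by-minimum, add a floor of 1e-12, normalize to sum 1.  The floor
#' guarantees shared support so the Bhattacharyya distance never takes
#' the logarithm of zero between two mapped vectors.
#'
#' @param v a `feature_vector` or finite numeric vector.
#' @return numeric probability vector (sums to 1, all > 0).
#' @export
features_to_distribution <- function(v) {
  x <- if (inherits(v, "feature_vector")) as_numeric_features(v) else v
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("features must be finite numeric values", call. = FALSE)
  }
  x <- x - min(x) + 1e-12
  unname(x / sum(x))
}
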