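#' Specification of a synthetic phantom image
#'
#' A phantom emulates a grayscale radiograph: a noisy uniform background
#' carrying a number of brighter disc-shaped "lesions" with smoothed
#' edges.  Phantoms stand in for real radiology so that every stage of the
#' pipeline is testable without downloads.
#'
#' @param width,height image size in pixels (>= 16).
#' @param n_blobs number of lesions (>= 0).
#' @param blob_radius_range `(min, max)` lesion radius in pixels.
#' @param blob_intensity_range `(min, max)` lesion peak intensity as a
#'   fraction of dynamic range; must exceed `background_level` so lesions
#'   are brighter than background before noise.
#' @param background_level background intensity fraction in \[0, 1\].
#' @param noise_sigma standard deviation of additive Gaussian noise
#'   (fraction of dynamic range, >= 0).
#' @param seed integer RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 64L, height = 64L, n_blobs = 3L,
                         blob_radius_range = c(4, 8),
                         blob_intensity_range = c(0.6, 0.9),
                         background_level = 0.2,
                         noise_sigma = 0.02,
                         seed = 1L) {
  .check_scalar_num(width, "width", 16); .check_scalar_num(height, "height", 16)
  .check_scalar_num(n_blobs, "n_blobs", 0)
  stopifnot(length(blob_radius_range) == 2L, length(blob_intensity_range) == 2L)
  if (blob_radius_range[1] > blob_radius_range[2] ||
      blob_intensity_range[1] > blob_intensity_range[2]) {
    stop("range minima must not exceed maxima", call. = FALSE)
  }
  .check_scalar_num(background_level, "background_level", 0, 1)
  .check_scalar_num(noise_sigma, "noise_sigma", 0)
  if (blob_radius_range[2] > min(width, height) / 2) {
    stop("blob radius larger than min(width, height)/2", call. = FALSE)
  }
  if (n_blobs > 0 && blob_intensity_range[1] <= background_level) {
    stop("blob intensities must exceed background_level", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_blobs = as.integer(n_blobs),
                 blob_radius_range = as.numeric(blob_radius_range),
                 blob_intensity_range = as.numeric(blob_intensity_range),
                 background_level = background_level,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom image and its ground-truth lesion mask
#'
#' Lesions are filled discs with sigmoid-smoothed edges, placed by
#' rejection sampling so that discs never overlap and lie fully inside
#' the frame.  The truth mask marks exactly the union of the discs
#' (pixels with centre distance <= radius).  Inside a disc the noiseless
#' intensity strictly exceeds `background_level`.
#'
#' @param spec a [phantom_spec()].
#' @param max_tries rejection-sampling attempts per lesion before failing.
#' @return list with `image` (matrix in \[0, 1\]) and `truth_mask`
#'   (logical matrix).
#' @export
generate_phantom_image <- function(spec, max_tries = 1000L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    img <- matrix(spec$background_level, h, w)
    mask <- matrix(FALSE, h, w)
    placed <- matrix(numeric(0), ncol = 3)  # row, col, radius
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    if (spec$n_blobs > 0) {
      for (b in seq_len(spec$n_blobs)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          r <- stats::runif(1, spec$blob_radius_range[1], spec$blob_radius_range[2])
          cy <- stats::runif(1, r + 2, h - r - 1)
          cx <- stats::runif(1, r + 2, w - r - 1)
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) >
                  placed[, 3] + r + 2)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place non-overlapping lesions; reduce n_blobs or radii",
                      call. = FALSE)
        placed <- rbind(placed, c(cy, cx, r))
        amp <- stats::runif(1, spec$blob_intensity_range[1],
                            spec$blob_intensity_range[2])
        d <- sqrt((rows - cy)^2 + (cols - cx)^2)
        # sigmoid edge over ~1 px; == 0.5 exactly at the disc boundary so
        # every truth-mask pixel sits strictly above background pre-noise
        s <- 1 / (1 + exp(-2 * (r - d)))
        img <- pmax(img, spec$background_level + (amp - spec$background_level) * s)
        mask <- mask | (d <= r)
      }
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, truth_mask = mask)
  })
}

#' Generate a labeled Gaussian-cluster feature matrix
#'
#' Draws `n_per_cluster` points from each of `k_clusters` isotropic
#' unit-variance Gaussians whose means are mutually at least `separation`
#' apart (means sit on scaled coordinate axes, pairwise distance exactly
#' `separation`).  Exercises the embedding engine with known structure.
#'
#' @param n_per_cluster points per cluster (>= 2).
#' @param k_clusters number of clusters (>= 1, <= `dim`).
#' @param dim feature dimension (>= 2).
#' @param separation minimum distance between cluster means (>= 0).
#' @param seed integer RNG seed.
#' @return object of class `labeled_features`: list with `matrix`
#'   (n x dim) and `labels` (integer vector).
#' @export
generate_cluster_features <- function(n_per_cluster, k_clusters, dim,
                                      separation, seed = 1L) {
  .check_scalar_num(n_per_cluster, "n_per_cluster", 2)
  .check_scalar_num(k_clusters, "k_clusters", 1)
  .check_scalar_num(dim, "dim", 2)
  .check_scalar_num(separation, "separation", 0)
  if (k_clusters > dim) {
    stop("k_clusters must not exceed dim (means are placed on coordinate axes)",
         call. = FALSE)
  }
  with_seed(seed, {
    n <- n_per_cluster * k_clusters
    means <- matrix(0, k_clusters, dim)
    for (k in seq_len(k_clusters)) means[k, k] <- separation / sqrt(2)
    labels <- rep(seq_len(k_clusters), each = n_per_cluster)
    X <- means[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * dim), n, dim)
    structure(list(matrix = X, labels = labels), class = "labeled_features")
  })
}

.modalities <- c("XRay", "CT", "Picture")
.regions <- c("head", "thorax", "abdomen", "pelvis", "limb")
.body_parts <- c("skull", "lung", "liver", "kidney", "femur", "spine")
.findings <- c("normal", "lesion", "fracture", "mass")
.devices <- c("scanner-A", "scanner-B", "portable-C")

#' Generate one 12-field patient metadata record
#'
#' Emulates a tabular radiology manifest: exactly twelve named fields
#' (identifier, modality, image path, timestamp, age, sex, region, body
#' part, finding label, device, notes, image checksum).  The checksum is
#' the MD5 digest of the referenced image file, so post-hoc tampering is
#' detectable.
#'
#' @param seed integer RNG seed.
#' @param image_ref path to an existing image file.
#' @return object of class `metadata_record` (named list of 12 fields).
#' @export
generate_metadata_record <- function(seed, image_ref) {
  if (!file.exists(image_ref)) {
    stop("image file does not exist: ", image_ref, call. = FALSE)
  }
  with_seed(seed, {
    rec <- list(
      record_id = sprintf("R%08X", as.integer(stats::runif(1, 0, 2^30))),
      modality = sample(.modalities, 1),
      image_ref = as.character(image_ref),
      datetime = format(as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
                          round(stats::runif(1, 0, 3.15e7)),
                        "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      age = as.integer(sample(0:120, 1)),
      sex = sample(c("M", "F", "O"), 1),
      region = sample(.regions, 1),
      body_part = sample(.body_parts, 1),
      finding_label = sample(.findings, 1),
      device = sample(.devices, 1),
      notes = sprintf("synthetic record seed=%d", as.integer(seed)),
      checksum = unname(tools::md5sum(image_ref))
    )
    structure(rec, class = "metadata_record")
  })
}

#' Verify that a record's checksum still matches its image bytes
#' @param record a `metadata_record`.
#' @return logical scalar.
#' @export
verify_record_checksum <- function(record) {
  stopifnot(inherits(record, "metadata_record"))
  file.exists(record$image_ref) &&
    identical(unname(tools::md5sum(record$image_ref)), record$checksum)
}

#' Write metadata records to CSV (RFC-4180, header row)
#' @param records list of `metadata_record` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(unclass(r), stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

# the 45-character alphanumeric QR alphabet, in standard value order
.qr_alnum <- c(0:9, LETTERS, " ", "$", "%", "*", "+", "-", ".", "/", ":")

#' Generate a random text payload
#'
#' @param length payload length in characters (>= 1).
#' @param charset one of `"numeric"` (digits), `"alphanumeric"` (the
#'   45-character QR alphabet) or `"byte"` (printable ASCII 32--126).
#' @param seed integer RNG seed.
#' @return character scalar of exactly `length` characters.
#' @export
generate_payload <- function(length, charset = c("numeric", "alphanumeric", "byte"),
                             seed = 1L) {
  .check_scalar_num(length, "length", 1)
  charset <- match.arg(charset)
  pool <- switch(charset,
    numeric = as.character(0:9),
    alphanumeric = as.character(.qr_alnum),
    byte = vapply(32:126, function(i) rawToChar(as.raw(i)), ""))
  with_seed(seed, paste(sample(pool, length, replace = TRUE), collapse = ""))
}
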