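#' Truncated-SVD compression of an image
#'
#' Keeps the leading `rank` singular triplets; by the Eckart-Young
#' theorem this is the best rank-`rank` approximation in Frobenius norm
#' and the squared reconstruction error equals the energy of the
#' discarded singular values.
#'
#' @param image numeric matrix.
#' @param rank number of singular values kept, `1 <= rank <= min(dim)`.
#' @return object of class `svd_factors`: `u` (rows x rank), `d`
#'   (singular values, nonincreasing), `v` (cols x rank), `shape`,
#'   `rank`.
#' @export
svd_compress <- function(image, rank) {
  stopifnot(is.matrix(image))
  if (rank < 1 || rank > min(dim(image))) {
    stop("rank out of range 1..min(rows, cols)", call. = FALSE)
  }
  s <- svd(image, nu = rank, nv = rank)
  structure(list(u = s$u, d = s$d[seq_len(rank)], v = s$v,
                 all_d = s$d, shape = dim(image), rank = as.integer(rank)),
            class = "svd_factors")
}

#' Reconstruct an image from truncated SVD factors
#'
#' @param f an `svd_factors` object.
#' @param clip clip the product to \[0, 1\] (the projection can only
#'   reduce the error to any target inside \[0, 1\]).  Set `FALSE` to
#'   obtain the raw low-rank product (exact Eckart-Young error).
#' @return numeric matrix with `f$shape`.
#' @export
svd_reconstruct <- function(f, clip = TRUE) {
  stopifnot(inherits(f, "svd_factors"))
  if (nrow(f$u) != f$shape[1] || nrow(f$v) != f$shape[2] ||
      length(f$d) != f$rank) {
    stop("inconsistent factor shapes", call. = FALSE)
  }
  rec <- f$u %*% (f$d * t(f$v))
  if (clip) rec <- pmin(pmax(rec, 0), 1)
  rec
}

#' Smallest rank capturing a fraction of spectral energy
#'
#' @param singular_values nonincreasing, nonnegative values.
#' @param energy_fraction target fraction of `sum(sigma^2)` in (0, 1\].
#' @return the smallest k with cumulative squared energy >= the target.
#' @export
choose_rank <- function(singular_values, energy_fraction) {
  stopifnot(length(singular_values) >= 1, all(diff(singular_values) <= 1e-9))
  .check_scalar_num(energy_fraction, "energy_fraction", 1e-12, 1)
  e <- singular_values^2
  if (sum(e) == 0) return(1L)
  frac <- cumsum(e) / sum(e)
  which(frac >= energy_fraction - 1e-12)[1L]
}

#' Similarity between two probability vectors
#'
#' `exp(-D_B(a, b))`, i.e. the Bhattacharyya coefficient: 1 for
#' identical distributions, 0 for disjoint supports.  The store's
#' "more than 70% similar" deduplication rule is evaluated on this
#' quantity.
#'
#' @param a,b probability vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
similarity <- function(a, b) bhattacharyya_coefficient(a, b)

#' Open (or create) a similarity-mapped store
#'
#' Layout on disk: `index.json` (atomic temp-file-rename writes),
#' `factors/<key>.bin` (flat binary: two integer dims, then the rank,
#' the singular values and the factor matrices as doubles, row-major),
#' `qr/<key>.pgm` (rendered symbol).
#'
#' @param dir store directory; created if missing.
#' @return object of class `qr_store` (environment).
#' @export
store_open <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "factors"), showWarnings = FALSE)
  dir.create(file.path(dir, "qr"), showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$dir <- dir
  idx <- file.path(dir, "index.json")
  st$index <- if (file.exists(idx)) {
    jsonlite::fromJSON(idx, simplifyVector = FALSE)
  } else list()
  class(st) <- "qr_store"
  st
}

.store_save_index <- function(st) {
  idx <- file.path(st$dir, "index.json")
  tmp <- paste0(idx, ".tmp")
  jsonlite::write_json(st$index, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, idx)
}

.store_write_factors <- function(st, key, f) {
  path <- file.path(st$dir, "factors", paste0(key, ".bin"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(f$shape, f$rank)), con, size = 4L)
  writeBin(as.numeric(f$d), con, size = 8L)
  writeBin(as.numeric(t(f$u)), con, size = 8L)
  writeBin(as.numeric(t(f$v)), con, size = 8L)
  path
}

.store_read_factors <- function(st, key) {
  path <- file.path(st$dir, "factors", paste0(key, ".bin"))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 3L, size = 4L)
  r <- hdr[3L]
  d <- readBin(con, "numeric", r, size = 8L)
  u <- matrix(readBin(con, "numeric", hdr[1L] * r, size = 8L), hdr[1L], r,
              byrow = TRUE)
  v <- matrix(readBin(con, "numeric", hdr[2L] * r, size = 8L), hdr[2L], r,
              byrow = TRUE)
  structure(list(u = u, d = d, v = v, shape = hdr[1:2], rank = r),
            class = "svd_factors")
}

# percent-escape for the key=value QR payload lines
.esc <- function(x) utils::URLencode(as.character(x), reserved = TRUE)
.unesc <- function(x) utils::URLdecode(x)

# versioned key=value payload; full entries carry the record fields,
# tagged entries carry the tag target instead of compression parameters
.store_payload <- function(key, record, tag_ref = NULL, similarity = NULL,
                           rank = NULL) {
  lines <- c("QRSTORE1", paste0("key=", .esc(key)))
  if (!is.null(tag_ref)) {
    lines <- c(lines, paste0("tag=", .esc(tag_ref)),
               paste0("sim=", format(similarity, digits = 6)))
  } else {
    lines <- c(lines, paste0("rank=", rank))
  }
  for (fld in names(unclass(record))) {
    lines <- c(lines, paste0(fld, "=", .esc(record[[fld]])))
  }
  paste(lines, collapse = "\n")
}

.parse_payload <- function(payload) {
  lines <- strsplit(payload, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 2L || lines[1] != "QRSTORE1") {
    stop("not a store payload", call. = FALSE)
  }
  kv <- strsplit(lines[-1], "=", fixed = TRUE)
  out <- stats::setNames(
    lapply(kv, function(p) .unesc(paste(p[-1], collapse = "="))),
    vapply(kv, `[[`, "", 1L))
  out
}

# feature distribution used for the similarity index: histogram features
# of the Otsu-segmented (fallback: whole-image) region
.store_features <- function(image, hist_bins = 32L) {
  mask <- segment(image, "otsu")
  if (!any(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  features_to_distribution(extract_features(image, mask, hist_bins))
}

#' Ingest a record + image into the store
#'
#' Computes the image's feature distribution and searches the index for
#' the most similar existing entry.  If the best similarity strictly
#' exceeds `threshold` (default 0.70) the new entry is a *tag*: it
#' references the near-duplicate's factors (tag targets always hold
#' factors, so chains never form) and its QR payload carries only the
#' key, the tag and the metadata.  Otherwise the image is compressed by
#' truncated SVD at the energy rank rule and stored in full with a
#' complete QR payload.
#'
#' @param st a `qr_store`.
#' @param record a `metadata_record`.
#' @param image numeric matrix in \[0, 1\].
#' @param energy_fraction spectral energy kept by [choose_rank()].
#' @param threshold tagging threshold on the Bhattacharyya similarity.
#' @param ec_level error-correction level for the rendered symbol.
#' @param flush rewrite `index.json` immediately (default).  Set `FALSE`
#'   during bulk loads and call [store_flush()] once at the end.
#' @return the new store entry (list), invisibly.
#' @export
store_ingest <- function(st, record, image, energy_fraction = 0.95,
                         threshold = 0.70, ec_level = "M", flush = TRUE) {
  stopifnot(inherits(st, "qr_store"), inherits(record, "metadata_record"))
  .check_image(image)
  key <- record$record_id
  if (!is.null(st$index[[key]])) stop("duplicate key: ", key, call. = FALSE)
  feat <- .store_features(image)

  best_key <- NULL; best_sim <- -Inf
  for (k in names(st$index)) {
    s <- similarity(feat, as.numeric(unlist(st$index[[k]]$features)))
    if (s > best_sim) { best_sim <- s; best_key <- k }
  }

  if (!is.null(best_key) && best_sim > threshold) {
    target <- best_key
    # flatten: if the best match is itself a tag, reference its target
    if (!is.null(st$index[[target]]$tag_ref)) {
      target <- st$index[[target]]$tag_ref
    }
    payload <- .store_payload(key, record, tag_ref = target,
                              similarity = best_sim)
    entry <- list(key = key, record = unclass(record), tag_ref = target,
                  similarity = best_sim, features = feat,
                  qr_payload = payload)
  } else {
    f <- svd_compress(image, choose_rank(svd(image, nu = 0, nv = 0)$d,
                                         energy_fraction))
    .store_write_factors(st, key, f)
    payload <- .store_payload(key, record, rank = f$rank)
    entry <- list(key = key, record = unclass(record), rank = f$rank,
                  features = feat, qr_payload = payload)
  }
  sym <- tryCatch(build_symbol(payload, ec_level = ec_level),
                  error = function(e) NULL)
  if (is.null(sym)) {
    # payload over byte capacity: symbol carries only key + checksum,
    # the index keeps the full data
    payload <- paste0("QRSTORE1\nkey=", .esc(key),
                      "\nchecksum=", record$checksum)
    entry$qr_payload <- payload
    sym <- build_symbol(payload, ec_level = ec_level)
  }
  qr_path <- file.path(st$dir, "qr", paste0(key, ".pgm"))
  write_pgm(render_symbol(sym), qr_path)
  entry$qr_image_ref <- qr_path
  st$index[[key]] <- entry
  if (isTRUE(flush)) .store_save_index(st)
  invisible(entry)
}

#' Persist the store index to disk
#' @param st a `qr_store`.
#' @return the store, invisibly.
#' @export
store_flush <- function(st) {
  stopifnot(inherits(st, "qr_store"))
  .store_save_index(st)
  invisible(st)
}

#' Retrieve a record and reconstructed image from the store
#'
#' @param st a `qr_store`.
#' @param key entry key, or `NULL` when retrieving by symbol.
#' @param qr_image a rendered symbol image (matrix) or path to one;
#'   decoded first to recover the key.
#' @return list with `record` (`metadata_record`, bit-exact as
#'   ingested), `image` (reconstruction from the stored or referenced
#'   factors), `entry` (the index entry).
#' @export
store_retrieve <- function(st, key = NULL, qr_image = NULL) {
  stopifnot(inherits(st, "qr_store"))
  if (is.null(key)) {
    if (is.null(qr_image)) stop("supply `key` or `qr_image`", call. = FALSE)
    if (is.character(qr_image)) qr_image <- read_pgm(qr_image)
    dec <- decode_symbol(qr_image)
    key <- .parse_payload(dec$payload)$key
  }
  entry <- st$index[[key]]
  if (is.null(entry)) stop("unknown key: ", key, call. = FALSE)
  source_key <- if (!is.null(entry$tag_ref)) entry$tag_ref else key
  img <- svd_reconstruct(.store_read_factors(st, source_key))
  rec <- lapply(entry$record, function(x) if (is.list(x)) x[[1]] else x)
  rec$age <- as.integer(rec$age)
  list(record = structure(rec, class = "metadata_record"),
       image = img, entry = entry)
}

#' Number of full (factor-holding) and tagged entries
#' @param st a `qr_store`.
#' @return named integer vector `c(full = , tagged = )`.
#' @export
store_counts <- function(st) {
  tagged <- sum(vapply(st$index, function(e) !is.null(e$tag_ref), TRUE))
  c(full = length(st$index) - tagged, tagged = tagged)
}
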