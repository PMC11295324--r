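# QR symbol reader.  Detection is deterministic finder-pattern search:
# scanlines are run-length encoded and dark:light:dark:light:dark runs
# matching 1:1:3:1:1 (within 50% per element) are cross-validated
# vertically and clustered.  Axis-aligned rotations (0/90/180/270
# degrees) of clean renders are supported; perspective rectification of
# camera photographs is out of scope.

# candidate finder hits on one scanline: returns centre positions + unit
.finder_hits_line <- function(v) {
  r <- rle(as.integer(v))
  k <- length(r$lengths)
  if (k < 5L) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hits <- NULL
  for (s in seq_len(k - 4L)) {
    if (r$values[s] != 1L) next               # must start dark
    len <- r$lengths[s:(s + 4L)]
    unit <- sum(len) / 7
    ratio <- c(1, 1, 3, 1, 1)
    if (all(abs(len - ratio * unit) <= 0.5 * ratio * unit + 0.5)) {
      centre <- (starts[s] + ends[s + 4L]) / 2
      hits <- rbind(hits, c(centre, unit))
    }
  }
  hits
}

#' Locate QR finder patterns in a grayscale image
#'
#' @param image numeric matrix in \[0, 1\] (or a 0/1 dark matrix).
#' @param threshold binarization threshold; pixels below it are dark.
#' @return matrix with columns `row`, `col`, `unit` (estimated module
#'   size in pixels), one row per detected finder centre; zero rows when
#'   no symbol is present.
#' @export
locate_finders <- function(image, threshold = 0.5) {
  stopifnot(is.matrix(image))
  dark <- (image < threshold) * 1L
  cands <- NULL
  for (i in seq_len(nrow(dark))) {
    h <- .finder_hits_line(dark[i, ])
    if (!is.null(h)) cands <- rbind(cands, cbind(i, h))
  }
  if (is.null(cands)) return(matrix(numeric(0), 0, 3,
                                    dimnames = list(NULL, c("row", "col", "unit"))))
  # cross-validate vertically at the candidate column
  keep <- logical(nrow(cands))
  vcentre <- numeric(nrow(cands))
  for (k in seq_len(nrow(cands))) {
    cc <- round(cands[k, 2L])
    vh <- .finder_hits_line(dark[, cc])
    if (is.null(vh)) next
    near <- which(abs(vh[, 1L] - cands[k, 1L]) <= 3.5 * cands[k, 3L])
    if (length(near)) {
      keep[k] <- TRUE
      vcentre[k] <- vh[near[which.min(abs(vh[near, 1L] - cands[k, 1L]))], 1L]
    }
  }
  cands <- cbind(vcentre[keep], cands[keep, 2L], cands[keep, 3L])
  if (nrow(cands) == 0L) return(matrix(numeric(0), 0, 3,
                                       dimnames = list(NULL, c("row", "col", "unit"))))
  # validate the full 7x7 module template at unit spacing around the
  # centre: scanline coincidences in the data region fail this, real
  # finder patterns pass it
  tpl7 <- matrix(1L, 7, 7); tpl7[2:6, 2:6] <- 0L; tpl7[3:5, 3:5] <- 1L
  tpl_ok <- vapply(seq_len(nrow(cands)), function(k) {
    u <- cands[k, 3L]
    rr <- round(cands[k, 1L] + (-3:3) * u)
    cc <- round(cands[k, 2L] + (-3:3) * u)
    if (min(rr, cc) < 1L || max(rr) > nrow(dark) || max(cc) > ncol(dark)) {
      return(FALSE)
    }
    sum(dark[rr, cc] != tpl7) <= 1L
  }, TRUE)
  cands <- cands[tpl_ok, , drop = FALSE]
  if (nrow(cands) == 0L) return(matrix(numeric(0), 0, 3,
                                       dimnames = list(NULL, c("row", "col", "unit"))))
  # cluster within ~3 modules
  centres <- NULL
  used <- rep(FALSE, nrow(cands))
  ord <- order(cands[, 1L], cands[, 2L])
  for (k in ord) {
    if (used[k]) next
    close <- which(!used &
                     abs(cands[, 1L] - cands[k, 1L]) <= 3 * cands[k, 3L] &
                     abs(cands[, 2L] - cands[k, 2L]) <= 3 * cands[k, 3L])
    used[close] <- TRUE
    centres <- rbind(centres, c(mean(cands[close, 1L]),
                                mean(cands[close, 2L]),
                                mean(cands[close, 3L]),
                                length(close)))
  }
  # require at least 2 supporting scanlines to reject speckle
  centres <- centres[centres[, 4L] >= 2, , drop = FALSE]
  out <- centres[, 1:3, drop = FALSE]
  colnames(out) <- c("row", "col", "unit")
  out
}

.rot90 <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]  # counter-clockwise
  m
}

.is_finder_at <- function(m, r0, c0) {
  pat <- matrix(1L, 7, 7); pat[2:6, 2:6] <- 0L; pat[3:5, 3:5] <- 1L
  blk <- m[r0 + 1:7, c0 + 1:7, drop = FALSE]
  sum(blk != pat) <= 2L   # tolerate a couple of corrupted modules
}

# decode the 15-bit format word by nearest valid codeword (<= 3 bit errors)
.decode_format <- function(bits) {
  best <- NULL
  for (lvl in c("L", "M", "Q", "H")) {
    for (id in 0:7) {
      ref <- .qr_format_bits(lvl, id)
      d <- sum(ref != bits)
      if (is.null(best) || d < best$dist) {
        best <- list(ec_level = lvl, mask_id = id, dist = d)
      }
    }
  }
  if (best$dist > 3L) return(NULL)
  best
}

#' Decode a QR symbol image back to its payload
#'
#' Locates the finder patterns, samples the module grid, orients the
#' symbol (trying the four axis-aligned rotations), BCH-decodes the
#' format word (up to 3 bit errors), unmasks, de-interleaves, corrects
#' each Reed-Solomon block (up to `floor(n_ec / 2)` byte errors), and
#' parses the bitstream.  `decode_symbol(render_symbol(build_symbol(x)))`
#' recovers `x` exactly for every valid payload.
#'
#' @param image numeric matrix in \[0, 1\] (dark < 0.5), or a `qr_symbol`.
#' @return list with `payload`, `version`, `ec_level`, `mask_id`,
#'   `mode`.  Signals condition class `qr_not_found` when no symbol is
#'   present and `qr_decode_error` when correction fails.
#' @export
decode_symbol <- function(image) {
  if (inherits(image, "qr_symbol")) {
    return(.decode_matrix_try(image$matrix))
  }
  stopifnot(is.matrix(image))
  dark <- image < 0.5
  if (!any(dark)) stop(.qr_not_found("no dark pixels: no symbol present"))
  finders <- locate_finders(image)
  if (nrow(finders) < 3L) {
    stop(.qr_not_found(sprintf("found %d finder pattern(s), need 3", nrow(finders))))
  }
  unit <- stats::median(finders[, "unit"])
  rr <- range(which(rowSums(dark) > 0))
  cr <- range(which(colSums(dark) > 0))
  side_px <- max(rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L)
  version <- max(1L, min(40L, round((side_px / unit - 17) / 4)))
  side <- qr_side(version)
  mod_px <- side_px / side
  # pixel k covers the interval [k-1, k): sample at module centres
  centres_r <- floor(rr[1] - 1 + (seq_len(side) - 0.5) * mod_px) + 1L
  centres_c <- floor(cr[1] - 1 + (seq_len(side) - 0.5) * mod_px) + 1L
  ri <- pmin(pmax(centres_r, 1L), nrow(image))
  ci <- pmin(pmax(centres_c, 1L), ncol(image))
  grid <- (image[ri, ci] < 0.5) * 1L
  .decode_matrix_try(grid)
}

# try the four rotations of a sampled module matrix
.decode_matrix_try <- function(m) {
  err <- NULL
  for (k in 0:3) {
    g <- .rot90(m, k)
    if (!(.is_finder_at(g, 0L, 0L) && .is_finder_at(g, 0L, ncol(g) - 7L) &&
          .is_finder_at(g, nrow(g) - 7L, 0L))) next
    res <- tryCatch(.decode_matrix(g), error = function(e) e)
    if (!inherits(res, "error")) return(res)
    err <- res
  }
  if (is.null(err)) {
    stop(.qr_not_found("no orientation shows the three corner finder patterns"))
  }
  stop(err)
}

.decode_matrix <- function(m) {
  side <- nrow(m)
  if (side != ncol(m) || (side - 17L) %% 4L != 0L) {
    stop(.qr_decode_error(sprintf("invalid module count %dx%d", side, ncol(m))))
  }
  version <- (side - 17L) %/% 4L
  fp <- .qr_format_positions(side)
  fmt <- .decode_format(m[fp$a])
  if (is.null(fmt)) fmt <- .decode_format(m[fp$b])
  if (is.null(fmt)) stop(.qr_decode_error("format information unreadable"))

  tpl <- .qr_template(version)
  ord <- .qr_placement_order(tpl)
  mm <- .qr_mask_matrix(fmt$mask_id, side)
  un <- m
  un[ord] <- bitwXor(un[ord], mm[ord])
  bits <- un[ord]
  lay <- qr_layout(version)
  bits <- bits[seq_len(8L * lay$total_codewords)]  # drop remainder bits
  stream <- .bits_to_bytes(bits)

  bs <- qr_block_structure(version, fmt$ec_level)
  nb <- bs$n_blocks
  sizes <- bs$block_data_sizes
  # de-interleave data codewords
  blocks <- lapply(sizes, function(s) integer(s))
  pos <- 1L
  for (k in seq_len(max(sizes))) {
    for (i in seq_len(nb)) {
      if (k <= sizes[i]) { blocks[[i]][k] <- stream[pos]; pos <- pos + 1L }
    }
  }
  ec_blocks <- lapply(seq_len(nb), function(i) integer(bs$ec_per_block))
  for (k in seq_len(bs$ec_per_block)) {
    for (i in seq_len(nb)) { ec_blocks[[i]][k] <- stream[pos]; pos <- pos + 1L }
  }
  data_bytes <- integer(0)
  for (i in seq_len(nb)) {
    corrected <- rs_correct(c(blocks[[i]], ec_blocks[[i]]), bs$ec_per_block)
    data_bytes <- c(data_bytes, corrected[seq_len(sizes[i])])
  }
  payload <- .parse_data_bits(data_bytes, version)
  c(payload, list(version = version, ec_level = fmt$ec_level,
                  mask_id = fmt$mask_id))
}

# parse the data bitstream: segments until terminator or exhaustion
.parse_data_bits <- function(bytes, version) {
  bits <- integer(0)
  for (b in bytes) bits <- c(bits, bitwAnd(bitwShiftR(b, 7:0), 1L))
  take <- function(n) {
    if (pos + n - 1L > length(bits)) {
      stop(.qr_decode_error("bitstream ended mid-segment"))
    }
    v <- sum(bits[pos:(pos + n - 1L)] * 2L^((n - 1L):0L))
    pos <<- pos + n
    v
  }
  pos <- 1L
  out <- character(0)
  mode_used <- character(0)
  repeat {
    if (pos + 3L > length(bits)) break
    ind <- take(4L)
    if (ind == 0L) break                       # terminator
    mode <- names(.qr_modes)[match(ind, .qr_modes)]
    if (is.na(mode)) stop(.qr_decode_error(sprintf("unsupported mode indicator %d", ind)))
    n <- take(.qr_cci_bits(version, mode))
    if (mode == "numeric") {
      digits <- character(0)
      left <- n
      while (left >= 3L) { digits <- c(digits, sprintf("%03d", take(10L))); left <- left - 3L }
      if (left == 2L) digits <- c(digits, sprintf("%02d", take(7L)))
      if (left == 1L) digits <- c(digits, sprintf("%d", take(4L)))
      out <- c(out, paste(digits, collapse = ""))
    } else if (mode == "alphanumeric") {
      chars <- character(0)
      left <- n
      while (left >= 2L) {
        v <- take(11L)
        chars <- c(chars, .qr_alnum[v %/% 45L + 1L], .qr_alnum[v %% 45L + 1L])
        left <- left - 2L
      }
      if (left == 1L) chars <- c(chars, .qr_alnum[take(6L) + 1L])
      out <- c(out, paste(chars, collapse = ""))
    } else {
      raw_bytes <- vapply(seq_len(n), function(i) take(8L), 0)
      out <- c(out, rawToChar(as.raw(raw_bytes)))
    }
    mode_used <- c(mode_used, mode)
  }
  list(payload = paste(out, collapse = ""),
       mode = if (length(mode_used) == 1L) mode_used else mode_used)
}
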