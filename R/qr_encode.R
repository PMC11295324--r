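# QR symbol encoder: payload -> bitstream -> Reed-Solomon blocks ->
# module matrix with mask selection, format and version information.
# Where the six-step generation procedure defers to "the QR code
# standard", ISO/IEC 18004 conventions are normative (capacity tables,
# block structure, mask formulas, placement order).

.qr_modes <- c(numeric = 1L, alphanumeric = 2L, byte = 4L)

#' Auto-select the densest encoding mode for a payload
#' @param content character scalar.
#' @return `"numeric"`, `"alphanumeric"` or `"byte"`.
#' @export
qr_detect_mode <- function(content) {
  if (grepl("^[0-9]+$", content)) return("numeric")
  chars <- strsplit(content, "", fixed = TRUE)[[1]]
  if (all(chars %in% .qr_alnum)) return("alphanumeric")
  "byte"
}

# append `width` bits of integer `value` (MSB first) to a bit vector
.append_bits <- function(bits, value, width) {
  c(bits, as.integer(bitwAnd(bitwShiftR(as.integer(value), (width - 1L):0L), 1L)))
}

#' Encode a payload into the padded data bitstream
#'
#' Mode indicator, character-count indicator (width depends on the
#' version class), mode-specific data bits, terminator (up to 4 zero
#' bits), zero padding to a byte boundary, then alternating pad bytes
#' 0xEC / 0x11 up to the data capacity of `(version, ec_level)`.
#'
#' @param content character payload (length >= 1).
#' @param version symbol version.
#' @param ec_level error-correction level.
#' @param mode encoding mode; default auto-detected.
#' @return integer 0/1 vector of exactly `8 * data_codewords` bits.
#' @export
encode_payload_bits <- function(content, version, ec_level,
                                mode = qr_detect_mode(content)) {
  stopifnot(is.character(content), length(content) == 1L, nchar(content) >= 1L)
  n <- nchar(content)
  if (n > qr_capacity(version, ec_level, mode)) {
    stop(sprintf(
      "payload (%d %s chars) exceeds capacity of version %d-%s; smallest sufficient version is %d",
      n, mode, version, ec_level, .qr_pick_version(n, mode, ec_level)),
      call. = FALSE)
  }
  bits <- integer(0)
  bits <- .append_bits(bits, .qr_modes[[mode]], 4L)
  bits <- .append_bits(bits, n, .qr_cci_bits(version, mode))
  if (mode == "numeric") {
    digits <- as.integer(strsplit(content, "", fixed = TRUE)[[1]])
    i <- 1L
    while (i <= n) {
      grp <- digits[i:min(i + 2L, n)]
      val <- sum(grp * 10^(rev(seq_along(grp)) - 1L))
      bits <- .append_bits(bits, val, c(4L, 7L, 10L)[length(grp)])
      i <- i + 3L
    }
  } else if (mode == "alphanumeric") {
    vals <- match(strsplit(content, "", fixed = TRUE)[[1]], .qr_alnum) - 1L
    i <- 1L
    while (i <= n) {
      if (i + 1L <= n) {
        bits <- .append_bits(bits, vals[i] * 45L + vals[i + 1L], 11L)
        i <- i + 2L
      } else {
        bits <- .append_bits(bits, vals[i], 6L)
        i <- i + 1L
      }
    }
  } else {
    for (b in as.integer(charToRaw(content))) bits <- .append_bits(bits, b, 8L)
  }
  cap_bits <- 8L * qr_block_structure(version, ec_level)$data_codewords
  stopifnot(length(bits) <= cap_bits)
  bits <- c(bits, integer(min(4L, cap_bits - length(bits))))   # terminator
  if (length(bits) %% 8L != 0L) {
    bits <- c(bits, integer(8L - length(bits) %% 8L))          # byte align
  }
  pad <- c(0xECL, 0x11L); k <- 1L
  while (length(bits) < cap_bits) {
    bits <- .append_bits(bits, pad[k], 8L)
    k <- 3L - k
  }
  bits
}

.bits_to_bytes <- function(bits) {
  stopifnot(length(bits) %% 8L == 0L)
  m <- matrix(bits, nrow = 8L)
  as.integer(colSums(m * 2L^(7:0)))
}

# split data codewords into RS blocks, compute EC, interleave
.qr_codeword_stream <- function(data_bytes, version, ec_level) {
  bs <- qr_block_structure(version, ec_level)
  stopifnot(length(data_bytes) == bs$data_codewords)
  blocks <- vector("list", bs$n_blocks)
  pos <- 1L
  for (i in seq_len(bs$n_blocks)) {
    sz <- bs$block_data_sizes[i]
    blocks[[i]] <- data_bytes[pos:(pos + sz - 1L)]
    pos <- pos + sz
  }
  ec_blocks <- lapply(blocks, rs_ec_codewords, n_ec = bs$ec_per_block)
  inter <- integer(0)
  for (k in seq_len(max(bs$block_data_sizes))) {
    for (i in seq_len(bs$n_blocks)) {
      if (k <= length(blocks[[i]])) inter <- c(inter, blocks[[i]][k])
    }
  }
  for (k in seq_len(bs$ec_per_block)) {
    for (i in seq_len(bs$n_blocks)) inter <- c(inter, ec_blocks[[i]][k])
  }
  inter
}

# block id of each byte of the interleaved codeword stream (data then
# EC); used by the error-injection harnesses
stream_block_map <- function(version, ec_level) {
  bs <- qr_block_structure(version, ec_level)
  map <- integer(0)
  for (k in seq_len(max(bs$block_data_sizes))) {
    for (i in seq_len(bs$n_blocks)) {
      if (k <= bs$block_data_sizes[i]) map <- c(map, i)
    }
  }
  for (k in seq_len(bs$ec_per_block)) map <- c(map, seq_len(bs$n_blocks))
  map
}

# zig-zag traversal order of data modules: matrix of 1-based (row, col)
.qr_placement_order <- function(tpl) {
  side <- tpl$side
  res <- tpl$reserved
  ord <- matrix(0L, sum(!res), 2L)
  k <- 0L
  col <- side                      # 1-based right column of the pair
  upward <- TRUE
  while (col >= 1L) {
    if (col == 7L) col <- 6L       # skip the timing column (0-based 6)
    rows <- if (upward) side:1L else 1L:side
    for (r in rows) {
      for (c in c(col, col - 1L)) {
        if (c >= 1L && !res[r, c]) {
          k <- k + 1L
          ord[k, ] <- c(r, c)
        }
      }
    }
    upward <- !upward
    col <- col - 2L
  }
  stopifnot(k == nrow(ord))
  ord
}

# mask predicate, 0-based row i / col j, mask ids 0..7
.qr_mask_bit <- function(id, i, j) {
  switch(id + 1L,
    (i + j) %% 2L == 0L,
    i %% 2L == 0L,
    j %% 3L == 0L,
    (i + j) %% 3L == 0L,
    (i %/% 2L + j %/% 3L) %% 2L == 0L,
    (i * j) %% 2L + (i * j) %% 3L == 0L,
    ((i * j) %% 2L + (i * j) %% 3L) %% 2L == 0L,
    ((i + j) %% 2L + (i * j) %% 3L) %% 2L == 0L)
}

.qr_mask_matrix <- function(id, side) {
  i <- matrix(0L:(side - 1L), side, side)
  j <- t(i)
  m <- .qr_mask_bit(id, i, j)
  storage.mode(m) <- "integer"
  m
}

#' Mask penalty score of a module matrix
#'
#' The four standard rules: same-color runs of length >= 5 in rows and
#' columns (3 + excess each); 2x2 same-color blocks (3 each); finder-like
#' 1:1:3:1:1 sequences flanked by 4 light modules, in rows and columns
#' (40 each); and deviation of the dark-module proportion from 50%
#' (10 per 5% step).
#'
#' @param m 0/1 module matrix (1 = dark).
#' @return integer penalty.
#' @export
qr_penalty <- function(m) {
  side <- nrow(m)
  storage.mode(m) <- "integer"
  # every row and column as a 0/1 string; maximal same-color runs and the
  # two finder-like patterns cannot self-overlap, so regex counts are exact
  lines <- c(do.call(paste0, as.data.frame(m)),
             do.call(paste0, as.data.frame(t(m))))
  runs <- gregexpr("1{5,}|0{5,}", lines)
  pen <- sum(vapply(runs, function(r) {
    if (r[1L] == -1L) return(0L)
    sum(attr(r, "match.length") - 2L)       # 3 + (len - 5) per run
  }, 0L))
  # 2x2 same-color blocks
  a <- m[-side, -side]; b <- m[-side, -1]; cc <- m[-1, -side]; d <- m[-1, -1]
  pen <- pen + 3L * sum(a == b & b == cc & cc == d)
  # finder-like 1:1:3:1:1 with 4-module light flank
  n3 <- 0L
  for (pat in c("10111010000", "00001011101")) {
    hits <- gregexpr(pat, lines, fixed = TRUE)
    n3 <- n3 + sum(vapply(hits, function(r) if (r[1L] == -1L) 0L else length(r), 0L))
  }
  pen <- pen + 40L * n3
  # dark-module proportion
  pct <- 100 * sum(m) / length(m)
  pen + 10L * as.integer(abs(pct - 50) %/% 5)
}

# 15-bit format word for (ec_level, mask): BCH(15,5), generator 0x537,
# XOR mask 0x5412; returned as bits 0..14, LSB first
.qr_format_bits <- function(ec_level, mask_id) {
  ec_bits <- c(L = 1L, M = 0L, Q = 3L, H = 2L)[[ec_level]]
  data <- bitwOr(bitwShiftL(ec_bits, 3L), mask_id)
  rem <- data
  for (i in 1:10) {
    rem <- bitwShiftL(rem, 1L)
    if (bitwAnd(rem, 0x400L) != 0L) rem <- bitwXor(rem, 0x537L)
  }
  word <- bitwXor(bitwOr(bitwShiftL(data, 10L), rem), 0x5412L)
  bitwAnd(bitwShiftR(word, 0:14), 1L)
}

# 18-bit version word: BCH(18,6), generator 0x1F25; bits 0..17 LSB first
.qr_version_bits <- function(version) {
  rem <- version
  for (i in 1:12) {
    rem <- bitwShiftL(rem, 1L)
    if (bitwAnd(rem, 0x1000L) != 0L) rem <- bitwXor(rem, 0x1F25L)
  }
  word <- bitwOr(bitwShiftL(version, 12L), rem)
  bitwAnd(bitwShiftR(word, 0:17), 1L)
}

#' Build a complete QR symbol from a payload
#'
#' Runs the full generation procedure: bitstream encoding,
#' Reed-Solomon block coding and interleaving, zig-zag placement, trial
#' of all eight masks scored by [qr_penalty()] (lowest penalty wins,
#' ties to the lowest mask id), then embedding of the BCH-protected
#' format word and, for version >= 7, the version word.
#'
#' @param content character payload.
#' @param ec_level `"L"`, `"M"`, `"Q"` or `"H"`.
#' @param version symbol version; `NULL` picks the smallest that fits.
#' @param mode encoding mode; default auto-detected.
#' @return object of class `qr_symbol`: list with `matrix` (0/1, 1 =
#'   dark), `version`, `ec_level`, `mask_id`, `mode`, `side`.
#' @export
build_symbol <- function(content, ec_level = "M", version = NULL,
                         mode = qr_detect_mode(content)) {
  stopifnot(ec_level %in% c("L", "M", "Q", "H"))
  if (is.null(version)) version <- .qr_pick_version(nchar(content), mode, ec_level)
  bits <- encode_payload_bits(content, version, ec_level, mode)
  stream <- .qr_codeword_stream(.bits_to_bytes(bits), version, ec_level)
  tpl <- .qr_template(version)
  side <- tpl$side
  lay <- qr_layout(version)
  data_bits <- integer(0)
  for (b in stream) data_bits <- .append_bits(data_bits, b, 8L)
  data_bits <- c(data_bits, integer(lay$remainder_bits))
  ord <- .qr_placement_order(tpl)
  stopifnot(nrow(ord) == length(data_bits))

  base <- tpl$dark
  base[ord] <- data_bits
  data_mask <- matrix(FALSE, side, side)
  data_mask[ord] <- TRUE

  best <- NULL
  for (id in 0:7) {
    mm <- .qr_mask_matrix(id, side)
    cand <- base
    cand[data_mask] <- bitwXor(cand[data_mask], mm[data_mask])
    cand <- .qr_write_info(cand, version, ec_level, id, side)
    p <- qr_penalty(cand)
    if (is.null(best) || p < best$penalty) {
      best <- list(matrix = cand, penalty = p, mask_id = id)
    }
  }
  structure(list(matrix = best$matrix, version = version, ec_level = ec_level,
                 mask_id = best$mask_id, mode = mode, side = side,
                 penalty = best$penalty),
            class = "qr_symbol")
}

# write format (and version) information into a module matrix
.qr_write_info <- function(m, version, ec_level, mask_id, side) {
  fb <- .qr_format_bits(ec_level, mask_id)
  fp <- .qr_format_positions(side)
  m[fp$a] <- fb
  m[fp$b] <- fb
  if (version >= 7) {
    vb <- .qr_version_bits(version)
    vp <- .qr_version_positions(side)
    m[vp$tr] <- vb
    m[vp$bl] <- vb
  }
  m
}

#' @export
print.qr_symbol <- function(x, ...) {
  cat(sprintf("QR symbol: version %d-%s, mask %d, %dx%d modules, mode %s\n",
              x$version, x$ec_level, x$mask_id, x$side, x$side, x$mode))
  invisible(x)
}

#' Render a QR symbol to a raster image
#'
#' Dark modules map to intensity 0 (black), light to 1 (white), with a
#' light quiet zone of at least 4 modules on all four sides.
#'
#' @param symbol a `qr_symbol`.
#' @param module_size pixels per module (>= 1).
#' @param quiet_zone quiet-zone width in modules (>= 4 by default).
#' @return numeric matrix in \[0, 1\] of side
#'   `(side + 2 * quiet_zone) * module_size`.
#' @export
render_symbol <- function(symbol, module_size = 4L, quiet_zone = 4L) {
  stopifnot(inherits(symbol, "qr_symbol"), module_size >= 1, quiet_zone >= 0)
  m <- symbol$matrix
  side <- symbol$side
  full <- matrix(0L, side + 2L * quiet_zone, side + 2L * quiet_zone)
  full[quiet_zone + seq_len(side), quiet_zone + seq_len(side)] <- m
  big <- full[rep(seq_len(nrow(full)), each = module_size),
              rep(seq_len(ncol(full)), each = module_size)]
  1 - big  # dark module -> 0 intensity
}
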