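# Symbol-structure tables.  Error-correction block structure ships as a
# documented CSV (one row per version x level: EC codewords per block and
# number of blocks); the group-1/group-2 split and all capacities are
# derived arithmetically from the module layout, never transcribed.

.qr_cache <- new.env(parent = emptyenv())

.qr_ec_table <- function() {
  if (is.null(.qr_cache$ec)) {
    path <- system.file("extdata", "qr_ec_blocks.csv", package = "qrstore")
    if (path == "") path <- file.path("inst", "extdata", "qr_ec_blocks.csv")
    .qr_cache$ec <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .qr_cache$ec
}

# alignment pattern centre coordinates (0-based), per version
.qr_alignment <- list(
  NULL, c(6, 18), c(6, 22), c(6, 26), c(6, 30), c(6, 34),
  c(6, 22, 38), c(6, 24, 42), c(6, 26, 46), c(6, 28, 50), c(6, 30, 54),
  c(6, 32, 58), c(6, 34, 62), c(6, 26, 46, 66), c(6, 26, 48, 70),
  c(6, 26, 50, 74), c(6, 30, 54, 78), c(6, 30, 56, 82), c(6, 30, 58, 86),
  c(6, 34, 62, 90), c(6, 28, 50, 72, 94), c(6, 26, 50, 74, 98),
  c(6, 30, 54, 78, 102), c(6, 28, 54, 80, 106), c(6, 32, 58, 84, 110),
  c(6, 30, 58, 86, 114), c(6, 34, 62, 90, 118), c(6, 26, 50, 74, 98, 122),
  c(6, 30, 54, 78, 102, 126), c(6, 26, 52, 78, 104, 130),
  c(6, 30, 56, 82, 108, 134), c(6, 34, 60, 86, 112, 138),
  c(6, 30, 58, 86, 114, 142), c(6, 34, 62, 90, 118, 146),
  c(6, 30, 54, 78, 102, 126, 150), c(6, 24, 50, 76, 102, 128, 154),
  c(6, 28, 54, 80, 106, 132, 158), c(6, 32, 58, 84, 110, 136, 162),
  c(6, 26, 54, 82, 110, 138, 166), c(6, 30, 58, 86, 114, 142, 170))

#' Side length of a QR symbol in modules
#' @param version symbol version 1..40.
#' @return integer side length `17 + 4 * version`.
#' @export
qr_side <- function(version) {
  stopifnot(version >= 1, version <= 40)
  17L + 4L * as.integer(version)
}

# function-pattern template: list(dark = 0/1 matrix, reserved = logical)
# with finders, separators, timing, alignment, dark module and the
# format/version areas reserved (format/version bits filled in later)
.qr_template <- function(version) {
  key <- as.character(version)
  if (!is.null(.qr_cache[[paste0("tpl", key)]])) {
    return(.qr_cache[[paste0("tpl", key)]])
  }
  side <- qr_side(version)
  dark <- matrix(0L, side, side)
  res <- matrix(FALSE, side, side)
  put <- function(r0, c0, pat) {      # r0, c0: 0-based top-left
    rr <- r0 + seq_len(nrow(pat)); cc <- c0 + seq_len(ncol(pat))
    dark[rr, cc] <<- pat
    res[rr, cc] <<- TRUE
  }
  finder <- matrix(1L, 7, 7)
  finder[2:6, 2:6] <- 0L
  finder[3:5, 3:5] <- 1L
  put(0L, 0L, finder); put(0L, side - 7L, finder); put(side - 7L, 0L, finder)
  # separators (light, one module, inside symbol)
  res[1:8, 8] <- TRUE; res[8, 1:8] <- TRUE
  res[1:8, side - 7L] <- TRUE; res[8, (side - 7L):side] <- TRUE
  res[side - 7L, 1:8] <- TRUE; res[(side - 7L):side, 8] <- TRUE
  # timing patterns (0-based row/col 6): dark at even coordinates
  tcols <- 8L:(side - 9L)             # 0-based
  dark[7L, tcols + 1L] <- as.integer(tcols %% 2L == 0L)
  res[7L, tcols + 1L] <- TRUE
  dark[tcols + 1L, 7L] <- as.integer(tcols %% 2L == 0L)
  res[tcols + 1L, 7L] <- TRUE
  # alignment patterns
  if (version >= 2) {
    ap <- matrix(1L, 5, 5); ap[2:4, 2:4] <- 0L; ap[3, 3] <- 1L
    centres <- .qr_alignment[[version]]
    for (r in centres) for (c in centres) {
      skip <- (r == 6 && c == 6) || (r == 6 && c == side - 7L) ||
        (r == side - 7L && c == 6)
      if (!skip) put(r - 2L, c - 2L, ap)
    }
  }
  # dark module
  dark[side - 7L, 9L] <- 1L; res[side - 7L, 9L] <- TRUE
  # reserve format information areas
  fmt <- .qr_format_positions(side)
  for (k in seq_len(nrow(fmt$a))) res[fmt$a[k, 1], fmt$a[k, 2]] <- TRUE
  for (k in seq_len(nrow(fmt$b))) res[fmt$b[k, 1], fmt$b[k, 2]] <- TRUE
  # reserve version information areas
  if (version >= 7) {
    vp <- .qr_version_positions(side)
    for (k in seq_len(nrow(vp$tr))) res[vp$tr[k, 1], vp$tr[k, 2]] <- TRUE
    for (k in seq_len(nrow(vp$bl))) res[vp$bl[k, 1], vp$bl[k, 2]] <- TRUE
  }
  out <- list(dark = dark, reserved = res, side = side)
  .qr_cache[[paste0("tpl", key)]] <- out
  out
}

# 1-based (row, col) positions of format bits 0..14 (LSB first), both copies
.qr_format_positions <- function(side) {
  a <- rbind(cbind(1:6, 9L),            # bits 0..5
             c(8L, 9L),                 # bit 6
             c(9L, 9L),                 # bit 7
             c(9L, 8L),                 # bit 8
             cbind(9L, 6:1))            # bits 9..14
  b <- rbind(cbind(9L, side - (0:7)),        # bits 0..7
             cbind(side - 14L + (8:14), 9L)) # bits 8..14 at rows side-6..side
  list(a = a, b = b)
}

# 1-based positions of version bits 0..17 (LSB first): top-right then
# bottom-left copy
.qr_version_positions <- function(side) {
  i <- 0:17
  tr <- cbind(i %/% 3L + 1L, side - 10L + i %% 3L)
  bl <- cbind(side - 10L + i %% 3L, i %/% 3L + 1L)
  list(tr = tr, bl = bl)
}

#' Codeword layout of a QR version
#'
#' Counts data modules from the actual function-pattern template: total
#' codewords are `floor(bits / 8)` with `bits %% 8` remainder bits.
#'
#' @param version symbol version.
#' @return list with `total_codewords`, `remainder_bits`, `side`.
#' @export
qr_layout <- function(version) {
  tpl <- .qr_template(version)
  bits <- sum(!tpl$reserved)
  list(total_codewords = bits %/% 8L, remainder_bits = bits %% 8L,
       side = tpl$side)
}

#' Error-correction block structure for (version, level)
#'
#' @param version symbol version 1..40.
#' @param ec_level `"L"`, `"M"`, `"Q"` or `"H"`.
#' @return list: `ec_per_block`, `n_blocks`, `data_codewords` (total),
#'   `block_data_sizes` (per-block data codeword counts, group 1 then
#'   group 2), `total_codewords`.
#' @export
qr_block_structure <- function(version, ec_level) {
  tab <- .qr_ec_table()
  row <- tab[tab$version == version & tab$level == ec_level, ]
  if (nrow(row) != 1L) stop("unknown (version, ec_level)", call. = FALSE)
  total <- qr_layout(version)$total_codewords
  ec <- row$ec_per_block; nb <- row$n_blocks
  dc_total <- total - ec * nb
  g1 <- dc_total %/% nb
  n_g2 <- dc_total %% nb
  sizes <- c(rep(g1, nb - n_g2), rep(g1 + 1L, n_g2))
  list(ec_per_block = ec, n_blocks = nb, data_codewords = dc_total,
       block_data_sizes = sizes, total_codewords = total)
}

# character-count-indicator width per version class and mode
.qr_cci_bits <- function(version, mode) {
  cls <- if (version <= 9) 1L else if (version <= 26) 2L else 3L
  switch(mode,
    numeric = c(10L, 12L, 14L)[cls],
    alphanumeric = c(9L, 11L, 13L)[cls],
    byte = c(8L, 16L, 16L)[cls],
    stop("unknown mode", call. = FALSE))
}

# number of data bits for a payload of n characters in a mode
.qr_data_bits <- function(n, mode) {
  switch(mode,
    numeric = 10L * (n %/% 3L) + c(0L, 4L, 7L)[n %% 3L + 1L],
    alphanumeric = 11L * (n %/% 2L) + 6L * (n %% 2L),
    byte = 8L * n)
}

#' Character capacity of a (version, ec_level, mode) combination
#' @param version symbol version.
#' @param ec_level error-correction level.
#' @param mode `"numeric"`, `"alphanumeric"` or `"byte"`.
#' @return maximum number of payload characters.
#' @export
qr_capacity <- function(version, ec_level, mode) {
  bs <- qr_block_structure(version, ec_level)
  avail <- 8L * bs$data_codewords - 4L - .qr_cci_bits(version, mode)
  if (avail <= 0) return(0L)
  switch(mode,
    numeric = {
      full <- (avail %/% 10L) * 3L
      rem <- avail %% 10L
      full + if (rem >= 7L) 2L else if (rem >= 4L) 1L else 0L
    },
    alphanumeric = {
      full <- (avail %/% 11L) * 2L
      full + if (avail %% 11L >= 6L) 1L else 0L
    },
    byte = avail %/% 8L)
}

# smallest version whose capacity fits n characters of the mode
.qr_pick_version <- function(n, mode, ec_level) {
  for (v in 1:40) {
    if (qr_capacity(v, ec_level, mode) >= n) return(v)
  }
  stop(sprintf("payload of %d %s characters exceeds version-40 capacity at level %s",
               n, mode, ec_level), call. = FALSE)
}
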