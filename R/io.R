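#' Read and write portable graymap (PGM) images
#'
#' The package stores every raster artifact — phantom images, segmentation
#' masks, rendered QR symbols — as 8-bit PGM.  PGM is lossless, text-
#' representable (P2) and read by essentially every imaging stack.
#' Internally images are real-valued matrices in \[0, 1\], row-major with
#' the origin at the top-left.
#'
#' @param path file path.
#' @param image numeric matrix in \[0, 1\].
#' @param ascii write the plain-text P2 dialect (default) rather than
#'   binary P5.
#' @param maxval maximum gray value (255 for 8-bit).
#' @return `read_pgm` returns a numeric matrix in \[0, 1\];
#'   `write_pgm` returns `path` invisibly.
#' @name pgm_io
NULL

#' @rdname pgm_io
#' @export
write_pgm <- function(image, path, ascii = TRUE, maxval = 255L) {
  .check_image(image)
  q <- round(image * maxval)
  if (ascii) {
    con <- file(path, "wb")  # binary mode keeps newlines deterministic
    on.exit(close(con))
    writeLines(c("P2",
                 paste(ncol(image), nrow(image)),
                 as.character(maxval)), con, sep = "\n")
    # one image row per line, pixels left-to-right
    rows <- apply(q, 1L, paste, collapse = " ")
    writeLines(rows, con, sep = "\n")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5",
                 paste(ncol(image), nrow(image)),
                 as.character(maxval)), con, sep = "\n")
    writeBin(as.raw(t(q)), con)
  }
  invisible(path)
}

#' @rdname pgm_io
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (P2/P5): ", path, call. = FALSE)
  }
  # header tokens: width height maxval, '#' comments allowed
  tok <- character(0)
  buf <- character(0)
  while (length(tok) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header: ", path, call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tok <- c(tok, paste(buf, collapse = "")); buf <- character(0) }
    } else {
      buf <- c(buf, ch)
    }
  }
  dims <- as.integer(tok)
  width <- dims[1L]; height <- dims[2L]; maxval <- dims[3L]
  n <- width * height
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("truncated PGM payload: ", path, call. = FALSE)
  matrix(vals, nrow = height, ncol = width, byrow = TRUE) / maxval
}
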