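# Arithmetic over GF(2^8) with primitive polynomial 0x11D
# (x^8 + x^4 + x^3 + x^2 + 1), the field used by QR Reed-Solomon codes.
# Elements are integers 0..255; alpha = 2 generates the multiplicative
# group.  Log/antilog tables are built once at load.

.gf <- new.env(parent = emptyenv())

.gf_init <- function() {
  exp <- integer(512)
  log <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1L] <- x
    log[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 0x11DL)
  }
  exp[256:512] <- exp[1:257]  # wraparound so exp[(a+b) mod 255] is index-safe
  assign("exp", exp, envir = .gf)
  assign("log", log, envir = .gf)
}

#' Multiply two elements of GF(256)
#' @param a,b integers in 0..255 (vectorized).
#' @return integer vector of products.
#' @export
gf_mul <- function(a, b) {
  out <- integer(max(length(a), length(b)))
  a <- rep_len(as.integer(a), length(out)); b <- rep_len(as.integer(b), length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- .gf$exp[((.gf$log[a[nz] + 1L] + .gf$log[b[nz] + 1L]) %% 255L) + 1L]
  out
}

#' Multiplicative inverse in GF(256)
#' @param a nonzero element.
#' @return integer inverse.
#' @export
gf_inv <- function(a) {
  a <- as.integer(a)
  if (any(a == 0L)) stop("zero has no inverse in GF(256)", call. = FALSE)
  .gf$exp[((255L - .gf$log[a + 1L]) %% 255L) + 1L]
}

#' Power of the generator alpha = 2
#' @param n exponent (any integer).
#' @return `alpha^n` as an integer in 1..255.
#' @export
gf_pow <- function(n) .gf$exp[(as.integer(n) %% 255L) + 1L]

# polynomial helpers; coefficient vectors are highest-degree first
.gf_poly_mul <- function(p, q) {
  out <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    prod <- gf_mul(p[i], q)
    idx <- seq(i, i + length(q) - 1L)
    out[idx] <- bitwXor(out[idx], prod)
  }
  out
}

.gf_poly_eval <- function(p, x) {          # Horner, highest degree first
  acc <- 0L
  for (coef in p) acc <- bitwXor(gf_mul(acc, x), as.integer(coef))
  acc
}

#' Reed-Solomon generator polynomial of degree `n_ec`
#'
#' Product of `(x - alpha^0)(x - alpha^1)...(x - alpha^(n_ec-1))` over
#' GF(256).  Returned highest-degree coefficient first (leading 1).
#'
#' @param n_ec number of error-correction codewords (>= 1).
#' @return integer coefficient vector of length `n_ec + 1`.
#' @export
rs_generator_poly <- function(n_ec) {
  stopifnot(n_ec >= 1)
  g <- 1L
  for (i in 0:(n_ec - 1L)) g <- .gf_poly_mul(g, c(1L, gf_pow(i)))
  g
}

#' Reed-Solomon error-correction codewords
#'
#' Remainder of `data(x) * x^n_ec` divided by the degree-`n_ec`
#' generator polynomial; appending the result to `data` yields a
#' codeword divisible by the generator (zero at alpha^0..alpha^(n_ec-1)).
#'
#' @param data integer vector of data codewords (0..255).
#' @param n_ec number of EC codewords (>= 1).
#' @return integer vector of `n_ec` EC codewords.
#' @export
rs_ec_codewords <- function(data, n_ec) {
  stopifnot(n_ec >= 1)
  data <- as.integer(data)
  gen <- rs_generator_poly(n_ec)[-1L]  # drop leading 1
  rem <- integer(n_ec)
  for (d in data) {
    factor <- bitwXor(rem[1L], d)
    rem <- c(rem[-1L], 0L)
    if (factor != 0L) rem <- bitwXor(rem, gf_mul(factor, gen))
  }
  rem
}

#' Correct a Reed-Solomon codeword in place
#'
#' Computes syndromes, runs Berlekamp-Massey for the error locator,
#' finds error positions by Chien search and solves for magnitudes via
#' the syndrome Vandermonde system.  Fails (signalling condition class
#' `qr_decode_error`) when the error count exceeds `floor(n_ec/2)` or
#' the locator is inconsistent.
#'
#' @param codeword integer vector: data codewords followed by `n_ec` EC
#'   codewords.
#' @param n_ec number of EC codewords.
#' @return the corrected codeword (full length, including EC bytes).
#' @export
rs_correct <- function(codeword, n_ec) {
  cw <- as.integer(codeword)
  n <- length(cw)
  synd <- vapply(0:(n_ec - 1L), function(j) .gf_poly_eval(cw, gf_pow(j)), 0L)
  if (all(synd == 0L)) return(cw)

  # Berlekamp-Massey: sigma in ascending order (sigma[1] = constant 1)
  sigma <- c(1L); B <- c(1L); L <- 0L; m <- 1L; b <- 1L
  for (r in seq_len(n_ec)) {
    d <- synd[r]
    if (L >= 1L) {
      for (i in seq_len(min(L, length(sigma) - 1L))) {
        d <- bitwXor(d, gf_mul(sigma[i + 1L], synd[r - i]))
      }
    }
    if (d == 0L) {
      m <- m + 1L
    } else if (2L * L <= r - 1L) {
      Tp <- sigma
      coef <- gf_mul(d, gf_inv(b))
      shiftB <- c(integer(m), B)
      len <- max(length(sigma), length(shiftB))
      sigma <- bitwXor(c(sigma, integer(len - length(sigma))),
                       gf_mul(coef, c(shiftB, integer(len - length(shiftB)))))
      L <- r - L; B <- Tp; b <- d; m <- 1L
    } else {
      coef <- gf_mul(d, gf_inv(b))
      shiftB <- c(integer(m), B)
      len <- max(length(sigma), length(shiftB))
      sigma <- bitwXor(c(sigma, integer(len - length(sigma))),
                       gf_mul(coef, c(shiftB, integer(len - length(shiftB)))))
      m <- m + 1L
    }
  }
  while (length(sigma) > 1L && sigma[length(sigma)] == 0L) {
    sigma <- sigma[-length(sigma)]
  }
  nu <- length(sigma) - 1L
  if (nu == 0L || nu > n_ec %/% 2L) {
    stop(.qr_decode_error("uncorrectable block: error count exceeds capacity"))
  }
  # Chien search: byte position k (1-based from start) has locator
  # X = alpha^(n - k); sigma has roots at X^{-1}
  sigma_desc <- rev(sigma)
  positions <- integer(0)
  Xs <- integer(0)
  for (k in seq_len(n)) {
    X <- gf_pow(n - k)
    if (.gf_poly_eval(sigma_desc, gf_inv(X)) == 0L) {
      positions <- c(positions, k)
      Xs <- c(Xs, X)
    }
  }
  if (length(positions) != nu) {
    stop(.qr_decode_error("uncorrectable block: locator roots inconsistent"))
  }
  # magnitudes from S_j = sum_i e_i X_i^j, j = 0..nu-1 (Vandermonde solve)
  A <- matrix(0L, nu, nu)
  for (j in seq_len(nu)) A[j, ] <- vapply(Xs, function(x) gf_pow((j - 1L) * .gf$log[x + 1L]), 0L)
  e <- .gf_solve(A, synd[seq_len(nu)])
  if (is.null(e)) {
    stop(.qr_decode_error("uncorrectable block: singular magnitude system"))
  }
  cw[positions] <- bitwXor(cw[positions], e)
  synd2 <- vapply(0:(n_ec - 1L), function(j) .gf_poly_eval(cw, gf_pow(j)), 0L)
  if (any(synd2 != 0L)) {
    stop(.qr_decode_error("uncorrectable block: residual syndromes after correction"))
  }
  cw
}

# Gaussian elimination over GF(256); returns NULL if singular
.gf_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (col in seq_len(n)) {
    piv <- which(M[col:n, col] != 0L)
    if (!length(piv)) return(NULL)
    piv <- piv[1L] + col - 1L
    if (piv != col) M[c(col, piv), ] <- M[c(piv, col), ]
    inv <- gf_inv(M[col, col])
    M[col, ] <- gf_mul(M[col, ], inv)
    for (r in seq_len(n)) {
      if (r != col && M[r, col] != 0L) {
        M[r, ] <- bitwXor(M[r, ], gf_mul(M[r, col], M[col, ]))
      }
    }
  }
  M[, n + 1L]
}

.qr_decode_error <- function(msg) {
  structure(class = c("qr_decode_error", "error", "condition"),
            list(message = msg, call = NULL))
}

.qr_not_found <- function(msg) {
  structure(class = c("qr_not_found", "qr_decode_error", "error", "condition"),
            list(message = msg, call = NULL))
}
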