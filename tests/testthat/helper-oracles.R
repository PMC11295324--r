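# Shared fixtures and *independent* oracles used across the suite.
# Oracles deliberately re-derive quantities by brute force / first
# principles, never by calling the code paths they check.

rand_simplex <- function(d) {
  x <- stats::rexp(d)
  x / sum(x)
}

# connected-component count by union-find over 4-neighbour edges
# (independent of the package's BFS labelling)
cc_count_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  parent <- as.numeric(seq_len(h * w))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  for (i in idx) {
    r <- ((i - 1) %% h) + 1; c <- ((i - 1) %/% h) + 1
    if (r < h && mask[r + 1, c]) union_(i, i + 1)
    if (c < w && mask[r, c + 1]) union_(i, i + h)
  }
  length(unique(vapply(idx, find, 0)))
}

# brute-force Otsu: sweep all 256 thresholds, maximize between-class
# variance computed straight from the definition
otsu_oracle <- function(img) {
  q <- pmin(floor(as.vector(img) * 256), 255)
  best_t <- 0; best_v <- -1
  for (t in 0:254) {
    lo <- q[q <= t]; hi <- q[q > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(q); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  (best_t + 0.5) / 256
}

# direct GLCM statistics at offset (0,1), symmetric, full mask
glcm_oracle <- function(img, bins) {
  q <- pmin(floor(img * bins), bins - 1) + 1
  counts <- matrix(0, bins, bins)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img) - 1)) {
      counts[q[r, c], q[r, c + 1]] <- counts[q[r, c], q[r, c + 1]] + 1
      counts[q[r, c + 1], q[r, c]] <- counts[q[r, c + 1], q[r, c]] + 1
    }
  }
  p <- counts / sum(counts)
  ii <- row(p); jj <- col(p)
  list(contrast = sum(p * (ii - jj)^2),
       homogeneity = sum(p / (1 + (ii - jj)^2)),
       energy = sum(p^2),
       entropy = -sum(ifelse(p > 0, p * log(p), 0)))
}

# schoolbook carry-less multiplication mod 0x11D (bit loops, no tables)
gf_schoolbook_mul <- function(a, b) {
  acc <- 0L
  aa <- as.integer(a)
  for (bit in 0:7) {
    if (bitwAnd(bitwShiftR(as.integer(b), bit), 1L) == 1L) {
      acc <- bitwXor(acc, bitwShiftL(aa, bit))
    }
  }
  for (bit in 15:8) {
    if (bitwAnd(bitwShiftR(acc, bit), 1L) == 1L) {
      acc <- bitwXor(acc, bitwShiftL(0x11DL, bit - 8L))
    }
  }
  acc
}

# BCH(15,5) format word by explicit GF(2) long division on bit vectors
bch_format_oracle <- function(ec_level, mask_id) {
  ec_bits <- c(L = 1L, M = 0L, Q = 3L, H = 2L)[[ec_level]]
  data5 <- c(bitwAnd(bitwShiftR(ec_bits, 1:0), 1L),
             bitwAnd(bitwShiftR(mask_id, 2:0), 1L))
  gen <- c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L)  # 0x537
  reg <- c(data5, integer(10))
  for (i in 1:5) {
    if (reg[i] == 1L) reg[i:(i + 10)] <- bitwXor(reg[i:(i + 10)], gen)
  }
  word15 <- c(data5, reg[6:15])
  # 0x5412 = 101 0100 0001 0010, MSB first
  xor_mask <- c(1L,0L,1L,0L,1L,0L,0L,0L,0L,0L,1L,0L,0L,1L,0L)
  bitwXor(word15, xor_mask)  # returned MSB first
}

# evaluate a GF(256) polynomial (highest degree first) via the package's
# public multiply only
gf_eval <- function(coefs, x) {
  acc <- 0L
  for (cf in coefs) acc <- bitwXor(gf_mul(acc, x), as.integer(cf))
  acc
}

# Dirichlet-family histogram clusters for the modified embedding mode
gen_dirichlet_clusters <- function(n_per, seed) {
  with_seed(seed, {
    alphas <- list(c(8, 2, 1, 1, 1, 1, 1, 1, 1, 1),
                   c(1, 1, 8, 2, 1, 1, 1, 1, 1, 1),
                   c(1, 1, 1, 1, 1, 8, 2, 1, 1, 1))
    X <- do.call(rbind, lapply(alphas, function(a) {
      g <- matrix(stats::rgamma(n_per * 10, shape = rep(a, each = n_per)),
                  n_per, 10)
      g / rowSums(g)
    }))
    list(matrix = X, labels = rep(1:3, each = n_per))
  })
}

# third-party decode via pyzbar (zbar): deliberately external to this
# package; errors when no independent decoder is installed
third_party_decode <- function(pgm_path) {
  script <- paste(
    "import sys",
    "from PIL import Image",
    "from pyzbar.pyzbar import decode",
    "res = decode(Image.open(sys.argv[1]).convert('L'))",
    "sys.stdout.write(res[0].data.decode('latin1') if len(res)==1 else '<FAIL>')",
    sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script), shQuote(pgm_path)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("no working third-party decoder (python + pyzbar): ",
         paste(out, collapse = " "))
  }
  paste(out, collapse = "\n")
}

# tiny embed config for fast unit tests
quick_cfg <- function(perplexity = 3, ...) {
  embed_config(perplexity = perplexity, max_iter = 120L,
               exaggeration_iter = 30L, momentum_switch = 60L, ...)
}

small_phantom <- function(seed = 1, noise = 0.02) {
  generate_phantom_image(phantom_spec(width = 48L, height = 48L, n_blobs = 2L,
                                      blob_radius_range = c(4, 6),
                                      noise_sigma = noise, seed = seed))
}
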