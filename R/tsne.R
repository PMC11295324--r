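#' Bhattacharyya coefficient and distance between two distributions
#'
#' For distributions P, Q over a finite sample space, the coefficient is
#' `BC = sum(sqrt(P * Q))` (overlap in \[0, 1\]) and the distance is
#' `D = -log(BC)`.  D is symmetric, zero iff P = Q and infinite for
#' disjoint supports; it does **not** satisfy the triangle inequality and
#' is not a Bregman divergence.
#'
#' @param p,q probability vectors of equal length (nonnegative, sum 1).
#' @return scalar coefficient in \[0, 1\] / distance in \[0, Inf\].
#' @export
bhattacharyya_coefficient <- function(p, q) {
  check_prob_vector(p, name = "p"); check_prob_vector(q, name = "q")
  if (length(p) != length(q)) stop("dimension mismatch", call. = FALSE)
  min(1, sum(sqrt(pmax(p, 0) * pmax(q, 0))))
}

#' @rdname bhattacharyya_coefficient
#' @export
bhattacharyya_distance <- function(p, q) {
  bc <- bhattacharyya_coefficient(p, q)
  if (bc <= 0) Inf else -log(bc)
}

#' Pairwise distance matrix under a chosen metric
#'
#' @param X numeric matrix, one observation per row.  For
#'   `metric = "bhattacharyya"` every row must be a probability vector
#'   (use [features_to_distribution()] upstream).
#' @param metric `"euclidean"` or `"bhattacharyya"`.
#' @return symmetric n x n matrix with zero diagonal (`Inf` allowed for
#'   disjoint-support pairs under the Bhattacharyya metric).
#' @export
pairwise_distances <- function(X, metric = c("euclidean", "bhattacharyya")) {
  metric <- match.arg(metric)
  if (inherits(X, "labeled_features")) X <- X$matrix
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(X))
    dimnames(D) <- NULL
    return(D)
  }
  for (i in seq_len(nrow(X))) check_prob_vector(X[i, ], name = sprintf("row %d", i))
  S <- sqrt(pmax(X, 0))
  BC <- pmin(S %*% t(S), 1)
  D <- -log(BC)           # Inf where BC == 0
  D[D < 0] <- 0
  D <- (D + t(D)) / 2     # exact symmetry despite FP rounding
  diag(D) <- 0
  D
}

# cap infinite (disjoint-support) distances so bandwidth bisection stays
# well-posed: 10x the largest finite distance
.cap_infinite <- function(D) {
  if (!any(is.infinite(D))) return(D)
  mx <- max(D[is.finite(D)], 0)
  D[is.infinite(D)] <- if (mx > 0) 10 * mx else 1
  D
}

#' Perplexity-calibrated conditional affinities
#'
#' Row i is `p(j|i) proportional to exp(-beta_i * D[i,j]^2)` with the
#' bandwidth `beta_i` found by bisection so that the row's perplexity
#' `2^H` (H, Shannon entropy in bits) matches the target within relative
#' tolerance `tol`.  Rows with no usable spread (all off-diagonal
#' distances equal) are returned uniform, achieving perplexity n-1.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param perplexity target in (1, n).
#' @param tol relative tolerance on achieved perplexity.
#' @param max_iter bisection iterations per row.
#' @return n x n row-stochastic matrix with zero diagonal.
#' @export
conditional_affinities <- function(D, perplexity, tol = 1e-4, max_iter = 200L) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (perplexity <= 1 || perplexity >= n) {
    stop("perplexity must lie in (1, n)", call. = FALSE)
  }
  D <- .cap_infinite(D)
  D2 <- D^2
  P <- matrix(0, n, n)
  log_target <- log2(perplexity)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    if (max(d2) - min(d2) < 1e-300) {          # degenerate: uniform row
      P[i, -i] <- 1 / (n - 1)
      next
    }
    d2 <- d2 - min(d2)                          # stabilized; shifts cancel
    beta <- 1; lo <- 0; hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      p <- w / sw
      H <- -sum(ifelse(p > 0, p * log2(p), 0))  # bits
      if (abs(2^H - perplexity) <= tol * perplexity) break
      if (H > log_target) {                     # too entropic: raise beta
        lo <- beta
        beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + hi) / 2
      }
    }
    P[i, -i] <- w / sw
  }
  if (any(!is.finite(P))) stop("non-finite affinity row", call. = FALSE)
  P
}

#' Achieved perplexity of each row of an affinity matrix
#' @param P row-stochastic matrix with zero diagonal.
#' @return numeric vector of per-row perplexities (`2^H`, H in bits).
#' @export
row_perplexities <- function(P) {
  apply(P, 1L, function(p) {
    p <- p[p > 0]
    2^(-sum(p * log2(p)))
  })
}

#' Bregman divergence between two nonnegative arrays
#'
#' `B_phi(P, Q) = phi(P) - phi(Q) - <grad phi(Q), P - Q>` summed over
#' elements.  `generator = "generalized_kl"` uses `phi = sum p log p`,
#' giving `sum(p log(p/q) - p + q)` — equal to the Kullback-Leibler
#' divergence when both arrays are normalized.  `"squared_euclidean"`
#' uses `phi = ||.||^2 / 2`, giving `sum((p - q)^2) / 2`.  Zero iff
#' P = Q; `+Inf` (not an error) where Q vanishes but P does not.
#'
#' @param P,Q numeric vectors or matrices of equal shape, nonnegative.
#' @param generator `"generalized_kl"` or `"squared_euclidean"`.
#' @return nonnegative scalar (possibly `Inf`).
#' @export
bregman_divergence <- function(P, Q,
                               generator = c("generalized_kl", "squared_euclidean")) {
  generator <- match.arg(generator)
  if (length(P) != length(Q)) stop("shape mismatch", call. = FALSE)
  p <- as.numeric(P); q <- as.numeric(Q)
  if (min(p) < 0 || min(q) < 0) stop("inputs must be nonnegative", call. = FALSE)
  if (generator == "squared_euclidean") return(0.5 * sum((p - q)^2))
  if (any(q == 0 & p > 0)) return(Inf)
  act <- p > 0
  sum(p[act] * log(p[act] / q[act])) - sum(p) + sum(q)
}

#' Configuration for the t-SNE embedding engine
#'
#' The baseline mode (classical t-SNE) is `input_metric = "euclidean"`,
#' `low_dim_kernel = "student_t"`, `divergence = "kl"`.  The modified
#' mode replaces the input metric with Bhattacharyya distances between
#' probability-vector rows and the objective with a Bregman divergence.
#' `low_dim_kernel = "simplex_bhattacharyya"` additionally realizes the
#' literal reading in which embedded points are mapped to the simplex by
#' a per-row softmax and compared by Bhattacharyya coefficient.
#'
#' @param perplexity target perplexity (> 1, < n).
#' @param out_dim embedding dimension (default 2).
#' @param max_iter maximum gradient-descent iterations (default 1000).
#' @param learning_rate step size (default 100).
#' @param momentum `(early, late)` momentum coefficients in \[0, 1);
#'   switch at `momentum_switch` iterations.
#' @param momentum_switch iteration at which late momentum starts.
#' @param early_exaggeration multiplier (>= 1) applied to the joint
#'   affinities for the first `exaggeration_iter` iterations.
#' @param exaggeration_iter duration of early exaggeration.
#' @param seed integer RNG seed for the random initialization.
#' @param input_metric `"euclidean"` or `"bhattacharyya"`.
#' @param low_dim_kernel `"student_t"` or `"simplex_bhattacharyya"`.
#' @param divergence `"kl"`, `"generalized_kl"` or `"squared_euclidean"`.
#' @param init `"random"` (isotropic Gaussian, sd 1e-4) or `"pca"`.
#' @return object of class `embed_config`.
#' @export
embed_config <- function(perplexity = 30, out_dim = 2L, max_iter = 1000L,
                         learning_rate = 100, momentum = c(0.5, 0.8),
                         momentum_switch = 250L,
                         early_exaggeration = 4, exaggeration_iter = 100L,
                         seed = 1L,
                         input_metric = c("euclidean", "bhattacharyya"),
                         low_dim_kernel = c("student_t", "simplex_bhattacharyya"),
                         divergence = c("kl", "generalized_kl", "squared_euclidean"),
                         init = c("random", "pca")) {
  .check_scalar_num(perplexity, "perplexity", 1 + 1e-9)
  .check_scalar_num(out_dim, "out_dim", 1)
  .check_scalar_num(max_iter, "max_iter", 1)
  .check_scalar_num(learning_rate, "learning_rate", 1e-12)
  stopifnot(length(momentum) == 2L, all(momentum >= 0), all(momentum < 1))
  .check_scalar_num(early_exaggeration, "early_exaggeration", 1)
  structure(list(
    perplexity = perplexity, out_dim = as.integer(out_dim),
    max_iter = as.integer(max_iter), learning_rate = learning_rate,
    momentum = momentum, momentum_switch = as.integer(momentum_switch),
    early_exaggeration = early_exaggeration,
    exaggeration_iter = as.integer(exaggeration_iter),
    seed = as.integer(seed),
    input_metric = match.arg(input_metric),
    low_dim_kernel = match.arg(low_dim_kernel),
    divergence = match.arg(divergence),
    init = match.arg(init)
  ), class = "embed_config")
}

# low-dimensional kernel: unnormalized similarities W (diag 0), joint
# Q = W / sum(W) floored at 1e-12, plus what the gradient needs
.low_dim_kernel <- function(Y, kernel) {
  n <- nrow(Y)
  if (kernel == "student_t") {
    d2 <- as.matrix(stats::dist(Y))^2
    W <- 1 / (1 + d2)
    diag(W) <- 0
    list(W = W, S = sum(W))
  } else {
    E <- exp(Y - apply(Y, 1L, max))      # row-wise softmax
    Sm <- E / rowSums(E)
    R <- sqrt(Sm)
    W <- R %*% t(R)                       # Bhattacharyya coefficients
    W <- pmin(W, 1)
    diag(W) <- 0
    list(W = W, S = sum(W), Sm = Sm, R = R)
  }
}

.joint_Q <- function(kern) pmax(kern$W / kern$S, 1e-12)

#' Embedding cost for a given configuration
#'
#' Computes the configured Bregman cost between the joint affinities `P`
#' and the low-dimensional joint `Q` induced by `Y`.  Exposed (together
#' with [tsne_gradient()]) so the analytic gradient can be verified
#' against finite differences.
#'
#' @param Y n x out_dim coordinate matrix.
#' @param P joint affinity matrix (nonnegative, typically sums to 1).
#' @param cfg an [embed_config()].
#' @return scalar cost.
#' @export
tsne_cost <- function(Y, P, cfg) {
  kern <- .low_dim_kernel(Y, cfg$low_dim_kernel)
  Q <- .joint_Q(kern)
  off <- row(P) != col(P)
  p <- P[off]; q <- Q[off]
  switch(cfg$divergence,
    kl = {
      act <- p > 0
      sum(p[act] * log(p[act] / q[act]))
    },
    generalized_kl = {
      act <- p > 0
      sum(p[act] * log(p[act] / q[act])) - sum(p) + sum(q)
    },
    squared_euclidean = 0.5 * sum((p - q)^2))
}

#' Analytic gradient of the embedding cost
#' @inheritParams tsne_cost
#' @return n x out_dim gradient matrix.
#' @export
tsne_gradient <- function(Y, P, cfg) {
  n <- nrow(Y)
  kern <- .low_dim_kernel(Y, cfg$low_dim_kernel)
  W <- kern$W; S <- kern$S
  Q <- .joint_Q(kern)
  # dC/dQ elementwise (off-diagonal)
  G <- switch(cfg$divergence,
    kl = -P / Q,
    generalized_kl = -P / Q + 1,
    squared_euclidean = Q - P)
  diag(G) <- 0
  if (cfg$divergence == "kl") G[P == 0] <- 0
  cs <- sum(G * Q)
  L <- (G - cs) / S
  diag(L) <- 0
  M <- L + t(L)
  if (cfg$low_dim_kernel == "student_t") {
    K <- M * W^2                       # dW_ij/dy_i = -2 W_ij^2 (y_i - y_j)
    -2 * (rowSums(K) * Y - K %*% Y)
  } else {
    Sm <- kern$Sm; R <- kern$R
    # dW_ij/dy_ik = (sqrt(s_ik s_jk) - s_ik W_ij) / 2
    term1 <- R * (M %*% R)
    term2 <- Sm * rowSums(M * W)
    0.5 * (term1 - term2)
  }
}

#' Embed data with (modified) t-SNE
#'
#' Calibrates perplexity-matched conditional affinities on the input
#' distances, symmetrizes them to a joint `P`, and minimizes the
#' configured divergence between `P` and the low-dimensional joint `Q`
#' by full-batch gradient descent with momentum, adaptive gains and
#' early exaggeration.  Deterministic for a fixed seed.
#'
#' @param X one of: a `labeled_features` object, a numeric matrix of
#'   observations (rows are probability vectors when
#'   `cfg$input_metric = "bhattacharyya"`), or a precomputed symmetric
#'   zero-diagonal distance matrix (detected automatically, or pass
#'   `is_distance = TRUE`).
#' @param cfg an [embed_config()].
#' @param is_distance force interpretation of `X` as a distance matrix.
#' @return list with `Y` (n x out_dim embedding), `cost_trace` (cost at
#'   every iteration, on the affinities being optimized at the time) and
#'   `iterations` used.
#' @export
tsne_embed <- function(X, cfg = embed_config(), is_distance = FALSE) {
  stopifnot(inherits(cfg, "embed_config"))
  feats <- NULL
  if (inherits(X, "labeled_features")) X <- X$matrix
  if (inherits(X, "dist")) { X <- as.matrix(X); is_distance <- TRUE }
  stopifnot(is.matrix(X))
  if (!is_distance && nrow(X) == ncol(X) && nrow(X) > 2 &&
      isTRUE(all.equal(X, t(X), tolerance = 1e-12)) && all(diag(X) == 0)) {
    is_distance <- TRUE
  }
  if (is_distance) {
    D <- X
  } else {
    feats <- X
    D <- pairwise_distances(X, cfg$input_metric)
  }
  n <- nrow(D)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (cfg$perplexity >= n) stop("perplexity must be < n", call. = FALSE)

  Pc <- conditional_affinities(D, cfg$perplexity)
  P <- (Pc + t(Pc)) / (2 * n)           # symmetrized joint, sums to 1
  P <- pmax(P, 1e-15)
  diag(P) <- 0

  Y <- with_seed(cfg$seed, {
    if (cfg$init == "pca") {
      if (!is.null(feats)) {
        sc <- scale(feats, center = TRUE, scale = FALSE)
        pr <- svd(sc, nu = cfg$out_dim, nv = 0)
        pr$u %*% diag(pr$d[seq_len(cfg$out_dim)], cfg$out_dim)
      } else {
        stats::cmdscale(.cap_infinite(D), k = cfg$out_dim)
      }
    } else {
      matrix(stats::rnorm(n * cfg$out_dim, sd = 1e-4), n, cfg$out_dim)
    }
  })

  inc <- matrix(0, n, cfg$out_dim)
  gains <- matrix(1, n, cfg$out_dim)
  cost_trace <- numeric(0)
  last_report <- Inf
  for (iter in seq_len(cfg$max_iter)) {
    Pit <- if (iter <= cfg$exaggeration_iter) P * cfg$early_exaggeration else P
    grad <- tsne_gradient(Y, Pit, cfg)
    if (any(!is.finite(grad))) {
      stop(sprintf("NaN/Inf gradient at iteration %d; reduce learning_rate", iter),
           call. = FALSE)
    }
    mom <- if (iter < cfg$momentum_switch) cfg$momentum[1] else cfg$momentum[2]
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- mom * inc - cfg$learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
    cost_trace[iter] <- tsne_cost(Y, Pit, cfg)
    if (iter > cfg$exaggeration_iter + 50 && iter %% 50 == 0) {
      cur <- cost_trace[iter]
      prev <- cost_trace[iter - 50]
      if (is.finite(cur) && is.finite(prev) &&
          abs(prev - cur) < 1e-7 * max(abs(prev), 1e-12)) break
    }
  }
  list(Y = Y, cost_trace = cost_trace, iterations = length(cost_trace))
}

#' Trustworthiness of a low-dimensional embedding
#'
#' Rank-based score in \[0, 1\] penalizing points that enter a point's
#' k-neighborhood in the embedding without being among its k nearest
#' neighbors in the input space; 1 means no intruders.
#'
#' @param D_high input-space distance matrix (symmetric, zero diagonal).
#' @param Y embedding coordinates (n x m).
#' @param k neighborhood size, `k < n/2`.
#' @return scalar in \[0, 1\].
#' @export
trustworthiness <- function(D_high, Y, k) {
  stopifnot(is.matrix(D_high), nrow(D_high) == ncol(D_high))
  n <- nrow(D_high)
  if (k >= n / 2 || k < 1) stop("k must satisfy 1 <= k < n/2", call. = FALSE)
  D_low <- as.matrix(stats::dist(Y))
  penalty <- 0
  for (i in seq_len(n)) {
    oh <- order(D_high[i, -i])
    others <- seq_len(n)[-i]
    high_rank <- integer(n)
    high_rank[others[oh]] <- seq_len(n - 1L)
    nn_high <- others[oh][seq_len(k)]
    ol <- order(D_low[i, -i])
    nn_low <- others[ol][seq_len(k)]
    intruders <- setdiff(nn_low, nn_high)
    if (length(intruders)) {
      penalty <- penalty + sum(high_rank[intruders] - k)
    }
  }
  1 - 2 * penalty / (n * k * (2 * n - 3 * k - 1))
}
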