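test_that("Bhattacharyya distance follows its closed form and properties", {
  expect_equal(bhattacharyya_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_identical(bhattacharyya_distance(c(1, 0), c(0, 1)), Inf)
  # independent evaluation of -ln(sum sqrt(PQ))
  expect_equal(bhattacharyya_distance(c(0.5, 0.5), c(0.9, 0.1)),
               -log(sqrt(0.45) + sqrt(0.05)), tolerance = 1e-12)
  expect_equal(bhattacharyya_distance(c(0.5, 0.5), c(0.9, 0.1)), 0.11157,
               tolerance = 1e-4)

  set.seed(10)
  for (i in 1:200) {
    d <- sample(2:12, 1)
    p <- rand_simplex(d); q <- rand_simplex(d)
    expect_equal(bhattacharyya_distance(p, q), bhattacharyya_distance(q, p),
                 tolerance = 1e-12)
    expect_gte(bhattacharyya_distance(p, q), 0)
    expect_lt(bhattacharyya_distance(p, p), 1e-12)
  }
  expect_error(bhattacharyya_distance(c(0.5, 0.5), c(1, 1)), "sum")
  expect_error(bhattacharyya_distance(c(0.5, 0.5), rand_simplex(3)), "mismatch")
})

test_that("pairwise distances agree with scalar calls and are symmetric", {
  set.seed(2)
  X <- t(replicate(4, rand_simplex(6)))
  D <- pairwise_distances(X, "bhattacharyya")
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(D[i, j], bhattacharyya_distance(X[i, ], X[j, ]),
                 tolerance = 1e-12)
  }
  X2 <- rbind(X, X[2, ])
  expect_equal(pairwise_distances(X2, "bhattacharyya")[2, 5], 0, tolerance = 1e-12)

  E <- matrix(rnorm(40), 10, 4)
  DE <- pairwise_distances(E, "euclidean")
  expect_equal(DE[3, 7], sqrt(sum((E[3, ] - E[7, ])^2)), tolerance = 1e-12)
})

test_that("conditional affinities hit the target perplexity", {
  # all off-diagonal distances equal -> uniform rows at perplexity n-1
  D <- matrix(1, 6, 6); diag(D) <- 0
  P <- conditional_affinities(D, 3)
  expect_equal(unname(P[1, -1]), rep(0.2, 5), tolerance = 1e-12)
  expect_equal(row_perplexities(P), rep(5, 6), tolerance = 1e-9)

  set.seed(5)
  for (target in c(2, 5, 10)) {
    n <- 20
    M <- matrix(runif(n * n, 0.1, 4), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    P <- conditional_affinities(D, target)
    expect_equal(unname(rowSums(P)), rep(1, n), tolerance = 1e-9)
    expect_true(all(abs(row_perplexities(P) - target) <= 1e-4 * target))
  }
  # the spec's 5-point example band
  D5 <- matrix(c(0, 1, 2, 3, 4,
                 1, 0, 1.5, 2.5, 3.5,
                 2, 1.5, 0, 1.2, 2.2,
                 3, 2.5, 1.2, 0, 1.1,
                 4, 3.5, 2.2, 1.1, 0), 5, 5)
  P5 <- conditional_affinities(D5, 2)
  expect_true(all(row_perplexities(P5) >= 1.9998 & row_perplexities(P5) <= 2.0002))
  expect_error(conditional_affinities(D5, 6), "perplexity")
})

test_that("Bregman divergences match hand evaluations and KL", {
  expect_equal(bregman_divergence(c(0.3, 0.7), c(0.3, 0.7), "generalized_kl"), 0)
  expect_equal(bregman_divergence(c(1, 0), c(0, 1), "squared_euclidean"), 1)
  expect_equal(bregman_divergence(c(1, 0), c(0.5, 0.5), "generalized_kl"),
               log(2), tolerance = 1e-12)
  expect_identical(bregman_divergence(c(1, 0), c(0, 1), "generalized_kl"), Inf)

  # equals textbook KL on normalized pairs
  set.seed(6)
  for (i in 1:50) {
    d <- sample(2:10, 1)
    p <- rand_simplex(d); q <- rand_simplex(d)
    kl <- sum(p * log(p / q))
    expect_equal(bregman_divergence(p, q, "generalized_kl"), kl,
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  lf <- generate_cluster_features(5, 2, 6, 4, seed = 3)
  D <- pairwise_distances(lf$matrix, "euclidean")
  Pc <- conditional_affinities(D, 3)
  P <- (Pc + t(Pc)) / (2 * nrow(D)); diag(P) <- 0
  eps <- 1e-6
  combos <- list(c("kl", "student_t"),
                 c("generalized_kl", "student_t"),
                 c("squared_euclidean", "student_t"),
                 c("generalized_kl", "simplex_bhattacharyya"))
  for (cb in combos) {
    cfg <- embed_config(perplexity = 3, divergence = cb[1], low_dim_kernel = cb[2])
    Y <- matrix(rnorm(nrow(D) * 2), ncol = 2)
    g <- tsne_gradient(Y, P, cfg)
    fd <- matrix(0, nrow(Y), 2)
    for (i in seq_len(nrow(Y))) for (j in 1:2) {
      Yp <- Y; Yp[i, j] <- Yp[i, j] + eps
      Ym <- Y; Ym[i, j] <- Ym[i, j] - eps
      fd[i, j] <- (tsne_cost(Yp, P, cfg) - tsne_cost(Ym, P, cfg)) / (2 * eps)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("embedding is seed-deterministic and converges", {
  lf <- generate_cluster_features(8, 3, 6, 8, seed = 4)
  cfg <- quick_cfg(seed = 11)
  a <- tsne_embed(lf, cfg)
  b <- tsne_embed(lf, cfg)
  expect_identical(a$Y, b$Y)
  expect_identical(dim(a$Y), c(24L, 2L))
  expect_true(all(is.finite(a$Y)))
  expect_length(a$cost_trace, a$iterations)

  # cost non-increasing (within momentum wobble) once exaggeration is off
  # and the step size is small
  cfg2 <- embed_config(perplexity = 3, max_iter = 250, learning_rate = 5,
                       early_exaggeration = 1, exaggeration_iter = 0,
                       seed = 2)
  tr <- tsne_embed(lf, cfg2)$cost_trace
  tail_tr <- tr[50:length(tr)]
  increases <- sum(diff(tail_tr) > 1e-12)
  expect_lte(increases, max(1, 0.01 * length(tail_tr)))
})

test_that("precomputed distance matrices and pca init are accepted", {
  lf <- generate_cluster_features(6, 2, 5, 6, seed = 8)
  D <- pairwise_distances(lf$matrix, "euclidean")
  e1 <- tsne_embed(D, quick_cfg(seed = 3), is_distance = TRUE)
  expect_identical(nrow(e1$Y), nrow(D))
  e2 <- tsne_embed(lf, quick_cfg(seed = 3, init = "pca"))
  expect_true(all(is.finite(e2$Y)))
})

test_that("trustworthiness is 1 under isometry and favors real structure", {
  set.seed(12)
  X <- matrix(rnorm(60), 30, 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  D <- as.matrix(dist(X))
  expect_equal(trustworthiness(D, X %*% R, 5), 1)

  lf <- generate_cluster_features(20, 3, 10, 8, seed = 2)
  Dh <- pairwise_distances(lf$matrix, "euclidean")
  good <- tsne_embed(lf, quick_cfg(perplexity = 10, seed = 5))$Y
  rand <- with_seed(1, matrix(rnorm(nrow(Dh) * 2), ncol = 2))
  expect_gt(trustworthiness(Dh, good, 5), trustworthiness(Dh, rand, 5))
  for (i in 1:5) {
    Yr <- matrix(rnorm(nrow(Dh) * 2), ncol = 2)
    tw <- trustworthiness(Dh, Yr, 5)
    expect_true(tw >= 0 && tw <= 1)
  }
  expect_error(trustworthiness(Dh, good, 40), "k must")
})
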