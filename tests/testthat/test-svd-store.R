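test_that("truncated SVD obeys Eckart-Young exactly", {
  # rank-1 outer product reconstructs exactly at rank 1
  u <- runif(12); v <- runif(9)
  A <- outer(u, v) / max(outer(u, v))
  f <- svd_compress(A, 1)
  expect_lt(sum((A - svd_reconstruct(f, clip = FALSE))^2), 1e-16)

  # 3x3 identity at rank 2 leaves squared error exactly 1
  f2 <- svd_compress(diag(3), 2)
  expect_equal(sum((diag(3) - svd_reconstruct(f2, clip = FALSE))^2), 1,
               tolerance = 1e-12)

  set.seed(41)
  for (i in 1:10) {
    A <- matrix(runif(32 * 24), 32, 24)
    sv <- svd(A)$d
    errs <- vapply(1:24, function(k) {
      f <- svd_compress(A, k)
      err <- sum((A - svd_reconstruct(f, clip = FALSE))^2)
      tail_energy <- sum(sv[-seq_len(k)]^2)
      if (tail_energy > 0) expect_lt(abs(err - tail_energy) / tail_energy, 1e-8)
      err
    }, 0)
    expect_true(all(diff(errs) <= 1e-10))   # monotone in rank
  }
  expect_error(svd_compress(diag(3), 4), "rank")
  # clipping never increases the error to an original inside [0, 1]
  A <- matrix(runif(100), 10, 10)
  f <- svd_compress(A, 3)
  expect_lte(sum((A - svd_reconstruct(f, clip = TRUE))^2),
             sum((A - svd_reconstruct(f, clip = FALSE))^2) + 1e-12)
  # full rank is lossless
  ffull <- svd_compress(A, 10)
  expect_equal(svd_reconstruct(ffull, clip = FALSE), A, tolerance = 1e-8)
})

test_that("rank selection by spectral energy", {
  expect_identical(choose_rank(c(2, 1, 1), 0.5), 1L)   # 4/6 >= 0.5
  expect_identical(choose_rank(c(2, 1, 1), 0.9), 3L)
  expect_identical(choose_rank(c(5, 0, 0), 1.0), 1L)
  fr <- seq(0.1, 1, by = 0.1)
  ranks <- vapply(fr, choose_rank, 0L, singular_values = c(4, 3, 2, 1, 0.5))
  expect_true(all(diff(ranks) >= 0))
})

test_that("similarity is the Bhattacharyya coefficient", {
  p <- rand_simplex(8)
  expect_equal(similarity(p, p), 1, tolerance = 1e-12)
  expect_equal(similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(similarity(c(0.5, 0.5), c(0.9, 0.1)),
               sqrt(0.45) + sqrt(0.05), tolerance = 1e-12)
  expect_equal(similarity(c(0.5, 0.5), c(0.9, 0.1)), 0.89443, tolerance = 1e-5)
})

test_that("ingest applies the 70% tagging rule and round-trips records", {
  dir <- withr::local_tempdir()
  st <- store_open(dir)
  ph <- small_phantom(51)
  img_path <- file.path(dir, "img.pgm")
  write_pgm(ph$image, img_path)
  r1 <- generate_metadata_record(1, img_path)
  r2 <- generate_metadata_record(2, img_path)

  e1 <- store_ingest(st, r1, ph$image)          # empty store: always full
  expect_null(e1$tag_ref)
  expect_true(e1$rank >= 1)

  e2 <- store_ingest(st, r2, ph$image)          # identical image: tagged
  expect_identical(e2$tag_ref, r1$record_id)
  expect_equal(e2$similarity, 1, tolerance = 1e-9)
  expect_gt(e2$similarity, 0.70)

  # retrieval: key path, bit-exact record, reconstruction from the
  # referenced entry for tagged rows
  got <- store_retrieve(st, key = r1$record_id)
  expect_identical(unclass(got$record), unclass(r1))
  got2 <- store_retrieve(st, key = r2$record_id)
  expect_identical(unclass(got2$record), unclass(r2))
  expect_identical(got2$image, got$image)

  # QR path equals key path
  via_qr <- store_retrieve(st, qr_image = st$index[[r1$record_id]]$qr_image_ref)
  expect_identical(via_qr$record, got$record)

  expect_error(store_ingest(st, r1, ph$image), "duplicate")
  expect_error(store_retrieve(st, key = "NOPE"), "unknown")
})

test_that("dissimilar images are stored in full, near-duplicates tagged", {
  dir <- withr::local_tempdir()
  st <- store_open(dir)
  # two images whose intensity histograms occupy different bins
  dark <- matrix(0.05, 32, 32); dark[10:20, 10:20] <- 0.25
  bright <- matrix(0.75, 32, 32); bright[5:12, 5:25] <- 0.98
  pth <- file.path(dir, "a.pgm"); write_pgm(dark, pth)
  ra <- generate_metadata_record(10, pth)
  rb <- generate_metadata_record(11, pth)
  ea <- store_ingest(st, ra, dark)
  eb <- store_ingest(st, rb, bright)
  expect_null(ea$tag_ref)
  expect_null(eb$tag_ref)
  expect_lt(similarity(ea$features, eb$features), 0.70)
})

test_that("randomized ingests never form tag chains; threshold is monotone", {
  imgs <- lapply(1:40, function(i) {
    base <- small_phantom(1 + (i %% 4))$image   # four base phantoms, noisy copies
    with_seed(900 + i, pmin(pmax(base + matrix(rnorm(48 * 48, 0, 0.01), 48), 0), 1))
  })
  pth <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(imgs[[1]], pth)
  recs <- lapply(1:40, function(i) {
    r <- generate_metadata_record(3000 + i, pth)
    r$record_id <- sprintf("K%03d", i)
    r
  })
  fulls <- vapply(c(0.3, 0.7, 0.99), function(thr) {
    dir <- withr::local_tempdir()
    st <- store_open(dir)
    for (i in 1:40) {
      store_ingest(st, recs[[i]], imgs[[i]], threshold = thr,
                   ec_level = "L", flush = FALSE)
    }
    store_flush(st)
    # no tag chains: every tag target holds factors
    for (e in st$index) {
      if (!is.null(e$tag_ref)) {
        expect_null(st$index[[e$tag_ref]]$tag_ref)
        expect_true(file.exists(file.path(dir, "factors",
                                          paste0(e$tag_ref, ".bin"))))
      }
    }
    store_counts(st)[["full"]]
  }, 0)
  expect_true(all(diff(fulls) >= 0))   # raising threshold keeps/raises fulls
})

test_that("a reopened store serves identical records and images", {
  dir <- withr::local_tempdir()
  st <- store_open(dir)
  ph <- small_phantom(60)
  pth <- file.path(dir, "img.pgm"); write_pgm(ph$image, pth)
  rec <- generate_metadata_record(5, pth)
  store_ingest(st, rec, ph$image)
  before <- store_retrieve(st, key = rec$record_id)

  st2 <- store_open(dir)   # fresh handle, index read back from JSON
  after <- store_retrieve(st2, key = rec$record_id)
  expect_identical(after$record, before$record)
  expect_equal(after$image, before$image, tolerance = 1e-12)
})
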