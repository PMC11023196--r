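test_that("wrapped distance: identity, wrap, antipode", {
  # 1-based indices; the examples use patches 1, 100, 11, 61 on n = 100
  expect_equal(wrapped_distance(1, 1, 100), 0)
  expect_equal(wrapped_distance(1, 100, 100), 1)
  expect_equal(wrapped_distance(11, 61, 100), 50)
  expect_equal(wrapped_distance(61, 11, 100), 50)
})

test_that("sigma from range fraction", {
  expect_equal(sigma_from_range(0, 100), 0)
  expect_equal(sigma_from_range(0.6, 100), 15)
  expect_equal(sigma_from_range(0.2, 100), 5)
})

test_that("kernel limits: sessile identity and flat", {
  expect_equal(build_kernel(0, 7)$probs, diag(7))
  k <- build_kernel(1e5, 50)
  expect_true(max(abs(k$probs - 1 / 50)) < 1e-6)
})

test_that("kernel rows are stochastic and the matrix is circulant-symmetric", {
  k <- build_kernel(3.2, 100)$probs
  expect_equal(rowSums(k), rep(1, 100), tolerance = 1e-12)
  expect_equal(k, t(k), tolerance = 1e-14)
  # circulant: row 2 is row 1 shifted by one
  expect_equal(k[2, c(2:100, 1)], k[1, ], tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("n = 5, sigma = 1 kernel row matches hand weights", {
  w <- c(1, exp(-1 / 2), exp(-2), exp(-2), exp(-1 / 2))
  expect_equal(build_kernel(1, 5)$probs[1, ], w / sum(w), tolerance = 1e-14)
})

test_that("attraction A = 1 returns the base kernel", {
  base <- build_kernel(2, 20)
  out <- apply_attraction(base, farm_patches = 5:6, zoi_patches = 3:8, A = 1)
  expect_true(max(abs(out$probs - base$probs)) < 1e-15)
})

test_that("attraction strictly increases farm-bound probability from the zone", {
  base <- build_kernel(2, 20)
  farms <- 5:6
  zoi <- 2:9
  for (A in c(2, 5, 15)) {
    out <- apply_attraction(base, farms, zoi, A)
    for (i in zoi) {
      expect_gt(sum(out$probs[i, farms]), sum(base$probs[i, farms]))
    }
    expect_equal(rowSums(out$probs), rep(1, 20), tolerance = 1e-12)
  }
})

test_that("attraction row matches brute-force normalisation (both forms)", {
  base <- build_kernel(1, 5)
  d1 <- c(0, 1, 2, 2, 1)  # wrapped distances from patch 1
  for (form in c("multiplicative", "exponent")) {
    out <- apply_attraction(base, farm_patches = 2, zoi_patches = 1:5, A = 4,
                            form = form)
    w <- exp(-d1^2 / 2)
    w[2] <- if (form == "multiplicative") 4 * exp(-1 / 2) else exp(-1 / 8)
    expect_equal(out$probs[1, ], w / sum(w), tolerance = 1e-14)
  }
})

test_that("movement through identity and flat kernels", {
  n <- 6
  ab <- matrix(runif(n * 3, 1, 5), n, 3)
  expect_equal(move(ab, build_kernel(0, n)), ab, ignore_attr = TRUE)
  flat <- build_kernel(1e5, n)
  mv <- move(ab, flat)
  for (a in 1:3) {
    expect_equal(mv[, a], rep(mean(ab[, a]), n), tolerance = 1e-6)
  }
})

test_that("movement matches explicit double-loop oracle and conserves totals", {
  set.seed(42)
  n <- 5
  ab <- matrix(runif(n * 2, 0, 10), n, 2)
  k <- build_kernel(1.3, n)
  mv <- move(ab, k)
  oracle <- matrix(0, n, 2)
  for (j in 1:n) {
    for (i in 1:n) {
      oracle[j, ] <- oracle[j, ] + ab[i, ] * k$probs[i, j]
    }
  }
  expect_equal(mv, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums(mv), colSums(ab), tolerance = 1e-12)
})
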