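test_that("feature standardisation is exact and affine-invariant", {
  img <- array(c(0, 2), dim = c(2, 1, 1))
  expect_equal(as.numeric(normalise_features(img)), c(-1, 1))
  set.seed(2)
  img <- array(rnorm(64, 5, 3), dim = c(8, 8, 1))
  f1 <- normalise_features(img)
  f2 <- normalise_features(3.7 * img + 11)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(mean(f1), 0, tolerance = 1e-12)
  expect_equal(mean(f1^2), 1, tolerance = 1e-12)
  # direct-formula oracle on a masked image
  mask <- array(runif(64) > 0.3, dim = c(8, 8, 1))
  f3 <- normalise_features(img, mask)
  mv <- img[mask]
  oracle <- (img - mean(mv)) / sqrt(mean((mv - mean(mv))^2))
  expect_lt(max(abs(f3 - oracle)), 1e-12)
  expect_error(normalise_features(array(5, c(4, 4, 1))), "constant")
})

test_that("anatomical kernel weights follow the Gaussian product form", {
  # equal features, axial neighbour at distance 1, sigma_d = 3
  v <- array(1, dim = c(4, 4, 1))
  v <- v + array(rnorm(16, sd = 1e-14), dim = dim(v))  # avoid exact ties
  kp <- kernel_params(sigma_m = 1, sigma_dm = 3, normalise_rows = FALSE)
  K <- build_mr_kernel(v, kp, c(4L, 4L, 1L))
  self_col <- which(colSums(K$offsets^2) == 0)
  expect_equal(unique(K$w[, self_col]), 1)         # self-similarity
  axial <- which(K$offsets[1, ] == 1 & K$offsets[2, ] == 0)
  j <- 6  # interior voxel
  expect_equal(K$w[j, axial], exp(-1 / 18), tolerance = 1e-6)
  # self weight is the row maximum
  expect_true(all(K$w[, self_col] >= apply(K$w, 1, max) - 1e-12))
})

test_that("kernel weight decays monotonically with feature difference", {
  dv <- seq(0, 6, by = 0.5)
  w <- vapply(dv, function(d) {
    v <- array(c(0, d), dim = c(2, 1, 1))
    K <- build_mr_kernel(v, kernel_params(normalise_rows = FALSE),
                         c(2L, 1L, 1L))
    K$w[1, which(K$offsets[1, ] == 1 & K$offsets[2, ] == 0)]
  }, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_lt(w[length(w)], 1e-6)
})

test_that("kernel matrices match a brute-force dense oracle", {
  set.seed(9)
  d <- c(6L, 5L, 1L)
  v <- array(rnorm(prod(d)), dim = d)
  z <- array(rnorm(prod(d)), dim = d)
  for (norm in c(FALSE, TRUE)) {
    kp <- kernel_params(normalise_rows = norm)
    km <- build_mr_kernel(v, kp, d)
    kz <- build_pet_kernel(z, kp, d)
    Km_o <- dense_kernel_oracle(v, 1, 3, d, normalise = norm)
    Kz_o <- dense_kernel_oracle(z, 1, 3, d, normalise = norm)
    expect_lt(max(abs(as.matrix(as_sparse_kernel(km)) - Km_o)), 1e-12)
    expect_lt(max(abs(as.matrix(as_sparse_kernel(kz)) - Kz_o)), 1e-12)
    # hybrid product against the dense element-wise product
    hy <- hybrid_kernel(km, kz)
    expect_lt(max(abs(as.matrix(as_sparse_kernel(hy)) - Km_o * Kz_o)),
              if (norm) 1 else 1e-12)  # normalised rows do not multiply
    if (!norm) {
      al <- runif(prod(d))
      expect_lt(max(abs(kernel_apply(hy, al) -
                          as.numeric((Km_o * Kz_o) %*% al))), 1e-12)
    }
  }
})

test_that("kernel apply and transpose form an exact adjoint pair", {
  set.seed(21)
  d <- c(7L, 6L, 1L)
  v <- array(rnorm(prod(d)), dim = d)
  for (norm in c(FALSE, TRUE)) {
    K <- build_mr_kernel(v, kernel_params(normalise_rows = norm), d)
    x <- runif(prod(d)); y <- runif(prod(d))
    expect_equal(sum(kernel_apply(K, x) * y),
                 sum(x * kernel_apply_transpose(K, y)), tolerance = 1e-12)
  }
})

test_that("uniform iterate reduces the PET kernel to pure distance weights", {
  d <- c(5L, 5L, 1L)
  z <- array(0, dim = d)  # standardised constant image maps to zero features
  K <- build_pet_kernel(z, kernel_params(normalise_rows = FALSE), d)
  distw <- exp(-colSums(K$offsets^2) / (2 * 9))
  for (f in seq_len(ncol(K$nb))) {
    ok <- K$nb[, f] > 0
    expect_true(all(abs(K$w[ok, f] - distw[f]) < 1e-14))
  }
})

test_that("large intensity scales reduce the kernel to distance weighting", {
  set.seed(5)
  d <- c(5L, 4L, 1L)
  v <- array(rnorm(prod(d), sd = 2), dim = d)
  K <- build_mr_kernel(v, kernel_params(sigma_m = 1e9,
                                        normalise_rows = FALSE), d)
  distw <- exp(-colSums(K$offsets^2) / (2 * 9))
  for (f in seq_len(ncol(K$nb))) {
    ok <- K$nb[, f] > 0
    expect_true(all(abs(K$w[ok, f] - distw[f]) < 1e-12))
  }
})

test_that("neighbourhood support is 9 in-plane and 27 in slab mode", {
  v2 <- array(rnorm(36), dim = c(6, 6, 1))
  K2 <- build_mr_kernel(v2, kernel_params(normalise_rows = FALSE),
                        c(6L, 6L, 1L))
  expect_equal(ncol(K2$nb), 9L)
  interior2 <- 15  # voxel (3, 3)
  expect_equal(sum(K2$nb[interior2, ] > 0), 9L)
  v3 <- array(rnorm(108), dim = c(6, 6, 3))
  K3 <- build_mr_kernel(v3, kernel_params(neighbourhood = 27L,
                                          normalise_rows = FALSE),
                        c(6L, 6L, 3L))
  expect_equal(ncol(K3$nb), 27L)
  interior3 <- 6 * 6 + 15  # voxel (3, 3, 2)
  expect_equal(sum(K3$nb[interior3, ] > 0), 27L)
  # row sums of unnormalised weights stay within [1, N]
  rs <- rowSums(K3$w)
  expect_true(all(rs >= 1 - 1e-12 & rs <= 27 + 1e-12))
  # normalised rows sum to one
  Kn <- build_mr_kernel(v3, kernel_params(neighbourhood = 27L), c(6L, 6L, 3L))
  expect_equal(rowSums(Kn$w), rep(1, nrow(Kn$w)), tolerance = 1e-12)
})

test_that("kernel component mismatch is rejected", {
  v <- array(rnorm(25), dim = c(5, 5, 1))
  km <- build_mr_kernel(v, kernel_params(), c(5L, 5L, 1L))
  v2 <- array(rnorm(16), dim = c(4, 4, 1))
  kp <- build_pet_kernel(v2, kernel_params(), c(4L, 4L, 1L))
  expect_error(hybrid_kernel(km, kp), "support")
})
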