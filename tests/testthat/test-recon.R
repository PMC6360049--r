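# toy identity system: A = I as a sparse matrix
identity_system <- function(n) {
  Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n), x = rep(1, n),
                       dims = c(n, n))
}

test_that("EM update has the expected fixed point and one-step behaviour", {
  A <- identity_system(2)
  # consistent data equal to the current estimate: fixed point
  a <- c(3, 5)
  expect_equal(em_update(a, A, y = a, s = 0), a, tolerance = 1e-14)
  # identity system converges in one step
  expect_equal(em_update(c(1, 1), A, y = c(4, 2), s = 0), c(4, 2),
               tolerance = 1e-14)
  expect_error(em_update(c(1, 1), A, y = c(-1, 2)), "nonnegative")
})

test_that("EM update matches a dense-matrix implementation", {
  set.seed(31)
  d <- c(8L, 8L, 1L)
  geom <- pet_geometry(c(8, 8), c(2, 2), n_angles = 6)
  A <- system_matrix(geom)
  Ad <- as.matrix(A)
  v <- array(rnorm(64), dim = d)
  for (norm in c(FALSE, TRUE)) {
    K <- build_mr_kernel(v, kernel_params(normalise_rows = norm), d)
    Kd <- as.matrix(as_sparse_kernel(K))
    alpha <- runif(64, 0.5, 2)
    y <- runif(nrow(Ad), 0, 10)
    s <- runif(nrow(Ad), 0, 0.5)
    got <- em_update(alpha, A, y, s, K = K)
    sens_d <- as.numeric(t(Kd) %*% (t(Ad) %*% rep(1, nrow(Ad))))
    yb <- as.numeric(Ad %*% (Kd %*% alpha)) + s
    oracle <- alpha / sens_d *
      as.numeric(t(Kd) %*% (t(Ad) %*% (y / pmax(yb, 1e-10))))
    expect_lt(max(abs(got - oracle)), 1e-10)
  }
})

test_that("compiled and reference reconstruction engines agree", {
  ph <- tiny_phantom()
  geom <- tiny_geometry(ph)
  att <- attenuation_factors(ph$mu, geom)
  sys <- make_em_system(geom, att, 4)
  act <- sample_activity_image(ph, default_tac_table(), c(24, 6))
  fr <- simulate_frame(act, att, geom, 6, counts_scale = 0.3, seed = 8)
  for (alg in c("osem", "kem", "hkem")) {
    st <- recon_settings(alg, n_subsets = 4, n_iterations = 3)
    i_cpp <- reconstruct(fr, sys, st, guidance = ph$guidance,
                         body_mask = ph$body_mask, engine = "cpp")
    i_r <- reconstruct(fr, sys, st, guidance = ph$guidance,
                       body_mask = ph$body_mask, engine = "R")
    expect_lt(max(abs(i_cpp - i_r)) / max(i_r), 1e-12)
  }
})

test_that("identity-kernel HKEM reproduces OSEM", {
  ph <- tiny_phantom()
  geom <- tiny_geometry(ph)
  att <- attenuation_factors(ph$mu, geom)
  sys <- make_em_system(geom, att, 4)
  act <- sample_activity_image(ph, default_tac_table(), c(24, 6))
  fr <- simulate_frame(act, att, geom, 6, counts_scale = 0.3, seed = 3)
  osem <- reconstruct(fr, sys, recon_settings("osem", n_subsets = 4,
                                              n_iterations = 5))
  hkem_id <- reconstruct(fr, sys,
                         recon_settings("hkem", n_subsets = 4,
                                        n_iterations = 5,
                                        kernel = identity_kernel_params()),
                         guidance = ph$guidance, body_mask = ph$body_mask)
  expect_lt(max(abs(osem - hkem_id)) / max(osem), 1e-8)
})

test_that("KEM equals HKEM with the PET component switched off, bitwise", {
  ph <- tiny_phantom()
  geom <- tiny_geometry(ph)
  att <- attenuation_factors(ph$mu, geom)
  sys <- make_em_system(geom, att, 4)
  act <- sample_activity_image(ph, default_tac_table(), c(24, 6))
  fr <- simulate_frame(act, att, geom, 6, counts_scale = 0.3, seed = 3)
  kem <- reconstruct(fr, sys, recon_settings("kem", n_subsets = 4,
                                             n_iterations = 3),
                     guidance = ph$guidance, body_mask = ph$body_mask)
  hk_off <- reconstruct(fr, sys,
                        recon_settings("hkem", n_subsets = 4, n_iterations = 3,
                                       kernel = kernel_params(
                                         use_pet_component = FALSE)),
                        guidance = ph$guidance, body_mask = ph$body_mask)
  expect_identical(as.numeric(kem), as.numeric(hk_off))
})

test_that("MLEM log-likelihood is nondecreasing on a 16x16 phantom", {
  set.seed(17)
  geom <- pet_geometry(c(16, 16), c(2, 2), n_angles = 12)
  A <- system_matrix(geom)
  xs <- (seq_len(16) - 8.5) * 2
  truth <- outer(xs, xs, function(x, y)
    2 * (x^2 + y^2 <= 12^2) + 5 * ((x - 4)^2 + y^2 <= 5^2))
  ybar0 <- as.numeric(A %*% as.numeric(truth))
  y <- rpois(length(ybar0), ybar0)
  alpha <- rep(1, 256)
  ll <- numeric(50)
  for (it in 1:50) {
    alpha <- em_update(alpha, A, y, s = 0)
    ll[it] <- loglik_poisson(y, as.numeric(A %*% alpha))
  }
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-1])))
  expect_true(all(alpha >= 0))
})

test_that("all algorithms produce nonnegative, deterministic images", {
  ph <- tiny_phantom()
  geom <- tiny_geometry(ph)
  att <- attenuation_factors(ph$mu, geom)
  sys <- make_em_system(geom, att, 4)
  act <- sample_activity_image(ph, default_tac_table(), c(24, 6))
  fr <- simulate_frame(act, att, geom, 6, counts_scale = 0.3, seed = 23)
  for (alg in c("osem", "osem_g", "kem", "hkem")) {
    st <- recon_settings(alg, n_subsets = 4, n_iterations = 3)
    i1 <- reconstruct(fr, sys, st, guidance = ph$guidance,
                      body_mask = ph$body_mask)
    i2 <- reconstruct(fr, sys, st, guidance = ph$guidance,
                      body_mask = ph$body_mask)
    expect_true(all(i1 >= 0))
    expect_identical(as.numeric(i1), as.numeric(i2))
  }
})

test_that("kernel algorithms require a guidance image", {
  ph <- tiny_phantom()
  geom <- tiny_geometry(ph)
  sys <- make_em_system(geom, attenuation_factors(ph$mu, geom), 4)
  fr <- list(prompts = array(1, c(geom$n_radial, geom$n_angles, 1)),
             additive = array(0, c(geom$n_radial, geom$n_angles, 1)))
  expect_error(reconstruct(fr, sys, recon_settings("kem", n_subsets = 4)),
               "guidance")
})

test_that("Gaussian postfilter has the stated width and preserves means", {
  # impulse response: 3 mm FWHM at 1.56 mm spacing
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  f <- gaussian_postfilter(img, 3, c(1.56, 1.56))
  expect_equal(profile_fwhm(f[, 17], 1.56), 3, tolerance = 0.02)
  expect_equal(profile_fwhm(f[17, ], 1.56), 3, tolerance = 0.02)
  expect_equal(sum(f), 1, tolerance = 1e-12)    # mean preserved
  # constant image is unchanged (reflective boundary, normalised kernel)
  cimg <- matrix(4.2, 20, 20)
  expect_equal(gaussian_postfilter(cimg, 3, c(1.56, 1.56)), cimg,
               tolerance = 1e-12)
  expect_error(gaussian_postfilter(cimg, -3, 1.56), "fwhm")
})

test_that("reconstruction recovers a noiseless phantom frame accurately", {
  ph <- tiny_phantom()
  geom <- tiny_geometry(ph, n_angles = 24)
  att <- attenuation_factors(ph$mu, geom)
  sys <- make_em_system(geom, att, 4)
  tacs <- default_tac_table()
  act <- sample_activity_image(ph, tacs, c(24, 6))
  fr <- simulate_frame(act, att, geom, 6, counts_scale = 10)  # noiseless
  st <- recon_settings("hkem", n_subsets = 4, n_iterations = 10)
  img <- reconstruct(fr, sys, st, guidance = ph$guidance,
                     body_mask = ph$body_mask)
  seg <- ph$labels == ph$label_names[["aorta"]]
  truth <- frame_average_tac(tacs$aorta, 24, 6)
  expect_lt(abs(mean(img[seg]) - truth) / truth, 0.05)
})
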