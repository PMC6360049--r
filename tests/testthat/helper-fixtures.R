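# Small fixtures shared across tests. Everything is generated in code;
# sizes are kept small so the full suite stays fast.

# compact phantom: 32 x 32, organs scaled down to fit a 40 mm body
tiny_phantom <- function(noise_sd = 0.05, seed = 11, n_slices = 1L) {
  make_phantom(grid_dim = c(32, 32), body_diameter_mm = 40,
               organ_large_diameter_mm = 14, organ_mid_diameter_mm = 8,
               guidance_noise_sd = noise_sd, seed = seed,
               n_slices = n_slices)
}

tiny_geometry <- function(ph, n_angles = 16L)
  pet_geometry(dim(ph$labels), ph$spacing[seq_along(dim(ph$labels))],
               n_angles = n_angles)

# dense system matrix built independently by projecting unit voxels
# (exercises linearity; the reference for dense-algebra checks)
dense_system_matrix <- function(geom) {
  V <- prod(geom$image_dim[1:2])
  cols <- lapply(seq_len(V), function(j) {
    e <- array(0, dim = geom$image_dim[1:2])
    e[j] <- 1
    as.numeric(forward_project(e, geom))
  })
  do.call(cbind, cols)
}

# brute-force voxel-wise kernel as a dense matrix: K[j, f] = k_fj
dense_kernel_oracle <- function(features, sigma_int, sigma_dist, dim3,
                                radius_z = 0L, normalise = FALSE) {
  V <- prod(dim3)
  co <- arrayInd(seq_len(V), dim3)
  Kd <- matrix(0, V, V)
  v <- as.numeric(features)
  for (j in seq_len(V)) for (f in seq_len(V)) {
    dd <- co[f, ] - co[j, ]
    if (all(abs(dd[1:2]) <= 1) && abs(dd[3]) <= radius_z) {
      Kd[j, f] <- exp(-(v[f] - v[j])^2 / (2 * sigma_int^2)) *
        exp(-sum(dd^2) / (2 * sigma_dist^2))
    }
  }
  if (normalise) Kd <- Kd / rowSums(Kd)
  Kd
}

# kernel parameters whose weights collapse to the identity matrix
identity_kernel_params <- function()
  kernel_params(sigma_m = 1e-8, sigma_dm = 1e-8,
                sigma_p = 1e8, sigma_dp = 1e-8)

# measure the FWHM (in mm) of a 1-D profile by linear interpolation of the
# half-maximum crossings
profile_fwhm <- function(profile, spacing) {
  m <- max(profile)
  half <- m / 2
  idx <- which(profile >= half)
  lo <- min(idx); hi <- max(idx)
  left <- if (lo > 1) {
    lo - (profile[lo] - half) / (profile[lo] - profile[lo - 1])
  } else lo
  right <- if (hi < length(profile)) {
    hi + (profile[hi] - half) / (profile[hi] - profile[hi + 1])
  } else hi
  (right - left) * spacing
}
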