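#' Reconstruction settings
#'
#' Bundle of reconstruction options. Algorithms:
#' * `"osem"` — ordered-subsets EM;
#' * `"osem_g"` — OSEM followed once by a Gaussian postfilter of
#'   `fwhm_mm` (default 3 mm), the standard clinical setting;
#' * `"kem"` — kernelised EM with a fixed anatomical kernel;
#' * `"hkem"` — hybrid kernelised EM, whose kernel is the element-wise
#'   product of the anatomical component and a PET component rebuilt from
#'   the current estimate at every subiteration.
#'
#' The default 21 subsets x 10 iterations (210 subiterations) applies to
#' all algorithms.
#'
#' @param algorithm one of `"osem"`, `"osem_g"`, `"kem"`, `"hkem"`.
#' @param n_subsets number of interleaved angle subsets.
#' @param n_iterations number of full iterations.
#' @param fwhm_mm postfilter width, mm (osem_g only).
#' @param kernel a [kernel_params()] (kem / hkem).
#' @param initial_value uniform initial image value inside the
#'   field-of-view mask (> 0).
#' @param epsilon floor applied to the projected estimate in the data
#'   ratio to avoid division by zero.
#' @param pet_kernel_update `"subiteration"` (default: PET component
#'   rebuilt every subiteration) or `"iteration"`.
#' @return object of class `recon_settings`.
#' @export
recon_settings <- function(algorithm = c("hkem", "osem", "osem_g", "kem"),
                           n_subsets = 21L, n_iterations = 10L,
                           fwhm_mm = 3, kernel = kernel_params(),
                           initial_value = 1, epsilon = 1e-10,
                           pet_kernel_update = c("subiteration", "iteration")) {
  algorithm <- match.arg(algorithm)
  pet_kernel_update <- match.arg(pet_kernel_update)
  stopifnot(n_subsets >= 1L, n_iterations >= 1L, initial_value > 0,
            epsilon > 0)
  if (algorithm == "osem_g" && fwhm_mm <= 0)
    stop("postfilter FWHM must be positive")
  structure(list(algorithm = algorithm, n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations), fwhm_mm = fwhm_mm,
                 kernel = kernel, initial_value = initial_value,
                 epsilon = epsilon, pet_kernel_update = pet_kernel_update),
            class = "recon_settings")
}

#' Precompute the subset system model
#'
#' Slices the (attenuated) system matrix into interleaved angle subsets and
#' precomputes per-subset sensitivity backprojections. Building this once
#' per study amortises the sparse-matrix work over all frames and
#' realisations. For slab images the per-slice projector is replicated
#' block-diagonally over slices.
#'
#' @param geom a [pet_geometry()].
#' @param attenuation attenuation factor sinogram ([attenuation_factors()]),
#'   or `NULL` for no attenuation.
#' @param n_subsets number of subsets.
#' @return object of class `em_system`: per-subset sparse matrices `mats`,
#'   sinogram row indices `rows` (per slice), angle subsets, and the
#'   V x n_subsets matrix `backones` of subset sensitivities (before any
#'   kernel).
#' @export
make_em_system <- function(geom, attenuation = NULL, n_subsets = 21L) {
  A <- system_matrix(geom)
  nz <- if (length(geom$image_dim) >= 3L) geom$image_dim[3] else 1L
  per_slice <- geom$n_radial * geom$n_angles
  if (!is.null(attenuation)) {
    av <- array(attenuation, dim = c(per_slice, nz))
  }
  subs <- partition_subsets(geom, n_subsets)
  mats <- vector("list", n_subsets)
  rows_list <- vector("list", n_subsets)
  for (s in seq_len(n_subsets)) {
    rows <- .subset_rows(geom, subs[[s]])
    rows_list[[s]] <- rows
    blocks <- lapply(seq_len(nz), function(z) {
      As <- A[rows, , drop = FALSE]
      if (!is.null(attenuation)) As <- As * av[rows, z]
      As
    })
    mats[[s]] <- if (nz == 1L) methods::as(blocks[[1]], "CsparseMatrix")
      else methods::as(Matrix::bdiag(blocks), "CsparseMatrix")
  }
  backones <- vapply(mats, Matrix::colSums,
                     numeric(prod(geom$image_dim)))
  structure(list(geom = geom, subsets = subs, rows = rows_list,
                 mats = mats, backones = backones,
                 n_subsets = as.integer(n_subsets), n_slices = nz,
                 per_slice = per_slice, attenuated = !is.null(attenuation)),
            class = "em_system")
}

# extract the subset-ordered data vector from a sinogram array
.subset_vector <- function(sino, system, s) {
  v <- as.numeric(sino)
  rows <- system$rows[[s]]
  if (system$n_slices == 1L) return(v[rows])
  idx <- as.vector(outer(rows, (seq_len(system$n_slices) - 1L) *
                           system$per_slice, `+`))
  v[idx]
}

# default circular field-of-view mask (inscribed in the in-plane grid)
.default_fov_mask <- function(geom) {
  nx <- geom$image_dim[1]; ny <- geom$image_dim[2]
  nz <- if (length(geom$image_dim) >= 3L) geom$image_dim[3] else 1L
  hx <- geom$image_spacing[1]; hy <- geom$image_spacing[2]
  xs <- (seq_len(nx) - (nx + 1) / 2) * hx
  ys <- (seq_len(ny) - (ny + 1) / 2) * hy
  r <- min(nx * hx, ny * hy) / 2
  m <- outer(xs, ys, function(x, y) x^2 + y^2 <= r^2)
  array(rep(m, nz), dim = c(nx, ny, nz))
}

#' One kernelised EM update (reference implementation)
#'
#' A single multiplicative EM subiteration on the kernel coefficients:
#' `alpha <- alpha / (K' A' 1) * K' A' ( y / (A K alpha + s) )`,
#' with `A` the (attenuated) subset projector and `K` the kernel (identity
#' when `K` is `NULL`). Voxels with zero sensitivity are pinned to 0. This
#' plain-R version is the reference against which the compiled loop is
#' validated; [reconstruct()] uses the compiled driver.
#'
#' @param alpha current coefficient vector (>= 0).
#' @param A subset system matrix (`dgCMatrix`, attenuation folded in).
#' @param y subset prompts vector (>= 0).
#' @param s subset additive (randoms + scatter) vector.
#' @param K optional `kernel_matrix`.
#' @param sens optional precomputed sensitivity `K' A' 1`.
#' @param eps ratio floor.
#' @return updated coefficient vector.
#' @export
em_update <- function(alpha, A, y, s = 0, K = NULL, sens = NULL,
                      eps = 1e-10) {
  if (any(y < 0)) stop("prompts must be nonnegative")
  if (any(alpha < 0)) stop("coefficients must be nonnegative")
  if (is.null(sens)) {
    sens <- Matrix::colSums(A)
    if (!is.null(K)) sens <- kernel_apply_transpose(K, sens)
  }
  lam <- if (is.null(K)) alpha else kernel_apply(K, alpha)
  yb <- as.numeric(A %*% lam) + s
  ratio <- y / pmax(yb, eps)
  bp <- as.numeric(Matrix::crossprod(A, ratio))
  corr <- if (is.null(K)) bp else kernel_apply_transpose(K, bp)
  ifelse(sens > 0, alpha * corr / sens, 0)
}

#' Iterative reconstruction of one frame
#'
#' Runs `n_iterations x n_subsets` EM subiterations with the configured
#' algorithm and returns the activity image `lambda = K alpha` (for OSEM,
#' `lambda = alpha`). The additive term (randoms + scatter estimate) enters
#' the forward model and is never subtracted from the data, so all iterates
#' stay nonnegative. Reconstruction is fully deterministic.
#'
#' @param data a `sinogram_set` (from [simulate_frame()] /
#'   [get_frame_data()]) or a list with elements `prompts` and `additive`.
#' @param system an [make_em_system()] object.
#' @param settings a [recon_settings()].
#' @param guidance anatomical guidance image (required for kem / hkem).
#' @param body_mask logical array over which feature images are
#'   standardised (default: field-of-view mask).
#' @param fov_mask logical array; the initial image is
#'   `initial_value` inside and 0 outside (default: inscribed circle).
#' @param engine `"cpp"` (compiled driver) or `"R"` (reference loop; slow,
#'   for validation).
#' @return activity image array (geometry grid), kBq/mL-equivalent, with
#'   attribute `provenance` recording algorithm and settings.
#' @export
reconstruct <- function(data, system, settings = recon_settings(),
                        guidance = NULL, body_mask = NULL, fov_mask = NULL,
                        engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(system, "em_system"))
  geom <- system$geom
  alg <- settings$algorithm
  use_kernel <- alg %in% c("kem", "hkem")
  use_pet <- alg == "hkem" && isTRUE(settings$kernel$use_pet_component)
  if (use_kernel && is.null(guidance))
    stop(alg, " requires a guidance image")
  if (any(data$prompts < 0)) stop("negative prompts")
  dim3 <- geom$image_dim
  if (length(dim3) == 2L) dim3 <- c(dim3, 1L)
  V <- prod(dim3)
  if (is.null(fov_mask)) fov_mask <- .default_fov_mask(geom)
  if (is.null(body_mask)) body_mask <- fov_mask
  alpha0 <- as.numeric(fov_mask) * settings$initial_value

  y_list <- lapply(seq_len(system$n_subsets), function(s)
    .subset_vector(data$prompts, system, s))
  add <- if (is.null(data$additive)) array(0, dim = dim(data$prompts))
    else data$additive
  s_list <- lapply(seq_len(system$n_subsets), function(s)
    .subset_vector(add, system, s))

  if (use_kernel) {
    v <- normalise_features(guidance, body_mask)
    km <- build_mr_kernel(v, settings$kernel, dim3)
    nb <- km$nb
    wm <- km$w
    distp <- exp(-colSums(km$offsets^2) / (2 * settings$kernel$sigma_dp^2))
  } else {
    nb <- matrix(0L, 1, 1); wm <- matrix(0, 1, 1); distp <- 0
  }

  if (engine == "cpp") {
    res <- em_run_cpp(lapply(system$mats, methods::slot, "p"),
                      lapply(system$mats, methods::slot, "i"),
                      lapply(system$mats, methods::slot, "x"),
                      y_list, s_list, system$backones,
                      nb, wm, distp, settings$kernel$sigma_p,
                      as.logical(body_mask), alpha0,
                      settings$n_iterations, settings$epsilon,
                      use_kernel, use_pet,
                      settings$pet_kernel_update == "subiteration",
                      isTRUE(settings$kernel$normalise_rows))
    lam <- res$lambda
  } else {
    lam <- .reconstruct_r(alpha0, system, settings, y_list, s_list,
                          nb, wm, distp, body_mask, use_kernel, use_pet)
  }
  # data are in counts; convert the estimate back to activity concentration
  if (!is.null(data$counts_scale) && !is.null(data$duration))
    lam <- lam / (data$counts_scale * data$duration)
  img <- array(lam, dim = geom$image_dim)
  if (alg == "osem_g")
    img <- gaussian_postfilter(img, settings$fwhm_mm, geom$image_spacing)
  attr(img, "provenance") <- list(algorithm = alg,
                                  n_subsets = settings$n_subsets,
                                  n_iterations = settings$n_iterations)
  img
}

# reference R loop, numerically identical to the compiled driver
.reconstruct_r <- function(alpha0, system, settings, y_list, s_list,
                           nb, wm, distp, body_mask, use_kernel, use_pet) {
  alpha <- alpha0
  mk_kernel <- function(lambda_img) {
    w <- wm
    if (use_pet) {
      # NULL iterate (the uniform start) carries no intensity information:
      # the PET component is then the pure distance factor
      z <- if (is.null(lambda_img)) array(0, dim = dim(body_mask))
        else .features_or_zero(array(lambda_img, dim = dim(body_mask)),
                               body_mask)
      zv <- as.numeric(z); zpad <- c(0, zv)
      for (f in seq_len(ncol(nb))) {
        dz <- zpad[nb[, f] + 1L] - zv
        w[, f] <- wm[, f] * exp(-dz^2 / (2 * settings$kernel$sigma_p^2)) *
          distp[f]
      }
      w[nb == 0L] <- 0
      if (isTRUE(settings$kernel$normalise_rows)) w <- w / rowSums(w)
    }
    structure(list(nb = nb, w = w, offsets = NULL, dim = dim(body_mask),
                   normalised = isTRUE(settings$kernel$normalise_rows)),
              class = "kernel_matrix")
  }
  K <- if (use_kernel) mk_kernel(NULL) else NULL
  lam <- if (use_kernel) kernel_apply(K, alpha) else alpha
  every <- settings$pet_kernel_update == "subiteration"
  for (it in seq_len(settings$n_iterations)) {
    for (s in seq_len(system$n_subsets)) {
      if (use_kernel && use_pet && (every || s == 1L) && !(it == 1L && s == 1L))
        K <- mk_kernel(lam)
      sens <- system$backones[, s]
      if (use_kernel) sens <- kernel_apply_transpose(K, sens)
      alpha <- em_update(alpha, system$mats[[s]], y_list[[s]], s_list[[s]],
                         K = K, sens = sens, eps = settings$epsilon)
      lam <- if (use_kernel) kernel_apply(K, alpha) else alpha
    }
  }
  lam
}

#' Gaussian postfilter
#'
#' Separable Gaussian smoothing with the stated full width at half maximum
#' in millimetres (`sigma_voxels = fwhm / (2 sqrt(2 log 2) * spacing)` per
#' axis). The kernel is normalised and the boundary is reflective, so a
#' constant image is unchanged and the image mean is preserved.
#'
#' @param image matrix or array.
#' @param fwhm_mm filter width, mm.
#' @param spacing voxel spacing per axis, mm.
#' @return filtered image, same shape.
#' @export
gaussian_postfilter <- function(image, fwhm_mm, spacing) {
  stopifnot(fwhm_mm > 0)
  d <- dim(image); if (is.null(d)) stop("image must be a matrix or array")
  nd <- length(d)
  spacing <- rep_len(spacing, nd)
  out <- image
  for (ax in seq_len(nd)) {
    if (d[ax] < 2L) next
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2)) * spacing[ax])
    r <- max(1L, ceiling(4 * sigma))
    kern <- exp(-(-r:r)^2 / (2 * sigma^2))
    kern <- kern / sum(kern)
    out <- .conv_axis_reflect(out, kern, ax)
  }
  out
}

# separable 1-D convolution along axis `ax` with reflective boundary
.conv_axis_reflect <- function(x, kern, ax) {
  d <- dim(x)
  perm <- c(ax, seq_along(d)[-ax])
  xp <- aperm(x, perm)
  n <- d[ax]
  m <- prod(d[-ax])
  dim(xp) <- c(n, m)
  r <- (length(kern) - 1L) / 2
  idx_pad <- (1L - r):(n + r)
  idx_pad <- ifelse(idx_pad < 1L, 2L - idx_pad, idx_pad)
  idx_pad <- ifelse(idx_pad > n, 2L * n - idx_pad, idx_pad)
  idx_pad <- pmin(pmax(idx_pad, 1L), n)   # clamp if kernel wider than axis
  pad <- xp[idx_pad, , drop = FALSE]
  res <- matrix(0, n, m)
  for (t in seq_along(kern))
    res <- res + kern[t] * pad[(t - 1L) + seq_len(n), , drop = FALSE]
  dim(res) <- d[perm]
  aperm(res, order(perm))
}

#' Poisson log-likelihood of projection data
#'
#' `sum(y * log(ybar) - ybar)` up to the data-only constant; used to verify
#' the monotonic ascent of MLEM on toy problems.
#'
#' @param y measured prompts.
#' @param ybar modelled mean (`A lambda + s`).
#' @param eps floor inside the logarithm.
#' @return scalar log-likelihood.
#' @export
loglik_poisson <- function(y, ybar, eps = 1e-12) {
  yb <- pmax(as.numeric(ybar), eps)
  sum(ifelse(as.numeric(y) > 0, as.numeric(y) * log(yb), 0)) - sum(yb)
}
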