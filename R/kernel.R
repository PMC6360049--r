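#' Kernel parameters for anatomically guided reconstruction
#'
#' Parameters of the voxel-wise hybrid kernel. Each voxel's feature is a
#' single scalar (its own value in the standardised feature image), and the
#' kernel weight between voxel j and a neighbour f is a product of a
#' Gaussian in the feature difference and a Gaussian in the spatial
#' distance. The defaults are `sigma_m = 1`, `sigma_dm = 3`, `sigma_p = 1`,
#' `sigma_dp = 3` with a 27-voxel (3x3x3) neighbourhood; in single-slice
#' mode the neighbourhood reduces to the in-plane 9-voxel 3x3 cube, which is
#' reported with a message.
#'
#' Feature images are standardised (zero mean, unit variance over the body
#' mask) before use, so the unit intensity scales are meaningful for
#' arbitrary image value ranges; spatial distances are measured in voxel
#' index units.
#'
#' @param sigma_m anatomical (MR) intensity scale, standardised units.
#' @param sigma_dm spatial scale of the anatomical component, voxels.
#' @param sigma_p PET-iterate intensity scale, standardised units (hybrid
#'   kernel only).
#' @param sigma_dp spatial scale of the PET component, voxels.
#' @param neighbourhood total neighbourhood voxel count: 27 (3-D) or 9
#'   (2-D); `NULL` picks automatically from the image dimensionality.
#' @param use_pet_component `TRUE` for the hybrid (HKEM) kernel, `FALSE`
#'   for the anatomical-only (KEM) kernel.
#' @param normalise_rows divide each kernel row by its sum (default `TRUE`,
#'   as in practical kernel-EM implementations). With raw Gaussian weights
#'   the kernel row sums vary several-fold between the interior and the rim
#'   of a small intensity-isolated structure (truncated neighbourhoods), so
#'   a uniform coefficient image maps to a strongly non-uniform activity
#'   image and the EM iterations spend hundreds of subiterations undoing
#'   that distortion; normalised rows make the kernel an averaging operator
#'   and restore uniform recovery within the usual iteration budget. Set to
#'   `FALSE` for the raw product-of-Gaussians weights.
#' @return object of class `kernel_params`.
#' @export
kernel_params <- function(sigma_m = 1, sigma_dm = 3, sigma_p = 1,
                          sigma_dp = 3, neighbourhood = NULL,
                          use_pet_component = TRUE,
                          normalise_rows = TRUE) {
  stopifnot(sigma_m > 0, sigma_dm > 0, sigma_p > 0, sigma_dp > 0)
  if (!is.null(neighbourhood) && !neighbourhood %in% c(9L, 27L))
    stop("neighbourhood must be 9 (2-D) or 27 (3-D slab)")
  structure(list(sigma_m = sigma_m, sigma_dm = sigma_dm, sigma_p = sigma_p,
                 sigma_dp = sigma_dp, neighbourhood = neighbourhood,
                 use_pet_component = isTRUE(use_pet_component),
                 normalise_rows = isTRUE(normalise_rows)),
            class = "kernel_params")
}

# neighbourhood offsets for an image dim; returns list(offsets = 3 x N int
# matrix, n = N)
.kernel_offsets <- function(dim3, neighbourhood = NULL) {
  nz <- if (length(dim3) >= 3L) dim3[3] else 1L
  want3d <- if (is.null(neighbourhood)) nz >= 3L else neighbourhood == 27L
  if (want3d && nz < 3L) {
    message("27-voxel neighbourhood requested on a single-slice image; ",
            "using the in-plane 9-voxel neighbourhood")
    want3d <- FALSE
  }
  dz <- if (want3d) -1:1 else 0L
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = dz))
  t(off)
}

# neighbour index table: V x N matrix of 1-based voxel indices, 0 where the
# neighbour falls outside the grid
.neighbour_table <- function(dim3) {
  force(dim3)
  function(offsets) {
    nx <- dim3[1]; ny <- dim3[2]
    nzv <- if (length(dim3) >= 3L) dim3[3] else 1L
    V <- nx * ny * nzv
    v0 <- seq_len(V) - 1L
    ix <- v0 %% nx
    iy <- (v0 %/% nx) %% ny
    iz <- v0 %/% (nx * ny)
    N <- ncol(offsets)
    nb <- matrix(0L, V, N)
    for (f in seq_len(N)) {
      dx <- offsets[1, f]; dy <- offsets[2, f]; dz <- offsets[3, f]
      ok <- ix + dx >= 0L & ix + dx < nx & iy + dy >= 0L & iy + dy < ny &
        iz + dz >= 0L & iz + dz < nzv
      idx <- v0 + dx + dy * nx + dz * nx * ny + 1L
      nb[, f] <- ifelse(ok, idx, 0L)
    }
    nb
  }
}

#' Standardise a feature image
#'
#' Centres and scales image values to zero mean and unit variance over the
#' given mask, so that unit kernel intensity scales are comparable across
#' images of arbitrary dynamic range. Voxels outside the mask are mapped
#' with the same affine transform.
#'
#' @param image numeric array.
#' @param mask logical array of the same shape (default: all voxels).
#' @return standardised array.
#' @export
normalise_features <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(image))
  v <- image[mask]
  s <- sqrt(mean((v - mean(v))^2))   # population SD: exact unit variance
  if (!is.finite(s) || s == 0)
    stop("feature image is constant over the mask; standardisation undefined")
  (image - mean(v)) / s
}

# lenient variant used on the evolving PET iterate: a (near-)constant image
# carries no intensity information, so its features are all-zero and the
# intensity factor of the kernel becomes 1
.features_or_zero <- function(image, mask) {
  v <- image[mask]
  s <- sqrt(mean((v - mean(v))^2))
  if (!is.finite(s) || s < 1e-12 * max(abs(v), 1))
    return(array(0, dim = dim(image)))
  (image - mean(v)) / s
}

.build_feature_kernel <- function(features, sigma_int, sigma_dist, dim3,
                                  offsets = NULL, nb = NULL,
                                  normalise_rows = FALSE) {
  if (is.null(offsets)) offsets <- .kernel_offsets(dim3)
  if (is.null(nb)) nb <- .neighbour_table(dim3)(offsets)
  dist2 <- colSums(offsets^2)
  distw <- exp(-dist2 / (2 * sigma_dist^2))
  V <- nrow(nb); N <- ncol(nb)
  vv <- as.numeric(features)
  vpad <- c(0, vv)
  W <- matrix(0, V, N)
  for (f in seq_len(N)) {
    dv <- vpad[nb[, f] + 1L] - vv
    W[, f] <- exp(-dv^2 / (2 * sigma_int^2)) * distw[f]
  }
  W[nb == 0L] <- 0
  if (normalise_rows) W <- W / rowSums(W)
  structure(list(nb = nb, w = W, offsets = offsets, dim = dim3,
                 sigma_int = sigma_int, sigma_dist = sigma_dist,
                 normalised = normalise_rows),
            class = "kernel_matrix")
}

#' Build the anatomical (MR-derived) kernel component
#'
#' For each voxel j and each neighbour f in its (2r+1)-cube, the weight is
#' `exp(-(v_f - v_j)^2 / (2 sigma_m^2)) * exp(-||x_f - x_j||^2 / (2 sigma_dm^2))`
#' with v the standardised guidance features and x in voxel units.
#' Out-of-image neighbours are dropped; the self weight is always 1 (the
#' row maximum). Rows are not normalised unless requested in the
#' parameters.
#'
#' @param features standardised guidance image (see [normalise_features()]).
#' @param params a [kernel_params()].
#' @param dim3 image dimensions (or a [pet_geometry()]).
#' @return object of class `kernel_matrix` (sparse neighbourhood weights).
#' @export
build_mr_kernel <- function(features, params = kernel_params(), dim3 = NULL) {
  if (inherits(dim3, "pet_geometry")) dim3 <- dim3$image_dim
  if (is.null(dim3)) dim3 <- dim(features)
  stopifnot(all(is.finite(features)))
  off <- .kernel_offsets(dim3, params$neighbourhood)
  .build_feature_kernel(features, params$sigma_m, params$sigma_dm, dim3,
                        offsets = off, normalise_rows = params$normalise_rows)
}

#' Build the PET (current-iterate) kernel component
#'
#' Same construction as [build_mr_kernel()] but from the standardised
#' current PET estimate, with scales `sigma_p` and `sigma_dp`. For a
#' uniform iterate all intensity differences vanish and every weight
#' reduces to the pure spatial distance factor.
#'
#' @param features standardised current-iterate image.
#' @inheritParams build_mr_kernel
#' @return a `kernel_matrix`.
#' @export
build_pet_kernel <- function(features, params = kernel_params(), dim3 = NULL) {
  if (inherits(dim3, "pet_geometry")) dim3 <- dim3$image_dim
  if (is.null(dim3)) dim3 <- dim(features)
  stopifnot(all(is.finite(features)))
  off <- .kernel_offsets(dim3, params$neighbourhood)
  .build_feature_kernel(features, params$sigma_p, params$sigma_dp, dim3,
                        offsets = off, normalise_rows = params$normalise_rows)
}

#' Hybrid kernel: element-wise product of components
#'
#' Combines the anatomical and PET kernel components into the hybrid kernel
#' by multiplying weights element-wise over the shared neighbourhood
#' support.
#'
#' @param km anatomical `kernel_matrix`.
#' @param kp PET `kernel_matrix` (same support pattern).
#' @return a `kernel_matrix`.
#' @export
hybrid_kernel <- function(km, kp) {
  stopifnot(inherits(km, "kernel_matrix"), inherits(kp, "kernel_matrix"))
  if (!identical(dim(km$nb), dim(kp$nb)) || !identical(km$nb, kp$nb))
    stop("kernel components have different neighbourhood support patterns")
  out <- km
  out$w <- km$w * kp$w
  out
}

#' Apply a kernel matrix (and its adjoint)
#'
#' `kernel_apply()` computes the activity image from kernel coefficients,
#' `lambda_j = sum_f alpha_f k_fj`; `kernel_apply_transpose()` is its exact
#' adjoint. For the (default) unnormalised symmetric-weight kernel the two
#' coincide; both are implemented generally so row-normalised kernels work
#' too.
#'
#' @param K a `kernel_matrix`.
#' @param x numeric vector or array of coefficients / image values.
#' @return numeric vector of length `prod(K$dim)`.
#' @export
kernel_apply <- function(K, x) {
  x <- as.numeric(x)
  if (length(x) != nrow(K$nb)) stop("coefficient length does not match kernel")
  xpad <- c(0, x)
  out <- numeric(length(x))
  for (f in seq_len(ncol(K$nb)))
    out <- out + K$w[, f] * xpad[K$nb[, f] + 1L]
  out
}

#' @rdname kernel_apply
#' @export
kernel_apply_transpose <- function(K, x) {
  x <- as.numeric(x)
  if (length(x) != nrow(K$nb)) stop("image length does not match kernel")
  out <- numeric(length(x))
  for (f in seq_len(ncol(K$nb))) {
    ok <- K$nb[, f] > 0L
    idx <- K$nb[ok, f]
    out[idx] <- out[idx] + K$w[ok, f] * x[ok]   # offset map is injective
  }
  out
}

#' Kernel matrix as a sparse Matrix
#'
#' Explicit `dgCMatrix` with `K[j, f] = k_fj`, mainly for testing against
#' dense linear algebra.
#'
#' @param K a `kernel_matrix`.
#' @return a `dgCMatrix` of dim V x V.
#' @export
as_sparse_kernel <- function(K) {
  V <- nrow(K$nb)
  j <- rep(seq_len(V), ncol(K$nb))
  f <- as.vector(K$nb)
  w <- as.vector(K$w)
  ok <- f > 0L & w != 0
  Matrix::sparseMatrix(i = j[ok], j = f[ok], x = w[ok], dims = c(V, V))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("voxel-wise kernel:", nrow(x$nb), "voxels,", ncol(x$nb),
      "-voxel neighbourhood,", if (x$normalised) "row-normalised"
      else "unnormalised", "\n")
  invisible(x)
}
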