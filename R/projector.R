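#' Parallel-beam tomographic geometry
#'
#' Describes a 2-D (or thin-slab, slice-by-slice) parallel-beam acquisition:
#' `n_angles` evenly spaced views over \[0, pi) and `n_radial` detector bins
#' whose field of view covers the image diagonal. The projector pair built
#' from this geometry is an exactly matched (true adjoint) linear operator,
#' which is what makes the multiplicative EM updates well behaved.
#'
#' @param image_dim image grid size: length 2 (`c(nx, ny)`) or 3 with the
#'   number of slices last.
#' @param image_spacing voxel spacing in mm, same length as `image_dim`.
#' @param n_angles number of projection angles (>= 2).
#' @param n_radial number of radial bins; default: smallest odd count whose
#'   extent covers the in-plane image diagonal.
#' @param radial_spacing radial bin width in mm (default: in-plane voxel
#'   size).
#' @return object of class `pet_geometry`.
#' @export
pet_geometry <- function(image_dim, image_spacing,
                         n_angles = 96L, n_radial = NULL,
                         radial_spacing = NULL) {
  stopifnot(length(image_dim) %in% c(2L, 3L),
            length(image_spacing) == length(image_dim),
            all(image_spacing > 0), n_angles >= 2L)
  if (is.null(radial_spacing)) radial_spacing <- image_spacing[1]
  diag_mm <- sqrt(sum((image_dim[1:2] * image_spacing[1:2])^2))
  if (is.null(n_radial)) {
    n_radial <- ceiling(diag_mm / radial_spacing)
    if (n_radial %% 2L == 0L) n_radial <- n_radial + 1L
  }
  if (n_radial * radial_spacing < diag_mm)
    stop("radial field of view does not cover the image diagonal")
  g <- list(image_dim = as.integer(image_dim),
            image_spacing = as.numeric(image_spacing),
            n_angles = as.integer(n_angles),
            n_radial = as.integer(n_radial),
            radial_spacing = as.numeric(radial_spacing),
            angles = (seq_len(n_angles) - 1) * pi / n_angles,
            cache = new.env(parent = emptyenv()))
  class(g) <- "pet_geometry"
  g
}

#' @export
print.pet_geometry <- function(x, ...) {
  cat("parallel-beam geometry:", x$n_angles, "angles x", x$n_radial,
      "radial bins (", signif(x$radial_spacing, 4), "mm ), image",
      paste(x$image_dim, collapse = " x "), "\n")
  invisible(x)
}

#' Sparse system matrix of the projector
#'
#' Assembles (and caches on the geometry object) the sparse matrix whose
#' rows are line integrals through the in-plane grid: each ray is sampled at
#' half-voxel steps with bilinear interpolation of the image, so forward and
#' back projection are exact transposes of one another by construction.
#' Row index is `(angle - 1) * n_radial + radial`; column index is the
#' column-major voxel index of one slice.
#'
#' @param geom a [pet_geometry()].
#' @return a `dgCMatrix` of dim `(n_angles * n_radial) x (nx * ny)`.
#' @export
system_matrix <- function(geom) {
  stopifnot(inherits(geom, "pet_geometry"))
  if (!is.null(geom$cache$A)) return(geom$cache$A)
  nx <- geom$image_dim[1]; ny <- geom$image_dim[2]
  hx <- geom$image_spacing[1]; hy <- geom$image_spacing[2]
  nr <- geom$n_radial
  r_pos <- (seq_len(nr) - (nr + 1) / 2) * geom$radial_spacing
  step <- hx / 2                      # ray sampling step, mm
  L <- nr * geom$radial_spacing
  s_pos <- seq(-L / 2, L / 2, by = step)
  ns <- length(s_pos)

  ii <- vector("list", geom$n_angles)
  jj <- vector("list", geom$n_angles)
  xx <- vector("list", geom$n_angles)
  for (a in seq_len(geom$n_angles)) {
    th <- geom$angles[a]
    # detector axis u, ray direction v
    px <- rep(r_pos, each = ns) * cos(th) - rep(s_pos, nr) * sin(th)
    py <- rep(r_pos, each = ns) * sin(th) + rep(s_pos, nr) * cos(th)
    row <- rep((a - 1L) * nr + seq_len(nr), each = ns)
    fx <- px / hx + (nx + 1) / 2      # fractional 1-based voxel index
    fy <- py / hy + (ny + 1) / 2
    ix <- floor(fx); wx <- fx - ix
    iy <- floor(fy); wy <- fy - iy
    tri_i <- c(row, row, row, row)
    tri_jx <- c(ix, ix + 1, ix, ix + 1)
    tri_jy <- c(iy, iy, iy + 1, iy + 1)
    tri_w <- step * c((1 - wx) * (1 - wy), wx * (1 - wy),
                      (1 - wx) * wy, wx * wy)
    ok <- tri_jx >= 1 & tri_jx <= nx & tri_jy >= 1 & tri_jy <= ny &
      tri_w > 0
    ii[[a]] <- tri_i[ok]
    jj[[a]] <- tri_jx[ok] + (tri_jy[ok] - 1) * nx
    xx[[a]] <- tri_w[ok]
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(geom$n_angles * nr, nx * ny))
  geom$cache$A <- A
  A
}

.check_image_dim <- function(image, geom) {
  d <- dim(image)
  if (is.null(d)) stop("image must be a matrix or array")
  if (length(d) == 2L) d <- c(d, 1L)
  gd <- geom$image_dim
  if (length(gd) == 2L) gd <- c(gd, 1L)
  if (!all(d == gd))
    stop("image grid ", paste(dim(image), collapse = "x"),
         " does not match geometry grid ", paste(geom$image_dim, collapse = "x"))
  d
}

.check_sino_dim <- function(sino, geom) {
  d <- dim(sino)
  if (is.null(d)) stop("sinogram must be a matrix or array")
  if (length(d) == 2L) d <- c(d, 1L)
  if (d[1] != geom$n_radial || d[2] != geom$n_angles)
    stop("sinogram of dim ", paste(dim(sino), collapse = "x"),
         " does not match geometry (", geom$n_radial, " radial x ",
         geom$n_angles, " angles)")
  d
}

#' Forward projection (line integrals)
#'
#' Projects an activity image into sinogram space. Linear and
#' nonnegativity-preserving; slices of a slab image are projected
#' independently.
#'
#' @param image matrix `(nx, ny)` or array `(nx, ny, nz)`.
#' @param geom a [pet_geometry()].
#' @return sinogram array `(n_radial, n_angles[, nz])`, units
#'   image-units x mm.
#' @export
forward_project <- function(image, geom) {
  d <- .check_image_dim(image, geom)
  A <- system_matrix(geom)
  nz <- d[3]
  out <- array(0, dim = c(geom$n_radial, geom$n_angles, nz))
  im <- array(image, dim = d)
  for (z in seq_len(nz))
    out[, , z] <- as.numeric(A %*% as.numeric(im[, , z]))
  if (length(dim(image)) == 2L) dim(out) <- c(geom$n_radial, geom$n_angles)
  out
}

#' Back projection (adjoint of [forward_project()])
#'
#' @param sino sinogram matrix `(n_radial, n_angles)` or array with slices.
#' @param geom a [pet_geometry()].
#' @return image array matching the geometry grid.
#' @export
back_project <- function(sino, geom) {
  d <- .check_sino_dim(sino, geom)
  A <- system_matrix(geom)
  nz <- d[3]
  nx <- geom$image_dim[1]; ny <- geom$image_dim[2]
  out <- array(0, dim = c(nx, ny, nz))
  sn <- array(sino, dim = d)
  for (z in seq_len(nz))
    out[, , z] <- as.numeric(Matrix::crossprod(A, as.numeric(sn[, , z])))
  if (length(dim(sino)) == 2L) dim(out) <- c(nx, ny)
  out
}

#' Attenuation correction factors
#'
#' Survival probability per line of response: `exp(-integral of mu)` along
#' each ray, with mu in mm^-1 and path length in mm; values in (0, 1].
#'
#' @param mu attenuation map matching the geometry grid, mm^-1, >= 0.
#' @param geom a [pet_geometry()].
#' @return sinogram-shaped array of factors.
#' @export
attenuation_factors <- function(mu, geom) {
  if (any(mu < 0)) stop("attenuation coefficients must be nonnegative")
  exp(-forward_project(mu, geom))
}

#' Interleaved angle subsets
#'
#' Partition of the projection angles for ordered-subsets reconstruction:
#' subset s takes angles s, s + n_subsets, s + 2 n_subsets, ... The subsets
#' are disjoint, cover all angles, and are maximally spread in angle.
#'
#' @param n_angles number of projection angles (or a [pet_geometry()]).
#' @param n_subsets number of subsets, <= `n_angles`.
#' @return list of integer vectors of 1-based angle indices.
#' @export
partition_subsets <- function(n_angles, n_subsets) {
  if (inherits(n_angles, "pet_geometry")) n_angles <- n_angles$n_angles
  n_angles <- as.integer(n_angles); n_subsets <- as.integer(n_subsets)
  if (n_subsets < 1L || n_subsets > n_angles)
    stop("n_subsets must be between 1 and the number of angles")
  lapply(seq_len(n_subsets), function(s) seq.int(s, n_angles, by = n_subsets))
}

# sinogram row indices (per slice) belonging to a vector of angle indices
.subset_rows <- function(geom, angle_idx) {
  as.vector(outer(seq_len(geom$n_radial),
                  (angle_idx - 1L) * geom$n_radial, `+`))
}
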