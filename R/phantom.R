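#' Synthetic dynamic phantom for blood-pool IDIF studies
#'
#' Builds a labelled voxel phantom emulating a preclinical abdominal field of
#' view: a soft-tissue body disc containing one large high-uptake organ, one
#' mid-sized organ, and a narrow cylindrical aorta whose diameter (default
#' 5 mm) is of the same order as the reconstruction resolution, so that the
#' partial volume effect on the blood-pool ROI is representative. Alongside
#' the label map it returns a water-like attenuation map and an anatomical
#' guidance image (piecewise constant per tissue plus optional Gaussian
#' texture noise) standing in for a segmented MR image.
#'
#' Geometry is 2-D by default (`n_slices = 1`); a thin 3-D slab is obtained
#' with `n_slices >= 3`, in which case organs are extruded along the axial
#' direction.
#'
#' @param grid_dim in-plane grid size, length-2 integer (default `c(96, 96)`).
#' @param spacing in-plane voxel spacing in mm (default 1.56 mm isotropic).
#' @param n_slices number of axial slices (1 = single-slice mode).
#' @param z_spacing axial voxel spacing in mm.
#' @param aorta_diameter_mm diameter of the aortic blood pool.
#' @param body_diameter_mm diameter of the soft-tissue body disc.
#' @param organ_large_diameter_mm,organ_mid_diameter_mm organ disc diameters.
#' @param mu_soft linear attenuation coefficient for all tissues, mm^-1
#'   (air is 0).
#' @param guidance_values named numeric vector of guidance-image intensities
#'   per tissue (air is 0); the blood pool is the brightest structure.
#' @param guidance_noise_sd standard deviation of additive Gaussian noise on
#'   the guidance image, in guidance intensity units (0 = noiseless).
#' @param seed optional seed for the guidance noise.
#' @return an object of class `petkem_phantom`: a list with `labels`
#'   (integer array), `label_names` (named integer vector), `spacing`
#'   (length-3, mm), `mu` (array, mm^-1), `guidance` (array), and
#'   `body_mask` (logical array, labels > 0).
#' @examples
#' ph <- make_phantom(grid_dim = c(64, 64))
#' sum(ph$labels == ph$label_names[["aorta"]])
#' @export
make_phantom <- function(grid_dim = c(96, 96),
                         spacing = c(1.56, 1.56),
                         n_slices = 1L,
                         z_spacing = 2.031,
                         aorta_diameter_mm = 5,
                         body_diameter_mm = 120,
                         organ_large_diameter_mm = 40,
                         organ_mid_diameter_mm = 16,
                         mu_soft = 0.0096,
                         guidance_values = c(soft_tissue = 1, organ_large = 2,
                                             organ_mid = 1.5, aorta = 3),
                         guidance_noise_sd = 0.05,
                         seed = NULL) {
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 2L || any(grid_dim < 32L))
    stop("grid_dim must have two entries, each >= 32")
  if (any(spacing <= 0) || z_spacing <= 0)
    stop("voxel spacing must be positive")
  if (aorta_diameter_mm < 2 * min(spacing))
    stop("aorta diameter below 2 voxels gives a degenerate ROI; ",
         "increase aorta_diameter_mm or refine spacing")
  n_slices <- as.integer(n_slices)
  stopifnot(n_slices >= 1L)

  nx <- grid_dim[1]; ny <- grid_dim[2]
  hx <- spacing[1]; hy <- spacing[2]
  # voxel centres, grid centred on the origin
  xs <- (seq_len(nx) - (nx + 1) / 2) * hx
  ys <- (seq_len(ny) - (ny + 1) / 2) * hy
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)

  # snap the aorta centre to a voxel centre so its voxel footprint is stable
  snap <- function(v, grid) grid[which.min(abs(grid - v))]
  aorta_centre <- c(snap(hx / 2, xs), snap(hy / 2, ys))

  disc <- function(cx, cy, diameter)
    (X - cx)^2 + (Y - cy)^2 <= (diameter / 2)^2

  labels <- matrix(0L, nx, ny)
  body <- disc(0, 0, body_diameter_mm)
  labels[body] <- 1L
  # organ centres scale with the body so any body size keeps all tissues;
  # organs and vessel are clipped to the body so the anatomy stays physical
  c_lg <- body_diameter_mm * c(-0.21, 0.10)
  c_md <- body_diameter_mm * c(0.18, -0.17)
  labels[body & disc(c_lg[1], c_lg[2], organ_large_diameter_mm)] <- 2L
  labels[body & disc(c_md[1], c_md[2], organ_mid_diameter_mm)] <- 3L
  labels[body & disc(aorta_centre[1], aorta_centre[2], aorta_diameter_mm)] <- 4L
  if (!any(labels == 4L))
    stop("aorta region is empty; enlarge aorta_diameter_mm")

  label_names <- c(soft_tissue = 1L, organ_large = 2L,
                   organ_mid = 3L, aorta = 4L)

  guide2d <- matrix(0, nx, ny)
  for (nm in names(label_names))
    guide2d[labels == label_names[[nm]]] <- guidance_values[[nm]]

  to_slab <- function(m) array(rep(m, n_slices), dim = c(nx, ny, n_slices))
  labs <- to_slab(labels)
  storage.mode(labs) <- "integer"
  mu <- to_slab(matrix(ifelse(labels > 0L, mu_soft, 0), nx, ny))
  guidance <- to_slab(guide2d)
  if (guidance_noise_sd > 0) {
    if (!is.null(seed)) {
      old <- .save_rng_state()
      on.exit(.restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    guidance <- guidance + array(stats::rnorm(length(guidance),
                                              sd = guidance_noise_sd),
                                 dim = dim(guidance))
  }

  structure(list(labels = labs,
                 label_names = label_names,
                 spacing = c(spacing, z_spacing),
                 mu = mu,
                 guidance = guidance,
                 body_mask = labs > 0L,
                 aorta_centre_mm = aorta_centre),
            class = "petkem_phantom")
}

#' @export
print.petkem_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("petkem phantom:", paste(d, collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  cat("tissues:", paste(names(x$label_names), collapse = ", "), "\n")
  cat("aorta voxels per slice:", sum(x$labels[, , 1] == 4L), "\n")
  invisible(x)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Dynamic frame scheme
#'
#' Expands a compact `(count, duration)` specification into a contiguous,
#' non-overlapping list of frames starting at t = 0. The default scheme is
#' the 45-frame dynamic protocol 17 x 6 s, 4 x 15 s, 4 x 30 s, 4 x 60 s,
#' 4 x 180 s, 12 x 300 s (80.7 min total).
#'
#' @param spec list of length-2 numeric vectors `c(count, duration_s)`.
#' @return a data.frame of class `frame_scheme` with columns `start`,
#'   `duration`, `end`, `mid` (seconds).
#' @examples
#' fs <- make_frame_scheme()
#' nrow(fs)          # 45
#' sum(fs$duration)  # 4842
#' @export
make_frame_scheme <- function(spec = default_frame_spec()) {
  if (length(spec) == 0L) stop("frame specification is empty")
  counts <- vapply(spec, `[`, numeric(1), 1L)
  durs <- vapply(spec, `[`, numeric(1), 2L)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("frame counts must be positive integers")
  if (any(durs <= 0)) stop("frame durations must be positive")
  duration <- rep(durs, times = counts)
  start <- cumsum(c(0, duration[-length(duration)]))
  out <- data.frame(start = start, duration = duration,
                    end = start + duration, mid = start + duration / 2)
  class(out) <- c("frame_scheme", "data.frame")
  out
}

#' @rdname make_frame_scheme
#' @export
default_frame_spec <- function() {
  list(c(17, 6), c(4, 15), c(4, 30), c(4, 60), c(4, 180), c(12, 300))
}

#' Parametric tissue time-activity curves
#'
#' Evaluates an activity concentration curve a(t) in kBq/mL at times `t`
#' (seconds). Two models are provided:
#'
#' * `"blood"` — an arterial input function of Feng type: after a delay
#'   `delay`, a ramp-times-exponential bolus plus two slower exponentials,
#'   `a(t') = (A1 t' - A2 - A3) exp(-l1 t') + A2 exp(-l2 t') + A3 exp(-l3 t')`
#'   with `t' = t - delay`, zero before the delay. The default parameters
#'   give a sharp peak near 25 s post-injection (well before 60 s) of about
#'   50 kBq/mL and a slowly decaying tail of a few kBq/mL, the shape expected
#'   of a venous bolus in a 90-min tracer study.
#' * `"uptake"` — a mono-exponential approach to a plateau,
#'   `a(t) = plateau (1 - exp(-t / tau))`, for background organs and tissues.
#'
#' Both models satisfy a(0) = 0 and a(t) >= 0.
#'
#' @param model `"blood"` or `"uptake"`.
#' @param params named list of model parameters; see
#'   [default_blood_params()] and [default_uptake_params()].
#' @param t times in seconds (vectorised), all >= 0.
#' @return activity concentrations, kBq/mL.
#' @examples
#' t <- seq(0, 300, by = 1)
#' peak_t <- t[which.max(tissue_tac("blood", t = t))]
#' @export
tissue_tac <- function(model = c("blood", "uptake"), params = NULL, t) {
  model <- match.arg(model)
  if (any(t < 0)) stop("negative times are not allowed")
  if (is.null(params))
    params <- switch(model, blood = default_blood_params(),
                     uptake = default_uptake_params())
  if (model == "blood") {
    p <- params
    stopifnot(p$A1 > 0, p$l1 > 0, p$l2 > 0, p$l3 > 0, p$delay >= 0)
    tp <- pmax(t - p$delay, 0)
    a <- (p$A1 * tp - p$A2 - p$A3) * exp(-p$l1 * tp) +
      p$A2 * exp(-p$l2 * tp) + p$A3 * exp(-p$l3 * tp)
    a[t <= p$delay] <- 0
    pmax(a, 0)
  } else {
    p <- params
    stopifnot(p$plateau >= 0, p$tau > 0)
    p$plateau * (1 - exp(-t / p$tau))
  }
}

#' @rdname tissue_tac
#' @export
default_blood_params <- function() {
  # rate constants are the classic tri-exponential input-function values
  # expressed per second; amplitudes scaled to a ~50 kBq/mL peak
  # delay 4 s: tracer reaches the aorta within seconds of injection at scan
  # start, so every frame (including 0-6 s) has positive true activity
  list(A1 = 9.5, A2 = 2.5, A3 = 5, l1 = 0.069, l2 = 0.002,
       l3 = 0.000175, delay = 4)
}

#' @rdname tissue_tac
#' @export
default_uptake_params <- function() list(plateau = 10, tau = 300)

#' Default tissue TAC table
#'
#' Maps each phantom tissue to its activity model: the aorta carries the
#' blood input function; organs and soft tissue follow saturating uptake
#' curves with organ-dependent plateaus, so the blood peak precedes every
#' tissue maximum and late frames show tissue activity above blood.
#'
#' @return a named list of class `tac_table`; each entry is
#'   `list(model =, params =)`.
#' @export
default_tac_table <- function() {
  structure(list(
    soft_tissue = list(model = "uptake",
                       params = list(plateau = 4, tau = 600)),
    organ_large = list(model = "uptake",
                       params = list(plateau = 25, tau = 300)),
    organ_mid = list(model = "uptake",
                     params = list(plateau = 12, tau = 400)),
    aorta = list(model = "blood", params = default_blood_params())
  ), class = "tac_table")
}

#' Frame-averaged activity of a single TAC
#'
#' Time average of a tissue curve over one frame by the trapezoid rule with
#' a fixed step (default 0.1 s; the early 6-s frames change rapidly, so
#' mid-frame sampling would be biased).
#'
#' @param entry one `tac_table` entry (`list(model, params)`).
#' @param start,duration frame start and duration, seconds.
#' @param dt quadrature step, seconds.
#' @return mean activity over the frame, kBq/mL.
#' @export
frame_average_tac <- function(entry, start, duration, dt = 0.1) {
  stopifnot(duration > 0)
  n <- max(2L, as.integer(ceiling(duration / dt)) + 1L)
  tt <- seq(start, start + duration, length.out = n)
  a <- tissue_tac(entry$model, entry$params, tt)
  w <- rep(1, n); w[c(1, n)] <- 0.5
  sum(w * a) / (n - 1)
}

#' Voxelise frame-averaged activity onto the phantom
#'
#' Assigns to every voxel the frame-averaged activity concentration of its
#' tissue (air stays 0), producing the noiseless ground-truth activity image
#' for one frame.
#'
#' @param phantom a `petkem_phantom`.
#' @param tacs a `tac_table`; must contain every named tissue of the phantom.
#' @param frame a length-2 numeric `c(start, duration)` or a single row of a
#'   [make_frame_scheme()] data frame.
#' @param dt quadrature step for the frame average, seconds.
#' @return activity image (array, same dim as the phantom), kBq/mL.
#' @export
sample_activity_image <- function(phantom, tacs, frame, dt = 0.1) {
  if (is.data.frame(frame)) frame <- c(frame$start[1], frame$duration[1])
  missing_lab <- setdiff(names(phantom$label_names), names(tacs))
  if (length(missing_lab))
    stop("no TAC defined for tissue(s): ", paste(missing_lab, collapse = ", "))
  img <- array(0, dim = dim(phantom$labels))
  for (nm in names(phantom$label_names)) {
    val <- frame_average_tac(tacs[[nm]], frame[1], frame[2], dt = dt)
    img[phantom$labels == phantom$label_names[[nm]]] <- val
  }
  img
}

#' Ground-truth IDIF over a frame scheme
#'
#' Frame-averaged blood (aorta) activity for every frame — the reference
#' values against which reconstructed IDIF means are compared.
#'
#' @param tacs a `tac_table` containing an `aorta` entry.
#' @param scheme a [make_frame_scheme()] data frame.
#' @param dt quadrature step, seconds.
#' @return numeric vector, one kBq/mL value per frame.
#' @export
true_idif <- function(tacs, scheme, dt = 0.1) {
  vapply(seq_len(nrow(scheme)), function(k)
    frame_average_tac(tacs$aorta, scheme$start[k], scheme$duration[k], dt = dt),
    numeric(1))
}
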