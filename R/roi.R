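#' Volume grid container
#'
#' Minimal axis-aligned volumetric image: an intensity array with voxel
#' spacing and world origin in millimetres, plus a declaration of which
#' world axis is the sagittal (left-right) axis, used to fix the in-plane
#' rotation of extracted slices.
#'
#' @param intensities 3-D numeric array.
#' @param spacing Length-3 mm-per-voxel along each array axis.
#' @param origin Length-3 world coordinate (mm) of voxel (1, 1, 1).
#' @param sagittal_axis Index (1-3) of the sagittal world axis.
#' @return A `tavr_volume`.
#' @export
volume_grid <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        sagittal_axis = 1) {
  stopifnot(length(dim(intensities)) == 3, all(spacing > 0))
  structure(
    list(
      intensities = intensities, spacing = as.numeric(spacing),
      origin = as.numeric(origin), sagittal_axis = as.integer(sagittal_axis)
    ),
    class = "tavr_volume"
  )
}

#' Aortic centerline landmarks
#'
#' Five ordered 3-D points (mm, world frame) on the aortic centerline from
#' the aortic root to the ascending aorta.
#'
#' @param points 5x3 numeric matrix (rows ordered root to ascending aorta).
#' @return A `tavr_landmarks`.
#' @export
landmark_set <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 5 || ncol(points) != 3) {
    abort("landmarks must be a 5x3 matrix of mm coordinates")
  }
  d <- sqrt(rowSums(diff(points)^2))
  if (any(d < 1e-9)) abort("consecutive landmarks must be distinct")
  structure(list(points = points), class = "tavr_landmarks")
}

#' Read landmarks from JSON
#'
#' Expects `{"points_mm": [[x,y,z], ...x5]}`.
#'
#' @param path JSON file path.
#' @return A `tavr_landmarks`.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::fromJSON(path)
  landmark_set(matrix(unlist(j$points_mm), ncol = 3, byrow = !is.matrix(j$points_mm)))
}

#' @rdname read_landmarks
#' @param landmarks A `tavr_landmarks`.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(
    list(points_mm = unname(landmarks$points)),
    path,
    digits = NA
  )
  invisible(path)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti. Only axis-aligned orientations are
#' interpreted; the voxel spacing is taken from the header and the origin
#' from the translation part of the xform.
#'
#' @param path NIfTI file path.
#' @param sagittal_axis Declared sagittal world axis index.
#' @return `read_volume()`: a `tavr_volume`.
#' @export
read_volume <- function(path, sagittal_axis = 1) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  volume_grid(array(as.numeric(img), dim(img)),
    spacing = abs(sp),
    origin = xf[1:3, 4], sagittal_axis = sagittal_axis
  )
}

#' @rdname read_volume
#' @param volume A `tavr_volume`.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$intensities
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr, datatype = "float")
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Fit a smoothing-spline centerline through the landmarks
#'
#' Each coordinate is fitted as a cubic smoothing spline against the
#' chord-length parameter of the five landmarks. `smoothing = 0`
#' interpolates the landmarks exactly; positive values trade fidelity for
#' smoothness to absorb landmark-localisation error. Whatever smoothing is
#' requested, the fit is relaxed (halving the penalty) until the maximum
#' deviation from the landmarks is at most `max_deviation` mm — half the
#' reported mean localisation error of automatic landmark placement.
#'
#' @param landmarks A [landmark_set()].
#' @param smoothing Non-negative smoothing penalty (`lambda` of
#'   [stats::smooth.spline()]); default `1e-3`.
#' @param max_deviation Maximum allowed landmark deviation in mm.
#' @param n_dense Dense samples used for the arc-length table.
#' @return A `tavr_centerline` with coordinate functions, derivatives and
#'   an arc-length table.
#' @export
fit_centerline <- function(landmarks, smoothing = 1e-3, max_deviation = 2,
                           n_dense = 2001) {
  if (smoothing < 0) abort("smoothing must be non-negative")
  pts <- landmarks$points
  tt <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  tt <- tt / max(tt)

  fit_coord <- function(lambda) {
    lapply(1:3, function(ax) {
      if (lambda == 0) {
        fn <- splinefun(tt, pts[, ax], method = "natural")
        list(f = fn, df = function(x) fn(x, deriv = 1))
      } else {
        sm <- smooth.spline(tt, pts[, ax], lambda = lambda, all.knots = TRUE,
                            keep.data = FALSE)
        list(
          f = function(x) predict(sm, x)$y,
          df = function(x) predict(sm, x, deriv = 1)$y
        )
      }
    })
  }

  lambda <- smoothing
  repeat {
    coords <- fit_coord(lambda)
    fitted_pts <- sapply(coords, function(cc) cc$f(tt))
    dev <- max(sqrt(rowSums((fitted_pts - pts)^2)))
    if (dev <= max_deviation || lambda == 0) break
    lambda <- if (lambda > 1e-8) lambda / 2 else 0
  }

  ts <- seq(0, 1, length.out = n_dense)
  dense <- sapply(coords, function(cc) cc$f(ts))
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  if (max(arc) <= 0) abort("degenerate zero-length centerline")
  structure(
    list(
      coords = coords, t_dense = ts, points_dense = dense, arc = arc,
      length = max(arc), lambda = lambda, landmark_deviation = dev
    ),
    class = "tavr_centerline"
  )
}

#' Sample points at equal arc-length along a centerline
#'
#' @param curve A [fit_centerline()] result.
#' @param n Number of samples (inclusive of both ends).
#' @return List with `centers` (n x 3 mm), `tangents` (n x 3, unit) and
#'   `spacing` (mm between consecutive samples).
#' @export
sample_centerline <- function(curve, n = 64) {
  if (n < 2) abort("need at least 2 samples")
  target <- seq(0, curve$length, length.out = n)
  ts <- approx(curve$arc, curve$t_dense, xout = target, ties = "ordered")$y
  centers <- sapply(curve$coords, function(cc) cc$f(ts))
  tang <- sapply(curve$coords, function(cc) cc$df(ts))
  tang <- tang / sqrt(rowSums(tang^2))
  list(centers = centers, tangents = tang, spacing = curve$length / (n - 1))
}

#' In-plane frame of a slice perpendicular to the centerline
#'
#' One in-plane axis is forced to the projection of the sagittal axis onto
#' the slice plane (removing the free rotation about the tangent); the
#' second completes a right-handed orthonormal triad `{u, v, t}`. If the
#' tangent is (numerically) parallel to the sagittal axis the axial axis is
#' used for the projection instead, and a message is emitted.
#'
#' @param tangent Unit tangent vector.
#' @param sagittal_axis Unit sagittal direction.
#' @param axial_axis Fallback projection direction.
#' @return List with unit vectors `u` and `v`.
#' @export
slice_frame <- function(tangent, sagittal_axis = c(1, 0, 0),
                        axial_axis = c(0, 0, 1)) {
  t_ <- tangent / sqrt(sum(tangent^2))
  s <- sagittal_axis / sqrt(sum(sagittal_axis^2))
  if (abs(sum(s * t_)) > 1 - 1e-6) {
    inform("tangent parallel to sagittal axis; projecting the axial axis instead")
    s <- axial_axis / sqrt(sum(axial_axis^2))
  }
  u <- s - sum(s * t_) * t_
  u <- u / sqrt(sum(u^2))
  v <- cross3(t_, u)
  list(u = u, v = v)
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Vectorized trilinear interpolation at world points (n x 3, mm).
# Out-of-volume positions get `fill`; the count is returned as an attribute.
trilinear_sample <- function(volume, pts, fill = -1000) {
  vx <- sweep(sweep(pts, 2, volume$origin), 2, volume$spacing, "/") + 1
  d <- dim(volume$intensities)
  i0 <- floor(vx)
  fr <- vx - i0
  inside <- vx[, 1] >= 1 & vx[, 1] <= d[1] &
    vx[, 2] >= 1 & vx[, 2] <= d[2] &
    vx[, 3] >= 1 & vx[, 3] <= d[3]
  # clamp so corner gathering stays in bounds; results outside get fill
  i0c <- pmin(pmax(i0, 1), rep(d - 1, each = nrow(pts)))
  frc <- pmin(pmax(vx - i0c, 0), 1)
  g <- function(dx, dy, dz) {
    volume$intensities[cbind(i0c[, 1] + dx, i0c[, 2] + dy, i0c[, 3] + dz)]
  }
  w <- function(f, delta) if (delta == 1) f else 1 - f
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    out <- out + g(dx, dy, dz) *
      w(frc[, 1], dx) * w(frc[, 2], dy) * w(frc[, 3], dz)
  }
  out[!inside] <- fill
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Resample one oblique slice from a volume
#'
#' Samples a `size x size` grid on the plane through `center` spanned by
#' the orthonormal frame `(u, v)`, by trilinear interpolation. Positions
#' outside the volume are filled with `fill` (air, -1000 HU) and counted.
#'
#' @param volume A `tavr_volume`.
#' @param center Plane center (mm).
#' @param frame List with unit vectors `u`, `v` from [slice_frame()].
#' @param size Slice size in pixels.
#' @param in_plane_spacing mm per pixel.
#' @param fill Fill value for out-of-volume samples.
#' @return `size x size` matrix with attribute `n_outside`.
#' @export
resample_slice <- function(volume, center, frame, size = 64,
                           in_plane_spacing = 1, fill = -1000) {
  off <- (seq_len(size) - (size + 1) / 2) * in_plane_spacing
  grid <- expand.grid(a = off, b = off)
  pts <- outer(grid$a, frame$u) + outer(grid$b, frame$v) +
    matrix(center, nrow(grid), 3, byrow = TRUE)
  vals <- trilinear_sample(volume, pts, fill)
  out <- matrix(vals, size, size)
  attr(out, "n_outside") <- attr(vals, "n_outside")
  out
}

#' ROI extraction configuration
#'
#' @param n_slices,size ROI dimensions (64 x 64 x 64 by default).
#' @param in_plane_spacing mm per in-plane pixel (default 1 mm isotropic;
#'   the slice spacing along the centerline is `arc length / (n_slices-1)`).
#' @param smoothing Centerline smoothing penalty.
#' @param fill Out-of-volume fill (HU).
#' @return A list of class `tavr_roi_config`.
#' @export
roi_config <- function(n_slices = 64, size = 64, in_plane_spacing = 1,
                       smoothing = 1e-3, fill = -1000) {
  structure(
    list(
      n_slices = n_slices, size = size, in_plane_spacing = in_plane_spacing,
      smoothing = smoothing, fill = fill
    ),
    class = "tavr_roi_config"
  )
}

#' Extract the straightened 64x64x64 ROI
#'
#' The four-step straightening: (1) fit a cubic smoothing spline through
#' the five landmarks; (2) place `n_slices` points at equal arc length
#' along it; (3) at each point resample a square slice perpendicular to the
#' local tangent, rotationally fixed by the sagittal projection; (4) stack
#' the slices. The result follows the aorta from root through ascending
#' aorta with the vessel axis mapped to the stack axis.
#'
#' @param volume A `tavr_volume`.
#' @param landmarks A [landmark_set()] within the volume bounds.
#' @param config A [roi_config()].
#' @return A `tavr_roi`: 64x64x64 intensities plus spacing and provenance.
#' @export
extract_roi <- function(volume, landmarks, config = roi_config()) {
  bb_lo <- volume$origin
  bb_hi <- volume$origin + (dim(volume$intensities) - 1) * volume$spacing
  pts <- landmarks$points
  if (any(sweep(pts, 2, bb_lo) < 0) || any(sweep(pts, 2, bb_hi) > 0)) {
    abort("landmarks fall outside the volume bounding box")
  }
  curve <- fit_centerline(landmarks, smoothing = config$smoothing)
  samp <- sample_centerline(curve, config$n_slices)
  sag <- diag(3)[volume$sagittal_axis, ]
  roi <- array(0, c(config$size, config$size, config$n_slices))
  n_outside <- 0
  for (i in seq_len(config$n_slices)) {
    fr <- slice_frame(samp$tangents[i, ], sag)
    sl <- resample_slice(
      volume, samp$centers[i, ], fr,
      size = config$size, in_plane_spacing = config$in_plane_spacing,
      fill = config$fill
    )
    n_outside <- n_outside + attr(sl, "n_outside")
    roi[, , i] <- sl
  }
  structure(
    list(
      intensities = roi,
      slice_spacing = samp$spacing,
      in_plane_spacing = config$in_plane_spacing,
      n_outside = n_outside,
      provenance = list(
        landmarks = landmarks$points, config = unclass(config),
        config_hash = rlang::hash(list(landmarks$points, unclass(config)))
      )
    ),
    class = "tavr_roi"
  )
}

#' @export
print.tavr_roi <- function(x, ...) {
  cat("<tavr_roi> 64x64x64, slice spacing ",
    signif(x$slice_spacing, 4), " mm, in-plane ",
    signif(x$in_plane_spacing, 4), " mm, ", x$n_outside,
    " out-of-volume samples\n",
    sep = ""
  )
  invisible(x)
}
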