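#' Extract the sample mask by background subtraction
#'
#' Thresholds the absolute difference between the sample image and the
#' background image at a fraction of the difference's dynamic range, then
#' cleans the result morphologically (opening, largest connected component,
#' hole filling). The mask's orientation is taken from the second-order
#' image moments and its centroid recorded.
#'
#' @param sample_image,background_image Intensity matrices of identical
#'   size, or a `scene_images` object passed as `sample_image`.
#' @param threshold Fraction of the difference dynamic range (default 0.1).
#' @param mm_per_pixel Scale in mm per pixel (taken from the scene object
#'   when one is supplied).
#' @return An object of class `sample_mask`: logical `mask`, `mm_per_pixel`,
#'   `principal_angle` (degrees, in (-90, 90]), `centroid` (x, y in pixels)
#'   plus moment-based centroid and extents in mm.
#' @export
subtract_background <- function(sample_image, background_image = NULL,
                                threshold = 0.1, mm_per_pixel = NULL) {
  if (inherits(sample_image, "scene_images")) {
    scn <- sample_image
    sample_image <- scn$sample
    background_image <- scn$background
    if (is.null(mm_per_pixel)) mm_per_pixel <- scn$mm_per_pixel
  }
  if (is.null(mm_per_pixel))
    stop("mm_per_pixel must be supplied with raw image matrices", call. = FALSE)
  if (!all(dim(sample_image) == dim(background_image)))
    stop("sample and background images must have the same size", call. = FALSE)
  d <- abs(sample_image - background_image)
  rng <- range(d)
  mask <- d > rng[1] + threshold * (rng[2] - rng[1])
  if (!any(mask)) stop("no sample detected", call. = FALSE)
  mask <- clean_mask(mask)
  if (!any(mask)) stop("no sample detected", call. = FALSE)
  new_sample_mask(mask, mm_per_pixel)
}

# morphological cleanup: opening, keep largest component, fill holes
clean_mask <- function(mask) {
  img <- EBImage::Image(mask * 1)
  brush <- EBImage::makeBrush(3, shape = "diamond")
  img <- EBImage::opening(img, brush)
  lab <- EBImage::bwlabel(img)
  tab <- tabulate(as.integer(lab[lab > 0]))
  if (length(tab) == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  img <- EBImage::Image((lab == which.max(tab)) * 1)
  img <- EBImage::fillHull(img)
  matrix(as.logical(EBImage::imageData(img) > 0.5), nrow(mask), ncol(mask))
}

# Image matrices are stored rows = y, cols = x; moments computed in mm.
new_sample_mask <- function(mask, mm_per_pixel, applied_rotation = 0) {
  s <- mm_per_pixel
  idx <- which(mask, arr.ind = TRUE)
  xs <- (idx[, 2] - 0.5) * s
  ys <- (idx[, 1] - 0.5) * s
  cx <- mean(xs); cy <- mean(ys)
  mu20 <- mean((xs - cx)^2); mu02 <- mean((ys - cy)^2)
  mu11 <- mean((xs - cx) * (ys - cy))
  if (abs(mu20 - mu02) < 1e-9 && abs(mu11) < 1e-9) {
    ang <- 0                      # isotropic mask: nothing to align
  } else {
    ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  }
  # report the major-axis angle; ties toward the longer bounding-box side
  structure(list(mask = mask, mm_per_pixel = s,
                 principal_angle = ang,
                 centroid = c(x = cx / s + 0.5, y = cy / s + 0.5),
                 centroid_mm = c(x = cx, y = cy),
                 extents_mm = c(x = sqrt(12 * mu20), y = sqrt(12 * mu02)),
                 area_mm2 = nrow(idx) * s^2,
                 applied_rotation = applied_rotation),
            class = "sample_mask")
}

#' @export
print.sample_mask <- function(x, ...) {
  cat(sprintf(
    "sample_mask: %d px (%.0f mm^2), angle %.2f deg, centroid (%.1f, %.1f) px\n",
    sum(x$mask), x$area_mm2, x$principal_angle, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Rotate the sample mask so its long axis aligns with x
#'
#' Software equivalent of the platform's rotation stage: the mask is rotated
#' about its centroid by minus its principal angle (nearest-neighbour
#' resampling, then closing and hole filling to smooth rasterisation
#' staircases). The applied rotation is recorded so grids built on the
#' normalised mask can be mapped back to the original image frame.
#'
#' @param mask A `sample_mask`.
#' @return A `sample_mask` whose `principal_angle` is close to zero and
#'   whose `applied_rotation` holds the angle that was removed.
#' @export
normalize_orientation <- function(mask) {
  stopifnot(inherits(mask, "sample_mask"))
  th <- mask$principal_angle
  if (abs(th) < 1e-6) {
    out <- mask
    out$applied_rotation <- mask$applied_rotation
    return(out)
  }
  m <- rotate_mask(mask$mask, th * pi / 180, mask$centroid)
  img <- EBImage::Image(m * 1)
  img <- EBImage::closing(img, EBImage::makeBrush(3, shape = "diamond"))
  img <- EBImage::fillHull(img)
  m <- matrix(as.logical(EBImage::imageData(img) > 0.5), nrow(m), ncol(m))
  new_sample_mask(m, mask$mm_per_pixel,
                  applied_rotation = mask$applied_rotation + th)
}

# Rotate a logical image by -theta about centre (given in pixel units):
# output pixel p takes the value of input at R(+theta) (p - c) + c.
rotate_mask <- function(mask, theta, centre) {
  nr <- nrow(mask); nc <- ncol(mask)
  cx <- centre[1]; cy <- centre[2]
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  rows <- matrix(rep(seq_len(nr), nc), nr, nc) - cy
  sx <- round(cos(theta) * cols - sin(theta) * rows + cx)
  sy <- round(sin(theta) * cols + cos(theta) * rows + cy)
  ok <- sx >= 1 & sx <= nc & sy >= 1 & sy <= nr
  out <- matrix(FALSE, nr, nc)
  out[ok] <- mask[cbind(sy[ok], sx[ok])]
  out
}

#' Build the indentation grid over a sample mask
#'
#' Lays an axis-aligned lattice with the given step over the mask, anchored
#' at the moment-based bounding box (centroid minus half the moment
#' extents - sub-pixel stable under re-rendering and rotation), and keeps
#' the points whose probe footprint, eroded by `margin`, lies inside the
#' mask: a point survives iff its distance to the nearest background pixel
#' is at least `margin`. Points are returned in row-major order in
#' sample-frame millimetres (origin at the moment bounding-box corner).
#'
#' @param mask A `sample_mask` (normally orientation-normalised first).
#' @param step Lattice step in mm (default 2).
#' @param margin Required clearance in mm between a grid point and the mask
#'   border (default 1.5, the probe radius, so the 3 mm probe face never
#'   overhangs the sample edge). `margin = 0` keeps every in-mask point.
#' @return An `indentation_grid`: `points` data frame (x, y in mm), `step`,
#'   `margin`, `mm_per_pixel` and the world-frame `origin_mm` of the lattice.
#' @export
build_indentation_grid <- function(mask, step = 2, margin = 1.5) {
  stopifnot(inherits(mask, "sample_mask"))
  if (!is.finite(step) || step <= 0) stop("step must be positive", call. = FALSE)
  if (!is.finite(margin) || margin < 0)
    stop("margin must be non-negative", call. = FALSE)
  s <- mask$mm_per_pixel
  dist_px <- EBImage::imageData(EBImage::distmap(EBImage::Image(t(mask$mask) * 1)))
  dist_px <- t(dist_px)   # back to rows = y
  x0 <- mask$centroid_mm[["x"]] - mask$extents_mm[["x"]] / 2
  y0 <- mask$centroid_mm[["y"]] - mask$extents_mm[["y"]] / 2
  xs <- x0 + step * seq(0, floor(mask$extents_mm[["x"]] / step + 1e-9))
  ys <- y0 + step * seq(0, floor(mask$extents_mm[["y"]] / step + 1e-9))
  thr <- max(margin / s, 1e-9)
  keep_x <- keep_y <- numeric(0)
  for (y in ys) for (x in xs) {
    col <- floor(x / s) + 1L; row <- floor(y / s) + 1L
    if (col >= 1L && col <= ncol(dist_px) && row >= 1L && row <= nrow(dist_px) &&
        dist_px[row, col] >= thr) {
      keep_x <- c(keep_x, x - x0); keep_y <- c(keep_y, y - y0)
    }
  }
  if (length(keep_x) == 0L)
    stop("sample too small for step: no interior grid points", call. = FALSE)
  structure(list(points = data.frame(x = keep_x, y = keep_y),
                 step = step, margin = margin, mm_per_pixel = s,
                 origin_mm = c(x = unname(x0), y = unname(y0))),
            class = "indentation_grid")
}

#' @export
print.indentation_grid <- function(x, ...) {
  cat(sprintf("indentation_grid: %d points, step %g mm, margin %g mm\n",
              nrow(x$points), x$step, x$margin))
  invisible(x)
}

#' Express grid points in the original camera-world frame
#'
#' Undoes the lattice-origin shift and any rotation applied by
#' [normalize_orientation()], yielding the physical stage coordinates at
#' which each grid point must be indented.
#'
#' @param grid An `indentation_grid` built on `mask`.
#' @param mask The (normalised) `sample_mask` the grid was built on.
#' @return Matrix of world (x, y) in mm.
#' @export
grid_points_world <- function(grid, mask) {
  stopifnot(inherits(grid, "indentation_grid"), inherits(mask, "sample_mask"))
  p <- cbind(grid$points$x + grid$origin_mm[["x"]],
             grid$points$y + grid$origin_mm[["y"]])
  th <- mask$applied_rotation * pi / 180
  if (abs(th) > 0) {
    c_mm <- c(mask$centroid_mm[["x"]], mask$centroid_mm[["y"]])
    d <- sweep(p, 2, c_mm)
    p <- cbind(cos(th) * d[, 1] - sin(th) * d[, 2],
               sin(th) * d[, 1] + cos(th) * d[, 2])
    p <- sweep(p, 2, c_mm, `+`)
  }
  colnames(p) <- c("x", "y")
  p
}
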