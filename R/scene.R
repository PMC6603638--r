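#' Render a synthetic camera scene of the phantom on the stage
#'
#' Produces the image pair the visual-analysis stage consumes: a textured
#' background (the empty stage) and the same background with the phantom
#' rendered as a brighter rotated rectangle at a given pose. Pixel centres
#' sit at `((col - 0.5), (row - 0.5)) * mm_per_pixel` in world millimetres,
#' with x along columns and y along rows.
#'
#' @param phantom A `phantom` (its footprint sets the rectangle size).
#' @param pose Numeric length-3 `(offset_x, offset_y, rotation_deg)`: the
#'   phantom centre is placed at the field centre plus the offset and the
#'   rectangle rotated by `rotation_deg` (counter-clockwise in the x/y pixel
#'   frame).
#' @param image_size Integer length-2 `(width_px, height_px)`.
#' @param mm_per_pixel Scale in mm per pixel.
#' @param seed Integer seed for the background texture and sensor noise.
#' @param sensor_noise_sd Per-image additive intensity noise SD.
#' @return An object of class `scene_images`: list with `sample` and
#'   `background` intensity matrices (rows = y), `mm_per_pixel` and `pose`.
#' @export
#' @examples
#' sc <- render_scene_image(make_reference_phantom(), c(0, 0, 20),
#'                          c(320, 320), 0.5, seed = 1)
render_scene_image <- function(phantom, pose = c(0, 0, 0),
                               image_size = c(320, 320), mm_per_pixel = 0.5,
                               seed = 0, sensor_noise_sd = 0.005) {
  stopifnot(length(pose) == 3, length(image_size) == 2)
  nx <- as.integer(image_size[1]); ny <- as.integer(image_size[2])
  s <- mm_per_pixel
  field <- c(nx, ny) * s
  cw <- field / 2 + pose[1:2]
  th <- pose[3] * pi / 180
  L <- phantom$length_mm; W <- phantom$width_mm
  # frame containment check on the rectangle corners
  corners <- rbind(c(-L, -W), c(L, -W), c(L, W), c(-L, W)) / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  wc <- sweep(corners %*% t(R), 2, cw, `+`)
  if (any(wc[, 1] < 0 | wc[, 1] > field[1] | wc[, 2] < 0 | wc[, 2] > field[2]))
    stop("pose places the phantom (partly) outside the camera frame",
         call. = FALSE)

  xs <- (seq_len(nx) - 0.5) * s
  ys <- (seq_len(ny) - 0.5) * s
  # world -> phantom frame for every pixel centre
  dx <- outer(ys * 0, xs, `+`) - cw[1]       # ny x nx of x offsets
  dy <- outer(ys, xs * 0, `+`) - cw[2]
  px <- cos(th) * dx + sin(th) * dy + L / 2
  py <- -sin(th) * dx + cos(th) * dy + W / 2
  fg <- px >= 0 & px <= L & py >= 0 & py <= W

  bg_base <- with_preserved_rng({
    set.seed(derive_seed(seed, 0L, 30L))
    a <- stats::runif(6, -1, 1)
    0.35 + 0.03 * (a[1] * sin(outer(ys, xs * 0, `+`) / (10 + 20 * abs(a[2]))) +
                   a[3] * cos(outer(ys * 0, xs, `+`) / (10 + 20 * abs(a[4]))) +
                   a[5] * sin(outer(ys, xs, `+`) / (15 + 15 * abs(a[6]))))
  })
  sample_img <- bg_base
  sample_img[fg] <- 0.75 + 0.02 * sin(px[fg] / 4) * cos(py[fg] / 4)
  if (sensor_noise_sd > 0) {
    bg_img <- bg_base + with_preserved_rng({
      set.seed(derive_seed(seed, 1L, 31L))
      stats::rnorm(length(bg_base), 0, sensor_noise_sd)
    })
    sample_img <- sample_img + with_preserved_rng({
      set.seed(derive_seed(seed, 2L, 31L))
      stats::rnorm(length(sample_img), 0, sensor_noise_sd)
    })
  } else {
    bg_img <- bg_base
  }
  structure(list(sample = sample_img, background = bg_img,
                 mm_per_pixel = s, pose = as.numeric(pose)),
            class = "scene_images")
}

#' Map points from camera-world millimetres to the phantom frame
#'
#' Inverts the pose used by [render_scene_image()]: the platform knows its
#' stage offsets and rotation exactly, so scan points chosen in the image
#' frame can be expressed in phantom coordinates for ground-truth
#' evaluation.
#'
#' @param points Two-column matrix/data frame of world (x, y) in mm.
#' @param phantom The `phantom` that was rendered.
#' @param pose The pose passed to [render_scene_image()].
#' @param image_size,mm_per_pixel Frame geometry used at render time.
#' @return Matrix of (x, y) in the phantom frame (origin at a block corner).
#' @export
world_to_phantom <- function(points, phantom, pose, image_size = c(320, 320),
                             mm_per_pixel = 0.5) {
  pts <- as.matrix(points)
  field <- as.numeric(image_size) * mm_per_pixel
  cw <- field / 2 + pose[1:2]
  th <- pose[3] * pi / 180
  d <- sweep(pts, 2, cw)
  out <- cbind(cos(th) * d[, 1] + sin(th) * d[, 2] + phantom$length_mm / 2,
               -sin(th) * d[, 1] + cos(th) * d[, 2] + phantom$width_mm / 2)
  colnames(out) <- c("x", "y")
  out
}
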