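#' Spherical inclusion buried in a phantom
#'
#' @param center Numeric length-3, inclusion centre (x, y, z) in mm. z is
#'   measured downward from the top surface.
#' @param diameter Sphere diameter in mm.
#' @param material `material_props` of the inclusion (default tumor agar).
#' @param has_air_bubble Whether an air bubble formed inside the inclusion
#'   during casting, which partially restores the bottom-plate echo.
#' @param bubble_fraction Fraction in \[0, 1) of the echo drop cancelled by
#'   the bubble; ignored unless `has_air_bubble`.
#' @return An object of class `inclusion`.
#' @export
inclusion <- function(center, diameter, material = tumor_material(),
                      has_air_bubble = FALSE, bubble_fraction = 0) {
  if (length(center) != 3L || !all(is.finite(center)))
    stop("center must be finite (x, y, z) in mm", call. = FALSE)
  if (!is.finite(diameter) || diameter <= 0)
    stop("diameter must be a positive length in mm", call. = FALSE)
  if (!inherits(material, "material_props"))
    stop("material must be a material_props object", call. = FALSE)
  if (!is.finite(bubble_fraction) || bubble_fraction < 0 || bubble_fraction >= 1)
    stop("bubble_fraction must lie in [0, 1)", call. = FALSE)
  structure(list(center = as.numeric(center), diameter = as.numeric(diameter),
                 material = material,
                 has_air_bubble = isTRUE(has_air_bubble),
                 bubble_fraction = as.numeric(bubble_fraction)),
            class = "inclusion")
}

#' Block phantom with buried spherical inclusions
#'
#' A rectangular agar block (reference size 100 x 60 x 15 mm) made of a soft
#' matrix material with zero or more stiffer spherical inclusions. The
#' coordinate frame has its origin at one top corner: x along the 100 mm
#' edge, y along the 60 mm edge, z downward from the top surface. All
#' inclusions must be fully contained in the block and pairwise
#' non-overlapping.
#'
#' @param length_mm,width_mm,thickness_mm Block dimensions (x, y, z) in mm.
#' @param matrix_material `material_props` of the surrounding matrix.
#' @param inclusions List of [inclusion()] objects.
#' @return An object of class `phantom`.
#' @export
#' @examples
#' phantom(inclusions = list(inclusion(c(50, 30, 7.5), 12)))
phantom <- function(length_mm = 100, width_mm = 60, thickness_mm = 15,
                    matrix_material = healthy_material(),
                    inclusions = list()) {
  dims <- c(length_mm, width_mm, thickness_mm)
  if (!all(is.finite(dims)) || any(dims <= 0))
    stop("phantom dimensions must be positive", call. = FALSE)
  if (!inherits(matrix_material, "material_props"))
    stop("matrix_material must be a material_props object", call. = FALSE)
  if (!is.list(inclusions) || !all(vapply(inclusions, inherits, TRUE, "inclusion")))
    stop("inclusions must be a list of inclusion objects", call. = FALSE)
  ph <- structure(list(length_mm = length_mm, width_mm = width_mm,
                       thickness_mm = thickness_mm,
                       matrix_material = matrix_material,
                       inclusions = inclusions),
                  class = "phantom")
  validate_phantom(ph)
  ph
}

validate_phantom <- function(ph) {
  for (inc in ph$inclusions) {
    r <- inc$diameter / 2
    ctr <- inc$center
    lo <- ctr - r
    hi <- ctr + r
    if (lo[1] < 0 || lo[2] < 0 || lo[3] < 0 ||
        hi[1] > ph$length_mm || hi[2] > ph$width_mm || hi[3] > ph$thickness_mm)
      stop("inclusion not fully contained in the phantom volume", call. = FALSE)
  }
  n <- length(ph$inclusions)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      a <- ph$inclusions[[i]]; b <- ph$inclusions[[j]]
      d <- sqrt(sum((a$center - b$center)^2))
      if (d <= (a$diameter + b$diameter) / 2)
        stop("inclusions overlap: centre distance must exceed the sum of radii",
             call. = FALSE)
    }
  }
  invisible(ph)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %g x %g x %g mm, %d inclusion(s)\n",
              x$length_mm, x$width_mm, x$thickness_mm, length(x$inclusions)))
  for (inc in x$inclusions) {
    cat(sprintf("  d = %4.1f mm at (%.1f, %.1f, %.1f)%s\n", inc$diameter,
                inc$center[1], inc$center[2], inc$center[3],
                if (inc$has_air_bubble) sprintf(" [air bubble %.0f%%]",
                                                100 * inc$bubble_fraction) else ""))
  }
  invisible(x)
}

# Canonical inclusion layout: two rows of four, largest to smallest,
# satisfying >= 10 mm planar surface separation and >= 5 mm lateral
# clearance at the reference 100 x 60 mm footprint.
reference_layout <- function(z_large, z_small) {
  data.frame(
    x = c(15, 40, 62, 82, 25, 50, 72, 90),
    y = c(18, 18, 18, 18, 42, 42, 42, 42),
    z = c(z_large, z_large, z_small, z_small,
          z_large, z_large, z_small, z_small),
    diameter = c(12, 9, 6, 3, 12, 9, 6, 3))
}

#' Build the reference eight-inclusion phantom
#'
#' Constructs a 100 x 60 x 15 mm healthy-matrix phantom containing eight
#' tumor-material spherical inclusions, two each of diameters 3, 6, 9 and
#' 12 mm, with planar separation of at least 10 mm between sphere surfaces
#' and at least 5 mm clearance from the lateral faces. Inclusion centres sit
#' at mid-thickness (z = 7.5 mm); with `bury_small = TRUE` the 3 mm and 6 mm
#' inclusions are buried deeper (centre z = 10 mm), the configuration that
#' makes the small nodules hardest to feel by palpation.
#'
#' @param seed Integer seed controlling randomised placement; the output is
#'   deterministic given the seed.
#' @param randomize_positions If `FALSE` (default) a fixed canonical layout
#'   is used; if `TRUE` positions are drawn by seeded rejection sampling
#'   under the same separation constraints.
#' @param bury_small Bury the 3 mm and 6 mm inclusions at centre depth
#'   10 mm instead of 7.5 mm.
#' @param bubble_fraction Air-bubble echo restoration applied to inclusions
#'   flagged with bubbles (none are flagged by this builder; exposed so
#'   callers can post-edit the phantom consistently).
#' @return A `phantom` with exactly 8 inclusions.
#' @export
#' @examples
#' make_reference_phantom(seed = 1, randomize_positions = TRUE)
make_reference_phantom <- function(seed = 0, randomize_positions = FALSE,
                                   bury_small = FALSE, bubble_fraction = 0) {
  L <- 100; W <- 60; Tz <- 15
  z_small <- if (bury_small) 10 else 7.5
  if (!randomize_positions) {
    lay <- reference_layout(7.5, z_small)
  } else {
    lay <- with_preserved_rng({
      set.seed(as.integer(seed %% .Machine$integer.max))
      draw_random_layout(L, W, z_large = 7.5, z_small = z_small)
    })
  }
  incs <- lapply(seq_len(nrow(lay)), function(i) {
    inclusion(center = c(lay$x[i], lay$y[i], lay$z[i]),
              diameter = lay$diameter[i], material = tumor_material(),
              has_air_bubble = FALSE, bubble_fraction = bubble_fraction)
  })
  phantom(length_mm = L, width_mm = W, thickness_mm = Tz,
          matrix_material = healthy_material(), inclusions = incs)
}

# Rejection-sample 8 centres (2 per diameter 12, 9, 6, 3), largest first:
# planar gap between sphere surfaces >= 10 mm, lateral clearance >= 5 mm.
draw_random_layout <- function(L, W, z_large, z_small, max_tries = 10000L) {
  diams <- c(12, 12, 9, 9, 6, 6, 3, 3)
  zs <- ifelse(diams >= 9, z_large, z_small)
  xs <- ys <- numeric(0)
  for (i in seq_along(diams)) {
    r <- diams[i] / 2
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, r + 5, L - r - 5)
      y <- stats::runif(1, r + 5, W - r - 5)
      if (length(xs) == 0L ||
          all(sqrt((xs - x)^2 + (ys - y)^2) - (diams[seq_along(xs)] / 2 + r) >= 10)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("inclusion placement failed after bounded retries", call. = FALSE)
    xs <- c(xs, x); ys <- c(ys, y)
  }
  data.frame(x = xs, y = ys, z = zs, diameter = diams)
}

# Run expr with the caller's .Random.seed untouched.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Vertical chord of each inclusion under a surface point
#'
#' For a vertical line dropped at `(x, y)`, returns for every inclusion the
#' length of its intersection with the sphere: `2 * sqrt(max(0, r^2 - d^2))`
#' where `d` is the planar distance from `(x, y)` to the projected centre.
#'
#' @param phantom A `phantom`.
#' @param x,y Surface coordinates in mm; must lie inside the footprint.
#' @return Numeric vector of chord lengths (mm), one per inclusion.
#' @export
inclusion_chord <- function(phantom, x, y) {
  check_in_footprint(phantom, x, y)
  chords_at(phantom, x, y)
}

check_in_footprint <- function(phantom, x, y) {
  if (!is.finite(x) || !is.finite(y) ||
      x < 0 || x > phantom$length_mm || y < 0 || y > phantom$width_mm)
    stop(sprintf("point (%.3g, %.3g) outside the phantom footprint", x, y),
         call. = FALSE)
  invisible(TRUE)
}

# No domain validation: used internally on probe-footprint sub-grids that
# may poke slightly past the lateral faces.
chords_at <- function(phantom, x, y) {
  if (length(phantom$inclusions) == 0L) return(numeric(0))
  vapply(phantom$inclusions, function(inc) {
    r <- inc$diameter / 2
    d2 <- (x - inc$center[1])^2 + (y - inc$center[2])^2
    2 * sqrt(max(0, r^2 - d2))
  }, numeric(1))
}

# Sub-grid of probe-footprint offsets (step 0.5 mm within the disc).
footprint_offsets <- function(footprint_diameter, step = 0.5) {
  r <- footprint_diameter / 2
  g <- seq(-r, r, by = step)
  off <- expand.grid(dx = g, dy = g)
  off[off$dx^2 + off$dy^2 <= r^2 + 1e-12, , drop = FALSE]
}

# Maximum inclusion chord seen anywhere under the probe face, plus which
# inclusion produced it. The rigid probe face feels (and insonifies) the
# stiffest/most-occluded column underneath.
footprint_max_chord <- function(phantom, x, y, footprint_diameter = 3) {
  if (length(phantom$inclusions) == 0L)
    return(list(chord = 0, inclusion = NA_integer_))
  off <- footprint_offsets(footprint_diameter)
  best <- 0; best_i <- NA_integer_
  for (k in seq_len(nrow(off))) {
    ch <- chords_at(phantom, x + off$dx[k], y + off$dy[k])
    i <- which.max(ch)
    if (ch[i] > best) { best <- ch[i]; best_i <- i }
  }
  list(chord = min(best, phantom$thickness_mm), inclusion = best_i)
}

#' Homogenised local indentation stiffness
#'
#' Effective stiffness felt by a flat probe of diameter `footprint_diameter`
#' at `(x, y)`: two springs in series along the indentation axis, the matrix
#' column of height `T - t` and the inclusion chord `t` (the maximum chord
#' anywhere under the probe face),
#' `k_eff = 1 / ((T - t) / (T k_matrix) + t / (T k_inclusion))`.
#' The value recovers the pure-material stiffness in both homogeneous
#' limits, lies between them otherwise, and increases with the chord, so
#' small inclusions raise the reading only slightly - which is what masks
#' them in palpation-only detection.
#'
#' @param phantom A `phantom`.
#' @param x,y Surface coordinates in mm, inside the footprint.
#' @param footprint_diameter Probe face diameter in mm (default 3, the
#'   needle-type ultrasound probe used for indentation).
#' @return Effective stiffness in N/mm.
#' @export
local_stiffness <- function(phantom, x, y, footprint_diameter = 3) {
  check_in_footprint(phantom, x, y)
  km <- phantom$matrix_material$stiffness
  hit <- footprint_max_chord(phantom, x, y, footprint_diameter)
  if (hit$chord <= 0) return(km)
  ki <- phantom$inclusions[[hit$inclusion]]$material$stiffness
  Tz <- phantom$thickness_mm
  t <- hit$chord
  1 / ((Tz - t) / (Tz * km) + t / (Tz * ki))
}
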