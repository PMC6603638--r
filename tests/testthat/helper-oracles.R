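# Brute-force minimiser of the fuzzy c-means objective on 1-D data:
# coarse-to-fine grid search over the two centroids, memberships optimised
# out in closed form. Independent of the iterative FCM path.
oracle_fcm <- function(x, m = 2, levels = 4, pts = 61) {
  rng <- range(x)
  lo1 <- lo2 <- rng[1]; hi1 <- hi2 <- rng[2]
  best <- Inf; bc <- c(NA_real_, NA_real_)
  for (lev in seq_len(levels)) {
    g1 <- seq(lo1, hi1, length.out = pts)
    g2 <- seq(lo2, hi2, length.out = pts)
    for (c1 in g1) for (c2 in g2) {
      J <- nodulecad:::fcm_reduced_objective(x, c(c1, c2), m)
      if (J < best) { best <- J; bc <- c(c1, c2) }
    }
    s1 <- diff(range(g1)) / (pts - 1); s2 <- diff(range(g2)) / (pts - 1)
    lo1 <- bc[1] - 2 * s1; hi1 <- bc[1] + 2 * s1
    lo2 <- bc[2] - 2 * s2; hi2 <- bc[2] + 2 * s2
  }
  list(objective = best, centroids = sort(bc))
}

# Small single-inclusion phantom for fast scan tests.
small_phantom <- function(diameter = 8, center = c(20, 15, 7.5)) {
  phantom(length_mm = 40, width_mm = 30, thickness_mm = 15,
          inclusions = list(inclusion(center, diameter)))
}

# Regular lattice over a phantom footprint with the given clearance,
# bypassing the vision stage.
phantom_lattice <- function(ph, step = 2, margin = 2) {
  xs <- seq(margin, ph$length_mm - margin, by = step)
  ys <- seq(margin, ph$width_mm - margin, by = step)
  as.matrix(expand.grid(x = xs, y = ys))[, c("x", "y")]
}

# A label map aligned with a set of points, for fusion tests.
label_map <- function(labels, grid = NULL) {
  nodulecad:::new_classification_map(
    grid, factor(labels, levels = c("healthy", "tumor")),
    as.integer(labels == "tumor"), c(0, 1), "test")
}
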