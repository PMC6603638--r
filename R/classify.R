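#' Fuzzy c-means parameters
#'
#' @param m Fuzzifier exponent (> 1, default 2).
#' @param tolerance Convergence threshold on the maximum membership change.
#' @param max_iterations Iteration cap.
#' @param seed Seed used only with `init = "random"`.
#' @param init Initialisation: `"quantile"` (default, deterministic and
#'   permutation-invariant: centroids start at the 25% and 75% feature
#'   quantiles, falling back to min/max when those coincide) or `"random"`
#'   (seeded random memberships).
#' @return An object of class `fcm_params` (two clusters, fixed).
#' @export
fcm_params <- function(m = 2, tolerance = 1e-5, max_iterations = 300,
                       seed = 0, init = c("quantile", "random")) {
  init <- match.arg(init)
  if (!is.finite(m) || m <= 1) stop("fuzzifier m must exceed 1", call. = FALSE)
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("tolerance must be positive", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(n_clusters = 2L, m = m, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), init = init),
            class = "fcm_params")
}

degenerate_error <- function(msg) {
  stop(structure(class = c("nodulecad_degenerate", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Two-cluster fuzzy c-means on a one-dimensional feature
#'
#' Alternating update of memberships and centroids for the fuzzy c-means
#' objective `J = sum_ij u_ij^m (x_i - c_j)^2`:
#' `u_ij = 1 / sum_k (d_ij^2 / d_ik^2)^(1/(m-1))` and
#' `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`, iterated until the maximum
#' membership change falls below `tolerance`. Points coincident with a
#' centroid get full membership in that cluster. Clusters are returned in
#' ascending centroid order.
#'
#' @param values Numeric feature vector with at least two distinct values.
#' @param params An `fcm_params`.
#' @return List with `memberships` (n x 2 matrix, columns ordered by
#'   centroid), `centroids` (ascending), `iterations`, `converged`,
#'   `objective`.
#' @export
#' @examples
#' fcm_cluster(c(0, 0, 0, 10, 10, 10))$centroids
fcm_cluster <- function(values, params = fcm_params()) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  n <- length(x)
  # treat float-dust spreads (e.g. a noiseless homogeneous scan) as identical
  if (n < 2L || diff(range(x)) <= 1e-10 * (1 + abs(mean(x))))
    degenerate_error("degenerate clustering: fewer than two distinct values")
  m <- params$m
  if (params$init == "random") {
    u <- with_preserved_rng({
      set.seed(params$seed)
      u0 <- matrix(stats::runif(2L * n), n, 2L)
      u0 / rowSums(u0)
    })
    cts <- fcm_centroids(x, u, m)
  } else {
    cts <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    if (cts[1] == cts[2]) cts <- range(x)
    u <- fcm_memberships(x, cts, m)
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(params$max_iterations)) {
    cts <- fcm_centroids(x, u, m)
    u_new <- fcm_memberships(x, cts, m)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < params$tolerance) { converged <- TRUE; break }
  }
  ord <- order(cts)
  cts <- cts[ord]; u <- u[, ord, drop = FALSE]
  d2 <- (outer(x, cts, `-`))^2
  list(memberships = u, centroids = cts, iterations = it,
       converged = converged, objective = sum(u^m * d2))
}

fcm_centroids <- function(x, u, m) {
  um <- u^m
  colSums(um * x) / colSums(um)
}

fcm_memberships <- function(x, cts, m) {
  d2 <- (outer(x, cts, `-`))^2
  u <- matrix(0, length(x), 2L)
  zero <- d2 <= 0
  on_centroid <- rowSums(zero) > 0
  if (any(on_centroid))        # full membership at a coincident centroid
    u[on_centroid, ] <- zero[on_centroid, , drop = FALSE] /
      rowSums(zero[on_centroid, , drop = FALSE])
  if (any(!on_centroid)) {
    w <- d2[!on_centroid, , drop = FALSE]^(-1 / (m - 1))
    u[!on_centroid, ] <- w / rowSums(w)
  }
  u
}

# FCM objective with memberships optimised out: for fixed centroids the
# inner minimum is J(c) = sum_i (sum_j d_ij^(-2/(m-1)))^(-(m-1)).
# Used by tests as a brute-force oracle and here for reporting.
fcm_reduced_objective <- function(x, cts, m) {
  d2 <- (outer(x, cts, `-`))^2
  ex <- -1 / (m - 1)
  sum(apply(d2, 1, function(d) {
    if (any(d == 0)) return(0)
    sum(d^ex)^(-(m - 1))
  }))
}

#' Turn FCM output into a binary tumor/healthy map
#'
#' The cluster with the larger centroid is labelled tumor: both detection
#' features (stiffness and CIA) are constructed to increase over
#' inclusions. Each point takes the label of its maximum membership; exact
#' 0.5/0.5 ties go to healthy.
#'
#' @param memberships n x 2 membership matrix, columns in ascending
#'   centroid order (as returned by [fcm_cluster()]), or the full
#'   [fcm_cluster()] result list.
#' @param centroids Length-2 numeric, ascending; ignored when a result list
#'   is given.
#' @param grid Optional matrix/data frame of the (x, y) points.
#' @param method Method tag: one of "stiffness", "ultrasound", "and", "or".
#' @return A `classification_map`: `grid`, `labels` (factor
#'   healthy/tumor), `membership_tumor`, `centroids`, `method`.
#' @export
assign_classes <- function(memberships, centroids = NULL, grid = NULL,
                           method = "stiffness") {
  if (is.list(memberships) && !is.null(memberships$memberships)) {
    centroids <- memberships$centroids
    memberships <- memberships$memberships
  }
  if (length(centroids) != 2L || centroids[1] == centroids[2])
    degenerate_error("degenerate model: cluster centroids are equal")
  if (centroids[1] > centroids[2]) {   # enforce ascending order
    centroids <- rev(centroids)
    memberships <- memberships[, 2:1, drop = FALSE]
  }
  u_tumor <- memberships[, 2]
  labels <- factor(ifelse(u_tumor > 0.5, "tumor", "healthy"),
                   levels = c("healthy", "tumor"))
  new_classification_map(grid, labels, u_tumor, centroids, method)
}

new_classification_map <- function(grid, labels, membership_tumor,
                                   centroids, method) {
  structure(list(grid = grid, labels = labels,
                 membership_tumor = membership_tumor,
                 centroids = centroids, method = method),
            class = "classification_map")
}

#' Classify one feature map
#'
#' Convenience wrapper: runs [fcm_cluster()] on the chosen feature of a
#' `feature_maps` object and assigns classes. When the map is degenerate
#' (all values identical, e.g. a noiseless homogeneous phantom) and
#' `degenerate_ok = TRUE`, an all-healthy map is returned with a warning
#' instead of an error.
#'
#' @param fm A `feature_maps` object.
#' @param feature "stiffness" (the k map) or "ultrasound" (the CIA map).
#' @param params An `fcm_params`.
#' @param degenerate_ok Downgrade degenerate clustering to a warning.
#' @return A `classification_map`.
#' @export
classify_feature_map <- function(fm, feature = c("stiffness", "ultrasound"),
                                 params = fcm_params(), degenerate_ok = FALSE) {
  feature <- match.arg(feature)
  stopifnot(inherits(fm, "feature_maps"))
  vals <- if (feature == "stiffness") fm$k_values else fm$cia_values
  tryCatch({
    assign_classes(fcm_cluster(vals, params), grid = fm$grid, method = feature)
  }, nodulecad_degenerate = function(e) {
    if (!degenerate_ok) stop(e)
    warning(sprintf("%s map: %s; returning all-healthy labels", feature,
                    conditionMessage(e)), call. = FALSE)
    n <- length(vals)
    new_classification_map(fm$grid,
                           factor(rep("healthy", n),
                                  levels = c("healthy", "tumor")),
                           rep(0, n), c(NA_real_, NA_real_), feature)
  })
}

check_same_grid <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  if (is.null(ga) != is.null(gb) ||
      (!is.null(ga) && (!all(dim(ga) == dim(gb)) || any(ga != gb))) ||
      length(a$labels) != length(b$labels))
    stop("classification maps are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Fuse two classification maps with AND / OR logic
#'
#' AND keeps only points called tumor by both inputs (fewer false
#' positives, at the price of missed small nodules); OR keeps points called
#' tumor by either input (fewer false negatives - the safe choice when no
#' cancerous tissue may be missed). Fused tumor memberships are the
#' pointwise min (AND) or max (OR) of the inputs.
#'
#' @param a,b `classification_map`s on the same grid.
#' @return A `classification_map` with method tag "and" / "or".
#' @export
fuse_and <- function(a, b) {
  check_same_grid(a, b)
  lab <- factor(ifelse(a$labels == "tumor" & b$labels == "tumor",
                       "tumor", "healthy"), levels = c("healthy", "tumor"))
  new_classification_map(a$grid, lab,
                         pmin(a$membership_tumor, b$membership_tumor),
                         c(NA_real_, NA_real_), "and")
}

#' @rdname fuse_and
#' @export
fuse_or <- function(a, b) {
  check_same_grid(a, b)
  lab <- factor(ifelse(a$labels == "tumor" | b$labels == "tumor",
                       "tumor", "healthy"), levels = c("healthy", "tumor"))
  new_classification_map(a$grid, lab,
                         pmax(a$membership_tumor, b$membership_tumor),
                         c(NA_real_, NA_real_), "or")
}

#' @export
print.classification_map <- function(x, ...) {
  cat(sprintf("classification_map [%s]: %d points, %d tumor / %d healthy\n",
              x$method, length(x$labels), sum(x$labels == "tumor"),
              sum(x$labels == "healthy")))
  invisible(x)
}
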