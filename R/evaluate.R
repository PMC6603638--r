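#' Ground-truth labels of grid points from the known phantom
#'
#' A grid point is truth-tumor iff its (x, y) lies within the projected
#' circle of any inclusion (planar distance at most the radius, boundary
#' inclusive). Depth is deliberately ignored: a point over a deeply buried
#' small inclusion still counts as tumor, which is exactly what makes
#' stiffness-only false negatives possible.
#'
#' @param phantom A `phantom`.
#' @param grid `indentation_grid`, matrix or data frame of (x, y) in
#'   phantom-frame mm.
#' @return Factor with levels `healthy`, `tumor`, one per grid point.
#' @export
ground_truth_labels <- function(phantom, grid) {
  pts <- as_grid_matrix(grid)
  tumor <- rep(FALSE, nrow(pts))
  for (inc in phantom$inclusions) {
    r <- inc$diameter / 2
    d2 <- (pts[, 1] - inc$center[1])^2 + (pts[, 2] - inc$center[2])^2
    tumor <- tumor | d2 <= r^2 + 1e-12
  }
  factor(ifelse(tumor, "tumor", "healthy"), levels = c("healthy", "tumor"))
}

#' Confusion matrix with class-conditional rates
#'
#' Cross-tabulates predicted against true labels and reports the rates the
#' way screening studies print them: TP% = TP/(TP+FN) and FN% = FN/(TP+FN)
#' over the true-tumor points, TN% = TN/(TN+FP) and FP% = FP/(TN+FP) over
#' the true-healthy points (each pair sums to 100), plus overall accuracy
#' and misclassification rate. If the truth contains a single class the
#' undefined rate pair is reported as `NA` while counts are still returned.
#'
#' @param pred A `classification_map` or a factor/character vector of
#'   healthy/tumor labels.
#' @param truth Factor/character vector of true labels, aligned with `pred`.
#' @return An object of class `confusion_summary`.
#' @export
#' @examples
#' confusion(c("tumor", "healthy", "tumor", "healthy"),
#'           c("tumor", "tumor", "healthy", "healthy"))
confusion <- function(pred, truth) {
  p <- if (inherits(pred, "classification_map")) pred$labels else pred
  p <- factor(as.character(p), levels = c("healthy", "tumor"))
  t_ <- factor(as.character(truth), levels = c("healthy", "tumor"))
  if (length(p) != length(t_) || any(is.na(p)) || any(is.na(t_)))
    stop("pred and truth must be aligned healthy/tumor label vectors",
         call. = FALSE)
  counts <- c(TP = sum(p == "tumor" & t_ == "tumor"),
              TN = sum(p == "healthy" & t_ == "healthy"),
              FP = sum(p == "tumor" & t_ == "healthy"),
              FN = sum(p == "healthy" & t_ == "tumor"))
  confusion_from_counts(counts)
}

confusion_from_counts <- function(counts) {
  counts <- as.integer(counts[c("TP", "TN", "FP", "FN")])
  names(counts) <- c("TP", "TN", "FP", "FN")
  pos <- counts[["TP"]] + counts[["FN"]]
  neg <- counts[["TN"]] + counts[["FP"]]
  total <- pos + neg
  rates <- c(TP = if (pos > 0) 100 * counts[["TP"]] / pos else NA_real_,
             FN = if (pos > 0) 100 * counts[["FN"]] / pos else NA_real_,
             TN = if (neg > 0) 100 * counts[["TN"]] / neg else NA_real_,
             FP = if (neg > 0) 100 * counts[["FP"]] / neg else NA_real_)
  acc <- 100 * (counts[["TP"]] + counts[["TN"]]) / total
  structure(list(counts = counts, rates = rates, accuracy = acc,
                 misclassification_rate = 100 - acc, n = total),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion: n = %d | TP %d  TN %d  FP %d  FN %d\n",
              x$n, x$counts[["TP"]], x$counts[["TN"]],
              x$counts[["FP"]], x$counts[["FN"]]))
  cat(sprintf("  TP%% %.2f  FN%% %.2f | TN%% %.2f  FP%% %.2f | accuracy %.2f%%\n",
              x$rates[["TP"]], x$rates[["FN"]], x$rates[["TN"]],
              x$rates[["FP"]], x$accuracy))
  invisible(x)
}

#' Pool confusion summaries by summing counts
#'
#' Counts are summed over phantoms and rates recomputed from the pooled
#' counts (equivalent to rates over the concatenated points).
#'
#' @param summaries List of `confusion_summary` objects.
#' @return A pooled `confusion_summary`.
#' @export
pool_confusion <- function(summaries) {
  stopifnot(length(summaries) > 0,
            all(vapply(summaries, inherits, TRUE, "confusion_summary")))
  counts <- Reduce(`+`, lapply(summaries, `[[`, "counts"))
  confusion_from_counts(counts)
}

#' Evaluate all four detection methods on one scan
#'
#' Computes one confusion summary per classification map (stiffness,
#' ultrasound, AND, OR) against the phantom ground truth, plus per-point
#' TP/TN/FP/FN category grids for plotting.
#'
#' @param dataset The `scan_dataset` (supplies phantom truth), or a
#'   `phantom` directly.
#' @param maps Named list of `classification_map`s on the dataset grid.
#' @param grid Grid points in phantom-frame mm; defaults to the dataset
#'   grid (supply explicitly when scan coordinates are not already in the
#'   phantom frame).
#' @return A `method_summary` list: `summaries` (named
#'   `confusion_summary`s), `categories` (data frame of x, y and one
#'   TP/TN/FP/FN factor column per method), `truth`.
#' @export
summarize_methods <- function(dataset, maps, grid = NULL) {
  ph <- if (inherits(dataset, "phantom")) dataset else dataset$phantom
  if (is.null(ph)) stop("phantom ground truth unavailable", call. = FALSE)
  if (is.null(grid)) grid <- dataset$grid
  pts <- as_grid_matrix(grid)
  truth <- ground_truth_labels(ph, pts)
  stopifnot(length(maps) > 0, !is.null(names(maps)))
  categories <- data.frame(x = pts[, 1], y = pts[, 2])
  summaries <- list()
  for (nm in names(maps)) {
    lab <- maps[[nm]]$labels
    if (length(lab) != length(truth))
      stop(sprintf("map '%s' is not aligned with the grid", nm), call. = FALSE)
    summaries[[nm]] <- confusion(lab, truth)
    categories[[nm]] <- factor(
      ifelse(truth == "tumor",
             ifelse(lab == "tumor", "TP", "FN"),
             ifelse(lab == "tumor", "FP", "TN")),
      levels = c("TP", "TN", "FP", "FN"))
  }
  structure(list(summaries = summaries, categories = categories,
                 truth = truth),
            class = "method_summary")
}

#' @export
print.method_summary <- function(x, ...) {
  for (nm in names(x$summaries)) {
    cat(sprintf("[%s]\n", nm)); print(x$summaries[[nm]])
  }
  invisible(x)
}

#' Index of the grid point nearest each inclusion centre
#'
#' @param phantom A `phantom`.
#' @param grid Grid points in phantom-frame mm.
#' @return Integer vector, one grid index per inclusion.
#' @export
inclusion_center_points <- function(phantom, grid) {
  pts <- as_grid_matrix(grid)
  vapply(phantom$inclusions, function(inc) {
    which.min((pts[, 1] - inc$center[1])^2 + (pts[, 2] - inc$center[2])^2)
  }, integer(1))
}
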