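#' Configuration of a full detection run
#'
#' Bundles everything needed to reproduce a run: the phantom build options,
#' the acquisition parameters, the clustering parameters, the vision
#' settings and one master seed from which phantom placement, scene pose,
#' sensor noise and any random clustering initialisation are all derived.
#'
#' @param master_seed Integer master seed.
#' @param acquisition An `acquisition_config`; its `seed` is overridden
#'   from `master_seed`.
#' @param fcm An `fcm_params`; its `seed` is overridden from `master_seed`.
#' @param phantom Optional explicit `phantom`; when `NULL` the reference
#'   eight-inclusion phantom is built from the master seed.
#' @param randomize_positions,bury_small Passed to
#'   [make_reference_phantom()] when `phantom` is `NULL`. The default run
#'   randomises positions and buries the 3 and 6 mm inclusions deeper.
#' @param subtract_threshold Background-subtraction threshold (fraction of
#'   dynamic range).
#' @param mm_per_pixel,image_size Camera scale and frame size.
#' @param grid_step,grid_margin Indentation lattice step and edge clearance
#'   in mm.
#' @param pose Scene pose `(offset_x, offset_y, rotation_deg)`; `NULL`
#'   draws a random pose from the master seed (offsets within +/- 8 mm,
#'   rotation within +/- 25 degrees).
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @param write_raw Also write the full scan dataset (bulky as text).
#' @param keep_raw Keep waveforms in the returned object.
#' @return An object of class `run_config`.
#' @export
run_config <- function(master_seed = 0,
                       acquisition = acquisition_config(),
                       fcm = fcm_params(),
                       phantom = NULL,
                       randomize_positions = TRUE,
                       bury_small = TRUE,
                       subtract_threshold = 0.1,
                       mm_per_pixel = 0.5,
                       image_size = c(320, 320),
                       grid_step = 2,
                       grid_margin = 1.5,
                       pose = NULL,
                       out_dir = NULL,
                       write_raw = FALSE,
                       keep_raw = FALSE) {
  acquisition$seed <- derive_seed(master_seed, 1L, 100L)
  fcm$seed <- derive_seed(master_seed, 2L, 100L)
  structure(list(master_seed = as.integer(master_seed),
                 acquisition = acquisition, fcm = fcm, phantom = phantom,
                 randomize_positions = randomize_positions,
                 bury_small = bury_small,
                 subtract_threshold = subtract_threshold,
                 mm_per_pixel = mm_per_pixel, image_size = image_size,
                 grid_step = grid_step, grid_margin = grid_margin,
                 pose = pose, out_dir = out_dir,
                 write_raw = write_raw, keep_raw = keep_raw),
            class = "run_config")
}

#' Run the full detection pipeline once
#'
#' End-to-end chain replacing the mechatronic platform: build (or accept) a
#' phantom, render the camera scene at a pose, recover the sample mask by
#' background subtraction, normalise its orientation, lay the indentation
#' grid, simulate the force/ultrasound scan at the grid points, extract the
#' stiffness and CIA feature maps, classify each map with fuzzy c-means,
#' fuse with AND/OR logic and score all four methods against the known
#' inclusion layout. Identical configs produce identical outputs.
#'
#' @param config A `run_config`.
#' @return A `pipeline_result`: `phantom`, `pose`, `grid_phantom` (points
#'   in phantom-frame mm), `features`, `maps` (stiffness, ultrasound, and,
#'   or), `evaluation` (a `method_summary`), `config`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(master_seed = 1))
#' res$evaluation$summaries$or
#' }
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  ph <- config$phantom
  if (is.null(ph))
    ph <- make_reference_phantom(seed = derive_seed(config$master_seed, 3L, 100L),
                                 randomize_positions = config$randomize_positions,
                                 bury_small = config$bury_small)
  pose <- config$pose
  if (is.null(pose)) {
    pose <- with_preserved_rng({
      set.seed(derive_seed(config$master_seed, 4L, 100L))
      c(stats::runif(2, -8, 8), stats::runif(1, -25, 25))
    })
  }
  scene <- render_scene_image(ph, pose, config$image_size, config$mm_per_pixel,
                              seed = derive_seed(config$master_seed, 5L, 100L))
  mask <- subtract_background(scene, threshold = config$subtract_threshold)
  mask_n <- normalize_orientation(mask)
  grid <- build_indentation_grid(mask_n, step = config$grid_step,
                                 margin = config$grid_margin)
  world <- grid_points_world(grid, mask_n)
  pts_ph <- world_to_phantom(world, ph, pose, config$image_size,
                             config$mm_per_pixel)
  # clearance-eroded mask keeps points interior, but clamp against tiny
  # numerical overshoot of the estimated rotation at the corners
  pts_ph[, 1] <- pmin(pmax(pts_ph[, 1], 0), ph$length_mm)
  pts_ph[, 2] <- pmin(pmax(pts_ph[, 2], 0), ph$width_mm)
  dataset <- simulate_scan(ph, pts_ph, config$acquisition)
  features <- build_feature_maps(dataset)
  if (!config$keep_raw && !config$write_raw) dataset$ascans <- NULL
  m_k <- classify_feature_map(features, "stiffness", config$fcm,
                              degenerate_ok = TRUE)
  m_us <- classify_feature_map(features, "ultrasound", config$fcm,
                               degenerate_ok = TRUE)
  maps <- list(stiffness = m_k, ultrasound = m_us,
               and = fuse_and(m_k, m_us), or = fuse_or(m_k, m_us))
  evaluation <- summarize_methods(ph, maps, grid = pts_ph)
  res <- structure(list(phantom = ph, pose = pose, scene = NULL,
                        grid_phantom = pts_ph, features = features,
                        maps = maps, evaluation = evaluation,
                        config = config,
                        dataset = if (config$keep_raw) dataset else NULL),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, dataset, scene)
  res
}

write_pipeline_outputs <- function(res, dataset, scene) {
  config <- res$config
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  write_phantom(res$phantom, out("phantom.yaml"))
  write_image_png(scene$sample, out("scene_sample.png"))
  write_image_png(scene$background, out("scene_background.png"))
  write_tsv_with_header(
    data.frame(x = fmt(res$grid_phantom[, 1]), y = fmt(res$grid_phantom[, 2])),
    out("grid_phantom.tsv"), "units: mm (phantom frame)")
  write_feature_maps(res$features, config$out_dir)
  for (nm in names(res$maps))
    write_classification_map(res$maps[[nm]], out(paste0("labels_", nm, ".tsv")))
  write_confusion_summaries(res$evaluation$summaries, out("confusion.tsv"))
  utils::write.table(res$evaluation$categories, out("categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (config$write_raw) write_scan_dataset(dataset, out("scan"))
  manifest <- list(schema = "nodulecad/run/1",
                   package_version = as.character(utils::packageVersion("nodulecad")),
                   master_seed = config$master_seed,
                   pose = as.numeric(res$pose),
                   acquisition = unclass(config$acquisition),
                   fcm = unclass(config$fcm)[c("m", "tolerance",
                                               "max_iterations", "seed", "init")],
                   n_grid_points = nrow(res$grid_phantom))
  yaml::write_yaml(manifest, out("manifest.yaml"), precision = 17)
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: seed %d, %d grid points\n",
              x$config$master_seed, nrow(x$grid_phantom)))
  print(x$evaluation)
  invisible(x)
}

#' Run the replicated phantom experiment
#'
#' Repeats [run_pipeline()] over `n_phantoms` independently placed
#' phantoms (the study design uses seven replicas) with per-replica seeds
#' derived from the master seed, and pools the per-phantom confusion counts
#' into one summary per method.
#'
#' @param n_phantoms Number of phantom replicas (default 7).
#' @param master_seed Integer master seed.
#' @param config Template `run_config`; its master seed is replaced per
#'   replica.
#' @return An `experiment_result`: `runs` (list of `pipeline_result`),
#'   `per_phantom` (list of per-method summary lists) and `pooled` (named
#'   `confusion_summary`s over all replicas).
#' @export
run_experiment <- function(n_phantoms = 7, master_seed = 0,
                           config = run_config()) {
  runs <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    cfg_i <- config
    cfg_i$master_seed <- derive_seed(master_seed, i, 200L)
    cfg_i$acquisition$seed <- derive_seed(cfg_i$master_seed, 1L, 100L)
    cfg_i$fcm$seed <- derive_seed(cfg_i$master_seed, 2L, 100L)
    if (!is.null(config$out_dir))
      cfg_i$out_dir <- file.path(config$out_dir, sprintf("phantom_%02d", i))
    runs[[i]] <- run_pipeline(cfg_i)
  }
  per_phantom <- lapply(runs, function(r) r$evaluation$summaries)
  methods <- names(per_phantom[[1]])
  pooled <- lapply(stats::setNames(methods, methods), function(m) {
    pool_confusion(lapply(per_phantom, `[[`, m))
  })
  if (!is.null(config$out_dir))
    write_confusion_summaries(pooled, file.path(config$out_dir, "pooled_confusion.tsv"))
  structure(list(runs = runs, per_phantom = per_phantom, pooled = pooled),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d phantom replicas; pooled rates:\n",
              length(x$runs)))
  for (nm in names(x$pooled)) {
    cat(sprintf("[%s]\n", nm)); print(x$pooled[[nm]])
  }
  invisible(x)
}
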