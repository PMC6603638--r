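#' Serialise a phantom to a structured text config
#'
#' Key-value YAML with the block dimensions, matrix material and an
#' inclusion list; [read_phantom()] restores an identical object.
#'
#' @param phantom A `phantom`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  mat <- function(m) m[c("acoustic_impedance", "speed_of_sound", "stiffness",
                         "attenuation", "attenuation_ref_mhz")]
  obj <- list(
    schema = "nodulecad/phantom/1",
    length_mm = phantom$length_mm, width_mm = phantom$width_mm,
    thickness_mm = phantom$thickness_mm,
    matrix_material = mat(phantom$matrix_material),
    inclusions = lapply(phantom$inclusions, function(inc) {
      list(center = as.numeric(inc$center), diameter = inc$diameter,
           material = mat(inc$material),
           has_air_bubble = inc$has_air_bubble,
           bubble_fraction = inc$bubble_fraction)
    }))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  obj <- yaml::read_yaml(path)
  mat <- function(l) do.call(material_props, l)
  phantom(length_mm = obj$length_mm, width_mm = obj$width_mm,
          thickness_mm = obj$thickness_mm,
          matrix_material = mat(obj$matrix_material),
          inclusions = lapply(obj$inclusions, function(l) {
            inclusion(center = as.numeric(l$center), diameter = l$diameter,
                      material = mat(l$material),
                      has_air_bubble = isTRUE(l$has_air_bubble),
                      bubble_fraction = l$bubble_fraction)
          }))
}

fmt <- function(x) sprintf("%.17g", x)

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^# ", "", grep("^# ", lines, value = TRUE))
  body <- grep("^# ", lines, invert = TRUE, value = TRUE)
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(h, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  list(data = df, meta = meta)
}

#' Export an indentation grid as delimited text
#'
#' @param grid An `indentation_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  write_tsv_with_header(
    data.frame(x = fmt(grid$points$x), y = fmt(grid$points$y)), path,
    c("units: mm", paste0("step: ", fmt(grid$step)),
      paste0("margin: ", fmt(grid$margin)),
      paste0("mm_per_pixel: ", fmt(grid$mm_per_pixel)),
      paste0("origin_mm: ", paste(fmt(grid$origin_mm), collapse = " "))))
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  r <- read_tsv_with_header(path)
  org <- as.numeric(strsplit(r$meta$origin_mm, " ")[[1]])
  structure(list(points = data.frame(x = as.numeric(r$data$x),
                                     y = as.numeric(r$data$y)),
                 step = as.numeric(r$meta$step),
                 margin = as.numeric(r$meta$margin),
                 mm_per_pixel = as.numeric(r$meta$mm_per_pixel),
                 origin_mm = c(x = org[1], y = org[2])),
            class = "indentation_grid")
}

#' Write / read a scan dataset as delimited text
#'
#' One directory per dataset: `manifest.yaml` (acquisition config, grid and
#' optional phantom), `traces.tsv` (long-format force/position samples) and
#' `ascans.tsv` (long-format waveform samples). All floats are printed with
#' 17 significant digits so the round trip is lossless to within double
#' precision. Intended for archival of small scans; full-resolution A-scans
#' are bulky as text.
#'
#' @param dataset A `scan_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(dataset$config)
  man <- list(schema = "nodulecad/scan/1", config = cfg,
              n_points = nrow(dataset$grid),
              grid_x = fmt(dataset$grid[, 1]), grid_y = fmt(dataset$grid[, 2]),
              trigger_index = vapply(dataset$records, `[[`, integer(1),
                                     "trigger_index"))
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"), precision = 17)
  if (!is.null(dataset$phantom))
    write_phantom(dataset$phantom, file.path(dir, "phantom.yaml"))
  traces <- do.call(rbind, lapply(seq_along(dataset$records), function(i) {
    r <- dataset$records[[i]]
    data.frame(point = i, z = fmt(r$z_trace), force = fmt(r$force_trace))
  }))
  write_tsv_with_header(traces, file.path(dir, "traces.tsv"),
                        c("units: mm, N", "columns: point z force"))
  asc <- do.call(rbind, lapply(seq_along(dataset$ascans), function(i) {
    a <- dataset$ascans[[i]]
    data.frame(point = i, amplitude = fmt(a$waveform))
  }))
  write_tsv_with_header(asc, file.path(dir, "ascans.tsv"),
                        c("units: dimensionless amplitude",
                          paste0("sample_rate: ",
                                 fmt(dataset$ascans[[1]]$sample_rate))))
  invisible(dir)
}

#' @rdname write_scan_dataset
#' @export
read_scan_dataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  config <- do.call(acquisition_config, man$config)
  grid <- cbind(x = as.numeric(man$grid_x), y = as.numeric(man$grid_y))
  ph_path <- file.path(dir, "phantom.yaml")
  ph <- if (file.exists(ph_path)) read_phantom(ph_path) else NULL
  tr <- read_tsv_with_header(file.path(dir, "traces.tsv"))$data
  ar <- read_tsv_with_header(file.path(dir, "ascans.tsv"))
  fs <- as.numeric(ar$meta$sample_rate)
  records <- lapply(seq_len(man$n_points), function(i) {
    sel <- tr$point == i
    structure(list(grid_point = as.numeric(grid[i, ]),
                   force_trace = as.numeric(tr$force[sel]),
                   z_trace = as.numeric(tr$z[sel]),
                   trigger_index = as.integer(man$trigger_index[i])),
              class = "indentation_record")
  })
  ascans <- lapply(seq_len(man$n_points), function(i) {
    structure(list(grid_point = as.numeric(grid[i, ]),
                   waveform = as.numeric(ar$data$amplitude[ar$data$point == i]),
                   sample_rate = fs),
              class = "ascan")
  })
  structure(list(phantom = ph, config = config, grid = grid,
                 records = records, ascans = ascans),
            class = "scan_dataset")
}

#' Export / import feature maps as delimited text grids
#'
#' Writes `k_map.tsv` and `cia_map.tsv` (x, y, value) sharing a header with
#' the grid geometry and the reference point index.
#'
#' @param fm A `feature_maps` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_feature_maps <- function(fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(paste0("n_points: ", nrow(fm$grid)),
           paste0("reference_point_index: ", fm$reference_point_index))
  write_tsv_with_header(
    data.frame(x = fmt(fm$grid[, 1]), y = fmt(fm$grid[, 2]),
               k = fmt(fm$k_values)),
    file.path(dir, "k_map.tsv"), c("units: mm, N/mm", hdr))
  write_tsv_with_header(
    data.frame(x = fmt(fm$grid[, 1]), y = fmt(fm$grid[, 2]),
               cia = fmt(fm$cia_values)),
    file.path(dir, "cia_map.tsv"), c("units: mm, dimensionless", hdr))
  invisible(dir)
}

#' @rdname write_feature_maps
#' @export
read_feature_maps <- function(dir) {
  km <- read_tsv_with_header(file.path(dir, "k_map.tsv"))
  cm <- read_tsv_with_header(file.path(dir, "cia_map.tsv"))
  grid <- cbind(x = as.numeric(km$data$x), y = as.numeric(km$data$y))
  structure(list(grid = grid, k_values = as.numeric(km$data$k),
                 cia_values = as.numeric(cm$data$cia),
                 reference_point_index =
                   as.integer(km$meta$reference_point_index)),
            class = "feature_maps")
}

#' Export / import a classification map as delimited text
#'
#' @param map A `classification_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_classification_map <- function(map, path) {
  write_tsv_with_header(
    data.frame(x = fmt(map$grid[, 1]), y = fmt(map$grid[, 2]),
               label = as.integer(map$labels == "tumor"),
               membership_tumor = fmt(map$membership_tumor)),
    path,
    c(paste0("method: ", map$method),
      paste0("centroids: ", paste(fmt(map$centroids), collapse = " "))))
}

#' @rdname write_classification_map
#' @export
read_classification_map <- function(path) {
  r <- read_tsv_with_header(path)
  cts <- suppressWarnings(as.numeric(strsplit(r$meta$centroids, " ")[[1]]))
  grid <- cbind(x = as.numeric(r$data$x), y = as.numeric(r$data$y))
  new_classification_map(
    grid,
    factor(ifelse(r$data$label == 1, "tumor", "healthy"),
           levels = c("healthy", "tumor")),
    as.numeric(r$data$membership_tumor), cts, r$meta$method)
}

#' Export confusion summaries as delimited text plus a readable report
#'
#' @param summaries Named list of `confusion_summary` objects.
#' @param path Output `.tsv` path; a `.txt` report is written alongside.
#' @return `path`, invisibly.
#' @export
write_confusion_summaries <- function(summaries, path) {
  df <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(method = nm, n = s$n,
               TP = s$counts[["TP"]], TN = s$counts[["TN"]],
               FP = s$counts[["FP"]], FN = s$counts[["FN"]],
               TP_pct = s$rates[["TP"]], TN_pct = s$rates[["TN"]],
               FP_pct = s$rates[["FP"]], FN_pct = s$rates[["FN"]],
               accuracy = s$accuracy,
               misclassification = s$misclassification_rate)
  }))
  write_tsv_with_header(df, path, "rates: class-conditional percentages")
  rep_path <- sub("\\.tsv$", ".txt", path)
  con <- file(rep_path, "w")
  on.exit(close(con))
  for (nm in names(summaries)) {
    writeLines(paste0("[", nm, "]"), con)
    writeLines(utils::capture.output(print(summaries[[nm]])), con)
  }
  invisible(path)
}

#' Write / read a grayscale image as PNG
#'
#' Intensities are clipped to \[0, 1\] and stored as 8-bit grayscale.
#'
#' @param image Numeric intensity matrix (rows = y).
#' @param path PNG file path.
#' @return `path` (write) or the intensity matrix (read).
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
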