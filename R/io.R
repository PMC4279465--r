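#' Write a frame stack as numbered 8-bit grayscale PNG files
#'
#' Frames are written as `frame_0000.png`, `frame_0001.png`, ... Masks
#' use the same scheme with prefix `mask_` and values 0/255.
#'
#' @param frames H x W x n array of gray values in `[0, 255]` (or a
#'   logical mask array).
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  if (is.list(frames)) frames <- simplify2array(frames)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(frames)[3]
  paths <- character(n)
  for (t in seq_len(n)) {
    fr <- frames[, , t]
    fr <- if (is.logical(fr)) fr * 1 else fr / 255
    paths[t] <- file.path(dir, sprintf("%s_%04d.png", prefix, t - 1L))
    png::writePNG(clamp01(fr), paths[t])
  }
  invisible(paths)
}

#' Read a directory of grayscale frames
#'
#' Reads the PNG or TIFF files in `dir` (sorted by name) into an
#' H x W x n array of gray values in `[0, 255]`. Multichannel images are
#' reduced to their first channel.
#'
#' @param dir Directory of `*.png`, `*.tif` or `*.tiff` files.
#' @param pattern Optional file-name regexp filter.
#' @return Numeric H x W x n array.
#' @export
read_frames <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("no frames found in ", dir)
  read1 <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE))
      png::readPNG(f) else tiff::readTIFF(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    round(img * 255)
  }
  simplify2array(lapply(files, read1))
}

#' Write a ground-truth manifest CSV
#'
#' One row per injected object per frame:
#' `frame, blob_id, klass, centroid_x, centroid_y, area` (x = column,
#' y = row, 0-based).
#'
#' @param truth The `truth` element returned by [generate_sequence()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  ob <- truth$objects
  out <- data.frame(frame = ob$frame, blob_id = ob$blob_id, klass = ob$klass,
                    centroid_x = ob$centroid_c - 1, centroid_y = ob$centroid_r - 1,
                    area = ob$area)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a labeled feature table CSV
#'
#' Columns: `frame`, `blob_id` (optional), the fifteen features in
#' canonical order, and optionally `label`. The feature order round-trips
#' unchanged.
#'
#' @param tab Data frame containing the feature columns.
#' @param path CSV path.
#' @return `write_feature_csv` invisibly returns `path`;
#'   `read_feature_csv` returns the data frame with `label` (if present)
#'   as a factor with canonical class levels.
#' @export
write_feature_csv <- function(tab, path) {
  keep <- intersect(c("frame", "blob_id", feature_names(), "label"), names(tab))
  utils::write.csv(tab[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tab <- utils::read.csv(path)
  missing <- setdiff(feature_names(), names(tab))
  if (length(missing))
    stop("feature columns missing from ", path, ": ",
         paste(missing, collapse = ", "))
  if ("label" %in% names(tab)) {
    lv <- if (all(tab$label %in% fm_classes())) fm_classes() else unique(tab$label)
    tab$label <- factor(tab$label, levels = lv)
  }
  tab
}

#' Save / load a fitted classifier as structured JSON
#'
#' The file stores the architecture, scaling ranges, connection weights,
#' thresholds, class order, feature subset and training metadata.
#'
#' @param object A fitted `mea_bp` model.
#' @param path JSON path.
#' @return `save_model` invisibly returns `path`; `load_model` returns
#'   the restored `mea_bp` object.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "mea_bp"))
  payload <- list(
    type = "mea_bp",
    architecture = c(object$mlp$n_in, object$mlp$n_hidden, object$mlp$n_out),
    genome = mlp_flatten(object$mlp),
    levels = object$levels,
    features = object$features,
    scaling = list(min = object$scaling[1, ], max = object$scaling[2, ]),
    method = object$method, seed = object$seed,
    train_accuracy = object$train_accuracy,
    final_xi = object$xi_trace[length(object$xi_trace)])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "mea_bp")) stop("not a classifier model file: ", path)
  arch <- as.integer(p$architecture)
  structure(list(
    mlp = mlp_parameters(arch[1], arch[2], arch[3], as.numeric(p$genome)),
    levels = p$levels, features = p$features,
    scaling = rbind(as.numeric(p$scaling$min), as.numeric(p$scaling$max)),
    method = p$method, seed = p$seed, mea = NULL,
    xi_trace = p$final_xi, train_accuracy = p$train_accuracy,
    call = NULL), class = "mea_bp")
}

#' Read a pipeline/scene configuration from YAML
#'
#' Recognized keys mirror the function arguments: a `gmm:` block
#' (`K, alpha, initial_variance, phi, T_R`), `connectivity`, `min_area`,
#' `warmup`, `features`, `decision_d` for pipelines; scene files use the
#' [scene_config()] fields plus a `particles:` list of
#' [particle_spec()] fields.
#'
#' @param path YAML file.
#' @return Named list of settings.
#' @export
read_config <- function(path) yaml::read_yaml(path)

scene_config_from_yaml <- function(cfg, seed = NULL) {
  particles <- lapply(cfg$particles %||% list(), function(p)
    do.call(particle_spec, p))
  args <- cfg[intersect(names(cfg),
                        c("frame_height", "frame_width", "n_frames",
                          "background_mean", "texture_amplitude",
                          "flicker_sigma", "pixel_noise_sigma", "seed"))]
  args$particles <- particles
  if (!is.null(seed)) args$seed <- seed
  do.call(scene_config, args)
}
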