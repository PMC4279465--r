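#' End-to-end pipeline configuration
#'
#' Settings for the detection pipeline: background-model parameters, blob
#' labeling, the feature subset fed to the classifier (default the six
#' retained by the dimensionality sweep: Hu 1, 2, 3, 5, the gray variance
#' and the entropy), the number of warm-up frames excluded while the
#' background model burns in, and the verdict rule (a bottle is
#' unqualified when foreign-matter blobs are called in at least
#' `decision_d` frames).
#'
#' @param gmm A [gmm_params()].
#' @param connectivity,min_area Passed to [label_components()].
#' @param warmup Leading frames excluded from blob harvesting (default 5).
#' @param features Character vector of feature columns the model expects.
#' @param decision_d Minimum number of frames with a foreign call to fail
#'   the bottle (default 1: any foreign call fails it).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(gmm = gmm_params(), connectivity = 8,
                            min_area = 4,
                            warmup = 5L,
                            features = c("f02_var", "f06_entropy", "f09_hu1",
                                         "f10_hu2", "f11_hu3", "f13_hu5"),
                            decision_d = 1L) {
  stopifnot(inherits(gmm, "gmm_params"), warmup >= 0, decision_d >= 1)
  structure(list(gmm = gmm, connectivity = connectivity,
                 min_area = min_area, warmup = as.integer(warmup),
                 features = features, decision_d = as.integer(decision_d)),
            class = "pipeline_config")
}

pipeline_config_from_yaml <- function(cfg) {
  g <- cfg$gmm %||% list()
  gmm <- gmm_params(K = g$K %||% 3L, alpha = g$alpha %||% 0.05,
                    initial_variance = g$initial_variance %||% 15,
                    phi = g$phi %||% 2.5, T_R = g$T_R %||% 0.25)
  pipeline_config(gmm = gmm,
                  connectivity = cfg$connectivity %||% 8,
                  min_area = cfg$min_area %||% 4,
                  warmup = cfg$warmup %||% 5L,
                  features = cfg$features %||%
                    c("f02_var", "f06_entropy", "f09_hu1", "f10_hu2",
                      "f11_hu3", "f13_hu5"),
                  decision_d = cfg$decision_d %||% 1L)
}

#' Decide a bottle verdict from per-blob class calls
#'
#' Pure function of the calls table: the bottle is unqualified iff
#' foreign-matter calls occur in at least `decision_d` distinct frames.
#'
#' @param calls Data frame with columns `frame` and `class`.
#' @param decision_d Frame threshold (default 1).
#' @param qualified Benign class name.
#' @return Logical: `TRUE` if qualified.
#' @export
decide_verdict <- function(calls, decision_d = 1L, qualified = "bubble") {
  if (is.null(calls) || nrow(calls) == 0L) return(TRUE)
  foreign_frames <- unique(calls$frame[calls$class != qualified])
  length(foreign_frames) < decision_d
}

#' Run detection and identification over a frame sequence
#'
#' The full inspection chain: per-pixel Gaussian-mixture background
#' subtraction, connected-component labeling, fifteen-feature extraction,
#' feature-subspace selection, classification of every blob, and the
#' qualified/unqualified verdict.
#'
#' @param frames Frame directory (read with [read_frames()]) or an
#'   H x W x n gray array.
#' @param model A fitted `mea_bp` classifier (or a model JSON path).
#' @param config A [pipeline_config()].
#' @param sequence_id Identifier recorded in the verdict.
#' @return Object of class `fm_verdict`: `sequence_id`, `qualified`,
#'   `calls` (frame, blob_id, class, confidence and the feature columns),
#'   `counts` per class, `n_frames`, `warmup`.
#' @export
run_detection <- function(frames, model, config = pipeline_config(),
                          sequence_id = "sequence") {
  if (is.character(frames)) frames <- read_frames(frames)
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "mea_bp"), inherits(config, "pipeline_config"))
  if (dim(frames)[3] < 2) stop("need at least 2 frames")
  if (!all(config$features %in% model$features %||% config$features) ||
      length(config$features) != model$mlp$n_in)
    stop("feature subset mismatch between model and pipeline config")
  bg <- subtract_background(frames, config$gmm)
  harvest <- seq_len(dim(frames)[3])
  harvest <- harvest[harvest > config$warmup]
  tab <- blob_feature_table(bg$masks, frames, frames_used = harvest,
                            connectivity = config$connectivity,
                            min_area = config$min_area)
  if (nrow(tab) > 0) {
    act <- predict(model, tab[, config$features, drop = FALSE], type = "prob")
    cls <- model$levels[max.col(act, ties.method = "first")]
    calls <- cbind(data.frame(frame = tab$frame, blob_id = tab$blob_id,
                              class = cls,
                              confidence = act[cbind(seq_len(nrow(act)),
                                                     max.col(act, ties.method = "first"))]),
                   tab[, feature_names()])
  } else {
    calls <- data.frame(frame = integer(), blob_id = integer(),
                        class = character(), confidence = numeric())
  }
  counts <- table(factor(calls$class, levels = model$levels))
  structure(list(sequence_id = sequence_id,
                 qualified = decide_verdict(calls, config$decision_d),
                 calls = calls, counts = counts,
                 n_frames = dim(frames)[3], warmup = config$warmup),
            class = "fm_verdict")
}

#' @export
print.fm_verdict <- function(x, ...) {
  cat(sprintf("Sequence '%s': %s\n", x$sequence_id,
              if (x$qualified) "QUALIFIED" else "UNQUALIFIED"))
  cat(sprintf("  %d frames (%d warm-up), %d blob calls\n",
              x$n_frames, x$warmup, nrow(x$calls)))
  print(x$counts)
  invisible(x)
}

#' Write a verdict as structured JSON
#'
#' @param verdict An `fm_verdict`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_verdict <- function(verdict, path) {
  jsonlite::write_json(list(
    sequence_id = verdict$sequence_id,
    qualified = verdict$qualified,
    counts = as.list(verdict$counts),
    calls = verdict$calls), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Harvest labeled blob features from simulated scenes
#'
#' Generates single-particle scenes for each class, runs background
#' subtraction and feature extraction, and labels every harvested blob
#' with the injected particle's class — a training set whose feature
#' distributions come from the detection chain itself rather than from
#' parametric class models.
#'
#' @param n_sequences Sequences per class.
#' @param n_frames Frames per sequence.
#' @param seed Integer seed.
#' @param config A [pipeline_config()] (controls GMM, labeling, warm-up).
#' @param frame_height,frame_width Scene geometry.
#' @return Data frame: `frame`, `blob_id`, the 15 features, `label`.
#' @export
harvest_labeled_features <- function(n_sequences = 3L, n_frames = 30L,
                                     seed = 1L,
                                     config = pipeline_config(),
                                     frame_height = 64L, frame_width = 64L) {
  rows <- list()
  for (ci in seq_along(fm_classes())) {
    k <- fm_classes()[ci]
    for (s in seq_len(n_sequences)) {
      sc <- scene_config(frame_height, frame_width, n_frames,
                         particles = list(particle_spec(k)),
                         seed = derive_seed(seed, 100 * ci + s))
      sq <- generate_sequence(sc)
      bg <- subtract_background(sq$frames, config$gmm)
      harvest <- which(seq_len(n_frames) > config$warmup)
      tab <- blob_feature_table(bg$masks, sq$frames, frames_used = harvest,
                                connectivity = config$connectivity,
                                min_area = config$min_area)
      if (nrow(tab)) {
        tab$label <- k
        tab$sequence <- s
        rows[[length(rows) + 1L]] <- tab
      }
    }
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = fm_classes())
  out
}

#' Reproduce the feature-weighting, dimensionality and network-size
#' experiments on synthetic data
#'
#' Three experiment suites over the default synthetic feature
#' distributions:
#' \describe{
#'   \item{weights}{ReliefF weight distribution, averaged over repeated
#'     runs and across independently drawn training sets.}
#'   \item{dims}{Classification accuracy as the feature subspace grows
#'     one feature at a time in descending weight order (dimension 1 to
#'     15).}
#'   \item{meabp}{BP versus MEA-initialized BP test accuracy across
#'     hidden-layer sizes, with across-seed means and SDs.}
#' }
#'
#' @param suite One of `"weights"`, `"dims"`, `"meabp"`.
#' @param seed Integer seed.
#' @param out_dir Optional directory to write CSV results into.
#' @param n_train,n_test Samples per set (defaults 300 and 200, drawn
#'   with balanced classes).
#' @param n_sets Training sets for the weights suite.
#' @param hidden_grid Hidden sizes for the meabp suite.
#' @param n_seeds Seeds per configuration for the meabp suite.
#' @param epochs BP epoch cap used inside the sweeps.
#' @return A data frame of results (also written to `out_dir` if given).
#' @export
run_experiment_suite <- function(suite = c("weights", "dims", "meabp"),
                                 seed = 1L, out_dir = NULL,
                                 n_train = 300L, n_test = 200L,
                                 n_sets = 10L, hidden_grid = c(3, 5, 8, 10),
                                 n_seeds = 11L, epochs = 2000L) {
  suite <- match.arg(suite)
  draw <- function(n, s) generate_feature_dataset(ceiling(n / 4), seed = s)
  res <- switch(suite,
    weights = {
      rows <- lapply(seq_len(n_sets), function(i) {
        d <- draw(200L, derive_seed(seed, i))
        w <- average_weight_runs(d[feature_names()], d$label,
                                 k = 8, m = 20, n_repeats = 20,
                                 seed = derive_seed(seed, 1000 + i))
        data.frame(set = i, feature = feature_names(),
                   weight = unname(w$weights))
      })
      do.call(rbind, rows)
    },
    dims = {
      train <- draw(n_train, derive_seed(seed, 1))
      test <- draw(n_test, derive_seed(seed, 2))
      w <- average_weight_runs(train[feature_names()], train$label,
                               seed = derive_seed(seed, 3))
      ord <- rank_and_select(w, 15)
      out <- data.frame(dims = 1:15, train_accuracy = NA_real_,
                        test_accuracy = NA_real_)
      for (m in 1:15) {
        feats <- feature_names()[ord[seq_len(m)]]
        fit <- mea_bp(train[feats], train$label, hidden = 5, method = "bp",
                      epochs = epochs, seed = derive_seed(seed, 10 + m))
        out$train_accuracy[m] <- 100 * fit$train_accuracy
        out$test_accuracy[m] <-
          100 * mean(predict(fit, test[feats]) == test$label)
      }
      out
    },
    meabp = {
      train <- draw(n_train, derive_seed(seed, 1))
      test <- draw(n_test, derive_seed(seed, 2))
      feats <- pipeline_config()$features
      grid <- expand.grid(hidden = hidden_grid, method = c("bp", "mea-bp"),
                          stringsAsFactors = FALSE)
      rows <- lapply(seq_len(nrow(grid)), function(i) {
        acc <- vapply(seq_len(n_seeds), function(s) {
          fit <- mea_bp(train[feats], train$label, hidden = grid$hidden[i],
                        method = grid$method[i], epochs = epochs,
                        seed = derive_seed(seed, 100 * i + s))
          100 * mean(predict(fit, test[feats]) == test$label)
        }, numeric(1))
        data.frame(hidden = grid$hidden[i], method = grid$method[i],
                   mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                   median_accuracy = stats::median(acc))
      })
      do.call(rbind, rows)
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, paste0(suite, ".csv")),
                     row.names = FALSE)
  }
  res
}
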