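#' Read a pressure frame from CSV
#'
#' Expects exactly 32 rows of 32 comma-separated non-negative numbers (no
#' header). Malformed input raises an error naming the offending row/column.
#'
#' @param path File path.
#' @param spec A [sensor_spec()].
#' @return A 32 x 32 numeric matrix.
#' @export
read_frame <- function(path, spec = sensor_spec()) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character")
  if (nrow(raw) != spec$rows) {
    stop(sprintf("'%s': expected %d rows, found %d", path, spec$rows,
                 nrow(raw)), call. = FALSE)
  }
  if (ncol(raw) != spec$cols) {
    stop(sprintf("'%s': expected %d columns, found %d", path, spec$cols,
                 ncol(raw)), call. = FALSE)
  }
  m <- matrix(NA_real_, spec$rows, spec$cols)
  for (i in seq_len(spec$rows)) {
    vals <- suppressWarnings(as.numeric(raw[i, ]))
    if (any(is.na(vals))) {
      j <- which(is.na(vals))[1L]
      stop(sprintf("'%s': non-numeric cell at row %d, col %d", path, i, j),
           call. = FALSE)
    }
    if (any(vals < 0)) {
      j <- which(vals < 0)[1L]
      stop(sprintf("'%s': negative value at row %d, col %d", path, i, j),
           call. = FALSE)
    }
    m[i, ] <- vals
  }
  m
}

#' Write a pressure frame to CSV
#'
#' Values are printed with 17 significant digits so reading the file back
#' reproduces them exactly.
#'
#' @param frame A 32 x 32 non-negative matrix.
#' @param path Output path.
#' @param spec A [sensor_spec()].
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, spec = sensor_spec()) {
  check_frame(frame, spec)
  txt <- apply(frame, 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = ",")
  })
  writeLines(txt, path)
  invisible(path)
}

#' Save a trained map as JSON
#'
#' Serializes grid coordinates, weights, node labels, configuration, and
#' iteration count at full floating-point precision; [load_model()] restores
#' a bit-identical model.
#'
#' @param model A `som_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(
    grid = list(n_nodes = model$grid$n_nodes,
                positions = model$grid$positions),
    weights = model$weights,
    node_labels = model$node_labels,
    config = unclass(model$config),
    n_iter = model$n_iter
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a map saved by [save_model()]
#'
#' @param path JSON path.
#' @return A `som_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- matrix(as.numeric(obj$grid$positions), ncol = 2L)
  grid <- structure(list(n_nodes = as.integer(obj$grid$n_nodes),
                         positions = pos,
                         dist = as.matrix(stats::dist(pos))),
                    class = "hex_grid")
  num_fields <- c("eta0", "tau_eta", "sigma0", "tau_sigma", "nc0", "r_min",
                  "eta_stop")
  obj$config[num_fields] <- lapply(obj$config[num_fields], as.numeric)
  cfg <- do.call(train_config, obj$config)
  labels <- as.character(obj$node_labels)
  labels[labels == "NA" | is.na(labels)] <- NA_character_
  structure(list(grid = grid, weights = matrix(as.numeric(obj$weights),
                                               nrow = grid$n_nodes),
                 node_labels = labels, config = cfg,
                 n_iter = as.integer(obj$n_iter)),
            class = "som_model")
}

#' Published worked-example confusion matrices
#'
#' Loads the two reported six-posture confusion matrices shipped with the
#' package as plain CSV (dataset 1: same-volunteer test split; dataset 2:
#' unseen volunteers), used as worked examples through the metrics layer.
#'
#' @param which `"dataset1"` or `"dataset2"`.
#' @return A `confusion_matrix`.
#' @export
reported_confusion <- function(which = c("dataset1", "dataset2")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("confusion_%s.csv", which),
                      package = "isomspr", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as_confusion(as.matrix(df), classes = rownames(df))
}

#' Experiment configuration
#'
#' Bundles every knob of the end-to-end pipeline with the published training
#' parameters as defaults.
#'
#' @param n_per_class Synthetic frames per class (default 100).
#' @param train Training parameters, a [train_config()].
#' @param spec A [sensor_spec()].
#' @param noise A [gen_noise()].
#' @param weight_range Subject weight range in kg (default 45-80).
#' @param k Principal components per frame (default 8).
#' @param reduction_mode `"pooled"` (default) fits one basis on the training
#'   frames; `"perframe"` projects each frame onto its own eigenbasis.
#'   Per-frame column-covariance bases are algebraically invariant to
#'   left-right mirroring of a frame, so they cannot separate the mirrored
#'   posture pairs (LC/RC, LL/LR); the pooled basis breaks that invariance
#'   and is therefore the pipeline default.
#' @param train_fraction Training share of the split (default 0.55).
#' @param seed Top-level seed; per-stage seeds are derived from it (data:
#'   seed, split: seed + 1, training: seed + 2).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_class = 100L, train = train_config(),
                            spec = sensor_spec(), noise = gen_noise(),
                            weight_range = c(45, 80), k = 8L,
                            reduction_mode = c("pooled", "perframe"),
                            train_fraction = 0.55, seed = 1L) {
  stopifnot(n_per_class >= 1, inherits(train, "train_config"),
            inherits(spec, "sensor_spec"), k >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_per_class = as.integer(n_per_class), train = train,
                 spec = spec, noise = noise, weight_range = weight_range,
                 k = as.integer(k),
                 reduction_mode = match.arg(reduction_mode),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full experiment: simulate, reduce, split, train, evaluate
#'
#' Generates a labeled synthetic dataset, computes feature vectors, splits
#' stratified train/test, fits both the plain map and the
#' filter-and-retrain variant with identical seeds, and evaluates both on
#' the held-out frames. When a stratified split is infeasible (a class with
#' fewer than two frames), the whole simulated set is used for training and
#' an independent test set of the same size is generated under a derived
#' seed. Fully reproducible from the config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, confusion matrices
#'   (published table layout), metrics, the filter report, and a summary
#'   JSON are written there.
#' @return List of class `spr_experiment` with `som`, `isom` (models),
#'   `cm_som`, `cm_isom`, `metrics_som`, `metrics_isom`, `filter_report`,
#'   and `summary`.
#' @export
run_experiment <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config", call. = FALSE)
  }
  data_seed <- config$seed
  split_seed <- config$seed + 1L
  train_seed <- config$seed + 2L

  ds <- generate_dataset(config$n_per_class, seed = data_seed,
                         spec = config$spec, noise = config$noise,
                         weight_range = config$weight_range)
  labels <- ds$meta$label

  if (all(table(labels) >= 2L)) {
    split <- train_test_split(labels, config$train_fraction, split_seed)
    train_frames <- ds$frames[split$train]
    train_labels <- labels[split$train]
    test_frames <- ds$frames[split$test]
    test_labels <- labels[split$test]
  } else {
    ds2 <- generate_dataset(config$n_per_class, seed = data_seed + 7L,
                            spec = config$spec, noise = config$noise,
                            weight_range = config$weight_range)
    train_frames <- ds$frames
    train_labels <- labels
    test_frames <- ds2$frames
    test_labels <- ds2$meta$label
  }

  train_feats <- frames_to_features(train_frames, k = config$k,
                                    mode = config$reduction_mode,
                                    spec = config$spec)
  test_feats <- frames_to_features(test_frames, k = config$k,
                                   mode = config$reduction_mode,
                                   basis_frames = if (config$reduction_mode ==
                                                      "pooled") train_frames,
                                   spec = config$spec)

  cfg <- config$train
  cfg$seed <- train_seed
  som <- som_train(train_feats, cfg, labels = train_labels)
  isom <- isom_train(train_feats, train_labels, cfg)

  pred_som <- predict(som, test_feats)
  pred_isom <- predict(isom, test_feats)
  cm_som <- build_confusion(test_labels, pred_som)
  cm_isom <- build_confusion(test_labels, pred_isom)
  met_som <- confusion_metrics(cm_som)
  met_isom <- confusion_metrics(cm_isom)

  summary <- list(
    seed = config$seed,
    n_train = nrow(train_feats),
    n_test = nrow(test_feats),
    som = list(accuracy = met_som$accuracy,
               macro_precision = met_som$macro_precision,
               macro_recall = met_som$macro_recall,
               internode_distance = internode_distance(som)),
    isom = list(accuracy = met_isom$accuracy,
                macro_precision = met_isom$macro_precision,
                macro_recall = met_isom$macro_recall,
                internode_distance = internode_distance(isom),
                n_removed = sum(!isom$filter$kept))
  )

  res <- structure(list(som = som, isom = isom, cm_som = cm_som,
                        cm_isom = cm_isom, metrics_som = met_som,
                        metrics_isom = met_isom,
                        filter_report = isom$filter, summary = summary),
                   class = "spr_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(format_confusion(cm_som),
               file.path(out_dir, "confusion_som.txt"))
    writeLines(format_confusion(cm_isom),
               file.path(out_dir, "confusion_isom.txt"))
    utils::write.csv(as.data.frame(unclass(cm_som)),
                     file.path(out_dir, "confusion_som.csv"))
    utils::write.csv(as.data.frame(unclass(cm_isom)),
                     file.path(out_dir, "confusion_isom.csv"))
    utils::write.csv(isom$filter, file.path(out_dir, "filter_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
    save_model(som, file.path(out_dir, "som_model.json"))
    save_model(isom, file.path(out_dir, "isom_model.json"))
  }
  res
}

#' @export
print.spr_experiment <- function(x, ...) {
  cat(sprintf("<spr_experiment> n_train = %d, n_test = %d\n",
              x$summary$n_train, x$summary$n_test))
  cat(sprintf("  SOM  accuracy: %.2f%%\n",
              round_half_up(100 * x$summary$som$accuracy)))
  cat(sprintf("  ISOM accuracy: %.2f%% (removed %d ambiguous samples)\n",
              round_half_up(100 * x$summary$isom$accuracy),
              x$summary$isom$n_removed))
  invisible(x)
}
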