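#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end flow (images -> pixel graphs ->
#' indices -> WS normalization -> classification) in one list that
#' round-trips losslessly through YAML. Unspecified fields take the package
#' defaults.
#'
#' @param input_dir directory of images with a `labels.csv` (columns
#'   `file`, `label`); ignored when an in-memory dataset is passed to the
#'   run functions.
#' @param tau pixel-graph similarity threshold.
#' @param resize working resolution (single side length for square resize),
#'   or `"native"` to skip resizing.
#' @param ws_p_ref,ws_reps matched WS reference parameters for feature
#'   normalization.
#' @param model_kind classifier for [cross_validate()].
#' @param folds,epochs cross-validation folds and neural-net epochs.
#' @param seed root seed; all pipeline randomness derives from it.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, tau = 0.95, resize = 32,
                       ws_p_ref = 0.25, ws_reps = 5, model_kind = "nn4",
                       folds = 5, epochs = 150, seed = 1, out_dir = NULL) {
  cfg <- list(input_dir = input_dir, tau = tau, resize = resize,
              ws_p_ref = ws_p_ref, ws_reps = ws_reps,
              model_kind = model_kind, folds = folds, epochs = epochs,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read and write run configurations as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[!vapply(vals, is.null, TRUE)])
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML serialization; changes whenever any parameter
#' changes, and is embedded in reports so a run can be re-created exactly.
#'
#' @param cfg a `run_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

load_input_images <- function(cfg) {
  lab_path <- file.path(cfg$input_dir, "labels.csv")
  if (is.null(cfg$input_dir) || !file.exists(lab_path)) {
    stop("input_dir must contain a labels.csv (columns file, label)",
         call. = FALSE)
  }
  lab <- utils::read.csv(lab_path)
  if (nrow(lab) == 0L) stop("empty labels.csv", call. = FALSE)
  list(images = lapply(file.path(cfg$input_dir, lab$file), load_grayscale),
       labels = lab$label)
}

#' Extract WS-normalized index features from a set of images
#'
#' For each image: grayscale -> optional area-average resize -> brightness
#' distance matrix -> min-max normalization -> threshold at `tau` ->
#' largest connected component -> six distance-based indices -> division by
#' a matched Watts-Strogatz reference ensemble mean. References are cached
#' per `(v, delta)` within the run and seeded deterministically from the
#' root seed, so identical configurations give identical feature tables.
#' Images whose pixel graph is too small for index computation are skipped
#' with a warning; the run fails if more than 10 percent of images fail.
#'
#' @param cfg a [run_config()].
#' @param dataset optional in-memory dataset (list with `images`, `labels`)
#'   overriding `cfg$input_dir`.
#' @return data.frame with `image_id`, the six normalized features, and
#'   `label`; configuration metadata in attribute `meta`.
#' @export
run_extract <- function(cfg, dataset = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(dataset)) dataset <- load_input_images(cfg)
  n <- length(dataset$images)
  if (n == 0L) stop("no input images", call. = FALSE)
  ref_cache <- new.env(parent = emptyenv())
  rows <- vector("list", n)
  failed <- 0L
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      img <- dataset$images[[i]]
      if (!identical(cfg$resize, "native")) {
        img <- downsample(img, cfg$resize, cfg$resize)
      }
      g <- image_to_graph(img, tau = cfg$tau, quiet = TRUE)
      if (igraph::vcount(g) < 3L) stop("pixel graph too small")
      dm <- all_pairs_distances(g)
      raw <- compute_index_vector(g, dm)
      v <- igraph::vcount(g)
      md <- 2 * igraph::ecount(g) / v
      delta <- min(max(2, 2 * round(md / 2)),
                   if ((v - 1) %% 2 == 0) v - 1 else v - 2)
      key <- paste(v, delta, sep = "_")
      if (is.null(ref_cache[[key]])) {
        # per-key seed derived from the root seed: cache-order independent
        ref_seed <- (cfg$seed + 1L + 61L * (v %% 10000L) + delta) %% .Machine$integer.max
        set.seed(ref_seed)
        ref_cache[[key]] <- ensemble_indices(v, delta, cfg$ws_p_ref,
                                             reps = cfg$ws_reps)
      }
      nv <- normalize_index_vector(raw, ref_cache[[key]])
      data.frame(image_id = i, Sz = nv["Sz"], ABC = nv["ABC"], PI = nv["PI"],
                 MO = nv["MO"], NGG = nv["NGG"], W = nv["W"],
                 label = dataset$labels[i], row.names = NULL)
    }, error = function(e) {
      warning(sprintf("image %d failed: %s", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(rows[[i]])) failed <- failed + 1L
  }
  if (failed > 0.1 * n) {
    stop(sprintf("%d of %d images failed feature extraction", failed, n),
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- c(tau = cfg$tau, resize = cfg$resize,
                         ws_p_ref = cfg$ws_p_ref, ws_reps = cfg$ws_reps,
                         seed = cfg$seed, config_hash = config_hash(cfg))
  out
}

#' Write and read feature tables with embedded metadata
#'
#' CSVs carry the extraction parameters as leading `#` comment lines so a
#' feature file is self-describing.
#'
#' @param features data.frame from [run_extract()].
#' @param path CSV path.
#' @return `write_features_csv` returns `path` invisibly; `read_features_csv`
#'   the data.frame (metadata in attribute `meta`).
#' @export
write_features_csv <- function(features, path) {
  meta <- attr(features, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), meta), con)
  }
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  out <- utils::read.csv(text = lines[setdiff(seq_along(lines), meta_lines)])
  if (length(meta_lines)) {
    kv <- sub("^# ", "", lines[meta_lines])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: ", "", kv)
    meta <- stats::setNames(vals, keys)
    attr(out, "meta") <- meta
  }
  out
}

#' Run the full pipeline: extraction plus cross-validated classification
#'
#' [run_extract()] followed by [cross_validate()] on the normalized
#' features. The returned report embeds the configuration, its hash, and
#' the package version, so results are re-runnable exactly.
#'
#' @inheritParams run_extract
#' @return List of class `run_report`: `config`, `config_hash`, `version`,
#'   `features`, `cv` (an `eval_report`), `mean_metrics`.
#' @export
run_full <- function(cfg, dataset = NULL) {
  feats <- run_extract(cfg, dataset = dataset)
  x <- as.matrix(feats[, c("Sz", "ABC", "PI", "MO", "NGG", "W")])
  y <- factor(feats$label)
  cv <- cross_validate(x, y, model_kind = cfg$model_kind, folds = cfg$folds,
                       hyper = list(epochs = cfg$epochs),
                       seed = (cfg$seed + 2L) %% .Machine$integer.max)
  rep <- list(config = unclass(cfg),
              config_hash = config_hash(cfg),
              version = as.character(utils::packageVersion("braintopo")),
              features = feats,
              cv = cv,
              mean_metrics = cv$mean)
  class(rep) <- "run_report"
  rep
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report %s, %d images, config %s>\n",
              x$config$model_kind, nrow(x$features), substr(x$config_hash, 1, 8)))
  print(round(x$mean_metrics, 4))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes per-fold metrics, the mean row, confusion matrices, loss curves,
#' and the reproducibility metadata (config, hash, version) as JSON.
#' Timestamps are deliberately excluded so identical runs produce identical
#' files.
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  fold_tab <- lapply(report$cv$folds, function(f) {
    c(f[c("accuracy", "precision", "recall", "f1", "auc")],
      list(confusion = unclass(f$confusion)))
  })
  out <- list(config = report$config,
              config_hash = report$config_hash,
              version = report$version,
              model_kind = report$cv$model_kind,
              folds = fold_tab,
              mean = as.list(report$mean_metrics),
              val_loss = report$cv$val_loss)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
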