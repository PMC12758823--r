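# End-to-end orchestration: extract -> fuse -> rule base -> knowledge graph ->
# sampled graph -> classify -> evaluate, from a single config.

#' Stratified train/test split
#'
#' @param labels Binary label vector.
#' @param train_frac Training fraction in `(0, 1)` (default 0.7).
#' @param seed Random seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, train_frac = 0.7, seed = 42L) {
  stopifnot(train_frac > 0, train_frac < 1)
  withr::with_seed(seed, {
    train <- unlist(lapply(unique(labels), function(l) {
      idx <- which(labels == l)
      sample(idx, max(1, round(train_frac * length(idx))))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

scale_with_ranges <- function(data, ranges) {
  for (cl in names(ranges)) {
    r <- ranges[[cl]]
    data[[cl]] <- if (diff(r) == 0) rep(0, nrow(data)) else (data[[cl]] - r[1]) / (r[2] - r[1])
  }
  data
}

default_config <- function() {
  list(
    synth = list(n = 100, seed = 42, prevalence = 0.5, lesion_effect = 2,
                 image_size = 96, blob_rate = 4),
    imaging = list(resize = NULL, levels = 16, distance = 1,
                   alpha = 1, sigma = 1, denoise_strength = 10,
                   template = 7, search = 21, clip_limit = 2, tile_grid = c(8, 8)),
    tabular = list(feature_cols = NULL, balance = TRUE),
    fusion = list(strategy = "feature_selection", k_img = 4, k_tab = 3,
                  rank = 3, common_dim = 4, corr_threshold = 0.7,
                  max_img = 4, max_tab = 3, min_img = 1, min_tab = 1, seed = 42),
    fkg = list(n_terms = 3, sample_rate = 0.3, error_threshold = 0.05,
               lambda = 0, max_iters = 200, seed = 42),
    split = list(train_frac = 0.7, seed = 42)
  )
}

merge_config <- function(config) {
  base <- default_config()
  for (sec in names(config)) {
    base[[sec]] <- if (is.list(config[[sec]]) && sec %in% names(base))
      utils::modifyList(base[[sec]], config[[sec]]) else config[[sec]]
  }
  base
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file path.
#' @return A config list with defaults filled in (see [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  merge_config(yaml::read_yaml(path))
}

load_run_dataset <- function(config) {
  if (!is.null(config$synth)) {
    # YAML 1.1 reads a bare `n:` key as the boolean FALSE; undo that
    nm <- names(config$synth)
    nm[nm == "FALSE"] <- "n"
    names(config$synth) <- nm
  }
  if (!is.null(config$dataset)) {
    stopifnot(inherits(config$dataset, "fkgmm_linked"))
    return(config$dataset)
  }
  if (!is.null(config$paths)) {
    p <- config$paths
    tab <- readr::read_csv(p$metadata, show_col_types = FALSE)
    imgs <- lapply(tab$id, function(id) {
      f <- list.files(p$images, pattern = paste0("^", id, "\\."), full.names = TRUE)[1]
      read_rgb_image(f, id = id)
    })
    return(structure(list(images = imgs, table = tab,
                          labels = as.integer(tab$label),
                          manifest = list(source = p)), class = "fkgmm_linked"))
  }
  do.call(generate_linked_dataset, config$synth)
}

fuse_train_features <- function(cfg, F_img, F_tab, y) {
  switch(cfg$strategy,
    feature_selection = feature_selection_fusion(F_img, F_tab, cfg$k_img, cfg$k_tab,
                                                 y = y, seed = cfg$seed),
    tensor = tensor_product_fusion(F_img, F_tab, cfg$rank),
    hadamard = hadamard_product_fusion(F_img, F_tab, cfg$common_dim, seed = cfg$seed),
    filter = filter_multimodal_selection(F_img, F_tab, y, cfg$k_img, cfg$k_tab,
                                         corr_threshold = cfg$corr_threshold, seed = cfg$seed),
    wrapper = wrapper_multimodal_selection(F_img, F_tab, y, cfg$max_img, cfg$max_tab,
                                           min_img = cfg$min_img, min_tab = cfg$min_tab,
                                           seed = cfg$seed),
    tabular_only = finish_fused(F_tab, list(strategy = "tabular_only")),
    image_only = finish_fused(F_img, list(strategy = "image_only")),
    rlang::abort(paste0("unknown fusion strategy: ", cfg$strategy), class = "fkgmm_config_error")
  )
}

apply_run_fusion <- function(fit, F_img, F_tab) {
  switch(fit$strategy,
    tabular_only = tibble::as_tibble(F_tab),
    image_only = tibble::as_tibble(F_img),
    apply_fusion(fit, F_img, F_tab)
  )
}

#' Run the full multi-modal classification pipeline
#'
#' Stages, in order: obtain the linked dataset (a supplied `fkgmm_linked`
#' object, image/metadata paths, or the synthetic generator), extract image
#' features, assemble tabular features, split 70/30 stratified by label, scale
#' features to the training ranges, fit the configured fusion on the training
#' set and apply it to the test set, optionally oversample the training
#' classes to balance, fit the membership scheme / rule base / knowledge
#' graph, sample the graph, classify the test set, and score it.
#'
#' @param config A (possibly partial) config list — see `default_config` in
#'   the package source, sections `synth`/`dataset`/`paths`, `imaging`,
#'   `tabular`, `fusion`, `fkg`, `split` — or a YAML path.
#' @param artifacts_dir Optional directory to persist intermediate CSV/JSON
#'   artifacts.
#' @return An object of class `fkgmm_report`: accuracy, confusion counts,
#'   achieved sampling error, selected features, per-stage timings, and the
#'   config echo.
#' @export
run_pipeline <- function(config = list(), artifacts_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dataset <- load_run_dataset(config)
  image_features <- config$image_features # optional precomputed feature table
  config <- merge_config(config[setdiff(names(config), c("dataset", "image_features"))])
  timings <- list()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  # image features
  t0 <- tic()
  im <- config$imaging
  F_img_all <- if (!is.null(image_features)) tibble::as_tibble(image_features) else
    extract_image_features(dataset$images, levels = im$levels,
                                      distance = im$distance, resize = im$resize,
                                      alpha = im$alpha, sigma = im$sigma,
                                      denoise_strength = im$denoise_strength,
                                      template = im$template, search = im$search,
                                      clip_limit = im$clip_limit, tile_grid = im$tile_grid)
  timings$image_features <- lap(t0)

  # tabular features
  t0 <- tic()
  tab <- dataset$table
  feat_cols <- config$tabular$feature_cols
  if (is.null(feat_cols))
    feat_cols <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], c("label"))
  F_tab_all <- tab[, feat_cols, drop = FALSE]
  y_all <- dataset$labels
  timings$tabular_features <- lap(t0)

  # split, then scale to the training ranges
  sp <- split_dataset(y_all, config$split$train_frac, config$split$seed)
  img_feats <- setdiff(names(F_img_all), "id")
  F_img_tr <- min_max_scale(F_img_all[sp$train, img_feats])
  F_img_te <- scale_with_ranges(F_img_all[sp$test, img_feats], attr(F_img_tr, "minmax_ranges"))
  F_tab_tr <- min_max_scale(F_tab_all[sp$train, , drop = FALSE])
  F_tab_te <- scale_with_ranges(F_tab_all[sp$test, , drop = FALSE], attr(F_tab_tr, "minmax_ranges"))
  y_tr <- y_all[sp$train]; y_te <- y_all[sp$test]

  # fusion
  t0 <- tic()
  fused_tr <- fuse_train_features(config$fusion, F_img_tr, F_tab_tr, y_tr)
  fit <- attr(fused_tr, "fit") %||% list(strategy = config$fusion$strategy)
  fused_te <- apply_run_fusion(fit, F_img_te, F_tab_te)
  timings$fusion <- lap(t0)

  # optional class balancing of the training set (random oversampling)
  if (isTRUE(config$tabular$balance) && length(unique(y_tr)) > 1) {
    btr <- balance_classes(dplyr::bind_cols(fused_tr, tibble::tibble(label = y_tr)),
                           target_col = "label", seed = config$split$seed)
    y_tr <- btr$label
    fused_tr <- btr[, setdiff(names(btr), "label"), drop = FALSE]
  }

  # rule base -> knowledge graph -> sampled graph
  t0 <- tic()
  scheme <- fit_membership_scheme(fused_tr, config$fkg$n_terms)
  frb <- generate_frb(fused_tr, y_tr, scheme = scheme)
  fkg <- build_fkg(frb)
  fkgs <- sample_fkgs(fkg, config$fkg$sample_rate, config$fkg$error_threshold,
                      seed = config$fkg$seed, max_iters = config$fkg$max_iters)
  timings$train <- lap(t0)

  # classify and score the test set
  t0 <- tic()
  preds <- fisa_classify(fkgs, fused_te, scheme = scheme, lambda = config$fkg$lambda)
  ev <- evaluate_classifier(preds$.pred, y_te, positive = "1")
  timings$test <- lap(t0)

  report <- structure(list(
    accuracy = ev$accuracy,
    confusion = ev$confusion,
    fkgs_error = fkgs$achieved_error,
    fkgs_converged = fkgs$converged,
    n_rules_full = nrow(frb), n_rules_sampled = nrow(fkgs$frb),
    n_train = length(sp$train), n_test = length(sp$test),
    selected = attr(fused_tr, "fit"),
    timings = timings,
    config = config
  ), class = "fkgmm_report")

  if (!is.null(artifacts_dir)) {
    dir.create(artifacts_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(F_img_all, file.path(artifacts_dir, "image_features.csv"))
    readr::write_csv(dplyr::bind_cols(fused_tr, tibble::tibble(label = y_tr)),
                     file.path(artifacts_dir, "fused_train.csv"))
    write_frb_csv(frb, file.path(artifacts_dir, "frb.csv"))
    write_fkg_json(fkgs, file.path(artifacts_dir, "fkgs.json"))
    jsonlite::write_json(report_to_list(report), file.path(artifacts_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_list <- function(report) {
  list(accuracy = report$accuracy,
       confusion = as.list(report$confusion),
       fkgs_error = report$fkgs_error,
       fkgs_converged = report$fkgs_converged,
       n_rules_full = report$n_rules_full,
       n_rules_sampled = report$n_rules_sampled,
       n_train = report$n_train, n_test = report$n_test,
       timings = report$timings,
       config = report$config[setdiff(names(report$config), "dataset")])
}

#' @export
print.fkgmm_report <- function(x, ...) {
  cat("fkgmm pipeline report\n")
  cat(sprintf("  strategy:       %s\n", x$config$fusion$strategy))
  cat(sprintf("  train/test:     %d / %d samples\n", x$n_train, x$n_test))
  cat(sprintf("  rules:          %d -> %d after sampling (error %.3f)\n",
              x$n_rules_full, x$n_rules_sampled, x$fkgs_error))
  cat(sprintf("  test accuracy:  %.3f\n", x$accuracy))
  cm <- x$confusion
  cat(sprintf("  confusion:      TP %d  FP %d  FN %d  TN %d\n", cm$tp, cm$fp, cm$fn, cm$tn))
  invisible(x)
}

#' One-row summary of a pipeline report
#'
#' @param x A `fkgmm_report`.
#' @param ... Unused.
#' @return A one-row tibble of the headline numbers.
#' @export
glance.fkgmm_report <- function(x, ...) {
  tibble::tibble(strategy = x$config$fusion$strategy, accuracy = x$accuracy,
                 fkgs_error = x$fkgs_error, n_train = x$n_train, n_test = x$n_test,
                 n_rules_sampled = x$n_rules_sampled)
}
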