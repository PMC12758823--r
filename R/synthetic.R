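# Seeded generators for paired fundus-style images and clinical-style tabular
# records (both carrying label signal), plus hand-transcribed published
# fixtures used by the worked-example tests.

stamp_blob <- function(img, cy, cx, radius, colour) {
  s <- dim(img)[1]
  r0 <- max(1, floor(cy - 3 * radius)):min(s, ceiling(cy + 3 * radius))
  c0 <- max(1, floor(cx - 3 * radius)):min(dim(img)[2], ceiling(cx + 3 * radius))
  if (length(r0) == 0 || length(c0) == 0) return(img)
  d2 <- outer((r0 - cy)^2, (c0 - cx)^2, "+")
  w <- exp(-d2 / (2 * radius^2))
  for (ch in 1:3) img[r0, c0, ch] <- img[r0, c0, ch] * (1 - w) + colour[ch] * w
  img
}

generate_one_fundus <- function(size, label, lesion_effect, blob_rate) {
  s <- size
  img <- array(0, c(s, s, 3))
  img[, , 1] <- 18; img[, , 2] <- 12; img[, , 3] <- 10
  cy <- s / 2; cx <- s / 2; R <- 0.48 * s
  d <- sqrt(outer((seq_len(s) - cy)^2, (seq_len(s) - cx)^2, "+"))
  field <- d <= R
  vign <- pmax(1 - (d / R)^2, 0) # radial falloff inside the field
  base <- c(150, 70, 35)
  for (ch in 1:3) {
    m <- img[, , ch]
    m[field] <- base[ch] * (0.55 + 0.45 * vign[field])
    img[, , ch] <- m
  }
  # optic disc: bright blob offset toward one side
  side <- sample(c(-1, 1), 1)
  img <- stamp_blob(img, cy + stats::rnorm(1, 0, 0.02 * s),
                    cx + side * 0.25 * s, 0.06 * s, c(235, 190, 120))
  # vessel-like dark random-walk curves radiating from the disc
  for (v in seq_len(4)) {
    py <- cy; px <- cx + side * 0.25 * s
    ang <- stats::runif(1, 0, 2 * pi)
    for (st in seq_len(round(0.6 * s))) {
      ang <- ang + stats::rnorm(1, 0, 0.25)
      py <- py + sin(ang); px <- px + cos(ang)
      if (py < 2 || py > s - 1 || px < 2 || px > s - 1) break
      if (sqrt((py - cy)^2 + (px - cx)^2) > R) break
      img <- stamp_blob(img, py, px, max(1, 0.004 * s), c(70, 22, 18))
    }
  }
  # lesion-like blobs: Poisson count, label-dependent mean
  n_blobs <- stats::rpois(1, blob_rate * (1 + lesion_effect * label))
  for (b in seq_len(n_blobs)) {
    repeat {
      by <- stats::runif(1, 1, s); bx <- stats::runif(1, 1, s)
      if (sqrt((by - cy)^2 + (bx - cx)^2) <= 0.9 * R) break
    }
    bright <- stats::runif(1) < 0.5
    col <- if (bright) c(240, 225, 170) else c(45, 12, 10)
    # floor the radius at 1.2 px so lesions stay resolvable on small rasters
    img <- stamp_blob(img, by, bx, max(stats::runif(1, 0.006, 0.014) * s, 1.2), col)
  }
  img <- img + array(stats::rnorm(s * s * 3, 0, 6), c(s, s, 3)) # speckle
  img[img < 0] <- 0; img[img > 255] <- 255
  img
}

#' Generate fundus-like RGB images with label-dependent lesions
#'
#' Each image is a dark circular retinal field with a radial intensity
#' falloff, a bright optic-disc blob, dark vessel-like random-walk curves, a
#' Poisson number of small bright/dark lesion-like blobs whose mean is
#' `blob_rate * (1 + lesion_effect * label)`, and additive speckle noise.
#' Fully deterministic given the seed.
#'
#' @param n Number of images.
#' @param labels Binary label per image (length `n`).
#' @param seed Random seed (default 42).
#' @param lesion_effect Multiplier of the label effect on the blob count
#'   (default 2; 0 makes the blob distribution label-independent).
#' @param size Image side length in pixels (default 256).
#' @param blob_rate Baseline Poisson blob rate (default 4).
#' @return A list of `n` [rgb_image()] arrays with ids `"s0001"`, ...
#' @export
generate_fundus_like_images <- function(n, labels, seed = 42L, lesion_effect = 2,
                                        size = 256L, blob_rate = 4) {
  stopifnot(n >= 1, length(labels) == n)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i)
      rgb_image(generate_one_fundus(size, labels[i], lesion_effect, blob_rate),
                id = sprintf("s%04d", i)))
  })
}

#' Generate clinical-style tabular records with label-dependent attributes
#'
#' Age is label-independent Normal; diabetes duration is Normal shifted by
#' `effects$duration` years for label-1 records; insulin use is Bernoulli with
#' probability raised by `effects$insulin` for label 1; sex and imaging device
#' are label-independent categoricals. Deterministic given the seed.
#'
#' @param n Number of records.
#' @param labels Binary label per record.
#' @param seed Random seed (default 42).
#' @param effects Named list of label effects: `duration` (mean shift in
#'   years, default 5), `insulin` (probability shift, default 0.3), `age`
#'   (mean shift, default 0).
#' @return A tibble: `id`, `age`, `duration`, `insulin`, `sex`, `device`,
#'   `label`.
#' @export
generate_tabular_records <- function(n, labels, seed = 42L,
                                     effects = list(duration = 5, insulin = 0.3, age = 0)) {
  stopifnot(n >= 1, length(labels) == n)
  eff <- utils::modifyList(list(duration = 5, insulin = 0.3, age = 0), as.list(effects))
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("s%04d", seq_len(n)),
      age = stats::rnorm(n, 60 + eff$age * labels, 10),
      duration = pmax(stats::rnorm(n, 8 + eff$duration * labels, 4), 0),
      insulin = stats::rbinom(n, 1, pmin(pmax(0.25 + eff$insulin * labels, 0), 1)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      device = sample(c("deviceA", "deviceB"), n, replace = TRUE),
      label = as.integer(labels)
    )
  })
}

#' Generate a linked image + tabular dataset
#'
#' Draws binary labels at the given prevalence and generates paired
#' [generate_fundus_like_images()] and [generate_tabular_records()] samples
#' with aligned ids. The generation manifest (all parameters and the seed)
#' reproduces the dataset exactly.
#'
#' @param n Number of samples.
#' @param seed Random seed (default 42).
#' @param prevalence Label-1 prevalence (default 0.5).
#' @param lesion_effect Image label effect (default 2).
#' @param effects Tabular label effects (see [generate_tabular_records()]).
#' @param image_size Image side length (default 256).
#' @param blob_rate Baseline blob rate (default 4).
#' @return An object of class `fkgmm_linked`: list with `images`, `table`,
#'   `labels`, and `manifest`.
#' @export
generate_linked_dataset <- function(n, seed = 42L, prevalence = 0.5, lesion_effect = 2,
                                    effects = list(duration = 5, insulin = 0.3, age = 0),
                                    image_size = 256L, blob_rate = 4) {
  labels <- withr::with_seed(seed, stats::rbinom(n, 1, prevalence))
  manifest <- list(n = n, seed = seed, prevalence = prevalence,
                   lesion_effect = lesion_effect, effects = effects,
                   image_size = image_size, blob_rate = blob_rate)
  structure(list(
    images = generate_fundus_like_images(n, labels, seed = seed + 1L,
                                         lesion_effect = lesion_effect,
                                         size = image_size, blob_rate = blob_rate),
    table = generate_tabular_records(n, labels, seed = seed + 2L, effects = effects),
    labels = as.integer(labels),
    manifest = manifest
  ), class = "fkgmm_linked")
}

#' Save a linked dataset to disk
#'
#' Writes `images/<id>.png`, `meta.csv`, and `manifest.json` under `dir`.
#'
#' @param dataset A `fkgmm_linked` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_linked_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fkgmm_linked"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (img in dataset$images)
    write_rgb_image(img, file.path(dir, "images", paste0(attr(img, "id"), ".png")))
  readr::write_csv(dataset$table, file.path(dir, "meta.csv"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---- published fixtures ------------------------------------------------------

frb_fixture_path <- function(name) {
  system.file("extdata", name, package = "fkgmm", mustWork = TRUE)
}

#' Load the packaged worked-example fixtures
#'
#' Returns the hand-transcribed rule tables and worked-example matrices used
#' by the fusion and sampling examples: a 6-rule three-attribute rule base
#' (`table1_frb`), the 14-rule weather-style rule base (`table2_frb`) and its
#' published 5-rule sample (`table3_fkgs`), the inputs and expected outputs of
#' the five fusion worked examples (`example1`..`example5`), and the published
#' per-strategy accuracy table (`scenario_accuracy`). Rule-table files are
#' checksum-verified.
#'
#' @return A named list of fixtures.
#' @export
load_paper_fixtures <- function() {
  files <- c(table1_frb = "table1_frb.csv", table2_frb = "table2_frb.csv",
             table3_fkgs = "table3_fkgs.csv")
  expected_md5 <- c(
    table1_frb = "7c0a7fbf694f58c76021f55541ef6f7e",
    table2_frb = "605633210b8ffe6f5bfff2f07dac28f9",
    table3_fkgs = "a2aefcb8c2a02f611edba212c9df5539"
  )
  frbs <- lapply(names(files), function(nm) {
    p <- frb_fixture_path(files[[nm]])
    md5 <- unname(tools::md5sum(p))
    if (!identical(md5, expected_md5[[nm]]))
      rlang::abort(paste0("fixture file corrupted: ", files[[nm]]),
                   class = "fkgmm_fixture_corruption")
    as_frb(readr::read_csv(p, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character())))
  })
  names(frbs) <- names(files)

  example1 <- list(
    img_features = paste0("fimg", 1:5), tab_features = paste0("ftab", 1:4),
    img_scores = c(0.7, 0.3, 0.8, 0.5, 0.4), tab_scores = c(0.6, 0.9, 0.3, 0.7),
    k_img = 3L, k_tab = 2L,
    expected = c("fimg3", "fimg1", "fimg4", "ftab2", "ftab4")
  )

  example2 <- list(
    F_img = matrix(c(4, 2, 8, 6, 1, 3), 2, 3, byrow = TRUE),
    F_tab = matrix(c(5, 3, 9, 2), 2, 2, byrow = TRUE),
    normalized_img_row1 = c(0.437, 0.218, 0.873),
    normalized_tab_row1 = c(0.858, 0.515)
  )

  example3 <- list(
    F_img = matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE),
    F_tab = matrix(c(7, 8, 9, 10), 2, 2, byrow = TRUE),
    W_img = matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 3, 2, byrow = TRUE),
    W_tab = matrix(c(0.7, 0.8, 0.9, 0.1), 2, 2, byrow = TRUE),
    W_fusion = matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.1, 0.2, 0.3),
                      6, 2, byrow = TRUE),
    common_dim = 2L,
    expected = matrix(c(1.915, 1.485, 1.914, 1.487), 2, 2, byrow = TRUE)
  )

  img_feats4 <- paste0("img", 1:5); tab_feats4 <- paste0("tab", 1:4)
  corr_img4 <- matrix(1, 3, 3, dimnames = list(c("img3", "img1", "img5"), c("img3", "img1", "img5")))
  corr_img4["img3", "img1"] <- corr_img4["img1", "img3"] <- 0.15
  corr_img4["img3", "img5"] <- corr_img4["img5", "img3"] <- 0.78
  corr_img4["img1", "img5"] <- corr_img4["img5", "img1"] <- 0.22
  corr_tab4 <- matrix(1, 3, 3, dimnames = list(c("tab2", "tab4", "tab1"), c("tab2", "tab4", "tab1")))
  corr_tab4["tab2", "tab4"] <- corr_tab4["tab4", "tab2"] <- 0.31
  corr_tab4["tab2", "tab1"] <- corr_tab4["tab1", "tab2"] <- 0.25
  corr_tab4["tab4", "tab1"] <- corr_tab4["tab1", "tab4"] <- 0.63
  example4 <- list(
    F_img = matrix(c(5, 2, 8, 6, 9, 7, 1, 4, 3, 8, 6, 3, 9, 5, 7), 3, 5, byrow = TRUE,
                   dimnames = list(NULL, img_feats4)),
    F_tab = matrix(c(3, 6, 2, 7, 8, 5, 1, 9, 4, 7, 3, 8), 3, 4, byrow = TRUE,
                   dimnames = list(NULL, tab_feats4)),
    target = c(0, 1, 0),
    mi_img = c(img1 = 0.38, img2 = 0.21, img3 = 0.52, img4 = 0.27, img5 = 0.35),
    rf_img = c(img1 = 0.18, img2 = 0.11, img3 = 0.35, img4 = 0.15, img5 = 0.21),
    mi_tab = c(tab1 = 0.31, tab2 = 0.43, tab3 = 0.22, tab4 = 0.40),
    rf_tab = c(tab1 = 0.22, tab2 = 0.32, tab3 = 0.13, tab4 = 0.33),
    corr_img = corr_img4, corr_tab = corr_tab4,
    k_img = 2L, k_tab = 2L, pool_img = 3L, pool_tab = 3L, corr_threshold = 0.7,
    expected = c("img3", "img1", "tab2", "tab4"),
    expected_score_img3 = 0.435
  )

  ex5_scores <- c(
    "img_1" = 0.65, "img_2" = 0.58, "img_3" = 0.72, "img_5" = 0.61,
    "tab_1" = 0.56, "tab_2" = 0.69, "tab_4" = 0.64,
    "img_1+img_3+tab_2" = 0.76, "img_2+img_3+tab_2" = 0.71, "img_3+img_5+tab_2" = 0.73,
    "img_3+tab_1+tab_2" = 0.72, "img_3+tab_2+tab_4" = 0.78,
    "img_1+img_3+tab_2+tab_4" = 0.83, "img_2+img_3+tab_2+tab_4" = 0.77,
    "img_3+img_5+tab_2+tab_4" = 0.80, "img_3+tab_1+tab_2+tab_4" = 0.79,
    "img_1+img_2+img_3+tab_2+tab_4" = 0.82, "img_1+img_3+img_5+tab_2+tab_4" = 0.85,
    "img_1+img_3+tab_1+tab_2+tab_4" = 0.84, "img_1+img_3+img_5+tab_1+tab_2+tab_4" = 0.84
  )
  example5 <- list(
    img_features = paste0("img_", 1:5), tab_features = paste0("tab_", 1:4),
    candidates_img = c("img_1", "img_2", "img_3", "img_5"),
    candidates_tab = c("tab_1", "tab_2", "tab_4"),
    max_img = 3L, max_tab = 2L, min_img = 1L, min_tab = 1L,
    scores = ex5_scores,
    expected_selection = c("img_3", "img_1", "img_5", "tab_2", "tab_4"),
    expected_score = 0.85
  )

  scenario_accuracy <- tibble::tibble(
    method = rep(c("feature_selection", "tensor", "hadamard", "filter", "wrapper"), each = 4),
    config = rep(c("r15_t02", "r15_t03", "r20_t02", "r20_t03"), times = 5),
    accuracy = c(84.19, 84.00, 85.35, 85.22,
                 81.18, 80.87, 82.73, 82.17,
                 77.01, 76.05, 78.58, 77.05,
                 81.40, 81.71, 82.70, 83.26,
                 77.22, 78.57, 78.59, 77.47)
  )

  c(frbs, list(example1 = example1, example2 = example2, example3 = example3,
               example4 = example4, example5 = example5,
               scenario_accuracy = scenario_accuracy))
}

#' Build an evaluator that returns scripted scores per feature subset
#'
#' The returned function keys a feature subset by its sorted column names
#' joined with `"+"` and looks the score up in `scores`; an unknown subset is
#' an error. Used to replay published wrapper-selection walk-throughs.
#'
#' @param scores Named numeric vector of subset scores.
#' @return A function `f(X, y) -> score`.
#' @export
scripted_evaluator <- function(scores) {
  function(X, y) {
    key <- paste(sort(colnames(X)), collapse = "+")
    if (!key %in% names(scores))
      rlang::abort(paste0("no scripted score for subset: ", key), class = "fkgmm_evaluation_error")
    unname(scores[[key]])
  }
}
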