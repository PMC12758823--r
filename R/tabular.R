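#' @importFrom dplyr %>%
NULL

#' Load and preprocess a clinical tabular table
#'
#' Selects the declared columns, applies categorical code mappings, coerces the
#' numeric columns (imputing missing values by the column mean), and remaps the
#' outcome label to `{0, 1}`.
#'
#' @param path CSV file path, or a data frame.
#' @param columns Character vector of columns to keep (must include
#'   `target_col`); `NULL` keeps all.
#' @param cat_mappings Named list: column name -> named vector mapping raw
#'   categorical values to codes.
#' @param numeric_cols Character vector of columns to coerce to numeric with
#'   mean imputation.
#' @param target_col Name of the label column.
#' @param label_map Named vector mapping raw label values to `0`/`1`; `NULL`
#'   if the labels are already 0/1.
#' @param id_col Optional name of a sample-id column; if absent, row numbers
#'   are used.
#' @return A tibble with an `id` column, the processed attributes, and the
#'   binary label in `target_col`.
#' @export
preprocess_table <- function(path, columns = NULL, cat_mappings = list(),
                             numeric_cols = character(), target_col = "label",
                             label_map = NULL, id_col = NULL) {
  df <- if (is.data.frame(path)) tibble::as_tibble(path) else {
    if (!file.exists(path)) rlang::abort(paste0("no such file: ", path), class = "fkgmm_schema_error")
    readr::read_csv(path, show_col_types = FALSE)
  }
  if (!is.null(columns)) {
    miss <- setdiff(unique(c(columns, target_col, id_col)), names(df))
    if (length(miss) > 0)
      rlang::abort(paste0("declared column(s) missing: ", paste(miss, collapse = ", ")),
                   class = "fkgmm_schema_error")
    df <- df[, unique(c(id_col, columns, target_col)), drop = FALSE]
  }
  if (!target_col %in% names(df))
    rlang::abort(paste0("target column not found: ", target_col), class = "fkgmm_schema_error")
  for (cl in names(cat_mappings)) {
    if (!cl %in% names(df))
      rlang::abort(paste0("mapped column missing: ", cl), class = "fkgmm_schema_error")
    df[[cl]] <- unname(cat_mappings[[cl]][as.character(df[[cl]])])
  }
  for (cl in numeric_cols) {
    if (!cl %in% names(df))
      rlang::abort(paste0("numeric column missing: ", cl), class = "fkgmm_schema_error")
    x <- suppressWarnings(as.numeric(df[[cl]]))
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    df[[cl]] <- x
  }
  if (!is.null(label_map)) {
    y <- unname(label_map[as.character(df[[target_col]])])
    if (anyNA(y))
      rlang::abort("label value not covered by label_map", class = "fkgmm_label_error")
    df[[target_col]] <- as.integer(y)
  }
  if (!all(df[[target_col]] %in% c(0L, 1L)))
    rlang::abort("labels must be binary {0, 1} after remapping", class = "fkgmm_label_error")
  if (is.null(id_col)) {
    df <- dplyr::bind_cols(tibble::tibble(id = as.character(seq_len(nrow(df)))), df)
  } else {
    names(df)[names(df) == id_col] <- "id"
    df$id <- as.character(df$id)
  }
  if (anyDuplicated(df$id)) rlang::abort("sample ids must be unique", class = "fkgmm_schema_error")
  df
}

#' Balance a binary-labeled table
#'
#' Random oversampling duplicates randomly chosen minority rows (all original
#' rows are retained) until both classes have equal counts; random
#' undersampling instead drops randomly chosen majority rows. Resampling is
#' reproducible under the given seed.
#'
#' @param table A tibble with a binary label column.
#' @param target_col Name of the label column (default `"label"`).
#' @param method `"oversample"` (default) or `"undersample"`.
#' @param seed Random seed (default 42).
#' @return A balanced tibble.
#' @export
balance_classes <- function(table, target_col = "label", method = c("oversample", "undersample"),
                            seed = 42L) {
  method <- match.arg(method)
  y <- table[[target_col]]
  lv <- sort(unique(y))
  counts <- vapply(lv, function(l) sum(y == l), numeric(1))
  if (length(counts) < 2)
    rlang::abort("cannot balance a single-class table", class = "fkgmm_balance_error")
  if (counts[1] == counts[2]) return(table)
  maj <- lv[which.max(counts)]
  minr <- lv[which.min(counts)]
  withr::with_seed(seed, {
    if (method == "oversample") {
      need <- max(counts) - min(counts)
      extra_idx <- sample(which(y == minr), need, replace = TRUE)
      out <- dplyr::bind_rows(table, table[extra_idx, , drop = FALSE])
    } else {
      keep_maj <- sample(which(y == maj), min(counts))
      out <- table[sort(c(which(y == minr), keep_maj)), , drop = FALSE]
    }
  })
  out
}

#' Mutual information between a feature and a discrete label
#'
#' Continuous features are discretized into equal-width bins over their range
#' (default 8); features with at most `bins` distinct values are treated as
#' already discrete. The estimate is the plug-in MI of the joint histogram, in
#' nats.
#'
#' @param x Numeric feature vector.
#' @param y Label vector (discrete).
#' @param bins Number of equal-width bins (default 8).
#' @return Nonnegative mutual-information estimate.
#' @export
mutual_information <- function(x, y, bins = 8L) {
  ux <- unique(x)
  xb <- if (length(ux) <= bins) {
    match(x, sort(ux))
  } else {
    r <- range(x)
    pmin(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
  }
  joint <- table(xb, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / outer(px, py)[pos]))
}

#' Two-step tabular feature selection
#'
#' Step 1 prunes correlated features: scanning features in decreasing order of
#' label relevance (mutual information), a feature is dropped when its absolute
#' Pearson correlation with an already-kept feature exceeds `corr_threshold`
#' (so of each such pair the lower-relevance member is dropped; ties keep the
#' earlier column). Step 2 ranks the survivors by mutual information with the
#' label and keeps the top `k`.
#'
#' @param table A tibble with numeric feature columns and a binary label.
#' @param target_col Name of the label column (default `"label"`).
#' @param corr_threshold Absolute Pearson correlation above which a pair is
#'   considered redundant (default 0.85).
#' @param k Number of features to keep; if larger than the survivor count, all
#'   survivors are kept with a warning.
#' @param bins Discretization bins for [mutual_information()].
#' @return A tibble with the selected feature columns (plus `id` and the label
#'   column if present in the input), with the selected feature names in the
#'   `"selected"` attribute.
#' @export
select_tabular_features <- function(table, target_col = "label", corr_threshold = 0.85,
                                    k = 5L, bins = 8L) {
  stopifnot(corr_threshold > 0, corr_threshold <= 1)
  y <- table[[target_col]]
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], target_col)
  feats <- setdiff(feats, "id")
  if (length(feats) < 2)
    rlang::abort("need at least two numeric features", class = "fkgmm_config_error")
  mi <- vapply(feats, function(f) mutual_information(table[[f]], y, bins), numeric(1))
  ord <- order(-mi) # stable: ties keep the earlier column
  X <- as.matrix(table[feats])
  kept <- character()
  for (f in feats[ord]) {
    if (length(kept) == 0) { kept <- f; next }
    cors <- abs(suppressWarnings(stats::cor(X[, f], X[, kept, drop = FALSE])))
    cors[is.na(cors)] <- 1 # constant columns are fully redundant
    if (all(cors <= corr_threshold)) kept <- c(kept, f)
  }
  if (k > length(kept)) {
    rlang::warn(paste0("k = ", k, " exceeds the ", length(kept), " surviving features; keeping all"))
    k <- length(kept)
  }
  sel <- kept[order(-mi[kept])][seq_len(k)]
  out <- table[, c(intersect(c("id", target_col), names(table)), sel), drop = FALSE]
  attr(out, "selected") <- sel
  attr(out, "mi_scores") <- mi
  out
}
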