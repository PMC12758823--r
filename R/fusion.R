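# Five strategies for combining an image feature matrix and a tabular feature
# matrix (rows = shared samples). All take data frames of numeric features and
# return tibbles whose "fit" attribute carries what is needed to apply the same
# fusion to new samples (see apply_fusion()).

as_feature_matrix <- function(F, arg = "F") {
  F <- tibble::as_tibble(F)
  F <- F[, vapply(F, is.numeric, logical(1)), drop = FALSE]
  if (ncol(F) == 0) rlang::abort(paste0(arg, " has no numeric feature columns"), class = "fkgmm_shape_error")
  if (anyNA(F)) rlang::abort(paste0(arg, " contains missing values"), class = "fkgmm_shape_error")
  F
}

check_aligned <- function(F_img, F_tab) {
  if (nrow(F_img) != nrow(F_tab))
    rlang::abort("image and tabular feature matrices must have the same number of rows",
                 class = "fkgmm_shape_error")
}

#' L2-normalize the rows of a matrix
#'
#' Each row is divided by its Euclidean norm; all-zero rows are left at zero.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with unit-norm (or zero) rows.
#' @export
l2_normalize_rows <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# coerce a scores argument (named/unnamed numeric vector or the tibble returned
# by compute_feature_importance) to a numeric vector aligned with `features`
as_scores <- function(scores, features) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$feature)
  if (!is.null(names(scores))) scores <- scores[features]
  if (length(scores) != length(features) || anyNA(scores))
    rlang::abort("scores do not match the feature columns", class = "fkgmm_config_error")
  as.numeric(scores)
}

#' Per-feature importance scores
#'
#' The default combined score is the arithmetic mean of (a) the mutual
#' information between the feature and the label and (b) the seeded
#' random-forest Gini importance normalized to proportions, mirroring the
#' average of the two criteria. `mi_scores`/`rf_scores` may be supplied
#' directly (e.g. precomputed values), in which case only the combination is
#' performed.
#'
#' @param X Data frame of numeric features.
#' @param y Binary label vector.
#' @param method `"combined"` (default), `"mi"`, `"rf"`, or `"variance"`.
#' @param mi_scores,rf_scores Optional per-feature numeric vectors overriding
#'   the computed criteria.
#' @param bins Discretization bins for [mutual_information()].
#' @param ntree Random-forest size (default 200).
#' @param seed Seed for the random forest (default 42).
#' @return A tibble with columns `feature`, `mi`, `rf`, `score`, and a
#'   `"method"` attribute.
#' @export
compute_feature_importance <- function(X, y, method = c("combined", "mi", "rf", "variance"),
                                       mi_scores = NULL, rf_scores = NULL,
                                       bins = 8L, ntree = 200L, seed = 42L) {
  method <- match.arg(method)
  X <- as_feature_matrix(X, "X")
  feats <- names(X)
  if (method != "variance" && is.null(mi_scores) && is.null(rf_scores) && length(unique(y)) < 2)
    rlang::abort("label is constant; importance is undefined", class = "fkgmm_importance_error")
  if (method == "variance") {
    v <- vapply(X, stats::var, numeric(1))
    return(structure(tibble::tibble(feature = feats, mi = NA_real_, rf = NA_real_, score = v),
                     method = "variance"))
  }
  mi <- if (!is.null(mi_scores)) as.numeric(mi_scores) else
    vapply(X, function(x) mutual_information(x, y, bins), numeric(1))
  rf <- if (!is.null(rf_scores)) as.numeric(rf_scores) else if (method == "mi") rep(NA_real_, length(feats)) else {
    imp <- withr::with_seed(seed, randomForest::randomForest(
      x = as.data.frame(X), y = factor(y), ntree = ntree)$importance[, "MeanDecreaseGini"])
    if (sum(imp) > 0) imp / sum(imp) else imp
  }
  score <- switch(method, combined = (mi + rf) / 2, mi = mi, rf = rf)
  structure(tibble::tibble(feature = feats, mi = mi, rf = rf, score = score), method = method)
}

finish_fused <- function(fused, fit) {
  fused <- tibble::as_tibble(fused)
  attr(fused, "fit") <- fit
  class(fused) <- c("fkgmm_fused", class(fused))
  fused
}

#' Fusion by per-modality importance ranking
#'
#' Ranks the features of each modality by importance (descending, stable in
#' input order on ties) and concatenates the top `k_img` image features
#' followed by the top `k_tab` tabular features.
#'
#' @param F_img,F_tab Data frames of numeric features with equal row counts.
#' @param k_img,k_tab Number of features to keep per modality.
#' @param y Binary labels, required when scores are not supplied.
#' @param scores_img,scores_tab Optional importance scores (numeric vectors or
#'   [compute_feature_importance()] tibbles).
#' @param seed Seed for the default importance computation.
#' @return A tibble of the selected columns in rank order; the `"fit"`
#'   attribute records the selection.
#' @export
feature_selection_fusion <- function(F_img, F_tab, k_img, k_tab, y = NULL,
                                     scores_img = NULL, scores_tab = NULL, seed = 42L) {
  F_img <- as_feature_matrix(F_img, "F_img"); F_tab <- as_feature_matrix(F_tab, "F_tab")
  check_aligned(F_img, F_tab)
  if (k_img == 0 && k_tab == 0)
    rlang::abort("k_img and k_tab are both zero; nothing to fuse", class = "fkgmm_empty_fusion")
  stopifnot(k_img <= ncol(F_img), k_tab <= ncol(F_tab))
  if (is.null(scores_img)) scores_img <- compute_feature_importance(F_img, y, seed = seed)
  if (is.null(scores_tab)) scores_tab <- compute_feature_importance(F_tab, y, seed = seed)
  s_img <- as_scores(scores_img, names(F_img))
  s_tab <- as_scores(scores_tab, names(F_tab))
  sel_img <- names(F_img)[order(-s_img)][seq_len(k_img)]
  sel_tab <- names(F_tab)[order(-s_tab)][seq_len(k_tab)]
  fit <- list(strategy = "feature_selection", sel_img = sel_img, sel_tab = sel_tab)
  finish_fused(dplyr::bind_cols(F_img[sel_img], F_tab[sel_tab]), fit)
}

#' Low-rank tensor-product fusion
#'
#' Rows of each modality are L2-normalized; each sample's outer product of the
#' two normalized rows is flattened row-major into a length `p*q` vector; the
#' truncated SVD of the resulting `n x (p*q)` matrix yields, for each retained
#' component, a rank-1 refactorization of its right singular vector into a
#' `p`-vector and a `q`-vector, which (scaled by the square roots of the
#' singular values) form the per-modality projections. The output concatenates
#' the projected image and tabular rows (`2 * rank` columns). Singular-vector
#' signs are fixed so the largest-magnitude entry of each left singular vector
#' is nonnegative.
#'
#' @param F_img,F_tab Data frames of numeric features with equal row counts.
#' @param rank Number of SVD components retained (`1 <= rank <= min(n, p*q)`).
#' @return A tibble with columns `tensor_img_*`, `tensor_tab_*`; the `"fit"`
#'   attribute carries the projections and the SVD of the unfolded matrix.
#' @export
tensor_product_fusion <- function(F_img, F_tab, rank) {
  F_img <- as_feature_matrix(F_img, "F_img"); F_tab <- as_feature_matrix(F_tab, "F_tab")
  check_aligned(F_img, F_tab)
  p <- ncol(F_img); q <- ncol(F_tab); n <- nrow(F_img)
  if (rank < 1 || rank > min(n, p * q))
    rlang::abort(paste0("rank must be between 1 and ", min(n, p * q)), class = "fkgmm_rank_error")
  Zi <- l2_normalize_rows(as.matrix(F_img))
  Zt <- l2_normalize_rows(as.matrix(F_tab))
  Z <- t(vapply(seq_len(n), function(kk) as.vector(t(outer(Zi[kk, ], Zt[kk, ]))), numeric(p * q)))
  sv <- svd(Z, nu = rank, nv = rank)
  U <- sv$u; V <- sv$v; S <- sv$d[seq_len(rank)]
  for (kk in seq_len(rank)) { # sign convention: dominant entry of U[,k] >= 0
    s <- sign(U[which.max(abs(U[, kk])), kk]); if (s < 0) { U[, kk] <- -U[, kk]; V[, kk] <- -V[, kk] }
  }
  P_img <- matrix(0, p, rank); P_tab <- matrix(0, q, rank)
  for (kk in seq_len(rank)) {
    Mk <- matrix(V[, kk], p, q, byrow = TRUE)
    sv1 <- svd(Mk, nu = 1, nv = 1)
    u1 <- sv1$u[, 1]; v1 <- sv1$v[, 1]
    s <- sign(u1[which.max(abs(u1))]); if (s < 0) { u1 <- -u1; v1 <- -v1 }
    P_img[, kk] <- sqrt(S[kk] * sv1$d[1]) * u1
    P_tab[, kk] <- sqrt(S[kk] * sv1$d[1]) * v1
  }
  fused <- cbind(Zi %*% P_img, Zt %*% P_tab)
  colnames(fused) <- c(paste0("tensor_img_", seq_len(rank)), paste0("tensor_tab_", seq_len(rank)))
  fit <- list(strategy = "tensor", P_img = P_img, P_tab = P_tab,
              svd = list(u = sv$u, d = sv$d, v = sv$v), rank = rank)
  finish_fused(fused, fit)
}

#' Hadamard-product fusion
#'
#' Projects each modality to a common dimension `d`, L2-normalizes the
#' projected rows, takes the elementwise (Hadamard) product, applies ReLU to
#' that product only, concatenates `[activated, imgNormalized, tabNormalized]`
#' (width `3d`), and linearly projects back to `d`. Projection matrices default
#' to seeded uniform(0, 1) draws and may be supplied explicitly.
#'
#' @param F_img,F_tab Data frames of numeric features with equal row counts.
#' @param common_dim The common dimension `d`.
#' @param W_img `p x d`, `W_tab` `q x d`, `W_fusion` `3d x d` projection
#'   matrices; `NULL` draws them from uniform(0, 1) under `seed`.
#' @param W_tab,W_fusion See `W_img`.
#' @param seed Seed for the default projection matrices (default 42).
#' @return A tibble with `d` columns `hadamard_*`; the `"fit"` attribute
#'   carries the projection matrices.
#' @export
hadamard_product_fusion <- function(F_img, F_tab, common_dim, W_img = NULL,
                                    W_tab = NULL, W_fusion = NULL, seed = 42L) {
  F_img <- as_feature_matrix(F_img, "F_img"); F_tab <- as_feature_matrix(F_tab, "F_tab")
  check_aligned(F_img, F_tab)
  d <- common_dim; p <- ncol(F_img); q <- ncol(F_tab)
  stopifnot(d >= 1)
  if (is.null(W_img) || is.null(W_tab) || is.null(W_fusion)) {
    withr::with_seed(seed, {
      if (is.null(W_img)) W_img <- matrix(stats::runif(p * d), p, d)
      if (is.null(W_tab)) W_tab <- matrix(stats::runif(q * d), q, d)
      if (is.null(W_fusion)) W_fusion <- matrix(stats::runif(3 * d * d), 3 * d, d)
    })
  }
  if (!all(dim(W_img) == c(p, d)) || !all(dim(W_tab) == c(q, d)) || !all(dim(W_fusion) == c(3 * d, d)))
    rlang::abort("projection matrix dimensions do not match (p x d, q x d, 3d x d)",
                 class = "fkgmm_shape_error")
  img_n <- l2_normalize_rows(as.matrix(F_img) %*% W_img)
  tab_n <- l2_normalize_rows(as.matrix(F_tab) %*% W_tab)
  had <- pmax(img_n * tab_n, 0) # ReLU on the Hadamard block only
  fused <- cbind(had, img_n, tab_n) %*% W_fusion
  colnames(fused) <- paste0("hadamard_", seq_len(d))
  fit <- list(strategy = "hadamard", W_img = W_img, W_tab = W_tab, W_fusion = W_fusion)
  finish_fused(fused, fit)
}

#' Greedy correlation pruning of a ranked candidate list
#'
#' Scanning candidates in their given (descending-score) order, a candidate is
#' dropped when its absolute Pearson correlation with any already-kept
#' candidate exceeds the threshold — i.e. of each redundant pair the
#' lower-scored member is removed.
#'
#' @param F Data frame containing the candidate columns.
#' @param candidates Character vector of column names, ordered by descending
#'   score.
#' @param threshold Absolute correlation threshold.
#' @param corr Optional precomputed correlation matrix with dimnames covering
#'   the candidates (e.g. published values); computed from `F` if `NULL`.
#' @return The surviving candidate names, in input order.
#' @export
remove_correlated_features <- function(F, candidates, threshold, corr = NULL) {
  if (is.null(corr)) {
    corr <- suppressWarnings(stats::cor(as.matrix(as_feature_matrix(F, "F")[candidates])))
    corr[is.na(corr)] <- 1
  }
  kept <- character()
  for (f in candidates) {
    if (length(kept) == 0 || all(abs(corr[f, kept]) <= threshold)) kept <- c(kept, f)
  }
  kept
}

#' Filter-based multimodal feature selection
#'
#' Ranks each modality by combined importance, forms per-modality candidate
#' pools (default size `2k`), prunes intra-modal correlated candidates with
#' [remove_correlated_features()], truncates to `k` per modality, and
#' concatenates. Cross-modal correlations between the selected features are
#' reported in the `"cross_modal_corr"` attribute as a diagnostic (they do not
#' prune).
#'
#' @param F_img,F_tab Data frames of numeric features with equal row counts.
#' @param y Binary labels (required unless scores are supplied).
#' @param k_img,k_tab Number of features to keep per modality.
#' @param corr_threshold Intra-modal absolute-correlation threshold
#'   (default 0.7).
#' @param pool_img,pool_tab Candidate pool sizes; default `2 * k`.
#' @param scores_img,scores_tab Optional importance scores.
#' @param corr_img,corr_tab Optional precomputed correlation matrices.
#' @param seed Seed for the default importance computation.
#' @return A tibble of the selected columns (image block first); attributes
#'   `"fit"` and `"cross_modal_corr"`.
#' @export
filter_multimodal_selection <- function(F_img, F_tab, y = NULL, k_img, k_tab,
                                        corr_threshold = 0.7,
                                        pool_img = NULL, pool_tab = NULL,
                                        scores_img = NULL, scores_tab = NULL,
                                        corr_img = NULL, corr_tab = NULL, seed = 42L) {
  F_img <- as_feature_matrix(F_img, "F_img"); F_tab <- as_feature_matrix(F_tab, "F_tab")
  check_aligned(F_img, F_tab)
  if (is.null(scores_img)) scores_img <- compute_feature_importance(F_img, y, seed = seed)
  if (is.null(scores_tab)) scores_tab <- compute_feature_importance(F_tab, y, seed = seed)
  s_img <- as_scores(scores_img, names(F_img)); s_tab <- as_scores(scores_tab, names(F_tab))
  if (is.null(pool_img)) pool_img <- 2L * k_img
  if (is.null(pool_tab)) pool_tab <- 2L * k_tab
  cand_img <- names(F_img)[order(-s_img)][seq_len(min(pool_img, ncol(F_img)))]
  cand_tab <- names(F_tab)[order(-s_tab)][seq_len(min(pool_tab, ncol(F_tab)))]
  surv_img <- remove_correlated_features(F_img, cand_img, corr_threshold, corr_img)
  surv_tab <- remove_correlated_features(F_tab, cand_tab, corr_threshold, corr_tab)
  if (length(surv_img) < k_img || length(surv_tab) < k_tab)
    rlang::warn("candidate pool exhausted below k after correlation pruning; keeping the survivors")
  sel_img <- surv_img[seq_len(min(k_img, length(surv_img)))]
  sel_tab <- surv_tab[seq_len(min(k_tab, length(surv_tab)))]
  cross <- if (length(sel_img) > 0 && length(sel_tab) > 0)
    suppressWarnings(stats::cor(as.matrix(F_img[sel_img]), as.matrix(F_tab[sel_tab]))) else NULL
  fit <- list(strategy = "filter", sel_img = sel_img, sel_tab = sel_tab)
  out <- finish_fused(dplyr::bind_cols(F_img[sel_img], F_tab[sel_tab]), fit)
  attr(out, "cross_modal_corr") <- cross
  out
}

#' Default wrapper evaluator: seeded random-forest out-of-bag accuracy
#'
#' @param seed Seed applied before every evaluation.
#' @param ntree Forest size (default 100).
#' @return A function `f(X, y)` returning the OOB accuracy of a random forest
#'   on the feature subset `X`.
#' @export
rf_oob_evaluator <- function(seed = 42L, ntree = 100L) {
  function(X, y) {
    rf <- withr::with_seed(seed, randomForest::randomForest(
      x = as.data.frame(X), y = factor(y), ntree = ntree))
    1 - rf$err.rate[ntree, "OOB"]
  }
}

#' Wrapper-based multimodal feature selection (sequential forward selection)
#'
#' Seeds the selection with the minimum number of features per modality, each
#' chosen as the single feature of that modality with the best evaluator score
#' (evaluated on that modality alone), then greedily adds the single remaining
#' feature — from either modality — whose addition gives the best evaluated
#' score on the concatenated subset. The loop stops when both modality limits
#' are reached or when the best candidate fails to improve on the current best
#' score. Ties prefer the image modality, then the lower feature index.
#'
#' @param F_img,F_tab Data frames of numeric features with equal row counts.
#' @param y Binary labels.
#' @param max_img,max_tab Maximum features per modality.
#' @param min_img,min_tab Minimum features per modality (default 1).
#' @param evaluator Function `f(X, y) -> score`; defaults to
#'   [rf_oob_evaluator()]. Evaluator errors are propagated.
#' @param candidates_img,candidates_tab Optional pre-filtered candidate column
#'   names (defaults: all columns).
#' @param seed Seed for the default evaluator.
#' @return A tibble of the selected columns; the `"fit"` attribute records
#'   `sel_img`, `sel_tab`, `best_score`, and the accepted score `trajectory`.
#' @export
wrapper_multimodal_selection <- function(F_img, F_tab, y, max_img, max_tab,
                                         min_img = 1L, min_tab = 1L,
                                         evaluator = NULL,
                                         candidates_img = NULL, candidates_tab = NULL,
                                         seed = 42L) {
  F_img <- as_feature_matrix(F_img, "F_img"); F_tab <- as_feature_matrix(F_tab, "F_tab")
  check_aligned(F_img, F_tab)
  stopifnot(min_img <= max_img, min_tab <= max_tab,
            max_img <= ncol(F_img), max_tab <= ncol(F_tab))
  if (is.null(evaluator)) evaluator <- rf_oob_evaluator(seed)
  if (is.null(candidates_img)) candidates_img <- names(F_img)
  if (is.null(candidates_tab)) candidates_tab <- names(F_tab)

  sel_img <- character(); sel_tab <- character()
  best_score <- -Inf
  # seed the minimum per-modality representation by best single-modality score
  for (step in seq_len(min_img)) {
    rem <- setdiff(candidates_img, sel_img)
    sc <- vapply(rem, function(f) evaluator(F_img[c(sel_img, f)], y), numeric(1))
    sel_img <- c(sel_img, rem[which.max(sc)])
    best_score <- max(sc)
  }
  for (step in seq_len(min_tab)) {
    rem <- setdiff(candidates_tab, sel_tab)
    sc <- vapply(rem, function(f) evaluator(F_tab[c(sel_tab, f)], y), numeric(1))
    sel_tab <- c(sel_tab, rem[which.max(sc)])
    best_score <- max(sc)
  }
  trajectory <- best_score

  repeat {
    open_img <- length(sel_img) < max_img
    open_tab <- length(sel_tab) < max_tab
    if (!open_img && !open_tab) break
    best_new <- -Inf; best_feat <- NULL; best_mod <- NULL
    if (open_img) {
      for (f in setdiff(candidates_img, sel_img)) {
        sc <- evaluator(dplyr::bind_cols(F_img[c(sel_img, f)], F_tab[sel_tab]), y)
        if (sc > best_new) { best_new <- sc; best_feat <- f; best_mod <- "img" }
      }
    }
    if (open_tab) {
      for (f in setdiff(candidates_tab, sel_tab)) {
        sc <- evaluator(dplyr::bind_cols(F_img[sel_img], F_tab[c(sel_tab, f)]), y)
        if (sc > best_new) { best_new <- sc; best_feat <- f; best_mod <- "tab" }
      }
    }
    if (is.null(best_feat) || best_new <= best_score) break
    if (best_mod == "img") sel_img <- c(sel_img, best_feat) else sel_tab <- c(sel_tab, best_feat)
    best_score <- best_new
    trajectory <- c(trajectory, best_new)
  }

  fit <- list(strategy = "wrapper", sel_img = sel_img, sel_tab = sel_tab,
              best_score = best_score, trajectory = trajectory)
  finish_fused(dplyr::bind_cols(F_img[sel_img], F_tab[sel_tab]), fit)
}

#' Apply a fitted fusion to new samples
#'
#' @param fit The `"fit"` attribute of a fused tibble (or the fused tibble
#'   itself).
#' @param F_img,F_tab New feature matrices with the same columns as used for
#'   fitting.
#' @return A tibble of fused features for the new samples.
#' @export
apply_fusion <- function(fit, F_img, F_tab) {
  if (inherits(fit, "fkgmm_fused")) fit <- attr(fit, "fit")
  F_img <- as_feature_matrix(F_img, "F_img"); F_tab <- as_feature_matrix(F_tab, "F_tab")
  check_aligned(F_img, F_tab)
  switch(fit$strategy,
    feature_selection = ,
    filter = ,
    wrapper = tibble::as_tibble(dplyr::bind_cols(F_img[fit$sel_img], F_tab[fit$sel_tab])),
    tensor = {
      Zi <- l2_normalize_rows(as.matrix(F_img)); Zt <- l2_normalize_rows(as.matrix(F_tab))
      fused <- cbind(Zi %*% fit$P_img, Zt %*% fit$P_tab)
      colnames(fused) <- c(paste0("tensor_img_", seq_len(fit$rank)),
                           paste0("tensor_tab_", seq_len(fit$rank)))
      tibble::as_tibble(fused)
    },
    hadamard = {
      img_n <- l2_normalize_rows(as.matrix(F_img) %*% fit$W_img)
      tab_n <- l2_normalize_rows(as.matrix(F_tab) %*% fit$W_tab)
      fused <- cbind(pmax(img_n * tab_n, 0), img_n, tab_n) %*% fit$W_fusion
      colnames(fused) <- paste0("hadamard_", seq_len(ncol(fused)))
      tibble::as_tibble(fused)
    },
    rlang::abort(paste0("unknown fusion strategy: ", fit$strategy), class = "fkgmm_config_error")
  )
}
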