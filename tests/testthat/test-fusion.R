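fx <- load_paper_fixtures()

rand_mats <- function(n, p, q, seed = 1, prefix_img = "i", prefix_tab = "t") {
  withr::with_seed(seed, list(
    img = tibble::as_tibble(matrix(rnorm(n * p), n, p,
                                   dimnames = list(NULL, paste0(prefix_img, seq_len(p))))),
    tab = tibble::as_tibble(matrix(rnorm(n * q), n, q,
                                   dimnames = list(NULL, paste0(prefix_tab, seq_len(q))))),
    y = rep_len(0:1, n)
  ))
}

test_that("combined importance averages mutual information and forest importance", {
  e4 <- fx$example4
  sc <- compute_feature_importance(as.data.frame(e4$F_img), e4$target,
                                   mi_scores = e4$mi_img, rf_scores = e4$rf_img)
  expect_equal(sc$score, c(0.28, 0.16, 0.435, 0.21, 0.28))
  sct <- compute_feature_importance(as.data.frame(e4$F_tab), e4$target,
                                    mi_scores = e4$mi_tab, rf_scores = e4$rf_tab)
  expect_equal(sct$score, c(0.265, 0.375, 0.175, 0.365))

  set.seed(21)
  X <- tibble::tibble(flat = rep(1, 30), sig = rnorm(30))
  y <- rep(0:1, 15)
  got <- compute_feature_importance(X, y, seed = 1)
  expect_equal(unname(got$mi[1]), 0) # constant feature has zero MI component
  expect_error(compute_feature_importance(X, rep(1, 30)),
               class = "fkgmm_importance_error")
})

test_that("importance-ranking fusion reproduces the worked ordering and a sort oracle", {
  e1 <- fx$example1
  m <- rand_mats(4, 5, 4, seed = 2)
  names(m$img) <- e1$img_features; names(m$tab) <- e1$tab_features
  f <- feature_selection_fusion(m$img, m$tab, e1$k_img, e1$k_tab,
                                scores_img = e1$img_scores, scores_tab = e1$tab_scores)
  expect_equal(names(f), e1$expected)

  # k = p, k = q: plain concatenation reordered by score
  full <- feature_selection_fusion(m$img, m$tab, 5, 4,
                                   scores_img = e1$img_scores, scores_tab = e1$tab_scores)
  expect_setequal(names(full), c(e1$img_features, e1$tab_features))
  expect_equal(names(full)[1:5], e1$img_features[order(-e1$img_scores)])

  # random scores match a sort-then-slice oracle
  m2 <- rand_mats(5, 6, 4, seed = 3)
  withr::with_seed(4, { si <- runif(6); st <- runif(4) })
  g <- feature_selection_fusion(m2$img, m2$tab, 3, 2, scores_img = si, scores_tab = st)
  oracle <- c(names(m2$img)[order(si, decreasing = TRUE)][1:3],
              names(m2$tab)[order(st, decreasing = TRUE)][1:2])
  expect_equal(names(g), oracle)
  expect_equal(nrow(g), 5)

  expect_error(feature_selection_fusion(m2$img, m2$tab, 0, 0),
               class = "fkgmm_empty_fusion")

  # permutation equivariance: permuting inputs with their scores permutes nothing selected
  perm <- c(4, 2, 6, 1, 5, 3)
  gp <- feature_selection_fusion(m2$img[perm], m2$tab, 3, 2,
                                 scores_img = si[perm], scores_tab = st)
  expect_setequal(names(gp), names(g))
})

test_that("tensor fusion normalizes, factorizes, and is scale invariant", {
  e2 <- fx$example2
  # normalization sub-steps vs the closed form x / sqrt(sum(x^2))
  n1 <- l2_normalize_rows(e2$F_img)[1, ]
  expect_equal(n1, c(4, 2, 8) / sqrt(84), tolerance = 1e-12)
  expect_equal(l2_normalize_rows(e2$F_tab)[1, ], c(5, 3) / sqrt(34), tolerance = 1e-12)

  m <- rand_mats(6, 3, 2, seed = 5)
  rank <- 6 # full rank of the 6 x 6 unfolded matrix
  f <- tensor_product_fusion(m$img, m$tab, rank)
  expect_equal(dim(f), c(6L, 12L))
  # full-rank SVD reconstructs the unfolded matrix (dense SVD oracle)
  fit <- attr(f, "fit")
  Zi <- l2_normalize_rows(as.matrix(m$img)); Zt <- l2_normalize_rows(as.matrix(m$tab))
  Z <- t(sapply(1:6, function(k) as.vector(t(outer(Zi[k, ], Zt[k, ])))))
  sv <- fit$svd
  expect_equal(sv$u %*% diag(sv$d) %*% t(sv$v), Z, tolerance = 1e-9,
               ignore_attr = TRUE)

  # invariance to positive rescaling of any input row
  img2 <- m$img; img2[3, ] <- img2[3, ] * 7.5
  f2 <- tensor_product_fusion(img2, m$tab, 2)
  f1 <- tensor_product_fusion(m$img, m$tab, 2)
  expect_equal(as.matrix(f2), as.matrix(f1), tolerance = 1e-9)

  expect_error(tensor_product_fusion(m$img, m$tab, 50), class = "fkgmm_rank_error")
})

test_that("hadamard fusion matches the printed example and a scalar pipeline oracle", {
  e3 <- fx$example3
  f <- hadamard_product_fusion(as.data.frame(e3$F_img), as.data.frame(e3$F_tab),
                               e3$common_dim, W_img = e3$W_img, W_tab = e3$W_tab,
                               W_fusion = e3$W_fusion)
  # printed values carry the example's 3-decimal intermediate rounding;
  # worst-case accumulation over six rounded products is < 0.003
  expect_equal(as.matrix(f), e3$expected, tolerance = 0.003, ignore_attr = TRUE)

  # scalar step-by-step oracle on a random case, 1e-9
  set.seed(6)
  Fi <- matrix(rnorm(9), 3, 3); Ft <- matrix(rnorm(9), 3, 3)
  Wi <- matrix(runif(6), 3, 2); Wt <- matrix(runif(6), 3, 2); Wf <- matrix(runif(12), 6, 2)
  got <- hadamard_product_fusion(as.data.frame(Fi), as.data.frame(Ft), 2,
                                 W_img = Wi, W_tab = Wt, W_fusion = Wf)
  oracle <- matrix(0, 3, 2)
  for (s in 1:3) {
    ip <- drop(Fi[s, ] %*% Wi); tp <- drop(Ft[s, ] %*% Wt)
    ipn <- ip / sqrt(sum(ip^2)); tpn <- tp / sqrt(sum(tp^2))
    had <- pmax(ipn * tpn, 0)
    oracle[s, ] <- drop(c(had, ipn, tpn) %*% Wf)
  }
  expect_equal(as.matrix(got), oracle, tolerance = 1e-9, ignore_attr = TRUE)

  # all-zero tabular rows: Hadamard block contributes nothing
  Ft0 <- matrix(0, 2, 2)
  Wf_id <- rbind(diag(2), matrix(0, 4, 2)) # reads out the activated block only
  z <- hadamard_product_fusion(as.data.frame(e3$F_img), as.data.frame(Ft0), 2,
                               W_img = e3$W_img, W_tab = e3$W_tab, W_fusion = Wf_id)
  expect_equal(as.matrix(z), matrix(0, 2, 2), ignore_attr = TRUE)

  expect_error(hadamard_product_fusion(as.data.frame(e3$F_img), as.data.frame(e3$F_tab),
                                       2, W_img = matrix(0, 2, 2), W_tab = e3$W_tab,
                                       W_fusion = e3$W_fusion),
               class = "fkgmm_shape_error")
})

test_that("correlation pruning drops the lower-scored member of each redundant pair", {
  e4 <- fx$example4
  kept <- remove_correlated_features(NULL, c("img3", "img1", "img5"),
                                     threshold = 0.7, corr = e4$corr_img)
  expect_equal(kept, c("img3", "img1"))

  # uncorrelated candidates are untouched
  id3 <- diag(3); dimnames(id3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(remove_correlated_features(NULL, c("a", "b", "c"), 0.5, corr = id3),
               c("a", "b", "c"))

  # random 5-feature case vs an exhaustive greedy pair-scan oracle
  set.seed(7)
  X <- tibble::as_tibble(matrix(rnorm(40 * 5), 40, 5,
                                dimnames = list(NULL, paste0("f", 1:5))))
  X$f2 <- X$f1 + rnorm(40, 0, 0.1)
  X$f5 <- -X$f3 + rnorm(40, 0, 0.1)
  cand <- paste0("f", 1:5)
  got <- remove_correlated_features(X, cand, 0.8)
  cm <- abs(cor(as.matrix(X)))
  oracle <- character()
  for (f in cand) {
    drop_it <- FALSE
    for (k in oracle) if (cm[f, k] > 0.8) drop_it <- TRUE
    if (!drop_it) oracle <- c(oracle, f)
  }
  expect_equal(got, oracle)
})

test_that("filter selection composes ranking, pruning, and truncation", {
  m <- rand_mats(30, 8, 6, seed = 8)
  # threshold 1.0 disables pruning: pure top-k by combined score
  sc_i <- seq(0.8, 0.1, length.out = 8); sc_t <- seq(0.9, 0.4, length.out = 6)
  f <- filter_multimodal_selection(m$img, m$tab, k_img = 3, k_tab = 2,
                                   corr_threshold = 1, scores_img = sc_i, scores_tab = sc_t)
  expect_equal(names(f), c(names(m$img)[1:3], names(m$tab)[1:2]))

  # random case equals the staged oracle: rank -> prune -> truncate
  withr::with_seed(9, { si <- runif(8); st <- runif(6) })
  got <- filter_multimodal_selection(m$img, m$tab, k_img = 3, k_tab = 2,
                                     corr_threshold = 0.4, scores_img = si, scores_tab = st)
  stage_oracle <- function(F, s, k, thr) {
    cand <- names(F)[order(-s)][seq_len(min(2 * k, ncol(F)))]
    cm <- abs(cor(as.matrix(F)))
    kept <- character()
    for (f2 in cand) if (length(kept) == 0 || all(cm[f2, kept] <= thr)) kept <- c(kept, f2)
    kept[seq_len(min(k, length(kept)))]
  }
  expect_equal(names(got),
               c(stage_oracle(m$img, si, 3, 0.4), stage_oracle(m$tab, st, 2, 0.4)))
  expect_true(is.matrix(attr(got, "cross_modal_corr")))
})

test_that("wrapper selection is greedy forward search with non-decreasing accepted scores", {
  e5 <- fx$example5
  m <- rand_mats(6, 5, 4, seed = 10)
  names(m$img) <- e5$img_features; names(m$tab) <- e5$tab_features

  w <- wrapper_multimodal_selection(m$img, m$tab, m$y, e5$max_img, e5$max_tab,
                                    evaluator = scripted_evaluator(e5$scores),
                                    candidates_img = e5$candidates_img,
                                    candidates_tab = e5$candidates_tab)
  fit <- attr(w, "fit")
  expect_equal(c(fit$sel_img, fit$sel_tab), e5$expected_selection)
  expect_equal(fit$best_score, e5$expected_score)
  expect_equal(fit$trajectory, sort(fit$trajectory)) # non-decreasing

  # monotone evaluator (subset size): adds until both limits are reached
  size_eval <- function(X, y) ncol(X)
  wm <- wrapper_multimodal_selection(m$img, m$tab, m$y, 3, 2, evaluator = size_eval)
  fitm <- attr(wm, "fit")
  expect_equal(length(fitm$sel_img), 3)
  expect_equal(length(fitm$sel_tab), 2)

  # deterministic evaluator vs a step-by-step greedy enumeration oracle
  withr::with_seed(11, vals <- runif(5 + 4))
  names(vals) <- c(names(m$img)[1:3], names(m$tab)[1:2],
                   names(m$img)[4:5], names(m$tab)[3:4])
  det_eval <- function(X, y) sum(vals[colnames(X)]) - 0.3 * ncol(X)^1.5
  got <- attr(wrapper_multimodal_selection(m$img[1:3], m$tab[1:2], m$y, 3, 2,
                                           evaluator = det_eval), "fit")
  # oracle: replay seeding + SFS by brute enumeration
  sel_i <- character(); sel_t <- character()
  sc <- sapply(names(m$img)[1:3], function(f) det_eval(m$img[f], m$y))
  sel_i <- names(which.max(sc))
  sc <- sapply(names(m$tab)[1:2], function(f) det_eval(m$tab[f], m$y))
  sel_t <- names(which.max(sc)); best <- max(sc)
  repeat {
    cands <- rbind(
      if (length(sel_i) < 3) data.frame(f = setdiff(names(m$img)[1:3], sel_i), mod = "i"),
      if (length(sel_t) < 2) data.frame(f = setdiff(names(m$tab)[1:2], sel_t), mod = "t"))
    if (is.null(cands) || nrow(cands) == 0) break
    scs <- apply(cands, 1, function(r) {
      ii <- c(sel_i, if (r[["mod"]] == "i") r[["f"]])
      tt <- c(sel_t, if (r[["mod"]] == "t") r[["f"]])
      det_eval(dplyr::bind_cols(m$img[ii], m$tab[tt]), m$y)
    })
    if (max(scs) <= best) break
    pick <- which.max(scs)
    if (cands$mod[pick] == "i") sel_i <- c(sel_i, cands$f[pick]) else sel_t <- c(sel_t, cands$f[pick])
    best <- max(scs)
  }
  expect_equal(got$sel_img, sel_i)
  expect_equal(got$sel_tab, sel_t)
  expect_equal(got$best_score, best)

  # evaluator failures propagate
  expect_error(wrapper_multimodal_selection(m$img, m$tab, m$y, 2, 1,
                                            evaluator = function(X, y) stop("boom")),
               "boom")
})

test_that("all five fusion strategies run end-to-end on one dataset and apply to new rows", {
  m <- rand_mats(20, 5, 4, seed = 12)
  fits <- list(
    feature_selection = feature_selection_fusion(m$img, m$tab, 3, 2, y = m$y, seed = 1),
    tensor = tensor_product_fusion(m$img, m$tab, 2),
    hadamard = hadamard_product_fusion(m$img, m$tab, 2, seed = 1),
    filter = filter_multimodal_selection(m$img, m$tab, m$y, 2, 2, seed = 1),
    wrapper = wrapper_multimodal_selection(m$img, m$tab, m$y, 2, 2,
                                           evaluator = function(X, y) {
                                             abs(cor(rowMeans(as.matrix(X)), y))
                                           })
  )
  for (nm in names(fits)) {
    f <- fits[[nm]]
    expect_equal(nrow(f), 20)
    expect_false(anyNA(f))
    # re-applying the fitted fusion to the training rows reproduces the output
    re <- apply_fusion(f, m$img, m$tab)
    expect_equal(as.matrix(re), as.matrix(f), tolerance = 1e-12, ignore_attr = TRUE)
  }
})
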