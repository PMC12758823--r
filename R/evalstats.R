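# Scoring and comparison statistics: accuracy/confusion matrix, one-way
# ANOVA (via stats::aov), balanced-design Tukey HSD.

#' Accuracy and confusion matrix of a binary classifier
#'
#' @param pred Predicted labels.
#' @param truth True labels (same length and coding as `pred`).
#' @param positive The positive class (default `"1"`).
#' @return A list with `accuracy` and `confusion`, a tibble of `tp`, `tn`,
#'   `fp`, `fn` counts.
#' @export
evaluate_classifier <- function(pred, truth, positive = "1") {
  if (length(pred) == 0 || length(pred) != length(truth))
    rlang::abort("pred and truth must be non-empty and equal length", class = "fkgmm_invalid_input")
  pred <- as.character(pred); truth <- as.character(truth); positive <- as.character(positive)
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  list(accuracy = (tp + tn) / length(pred),
       confusion = tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn))
}

groups_to_df <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    return(data.frame(group = factor(groups$group), value = as.numeric(groups$value)))
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  data.frame(group = factor(rep(names(groups), lengths(groups))),
             value = as.numeric(unlist(groups)))
}

#' One-way analysis of variance
#'
#' Classical one-way decomposition, delegated to [stats::aov()]; a
#' zero-within-variance design is reported with `F = Inf`, `p = 0`, and
#' `degenerate = TRUE`.
#'
#' @param groups A named list of numeric vectors, or a data frame with
#'   `group` and `value` columns.
#' @return A one-row tibble: `ss_between`, `ss_within`, `df_between`,
#'   `df_within`, `ms_between`, `ms_within`, `statistic` (F), `p_value`,
#'   `degenerate`.
#' @export
one_way_anova <- function(groups) {
  d <- groups_to_df(groups)
  if (nlevels(d$group) < 2 || any(table(d$group) < 2))
    rlang::abort("need >= 2 groups with >= 2 values each", class = "fkgmm_invalid_input")
  fit <- stats::aov(value ~ group, data = d)
  # a perfect fit (zero within-variance) is handled explicitly below
  tab <- suppressWarnings(stats::anova(fit))
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  dfb <- tab$Df[1]; dfw <- tab$Df[2]
  msb <- ssb / dfb; msw <- ssw / dfw
  # guard against floating-point residue when every group is constant
  if (msw <= 1e-12 * max(msb, 1)) {
    return(tibble::tibble(ss_between = ssb, ss_within = 0, df_between = dfb,
                          df_within = dfw, ms_between = msb, ms_within = 0,
                          statistic = if (ssb > 0) Inf else 0,
                          p_value = if (ssb > 0) 0 else 1, degenerate = TRUE))
  }
  tibble::tibble(ss_between = ssb, ss_within = ssw, df_between = dfb,
                 df_within = dfw, ms_between = msb, ms_within = msw,
                 statistic = msb / msw, p_value = tab$`Pr(>F)`[1], degenerate = FALSE)
}

#' Tukey honestly-significant-difference test (balanced designs)
#'
#' For every pair of groups: mean difference, studentized-range statistic
#' `q = |mean difference| / sqrt(ms_within / n)`, p-value from the studentized
#' range distribution, and significance at `alpha`. Only balanced designs
#' (equal group sizes) are supported; unbalanced input is an error.
#'
#' @param groups As in [one_way_anova()].
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per pair: `group1`, `group2`, `mean_diff`,
#'   `q_value`, `p_value`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  d <- groups_to_df(groups)
  sizes <- table(d$group)
  if (length(unique(as.numeric(sizes))) != 1)
    rlang::abort("tukey_hsd supports balanced designs only", class = "fkgmm_invalid_input")
  n <- as.numeric(sizes[1])
  k <- nlevels(d$group)
  an <- one_way_anova(d)
  means <- tapply(d$value, d$group, mean)
  se <- sqrt(an$ms_within / n)
  pairs <- utils::combn(levels(d$group), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    diff <- means[[g1]] - means[[g2]]
    q <- if (se == 0) { if (diff == 0) 0 else Inf } else abs(diff) / se
    p <- if (is.infinite(q)) 0 else stats::ptukey(q, nmeans = k, df = an$df_within, lower.tail = FALSE)
    tibble::tibble(group1 = g1, group2 = g2, mean_diff = diff, q_value = q,
                   p_value = p, significant = p < alpha)
  })
}
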