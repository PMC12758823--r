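# Fuzzy rule base -> fuzzy knowledge graph -> sampled graph -> classification.
#
# A fuzzy knowledge graph is the tuple (V, L, A, B, R): attribute-term
# vertices V, labels L, vertex-vertex weights A, vertex-label weights B, and
# the source rule base R. Vertices are named "<attribute>=<term>".

default_term_names <- function(n) {
  if (n == 2) c("Low", "High")
  else if (n == 3) c("Low", "Medium", "High")
  else paste0("T", seq_len(n))
}

# membership of x under a triangular term (left, peak, right); shoulders
# (left == peak or peak == right) are flat on that side
triangular_membership <- function(x, left, peak, right) {
  up <- if (peak > left) pmax(pmin((x - left) / (peak - left), 1), 0) else rep(1, length(x))
  dn <- if (right > peak) pmax(pmin((right - x) / (right - peak), 1), 0) else rep(1, length(x))
  mu <- ifelse(x <= peak, up, dn)
  mu[x < left | x > right] <- 0
  mu
}

#' Fit a linguistic membership scheme to a feature matrix
#'
#' Per attribute, `n_terms` triangular membership functions are anchored on the
#' training range: peaks evenly spaced from the minimum to the maximum, each
#' term spanning its neighbouring peaks, with flat shoulders at the ends (for 3
#' terms: `(min, min, mid)`, `(min, mid, max)`, `(mid, max, max)`). A constant
#' attribute degenerates to a single always-on term, with a warning.
#'
#' @param X Data frame of numeric features.
#' @param n_terms Number of linguistic terms per attribute (default 3:
#'   Low/Medium/High).
#' @return An object of class `fkgmm_scheme`.
#' @export
fit_membership_scheme <- function(X, n_terms = 3L) {
  stopifnot(n_terms >= 2)
  X <- as_feature_matrix(X, "X")
  attrs <- lapply(X, function(x) {
    r <- range(x)
    if (diff(r) == 0) {
      rlang::warn("constant attribute: degenerate single-term scheme")
      return(list(terms = "Constant",
                  params = matrix(r[1], 1, 3, dimnames = list(NULL, c("left", "peak", "right"))),
                  range = r))
    }
    peaks <- seq(r[1], r[2], length.out = n_terms)
    params <- cbind(left = c(peaks[1], peaks[-n_terms]),
                    peak = peaks,
                    right = c(peaks[-1], peaks[n_terms]))
    list(terms = default_term_names(n_terms), params = params, range = r)
  })
  structure(list(attributes = attrs, n_terms = n_terms), class = "fkgmm_scheme")
}

#' Membership degrees of values under a fitted scheme
#'
#' @param scheme A `fkgmm_scheme`.
#' @param attribute Attribute name.
#' @param x Numeric values; values outside the training range are clamped.
#' @return Matrix `length(x) x n_terms` of membership degrees.
#' @export
membership_degrees <- function(scheme, attribute, x) {
  a <- scheme$attributes[[attribute]]
  if (is.null(a)) rlang::abort(paste0("attribute not in scheme: ", attribute),
                               class = "fkgmm_config_error")
  x <- pmin(pmax(x, a$range[1]), a$range[2])
  mu <- vapply(seq_along(a$terms),
               function(t) triangular_membership(x, a$params[t, 1], a$params[t, 2], a$params[t, 3]),
               numeric(length(x)))
  mu <- matrix(mu, nrow = length(x), dimnames = list(NULL, a$terms))
  mu
}

#' Generate a fuzzy rule base from labeled features
#'
#' Each record yields one candidate rule: per attribute the argmax-membership
#' term (ties take the lower term) with its membership degree. Rules with
#' identical antecedents and labels are merged (weights summed, memberships
#' averaged); identical antecedents with conflicting labels resolve to the
#' label with the larger total weight (ties to the smaller label).
#'
#' @param X Data frame of numeric features.
#' @param y Label vector (coerced to character).
#' @param scheme A `fkgmm_scheme` fitted on (a superset of) `X`; fitted on `X`
#'   if `NULL`.
#' @param n_terms Passed to [fit_membership_scheme()] when `scheme` is `NULL`.
#' @return An object of class `fkgmm_frb`: a tibble with columns `rule`, one
#'   term column per attribute, `mu_<attribute>` membership columns, `label`,
#'   and `weight`; the scheme rides along in the `"scheme"` attribute.
#' @export
generate_frb <- function(X, y, scheme = NULL, n_terms = 3L) {
  X <- as_feature_matrix(X, "X")
  if (nrow(X) == 0) rlang::abort("no records to compile into rules", class = "fkgmm_empty_frb")
  if (is.null(scheme)) scheme <- fit_membership_scheme(X, n_terms)
  attrs <- names(X)
  y <- as.character(y)
  terms <- matrix("", nrow(X), length(attrs), dimnames = list(NULL, attrs))
  mus <- matrix(0, nrow(X), length(attrs), dimnames = list(NULL, paste0("mu_", attrs)))
  for (a in attrs) {
    mu <- membership_degrees(scheme, a, X[[a]])
    best <- max.col(mu, ties.method = "first")
    terms[, a] <- colnames(mu)[best]
    mus[, paste0("mu_", a)] <- mu[cbind(seq_len(nrow(mu)), best)]
  }
  df <- dplyr::bind_cols(tibble::as_tibble(terms), tibble::as_tibble(mus),
                         tibble::tibble(label = y))
  merged <- df %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(attrs, "label")))) %>%
    dplyr::summarise(dplyr::across(dplyr::starts_with("mu_"), mean),
                     weight = dplyr::n(), .groups = "drop")
  # conflicting labels on one antecedent: weight majority, ties to smaller label
  resolved <- merged %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(attrs))) %>%
    dplyr::arrange(dplyr::desc(.data$weight), .data$label, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(dplyr::desc(.data$weight))
  out <- dplyr::bind_cols(tibble::tibble(rule = paste0("R", seq_len(nrow(resolved)))), resolved)
  new_frb(out, attributes = attrs, scheme = scheme)
}

new_frb <- function(rules, attributes, scheme = NULL) {
  structure(tibble::as_tibble(rules),
            attributes = attributes,
            labels = sort(unique(rules$label)),
            scheme = scheme,
            class = c("fkgmm_frb", class(tibble::tibble())))
}

#' Construct a fuzzy rule base from a table of rules
#'
#' @param rules Data frame with a term column per attribute, a `label` column,
#'   and optional `rule`, `weight`, and `mu_<attribute>` columns (defaulting to
#'   sequential ids, weight 1, and crisp membership 1).
#' @param attributes Character vector of attribute column names; defaults to
#'   all columns other than `rule`, `label`, `weight`, and `mu_*`.
#' @return An object of class `fkgmm_frb`.
#' @export
as_frb <- function(rules, attributes = NULL) {
  rules <- tibble::as_tibble(rules)
  if (!"label" %in% names(rules)) rlang::abort("rules need a label column", class = "fkgmm_empty_frb")
  if (nrow(rules) == 0) rlang::abort("empty rule base", class = "fkgmm_empty_frb")
  if (is.null(attributes))
    attributes <- setdiff(names(rules)[!grepl("^mu_", names(rules))], c("rule", "label", "weight"))
  if (!"rule" %in% names(rules)) rules$rule <- paste0("R", seq_len(nrow(rules)))
  if (!"weight" %in% names(rules)) rules$weight <- 1
  for (a in attributes) {
    rules[[a]] <- as.character(rules[[a]]) # terms are linguistic labels
    mc <- paste0("mu_", a)
    if (!mc %in% names(rules)) rules[[mc]] <- 1
  }
  rules$label <- as.character(rules$label)
  new_frb(rules[, c("rule", attributes, paste0("mu_", attributes), "label", "weight")], attributes)
}

#' Build a fuzzy knowledge graph from a rule base
#'
#' Vertex-vertex weights: `A[u, v]` is the weighted sum over rules containing
#' both vertices (in different attributes) of `min(mu(u), mu(v))`, divided by
#' the total rule weight. Vertex-label weights: `B[u, l]` is the weighted
#' membership mass of `u` in rules with label `l`, normalized so each row of
#' `B` sums to 1.
#'
#' @param frb A `fkgmm_frb`.
#' @return An object of class `fkgmm_fkg`: list with `V` (vertex tibble),
#'   `L` (labels), `A`, `B`, `frb`, and the membership `scheme` if available.
#' @export
build_fkg <- function(frb) {
  stopifnot(inherits(frb, "fkgmm_frb"))
  attrs <- attr(frb, "attributes")
  labels <- attr(frb, "labels")
  vert <- unique(do.call(rbind, lapply(attrs, function(a)
    data.frame(attribute = a, term = frb[[a]], stringsAsFactors = FALSE))))
  vert$vertex <- paste0(vert$attribute, "=", vert$term)
  vert <- vert[order(match(vert$attribute, attrs), vert$term), c("vertex", "attribute", "term")]
  nv <- nrow(vert)
  A <- matrix(0, nv, nv, dimnames = list(vert$vertex, vert$vertex))
  Bnum <- matrix(0, nv, length(labels), dimnames = list(vert$vertex, labels))
  W <- sum(frb$weight)
  for (r in seq_len(nrow(frb))) {
    w <- frb$weight[r]
    vs <- paste0(attrs, "=", vapply(attrs, function(a) frb[[a]][r], character(1)))
    mus <- vapply(attrs, function(a) frb[[paste0("mu_", a)]][r], numeric(1))
    for (ii in seq_along(attrs)) {
      Bnum[vs[ii], frb$label[r]] <- Bnum[vs[ii], frb$label[r]] + w * mus[ii]
      if (ii < length(attrs)) for (jj in (ii + 1):length(attrs)) {
        inc <- w * min(mus[ii], mus[jj])
        A[vs[ii], vs[jj]] <- A[vs[ii], vs[jj]] + inc
        A[vs[jj], vs[ii]] <- A[vs[jj], vs[ii]] + inc
      }
    }
  }
  A <- A / W
  rs <- rowSums(Bnum)
  B <- Bnum / ifelse(rs > 0, rs, 1)
  structure(list(V = tibble::as_tibble(vert), L = labels, A = A, B = B, frb = frb,
                 scheme = attr(frb, "scheme")),
            class = "fkgmm_fkg")
}

# stratified-by-label target allocation (largest remainder), each label >= 1
# when the target size allows
stratify_counts <- function(labels_per_rule, m) {
  tab <- table(labels_per_rule)
  raw <- m * as.numeric(tab) / length(labels_per_rule)
  base <- floor(raw)
  rem <- m - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  if (m >= length(tab)) {
    while (any(base == 0)) {
      z <- which(base == 0)[1]
      donor <- which.max(base)
      base[z] <- 1; base[donor] <- base[donor] - 1
    }
  }
  base <- pmin(base, as.numeric(tab))
  stats::setNames(base, names(tab))
}

#' Sample a fuzzy knowledge graph (FKGS)
#'
#' Draws label-stratified random rule subsets of size
#' `ceiling(sample_rate * |R|)` (seeded) and accepts the first whose
#' vertex-label matrix `B` approximates the full graph's within
#' `error_threshold`; otherwise the minimum-error subset over `max_iters`
#' draws is returned with `converged = FALSE`. The approximation error is the
#' mean absolute difference between the sampled and full `B` entries over the
#' vertices present in the sample.
#'
#' @param fkg A `fkgmm_fkg`.
#' @param sample_rate Fraction of rules to retain, in `(0, 1]`.
#' @param error_threshold Acceptable approximation error (`>= 0`).
#' @param seed Random seed (default 42).
#' @param max_iters Maximum subsets drawn (default 200).
#' @param stratified Stratify draws by rule label (default `TRUE`).
#' @return An object of class `fkgmm_fkgs` (also `fkgmm_fkg`) with extra
#'   fields `sample_rate`, `error_threshold`, `achieved_error`, `seed`,
#'   `converged`, and `rule_ids`.
#' @export
sample_fkgs <- function(fkg, sample_rate, error_threshold, seed = 42L,
                        max_iters = 200L, stratified = TRUE) {
  stopifnot(inherits(fkg, "fkgmm_fkg"), sample_rate > 0, sample_rate <= 1,
            error_threshold >= 0)
  frb <- fkg$frb
  n <- nrow(frb)
  m <- as.integer(ceiling(sample_rate * n))
  draw_once <- function() {
    if (stratified && length(unique(frb$label)) > 1) {
      cnt <- stratify_counts(frb$label, m)
      unlist(lapply(names(cnt), function(l) {
        idx <- which(frb$label == l)
        if (cnt[[l]] == 0) integer() else sort(sample(idx, cnt[[l]]))
      }), use.names = FALSE)
    } else sort(sample(n, m))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (it in seq_len(max_iters)) {
      idx <- if (m >= n) seq_len(n) else draw_once()
      sub <- new_frb(frb[idx, , drop = FALSE], attributes = attr(frb, "attributes"),
                     scheme = attr(frb, "scheme"))
      g <- build_fkg(sub)
      err <- fkgs_error(g, fkg)
      if (is.null(best) || err < best$err) best <- list(g = g, err = err, idx = idx)
      if (err <= error_threshold || m >= n) break
    }
  })
  out <- best$g
  out$sample_rate <- sample_rate
  out$error_threshold <- error_threshold
  out$achieved_error <- best$err
  out$seed <- seed
  out$converged <- best$err <= error_threshold
  out$rule_ids <- frb$rule[best$idx]
  out$full_fkg <- fkg
  class(out) <- c("fkgmm_fkgs", class(out))
  if (!out$converged)
    rlang::warn(sprintf("FKGS sampling did not reach error <= %.3g in %d draws (best %.3g)",
                        error_threshold, max_iters, best$err))
  out
}

#' Approximation error of a sampled graph
#'
#' Mean absolute difference between the sampled and full vertex-label weights
#' over the vertices present in the sample.
#'
#' @param sub,full `fkgmm_fkg` objects (sampled and full).
#' @return Nonnegative error.
#' @export
fkgs_error <- function(sub, full) {
  vs <- rownames(sub$B)
  Bfull <- matrix(0, length(vs), length(sub$L), dimnames = list(vs, colnames(sub$B)))
  common_l <- intersect(colnames(sub$B), colnames(full$B))
  Bfull[, common_l] <- full$B[vs, common_l]
  mean(abs(sub$B - Bfull))
}

#' Classify records on a fuzzy knowledge graph
#'
#' Each record is fuzzified to membership degrees over every vertex of the
#' graph; the additive label score is `score(l) = sum_u mu(u) * B[u, l]`, with
#' an optional pairwise credit `lambda * sum_{u,v} min(mu(u), mu(v)) *
#' A[u, v] * B[v, l]` (default `lambda = 0`). The predicted label is the
#' argmax, ties going to the smallest label.
#'
#' @param model A `fkgmm_fkg` or `fkgmm_fkgs`.
#' @param newdata Data frame of records: numeric attribute columns (fuzzified
#'   through `scheme`) or character columns naming the term per attribute
#'   (crisp membership 1).
#' @param scheme Membership scheme for numeric records; defaults to the one
#'   stored in the model.
#' @param lambda Weight of the pairwise co-occurrence credit (default 0).
#' @return A tibble with the predicted label `.pred` and one `score_<label>`
#'   column per label.
#' @export
fisa_classify <- function(model, newdata, scheme = NULL, lambda = 0) {
  stopifnot(inherits(model, "fkgmm_fkg"))
  if (is.null(scheme)) scheme <- model$scheme
  newdata <- tibble::as_tibble(newdata)
  attrs <- unique(model$V$attribute)
  miss <- setdiff(attrs, names(newdata))
  if (length(miss) > 0)
    rlang::abort(paste0("record is missing attribute(s): ", paste(miss, collapse = ", ")),
                 class = "fkgmm_config_error")
  n <- nrow(newdata)
  Mu <- matrix(0, n, nrow(model$V), dimnames = list(NULL, model$V$vertex))
  for (a in attrs) {
    vids <- which(model$V$attribute == a)
    x <- newdata[[a]]
    if (is.numeric(x)) {
      if (is.null(scheme))
        rlang::abort("numeric records need a membership scheme", class = "fkgmm_config_error")
      mu <- membership_degrees(scheme, a, x)
      for (v in vids) {
        trm <- model$V$term[v]
        if (trm %in% colnames(mu)) Mu[, model$V$vertex[v]] <- mu[, trm]
      }
    } else {
      for (v in vids) Mu[, model$V$vertex[v]] <- as.numeric(as.character(x) == model$V$term[v])
    }
  }
  if (any(rowSums(Mu) == 0))
    rlang::abort("record has zero membership on every vertex; cannot classify",
                 class = "fkgmm_abstain_error")
  scores <- Mu %*% model$B
  if (lambda != 0) {
    for (i in seq_len(n)) {
      mu <- Mu[i, ]
      pair <- outer(mu, mu, pmin) * model$A # min(mu(u), mu(v)) * A[u, v]
      scores[i, ] <- scores[i, ] + lambda * as.numeric(colSums(pair) %*% model$B)
    }
  }
  labs <- colnames(model$B)
  pred <- labs[apply(scores, 1, which.max)] # ties: first (smallest) label
  out <- tibble::as_tibble(as.data.frame(scores))
  names(out) <- paste0("score_", labs)
  dplyr::bind_cols(tibble::tibble(.pred = pred), out)
}

# ---- serialization -----------------------------------------------------------

#' Read / write a fuzzy rule base as CSV
#'
#' One rule per row: `rule`, a term column per attribute, `mu_<attribute>`
#' membership columns, `label`, `weight` (the shape of a printed rule table).
#'
#' @param frb A `fkgmm_frb`.
#' @param path CSV path.
#' @return `write_frb_csv` returns `path` invisibly; `read_frb_csv` returns a
#'   `fkgmm_frb`.
#' @export
write_frb_csv <- function(frb, path) {
  readr::write_csv(tibble::as_tibble(frb), path)
  invisible(path)
}

#' @rdname write_frb_csv
#' @export
read_frb_csv <- function(path) {
  as_frb(readr::read_csv(path, show_col_types = FALSE))
}

#' Read / write a fuzzy knowledge graph as JSON
#'
#' Serializes `V`, `L`, dense `A` and `B`, and the rule table.
#'
#' @param fkg A `fkgmm_fkg`.
#' @param path JSON path.
#' @return `write_fkg_json` returns `path` invisibly; `read_fkg_json` returns
#'   a `fkgmm_fkg`.
#' @export
write_fkg_json <- function(fkg, path) {
  obj <- list(V = fkg$V, L = fkg$L,
              A = fkg$A, B = fkg$B,
              rules = tibble::as_tibble(fkg$frb),
              attributes = attr(fkg$frb, "attributes"))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fkg_json
#' @export
read_fkg_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  frb <- as_frb(tibble::as_tibble(obj$rules), attributes = obj$attributes)
  g <- build_fkg(frb)
  g
}

# ---- broom-style methods and plots ------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fuzzy knowledge graph into vertex-label weights
#'
#' @param x A `fkgmm_fkg`.
#' @param ... Unused.
#' @return A tibble with columns `vertex`, `attribute`, `term`, `label`,
#'   `weight` (the entries of `B`).
#' @export
tidy.fkgmm_fkg <- function(x, ...) {
  b <- tibble::as_tibble(as.data.frame(x$B, check.names = FALSE))
  b$vertex <- rownames(x$B)
  out <- tidyr::pivot_longer(b, -dplyr::all_of("vertex"),
                             names_to = "label", values_to = "weight")
  dplyr::left_join(out, x$V, by = "vertex")[, c("vertex", "attribute", "term", "label", "weight")]
}

#' One-row summary of a fuzzy knowledge graph
#'
#' @param x A `fkgmm_fkg` or `fkgmm_fkgs`.
#' @param ... Unused.
#' @return A one-row tibble: vertex, label, and rule counts (plus sampling
#'   fields for a sampled graph).
#' @export
glance.fkgmm_fkg <- function(x, ...) {
  out <- tibble::tibble(n_vertices = nrow(x$V), n_labels = length(x$L),
                        n_rules = nrow(x$frb))
  if (inherits(x, "fkgmm_fkgs"))
    out <- dplyr::bind_cols(out, tibble::tibble(sample_rate = x$sample_rate,
                                                achieved_error = x$achieved_error,
                                                converged = x$converged))
  out
}

#' Tidy a fuzzy rule base
#'
#' @param x A `fkgmm_frb`.
#' @param ... Unused.
#' @return The rule tibble.
#' @export
tidy.fkgmm_frb <- function(x, ...) tibble::as_tibble(x)

#' Plot the vertex-label weights of a fuzzy knowledge graph
#'
#' @param object A `fkgmm_fkg`.
#' @param ... Unused.
#' @return A ggplot heatmap of `B`.
#' @export
autoplot.fkgmm_fkg <- function(object, ...) {
  d <- tidy.fkgmm_fkg(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$vertex, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "label", y = "attribute-term vertex", fill = "B[u, l]") +
    ggplot2::theme_minimal()
}

#' Plot the membership functions of a fitted scheme
#'
#' @param object A `fkgmm_scheme`.
#' @param n_points Curve resolution per attribute.
#' @param ... Unused.
#' @return A ggplot of the triangular membership functions, one facet per
#'   attribute.
#' @export
autoplot.fkgmm_scheme <- function(object, n_points = 200L, ...) {
  d <- purrr::map_dfr(names(object$attributes), function(a) {
    at <- object$attributes[[a]]
    xs <- seq(at$range[1], at$range[2], length.out = n_points)
    purrr::map_dfr(seq_along(at$terms), function(t)
      tibble::tibble(attribute = a, term = at$terms[t], x = xs,
                     mu = triangular_membership(xs, at$params[t, 1], at$params[t, 2], at$params[t, 3])))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$mu, colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~attribute, scales = "free_x") +
    ggplot2::labs(x = "attribute value", y = "membership degree") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
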