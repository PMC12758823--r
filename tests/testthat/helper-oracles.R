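# Independent oracles and small fixture builders shared across the suite.

gray_rgb <- function(m) array(rep(m, 3), c(dim(m), 3))

make_preprocessed <- function(gray, mask = NULL, enhanced = NULL, id = "t") {
  if (is.null(mask)) mask <- matrix(1L, nrow(gray), ncol(gray))
  if (is.null(enhanced)) enhanced <- gray_rgb(gray)
  structure(list(enhanced = enhanced, gray = gray, mask = mask, id = id),
            class = "fkgmm_preprocessed")
}

# direct (non-separable) 2D Gaussian convolution with reflective borders,
# kernel radius ceiling(3 * sigma)
oracle_gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- outer(-r:r, -r:r, function(y, x) exp(-(y^2 + x^2) / (2 * sigma^2)))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  reflect <- function(i, n) {
    i[i < 1] <- 2 - i[i < 1]
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + k[di + r + 1, dj + r + 1] * m[reflect(i + di, nr), reflect(j + dj, nc)]
    out[i, j] <- acc
  }
  out
}

# plain histogram equalization by direct CDF mapping over integer intensities
oracle_hist_equalize <- function(m) {
  vals <- sort(unique(as.vector(m)))
  cdf <- cumsum(tabulate(match(as.vector(m), vals), length(vals))) / length(m)
  cdf_min <- cdf[1]
  map <- if (cdf_min >= 1) stats::setNames(vals, vals) else
    stats::setNames((cdf - cdf_min) / (1 - cdf_min) * 255, vals)
  matrix(map[as.character(m)], nrow(m), ncol(m))
}

# exhaustive Otsu: search all 256 thresholds for max between-class variance
oracle_otsu <- function(gray) {
  v <- as.vector(gray)
  best_t <- 0; best_var <- -1
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best_var) { best_var <- bc; best_t <- t }
  }
  best_t
}

# co-occurrence counting by explicit pixel-pair loops
oracle_glcm <- function(q, levels, distance, angle) {
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  counts <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
    a <- q[i, j]; b <- q[i2, j2]
    if (is.na(a) || is.na(b)) next
    counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
  }
  counts / sum(counts)
}

# Haralick descriptors by naive double loops over P
oracle_glcm_descriptors <- function(P) {
  N <- nrow(P)
  contrast <- 0; homog <- 0; asm <- 0; entropy <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    p <- P[i + 1, j + 1]
    contrast <- contrast + (i - j)^2 * p
    homog <- homog + p / (1 + (i - j)^2)
    asm <- asm + p^2
    if (p > 0) entropy <- entropy - p * log(p)
    mu_i <- mu_i + i * p
    mu_j <- mu_j + j * p
  }
  s_i <- 0; s_j <- 0; num <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    p <- P[i + 1, j + 1]
    s_i <- s_i + (i - mu_i)^2 * p
    s_j <- s_j + (j - mu_j)^2 * p
    num <- num + p * (i - mu_i) * (j - mu_j)
  }
  corr <- if (s_i < 1e-12 || s_j < 1e-12) 1 else num / sqrt(s_i * s_j)
  c(contrast = contrast, homogeneity = homog, energy = sqrt(asm),
    entropy = entropy, correlation = corr, asm = asm)
}

# small random FRB builder for sampling-law sweeps
random_frb <- function(n_rules, n_attrs = 4, seed = 1) {
  withr::with_seed(seed, {
    terms <- c("Low", "Medium", "High")
    rules <- as.data.frame(matrix(sample(terms, n_rules * n_attrs, replace = TRUE),
                                  n_rules, n_attrs))
    names(rules) <- paste0("A", seq_len(n_attrs))
    rules$label <- as.character(sample(1:2, n_rules, replace = TRUE))
    if (length(unique(rules$label)) == 1 && n_rules > 1)
      rules$label[1] <- setdiff(c("1", "2"), rules$label[1])
    as_frb(rules)
  })
}

# tiny shared linked dataset (lazy, cached) for end-to-end smoke tests
tiny_linked <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_linked_dataset(24, seed = 9, image_size = 32, lesion_effect = 2)
    cache
  }
})

fast_imaging <- list(resize = NULL, search = 7, template = 3)
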