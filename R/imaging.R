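#' @useDynLib fkgmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang abort warn .data
NULL

# ---- image container helpers -------------------------------------------------

#' Create an RGB image object
#'
#' Images are stored as plain numeric arrays of shape `height x width x 3` with
#' intensities on the 0-255 scale, carrying a sample identifier in the `"id"`
#' attribute.
#'
#' @param pixels Numeric array `h x w x 3`, intensities in `[0, 255]`.
#' @param id Sample identifier (character scalar).
#' @return The validated array with class `fkgmm_rgb`.
#' @export
rgb_image <- function(pixels, id = "img") {
  validate_rgb(pixels)
  structure(pixels, id = as.character(id), class = "fkgmm_rgb")
}

validate_rgb <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    abort("image must be a height x width x 3 array", class = "fkgmm_invalid_input")
  d <- dim(pixels)
  if (d[1] < 8 || d[2] < 8)
    abort("image height and width must be >= 8", class = "fkgmm_invalid_input")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    abort("image intensities must lie in [0, 255]", class = "fkgmm_invalid_input")
  invisible(pixels)
}

#' Read an RGB image from a JPEG/PNG/TIFF file
#'
#' @param path File path.
#' @param id Sample identifier; defaults to the file name without extension.
#' @return An [rgb_image()] array (`h x w x 3`, 0-255).
#' @export
read_rgb_image <- function(path, id = NULL) {
  if (!file.exists(path)) abort(paste0("no such image file: ", path), class = "fkgmm_invalid_input")
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img) # x (width) first in EBImage
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  px <- aperm(px, c(2, 1, 3)) * 255
  px[px < 0] <- 0; px[px > 255] <- 255
  rgb_image(px, id = if (is.null(id)) sub("\\.[^.]+$", "", basename(path)) else id)
}

#' Write an RGB image to PNG
#'
#' @param image `h x w x 3` array on the 0-255 scale.
#' @param path Output file path (extension selects the format).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  validate_rgb(image)
  EBImage::writeImage(EBImage::Image(aperm(image / 255, c(2, 1, 3)), colormode = "Color"), path)
  invisible(path)
}

#' Resize an RGB image (bilinear)
#'
#' @param image `h x w x 3` array, 0-255.
#' @param size Target side length; the output is `size x size`.
#' @return Resized array.
#' @export
resize_image <- function(image, size) {
  validate_rgb(image)
  if (all(dim(image)[1:2] == size)) return(image)
  im <- EBImage::Image(aperm(image / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(im, w = size, h = size)
  px <- aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
  px[px < 0] <- 0; px[px > 255] <- 255
  structure(px, id = attr(image, "id"), class = "fkgmm_rgb")
}

# ---- separable Gaussian blur -------------------------------------------------

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# reflect-padded 1D convolution along matrix rows
convolve_cols <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n <- ncol(m)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r)) # reflect (no edge dup)
  padded <- m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), n)
  for (s in seq_along(k)) out <- out + k[s] * padded[, s:(s + n - 1L), drop = FALSE]
  out
}

gaussian_blur_channel <- function(m, sigma) {
  k <- gaussian_kernel_1d(sigma)
  t(convolve_cols(t(convolve_cols(m, k)), k))
}

#' Sharpen an image by unsharp masking
#'
#' Computes `image * (1 + alpha) - blur(image, sigma) * alpha` channel-wise and
#' clips to `[0, 255]`. The blur is a separable Gaussian with a discrete kernel
#' of radius `ceiling(3 * sigma)` and reflective borders.
#'
#' @param image `h x w x 3` array, 0-255.
#' @param alpha Sharpening amount, `>= 0`. `alpha = 0` returns the input.
#' @param sigma Gaussian standard deviation in pixels, `> 0`.
#' @return Sharpened array of the same shape.
#' @export
unsharp_mask <- function(image, alpha = 1, sigma = 1) {
  validate_rgb(image)
  stopifnot(alpha >= 0, sigma > 0)
  if (alpha == 0) return(image)
  out <- image
  for (ch in 1:3) {
    blurred <- gaussian_blur_channel(image[, , ch], sigma)
    out[, , ch] <- image[, , ch] * (1 + alpha) - blurred * alpha
  }
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

# ---- sRGB <-> CIELAB (D65) ---------------------------------------------------

srgb_to_lab <- function(image) {
  v <- image / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  R <- lin[, , 1]; G <- lin[, , 2]; B <- lin[, , 3]
  X <- (0.4124564 * R + 0.3575761 * G + 0.1804375 * B) / 0.95047
  Y <- 0.2126729 * R + 0.7151522 * G + 0.0721750 * B
  Z <- (0.0193339 * R + 0.1191920 * G + 0.9503041 * B) / 1.08883
  eps <- (6 / 29)^3
  f <- function(t) ifelse(t > eps, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fX <- f(X); fY <- f(Y); fZ <- f(Z)
  list(L = 116 * fY - 16, a = 500 * (fX - fY), b = 200 * (fY - fZ))
}

lab_to_srgb <- function(lab) {
  fY <- (lab$L + 16) / 116
  fX <- fY + lab$a / 500
  fZ <- fY - lab$b / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  X <- finv(fX) * 0.95047; Y <- finv(fY); Z <- finv(fZ) * 1.08883
  R <- 3.2404542 * X - 1.5371385 * Y - 0.4985314 * Z
  G <- -0.9692660 * X + 1.8760108 * Y + 0.0415560 * Z
  B <- 0.0556434 * X - 0.2040259 * Y + 1.0572252 * Z
  gam <- function(v) {
    v[v < 0] <- 0
    ifelse(v <= 0.0031308, v * 12.92, 1.055 * v^(1 / 2.4) - 0.055)
  }
  out <- array(0, c(dim(lab$L), 3))
  out[, , 1] <- gam(R); out[, , 2] <- gam(G); out[, , 3] <- gam(B)
  out <- out * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

# ---- CLAHE -------------------------------------------------------------------

# Contrast-limited adaptive histogram equalization of one channel.
# Values are binned over [vmin, vmax]; per-tile histograms are clipped at
# clip_limit * tile_pixels / bins with the excess redistributed uniformly;
# the per-tile map is the full-range CDF mapping
#   (cdf(v) - cdf(min)) / (1 - cdf(min))
# and pixels are bilinearly interpolated between the four neighbouring tile
# maps. A tile whose values fall in a single bin maps identically (so constant
# regions are preserved).
clahe_channel <- function(m, clip_limit, nx, ny, bins = 256L, vmin = 0, vmax = 255) {
  nr <- nrow(m); nc <- ncol(m)
  v01 <- (m - vmin) / (vmax - vmin)
  v01[v01 < 0] <- 0; v01[v01 > 1] <- 1
  bin <- pmin(floor(v01 * bins) + 1L, bins)

  tile_h <- nr / ny; tile_w <- nc / nx
  t_row <- pmin(ceiling(row(m) / tile_h), ny)
  t_col <- pmin(ceiling(col(m) / tile_w), nx)

  # per-tile clipped-histogram CDF maps (lut[tile, bin] in [0,1])
  lut <- array(0, c(ny, nx, bins))
  for (ti in seq_len(ny)) for (tj in seq_len(nx)) {
    sel <- t_row == ti & t_col == tj
    b <- bin[sel]
    npix <- length(b)
    hst <- tabulate(b, nbins = bins)
    nz <- which(hst > 0)
    if (length(nz) <= 1L) {
      lut[ti, tj, ] <- mean(v01[sel]) # (near-)constant tile maps to itself
      next
    }
    clip <- max(1, clip_limit * npix / bins)
    excess <- sum(pmax(hst - clip, 0))
    hst <- pmin(hst, clip) + excess / bins
    cdf <- cumsum(hst) / npix
    cdf_min <- cdf[nz[1]]
    map <- (cdf - cdf_min) / (1 - cdf_min)
    map[map < 0] <- 0; map[map > 1] <- 1
    lut[ti, tj, ] <- map
  }

  # bilinear interpolation between tile centres
  gy <- (row(m) - 0.5) / tile_h - 0.5
  gx <- (col(m) - 0.5) / tile_w - 0.5
  y0 <- floor(gy); x0 <- floor(gx)
  wy <- gy - y0; wx <- gx - x0
  y0c <- pmin(pmax(y0, 0), ny - 1); y1c <- pmin(y0 + 1, ny - 1); y1c <- pmax(y1c, 0)
  x0c <- pmin(pmax(x0, 0), nx - 1); x1c <- pmin(x0 + 1, nx - 1); x1c <- pmax(x1c, 0)
  look <- function(ty, tx) lut[cbind(as.vector(ty) + 1L, as.vector(tx) + 1L, as.vector(bin))]
  vals <- (1 - wy) * (1 - wx) * look(y0c, x0c) +
    (1 - wy) * wx * look(y0c, x1c) +
    wy * (1 - wx) * look(y1c, x0c) +
    wy * wx * look(y1c, x1c)
  matrix(vals, nr, nc) * (vmax - vmin) + vmin
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Converts the image to CIELAB, equalizes the luminance (L) channel with
#' tile-wise clipped-histogram equalization, leaves the chroma channels
#' untouched, and converts back to sRGB.
#'
#' @param image `h x w x 3` array, 0-255.
#' @param clip_limit Histogram clip limit as a multiple of the uniform bin
#'   count (default 2, the usual CLAHE setting).
#' @param tile_grid Integer pair `c(rows, cols)` of tiles (default `c(8, 8)`).
#' @param bins Number of histogram bins (default 256).
#' @return Equalized array of the same shape.
#' @export
apply_clahe <- function(image, clip_limit = 2, tile_grid = c(8, 8), bins = 256L) {
  validate_rgb(image)
  stopifnot(clip_limit > 0, length(tile_grid) == 2, all(tile_grid >= 1))
  lab <- srgb_to_lab(image)
  lab$L <- clahe_channel(lab$L, clip_limit, nx = tile_grid[2], ny = tile_grid[1],
                         bins = bins, vmin = 0, vmax = 100)
  out <- lab_to_srgb(lab)
  structure(out, id = attr(image, "id"), class = class(image))
}

# ---- denoising ---------------------------------------------------------------

#' Non-local-means denoising
#'
#' Channel-wise non-local-means filtering: each pixel is replaced by a weighted
#' average of pixels in a search window, weighted by the similarity of their
#' surrounding patches, `w = exp(-d2 / strength^2)` with `d2` the mean squared
#' patch difference.
#'
#' @param image `h x w x 3` array, 0-255.
#' @param strength Filter strength `h` (default 10). `0` returns the input.
#' @param template Patch diameter in pixels (odd, default 7).
#' @param search Search-window diameter in pixels (odd, default 21).
#' @return Denoised array of the same shape.
#' @export
denoise_image <- function(image, strength = 10, template = 7L, search = 21L) {
  validate_rgb(image)
  stopifnot(strength >= 0, template %% 2 == 1, search %% 2 == 1)
  if (strength == 0) return(image)
  out <- image
  for (ch in 1:3) out[, , ch] <- .nlm_denoise_channel(image[, , ch], strength, as.integer(template), as.integer(search))
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

# ---- grayscale, Otsu, full preprocessing ------------------------------------

#' Convert an RGB image to grayscale (ITU-R BT.601 luma)
#'
#' @param image `h x w x 3` array, 0-255.
#' @return `h x w` matrix of luma intensities.
#' @export
rgb_to_gray <- function(image) {
  validate_rgb(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Otsu binarization threshold
#'
#' @param gray Numeric matrix of intensities on the 0-255 scale.
#' @return The threshold (0-255 scale) maximizing between-class variance, or
#'   `0` for a single-intensity image.
#' @export
otsu_threshold <- function(gray) {
  if (diff(range(gray)) == 0) return(0)
  as.numeric(EBImage::otsu(EBImage::Image(t(gray) / 255), range = c(0, 1), levels = 256)) * 255
}

#' Preprocess a fundus-style image
#'
#' Runs the full enhancement pipeline in fixed order: optional resize, unsharp
#' sharpening, non-local-means denoising, CLAHE, grayscale conversion, and Otsu
#' lesion masking (`mask = gray > threshold`, the bright side). A
#' single-intensity grayscale yields an all-ones mask so downstream feature
#' extraction never sees an empty region.
#'
#' @param image `h x w x 3` array, 0-255 (see [rgb_image()]).
#' @param resize Target square size before processing, or `NULL` to keep the
#'   input size (default 512, matching the extraction defaults).
#' @param alpha,sigma Unsharp-mask parameters (see [unsharp_mask()]).
#' @param denoise_strength,template,search Non-local-means parameters (see
#'   [denoise_image()]).
#' @param clip_limit,tile_grid CLAHE parameters (see [apply_clahe()]).
#' @return An object of class `fkgmm_preprocessed`: a list with `enhanced`
#'   (`h x w x 3`), `gray` (`h x w`), `mask` (binary `h x w`), and `id`.
#' @export
preprocess_image <- function(image, resize = 512L, alpha = 1, sigma = 1,
                             denoise_strength = 10, template = 7L, search = 21L,
                             clip_limit = 2, tile_grid = c(8, 8)) {
  validate_rgb(image)
  if (!is.null(resize)) image <- resize_image(image, resize)
  sharpened <- unsharp_mask(image, alpha = alpha, sigma = sigma)
  denoised <- denoise_image(sharpened, strength = denoise_strength,
                            template = template, search = search)
  enhanced <- apply_clahe(denoised, clip_limit = clip_limit, tile_grid = tile_grid)
  gray <- rgb_to_gray(enhanced)
  if (diff(range(gray)) == 0) {
    mask <- matrix(1L, nrow(gray), ncol(gray))
  } else {
    thr <- otsu_threshold(gray)
    mask <- matrix(as.integer(gray > thr), nrow(gray), ncol(gray))
    if (all(mask == 0L)) mask[] <- 1L
  }
  structure(list(enhanced = enhanced, gray = gray, mask = mask,
                 id = attr(image, "id") %||% "img"),
            class = "fkgmm_preprocessed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- GLCM --------------------------------------------------------------------

angle_offset <- function(angle, distance) {
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    abort("angle must be one of 0, 45, 90, 135", class = "fkgmm_config_error")
  )
}

# Symmetrically normalized co-occurrence matrix of a quantized image (values
# 0..levels-1, NA outside the region of interest).
glcm_matrix <- function(q, levels, distance, angle) {
  off <- angle_offset(angle, distance)
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1, 1 - off[1]):min(nr, nr - off[1])
  c0 <- max(1, 1 - off[2]):min(nc, nc - off[2])
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + off[1], c0 + off[2], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  counts <- matrix(0, levels, levels)
  if (any(keep)) {
    idx <- a[keep] * levels + b[keep] + 1L
    tab <- tabulate(idx, nbins = levels * levels)
    counts <- matrix(tab, levels, levels, byrow = TRUE)
  }
  counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot == 0) abort("no co-occurring pixel pairs in the masked region", class = "fkgmm_empty_region")
  counts / tot
}

# Haralick-style descriptors of one normalized, symmetric GLCM.
glcm_descriptors <- function(P) {
  N <- nrow(P)
  i <- matrix(0:(N - 1), N, N)
  j <- t(i)
  pi_ <- rowSums(P)
  mu_i <- sum((0:(N - 1)) * pi_)
  sig_i <- sqrt(sum((0:(N - 1) - mu_i)^2 * pi_))
  contrast <- sum((i - j)^2 * P)
  homogeneity <- sum(P / (1 + (i - j)^2))
  asm <- sum(P^2)
  pos <- P > 0
  entropy <- -sum(P[pos] * log(P[pos]))
  correlation <- if (sig_i < 1e-12) 1 else sum(P * (i - mu_i) * (j - mu_i)) / sig_i^2
  c(contrast = contrast, homogeneity = homogeneity, energy = sqrt(asm),
    entropy = entropy, correlation = correlation, asm = asm)
}

quantize_gray <- function(gray, mask, levels) {
  v <- gray
  v[mask == 0L] <- NA
  if (all(is.na(v))) abort("lesion mask selects no pixels", class = "fkgmm_empty_region")
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) {
    q <- v * 0
  } else {
    q <- floor((v - rng[1]) / (rng[2] - rng[1]) * levels)
    q[q > levels - 1] <- levels - 1
  }
  q
}

#' Extract GLCM texture features
#'
#' Quantizes the masked grayscale into `levels` gray levels (linear rescale of
#' the masked intensity range), builds the symmetric, normalized co-occurrence
#' matrix at the given pixel distance for each angle, computes contrast,
#' homogeneity, energy, entropy, correlation, and angular second moment (ASM),
#' and averages each descriptor over the angles. Entropy uses the natural
#' logarithm; energy is `sqrt(ASM)`; correlation of a zero-variance GLCM is 1
#' by convention.
#'
#' @param pre A `fkgmm_preprocessed` object from [preprocess_image()].
#' @param levels Number of gray levels (default 16).
#' @param distance Pixel offset (default 1).
#' @param angles Offsets in degrees, subset of `c(0, 45, 90, 135)`.
#' @return A one-row tibble with columns `contrast`, `homogeneity`, `energy`,
#'   `entropy`, `correlation`, `asm`.
#' @export
extract_glcm_features <- function(pre, levels = 16L, distance = 1L,
                                  angles = c(0, 45, 90, 135)) {
  stopifnot(inherits(pre, "fkgmm_preprocessed"), levels >= 2)
  if (all(pre$mask == 0L)) abort("lesion mask selects no pixels", class = "fkgmm_empty_region")
  q <- quantize_gray(pre$gray, pre$mask, levels)
  per_angle <- vapply(angles, function(a) glcm_descriptors(glcm_matrix(q, levels, distance, a)),
                      numeric(6))
  as_tibble(as.list(rowMeans(per_angle)))
}

#' Extract first-order statistical features
#'
#' Mean, population variance, standard deviation, and root mean square of the
#' grayscale intensities (equivalently, moments of the normalized intensity
#' histogram). The RMS uses center 0, so `rms^2 = variance + mean^2`.
#'
#' @param pre A `fkgmm_preprocessed` object from [preprocess_image()].
#' @param masked If `TRUE`, restrict to the lesion mask; default `FALSE`
#'   (whole enhanced grayscale).
#' @return A one-row tibble with columns `mean`, `variance`, `sd`, `rms`.
#' @export
extract_statistical_features <- function(pre, masked = FALSE) {
  stopifnot(inherits(pre, "fkgmm_preprocessed"))
  v <- if (masked) pre$gray[pre$mask == 1L] else as.vector(pre$gray)
  if (length(v) == 0) abort("no pixels in region", class = "fkgmm_empty_region")
  m <- mean(v)
  va <- mean((v - m)^2)
  tibble(mean = m, variance = va, sd = sqrt(va), rms = sqrt(mean(v^2)))
}

#' Extract the full image feature vector for a set of images
#'
#' Runs [preprocess_image()], [extract_statistical_features()], and
#' [extract_glcm_features()] on each image and binds the per-image rows.
#'
#' @param images A list of [rgb_image()] arrays (or a single one).
#' @param levels,distance,angles GLCM settings (see [extract_glcm_features()]).
#' @param ... Further arguments passed to [preprocess_image()] (e.g. `resize`,
#'   `denoise_strength`).
#' @return A tibble with one row per image: `id`, `contrast`, `homogeneity`,
#'   `energy`, `entropy`, `correlation`, `asm`, `mean`, `variance`, `sd`, `rms`.
#' @export
extract_image_features <- function(images, levels = 16L, distance = 1L,
                                   angles = c(0, 45, 90, 135), ...) {
  if (!is.list(images)) images <- list(images)
  rows <- lapply(images, function(img) {
    pre <- preprocess_image(img, ...)
    dplyr::bind_cols(tibble(id = pre$id),
                     extract_glcm_features(pre, levels, distance, angles),
                     extract_statistical_features(pre))
  })
  dplyr::bind_rows(rows)
}

# ---- min-max scaling ---------------------------------------------------------

#' Min-max scale feature columns to \[0, 1\]
#'
#' Each selected column is mapped to `[0, 1]` by its own range; a constant
#' column maps to all zeros. The per-column ranges are stored in the
#' `"minmax_ranges"` attribute so [min_max_unscale()] can invert the transform.
#'
#' @param data A data frame of features.
#' @param columns Character vector of columns to scale; default all numeric
#'   columns.
#' @return A tibble with the selected columns rescaled.
#' @export
min_max_scale <- function(data, columns = NULL) {
  data <- as_tibble(data)
  if (is.null(columns)) columns <- names(data)[vapply(data, is.numeric, logical(1))]
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0)
    abort(paste0("unknown column(s): ", paste(missing_cols, collapse = ", ")),
          class = "fkgmm_config_error")
  ranges <- lapply(stats::setNames(columns, columns), function(cl) range(data[[cl]]))
  for (cl in columns) {
    r <- ranges[[cl]]
    data[[cl]] <- if (diff(r) == 0) rep(0, nrow(data)) else (data[[cl]] - r[1]) / (r[2] - r[1])
  }
  attr(data, "minmax_ranges") <- ranges
  data
}

#' Invert a min-max scaling
#'
#' @param data A tibble produced by [min_max_scale()] (or any data frame).
#' @param ranges The `"minmax_ranges"` attribute of the scaled data; taken from
#'   `data` if omitted.
#' @return A tibble on the original scale (constant columns are restored to
#'   their original constant value).
#' @export
min_max_unscale <- function(data, ranges = attr(data, "minmax_ranges")) {
  if (is.null(ranges)) abort("no min-max ranges supplied", class = "fkgmm_config_error")
  data <- as_tibble(data)
  for (cl in names(ranges)) {
    r <- ranges[[cl]]
    data[[cl]] <- if (diff(r) == 0) rep(r[1], nrow(data)) else data[[cl]] * (r[2] - r[1]) + r[1]
  }
  attr(data, "minmax_ranges") <- NULL
  data
}
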