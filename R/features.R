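#' Feature extraction configuration
#'
#' Defines the appearance descriptor. The default configuration yields
#' `12 + 144 + 2420 = 2576` features:
#'
#' * **Color** (`MC = 12`): mean, population SD, skewness and excess
#'   kurtosis of each RGB channel over the region of interest.
#' * **Wavelet texture** (`MW = 144`): the same four statistics of the
#'   detail coefficients of a multi-level 2-D DWT of the ROI's largest
#'   rectangle, for 3 detail subbands x 4 levels x 3 channels.
#' * **GLCM** (`MG = 2420`): all entries of the symmetric, normalized
#'   gray-level co-occurrence matrix of the rectangle for every
#'   (distance, angle) pair: 11^2 levels x 5 distances x 4 angles.
#'
#' @param wavelet_family `"db4"` (default) or `"haar"`.
#' @param wavelet_levels Decomposition depth (default 4).
#' @param wavelet_channels Channels to decompose (default R, G, B).
#' @param glcm_levels Number of gray levels for quantization (default 11).
#' @param glcm_distances Pixel displacements (default 1:5).
#' @param glcm_angles Displacement directions in degrees (default 0, 45,
#'   90, 135).
#' @param glcm_symmetric Count each pixel pair in both directions (default
#'   `TRUE`).
#' @param glcm_gray_limits Intensity range mapped onto the gray levels;
#'   `NULL` (default) uses the crop's own min-max range, or give a fixed
#'   range such as `c(0, 255)`.
#' @param gray_weights RGB weights of the grayscale conversion (default the
#'   ITU-601 luma weights 0.299/0.587/0.114).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(wavelet_family = "db4",
                           wavelet_levels = 4,
                           wavelet_channels = c("R", "G", "B"),
                           glcm_levels = 11,
                           glcm_distances = 1:5,
                           glcm_angles = c(0, 45, 90, 135),
                           glcm_symmetric = TRUE,
                           glcm_gray_limits = NULL,
                           gray_weights = c(0.299, 0.587, 0.114)) {
  if (glcm_levels < 2) stop_vqc("config", "glcm_levels must be >= 2")
  structure(
    list(wavelet_family = wavelet_family,
         wavelet_levels = as.integer(wavelet_levels),
         wavelet_channels = wavelet_channels,
         glcm_levels = as.integer(glcm_levels),
         glcm_distances = as.integer(glcm_distances),
         glcm_angles = glcm_angles,
         glcm_symmetric = isTRUE(glcm_symmetric),
         glcm_gray_limits = glcm_gray_limits,
         gray_weights = gray_weights),
    class = "feature_config"
  )
}

n_color_features <- function(config) 12L
n_wavelet_features <- function(config) {
  4L * 3L * config$wavelet_levels * length(config$wavelet_channels)
}
n_glcm_features <- function(config) {
  config$glcm_levels^2 * length(config$glcm_distances) *
    length(config$glcm_angles)
}

# mean, population SD, skewness, excess kurtosis; zero-variance input gives
# skewness = kurtosis = 0 by convention
four_moments <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  if (s == 0) return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0))
  c(mean = m, sd = s,
    skewness = mean((x - m)^3) / s^3,
    kurtosis = mean((x - m)^4) / v^2 - 3)
}

#' Color features of the region of interest
#'
#' Mean, population standard deviation, skewness and Fisher excess kurtosis
#' of each RGB channel over the masked pixels, ordered R-stats, G-stats,
#' B-stats (12 values).
#'
#' @param image 8-bit `H x W x 3` array.
#' @param mask Logical `H x W` matrix (e.g. from [segment_roi()]).
#' @return A named numeric vector of length 12.
#' @export
color_features <- function(image, mask) {
  mask <- unclass(mask)
  if (!any(mask)) stop_vqc("empty_mask", "mask has no foreground pixels")
  out <- lapply(1:3, function(ch) four_moments(image[, , ch][mask]))
  names(out) <- c("R", "G", "B")
  vec <- unlist(out)
  names(vec) <- paste0("col_", sub("\\.", "_", names(vec)))
  vec
}

#' Grayscale conversion
#'
#' Weighted channel sum re-quantized to 8 bits (round half up). Default
#' weights are the ITU-601 luma coefficients, which sum to 1.
#'
#' @param image 8-bit `H x W x 3` array.
#' @param weights RGB weights.
#' @return An `H x W` matrix with integer values in `[0, 255]`.
#' @export
rgb_to_gray <- function(image, weights = c(0.299, 0.587, 0.114)) {
  g <- weights[1] * image[, , 1] + weights[2] * image[, , 2] +
    weights[3] * image[, , 3]
  matrix(round_half_up(clip8(g)), dim(image)[1], dim(image)[2])
}

crop_rect <- function(m, rect) m[rect_rows(rect), rect_cols(rect)]

# largest centered sub-rectangle whose sides are divisible by 2^levels
trim_for_dwt <- function(rect, levels) {
  unit <- 2L^levels
  h <- (rect$height %/% unit) * unit
  w <- (rect$width %/% unit) * unit
  if (h < unit || w < unit) {
    stop_vqc("decomposition_depth",
             sprintf("rectangle %dx%d too small for a %d-level decomposition",
                     rect$height, rect$width, levels))
  }
  rect_region(rect$top + (rect$height - h) %/% 2,
              rect$left + (rect$width - w) %/% 2, h, w)
}

#' Wavelet texture features
#'
#' Multi-level 2-D DWT of each configured channel of the rectangle crop
#' (trimmed to the largest centered sub-rectangle divisible by
#' `2^wavelet_levels`); for every level and detail subband (H, V, D) the four
#' moment statistics of the coefficients are reported. Default:
#' 4 stats x 3 subbands x 4 levels x 3 channels = 144 values, in fixed order
#' channel > level > subband > statistic.
#'
#' @param image 8-bit `H x W x 3` array.
#' @param rect A [rect_region()] inside the image.
#' @param config A [feature_config()].
#' @return A named numeric vector (length 144 under the default config).
#' @export
wavelet_features <- function(image, rect, config = feature_config()) {
  rect <- trim_for_dwt(rect, config$wavelet_levels)
  ch_idx <- match(config$wavelet_channels, c("R", "G", "B"))
  out <- numeric(0)
  for (ci in seq_along(ch_idx)) {
    crop <- image[rect_rows(rect), rect_cols(rect), ch_idx[ci]]
    dec <- dwt2(crop, levels = config$wavelet_levels,
                family = config$wavelet_family)
    for (lv in seq_len(config$wavelet_levels)) {
      for (sb in c("H", "V", "D")) {
        stats <- four_moments(as.numeric(dec$detail[[lv]][[sb]]))
        names(stats) <- sprintf("wav_%s_l%d_%s_%s",
                                config$wavelet_channels[ci], lv, sb,
                                names(stats))
        out <- c(out, stats)
      }
    }
  }
  out
}

quantize_gray <- function(crop, levels, limits = NULL) {
  if (is.null(limits)) limits <- range(crop)
  lo <- limits[1]; hi <- limits[2]
  if (hi <= lo) return(matrix(0L, nrow(crop), ncol(crop)))
  q <- floor((crop - lo) / (hi - lo) * levels)
  q[] <- pmin(pmax(q, 0L), levels - 1L)
  matrix(as.integer(q), nrow(crop), ncol(crop))
}

angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d),
         "45" = c(-d, d),
         "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop_vqc("config", sprintf("unsupported GLCM angle %s", angle)))
}

# normalized (optionally symmetric) co-occurrence matrix for one offset
glcm_matrix <- function(q, levels, dr, dc, symmetric = TRUE) {
  h <- nrow(q); w <- ncol(q)
  if (abs(dr) >= h || abs(dc) >= w) {
    stop_vqc("insufficient_extent",
             "crop smaller than the requested GLCM displacement")
  }
  r1 <- max(1L, 1L - dr):min(h, h - dr)
  c1 <- max(1L, 1L - dc):min(w, w - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(tabulate(a * levels + b + 1L, nbins = levels^2),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

#' Gray-level co-occurrence features
#'
#' Quantizes the rectangle crop of a grayscale image to `glcm_levels`
#' equal-width bins (over the crop's min-max range by default, or the fixed
#' `glcm_gray_limits`), builds the normalized symmetric co-occurrence matrix
#' for every (distance, angle) pair and returns all matrix entries flattened
#' in fixed order distance > angle > row-major entries. Default:
#' 11^2 x 5 x 4 = 2420 values.
#'
#' @param gray `H x W` grayscale matrix (see [rgb_to_gray()]).
#' @param rect A [rect_region()] inside the image.
#' @param config A [feature_config()].
#' @return A named numeric vector (length 2420 under the default config).
#' @export
glcm_features <- function(gray, rect, config = feature_config()) {
  crop <- crop_rect(gray, rect)
  q <- quantize_gray(crop, config$glcm_levels, config$glcm_gray_limits)
  L <- config$glcm_levels
  entry_names <- as.vector(t(outer(0:(L - 1), 0:(L - 1),
                                   function(i, j) sprintf("%d_%d", i, j))))
  out <- numeric(0)
  for (d in config$glcm_distances) {
    for (ang in config$glcm_angles) {
      off <- angle_offset(ang, d)
      p <- glcm_matrix(q, L, off[1], off[2], config$glcm_symmetric)
      v <- as.numeric(t(p))  # row-major flattening
      names(v) <- sprintf("glcm_d%d_a%d_%s", d, ang, entry_names)
      out <- c(out, v)
    }
  }
  out
}

#' Assemble the full feature vector
#'
#' Concatenates the color, wavelet and GLCM blocks (in that order) after
#' checking each block length against the configuration.
#'
#' @param color,wavelet,glcm Named numeric vectors from [color_features()],
#'   [wavelet_features()], [glcm_features()].
#' @param config A [feature_config()].
#' @return A named numeric vector of length `M` (2576 by default).
#' @export
assemble_features <- function(color, wavelet, glcm,
                              config = feature_config()) {
  if (length(color) != n_color_features(config) ||
      length(wavelet) != n_wavelet_features(config) ||
      length(glcm) != n_glcm_features(config)) {
    stop_vqc("config_inconsistency",
             sprintf("block lengths %d/%d/%d do not match the configuration (%d/%d/%d)",
                     length(color), length(wavelet), length(glcm),
                     n_color_features(config), n_wavelet_features(config),
                     n_glcm_features(config)))
  }
  out <- c(color, wavelet, glcm)
  if (anyDuplicated(names(out))) {
    stop_vqc("config_inconsistency", "duplicated feature names")
  }
  out
}

#' Extract the appearance descriptor of one image
#'
#' Convenience wrapper running [color_features()] on the ROI,
#' [wavelet_features()] and [glcm_features()] on the ROI's largest inscribed
#' rectangle, and [assemble_features()].
#'
#' @param image Standardized 8-bit `H x W x 3` array.
#' @param mask ROI mask from [segment_roi()].
#' @param rect Largest inscribed rectangle; computed from `mask` if `NULL`.
#' @param config A [feature_config()].
#' @return A named numeric vector of length `M` (2576 by default).
#' @export
extract_features <- function(image, mask, rect = NULL,
                             config = feature_config()) {
  if (is.null(rect)) rect <- largest_inscribed_rectangle(mask)
  gray <- rgb_to_gray(image, config$gray_weights)
  assemble_features(
    color = color_features(image, mask),
    wavelet = wavelet_features(image, rect, config),
    glcm = glcm_features(gray, rect, config),
    config = config
  )
}
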