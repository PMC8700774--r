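#' Locate the white and black references in a scene
#'
#' With a layout hint the designated regions are used directly. Without one,
#' the frame is tiled into blocks; the brightest connected patch of
#' low-variance blocks is taken as the white reference and the darkest as
#' the black reference. Per-channel trimmed means (central 80% of pixels)
#' make the estimates robust to specular pixels.
#'
#' @param image 8-bit `H x W x 3` array.
#' @param layout_hint Optional [scene_layout()] giving the true regions.
#' @param block Block size in pixels for the blind search.
#' @param sd_max Maximum within-block gray SD for a block to count as
#'   uniform.
#' @return A list of class `reference_estimate` with `white_mean`,
#'   `black_mean` (RGB triples) and `white_region`, `black_region`
#'   ([rect_region()]s).
#' @export
locate_references <- function(image, layout_hint = NULL, block = 16,
                              sd_max = 12) {
  if (!is.null(layout_hint)) {
    wr <- layout_hint$white_ref
    br <- layout_hint$black_ref
    return(new_reference_estimate(image, wr, br))
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  block <- max(4L, min(as.integer(block), min(h, w) %/% 16L))
  nbr <- h %/% block; nbc <- w %/% block
  if (nbr < 2 || nbc < 2) stop_vqc("reference_not_found", "image too small")
  bmean <- matrix(0, nbr, nbc); bsd <- matrix(0, nbr, nbc)
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    blk <- gray[((i - 1) * block + 1):(i * block),
                ((j - 1) * block + 1):(j * block)]
    bmean[i, j] <- mean(blk); bsd[i, j] <- stats::sd(as.numeric(blk))
  }
  uniform <- bsd <= sd_max
  if (!any(uniform)) {
    stop_vqc("reference_not_found",
             "no uniform patch found for reference estimation")
  }
  white_region <- grow_patch(gray, bmean, uniform,
                             which.max(replace(bmean, !uniform, -Inf)),
                             block, tol = 20, sd_max = sd_max)
  black_region <- grow_patch(gray, bmean, uniform,
                             which.min(replace(bmean, !uniform, Inf)),
                             block, tol = 20, sd_max = sd_max)
  est <- new_reference_estimate(image, white_region, black_region)
  if (mean(est$white_mean) - mean(est$black_mean) < 30) {
    stop_vqc("reference_not_found",
             "white and black candidate patches are not separated")
  }
  est
}

# largest uniform rectangle around a seed block: take the biggest rectangle
# of connected uniform blocks with a similar mean, then refine each edge at
# pixel resolution
grow_patch <- function(gray, bmean, uniform, seed_idx, block, tol, sd_max) {
  ok <- uniform & abs(bmean - bmean[seed_idx]) <= tol
  lab <- EBImage::bwlabel(ok * 1)
  comp_mask <- lab == lab[seed_idx] & lab > 0
  rect_b <- largest_inscribed_rectangle(comp_mask)
  top <- (rect_b$top - 1L) * block + 1L
  left <- (rect_b$left - 1L) * block + 1L
  bottom <- top + rect_b$height * block - 1L
  right <- left + rect_b$width * block - 1L
  target <- bmean[seed_idx]

  line_ok <- function(v) {
    abs(mean(v) - target) <= tol && stats::sd(v) <= 1.5 * sd_max
  }
  for (i in seq_len(block)) {  # extend each side at most one block
    if (top > 1 && line_ok(gray[top - 1, left:right])) top <- top - 1L
    if (bottom < nrow(gray) && line_ok(gray[bottom + 1, left:right])) {
      bottom <- bottom + 1L
    }
    if (left > 1 && line_ok(gray[top:bottom, left - 1])) left <- left - 1L
    if (right < ncol(gray) && line_ok(gray[top:bottom, right + 1])) {
      right <- right + 1L
    }
  }
  rect_region(top, left, bottom - top + 1L, right - left + 1L)
}

trimmed_mean_rgb <- function(image, region, trim = 0.1) {
  vapply(1:3, function(ch) {
    mean(image[rect_rows(region), rect_cols(region), ch], trim = trim)
  }, numeric(1))
}

new_reference_estimate <- function(image, white_region, black_region) {
  structure(
    list(white_mean = trimmed_mean_rgb(image, white_region),
         black_mean = trimmed_mean_rgb(image, black_region),
         white_region = white_region, black_region = black_region),
    class = "reference_estimate"
  )
}

#' Standardize an image against its references
#'
#' Per-channel two-point (affine) color correction: the map sending the
#' measured white reference mean to `nominal_white` and the black reference
#' mean to `nominal_black` is applied to every pixel, then clipped to
#' `[0, 255]` and re-quantized to 8 bits (round half up). This compensates
#' frame-wide affine lighting variation and reconstructs reference-anchored
#' color.
#'
#' @param image 8-bit `H x W x 3` array.
#' @param refs A `reference_estimate` from [locate_references()].
#' @param nominal_white,nominal_black Target RGB values for the references
#'   (defaults 255 and 0).
#' @return The standardized 8-bit image array.
#' @export
standardize_image <- function(image, refs,
                              nominal_white = c(255, 255, 255),
                              nominal_black = c(0, 0, 0)) {
  wm <- refs$white_mean; bm <- refs$black_mean
  if (any(wm <= bm)) {
    stop_vqc("degenerate_references",
             "white reference must exceed black reference in every channel")
  }
  if (any(nominal_white <= nominal_black)) {
    stop_vqc("degenerate_references",
             "nominal white must exceed nominal black in every channel")
  }
  out <- image
  for (ch in 1:3) {
    slope <- (nominal_white[ch] - nominal_black[ch]) / (wm[ch] - bm[ch])
    out[, , ch] <- (image[, , ch] - bm[ch]) * slope + nominal_black[ch]
  }
  out[] <- round_half_up(clip8(out))
  out
}
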