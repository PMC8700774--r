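#' Read and write 8-bit scene images as PNG
#'
#' Thin wrappers around the png package keeping the package's `[0, 255]`
#' integer array convention. ROI masks round-trip as single-channel 0/255
#' PNGs.
#'
#' @param image 8-bit `H x W x 3` array.
#' @param mask Logical `H x W` matrix.
#' @param path File path.
#' @return `read_scene_png()` returns the image array; `read_mask_png()` a
#'   logical matrix; the writers return `path` invisibly.
#' @name scene_io
NULL

#' @rdname scene_io
#' @export
write_scene_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_vqc("io", "the png package is required for PNG output")
  }
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname scene_io
#' @export
read_scene_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_vqc("io", "the png package is required for PNG input")
  }
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3 && dim(arr)[3] > 3) arr <- arr[, , 1:3]
  round_half_up(arr * 255)
}

#' @rdname scene_io
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_vqc("io", "the png package is required for PNG output")
  }
  png::writePNG(unclass(mask) * 1, target = path)
  invisible(path)
}

#' @rdname scene_io
#' @export
read_mask_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_vqc("io", "the png package is required for PNG input")
  }
  png::readPNG(path) > 0.5
}
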