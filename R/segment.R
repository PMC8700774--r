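#' Segment the sample region of interest
#'
#' Clusters the pixels of a standardized image in RGB space with k-means and
#' selects the cluster belonging to the food sample: clusters that are dark
#' (background), bright and unsaturated (white reference) or unsaturated
#' (gray indicator) are excluded, and among the remainder the cluster whose
#' mean hue is closest to `sample_hue` is chosen. The selected mask is
#' cleaned by morphological opening and closing and reduced to its largest
#' connected component.
#'
#' Cluster seeding is k-means++-style farthest-point seeding from `seed`
#' followed by Lloyd iterations, so the result is deterministic given the
#' seed.
#'
#' @param image Standardized 8-bit `H x W x 3` array.
#' @param k Number of color clusters (default 4: background, sample, white
#'   reference, indicator).
#' @param seed Integer seed for the clustering initialization.
#' @param sample_hue Expected hue of the sample in `[0, 1)` (default 0.08,
#'   a carrot orange).
#' @param min_saturation Minimum cluster-mean saturation for a cluster to be
#'   a sample candidate.
#' @param min_area Minimum ROI area as a fraction of the frame.
#' @param brush_size Diameter (pixels, odd) of the disc brush used for the
#'   opening step of the morphological cleanup.
#' @param close_size Diameter of the closing brush; `NULL` (default) scales
#'   it to 15% of the frame so that degraded (e.g. whitened) patches cut
#'   into the sample boundary are bridged back into the region.
#' @param convex_fill Fill the convex hull of the cleaned component (default
#'   `TRUE`). Appropriate for convex samples such as slices/discs: strongly
#'   degraded tissue at the rim or interior is still sample and must stay in
#'   the region of interest.
#' @return A logical `H x W` matrix of class `roi_mask` with attribute
#'   `pixel_count`.
#' @export
segment_roi <- function(image, k = 4, seed = 1L, sample_hue = 0.08,
                        min_saturation = 0.15, min_area = 0.002,
                        brush_size = 5, close_size = NULL,
                        convex_fill = TRUE) {
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- cbind(as.numeric(image[, , 1]), as.numeric(image[, , 2]),
              as.numeric(image[, , 3]))
  ux <- unique(px)
  if (nrow(ux) < k) {
    stop_vqc("degenerate_clustering",
             sprintf("only %d distinct colors for k = %d clusters", nrow(ux), k))
  }
  centers <- farthest_point_centers(px, k, seed)
  km <- suppressWarnings(
    kmeans(px, centers = centers, iter.max = 100, algorithm = "Lloyd"))

  ctr <- km$centers
  hsv <- grDevices::rgb2hsv(t(ctr), maxColorValue = 255)
  value <- hsv["v", ]; sat <- hsv["s", ]
  candidate <- value > 0.15 & !(value > 0.7 & sat < min_saturation) &
    sat >= min_saturation
  if (!any(candidate)) {
    stop_vqc("roi_not_found", "no cluster matches the expected sample colors")
  }
  hue_dist <- pmin(abs(hsv["h", ] - sample_hue),
                   1 - abs(hsv["h", ] - sample_hue))
  roi_cluster <- which(candidate)[which.min(hue_dist[candidate])]

  mask <- matrix(km$cluster == roi_cluster, h, w)
  if (is.null(close_size)) {
    close_size <- max(brush_size, 2L * (round(0.15 * min(h, w)) %/% 2L) + 1L)
  }
  mask <- EBImage::opening(mask * 1,
                           EBImage::makeBrush(brush_size, shape = "disc"))
  mask <- EBImage::closing(mask,
                           EBImage::makeBrush(close_size, shape = "disc"))
  # degraded (e.g. whitened) tissue inside the sample belongs to the region
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) {
    stop_vqc("roi_not_found", "segmented region vanished after cleanup")
  }
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  mask <- matrix(lab == best, h, w)
  if (convex_fill) mask <- fill_convex_hull(mask)
  if (sum(mask) < min_area * h * w) {
    stop_vqc("roi_not_found",
             "largest segmented component is below the area threshold")
  }
  structure(mask, class = c("roi_mask", class(mask)),
            pixel_count = sum(mask))
}

# fill the convex hull of a mask's foreground: every pixel on the inner side
# of all hull edges (consistent orientation) becomes foreground
fill_convex_hull <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(mask)
  hull <- grDevices::chull(pts[, 2], pts[, 1])  # (x = col, y = row)
  hx <- pts[hull, 2]; hy <- pts[hull, 1]
  nh <- length(hull)
  if (nh < 3) return(mask)
  # orientation from the signed area
  area2 <- sum(hx * hy[c(2:nh, 1)] - hx[c(2:nh, 1)] * hy)
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }
  h <- nrow(mask); w <- ncol(mask)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- matrix(TRUE, h, w)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (rr - hy[i]) - (hy[j] - hy[i]) * (cc - hx[i])
    inside <- inside & (cross >= 0)
  }
  mask | inside
}

# k-means++-style seeding: random first center (seeded), then repeatedly the
# point farthest from all chosen centers; deterministic given the seed.
farthest_point_centers <- function(px, k, seed) {
  n <- nrow(px)
  idx <- integer(k)
  idx[1] <- with_seed_local(seed, sample.int(n, 1))
  d2 <- rowSums((px - matrix(px[idx[1], ], n, ncol(px), byrow = TRUE))^2)
  if (k > 1) for (j in 2:k) {
    idx[j] <- which.max(d2)
    d2 <- pmin(d2, rowSums((px - matrix(px[idx[j], ], n, ncol(px),
                                        byrow = TRUE))^2))
  }
  px[idx, , drop = FALSE]
}

#' Largest axis-aligned rectangle inside a mask
#'
#' Finds the maximal-area axis-aligned rectangle wholly contained in the
#' foreground of a binary mask, via the histogram-stack dynamic program
#' (O(H*W)). Ties are broken deterministically by the smallest `(top, left)`
#' in lexicographic order.
#'
#' @param mask Logical `H x W` matrix (or [segment_roi()] output).
#' @return A [rect_region()].
#' @export
largest_inscribed_rectangle <- function(mask) {
  mask <- unclass(mask)
  if (!any(mask)) stop_vqc("empty_mask", "mask has no foreground pixels")
  h <- nrow(mask); w <- ncol(mask)
  heights <- integer(w)
  best_area <- 0L; best <- NULL
  for (r in seq_len(h)) {
    heights <- ifelse(mask[r, ], heights + 1L, 0L)
    # maximal rectangles with their bottom edge on row r
    stack_col <- integer(0); stack_h <- integer(0)
    for (cpos in seq_len(w + 1L)) {
      cur <- if (cpos <= w) heights[cpos] else 0L
      start <- cpos
      while (length(stack_h) > 0 && stack_h[length(stack_h)] > cur) {
        top_h <- stack_h[length(stack_h)]
        top_c <- stack_col[length(stack_col)]
        stack_h <- stack_h[-length(stack_h)]
        stack_col <- stack_col[-length(stack_col)]
        area <- top_h * (cpos - top_c)
        if (area > best_area ||
            (area == best_area && !is.null(best) &&
             (r - top_h + 1L < best$top ||
              (r - top_h + 1L == best$top && top_c < best$left)))) {
          best_area <- area
          best <- list(top = r - top_h + 1L, left = top_c,
                       height = top_h, width = cpos - top_c)
        }
        start <- top_c
      }
      if (cur > 0 && (length(stack_h) == 0 ||
                      stack_h[length(stack_h)] < cur)) {
        stack_col <- c(stack_col, start)
        stack_h <- c(stack_h, cur)
      }
    }
  }
  rect_region(best$top, best$left, best$height, best$width)
}
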