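# Shared fixtures and independent brute-force oracles.

# small frame used across tests; geometry proportional to the default layout
test_layout <- function(size = 128, white_level = 250) {
  scene_layout(size, size, white_level = white_level)
}

test_params <- function(seed = 42, ...) {
  appearance_params(seed = seed, ...)
}

# one standardized scene, cached per test run
std_test_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lay <- test_layout()
      img <- render_scene(lay, test_params())
      refs <- locate_references(img, layout_hint = lay)
      cache <<- list(layout = lay, raw = img,
                     std = standardize_image(img, refs))
    }
    cache
  }
})

iou <- function(a, b) sum(a & b) / sum(a | b)

rect_to_mask <- function(rect, h, w) {
  m <- matrix(FALSE, h, w)
  m[rect_rows(rect), rect_cols(rect)] <- TRUE
  m
}

# exhaustive maximal all-ones rectangle area via an integral image
brute_max_rect_area <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  S <- matrix(0, h + 1, w + 1)
  S[-1, -1] <- t(apply(apply(mask, 2, cumsum), 1, cumsum))
  best <- 0L
  for (t in 1:h) for (l in 1:w) for (b in t:h) for (r in l:w) {
    area <- (b - t + 1L) * (r - l + 1L)
    if (area > best &&
        S[b + 1, r + 1] - S[t, r + 1] - S[b + 1, l] + S[t, l] == area) {
      best <- area
    }
  }
  best
}

# brute-force symmetric normalized co-occurrence matrix by explicit pair
# enumeration
brute_glcm <- function(q, levels, dr, dc) {
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (r in 1:h) for (c in 1:w) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
      i <- q[r, c] + 1L; j <- q[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  counts / sum(counts)
}

# F quantile through the beta-distribution relation, independent of qf()
qf_via_beta <- function(p, d1, d2) {
  b <- qbeta(p, d1 / 2, d2 / 2)
  (d2 / d1) * b / (1 - b)
}

# a quick design small enough for full pipeline runs
small_design <- function(control_times = c(0, 3), replicates = 2,
                         controls = FALSE) {
  study_design(
    maps = "MAP1",
    conditions = treatment_condition("TC2", 40, 6, 15),
    center_replicates = 1,
    control_times = control_times,
    replicates = replicates,
    controls = controls)
}
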