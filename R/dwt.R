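# Orthonormal periodized discrete wavelet transform, 1-D and 2-D.
#
# Decomposition filters (analysis lowpass h, highpass g by the usual
# alternating-flip construction). "haar" and the 8-tap Daubechies filter
# ("db4", four vanishing moments) are supported; the constants are the
# published Daubechies coefficients.

wavelet_filters <- function(family = c("db4", "haar")) {
  family <- match.arg(family)
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    db4 = c(-0.010597401785069032, 0.032883011666885197,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.63088076792985892,
            0.71484657055291567, 0.23037781330889651)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, length = L)
}

# one periodized analysis step on an even-length signal; returns approx and
# detail coefficients of length n/2
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- filt$length
  # x circularly extended; coefficient k uses samples (2k-1, 2k, ...) so the
  # transform is orthonormal on the circle
  idx <- outer(seq(1, n, by = 2), seq_len(L) - 1L, "+")
  idx <- ((idx - 1L) %% n) + 1L
  xm <- matrix(x[idx], ncol = L)
  list(a = as.numeric(xm %*% filt$h), d = as.numeric(xm %*% filt$g))
}

idwt_step <- function(a, d, filt) {
  n2 <- length(a)
  n <- 2L * n2
  L <- filt$length
  x <- numeric(n)
  pos <- seq(1, n, by = 2)
  for (j in seq_len(L)) {
    tgt <- ((pos + j - 2L) %% n) + 1L
    contrib <- a * filt$h[j] + d * filt$g[j]
    x[tgt] <- x[tgt] + contrib
  }
  x
}

# single-level 2-D step: filter along rows (dim 1), then along columns.
# Returns LL plus the three detail subbands: H (horizontal detail:
# low along rows, high along columns), V (vertical detail) and D (diagonal).
dwt2_step <- function(m, filt) {
  h <- nrow(m); w <- ncol(m)
  lo <- matrix(0, h / 2, w); hi <- matrix(0, h / 2, w)
  for (j in seq_len(w)) {
    s <- dwt_step(m[, j], filt)
    lo[, j] <- s$a; hi[, j] <- s$d
  }
  ll <- matrix(0, h / 2, w / 2); lh <- matrix(0, h / 2, w / 2)
  hl <- matrix(0, h / 2, w / 2); hh <- matrix(0, h / 2, w / 2)
  for (i in seq_len(h / 2)) {
    s <- dwt_step(lo[i, ], filt)
    ll[i, ] <- s$a; lh[i, ] <- s$d
    s <- dwt_step(hi[i, ], filt)
    hl[i, ] <- s$a; hh[i, ] <- s$d
  }
  list(LL = ll, H = lh, V = hl, D = hh)
}

idwt2_step <- function(bands, filt) {
  h2 <- nrow(bands$LL); w2 <- ncol(bands$LL)
  lo <- matrix(0, h2, 2L * w2); hi <- matrix(0, h2, 2L * w2)
  for (i in seq_len(h2)) {
    lo[i, ] <- idwt_step(bands$LL[i, ], bands$H[i, ], filt)
    hi[i, ] <- idwt_step(bands$V[i, ], bands$D[i, ], filt)
  }
  m <- matrix(0, 2L * h2, 2L * w2)
  for (j in seq_len(2L * w2)) {
    m[, j] <- idwt_step(lo[, j], hi[, j], filt)
  }
  m
}

#' Multi-level 2-D discrete wavelet transform
#'
#' Orthonormal, periodized (circular boundary) 2-D DWT. Both matrix
#' dimensions must be divisible by `2^levels`. At each level the
#' approximation band is decomposed further; the three detail subbands are
#' returned per level: `H` (horizontal detail), `V` (vertical detail), `D`
#' (diagonal detail).
#'
#' @param m Numeric matrix.
#' @param levels Decomposition depth.
#' @param family Wavelet family, `"db4"` (8-tap Daubechies, default) or
#'   `"haar"`.
#' @return A list with `approx` (the final LL band) and `detail`, a list of
#'   `levels` elements each holding matrices `H`, `V`, `D`.
#' @seealso [idwt2()] for the exact inverse.
#' @export
dwt2 <- function(m, levels = 1, family = "db4") {
  if (nrow(m) %% 2^levels != 0 || ncol(m) %% 2^levels != 0) {
    stop_vqc("decomposition_depth",
             sprintf("matrix %dx%d is not divisible by 2^%d",
                     nrow(m), ncol(m), levels))
  }
  filt <- wavelet_filters(family)
  detail <- vector("list", levels)
  cur <- m
  for (lv in seq_len(levels)) {
    s <- dwt2_step(cur, filt)
    detail[[lv]] <- s[c("H", "V", "D")]
    cur <- s$LL
  }
  list(approx = cur, detail = detail, family = family, levels = levels)
}

#' Inverse multi-level 2-D discrete wavelet transform
#'
#' Exact inverse of [dwt2()] (the transform is orthonormal).
#'
#' @param decomp The list returned by [dwt2()].
#' @return The reconstructed matrix.
#' @export
idwt2 <- function(decomp) {
  filt <- wavelet_filters(decomp$family)
  cur <- decomp$approx
  for (lv in rev(seq_len(decomp$levels))) {
    bands <- decomp$detail[[lv]]
    bands$LL <- cur
    cur <- idwt2_step(bands, filt)
  }
  cur
}
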