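toy_features <- function(n = 50, p = 10, seed = 17) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(seq(p, 1)))
  })
  colnames(x) <- sprintf("col_f%02d", seq_len(p))
  x
}

test_that("an exact low-rank model has zero calibration residuals", {
  withr::with_seed(2, {
    scores <- matrix(rnorm(40), 20, 2)
    w <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  })
  x <- scores %*% t(w) + matrix(rep(c(5, 2, -1, 0, 3), each = 20), 20, 5)
  colnames(x) <- sprintf("col_f%d", 1:5)
  m <- fit_pca(x, ncomp = 2)
  expect_lt(max(m$calibration$q), 1e-20)
  expect_equal(m$q_lim, 0)
})

test_that("loadings are orthonormal and score variances match the eigen oracle", {
  x <- toy_features()
  m <- fit_pca(x, ncomp = 3)
  expect_equal(t(m$loadings) %*% m$loadings, diag(3))
  ev <- eigen(stats::cov(scale(x)))
  expect_equal(unname(m$score_variances), ev$values[1:3])
})

test_that("T2 and Q match the dense eigendecomposition oracle", {
  x <- toy_features(n = 50, p = 10)
  m <- fit_pca(x, ncomp = 3)
  z <- scale(x)
  ev <- eigen(stats::cov(z))
  P <- ev$vectors[, 1:3]
  sc <- z %*% P
  t2_oracle <- rowSums(sweep(sc^2, 2, ev$values[1:3], "/"))
  q_oracle <- rowSums((z - sc %*% t(P))^2)
  pts <- project_samples(m, x)
  expect_equal(pts$t2, unname(t2_oracle), tolerance = 1e-10)
  expect_equal(pts$q, unname(q_oracle), tolerance = 1e-10)
})

test_that("projection has the documented closed forms", {
  x <- toy_features()
  m <- fit_pca(x, ncomp = 3)
  # the calibration mean projects to the origin
  ctr <- matrix(m$center, 1, dimnames = list(NULL, m$feature_names))
  p0 <- project_samples(m, ctr)
  expect_equal(p0$t2, 0)
  expect_equal(p0$q, 0, tolerance = 1e-20)
  # a scaled vector along the first loading: T2 = c^2 / lambda_1, Q = 0
  cc <- 3
  x1 <- matrix(m$center + m$scale * (cc * m$loadings[, 1]), 1,
               dimnames = list(NULL, m$feature_names))
  p1 <- project_samples(m, x1)
  expect_equal(p1$t2, cc^2 / m$score_variances[1])
  expect_equal(p1$q, 0, tolerance = 1e-12)
  # a vector orthogonal to the loading span: T2 = 0, Q = |z|^2
  withr::with_seed(3, v <- rnorm(length(m$feature_names)))
  v <- v - m$loadings %*% (t(m$loadings) %*% v)
  v <- v / sqrt(sum(v^2)) * 2.5
  x2 <- matrix(m$center + m$scale * as.numeric(v), 1,
               dimnames = list(NULL, m$feature_names))
  p2 <- project_samples(m, x2)
  expect_equal(p2$t2, 0, tolerance = 1e-12)
  expect_equal(p2$q, 2.5^2)
})

test_that("statistics are invariant to row order and feature permutation", {
  x <- toy_features()
  m1 <- fit_pca(x, ncomp = 3)
  m2 <- fit_pca(x[sample(nrow(x)), ], ncomp = 3)
  expect_equal(m1$t2_lim, m2$t2_lim)
  expect_equal(m1$q_lim, m2$q_lim)
  pts1 <- project_samples(m1, x)
  perm <- x[, sample(ncol(x)), drop = FALSE]
  pts2 <- project_samples(m1, perm)
  expect_equal(pts1$t2, pts2$t2)
  expect_equal(pts1$q, pts2$q)
})

test_that("the T2 limit follows the F form and its chi-square limit", {
  # A = 1, O large: converges to the 0.95 chi-square(1) quantile
  expect_equal(t2_limit(1, 1e7, 0.05), qchisq(0.95, 1), tolerance = 1e-4)
  # A = 7, O = 336 against an independent beta-relation F quantile
  expect_equal(t2_limit(7, 336, 0.05),
               7 * 335 / 329 * qf_via_beta(0.95, 7, 329), tolerance = 1e-10)
  # A = 1, O = 3: multiplier A(O-1)/(O-A) = 1
  expect_equal(t2_limit(1, 3, 0.5), qf_via_beta(0.5, 1, 2),
               tolerance = 1e-10)
  # the new-observation form carries the (O + 1) / O factor
  expect_equal(t2_limit(7, 336, 0.05, form = "new") / t2_limit(7, 336, 0.05),
               337 / 336)
  expect_error(t2_limit(7, 5), class = "visionqc_degrees_of_freedom")
})

test_that("the Q limit follows the Box chi-square form", {
  # mu = 5, nu = 10: g = 1, h = 5
  expect_equal(q_limit(5, 10, 0.05), qchisq(0.95, 5))
  # scaling identity of the Box form
  cc <- 2.5
  expect_equal(q_limit(cc * 5, cc^2 * 10), cc * q_limit(5, 10))
  # vanishing residual variance concentrates the limit at mu
  expect_equal(q_limit(5, 1e-10), 5, tolerance = 1e-3)
  # sd parameterization squares nu internally
  expect_equal(q_limit(5, sqrt(10), nu_is = "sd"), q_limit(5, 10))
  expect_error(q_limit(-1, 2), class = "visionqc_moment")
})

test_that("conformance summaries count rejections per group", {
  pts <- tibble::tibble(
    condition = rep(c("TC1", "TC2"), c(12, 4)),
    storage_day = 3,
    t2 = 1, q = 1,
    conform = c(rep(FALSE, 11), TRUE, rep(FALSE, 4)))
  out <- conformance_test(pts)
  tc1 <- out[out$condition == "TC1", ]
  expect_equal(tc1$n_reject, 11)
  expect_equal(tc1$rejection_pct, 91.7)  # 11 of 12 rejected
  expect_equal(out$rejection_pct[out$condition == "TC2"], 100)
  expect_error(conformance_test(pts[0, ]), class = "visionqc_empty_group")
})

test_that("a sample exactly at a limit does not conform (strict inequality)", {
  model <- structure(
    list(center = c(a = 0, b = 0), scale = c(a = 1, b = 1),
         loadings = matrix(c(1, 0), 2, 1, dimnames = list(c("a", "b"), NULL)),
         score_variances = 1, ncomp = 1L, n_calib = 100,
         q_mean = 1, q_var = 1, alpha = 0.05,
         t2_lim = 4, q_lim = 1, feature_names = c("a", "b"),
         dropped = character(0), scaled = TRUE, q_nu = "variance"),
    class = "pca_mspc")
  x <- matrix(c(2, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  pts <- project_samples(model, x)
  expect_equal(pts$t2, c(4, 0, 1))
  expect_equal(pts$q, c(0, 1, 0))
  expect_equal(pts$conform, c(FALSE, FALSE, TRUE))
})

test_that("zero-variance features are dropped and recorded", {
  x <- toy_features(n = 30, p = 6)
  x[, 2] <- 7
  expect_message(m <- fit_pca(x, ncomp = 2),
                 class = "visionqc_zero_variance")
  expect_equal(m$dropped, colnames(x)[2])
  pts <- project_samples(m, x)
  expect_equal(nrow(pts), 30)
})

test_that("models round-trip through JSON serialization", {
  x <- toy_features()
  m <- fit_pca(x, ncomp = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(m, path)
  m2 <- read_pca_model(path)
  expect_equal(m2$t2_lim, m$t2_lim)
  expect_equal(m2$q_lim, m$q_lim)
  expect_equal(unname(m2$loadings), unname(m$loadings))
  pts1 <- project_samples(m, x)
  pts2 <- project_samples(m2, x)
  expect_equal(pts1$t2, pts2$t2)
  expect_equal(pts1$q, pts2$q)
})

test_that("tidy, glance and autoplot methods work on fitted models", {
  x <- toy_features()
  m <- fit_pca(x, ncomp = 3)
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$prop_retained), 1)
  gl <- glance(m)
  expect_equal(gl$ncomp, 3)
  expect_equal(gl$t2_lim, m$t2_lim)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
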