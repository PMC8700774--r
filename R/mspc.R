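feature_cols_of <- function(data) {
  grep("^(col|wav|glcm)_", names(data), value = TRUE)
}

# coerce a features tibble (or plain matrix) to the numeric feature matrix
# plus the metadata columns
as_feature_matrix <- function(data, feature_cols = NULL) {
  if (is.matrix(data)) {
    x <- data
    if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
    return(list(x = x, meta = tibble(.rows = nrow(x))))
  }
  if (is.null(feature_cols)) {
    feature_cols <- feature_cols_of(data)
    if (length(feature_cols) == 0) {
      feature_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    }
  }
  x <- as.matrix(data[, feature_cols, drop = FALSE])
  meta <- data[, setdiff(names(data), feature_cols), drop = FALSE]
  list(x = x, meta = as_tibble(meta))
}

#' Hotelling's T-squared control limit
#'
#' The calibration-form F-distribution limit
#' `A (O - 1) / (O - A) * F_{A, O-A; 1-alpha}`. The alternative
#' new-observation form `A (O^2 - 1) / (O (O - A)) * F` is available via
#' `form = "new"`; at calibration sizes in the hundreds the two differ by a
#' factor `(O + 1) / O`.
#'
#' @param ncomp Number of retained principal components (A).
#' @param n Number of calibration samples (O).
#' @param alpha Significance level (default 0.05 for 95% limits).
#' @param form `"calibration"` (default) or `"new"`.
#' @return The T-squared limit (a positive number).
#' @export
t2_limit <- function(ncomp, n, alpha = 0.05, form = c("calibration", "new")) {
  form <- match.arg(form)
  if (n <= ncomp) {
    stop_vqc("degrees_of_freedom",
             "need more calibration samples than components")
  }
  if (alpha <= 0 || alpha >= 1) stop_vqc("alpha", "alpha must be in (0, 1)")
  f <- qf(1 - alpha, ncomp, n - ncomp)
  mult <- switch(form,
                 calibration = ncomp * (n - 1) / (n - ncomp),
                 new = ncomp * (n^2 - 1) / (n * (n - ncomp)))
  mult * f
}

#' Q-residual (squared prediction error) control limit
#'
#' The Box-type weighted chi-squared approximation
#' `(nu / (2 mu)) * chisq_{2 mu^2 / nu; 1-alpha}` where `mu` is the mean of
#' the calibration Q residuals and `nu` their variance. If the residual
#' spread is supplied as a standard deviation, set `nu_is = "sd"` and it is
#' squared internally.
#'
#' @param mu Mean of the calibration Q residuals (must be positive).
#' @param nu Variance of the calibration Q residuals (or their SD when
#'   `nu_is = "sd"`); must be positive.
#' @param alpha Significance level.
#' @param nu_is `"variance"` (default) or `"sd"`.
#' @return The Q limit (a positive number).
#' @export
q_limit <- function(mu, nu, alpha = 0.05, nu_is = c("variance", "sd")) {
  nu_is <- match.arg(nu_is)
  if (mu <= 0 || nu <= 0) {
    stop_vqc("moment", "mu and nu must both be positive")
  }
  if (nu_is == "sd") nu <- nu^2
  g <- nu / (2 * mu)
  h <- 2 * mu^2 / nu
  g * qchisq(1 - alpha, df = h)
}

#' Fit the fresh-reference PCA monitoring model
#'
#' Autoscales the calibration feature matrix (mean-centered, unit sample
#' variance; zero-variance columns are dropped and recorded), extracts the
#' top `ncomp` principal directions by SVD, and derives the Hotelling's
#' T-squared and Q-residual control limits at significance `alpha`
#' ([t2_limit()], [q_limit()]).
#'
#' @param data Features: a tibble whose feature columns are named `col_*`,
#'   `wav_*`, `glcm_*` (other columns are treated as metadata), or a plain
#'   numeric matrix.
#' @param ncomp Number of principal components to retain (A, default 7).
#' @param alpha Significance level of the control limits (default 0.05).
#' @param scale Autoscale to unit variance (default `TRUE`); `FALSE` only
#'   mean-centers.
#' @param feature_cols Optional explicit feature column names.
#' @param q_nu Interpretation of the residual spread entering the Q limit:
#'   `"variance"` (default, the Box form) or `"sd"`.
#' @return An object of class `pca_mspc` with elements `center`, `scale`,
#'   `loadings` (M x A, orthonormal columns), `score_variances`, `ncomp`,
#'   `n_calib`, `q_mean`, `q_var`, `alpha`, `t2_lim`, `q_lim`,
#'   `feature_names`, `dropped` (zero-variance columns) and `calibration`
#'   (per-sample T-squared/Q of the calibration set).
#' @export
fit_pca <- function(data, ncomp = 7, alpha = 0.05, scale = TRUE,
                    feature_cols = NULL, q_nu = c("variance", "sd")) {
  q_nu <- match.arg(q_nu)
  fm <- as_feature_matrix(data, feature_cols)
  x <- fm$x
  n <- nrow(x)
  if (n < ncomp + 2) {
    stop_vqc("rank", "need at least ncomp + 2 calibration samples")
  }
  center <- colMeans(x)
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  dropped <- colnames(x)[!keep]
  if (length(dropped) > 0) {
    rlang::inform(sprintf("dropping %d zero-variance feature(s)",
                          length(dropped)),
                  class = "visionqc_zero_variance")
  }
  xk <- x[, keep, drop = FALSE]
  scl <- if (scale) sds[keep] else rep(1, sum(keep))
  z <- sweep(sweep(xk, 2, center[keep]), 2, scl, "/")
  sv <- svd(z)
  rank <- sum(sv$d > max(dim(z)) * .Machine$double.eps * sv$d[1])
  if (ncomp > rank) {
    stop_vqc("rank", sprintf("ncomp = %d exceeds the data rank (%d)",
                             ncomp, rank))
  }
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  rownames(loadings) <- colnames(xk)
  scores <- z %*% loadings
  lambda <- apply(scores, 2, var)

  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  resid <- z - scores %*% t(loadings)
  q <- rowSums(resid^2)
  q_mean <- mean(q)
  q_var <- var(q)

  model <- structure(
    list(center = center[keep], scale = scl, loadings = loadings,
         score_variances = lambda, ncomp = as.integer(ncomp),
         n_calib = n, q_mean = q_mean, q_var = q_var, alpha = alpha,
         t2_lim = t2_limit(ncomp, n, alpha),
         # a model that reconstructs the data exactly has no residual
         # distribution to set a limit from
         q_lim = if (q_mean > 0 && q_var > 0) {
           q_limit(q_mean, if (q_nu == "variance") q_var else sqrt(q_var),
                   alpha, nu_is = q_nu)
         } else 0,
         feature_names = colnames(xk), dropped = dropped,
         scaled = scale, q_nu = q_nu),
    class = "pca_mspc"
  )
  model$calibration <- dplyr::bind_cols(
    fm$meta, tibble(t2 = t2, q = q,
                    conform = t2 < model$t2_lim & q < model$q_lim))
  model
}

#' @export
print.pca_mspc <- function(x, ...) {
  cat(sprintf("PCA monitoring model: %d components, %d calibration samples, %d features\n",
              x$ncomp, x$n_calib, length(x$feature_names)))
  cat(sprintf("limits (alpha = %g): T2 < %.4g, Q < %.4g\n",
              x$alpha, x$t2_lim, x$q_lim))
  invisible(x)
}

#' Project samples onto the monitoring model
#'
#' Computes each sample's Hotelling's T-squared (Mahalanobis distance of its
#' scores from the calibration mean) and Q residual (squared norm of the part
#' of the scaled sample outside the model plane), and the conformance
#' verdict: a sample conforms when **both** statistics fall strictly below
#' their limits.
#'
#' Feature columns are matched to the model by name, so column order in
#' `data` is irrelevant.
#'
#' @param model A fitted [fit_pca()] model.
#' @param data Features tibble or matrix (same conventions as [fit_pca()]).
#' @param feature_cols Optional explicit feature column names.
#' @return A tibble: the metadata columns of `data` plus `t2`, `q`,
#'   `conform`.
#' @export
project_samples <- function(model, data, feature_cols = NULL) {
  fm <- as_feature_matrix(data, feature_cols)
  x <- fm$x
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing) > 0) {
    stop_vqc("feature_map",
             sprintf("%d model feature(s) absent from the data (first: %s)",
                     length(missing), missing[1]))
  }
  x <- x[, model$feature_names, drop = FALSE]
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  scores <- z %*% model$loadings
  t2 <- rowSums(sweep(scores^2, 2, model$score_variances, "/"))
  resid <- z - scores %*% t(model$loadings)
  q <- rowSums(resid^2)
  dplyr::bind_cols(
    fm$meta,
    tibble(t2 = t2, q = q, conform = t2 < model$t2_lim & q < model$q_lim))
}

#' @export
predict.pca_mspc <- function(object, newdata, ...) {
  project_samples(object, newdata, ...)
}

#' Per-group conformance summary
#'
#' Counts rejections of the fresh-appearance null hypothesis per group. A
#' sample is rejected when T-squared or Q meets or exceeds its limit.
#'
#' @param points Chart-point tibble from [project_samples()].
#' @param group_cols Grouping columns present in `points` (default
#'   condition and storage day, dropping those absent).
#' @return A tibble with the grouping columns, `n`, `n_reject`, `rejection`
#'   (fraction) and `rejection_pct` (percent, one decimal).
#' @export
conformance_test <- function(points,
                             group_cols = c("condition", "storage_day")) {
  if (nrow(points) == 0) stop_vqc("empty_group", "no samples to summarize")
  group_cols <- intersect(group_cols, names(points))
  points |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_reject = sum(!.data$conform),
      rejection = .data$n_reject / .data$n,
      rejection_pct = round(100 * .data$n_reject / .data$n, 1),
      .groups = "drop")
}

#' Tidy a PCA monitoring model
#'
#' Per-component summary: score variance (lambda) and the share of retained
#' variance per component.
#'
#' @param x A `pca_mspc` model from [fit_pca()].
#' @param ... Unused.
#' @return A tibble with one row per retained component.
#' @export
tidy.pca_mspc <- function(x, ...) {
  tibble(component = seq_len(x$ncomp),
         score_variance = x$score_variances,
         prop_retained = x$score_variances / sum(x$score_variances))
}

#' One-row summary of a PCA monitoring model
#'
#' @param x A `pca_mspc` model from [fit_pca()].
#' @param ... Unused.
#' @return A one-row tibble of model dimensions, moments and limits.
#' @export
glance.pca_mspc <- function(x, ...) {
  tibble(ncomp = x$ncomp, n_calib = x$n_calib,
         n_features = length(x$feature_names),
         n_dropped = length(x$dropped), alpha = x$alpha,
         t2_lim = x$t2_lim, q_lim = x$q_lim,
         q_mean = x$q_mean, q_var = x$q_var)
}

#' Control chart of T-squared versus Q
#'
#' Scatter of chart points with dashed lines at the model's control limits;
#' samples inside the lower-left box conform to the fresh reference.
#'
#' @param points Chart points from [project_samples()] (the model's
#'   calibration set is drawn in gray as the fresh reference).
#' @param model The fitted [fit_pca()] model.
#' @param color Optional name of a column in `points` to color by.
#' @param log_axes Draw both axes on log10 scale (default `TRUE`; deviations
#'   span orders of magnitude).
#' @return A ggplot object.
#' @export
plot_control_chart <- function(points, model, color = NULL,
                               log_axes = TRUE) {
  calib <- model$calibration
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$t2, y = .data$q)) +
    ggplot2::geom_point(data = calib, color = "gray60", shape = 15,
                        alpha = 0.6) +
    ggplot2::geom_hline(yintercept = model$q_lim, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = model$t2_lim, linetype = "dashed") +
    ggplot2::labs(x = expression(T^2), y = "Q (squared prediction error)")
  p <- if (is.null(color)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data[[color]]))
  }
  if (log_axes) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Control chart of a fitted monitoring model
#'
#' Autoplot method drawing the calibration control chart (see
#' [plot_control_chart()]).
#'
#' @param object A `pca_mspc` model from [fit_pca()].
#' @param ... Passed on to [plot_control_chart()].
#' @return A ggplot object.
#' @export
autoplot.pca_mspc <- function(object, ...) {
  plot_control_chart(object$calibration, object, ...)
}

#' Serialize a monitoring model to JSON
#'
#' Writes every model component (centering/scaling vectors, loadings, score
#' variances, residual moments, limits, feature names, dropped columns) as
#' JSON so a model can be stored and reloaded without R serialization.
#'
#' @param model A [fit_pca()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pca_model <- function(model, path) {
  payload <- list(
    center = model$center, scale = model$scale,
    loadings = model$loadings, score_variances = model$score_variances,
    ncomp = model$ncomp, n_calib = model$n_calib,
    q_mean = model$q_mean, q_var = model$q_var, alpha = model$alpha,
    t2_lim = model$t2_lim, q_lim = model$q_lim,
    feature_names = model$feature_names, dropped = model$dropped,
    scaled = model$scaled, q_nu = model$q_nu)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized monitoring model
#'
#' @param path Path written by [write_pca_model()].
#' @return A `pca_mspc` model (without the calibration chart points).
#' @export
read_pca_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- as.matrix(p$loadings)
  rownames(loadings) <- p$feature_names
  structure(
    list(center = setNames(p$center, p$feature_names),
         scale = setNames(p$scale, p$feature_names),
         loadings = loadings, score_variances = p$score_variances,
         ncomp = as.integer(p$ncomp), n_calib = p$n_calib,
         q_mean = p$q_mean, q_var = p$q_var, alpha = p$alpha,
         t2_lim = p$t2_lim, q_lim = p$q_lim,
         feature_names = p$feature_names,
         dropped = as.character(p$dropped %||% character(0)),
         scaled = p$scaled, q_nu = p$q_nu, calibration = NULL),
    class = "pca_mspc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
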