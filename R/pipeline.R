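#' Run a full simulated appearance-monitoring study
#'
#' End-to-end orchestration: enumerate the design, render every image,
#' standardize it against the in-scene references, segment the sample ROI,
#' extract the appearance descriptor, calibrate the PCA monitoring model on
#' the fresh-state images only, project every treated and control image, and
#' summarize rejections per (state, condition, storage day). Images are
#' processed one at a time, so memory stays flat in the cohort size. Fully
#' reproducible given `seed`.
#'
#' @param design A [study_design()].
#' @param effects An [effect_model()] or `NULL`.
#' @param layout A [scene_layout()].
#' @param population An [appearance_population()].
#' @param config A [feature_config()].
#' @param ncomp,alpha Monitoring model settings (defaults 7 and 0.05).
#' @param seed Integer cohort seed.
#' @param segment_args Extra arguments passed to [segment_roi()].
#' @return An object of class `vqc_study`: a list with `inventory`,
#'   `features` (one row per image: metadata plus 2576 feature columns),
#'   `model` (the fitted `pca_mspc`), `chart` (chart points for all
#'   non-fresh images) and `rejections` (per-group summary).
#' @export
run_study <- function(design, effects = NULL, layout = scene_layout(),
                      population = appearance_population(),
                      config = feature_config(), ncomp = 7, alpha = 0.05,
                      seed = 1L, segment_args = list()) {
  cp <- cohort_params(design, effects, population, seed)
  inv <- cp$images

  feat_rows <- purrr::map(seq_len(nrow(inv)), function(i) {
    rec <- inv[i, ]
    img <- render_record(layout, rec)
    refs <- locate_references(img, layout_hint = layout)
    std <- standardize_image(img, refs)
    mask <- rlang::exec(segment_roi, std,
                        seed = rec$img_seed, !!!segment_args)
    vec <- extract_features(std, mask, config = config)
    dplyr::bind_cols(
      tibble(image_id = rec$image_id, map = rec$map,
             condition = rec$condition, run = rec$run,
             replicate = rec$replicate, slice = rec$slice,
             event = rec$event, storage_day = rec$storage_day,
             state = rec$state),
      as_tibble(as.list(vec)))
  })
  features <- dplyr::bind_rows(feat_rows)

  fresh <- dplyr::filter(features, .data$state == "fresh")
  if (nrow(fresh) == 0) {
    stop_vqc("pipeline", "the design yields no fresh-state calibration images")
  }
  model <- fit_pca(fresh, ncomp = ncomp, alpha = alpha)

  scored <- dplyr::filter(features, .data$state != "fresh")
  chart <- if (nrow(scored) > 0) project_samples(model, scored) else NULL
  rejections <- if (!is.null(chart)) {
    conformance_test(chart, group_cols = c("state", "condition",
                                           "storage_day"))
  } else NULL

  structure(list(inventory = inv, features = features, model = model,
                 chart = chart, rejections = rejections, seed = seed),
            class = "vqc_study")
}

#' @export
print.vqc_study <- function(x, ...) {
  cat(sprintf("Appearance-monitoring study: %d images (%d fresh calibration)\n",
              nrow(x$inventory), sum(x$inventory$state == "fresh")))
  print(x$model)
  if (!is.null(x$rejections)) {
    cat("rejection summary:\n")
    print(x$rejections, n = 20)
  }
  invisible(x)
}

#' Microbial log reduction
#'
#' The decimal log reduction `log10(N / N0)` of viable counts after a
#' treatment, where `N0` is the untreated count and `N` the survivor count
#' (both CFU/g). Survivor counts below the plating detection limit are
#' censored: the reported value is the bound `log10(detection_limit / N0)`
#' and the result is flagged with a `"< value"` label.
#'
#' @param n Survivor count, CFU/g (vectorized).
#' @param n0 Untreated count, CFU/g; must be positive.
#' @param detection_limit Detection limit of the count, CFU/g (default 0 =
#'   no censoring).
#' @return A tibble with columns `n`, `n0`, `log_reduction`, `censored`,
#'   `label`.
#' @export
log_reduction <- function(n, n0, detection_limit = 0) {
  if (any(n0 <= 0)) stop_vqc("domain", "n0 must be positive")
  if (any(n < 0)) stop_vqc("domain", "n must be non-negative")
  censored <- n < detection_limit
  value <- ifelse(censored, log10(detection_limit / n0), log10(n / n0))
  tibble(
    n = n, n0 = n0, log_reduction = value, censored = censored,
    label = ifelse(censored, sprintf("< %.3g", value), sprintf("%.3g", value)))
}
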