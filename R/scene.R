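#' Rectangular region
#'
#' A rectangle in image coordinates. Coordinates are 1-based and inclusive:
#' the region spans rows `top ... top + height - 1` and columns
#' `left ... left + width - 1`, matching R's matrix indexing.
#'
#' @param top,left First row / column of the rectangle (1-based).
#' @param height,width Extent in rows / columns; both must be `>= 1`.
#' @return An object of class `rect_region`.
#' @export
rect_region <- function(top, left, height, width) {
  if (height < 1 || width < 1) {
    stop_vqc("invalid_rect", "rectangle height and width must be >= 1")
  }
  structure(
    list(top = as.integer(top), left = as.integer(left),
         height = as.integer(height), width = as.integer(width)),
    class = "rect_region"
  )
}

rect_rows <- function(r) seq(r$top, r$top + r$height - 1L)
rect_cols <- function(r) seq(r$left, r$left + r$width - 1L)

rects_overlap <- function(a, b) {
  !(a$top + a$height - 1L < b$top || b$top + b$height - 1L < a$top ||
      a$left + a$width - 1L < b$left || b$left + b$width - 1L < a$left)
}

# does an axis-aligned rectangle intersect a disc?
rect_disc_overlap <- function(r, center, radius) {
  cr <- pmin(pmax(center[1], r$top), r$top + r$height - 1L)
  cc <- pmin(pmax(center[2], r$left), r$left + r$width - 1L)
  (cr - center[1])^2 + (cc - center[2])^2 < radius^2
}

#' Scene layout
#'
#' Geometry of a synthetic imaging scene: a circular food-sample disc on a
#' black background, a uniform white reflectance reference, a designated
#' black-reference patch (part of the background) and a dimensional-indicator
#' tile. All regions must be pairwise disjoint and the disc must lie fully
#' inside the frame. The default geometry scales proportionally with the
#' frame size.
#'
#' @param height,width Frame size in pixels (default 512 x 512).
#' @param disc_center Numeric `(row, col)` of the sample disc center.
#' @param disc_radius Disc radius in pixels.
#' @param white_ref,black_ref,indicator [rect_region()] objects.
#' @param white_level,black_level Nominal 8-bit intensities of the white and
#'   black references as rendered (defaults 250 and 5).
#' @return An object of class `scene_layout`.
#' @export
scene_layout <- function(height = 512, width = 512,
                         disc_center = c(0.5, 0.42) * c(height, width),
                         disc_radius = 0.27 * min(height, width),
                         white_ref = rect_region(
                           top = max(1, round(0.06 * height)),
                           left = round(0.72 * width),
                           height = round(0.16 * height),
                           width = round(0.20 * width)),
                         black_ref = rect_region(
                           top = round(0.80 * height),
                           left = round(0.74 * width),
                           height = round(0.13 * height),
                           width = round(0.18 * width)),
                         indicator = rect_region(
                           top = round(0.84 * height),
                           left = max(1, round(0.06 * width)),
                           height = round(0.11 * height),
                           width = round(0.22 * width)),
                         white_level = 250, black_level = 5) {
  layout <- structure(
    list(height = as.integer(height), width = as.integer(width),
         disc_center = as.numeric(disc_center),
         disc_radius = as.numeric(disc_radius),
         white_ref = white_ref, black_ref = black_ref, indicator = indicator,
         white_level = white_level, black_level = black_level),
    class = "scene_layout"
  )
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  if (layout$disc_radius <= 0) {
    stop_vqc("layout", "disc_radius must be > 0")
  }
  ctr <- layout$disc_center
  r <- layout$disc_radius
  if (ctr[1] - r < 1 || ctr[1] + r > layout$height ||
      ctr[2] - r < 1 || ctr[2] + r > layout$width) {
    stop_vqc("layout", "sample disc extends outside the frame")
  }
  regions <- list(layout$white_ref, layout$black_ref, layout$indicator)
  for (rg in regions) {
    if (rg$top < 1 || rg$left < 1 ||
        rg$top + rg$height - 1L > layout$height ||
        rg$left + rg$width - 1L > layout$width) {
      stop_vqc("layout", "reference region extends outside the frame")
    }
    if (rect_disc_overlap(rg, ctr, r)) {
      stop_vqc("layout", "a reference region overlaps the sample disc")
    }
  }
  for (i in 1:2) for (j in (i + 1):3) {
    if (rects_overlap(regions[[i]], regions[[j]])) {
      stop_vqc("layout", "scene regions overlap")
    }
  }
  invisible(layout)
}

#' Appearance parameters for one rendered sample
#'
#' Controls the rendered look of the sample disc. The disc interior is the
#' base color plus a spatially correlated Gaussian texture field (shared
#' across channels) plus independent per-pixel noise; `whitening_fraction`
#' of the disc area is covered by blotches blended fully toward the scene's
#' white reference level, emulating the surface whitening of dehydrated,
#' lignified vegetable tissue. The whole frame is finally passed through an
#' affine illumination model `gain * I + offset` and quantized to 8 bits.
#'
#' @param base_color RGB triple in `[0, 255]` (default a carrot orange).
#' @param color_noise_sd SD of the independent per-pixel, per-channel noise,
#'   in intensity units.
#' @param texture_correlation_length Correlation length (pixels) of the
#'   Gaussian texture field; 0 disables smoothing (white noise texture).
#' @param texture_amplitude SD of the texture field in intensity units.
#' @param whitening_fraction Fraction of disc area covered by white blotches,
#'   in `[0, 1]`.
#' @param illumination_gain,illumination_offset Frame-wide affine lighting
#'   model; `gain` must be positive.
#' @param seed Integer seed; renders are bit-identical for identical seeds.
#' @return An object of class `appearance_params`.
#' @export
appearance_params <- function(base_color = c(230, 130, 40),
                              color_noise_sd = 8,
                              texture_correlation_length = 6,
                              texture_amplitude = 10,
                              whitening_fraction = 0,
                              illumination_gain = 1,
                              illumination_offset = 0,
                              seed = 1L) {
  if (whitening_fraction < 0 || whitening_fraction > 1) {
    stop_vqc("params", "whitening_fraction must lie in [0, 1]")
  }
  if (illumination_gain <= 0) {
    stop_vqc("params", "illumination_gain must be > 0")
  }
  structure(
    list(base_color = as.numeric(base_color),
         color_noise_sd = color_noise_sd,
         texture_correlation_length = texture_correlation_length,
         texture_amplitude = texture_amplitude,
         whitening_fraction = whitening_fraction,
         illumination_gain = illumination_gain,
         illumination_offset = illumination_offset,
         seed = as.integer(seed)),
    class = "appearance_params"
  )
}

disc_mask <- function(layout) {
  rr <- matrix(seq_len(layout$height), layout$height, layout$width)
  cc <- matrix(seq_len(layout$width), layout$height, layout$width, byrow = TRUE)
  (rr - layout$disc_center[1])^2 + (cc - layout$disc_center[2])^2 <=
    layout$disc_radius^2
}

# zero-mean, unit-variance Gaussian random field with the given correlation
# length (Gaussian-kernel smoothed white noise)
texture_field <- function(h, w, corr_len) {
  z <- matrix(rnorm(h * w), h, w)
  if (corr_len > 0) {
    z <- EBImage::gblur(z, sigma = corr_len)
  }
  s <- stats::sd(as.numeric(z))
  if (s > 0) z <- (z - mean(z)) / s
  z
}

# logical mask of white blotches covering ~frac of the disc area
whitening_mask <- function(layout, frac) {
  h <- layout$height; w <- layout$width
  disc <- disc_mask(layout)
  if (frac >= 1) return(disc)
  mask <- matrix(FALSE, h, w)
  if (frac <= 0) return(mask)
  target <- frac * sum(disc)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(400)) {
    if (sum(mask & disc) >= target) break
    theta <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * layout$disc_radius
    ctr <- layout$disc_center + rad * c(cos(theta), sin(theta))
    br <- runif(1, 0.05, 0.18) * layout$disc_radius
    mask <- mask | ((rr - ctr[1])^2 + (cc - ctr[2])^2 <= br^2)
  }
  mask & disc
}

#' Render a synthetic scene image
#'
#' Draws the scene described by `layout` with the sample appearance in
#' `params`: near-black background, near-white reflectance reference, a
#' checkerboard dimensional indicator and the textured sample disc. Rendering
#' is deterministic given `params$seed`.
#'
#' @param layout A [scene_layout()].
#' @param params An [appearance_params()].
#' @return An `height x width x 3` numeric array with integer values in
#'   `[0, 255]` (8-bit RGB, channel order R, G, B).
#' @export
render_scene <- function(layout, params) {
  validate_layout(layout)
  h <- layout$height; w <- layout$width
  with_seed_local(params$seed, {
    sd_fix <- 2  # fixture noise on background/references
    img <- array(0, dim = c(h, w, 3))
    bg <- matrix(rnorm(h * w, layout$black_level, sd_fix), h, w)
    for (ch in 1:3) img[, , ch] <- bg

    wr <- layout$white_ref
    img[rect_rows(wr), rect_cols(wr), ] <-
      rnorm(wr$height * wr$width * 3, layout$white_level, sd_fix)

    ind <- layout$indicator
    tile <- outer(rect_rows(ind) %/% 8L, rect_cols(ind) %/% 8L, "+") %% 2L
    ind_base <- ifelse(tile == 0L, 120, 190)
    for (ch in 1:3) {
      img[rect_rows(ind), rect_cols(ind), ch] <-
        ind_base + rnorm(length(ind_base), 0, sd_fix)
    }

    disc <- disc_mask(layout)
    n_disc <- sum(disc)
    tex <- texture_field(h, w, params$texture_correlation_length) *
      params$texture_amplitude
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[disc] <- params$base_color[ch] + tex[disc] +
        rnorm(n_disc, 0, params$color_noise_sd)
      img[, , ch] <- plane
    }

    if (params$whitening_fraction > 0) {
      wm <- whitening_mask(layout, params$whitening_fraction)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[wm] <- layout$white_level
        img[, , ch] <- plane
      }
    }

    img <- params$illumination_gain * img + params$illumination_offset
    img[] <- round_half_up(clip8(img))
    img
  })
}

#' Treatment condition
#'
#' One high-pressure CO2 treatment run setting. Values must lie inside the
#' apparatus envelope: 25–50 °C, 4–20 MPa.
#'
#' @param name Condition label.
#' @param temperature Process temperature, °C.
#' @param pressure Process pressure, MPa.
#' @param time Treatment time, minutes.
#' @param center Whether this is the replicated center point of the design.
#' @return A one-row tibble.
#' @export
treatment_condition <- function(name, temperature, pressure, time,
                                center = FALSE) {
  if (temperature < 25 || temperature > 50) {
    stop_vqc("condition", "temperature outside the apparatus envelope (25-50 degC)")
  }
  if (pressure < 4 || pressure > 20) {
    stop_vqc("condition", "pressure outside the apparatus envelope (4-20 MPa)")
  }
  if (time <= 0) stop_vqc("condition", "treatment time must be positive")
  tibble(name = name, temperature = temperature, pressure = pressure,
         time = time, center = center)
}

#' Default treatment plan
#'
#' The half-fraction (2^(3-1)) factorial over temperature (25/40 °C),
#' pressure (6/12 MPa) and time (15/45 min), plus the center point
#' (32.5 °C, 9 MPa, 30 min) which is run in triplicate.
#'
#' @return A tibble with columns `name`, `temperature`, `pressure`, `time`,
#'   `center`.
#' @export
default_conditions <- function() {
  dplyr::bind_rows(
    treatment_condition("TC1", 32.5, 9, 30, center = TRUE),
    treatment_condition("TC2", 40, 6, 15),
    treatment_condition("TC3", 25, 6, 45),
    treatment_condition("TC4", 25, 12, 15),
    treatment_condition("TC5", 40, 12, 45)
  )
}

#' Study design
#'
#' Bookkeeping for a packaging/treatment/storage study: every combination of
#' modified-atmosphere composition (MAP), treatment run and replicate yields
#' one package per control time; each package holds `slices_per_package`
#' sample slices, each imaged `imaging_events_per_package` times (once fresh
#' before packaging, once after treatment/storage). Untreated control
#' packages are added per MAP for each non-zero control time and are imaged
#' on the same two events.
#'
#' With the defaults this reproduces the full study inventory:
#' 3 MAPs x (4 factorial + 3 center) runs x 4 control times x 2 replicates =
#' 168 treated packages, 9 control packages, and (168 + 9) x 4 = 708 images.
#'
#' @param maps Character vector of MAP composition labels.
#' @param conditions Tibble of treatment conditions (see
#'   [default_conditions()]); the `center` condition is replicated
#'   `center_replicates` times as separate runs.
#' @param center_replicates Number of runs of the center condition.
#' @param control_times Storage control times in days; one package is
#'   assigned to each.
#' @param replicates Treatment replicates (parallel vessels).
#' @param slices_per_package,imaging_events_per_package Per-package imaging
#'   inventory.
#' @param controls Whether to add untreated control packages (one per MAP per
#'   non-zero control time).
#' @return An object of class `study_design`.
#' @export
study_design <- function(maps = c("MAP1", "MAP2", "MAP3"),
                         conditions = default_conditions(),
                         center_replicates = 3,
                         control_times = c(0, 3, 7, 14),
                         replicates = 2,
                         slices_per_package = 2,
                         imaging_events_per_package = 2,
                         controls = TRUE) {
  if (!all(c("name", "temperature", "pressure", "time", "center") %in%
             names(conditions))) {
    stop_vqc("design", "conditions must have columns name/temperature/pressure/time/center")
  }
  structure(
    list(maps = maps, conditions = conditions,
         center_replicates = as.integer(center_replicates),
         control_times = control_times,
         replicates = as.integer(replicates),
         slices_per_package = as.integer(slices_per_package),
         imaging_events_per_package = as.integer(imaging_events_per_package),
         controls = isTRUE(controls)),
    class = "study_design"
  )
}

design_runs <- function(design) {
  cond <- design$conditions
  reps <- ifelse(cond$center, design$center_replicates, 1L)
  runs <- cond[rep(seq_len(nrow(cond)), reps), ]
  runs$run <- seq_len(nrow(runs))
  runs
}

#' Enumerate the study inventory
#'
#' Expands a [study_design()] into one record per package and one record per
#' image. Treated packages produce one fresh image and one treated image per
#' slice; control packages are imaged on the same schedule but all their
#' images carry state `"control"`, so fresh-state records come exclusively
#' from treated packages (the calibration population).
#'
#' @param design A [study_design()].
#' @return A list with tibbles `packages` (package_id, map, condition, run,
#'   control_time, replicate, state) and `images` (image_id, package_id, map,
#'   condition, run, replicate, slice, event, storage_day, state).
#' @export
enumerate_design <- function(design) {
  runs <- design_runs(design)
  pkgs <- tidyr::expand_grid(
    map = design$maps,
    run = runs$run,
    control_time = design$control_times,
    replicate = seq_len(design$replicates)
  )
  pkgs$condition <- runs$name[match(pkgs$run, runs$run)]
  pkgs$state <- "treated"
  pkgs$package_id <- sprintf("P%03d", seq_len(nrow(pkgs)))

  if (design$controls) {
    nz <- design$control_times[design$control_times > 0]
    ctrl <- tidyr::expand_grid(map = design$maps, control_time = nz)
    if (nrow(ctrl) > 0) {
      ctrl$run <- NA_integer_
      ctrl$condition <- NA_character_
      ctrl$replicate <- 1L
      ctrl$state <- "control"
      ctrl$package_id <- sprintf("C%02d", seq_len(nrow(ctrl)))
      pkgs <- dplyr::bind_rows(pkgs, ctrl)
    }
  }
  pkgs <- dplyr::select(pkgs, "package_id", "map", "condition", "run",
                        "control_time", "replicate", "state")

  imgs <- tidyr::expand_grid(
    package_id = pkgs$package_id,
    slice = seq_len(design$slices_per_package),
    event = seq_len(design$imaging_events_per_package)
  )
  imgs <- dplyr::left_join(imgs, pkgs, by = "package_id")
  imgs$storage_day <- ifelse(imgs$event == 1L, 0, imgs$control_time)
  imgs$state <- dplyr::case_when(
    imgs$state == "control" ~ "control",
    imgs$event == 1L ~ "fresh",
    TRUE ~ "treated"
  )
  imgs$image_id <- sprintf("%s_s%d_e%d", imgs$package_id, imgs$slice, imgs$event)
  imgs <- dplyr::select(imgs, "image_id", "package_id", "map", "condition",
                        "run", "replicate", "slice", "event", "storage_day",
                        "state")
  list(packages = pkgs, images = imgs)
}

#' Degradation effect model
#'
#' Per (condition, storage day) appearance perturbations applied to treated
#' and control samples on top of their fresh appearance: an RGB color shift,
#' an increment to the whitening fraction, and an increment to the texture
#' amplitude. Severity should be monotone non-decreasing in storage day for
#' each condition; a violation triggers a warning, not an error.
#'
#' Control (untreated, stored) samples are looked up under the condition
#' label `"control"`; conditions or days missing from the table get zero
#' effect.
#'
#' @param table Tibble with columns `condition`, `storage_day`, `dr`, `dg`,
#'   `db` (RGB shift), `whitening_delta`, `texture_delta`.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(table) {
  need <- c("condition", "storage_day", "dr", "dg", "db",
            "whitening_delta", "texture_delta")
  if (!all(need %in% names(table))) {
    stop_vqc("effects", paste("effect table needs columns:",
                              paste(need, collapse = ", ")))
  }
  tab <- as_tibble(table)
  tab$.sev <- sqrt(tab$dr^2 + tab$dg^2 + tab$db^2) +
    255 * pmax(tab$whitening_delta, 0) + abs(tab$texture_delta)
  chk <- tab |>
    dplyr::group_by(.data$condition) |>
    dplyr::arrange(.data$storage_day, .by_group = TRUE) |>
    dplyr::summarise(mono = all(diff(.data$.sev) >= -1e-9), .groups = "drop")
  if (!all(chk$mono)) {
    warn("effect severity is not monotone non-decreasing in storage day",
         class = "visionqc_effects_nonmonotone")
  }
  structure(list(table = dplyr::select(tab, -".sev")), class = "effect_model")
}

#' Linear-in-time effect model
#'
#' Convenience constructor: each listed condition gets an immediate
#' (day-zero) effect plus a per-day drift, both monotone in storage day.
#'
#' @param conditions Character vector of condition labels (use `"control"`
#'   for untreated stored samples).
#' @param days Storage days to tabulate.
#' @param whitening0,whitening_per_day Whitening fraction at day 0 and added
#'   per day of storage.
#' @param color0,color_per_day RGB shift at day 0 and per day (length-3).
#' @param texture0,texture_per_day Texture-amplitude increment at day 0 and
#'   per day.
#' @return An [effect_model()].
#' @export
effect_model_linear <- function(conditions, days,
                                whitening0 = 0, whitening_per_day = 0,
                                color0 = c(0, 0, 0), color_per_day = c(0, 0, 0),
                                texture0 = 0, texture_per_day = 0) {
  tab <- tidyr::expand_grid(condition = conditions, storage_day = days)
  tab$dr <- color0[1] + color_per_day[1] * tab$storage_day
  tab$dg <- color0[2] + color_per_day[2] * tab$storage_day
  tab$db <- color0[3] + color_per_day[3] * tab$storage_day
  tab$whitening_delta <- whitening0 + whitening_per_day * tab$storage_day
  tab$texture_delta <- texture0 + texture_per_day * tab$storage_day
  effect_model(tab)
}

#' Zero-effect model
#' @param days Storage days to tabulate.
#' @param conditions Condition labels (default `"control"` plus the default
#'   treatment plan).
#' @return An [effect_model()] with all-zero perturbations.
#' @export
effect_model_null <- function(days = c(0, 3, 7, 14),
                              conditions = c(default_conditions()$name,
                                             "control")) {
  effect_model_linear(conditions, days)
}

lookup_effect <- function(effects, condition, storage_day) {
  zero <- c(dr = 0, dg = 0, db = 0, whitening_delta = 0, texture_delta = 0)
  if (is.null(effects)) return(zero)
  key <- if (is.na(condition)) "control" else condition
  tab <- effects$table
  hit <- which(tab$condition == key & tab$storage_day == storage_day)
  if (length(hit) == 0) return(zero)
  row <- tab[hit[1], ]
  c(dr = row$dr, dg = row$dg, db = row$db,
    whitening_delta = row$whitening_delta, texture_delta = row$texture_delta)
}

#' Fresh-sample population
#'
#' Distribution of [appearance_params()] across fresh samples: each physical
#' slice draws its own base color, texture amplitude and (slightly varying)
#' illumination gain around the population base. Illumination varies per
#' imaging event, emulating lighting drift between acquisitions.
#'
#' @param base An [appearance_params()] giving the population center.
#' @param color_sd Between-sample SD of each base-color channel.
#' @param texture_amplitude_sd Between-sample SD of the texture amplitude.
#' @param gain_sd Between-image SD of the illumination gain.
#' @return An object of class `appearance_population`.
#' @export
appearance_population <- function(base = appearance_params(),
                                  color_sd = 6,
                                  texture_amplitude_sd = 2,
                                  gain_sd = 0.02) {
  structure(list(base = base, color_sd = color_sd,
                 texture_amplitude_sd = texture_amplitude_sd,
                 gain_sd = gain_sd),
            class = "appearance_population")
}

# Per-image rendering parameters for a whole cohort. Sample-level draws are
# keyed by (package, slice) so the fresh and post-treatment images of one
# slice share their underlying appearance; effects apply to event-2 records
# and to stored control images.
cohort_params <- function(design, effects, population, seed) {
  inv <- enumerate_design(design)
  imgs <- inv$images
  base <- population$base

  sample_key <- paste(imgs$package_id, imgs$slice)
  samples <- unique(sample_key)
  sdraw <- purrr::map(seq_along(samples), function(i) {
    with_seed_local(derive_seed(seed, i), {
      list(base_color = base$base_color + rnorm(3, 0, population$color_sd),
           texture_amplitude = max(0, base$texture_amplitude +
                                     rnorm(1, 0, population$texture_amplitude_sd)))
    })
  })
  names(sdraw) <- samples

  n_clip <- 0L
  rows <- purrr::map(seq_len(nrow(imgs)), function(i) {
    rec <- imgs[i, ]
    sp <- sdraw[[paste(rec$package_id, rec$slice)]]
    eff <- if (rec$event == 1L) {
      c(dr = 0, dg = 0, db = 0, whitening_delta = 0, texture_delta = 0)
    } else {
      lookup_effect(effects, rec$condition, rec$storage_day)
    }
    img_seed <- derive_seed(seed, 100000 + i)
    gain <- with_seed_local(img_seed + 1,
                            max(0.5, rnorm(1, base$illumination_gain,
                                           population$gain_sd)))
    whit <- base$whitening_fraction + eff[["whitening_delta"]]
    if (whit < 0 || whit > 1) n_clip <<- n_clip + 1L
    tibble(
      image_id = rec$image_id,
      base_r = sp$base_color[1] + eff[["dr"]],
      base_g = sp$base_color[2] + eff[["dg"]],
      base_b = sp$base_color[3] + eff[["db"]],
      color_noise_sd = base$color_noise_sd,
      texture_correlation_length = base$texture_correlation_length,
      texture_amplitude = max(0, sp$texture_amplitude + eff[["texture_delta"]]),
      whitening_fraction = min(1, max(0, whit)),
      illumination_gain = gain,
      illumination_offset = base$illumination_offset,
      img_seed = img_seed
    )
  })
  params <- dplyr::bind_rows(rows)
  if (n_clip > 0) {
    warn(sprintf("%d image(s) had effect severity outside parameter bounds; clipped",
                 n_clip), class = "visionqc_effects_clipped")
  }
  list(packages = inv$packages, images = dplyr::left_join(imgs, params,
                                                          by = "image_id"))
}

render_record <- function(layout, rec) {
  render_scene(layout, appearance_params(
    base_color = c(rec$base_r, rec$base_g, rec$base_b),
    color_noise_sd = rec$color_noise_sd,
    texture_correlation_length = rec$texture_correlation_length,
    texture_amplitude = rec$texture_amplitude,
    whitening_fraction = rec$whitening_fraction,
    illumination_gain = rec$illumination_gain,
    illumination_offset = rec$illumination_offset,
    seed = rec$img_seed))
}

#' Simulate a full imaging cohort
#'
#' Renders one scene per inventory record of the design: fresh-state images
#' are drawn from the fresh-sample population; post-treatment and stored
#' control images are additionally perturbed by the effect model at their
#' (condition, storage day). Reproducible given `seed`; effect severities
#' that would push a parameter outside its bounds are clipped with a warning.
#'
#' @param design A [study_design()].
#' @param effects An [effect_model()] or `NULL` for no effects.
#' @param layout A [scene_layout()].
#' @param population An [appearance_population()].
#' @param seed Integer cohort seed.
#' @return A list with `inventory` (the image tibble augmented with per-image
#'   rendering parameters) and `images` (named list of 8-bit arrays keyed by
#'   `image_id`).
#' @export
simulate_cohort <- function(design, effects = NULL, layout = scene_layout(),
                            population = appearance_population(), seed = 1L) {
  cp <- cohort_params(design, effects, population, seed)
  imgs <- purrr::map(seq_len(nrow(cp$images)), function(i) {
    render_record(layout, cp$images[i, ])
  })
  names(imgs) <- cp$images$image_id
  list(inventory = cp$images, images = imgs)
}
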