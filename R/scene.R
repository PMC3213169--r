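#' Imaging scene specification for the synthetic embryo renderer
#'
#' Geometry and camera parameters of the rendered midsagittal view: an
#' ellipsoidal embryo imaged laterally (anterior left, dorsal up), a cortical
#' monolayer of cycle-14 nuclei, interior yolk autofluorescence, a bright
#' thin vitelline-membrane ring just outside the embryo surface, and an
#' optional schedule of cellularization-membrane artifacts that split single
#' nuclei into an inner (yolk-side) and outer (surface-side) part.
#'
#' Frames are matrices indexed [x, y]: x runs along the AP axis (anterior at
#' x = 1), y runs downwards (dorsal at small y). Intensities are quantized to
#' the camera bit depth.
#'
#' @param width,height image size in pixels.
#' @param semi_a,semi_b embryo ellipse semi-axes (px).
#' @param band_px thickness of the cortical nuclear band (px).
#' @param nucleus_radius nucleus radius (px).
#' @param n_nuclei number of nuclei around the cortical ring.
#' @param bit_depth camera bit depth.
#' @param nuc_level,yolk_level,ring_level,offset nuclear-channel intensity of
#'   nuclei, yolk autofluorescence, vitelline ring, and camera offset.
#' @param reporter_gain,reporter_bg reporter-channel scale (units per model
#'   intensity) and embryo background.
#' @param ring_gap,ring_thickness vitelline ring geometry (px).
#' @param read_noise,shot_scale Gaussian read noise sd and multiplier on the
#'   sqrt-intensity (Poisson-like) shot noise; set both to 0 for noiseless
#'   rendering.
#' @param membrane_schedule data.frame with columns `time`, `nucleus`: which
#'   nuclei are split by a membrane-line artifact at which frame time.
#' @return object of class \code{scene_spec}.
#' @export
scene_spec <- function(width = 512, height = 512,
                       semi_a = 230, semi_b = 120,
                       band_px = 16, nucleus_radius = 4, n_nuclei = 100,
                       bit_depth = 16,
                       nuc_level = 30000, yolk_level = 12000,
                       ring_level = 45000, offset = 200,
                       reporter_gain = 20000, reporter_bg = 800,
                       ring_gap = 2, ring_thickness = 1.5,
                       read_noise = 150, shot_scale = 2,
                       membrane_schedule = NULL) {
  if (is.null(membrane_schedule))
    membrane_schedule <- data.frame(time = numeric(0), nucleus = integer(0))
  sc <- structure(as.list(environment()), class = "scene_spec")
  # feasibility: nuclei must fit in the band without overlap
  a0 <- semi_a - band_px / 2 - 1; b0 <- semi_b - band_px / 2 - 1
  per <- ellipse_perimeter(a0, b0)
  if (per / n_nuclei < 2 * (nucleus_radius + 1))
    abort("%d nuclei do not fit on the cortical band (spacing %.1f px < %d px)",
          n_nuclei, per / n_nuclei, 2 * (nucleus_radius + 1))
  if (band_px < 2 * nucleus_radius + 2)
    abort("cortical band thinner than a nucleus")
  sc
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Scene: %dx%d px, embryo %dx%d, %d nuclei (r = %d px), %d-bit\n",
              x$width, x$height, 2 * x$semi_a, 2 * x$semi_b, x$n_nuclei,
              x$nucleus_radius, x$bit_depth))
  invisible(x)
}

ellipse_perimeter <- function(a, b) {
  th <- seq(0, 2 * pi, length.out = 4096)
  sum(sqrt((a * diff(cos(th)))^2 + (b * diff(sin(th)))^2))
}

# n points equally spaced in arc length on the ellipse (a, b), centred at
# (cx, cy); first point at the anterior pole (theta = pi)
ellipse_ring_points <- function(n, a, b, cx, cy) {
  th <- seq(pi, 3 * pi, length.out = 8193)[-8193]
  x <- cx + a * cos(th); y <- cy + b * sin(th)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  tot <- s[length(s)] + sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2)
  want <- (seq_len(n) - 1) / n * tot
  ix <- findInterval(want, s)
  data.frame(x = x[ix], y = y[ix], theta = th[ix] %% (2 * pi))
}

#' Render a synthetic two-channel embryo movie with ground truth
#'
#' Draws the embryo's latent effects from `seed`, then renders, for every
#' frame time, a nuclear-marker channel (nuclei, yolk autofluorescence,
#' vitelline ring, optional membrane-line split artifacts) and a reporter
#' channel whose per-nucleus intensity is the generative stripe model
#' evaluated at the nucleus AP position. Deterministic given
#' (params, scene, seed).
#'
#' @param params a \code{stripe_model_params}.
#' @param scene a \code{scene_spec} (default geometry if NULL).
#' @param times frame times, minutes (3-min cadence spanning stripe
#'   maturation by default).
#' @param seed integer seed.
#' @param embryo_id identifier.
#' @return object of class \code{embryo_image_series}: list with `frames`
#'   (per time: list(nuclear, reporter) matrices), `truth` (static nucleus
#'   table with true centroids/AP/side, per-frame true rendered and model
#'   reporter values, split schedule, latent effects), `scene`, `times`,
#'   `axis` (anterior/posterior pole pixel coordinates, 0-based).
#' @export
generate_embryo_series <- function(params, scene = NULL,
                                   times = seq(24, 48, by = 3), seed = 1L,
                                   embryo_id = "embryo1") {
  stopifnot(inherits(params, "stripe_model_params"))
  if (is.null(scene)) scene <- scene_spec()
  win <- model_window(params)
  if (any(times < win[1] | times > win[2]))
    abort("requested times fall outside the modeled window [%.1f, %.1f]",
          win[1], win[2])
  sc <- scene
  cx <- (sc$width + 1) / 2; cy <- (sc$height + 1) / 2
  a0 <- sc$semi_a - sc$band_px / 2 - 1
  b0 <- sc$semi_b - sc$band_px / 2 - 1
  nuc <- ellipse_ring_points(sc$n_nuclei, a0, b0, cx, cy)
  nuc$id <- seq_len(nrow(nuc))
  nuc$ap <- (nuc$x - (cx - sc$semi_a)) / (2 * sc$semi_a) * 100
  nuc$side <- ifelse(nuc$y < cy, "dorsal", "ventral")
  # outward surface normal at each nucleus (for the membrane-line artifact)
  nx <- (nuc$x - cx) / a0^2; ny <- (nuc$y - cy) / b0^2
  nl <- sqrt(nx^2 + ny^2); nuc$nx <- nx / nl; nuc$ny <- ny / nl

  X <- matrix(rep(seq_len(sc$width), sc$height), sc$width, sc$height)
  Y <- matrix(rep(seq_len(sc$height), each = sc$width), sc$width, sc$height)
  in_embryo <- ((X - cx) / sc$semi_a)^2 + ((Y - cy) / sc$semi_b)^2 <= 1
  in_yolk <- ((X - cx) / (sc$semi_a - sc$band_px))^2 +
             ((Y - cy) / (sc$semi_b - sc$band_px))^2 <= 1
  go <- sc$ring_gap; gt <- sc$ring_gap + sc$ring_thickness
  ring <- (((X - cx) / (sc$semi_a + gt))^2 + ((Y - cy) / (sc$semi_b + gt))^2 <= 1) &
          (((X - cx) / (sc$semi_a + go))^2 + ((Y - cy) / (sc$semi_b + go))^2 > 1)

  maxval <- 2^sc$bit_depth - 1
  r <- sc$nucleus_radius

  with_seed(seed, {
    eff <- draw_embryo_effects(params)
    frames <- vector("list", length(times))
    values_model <- matrix(NA_real_, nrow(nuc), length(times))
    truth_feat <- vector("list", length(times))
    for (fi in seq_along(times)) {
      t <- times[fi]
      nuclear <- matrix(sc$offset, sc$width, sc$height)
      nuclear[in_yolk] <- nuclear[in_yolk] + sc$yolk_level
      nuclear[ring] <- nuclear[ring] + sc$ring_level
      reporter <- matrix(sc$offset, sc$width, sc$height)
      reporter[in_embryo] <- reporter[in_embryo] + sc$reporter_bg

      v <- eval_stripe_model(params, t, nuc$ap, eff)
      values_model[, fi] <- v
      split_now <- sc$membrane_schedule$nucleus[sc$membrane_schedule$time == t]
      for (k in seq_len(nrow(nuc))) {
        xs <- max(1, round(nuc$x[k] - r)):min(sc$width, round(nuc$x[k] + r))
        ys <- max(1, round(nuc$y[k] - r)):min(sc$height, round(nuc$y[k] + r))
        dx <- outer(xs - nuc$x[k], rep(1, length(ys)))
        dy <- outer(rep(1, length(xs)), ys - nuc$y[k])
        disc <- dx^2 + dy^2 <= r^2
        blkn <- nuclear[xs, ys]
        blkn[disc] <- sc$offset + sc$nuc_level
        if (k %in% split_now) {
          # dark cellularization-membrane line tangential to the surface
          d_norm <- dx * nuc$nx[k] + dy * nuc$ny[k]
          line <- disc & abs(d_norm) <= 2
          blkn[line] <- sc$offset + 0.78 * sc$nuc_level
        }
        nuclear[xs, ys] <- blkn
        blkr <- reporter[xs, ys]
        blkr[disc] <- sc$offset + sc$reporter_bg + sc$reporter_gain * v[k]
        reporter[xs, ys] <- blkr
      }
      quantize <- function(img) {
        if (sc$read_noise > 0 || sc$shot_scale > 0) {
          img <- img + stats::rnorm(length(img), 0, sc$read_noise) +
            stats::rnorm(length(img)) * sc$shot_scale * sqrt(pmax(img, 0))
        }
        matrix(pmin(pmax(round(img), 0), maxval), nrow(img), ncol(img))
      }
      frames[[fi]] <- list(nuclear = quantize(nuclear),
                           reporter = quantize(reporter))
      truth_feat[[fi]] <- true_stripe_features(params, t, embryo = eff)
    }
    names(frames) <- as.character(times)
    truth <- list(
      nuclei = data.frame(id = nuc$id, x_px = nuc$x - 1, y_px = nuc$y - 1,
                          ap_percent_el = nuc$ap, side = nuc$side),
      values_model = values_model,
      values_rendered = sc$offset + sc$reporter_bg +
        sc$reporter_gain * values_model,
      splits = sc$membrane_schedule,
      effects = eff, features = truth_feat)
    structure(list(embryo_id = embryo_id, times = times, frames = frames,
                   truth = truth, scene = sc,
                   axis = list(anterior = c(cx - sc$semi_a - 1, cy - 1),
                               posterior = c(cx + sc$semi_a - 1, cy - 1))),
              class = "embryo_image_series")
  })
}

#' @export
print.embryo_image_series <- function(x, ...) {
  cat(sprintf("Embryo image series '%s': %d frames (%g-%g min), %dx%d px, %d nuclei\n",
              x$embryo_id, length(x$times), min(x$times), max(x$times),
              x$scene$width, x$scene$height, nrow(x$truth$nuclei)))
  invisible(x)
}

#' Write an embryo image series to multi-frame TIFF files
#'
#' One file per channel, frames in time order, 16-bit.
#'
#' @param series an \code{embryo_image_series}.
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
write_embryo_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maxval <- 2^series$scene$bit_depth - 1
  paths <- character(2); names(paths) <- c("nuclear", "reporter")
  for (ch in names(paths)) {
    imgs <- lapply(series$frames, function(f) f[[ch]] / maxval)
    img <- EBImage::Image(simplify2array(imgs))
    paths[ch] <- file.path(dir, sprintf("%s_%s.tif", series$embryo_id, ch))
    EBImage::writeImage(img, paths[ch], type = "tiff", bits.per.sample = 16L)
  }
  invisible(paths)
}
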