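#' Parameters of the generative seven-stripe expression model
#'
#' Builds the parameter set used by the synthetic-data generator. The model
#' describes mean nuclear reporter fluorescence along the anteroposterior
#' (AP) axis as a sum of seven Gaussian stripe components over a constant
#' baseline, plus two localized "fill" components in the 1-2 and 2-3
#' interstripes that set the depths of the stripe-2 borders. Three temporal
#' mechanisms shape the pattern:
#' \itemize{
#'   \item amplitudes A_s(t), piecewise linear on a 3-minute knot grid;
#'   \item a common width-narrowing trajectory (stripes sharpen from a broad
#'     early domain to their mature width), with stripe 2's anterior and
#'     posterior widths narrowing on their own, per-embryo-jittered
#'     schedules — the interstripe minima flanking stripe 2 appear when the
#'     widths fall below the stripe spacing, so incipient-stripe timing and
#'     border-formation order are emergent;
#'   \item interstripe fill amplitudes F12(t), F23(t) that raise the flanking
#'     minima and thereby control the anterior/posterior border heights
#'     (relative repression) without touching the peaks.
#' }
#' All stripes share the narrowing schedule so that the smoothing-spline
#' peak attenuation, which depends on stripe width, cancels in the
#' stripe-2/stripe-1 peak ratio.
#'
#' Presets encode three enhancer genotypes at two growth temperatures:
#' \describe{
#'   \item{WT}{relative activation (stripe-2/stripe-1 peak ratio) rises from
#'     0.6 to 1.0 over 30--48 min; the anterior border deepens steadily
#'     (F12 decays); positional spread shrinks over time; mild
#'     posterior-first border bias.}
#'   \item{MSE}{relative activation decreases over time; borders symmetric
#'     from the start (both fills low); positional spread grows over time;
#'     anterior-first bias.}
#'   \item{INV_MSE}{relative activation near-constant; the anterior border
#'     stays derepressed (F12 persists); strong posterior-first bias.}
#' }
#' At 29C the developmental timeline is compressed by the ratio of the
#' cellularization landmark times (the time at which the cellularization
#' membrane reaches the basal end of the nuclei: 38.2 min at 25C, 30.6 min
#' at 29C): model trajectories are evaluated at t * 38.2/30.6.
#'
#' @param preset genotype preset: "WT", "MSE" or "INV_MSE".
#' @param temperature "25C" or "29C".
#' @param mu stripe centres, percent egg length (EL), strictly increasing.
#' @param sigma mature stripe widths (percent EL), one per stripe, positive.
#' @param amp_times amplitude/fill knot grid (minutes, model time).
#' @param amp stripes x knots matrix of nonnegative amplitudes (arbitrary
#'   units); row s is the trajectory A_s(t).
#' @param baseline constant background level.
#' @param sigma_n nucleus-level additive Gaussian noise sd (same units as
#'   amp).
#' @param sigma_pos embryo-level positional jitter sd (percent EL); scalar
#'   or one value per knot for time-varying spread.
#' @param rel_amp_sd sd of the per-embryo lognormal factor on the stripe-2
#'   amplitude (embryo-to-embryo variability of relative activation).
#' @param border_jitter_sd sd (minutes) of the per-embryo jitter on the
#'   stripe-2 anterior/posterior width-narrowing times.
#' @param stripe2 list with `t_anterior`, `t_posterior`: the narrowing times
#'   of the stripe-2 anterior/posterior widths, or NULL for a static model
#'   (no width dynamics, no fills; used for simple custom patterns).
#' @param derepression anterior-border derepression trajectory (one value
#'   per knot): extra fill amplitude added in the 1-2 interstripe on top of
#'   the tail-balancing term, raising the anterior minimum and lowering the
#'   relative repression.
#' @param fill_base common baseline fill amplitude in both interstripes.
#' @param fill_sigma width of the fill components (percent EL).
#' @param fill_ramp c(t0, t1): fills ramp linearly from 0 to full between
#'   these model times (no fills while the stripes are still merged).
#' @param width_start,width_break early and breakpoint stripe widths of the
#'   narrowing trajectory; each stripe narrows from `width_start` (8 min
#'   before its narrowing time) through `width_break` (at it) to its mature
#'   width (4 min after it).
#' @param t_width_break common narrowing time of stripes other than 2.
#' @param landmark_25C,landmark_29C cellularization landmark times (minutes)
#'   used for the 29C time compression.
#' @return an object of class \code{stripe_model_params}.
#' @export
stripe_model_params <- function(preset = c("WT", "MSE", "INV_MSE"),
                                temperature = c("25C", "29C"),
                                mu = c(33, 41, 47, 53, 59, 65, 71),
                                sigma = rep(1.8, length(mu)),
                                amp_times = seq(21, 51, by = 3),
                                amp = NULL,
                                baseline = 0.05,
                                sigma_n = 0.06,
                                sigma_pos = NULL,
                                rel_amp_sd = 0.2,
                                border_jitter_sd = 2.5,
                                stripe2 = NULL,
                                derepression = NULL,
                                fill_base = 0.05,
                                fill_sigma = 1.8,
                                fill_ramp = c(28, 33),
                                width_start = 4.8, width_break = 3.8,
                                t_width_break = 26,
                                landmark_25C = 38.2,
                                landmark_29C = 30.6) {
  preset <- match.arg(preset)
  temperature <- match.arg(temperature)
  nk <- length(amp_times)
  dynamic <- length(mu) >= 3

  if (is.null(amp)) {
    a2_late <- switch(preset,
      WT      = seq(0.60, 1.00, length.out = 7),
      MSE     = seq(0.60, 0.52, length.out = 7),
      INV_MSE = rep(0.60, 7))
    a2 <- c(0.25, 0.38, 0.50, a2_late,
            switch(preset, WT = 1.067, MSE = 0.51, INV_MSE = 0.60))
    others <- seq(0.25, 0.95, length.out = nk)
    amp <- rbind(rep(1, nk), a2,
                 matrix(rep(others, 5), nrow = 5, byrow = TRUE))
    rownames(amp) <- paste0("stripe", 1:7)
  }
  if (is.null(sigma_pos)) {
    sigma_pos <- switch(preset,
      WT      = c(2.0, 1.95, 1.9, 1.8, 1.65, 1.5, 1.4, 1.3, 1.15, 1.0, 0.95),
      MSE     = c(1.2, 1.2, 1.2, 1.2, 1.35, 1.5, 1.65, 1.8, 2.0, 2.2, 2.3),
      INV_MSE = rep(1.5, nk))
    if (length(sigma_pos) != nk) sigma_pos <- rep(sigma_pos[1], nk)
  }
  if (is.null(stripe2) && dynamic) {
    stripe2 <- switch(preset,
      WT      = list(t_anterior = 25.3, t_posterior = 24.3),
      MSE     = list(t_anterior = 23.5, t_posterior = 25.5),
      INV_MSE = list(t_anterior = 25.5, t_posterior = 23.7))
  }
  if (is.null(derepression) && dynamic) {
    derepression <- switch(preset,
      WT      = c(0.25, 0.25, 0.25, seq(0.25, 0.03, length.out = 7), 0.01),
      MSE     = rep(0, nk),
      INV_MSE = c(0.25, 0.25, 0.25, seq(0.25, 0.12, length.out = 7), 0.11))
  }
  if (!dynamic) { stripe2 <- NULL; derepression <- rep(0, nk) }

  p <- structure(list(
    preset = preset, temperature = temperature,
    mu = mu, sigma = sigma,
    amp_times = amp_times, amp = amp, baseline = baseline,
    sigma_n = sigma_n, sigma_pos = sigma_pos,
    rel_amp_sd = rel_amp_sd, border_jitter_sd = border_jitter_sd,
    stripe2 = stripe2, derepression = derepression,
    fill_base = fill_base, fill_sigma = fill_sigma, fill_ramp = fill_ramp,
    width_start = width_start, width_break = width_break,
    t_width_break = t_width_break,
    dynamic = dynamic && !is.null(stripe2),
    time_scale = if (temperature == "29C") landmark_25C / landmark_29C else 1
  ), class = "stripe_model_params")
  validate_stripe_model_params(p)
  p
}

validate_stripe_model_params <- function(p) {
  if (any(diff(p$mu) <= 0)) abort("stripe centres mu must be strictly increasing")
  if (any(p$sigma <= 0)) abort("stripe widths sigma must be positive")
  if (any(p$amp < 0)) abort("amplitudes A_s(t) must be nonnegative")
  if (nrow(p$amp) != length(p$mu))
    abort("amp must have one row per stripe")
  if (ncol(p$amp) != length(p$amp_times))
    abort("amp must have one column per amplitude knot")
  if (length(p$sigma_pos) != 1 && length(p$sigma_pos) != length(p$amp_times))
    abort("sigma_pos must be a scalar or one value per amplitude knot")
  if (length(p$derepression) != length(p$amp_times) ||
      any(p$derepression < 0))
    abort("derepression must be one nonnegative value per knot")
  invisible(p)
}

#' @export
print.stripe_model_params <- function(x, ...) {
  cat(sprintf("Seven-stripe expression model (%s preset, %s)\n",
              x$preset, x$temperature))
  cat(sprintf("  %d stripes at %s%% EL; window %g-%g min (model time)\n",
              length(x$mu), paste(x$mu, collapse = ", "),
              min(x$amp_times), max(x$amp_times)))
  cat(sprintf("  sigma_n = %g, mean sigma_pos = %g%% EL\n",
              x$sigma_n, mean(x$sigma_pos)))
  invisible(x)
}

# model-time window expressed in absolute minutes for this temperature
model_window <- function(params) range(params$amp_times) / params$time_scale

# amplitude of stripe s at absolute time t (after temperature rescaling)
stripe_amplitude <- function(params, s, t) {
  traj_at(params$amp_times, params$amp[s, ], t * params$time_scale)
}

# positional jitter sd at absolute time t
sigma_pos_at <- function(params, t) {
  if (length(params$sigma_pos) == 1) return(params$sigma_pos)
  traj_at(params$amp_times, params$sigma_pos, t * params$time_scale)
}

# width of the boundary between stripes b and b+1 at model time td.
# Widths belong to boundaries, not stripes: the two flanks facing an
# interstripe share one width trajectory, so the interstripe minimum appears
# when that single width crosses the merge threshold, and the smoothing
# attenuation of the two adjacent peaks stays symmetric. Boundaries 1-2 and
# 2-3 follow the stripe-2 narrowing times (plus the embryo's jitters da,
# dp); all other boundaries share `t_width_break`.
boundary_width_at <- function(params, b, td, da = 0, dp = 0) {
  t_nar <- if (b == 1) params$stripe2$t_anterior + da
           else if (b == 2) params$stripe2$t_posterior + dp
           else params$t_width_break
  kn_t <- c(t_nar - 8, t_nar, t_nar + 4)
  kn_s <- c(params$width_start, params$width_break,
            max(params$sigma[b], params$sigma[b + 1]))
  tt <- min(max(td, kn_t[1]), kn_t[3])
  stats::approx(kn_t, kn_s, xout = tt)$y
}

# left/right flank widths of stripe s (outermost flanks keep mature width)
stripe_flanks_at <- function(params, s, td, da = 0, dp = 0) {
  S <- length(params$mu)
  if (!params$dynamic) return(c(left = params$sigma[s], right = params$sigma[s]))
  c(left = if (s == 1) params$sigma[1]
           else boundary_width_at(params, s - 1, td, da, dp),
    right = if (s == S) params$sigma[S]
            else boundary_width_at(params, s, td, da, dp))
}

# interstripe fill amplitudes at model time td for this embryo: a common
# baseline, a tail-balancing term that equalizes the two minima floors when
# derepression is zero, and the preset derepression on the anterior side;
# ramped in while the stripes resolve
fill_amplitudes <- function(params, t, embryo) {
  td <- t * params$time_scale
  r <- min(1, max(0, (td - params$fill_ramp[1]) /
                     (params$fill_ramp[2] - params$fill_ramp[1])))
  if (r == 0) return(c(f12 = 0, f23 = 0))
  A1 <- stripe_amplitude(params, 1, t)
  A2 <- stripe_amplitude(params, 2, t) * embryo$a2_factor
  A3 <- stripe_amplitude(params, 3, t)
  s12 <- boundary_width_at(params, 1, td, embryo$da, embryo$dp)
  s23 <- boundary_width_at(params, 2, td, embryo$da, embryo$dp)
  h12 <- (params$mu[2] - params$mu[1]) / 2
  h23 <- (params$mu[3] - params$mu[2]) / 2
  floor12 <- (A1 + A2) * exp(-h12^2 / (2 * s12^2))
  floor23 <- (A2 + A3) * exp(-h23^2 / (2 * s23^2))
  D <- traj_at(params$amp_times, params$derepression, td)
  c(f12 = r * (params$fill_base + max(0, floor23 - floor12) + D),
    f23 = r * params$fill_base)
}

# draw the per-embryo latent effects (uses the current RNG stream)
draw_embryo_effects <- function(params) {
  list(z_pos = stats::rnorm(1),
       a2_factor = exp(stats::rnorm(1, 0, params$rel_amp_sd)),
       da = stats::rnorm(1, 0, params$border_jitter_sd),
       dp = stats::rnorm(1, 0, params$border_jitter_sd))
}

no_embryo_effects <- function() list(z_pos = 0, a2_factor = 1, da = 0, dp = 0)

#' Evaluate the noiseless expression model
#'
#' Mean reporter intensity at AP positions `x` (percent EL) and absolute
#' time `t` (minutes), optionally under the latent per-embryo effects
#' `embryo` (positional shift, stripe-2 amplitude factor, border-narrowing
#' jitter).
#'
#' @param params a \code{stripe_model_params} object.
#' @param t absolute time in minutes (must lie in the modeled window).
#' @param x AP positions, percent EL.
#' @param embryo per-embryo latent effects; NULL for the population
#'   reference.
#' @return numeric vector of intensities.
#' @export
eval_stripe_model <- function(params, t, x, embryo = NULL) {
  if (is.null(embryo)) embryo <- no_embryo_effects()
  td <- t * params$time_scale
  shift <- embryo$z_pos * sigma_pos_at(params, t)
  S <- length(params$mu)
  y <- rep(params$baseline, length(x))
  for (s in seq_len(S)) {
    a <- stripe_amplitude(params, s, t)
    if (s == 2) a <- a * embryo$a2_factor
    m <- params$mu[s] + shift
    fl <- stripe_flanks_at(params, s, td, embryo$da, embryo$dp)
    sa <- ifelse(x <= m, fl[["left"]], fl[["right"]])
    y <- y + a * exp(-(x - m)^2 / (2 * sa^2))
  }
  if (params$dynamic && S >= 3) {
    f <- fill_amplitudes(params, t, embryo)
    c12 <- (params$mu[1] + params$mu[2]) / 2 + shift
    c23 <- (params$mu[2] + params$mu[3]) / 2 + shift
    y <- y + f[["f12"]] * exp(-(x - c12)^2 / (2 * params$fill_sigma^2))
    y <- y + f[["f23"]] * exp(-(x - c23)^2 / (2 * params$fill_sigma^2))
  }
  y
}

#' Generate a synthetic AP expression profile
#'
#' Samples the generative stripe model at nucleus spacing along the AP axis
#' and adds nucleus-level Gaussian noise. Deterministic given `seed`.
#'
#' @inheritParams eval_stripe_model
#' @param seed integer seed controlling the embryo effects and noise.
#' @param n_nuclei number of nuclei along the profile.
#' @param ap_range AP interval sampled (percent EL).
#' @param embryo optional pre-drawn embryo effects; if NULL they are drawn
#'   from `seed` (so all timepoints of one embryo share effects when the
#'   caller passes the same list).
#' @return an \code{expression_profile}: data.frame with columns `ap`,
#'   `intensity`, plus attributes `t`, `edge`, `embryo` (latent truth) and
#'   `params`.
#' @export
generate_profile <- function(params, t, seed = 1L, n_nuclei = 110,
                             ap_range = c(2, 98), embryo = NULL) {
  stopifnot(inherits(params, "stripe_model_params"))
  win <- model_window(params)
  if (t < win[1] || t > win[2])
    abort("time %g min is outside the modeled window [%.1f, %.1f]",
          t, win[1], win[2])
  with_seed(seed, {
    if (is.null(embryo)) embryo <- draw_embryo_effects(params)
    ap <- seq(ap_range[1], ap_range[2], length.out = n_nuclei)
    y <- eval_stripe_model(params, t, ap, embryo) +
      stats::rnorm(n_nuclei, 0, params$sigma_n)
    y <- pmax(y, 0)
    new_expression_profile(ap, y, t = t, embryo = embryo, params = params)
  })
}

new_expression_profile <- function(ap, intensity, t = NA_real_,
                                   edge = "ventral", embryo_id = NA_character_,
                                   normalized_to = NA_integer_,
                                   embryo = NULL, params = NULL) {
  if (is.unsorted(ap, strictly = TRUE)) abort("AP positions must be strictly increasing")
  structure(data.frame(ap = ap, intensity = intensity),
            t = t, edge = edge, embryo_id = embryo_id,
            normalized_to = normalized_to, embryo = embryo, params = params,
            class = c("expression_profile", "data.frame"))
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("AP expression profile: %d nuclei, t = %s min, edge = %s%s\n",
              nrow(x), format(attr(x, "t")), attr(x, "edge"),
              if (!is.na(attr(x, "normalized_to")))
                sprintf(", normalized to stripe %d", attr(x, "normalized_to"))
              else ""))
  invisible(x)
}

#' Ground-truth stripe features of the noiseless model
#'
#' Brute-force extrema of the noiseless model on a dense AP grid, with the
#' stripe-2 peak, flanking minima, border positions (mean-crossing rule) and
#' border heights. Used as the oracle for the feature-detection pipeline.
#'
#' @inheritParams eval_stripe_model
#' @param step dense grid step in percent EL.
#' @param ap_range AP interval evaluated.
#' @param min_contrast adjacent extrema pairs whose value difference is
#'   below this are pruned (persistence filter): a feature this shallow is
#'   not a formed border.
#' @return list with `extrema`, `peaks` (all maxima), `activation` (true
#'   stripe2/stripe1 peak ratio) and `stripe2` (peak position/value,
#'   anterior/posterior minimum presence, border positions and heights).
#' @export
true_stripe_features <- function(params, t, embryo = NULL, step = 0.005,
                                 ap_range = c(2, 98), min_contrast = 0.01) {
  x <- seq(ap_range[1], ap_range[2], by = step)
  y <- eval_stripe_model(params, t, x, embryo)
  d <- diff(y)
  d[abs(d) < 1e-11] <- 0                 # ignore flat-baseline float noise
  s <- sign(d)
  nz <- which(s != 0)
  idx <- integer(0); type <- character(0)
  if (length(nz) > 1) {
    chg <- which(s[nz][-1] != s[nz][-length(nz)])
    idx <- nz[chg] + 1L
    type <- ifelse(s[nz][chg + 1L] > 0, "min", "max")
  }
  ext <- data.frame(position = x[idx], value = y[idx], type = type,
                    stringsAsFactors = FALSE)
  # persistence pruning: drop adjacent extrema pairs with negligible
  # contrast (removing an adjacent pair preserves alternation)
  while (nrow(ext) >= 2) {
    dv <- abs(diff(ext$value))
    k <- which.min(dv)
    if (dv[k] >= min_contrast) break
    ext <- ext[-c(k, k + 1L), , drop = FALSE]
  }
  shift <- if (is.null(embryo)) 0 else embryo$z_pos * sigma_pos_at(params, t)
  mu2 <- params$mu[2] + shift
  maxima <- ext[ext$type == "max", , drop = FALSE]
  mins_all <- ext[ext$type == "min", , drop = FALSE]
  out <- list(extrema = ext, peaks = maxima, activation = NA_real_,
              stripe2 = list(peak_position = NA_real_, peak_value = NA_real_,
                             anterior_min = FALSE, posterior_min = FALSE,
                             anterior_border = NA_real_, posterior_border = NA_real_,
                             height_anterior = NA_real_, height_posterior = NA_real_))
  # the interstripe minima are scored in their expected windows, so a
  # one-sided state (a border formed while the other side is still merged)
  # is representable
  if (length(params$mu) >= 3) {
    out$stripe2$anterior_min <- any(mins_all$position > params$mu[1] + shift &
                                    mins_all$position < mu2)
    out$stripe2$posterior_min <- any(mins_all$position > mu2 &
                                     mins_all$position < params$mu[3] + shift)
  }
  if (nrow(maxima) == 0) return(out)
  k2 <- which.min(abs(maxima$position - mu2))
  pk <- maxima[k2, ]
  if (abs(pk$position - mu2) > 3) return(out)   # stripe 2 not individuated
  st2 <- out$stripe2
  st2$peak_position <- pk$position; st2$peak_value <- pk$value
  mins <- mins_all
  amin <- mins[mins$position < pk$position, , drop = FALSE]
  pmin_ <- mins[mins$position > pk$position, , drop = FALSE]
  cross <- function(lo, hi, level) {
    seg <- which(x >= lo & x <= hi)
    j <- seg[which.min(abs(y[seg] - level))]
    x[j]
  }
  if (nrow(amin) > 0) {
    am <- amin[nrow(amin), ]         # minimum immediately anterior
    st2$anterior_min <- TRUE
    st2$height_anterior <- pk$value - am$value
    st2$anterior_border <- cross(am$position, pk$position,
                                 (pk$value + am$value) / 2)
  }
  if (nrow(pmin_) > 0) {
    pm <- pmin_[1, ]                 # minimum immediately posterior
    st2$posterior_min <- TRUE
    st2$height_posterior <- pk$value - pm$value
    st2$posterior_border <- cross(pk$position, pm$position,
                                  (pk$value + pm$value) / 2)
  }
  out$stripe2 <- st2
  k1 <- which.min(abs(maxima$position - (params$mu[1] + shift)))
  if (abs(maxima$position[k1] - (params$mu[1] + shift)) <= 3)
    out$activation <- pk$value / maxima$value[k1]
  out
}
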