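#' Generate the profile time series of one synthetic embryo
#'
#' Draws the embryo's latent effects once (positional jitter, stripe-2
#' amplitude factor, border-clearing jitter) and samples a noisy AP profile at
#' each requested timepoint, together with ground truth computed by dense
#' evaluation of the noiseless model under the same latent effects.
#'
#' @param params a \code{stripe_model_params} object.
#' @param times frame times in minutes (3-min cadence by convention).
#' @param seed integer seed; fully determines the embryo.
#' @param embryo_id identifier stored on the profiles.
#' @param n_nuclei nuclei per profile.
#' @return list with `profiles` (one \code{expression_profile} per timepoint),
#'   `truth` (per-timepoint \code{true_stripe_features} plus the latent
#'   effects, the true border order and true incipient time on the frame
#'   grid), `embryo_id` and `seed`.
#' @export
generate_embryo_profiles <- function(params, times = seq(24, 48, by = 3),
                                     seed = 1L, embryo_id = "embryo1",
                                     n_nuclei = 110) {
  stopifnot(inherits(params, "stripe_model_params"))
  win <- model_window(params)
  if (any(times < win[1] | times > win[2]))
    abort("requested times fall outside the modeled window [%.1f, %.1f]",
          win[1], win[2])
  eff <- with_seed(seed, draw_embryo_effects(params))
  profiles <- vector("list", length(times))
  truth_t <- vector("list", length(times))
  for (i in seq_along(times)) {
    pr <- generate_profile(params, times[i], seed = seed + 7919L * i,
                           n_nuclei = n_nuclei, embryo = eff)
    attr(pr, "embryo_id") <- embryo_id
    profiles[[i]] <- pr
    truth_t[[i]] <- true_stripe_features(params, times[i], embryo = eff)
  }
  names(profiles) <- names(truth_t) <- as.character(times)
  amin <- vapply(truth_t, function(f) f$stripe2$anterior_min, logical(1))
  pmin_ <- vapply(truth_t, function(f) f$stripe2$posterior_min, logical(1))
  t_a <- if (any(amin)) times[which(amin)[1]] else NA_real_
  t_p <- if (any(pmin_)) times[which(pmin_)[1]] else NA_real_
  order <- if (is.na(t_a) || is.na(t_p) || t_a == t_p) "unresolved"
           else if (t_a < t_p) "anterior_first" else "posterior_first"
  both <- amin & pmin_
  t_inc <- if (any(both)) times[which(both)[1]] else NA_real_
  list(embryo_id = embryo_id, seed = seed, times = times,
       profiles = profiles,
       truth = list(effects = eff, features = truth_t,
                    border_order = order, initiation_time = t_inc,
                    activation = vapply(truth_t, function(f) f$activation,
                                        numeric(1))))
}

#' Generate a cohort of synthetic embryos
#'
#' A cohort is a set of embryos sharing the same model parameters, each with
#' its own latent effects and noise realisation. With `output = "profiles"`
#' (the default analysis substrate) each embryo carries its profile time
#' series; with `output = "images"` each embryo carries a rendered two-channel
#' image series (see \code{\link{generate_embryo_series}}).
#'
#' @inheritParams generate_embryo_profiles
#' @param n_embryos number of embryos (>= 2).
#' @param seeds integer vector of per-embryo seeds (default derived from
#'   `seed`); recorded on each embryo.
#' @param seed base seed used when `seeds` is NULL.
#' @param output "profiles" or "images".
#' @param scene a \code{scene_spec}, used only for image output.
#' @return list of embryos (class \code{stripe_cohort}) with the shared
#'   `params` attached as an attribute.
#' @export
generate_cohort <- function(params, n_embryos, times = seq(24, 48, by = 3),
                            seeds = NULL, seed = 1L,
                            output = c("profiles", "images"),
                            scene = NULL, n_nuclei = 110) {
  output <- match.arg(output)
  if (n_embryos < 2) abort("a cohort needs at least 2 embryos")
  if (is.null(seeds)) seeds <- seed + seq_len(n_embryos) * 1000L
  if (length(seeds) != n_embryos) abort("need one seed per embryo")
  embryos <- vector("list", n_embryos)
  for (i in seq_len(n_embryos)) {
    id <- sprintf("embryo%02d", i)
    embryos[[i]] <- if (output == "profiles") {
      generate_embryo_profiles(params, times, seed = seeds[i],
                               embryo_id = id, n_nuclei = n_nuclei)
    } else {
      generate_embryo_series(params, scene = scene, times = times,
                             seed = seeds[i], embryo_id = id)
    }
  }
  structure(embryos, params = params, class = "stripe_cohort")
}

#' @export
print.stripe_cohort <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Synthetic cohort: %d embryos (%s preset, %s)\n",
              length(x), p$preset, p$temperature))
  invisible(x)
}
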