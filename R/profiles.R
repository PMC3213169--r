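#' Register frame times to the completion of the 13th nuclear division
#'
#' Embryo movies are synchronised by starting the clock at the end of the
#' final syncytial mitotic wave; frame times become minutes since that event.
#' The wave lasts about half a minute, so registered times carry a stated
#' uncertainty of +/- 0.5 min.
#'
#' @param frame_times acquisition times in minutes, strictly increasing.
#' @param t0_event_time time of the registration event (same clock).
#' @param uncertainty_min stated registration uncertainty, minutes.
#' @return numeric vector of registered times with attribute
#'   `uncertainty_min`.
#' @export
register_time <- function(frame_times, t0_event_time, uncertainty_min = 0.5) {
  if (missing(t0_event_time) || is.null(t0_event_time) || is.na(t0_event_time))
    abort("t0_event_time is required to register frame times")
  if (is.unsorted(frame_times, strictly = TRUE))
    abort("frame times must be strictly increasing")
  structure(frame_times - t0_event_time, uncertainty_min = uncertainty_min)
}

#' Extract a dorsal or ventral AP expression profile from a nucleus table
#'
#' Projects nucleus centroids onto the embryo's AP axis (anterior pole = 0
#' percent EL, posterior pole = 100) and keeps nuclei on the requested side of
#' the midline. In image coordinates (rows increase downwards, anterior left,
#' dorsal up) the dorsal side is above the AP axis.
#'
#' @param nuclei data.frame with columns `x_px`, `y_px`, `mean_fluo` (as
#'   produced by \code{\link{quantify_nuclei}}).
#' @param edge "ventral" (the default analysis substrate, as it shows the most
#'   mature pattern) or "dorsal".
#' @param embryo_axis list with `anterior` and `posterior` pole pixel
#'   coordinates c(x, y).
#' @param min_n below this sample count the profile is flagged `low_n`.
#' @return an \code{expression_profile} (columns `ap`, `intensity`).
#' @export
extract_edge_profile <- function(nuclei, edge = c("ventral", "dorsal"),
                                 embryo_axis, min_n = 30) {
  edge <- match.arg(edge)
  stopifnot(all(c("x_px", "y_px", "mean_fluo") %in% names(nuclei)))
  a <- embryo_axis$anterior; b <- embryo_axis$posterior
  v <- b - a
  len2 <- sum(v^2)
  if (len2 <= 0) abort("embryo axis poles coincide")
  dx <- nuclei$x_px - a[1]; dy <- nuclei$y_px - a[2]
  ap <- (dx * v[1] + dy * v[2]) / len2 * 100
  cross <- v[1] * dy - v[2] * dx
  side <- if (edge == "dorsal") cross < 0 else cross >= 0
  ap <- ap[side]; y <- nuclei$mean_fluo[side]
  o <- order(ap); ap <- ap[o]; y <- y[o]
  if (any(duplicated(ap))) {
    y <- as.numeric(tapply(y, ap, mean)); ap <- sort(unique(ap))
  }
  pr <- new_expression_profile(ap, y,
    t = if ("t_min" %in% names(nuclei)) nuclei$t_min[1] else NA_real_,
    edge = edge,
    embryo_id = if ("embryo_id" %in% names(nuclei)) nuclei$embryo_id[1]
                else NA_character_)
  attr(pr, "low_n") <- length(ap) < min_n
  if (attr(pr, "low_n"))
    warning(sprintf("only %d nuclei in the %s profile (minimum %d)",
                    length(ap), edge, min_n), call. = FALSE)
  pr
}

#' Normalize a profile to the peak of a reference stripe
#'
#' Divides all intensities by the fitted peak value of the reference stripe
#' (stripe 1 by default; stripes 3 or 6 are the alternative references).
#' Stripes are the prominent spline maxima numbered anterior to posterior.
#' Because the spline is linear in the data, normalization is idempotent and
#' stripe positions are unchanged.
#'
#' @param profile an \code{expression_profile}.
#' @param reference reference stripe index (anterior-to-posterior numbering).
#' @param p roughness parameter used to locate the reference peak.
#' @return the normalized \code{expression_profile}; attribute
#'   `normalized_to` records the reference.
#' @export
normalize_profile <- function(profile, reference = 1L, p = 0.5) {
  fit <- fit_smoothing_spline(profile, p = p)
  f <- stripe_features(detect_extrema(fit), fit)
  pk <- f$peaks[!is.na(f$peaks$stripe), , drop = FALSE]
  w <- which(pk$stripe == reference)
  if (length(w) != 1)
    abort("reference stripe %d peak is absent at this timepoint", reference)
  ref_value <- pk$value[w]
  if (ref_value <= 0) abort("reference peak value is not positive")
  out <- profile
  out$intensity <- profile$intensity / ref_value
  attr(out, "normalized_to") <- as.integer(reference)
  out
}

#' Stripe features from spline extrema
#'
#' Computes, for every spline maximum with an adjacent minimum, the border
#' position — the unique position between the two extrema where the spline
#' crosses the mean of their values — and the border height, the difference
#' between the intensities at the maximum and the associated minimum. Stripe
#' identities (numbered anterior to posterior starting at stripe 1) are
#' assigned to maxima whose prominence exceeds `prominence_frac` of the
#' fitted range, so low-amplitude noise wiggles outside the expression
#' domain are not counted as stripes; in a time series the identities are
#' afterwards reconciled by \code{\link{feature_series}}.
#'
#' @param extrema data.frame from \code{\link{detect_extrema}}.
#' @param fit the \code{smoothing_spline} the extrema came from.
#' @param t registered timepoint carried through for bookkeeping.
#' @param prominence_frac minimum peak prominence, as a fraction of the
#'   fitted intensity range, for a maximum to be numbered as a stripe.
#' @param value_frac minimum peak value above the fitted floor, as a
#'   fraction of the fitted range, for a maximum to be numbered as a stripe
#'   (rejects baseline noise wiggles outside the expression domain).
#' @return object of class \code{stripe_features}: list with `t`, `extrema`,
#'   `peaks` (idx, stripe, position, value, prominence) and `borders`
#'   (peak_idx, stripe, side, position, height, level).
#' @export
stripe_features <- function(extrema, fit, t = NA_real_,
                            prominence_frac = 0.03, value_frac = 0.1) {
  stopifnot(inherits(fit, "smoothing_spline"))
  if (nrow(extrema) > 1 &&
      any(extrema$type[-1] == extrema$type[-nrow(extrema)]))
    abort("extrema must alternate min/max along the AP axis")
  peaks_ix <- which(extrema$type == "max")
  dom <- range(fit$x)
  edge_vals <- predict(fit, dom)
  neigh_val <- function(i, step) {
    j <- i + step
    if (j < 1 || j > nrow(extrema)) edge_vals[if (step < 0) 1 else 2]
    else extrema$value[j]
  }
  prominence <- vapply(peaks_ix, function(i)
    extrema$value[i] - max(neigh_val(i, -1L), neigh_val(i, 1L)), numeric(1))
  allv <- c(extrema$value, edge_vals)
  lo <- min(allv); rng <- diff(range(allv))
  is_stripe <- if (rng > 0) {
    prominence >= prominence_frac * rng &
      extrema$value[peaks_ix] >= lo + value_frac * rng
  } else rep(TRUE, length(peaks_ix))
  stripe_id <- rep(NA_integer_, length(peaks_ix))
  stripe_id[is_stripe] <- seq_len(sum(is_stripe))
  peaks <- data.frame(idx = seq_along(peaks_ix), stripe = stripe_id,
                      position = extrema$position[peaks_ix],
                      value = extrema$value[peaks_ix],
                      prominence = prominence)
  borders <- data.frame(peak_idx = integer(0), stripe = integer(0),
                        side = character(0), position = numeric(0),
                        height = numeric(0), level = numeric(0),
                        stringsAsFactors = FALSE)
  for (k in seq_along(peaks_ix)) {
    i <- peaks_ix[k]
    for (side in c("anterior", "posterior")) {
      j <- if (side == "anterior") i - 1L else i + 1L
      if (j < 1 || j > nrow(extrema)) next
      lo <- min(extrema$position[i], extrema$position[j])
      hi <- max(extrema$position[i], extrema$position[j])
      level <- (extrema$value[i] + extrema$value[j]) / 2
      root <- stats::uniroot(function(z) predict(fit, z) - level,
                             lower = lo, upper = hi, tol = 1e-10)$root
      borders <- rbind(borders, data.frame(
        peak_idx = k, stripe = stripe_id[k], side = side, position = root,
        height = extrema$value[i] - extrema$value[j], level = level,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(t = t, extrema = extrema, peaks = peaks, borders = borders,
                 fit = fit),
            class = "stripe_features")
}

#' @export
print.stripe_features <- function(x, ...) {
  cat(sprintf("Stripe features at t = %s min: %d peaks, %d borders\n",
              format(x$t), nrow(x$peaks), nrow(x$borders)))
  invisible(x)
}

#' Stripe features for a profile time series, with identity tracking
#'
#' Fits the smoothing spline and extracts stripe features at every timepoint,
#' then reconciles stripe identities across time: identities are assigned by
#' anterior-to-posterior numbering at the final (most mature) timepoint and
#' propagated backwards by nearest-position matching with a 3 percent EL gate;
#' unmatched peaks keep NA identity.
#'
#' @param profiles list of \code{expression_profile}s ordered by time.
#' @param p roughness parameter.
#' @param normalize if TRUE each profile is first normalized to its stripe-1
#'   peak (when identifiable).
#' @param gate_el identity-tracking gate, percent EL.
#' @param n_stripes expected stripe count: at the anchor (final) frame the
#'   `n_stripes` most prominent maxima are taken as the stripes, which is
#'   robust to weak genuine stripes and to low-prominence noise shoulders.
#' @return list of \code{stripe_features} (one per timepoint), same names as
#'   `profiles`.
#' @export
feature_series <- function(profiles, p = 0.5, normalize = TRUE, gate_el = 3,
                           n_stripes = 7) {
  feats <- lapply(profiles, function(pr) {
    if (normalize) pr <- tryCatch(normalize_profile(pr, 1L, p = p),
                                  error = function(e) pr)
    fit <- fit_smoothing_spline(pr, p = p)
    stripe_features(detect_extrema(fit), fit, t = attr(pr, "t"))
  })
  nT <- length(feats)
  # anchor: among final-frame maxima standing clearly above the profile
  # floor, the n_stripes most prominent, numbered anterior to posterior
  anchor <- feats[[nT]]$peaks
  fitvals <- c(feats[[nT]]$extrema$value,
               predict(feats[[nT]]$fit, range(feats[[nT]]$fit$x)))
  lo <- min(fitvals); rng <- diff(range(fitvals))
  cand <- which(anchor$value >= lo + 0.2 * rng)
  if (length(cand) == 0) cand <- seq_len(nrow(anchor))
  take <- sort(cand[order(anchor$prominence[cand], decreasing = TRUE)][
    seq_len(min(n_stripes, length(cand)))])
  ids <- rep(NA_integer_, nrow(anchor))
  # quasi-periodic template numbering: a missing stripe (e.g. a weak stripe
  # merged into its neighbour) leaves a gap in the numbering instead of
  # shifting every later identity
  pos <- anchor$position[take]
  if (length(pos) >= 3) {
    spacing <- stats::median(diff(pos))
    tmpl <- 1L + as.integer(round((pos - pos[1]) / spacing))
    if (all(diff(tmpl) >= 1) && all(tmpl <= 2L * n_stripes))
      ids[take] <- tmpl
    else ids[take] <- seq_along(take)
  } else ids[take] <- seq_along(take)
  feats[[nT]]$peaks$stripe <- ids
  if (nrow(feats[[nT]]$borders) > 0)
    feats[[nT]]$borders$stripe <-
      ids[match(feats[[nT]]$borders$peak_idx, feats[[nT]]$peaks$idx)]
  if (nT < 2) return(feats)
  # reference stripe positions: seeded at the anchor and updated walking
  # backwards, so a one-frame detection gap does not break the identity
  # chain
  ref <- feats[[nT]]$peaks
  ref <- ref[!is.na(ref$stripe), c("stripe", "position")]
  for (i in (nT - 1):1) {
    cur <- feats[[i]]$peaks
    ids <- rep(NA_integer_, nrow(cur))
    if (nrow(cur) > 0 && nrow(ref) > 0) {
      cand <- expand.grid(r = seq_len(nrow(cur)), k = seq_len(nrow(ref)))
      cand$dist <- abs(cur$position[cand$r] - ref$position[cand$k])
      cand <- cand[cand$dist <= gate_el, , drop = FALSE]
      cand <- cand[order(cand$dist), , drop = FALSE]
      used_r <- used_k <- logical(0)
      for (rw in seq_len(nrow(cand))) {
        r <- cand$r[rw]; k <- cand$k[rw]
        if (r %in% used_r || k %in% used_k) next
        ids[r] <- ref$stripe[k]
        used_r <- c(used_r, r); used_k <- c(used_k, k)
      }
    }
    feats[[i]]$peaks$stripe <- ids
    if (nrow(feats[[i]]$borders) > 0)
      feats[[i]]$borders$stripe <-
        ids[match(feats[[i]]$borders$peak_idx, feats[[i]]$peaks$idx)]
    # update reference positions with this frame's matches
    hit <- !is.na(ids)
    if (any(hit))
      ref$position[match(ids[hit], ref$stripe)] <- cur$position[hit]
  }
  feats
}

# convenience accessors used by the phenotype layer -------------------------

peak_of <- function(features, stripe) {
  pk <- features$peaks
  w <- which(pk$stripe == stripe)
  if (length(w) != 1) return(NULL)
  pk[w, , drop = FALSE]
}

border_of <- function(features, stripe, side) {
  b <- features$borders
  w <- which(b$stripe == stripe & b$side == side)
  if (length(w) != 1) return(NULL)
  b[w, , drop = FALSE]
}
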