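#' Relative activation of stripe 2
#'
#' Ratio of the stripe-2 peak expression to that of a reference stripe
#' (stripe 1 by default): a within-embryo measure of stripe-2 activation that
#' cancels embryo-to-embryo imaging variation.
#'
#' @param features a \code{stripe_features} object.
#' @param reference reference stripe index.
#' @return the ratio, or NA if either peak is missing (excluded upstream).
#' @export
relative_activation <- function(features, reference = 1L) {
  p2 <- peak_of(features, 2L); pr <- peak_of(features, reference)
  if (is.null(p2) || is.null(pr)) return(NA_real_)
  p2$value / pr$value
}

#' Relative repression of the stripe-2 anterior border
#'
#' Ratio of the anterior (2A) to posterior (2P) stripe-2 border heights. A
#' ratio near 1 means symmetric borders; small values mean a derepressed
#' anterior border. Very large ratios arising while a border is first
#' established are flagged for exclusion from time-series plots but retained
#' for statistics.
#'
#' @param features a \code{stripe_features} object.
#' @param exclusion_threshold plot-exclusion cutoff on the ratio.
#' @return the ratio (possibly Inf) with attribute `plot_excluded`; NA if a
#'   border height is missing.
#' @export
relative_repression <- function(features, exclusion_threshold = 10) {
  a <- border_of(features, 2L, "anterior")
  p <- border_of(features, 2L, "posterior")
  if (is.null(a) || is.null(p)) return(NA_real_)
  r <- if (p$height == 0) Inf else a$height / p$height
  structure(r, plot_excluded = is.infinite(r) || r > exclusion_threshold)
}

# presence of the two interstripe minima flanking stripe 2 at each
# timepoint. Minima are scored inside the 1-2 and 2-3 interstripe windows
# (taken from the anchor-frame stripe positions), after pruning spline
# extrema pairs of negligible contrast, so a one-sided emergence state (one
# border formed while the stripe is still merged on the other side) is
# detectable before the stripe-2 peak individuates.
flanking_minima_presence <- function(series, min_contrast = 0.02) {
  nT <- length(series)
  anchor <- series[[nT]]$peaks
  pos <- function(id) {
    w <- which(anchor$stripe == id)
    if (length(w) == 1) anchor$position[w] else NA_real_
  }
  p1 <- pos(1L); p2 <- pos(2L); p3 <- pos(3L)
  if (any(is.na(c(p1, p2, p3)))) {
    # fall back to peak-adjacent borders when the stripe template is absent
    return(t(vapply(series, function(f) {
      c(anterior = !is.null(border_of(f, 2L, "anterior")),
        posterior = !is.null(border_of(f, 2L, "posterior")))
    }, logical(2))))
  }
  t(vapply(series, function(f) {
    ext <- f$extrema
    while (nrow(ext) >= 2) {
      dv <- abs(diff(ext$value))
      k <- which.min(dv)
      if (dv[k] >= min_contrast) break
      ext <- ext[-c(k, k + 1L), , drop = FALSE]
    }
    mins <- ext$position[ext$type == "min"]
    c(anterior = any(mins > p1 & mins < p2),
      posterior = any(mins > p2 & mins < p3))
  }, logical(2)))
}

#' Time of first appearance of an incipient stripe 2
#'
#' An incipient stripe 2 has formed at the earliest timepoint at which both
#' local minima corresponding to the future 1-2 and 2-3 interstripes are
#' detected and stably maintained at all subsequent timepoints, tolerating at
#' most one missing later timepoint (weak stripes can drop below detection
#' for a single frame).
#'
#' @param series list of \code{stripe_features} ordered by time (as from
#'   \code{\link{feature_series}}).
#' @param times timepoints (minutes); defaults to the `t` stored on the
#'   features.
#' @return initiation time in minutes, or NA if never satisfied.
#' @export
detect_incipient_stripe <- function(series, times = NULL) {
  if (length(series) < 3) abort("need features at >= 3 timepoints")
  if (is.null(times)) times <- vapply(series, function(f) f$t, numeric(1))
  pres <- flanking_minima_presence(series)
  both <- pres[, "anterior"] & pres[, "posterior"]
  n <- length(both)
  for (i in seq_len(n)) {
    if (!both[i]) next
    if (sum(!both[i:n]) <= 1) return(times[i])
  }
  NA_real_
}

#' Order of appearance of the stripe-2 borders
#'
#' Classifies an embryo by which of the two interstripe minima flanking the
#' stripe-2 peak was detected first. A minimum counts only if it is genuine:
#' it must persist to the final timepoint (developing into a mature
#' interstripe), tolerating at most one missing intermediate frame. Embryos
#' whose two minima first appear in the same frame, or in which a genuine
#' minimum cannot be established, are unresolved.
#'
#' @inheritParams detect_incipient_stripe
#' @return "anterior_first", "posterior_first" or "unresolved".
#' @export
classify_border_order <- function(series, times = NULL) {
  if (is.null(times)) times <- vapply(series, function(f) f$t, numeric(1))
  pres <- flanking_minima_presence(series)
  n <- nrow(pres)
  first_valid <- function(v) {
    if (!v[n]) return(NA_real_)          # never matured
    for (i in seq_len(n)) {
      if (!v[i]) next
      if (sum(!v[i:n]) <= 1) return(times[i])
    }
    NA_real_
  }
  ta <- first_valid(pres[, "anterior"])
  tp <- first_valid(pres[, "posterior"])
  if (is.na(ta) || is.na(tp) || ta == tp) return("unresolved")
  if (ta < tp) "anterior_first" else "posterior_first"
}

#' Across-embryo positional variation of stripe-2 landmarks
#'
#' Sample standard deviation (n-1 denominator), across embryos, of the
#' stripe-2 peak, anterior-border or posterior-border position at each
#' timepoint. The SD is over embryos, never over nuclei.
#'
#' @param cohort_features list (one element per embryo) of feature series as
#'   from \code{\link{feature_series}}.
#' @param trait "peak", "anterior" or "posterior".
#' @param times common timepoint grid; defaults to the first embryo's.
#' @return data.frame with `t`, `sd` (percent EL) and `n`; cells with n < 2
#'   are NA.
#' @export
positional_variation <- function(cohort_features,
                                 trait = c("peak", "anterior", "posterior"),
                                 times = NULL) {
  trait <- match.arg(trait)
  if (is.null(times))
    times <- vapply(cohort_features[[1]], function(f) f$t, numeric(1))
  get_pos <- function(f) {
    if (trait == "peak") {
      p <- peak_of(f, 2L); if (is.null(p)) NA_real_ else p$position
    } else {
      b <- border_of(f, 2L, trait); if (is.null(b)) NA_real_ else b$position
    }
  }
  out <- data.frame(t = times, sd = NA_real_, n = 0L)
  for (i in seq_along(times)) {
    v <- vapply(cohort_features, function(ser) get_pos(ser[[i]]), numeric(1))
    v <- v[is.finite(v)]
    out$n[i] <- length(v)
    if (length(v) >= 2) out$sd[i] <- stats::sd(v)
  }
  out
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum comparison
#'
#' Compares two samples of phenotype values with the rank-sum test (the test
#' used for all phenotype comparisons here). For small samples
#' (min(n) <= 8 and a feasible enumeration) the two-sided p-value is computed
#' by exhaustive enumeration of all rank assignments, which handles ties
#' exactly; otherwise the normal approximation with tie correction is used
#' (no continuity correction).
#'
#' @param a,b numeric samples (plot-excluded values are included; infinite
#'   values are supported by the ranking).
#' @return two-sided p-value.
#' @export
compare_groups <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) abort("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)               # midranks for ties; handles +/-Inf
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (n1 + n2 + 1) / 2
  if (min(n1, n2) <= 8 && choose(n1 + n2, n1) <= 2e5) {
    dev <- abs(W - EW)
    combs <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    return(mean(abs(sums - EW) >= dev - 1e-9))
  }
  ties <- table(r)
  n <- n1 + n2
  varW <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  if (varW <= 0) return(1)
  z <- (W - EW) / sqrt(varW)
  2 * stats::pnorm(-abs(z))
}

#' Rescale absolute time by the developmental-rate ratio
#'
#' Maps a time measured at the faster temperature onto the 25C developmental
#' timeline: t_scaled = t * landmark_25C / landmark_29C, where the landmarks
#' are the times at which the cellularization membrane reaches the basal end
#' of the nuclei (38.2 min at 25C, 30.6 min at 29C).
#'
#' @param t absolute minutes.
#' @param rate_25C_landmark,rate_29C_landmark landmark times, minutes (> 0).
#' @return scaled minutes.
#' @export
scale_developmental_time <- function(t, rate_25C_landmark = 38.2,
                                     rate_29C_landmark = 30.6) {
  if (rate_25C_landmark <= 0 || rate_29C_landmark <= 0)
    abort("landmark times must be positive")
  t * rate_25C_landmark / rate_29C_landmark
}

#' Per-embryo concordance of two fluorescence channels
#'
#' Squared Pearson correlation between paired per-nucleus values from two
#' channels, each first normalized to the maximum observed in that embryo
#' and channel. Used to establish the fidelity of a tagged reporter against
#' an antibody stain.
#'
#' @param nuclei data.frame with columns `embryo_id`, `channel1`, `channel2`
#'   (per-nucleus mean fluorescence).
#' @return data.frame with `embryo_id`, `r2`, `n`; r2 is NA if a channel is
#'   constant.
#' @export
channel_concordance <- function(nuclei) {
  stopifnot(all(c("embryo_id", "channel1", "channel2") %in% names(nuclei)))
  res <- lapply(split(nuclei, nuclei$embryo_id), function(d) {
    x <- d$channel1 / max(d$channel1)
    y <- d$channel2 / max(d$channel2)
    r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
          else stats::cor(x, y)^2
    data.frame(embryo_id = d$embryo_id[1], r2 = r2, n = nrow(d))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Phenotype time series of one embryo
#'
#' Runs the feature pipeline on an embryo's profile series and assembles the
#' per-timepoint stripe-2 phenotypes plus the series-level initiation time
#' and border-order class.
#'
#' @param profiles list of \code{expression_profile}s ordered by time.
#' @param p roughness parameter.
#' @param exclusion_threshold plot-exclusion cutoff for relative repression.
#' @return object of class \code{phenotype_series}: list with `table`
#'   (data.frame t, activation, repression, repression_excluded, peak_pos,
#'   anterior_pos, posterior_pos), `initiation_time`, `border_order`,
#'   `features`.
#' @export
embryo_phenotypes <- function(profiles, p = 0.5, exclusion_threshold = 10) {
  feats <- feature_series(profiles, p = p)
  times <- vapply(feats, function(f) f$t, numeric(1))
  tab <- data.frame(t = times, activation = NA_real_, repression = NA_real_,
                    repression_excluded = FALSE, peak_pos = NA_real_,
                    anterior_pos = NA_real_, posterior_pos = NA_real_)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    tab$activation[i] <- relative_activation(f)
    rr <- relative_repression(f, exclusion_threshold)
    tab$repression[i] <- as.numeric(rr)
    tab$repression_excluded[i] <- isTRUE(attr(rr, "plot_excluded"))
    pk <- peak_of(f, 2L)
    if (!is.null(pk)) tab$peak_pos[i] <- pk$position
    ba <- border_of(f, 2L, "anterior")
    if (!is.null(ba)) tab$anterior_pos[i] <- ba$position
    bp <- border_of(f, 2L, "posterior")
    if (!is.null(bp)) tab$posterior_pos[i] <- bp$position
  }
  structure(list(table = tab,
                 initiation_time = detect_incipient_stripe(feats, times),
                 border_order = classify_border_order(feats, times),
                 features = feats),
            class = "phenotype_series")
}

#' @export
print.phenotype_series <- function(x, ...) {
  cat(sprintf("Stripe-2 phenotype series: %d timepoints, initiation %s min, %s\n",
              nrow(x$table), format(x$initiation_time), x$border_order))
  invisible(x)
}

#' Cohort summary of stripe-2 phenotypes
#'
#' Per-timepoint mean, SD and SEM across embryos for a phenotype, with sample
#' sizes. A missing phenotype at a timepoint drops that cell, never the
#' embryo.
#'
#' @param phenos list of \code{phenotype_series} (one per embryo).
#' @param what "activation" or "repression".
#' @return data.frame t, mean, sd, sem, n.
#' @export
cohort_summary <- function(phenos, what = c("activation", "repression")) {
  what <- match.arg(what)
  times <- phenos[[1]]$table$t
  out <- data.frame(t = times, mean = NA_real_, sd = NA_real_,
                    sem = NA_real_, n = 0L)
  for (i in seq_along(times)) {
    v <- vapply(phenos, function(ph) ph$table[[what]][i], numeric(1))
    v <- v[is.finite(v)]
    out$n[i] <- length(v)
    if (length(v) >= 2) {
      out$mean[i] <- mean(v); out$sd[i] <- stats::sd(v)
      out$sem[i] <- out$sd[i] / sqrt(length(v))
    } else if (length(v) == 1) out$mean[i] <- v
  }
  out
}
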