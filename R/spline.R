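#' Fit a smoothing cubic spline with an explicit roughness parameter
#'
#' Fits the natural cubic smoothing spline f minimising
#' \deqn{p \sum_i (y_i - f(x_i))^2 + (1 - p) \int f''(x)^2 dx,}
#' the convention in which \code{p = 1} interpolates the data (zero residuals)
#' and \code{p = 0} is the least-squares straight line. The fit is
#' scale-dependent: by contract x is AP position in percent EL and y is
#' fluorescence normalized to [0, 1], and the default \code{p = 0.5} is the
#' operating point used throughout the stripe analysis.
#'
#' Data sharing an AP bin of 0.1 percent EL are averaged before fitting.
#'
#' @param x AP positions (percent EL), or an \code{expression_profile} (then
#'   `y` is taken from it).
#' @param y intensities.
#' @param p roughness parameter in [0, 1]; default 0.5.
#' @return an object of class \code{smoothing_spline} with knots, fitted knot
#'   values, natural second derivatives, residuals and `p`.
#' @export
fit_smoothing_spline <- function(x, y = NULL, p = 0.5) {
  if (inherits(x, "expression_profile")) { y <- x$intensity; x <- x$ap }
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1)
    abort("roughness parameter p must lie in [0, 1]")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  # average duplicates within 0.1 %EL bins
  bin <- round(x / 0.1)
  if (anyDuplicated(bin)) {
    x <- as.numeric(tapply(x, bin, mean))
    y <- as.numeric(tapply(y, bin, mean))
  }
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  if (n < 4) abort("need at least 4 distinct samples to fit a spline")

  if (p == 0) {
    fit <- stats::lm.fit(cbind(1, x), y)
    return(structure(list(p = 0, x = x, y = y, coef = fit$coefficients,
                          residuals = fit$residuals),
                     class = "smoothing_spline"))
  }

  h <- diff(x)
  if (p == 1) {
    a <- y
    m <- natural_second_derivs(x, y)
    res <- rep(0, n)
  } else {
    alpha <- (1 - p) / p
    Q <- matrix(0, n, n - 2)
    for (j in seq_len(n - 2)) {
      Q[j, j]     <- 1 / h[j]
      Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
      Q[j + 2, j] <- 1 / h[j + 1]
    }
    R <- matrix(0, n - 2, n - 2)
    diag(R) <- (h[-(n - 1)] + h[-1]) / 3
    if (n > 3) {
      for (j in seq_len(n - 3)) R[j, j + 1] <- R[j + 1, j] <- h[j + 1] / 6
    }
    gam <- solve(R + alpha * crossprod(Q), crossprod(Q, y))
    a <- y - alpha * as.numeric(Q %*% gam)
    m <- c(0, as.numeric(gam), 0)
    res <- y - a
  }
  structure(list(p = p, x = x, y = y, knots = x, a = a, m = m,
                 residuals = res),
            class = "smoothing_spline")
}

# second derivatives of the natural interpolating spline through (x, y)
natural_second_derivs <- function(x, y) {
  n <- length(x); h <- diff(x)
  if (n < 3) return(rep(0, n))
  R <- matrix(0, n - 2, n - 2)
  diag(R) <- (h[-(n - 1)] + h[-1]) / 3
  if (n > 3) for (j in seq_len(n - 3)) R[j, j + 1] <- R[j + 1, j] <- h[j + 1] / 6
  d2 <- diff(y) / h
  rhs <- diff(d2)
  c(0, solve(R, rhs), 0)
}

#' Evaluate a smoothing spline (or its derivatives)
#'
#' @param object a \code{smoothing_spline}.
#' @param x evaluation positions (clamped extrapolation is linear, as the
#'   natural spline's second derivative vanishes at the boundary).
#' @param deriv 0, 1 or 2.
#' @param ... unused.
#' @return numeric vector of f(x), f'(x) or f''(x).
#' @export
predict.smoothing_spline <- function(object, x, deriv = 0, ...) {
  if (object$p == 0) {
    b <- object$coef
    return(switch(as.character(deriv),
                  "0" = b[1] + b[2] * x,
                  "1" = rep(b[2], length(x)),
                  "2" = rep(0, length(x))))
  }
  kn <- object$knots; a <- object$a; m <- object$m
  n <- length(kn)
  i <- findInterval(x, kn, all.inside = TRUE)
  h <- kn[i + 1] - kn[i]
  u <- x - kn[i]; v <- kn[i + 1] - x
  if (deriv == 0) {
    a[i] * v / h + a[i + 1] * u / h +
      (v^3 / h - h * v) * m[i] / 6 + (u^3 / h - h * u) * m[i + 1] / 6
  } else if (deriv == 1) {
    (a[i + 1] - a[i]) / h - (3 * v^2 / h - h) * m[i] / 6 +
      (3 * u^2 / h - h) * m[i + 1] / 6
  } else if (deriv == 2) {
    m[i] * v / h + m[i + 1] * u / h
  } else abort("deriv must be 0, 1 or 2")
}

#' @export
residuals.smoothing_spline <- function(object, ...) object$residuals

#' @export
print.smoothing_spline <- function(x, ...) {
  cat(sprintf("Smoothing cubic spline: p = %g, %d knots on [%.2f, %.2f]\n",
              x$p, length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

#' Locate the interior extrema of a fitted spline
#'
#' Solves f'(x) = 0 analytically on each knot interval (f' is piecewise
#' quadratic) and classifies each root by the sign of f''. Domain endpoints
#' are excluded. Extrema alternate min/max along the axis.
#'
#' @param fit a \code{smoothing_spline}.
#' @return data.frame with columns `position`, `value`, `type` ("min"/"max"),
#'   ordered by position.
#' @export
detect_extrema <- function(fit) {
  stopifnot(inherits(fit, "smoothing_spline"))
  empty <- data.frame(position = numeric(0), value = numeric(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (fit$p == 0) return(empty)
  kn <- fit$knots; a <- fit$a; m <- fit$m
  n <- length(kn)
  pos <- numeric(0)
  for (i in seq_len(n - 1)) {
    h <- kn[i + 1] - kn[i]
    A <- (m[i + 1] - m[i]) / (2 * h)
    B <- m[i]
    C <- (a[i + 1] - a[i]) / h - h * (2 * m[i] + m[i + 1]) / 6
    roots <- quad_roots(A, B, C)
    roots <- roots[roots >= -1e-9 & roots < h - 1e-9]
    pos <- c(pos, kn[i] + roots)
  }
  if (length(pos) == 0) return(empty)
  pos <- sort(unique(pos))
  # drop near-duplicates and domain endpoints
  if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) > 1e-7)]
  eps <- 1e-7 * (kn[n] - kn[1])
  pos <- pos[pos > kn[1] + eps & pos < kn[n] - eps]
  if (length(pos) == 0) return(empty)
  d2 <- predict(fit, pos, deriv = 2)
  keep <- abs(d2) > 1e-12
  pos <- pos[keep]; d2 <- d2[keep]
  if (length(pos) == 0) return(empty)
  ext <- data.frame(position = pos, value = predict(fit, pos),
                    type = ifelse(d2 > 0, "min", "max"),
                    stringsAsFactors = FALSE)
  # enforce alternation: among runs of equal type keep the most extreme
  if (nrow(ext) > 1) {
    run <- cumsum(c(TRUE, ext$type[-1] != ext$type[-nrow(ext)]))
    keep <- unlist(lapply(split(seq_len(nrow(ext)), run), function(ix) {
      if (length(ix) == 1) return(ix)
      if (ext$type[ix[1]] == "max") ix[which.max(ext$value[ix])]
      else ix[which.min(ext$value[ix])]
    }))
    ext <- ext[sort(keep), , drop = FALSE]
    rownames(ext) <- NULL
  }
  ext
}

# real roots of A u^2 + B u + C = 0, degenerate cases included
quad_roots <- function(A, B, C) {
  if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) return(numeric(0))
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  sq <- sqrt(disc)
  # numerically stable quadratic roots
  q <- -(B + sign(B + (B == 0)) * sq) / 2
  r <- c(q / A, if (abs(q) > 1e-300) C / q else numeric(0))
  unique(r)
}
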