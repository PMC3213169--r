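# Stripe-2 phenotypes and cohort statistics.

# minimal hand-built feature objects for the ratio operations
fake_features <- function(peaks, borders) {
  structure(list(t = NA_real_,
                 extrema = data.frame(position = numeric(0),
                                      value = numeric(0),
                                      type = character(0)),
                 peaks = peaks, borders = borders),
            class = "stripe_features")
}

test_that("relative activation is the stripe-2 / reference peak ratio", {
  pk <- data.frame(idx = 1:2, stripe = 1:2, position = c(33, 41),
                   value = c(1.0, 0.5), prominence = c(1, 0.5))
  f <- fake_features(pk, data.frame())
  expect_equal(relative_activation(f), 0.5)
  pk$value <- c(0.8, 0.8)
  expect_equal(relative_activation(fake_features(pk, data.frame())), 1.0)
  pk2 <- pk[1, ]
  expect_true(is.na(relative_activation(fake_features(pk2, data.frame()))))
})

test_that("relative repression follows the border-height ratio and exclusion rule", {
  bd <- function(a, p) data.frame(peak_idx = 2, stripe = 2,
                                  side = c("anterior", "posterior"),
                                  position = c(37, 44), height = c(a, p),
                                  level = c(0.5, 0.5))
  pk <- data.frame(idx = 2, stripe = 2, position = 41, value = 0.9,
                   prominence = 0.5)
  expect_equal(as.numeric(relative_repression(fake_features(pk, bd(0.4, 0.4)))), 1)
  expect_equal(as.numeric(relative_repression(fake_features(pk, bd(0.2, 0.4)))), 0.5)
  r <- relative_repression(fake_features(pk, bd(6, 0.1)))
  expect_equal(as.numeric(r), 60)
  expect_true(attr(r, "plot_excluded"))
  rinf <- relative_repression(fake_features(pk, bd(1, 0)))
  expect_true(is.infinite(rinf))
  expect_true(attr(rinf, "plot_excluded"))
  # flagged values stay usable for statistics
  expect_silent(compare_groups(c(1, 2, as.numeric(r)), c(1, 2, 3)))
})

# build a feature series with prescribed per-frame minima presence; the
# anchor frame carries stripes 1..3 so the interstripe windows are defined
presence_series <- function(times, amin, pmin) {
  mapply(function(t, a, p) {
    ext <- data.frame(position = 33, value = 1, type = "max")
    if (a) ext <- rbind(ext, data.frame(position = 37, value = 0.4, type = "min"))
    ext <- rbind(ext, data.frame(position = 41, value = 0.8, type = "max"))
    if (p) ext <- rbind(ext, data.frame(position = 44, value = 0.35, type = "min"))
    ext <- rbind(ext, data.frame(position = 47, value = 0.9, type = "max"))
    ext <- ext[order(ext$position), ]
    pk <- ext[ext$type == "max", ]
    peaks <- data.frame(idx = seq_len(nrow(pk)), stripe = 1:3,
                        position = pk$position, value = pk$value,
                        prominence = 0.5)
    structure(list(t = t, extrema = ext, peaks = peaks,
                   borders = data.frame()),
              class = "stripe_features")
  }, times, amin, pmin, SIMPLIFY = FALSE)
}

test_that("incipient-stripe timing applies the one-missing-frame tolerance", {
  ts <- seq(30, 48, 3)
  both <- presence_series(ts, rep(TRUE, 7), rep(TRUE, 7))
  expect_equal(detect_incipient_stripe(both, ts), 30)
  # present at 33, absent at 36, present after: the miss is tolerated
  a <- c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  ser <- presence_series(ts, a, rep(TRUE, 7))
  expect_equal(detect_incipient_stripe(ser, ts), 33)
  # two missing later frames: the start moves past them
  a2 <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  expect_equal(detect_incipient_stripe(presence_series(ts, a2, rep(TRUE, 7)), ts), 39)
  # a minimum that never appears leaves the time undefined
  none <- presence_series(ts, rep(FALSE, 7), rep(TRUE, 7))
  expect_true(is.na(detect_incipient_stripe(none, ts)))
  expect_error(detect_incipient_stripe(both[1:2]), ">= 3")
})

test_that("border order reflects first valid detection; ties unresolved", {
  ts <- seq(24, 39, 3)
  post_first <- presence_series(ts, c(F, T, T, T, T, T), c(T, T, T, T, T, T))
  expect_identical(classify_border_order(post_first, ts), "posterior_first")
  ant_first <- presence_series(ts, c(T, T, T, T, T, T), c(F, T, T, T, T, T))
  expect_identical(classify_border_order(ant_first, ts), "anterior_first")
  tie <- presence_series(ts, c(F, T, T, T, T, T), c(F, T, T, T, T, T))
  expect_identical(classify_border_order(tie, ts), "unresolved")
  # a minimum absent at the final frame never matured: unresolved
  flicker <- presence_series(ts, c(T, T, F, F, T, F), c(T, T, T, T, T, T))
  expect_identical(classify_border_order(flicker, ts), "unresolved")
})

test_that("positional variation is the across-embryo n-1 sample SD", {
  ts <- c(36, 39)
  mk <- function(shift) presence_series(ts, c(TRUE, TRUE), c(TRUE, TRUE)) |>
    lapply(function(f) { f$peaks$position <- f$peaks$position + shift; f })
  cohort <- lapply(c(-1, 0, 2), mk)
  pv <- positional_variation(cohort, "peak", ts)
  expect_equal(pv$sd, rep(stats::sd(c(-1, 0, 2)), 2))
  expect_identical(pv$n, c(3L, 3L))
  # identical positions: zero SD; single embryo: undefined
  same <- lapply(c(0, 0), mk)
  expect_equal(positional_variation(same, "peak", ts)$sd, c(0, 0))
  one <- lapply(0, mk)
  expect_true(all(is.na(positional_variation(one, "peak", ts)$sd)))
  # against the direct formula on random vectors
  set.seed(8)
  v <- rnorm(20, 40, 2)
  cohort2 <- lapply(v - 33, mk)   # peaks at 33 + shift
  expect_equal(positional_variation(cohort2, "peak", ts)$sd[1],
               sqrt(sum((v - mean(v))^2) / 19), tolerance = 1e-12)
})

test_that("rank-sum p-values match exhaustive enumeration for small samples", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(11)
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    a <- sample(1:6, n1, replace = TRUE)   # ties included
    b <- sample(1:6, n2, replace = TRUE)
    expect_equal(compare_groups(a, b), ranksum_enum(a, b),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("large-sample rank-sum agrees with the tie-corrected normal form", {
  set.seed(12)
  a <- rnorm(30); b <- rnorm(35, 0.5)
  p <- compare_groups(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p, ref, tolerance = 1e-10)
  # with ties
  a2 <- sample(1:5, 25, TRUE); b2 <- sample(1:5, 30, TRUE)
  expect_equal(compare_groups(a2, b2),
               stats::wilcox.test(a2, b2, exact = FALSE,
                                  correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("developmental-time scaling is the landmark ratio and is linear", {
  expect_equal(scale_developmental_time(30, 38.2, 30.6), 30 * 38.2 / 30.6)
  expect_equal(scale_developmental_time(30, 38.2, 30.6), 37.45, tolerance = 0.01)
  expect_equal(scale_developmental_time(12, 35, 35), 12)
  expect_equal(scale_developmental_time(24, 38.2, 30.6),
               2 * scale_developmental_time(12, 38.2, 30.6))
  expect_error(scale_developmental_time(10, 0, 30), "positive")
})

test_that("channel concordance recovers exact and analytic r-squared", {
  x <- runif(50, 0.1, 1)
  d <- rbind(data.frame(embryo_id = "a", channel1 = x, channel2 = x),
             data.frame(embryo_id = "b", channel1 = x, channel2 = 2 * x))
  cc <- channel_concordance(d)
  expect_equal(cc$r2, c(1, 1), tolerance = 1e-12)
  # additive noise: r2 -> var(x) / (var(x) + sigma^2)
  set.seed(13)
  n <- 1e4
  xx <- rnorm(n, 0.5, 0.2); yy <- xx + rnorm(n, 0, 0.1)
  cc2 <- channel_concordance(data.frame(embryo_id = "c",
                                        channel1 = xx - min(xx) + 0.01,
                                        channel2 = yy - min(yy) + 0.01))
  expect_equal(cc2$r2, 0.04 / (0.04 + 0.01), tolerance = 0.02)
  # constant channel: undefined
  cc3 <- channel_concordance(data.frame(embryo_id = "d", channel1 = rep(1, 5),
                                        channel2 = 1:5))
  expect_true(is.na(cc3$r2))
})
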