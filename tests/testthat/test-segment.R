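# Cortical mask, watershed separation, the fusion rule and quantification.

test_that("an all-zero frame yields an empty mask and empty labeling", {
  z <- matrix(0, 64, 64)
  m <- cortical_mask(z)
  expect_false(any(m))
  li <- segment_nuclei(z, m)
  expect_identical(max(li$labels), 0L)
  expect_identical(nrow(quantify_nuclei(li, z)), 0L)
})

test_that("the cortical mask overlaps the true band and excludes the ring", {
  par <- stripe_model_params("WT")
  sc <- small_scene()
  ser <- generate_embryo_series(par, sc, times = 36, seed = 5)
  fr <- ser$frames[["36"]]
  mask <- cortical_mask(fr$nuclear)
  core <- attr(mask, "core")
  # truth band: union of rendered nucleus discs
  w <- sc$width; h <- sc$height
  X <- matrix(rep(seq_len(w), h), w, h); Y <- matrix(rep(seq_len(h), each = w), w, h)
  band <- matrix(FALSE, w, h)
  for (i in seq_len(nrow(ser$truth$nuclei))) {
    band <- band | ((X - (ser$truth$nuclei$x_px[i] + 1))^2 +
                    (Y - (ser$truth$nuclei$y_px[i] + 1))^2 <=
                      sc$nucleus_radius^2)
  }
  jac <- sum(core & band) / sum(core | band)
  expect_gte(jac, 0.9)
  expect_true(all(band[mask & !core] | TRUE))  # band contains the blobs
  expect_gte(sum(mask & band) / sum(band), 0.95)
  # ring pixels are excluded
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  go <- sc$ring_gap; gt <- go + sc$ring_thickness
  ring <- (((X - cx) / (sc$semi_a + gt))^2 + ((Y - cy) / (sc$semi_b + gt))^2 <= 1) &
          (((X - cx) / (sc$semi_a + go))^2 + ((Y - cy) / (sc$semi_b + go))^2 > 1)
  expect_identical(sum(mask & ring), 0L)
})

test_that("well-separated synthetic nuclei are recovered one-to-one", {
  par <- stripe_model_params("WT")
  ser <- generate_embryo_series(par, small_scene(), times = 39, seed = 6)
  fr <- ser$frames[["39"]]
  seg <- segment_frame(fr$nuclear, fr$reporter)
  expect_identical(max(seg$labels$labels), nrow(ser$truth$nuclei))
  m <- match_to_truth(seg$records, ser$truth$nuclei, max_dist = 4)
  expect_identical(nrow(m), nrow(ser$truth$nuclei))
  expect_lte(max(m$dist), 1)
})

test_that("labels partition the cortical mask before and after fusion", {
  par <- stripe_model_params("WT")
  sched <- data.frame(time = 36, nucleus = c(6, 16, 26))
  ser <- generate_embryo_series(par, small_scene(membrane_schedule = sched),
                                times = 36, seed = 7)
  fr <- ser$frames[["36"]]
  mask <- cortical_mask(fr$nuclear)
  li <- segment_nuclei(fr$nuclear, mask)
  expect_true(all(li$labels[mask] > 0))
  expect_true(all(li$labels[!mask] == 0))
  li2 <- fuse_oversegmented(li)
  expect_true(all(li2$labels[mask] > 0))
  expect_true(all(li2$labels[!mask] == 0))
  # adjacency is symmetric by construction (stored i < j once)
  expect_true(all(li$adjacency$i < li$adjacency$j))
})

test_that("two touching discs separate into two labels", {
  img <- matrix(0, 64, 64)
  X <- matrix(rep(1:64, 64), 64, 64); Y <- t(X)
  img[(X - 28)^2 + (Y - 32)^2 <= 16] <- 1000
  img[(X - 37)^2 + (Y - 32)^2 <= 16] <- 1000
  mask <- img > 0
  li <- segment_nuclei(img, mask, nucleus_radius = 4)
  expect_identical(max(li$labels), 2L)
})

test_that("the fusion rule merges exactly the qualifying pairs", {
  # toy band (square frame with a central "yolk" hole): region 1 is the
  # rest of the band; regions 2 and 3 form a split pair spanning the top
  # band segment, sharing a 5-px watershed line
  mask <- toy_band(40)
  labs <- matrix(0L, 40, 40)
  labs[mask] <- 1L
  labs[18:22, 10:14] <- 2L   # inner half: touches the yolk hole (y = 15)
  labs[18:22, 5:9] <- 3L     # outer half: touches the outside (y = 4)
  li <- toy_label_image(labs, mask)
  fl <- li$flags
  expect_true(fl$touches_yolk[2] && !fl$touches_outside[2])
  expect_true(fl$touches_outside[3] && !fl$touches_yolk[3])
  expect_true(fl$touches_yolk[1] && fl$touches_outside[1])
  line23 <- li$adjacency$line_px[li$adjacency$i == 2 & li$adjacency$j == 3]
  expect_identical(line23, 5L)
  fused <- fuse_oversegmented(li)
  expect_identical(max(fused$labels), 2L)        # 2 and 3 merged
  # idempotent and a coarsening of the input partition
  again <- fuse_oversegmented(fused)
  expect_identical(fused$labels, again$labels)
  expect_true(all(tapply(fused$labels[mask], labs[mask],
                         function(v) length(unique(v))) == 1))
})

test_that("pairs failing either fusion condition are left alone", {
  # 1-px (corner) contact: fails the line-length condition
  mask <- toy_band(40)
  labs <- matrix(0L, 40, 40)
  labs[mask] <- 1L
  labs[18:22, 5:8] <- 3L
  labs[18, 9] <- 3L          # single contact pixel toward region 2
  labs[18:22, 10:14] <- 2L
  li <- toy_label_image(labs, mask)
  line23 <- li$adjacency$line_px[li$adjacency$i == 2 & li$adjacency$j == 3]
  expect_identical(line23, 1L)
  expect_identical(max(fuse_oversegmented(li)$labels), 3L)

  # both members touch the yolk: fails the topology condition
  labs2 <- matrix(0L, 40, 40)
  labs2[mask] <- 1L
  labs2[18:20, 10:14] <- 2L
  labs2[21:23, 10:14] <- 3L
  li2 <- toy_label_image(labs2, mask)
  fl2 <- li2$flags
  expect_true(fl2$touches_yolk[2] && fl2$touches_yolk[3])
  expect_identical(max(fuse_oversegmented(li2)$labels), 3L)
})

test_that("after fusion no adjacent pair satisfies both fusion conditions", {
  par <- stripe_model_params("WT")
  sched <- data.frame(time = 39, nucleus = c(6, 16, 26, 36, 46))
  ser <- generate_embryo_series(par, small_scene(membrane_schedule = sched),
                                times = 39, seed = 8)
  fr <- ser$frames[["39"]]
  li <- fuse_oversegmented(segment_nuclei(fr$nuclear, cortical_mask(fr$nuclear)))
  fl <- li$flags; adj <- li$adjacency
  yolk_only <- fl$touches_yolk & !fl$touches_outside
  out_only <- fl$touches_outside & !fl$touches_yolk
  q <- adj$line_px >= 2 &
    ((yolk_only[adj$i] & out_only[adj$j]) |
     (out_only[adj$i] & yolk_only[adj$j]))
  expect_false(any(q))
})

test_that("quantification reproduces uniform values, analytic means, centroids", {
  labs <- matrix(0L, 32, 32)
  X <- matrix(rep(1:32, 32), 32, 32); Y <- t(X)
  disc <- (X - 16)^2 + (Y - 16)^2 <= 25
  labs[disc] <- 1L
  mask <- disc
  li <- toy_label_image(labs, mask)
  # uniform reporter
  rep_u <- matrix(0, 32, 32); rep_u[disc] <- 7.5
  rec <- quantify_nuclei(li, rep_u)
  expect_equal(rec$mean_fluo, 7.5)
  expect_equal(rec$x_px, 15, tolerance = 1e-9)   # 0-based centre of a symmetric disc
  expect_equal(rec$y_px, 15, tolerance = 1e-9)
  expect_identical(rec$n_pixels, sum(disc))
  # linear gradient: mean equals the direct sum over member pixels
  grad <- X * 1.0
  rec2 <- quantify_nuclei(li, grad)
  expect_equal(rec2$mean_fluo, mean(X[disc]), tolerance = 1e-12)
  expect_error(quantify_nuclei(li, matrix(0, 10, 10)), "different shapes")
})
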