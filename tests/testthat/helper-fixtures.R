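# Shared fixtures: all built in code at test time.

# a small static single-stripe model (no width dynamics, no fills)
single_stripe_params <- function(mu = 40, sigma = 1, A = 1, sigma_n = 0,
                                 baseline = 0) {
  stripe_model_params(mu = mu, sigma = sigma,
                      amp = matrix(A, 1, 11),
                      baseline = baseline, sigma_n = sigma_n,
                      sigma_pos = 0, rel_amp_sd = 0, border_jitter_sd = 0)
}

# a small scene that renders and segments quickly
small_scene <- function(...) {
  scene_spec(width = 256, height = 256, semi_a = 110, semi_b = 60,
             band_px = 14, n_nuclei = 46, ...)
}

# construct a label_image by hand from a labels matrix plus a band mask;
# used to exercise the fusion rule on exactly controlled geometry
toy_label_image <- function(labels, mask) {
  stripeflow:::make_label_image(labels, mask, mask)
}

# a toy annulus-like band: rectangle frame with a rectangular hole (the
# "yolk"), so the mask complement has an interior and an exterior component
toy_band <- function(n = 40, outer = 5, inner = 15) {
  m <- matrix(FALSE, n, n)
  m[outer:(n - outer), outer:(n - outer)] <- TRUE
  m[inner:(n - inner), inner:(n - inner)] <- FALSE
  m
}

# independent brute-force rank-sum p-value by full enumeration
ranksum_enum <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (length(pooled) + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(sums - EW) >= abs(W - EW) - 1e-9)
}

# independent reverse complement (no Biostrings)
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}
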