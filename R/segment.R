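# Midsagittal-plane nuclei segmentation: cortical mask, watershed, the
# membrane-split fusion rule, and per-nucleus quantification.

# morphological reconstruction by dilation (geodesic, 8-connectivity)
reconstruct_by_dilation <- function(marker, mask) {
  kern <- EBImage::makeBrush(3, shape = "box")
  cur <- marker & mask
  repeat {
    nxt <- (EBImage::imageData(EBImage::dilate(EBImage::Image(cur * 1),
                                               kern)) > 0.5) & mask
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

#' Build the cortical mask of a midsagittal nuclear-channel frame
#'
#' The gray-scale top-hat transformation followed by Otsu thresholding
#' removes the smooth yolk autofluorescence; erosions followed by
#' morphological reconstruction then remove the thin, bright vitelline
#' membrane ring (which does not survive erosion, while nuclei do and are
#' regrown). A final morphological closing seals the small gaps between the
#' tightly packed cycle-14 nuclei so the mask forms the cortical band, whose
#' complement separates into the interior yolk cavity and the exterior.
#'
#' @param nuclear_frame numeric matrix [x, y], nonnegative intensities.
#' @param nucleus_radius expected nucleus radius (px); sets the top-hat
#'   structuring element (radius ~ 2x nucleus radius) and the closing.
#' @param erode_radius erosion radius used against the vitelline ring; must
#'   exceed half the ring thickness yet spare the halves of membrane-split
#'   nuclei.
#' @return logical matrix: the cortical band mask, with attribute `core`
#'   (the pre-closing nucleus blobs, used for quantification).
#' @export
cortical_mask <- function(nuclear_frame, nucleus_radius = 4,
                          erode_radius = 1) {
  stopifnot(is.matrix(nuclear_frame))
  if (max(nuclear_frame) <= 0) {
    m <- matrix(FALSE, nrow(nuclear_frame), ncol(nuclear_frame))
    attr(m, "core") <- m
    return(m)
  }
  img <- nuclear_frame / max(nuclear_frame)
  brush_odd <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
  th <- EBImage::whiteTopHat(EBImage::Image(img), brush_odd(2 * nucleus_radius))
  thr <- EBImage::otsu(th, range = c(0, 1))
  bw <- EBImage::imageData(th) > thr
  er <- EBImage::imageData(EBImage::erode(EBImage::Image(bw * 1),
                                          brush_odd(erode_radius))) > 0.5
  core <- reconstruct_by_dilation(er, bw)
  band <- EBImage::imageData(EBImage::closing(EBImage::Image(core * 1),
                                              brush_odd(nucleus_radius))) > 0.5
  attr(band, "core") <- core & band
  band
}

# classify the complement of the band mask: 0 none, 1 yolk (largest interior
# component), 2 outside (components touching the image border)
complement_classes <- function(mask) {
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((!mask) * 1)))
  comp <- round(comp)
  cls <- matrix(0L, nrow(mask), ncol(mask))
  if (max(comp) == 0) return(cls)
  border_labels <- unique(c(comp[1, ], comp[nrow(comp), ],
                            comp[, 1], comp[, ncol(comp)]))
  border_labels <- setdiff(border_labels, 0)
  cls[comp %in% border_labels] <- 2L
  interior <- setdiff(seq_len(max(comp)), c(0, border_labels))
  if (length(interior)) {
    sizes <- tabulate(comp, nbins = max(comp))[interior]
    yolk <- interior[which.max(sizes)]
    cls[comp == yolk] <- 1L
  }
  cls
}

shift_mat <- function(m, dx, dy, fill = 0L) {
  out <- matrix(fill, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  xs_src <- xs - dx; ys_src <- ys - dy
  okx <- xs_src >= 1 & xs_src <= nrow(m)
  oky <- ys_src >= 1 & ys_src <= ncol(m)
  out[xs[okx], ys[oky]] <- m[xs_src[okx], ys_src[oky]]
  out
}

# assemble a label_image: adjacency graph with watershed-line lengths and
# the touches_yolk / touches_outside flags
make_label_image <- function(labels, mask, core) {
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  nlab <- max(labels)
  dirs8 <- expand.grid(dx = -1:1, dy = -1:1)
  dirs8 <- dirs8[!(dirs8$dx == 0 & dirs8$dy == 0), ]
  recs <- vector("list", nrow(dirs8))
  for (d in seq_len(nrow(dirs8))) {
    nb <- shift_mat(labels, dirs8$dx[d], dirs8$dy[d])
    sel <- which(labels > 0 & nb > 0 & labels != nb)
    if (length(sel))
      recs[[d]] <- data.frame(px = sel, i = labels[sel], j = nb[sel])
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs) || nrow(recs) == 0) {
    adj <- data.frame(i = integer(0), j = integer(0), line_px = integer(0))
  } else {
    recs <- unique(recs)                      # pixel counted once per pair
    key <- paste(recs$i, recs$j)
    cnt <- tapply(recs$px, key, length)
    ij <- do.call(rbind, strsplit(names(cnt), " "))
    dir_cnt <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                          n = as.integer(cnt))
    und <- dir_cnt[dir_cnt$i < dir_cnt$j, ]
    rev <- dir_cnt[dir_cnt$i > dir_cnt$j, ]
    m <- merge(und, data.frame(i = rev$j, j = rev$i, n_rev = rev$n),
               by = c("i", "j"), all = TRUE)
    # both directed counts exist whenever regions touch; the shared-line
    # length is the smaller one so a corner contact counts as 1 px
    m$n[is.na(m$n)] <- m$n_rev[is.na(m$n)]
    m$n_rev[is.na(m$n_rev)] <- m$n[is.na(m$n_rev)]
    adj <- data.frame(i = m$i, j = m$j, line_px = pmin(m$n, m$n_rev))
  }
  cls <- complement_classes(mask)
  touches <- function(code) {
    hit <- rep(FALSE, nlab)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- shift_mat(cls, d[1], d[2])
      sel <- labels > 0 & nb == code
      if (any(sel)) hit[unique(labels[sel])] <- TRUE
    }
    hit
  }
  flags <- data.frame(label = seq_len(nlab),
                      touches_yolk = touches(1L),
                      touches_outside = touches(2L))
  structure(list(labels = labels, adjacency = adj, flags = flags,
                 mask = mask, core = core),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("Label image: %d regions, %d adjacent pairs\n",
              max(x$labels), nrow(x$adjacency)))
  invisible(x)
}

#' Watershed separation of nuclei within the cortical mask
#'
#' Gaussian smoothing followed by the watershed transform on the masked
#' nuclear channel: one label per intensity basin, labels confined to the
#' mask, with the region adjacency graph (watershed-line lengths in pixels)
#' and the touches_yolk / touches_outside flags populated.
#'
#' @param nuclear_frame numeric matrix [x, y].
#' @param mask cortical mask from \code{\link{cortical_mask}}.
#' @param nucleus_radius expected nucleus radius; the smoothing sd defaults
#'   to half of it.
#' @param smooth_sd Gaussian smoothing sd (px).
#' @param tolerance watershed merging tolerance (on intensities normalized
#'   to [0, 1]).
#' @return a \code{label_image}.
#' @export
segment_nuclei <- function(nuclear_frame, mask, nucleus_radius = 4,
                           smooth_sd = nucleus_radius / 4, tolerance = 0.03) {
  stopifnot(is.matrix(nuclear_frame))
  core <- attr(mask, "core")
  if (is.null(core)) core <- mask
  if (!any(mask))
    return(make_label_image(matrix(0L, nrow(mask), ncol(mask)), mask, core))
  img <- nuclear_frame / max(nuclear_frame)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                          sigma = smooth_sd))
  sm[!mask] <- 0
  ws <- EBImage::imageData(EBImage::watershed(EBImage::Image(sm),
                                              tolerance = tolerance, ext = 1))
  make_label_image(ws, mask, core)
}

#' Fuse watershed regions split by the cellularization membrane
#'
#' During mid cycle 14 the invaginating cell membrane bisects the image of a
#' nucleus, and the watershed splits it into two basins stacked across the
#' cortical band. A pair of adjacent regions is considered one nucleus if
#' (1) their shared watershed line is longer than one pixel (>= 2 boundary
#' pixels) and (2) one region touches the yolk but not the outside while the
#' other touches the outside and not the yolk. All qualifying pairs are
#' fused; the result is a coarsening of the input partition and the
#' operation is idempotent.
#'
#' @param label_image a \code{label_image}.
#' @param min_line_px minimum watershed-line length (pixels) to qualify.
#' @return the fused \code{label_image} (labels renumbered contiguously).
#' @export
fuse_oversegmented <- function(label_image, min_line_px = 2) {
  stopifnot(inherits(label_image, "label_image"))
  fl <- label_image$flags
  adj <- label_image$adjacency
  if (nrow(adj) == 0 || nrow(fl) == 0) return(label_image)
  yolk_only <- fl$touches_yolk & !fl$touches_outside
  out_only <- fl$touches_outside & !fl$touches_yolk
  q <- adj$line_px >= min_line_px &
    ((yolk_only[adj$i] & out_only[adj$j]) |
     (out_only[adj$i] & yolk_only[adj$j]))
  if (!any(q)) return(label_image)
  # union-find over qualifying pairs
  parent <- seq_len(nrow(fl))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in which(q)) {
    ri <- find(adj$i[k]); rj <- find(adj$j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  newid <- match(root, sort(unique(root)))
  labs <- label_image$labels
  pos <- labs > 0
  labs[pos] <- newid[labs[pos]]
  make_label_image(labs, label_image$mask, label_image$core)
}

#' Per-nucleus reporter quantification
#'
#' Mean reporter fluorescence and unweighted pixel centroid for every label.
#' Quantification is restricted to the nucleus-core pixels of each basin
#' (the thresholded blobs) so inter-nucleus mask pixels do not dilute the
#' mean; basins without core pixels fall back to the full basin. Centroids
#' are reported in 0-based pixel coordinates.
#'
#' @param label_image a \code{label_image}.
#' @param reporter_frame numeric matrix, same dimensions as the labels.
#' @param embryo_id,t_min bookkeeping columns.
#' @return data.frame: embryo_id, t_min, label, x_px, y_px, mean_fluo,
#'   n_pixels.
#' @export
quantify_nuclei <- function(label_image, reporter_frame,
                            embryo_id = NA_character_, t_min = NA_real_) {
  stopifnot(inherits(label_image, "label_image"))
  labs <- label_image$labels
  if (!all(dim(labs) == dim(reporter_frame)))
    abort("label image and reporter frame have different shapes")
  nlab <- max(labs)
  if (nlab == 0)
    return(data.frame(embryo_id = character(0), t_min = numeric(0),
                      label = integer(0), x_px = numeric(0), y_px = numeric(0),
                      mean_fluo = numeric(0), n_pixels = integer(0)))
  lab_core <- labs; lab_core[!label_image$core] <- 0L
  use <- lab_core
  missing <- setdiff(seq_len(nlab), unique(use[use > 0]))
  if (length(missing)) use[labs %in% missing] <- labs[labs %in% missing]
  sel <- which(use > 0)
  l <- use[sel]
  xs <- (sel - 1) %% nrow(labs) + 1
  ys <- (sel - 1) %/% nrow(labs) + 1
  mean_f <- tapply(reporter_frame[sel], l, mean)
  cx <- tapply(xs, l, mean); cy <- tapply(ys, l, mean)
  np <- tapply(l, l, length)
  ids <- as.integer(names(mean_f))
  data.frame(embryo_id = embryo_id, t_min = t_min, label = ids,
             x_px = as.numeric(cx) - 1, y_px = as.numeric(cy) - 1,
             mean_fluo = as.numeric(mean_f), n_pixels = as.integer(np),
             row.names = NULL)
}

#' Segment and quantify one two-channel frame
#'
#' Convenience wrapper: cortical mask, watershed, membrane-split fusion,
#' per-nucleus quantification.
#'
#' @param nuclear_frame,reporter_frame numeric matrices [x, y].
#' @param nucleus_radius expected nucleus radius (px).
#' @param embryo_id,t_min bookkeeping.
#' @param ... passed to \code{\link{segment_nuclei}}.
#' @return list with `records` (nucleus table), `labels` (fused
#'   \code{label_image}), `mask`.
#' @export
segment_frame <- function(nuclear_frame, reporter_frame, nucleus_radius = 4,
                          embryo_id = NA_character_, t_min = NA_real_, ...) {
  mask <- cortical_mask(nuclear_frame, nucleus_radius = nucleus_radius)
  li <- segment_nuclei(nuclear_frame, mask, nucleus_radius = nucleus_radius, ...)
  li <- fuse_oversegmented(li)
  list(records = quantify_nuclei(li, reporter_frame, embryo_id, t_min),
       labels = li, mask = mask)
}

#' One-to-one matching of segmented nuclei to ground truth
#'
#' Greedy closest-pair matching between detected centroids and true nucleus
#' centres, with a maximum matching distance. Used to score recovery on
#' synthetic data.
#'
#' @param records nucleus table from \code{\link{quantify_nuclei}}.
#' @param truth_nuclei data.frame with `x_px`, `y_px` (0-based).
#' @param max_dist maximum centroid distance (px) for a valid match.
#' @return data.frame with `truth_row`, `record_row`, `dist`.
#' @export
match_to_truth <- function(records, truth_nuclei, max_dist = 4) {
  if (nrow(records) == 0 || nrow(truth_nuclei) == 0)
    return(data.frame(truth_row = integer(0), record_row = integer(0),
                      dist = numeric(0)))
  D <- outer(truth_nuclei$x_px, records$x_px, "-")^2 +
       outer(truth_nuclei$y_px, records$y_px, "-")^2
  D <- sqrt(D)
  matches <- data.frame(truth_row = integer(0), record_row = integer(0),
                        dist = numeric(0))
  repeat {
    k <- which.min(D)
    if (!length(k) || !is.finite(D[k]) || D[k] > max_dist) break
    i <- (k - 1) %% nrow(D) + 1; j <- (k - 1) %/% nrow(D) + 1
    matches <- rbind(matches,
                     data.frame(truth_row = i, record_row = j, dist = D[k]))
    D[i, ] <- Inf; D[, j] <- Inf
  }
  matches
}
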