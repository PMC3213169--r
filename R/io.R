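# Plain-text I/O for the pipeline's tabular interchange formats.

#' Write / read a nucleus record table
#'
#' Columns: embryo_id, t_min, x_px, y_px, ap_percent_el (if present),
#' mean_fluo, label, n_pixels. Pixel coordinates are 0-based.
#'
#' @param records nucleus table (see \code{\link{quantify_nuclei}}).
#' @param path CSV path.
#' @return `read_nucleus_records` returns the data.frame.
#' @export
write_nucleus_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nucleus_records
#' @export
read_nucleus_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Flatten stripe features to a long table
#'
#' One row per feature: embryo_id, t_min, feature ("peak" or "border"),
#' stripe, side (borders only), position_el, value (peak value or border
#' height).
#'
#' @param series list of \code{stripe_features} (one embryo's time series).
#' @param embryo_id identifier column value.
#' @return data.frame in long format.
#' @export
features_long <- function(series, embryo_id = NA_character_) {
  rows <- lapply(series, function(f) {
    pk <- f$peaks
    out <- NULL
    if (nrow(pk))
      out <- data.frame(embryo_id = embryo_id, t_min = f$t, feature = "peak",
                        stripe = pk$stripe, side = NA_character_,
                        position_el = pk$position, value = pk$value)
    b <- f$borders
    if (nrow(b))
      out <- rbind(out, data.frame(embryo_id = embryo_id, t_min = f$t,
                                   feature = "border", stripe = b$stripe,
                                   side = b$side, position_el = b$position,
                                   value = b$height))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
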