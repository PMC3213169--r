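#' Enhancer annotation: sequence, named intervals, binding sites
#'
#' Coordinates are 1-based and inclusive, the molecular-biology convention
#' used for all bp arithmetic here.
#'
#' @param sequence DNA sequence (character or \code{Biostrings::DNAString}),
#'   or NULL for interval-only bookkeeping.
#' @param intervals data.frame with `name`, `start`, `end`.
#' @param sites data.frame with `id`, `factor`, `start`, `end`, `strand`
#'   ("+"/"-"); ids must be unique.
#' @param length_bp total annotated length; required when `sequence` is NULL.
#' @return object of class \code{enhancer_annotation}.
#' @export
enhancer_annotation <- function(sequence = NULL, intervals, sites = NULL,
                                length_bp = NULL) {
  if (!is.null(sequence)) {
    sequence <- as.character(sequence)
    length_bp <- nchar(sequence)
  }
  if (is.null(length_bp)) abort("length_bp required when no sequence is given")
  if (is.null(sites))
    sites <- data.frame(id = character(0), factor = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(intervals)),
            all(c("id", "factor", "start", "end", "strand") %in% names(sites)))
  if (anyDuplicated(sites$id)) abort("binding-site ids must be unique")
  chk <- rbind(intervals[, c("start", "end")], sites[, c("start", "end")])
  if (nrow(chk) && (any(chk$start < 1) || any(chk$end > length_bp) ||
                    any(chk$start > chk$end)))
    abort("intervals must lie within [1, %d] with start <= end", length_bp)
  structure(list(sequence = sequence, length_bp = length_bp,
                 intervals = intervals, sites = sites),
            class = "enhancer_annotation")
}

#' @export
print.enhancer_annotation <- function(x, ...) {
  cat(sprintf("Enhancer annotation: %d bp, %d intervals, %d binding sites%s\n",
              x$length_bp, nrow(x$intervals), nrow(x$sites),
              if (is.null(x$sequence)) " (no sequence)" else ""))
  invisible(x)
}

interval_of <- function(ann, name) {
  w <- which(ann$intervals$name == name)
  if (length(w) != 1) abort("interval '%s' is not annotated", name)
  ann$intervals[w, , drop = FALSE]
}

#' Reference annotation of the stripe 2 enhancer region
#'
#' A self-consistent stand-in for the 798 bp S2E reference: the interval
#' layout carries the published lengths (26 bp and 18 bp conserved border
#' blocks a and b, a 33 bp distal and a 211 bp proximal deletion fragment, a
#' 509 bp minimal element composed of a 29 bp distal extension plus the
#' classic 480 bp minimal stripe element), and the footprinted binding-site
#' complement (five bcd, three hb, six kr, three gt, one slp1). The DNA
#' sequence is SYNTHETIC (seeded random bases) and the exact in-deletion
#' placement of kr-1, kr-2, hb-1 and hb-2 is synthetic too: real sequence
#' work should load a user FASTA with \code{\link{enhancer_annotation}}.
#'
#' Layout (1-based, inclusive): block a 1-26, distal deletion 27-59, distal
#' extension 60-88 (no mapped TFBS), classic MSE 89-568, proximal deletion
#' 569-779, spacer 780, block b 781-798.
#'
#' @param seed seed for the synthetic sequence.
#' @return an \code{enhancer_annotation} of length 798.
#' @export
s2e_reference_annotation <- function(seed = 798L) {
  seq_chr <- with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), 798, replace = TRUE), collapse = ""))
  intervals <- data.frame(
    name = c("block_a", "distal_deletion", "distal_extension", "classic_mse",
             "mse", "proximal_deletion", "block_b", "s2e"),
    start = c(1, 27, 60, 89, 60, 569, 781, 1),
    end   = c(26, 59, 88, 568, 568, 779, 798, 798),
    stringsAsFactors = FALSE)
  sites <- data.frame(
    id = c("kr-2", "kr-1", "hb-1", "hb-2",
           paste0("bcd-", 1:5), "hb-3", paste0("kr-", 3:6),
           paste0("gt-", 1:3), "slp1-1"),
    factor = c("kr", "kr", "hb", "hb",
               rep("bcd", 5), "hb", rep("kr", 4), rep("gt", 3), "slp1"),
    start = c(35, 600, 640, 700,
              100, 160, 220, 280, 340, 130, 190, 250, 310, 370, 430, 470, 510, 540),
    end   = c(44, 609, 649, 709,
              109, 169, 229, 289, 349, 139, 199, 259, 319, 379, 439, 479, 519, 549),
    strand = "+", stringsAsFactors = FALSE)
  enhancer_annotation(sequence = seq_chr, intervals = intervals, sites = sites)
}

#' Delete intervals from an enhancer annotation
#'
#' Removes the given intervals from the sequence, shifts all remaining
#' coordinates, and reports binding sites that were fully contained in a
#' deletion as absent. A site straddling a deletion edge is an error: the
#' deletions of interest were designed around intact sites.
#'
#' @param ann an \code{enhancer_annotation}.
#' @param deletions character vector of annotated interval names, or a
#'   data.frame with `start`, `end`.
#' @param variant_name label recorded in the report.
#' @return list with `annotation` (the edited \code{enhancer_annotation}) and
#'   `report` (a \code{variant_report}: variant name, resulting length,
#'   removed bp, absent binding-site ids, orientation flag).
#' @export
apply_deletions <- function(ann, deletions, variant_name = "variant") {
  stopifnot(inherits(ann, "enhancer_annotation"))
  if (is.character(deletions)) {
    dels <- if (length(deletions) == 0) {
      data.frame(start = numeric(0), end = numeric(0))
    } else do.call(rbind, lapply(deletions, function(nm)
      interval_of(ann, nm)[, c("start", "end")]))
  } else dels <- as.data.frame(deletions)[, c("start", "end")]
  if (nrow(dels) == 0) {
    rep0 <- variant_report(variant_name, ann$length_bp, 0, character(0), FALSE)
    return(list(annotation = ann, report = rep0))
  }
  if (any(dels$start < 1) || any(dels$end > ann$length_bp) ||
      any(dels$start > dels$end))
    abort("deletion intervals out of bounds")
  dels <- dels[order(dels$start), , drop = FALSE]
  if (nrow(dels) > 1 && any(dels$start[-1] <= dels$end[-nrow(dels)]))
    abort("deletion intervals overlap")

  inside <- function(s, e) # fully contained in some deletion
    vapply(seq_along(s), function(i)
      any(s[i] >= dels$start & e[i] <= dels$end), logical(1))
  touches <- function(s, e)
    vapply(seq_along(s), function(i)
      any(s[i] <= dels$end & e[i] >= dels$start), logical(1))
  st <- ann$sites
  straddle <- touches(st$start, st$end) & !inside(st$start, st$end)
  if (any(straddle))
    abort("binding site(s) straddle a deletion edge: %s",
          paste(st$id[straddle], collapse = ", "))
  absent <- st$id[inside(st$start, st$end)]

  removed <- sum(dels$end - dels$start + 1)
  # coordinate shift: new position = old - (deleted bases before it)
  shift <- function(pos) {
    pos - vapply(pos, function(p) sum(pmax(0, pmin(p - 1, dels$end) -
                                             dels$start + 1)), numeric(1))
  }
  new_len <- ann$length_bp - removed
  new_seq <- NULL
  if (!is.null(ann$sequence)) {
    keep <- rep(TRUE, ann$length_bp)
    for (i in seq_len(nrow(dels))) keep[dels$start[i]:dels$end[i]] <- FALSE
    new_seq <- paste(strsplit(ann$sequence, "")[[1]][keep], collapse = "")
  }
  iv <- ann$intervals
  iv_gone <- touches(iv$start, iv$end) & inside(iv$start, iv$end)
  iv_cut <- touches(iv$start, iv$end) & !iv_gone
  iv <- iv[!iv_gone & !iv_cut, , drop = FALSE]   # drop deleted/truncated
  iv$start <- shift(iv$start); iv$end <- shift(iv$end)
  st <- st[!st$id %in% absent, , drop = FALSE]
  st$start <- shift(st$start); st$end <- shift(st$end)
  out <- enhancer_annotation(sequence = new_seq, intervals = iv, sites = st,
                             length_bp = new_len)
  list(annotation = out,
       report = variant_report(variant_name, new_len, removed, absent, FALSE))
}

variant_report <- function(name, length_bp, removed_bp, absent_sites,
                           inverted) {
  structure(list(variant = name, length_bp = length_bp,
                 removed_bp = removed_bp, absent_sites = absent_sites,
                 inverted = inverted),
            class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat(sprintf("Variant %s: %d bp (%d bp removed)%s\n", x$variant,
              x$length_bp, x$removed_bp,
              if (x$inverted) ", inverted orientation" else ""))
  if (length(x$absent_sites))
    cat("  absent sites:", paste(x$absent_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Audit the minimal stripe element composition
#'
#' The minimal element is the classic minimal stripe element plus a distal
#' extension added to keep two repressor sites apart in the inverted variant;
#' this reports its length arithmetic and flags any mapped binding site
#' inside the extension (there should be none).
#'
#' @param ann an \code{enhancer_annotation} carrying `classic_mse` and
#'   `distal_extension` intervals.
#' @return list with `classic_bp`, `extension_bp`, `minimal_element_bp` and
#'   `extension_sites` (ids of sites overlapping the extension).
#' @export
build_minimal_element <- function(ann) {
  cl <- interval_of(ann, "classic_mse")
  ex <- interval_of(ann, "distal_extension")
  in_ext <- ann$sites$start <= ex$end & ann$sites$end >= ex$start
  list(classic_bp = cl$end - cl$start + 1,
       extension_bp = ex$end - ex$start + 1,
       minimal_element_bp = (cl$end - cl$start + 1) + (ex$end - ex$start + 1),
       extension_sites = ann$sites$id[in_ext])
}

#' Invert (reverse-complement) a segment of the annotation in place
#'
#' Replaces the interval with its reverse complement; length is unchanged and
#' the flanking border blocks must not be touched. Binding sites inside the
#' interval have their coordinates remapped end-for-end and their strand
#' flipped.
#'
#' @param ann an \code{enhancer_annotation} with a sequence.
#' @param interval c(start, end) or an annotated interval name.
#' @param protected names of intervals the inversion may not overlap.
#' @return the edited \code{enhancer_annotation}.
#' @export
invert_segment <- function(ann, interval,
                           protected = c("block_a", "block_b")) {
  stopifnot(inherits(ann, "enhancer_annotation"))
  if (is.null(ann$sequence)) abort("inversion requires a sequence")
  if (is.character(interval)) {
    iv <- interval_of(ann, interval); s <- iv$start; e <- iv$end
  } else { s <- interval[1]; e <- interval[2] }
  if (s < 1 || e > ann$length_bp || s > e) abort("interval out of bounds")
  for (pn in intersect(protected, ann$intervals$name)) {
    pv <- interval_of(ann, pn)
    if (s <= pv$end && e >= pv$start)
      abort("inversion overlaps protected border block '%s'", pn)
  }
  chars <- strsplit(ann$sequence, "")[[1]]
  seg <- paste(chars[s:e], collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  chars[s:e] <- strsplit(rc, "")[[1]]
  new_seq <- paste(chars, collapse = "")
  st <- ann$sites
  inside <- st$start >= s & st$end <= e
  part <- (st$start <= e & st$end >= s) & !inside
  if (any(part))
    abort("binding site(s) straddle the inversion edge: %s",
          paste(st$id[part], collapse = ", "))
  if (any(inside)) {
    ns <- s + e - st$end[inside]
    ne <- s + e - st$start[inside]
    st$start[inside] <- ns; st$end[inside] <- ne
    st$strand[inside] <- ifelse(st$strand[inside] == "+", "-", "+")
  }
  enhancer_annotation(sequence = new_seq, intervals = ann$intervals,
                      sites = st)
}

#' Build a named S2E variant from the reference annotation
#'
#' WT returns the annotation unchanged; MSE applies the distal and proximal
#' deletions; INV_MSE additionally reverse-complements the minimal element
#' between the conserved border sequences.
#'
#' @param ann reference annotation (default
#'   \code{\link{s2e_reference_annotation}()}).
#' @param variant "WT", "MSE" or "INV_MSE".
#' @return list with `annotation` and `report`.
#' @export
build_variant <- function(ann = s2e_reference_annotation(),
                          variant = c("WT", "MSE", "INV_MSE")) {
  variant <- match.arg(variant)
  if (variant == "WT")
    return(list(annotation = ann,
                report = variant_report("WT", ann$length_bp, 0,
                                        character(0), FALSE)))
  del <- apply_deletions(ann, c("distal_deletion", "proximal_deletion"),
                         variant_name = variant)
  if (variant == "MSE") return(del)
  mse_iv <- interval_of(del$annotation, "mse")
  inv <- invert_segment(del$annotation, c(mse_iv$start, mse_iv$end))
  rep <- del$report; rep$inverted <- TRUE
  list(annotation = inv, report = rep)
}
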