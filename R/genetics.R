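#' Define a two-parent cross over autosomal chromosome pairs
#'
#' Encodes the maternal and paternal genotypes as per-chromosome allele
#' pairs, together with the lethality rules applied to the offspring classes.
#' By default balancer homozygotes (CyO/CyO, TM3/TM3) are lethal and removed
#' before frequencies are renormalized; eve-null rescue classes are never
#' auto-removed — their depletion is the measurand of the viability assay.
#'
#' @param chromosomes named list; each element is a list with `mother` and
#'   `father`, each a character vector of two allele names, e.g.
#'   \code{list(chr2 = list(mother = c("R13","CyO"), father = c("R13","R13")))}.
#' @param lethal_homozygotes alleles whose homozygotes die (balancers).
#' @return object of class \code{cross_schema}.
#' @export
cross_schema <- function(chromosomes,
                         lethal_homozygotes = c("CyO", "TM3")) {
  for (nm in names(chromosomes)) {
    ch <- chromosomes[[nm]]
    if (!is.list(ch) || !all(c("mother", "father") %in% names(ch)))
      abort("chromosome %s needs 'mother' and 'father' allele pairs", nm)
    if (length(ch$mother) != 2 || length(ch$father) != 2)
      abort("chromosome %s: each parent carries exactly two alleles", nm)
  }
  structure(list(chromosomes = chromosomes,
                 lethal_homozygotes = lethal_homozygotes),
            class = "cross_schema")
}

#' @export
print.cross_schema <- function(x, ...) {
  cat("Cross schema:\n")
  for (nm in names(x$chromosomes)) {
    ch <- x$chromosomes[[nm]]
    cat(sprintf("  %s: %s/%s (mother) x %s/%s (father)\n", nm,
                ch$mother[1], ch$mother[2], ch$father[1], ch$father[2]))
  }
  cat(sprintf("  lethal homozygotes: %s\n",
              paste(x$lethal_homozygotes, collapse = ", ")))
  invisible(x)
}

# canonical unordered genotype label for one chromosome
pair_label <- function(a1, a2)
  paste(sort(c(a1, a2), method = "radix"), collapse = "/")

# Mendelian segregation of one chromosome: unordered genotype frequencies
segregate_chromosome <- function(ch) {
  tab <- list()
  for (m in ch$mother) for (f in ch$father) {
    lab <- pair_label(m, f)
    tab[[lab]] <- (tab[[lab]] %||% 0) + 0.25
  }
  data.frame(genotype = names(tab), freq = unlist(tab, use.names = FALSE),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mendelian offspring class frequencies of a cross
#'
#' Applies independent assortment across chromosomes, removes the lethal
#' balancer-homozygote classes, and renormalizes frequencies over the
#' surviving classes (which then sum to 1).
#'
#' @param cross a \code{cross_schema}.
#' @return data.frame with one column per chromosome (genotype labels), a
#'   combined `class` label, and `freq`.
#' @export
cross_expectation <- function(cross) {
  stopifnot(inherits(cross, "cross_schema"))
  margs <- lapply(cross$chromosomes, segregate_chromosome)
  grid <- Reduce(function(acc, nm) {
    m <- margs[[nm]]
    out <- merge(acc, m, by = NULL)   # cartesian product
    out$freq <- out$freq.x * out$freq.y
    out$freq.x <- out$freq.y <- NULL
    names(out)[names(out) == "genotype"] <- nm
    out
  }, names(margs)[-1],
  init = {
    m <- margs[[1]]
    names(m)[1] <- names(margs)[1]
    m
  })
  # balancer homozygotes die
  lethal <- vapply(cross$lethal_homozygotes, function(al)
    pair_label(al, al), character(1))
  surv <- grid
  for (nm in names(cross$chromosomes))
    surv <- surv[!(surv[[nm]] %in% lethal), , drop = FALSE]
  if (sum(surv$freq) <= 0) abort("no surviving offspring classes")
  surv$freq <- surv$freq / sum(surv$freq)
  surv$class <- do.call(paste, c(surv[names(cross$chromosomes)], sep = "; "))
  rownames(surv) <- NULL
  surv[, c("class", names(cross$chromosomes), "freq")]
}

#' The standard viability intercross
#'
#' Both parents are b,R13/CyO on chromosome 2 and carry the transgene over
#' TM3 on chromosome 3 (tg/TM3). The eve-null rescue classes are R13/R13 with
#' one (hemizygous) or two (homozygous) transgene copies; the control classes
#' carry one endogenous eve (R13/CyO) and one or two transgene copies.
#'
#' @param null_allele name of the eve-null chromosome-2 allele.
#' @return a \code{cross_schema}.
#' @export
standard_intercross <- function(null_allele = "R13") {
  cross_schema(list(
    chr2 = list(mother = c(null_allele, "CyO"), father = c(null_allele, "CyO")),
    chr3 = list(mother = c("tg", "TM3"), father = c("tg", "TM3"))))
}

#' The 50-percent-hemizygote assay cross
#'
#' Mother b,R13/CyO with untransformed chromosome 3; father b,R13 homozygous
#' for the chromosome-3 transgene (tg/tg). Half the surviving offspring are
#' hemizygous-rescue (R13/R13; tg/+).
#'
#' @inheritParams standard_intercross
#' @return a \code{cross_schema}.
#' @export
hemizygote_assay_cross <- function(null_allele = "R13") {
  cross_schema(list(
    chr2 = list(mother = c(null_allele, "CyO"), father = c(null_allele, null_allele)),
    chr3 = list(mother = c("+", "+"), father = c("tg", "tg"))))
}

# class predicates ---------------------------------------------------------

n_transgene <- function(chr3_label) {
  sum(strsplit(chr3_label, "/", fixed = TRUE)[[1]] == "tg")
}

is_rescue_class <- function(chr2_label, null_allele = "R13") {
  chr2_label == pair_label(null_allele, null_allele)
}

is_control_class <- function(chr2_label, chr3_label, null_allele = "R13") {
  chr2_label == pair_label(null_allele, "CyO") &
    vapply(chr3_label, n_transgene, numeric(1)) >= 1
}

#' Rescue percentages with binomial standard deviations
#'
#' Relative viability of the eve-null rescue classes. The expected count of a
#' rescue class is scaled from the combined count of the control classes
#' (one endogenous eve copy plus one or two transgene-bearing third
#' chromosomes): expected = control_total * freq(class) / freq(controls).
#' The rescue percentage is 100 * observed / expected, with binomial SD
#' 100 * sqrt(phat (1 - phat) / expected) where phat = observed / expected
#' capped to [0, 1].
#'
#' @param counts data.frame with columns `class` and `count` (an optional
#'   `sex` column is summed over).
#' @param cross the \code{cross_schema} that generated the counts.
#' @param null_allele eve-null allele name on chromosome 2.
#' @return data.frame (one row per rescue class): class, n_transgene,
#'   observed, expected, rescue_pct, binom_sd, p_value (chi-squared of the
#'   observed rescue/control split against the Mendelian expectation).
#' @export
rescue_percentage <- function(counts, cross, null_allele = "R13") {
  stopifnot(all(c("class", "count") %in% names(counts)))
  freq <- cross_expectation(cross)
  if (!"chr3" %in% names(freq)) abort("cross must include a chr3 transgene")
  obs <- tapply(counts$count, counts$class, sum)
  ctrl <- is_control_class(freq$chr2, freq$chr3, null_allele)
  resc <- is_rescue_class(freq$chr2, null_allele) &
    vapply(freq$chr3, n_transgene, numeric(1)) >= 1
  if (!any(ctrl)) abort("control classes absent from the cross expectation")
  f_ctrl <- sum(freq$freq[ctrl])
  n_ctrl <- sum(obs[freq$class[ctrl]], na.rm = TRUE)
  if (n_ctrl <= 0) abort("control classes absent from the observed counts")
  res <- freq[resc, , drop = FALSE]
  out <- data.frame(class = res$class,
                    n_transgene = vapply(res$chr3, n_transgene, numeric(1)),
                    observed = as.numeric(obs[res$class]),
                    expected = n_ctrl * res$freq / f_ctrl)
  out$observed[is.na(out$observed)] <- 0
  if (any(out$expected <= 0)) abort("zero expected count for a rescue class")
  phat <- pmin(pmax(out$observed / out$expected, 0), 1)
  out$rescue_pct <- 100 * out$observed / out$expected
  out$binom_sd <- 100 * sqrt(phat * (1 - phat) / out$expected)
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    o <- c(out$observed[i], n_ctrl)
    e <- c(res$freq[i], f_ctrl)
    ratio_test(o, e)$p_value
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Pearson chi-squared ratio test
#'
#' Tests observed class counts against expected frequencies (df = classes - 1,
#' no continuity correction).
#'
#' @param observed nonnegative integer counts, length >= 2.
#' @param expected_freq expected frequencies or weights (> 0); normalized
#'   internally.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
ratio_test <- function(observed, expected_freq) {
  if (length(observed) < 2) abort("need at least 2 classes")
  if (length(expected_freq) != length(observed))
    abort("observed and expected lengths differ")
  if (any(expected_freq <= 0)) abort("expected frequencies must be positive")
  p <- expected_freq / sum(expected_freq)
  e <- sum(observed) * p
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), expected = e)
}

#' Chi-squared test of a 1:1 sex ratio
#'
#' @param counts length-2 vector of counts by sex within a genotype class.
#' @return as \code{\link{ratio_test}}.
#' @export
sex_ratio_test <- function(counts) {
  if (length(counts) != 2) abort("need counts for exactly two sexes")
  ratio_test(counts, c(1, 1))
}

#' Parasegment-3 length ratio
#'
#' The En-pattern readout of stripe-2 function: the length of parasegment 3
#' divided by the summed lengths of parasegments 3 and 4, measured at the
#' ventral midline. Lies in (0, 1); 0.5 means equal parasegments.
#'
#' @param len_ps3,len_ps4 lengths (> 0), any common unit.
#' @return the ratio ps3 / (ps3 + ps4).
#' @export
parasegment_ratio <- function(len_ps3, len_ps4) {
  if (any(len_ps3 <= 0) || any(len_ps4 <= 0))
    abort("parasegment lengths must be positive")
  len_ps3 / (len_ps3 + len_ps4)
}

#' Simulate an adult genotype count table for a cross
#'
#' Multinomial draw of `total_n` scored adults over the surviving offspring
#' classes, with per-class (optionally per-class-and-sex) viability
#' multipliers in [0, 1]; sexes split 1:1 before multipliers apply.
#'
#' @param cross a \code{cross_schema}.
#' @param total_n total number of adults scored.
#' @param viability_multipliers named numeric vector: names are class labels
#'   (see \code{\link{cross_expectation}}) or "class|sex" (sex in "F","M");
#'   missing classes default to 1.
#' @param seed integer seed; the table is reproducible given the seed.
#' @return a data.frame with `class`, `sex`, `count`.
#' @export
generate_count_table <- function(cross, total_n, viability_multipliers = NULL,
                                 seed = 1L) {
  freq <- cross_expectation(cross)
  cells <- merge(freq[, c("class", "freq")],
                 data.frame(sex = c("F", "M")), by = NULL)
  cells$freq <- cells$freq / 2
  mult <- rep(1, nrow(cells))
  if (!is.null(viability_multipliers)) {
    if (any(viability_multipliers < 0 | viability_multipliers > 1))
      abort("viability multipliers must lie in [0, 1]")
    keys_sex <- paste(cells$class, cells$sex, sep = "|")
    for (nm in names(viability_multipliers)) {
      hit <- if (grepl("|", nm, fixed = TRUE)) keys_sex == nm
             else cells$class == nm
      if (!any(hit)) abort("unknown genotype class in multipliers: %s", nm)
      mult[hit] <- viability_multipliers[[nm]]
    }
  }
  w <- cells$freq * mult
  if (sum(w) <= 0) abort("viability multipliers leave no positive mass")
  counts <- with_seed(seed, stats::rmultinom(1, total_n, prob = w)[, 1])
  data.frame(class = cells$class, sex = cells$sex, count = as.integer(counts),
             stringsAsFactors = FALSE)
}
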