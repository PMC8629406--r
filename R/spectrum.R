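SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Pyrimidine-referenced substitution class of an SNV
#'
#' Maps a single-base substitution to one of the six canonical classes
#' C>A, C>G, C>T, T>A, T>C, T>G.  Substitutions written with a purine
#' reference are folded onto the complementary strand (e.g. G>A becomes
#' C>T), the standard convention in mutational-signature work; folding is
#' idempotent.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return character vector of classes.
#' @export
substitution_class <- function(ref, alt) {
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L)) {
    stop("substitution_class is defined for single-base substitutions only")
  }
  if (any(!ref %in% BASES) || any(!alt %in% BASES)) {
    stop("alleles must be A/C/G/T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  fold <- ref %in% c("A", "G")
  ref[fold] <- comp[ref[fold]]
  alt[fold] <- comp[alt[fold]]
  cls <- paste0(ref, ">", alt)
  stopifnot(all(cls %in% SUBSTITUTION_CLASSES))
  cls
}

#' Six-class substitution spectrum of a call set
#'
#' Indels and multi-nucleotide variants are excluded; only single-base
#' substitutions enter the spectrum.
#'
#' @param calls call data frame.
#' @return a `spectrum_counts` named integer vector over the six classes
#'   with attribute `total` (= sum of the six classes = number of SNVs).
#' @export
spectrum_counts <- function(calls) {
  snv <- calls[nchar(calls$ref) == 1L & nchar(calls$alt) == 1L, , drop = FALSE]
  counts <- setNames(integer(length(SUBSTITUTION_CLASSES)),
                     SUBSTITUTION_CLASSES)
  if (nrow(snv) > 0L) {
    cls <- substitution_class(snv$ref, snv$alt)
    tab <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
    counts[] <- as.integer(tab)
  }
  structure(counts, total = sum(counts), class = "spectrum_counts")
}

#' @export
print.spectrum_counts <- function(x, ...) {
  cat("substitution spectrum (", attr(x, "total"), " SNVs):\n", sep = "")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Substitution spectra before and after chemotherapy
#'
#' Pools single-base substitutions across tumor samples by treatment
#' stage: pre-chemotherapy (primary surgery) versus post-chemotherapy
#' (second and third surgery).
#'
#' @param calls passing calls.
#' @param meta sample sheet.
#' @return list with `pre_chemo` and `post_chemo` [spectrum_counts()];
#'   an empty post-chemotherapy set yields a zero spectrum with a warning
#'   (the comparison is then skipped by callers).
#' @export
spectrum_by_stage <- function(calls, meta) {
  tumor <- meta[meta$role == "tumor", , drop = FALSE]
  idx <- match(calls$sample_id, tumor$sample_id)
  calls <- calls[!is.na(idx), , drop = FALSE]
  stage <- tumor$stage[idx[!is.na(idx)]]
  pre <- spectrum_counts(calls[stage == "primary", , drop = FALSE])
  post <- spectrum_counts(calls[stage != "primary", , drop = FALSE])
  if (attr(post, "total") == 0L) {
    warning("no post-chemotherapy SNVs: spectrum comparison will be skipped")
  }
  list(pre_chemo = pre, post_chemo = post)
}

#' Chi-squared homogeneity test between two spectra
#'
#' Tests whether the six-class substitution composition differs between
#' two spectra (e.g. pre- vs post-chemotherapy) with a chi-squared test on
#' the 6 x 2 contingency table; classes absent from both spectra are
#' dropped and the degrees of freedom adjust accordingly.  Identical
#' spectra give statistic 0 and p = 1.
#'
#' @param pre,post [spectrum_counts()] vectors; both totals must be
#'   positive.
#' @return list with `statistic`, `df`, `p_value` and the contingency
#'   `table` used.
#' @export
compare_spectra <- function(pre, post) {
  if (attr(pre, "total") == 0L || attr(post, "total") == 0L) {
    stop("both spectra must contain at least one SNV")
  }
  tab <- cbind(pre = as.integer(pre), post = as.integer(post))
  rownames(tab) <- SUBSTITUTION_CLASSES
  tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
  if (nrow(tab) < 2L) {
    # a single surviving class is trivially homogeneous
    return(list(statistic = 0, df = 0L, p_value = 1, table = tab))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, table = tab)
}
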