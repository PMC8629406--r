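#' Somatic filter configuration
#'
#' Thresholds for the matched-normal somatic filter.  The defaults encode
#' the analysis settings of the targeted amplicon design the package
#' emulates: minimum coverage of 200-fold (inclusive) and allelic fraction
#' strictly above 1% in the tumor.  A locus is treated as germline when the
#' matched blood shows AF above `germline_max_af_in_blood` at adequate
#' blood coverage; 2% is a conventional matched-normal cutoff far below the
#' 50% heterozygous expectation.
#'
#' @param min_depth minimum tumor coverage, inclusive (default 200).
#' @param min_af minimum tumor allelic fraction, strict (default 0.01).
#' @param caller_mode how two callers' outputs are harmonized, `"union"`
#'   (default, maximizes sensitivity at high panel depth) or
#'   `"intersection"`.
#' @param germline_max_af_in_blood blood AF above which a locus is germline
#'   (default 0.02).
#' @param germline_min_blood_depth minimum blood coverage for the germline
#'   call to be trusted (default 50); below it the locus is retained and
#'   flagged `blood_low_coverage`.
#' @param extra_predicates optional named list of functions
#'   `f(calls) -> logical` (TRUE = keep); rejections they cause are
#'   reported under the predicate's name, after the built-in reasons.
#' @param locus_key `"allele"` or `"site"`, see [locus_key()].
#' @return a `filter_config` object.
#' @export
filter_config <- function(min_depth = 200L, min_af = 0.01,
                          caller_mode = c("union", "intersection"),
                          germline_max_af_in_blood = 0.02,
                          germline_min_blood_depth = 50L,
                          extra_predicates = list(),
                          locus_key = c("allele", "site")) {
  caller_mode <- match.arg(caller_mode)
  locus_key <- match.arg(locus_key)
  stopifnot(min_depth >= 1L, min_af >= 0, min_af < 1,
            germline_max_af_in_blood >= 0, germline_min_blood_depth >= 0)
  if (length(extra_predicates) > 0L &&
      (is.null(names(extra_predicates)) || any(!nzchar(names(extra_predicates))))) {
    stop("extra_predicates must be a named list")
  }
  structure(list(min_depth = as.integer(min_depth), min_af = min_af,
                 caller_mode = caller_mode,
                 germline_max_af_in_blood = germline_max_af_in_blood,
                 germline_min_blood_depth = as.integer(germline_min_blood_depth),
                 extra_predicates = extra_predicates,
                 locus_key = locus_key),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(
    "somatic filter: depth >= %d, AF > %.4g, callers: %s, germline: blood AF > %.4g (blood depth >= %d)\n",
    x$min_depth, x$min_af, x$caller_mode, x$germline_max_af_in_blood,
    x$germline_min_blood_depth))
  invisible(x)
}

#' Harmonize two variant callers' outputs for one sample
#'
#' Union mode keeps every locus reported by either caller; intersection
#' keeps loci reported by both.  When both callers report a locus, depth
#' and alt-read counts are taken from the caller with the higher depth
#' (ties go to `calls_a`) and the caller provenance tags are merged, so the
#' result records whether a call is single-caller or consensus.
#'
#' @param calls_a,calls_b call tables from the two callers; both must come
#'   from the same sample.
#' @param mode `"union"` or `"intersection"`.
#' @param label_a,label_b provenance labels used when a table's `callers`
#'   column is empty.
#' @param key locus key mode, see [locus_key()].
#' @return merged, validated call table with a filled `callers` column.
#' @export
merge_callers <- function(calls_a, calls_b, mode = c("union", "intersection"),
                          label_a = "caller_a", label_b = "caller_b",
                          key = "allele") {
  mode <- match.arg(mode)
  calls_a <- validate_calls(calls_a)
  calls_b <- validate_calls(calls_b)
  sa <- unique(calls_a$sample_id)
  sb <- unique(calls_b$sample_id)
  if (length(sa) > 1L || length(sb) > 1L) {
    stop("merge_callers expects single-sample call tables")
  }
  if (length(sa) == 1L && length(sb) == 1L && sa != sb) {
    stop("call tables are from different samples: ", sa, " vs ", sb)
  }
  fill_callers <- function(calls, label) {
    calls$callers <- ifelse(is.na(calls$callers) | !nzchar(calls$callers),
                            label, calls$callers)
    calls
  }
  calls_a <- fill_callers(calls_a, label_a)
  calls_b <- fill_callers(calls_b, label_b)
  ka <- locus_key(calls_a, key)
  kb <- locus_key(calls_b, key)

  merge_tags <- function(a, b) {
    tags <- sort(unique(unlist(strsplit(c(a, b), ",", fixed = TRUE))))
    paste(tags, collapse = ",")
  }
  both <- intersect(ka, kb)
  rows <- list()
  for (k in both) {
    ra <- calls_a[match(k, ka), , drop = FALSE]
    rb <- calls_b[match(k, kb), , drop = FALSE]
    keep <- if (rb$depth > ra$depth) rb else ra
    keep$callers <- merge_tags(ra$callers, rb$callers)
    rows[[length(rows) + 1L]] <- keep
  }
  merged_both <- if (length(rows) > 0L) do.call(rbind, rows) else
    calls_a[0L, , drop = FALSE]
  out <- if (mode == "intersection") {
    merged_both
  } else {
    rbind(merged_both,
          calls_a[!(ka %in% both), , drop = FALSE],
          calls_b[!(kb %in% both), , drop = FALSE])
  }
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the matched-normal somatic filters
#'
#' A tumor call passes when its depth reaches `min_depth`, its allelic
#' fraction strictly exceeds `min_af`, the matched blood does not show the
#' variant above the germline cutoff, and all extra predicates (if any)
#' hold.  Each rejected call carries exactly one primary reason, assigned
#' in the fixed order germline, depth, af, then extra predicates, so
#' rejection summaries are deterministic.  Loci where the blood sample is
#' covered below `germline_min_blood_depth` cannot be assessed for germline
#' status: they are retained (subject to the other filters), flagged
#' `blood_low_coverage = TRUE`, and a warning is emitted.
#'
#' @param tumor_calls calls from one patient's tumor sample(s).
#' @param blood_calls calls from that patient's matched blood; an empty
#'   data frame means the blood was sequenced and shows no variant, but
#'   `NULL` (no matched normal at all) is an error, because the design
#'   requires a matched blood reference.
#' @param cfg a [filter_config()].
#' @return list with `passing` (calls, plus `blood_low_coverage` flag
#'   column) and `rejected` (calls plus `reason` column).
#' @export
apply_somatic_filters <- function(tumor_calls, blood_calls,
                                  cfg = filter_config()) {
  if (is.null(blood_calls)) {
    stop("matched blood sample is required to exclude germline variants")
  }
  tumor_calls <- validate_calls(tumor_calls)
  blood_calls <- validate_calls(blood_calls)
  n <- nrow(tumor_calls)
  key <- cfg$locus_key
  tk <- locus_key(tumor_calls, key)
  bk <- locus_key(blood_calls, key)
  idx <- match(tk, bk)
  blood_af <- ifelse(is.na(idx), 0, blood_calls$af[idx])
  blood_depth <- ifelse(is.na(idx), NA_integer_, blood_calls$depth[idx])

  # a blood record below the trust depth cannot rule germline in or out
  low_cov <- !is.na(idx) & blood_depth < cfg$germline_min_blood_depth
  germline <- !is.na(idx) & !low_cov & blood_af > cfg$germline_max_af_in_blood
  fail_depth <- tumor_calls$depth < cfg$min_depth
  fail_af <- !(tumor_calls$af > cfg$min_af)

  reason <- rep(NA_character_, n)
  reason[fail_af] <- "af"
  reason[fail_depth] <- "depth"
  reason[germline] <- "germline"
  for (nm in rev(names(cfg$extra_predicates))) {
    keep <- cfg$extra_predicates[[nm]](tumor_calls)
    if (!is.logical(keep) || length(keep) != n) {
      stop("extra predicate '", nm, "' must return one logical per call")
    }
    reason[is.na(reason) & !keep] <- nm
  }

  pass <- is.na(reason)
  if (any(low_cov & pass)) {
    warning(sum(low_cov & pass),
            " passing call(s) at loci with blood coverage below ",
            cfg$germline_min_blood_depth, "x; germline status unresolved")
  }
  passing <- tumor_calls[pass, , drop = FALSE]
  passing$blood_low_coverage <- low_cov[pass]
  rejected <- tumor_calls[!pass, , drop = FALSE]
  rejected$reason <- reason[!pass]
  rownames(passing) <- rownames(rejected) <- NULL
  list(passing = passing, rejected = rejected, config = cfg)
}

#' Count rejections per filter reason
#'
#' @param rejected the `rejected` element of [apply_somatic_filters()].
#' @return named integer vector over the built-in reasons (germline, depth,
#'   af) plus any extra-predicate reasons observed; sums to `nrow(rejected)`.
#' @export
filter_summary <- function(rejected) {
  reasons <- c("germline", "depth", "af")
  extra <- setdiff(unique(rejected$reason), reasons)
  reasons <- c(reasons, sort(extra))
  counts <- vapply(reasons, function(r) sum(rejected$reason == r), integer(1))
  stopifnot(sum(counts) == nrow(rejected))
  counts
}
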