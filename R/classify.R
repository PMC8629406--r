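#' Classify a variant's predicted effect
#'
#' Variants are assigned to four mutually exclusive classes:
#' length-changing variants are `indel` (insertions/deletions below 50 bp;
#' larger length changes are outside the targeted-panel scope and raise an
#' error); single-nucleotide variants with a codon annotation are
#' `synonymous` when reference and alternate codons encode the same amino
#' acid and `non_synonymous` otherwise; SNVs without interpretable
#' annotation are variants of unknown significance (`vus`).
#'
#' @param ref,alt allele strings (A/C/G/T).
#' @param ref_codon,alt_codon optional 3-base codons around an SNV; both or
#'   neither must be given.
#' @return one of `"indel"`, `"synonymous"`, `"non_synonymous"`, `"vus"`.
#' @export
classify_effect <- function(ref, alt, ref_codon = NULL, alt_codon = NULL) {
  stopifnot(length(ref) == 1L, length(alt) == 1L)
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt) || ref == alt) {
    stop("ref and alt must be distinct A/C/G/T strings")
  }
  len_diff <- abs(nchar(ref) - nchar(alt))
  if (len_diff >= 50L) {
    stop("length change of ", len_diff, " bp is out of panel scope (< 50 bp)")
  }
  if (len_diff > 0L) return("indel")
  if (nchar(ref) > 1L) return("vus")  # equal-length MNV: not interpretable here
  if (is.null(ref_codon) != is.null(alt_codon)) {
    stop("provide both ref_codon and alt_codon, or neither")
  }
  if (is.null(ref_codon)) return("vus")
  aa <- function(codon) {
    if (!grepl("^[ACGT]{3}$", codon)) stop("codon must be 3 bases: ", codon)
    seqinr::translate(strsplit(codon, "")[[1L]])
  }
  if (aa(ref_codon) == aa(alt_codon)) "synonymous" else "non_synonymous"
}

# Effect label for a set of calls at one locus: first non-missing label,
# "unclassified" mapped to vus (no interpretable annotation).
consensus_effect <- function(effects) {
  effects <- effects[!is.na(effects)]
  effects[effects == "unclassified"] <- "vus"
  if (length(effects) == 0L) return("vus")
  tab <- table(effects)
  names(tab)[which.max(tab)]
}

# Restrict calls to primary-surgery tumor samples and attach site info.
primary_tumor_calls <- function(calls, meta) {
  keep <- meta$sample_id[meta$role == "tumor" & meta$stage == "primary"]
  calls <- calls[calls$sample_id %in% keep, , drop = FALSE]
  idx <- match(calls$sample_id, meta$sample_id)
  calls$site <- meta$site[idx]
  calls$patient_id <- meta$patient_id[idx]
  calls
}

#' Cohort-level shared-mutation labels
#'
#' A locus is *shared* when it is called in at least one ovary sample and
#' at least one synchronous (non-ovary, primary-surgery) lesion anywhere in
#' the cohort — the two occurrences need not come from the same patient.
#' Only primary-surgery tumor samples are considered.
#'
#' @param calls passing somatic calls (cohort).
#' @param meta sample sheet (see [read_sample_sheet()]).
#' @param key locus key mode, see [locus_key()].
#' @return named character vector, locus key -> `"shared"`/`"not_shared"`.
#' @export
label_sharing_cohort <- function(calls, meta, key = "allele") {
  calls <- primary_tumor_calls(calls, meta)
  if (nrow(calls) == 0L) return(setNames(character(0), character(0)))
  k <- locus_key(calls, key)
  in_ovary <- tapply(calls$site == "ovary", k, any)
  in_sync <- tapply(calls$site != "ovary", k, any)
  loci <- names(in_ovary)
  setNames(ifelse(in_ovary[loci] & in_sync[loci], "shared", "not_shared"),
           loci)
}

#' Per-patient concordance labels
#'
#' Within one patient's primary-surgery samples, a locus is *concordant*
#' when it is called in at least one ovary sample and at least one matched
#' synchronous lesion; a locus present in two or more synchronous lesions
#' but in no ovary sample is *synchronous_recurrent* (a class the binary
#' concordant/private split would otherwise corrupt); every other locus is
#' *private* (in the typical case, confined to a single biopsy).
#'
#' @param calls passing calls of one patient.
#' @param meta sample sheet.
#' @param key locus key mode.
#' @return named character vector, locus key ->
#'   `"concordant"`/`"private"`/`"synchronous_recurrent"`.
#' @export
label_concordant_patient <- function(calls, meta, key = "allele") {
  calls <- primary_tumor_calls(calls, meta)
  patients <- unique(calls$patient_id)
  if (length(patients) > 1L) {
    stop("label_concordant_patient expects calls from a single patient")
  }
  if (nrow(calls) > 0L) {
    psamples <- meta[meta$patient_id == patients & meta$role == "tumor" &
                       meta$stage == "primary", , drop = FALSE]
    if (!any(psamples$site == "ovary")) {
      stop("patient ", patients, " has no ovary sample at primary surgery")
    }
  }
  if (nrow(calls) == 0L) return(setNames(character(0), character(0)))
  k <- locus_key(calls, key)
  n_ovary <- tapply(calls$site == "ovary", k, sum)
  n_sync_samples <- tapply(
    paste(calls$sample_id)[calls$site != "ovary"],
    k[calls$site != "ovary"],
    function(s) length(unique(s)))
  loci <- names(n_ovary)
  n_sync <- ifelse(is.na(n_sync_samples[loci]), 0L, n_sync_samples[loci])
  lab <- ifelse(n_ovary[loci] > 0L & n_sync > 0L, "concordant",
                ifelse(n_sync >= 2L, "synchronous_recurrent", "private"))
  setNames(lab, loci)
}

#' Category table: compartment-by-effect variant counts
#'
#' Counts the distinct somatic variants found at primary surgery in a
#' 3 x 4 layout: compartments ovary-exclusive, synchronous-exclusive and
#' shared (rows) against the four effect classes (columns), with row and
#' column totals.  Shared loci (see [label_sharing_cohort()]) are counted
#' once cohort-wide in the shared row and excluded from the other two; the
#' exclusive compartments count one unit per (patient, locus), i.e. a locus
#' is deduplicated across the samples of one patient but counted again
#' when an independent patient carries it.
#'
#' @param calls passing calls with effect labels (calls lacking one are an
#'   error).
#' @param meta sample sheet.
#' @param key locus key mode.
#' @return a `category_table`: integer matrix with rows `ovary,
#'   synchronous, shared, total` and columns `non_synonymous, synonymous,
#'   indel, vus, total`.
#' @export
category_table <- function(calls, meta, key = "allele") {
  pcalls <- primary_tumor_calls(calls, meta)
  effects <- c("non_synonymous", "synonymous", "indel", "vus")
  tab <- matrix(0L, nrow = 3L, ncol = 4L,
                dimnames = list(c("ovary", "synchronous", "shared"), effects))
  if (nrow(pcalls) > 0L) {
    if (any(is.na(pcalls$effect))) {
      stop("call without effect label at row ", which(is.na(pcalls$effect))[1L])
    }
    sharing <- label_sharing_cohort(pcalls, meta, key)
    k <- locus_key(pcalls, key)
    eff_of <- tapply(pcalls$effect, k, consensus_effect)

    shared_loci <- names(sharing)[sharing == "shared"]
    for (e in effects) {
      tab["shared", e] <- sum(eff_of[shared_loci] == e)
    }
    rest <- pcalls[!(k %in% shared_loci), , drop = FALSE]
    if (nrow(rest) > 0L) {
      rk <- locus_key(rest, key)
      unit <- !duplicated(paste(rest$patient_id, rk))
      units <- rest[unit, , drop = FALSE]
      uk <- rk[unit]
      comp <- ifelse(units$site == "ovary", "ovary", "synchronous")
      ueff <- unname(eff_of[uk])
      for (cmp in c("ovary", "synchronous")) {
        for (e in effects) {
          tab[cmp, e] <- tab[cmp, e] + sum(comp == cmp & ueff == e)
        }
      }
    }
  }
  out <- rbind(tab, total = colSums(tab))
  out <- cbind(out, total = rowSums(out))
  structure(out, class = c("category_table", class(out)))
}

#' @export
print.category_table <- function(x, ...) {
  print(unclass(x))
  tot <- x["total", "total"]
  if (tot > 0) {
    cat(sprintf("shared: %.1f%% of all variants; shared VUS: %.1f%% of VUS\n",
                100 * x["shared", "total"] / tot,
                100 * x["shared", "vus"] / max(x["total", "vus"], 1L)))
  }
  invisible(x)
}

#' Expand a compartment-by-effect count table into a minimal call set
#'
#' Reconstructs a smallest cohort realizing given category counts: every
#' ovary-exclusive unit becomes a locus private to one patient's ovary
#' biopsy, every synchronous-exclusive unit a locus private to a second
#' patient's omentum biopsy, and every shared unit a locus called in the
#' first patient's ovary and the second patient's omentum (sharing across
#' patients, as the cohort-level definition allows).  Feeding the result
#' to [category_table()] returns the original counts, which makes
#' published summary tables directly checkable against the counting
#' logic.
#'
#' @param counts data frame with a `compartment` column (values `ovary`,
#'   `synchronous`, `shared`) and the four effect-class columns.
#' @return list with `calls` and `meta` ready for [category_table()].
#' @export
expand_category_counts <- function(counts) {
  effects <- c("non_synonymous", "synonymous", "indel", "vus")
  stopifnot(all(c("compartment", effects) %in% names(counts)),
            all(counts$compartment %in% c("ovary", "synchronous", "shared")))
  meta <- data.frame(
    sample_id = c("A-OV", "B-OM"),
    patient_id = c("A", "B"),
    role = "tumor",
    site = c("ovary", "omentum"),
    stage = "primary",
    stringsAsFactors = FALSE)
  rows <- list()
  pos <- 0L
  add <- function(sample_id, pos, effect) {
    ref <- if (effect == "indel") "CA" else "C"
    data.frame(sample_id = sample_id, chrom = "chr1", pos = 1000L + pos,
               ref = ref, alt = "T", depth = 1000L, alt_reads = 100L,
               af = 0.1, effect = effect, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(counts))) {
    cmp <- counts$compartment[i]
    for (e in effects) {
      k <- as.integer(counts[[e]][i])
      for (j in seq_len(k)) {
        pos <- pos + 1L
        rows[[length(rows) + 1L]] <- switch(
          cmp,
          ovary = add("A-OV", pos, e),
          synchronous = add("B-OM", pos, e),
          shared = rbind(add("A-OV", pos, e), add("B-OM", pos, e)))
      }
    }
  }
  list(calls = validate_calls(do.call(rbind, rows)),
       meta = validate_sample_sheet(meta))
}

#' @export
summary.category_table <- function(object, ...) {
  tot <- object["total", "total"]
  list(
    ovary_total = unname(object["ovary", "total"]),
    synchronous_total = unname(object["synchronous", "total"]),
    shared_total = unname(object["shared", "total"]),
    grand_total = unname(tot),
    shared_pct = if (tot > 0) round(100 * object["shared", "total"] / tot, 1)
    else NA_real_,
    shared_vus_pct = if (object["total", "vus"] > 0)
      round(100 * object["shared", "vus"] / object["total", "vus"], 1)
    else NA_real_
  )
}
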