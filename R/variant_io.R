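#' Locus identity keys
#'
#' Builds the string key that identifies a variant locus.  The default
#' (`"allele"`) is allele-aware — two calls are "the same locus" only when
#' chromosome, position, reference and alternate allele all agree — which
#' reads "same locus" conservatively as "same variant" and prevents two
#' different substitutions at one site from counting as concordant.  The
#' looser `"site"` key matches on chromosome and position alone.
#'
#' @param calls data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param key `"allele"` (default) or `"site"`.
#' @return character vector of keys, one per row.
#' @export
locus_key <- function(calls, key = c("allele", "site")) {
  key <- match.arg(key)
  if (key == "allele") {
    paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  } else {
    paste(calls$chrom, calls$pos, sep = ":")
  }
}

#' Validate a variant call table
#'
#' Checks the invariants of the internal call table: positive 1-based
#' positions, alleles over A/C/G/T with `ref != alt`, `alt_reads <= depth`,
#' allelic fraction in `[0, 1]` and consistent with read counts when both
#' are present, indel length difference below 50 bp, and uniqueness of
#' `(sample_id, chrom, pos, ref, alt)`.
#'
#' @param calls data frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_reads`, `af` and optionally `gene`, `effect`,
#'   `callers`.
#' @return the validated (and column-completed) data frame, invisibly usable.
#' @export
validate_calls <- function(calls) {
  required <- c("sample_id", "chrom", "pos", "ref", "alt", "depth",
                "alt_reads", "af")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("gene", "effect", "callers")) {
    if (is.null(calls[[col]])) calls[[col]] <- rep(NA_character_, nrow(calls))
  }
  calls$pos <- as.integer(calls$pos)
  calls$depth <- as.integer(calls$depth)
  calls$alt_reads <- as.integer(calls$alt_reads)
  calls$af <- as.numeric(calls$af)

  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0L) stop(msg, " (row ", i[1L], ")")
  }
  bad(is.na(calls$pos) | calls$pos < 1L, "pos must be an integer >= 1")
  allele_ok <- function(x) !is.na(x) & nzchar(x) & grepl("^[ACGT]+$", x)
  bad(!allele_ok(calls$ref), "ref must be a nonempty A/C/G/T string")
  bad(!allele_ok(calls$alt), "alt must be a nonempty A/C/G/T string")
  bad(calls$ref == calls$alt, "ref and alt must differ")
  bad(is.na(calls$depth) | calls$depth < 0L, "depth must be >= 0")
  bad(is.na(calls$alt_reads) | calls$alt_reads < 0L, "alt_reads must be >= 0")
  bad(calls$alt_reads > calls$depth, "alt_reads exceeds depth")
  # derive af from counts where absent; an explicitly reported af is kept
  # (callers may report an af that differs slightly from the AD ratio)
  calls$af[is.na(calls$af)] <-
    ifelse(calls$depth[is.na(calls$af)] > 0L,
           calls$alt_reads[is.na(calls$af)] /
             pmax(calls$depth[is.na(calls$af)], 1L), 0)
  bad(is.na(calls$af) | calls$af < 0 | calls$af > 1, "af must lie in [0, 1]")
  len_diff <- abs(nchar(calls$ref) - nchar(calls$alt))
  bad(len_diff >= 50L, "indel length difference must be < 50 bp")
  known_eff <- is.na(calls$effect) | calls$effect %in% EFFECT_LEVELS
  bad(!known_eff, "unknown effect label")
  bad(!is.na(calls$effect) & calls$effect == "indel" & len_diff == 0L,
      "effect 'indel' requires differing allele lengths")

  ids <- paste(calls$sample_id, locus_key(calls), sep = "@")
  if (anyDuplicated(ids)) {
    stop("duplicated (sample, locus) record (row ",
         which(duplicated(ids))[1L], ")")
  }
  calls
}

#' Read a variant table (TSV dialect or VCF)
#'
#' The TSV dialect is tab-separated with a header row and columns
#' `sample_id, chrom, pos, ref, alt, depth, alt_reads` plus optional
#' `af, gene, effect, callers`; positions are 1-based.  The allelic
#' fraction is computed as `alt_reads / depth` when the `af` column is
#' absent.  VCF input (v4.x) must carry per-sample `DP` and `AD` fields;
#' multi-allelic records are split into one call per alternate allele.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return validated call data frame (see [validate_calls()]).
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "tsv") read_variant_tsv(path) else read_variant_vcf(path)
}

read_variant_tsv <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "chrom", "pos", "ref", "alt", "depth",
                "alt_reads")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("variant TSV ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(tab)
  calls <- data.frame(
    sample_id = tab$sample_id,
    chrom = tab$chrom,
    pos = suppressWarnings(as.integer(tab$pos)),
    ref = tab$ref,
    alt = tab$alt,
    depth = suppressWarnings(as.integer(tab$depth)),
    alt_reads = suppressWarnings(as.integer(tab$alt_reads)),
    stringsAsFactors = FALSE
  )
  bad_num <- which(is.na(calls$pos) | is.na(calls$depth) |
                     is.na(calls$alt_reads))
  if (length(bad_num) > 0L) {
    # +1 for the header so the message points at the file line
    stop("malformed numeric field in ", path, " at line ", bad_num[1L] + 1L)
  }
  calls$af <- if ("af" %in% names(tab)) {
    suppressWarnings(as.numeric(tab$af))
  } else {
    ifelse(calls$depth > 0L, calls$alt_reads / calls$depth, 0)
  }
  for (col in c("gene", "effect", "callers")) {
    calls[[col]] <- if (col %in% names(tab)) {
      ifelse(nzchar(tab[[col]]), tab[[col]], NA_character_)
    } else NA_character_
  }
  if (n == 0L) return(validate_calls(calls))
  tryCatch(validate_calls(calls), error = function(e) {
    stop("invalid record in ", path, ": ", conditionMessage(e))
  })
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- rbind(vcfR::getFIX(vcf))  # single records drop to a vector
  if (nrow(fix) == 0L) {
    return(validate_calls(data.frame(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), depth = integer(),
      alt_reads = integer(), af = numeric(), stringsAsFactors = FALSE)))
  }
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if (!all(c("DP", "AD") %in% fmt_keys)) {
    stop("VCF ", path, " lacks per-sample DP/AD depth fields")
  }
  dp <- vcfR::extract.gt(vcf, element = "DP")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(dp)
  out <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    rows <- list()
    for (i in seq_len(nrow(fix))) {
      if (is.na(ad[i, s]) || is.na(dp[i, s])) next
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
      ad_i <- suppressWarnings(as.integer(
        strsplit(ad[i, s], ",", fixed = TRUE)[[1L]]))
      if (length(ad_i) != length(alts) + 1L) {
        stop("VCF ", path, ": AD field inconsistent with ALT at record ", i)
      }
      depth_i <- suppressWarnings(as.integer(dp[i, s]))
      for (a in seq_along(alts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = samples[s],
          chrom = fix[i, "CHROM"],
          pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"],
          alt = alts[a],
          depth = depth_i,
          alt_reads = ad_i[a + 1L],
          stringsAsFactors = FALSE
        )
      }
    }
    out[[s]] <- do.call(rbind, rows)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) stop("VCF ", path, " yielded no usable records")
  calls <- calls[calls$alt_reads > 0L | calls$depth == 0L, , drop = FALSE]
  calls$af <- ifelse(calls$depth > 0L, calls$alt_reads / calls$depth, 0)
  rownames(calls) <- NULL
  validate_calls(calls)
}

#' Write a variant table in the package TSV dialect
#'
#' @param calls validated call data frame.
#' @param path output path.
#' @export
write_variant_table <- function(calls, path) {
  calls <- validate_calls(calls)
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "depth", "alt_reads",
            "af", "gene", "effect", "callers")
  out <- calls[, cols]
  out$af <- sprintf("%.10g", out$af)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects a CSV or TSV with columns `sample_id, patient_id, role, site,
#' stage` and optionally `histotype, grade, pt_status`.  Blood samples may
#' leave `site`/`stage` empty (they are ignored downstream).  Unknown
#' categorical values, duplicate blood samples for one patient, and tumor
#' samples without a patient id are errors.
#'
#' @param path path to the sheet (`.csv` uses commas, anything else tabs).
#' @return validated metadata data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, header = TRUE,
                    colClasses = "character", check.names = FALSE)
  validate_sample_sheet(tab)
}

#' @rdname read_sample_sheet
#' @param meta a data frame with the sample-sheet columns.
#' @export
validate_sample_sheet <- function(meta) {
  required <- c("sample_id", "patient_id", "role", "site", "stage")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("histotype", "grade", "pt_status")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  }
  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(x), NA_character_, x)
  for (col in c("site", "stage", "histotype", "grade", "pt_status")) {
    meta[[col]] <- blank_to_na(meta[[col]])
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  }
  check_enum <- function(x, levels, what, required_for) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop("unknown ", what, " value '", x[bad][1L], "'")
    }
    need <- required_for & is.na(x)
    if (any(need)) {
      stop(what, " missing for sample ", meta$sample_id[need][1L])
    }
  }
  check_enum(meta$role, ROLE_LEVELS, "role", rep(TRUE, nrow(meta)))
  is_tumor <- meta$role == "tumor"
  check_enum(meta$site, SITE_LEVELS, "site", is_tumor)
  check_enum(meta$stage, STAGE_LEVELS, "stage", is_tumor)
  check_enum(meta$histotype, HISTO_LEVELS, "histotype", rep(FALSE, nrow(meta)))
  check_enum(meta$grade, GRADE_LEVELS, "grade", rep(FALSE, nrow(meta)))
  check_enum(meta$pt_status, PT_LEVELS, "pt_status", rep(FALSE, nrow(meta)))
  no_patient <- is_tumor & (is.na(meta$patient_id) | !nzchar(meta$patient_id))
  if (any(no_patient)) {
    stop("tumor sample without patient id: ", meta$sample_id[no_patient][1L])
  }
  bloods <- meta$patient_id[meta$role == "blood"]
  if (anyDuplicated(bloods)) {
    stop("patient ", bloods[duplicated(bloods)][1L],
         " has more than one blood sample")
  }
  rownames(meta) <- NULL
  meta
}

#' Read a gene panel (BED intervals + gene-to-pathway map)
#'
#' The BED file gives per-gene target intervals in 0-based half-open
#' coordinates (`chrom, start, end, gene`); the pathway map is a two-column
#' TSV (`gene, pathway`).  Intervals of one gene must not overlap and every
#' panel gene must have exactly one pathway label.
#'
#' @param bed_path BED file of gene intervals.
#' @param pathway_path two-column gene/pathway TSV.
#' @return a `gene_panel` list with `intervals` (data frame) and
#'   `pathway_of` (named character vector).
#' @export
read_gene_panel <- function(bed_path, pathway_path) {
  bed <- read.delim(bed_path, header = FALSE, colClasses = "character")
  if (ncol(bed) < 4L) stop("panel BED needs chrom,start,end,gene columns")
  intervals <- data.frame(
    chrom = bed[[1L]],
    start = as.integer(bed[[2L]]),
    end = as.integer(bed[[3L]]),
    gene = bed[[4L]],
    stringsAsFactors = FALSE
  )
  pw <- read.delim(pathway_path, header = TRUE, colClasses = "character")
  if (!all(c("gene", "pathway") %in% names(pw))) {
    names(pw)[1:2] <- c("gene", "pathway")
  }
  pathway_of <- setNames(pw$pathway, pw$gene)
  gene_panel(intervals, pathway_of)
}

#' Construct and validate a gene panel
#'
#' @param intervals data frame `chrom, start, end, gene` (0-based half-open).
#' @param pathway_of named character vector mapping gene symbol to pathway.
#' @return `gene_panel` object.
#' @export
gene_panel <- function(intervals, pathway_of) {
  if (any(intervals$end <= intervals$start)) {
    stop("panel interval with end <= start")
  }
  # per-gene (and per-chromosome) overlap check
  by_key <- split(intervals, paste(intervals$gene, intervals$chrom))
  for (iv in by_key) {
    if (nrow(iv) < 2L) next
    iv <- iv[order(iv$start), ]
    if (any(iv$start[-1L] < iv$end[-nrow(iv)])) {
      stop("overlapping intervals for gene ", iv$gene[1L])
    }
  }
  genes <- unique(intervals$gene)
  missing_pw <- setdiff(genes, names(pathway_of))
  if (length(missing_pw) > 0L) {
    stop("gene without pathway label: ", missing_pw[1L])
  }
  if (anyDuplicated(names(pathway_of))) {
    stop("gene with more than one pathway label: ",
         names(pathway_of)[duplicated(names(pathway_of))][1L])
  }
  structure(list(intervals = intervals,
                 pathway_of = pathway_of[genes]),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("gene panel:", length(unique(x$intervals$gene)), "genes,",
      nrow(x$intervals), "intervals,",
      length(unique(x$pathway_of)), "pathways\n")
  invisible(x)
}

#' Write a panel to BED + pathway TSV
#'
#' @param panel `gene_panel` object.
#' @param bed_path,pathway_path output paths.
#' @export
write_gene_panel <- function(panel, bed_path, pathway_path) {
  write.table(panel$intervals[, c("chrom", "start", "end", "gene")],
              bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(gene = names(panel$pathway_of),
                         pathway = unname(panel$pathway_of)),
              pathway_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}

# Quote a tip label for Newick if it contains metacharacters.
newick_quote <- function(labels) {
  needs <- grepl("[]['():;,[:space:]]", labels)
  labels[needs] <- paste0("'", gsub("'", "''", labels[needs]), "'")
  labels
}

#' Write / read a phylogenetic tree in Newick format
#'
#' Thin wrappers over \pkg{ape} that quote tip labels containing Newick
#' metacharacters so that write-then-read round trips preserve labels and
#' branch lengths (to 1e-6).
#'
#' @param tree an `ape::phylo` tree with unique leaf labels and nonnegative
#'   branch lengths.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths")
  }
  tree$tip.label <- newick_quote(tree$tip.label)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file ", path)
  tr$tip.label <- gsub("^'|'$", "", tr$tip.label)
  tr
}
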