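#' Per-sample mutational burden
#'
#' Counts passing somatic variants per tumor sample, broken down by effect
#' class.  Blood and control samples are excluded; tumor samples with zero
#' passing calls appear with all-zero counts (the observed inter-patient
#' range starts at zero).
#'
#' @param calls passing calls with effect labels.
#' @param meta sample sheet.
#' @return data frame with one row per tumor sample: `sample_id`,
#'   `patient_id`, the four effect-class counts, and `total`.
#' @export
mutational_burden <- function(calls, meta) {
  tumor <- meta[meta$role == "tumor", , drop = FALSE]
  effects <- c("non_synonymous", "synonymous", "indel", "vus")
  calls <- calls[calls$sample_id %in% tumor$sample_id, , drop = FALSE]
  eff <- calls$effect
  eff[is.na(eff) | eff == "unclassified"] <- "vus"
  out <- data.frame(sample_id = tumor$sample_id,
                    patient_id = tumor$patient_id,
                    stringsAsFactors = FALSE)
  for (e in effects) {
    out[[e]] <- vapply(tumor$sample_id, function(s)
      sum(calls$sample_id == s & eff == e), integer(1), USE.NAMES = FALSE)
  }
  out$total <- rowSums(out[, effects])
  out
}

# Map call positions (1-based) onto panel genes (0-based half-open
# intervals); returns the gene symbol or "off_target".
assign_gene <- function(calls, panel) {
  iv <- panel$intervals
  genes <- rep("off_target", nrow(calls))
  pos0 <- calls$pos - 1L
  for (chr in unique(iv$chrom)) {
    ic <- iv[iv$chrom == chr, , drop = FALSE]
    ic <- ic[order(ic$start), , drop = FALSE]
    sel <- which(calls$chrom == chr)
    if (length(sel) == 0L) next
    j <- findInterval(pos0[sel], ic$start)
    hit <- j > 0L & pos0[sel] < ic$end[pmax(j, 1L)]
    genes[sel[hit]] <- ic$gene[j[hit]]
  }
  genes
}

# Compartment of a tumor sample: ovary / synchronous (non-ovary primary) /
# metachronous (post-chemotherapy surgery).
sample_compartment <- function(meta) {
  ifelse(meta$stage != "primary", "metachronous",
         ifelse(meta$site == "ovary", "ovary", "synchronous"))
}

#' Per-gene mutation counts
#'
#' Counts passing variants per panel gene, grouped either by anatomical
#' compartment (ovary / synchronous / metachronous) or by sample.  Genes
#' are assigned by interval overlap with the panel; variants falling
#' outside every panel gene are collected under `off_target`.
#'
#' @param calls passing calls.
#' @param panel a [gene_panel()].
#' @param meta sample sheet.
#' @param group_by `"compartment"` (default) or `"sample"`.
#' @return integer matrix, genes (plus `off_target` when present) x groups.
#' @export
per_gene_counts <- function(calls, panel, meta,
                            group_by = c("compartment", "sample")) {
  group_by <- match.arg(group_by)
  tumor <- meta[meta$role == "tumor", , drop = FALSE]
  calls <- calls[calls$sample_id %in% tumor$sample_id, , drop = FALSE]
  idx <- match(calls$sample_id, tumor$sample_id)
  group <- if (group_by == "sample") calls$sample_id else
    sample_compartment(tumor)[idx]
  gene <- assign_gene(calls, panel)
  all_genes <- unique(panel$intervals$gene)
  if ("off_target" %in% gene) all_genes <- c(all_genes, "off_target")
  groups <- if (group_by == "sample") sort(unique(tumor$sample_id)) else
    c("ovary", "synchronous", "metachronous")
  m <- matrix(0L, nrow = length(all_genes), ncol = length(groups),
              dimnames = list(all_genes, groups))
  if (nrow(calls) > 0L) {
    tab <- table(factor(gene, levels = all_genes),
                 factor(group, levels = groups))
    m[] <- as.integer(tab)
  }
  m
}

#' Per-pathway mutation counts with compartment comparison
#'
#' Aggregates per-gene counts to pathways and, for each pathway, compares
#' the proportion of mutations falling in that pathway between the ovary
#' and synchronous compartments with a two-sided two-proportion test
#' (chi-squared with one degree of freedom).
#'
#' @param gene_counts output of [per_gene_counts()] with
#'   `group_by = "compartment"`.
#' @param panel a [gene_panel()]; every counted gene must carry a pathway.
#' @return list with `counts` (pathway x group matrix; off-target calls,
#'   if any, under `off_target`) and `tests` (data frame of per-pathway
#'   ovary-vs-synchronous p-values).
#' @export
per_pathway_counts <- function(gene_counts, panel) {
  genes <- rownames(gene_counts)
  pw <- panel$pathway_of[genes]
  pw[genes == "off_target"] <- "off_target"
  if (any(is.na(pw))) {
    stop("gene without pathway label: ", genes[is.na(pw)][1L])
  }
  counts <- rowsum(gene_counts, group = pw)
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  tests <- NULL
  if (all(c("ovary", "synchronous") %in% colnames(counts))) {
    n_ov <- sum(counts[, "ovary"])
    n_sy <- sum(counts[, "synchronous"])
    pvals <- vapply(rownames(counts), function(p) {
      x <- c(counts[p, "ovary"], counts[p, "synchronous"])
      if (n_ov == 0 || n_sy == 0 || sum(x) == 0) return(NA_real_)
      suppressWarnings(prop.test(x, c(n_ov, n_sy))$p.value)
    }, numeric(1))
    tests <- data.frame(pathway = rownames(counts),
                        ovary = counts[, "ovary"],
                        synchronous = counts[, "synchronous"],
                        p_value = pvals,
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(counts = counts, tests = tests)
}

#' Patient-by-gene concordant-mutation matrix
#'
#' Cell (p, g) counts the concordant loci of patient p (see
#' [label_concordant_patient()]) that fall in panel gene g; zero encodes
#' absence of concordant mutations.  Patients without both an ovary and a
#' synchronous primary sample cannot have concordant loci and get all-zero
#' rows.
#'
#' @param calls passing calls (cohort).
#' @param meta sample sheet.
#' @param panel a [gene_panel()].
#' @param key locus key mode.
#' @return integer matrix, patients x genes.
#' @export
concordance_heatmap_matrix <- function(calls, meta, panel, key = "allele") {
  tumor <- meta[meta$role == "tumor" & meta$stage == "primary", , drop = FALSE]
  patients <- sort(unique(tumor$patient_id))
  genes <- unique(panel$intervals$gene)
  m <- matrix(0L, nrow = length(patients), ncol = length(genes),
              dimnames = list(patients, genes))
  for (p in patients) {
    psamp <- tumor$sample_id[tumor$patient_id == p]
    has_ovary <- any(tumor$site[tumor$patient_id == p] == "ovary")
    has_sync <- any(tumor$site[tumor$patient_id == p] != "ovary")
    if (!has_ovary || !has_sync) next
    pcalls <- calls[calls$sample_id %in% psamp, , drop = FALSE]
    if (nrow(pcalls) == 0L) next
    lab <- label_concordant_patient(pcalls, meta, key)
    conc <- names(lab)[lab == "concordant"]
    if (length(conc) == 0L) next
    k <- locus_key(pcalls, key)
    first <- pcalls[match(conc, k), , drop = FALSE]
    g <- assign_gene(first, panel)
    for (gi in g[g %in% genes]) m[p, gi] <- m[p, gi] + 1L
  }
  m
}

#' Leaf-pair similarity over a patient's locus universe
#'
#' For two biopsies of one patient, partitions the patient's locus universe
#' into *concordant* (called in both), *private* (called in exactly one)
#' and *wild type* (called in neither) and reports the three percentages.
#' The default universe is every locus somatic in at least one sample of
#' the patient, which makes the three classes a well-defined finite
#' partition; percentages therefore always sum to 100.
#'
#' @param loci_a,loci_b character vectors of locus keys called in each
#'   sample.
#' @param universe character vector of locus keys (the patient universe);
#'   must be nonempty and must contain every called locus.
#' @param sample_a,sample_b optional labels carried into the result.
#' @return a `similarity_triple` list with `concordant_pct`, `private_pct`,
#'   `wt_pct` (percent of the universe) and the counts behind them.
#' @export
leaf_pair_similarity <- function(loci_a, loci_b, universe,
                                 sample_a = "A", sample_b = "B") {
  universe <- unique(universe)
  if (length(universe) == 0L) {
    stop("empty locus universe: similarity percentages are undefined")
  }
  loci_a <- unique(loci_a)
  loci_b <- unique(loci_b)
  stray <- setdiff(c(loci_a, loci_b), universe)
  if (length(stray) > 0L) {
    stop("called locus outside the universe: ", stray[1L])
  }
  in_a <- universe %in% loci_a
  in_b <- universe %in% loci_b
  n <- length(universe)
  conc <- sum(in_a & in_b)
  priv <- sum(xor(in_a, in_b))
  wt <- sum(!in_a & !in_b)
  structure(list(sample_a = sample_a, sample_b = sample_b,
                 n_universe = n, n_concordant = conc, n_private = priv,
                 n_wt = wt,
                 concordant_pct = 100 * conc / n,
                 private_pct = 100 * priv / n,
                 wt_pct = 100 * wt / n),
            class = "similarity_triple")
}

#' @export
print.similarity_triple <- function(x, ...) {
  cat(sprintf("%s vs %s (universe %d loci)\n", x$sample_a, x$sample_b,
              x$n_universe))
  cat(sprintf("  concordant %.2f%%  private %.2f%%  wt %.2f%%\n",
              x$concordant_pct, x$private_pct, x$wt_pct))
  invisible(x)
}

#' Similarity table for the cherries of a patient tree
#'
#' Applies [leaf_pair_similarity()] to every cherry (pair of leaves
#' sharing an immediate ancestor, outgroup excluded) of a patient's
#' phylogenetic tree.
#'
#' @param tree `phylo` tree over a patient's biopsies (plus outgroup).
#' @param calls passing calls of that patient.
#' @param outgroup outgroup label to exclude from pairs.
#' @param key locus key mode.
#' @return data frame with one row per cherry: samples, percentages
#'   (printed to two decimals in exports), and the universe size.
#' @export
similarity_table <- function(tree, calls, outgroup = NULL, key = "allele") {
  pairs <- tree_leaf_pairs(tree, exclude = outgroup)
  k <- locus_key(calls, key)
  universe <- unique(k)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$sample_a[i]
    b <- pairs$sample_b[i]
    tr <- leaf_pair_similarity(k[calls$sample_id == a],
                               k[calls$sample_id == b],
                               universe, a, b)
    data.frame(sample_a = a, sample_b = b,
               concordant_pct = round(tr$concordant_pct, 2),
               private_pct = round(tr$private_pct, 2),
               wt_pct = round(tr$wt_pct, 2),
               n_universe = tr$n_universe,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      concordant_pct = numeric(), private_pct = numeric(),
                      wt_pct = numeric(), n_universe = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
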