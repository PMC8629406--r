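#' Pipeline run configuration
#'
#' Collects the inputs and analysis toggles for [run_pipeline()].  Either
#' file paths (`variants`, `samples`, `panel_bed`, `panel_pathways`) or a
#' `simulate` block (a [sim_config()]) must be supplied.
#'
#' @param variants,samples,panel_bed,panel_pathways input file paths
#'   (ignored when `simulate` is given).
#' @param simulate optional [sim_config()]: generate the cohort in-line.
#' @param filter a [filter_config()].
#' @param exclude_synonymous drop synonymous loci from the AF clustering
#'   matrix (default TRUE, the usual convention).
#' @param metric distance metric for clustering and trees (`"euclidean"`
#'   or `"manhattan"`).
#' @param linkage clustering linkage (default `"average"`).
#' @param locus_universe `"patient"` (default): per-patient trees use that
#'   patient's loci; `"cohort"`: all loci called anywhere.
#' @param spectra_mode `"pooled"` (default) or `"per_patient"`.
#' @param seed integer seed (propagated to the simulator).
#' @return a `run_config` list.
#' @export
run_config <- function(variants = NULL, samples = NULL, panel_bed = NULL,
                       panel_pathways = NULL, simulate = NULL,
                       filter = filter_config(),
                       exclude_synonymous = TRUE,
                       metric = c("euclidean", "manhattan"),
                       linkage = "average",
                       locus_universe = c("patient", "cohort"),
                       spectra_mode = c("pooled", "per_patient"),
                       seed = 1L) {
  metric <- match.arg(metric)
  locus_universe <- match.arg(locus_universe)
  spectra_mode <- match.arg(spectra_mode)
  if (is.null(simulate) &&
      (is.null(variants) || is.null(samples) || is.null(panel_bed) ||
       is.null(panel_pathways))) {
    stop("run_config needs either input file paths or a simulate block")
  }
  structure(list(variants = variants, samples = samples,
                 panel_bed = panel_bed, panel_pathways = panel_pathways,
                 simulate = simulate, filter = filter,
                 exclude_synonymous = exclude_synonymous, metric = metric,
                 linkage = linkage, locus_universe = locus_universe,
                 spectra_mode = spectra_mode, seed = as.integer(seed)),
            class = "run_config")
}

# Serializable view of a run_config (function-free), used for the config
# hash recorded in the manifest.
config_as_list <- function(cfg) {
  sim <- cfg$simulate
  list(
    inputs = list(variants = cfg$variants, samples = cfg$samples,
                  panel_bed = cfg$panel_bed,
                  panel_pathways = cfg$panel_pathways),
    simulate = if (!is.null(sim)) {
      s <- unclass(sim)
      s$panel <- NULL
      s$effect_props <- as.list(s$effect_props)
      s$spectrum_weights <- as.list(s$spectrum_weights)
      s
    },
    filter = unclass(cfg$filter)[c("min_depth", "min_af", "caller_mode",
                                   "germline_max_af_in_blood",
                                   "germline_min_blood_depth", "locus_key")],
    exclude_synonymous = cfg$exclude_synonymous,
    metric = cfg$metric, linkage = cfg$linkage,
    locus_universe = cfg$locus_universe, spectra_mode = cfg$spectra_mode,
    seed = cfg$seed)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

write_tsv_rn <- function(x, path, rowname_col) {
  df <- data.frame(rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- rowname_col
  write_tsv(df, path)
}

#' Run the full heterogeneity pipeline
#'
#' Executes the analysis end to end — load or simulate, somatic filtering
#' against each patient's matched blood, effect/sharing classification,
#' category table, mutational burden, per-gene and per-pathway counts,
#' concordance matrix, AF clustering, per-patient phylogenies rooted on
#' the unrelated control, leaf-pair similarity, substitution spectra —
#' and writes one TSV (or Newick) per stage plus a YAML manifest into
#' `out_dir`.  A rerun with the same config and seed is byte-identical.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return a `het_run` object: all stage results plus `files` (paths) and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- load or simulate ------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    sim_cfg$seed <- cfg$seed
    sim <- stage("simulate", simulate_cohort(sim_cfg))
    calls <- sim$calls
    meta <- sim$meta
    panel <- sim$panel
  } else {
    calls <- stage("load", read_variant_table(cfg$variants))
    meta <- stage("load", read_sample_sheet(cfg$samples))
    panel <- stage("load", read_gene_panel(cfg$panel_bed, cfg$panel_pathways))
    sim <- NULL
  }
  key <- cfg$filter$locus_key

  # --- somatic filtering per patient ----------------------------------
  filt <- stage("filter", {
    passing <- list()
    rejected <- list()
    tumor_meta <- meta[meta$role == "tumor", , drop = FALSE]
    for (pid in unique(tumor_meta$patient_id)) {
      blood_id <- meta$sample_id[meta$role == "blood" &
                                   meta$patient_id == pid]
      if (length(blood_id) != 1L) {
        stop("patient ", pid, " lacks a matched blood sample")
      }
      tcalls <- calls[calls$sample_id %in%
                        tumor_meta$sample_id[tumor_meta$patient_id == pid], ,
                      drop = FALSE]
      bcalls <- calls[calls$sample_id == blood_id, , drop = FALSE]
      res <- suppressWarnings(
        apply_somatic_filters(tcalls, bcalls, cfg$filter))
      passing[[pid]] <- res$passing
      rejected[[pid]] <- res$rejected
    }
    list(passing = do.call(rbind, passing),
         rejected = do.call(rbind, rejected))
  })
  passing <- filt$passing
  rownames(passing) <- NULL
  passing$effect[is.na(passing$effect)] <- "vus"
  passing$effect[passing$effect == "unclassified"] <- "vus"

  # --- classification and statistics ----------------------------------
  cat_tab <- stage("classify", category_table(passing, meta, key))
  burden <- stage("burden", mutational_burden(passing, meta))
  gene_counts <- stage("per_gene",
                       per_gene_counts(passing, panel, meta, "compartment"))
  pathway <- stage("per_pathway", per_pathway_counts(gene_counts, panel))
  conc_matrix <- stage("concordance",
                       concordance_heatmap_matrix(passing, meta, panel, key))

  # --- clustering ------------------------------------------------------
  tumor_ids <- meta$sample_id[meta$role == "tumor"]
  clust <- stage("cluster", {
    m <- build_af_matrix(passing[passing$sample_id %in% tumor_ids, ,
                                 drop = FALSE],
                         samples = sort(intersect(tumor_ids,
                                                  passing$sample_id)),
                         exclude_synonymous = cfg$exclude_synonymous,
                         key = key)
    if (nrow(m) >= 2L) cluster_samples(m, cfg$metric, cfg$linkage) else NULL
  })

  # --- per-patient trees and leaf-pair similarity ---------------------
  control_id <- meta$sample_id[meta$role == "control"]
  tree_stage <- stage("trees", {
    trees <- list()
    similarity <- list()
    std_cols <- c("sample_id", "chrom", "pos", "ref", "alt", "depth",
                  "alt_reads", "af", "gene", "effect", "callers")
    if (length(control_id) >= 1L) {
      ctrl <- control_id[1L]
      ctrl_calls <- calls[calls$sample_id == ctrl, std_cols, drop = FALSE]
      # cohort mode: one matrix over every called locus, rows subset per
      # patient (absent samples keep AF 0 at foreign loci)
      cohort_m <- if (cfg$locus_universe == "cohort") {
        build_af_matrix(rbind(passing[, std_cols], ctrl_calls), key = key)
      } else NULL
      for (pid in sort(unique(meta$patient_id[meta$role == "tumor"]))) {
        pids <- meta$sample_id[meta$role == "tumor" & meta$patient_id == pid]
        pcalls <- passing[passing$sample_id %in% pids, std_cols,
                          drop = FALSE]
        if (length(unique(pcalls$sample_id)) < 2L) next
        wanted <- c(sort(unique(pcalls$sample_id)), ctrl)
        m <- if (!is.null(cohort_m)) {
          cohort_m[intersect(wanted, rownames(cohort_m)), , drop = FALSE]
        } else {
          build_af_matrix(rbind(pcalls, ctrl_calls), samples = wanted,
                          key = key)
        }
        tr <- build_patient_tree(af_distance(m, cfg$metric), ctrl)
        trees[[pid]] <- tr
        st <- similarity_table(tr, pcalls, outgroup = ctrl, key = key)
        if (nrow(st) > 0L) {
          similarity[[pid]] <- cbind(patient_id = pid, st,
                                     stringsAsFactors = FALSE)
        }
      }
    }
    list(trees = trees, similarity = similarity)
  })
  trees <- tree_stage$trees
  similarity <- tree_stage$similarity
  similarity <- if (length(similarity) > 0L)
    do.call(rbind, c(similarity, make.row.names = FALSE)) else
      data.frame(patient_id = character(), sample_a = character(),
                 sample_b = character(), concordant_pct = numeric(),
                 private_pct = numeric(), wt_pct = numeric(),
                 n_universe = integer(), stringsAsFactors = FALSE)

  # --- spectra ---------------------------------------------------------
  spectra <- stage("spectrum", suppressWarnings(
    spectrum_by_stage(passing, meta)))
  spec_test <- if (attr(spectra$pre_chemo, "total") > 0L &&
                   attr(spectra$post_chemo, "total") > 0L) {
    compare_spectra(spectra$pre_chemo, spectra$post_chemo)
  } else NULL

  # --- write bundle ----------------------------------------------------
  files <- c(
    passing = "passing_variants.tsv", audit = "filter_audit.tsv",
    category = "category_table.tsv", burden = "burden.tsv",
    genes = "gene_counts.tsv", pathways = "pathway_counts.tsv",
    concordance = "concordance_matrix.tsv", similarity = "similarity.tsv",
    clusters = "clusters.tsv", trees = "trees.nwk",
    spectra = "spectra.tsv", manifest = "manifest.yaml")
  files <- setNames(file.path(out_dir, files), names(files))

  write_variant_table(passing, files["passing"])
  rej <- filt$rejected
  rownames(rej) <- NULL
  write_tsv(rej[, c("sample_id", "chrom", "pos", "ref", "alt", "depth",
                    "alt_reads", "af", "reason")], files["audit"])
  write_tsv_rn(cat_tab, files["category"], "compartment")
  write_tsv(burden, files["burden"])
  write_tsv_rn(gene_counts, files["genes"], "gene")
  pw_out <- data.frame(pathway = rownames(pathway$counts),
                       as.data.frame(pathway$counts, check.names = FALSE),
                       check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(pathway$tests)) {
    pw_out$p_value_ovary_vs_synchronous <-
      signif(pathway$tests$p_value[match(pw_out$pathway,
                                         pathway$tests$pathway)], 6)
  }
  write_tsv(pw_out, files["pathways"])
  write_tsv_rn(conc_matrix, files["concordance"], "patient_id")
  write_tsv(similarity, files["similarity"])
  if (!is.null(clust)) {
    write_tsv(data.frame(sample_id = names(clust$clusters),
                         cluster = unname(clust$clusters),
                         order = match(names(clust$clusters),
                                       rownames(clust$ordered)),
                         stringsAsFactors = FALSE), files["clusters"])
  } else {
    write_tsv(data.frame(sample_id = character(), cluster = integer(),
                         order = integer()), files["clusters"])
  }
  if (length(trees) > 0L) {
    class(trees) <- "multiPhylo"
    names(trees) <- NULL
    ape::write.tree(trees, file = files["trees"])
  } else {
    writeLines(character(0), files["trees"])
  }
  spec_out <- data.frame(
    class = SUBSTITUTION_CLASSES,
    pre_chemo = as.integer(spectra$pre_chemo),
    post_chemo = as.integer(spectra$post_chemo),
    stringsAsFactors = FALSE)
  write_tsv(spec_out, files["spectra"])

  cfg_list <- config_as_list(cfg)
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg_list, cfg_file)
  manifest <- list(
    package_version = as.character(packageVersion("clonehet")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    rows = list(
      input_calls = nrow(calls),
      passing = nrow(passing),
      rejected = nrow(filt$rejected),
      burden_samples = nrow(burden),
      similarity_pairs = nrow(similarity),
      trees = length(trees),
      pre_chemo_snvs = as.integer(attr(spectra$pre_chemo, "total")),
      post_chemo_snvs = as.integer(attr(spectra$post_chemo, "total"))),
    spectrum_p_value = if (!is.null(spec_test))
      signif(spec_test$p_value, 6))
  yaml::write_yaml(manifest, files["manifest"])

  structure(list(calls = calls, meta = meta, panel = panel, sim = sim,
                 passing = passing, rejected = filt$rejected,
                 category_table = cat_tab, burden = burden,
                 gene_counts = gene_counts, pathway = pathway,
                 concordance_matrix = conc_matrix, cluster = clust,
                 trees = trees, similarity = similarity,
                 spectra = spectra, spectrum_test = spec_test,
                 files = files, manifest = manifest, config = cfg),
            class = "het_run")
}

#' @export
print.het_run <- function(x, ...) {
  cat("heterogeneity pipeline run (seed", x$config$seed, ")\n")
  cat(sprintf("  %d input calls -> %d passing, %d rejected\n",
              nrow(x$calls), nrow(x$passing), nrow(x$rejected)))
  cat(sprintf("  %d tumor samples, %d patients, %d trees, %d cherry pairs\n",
              sum(x$meta$role == "tumor"),
              length(unique(x$meta$patient_id[x$meta$role == "tumor"])),
              length(x$trees), nrow(x$similarity)))
  if (!is.null(x$spectrum_test)) {
    cat(sprintf("  pre/post spectrum chi-squared p = %.3g\n",
                x$spectrum_test$p_value))
  }
  cat("  outputs:", dirname(x$files[["manifest"]]), "\n")
  invisible(x)
}

#' @export
summary.het_run <- function(object, ...) {
  list(category = summary(object$category_table),
       filter = filter_summary(object$rejected),
       n_passing = nrow(object$passing),
       similarity = object$similarity,
       spectrum_p = if (!is.null(object$spectrum_test))
         object$spectrum_test$p_value else NA_real_)
}
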