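#' Default synthetic 65-gene targeted panel
#'
#' A synthetic stand-in for a pharmacologically oriented 65-gene targeted
#' amplicon panel: genes from homologous recombination, mismatch repair,
#' TP53, PI3K/AKT, RTK, RAS/MAPK, WNT, adhesion/EMT, chromatin, TGF-beta
#' and drug-target pathways, each with one coding interval (0-based
#' half-open) of deterministic pseudo-length placed on chr1-chr17.  The
#' interval coordinates are synthetic; only interval lengths (mutation
#' opportunity) and the gene-to-pathway map matter downstream.
#'
#' @return a [gene_panel()].
#' @export
default_panel <- function() {
  pathways <- list(
    HR = c("BRCA1", "BRCA2", "C11orf30", "RAD51", "PALB2", "ATM", "ATR",
           "CHEK1", "CHEK2", "BARD1", "BRIP1", "FANCA"),
    MMR = c("MLH1", "MSH2", "MSH6", "PMS2", "MLH3"),
    TP53_pathway = c("TP53", "MDM2", "CDKN2A", "RB1"),
    PI3K_AKT = c("PIK3CA", "PIK3R1", "PTEN", "AKT1", "AKT2", "MTOR", "TSC1"),
    RTK = c("EGFR", "ERBB2", "ERBB3", "IGF1R", "KIT", "MET", "FGFR1",
            "FGFR2"),
    RAS_MAPK = c("KRAS", "NRAS", "HRAS", "BRAF", "MAP2K1"),
    WNT = c("CTNNB1", "APC", "AXIN1"),
    adhesion_EMT = c("CDH1", "VIM", "ZEB1", "ZEB2", "FN1", "VCAM1",
                     "COL3A1", "ID4"),
    chromatin = c("ARID1A", "SMARCA4", "KMT2D", "EZH2"),
    TGF_beta = c("TGFB3", "TGFBR1", "TGFBR2", "SMAD4"),
    drug_target = c("TOP2A", "TOP1", "TUBB3", "ABCB1", "DICER1")
  )
  genes <- unlist(pathways, use.names = FALSE)
  stopifnot(length(genes) == 65L, !anyDuplicated(genes))
  pathway_of <- setNames(rep(names(pathways), lengths(pathways)), genes)
  i <- seq_along(genes)
  len <- 900L + 150L * ((7L * i) %% 29L)
  chrom <- paste0("chr", ((i - 1L) %% 17L) + 1L)
  slot <- (i - 1L) %/% 17L
  start <- 1000000L + slot * 3000000L
  intervals <- data.frame(chrom = chrom, start = start,
                          end = start + len, gene = genes,
                          stringsAsFactors = FALSE)
  gene_panel(intervals, pathway_of)
}

#' Simulation configuration
#'
#' Parameters of the forward clonal-evolution simulator.  Defaults emulate
#' a multi-biopsy targeted-panel study of advanced epithelial ovarian
#' cancer: ~2500-fold mean amplicon coverage (negative-binomial, i.e.
#' overdispersed, as amplicon panels are), a handful of founder (trunk)
#' mutations against a few tens of branch-private mutations per lesion
#' (so biopsies carry on the order of 20-50 somatic variants and the
#' concordant fraction is small), biopsy purity 0.8, a 1e-3 per-base
#' substitution error spread uniformly over the three non-reference bases,
#' heterozygous germline variants in the matched blood, and relapse
#' biopsies descending from exactly one primary subclone.  Effect-class
#' proportions default to the mix observed in a 1131-variant EOC cohort
#' (37% non-synonymous, 9% synonymous, 4% indel, 50% VUS).
#'
#' @param n_patients number of patients (default 19).
#' @param n_founder_mut trunk mutations per patient (default 6).
#' @param clade_private_mean Poisson mean of mutations on the site-clade
#'   edges (default 10), see `site_structured`.
#' @param branch_private_mean Poisson mean of lesion-private mutations
#'   (default 20).
#' @param relapse_private_mean Poisson mean of additional relapse-private
#'   mutations (default 15).
#' @param site_structured when TRUE (default) a patient's subclone tree
#'   first splits into an ovary clade and a synchronous-lesion clade, so
#'   lesions of one site share clade mutations — the branch structure the
#'   AF clustering of real cohorts displays.
#' @param relapse `"from_one_primary_subclone"` (default: all relapse
#'   biopsies of a patient descend from the dominant subclone of one
#'   randomly chosen primary lesion) or `"none"` (relapse lesions branch
#'   from the founder like primaries).
#' @param purity tumor cell fraction of each biopsy, in (0, 1] (default
#'   0.8).
#' @param dominant_fraction fraction of tumor cells belonging to the
#'   biopsy's own dominant subclone (default 1 = biopsy is one subclone
#'   plus its ancestors' mutations); mutations on the dominant subclone's
#'   own branch get cancer-cell fraction `dominant_fraction`.
#' @param mean_depth mean sequencing depth (default 2500).
#' @param depth_dispersion negative-binomial size parameter (default 20).
#' @param error_rate per-base substitution error rate in `[0, 0.01]`
#'   (default 1e-3).
#' @param germline_hets heterozygous germline variants per patient
#'   (default 30).
#' @param n_error_sites sequencing-error candidate sites per sample
#'   (default 25).
#' @param effect_props named proportions over the four effect classes.
#' @param spectrum_weights named weights over the six substitution
#'   classes (C>T-dominant by default, as in most tumor spectra).
#' @param include_control add an unrelated control sample (`CTRL`) with
#'   its own independent mutation profile, used as phylogeny outgroup.
#' @param control_mut mutations private to the control (default 60).
#' @param panel a [gene_panel()]; defaults to [default_panel()].
#' @param seed integer RNG seed used by [simulate_cohort()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 19L,
                       n_founder_mut = 6L,
                       clade_private_mean = 10,
                       branch_private_mean = 20,
                       relapse_private_mean = 15,
                       site_structured = TRUE,
                       relapse = c("from_one_primary_subclone", "none"),
                       purity = 0.8,
                       dominant_fraction = 1,
                       mean_depth = 2500,
                       depth_dispersion = 20,
                       error_rate = 1e-3,
                       germline_hets = 30L,
                       n_error_sites = 25L,
                       effect_props = c(non_synonymous = 416, synonymous = 106,
                                        indel = 45, vus = 564) / 1131,
                       spectrum_weights = c("C>A" = 0.10, "C>G" = 0.08,
                                            "C>T" = 0.45, "T>A" = 0.07,
                                            "T>C" = 0.22, "T>G" = 0.08),
                       include_control = TRUE,
                       control_mut = 60L,
                       panel = default_panel(),
                       seed = 1L) {
  relapse <- match.arg(relapse)
  stopifnot(n_patients >= 1L, n_founder_mut >= 0L, clade_private_mean >= 0,
            branch_private_mean >= 0, relapse_private_mean >= 0,
            purity > 0, purity <= 1,
            dominant_fraction > 0, dominant_fraction <= 1,
            mean_depth > 0, depth_dispersion > 0,
            error_rate >= 0, error_rate <= 0.01,
            germline_hets >= 0L, n_error_sites >= 0L,
            abs(sum(effect_props) - 1) < 1e-8,
            all(names(effect_props) %in% EFFECT_LEVELS),
            all(names(spectrum_weights) %in% SUBSTITUTION_CLASSES))
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "simulation: %d patient(s), depth %g (NB size %g), purity %g, error %g\n",
    x$n_patients, x$mean_depth, x$depth_dispersion, x$purity, x$error_rate))
  cat(sprintf("  trunk %d, clade ~Pois(%g), branch ~Pois(%g), relapse: %s\n",
              x$n_founder_mut, x$clade_private_mean, x$branch_private_mean,
              x$relapse))
  invisible(x)
}

SITE_CODES <- c(ovary = "OV", omentum = "OM", peritoneum = "PE",
                metastasis = "ME", other = "OT")

# Biopsy layout for one patient: sites and surgery stages.
default_patient_layout <- function() {
  data.frame(site = c("ovary", "omentum", "peritoneum", "metastasis"),
             stage = c("primary", "primary", "primary", "second_surgery"),
             stringsAsFactors = FALSE)
}

#' Cohort biopsy layout emulating a 19-patient EOC study
#'
#' Produces the per-patient biopsy layouts of a 19-patient cohort with 71
#' tumor biopsies: 21 ovary samples (two patients contribute left and
#' right ovaries), 24 synchronous lesions at primary surgery, 24
#' second-surgery and 2 third-surgery relapse biopsies (both from the
#' first patient), each patient with one matched blood.
#'
#' @return named list of per-patient layout data frames (site, stage).
#' @export
default_cohort_layout <- function() {
  layouts <- list()
  for (i in 1:19) {
    n_ov <- if (i <= 2L) 2L else 1L
    sync_sites <- if (i <= 5L) c("omentum", "peritoneum") else "omentum"
    rel_sites <- if (i <= 5L) c("metastasis", "other") else "metastasis"
    lay <- data.frame(
      site = c(rep("ovary", n_ov), sync_sites, rel_sites),
      stage = c(rep("primary", n_ov + length(sync_sites)),
                rep("second_surgery", length(rel_sites))),
      stringsAsFactors = FALSE)
    if (i == 1L) {
      lay <- rbind(lay, data.frame(site = c("metastasis", "other"),
                                   stage = "third_surgery"))
    }
    layouts[[sprintf("PT%02d", i)]] <- lay
  }
  layouts
}

# Sample names in the {patient}-{SITE}[-2ME|-3ME] convention, with L-/R-
# prefixes for bilateral ovaries and numeric suffixes for repeated sites.
layout_sample_ids <- function(patient_id, layout) {
  code <- SITE_CODES[layout$site]
  if (sum(layout$site == "ovary") == 2L) {
    code[layout$site == "ovary"] <- c("L-OV", "R-OV")
  }
  suffix <- ifelse(layout$stage == "second_surgery", "-2ME",
                   ifelse(layout$stage == "third_surgery", "-3ME", ""))
  base <- paste0(code, suffix)
  for (b in unique(base[duplicated(base)])) {
    idx <- which(base == b)
    base[idx[-1L]] <- paste0(b, "-", seq_along(idx[-1L]) + 1L)
  }
  paste0(patient_id, "-", base)
}

# Draw n distinct loci on the panel: gene sampled proportionally to coding
# length, position uniform inside the gene interval (1-based).  Avoids
# keys already in `taken`.
draw_loci <- function(n, panel, taken = character(0)) {
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      gene = character(), stringsAsFactors = FALSE))
  }
  iv <- panel$intervals
  w <- iv$end - iv$start
  out <- vector("list", n)
  got <- 0L
  while (got < n) {
    g <- sample.int(nrow(iv), 1L, prob = w)
    pos <- iv$start[g] + sample.int(w[g], 1L)  # 1-based inside [start,end)
    key <- paste(iv$chrom[g], pos, sep = ":")
    if (key %in% taken) next
    taken <- c(taken, key)
    got <- got + 1L
    out[[got]] <- data.frame(chrom = iv$chrom[g], pos = pos,
                             gene = iv$gene[g], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Attach alleles and effect labels to drawn loci.
draw_alleles <- function(loci, cfg) {
  n <- nrow(loci)
  if (n == 0L) {
    loci$ref <- loci$alt <- loci$effect <- character(0)
    return(loci)
  }
  effect <- sample(names(cfg$effect_props), n, replace = TRUE,
                   prob = cfg$effect_props)
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    if (effect[i] == "indel") {
      anchor <- sample(BASES, 1L)
      extra <- paste(sample(BASES, sample.int(5L, 1L), replace = TRUE),
                     collapse = "")
      if (runif(1) < 0.5) {            # insertion
        ref[i] <- anchor
        alt[i] <- paste0(anchor, extra)
      } else {                         # deletion
        ref[i] <- paste0(anchor, extra)
        alt[i] <- anchor
      }
    } else {
      cls <- sample(names(cfg$spectrum_weights), 1L,
                    prob = cfg$spectrum_weights)
      from <- substr(cls, 1L, 1L)
      to <- substr(cls, 3L, 3L)
      if (runif(1) < 0.5) {            # write on the complementary strand
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        from <- comp[[from]]
        to <- comp[[to]]
      }
      ref[i] <- from
      alt[i] <- to
    }
  }
  loci$ref <- ref
  loci$alt <- alt
  loci$effect <- effect
  loci
}

# Negative-binomial depths (>= 1) around the configured mean.
draw_depth <- function(n, cfg) {
  pmax(rnbinom(n, mu = cfg$mean_depth, size = cfg$depth_dispersion), 1L)
}

# Observed call rows for one sample given per-locus expected variant-read
# probability p; rows with zero alt reads are not emitted (no caller
# reports them).
observe_sample <- function(sample_id, loci, p, cfg) {
  n <- nrow(loci)
  if (n == 0L) return(NULL)
  depth <- draw_depth(n, cfg)
  alt_reads <- rbinom(n, depth, pmin(p, 1))
  keep <- alt_reads > 0L
  if (!any(keep)) return(NULL)
  data.frame(sample_id = sample_id,
             chrom = loci$chrom[keep], pos = loci$pos[keep],
             ref = loci$ref[keep], alt = loci$alt[keep],
             depth = depth[keep], alt_reads = alt_reads[keep],
             af = alt_reads[keep] / depth[keep],
             gene = loci$gene[keep], effect = loci$effect[keep],
             callers = "mutect,varscan2",
             stringsAsFactors = FALSE)
}

#' Simulate one patient's multi-biopsy variant data with ground truth
#'
#' Draws a branched subclone tree (founder trunk, optional ovary /
#' synchronous site clades, one dominant subclone per biopsy, relapse
#' subclones descending from one primary subclone), places mutations on
#' its edges (genes proportional to coding length, effects and
#' substitution classes from the configured proportions), then sequences
#' every biopsy: depth is negative-binomial around the configured mean and
#' variant reads are binomial with success probability
#' `purity * cancer-cell-fraction * 0.5 + error/3` (heterozygous diploid
#' model).  The matched blood carries the germline heterozygotes at
#' AF ~ 0.5 and sequencing error only elsewhere.  Uses the current RNG
#' stream (seed it, or call via [simulate_cohort()]).
#'
#' @param cfg a [sim_config()].
#' @param patient_id patient identifier.
#' @param layout data frame with columns `site`, `stage`, one row per
#'   biopsy; defaults to ovary + omentum + peritoneum at primary surgery
#'   plus one second-surgery metastasis.
#' @return list with `calls` (tumor + blood call rows), `meta` (sample
#'   sheet rows) and `truth` (a `clonal_truth` list: subclone `nodes`,
#'   `mutations` with edge assignment, `lesions` with dominant subclone
#'   and purity, per-lesion cancer-cell-fraction matrix `ccf`, germline
#'   and error-site keys, the true lineage tree in Newick, and
#'   `trunk_fraction`).
#' @export
simulate_patient <- function(cfg = sim_config(), patient_id = "PT01",
                             layout = default_patient_layout()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(layout) == 0L) stop("patient layout has zero lesions")
  if (!all(layout$site %in% SITE_LEVELS) ||
      !all(layout$stage %in% STAGE_LEVELS)) {
    stop("invalid site/stage in layout")
  }
  layout$sample_id <- layout_sample_ids(patient_id, layout)
  primary <- layout$stage == "primary"
  is_ovary <- layout$site == "ovary" & primary

  # --- subclone tree ---------------------------------------------------
  # node 1 = founder; edges carry mutation counts
  nodes <- data.frame(node = 1L, parent = NA_integer_, type = "founder",
                      n_mut = cfg$n_founder_mut, stringsAsFactors = FALSE)
  add_node <- function(parent, type, n_mut) {
    id <- nrow(nodes) + 1L
    nodes <<- rbind(nodes, data.frame(node = id, parent = parent,
                                      type = type, n_mut = n_mut,
                                      stringsAsFactors = FALSE))
    id
  }
  use_clades <- cfg$site_structured && any(is_ovary) && any(primary & !is_ovary)
  clade_ov <- clade_sy <- 1L
  if (use_clades) {
    clade_ov <- add_node(1L, "clade_ovary", rpois(1L, cfg$clade_private_mean))
    clade_sy <- add_node(1L, "clade_synchronous",
                         rpois(1L, cfg$clade_private_mean))
  }
  dominant <- integer(nrow(layout))
  for (i in which(primary)) {
    parent <- if (is_ovary[i]) clade_ov else clade_sy
    dominant[i] <- add_node(parent, "lesion",
                            rpois(1L, cfg$branch_private_mean))
  }
  relapse_rows <- which(!primary)
  relapse_parent_lesion <- NA_character_
  if (length(relapse_rows) > 0L) {
    if (cfg$relapse == "from_one_primary_subclone" && any(primary)) {
      src <- sample(which(primary), 1L)
      relapse_parent_lesion <- layout$sample_id[src]
      parent <- dominant[src]
    } else {
      parent <- 1L
    }
    for (i in relapse_rows) {
      dominant[i] <- add_node(parent, "relapse",
                              rpois(1L, cfg$relapse_private_mean))
    }
  }
  layout$dominant <- dominant

  # --- mutations on edges ---------------------------------------------
  n_total <- sum(nodes$n_mut)
  loci <- draw_loci(n_total, cfg$panel)
  loci <- draw_alleles(loci, cfg)
  loci$node <- rep(nodes$node, nodes$n_mut)
  loci$is_trunk <- loci$node == 1L
  somatic_keys <- paste(loci$chrom, loci$pos, loci$ref, loci$alt, sep = ":")
  site_keys <- paste(loci$chrom, loci$pos, sep = ":")

  # ancestors (inclusive) of each node
  ancestors <- function(v) {
    path <- v
    while (!is.na(nodes$parent[v])) {
      v <- nodes$parent[v]
      path <- c(path, v)
    }
    path
  }
  ccf <- matrix(0, nrow = n_total, ncol = nrow(layout),
                dimnames = list(somatic_keys, layout$sample_id))
  for (j in seq_len(nrow(layout))) {
    anc <- ancestors(layout$dominant[j])
    on_path <- loci$node %in% anc
    ccf[on_path, j] <- ifelse(loci$node[on_path] == layout$dominant[j],
                              cfg$dominant_fraction, 1)
  }

  # --- germline heterozygotes and error sites -------------------------
  taken <- site_keys
  germ <- draw_loci(cfg$germline_hets, cfg$panel, taken)
  taken <- c(taken, paste(germ$chrom, germ$pos, sep = ":"))
  germ <- draw_alleles(germ, cfg)
  germ$effect <- rep("unclassified", nrow(germ))

  calls <- list()
  err_keys <- list()
  samples <- c(layout$sample_id, paste0(patient_id, "-BL"))
  for (j in seq_along(samples)) {
    s <- samples[j]
    is_blood <- j > nrow(layout)
    err <- draw_loci(cfg$n_error_sites, cfg$panel, taken)
    err <- draw_alleles(err, cfg)
    err$effect <- rep("unclassified", nrow(err))
    err_keys[[s]] <- paste(err$chrom, err$pos, err$ref, err$alt, sep = ":")
    e3 <- cfg$error_rate / 3
    if (is_blood) {
      cand <- rbind(loci[, c("chrom", "pos", "ref", "alt", "gene", "effect")],
                    germ[, c("chrom", "pos", "ref", "alt", "gene", "effect")],
                    err[, c("chrom", "pos", "ref", "alt", "gene", "effect")])
      p <- c(rep(e3, nrow(loci)), rep(0.5, nrow(germ)), rep(e3, nrow(err)))
    } else {
      cand <- rbind(loci[, c("chrom", "pos", "ref", "alt", "gene", "effect")],
                    germ[, c("chrom", "pos", "ref", "alt", "gene", "effect")],
                    err[, c("chrom", "pos", "ref", "alt", "gene", "effect")])
      p <- c(cfg$purity * ccf[, j] * 0.5 + e3,
             rep(0.5, nrow(germ)), rep(e3, nrow(err)))
    }
    calls[[s]] <- observe_sample(s, cand, p, cfg)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  # --- metadata --------------------------------------------------------
  meta <- data.frame(
    sample_id = samples,
    patient_id = patient_id,
    role = c(rep("tumor", nrow(layout)), "blood"),
    site = c(layout$site, NA),
    stage = c(layout$stage, NA),
    histotype = "serous", grade = "high", pt_status = "sensitive",
    stringsAsFactors = FALSE)

  truth <- structure(list(
    patient_id = patient_id,
    nodes = nodes,
    mutations = data.frame(key = somatic_keys, loci,
                           stringsAsFactors = FALSE),
    lesions = data.frame(sample_id = layout$sample_id, site = layout$site,
                         stage = layout$stage, dominant = layout$dominant,
                         purity = cfg$purity, stringsAsFactors = FALSE),
    ccf = ccf,
    germline_keys = paste(germ$chrom, germ$pos, germ$ref, germ$alt,
                          sep = ":"),
    error_keys = err_keys,
    relapse_parent_lesion = relapse_parent_lesion,
    lineage_newick = lineage_newick(nodes, layout),
    trunk_fraction = if (n_total > 0L) sum(loci$is_trunk) / n_total else NA_real_
  ), class = "clonal_truth")

  list(calls = calls, meta = meta, truth = truth)
}

# Newick string of the true biopsy lineage tree: leaves are sample ids
# placed at their dominant subclone; edge lengths are edge mutation counts.
lineage_newick <- function(nodes, layout) {
  frag <- function(v, extra) {
    kids <- nodes$node[!is.na(nodes$parent) & nodes$parent == v]
    here <- layout$sample_id[layout$dominant == v]
    len <- nodes$n_mut[v] + extra
    if (length(kids) + length(here) == 1L) {
      # unary chain: fold this edge's length into the single descendant
      if (length(kids) == 1L) return(frag(kids, len))
      return(paste0(here, ":", len))
    }
    parts <- c(vapply(kids, function(k) frag(k, 0), character(1)),
               if (length(here) > 0L) paste0(here, ":0"))
    paste0("(", paste(parts, collapse = ","), "):", len)
  }
  paste0(frag(1L, 0), ";")
}

#' @export
print.clonal_truth <- function(x, ...) {
  cat("clonal truth for", x$patient_id, "-", nrow(x$mutations),
      "somatic mutations on", nrow(x$nodes), "subclone edges;",
      nrow(x$lesions), "biopsies\n")
  cat(sprintf("  trunk fraction %.3f\n", x$trunk_fraction))
  invisible(x)
}

#' Simulate a multi-patient cohort (with optional file bundle)
#'
#' Runs [simulate_patient()] for every patient of the layout (by default
#' the 19-patient, 71-biopsy cohort of [default_cohort_layout()]), adds an
#' unrelated control sample with an independent mutation profile, and
#' optionally writes the bundle to disk: the variant TSV, the sample
#' sheet, panel BED + pathway map, true lineage trees in Newick and a YAML
#' truth manifest.  Identical seeds give byte-identical outputs.
#'
#' @param cfg a [sim_config()]; `cfg$seed` seeds all randomness.
#' @param layouts named list of per-patient layout data frames; defaults
#'   to [default_cohort_layout()] when `cfg$n_patients == 19`, otherwise
#'   `n_patients` copies of the single-patient default layout.
#' @param out_dir optional output directory; pre-existing bundle files are
#'   a collision error unless `overwrite = TRUE`.
#' @param overwrite allow overwriting an existing bundle.
#' @return a `sim_cohort` list: `calls`, `meta`, `panel`, `truth` (one
#'   `clonal_truth` per patient), `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), layouts = NULL,
                            out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(layouts)) {
    layouts <- if (cfg$n_patients == 19L) default_cohort_layout() else
      setNames(replicate(cfg$n_patients, default_patient_layout(),
                         simplify = FALSE),
               sprintf("PT%02d", seq_len(cfg$n_patients)))
  }
  calls <- list()
  meta <- list()
  truth <- list()
  for (pid in names(layouts)) {
    sim <- simulate_patient(cfg, pid, layouts[[pid]])
    calls[[pid]] <- sim$calls
    meta[[pid]] <- sim$meta
    truth[[pid]] <- sim$truth
  }
  if (cfg$include_control) {
    taken <- unlist(lapply(truth, function(t)
      sub(":[ACGT]+:[ACGT]+$", "", t$mutations$key)), use.names = FALSE)
    ctrl_loci <- draw_alleles(draw_loci(cfg$control_mut, cfg$panel, taken),
                              cfg)
    ctrl <- observe_sample("CTRL", ctrl_loci,
                           rep(0.5, nrow(ctrl_loci)), cfg)
    calls[["CTRL"]] <- ctrl
    meta[["CTRL"]] <- data.frame(
      sample_id = "CTRL", patient_id = "CTRL", role = "control",
      site = NA, stage = NA, histotype = NA, grade = NA, pt_status = NA,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$sample_id, calls$chrom, calls$pos, calls$ref,
                       calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  out <- structure(list(calls = validate_calls(calls),
                        meta = validate_sample_sheet(meta),
                        panel = cfg$panel, truth = truth, config = cfg),
                   class = "sim_cohort")
  if (!is.null(out_dir)) write_sim_bundle(out, out_dir, overwrite)
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  n_tumor <- sum(x$meta$role == "tumor")
  cat("simulated cohort:", length(x$truth), "patients,", n_tumor,
      "tumor biopsies,", sum(x$meta$role == "blood"), "bloods,",
      nrow(x$calls), "call rows (seed", x$config$seed, ")\n")
  invisible(x)
}

write_sim_bundle <- function(sim, out_dir, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("variants.tsv", "samples.tsv", "panel.bed",
                                "pathways.tsv", "truth.yaml"))
  if (!overwrite && any(file.exists(files))) {
    stop("output collision in ", out_dir, ": ",
         basename(files[file.exists(files)][1L]), " already exists")
  }
  write_variant_table(sim$calls, files[1L])
  write.table(sim$meta, files[2L], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write_gene_panel(sim$panel, files[3L], files[4L])
  tree_dir <- file.path(out_dir, "truth_trees")
  dir.create(tree_dir, showWarnings = FALSE)
  for (pid in names(sim$truth)) {
    writeLines(sim$truth[[pid]]$lineage_newick,
               file.path(tree_dir, paste0(pid, ".nwk")))
  }
  manifest <- list(
    seed = sim$config$seed,
    n_patients = length(sim$truth),
    patients = lapply(sim$truth, function(t) list(
      n_mutations = nrow(t$mutations),
      trunk_fraction = round(t$trunk_fraction, 6),
      relapse_parent_lesion = if (is.na(t$relapse_parent_lesion)) NULL else
        t$relapse_parent_lesion,
      lesions = setNames(as.list(t$lesions$dominant), t$lesions$sample_id)))
  )
  yaml::write_yaml(manifest, files[5L])
  invisible(out_dir)
}

#' Compare pipeline output against simulator ground truth
#'
#' Measures, for one simulated patient, (a) sensitivity of the somatic
#' calls over truth mutations whose expected allelic fraction reaches
#' `af_detect`, and specificity over the non-somatic candidate sites the
#' simulator sequenced (germline heterozygotes and error sites); (b) the
#' unrooted Robinson-Foulds distance between the inferred patient tree
#' (outgroup removed) and the true biopsy lineage tree; (c) the absolute
#' error between the concordant percentage of an ovary/synchronous biopsy
#' pair and the patient's true trunk fraction.
#'
#' @param truth a `clonal_truth` from [simulate_patient()].
#' @param passing passing calls for this patient (post-filter).
#' @param tree optional inferred `phylo` tree (with outgroup attribute or
#'   `outgroup` argument) for the RF comparison.
#' @param outgroup outgroup label in `tree`.
#' @param af_detect expected-AF detectability threshold (default 0.05).
#' @return list with `sensitivity`, `specificity`, `n_detectable`,
#'   `false_positives`, `rf_distance` (NA without a tree),
#'   `concordant_pct`, `trunk_fraction_pct`, `concordant_abs_error`.
#' @export
truth_compare <- function(truth, passing, tree = NULL,
                          outgroup = attr(tree, "outgroup"),
                          af_detect = 0.05) {
  stopifnot(inherits(truth, "clonal_truth"))
  lesions <- truth$lesions$sample_id
  if (!all(unique(passing$sample_id) %in% c(lesions))) {
    stop("passing calls contain samples not in the truth: ",
         setdiff(unique(passing$sample_id), lesions)[1L])
  }
  pk <- paste(passing$sample_id, locus_key(passing), sep = "@")

  exp_af <- truth$ccf * truth$lesions$purity[1L] * 0.5
  detectable <- which(exp_af >= af_detect, arr.ind = TRUE)
  truth_pairs <- paste(colnames(exp_af)[detectable[, 2L]],
                       rownames(exp_af)[detectable[, 1L]], sep = "@")
  sens <- if (length(truth_pairs) > 0L) mean(truth_pairs %in% pk) else NA_real_

  somatic_keys <- truth$mutations$key
  fp <- sum(!(locus_key(passing) %in% somatic_keys))
  n_negative <- length(lesions) *
    (length(truth$germline_keys) + length(truth$error_keys[[1L]]))
  spec <- if (n_negative > 0L) 1 - fp / n_negative else NA_real_

  rf <- NA_real_
  if (!is.null(tree)) {
    inferred <- tree
    if (!is.null(outgroup) && outgroup %in% inferred$tip.label) {
      inferred <- ape::drop.tip(inferred, outgroup)
    }
    true_tree <- ape::read.tree(text = truth$lineage_newick)
    common <- intersect(inferred$tip.label, true_tree$tip.label)
    if (length(common) >= 4L) {
      inferred <- ape::keep.tip(inferred, common)
      true_tree <- ape::keep.tip(true_tree, common)
      rf <- phangorn::RF.dist(ape::unroot(inferred), ape::unroot(true_tree))
    } else {
      rf <- 0
    }
  }

  conc_pct <- trunk_pct <- conc_err <- NA_real_
  ov <- truth$lesions$sample_id[truth$lesions$site == "ovary" &
                                  truth$lesions$stage == "primary"]
  sy <- truth$lesions$sample_id[truth$lesions$site != "ovary" &
                                  truth$lesions$stage == "primary"]
  if (length(ov) > 0L && length(sy) > 0L && nrow(passing) > 0L) {
    k <- locus_key(passing)
    universe <- unique(k)
    tr <- leaf_pair_similarity(k[passing$sample_id == ov[1L]],
                               k[passing$sample_id == sy[1L]],
                               universe, ov[1L], sy[1L])
    conc_pct <- tr$concordant_pct
    trunk_pct <- 100 * truth$trunk_fraction
    conc_err <- abs(conc_pct - trunk_pct)
  }

  list(sensitivity = sens, specificity = spec,
       n_detectable = length(truth_pairs), false_positives = fp,
       rf_distance = rf,
       concordant_pct = conc_pct, trunk_fraction_pct = trunk_pct,
       concordant_abs_error = conc_err)
}

#' Replicated parameter-recovery experiment
#'
#' Simulates independent single-patient cohorts (two ovary biopsies, two
#' synchronous lesions, one relapse biopsy, plus matched blood and the
#' unrelated control), runs the somatic filter and tree construction on
#' each, and scores recovery against the ground truth: somatic-call
#' sensitivity over detectable loci, the absolute error between an
#' ovary/synchronous pair's concordant percentage and the true trunk
#' fraction, whether the relapse leaf attaches next to its parent lesion
#' (nearest tumor leaf by patristic distance), and whether flat k = 2
#' clustering of the primary biopsies separates ovary from synchronous
#' samples.  Trees use Manhattan AF distance, which is additive under the
#' clonal model.
#'
#' @param n_reps number of replicates (default 50).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param cfg simulation settings (default: depth 2500, purity 0.7,
#'   error 1e-3).
#' @return list of per-replicate vectors (`sensitivity`,
#'   `concordant_abs_error`, `relapse_attached`, `site_separated`) and
#'   their summaries.
#' @export
recovery_rates <- function(n_reps = 50L, seed = 1L,
                           cfg = sim_config(purity = 0.7,
                                            error_rate = 1e-3)) {
  layout <- data.frame(
    site = c("ovary", "ovary", "omentum", "peritoneum", "metastasis"),
    stage = c(rep("primary", 4L), "second_surgery"),
    stringsAsFactors = FALSE)
  sens <- conc_err <- numeric(n_reps)
  attached <- separated <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- seed + r
    cfg_r$n_patients <- 1L
    sim <- simulate_cohort(cfg_r, layouts = list(PT01 = layout))
    truth <- sim$truth[["PT01"]]
    meta <- sim$meta
    tumor_ids <- truth$lesions$sample_id
    blood_id <- meta$sample_id[meta$role == "blood"]
    passing <- suppressWarnings(apply_somatic_filters(
      sim$calls[sim$calls$sample_id %in% tumor_ids, , drop = FALSE],
      sim$calls[sim$calls$sample_id == blood_id, , drop = FALSE]))$passing

    ctrl <- sim$calls[sim$calls$sample_id == "CTRL", , drop = FALSE]
    m <- build_af_matrix(rbind(passing[, names(ctrl)], ctrl),
                         samples = c(sort(tumor_ids), "CTRL"))
    tree <- build_patient_tree(af_distance(m, "manhattan"), "CTRL")
    rep_r <- truth_compare(truth, passing, tree)
    sens[r] <- rep_r$sensitivity
    conc_err[r] <- rep_r$concordant_abs_error

    relapse_id <- truth$lesions$sample_id[truth$lesions$stage != "primary"][1L]
    pd <- cophenetic(tree)
    others <- setdiff(tumor_ids, relapse_id)
    attached[r] <- others[which.min(pd[relapse_id, others])] ==
      truth$relapse_parent_lesion

    primary_ids <- truth$lesions$sample_id[truth$lesions$stage == "primary"]
    mp <- m[primary_ids, colSums(m[primary_ids, , drop = FALSE]) > 0,
            drop = FALSE]
    cl <- cluster_samples(mp, k = 2L)$clusters
    ov <- truth$lesions$sample_id[truth$lesions$site == "ovary"]
    sy <- setdiff(primary_ids, ov)
    separated[r] <- length(unique(cl[ov])) == 1L &&
      length(unique(cl[sy])) == 1L && cl[ov][1L] != cl[sy][1L]
  }
  list(sensitivity = sens, concordant_abs_error = conc_err,
       relapse_attached = attached, site_separated = separated,
       mean_sensitivity = mean(sens),
       mean_concordant_abs_error = mean(conc_err),
       relapse_attach_rate = mean(attached),
       site_separation_rate = mean(separated),
       n_reps = n_reps)
}
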