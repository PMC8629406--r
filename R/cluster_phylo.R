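#' Build a samples-by-loci allelic-fraction matrix
#'
#' Rows are samples (lexicographic order), columns are loci (ordered by
#' chromosome, position, alleles); the entry is the call's allelic fraction
#' and 0 where a sample has no call — with matched-normal filtering at
#' amplicon depth, absence of a call is strong evidence of absence, so no
#' imputation is attempted.  Synonymous variants can be excluded, matching
#' the convention of dropping them from heterogeneity analyses.
#'
#' @param calls passing calls.
#' @param samples optional character vector restricting/ordering samples;
#'   defaults to all samples present in `calls`.
#' @param exclude_synonymous drop loci whose consensus effect is synonymous.
#' @param key locus key mode.
#' @return numeric matrix with `sample_ids` as rownames and locus keys as
#'   colnames.
#' @export
build_af_matrix <- function(calls, samples = NULL, exclude_synonymous = FALSE,
                            key = "allele") {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  calls <- calls[calls$sample_id %in% samples, , drop = FALSE]
  if (exclude_synonymous && nrow(calls) > 0L) {
    k <- locus_key(calls, key)
    eff <- tapply(calls$effect, k, consensus_effect)
    syn <- names(eff)[eff == "synonymous"]
    calls <- calls[!(k %in% syn), , drop = FALSE]
  }
  if (nrow(calls) == 0L) {
    stop("no loci left for the AF matrix",
         if (exclude_synonymous) " after excluding synonymous variants")
  }
  ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  loci <- unique(locus_key(calls, key))
  m <- matrix(0, nrow = length(samples), ncol = length(loci),
              dimnames = list(samples, loci))
  k <- locus_key(calls, key)
  m[cbind(match(calls$sample_id, samples), match(k, loci))] <- calls$af
  m
}

#' Unsupervised clustering of an AF matrix
#'
#' Agglomerative hierarchical clustering of samples (rows) and of loci
#' (columns) of an allelic-fraction matrix.  Rows are sorted
#' lexicographically before clustering so that distance ties are broken
#' deterministically by sample id.  Flat sample clusters at `k` groups
#' (default 2, the ovary-vs-synchronous branch structure) are reported.
#'
#' @param m AF matrix from [build_af_matrix()].
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @param k number of flat clusters to cut (default 2).
#' @return an `af_cluster` list: `sample_hclust`, `locus_hclust`,
#'   `ordered` (matrix reordered by both dendrograms), `clusters` (named
#'   integer vector at the `k` cut).
#' @export
cluster_samples <- function(m, metric = c("euclidean", "manhattan"),
                            linkage = "average", k = 2L) {
  metric <- match.arg(metric)
  if (anyNA(m) || any(!is.finite(m))) stop("AF matrix contains NaN/NA")
  if (nrow(m) < 2L) stop("clustering needs at least 2 samples")
  m <- m[order(rownames(m)), , drop = FALSE]
  sh <- hclust(dist(m, method = metric), method = linkage)
  lh <- if (ncol(m) >= 2L)
    hclust(dist(t(m), method = metric), method = linkage) else NULL
  k <- min(k, nrow(m))
  clusters <- cutree(sh, k = k)
  ordered <- m[sh$order, if (is.null(lh)) 1L else lh$order, drop = FALSE]
  structure(list(sample_hclust = sh, locus_hclust = lh,
                 ordered = ordered, clusters = clusters, metric = metric,
                 linkage = linkage),
            class = "af_cluster")
}

#' @export
print.af_cluster <- function(x, ...) {
  cat("AF clustering:", length(x$clusters), "samples,",
      ncol(x$ordered), "loci;", x$metric, "distance,", x$linkage,
      "linkage\n")
  for (g in sort(unique(x$clusters))) {
    cat(sprintf("  cluster %d: %s\n", g,
                paste(names(x$clusters)[x$clusters == g], collapse = ", ")))
  }
  invisible(x)
}

#' Pairwise sample distances on allelic fractions
#'
#' @param m AF matrix.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return symmetric distance matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
af_distance <- function(m, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (anyNA(m) || any(!is.finite(m))) stop("AF matrix contains NaN/NA")
  as.matrix(dist(m, method = metric))
}

# Move negative neighbor-joining branch lengths onto the sister branch:
# the negative edge is set to zero and its (negative) length added to the
# other edges descending from the same node, conserving path lengths
# through that node as far as possible; a final clamp guarantees
# nonnegativity.
clamp_negative_edges <- function(tree) {
  if (is.null(tree$edge.length)) return(tree)
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    i <- neg[1L]
    parent <- tree$edge[i, 1L]
    siblings <- setdiff(which(tree$edge[, 1L] == parent), i)
    deficit <- tree$edge.length[i]
    tree$edge.length[i] <- 0
    if (length(siblings) > 0L) {
      tree$edge.length[siblings] <- tree$edge.length[siblings] + deficit
    }
    if (all(tree$edge.length[siblings] >= 0)) next
    # sibling went negative: clamp it without further transfer
    tree$edge.length[siblings] <- pmax(tree$edge.length[siblings], 0)
  }
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Neighbor-joining patient tree rooted on an unrelated control
#'
#' Builds a neighbor-joining tree from a sample distance matrix and roots
#' it on the designated outgroup — an unrelated control profile whose
#' allelic fractions are independent of every biopsy, so the root edge
#' represents "no shared somatic history".  Negative NJ branch lengths are
#' clamped to zero with the deficit moved to the adjacent branch.  The
#' construction is deterministic for a fixed input matrix.
#'
#' @param d distance matrix (as from [af_distance()]) or `dist` object.
#' @param outgroup sample id of the unrelated control; must be in `d`.
#' @return rooted `phylo` tree with nonnegative branch lengths and
#'   attribute `outgroup`.
#' @export
build_patient_tree <- function(d, outgroup) {
  d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must carry sample ids")
  if (nrow(d) < 3L) stop("tree building needs at least 3 taxa")
  if (!outgroup %in% ids) stop("outgroup '", outgroup, "' absent from matrix")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  tr <- clamp_negative_edges(tr)
  rooted <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  attr(rooted, "outgroup") <- outgroup
  rooted
}

#' Cherries (closest leaf pairs) of a tree
#'
#' A cherry is a pair of leaves sharing an immediate ancestor.  With
#' multifurcations every pair of leaf children of the node is reported.
#' Pairs involving an excluded label (typically the outgroup) are dropped.
#'
#' @param tree `phylo` tree.
#' @param exclude leaf labels to exclude (e.g. the outgroup).
#' @return data frame with columns `sample_a`, `sample_b`.
#' @export
tree_leaf_pairs <- function(tree, exclude = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  is_tip <- tree$edge[, 2L] <= ntip
  rows <- list()
  for (node in unique(tree$edge[, 1L])) {
    kids <- tree$edge[tree$edge[, 1L] == node & is_tip, 2L]
    labels <- sort(tree$tip.label[kids])
    labels <- setdiff(labels, exclude)
    if (length(labels) < 2L) next
    combs <- utils::combn(labels, 2L)
    for (j in seq_len(ncol(combs))) {
      rows[[length(rows) + 1L]] <- data.frame(sample_a = combs[1L, j],
                                              sample_b = combs[2L, j],
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$sample_a, out$sample_b), , drop = FALSE]
}
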