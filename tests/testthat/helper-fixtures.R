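# Shared in-code fixtures: no binary files, everything built at test time.

# One-call-per-row builder with sensible defaults.
make_calls <- function(sample_id, chrom = "chr1", pos, ref = "A", alt = "T",
                       depth = 1000L, alt_reads = 100L,
                       af = NULL, gene = NA_character_,
                       effect = NA_character_, callers = NA_character_) {
  n <- max(lengths(list(sample_id, pos)))
  df <- data.frame(sample_id = rep_len(sample_id, n),
                   chrom = rep_len(chrom, n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   depth = rep_len(as.integer(depth), n),
                   alt_reads = rep_len(as.integer(alt_reads), n),
                   gene = rep_len(gene, n), effect = rep_len(effect, n),
                   callers = rep_len(callers, n),
                   stringsAsFactors = FALSE)
  df$af <- if (is.null(af)) ifelse(df$depth > 0, df$alt_reads / df$depth, 0)
  else rep_len(af, n)
  validate_calls(df)
}

# Two-patient metadata: P1 with ovary + omentum (+ blood), P2 with ovary
# + peritoneum (+ blood), plus an unrelated control.
tiny_meta <- function() {
  validate_sample_sheet(data.frame(
    sample_id = c("P1-OV", "P1-OM", "P1-BL", "P2-OV", "P2-PE", "P2-BL",
                  "CTRL"),
    patient_id = c("P1", "P1", "P1", "P2", "P2", "P2", "CTRL"),
    role = c("tumor", "tumor", "blood", "tumor", "tumor", "blood",
             "control"),
    site = c("ovary", "omentum", NA, "ovary", "peritoneum", NA, NA),
    stage = c("primary", "primary", NA, "primary", "primary", NA, NA),
    stringsAsFactors = FALSE))
}

# Small panel: three genes on two chromosomes, two pathways.
tiny_panel <- function() {
  gene_panel(
    data.frame(chrom = c("chr1", "chr1", "chr2"),
               start = c(0L, 5000L, 0L),
               end = c(2000L, 8000L, 3000L),
               gene = c("BRCA1", "TP53", "ATM"),
               stringsAsFactors = FALSE),
    c(BRCA1 = "HR", TP53 = "TP53_pathway", ATM = "HR"))
}

# The published-style compartment x effect count fixture shipped with the
# package.
category_fixture <- function() {
  read.delim(system.file("extdata", "cohort_category_counts.tsv",
                         package = "clonehet"),
             check.names = FALSE, stringsAsFactors = FALSE)
}

# Random call table over a small locus grid, for property tests.
random_calls <- function(n, sample_id = "S1", seed_pos_max = 500L) {
  pos <- sample.int(seed_pos_max, n, replace = FALSE)
  depth <- sample(50:400, n, replace = TRUE)
  alt <- vapply(depth, function(d) sample.int(d, 1L), integer(1))
  make_calls(sample_id, pos = pos, depth = depth, alt_reads = alt)
}
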