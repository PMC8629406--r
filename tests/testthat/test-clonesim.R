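# Helper: passing calls for one simulated patient, filtered against its
# matched blood.
filter_sim_patient <- function(sim, pid = names(sim$truth)[1L]) {
  meta <- sim$meta
  tumor_ids <- meta$sample_id[meta$role == "tumor" & meta$patient_id == pid]
  blood_id <- meta$sample_id[meta$role == "blood" & meta$patient_id == pid]
  suppressWarnings(apply_somatic_filters(
    sim$calls[sim$calls$sample_id %in% tumor_ids, ],
    sim$calls[sim$calls$sample_id == blood_id, ]))$passing
}

test_that("expected AF follows the heterozygous diploid model", {
  cfg <- sim_config(purity = 1, error_rate = 0, mean_depth = 1e6,
                    n_error_sites = 0L, germline_hets = 0L, seed = 1L)
  set.seed(1)
  sim <- simulate_patient(cfg)
  truth <- sim$truth
  trunk_keys <- truth$mutations$key[truth$mutations$is_trunk]
  calls <- sim$calls
  trunk_calls <- calls[locus_key(calls) %in% trunk_keys &
                         calls$sample_id %in% truth$lesions$sample_id, ]
  # purity 1, clone fraction 1: expected AF 0.5; binomial concentration at
  # depth 1e6 keeps the observed AF within 0.002
  expect_true(all(abs(trunk_calls$af - 0.5) < 0.002))
})

test_that("trunk mutations are in every tumor biopsy and never in blood", {
  cfg <- sim_config(purity = 1, error_rate = 0, seed = 3L)
  set.seed(3)
  sim <- simulate_patient(cfg)
  truth <- sim$truth
  expect_true(all(truth$ccf[truth$mutations$is_trunk, ] == 1))
  trunk_keys <- truth$mutations$key[truth$mutations$is_trunk]
  calls <- sim$calls
  blood_id <- paste0(truth$patient_id, "-BL")
  for (s in truth$lesions$sample_id) {
    got <- locus_key(calls[calls$sample_id == s, ])
    expect_true(all(trunk_keys %in% got))
  }
  blood_keys <- locus_key(calls[calls$sample_id == blood_id, ])
  expect_length(intersect(trunk_keys, blood_keys), 0L)
})

test_that("relapse subclones descend from one primary lesion's subclone", {
  cfg <- sim_config(seed = 4L)
  set.seed(4)
  sim <- simulate_patient(cfg)
  truth <- sim$truth
  expect_false(is.na(truth$relapse_parent_lesion))
  parent_node <- truth$lesions$dominant[truth$lesions$sample_id ==
                                          truth$relapse_parent_lesion]
  relapse_nodes <- truth$lesions$dominant[truth$lesions$stage != "primary"]
  for (v in relapse_nodes) {
    path <- v
    while (!is.na(truth$nodes$parent[v])) {
      v <- truth$nodes$parent[v]
      path <- c(path, v)
    }
    expect_true(parent_node %in% path)
  }
})

test_that("depth model is calibrated and overdispersed", {
  cfg <- sim_config()
  set.seed(5)
  d <- clonehet:::draw_depth(1e4, cfg)
  expect_lt(abs(mean(d) - cfg$mean_depth) / cfg$mean_depth, 0.02)
  expect_gt(stats::var(d), cfg$mean_depth)  # overdispersion vs Poisson
})

test_that("cohort simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 2L, seed = 6L)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sim1 <- simulate_cohort(cfg, out_dir = dir1)
  sim2 <- simulate_cohort(cfg, out_dir = dir2)
  expect_identical(sim1$calls, sim2$calls)
  for (f in list.files(dir1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
  # rewriting into a populated directory is a collision
  expect_error(simulate_cohort(cfg, out_dir = dir1), "collision")
})

test_that("the default cohort layout yields 71 tumor biopsies + 19 bloods", {
  layouts <- default_cohort_layout()
  expect_length(layouts, 19L)
  sites <- do.call(rbind, layouts)
  expect_equal(sum(sites$site == "ovary" & sites$stage == "primary"), 21L)
  expect_equal(sum(sites$site != "ovary" & sites$stage == "primary"), 24L)
  expect_equal(sum(sites$stage == "second_surgery"), 24L)
  expect_equal(sum(sites$stage == "third_surgery"), 2L)
  expect_equal(nrow(sites), 71L)

  cfg <- sim_config(seed = 7L)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$meta$role == "tumor"), 71L)
  expect_equal(sum(sim$meta$role == "blood"), 19L)
  # sample naming follows the {patient}-{SITE}[-2ME/-3ME] convention
  expect_true("PT01-L-OV" %in% sim$meta$sample_id)
  expect_true(any(grepl("-2ME$", sim$meta$sample_id)))
  expect_true(any(grepl("-3ME", sim$meta$sample_id)))
})

test_that("truth reconciles with pipeline burden in the noiseless regime", {
  cfg <- sim_config(purity = 1, error_rate = 0, n_error_sites = 0L,
                    seed = 8L)
  set.seed(8)
  sim1 <- simulate_patient(cfg)
  meta <- validate_sample_sheet(sim1$meta)
  passing <- suppressWarnings(apply_somatic_filters(
    sim1$calls[sim1$calls$sample_id %in% sim1$truth$lesions$sample_id, ],
    sim1$calls[grepl("-BL$", sim1$calls$sample_id), ]))$passing
  burden <- mutational_burden(passing, meta)
  for (s in sim1$truth$lesions$sample_id) {
    expect_equal(burden$total[burden$sample_id == s],
                 sum(sim1$truth$ccf[, s] > 0))
  }
})

test_that("noiseless high-depth runs recover the true lineage exactly", {
  cfg <- sim_config(n_patients = 1L, purity = 1, error_rate = 0,
                    n_error_sites = 0L, seed = 9L)
  layout <- data.frame(
    site = c("ovary", "ovary", "omentum", "peritoneum", "metastasis"),
    stage = c(rep("primary", 4L), "second_surgery"),
    stringsAsFactors = FALSE)
  sim <- simulate_cohort(cfg, layouts = list(PT01 = layout))
  passing <- filter_sim_patient(sim)
  truth <- sim$truth[["PT01"]]
  ctrl <- sim$calls[sim$calls$sample_id == "CTRL",
                    setdiff(names(sim$calls), "blood_low_coverage")]
  m <- build_af_matrix(rbind(passing[, names(ctrl)], ctrl))
  # Manhattan AF distance is additive under the clonal model
  tree <- build_patient_tree(af_distance(m, "manhattan"), "CTRL")
  rep <- truth_compare(truth, passing, tree)
  expect_equal(rep$rf_distance, 0)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_lt(rep$concordant_abs_error, 2)
})
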